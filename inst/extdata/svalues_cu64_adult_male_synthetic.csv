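target,source,S_mSv_per_MBq_h
liver,liver,0.0465
liver,heart_wall,0.002172
liver,heart_contents,0.002172
liver,spleen,0.002172
liver,lungs,0.004343
liver,kidneys,0.004343
liver,red_marrow,0.002172
liver,muscle,0.002172
liver,rest_of_body,0.001448
heart_wall,liver,0.002172
heart_wall,heart_wall,0.2563
heart_wall,heart_contents,0.0511
heart_wall,spleen,0.002172
heart_wall,lungs,0.004343
heart_wall,kidneys,0.002172
heart_wall,red_marrow,0.002172
heart_wall,muscle,0.002172
heart_wall,rest_of_body,0.001448
spleen,liver,0.002172
spleen,heart_wall,0.002172
spleen,heart_contents,0.002172
spleen,spleen,0.4342
spleen,lungs,0.004343
spleen,kidneys,0.004343
spleen,red_marrow,0.002172
spleen,muscle,0.002172
spleen,rest_of_body,0.001448
lungs,liver,0.004343
lungs,heart_wall,0.004343
lungs,heart_contents,0.004343
lungs,spleen,0.004343
lungs,lungs,0.08543
lungs,kidneys,0.002172
lungs,red_marrow,0.002172
lungs,muscle,0.002172
lungs,rest_of_body,0.001448
kidneys,liver,0.004343
kidneys,heart_wall,0.002172
kidneys,heart_contents,0.002172
kidneys,spleen,0.004343
kidneys,lungs,0.002172
kidneys,kidneys,0.2703
kidneys,red_marrow,0.002172
kidneys,muscle,0.002172
kidneys,rest_of_body,0.001448
red_marrow,liver,0.004343
red_marrow,heart_wall,0.004343
red_marrow,heart_contents,0.004343
red_marrow,spleen,0.004343
red_marrow,lungs,0.004343
red_marrow,kidneys,0.004343
red_marrow,red_marrow,0.07676
red_marrow,muscle,0.004343
red_marrow,rest_of_body,0.001448
muscle,liver,0.002172
muscle,heart_wall,0.002172
muscle,heart_contents,0.002172
muscle,spleen,0.002172
muscle,lungs,0.002172
muscle,kidneys,0.002172
muscle,red_marrow,0.002172
muscle,muscle,0.003832
muscle,rest_of_body,0.001448
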