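organ,method,group,dose_uSv_per_MBq,sd_uSv_per_MBq
adrenals,pet,blk,1.89,0.028
brain,pet,blk,0.072,0.002
breasts,pet,blk,0.502,0.002
gallbladder_wall,pet,blk,3.24,0.084
lli_wall,pet,blk,0.388,0.01
small_intestine,pet,blk,0.694,0.003
stomach_wall,pet,blk,0.932,3e-4
uli_wall,pet,blk,0.928,0.011
heart_wall,pet,blk,17.05,1.484
kidneys,pet,blk,1.335,0.021
liver,pet,blk,35.15,1.202
lungs,pet,blk,1.045,0.007
muscle,pet,blk,1.825,0.049
ovaries,pet,blk,0.502,0.008
pancreas,pet,blk,1.735,0.021
red_marrow,pet,blk,0.621,4e-4
osteogenic_cells,pet,blk,0.5,0.003
skin,pet,blk,0.339,0.002
spleen,pet,blk,6.705,0.289
testes,pet,blk,0.273,0.009
thymus,pet,blk,0.704,0.021
thyroid,pet,blk,0.345,0.01
urinary_bladder_wall,pet,blk,0.4,0.01
uterus,pet,blk,0.473,0.008
total_body,pet,blk,2.015,0.007
adrenals,pet,nblk,2.005,0.12
brain,pet,nblk,0.075,0.001
breasts,pet,nblk,0.53,0.038
gallbladder_wall,pet,nblk,3.45,0.197
lli_wall,pet,nblk,0.405,0.009
small_intestine,pet,nblk,0.733,0.031
stomach_wall,pet,nblk,0.977,0.046
uli_wall,pet,nblk,0.985,0.049
heart_wall,pet,nblk,17.75,3.46
kidneys,pet,nblk,1.41,0.07
liver,pet,nblk,37.55,2.192
lungs,pet,nblk,1.105,0.077
muscle,pet,nblk,1.905,0.049
ovaries,pet,nblk,0.526,0.015
pancreas,pet,nblk,1.83,0.098
red_marrow,pet,nblk,0.655,0.032
osteogenic_cells,pet,nblk,0.526,0.023
skin,pet,nblk,0.357,0.015
spleen,pet,nblk,6.075,0.572
testes,pet,nblk,0.284,0.004
thymus,pet,nblk,0.739,0.062
thyroid,pet,nblk,0.36,0.01
urinary_bladder_wall,pet,nblk,0.418,0.009
uterus,pet,nblk,0.495,0.014
total_body,pet,nblk,2.125,0.106
adrenals,exvivo,blk,2.856,0.12
brain,exvivo,blk,0.422,0.02
breasts,exvivo,blk,0.867,0.036
gallbladder_wall,exvivo,blk,3.71,0.247
lli_wall,exvivo,blk,1.173,0.06
small_intestine,exvivo,blk,6.14,0.704
stomach_wall,exvivo,blk,3.256,0.669
uli_wall,exvivo,blk,5.03,1.18
heart_wall,exvivo,blk,6.51,0.4
kidneys,exvivo,blk,13.166,0.602
liver,exvivo,blk,32.866,3.617
lungs,exvivo,blk,10.383,0.748
muscle,exvivo,blk,2.12,0.156
ovaries,exvivo,blk,1.413,0.075
pancreas,exvivo,blk,6.123,0.751
red_marrow,exvivo,blk,18.566,0.85
osteogenic_cells,exvivo,blk,10.373,0.44
skin,exvivo,blk,0.594,0.024
spleen,exvivo,blk,13.5,3.377
testes,exvivo,blk,0.464,0.034
thymus,exvivo,blk,1.173,0.049
thyroid,exvivo,blk,0.691,0.038
urinary_bladder_wall,exvivo,blk,0.784,0.047
uterus,exvivo,blk,1.16,0.059
total_body,exvivo,blk,3.08,0.095
adrenals,exvivo,nblk,3.38,0.319
brain,exvivo,nblk,0.615,0.041
breasts,exvivo,nblk,1.076,0.11
gallbladder_wall,exvivo,nblk,4.14,0.438
lli_wall,exvivo,nblk,1.526,0.127
small_intestine,exvivo,nblk,6.88,1.462
stomach_wall,exvivo,nblk,3.826,0.967
uli_wall,exvivo,nblk,7.286,1.992
heart_wall,exvivo,nblk,7.606,1.377
kidneys,exvivo,nblk,17.866,4.834
liver,exvivo,nblk,34.166,3.35
lungs,exvivo,nblk,12.036,1.908
muscle,exvivo,nblk,2.59,0.33
ovaries,exvivo,nblk,1.81,0.181
pancreas,exvivo,nblk,8.36,2.314
red_marrow,exvivo,nblk,24.133,0.251
osteogenic_cells,exvivo,nblk,13.6,0.1
skin,exvivo,nblk,0.8,0.114
spleen,exvivo,nblk,18.766,7.479
testes,exvivo,nblk,0.638,0.067
thymus,exvivo,nblk,1.46,0.165
thyroid,exvivo,nblk,0.917,0.08
urinary_bladder_wall,exvivo,nblk,1.037,0.101
uterus,exvivo,nblk,1.523,0.191
total_body,exvivo,nblk,3.693,0.332
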