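# Shared fixtures built in code.

# A tiny random S-value table with guaranteed positive self-dose terms.
random_svalues <- function(organs, seed = 42) {
  withr::with_seed(seed, {
    grid <- expand.grid(target = organs, source = organs,
                        stringsAsFactors = FALSE)
    grid$S_mSv_per_MBq_h <- stats::runif(nrow(grid), 0.0005, 0.005)
    self <- grid$target == grid$source
    grid$S_mSv_per_MBq_h[self] <- stats::runif(sum(self), 0.05, 0.5)
    tibble::as_tibble(grid)
  })
}

# Organ-dose vector covering every ICRP-60 tissue (via aliases) plus the
# remainder set, all at the same dose d.
uniform_doses <- function(d = 1) {
  organs <- c(
    "testes", "red_marrow", "uli_wall", "lli_wall", "lungs",
    "stomach_wall", "urinary_bladder_wall", "breasts", "liver",
    "thymus", "thyroid", "skin", "osteogenic_cells",
    "adrenals", "brain", "small_intestine", "kidneys", "muscle",
    "pancreas", "spleen", "uterus"
  )
  stats::setNames(rep(d, length(organs)), organs)
}

pet_blk_doses <- function() cudosim::organ_dose_table("pet", "blk")
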