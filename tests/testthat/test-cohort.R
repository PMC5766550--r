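test_that("simulated uptake is zero at injection and saturates to the amplitude", {
  kin <- organ_kinetics("liver", 10, 5, 0)
  expect_equal(simulate_uptake(kin, 0), 0)
  # lambda_clear = 0, large lambda_uptake: plateau equals the amplitude
  expect_equal(simulate_uptake(kin, 100), 10, tolerance = 1e-6)
  # one physical half-life halves the non-decay-corrected signal
  expect_equal(
    simulate_uptake(kin, 12.7, decay_corrected = FALSE, half_life_h = 12.7),
    5, tolerance = 1e-6
  )
  expect_error(simulate_uptake(kin, -1), "non-negative")
})

test_that("decay-corrected uptake dominates the raw signal for t > 0", {
  kin <- organ_kinetics("spleen", 8, 0.4, 0.01)
  t <- c(0.5, 2, 24, 48)
  expect_true(all(simulate_uptake(kin, t, decay_corrected = TRUE) >=
    simulate_uptake(kin, t, decay_corrected = FALSE)))
})

test_that("kinetic parameter invariants are enforced", {
  expect_error(organ_kinetics("x", -1, 1, 0), "non-negative")
  expect_error(organ_kinetics("x", 1, 0.1, 0.2), "lambda_uptake")
  expect_error(organ_kinetics("x", 1, 1, 0, blocking_factor = 1.2), "\\[0, 1\\]")
})

test_that("zero-noise cohorts reproduce the kinetic curves exactly", {
  cfg <- cohort_config("hNSG_A375", n_per_group = 1, noise_sigma = 0)
  tbl <- generate_cohort(cfg)
  curve <- uptake_curve(default_kinetics("hNSG_A375"), cfg$sample_times_h,
    blocked = FALSE, decay_corrected = FALSE
  )
  got <- tbl |>
    dplyr::filter(group == "nblk", organ == "spleen") |>
    dplyr::arrange(time_h)
  want <- curve |>
    dplyr::filter(organ == "spleen") |>
    dplyr::arrange(time_h)
  expect_equal(got$pid_per_g, want$pid_per_g)
})

test_that("cohort generation is deterministic in the seed", {
  cfg1 <- cohort_config("hNSG_A375", seed = 7)
  expect_identical(generate_cohort(cfg1), generate_cohort(cfg1))
  cfg2 <- cohort_config("hNSG_A375", seed = 8)
  a <- generate_cohort(cfg1)
  b <- generate_cohort(cfg2)
  expect_identical(names(a), names(b))
  expect_identical(dim(a), dim(b))
  expect_false(identical(a$pid_per_g, b$pid_per_g))
})

test_that("blocking lowers tumor uptake at every time point", {
  k <- default_kinetics("NSG_293T_hPD1")
  t <- seq(0.5, 48, by = 0.5)
  blk <- uptake_curve(k, t, blocked = TRUE) |> dplyr::filter(organ == "tumor")
  nblk <- uptake_curve(k, t, blocked = FALSE) |> dplyr::filter(organ == "tumor")
  expect_true(all(blk$pid_per_g < nblk$pid_per_g))
})

test_that("empty kinetics and unknown models are rejected", {
  expect_error(
    generate_cohort(cohort_config(), default_kinetics("hNSG_A375")[0, ]),
    "empty"
  )
  expect_error(default_kinetics("NSG_unknown"), "arg")
  expect_error(cohort_config(sample_times_h = c(2, 1)), "increasing")
  expect_error(cohort_config(noise_sigma = -1), "noise_sigma")
})

test_that("log-linear regression on late noise-free samples recovers the clearance rate", {
  for (lc in c(0.005, 0.02, 0.08)) {
    kin <- organ_kinetics("o", 5, 1.5, lc)
    t <- seq(48, 96, by = 6) # uptake exponential has died away
    v <- simulate_uptake(kin, t, decay_corrected = TRUE)
    expect_equal(fit_clearance_rate(t, v), lc, tolerance = 0.01)
  }
})
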