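test_that("organ fraction is pid_per_g times mass over 100", {
  expect_equal(to_organ_fraction(5, 2), 0.10)
  expect_equal(to_organ_fraction(100, 1), 1.0)
  expect_equal(to_organ_fraction(7.3, 1.5), 0.1095)
  expect_warning(to_organ_fraction(300, 1), "exceeds 1")
  expect_error(to_organ_fraction(-1, 1), "non-negative")
})

test_that("trapezoidal TIA of a fully retained decaying source approaches T1/2 / ln 2", {
  t <- seq(0.01, 150, by = 0.01)
  tia <- integrate_tia(t, 2^(-t / 12.7),
    half_life_h = 12.7,
    tail_mode = "physical_decay"
  )
  expect_equal(tia, 12.7 / log(2), tolerance = 1e-3)
  expect_equal(integrate_tia(c(1, 2, 4), rep(0, 3)), 0)
})

test_that("decay-corrected curves are un-corrected before integration", {
  t <- seq(0.01, 150, by = 0.01)
  # constant decay-corrected retention == pure-decay raw curve
  tia <- integrate_tia(t, rep(0.5, length(t)),
    decay_corrected = TRUE,
    half_life_h = 12.7, tail_mode = "physical_decay"
  )
  expect_equal(tia, 0.5 * 12.7 / log(2), tolerance = 1e-3)
})

test_that("sparse-grid TIA matches a fine-grid oracle within the trapezoid bias bound", {
  # curve consistent with the (0,0) injection anchor
  f <- function(t) (1 - exp(-2 * t)) * exp(-0.1 * t) * 2^(-t / 12.7)
  coarse_t <- c(1, 2, 4, 18, 24, 48)
  coarse <- integrate_tia(coarse_t, f(coarse_t), tail_mode = "physical_decay")
  # oracle: same rule (anchor + trapezoid + physical tail) on a fine grid
  fine_t <- seq(1e-4, 48, by = 1e-4)
  fine <- integrate_tia(fine_t, f(fine_t), tail_mode = "physical_decay")
  # per-interval trapezoid bias bound sum (dt^3 * max|f''| / 12)
  d2 <- function(t) {
    h <- 1e-4
    (f(t + h) - 2 * f(t) + f(t - h)) / h^2
  }
  grid <- c(0, coarse_t)
  bound <- sum(vapply(seq_len(length(grid) - 1), function(i) {
    tt <- seq(max(grid[i], 1e-3), grid[i + 1], length.out = 200)
    diff(grid)[i]^3 * max(abs(d2(tt))) / 12
  }, numeric(1)))
  expect_lt(abs(coarse - fine), bound)
})

test_that("trapezoid error decreases monotonically under grid refinement", {
  f <- function(t) (1 - exp(-2 * t)) * exp(-0.08 * t) * 2^(-t / 12.7)
  ref_t <- seq(1e-4, 48, by = 1e-4)
  ref <- integrate_tia(ref_t, f(ref_t), tail_mode = "physical_decay")
  errs <- vapply(c(3, 6, 12, 24, 48, 96), function(n) {
    t <- seq(48 / n, 48, length.out = n)
    abs(integrate_tia(t, f(t), tail_mode = "physical_decay") - ref)
  }, numeric(1))
  expect_true(all(diff(errs) < 0))
})

test_that("integration tails are ordered zero <= fitted_exp <= physical_decay", {
  kin <- organ_kinetics("o", 5, 0.8, 0.02)
  t <- c(1, 2, 4, 18, 24, 48)
  v <- to_organ_fraction(
    simulate_uptake(kin, t, decay_corrected = FALSE), 1.3
  )
  tias <- vapply(
    c("zero", "fitted_exp", "physical_decay"),
    function(m) integrate_tia(t, v, tail_mode = m), numeric(1)
  )
  expect_true(all(diff(tias) >= 0))
})

test_that("no organ residence time outlives the isotope", {
  for (model in c("NSG_293T_hPD1", "hNSG_A375")) {
    cfg <- cohort_config(model, n_per_group = 2, noise_sigma = 0.1, seed = 3)
    tac <- tac_from_measurements(generate_cohort(cfg))
    taus <- residence_times(tac, tail_mode = "physical_decay")
    expect_true(all(taus$tau_h <= 1.443 * 12.7))
    expect_true(all(taus$tau_h >= 0))
  }
})

test_that("degenerate curves are rejected", {
  expect_error(integrate_tia(1, 0.5), "two time points")
  expect_error(integrate_tia(c(2, 1), c(0.1, 0.2)), "increasing")
  expect_error(integrate_tia(c(1, 2), c(0.1, -0.2)), "non-negative")
})

test_that("remainder of body is the floored whole-body excess", {
  taus <- tibble::tibble(organ = c("a", "b"), tau_h = c(3, 4))
  expect_equal(remainder_of_body(taus, whole_body_tau_h = 10), 3)
  expect_warning(
    rem <- remainder_of_body(taus, whole_body_tau_h = 5),
    "floored"
  )
  expect_equal(rem, 0)
  expect_warning(rem2 <- remainder_of_body(taus), "No whole-body")
  expect_equal(rem2, 0)
})
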