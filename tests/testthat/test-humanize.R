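test_that("relative-organ-mass scaling matches the closed form", {
  expect_equal(kirschner_scale(0, "liver"), 0)
  # 7 %ID/g * 23 g mouse * 1910 g liver / 73700 g body
  expect_equal(kirschner_scale(7, "liver"), 7 * 23 * 1910 / 73700)
  # linear in the human organ mass
  ph <- tibble::tibble(
    organ = c("liver", "total_body"),
    mass_g = c(1910, 73700)
  )
  ph2 <- dplyr::mutate(ph, mass_g = ifelse(organ == "liver", 2 * mass_g, mass_g))
  expect_equal(
    kirschner_scale(3, "liver", phantom = ph2),
    2 * kirschner_scale(3, "liver", phantom = ph)
  )
  expect_error(kirschner_scale(1, "antenna"), "antenna")
})

test_that("human residence times compose scaling with integration", {
  t <- seq(0.01, 96, by = 0.01)
  curves <- tibble::tibble(
    organ = "liver", time_h = t,
    pid_per_g = 4, decay_corrected = TRUE
  )
  taus <- human_residence_times(curves, tail_mode = "physical_decay")
  f <- 4 * 23 * 1910 / 73700 / 100 # constant human retained fraction
  expect_equal(taus$tau_h, f * 12.7 / log(2), tolerance = 1e-3)
  # all-zero curves give zero residence times
  zero <- dplyr::mutate(curves, pid_per_g = 0)
  expect_equal(human_residence_times(zero)$tau_h, 0)
})

test_that("the humanisation stage is linear in uptake", {
  t <- c(1, 4, 24, 48)
  curves <- tibble::tibble(
    organ = rep(c("liver", "spleen"), each = 4), time_h = rep(t, 2),
    pid_per_g = c(1, 3, 2, 1, 0.5, 1.5, 1, 0.4), decay_corrected = FALSE
  )
  tau1 <- human_residence_times(curves)
  tau2 <- human_residence_times(dplyr::mutate(curves, pid_per_g = 2 * pid_per_g))
  expect_equal(tau2$tau_h, 2 * tau1$tau_h)
})

test_that("scaling before integration equals integrating then mass-scaling", {
  t <- c(1, 2, 4, 18, 24, 48)
  pid <- simulate_uptake(organ_kinetics("liver", 5, 0.6, 0.01), t,
    decay_corrected = FALSE
  )
  curves <- tibble::tibble(
    organ = "liver", time_h = t,
    pid_per_g = pid, decay_corrected = FALSE
  )
  tau_scaled <- human_residence_times(curves)$tau_h
  # integrate the mouse %ID/g curve, then apply the (linear) mass factor
  tau_mouse <- integrate_tia(t, pid / 100, tail_mode = "physical_decay")
  expect_equal(tau_scaled, tau_mouse * 23 * 1910 / 73700)
})

test_that("organs absent from the phantom are excluded and reported", {
  curves <- tibble::tibble(
    organ = rep(c("liver", "tumor"), each = 2),
    time_h = rep(c(1, 24), 2), pid_per_g = 1, decay_corrected = FALSE
  )
  expect_warning(taus <- human_residence_times(curves), "tumor")
  expect_identical(attr(taus, "excluded_organs"), "tumor")
  expect_identical(taus$organ, "liver")
})

test_that("summed human %ID never exceeds the mouse whole-body equivalent", {
  ph <- human_phantom()
  organs <- setdiff(ph$organ, "total_body")
  p <- 2.5 # uniform mouse %ID/g everywhere
  human_total <- sum(kirschner_scale(p, organs))
  # uniform %ID/g over the whole 23 g mouse holds p * 23 %ID in total
  expect_lte(human_total, p * 23)
})

test_that("source mapping renames measured organs and flags collisions", {
  x <- tibble::tibble(organ = c("heart", "liver"), time_h = 1)
  expect_identical(map_sources(x)$organ, c("heart_contents", "liver"))
  y <- tibble::tibble(organ = c("heart", "blood"), time_h = 1)
  expect_warning(map_sources(y), "one source")
})
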