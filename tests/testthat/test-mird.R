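test_that("S-value tables are validated", {
  bad <- tibble::tibble(target = "a", source = "a", S_mSv_per_MBq_h = -1)
  expect_error(as_svalue_matrix(bad), "non-negative")
  no_self <- tibble::tibble(
    target = c("a", "b"), source = c("b", "a"),
    S_mSv_per_MBq_h = c(0.01, 0.2)
  )
  expect_error(as_svalue_matrix(no_self), "self-dose")
  expect_gt(nrow(cu64_svalues()), 0)
})

test_that("organ doses follow the MIRD sum over sources", {
  s1 <- tibble::tibble(target = "t", source = "s", S_mSv_per_MBq_h = 0.003)
  tau <- tibble::tibble(organ = "s", tau_h = 2)
  expect_equal(organ_doses(tau, s1)$dose_uSv_per_MBq, 6)
  expect_equal(
    organ_doses(dplyr::mutate(tau, tau_h = 0), s1)$dose_uSv_per_MBq, 0
  )
  expect_error(
    organ_doses(tibble::tibble(organ = "x", tau_h = 1), s1),
    "x"
  )
})

test_that("organ doses match a brute-force double loop on random 5x5 matrices", {
  organs <- letters[1:5]
  for (seed in 1:3) {
    sv <- random_svalues(organs, seed = seed)
    taus <- withr::with_seed(
      100 + seed,
      tibble::tibble(organ = organs, tau_h = stats::runif(5, 0, 10))
    )
    got <- organ_doses(taus, sv)
    want <- vapply(organs, function(tg) {
      acc <- 0
      for (src in organs) {
        s <- sv$S_mSv_per_MBq_h[sv$target == tg & sv$source == src]
        acc <- acc + 1000 * s * taus$tau_h[taus$organ == src]
      }
      acc
    }, numeric(1))
    expect_equal(
      got$dose_uSv_per_MBq[match(organs, got$organ)],
      unname(want)
    )
  }
})

test_that("organ doses are linear in the residence times", {
  sv <- random_svalues(letters[1:4], seed = 9)
  taus <- tibble::tibble(organ = letters[1:4], tau_h = c(1, 2, 0.5, 3))
  d1 <- organ_doses(taus, sv)
  d3 <- organ_doses(dplyr::mutate(taus, tau_h = 3 * tau_h), sv)
  expect_equal(d3$dose_uSv_per_MBq, 3 * d1$dose_uSv_per_MBq)
})

test_that("ICRP-60 effective dose reduces to known closed forms", {
  # uniform dose over every weighted tissue and remainder organ
  expect_equal(effective_dose(uniform_doses(2.5)), 2.5)
  # single-tissue dose: liver alone at 20 with weight 0.05
  only_liver <- uniform_doses(0)
  only_liver["liver"] <- 20
  expect_equal(effective_dose(only_liver), 1.0)
  # bounded by the extremes of the input doses
  d <- withr::with_seed(5, uniform_doses(0) + stats::runif(21, 0, 10))
  ed <- effective_dose(d)
  expect_gte(ed, min(d))
  expect_lte(ed, max(d))
})

test_that("ICRP-26 effective dose equivalent reduces to known closed forms", {
  expect_equal(effective_dose_equivalent(uniform_doses(1.7)), 1.7)
  # one unnamed organ at 10 occupies a single 0.06 remainder slot
  one <- c(uniform_doses(0)["testes"], pancreas = 10)
  ede <- suppressWarnings(effective_dose_equivalent(one))
  expect_equal(ede, 0.6)
  w <- capture_warnings(effective_dose_equivalent(one))
  expect_match(w, "candidates", all = FALSE)
})

test_that("scheme weights must close to unity", {
  sch <- tissue_weight_scheme("ICRP60_ED")
  expect_equal(sum(sch$weights) + sch$remainder_weight, 1.0)
  sch$weights["liver"] <- 0.2
  expect_error(effective_dose(uniform_doses(1), scheme = sch), "sum to 1")
  ede <- tissue_weight_scheme("ICRP26_EDE")
  expect_equal(sum(ede$weights) + 5 * ede$remainder_weight, 1.0)
})

test_that("YAML scheme files mirror the built-in schemes", {
  for (id in c("ICRP60_ED", "ICRP26_EDE")) {
    path <- system.file("extdata",
      paste0(tolower(sub("_ED.*", "", id)), "_",
        tolower(sub(".*_", "", id)), ".yaml"
      ),
      package = "cudosim"
    )
    got <- read_weight_scheme(path)
    want <- tissue_weight_scheme(id)
    expect_equal(got$weights[names(want$weights)], want$weights)
    expect_equal(got$remainder_rule, want$remainder_rule)
  }
})

test_that("the dose-limiting organ is the argmax with deterministic ties", {
  d <- c(liver = 35.15, heart_wall = 17.05, spleen = 6.705)
  expect_identical(dose_limiting_organ(d), "liver")
  expect_identical(dose_limiting_organ(c(b = 1, a = 1)), "a")
  expect_identical(dose_limiting_organ(c(kidneys = 2)), "kidneys")
  # total body is not an organ
  expect_identical(dose_limiting_organ(c(total_body = 99, liver = 1)), "liver")
  expect_error(dose_limiting_organ(c(total_body = 1)), "non-empty")
})

test_that("administrable activity divides each limit by its coefficient", {
  adm <- administrable_activity(c(liver = 35.15), 2.37)
  organ_single <- adm[adm$constraint == "organ_single_study", ]
  expect_equal(organ_single$activity_MBq, 50000 / 35.15)
  expect_equal(organ_single$activity_GBq, 1.42)
  expect_true(organ_single$binding)
  # uniform coefficients: every activity is limit / coefficient
  adm_u <- administrable_activity(c(a = 4, b = 4), 4)
  expect_equal(adm_u$activity_MBq, 1000 * adm_u$limit_mSv / 4)
  expect_error(administrable_activity(c(a = 0), 0), "positive")
  # scans per year from the binding annual constraint
  expect_equal(
    attr(adm, "scans_per_year"),
    floor(min(adm$activity_MBq[grepl("annual", adm$constraint)]) / 185)
  )
})

test_that("regulatory limit invariants hold", {
  expect_error(regulatory_limits(whole_body_single_mSv = 60), "exceed")
  lim <- regulatory_limits()
  expect_equal(lim$whole_body_annual_mSv, 50)
  expect_equal(lim$other_organ_single_mSv, 50)
})
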