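#' Convert gamma-counter counts to percent injected dose per gram
#'
#' The standard biodistribution quantity: background-subtracted organ
#' counts as a fraction of the injected-dose counts, per gram of tissue,
#' times 100. With `correct_to_injection = TRUE` the value is also
#' decay-corrected back to injection time (multiplied by
#' `2^(t / half_life)`), the usual gamma-counting convention.
#'
#' @param raw_counts_cpm Measured organ counts per minute.
#' @param injected_dose_cpm Counts-per-minute equivalent of the injected
#'   dose (> 0), measured on the same counter.
#' @param organ_mass_g Organ mass in grams (> 0).
#' @param background_cpm Background counts per minute (default 0; must
#'   not exceed `raw_counts_cpm`).
#' @param time_h Hours post-injection at which the sample was counted.
#' @param half_life_h Physical half-life, hours.
#' @param correct_to_injection Logical; decay-correct to injection time?
#' @return %ID/g values. The decay-correction state of the result equals
#'   `correct_to_injection`.
#' @examples
#' cpm_to_pid_per_g(1100, 1e5, 0.5, background_cpm = 100) # 2 %ID/g
#' @export
cpm_to_pid_per_g <- function(raw_counts_cpm, injected_dose_cpm, organ_mass_g,
                             background_cpm = 0, time_h = 0,
                             half_life_h = CU64_HALF_LIFE_H,
                             correct_to_injection = TRUE) {
  if (any(injected_dose_cpm <= 0)) abort("`injected_dose_cpm` must be positive.")
  if (any(organ_mass_g <= 0)) abort("`organ_mass_g` must be positive.")
  if (any(background_cpm > raw_counts_cpm)) {
    abort("`background_cpm` exceeds `raw_counts_cpm`.")
  }
  net <- raw_counts_cpm - background_cpm
  if (correct_to_injection) net <- decay_correct(net, time_h, half_life_h)
  100 * net / (injected_dose_cpm * organ_mass_g)
}

#' Quantify a raw measurement table
#'
#' Fills in the `pid_per_g` column of a long-format biodistribution
#' table. Rows that already carry `pid_per_g` are passed through
#' unchanged; rows with `raw_counts_cpm` (plus `injected_dose_cpm`,
#' `organ_mass_g`, optional `background_cpm`) are converted with
#' [cpm_to_pid_per_g()]. Each row must provide exactly one of the two.
#'
#' @param measurements Tibble with at least `organ`, `time_h`,
#'   `organ_mass_g` and either `pid_per_g` or `raw_counts_cpm` +
#'   `injected_dose_cpm`.
#' @inheritParams cpm_to_pid_per_g
#' @return The input tibble with `pid_per_g` and `decay_corrected`
#'   columns set.
#' @export
quantify_measurements <- function(measurements,
                                  half_life_h = CU64_HALF_LIFE_H,
                                  correct_to_injection = TRUE) {
  m <- as_tibble(measurements)
  if (!"pid_per_g" %in% names(m)) m$pid_per_g <- NA_real_
  if (!"raw_counts_cpm" %in% names(m)) m$raw_counts_cpm <- NA_real_
  if (!"background_cpm" %in% names(m)) m$background_cpm <- 0
  has_pid <- !is.na(m$pid_per_g)
  has_cpm <- !is.na(m$raw_counts_cpm)
  if (any(has_pid == has_cpm)) {
    abort("Each row must have exactly one of `pid_per_g` or `raw_counts_cpm`.")
  }
  if (any(has_cpm) && !"injected_dose_cpm" %in% names(m)) {
    abort("Counts rows need an `injected_dose_cpm` column.")
  }
  if (!"decay_corrected" %in% names(m)) m$decay_corrected <- NA
  idx <- which(has_cpm)
  if (length(idx)) {
    m$pid_per_g[idx] <- cpm_to_pid_per_g(
      m$raw_counts_cpm[idx], m$injected_dose_cpm[idx], m$organ_mass_g[idx],
      background_cpm = m$background_cpm[idx], time_h = m$time_h[idx],
      half_life_h = half_life_h, correct_to_injection = correct_to_injection
    )
    m$decay_corrected[idx] <- correct_to_injection
  }
  m
}

#' Uptake ratio of a target region to a reference region
#'
#' Ratio of mean target uptake to mean reference uptake (e.g. the
#' xenograft-to-muscle ratio, XMR), with a first-order propagated
#' standard deviation:
#' \deqn{\sigma_r = r\sqrt{(s_x/\bar x)^2 + (s_y/\bar y)^2}.}
#' Both inputs must share the same decay-correction state; the ratio is
#' invariant to rescaling both lists by a common factor.
#'
#' @param target,reference Numeric vectors of %ID/g values.
#' @return One-row tibble with `ratio`, `sd`, `n_target`, `n_reference`.
#' @export
uptake_ratio <- function(target, reference) {
  if (length(target) == 0 || length(reference) == 0) {
    abort("`target` and `reference` must be non-empty.")
  }
  mx <- mean(target)
  my <- mean(reference)
  if (my == 0) abort("Reference mean is zero; ratio undefined.")
  r <- mx / my
  sdr <- abs(r) * sqrt((stats::sd(target) / mx)^2 + (stats::sd(reference) / my)^2)
  tibble(
    ratio = r, sd = sdr,
    n_target = length(target), n_reference = length(reference)
  )
}

#' Ellipsoid tumor volume from caliper measurements
#'
#' \eqn{V = \pi h w l / 6}. When the height cannot be measured (as for
#' flat subcutaneous melanomas) it is estimated as two thirds of the
#' length, `h = 2 l / 3`.
#'
#' @param length_mm,width_mm Caliper length and width, mm (> 0).
#' @param height_mm Caliper height, mm; may be `NULL`/`NA` only when
#'   `estimate_height = TRUE`.
#' @param estimate_height Logical; use the `h = 2 l / 3` rule?
#' @return Volume in cubic millimetres.
#' @examples
#' tumor_volume(2, 2, 2)                       # sphere of diameter 2
#' tumor_volume(9, 6, estimate_height = TRUE)  # h = 6 by the 2/3 rule
#' @export
tumor_volume <- function(length_mm, width_mm, height_mm = NULL,
                         estimate_height = FALSE) {
  if (any(length_mm <= 0) || any(width_mm <= 0)) {
    abort("Tumor dimensions must be positive.")
  }
  if (estimate_height) {
    height_mm <- 2 * length_mm / 3
  } else if (is.null(height_mm) || anyNA(height_mm)) {
    abort("`height_mm` is missing; set `estimate_height = TRUE` to impute it.")
  }
  if (any(height_mm <= 0)) abort("Tumor dimensions must be positive.")
  pi * height_mm * width_mm * length_mm / 6
}

#' Compare two groups with an unpaired Student's t test
#'
#' Classical pooled-variance, two-tailed, unpaired t test, the standard
#' test for blocked-versus-non-blocked uptake comparisons. Significance
#' is flagged at p < 0.05.
#'
#' @param a,b Numeric vectors, one per group (each of length >= 2).
#' @return One-row tibble with `mean_a`, `mean_b`, `t`, `df`, `p_value`,
#'   `significant`.
#' @export
group_compare <- function(a, b) {
  if (length(a) < 2 || length(b) < 2) {
    abort("Each group needs at least two values.")
  }
  tt <- t.test(a, b, var.equal = TRUE, alternative = "two.sided")
  tibble(
    mean_a = mean(a), mean_b = mean(b),
    t = unname(tt$statistic), df = unname(tt$parameter),
    p_value = tt$p.value, significant = tt$p.value < 0.05
  )
}
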