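#' Convert per-gram uptake to the fraction of injected activity in an organ
#'
#' `fraction = pid_per_g * organ_mass_g / 100`. A fraction above 1 means
#' the organ would hold more than the injected dose; such values are
#' reported with a warning (never silently clipped) because they signal
#' inconsistent inputs.
#'
#' @param pid_per_g %ID/g values (>= 0).
#' @param organ_mass_g Organ mass in grams (> 0).
#' @return Unitless fraction of the injected activity in the organ.
#' @export
to_organ_fraction <- function(pid_per_g, organ_mass_g) {
  if (any(pid_per_g < 0)) abort("`pid_per_g` must be non-negative.")
  if (any(organ_mass_g <= 0)) abort("`organ_mass_g` must be positive.")
  f <- pid_per_g * organ_mass_g / 100
  if (any(f > 1)) {
    warn("Organ fraction exceeds 1 (more than the injected dose); check inputs.")
  }
  f
}

#' Build mean time-activity curves from a measurement table
#'
#' Collapses a per-animal biodistribution table into one mean
#' time-activity curve per organ (and per any other grouping column,
#' e.g. `group`): %ID/g is converted to the fraction of injected
#' activity in the organ with [to_organ_fraction()] and averaged across
#' animals at each time point.
#'
#' @param measurements Tibble with `organ`, `time_h`, `pid_per_g`,
#'   `organ_mass_g`, `decay_corrected` and optional extra grouping
#'   columns named in `by`.
#' @param by Extra grouping columns (default `"group"` when present).
#' @return Tibble with columns `by`..., `organ`, `time_h`, `fraction`,
#'   `decay_corrected`.
#' @export
tac_from_measurements <- function(measurements,
                                  by = intersect("group", names(measurements))) {
  m <- as_tibble(measurements)
  if (length(unique(m$decay_corrected)) != 1) {
    abort("Mixed decay-correction states in one table.")
  }
  m |>
    mutate(fraction = to_organ_fraction(.data$pid_per_g, .data$organ_mass_g)) |>
    group_by(across(all_of(c(by, "organ", "time_h")))) |>
    summarise(
      fraction = mean(.data$fraction),
      decay_corrected = .data$decay_corrected[1],
      .groups = "drop"
    ) |>
    arrange(across(all_of(c(by, "organ", "time_h"))))
}

#' Time-integrated activity of one organ curve
#'
#' Trapezoidal integration of the non-decay-corrected fraction of
#' injected activity, i.e. the cumulated activity per unit injected
#' activity (hours). A `(0, 0)` anchor is prepended because the tracer
#' is injected intravenously at t = 0. Decay-corrected input is
#' automatically un-corrected first: cumulated activity must include
#' physical decay. Beyond the last sample the curve is extrapolated
#' according to `tail_mode`:
#'
#' * `"physical_decay"` (default, conservative): biological retention
#'   with physical decay only, contributing `A_last / lambda_phys`.
#' * `"zero"`: no tail.
#' * `"fitted_exp"`: a biological clearance rate is fitted log-linearly
#'   to the last `n_tail_fit` decay-corrected points (floored at zero)
#'   and added to the physical decay constant, contributing
#'   `A_last / (lambda_phys + lambda_fit)`.
#'
#' @param time_h Strictly increasing sampling times, hours (> 0), at
#'   least two.
#' @param fraction Fraction of injected activity in the organ at each
#'   time, in `[0, 1]`.
#' @param decay_corrected Logical; is `fraction` decay-corrected?
#' @param half_life_h Physical half-life, hours.
#' @param tail_mode One of `"physical_decay"`, `"zero"`, `"fitted_exp"`.
#' @param n_tail_fit Number of trailing points for the `"fitted_exp"`
#'   fit (>= 2).
#' @return Cumulated activity per unit injected activity, in hours.
#' @examples
#' # pure physical decay of a fully retained tracer -> T1/2 / ln 2
#' t <- seq(0.05, 96, by = 0.05)
#' integrate_tia(t, 2^(-t / 12.7), tail_mode = "physical_decay")
#' @export
integrate_tia <- function(time_h, fraction, decay_corrected = FALSE,
                          half_life_h = CU64_HALF_LIFE_H,
                          tail_mode = c("physical_decay", "zero", "fitted_exp"),
                          n_tail_fit = 3) {
  tail_mode <- match.arg(tail_mode)
  if (length(time_h) < 2) abort("Need at least two time points.")
  if (length(time_h) != length(fraction)) abort("Length mismatch.")
  if (any(time_h <= 0) || is.unsorted(time_h, strictly = TRUE)) {
    abort("`time_h` must be strictly increasing and positive.")
  }
  if (any(fraction < 0)) abort("`fraction` must be non-negative.")
  if (decay_corrected) {
    fraction <- decay_uncorrect(fraction, time_h, half_life_h)
  }
  lambda_phys <- log(2) / half_life_h
  auc <- pracma::trapz(c(0, time_h), c(0, fraction))
  a_last <- fraction[length(fraction)]
  tail <- switch(tail_mode,
    zero = 0,
    physical_decay = a_last / lambda_phys,
    fitted_exp = {
      k <- max(2, min(n_tail_fit, length(time_h)))
      ti <- tail(time_h, k)
      fi <- decay_correct(tail(fraction, k), ti, half_life_h)
      lambda_fit <- if (all(fi > 0)) max(0, fit_clearance_rate(ti, fi)) else Inf
      if (is.finite(lambda_fit)) a_last / (lambda_phys + lambda_fit) else 0
    }
  )
  auc + tail
}

#' Residence time from cumulated activity
#'
#' With the injected activity normalised to 1, the residence time of a
#' source organ equals its time-integrated activity; this explicit named
#' step validates and relabels the quantity OLINDA-style phantom
#' software consumes (MBq h per MBq injected).
#'
#' @param tia_h Cumulated activity per unit injected activity, hours
#'   (>= 0).
#' @return Residence time in hours.
#' @export
residence_time <- function(tia_h) {
  if (any(tia_h < 0)) abort("Cumulated activity must be non-negative.")
  tia_h
}

#' Residence times for every organ curve in a table
#'
#' Applies [integrate_tia()] per organ (and per extra grouping column)
#' of a time-activity table as built by [tac_from_measurements()]. A
#' residence time exceeding the pure-decay bound
#' `1.443 * half_life_h` (an organ retaining the entire injected dose
#' forever) indicates inconsistent input and draws a warning.
#'
#' @param tac Tibble with `organ`, `time_h`, `fraction`,
#'   `decay_corrected` and optional grouping columns.
#' @inheritParams integrate_tia
#' @param by Extra grouping columns (default `"group"` when present).
#' @return Tibble with `by`..., `organ`, `tau_h`, `tail_mode`.
#' @export
residence_times <- function(tac,
                            tail_mode = c("physical_decay", "zero", "fitted_exp"),
                            half_life_h = CU64_HALF_LIFE_H,
                            by = intersect("group", names(tac))) {
  tail_mode <- match.arg(tail_mode)
  out <- tac |>
    group_by(across(all_of(c(by, "organ")))) |>
    summarise(
      tau_h = residence_time(integrate_tia(
        .data$time_h, .data$fraction,
        decay_corrected = .data$decay_corrected[1],
        half_life_h = half_life_h, tail_mode = tail_mode
      )),
      .groups = "drop"
    ) |>
    mutate(tail_mode = tail_mode)
  if (any(out$tau_h > 1.443 * half_life_h)) {
    warn("Residence time exceeds the pure-decay bound 1.443 * half-life.")
  }
  out
}

#' Residence time of the remainder of the body
#'
#' Phantom dose software expects a "remainder of body" source. When a
#' whole-body residence time is available the remainder is the excess of
#' the whole body over the summed organs, floored at zero (a negative
#' excess signals inconsistent curves and draws a warning). Without a
#' whole-body curve nothing is assumed: the remainder is zero, with a
#' warning that remainder dose is omitted.
#'
#' @param organ_taus Tibble with a `tau_h` column (as from
#'   [residence_times()]).
#' @param whole_body_tau_h Optional whole-body residence time, hours.
#' @return Remainder-of-body residence time, hours.
#' @export
remainder_of_body <- function(organ_taus, whole_body_tau_h = NULL) {
  total <- sum(organ_taus$tau_h)
  if (is.null(whole_body_tau_h)) {
    warn("No whole-body curve: remainder-of-body residence time set to 0.")
    return(0)
  }
  rem <- whole_body_tau_h - total
  if (rem < 0) {
    warn("Organ residence times exceed the whole body; remainder floored at 0.")
    rem <- 0
  }
  rem
}
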