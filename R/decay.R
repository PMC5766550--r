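#' Decay-correct an activity-like quantity to the time of injection
#'
#' Physical decay correction rescales a measured activity (or any
#' activity-proportional quantity such as %ID/g) to the value it would
#' have had at injection time: multiplication by `2^(t / half_life)`.
#' [decay_uncorrect()] is the exact inverse and restores the physically
#' decaying signal.
#'
#' @param x Numeric vector, activity-like values.
#' @param time_h Hours elapsed since injection (non-negative, recycled
#'   against `x`).
#' @param half_life_h Physical half-life in hours (default copper-64,
#'   12.7 h).
#' @return Numeric vector of the same length as `x`.
#' @examples
#' decay_correct(1, 25.4)            # two half-lives -> 4
#' decay_uncorrect(decay_correct(0.37, 48), 48)  # round trip -> 0.37
#' @export
decay_correct <- function(x, time_h, half_life_h = CU64_HALF_LIFE_H) {
  check_decay_args(time_h, half_life_h)
  x * 2^(time_h / half_life_h)
}

#' @rdname decay_correct
#' @export
decay_uncorrect <- function(x, time_h, half_life_h = CU64_HALF_LIFE_H) {
  check_decay_args(time_h, half_life_h)
  x * 2^(-time_h / half_life_h)
}

check_decay_args <- function(time_h, half_life_h) {
  if (any(half_life_h <= 0)) {
    abort("`half_life_h` must be positive.")
  }
  if (any(time_h < 0)) {
    abort("`time_h` must be non-negative.")
  }
  invisible(TRUE)
}
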