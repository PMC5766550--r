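#' Tidy a dose report
#'
#' Returns the per-organ dose coefficients as a long tibble, one row per
#' group and target organ.
#'
#' @param x A `dose_report` from [run_dosimetry_pipeline()].
#' @param ... Unused.
#' @return Tibble with `group`, `organ`, `dose_uSv_per_MBq`.
#' @export
tidy.dose_report <- function(x, ...) {
  x$organ_doses
}

#' Summarise a dose report in one row per group
#'
#' @inheritParams tidy.dose_report
#' @return Tibble with one row per group: effective dose, effective dose
#'   equivalent, dose-limiting organ, its coefficient, and the binding
#'   administrable activity.
#' @export
glance.dose_report <- function(x, ...) {
  binding <- x$administrable |>
    filter(.data$binding) |>
    select("group",
      binding_constraint = "constraint",
      binding_activity_MBq = "activity_MBq",
      binding_activity_GBq = "activity_GBq"
    )
  x$summary |> left_join(binding, by = "group")
}

#' Plot the organ dose coefficients of a dose report
#'
#' Bar chart of per-organ dose coefficients, one panel position per
#' cohort, with the dose-limiting organ of each group highlighted.
#'
#' @param object A `dose_report`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.dose_report <- function(object, ...) {
  d <- object$organ_doses |>
    left_join(
      object$summary |> select("group", "dose_limiting_organ"),
      by = "group"
    ) |>
    mutate(limiting = .data$organ == .data$dose_limiting_organ)
  ggplot2::ggplot(
    d,
    ggplot2::aes(
      x = stats::reorder(.data$organ, .data$dose_uSv_per_MBq),
      y = .data$dose_uSv_per_MBq, fill = .data$limiting
    )
  ) +
    ggplot2::geom_col(show.legend = FALSE) +
    ggplot2::coord_flip() +
    ggplot2::facet_wrap(~group) +
    ggplot2::scale_fill_manual(values = c(`FALSE` = "grey60", `TRUE` = "firebrick")) +
    ggplot2::labs(
      x = NULL, y = "Absorbed dose coefficient (µSv/MBq)",
      title = "Predicted human organ doses",
      subtitle = "Dose-limiting organ highlighted"
    )
}

#' Plot time-activity curves of a biodistribution table
#'
#' Mean uptake (%ID/g) against time post-injection, one line per organ,
#' faceted by cohort.
#'
#' @param measurements Tibble in the [generate_cohort()] schema.
#' @return A ggplot object.
#' @export
plot_time_activity <- function(measurements) {
  d <- measurements |>
    group_by(.data$group, .data$organ, .data$time_h) |>
    summarise(pid_per_g = mean(.data$pid_per_g), .groups = "drop")
  ggplot2::ggplot(
    d,
    ggplot2::aes(.data$time_h, .data$pid_per_g, colour = .data$organ)
  ) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::facet_wrap(~group) +
    ggplot2::labs(
      x = "Time post-injection (h)", y = "Uptake (%ID/g)",
      colour = "Organ"
    )
}
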