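#' Configure a full dosimetry pipeline run
#'
#' Bundles everything one end-to-end run needs: where the measurements
#' come from (`"simulate"` for the synthetic generator, `"ingest"` for a
#' CSV of real measurements), the animal and phantom contexts, the
#' S-value table, the organ-to-source mapping, the integration tail, the
#' regulatory limits and the planned per-scan activity.
#'
#' @param mode `"simulate"` or `"ingest"`.
#' @param cohort A [cohort_config()] (simulate mode).
#' @param input_path CSV of measurements (ingest mode), in the schema of
#'   [generate_cohort()] or with raw counts columns for
#'   [quantify_measurements()].
#' @param animal An [animal_context()].
#' @param phantom A phantom table, see [human_phantom()].
#' @param svalues An S-value table, see [as_svalue_matrix()].
#' @param source_map Organ-to-source mapping, see [default_source_map()].
#' @param tail_mode Integration tail, see [integrate_tia()].
#' @param limits A [regulatory_limits()].
#' @param per_scan_MBq Planned activity per scan, MBq.
#' @param out_dir Optional directory; when set, intermediate tables and
#'   the dose report are written there as CSV/JSON.
#' @return List of class `"dosimetry_config"`.
#' @export
dosimetry_config <- function(mode = c("simulate", "ingest"),
                             cohort = cohort_config(),
                             input_path = NULL,
                             animal = animal_context(),
                             phantom = human_phantom(),
                             svalues = cu64_svalues(),
                             source_map = default_source_map(),
                             tail_mode = "physical_decay",
                             limits = regulatory_limits(),
                             per_scan_MBq = 185,
                             out_dir = NULL) {
  mode <- match.arg(mode)
  if (mode == "ingest") {
    if (is.null(input_path) || !file.exists(input_path)) {
      abort("Ingest mode needs an existing `input_path`.")
    }
  } else if (!inherits(cohort, "cohort_config")) {
    abort("Simulate mode needs a `cohort_config()`.")
  }
  structure(
    list(
      mode = mode, cohort = cohort, input_path = input_path,
      animal = animal, phantom = phantom, svalues = svalues,
      source_map = source_map, tail_mode = tail_mode,
      limits = limits, per_scan_MBq = per_scan_MBq, out_dir = out_dir
    ),
    class = "dosimetry_config"
  )
}

#' Validate a measurement table
#'
#' Schema, range and consistency checks on a long-format biodistribution
#' table: required columns, non-negative times, positive organ masses,
#' non-negative uptake, monotone time points per animal and organ, and a
#' single decay-correction state. Problems are reported, never fixed.
#'
#' @param measurements Tibble in the [generate_cohort()] schema.
#' @return Tibble of issues with columns `check` and `detail`; zero rows
#'   means the table is valid.
#' @export
validate_measurements <- function(measurements) {
  issues <- list()
  flag <- function(check, detail) {
    issues[[length(issues) + 1]] <<- tibble(check = check, detail = detail)
  }
  need <- c("animal_id", "organ", "time_h", "pid_per_g",
            "decay_corrected", "organ_mass_g")
  miss <- setdiff(need, names(measurements))
  if (length(miss)) {
    flag("schema", paste("missing column(s):", paste(miss, collapse = ", ")))
    return(list_rbind(issues))
  }
  if (any(measurements$time_h < 0)) flag("range", "negative time_h")
  if (any(measurements$organ_mass_g <= 0, na.rm = TRUE)) {
    flag("range", "non-positive organ_mass_g")
  }
  if (any(measurements$pid_per_g < 0, na.rm = TRUE)) {
    flag("range", "negative pid_per_g")
  }
  if (length(unique(measurements$decay_corrected)) > 1) {
    flag("decay_flag", "mixed decay-correction states in one table")
  }
  bad_order <- measurements |>
    group_by(.data$animal_id, .data$organ) |>
    summarise(ok = !is.unsorted(.data$time_h, strictly = TRUE), .groups = "drop") |>
    filter(!.data$ok)
  if (nrow(bad_order)) {
    flag("monotone_time", paste(
      "non-increasing times for",
      paste(unique(bad_order$animal_id), collapse = ", ")
    ))
  }
  if (length(issues)) list_rbind(issues) else tibble(check = character(), detail = character())
}

run_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    abort(paste0("Pipeline stage `", stage, "` failed: ", conditionMessage(e)))
  })
}

#' Run the full preclinical-to-clinical dosimetry pipeline
#'
#' Simulates (or ingests) a mouse biodistribution study, averages it
#' into per-group organ uptake curves, maps measured organs onto phantom
#' source regions, scales to human-equivalent curves and integrates them
#' into residence times, folds the residence times through the S-value
#' matrix into organ dose coefficients, derives the ICRP-60 effective
#' dose and ICRP-26 effective dose equivalent, identifies the
#' dose-limiting organ and computes the administrable activity for every
#' regulatory constraint. Blocked and non-blocked cohorts are processed
#' as independent arms. With identical configuration (including the
#' seed) the result is identical.
#'
#' @param config A [dosimetry_config()].
#' @return A `dose_report` object: a list with `measurements`, `curves`
#'   (per-group mean uptake), `residence_times`, `organ_doses`,
#'   `summary` (per group: effective dose, effective dose equivalent,
#'   dose-limiting organ and its coefficient), `administrable` (per
#'   group), and `config`. Supports [tidy()], [glance()], [autoplot()]
#'   and `print()`.
#' @examples
#' cfg <- dosimetry_config(cohort = cohort_config("hNSG_A375",
#'   noise_sigma = 0, n_per_group = 1
#' ))
#' report <- run_dosimetry_pipeline(cfg)
#' glance(report)
#' @export
run_dosimetry_pipeline <- function(config = dosimetry_config()) {
  stopifnot(inherits(config, "dosimetry_config"))
  measurements <- run_stage("measurements", {
    if (config$mode == "simulate") {
      generate_cohort(config$cohort)
    } else {
      quantify_measurements(read_biodistribution(config$input_path))
    }
  })
  run_stage("validate", {
    iss <- validate_measurements(measurements)
    if (nrow(iss)) {
      abort(paste(
        "invalid measurements:",
        paste(iss$check, iss$detail, sep = ": ", collapse = "; ")
      ))
    }
  })
  curves <- run_stage("average_curves", {
    measurements |>
      group_by(.data$group, .data$organ, .data$time_h) |>
      summarise(
        pid_per_g = mean(.data$pid_per_g),
        decay_corrected = .data$decay_corrected[1],
        .groups = "drop"
      )
  })
  taus <- run_stage("residence_times", {
    curves |>
      map_sources(config$source_map) |>
      human_residence_times(
        animal = config$animal, phantom = config$phantom,
        tail_mode = config$tail_mode
      )
  })
  doses <- run_stage("organ_doses", {
    taus |>
      group_by(.data$group) |>
      group_modify(~ organ_doses(.x, config$svalues)) |>
      ungroup()
  })
  summary <- run_stage("effective_dose", {
    doses |>
      group_by(.data$group) |>
      group_modify(function(d, key) {
        tibble(
          effective_dose_uSv_per_MBq = effective_dose(d, phantom = config$phantom),
          effective_dose_equivalent_uSv_per_MBq = effective_dose_equivalent(d),
          dose_limiting_organ = dose_limiting_organ(d),
          max_organ_dose_uSv_per_MBq = max(d$dose_uSv_per_MBq)
        )
      }) |>
      ungroup()
  })
  administrable <- run_stage("administrable_activity", {
    summary |>
      group_by(.data$group) |>
      group_modify(function(s, key) {
        administrable_activity(
          doses |> filter(.data$group == key$group) |> select(-"group"),
          effective_dose_uSv_per_MBq = s$effective_dose_uSv_per_MBq,
          limits = config$limits, per_scan_MBq = config$per_scan_MBq
        )
      }) |>
      ungroup()
  })
  report <- structure(
    list(
      measurements = measurements, curves = curves, residence_times = taus,
      organ_doses = doses, summary = summary, administrable = administrable,
      config = config
    ),
    class = "dose_report"
  )
  if (!is.null(config$out_dir)) write_dose_report(report, config$out_dir)
  report
}

#' Dose report from a precomputed organ-dose table
#'
#' Entry point for the weighting and limit logic alone: takes per-organ
#' dose coefficients (uSv/MBq) as published dosimetry tables provide
#' them, and recomputes effective dose, effective dose equivalent, the
#' dose-limiting organ and administrable activity without raw curves.
#'
#' @inheritParams effective_dose
#' @inheritParams administrable_activity
#' @param phantom Phantom table for the mass weightings.
#' @return One-row tibble with `effective_dose_uSv_per_MBq`,
#'   `effective_dose_equivalent_uSv_per_MBq`, `dose_limiting_organ`,
#'   `max_organ_dose_uSv_per_MBq` and the binding administrable activity
#'   columns.
#' @export
dose_report_from_organ_doses <- function(organ_dose,
                                         phantom = human_phantom(),
                                         limits = regulatory_limits(),
                                         per_scan_MBq = 185) {
  ed <- effective_dose(organ_dose, phantom = phantom)
  ede <- effective_dose_equivalent(organ_dose)
  adm <- administrable_activity(organ_dose, ed,
    limits = limits, per_scan_MBq = per_scan_MBq
  )
  binding <- adm |> filter(.data$binding)
  doses <- as_dose_vector(organ_dose)
  tibble(
    effective_dose_uSv_per_MBq = ed,
    effective_dose_equivalent_uSv_per_MBq = ede,
    dose_limiting_organ = dose_limiting_organ(organ_dose),
    max_organ_dose_uSv_per_MBq = max(doses[names(doses) != "total_body"]),
    binding_constraint = binding$constraint[1],
    binding_activity_MBq = binding$activity_MBq[1],
    binding_activity_GBq = binding$activity_GBq[1]
  )
}

#' @export
print.dose_report <- function(x, ...) {
  cat("<dose_report>\n")
  cat("  groups:", paste(unique(x$summary$group), collapse = ", "), "\n")
  for (i in seq_len(nrow(x$summary))) {
    s <- x$summary[i, ]
    cat(sprintf(
      "  %s: dose-limiting organ %s (%.3f uSv/MBq), ED %.3f, EDE %.3f uSv/MBq\n",
      s$group, s$dose_limiting_organ, s$max_organ_dose_uSv_per_MBq,
      s$effective_dose_uSv_per_MBq, s$effective_dose_equivalent_uSv_per_MBq
    ))
  }
  binding <- x$administrable |> filter(.data$binding)
  for (i in seq_len(nrow(binding))) {
    b <- binding[i, ]
    cat(sprintf(
      "  %s: binding constraint %s -> %.2f GBq\n",
      b$group, b$constraint, b$activity_GBq
    ))
  }
  invisible(x)
}

#' Write the tables of a dose report to disk
#'
#' Writes the measurement table, per-group mean curves, residence times
#' and organ doses as CSV, and the summary plus administrable-activity
#' table as JSON, into `dir`.
#'
#' @param report A `dose_report` from [run_dosimetry_pipeline()].
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_dose_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  readr::write_csv(report$measurements, file.path(dir, "measurements.csv"))
  readr::write_csv(report$curves, file.path(dir, "uptake_curves.csv"))
  readr::write_csv(report$residence_times, file.path(dir, "residence_times.csv"))
  readr::write_csv(report$organ_doses, file.path(dir, "organ_doses.csv"))
  jsonlite::write_json(
    list(
      summary = report$summary,
      administrable = report$administrable
    ),
    file.path(dir, "dose_report.json"),
    dataframe = "rows", auto_unbox = TRUE, digits = NA
  )
  invisible(dir)
}

#' Read a long-format biodistribution CSV
#'
#' @param path CSV in the [generate_cohort()] schema (or with raw counts
#'   columns to be quantified).
#' @return Tibble of measurements.
#' @export
read_biodistribution <- function(path) {
  readr::read_csv(path, show_col_types = FALSE)
}
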