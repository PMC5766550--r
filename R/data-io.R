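#' Published human organ-dose coefficients for 64Cu-pembrolizumab
#'
#' Per-organ total dose coefficients (uSv/MBq, mean and SD) reported in
#' a published preclinical dosimetry study of the 64Cu-pembrolizumab
#' immunoPET tracer, estimated there with OLINDA/EXM 1.2 from
#' PET/CT-ROI-based and ex-vivo biodistribution of blocked ("blk") and
#' non-blocked ("nblk") cohorts of a humanised melanoma mouse model.
#' These values are inputs for the report-only entry point
#' ([dose_report_from_organ_doses()]): the tissue weighting and
#' administrable-activity logic can be exercised against them without
#' raw curves.
#'
#' @param method `"pet"` (PET/CT ROI) or `"exvivo"`.
#' @param group Cohort, `"blk"` or `"nblk"`.
#' @return Tibble with `organ`, `dose_uSv_per_MBq`, `sd_uSv_per_MBq` for
#'   the chosen column (24 organs plus `total_body`).
#' @export
organ_dose_table <- function(method = c("pet", "exvivo"),
                             group = c("blk", "nblk")) {
  method <- match.arg(method)
  group <- match.arg(group)
  readr::read_csv(
    system.file("extdata", "cu64_pembrolizumab_organ_doses.csv",
      package = "cudosim", mustWork = TRUE
    ),
    show_col_types = FALSE
  ) |>
    filter(.data$method == !!method, .data$group == !!group) |>
    select("organ", "dose_uSv_per_MBq", "sd_uSv_per_MBq")
}
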