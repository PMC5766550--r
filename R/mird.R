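#' S-value matrices
#'
#' An S value is the equivalent dose rate to a target region per unit
#' activity in a source region, tabulated for a phantom and a
#' radionuclide; the package consumes them as data in
#' mSv/(MBq h). `as_svalue_matrix()` validates a long-format table
#' (columns `target`, `source`, `S_mSv_per_MBq_h`): values must be
#' non-negative and every target that also appears as a source must have
#' a positive self-dose entry. `read_svalue_matrix()` reads such a table
#' from CSV; `cu64_svalues()` loads the small synthetic copper-64
#' adult-male matrix shipped for tests and examples (see the file
#' `svalues_cu64_adult_male_synthetic.csv` and the methods vignette:
#' these are physics-informed surrogate values, not a published
#' tabulation).
#'
#' @param x Data frame with columns `target`, `source`,
#'   `S_mSv_per_MBq_h`.
#' @param path Path to a CSV file with those columns.
#' @return A validated tibble of S values.
#' @export
as_svalue_matrix <- function(x) {
  s <- as_tibble(x)
  need <- c("target", "source", "S_mSv_per_MBq_h")
  if (!all(need %in% names(s))) {
    abort("S-value table needs columns `target`, `source`, `S_mSv_per_MBq_h`.")
  }
  if (any(s$S_mSv_per_MBq_h < 0)) abort("S values must be non-negative.")
  if (anyDuplicated(s[c("target", "source")])) {
    abort("Duplicate (target, source) pairs in S-value table.")
  }
  for (tg in unique(s$target)) {
    self <- s$S_mSv_per_MBq_h[s$target == tg & s$source == tg]
    if (tg %in% s$source && (length(self) == 0 || self <= 0)) {
      abort(paste0("Target `", tg, "` lacks a positive self-dose entry."))
    }
  }
  s
}

#' @rdname as_svalue_matrix
#' @export
read_svalue_matrix <- function(path) {
  as_svalue_matrix(readr::read_csv(path, show_col_types = FALSE))
}

#' @rdname as_svalue_matrix
#' @export
cu64_svalues <- function() {
  read_svalue_matrix(system.file("extdata",
    "svalues_cu64_adult_male_synthetic.csv",
    package = "cudosim", mustWork = TRUE
  ))
}

#' Absorbed dose coefficients per target organ (MIRD schema)
#'
#' \deqn{D_T = \sum_S \tau_S \, S(T \leftarrow S)} for every target in
#' the S-value table, converted to uSv/MBq. Linear in the residence
#' times. Every source in `taus` must be present in the S-value table;
#' unmapped sources raise an error naming the offending pair rather than
#' being dropped.
#'
#' @param taus Tibble of residence times with columns `organ` (source
#'   region) and `tau_h` (hours), e.g. from [human_residence_times()].
#'   Rows sharing a source region are summed.
#' @param svalues S-value table, see [as_svalue_matrix()].
#' @return Tibble with columns `organ` (target) and `dose_uSv_per_MBq`.
#' @export
organ_doses <- function(taus, svalues) {
  svalues <- as_svalue_matrix(svalues)
  src <- taus |>
    group_by(organ = .data$organ) |>
    summarise(tau_h = sum(.data$tau_h), .groups = "drop")
  missing <- setdiff(src$organ, unique(svalues$source))
  if (length(missing)) {
    abort(paste0(
      "Source region(s) absent from the S-value table: ",
      paste(missing, collapse = ", ")
    ))
  }
  svalues |>
    inner_join(src, by = c(source = "organ")) |>
    group_by(organ = .data$target) |>
    summarise(
      dose_uSv_per_MBq = 1000 * sum(.data$S_mSv_per_MBq_h * .data$tau_h),
      .groups = "drop"
    )
}

#' Tissue weighting schemes for effective dose
#'
#' Two schemes are shipped:
#'
#' * `"ICRP60_ED"` — the ICRP Publication 60 effective dose: named
#'   tissue weights (gonads 0.20; red marrow, colon, lungs, stomach each
#'   0.12; bladder, breasts, liver, esophagus, thyroid each 0.05; skin
#'   and bone surface each 0.01) plus a 0.05 remainder taken as the
#'   mass-weighted mean dose of the remainder organs.
#' * `"ICRP26_EDE"` — the ICRP Publication 26 effective dose equivalent:
#'   gonads 0.25, breasts 0.15, red marrow and lungs 0.12, thyroid and
#'   bone surface 0.03, plus 0.06 for each of the five highest-dose
#'   remaining organs.
#'
#' Organ aliases map reported organs onto scheme tissues: the colon dose
#' is the organ-mass-weighted combination of the upper and lower large
#' intestine walls, the thymus stands in for the esophagus, the gonad
#' dose is taken from the testes (falling back to the ovaries), and
#' "osteogenic cells" are the bone surface.
#'
#' @param scheme_id `"ICRP60_ED"` or `"ICRP26_EDE"`.
#' @return List with elements `scheme_id`, `weights` (named numeric),
#'   `remainder_rule`, `remainder_weight`, `remainder_organs` /
#'   `excluded_from_remainder`, and `aliases`.
#' @export
tissue_weight_scheme <- function(scheme_id = c("ICRP60_ED", "ICRP26_EDE")) {
  scheme_id <- match.arg(scheme_id)
  aliases <- list(
    colon = c("uli_wall", "lli_wall"),
    esophagus = "thymus",
    gonads = c("testes", "ovaries"),
    bone_surface = "osteogenic_cells",
    stomach = "stomach_wall",
    urinary_bladder = "urinary_bladder_wall"
  )
  if (scheme_id == "ICRP60_ED") {
    list(
      scheme_id = scheme_id,
      weights = c(
        gonads = 0.20, red_marrow = 0.12, colon = 0.12, lungs = 0.12,
        stomach = 0.12, urinary_bladder = 0.05, breasts = 0.05,
        liver = 0.05, esophagus = 0.05, thyroid = 0.05,
        skin = 0.01, bone_surface = 0.01
      ),
      remainder_rule = "mass_weighted_mean",
      remainder_weight = 0.05,
      remainder_organs = c(
        "adrenals", "brain", "small_intestine", "kidneys",
        "muscle", "pancreas", "spleen", "uterus"
      ),
      aliases = aliases
    )
  } else {
    list(
      scheme_id = scheme_id,
      weights = c(
        gonads = 0.25, breasts = 0.15, red_marrow = 0.12,
        lungs = 0.12, thyroid = 0.03, bone_surface = 0.03
      ),
      remainder_rule = "top5_at_0.06",
      remainder_weight = 0.06,
      excluded_from_remainder = c("skin", "total_body"),
      aliases = aliases
    )
  }
}

#' Read a tissue weighting scheme from YAML
#'
#' Accepts a YAML file mirroring the structure returned by
#' [tissue_weight_scheme()] (the two shipped schemes are also available
#' as YAML under `inst/extdata/`).
#'
#' @param path Path to a YAML scheme file.
#' @return A scheme list as from [tissue_weight_scheme()].
#' @export
read_weight_scheme <- function(path) {
  s <- yaml::read_yaml(path)
  s$weights <- unlist(s$weights)
  s$aliases <- lapply(s$aliases, unlist)
  s
}

# Resolve the dose of one scheme tissue from a named organ-dose vector,
# applying aliases. Returns NA when no aliased organ is reported.
resolve_tissue_dose <- function(tissue, doses, aliases, phantom) {
  if (tissue %in% names(doses)) {
    return(unname(doses[tissue]))
  }
  al <- aliases[[tissue]]
  if (is.null(al)) {
    return(NA_real_)
  }
  present <- al[al %in% names(doses)]
  if (!length(present)) {
    return(NA_real_)
  }
  if (tissue == "colon") {
    w <- phantom_mass(phantom, present)
    return(sum(doses[present] * w) / sum(w))
  }
  unname(doses[present[1]])
}

as_dose_vector <- function(organ_dose) {
  if (is.data.frame(organ_dose)) {
    setNames(organ_dose$dose_uSv_per_MBq, organ_dose$organ)
  } else {
    organ_dose
  }
}

#' Effective dose (ICRP-60 weighting)
#'
#' Tissue-weighted sum of organ dose coefficients,
#' \eqn{ED = \sum_T w_T H_T}, under the ICRP-60 scheme: aliases are
#' applied (mass-weighted ULI/LLI colon, thymus-for-esophagus), the
#' remainder is the organ-mass-weighted mean dose of the remainder
#' organs, and scheme tissues with no reported dose contribute zero with
#' a warning. The named weights plus the remainder weight must sum to 1.
#'
#' @param organ_dose Tibble with columns `organ` and `dose_uSv_per_MBq`
#'   (or a named numeric vector).
#' @param scheme A scheme from [tissue_weight_scheme()] (must be
#'   `"ICRP60_ED"`).
#' @param phantom Phantom table for the mass weighting.
#' @return Effective dose in uSv/MBq (scalar).
#' @export
effective_dose <- function(organ_dose,
                           scheme = tissue_weight_scheme("ICRP60_ED"),
                           phantom = human_phantom()) {
  if (scheme$scheme_id != "ICRP60_ED") {
    abort("`effective_dose()` expects the ICRP60_ED scheme.")
  }
  total_w <- sum(scheme$weights) + scheme$remainder_weight
  if (abs(total_w - 1) > 1e-8) abort("Scheme weights must sum to 1.")
  doses <- as_dose_vector(organ_dose)
  h <- vapply(names(scheme$weights), resolve_tissue_dose,
    numeric(1),
    doses = doses, aliases = scheme$aliases, phantom = phantom
  )
  if (anyNA(h)) {
    warn(paste0(
      "No reported dose for tissue(s), counted as 0: ",
      paste(names(h)[is.na(h)], collapse = ", ")
    ))
    h[is.na(h)] <- 0
  }
  rem <- intersect(scheme$remainder_organs, names(doses))
  remainder <- if (length(rem)) {
    w <- phantom_mass(phantom, rem)
    sum(doses[rem] * w) / sum(w)
  } else {
    0
  }
  sum(scheme$weights * h) + scheme$remainder_weight * remainder
}

#' Effective dose equivalent (ICRP-26 weighting)
#'
#' \eqn{EDE = \sum_T w_T H_T + 0.06 \sum_{5} H}, where the second sum
#' runs over the five highest-dose organs not already carrying a named
#' weight (skin and total body are never candidates). With fewer than
#' five candidates all of them are used, with a warning.
#'
#' @inheritParams effective_dose
#' @param scheme A scheme from [tissue_weight_scheme()] (must be
#'   `"ICRP26_EDE"`).
#' @return Effective dose equivalent in uSv/MBq (scalar).
#' @export
effective_dose_equivalent <- function(organ_dose,
                                      scheme = tissue_weight_scheme("ICRP26_EDE")) {
  if (scheme$scheme_id != "ICRP26_EDE") {
    abort("`effective_dose_equivalent()` expects the ICRP26_EDE scheme.")
  }
  doses <- as_dose_vector(organ_dose)
  phantom <- human_phantom()
  h <- vapply(names(scheme$weights), resolve_tissue_dose,
    numeric(1),
    doses = doses, aliases = scheme$aliases, phantom = phantom
  )
  if (anyNA(h)) {
    warn(paste0(
      "No reported dose for tissue(s), counted as 0: ",
      paste(names(h)[is.na(h)], collapse = ", ")
    ))
    h[is.na(h)] <- 0
  }
  named_organs <- unique(c(
    names(scheme$weights),
    unlist(scheme$aliases[names(scheme$weights)], use.names = FALSE)
  ))
  candidates <- doses[!names(doses) %in%
    c(named_organs, scheme$excluded_from_remainder)]
  if (length(candidates) < 5) {
    warn("Fewer than five remainder candidates; using all of them.")
  }
  top <- sort(candidates, decreasing = TRUE)[seq_len(min(5, length(candidates)))]
  sum(scheme$weights * h) + scheme$remainder_weight * sum(top)
}

#' Dose-limiting organ
#'
#' The target organ with the highest absorbed dose coefficient; ties are
#' broken lexicographically so the result is deterministic. The
#' `total_body` entry, if present, is not an organ and is ignored.
#'
#' @inheritParams effective_dose
#' @return Organ name (character scalar).
#' @export
dose_limiting_organ <- function(organ_dose) {
  doses <- as_dose_vector(organ_dose)
  doses <- doses[names(doses) != "total_body"]
  if (!length(doses)) abort("`organ_dose` must be non-empty.")
  nm <- names(doses)[order(-doses, names(doses))]
  nm[1]
}

#' Regulatory dose limits for research subjects
#'
#' Annual and single-study limits: 50 mSv annual / 30 mSv single-study
#' for the whole body (and gonads, blood-forming organs, lens of the
#' eye), and 150 mSv annual / 50 mSv single-study for all other organs.
#'
#' @param whole_body_annual_mSv,whole_body_single_mSv,other_organ_annual_mSv,other_organ_single_mSv
#'   Limits in mSv.
#' @return List of class `"regulatory_limits"`.
#' @export
regulatory_limits <- function(whole_body_annual_mSv = 50,
                              whole_body_single_mSv = 30,
                              other_organ_annual_mSv = 150,
                              other_organ_single_mSv = 50) {
  if (whole_body_single_mSv > whole_body_annual_mSv ||
    other_organ_single_mSv > other_organ_annual_mSv) {
    abort("Single-study limits must not exceed annual limits.")
  }
  structure(
    list(
      whole_body_annual_mSv = whole_body_annual_mSv,
      whole_body_single_mSv = whole_body_single_mSv,
      other_organ_annual_mSv = other_organ_annual_mSv,
      other_organ_single_mSv = other_organ_single_mSv
    ),
    class = "regulatory_limits"
  )
}

#' Maximum administrable activity under regulatory limits
#'
#' For each limit the administrable activity is the limit divided by the
#' governing dose coefficient: organ limits divide by the maximum organ
#' dose coefficient (the dose-limiting organ), whole-body limits divide
#' by the effective dose. The binding constraint is the minimum. The
#' number of scans allowed per year at a given per-scan activity is
#' derived from the binding annual constraint.
#'
#' @inheritParams effective_dose
#' @param effective_dose_uSv_per_MBq Effective dose coefficient,
#'   uSv/MBq.
#' @param limits A [regulatory_limits()].
#' @param per_scan_MBq Planned activity per scan, MBq (default 185 MBq).
#' @return Tibble with one row per constraint: `constraint`, `limit_mSv`,
#'   `coefficient_uSv_per_MBq`, `activity_MBq`, `activity_GBq` (rounded
#'   to 2 decimals), `binding`; attribute `scans_per_year`.
#' @examples
#' administrable_activity(tibble::tibble(
#'   organ = "liver",
#'   dose_uSv_per_MBq = 35.15
#' ), effective_dose_uSv_per_MBq = 2.37)
#' @export
administrable_activity <- function(organ_dose, effective_dose_uSv_per_MBq,
                                   limits = regulatory_limits(),
                                   per_scan_MBq = 185) {
  doses <- as_dose_vector(organ_dose)
  max_organ <- max(doses[names(doses) != "total_body"])
  if (max_organ <= 0 || effective_dose_uSv_per_MBq <= 0) {
    abort("Dose coefficients must be positive.")
  }
  out <- tibble(
    constraint = c(
      "organ_single_study", "organ_annual",
      "whole_body_single_study", "whole_body_annual"
    ),
    limit_mSv = c(
      limits$other_organ_single_mSv, limits$other_organ_annual_mSv,
      limits$whole_body_single_mSv, limits$whole_body_annual_mSv
    ),
    coefficient_uSv_per_MBq = c(
      max_organ, max_organ,
      effective_dose_uSv_per_MBq, effective_dose_uSv_per_MBq
    )
  ) |>
    mutate(
      activity_MBq = 1000 * .data$limit_mSv / .data$coefficient_uSv_per_MBq,
      activity_GBq = round(.data$activity_MBq / 1000, 2),
      binding = .data$activity_MBq == min(.data$activity_MBq)
    )
  annual <- out |> filter(grepl("annual", .data$constraint))
  attr(out, "scans_per_year") <- floor(min(annual$activity_MBq) / per_scan_MBq)
  out
}
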