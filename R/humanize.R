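#' Animal context for interspecies scaling
#'
#' Body mass and organ masses of the measured animal. Only the body mass
#' enters the relative-organ-mass scaling; organ masses are carried for
#' per-organ %ID bookkeeping.
#'
#' @param body_mass_g Mouse body mass, grams (default 23 g).
#' @param organ_mass_g Named numeric vector of organ masses, grams.
#' @return List of class `"animal_context"`.
#' @export
animal_context <- function(body_mass_g = 23.0,
                           organ_mass_g = mouse_organ_masses(body_mass_g)) {
  if (body_mass_g <= 0 || any(organ_mass_g <= 0)) {
    abort("Masses must be positive.")
  }
  structure(
    list(body_mass_g = body_mass_g, organ_mass_g = organ_mass_g),
    class = "animal_context"
  )
}

#' Read a human phantom organ-mass table
#'
#' A phantom is a tibble with columns `organ` and `mass_g`, one row per
#' organ plus a `total_body` row. [human_phantom()] loads the reference
#' adult-male phantom shipped with the package (73,700 g body mass,
#' standard anthropomorphic organ masses).
#'
#' @param path Path to a CSV file with columns `organ`, `mass_g`.
#' @return Tibble with columns `organ`, `mass_g`.
#' @export
read_phantom <- function(path) {
  p <- readr::read_csv(path, show_col_types = FALSE)
  if (!all(c("organ", "mass_g") %in% names(p))) {
    abort("Phantom file needs `organ` and `mass_g` columns.")
  }
  if (any(p$mass_g <= 0)) abort("Phantom masses must be positive.")
  if (!"total_body" %in% p$organ) abort("Phantom needs a `total_body` row.")
  total <- p$mass_g[p$organ == "total_body"]
  if (sum(p$mass_g[p$organ != "total_body"]) > total) {
    abort("Phantom organ masses exceed the total body mass.")
  }
  as_tibble(p)
}

#' @rdname read_phantom
#' @export
human_phantom <- function() {
  read_phantom(system.file("extdata", "phantom_adult_male.csv",
    package = "cudosim", mustWork = TRUE
  ))
}

phantom_mass <- function(phantom, organ) {
  i <- match(organ, phantom$organ)
  if (anyNA(i)) {
    abort(paste0(
      "Organ(s) missing from phantom: ",
      paste(organ[is.na(i)], collapse = ", ")
    ))
  }
  phantom$mass_g[i]
}

#' Mouse-to-human uptake scaling by relative organ mass
#'
#' Converts mouse %ID/g to the human-equivalent percent of injected dose
#' in the whole organ by the relative-organ-mass (Kirschner-type)
#' extrapolation:
#' \deqn{(\%ID/organ)_{human} = (\%ID/g)_{mouse} \times M_{body,mouse}
#'   \times \frac{M_{organ,human}}{M_{body,human}}}
#' with all masses in grams. Applied pointwise over a curve this
#' preserves sampling times and the decay-correction state, and it is
#' linear in the uptake, so scaling commutes with time integration.
#'
#' @param pid_per_g Mouse %ID/g values.
#' @param organ Organ name(s), matched against the phantom table.
#' @param animal An [animal_context()].
#' @param phantom A phantom tibble, see [human_phantom()].
#' @return Human-equivalent %ID per organ.
#' @examples
#' kirschner_scale(7, "liver") # 7 * 23 * 1910 / 73700
#' @export
kirschner_scale <- function(pid_per_g, organ, animal = animal_context(),
                            phantom = human_phantom()) {
  m_organ <- phantom_mass(phantom, organ)
  m_body <- phantom_mass(phantom, "total_body")
  pid_per_g * animal$body_mass_g * m_organ / m_body
}

#' Human-equivalent residence times from mouse uptake curves
#'
#' Composes the relative-organ-mass scaling with trapezoidal time
#' integration: mouse %ID/g curves are converted pointwise to
#' human-equivalent organ fractions of the injected dose, then
#' integrated per organ with [integrate_tia()]. Organs absent from the
#' phantom (e.g. `tumor`) cannot be scaled; they are excluded with a
#' warning and listed in the `excluded_organs` attribute.
#'
#' @param curves Tibble of mouse uptake curves with columns `organ`,
#'   `time_h`, `pid_per_g`, `decay_corrected` and optional grouping
#'   columns.
#' @inheritParams kirschner_scale
#' @inheritParams residence_times
#' @return Tibble of human residence times (`organ`, `tau_h`,
#'   `tail_mode`, plus grouping columns), with attribute
#'   `excluded_organs`.
#' @export
human_residence_times <- function(curves, animal = animal_context(),
                                  phantom = human_phantom(),
                                  tail_mode = c("physical_decay", "zero", "fitted_exp"),
                                  half_life_h = CU64_HALF_LIFE_H,
                                  by = intersect("group", names(curves))) {
  tail_mode <- match.arg(tail_mode)
  excluded <- setdiff(unique(curves$organ), phantom$organ)
  if (length(excluded)) {
    warn(paste0(
      "Organ(s) not in the phantom excluded from human scaling: ",
      paste(excluded, collapse = ", ")
    ))
  }
  scaled <- curves |>
    filter(!.data$organ %in% excluded) |>
    mutate(
      fraction = kirschner_scale(.data$pid_per_g, .data$organ,
        animal = animal, phantom = phantom
      ) / 100
    )
  out <- residence_times(scaled,
    tail_mode = tail_mode,
    half_life_h = half_life_h, by = by
  )
  attr(out, "excluded_organs") <- excluded
  out
}

#' Default mapping of measured organs onto phantom source regions
#'
#' Measured compartments do not always coincide with phantom source
#' regions: the heart ROI of an intact antibody tracer is dominated by
#' blood, so both `heart` and `blood` map onto the `heart_contents`
#' source. All other organs map onto the source of the same name.
#'
#' @return Named character vector: `names()` are measured organs,
#'   values are phantom source regions.
#' @export
default_source_map <- function() {
  c(heart = "heart_contents", blood = "heart_contents")
}

#' Rename measured organs to phantom source regions
#'
#' @param x Tibble with an `organ` column.
#' @param map Named character vector as in [default_source_map()];
#'   organs not named in the map are left unchanged.
#' @return `x` with `organ` renamed. If two measured organs map onto the
#'   same source for the same grouping, a warning is raised (their
#'   contributions will be summed downstream).
#' @export
map_sources <- function(x, map = default_source_map()) {
  hit <- x$organ %in% names(map)
  new <- x$organ
  new[hit] <- unname(map[x$organ[hit]])
  n_sources <- length(unique(new))
  if (n_sources < length(unique(x$organ))) {
    warn("Several measured organs map onto one source; contributions add.")
  }
  x$organ <- new
  x
}
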