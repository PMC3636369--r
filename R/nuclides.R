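#' Radioactive decay constant
#'
#' @param half_life half-life in years, > 0.
#' @return decay constant lambda = ln(2) / half-life, per year.
#' @examples
#' decay_constant(1600)    # Ra-226 order of magnitude, ~4.33e-4 /a
#' decay_constant(1.57e7)  # I-129 order of magnitude, ~4.4e-8 /a
#' @export
decay_constant <- function(half_life) {
  if (!is.numeric(half_life) || any(is.na(half_life)) || any(half_life <= 0))
    stop("half-life must be a positive number of years", call. = FALSE)
  log(2) / half_life
}

#' Dose coefficients for a radionuclide
#'
#' Conversion factors from intake or ambient concentration to effective
#' dose for an adult. Treated as constants (no probability distribution).
#'
#' @param ingestion Sv per Bq ingested.
#' @param inhalation Sv per Bq inhaled.
#' @param external_soil (Sv/a) per (Bq/kg dw) in surface soil.
#' @param external_water_immersion (Sv/a) per (Bq/m3) in water.
#' @return object of class `dose_coefficients`.
#' @export
dose_coefficients <- function(ingestion = 0, inhalation = 0,
                              external_soil = 0, external_water_immersion = 0) {
  for (v in c("ingestion", "inhalation", "external_soil", "external_water_immersion"))
    check_scalar(get(v), v, min = 0)
  structure(list(ingestion = ingestion, inhalation = inhalation,
                 external_soil = external_soil,
                 external_water_immersion = external_water_immersion),
            class = "dose_coefficients")
}

#' Element-specific sorption and uptake properties
#'
#' Distribution coefficients (Kd, m3/kg dw) quantify the equilibrium
#' partitioning of a radionuclide between pore water and the solid phase
#' of a compartment; concentration ratios (CR) quantify the equilibrium
#' concentration in newly produced biomass relative to its environmental
#' medium (kg dw soil per kg C for terrestrial producers and foods,
#' m3 per kg C for aquatic).
#'
#' @param kd named list/vector: medium id -> Kd (m3/kg dw), >= 0. Media used
#'   by the compartment model: `regolith_low`, `regolith_mid`, `regolith_up`,
#'   `water` (suspended particles). Missing media default to 0 on lookup
#'   unless `strict` validation is requested at library level.
#' @param cr named list/vector: biota type -> CR, >= 0. Biota types used by
#'   the dose model: `ter_producer`, `aqu_producer`, `crops`, `aquatic_food`.
#' @param degassing_rate first-order volatilisation rate (per year) from
#'   surface water and upper terrestrial regolith to the atmosphere;
#'   0 for non-volatile elements.
#' @return object of class `element_properties`.
#' @export
element_properties <- function(kd = list(), cr = list(), degassing_rate = 0) {
  kd <- as.list(kd); cr <- as.list(cr)
  for (m in names(kd)) check_scalar(kd[[m]], paste0("kd.", m), min = 0)
  for (b in names(cr)) check_scalar(cr[[b]], paste0("cr.", b), min = 0)
  check_scalar(degassing_rate, "degassing_rate", min = 0)
  structure(list(kd = kd, cr = cr, degassing_rate = degassing_rate),
            class = "element_properties")
}

kd_of <- function(element, medium) {
  v <- element$kd[[medium]]
  if (is.null(v)) 0 else v
}

cr_of <- function(element, biota) {
  v <- element$cr[[biota]]
  if (is.null(v)) stop(sprintf("no CR value for biota type '%s'", biota), call. = FALSE)
  v
}

#' Define a radionuclide
#'
#' @param name identifier (e.g. "Ra226syn").
#' @param half_life years, > 0.
#' @param element an [element_properties()] object.
#' @param dose_coeff a [dose_coefficients()] object.
#' @param parent identifier of the parent nuclide, or NULL for a chain head.
#' @param branching_fraction fraction of parent decays producing this
#'   nuclide, in (0, 1]; default 1 (linear chains).
#' @return object of class `radionuclide`.
#' @export
radionuclide <- function(name, half_life, element,
                         dose_coeff = dose_coefficients(),
                         parent = NULL, branching_fraction = 1) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  check_scalar(half_life, "half_life", min = 0, strict = TRUE)
  if (!inherits(element, "element_properties")) stop("element must be element_properties", call. = FALSE)
  if (!inherits(dose_coeff, "dose_coefficients")) stop("dose_coeff must be dose_coefficients", call. = FALSE)
  check_scalar(branching_fraction, "branching_fraction", min = 0, strict = TRUE)
  if (branching_fraction > 1) stop("branching_fraction must be in (0, 1]", call. = FALSE)
  structure(list(name = name, half_life = half_life,
                 lambda = decay_constant(half_life),
                 element = element, dose_coeff = dose_coeff,
                 parent = parent, branching_fraction = branching_fraction),
            class = "radionuclide")
}

#' Build a nuclide library
#'
#' Validates chain links: every named parent exists, the parent graph is
#' acyclic, and branching fractions out of any parent sum to at most 1.
#'
#' @param ... `radionuclide` objects.
#' @return object of class `nuclide_library` (named list of radionuclides).
#' @export
nuclide_library <- function(...) {
  nucs <- list(...)
  if (length(nucs) == 1L && is.list(nucs[[1]]) && !inherits(nucs[[1]], "radionuclide"))
    nucs <- nucs[[1]]
  if (!all(vapply(nucs, inherits, logical(1), "radionuclide")))
    stop("all entries must be radionuclide objects", call. = FALSE)
  names(nucs) <- vapply(nucs, `[[`, character(1), "name")
  if (anyDuplicated(names(nucs))) stop("duplicate nuclide names", call. = FALSE)

  pr <- new_problems()
  for (n in nucs) {
    if (!is.null(n$parent) && !n$parent %in% names(nucs))
      add_problem(pr, "nuclide '%s' names missing parent '%s'", n$name, n$parent)
  }
  # branching sums per parent
  parents <- vapply(nucs, function(n) n$parent %||% NA_character_, character(1))
  for (p in unique(stats::na.omit(parents))) {
    bsum <- sum(vapply(nucs[which(parents == p)], `[[`, numeric(1), "branching_fraction"))
    if (bsum > 1 + 1e-12)
      add_problem(pr, "branching fractions out of '%s' sum to %g > 1", p, bsum)
  }
  # acyclicity by walking parent links
  for (n in nucs) {
    seen <- character(0); cur <- n$name
    while (!is.null(cur)) {
      if (cur %in% seen) { add_problem(pr, "decay chain cycle involving '%s'", cur); break }
      seen <- c(seen, cur)
      cur <- if (cur %in% names(nucs)) nucs[[cur]]$parent else NULL
    }
  }
  report_problems(pr, "nuclide library validation")
  structure(nucs, class = "nuclide_library")
}

#' Extract a decay chain in parent-before-daughter order
#'
#' @param library a [nuclide_library()].
#' @param head identifier of the released (chain head) nuclide.
#' @return character vector of nuclide names, topologically ordered so every
#'   parent precedes its daughters, starting at `head`.
#' @export
build_chain <- function(library, head) {
  if (!head %in% names(library)) stop(sprintf("nuclide '%s' not in library", head), call. = FALSE)
  parents <- lapply(library, `[[`, "parent")
  chain <- head
  repeat {
    daughters <- names(library)[vapply(parents, function(p) !is.null(p) && p %in% chain, logical(1))]
    new <- setdiff(daughters, chain)
    if (!length(new)) break
    chain <- c(chain, new)
    if (length(chain) > length(library)) stop("decay chain cycle detected", call. = FALSE)
  }
  chain
}

#' @export
print.nuclide_library <- function(x, ...) {
  cat(sprintf("<nuclide_library> %d nuclide(s)\n", length(x)))
  for (n in x) {
    cat(sprintf("  %-10s T1/2 = %-10.4g a  lambda = %-10.4g /a  parent = %s\n",
                n$name, n$half_life, n$lambda, n$parent %||% "-"))
  }
  invisible(x)
}
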