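# Synthetic fixture generators: a two-nuclide reference library and a
# coastal landscape of succeeding biosphere objects. All values are
# synthetic, order-of-magnitude-plausible choices (documented in the
# package vignette); they are not site data.

#' Synthetic two-nuclide reference library
#'
#' A mobile, very long-lived iodine-like nuclide ("I129syn", half-life
#' 1.57e7 a, low Kd) and a sorbing, shorter-lived radium-like nuclide
#' ("Ra226syn", half-life 1600 a, high Kd). Kd/CR and dose-coefficient
#' values are synthetic but order-of-magnitude plausible for the two
#' elements; the pair is designed so the contrast between Kd retardation
#' plus decay losses (Ra-like) and mobile transit (I-like) is visible in
#' surface-water concentrations per unit release.
#'
#' @return a [nuclide_library()] with nuclides `I129syn` and `Ra226syn`.
#' @export
reference_nuclides <- function() {
  iodine <- element_properties(
    kd = list(regolith_low = 5e-4, regolith_mid = 2e-3, regolith_up = 5e-3, water = 1e-3),
    cr = list(ter_producer = 0.05, aqu_producer = 0.3, crops = 0.05, aquatic_food = 0.5))
  radium <- element_properties(
    kd = list(regolith_low = 2, regolith_mid = 5, regolith_up = 8, water = 5),
    cr = list(ter_producer = 0.02, aqu_producer = 0.2, crops = 0.02, aquatic_food = 0.2))
  nuclide_library(
    radionuclide("I129syn", half_life = 1.57e7, element = iodine,
                 dose_coeff = dose_coefficients(ingestion = 1.1e-7, inhalation = 3.6e-8,
                                                external_soil = 1e-9,
                                                external_water_immersion = 1e-11)),
    radionuclide("Ra226syn", half_life = 1600, element = radium,
                 dose_coeff = dose_coefficients(ingestion = 2.8e-7, inhalation = 3.5e-6,
                                                external_soil = 6e-7,
                                                external_water_immersion = 3e-10)))
}

# piecewise-linear series from stage weights: value = sum_s w_s(t) * v_s,
# sampled on the schedule knots (exact under linear interpolation between
# consecutive knots of the weight functions)
stage_series <- function(schedule, span, sea, lake, wetland, agricultural = wetland) {
  knots <- sort(unique(c(span, schedule_breaks(schedule))))
  knots <- knots[knots >= span[1] & knots <= span[2]]
  if (length(knots) < 2) knots <- span
  w <- stage_weights(schedule, knots)
  y <- w[, "sea"] * sea + w[, "lake"] * lake + w[, "wetland"] * wetland +
    w[, "agricultural"] * agricultural
  ts_series(knots, y)
}

# one synthetic biosphere object developing sea -> lake -> wetland
# (optionally -> agricultural land)
synthetic_object <- function(id, schedule, area_total = 2e5, span = c(-9000, 59600),
                             runoff = 0.2, deep_flux_density = 0.03,
                             deep_flux_sea_factor = 1e-3, jitter = 1) {
  A <- area_total * jitter
  f_aq <- function(sea, lake, wet) stage_series(schedule, span, sea, lake, wet)
  aq_frac <- f_aq(1, 0.3, 0.02)
  ter_frac <- ts_series(aq_frac$t, 1 - aq_frac$y)
  depth <- f_aq(5, 2, 0.5)
  knots <- aq_frac$t
  A_aq <- ts_series(knots, A * aq_frac$y)
  A_ter <- ts_series(knots, A * ter_frac$y)
  scale_ts <- function(s, f) ts_series(s$t, s$y * f)
  # regolith layers: (thickness m, dry bulk density kg/m3, porosity)
  geom <- function(area_s, thick, dens, por) {
    list(solid_mass = scale_ts(area_s, thick * dens),
         water_volume = scale_ts(area_s, thick * por),
         area = area_s, thickness = thick)
  }
  compartments <- list(
    REGOLITH_LOW = geom(ts_constant(A), 4, 1300, 0.35),
    AQU_REGOLITH_MID = geom(A_aq, 1.5, 400, 0.7),
    AQU_REGOLITH_UP = geom(A_aq, 0.1, 150, 0.8),
    TER_REGOLITH_MID = geom(A_ter, 1.5, 400, 0.7),
    TER_REGOLITH_UP = geom(A_ter, 0.3, 150, 0.8),
    LITTER = list(solid_mass = scale_ts(A_ter, 0.5), water_volume = 0,
                  area = A_ter, thickness = 0.05),
    WATER = list(solid_mass = 0,
                 water_volume = ts_series(knots, A * aq_frac$y * depth$y),
                 area = A_aq, thickness = depth),
    AQU_PP = list(area = A_aq), TER_PP = list(area = A_ter),
    ATMOSPHERE = list(area = ts_constant(A), thickness = 500))
  # vertical water fluxes: minute under the sea bed, substantial after
  # emergence; split between aquatic and terrestrial columns by area share
  q_deep <- f_aq(deep_flux_density * deep_flux_sea_factor,
                 deep_flux_density, deep_flux_density)
  Q_low <- ts_series(knots, q_deep$y * A)
  Q_aq <- ts_series(knots, q_deep$y * A * aq_frac$y)
  Q_ter <- ts_series(knots, q_deep$y * A * ter_frac$y)
  Q_runoff <- ts_series(knots, (q_deep$y + runoff) * A * ter_frac$y)
  water_fluxes <- list(
    list(from = "REGOLITH_LOW", to = "AQU_REGOLITH_MID", flux = Q_aq),
    list(from = "REGOLITH_LOW", to = "TER_REGOLITH_MID", flux = Q_ter),
    list(from = "AQU_REGOLITH_MID", to = "AQU_REGOLITH_UP", flux = Q_aq),
    list(from = "AQU_REGOLITH_UP", to = "WATER", flux = Q_aq),
    list(from = "TER_REGOLITH_MID", to = "TER_REGOLITH_UP", flux = Q_ter),
    list(from = "TER_REGOLITH_UP", to = "WATER", flux = Q_runoff))
  diffusion <- list(
    list(pair = c("REGOLITH_LOW", "AQU_REGOLITH_MID"), diffusivity = 1e-2, area = A_aq, length = 2.75),
    list(pair = c("AQU_REGOLITH_MID", "AQU_REGOLITH_UP"), diffusivity = 1e-2, area = A_aq, length = 0.8),
    list(pair = c("AQU_REGOLITH_UP", "WATER"), diffusivity = 1e-2, area = A_aq, length = 0.3),
    list(pair = c("REGOLITH_LOW", "TER_REGOLITH_MID"), diffusivity = 1e-2, area = A_ter, length = 2.75),
    list(pair = c("TER_REGOLITH_MID", "TER_REGOLITH_UP"), diffusivity = 1e-2, area = A_ter, length = 0.9))
  biosphere_object(
    id = id, compartments = compartments, water_fluxes = water_fluxes,
    diffusion = diffusion,
    sedimentation_flux = f_aq(0.2, 0.1, 0.02),
    resuspension_flux = f_aq(0.05, 0.02, 0),
    suspended_solids = f_aq(0.005, 0.003, 0.002),
    production = list(terrestrial = 0.2, aquatic = 0.15),
    biomass = list(terrestrial = 1, aquatic = 0.05),
    litter_decomposition_rate = 0.3, atmosphere_turnover = 1e3,
    aquatic_return_split = 0.5, schedule = schedule)
}

#' Generate a synthetic coastal landscape
#'
#' A chain of `n_objects` biosphere objects draining into an outer coastal
#' object and onward to the outlet sink. Objects start submerged at the
#' beginning of the temperate period, isolate at staggered times (500-year
#' isolation windows), develop into wetlands, and the first object is
#' optionally converted to agricultural land. During the sea stage each
#' object exchanges water in both directions with the coastal object;
#' after isolation it discharges along the downstream chain.
#'
#' @param n_objects number of succeeding objects (>= 1).
#' @param seed integer seed for the (mild, log-uniform) parameter jitter
#'   between objects; the generator is deterministic given the seed.
#' @param area_total object area, m2.
#' @param isolation_first year CE at which the first object starts
#'   isolating.
#' @param isolation_stagger years between successive objects' isolation.
#' @param isolation_window length of the isolation window, years.
#' @param agricultural if TRUE the first object converts to agricultural
#'   land 2000 years after isolation completes.
#' @param span simulated span, years CE (defaults to the full reference
#'   glacial cycle).
#' @return a [landscape()] with objects `obj1..objN` and `COAST`, outlet
#'   `BALTIC`.
#' @export
generate_landscape <- function(n_objects = 3, seed = 42, area_total = 2e5,
                               isolation_first = -6500, isolation_stagger = 1500,
                               isolation_window = 500, agricultural = TRUE,
                               span = c(-9000, 59600)) {
  stopifnot(n_objects >= 1)
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(seed)
  jitters <- 10^stats::runif(n_objects, -0.1, 0.1)

  objects <- vector("list", n_objects)
  for (i in seq_len(n_objects)) {
    iso <- isolation_first + (i - 1) * isolation_stagger
    agri <- if (agricultural && i == 1L) iso + isolation_window + 2000 else NULL
    sched <- succession_schedule(isolation_start = iso,
                                 isolation_end = iso + isolation_window,
                                 agricultural_from = agri)
    objects[[i]] <- synthetic_object(sprintf("obj%d", i), sched,
                                     area_total = area_total, span = span,
                                     jitter = jitters[i])
  }
  # outer coastal object: a large, permanently submerged basin
  coast_sched <- succession_schedule(isolation_start = span[2] + 1e5)
  coast <- synthetic_object("COAST", coast_sched, area_total = 1e7, span = span)

  discharge <- 2 * area_total  # runoff-driven discharge per object, m3/a
  edges <- list()
  for (i in seq_len(n_objects)) {
    to <- if (i < n_objects) sprintf("obj%d", i + 1) else "COAST"
    edges[[i]] <- list(from = sprintf("obj%d", i), to = to, flux = discharge * i)
  }
  edges[[n_objects + 1L]] <- list(from = "COAST", to = "BALTIC", flux = 1e9)
  exchange <- lapply(seq_len(n_objects), function(i) {
    list(object = sprintf("obj%d", i), coast = "COAST",
         flux_out = 20 * area_total, flux_in = 20 * area_total)
  })
  landscape(objects = c(objects, list(coast)), downstream_edges = edges,
            sea_exchange = exchange, outlet = "BALTIC")
}

#' A closed single-object landscape for analytic benchmarks
#'
#' One static object with all transport fluxes, production and particle
#' processes switched off: the only dynamics are radioactive decay and
#' chain ingrowth. Used to compare the numerical solver against the
#' analytic decay-chain solution.
#'
#' @param solid_mass,water_volume,area geometry given to every regolith
#'   compartment and the water column.
#' @return a [landscape()] with a single object `obj1` and no edges.
#' @export
closed_object_landscape <- function(solid_mass = 1e6, water_volume = 1e4, area = 1e4) {
  sched <- succession_schedule(isolation_start = 1e6)
  geom <- list(solid_mass = solid_mass, water_volume = water_volume,
               area = area, thickness = 1)
  compartments <- stats::setNames(rep(list(geom), length(COMPARTMENTS)), COMPARTMENTS)
  obj <- biosphere_object("obj1", compartments, schedule = sched)
  landscape(objects = list(obj), downstream_edges = list(), sea_exchange = list())
}
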