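#' Compartment identifiers of a biosphere object
#'
#' The ten compartments of one biosphere object: a common lower regolith
#' and atmosphere, an aquatic part (mid/upper regolith = sediments, surface
#' water, aquatic primary producers) and a terrestrial part (mid/upper
#' regolith, litter, terrestrial primary producers). A submerged object has
#' zero-size terrestrial compartments.
#'
#' @format character vector of length 10.
#' @export
COMPARTMENTS <- c("REGOLITH_LOW", "AQU_REGOLITH_MID", "AQU_REGOLITH_UP",
                  "TER_REGOLITH_MID", "TER_REGOLITH_UP", "LITTER",
                  "WATER", "AQU_PP", "TER_PP", "ATMOSPHERE")

# Kd medium used for each compartment; producers and atmosphere carry no
# solids. LITTER uses the upper terrestrial regolith Kd (organic layer).
COMPARTMENT_MEDIUM <- c(
  REGOLITH_LOW = "regolith_low", AQU_REGOLITH_MID = "regolith_mid",
  AQU_REGOLITH_UP = "regolith_up", TER_REGOLITH_MID = "regolith_mid",
  TER_REGOLITH_UP = "regolith_up", LITTER = "regolith_up",
  WATER = "water", AQU_PP = NA, TER_PP = NA, ATMOSPHERE = NA)

#' Define a biosphere object
#'
#' A biosphere object is an area of the landscape that can receive
#' radionuclide releases from the geosphere (into its lower regolith) or in
#' contaminated surface water from upstream objects. Its geometry, water
#' fluxes and ecosystem parameters are piecewise-linear time series on one
#' breakpoint grid, so the object develops continuously from sea bay
#' through lake and wetland to (optionally) agricultural land.
#'
#' @param id object identifier.
#' @param compartments named list over [COMPARTMENTS] (producers and
#'   ATMOSPHERE may omit solids); each entry a list with `ts_series` (or
#'   constants) `solid_mass` (kg dw), `water_volume` (m3), `area` (m2),
#'   `thickness` (m).
#' @param water_fluxes list of `list(from=, to=, flux=ts)` internal water
#'   fluxes in m3/a between compartments of this object.
#' @param diffusion list of `list(pair=c(i, j), diffusivity=, area=ts,
#'   length=)` diffusive connections.
#' @param sedimentation_flux,resuspension_flux kg dw/m2/a (`ts_series`).
#' @param suspended_solids kg dw/m3 in the water column (`ts_series`).
#' @param production list with `terrestrial` and `aquatic` primary
#'   production, kg C/m2/a (`ts_series`).
#' @param biomass list with `terrestrial` and `aquatic` standing producer
#'   biomass, kg C/m2 (`ts_series`).
#' @param litter_decomposition_rate /a, litter to upper terrestrial regolith.
#' @param atmosphere_turnover /a, ventilation of the atmosphere box.
#' @param aquatic_return_split fraction of the aquatic producer turnover
#'   returned to WATER (the rest goes to the upper aquatic sediment).
#' @param schedule a [succession_schedule()] for this object.
#' @return object of class `biosphere_object`.
#' @export
biosphere_object <- function(id, compartments, water_fluxes = list(),
                             diffusion = list(),
                             sedimentation_flux = 0, resuspension_flux = 0,
                             suspended_solids = 0,
                             production = list(terrestrial = 0, aquatic = 0),
                             biomass = list(terrestrial = 0, aquatic = 0),
                             litter_decomposition_rate = 0,
                             atmosphere_turnover = 0,
                             aquatic_return_split = 0.5,
                             schedule = NULL) {
  stopifnot(is.character(id), length(id) == 1L)
  pr <- new_problems()
  for (cmp in names(compartments)) {
    if (!cmp %in% COMPARTMENTS) add_problem(pr, "unknown compartment '%s'", cmp)
  }
  for (wf in water_fluxes) {
    if (!wf$from %in% COMPARTMENTS) add_problem(pr, "water flux from unknown compartment '%s'", wf$from)
    if (!wf$to %in% COMPARTMENTS) add_problem(pr, "water flux to unknown compartment '%s'", wf$to)
  }
  for (df in diffusion) {
    if (!all(df$pair %in% COMPARTMENTS)) add_problem(pr, "diffusion pair references unknown compartment")
  }
  if (aquatic_return_split < 0 || aquatic_return_split > 1)
    add_problem(pr, "aquatic_return_split must be in [0,1]")
  report_problems(pr, sprintf("biosphere object '%s'", id))

  # normalise all series
  norm_geom <- function(g) {
    list(solid_mass = as_ts(g$solid_mass %||% 0),
         water_volume = as_ts(g$water_volume %||% 0),
         area = as_ts(g$area %||% 0),
         thickness = as_ts(g$thickness %||% 0))
  }
  compartments <- lapply(compartments, norm_geom)
  for (cmp in setdiff(COMPARTMENTS, names(compartments)))
    compartments[[cmp]] <- norm_geom(list())
  compartments <- compartments[COMPARTMENTS]
  water_fluxes <- lapply(water_fluxes, function(wf) {
    wf$flux <- as_ts(wf$flux); wf
  })
  diffusion <- lapply(diffusion, function(df) {
    df$diffusivity <- as_ts(df$diffusivity); df$area <- as_ts(df$area); df
  })
  structure(list(
    id = id, compartments = compartments, water_fluxes = water_fluxes,
    diffusion = diffusion,
    sedimentation_flux = as_ts(sedimentation_flux),
    resuspension_flux = as_ts(resuspension_flux),
    suspended_solids = as_ts(suspended_solids),
    production = lapply(production, as_ts),
    biomass = lapply(biomass, as_ts),
    litter_decomposition_rate = litter_decomposition_rate,
    atmosphere_turnover = atmosphere_turnover,
    aquatic_return_split = aquatic_return_split,
    schedule = schedule), class = "biosphere_object")
}

# Precompiled parameter table of an object: every time-varying quantity
# sampled on the union of its breakpoints, so one interpolation per query
# time yields all values at once. Rebuilt per simulation (objects may have
# been modified between runs).
compile_object <- function(o) {
  specs <- list()
  for (cmp in COMPARTMENTS) {
    g <- o$compartments[[cmp]]
    for (f in c("solid_mass", "water_volume", "area", "thickness"))
      specs[[paste(cmp, f, sep = ".")]] <- g[[f]]
  }
  for (j in seq_along(o$water_fluxes)) specs[[paste0("wf", j)]] <- o$water_fluxes[[j]]$flux
  for (j in seq_along(o$diffusion)) {
    specs[[paste0("diffD", j)]] <- o$diffusion[[j]]$diffusivity
    specs[[paste0("diffA", j)]] <- o$diffusion[[j]]$area
  }
  specs$sed <- o$sedimentation_flux; specs$res <- o$resuspension_flux
  specs$ss <- o$suspended_solids
  specs$prod_ter <- o$production$terrestrial; specs$prod_aq <- o$production$aquatic
  specs$bio_ter <- o$biomass$terrestrial; specs$bio_aq <- o$biomass$aquatic
  knots <- sort(unique(unlist(lapply(specs, ts_breaks))))
  if (!length(knots)) knots <- 0
  Y <- vapply(specs, function(s) interp_series(s, knots), numeric(length(knots)))
  if (length(knots) == 1L) Y <- matrix(Y, 1L, dimnames = list(NULL, names(specs)))
  list(knots = knots, Y = Y)
}

compiled_values_at <- function(cp, t) {
  k <- cp$knots; n <- length(k)
  if (n == 1L) return(cp$Y[1L, ])
  tt <- min(max(t, k[1L]), k[n])
  i <- findInterval(tt, k, all.inside = TRUE)
  f <- (tt - k[i]) / (k[i + 1L] - k[i])
  cp$Y[i, ] + f * (cp$Y[i + 1L, ] - cp$Y[i, ])
}

# interpolated geometry of one compartment at time t
geometry_at <- function(object, cmp, t) {
  g <- object$compartments[[cmp]]
  list(solid_mass = interp_series(g$solid_mass, t),
       water_volume = interp_series(g$water_volume, t),
       area = interp_series(g$area, t),
       thickness = interp_series(g$thickness, t))
}

# distribution capacity (m3-equivalents) of compartment cmp for an element.
# WATER includes suspended solids as its solid phase; producers and the
# atmosphere are pure pools (capacity = inventory carrier, set to 1 so
# first-order rates act directly on inventory where needed).
capacity_at <- function(object, cmp, element, t) {
  g <- geometry_at(object, cmp, t)
  kd <- COMPARTMENT_MEDIUM[[cmp]]
  if (is.na(kd)) return(NA_real_)
  solid <- g$solid_mass
  if (cmp == "WATER") solid <- interp_series(object$suspended_solids, t) * g$water_volume
  capacity(g$water_volume, kd_of(element, kd), solid)
}

#' Assemble the transfer-rate matrix of one biosphere object
#'
#' Builds the 10 x 10 first-order rate matrix over [COMPARTMENTS] at time
#' `t` for one nuclide, from the flux classes of the conceptual model:
#' water fluxes (advection + diffusion with Kd retardation), particle
#' fluxes (sedimentation/resuspension), gas fluxes (degassing and
#' atmosphere ventilation), wetland growth, and biological
#' uptake/decomposition. Radioactive decay and exports (atmosphere
#' ventilation) are included in the diagonal, so every column sums to
#' -(decay + export rates). Geosphere releases enter REGOLITH_LOW and are
#' handled by the solver's source term, not here.
#'
#' @param object a [biosphere_object()].
#' @param element an [element_properties()] object.
#' @param nuclide a [radionuclide()] (for its decay constant).
#' @param t time, years CE.
#' @return 10 x 10 matrix (per-year rates); attribute `exports` holds the
#'   per-compartment export rates (to the atmosphere sink).
#' @export
assemble_object_matrix <- function(object, element, nuclide, t) {
  n <- length(COMPARTMENTS)
  K <- matrix(0, n, n, dimnames = list(COMPARTMENTS, COMPARTMENTS))
  add <- function(from, to, rate) {
    if (rate < 0) stop("internal: negative transfer rate", call. = FALSE)
    K[to, from] <<- K[to, from] + rate
    K[from, from] <<- K[from, from] - rate
  }
  cp <- object$.compiled %||% compile_object(object)
  v <- compiled_values_at(cp, t)
  caps <- vapply(COMPARTMENTS, function(cmp) {
    kd_medium <- COMPARTMENT_MEDIUM[[cmp]]
    if (is.na(kd_medium)) return(NA_real_)
    solid <- v[[paste0(cmp, ".solid_mass")]]
    vw <- v[[paste0(cmp, ".water_volume")]]
    if (cmp == "WATER") solid <- v[["ss"]] * vw
    capacity(vw, kd_of(element, kd_medium), solid)
  }, numeric(1))

  # (2) advection with sorption retardation
  for (j in seq_along(object$water_fluxes)) {
    wf <- object$water_fluxes[[j]]
    add(wf$from, wf$to, rate_or_zero(v[[paste0("wf", j)]], caps[[wf$from]], "water flux"))
  }
  # (2) diffusion, symmetric on pore-water concentration
  for (j in seq_along(object$diffusion)) {
    df <- object$diffusion[[j]]
    i <- df$pair[1]; k2 <- df$pair[2]
    G <- v[[paste0("diffD", j)]] * v[[paste0("diffA", j)]] / df$length
    add(i, k2, rate_or_zero(G, caps[[i]], "diffusive conductance"))
    add(k2, i, rate_or_zero(G, caps[[k2]], "diffusive conductance"))
  }
  # (4) sedimentation / resuspension between WATER and AQU_REGOLITH_UP
  sed <- v[["sed"]]; res <- v[["res"]]
  if (sed > 0 || res > 0) {
    kr <- particle_rates(sed, res, v[["WATER.area"]], v[["WATER.water_volume"]],
                         v[["ss"]] * v[["WATER.water_volume"]],
                         kd_of(element, "water"),
                         v[["AQU_REGOLITH_UP.solid_mass"]],
                         v[["AQU_REGOLITH_UP.water_volume"]],
                         kd_of(element, "regolith_up"))
    add("WATER", "AQU_REGOLITH_UP", kr[["k_sed"]])
    add("AQU_REGOLITH_UP", "WATER", kr[["k_res"]])
  }
  # (5) wetland growth: annexed bed carries inventory to terrestrial layers.
  # The difference half-width is kept well below the solver's finest step so
  # the derivative never smears across a schedule breakpoint.
  h <- 1e-3
  daq_dt <- (compiled_values_at(cp, t + h)[["AQU_REGOLITH_UP.area"]] -
             compiled_values_at(cp, t - h)[["AQU_REGOLITH_UP.area"]]) / (2 * h)
  k_wg <- wetland_growth_rate(max(v[["AQU_REGOLITH_UP.area"]], 0), daq_dt)
  if (k_wg > 0) {
    add("AQU_REGOLITH_MID", "TER_REGOLITH_MID", k_wg)
    add("AQU_REGOLITH_UP", "TER_REGOLITH_UP", k_wg)
  }
  # (6) biological uptake and decomposition
  p_ter <- v[["prod_ter"]] * v[["TER_REGOLITH_UP.area"]]
  b_ter <- v[["bio_ter"]] * v[["TER_REGOLITH_UP.area"]]
  if (p_ter > 0) {
    br <- biota_rates(p_ter, b_ter, cr_of(element, "ter_producer"),
                      v[["TER_REGOLITH_UP.solid_mass"]])
    add("TER_REGOLITH_UP", "TER_PP", br[["k_uptake"]])
    add("TER_PP", "LITTER", br[["k_return"]])
  }
  p_aq <- v[["prod_aq"]] * v[["WATER.area"]]
  b_aq <- v[["bio_aq"]] * v[["WATER.area"]]
  if (p_aq > 0) {
    br <- biota_rates(p_aq, b_aq, cr_of(element, "aqu_producer"),
                      v[["WATER.water_volume"]])
    split <- object$aquatic_return_split
    add("WATER", "AQU_PP", br[["k_uptake"]])
    add("AQU_PP", "WATER", br[["k_return"]] * split)
    add("AQU_PP", "AQU_REGOLITH_UP", br[["k_return"]] * (1 - split))
  }
  if (object$litter_decomposition_rate > 0 && v[["LITTER.solid_mass"]] > 0)
    add("LITTER", "TER_REGOLITH_UP", object$litter_decomposition_rate)
  # (3) gas fluxes
  exports <- stats::setNames(numeric(n), COMPARTMENTS)
  gr <- gas_rates(element$degassing_rate, object$atmosphere_turnover)
  if (gr[["k_degas"]] > 0) {
    add("WATER", "ATMOSPHERE", gr[["k_degas"]])
    add("TER_REGOLITH_UP", "ATMOSPHERE", gr[["k_degas"]])
  }
  if (gr[["k_vent"]] > 0) {
    exports[["ATMOSPHERE"]] <- gr[["k_vent"]]
    K["ATMOSPHERE", "ATMOSPHERE"] <- K["ATMOSPHERE", "ATMOSPHERE"] - gr[["k_vent"]]
  }
  # radioactive decay on every diagonal entry
  diag(K) <- diag(K) - nuclide$lambda

  if (any(K[row(K) != col(K)] < 0))
    stop("internal: negative off-diagonal rate in object matrix", call. = FALSE)
  attr(K, "exports") <- exports
  K
}

#' @export
print.biosphere_object <- function(x, ...) {
  cat(sprintf("<biosphere_object> '%s': %d water flux(es), %d diffusive link(s)\n",
              x$id, length(x$water_fluxes), length(x$diffusion)))
  invisible(x)
}

# union of all parameter breakpoints of an object (for solver segmentation)
object_breaks <- function(object) {
  b <- c(unlist(lapply(object$compartments, function(g) {
           c(ts_breaks(g$solid_mass), ts_breaks(g$water_volume),
             ts_breaks(g$area), ts_breaks(g$thickness))
         })),
         unlist(lapply(object$water_fluxes, function(wf) ts_breaks(wf$flux))),
         unlist(lapply(object$diffusion, function(df) c(ts_breaks(df$diffusivity), ts_breaks(df$area)))),
         ts_breaks(object$sedimentation_flux), ts_breaks(object$resuspension_flux),
         ts_breaks(object$suspended_solids),
         unlist(lapply(object$production, ts_breaks)),
         unlist(lapply(object$biomass, ts_breaks)))
  sort(unique(b))
}
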