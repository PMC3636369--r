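#' Succession schedule of a biosphere object
#'
#' Encodes the continuous sea bay -> lake -> wetland (-> agricultural)
#' development of one object within a glacial cycle, together with the
#' climate-period scheduling of the cycle. Defaults follow the reference
#' glacial cycle: a temperate (interglacial) period of 18 400 years from
#' -9000 to 9400 CE, followed by 50 200 years of periglacial conditions,
#' and a ~500-year isolation window during which the sea bay becomes a
#' lake.
#'
#' @param isolation_start year CE at which isolation from the sea begins.
#' @param isolation_end year CE at which the object is fully isolated
#'   (default `isolation_start + 500`).
#' @param submerged_until year CE up to which the object is fully
#'   submerged; must be <= `isolation_start` (default equal to it).
#' @param wetland_established year CE by which lake infilling is complete
#'   and the object is a wetland (default one isolation-window length
#'   after `isolation_end`).
#' @param agricultural_from optional year CE at which the wetland is
#'   converted to agricultural land (ramped over `agricultural_ramp`
#'   years); NULL for no conversion.
#' @param agricultural_ramp length of the conversion ramp, years.
#' @param climate_periods data.frame with columns `label`, `start`, `end`;
#'   default encodes the temperate and periglacial periods above.
#' @return object of class `succession_schedule`.
#' @export
succession_schedule <- function(isolation_start,
                                isolation_end = isolation_start + 500,
                                submerged_until = isolation_start,
                                wetland_established = NULL,
                                agricultural_from = NULL,
                                agricultural_ramp = 50,
                                climate_periods = default_climate_periods()) {
  if (is.null(wetland_established))
    wetland_established <- isolation_end + (isolation_end - isolation_start)
  pr <- new_problems()
  if (submerged_until > isolation_start)
    add_problem(pr, "submerged_until (%g) must be <= isolation_start (%g)",
                submerged_until, isolation_start)
  if (isolation_end <= isolation_start)
    add_problem(pr, "isolation_end must be after isolation_start")
  if (wetland_established < isolation_end)
    add_problem(pr, "wetland_established must be >= isolation_end")
  if (!is.null(agricultural_from) && agricultural_from < isolation_end)
    add_problem(pr, "agricultural conversion cannot precede isolation")
  report_problems(pr, "succession schedule")
  structure(list(submerged_until = submerged_until,
                 isolation_start = isolation_start,
                 isolation_end = isolation_end,
                 wetland_established = wetland_established,
                 agricultural_from = agricultural_from,
                 agricultural_ramp = agricultural_ramp,
                 climate_periods = climate_periods),
            class = "succession_schedule")
}

#' Default climate-period scheduling of the reference glacial cycle
#'
#' @return data.frame with the temperate (interglacial) period of
#'   18 400 years (-9000 to 9400 CE) and the periglacial period of
#'   50 200 years (9400 to 59 600 CE).
#' @export
default_climate_periods <- function() {
  data.frame(label = c("temperate", "periglacial"),
             start = c(-9000, 9400),
             end = c(9400, 59600),
             stringsAsFactors = FALSE)
}

#' Ecosystem stage weights
#'
#' Continuous, piecewise-linear weights of the four ecosystem stages of an
#' object (sea, lake, wetland, agricultural), summing to 1 at every time.
#' The sea weight ramps from 1 to 0 across the isolation window while the
#' lake weight ramps up; the lake then gives way to wetland across the
#' infill window ending at `wetland_established`; agricultural conversion,
#' if scheduled, ramps the wetland weight into the agricultural weight.
#' The continuity of these weights (no discrete-event switching) is what
#' lets inventories and concentrations develop smoothly through ecosystem
#' transitions.
#'
#' @param schedule a [succession_schedule()].
#' @param t numeric vector of times, years CE.
#' @return matrix with columns `sea`, `lake`, `wetland`, `agricultural`
#'   (one row per element of `t`).
#' @export
stage_weights <- function(schedule, t) {
  s <- schedule
  ramp <- function(t, from, to) pmin(1, pmax(0, (t - from) / (to - from)))
  u_iso <- ramp(t, s$isolation_start, s$isolation_end)     # 0 sea -> 1 isolated
  u_wet <- ramp(t, s$isolation_end, s$wetland_established) # 0 lake -> 1 wetland
  u_agr <- if (is.null(s$agricultural_from)) rep(0, length(t)) else
    ramp(t, s$agricultural_from, s$agricultural_from + s$agricultural_ramp)
  sea <- 1 - u_iso
  lake <- u_iso * (1 - u_wet)
  wet_tot <- u_iso * u_wet
  agricultural <- wet_tot * u_agr
  wetland <- wet_tot - agricultural
  cbind(sea = sea, lake = lake, wetland = wetland, agricultural = agricultural)
}

schedule_breaks <- function(schedule) {
  s <- schedule
  b <- c(s$submerged_until, s$isolation_start, s$isolation_end, s$wetland_established)
  if (!is.null(s$agricultural_from))
    b <- c(b, s$agricultural_from, s$agricultural_from + s$agricultural_ramp)
  sort(unique(b))
}

#' Couple biosphere objects into a landscape graph
#'
#' Objects are coupled through their WATER compartments: during the
#' terrestrial/lake phase each object discharges to its downstream
#' neighbour(s) along the surface-water flow paths, ending at the outlet
#' sink (the Baltic); during an object's sea stage it instead exchanges
#' water in both directions with the outer coastal object. The two regimes
#' are blended continuously with the object's sea-stage weight.
#'
#' @param objects list of [biosphere_object()]s (each with a schedule).
#' @param downstream_edges list of `list(from=, to=, flux=ts)` with `to`
#'   either an object id or the outlet id; fluxes in m3/a.
#' @param sea_exchange list of `list(object=, coast=, flux_out=ts,
#'   flux_in=ts)` two-way exchange (m3/a) between a submerged object and
#'   the coastal object.
#' @param outlet identifier of the absorbing external sink.
#' @return object of class `landscape`.
#' @export
landscape <- function(objects, downstream_edges = list(),
                      sea_exchange = list(), outlet = "BALTIC") {
  names(objects) <- vapply(objects, `[[`, character(1), "id")
  pr <- new_problems()
  ids <- names(objects)
  for (e in downstream_edges) {
    if (!e$from %in% ids) add_problem(pr, "downstream edge from unknown object '%s'", e$from)
    if (!e$to %in% c(ids, outlet)) add_problem(pr, "downstream edge to unknown object '%s'", e$to)
  }
  for (e in sea_exchange) {
    if (!e$object %in% ids) add_problem(pr, "sea exchange for unknown object '%s'", e$object)
    if (!e$coast %in% ids) add_problem(pr, "sea exchange with unknown coastal object '%s'", e$coast)
  }
  for (o in objects) {
    if (is.null(o$schedule)) add_problem(pr, "object '%s' has no succession schedule", o$id)
  }
  # downstream edges must form a DAG ending at the outlet
  adj <- lapply(ids, function(i) {
    vapply(Filter(function(e) e$from == i, downstream_edges), `[[`, character(1), "to")
  })
  names(adj) <- ids
  state <- stats::setNames(rep(0L, length(ids)), ids) # 0 new, 1 visiting, 2 done
  visit <- function(v) {
    if (!v %in% ids) return(invisible(NULL))
    if (state[[v]] == 1L) { add_problem(pr, "cycle in downstream edges at '%s'", v); return(invisible(NULL)) }
    if (state[[v]] == 2L) return(invisible(NULL))
    state[[v]] <<- 1L
    for (w in adj[[v]]) visit(w)
    state[[v]] <<- 2L
  }
  for (v in ids) visit(v)
  report_problems(pr, "landscape validation")
  downstream_edges <- lapply(downstream_edges, function(e) { e$flux <- as_ts(e$flux); e })
  sea_exchange <- lapply(sea_exchange, function(e) {
    e$flux_out <- as_ts(e$flux_out); e$flux_in <- as_ts(e$flux_in); e
  })
  structure(list(objects = objects, downstream_edges = downstream_edges,
                 sea_exchange = sea_exchange, outlet = outlet),
            class = "landscape")
}

#' @export
print.landscape <- function(x, ...) {
  cat(sprintf("<landscape> %d object(s), %d downstream edge(s), %d sea-exchange pair(s), outlet '%s'\n",
              length(x$objects), length(x$downstream_edges), length(x$sea_exchange), x$outlet))
  for (e in x$downstream_edges) cat(sprintf("  %s -> %s\n", e$from, e$to))
  invisible(x)
}

# state naming: one entry per (object, compartment)
landscape_state_names <- function(graph) {
  as.vector(t(outer(names(graph$objects), COMPARTMENTS, paste, sep = ".")))
}

landscape_breaks <- function(graph) {
  b <- unlist(lapply(graph$objects, function(o) {
    c(object_breaks(o), schedule_breaks(o$schedule))
  }))
  b <- c(b, unlist(lapply(graph$downstream_edges, function(e) ts_breaks(e$flux))),
         unlist(lapply(graph$sea_exchange, function(e) c(ts_breaks(e$flux_out), ts_breaks(e$flux_in)))))
  sort(unique(b))
}

# sea-stage weight of one object at t
sea_weight <- function(object, t) stage_weights(object$schedule, t)[, "sea"]

#' Assemble the landscape rate matrix for one nuclide
#'
#' Block-diagonal object matrices plus WATER-to-WATER inter-object
#' couplings. Downstream couplings are weighted by (1 - sea weight) of the
#' source object; sea-stage exchange with the coastal object is weighted
#' by the sea weight, so the transition between the two regimes is
#' continuous. Edges into the outlet are always active and appear as
#' export rates (the outlet is an absorbing sink, tracked but not a
#' state).
#'
#' @param graph a [landscape()].
#' @param element an [element_properties()] object.
#' @param nuclide a [radionuclide()].
#' @param t time, years CE.
#' @return square matrix over all objects x compartments; attribute
#'   `exports_water` and `exports_atm` hold per-state export rates to the
#'   outlet and atmosphere sinks.
#' @export
assemble_landscape_matrix <- function(graph, element, nuclide, t) {
  ids <- names(graph$objects)
  nm <- landscape_state_names(graph)
  n <- length(nm)
  K <- matrix(0, n, n, dimnames = list(nm, nm))
  exp_w <- stats::setNames(numeric(n), nm)
  exp_a <- stats::setNames(numeric(n), nm)
  idx <- function(obj, cmp) match(paste(obj, cmp, sep = "."), nm)

  for (id in ids) {
    Ko <- assemble_object_matrix(graph$objects[[id]], element, nuclide, t)
    sel <- idx(id, COMPARTMENTS)
    K[sel, sel] <- K[sel, sel] + Ko
    exp_a[sel] <- exp_a[sel] + attr(Ko, "exports")
  }
  add <- function(i_from, i_to, rate) {
    K[i_to, i_from] <<- K[i_to, i_from] + rate
    K[i_from, i_from] <<- K[i_from, i_from] - rate
  }
  water_cap <- function(id) {
    capacity_at(graph$objects[[id]], "WATER", element, t)
  }
  for (e in graph$downstream_edges) {
    w_active <- if (e$to == graph$outlet) 1 else 1 - sea_weight(graph$objects[[e$from]], t)
    flux <- interp_series(e$flux, t) * w_active
    k <- rate_or_zero(flux, water_cap(e$from), "downstream water flux")
    i_from <- idx(e$from, "WATER")
    if (e$to == graph$outlet) {
      exp_w[i_from] <- exp_w[i_from] + k
      K[i_from, i_from] <- K[i_from, i_from] - k
    } else {
      add(i_from, idx(e$to, "WATER"), k)
    }
  }
  for (e in graph$sea_exchange) {
    w <- sea_weight(graph$objects[[e$object]], t)
    if (w > 0) {
      k_out <- rate_or_zero(interp_series(e$flux_out, t) * w, water_cap(e$object), "sea exchange")
      k_in <- rate_or_zero(interp_series(e$flux_in, t) * w, water_cap(e$coast), "sea exchange")
      add(idx(e$object, "WATER"), idx(e$coast, "WATER"), k_out)
      add(idx(e$coast, "WATER"), idx(e$object, "WATER"), k_in)
    }
  }
  attr(K, "exports_water") <- exp_w
  attr(K, "exports_atm") <- exp_a
  K
}

#' Assemble the full system matrix for a decay chain
#'
#' Stacks the per-nuclide landscape matrices of all chain members into one
#' block system and adds the chain-ingrowth coupling (in activity units, a
#' daughter gains `branching_fraction * lambda_daughter * A_parent` in the
#' same compartment). This is the matrix the solver propagates; it is also
#' the input to [steady_state()] for frozen-parameter analyses.
#'
#' @param graph a [landscape()].
#' @param library a [nuclide_library()].
#' @param chain character vector of chain members in parent-first order
#'   (from [build_chain()]).
#' @param t time, years CE.
#' @return list with `K` (square matrix over members x objects x
#'   compartments, states named `nuclide|object.compartment`),
#'   `exports_water`, `exports_atm` (per-state export rates), `ingrowth`
#'   (list of member/parent/coefficient triples), `lambdas`, `n_states`,
#'   `n_members`, `state_names`.
#' @export
assemble_system_matrix <- function(graph, library, chain, t) {
  nm1 <- landscape_state_names(graph)
  ns <- length(nm1)
  nmem <- length(chain)
  nm <- as.vector(vapply(chain, function(m) paste(m, nm1, sep = "|"), character(ns)))
  n <- ns * nmem
  K <- matrix(0, n, n, dimnames = list(nm, nm))
  exp_w <- stats::setNames(numeric(n), nm)
  exp_a <- stats::setNames(numeric(n), nm)
  for (m in seq_len(nmem)) {
    nuc <- library[[chain[m]]]
    Km <- assemble_landscape_matrix(graph, nuc$element, nuc, t)
    sel <- (m - 1L) * ns + seq_len(ns)
    K[sel, sel] <- Km
    exp_w[sel] <- attr(Km, "exports_water")
    exp_a[sel] <- attr(Km, "exports_atm")
  }
  # chain ingrowth: in activity units the daughter gains b * lambda_d * A_parent
  ingrowth <- list()
  for (m in seq_len(nmem)) {
    nuc <- library[[chain[m]]]
    if (!is.null(nuc$parent) && nuc$parent %in% chain) {
      mp <- match(nuc$parent, chain)
      coef <- nuc$branching_fraction * nuc$lambda
      sel_d <- (m - 1L) * ns + seq_len(ns)
      sel_p <- (mp - 1L) * ns + seq_len(ns)
      K[cbind(sel_d, sel_p)] <- K[cbind(sel_d, sel_p)] + coef
      ingrowth[[length(ingrowth) + 1L]] <- list(member = m, parent = mp, coef = coef)
    }
  }
  lambdas <- vapply(chain, function(m) library[[m]]$lambda, numeric(1))
  list(K = K, exports_water = exp_w, exports_atm = exp_a,
       ingrowth = ingrowth, lambdas = lambdas, n_states = ns, n_members = nmem,
       state_names = nm)
}
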