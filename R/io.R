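# JSON configuration round trip, tidy CSV result writers and the run
# manifest. JSON is the single configuration dialect; the time axis is
# years CE (negative = BC). Floats in CSV outputs are pinned to 9
# significant digits so reruns with the same seed are byte-identical.

ts_to_list <- function(s) { s <- as_ts(s); list(t = s$t, y = s$y) }
ts_from_list <- function(l) ts_series(as.numeric(l$t), as.numeric(l$y))

#' Write a nuclide library to JSON
#'
#' @param library a [nuclide_library()].
#' @param path output file.
#' @export
write_nuclides <- function(library, path) {
  recs <- lapply(unclass(library), function(n) {
    list(name = n$name, half_life = n$half_life, parent = n$parent,
         branching_fraction = n$branching_fraction,
         element = list(kd = n$element$kd, cr = n$element$cr,
                        degassing_rate = n$element$degassing_rate),
         dose_coefficients = unclass(n$dose_coeff))
  })
  jsonlite::write_json(unname(recs), path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Load a nuclide library from JSON
#'
#' Validates chain links and requires explicit Kd entries for every solid
#' medium of the compartment model (`regolith_low`, `regolith_mid`,
#' `regolith_up`, `water`); 0 is allowed but omission is an error.
#'
#' @param path JSON file written by [write_nuclides()] (or hand-authored
#'   in the same layout).
#' @return a [nuclide_library()].
#' @export
load_nuclides <- function(path) {
  recs <- jsonlite::read_json(path, simplifyVector = FALSE)
  pr <- new_problems()
  media <- c("regolith_low", "regolith_mid", "regolith_up", "water")
  nucs <- lapply(recs, function(r) {
    missing_kd <- setdiff(media, names(r$element$kd))
    if (length(missing_kd))
      add_problem(pr, "nuclide '%s': missing Kd for medium/media %s",
                  r$name, paste(missing_kd, collapse = ", "))
    radionuclide(r$name, as.numeric(r$half_life),
                 element = element_properties(kd = lapply(r$element$kd, as.numeric),
                                              cr = lapply(r$element$cr, as.numeric),
                                              degassing_rate = as.numeric(r$element$degassing_rate %||% 0)),
                 dose_coeff = do.call(dose_coefficients, lapply(r$dose_coefficients, as.numeric)),
                 parent = if (length(r$parent) != 1L) NULL else as.character(r$parent),
                 branching_fraction = as.numeric(r$branching_fraction %||% 1))
  })
  report_problems(pr, sprintf("nuclide file '%s'", path))
  nuclide_library(nucs)
}

schedule_to_list <- function(s) {
  list(submerged_until = s$submerged_until, isolation_start = s$isolation_start,
       isolation_end = s$isolation_end, wetland_established = s$wetland_established,
       agricultural_from = s$agricultural_from, agricultural_ramp = s$agricultural_ramp,
       climate_periods = s$climate_periods)
}

schedule_from_list <- function(l) {
  cp <- l$climate_periods
  periods <- data.frame(
    label = vapply(cp, function(p) as.character(p$label), character(1)),
    start = vapply(cp, function(p) as.numeric(p$start), numeric(1)),
    end = vapply(cp, function(p) as.numeric(p$end), numeric(1)),
    stringsAsFactors = FALSE)
  succession_schedule(isolation_start = as.numeric(l$isolation_start),
                      isolation_end = as.numeric(l$isolation_end),
                      submerged_until = as.numeric(l$submerged_until),
                      wetland_established = as.numeric(l$wetland_established),
                      agricultural_from = if (length(l$agricultural_from) != 1L) NULL else
                        as.numeric(l$agricultural_from),
                      agricultural_ramp = as.numeric(l$agricultural_ramp %||% 50),
                      climate_periods = periods)
}

object_to_list <- function(o) {
  list(id = o$id,
       compartments = lapply(o$compartments, function(g)
         list(solid_mass = ts_to_list(g$solid_mass), water_volume = ts_to_list(g$water_volume),
              area = ts_to_list(g$area), thickness = ts_to_list(g$thickness))),
       water_fluxes = lapply(o$water_fluxes, function(wf)
         list(from = wf$from, to = wf$to, flux = ts_to_list(wf$flux))),
       diffusion = lapply(o$diffusion, function(df)
         list(pair = as.list(df$pair), diffusivity = ts_to_list(df$diffusivity),
              area = ts_to_list(df$area), length = df$length)),
       sedimentation_flux = ts_to_list(o$sedimentation_flux),
       resuspension_flux = ts_to_list(o$resuspension_flux),
       suspended_solids = ts_to_list(o$suspended_solids),
       production = lapply(o$production, ts_to_list),
       biomass = lapply(o$biomass, ts_to_list),
       litter_decomposition_rate = o$litter_decomposition_rate,
       atmosphere_turnover = o$atmosphere_turnover,
       aquatic_return_split = o$aquatic_return_split,
       schedule = schedule_to_list(o$schedule))
}

object_from_list <- function(l) {
  biosphere_object(
    id = l$id,
    compartments = lapply(l$compartments, function(g) lapply(g, ts_from_list)),
    water_fluxes = lapply(l$water_fluxes, function(wf)
      list(from = wf$from, to = wf$to, flux = ts_from_list(wf$flux))),
    diffusion = lapply(l$diffusion, function(df)
      list(pair = unlist(df$pair), diffusivity = ts_from_list(df$diffusivity),
           area = ts_from_list(df$area), length = as.numeric(df$length))),
    sedimentation_flux = ts_from_list(l$sedimentation_flux),
    resuspension_flux = ts_from_list(l$resuspension_flux),
    suspended_solids = ts_from_list(l$suspended_solids),
    production = lapply(l$production, ts_from_list),
    biomass = lapply(l$biomass, ts_from_list),
    litter_decomposition_rate = as.numeric(l$litter_decomposition_rate),
    atmosphere_turnover = as.numeric(l$atmosphere_turnover),
    aquatic_return_split = as.numeric(l$aquatic_return_split),
    schedule = schedule_from_list(l$schedule))
}

#' Write a landscape to JSON
#' @param graph a [landscape()].
#' @param path output file.
#' @export
write_landscape <- function(graph, path) {
  l <- list(objects = lapply(unname(graph$objects), object_to_list),
            downstream_edges = lapply(graph$downstream_edges, function(e)
              list(from = e$from, to = e$to, flux = ts_to_list(e$flux))),
            sea_exchange = lapply(graph$sea_exchange, function(e)
              list(object = e$object, coast = e$coast,
                   flux_out = ts_to_list(e$flux_out), flux_in = ts_to_list(e$flux_in))),
            outlet = graph$outlet)
  jsonlite::write_json(l, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Load a landscape from JSON
#' @param path JSON file written by [write_landscape()].
#' @return a [landscape()].
#' @export
load_landscape <- function(path) {
  l <- jsonlite::read_json(path, simplifyVector = FALSE)
  landscape(objects = lapply(l$objects, object_from_list),
            downstream_edges = lapply(l$downstream_edges, function(e)
              list(from = e$from, to = e$to, flux = ts_from_list(e$flux))),
            sea_exchange = lapply(l$sea_exchange, function(e)
              list(object = e$object, coast = e$coast,
                   flux_out = ts_from_list(e$flux_out), flux_in = ts_from_list(e$flux_in))),
            outlet = l$outlet)
}

#' Load and cross-validate a model configuration
#'
#' Loads the landscape and nuclide files, then checks cross-references:
#' CR coverage for the biota types used by the uptake and dose models and
#' Kd coverage for all solid media. All violations are aggregated into a
#' single human-readable report.
#'
#' @param landscape_path,nuclides_path JSON configuration files.
#' @return list with `graph` and `library`.
#' @export
load_and_validate <- function(landscape_path, nuclides_path) {
  graph <- load_landscape(landscape_path)
  library <- load_nuclides(nuclides_path)
  pr <- new_problems()
  for (n in library) {
    for (b in c("ter_producer", "aqu_producer", "crops", "aquatic_food")) {
      if (is.null(n$element$cr[[b]]))
        add_problem(pr, "nuclide '%s': missing CR for biota type '%s'", n$name, b)
    }
  }
  report_problems(pr, "configuration cross-validation")
  list(graph = graph, library = library)
}

# 9-significant-digit float pinning for reproducible CSVs
fmt_num <- function(x) {
  if (is.numeric(x)) sprintf("%.9g", x) else x
}

write_tidy_csv <- function(df, path) {
  out <- as.data.frame(lapply(df, fmt_num), stringsAsFactors = FALSE,
                       check.names = FALSE)
  names(out) <- names(df)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Tidy inventory series of a transport result
#'
#' @param result a `transport_result`.
#' @return data.frame with columns `time`, `object`, `compartment`,
#'   `nuclide`, `inventory_Bq`.
#' @export
tidy_inventories <- function(result) {
  nm <- colnames(result$inventories)
  parts <- strsplit(nm, "[|.]")
  data.frame(
    time = rep(result$times, times = length(nm)),
    object = rep(vapply(parts, `[`, character(1), 2), each = length(result$times)),
    compartment = rep(vapply(parts, function(p) paste(p[-(1:2)], collapse = "."), character(1)),
                      each = length(result$times)),
    nuclide = rep(vapply(parts, `[`, character(1), 1), each = length(result$times)),
    inventory_Bq = as.vector(result$inventories),
    stringsAsFactors = FALSE)
}

#' Write simulation results to a directory
#'
#' Writes tidy CSV files for whatever result types are supplied (dose
#' series + LDF table for `dose_result`s, inventories for
#' `transport_result`s, samples + sensitivity for `mc_result`s) and one
#' JSON run manifest with a hash of the configuration, the seed and the
#' solver settings.
#'
#' @param results named list of result objects.
#' @param dir output directory (created if needed).
#' @param seed seed to record in the manifest.
#' @param config optional configuration object(s) to hash into the
#'   manifest.
#' @param solver_settings optional named list recorded verbatim.
#' @return invisibly, the manifest path.
#' @export
write_results <- function(results, dir, seed = NULL, config = NULL,
                          solver_settings = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ldf_rows <- list()
  for (nm in names(results)) {
    x <- results[[nm]]
    if (inherits(x, "dose_result")) {
      write_tidy_csv(x$dose, file.path(dir, paste0(nm, "_dose_series.csv")))
      ldf_rows[[nm]] <- data.frame(
        nuclide = x$nuclide, period = x$period,
        kind = if (!is.null(x$ldf)) "constant" else "pulse",
        ldf = x$ldf %||% x$ldf_pulse,
        argmax_object = x$argmax_object, argmax_year = x$argmax_time,
        stringsAsFactors = FALSE)
    } else if (inherits(x, "transport_result")) {
      write_tidy_csv(tidy_inventories(x), file.path(dir, paste0(nm, "_inventories.csv")))
    } else if (inherits(x, "mc_result")) {
      write_tidy_csv(x$samples, file.path(dir, paste0(nm, "_mc_samples.csv")))
      write_tidy_csv(rank_sensitivity(x), file.path(dir, paste0(nm, "_sensitivity.csv")))
      write_tidy_csv(data.frame(statistic = names(x$summary), value = unname(x$summary)),
                     file.path(dir, paste0(nm, "_mc_summary.csv")))
    }
  }
  if (length(ldf_rows))
    write_tidy_csv(do.call(rbind, ldf_rows), file.path(dir, "ldf_table.csv"))

  config_hash <- NA_character_
  if (!is.null(config)) {
    tmp <- tempfile(fileext = ".json")
    on.exit(unlink(tmp), add = TRUE)
    jsonlite::write_json(config, tmp, auto_unbox = TRUE, digits = NA, force = TRUE)
    config_hash <- unname(tools::md5sum(tmp))
  }
  manifest <- list(package = "radbiosphere",
                   version = as.character(utils::packageVersion("radbiosphere")),
                   config_hash = config_hash, seed = seed,
                   solver_settings = solver_settings,
                   written = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
                   outputs = sort(list.files(dir, pattern = "\\.csv$")))
  mp <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, mp, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(mp)
}
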