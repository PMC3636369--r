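# Shared fixture builders. All fixtures are constructed in code; none are
# read from disk.

# linear decay chain with inert transport properties (Kd = 0 everywhere)
make_decay_library <- function(half_lives, kd_low = 0) {
  el <- element_properties(
    kd = list(regolith_low = kd_low, regolith_mid = 0, regolith_up = 0, water = 0),
    cr = list(ter_producer = 0, aqu_producer = 0, crops = 0, aquatic_food = 0))
  nucs <- lapply(seq_along(half_lives), function(i)
    radionuclide(paste0("N", i), half_lives[i], el,
                 dose_coeff = dose_coefficients(ingestion = 1e-8),
                 parent = if (i > 1) paste0("N", i - 1) else NULL))
  nuclide_library(nucs)
}

# single-object coastal fixture with coarse solver settings for fast runs
small_fixture <- function(seed = 7) {
  list(graph = generate_landscape(1, seed = seed),
       library = reference_nuclides())
}

coarse <- list(max_step = 100, fine_step = 10, fine_window = 50)

ldf_coarse <- function(graph, library, nuclide, ...) {
  compute_ldf(graph, library, nuclide,
              max_step = coarse$max_step, fine_step = coarse$fine_step,
              fine_window = coarse$fine_window, ...)
}

# inventory of a single state across time
state_series <- function(result, member, object, cmp) {
  result$inventories[, paste0(member, "|", object, ".", cmp)]
}
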