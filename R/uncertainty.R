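#' Define a parameter probability distribution
#'
#' Describes the uncertainty of one time-independent scalar parameter for
#' probabilistic simulation, alongside its best-estimate (BE) value used
#' in deterministic runs. The parameter is addressed by a `/`-separated
#' path into the model configuration (a list with components `graph`,
#' `library`, `habits`), e.g.
#' `"library/Ra226syn/element/kd/regolith_low"`.
#'
#' @param path parameter path (see above).
#' @param kind one of "constant", "uniform", "loguniform", "triangular",
#'   "normal", "lognormal".
#' @param best_estimate BE value; must lie inside the support.
#' @param min,max support bounds (uniform, loguniform, triangular;
#'   optional truncation for normal/lognormal).
#' @param mode mode of the triangular distribution.
#' @param mean,sd normal parameters.
#' @param meanlog,sdlog lognormal parameters.
#' @return object of class `param_dist`.
#' @export
param_dist <- function(path, kind = c("constant", "uniform", "loguniform",
                                      "triangular", "normal", "lognormal"),
                       best_estimate, min = NULL, max = NULL, mode = NULL,
                       mean = NULL, sd = NULL, meanlog = NULL, sdlog = NULL) {
  kind <- match.arg(kind)
  d <- structure(list(path = path, kind = kind, best_estimate = best_estimate,
                      min = min, max = max, mode = mode, mean = mean, sd = sd,
                      meanlog = meanlog, sdlog = sdlog), class = "param_dist")
  # validate support and BE location
  q <- dist_quantile(d, c(0, 1))
  if (kind != "constant" && (best_estimate < q[1] || best_estimate > q[2]))
    stop(sprintf("best estimate of '%s' lies outside the support [%g, %g]",
                 path, q[1], q[2]), call. = FALSE)
  d
}

# inverse CDF of a param_dist (vectorised over p)
dist_quantile <- function(d, p) {
  switch(d$kind,
    constant = rep(d$best_estimate, length(p)),
    uniform = {
      stopifnot(!is.null(d$min), !is.null(d$max), d$max > d$min)
      d$min + p * (d$max - d$min)
    },
    loguniform = {
      stopifnot(!is.null(d$min), !is.null(d$max), d$min > 0, d$max > d$min)
      exp(log(d$min) + p * (log(d$max) - log(d$min)))
    },
    triangular = {
      stopifnot(!is.null(d$min), !is.null(d$max), !is.null(d$mode))
      a <- d$min; b <- d$max; m <- d$mode
      fc <- (m - a) / (b - a)
      ifelse(p < fc, a + sqrt(p * (b - a) * (m - a)),
             b - sqrt((1 - p) * (b - a) * (b - m)))
    },
    normal = {
      stopifnot(!is.null(d$mean), !is.null(d$sd))
      lo <- if (is.null(d$min)) -Inf else d$min
      hi <- if (is.null(d$max)) Inf else d$max
      pa <- stats::pnorm(lo, d$mean, d$sd); pb <- stats::pnorm(hi, d$mean, d$sd)
      stats::qnorm(pa + p * (pb - pa), d$mean, d$sd)
    },
    lognormal = {
      stopifnot(!is.null(d$meanlog), !is.null(d$sdlog))
      lo <- if (is.null(d$min)) 0 else d$min
      hi <- if (is.null(d$max)) Inf else d$max
      pa <- stats::plnorm(lo, d$meanlog, d$sdlog); pb <- stats::plnorm(hi, d$meanlog, d$sdlog)
      stats::qlnorm(pa + p * (pb - pa), d$meanlog, d$sdlog)
    })
}

#' Sample parameter sets from their distributions
#'
#' Simple random sampling (default) or Latin hypercube sampling of the
#' time-independent uncertain parameters. Sampling is reproducible given
#' the seed; with simple random sampling each parameter uses its own
#' seeded stream, so extending `n` preserves the first draws. Constants
#' are passed through unchanged.
#'
#' @param dists list of [param_dist()] objects.
#' @param n number of parameter sets, >= 1.
#' @param seed integer seed.
#' @param method "random" or "lhs".
#' @return data.frame (n rows, one column per parameter path).
#' @export
sample_parameters <- function(dists, n, seed, method = c("random", "lhs")) {
  method <- match.arg(method)
  stopifnot(n >= 1)
  paths <- vapply(dists, `[[`, character(1), "path")
  if (anyDuplicated(paths)) stop("duplicate parameter paths", call. = FALSE)
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  if (method == "lhs") {
    set.seed(seed)
    U <- lhs::randomLHS(n, length(dists))
  } else {
    U <- matrix(0, n, length(dists))
    for (j in seq_along(dists)) {
      set.seed(seed + 7919L * j)
      U[, j] <- stats::runif(n)
    }
  }
  out <- as.data.frame(lapply(seq_along(dists), function(j) dist_quantile(dists[[j]], U[, j])))
  names(out) <- paths
  out
}

# assign a value at a /-separated path inside a nested list
set_path <- function(x, parts, value) {
  key <- parts[1]
  if (is.null(x[[key]])) stop(sprintf("parameter path component '%s' not found", key), call. = FALSE)
  if (length(parts) == 1L) {
    leaf <- x[[key]]
    if (!is.numeric(leaf) || length(leaf) != 1L)
      stop(sprintf("parameter path leaf '%s' is not a scalar", key), call. = FALSE)
    x[[key]] <- value
  } else {
    x[[key]] <- set_path(x[[key]], parts[-1], value)
  }
  x
}

#' Apply sampled parameter values to a model configuration
#'
#' @param config list with components `graph`, `library`, `habits`.
#' @param values named numeric vector; names are `/`-separated paths.
#' @return the modified configuration.
#' @export
apply_parameter_values <- function(config, values) {
  for (p in names(values)) {
    config <- set_path(config, strsplit(p, "/", fixed = TRUE)[[1]], values[[p]])
  }
  # re-class containers whose attributes survive [[<- anyway; validate habits
  config
}

#' Probabilistic LDF simulation
#'
#' Runs the deterministic best-estimate (baseline) LDF, then `n`
#' independent end-to-end LDF simulations with parameters drawn from their
#' distributions, and summarises the LDF sample. Individual run failures
#' are recorded and excluded.
#'
#' @param graph a [landscape()].
#' @param library a [nuclide_library()].
#' @param nuclide released nuclide id.
#' @param dists list of [param_dist()] objects.
#' @param n number of Monte Carlo runs.
#' @param seed integer seed.
#' @param period climate period (see [compute_ldf()]).
#' @param habits an [exposure_habits()] object.
#' @param method sampling method, "random" or "lhs".
#' @param ... passed to [compute_ldf()] (solver resolution etc.).
#' @return object of class `mc_result`: `samples` (parameter draws +
#'   column `ldf`), `summary` (mean, median, q05, q95, baseline,
#'   n_failed), `baseline` (the deterministic `dose_result`).
#' @export
run_probabilistic <- function(graph, library, nuclide, dists, n, seed,
                              period = "temperate", habits = exposure_habits(),
                              method = "random", ...) {
  baseline <- compute_ldf(graph, library, nuclide, period = period, habits = habits, ...)
  draws <- sample_parameters(dists, n, seed, method = method)
  ldf <- rep(NA_real_, n)
  failures <- character(0)
  for (i in seq_len(n)) {
    cfg <- apply_parameter_values(list(graph = graph, library = library, habits = habits),
                                  unlist(draws[i, , drop = FALSE]))
    r <- tryCatch(
      compute_ldf(cfg$graph, cfg$library, nuclide, period = period,
                  habits = cfg$habits, ...),
      error = function(e) e)
    if (inherits(r, "error")) failures <- c(failures, conditionMessage(r))
    else ldf[i] <- r$ldf
  }
  ok <- !is.na(ldf)
  summary <- c(mean = mean(ldf[ok]), median = stats::median(ldf[ok]),
               q05 = unname(stats::quantile(ldf[ok], 0.05)),
               q95 = unname(stats::quantile(ldf[ok], 0.95)),
               baseline = baseline$ldf, n_failed = sum(!ok))
  structure(list(samples = cbind(draws, ldf = ldf), summary = summary,
                 baseline = baseline, failures = failures, seed = seed,
                 nuclide = nuclide, period = period),
            class = "mc_result")
}

#' @export
print.mc_result <- function(x, ...) {
  cat(sprintf("<mc_result> %s (%s): n = %d, baseline LDF = %.4g, median = %.4g [%.4g, %.4g]\n",
              x$nuclide, x$period, nrow(x$samples), x$summary[["baseline"]],
              x$summary[["median"]], x$summary[["q05"]], x$summary[["q95"]]))
  invisible(x)
}

#' Spearman rank sensitivity of the LDF to uncertain parameters
#'
#' Rank correlation of each sampled parameter with the LDF sample, sorted
#' by absolute correlation. Constant (zero-variance) parameter columns are
#' reported with correlation 0 and flagged.
#'
#' @param samples data.frame of parameter draws (one column per parameter)
#'   or an `mc_result`.
#' @param ldf numeric vector of LDF values (omit when `samples` is an
#'   `mc_result`).
#' @return data.frame with columns `parameter`, `rho`, `abs_rho`,
#'   `constant`, sorted by decreasing `abs_rho`.
#' @export
rank_sensitivity <- function(samples, ldf = NULL) {
  if (inherits(samples, "mc_result")) {
    ldf <- samples$samples$ldf
    samples <- samples$samples[, setdiff(names(samples$samples), "ldf"), drop = FALSE]
  }
  if (length(ldf) < 2) stop("need at least two LDF samples", call. = FALSE)
  ok <- !is.na(ldf)
  rho <- vapply(names(samples), function(p) {
    x <- samples[[p]][ok]
    if (stats::sd(x) == 0) return(NA_real_)
    stats::cor(x, ldf[ok], method = "spearman")
  }, numeric(1))
  out <- data.frame(parameter = names(samples),
                    rho = ifelse(is.na(rho), 0, rho),
                    abs_rho = abs(ifelse(is.na(rho), 0, rho)),
                    constant = is.na(rho),
                    stringsAsFactors = FALSE)
  out[order(-out$abs_rho), , drop = FALSE]
}
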