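#' Define a release scenario
#'
#' Releases from the geosphere enter the lower regolith (REGOLITH_LOW) of
#' the target objects. The default is a constant unit release of
#' 1 Bq per year, the basis of LDF derivation; a pulse release spreads a
#' fixed amount over a square pulse (default one year); a table release
#' follows a user-supplied rate time series.
#'
#' @param nuclide identifier of the released nuclide (chain head).
#' @param mode one of "constant", "pulse", "table".
#' @param rate constant release rate, Bq/a (mode "constant").
#' @param amount released amount, Bq (mode "pulse").
#' @param start pulse start, years CE (default: simulation start).
#' @param duration pulse duration, years (default 1).
#' @param series a `ts_series` of release rate in Bq/a (mode "table").
#' @param targets named numeric of object ids -> fractions (must sum to 1).
#' @return object of class `release_scenario`.
#' @export
release_scenario <- function(nuclide, mode = c("constant", "pulse", "table"),
                             rate = 1, amount = 1, start = NULL, duration = 1,
                             series = NULL, targets = NULL) {
  mode <- match.arg(mode)
  if (mode == "constant") check_scalar(rate, "rate", min = 0)
  if (mode == "pulse") {
    check_scalar(amount, "amount", min = 0)
    check_scalar(duration, "duration", min = 0, strict = TRUE)
  }
  if (mode == "table" && is.null(series)) stop("table mode requires a rate series", call. = FALSE)
  if (!is.null(targets)) {
    if (abs(sum(targets) - 1) > 1e-9) stop("target fractions must sum to 1", call. = FALSE)
  }
  structure(list(nuclide = nuclide, mode = mode, rate = rate, amount = amount,
                 start = start, duration = duration, series = series,
                 targets = targets), class = "release_scenario")
}

# release rate (Bq/a) at time t, and the discontinuity points of the rate
release_rate_at <- function(scenario, t, t0) {
  switch(scenario$mode,
    constant = rep(scenario$rate, length(t)),
    pulse = {
      s <- scenario$start %||% t0
      ifelse(t >= s & t < s + scenario$duration, scenario$amount / scenario$duration, 0)
    },
    table = interp_series(scenario$series, t))
}

release_breaks <- function(scenario, t0) {
  switch(scenario$mode,
    constant = numeric(0),
    pulse = { s <- scenario$start %||% t0; c(s, s + scenario$duration) },
    table = ts_breaks(scenario$series))
}

# integration time grid: parameter/schedule breakpoints, a coarse base grid,
# and fine (<= fine_step) resolution within fine_window of every schedule or
# source breakpoint
build_time_grid <- function(t_span, breaks, fine_points, max_step, fine_step, fine_window) {
  t0 <- t_span[1]; t1 <- t_span[2]
  g <- seq(t0, t1, by = max_step)
  pts <- c(g, t1, breaks[breaks > t0 & breaks < t1])
  for (fp in fine_points) {
    a <- max(t0, fp - fine_window); b <- min(t1, fp + fine_window)
    if (b > a) pts <- c(pts, seq(a, b, by = fine_step), b)
  }
  sort(unique(pts))
}

#' Integrate the landscape transport system
#'
#' Solves dA/dt = K(t) A + S(t) for the full decay chain over all objects
#' and compartments. The system is propagated segment-by-segment with the
#' matrix exponential of the rate matrix frozen at each segment midpoint
#' (exact for a linear system with constant coefficients), with segments
#' bounded by every parameter and schedule breakpoint, at most `max_step`
#' years long, and at most `fine_step` years long within `fine_window`
#' years of any schedule or source breakpoint. Cumulative decay, export
#' (outlet and atmosphere), chain-ingrowth and injection ledgers are
#' integrated as auxiliary states of the same exponential, which makes the
#' mass-balance audit exact up to floating-point rounding.
#'
#' @param graph a [landscape()].
#' @param library a [nuclide_library()].
#' @param scenario a [release_scenario()].
#' @param t_span numeric c(start, end), years CE.
#' @param max_step coarse segment length, years.
#' @param fine_step segment length near transitions, years.
#' @param fine_window half-width of the fine-resolution window, years.
#' @param output_grid optional numeric vector of additional times (years
#'   CE, within `t_span`) at which the state is reported.
#' @param nonneg_tol inventories more negative than `nonneg_tol` times the
#'   total are an error; smaller negatives are clipped to zero.
#' @param freeze_at optional time (years CE) at which all time-varying
#'   parameters are frozen for the whole run; used to integrate a
#'   constant-coefficient system (e.g. for steady-state comparisons).
#' @return object of class `transport_result` with elements `times`,
#'   `inventories` (times x states matrix, states named
#'   `nuclide|object.compartment`), per-member ledger matrices `decayed`,
#'   `exported_water`, `exported_atm`, `ingrown`, `injected`, plus `chain`,
#'   `graph`, `library`, `scenario`.
#' @export
simulate_transport <- function(graph, library, scenario, t_span,
                               max_step = 10, fine_step = 1, fine_window = 100,
                               output_grid = NULL, nonneg_tol = 1e-12,
                               freeze_at = NULL) {
  stopifnot(length(t_span) == 2L, t_span[2] > t_span[1])
  chain <- build_chain(library, scenario$nuclide)
  t0 <- t_span[1]
  # precompile per-object parameter tables for fast repeated assembly
  graph$objects <- lapply(graph$objects, function(o) {
    o$.compiled <- compile_object(o); o
  })
  sched_breaks <- sort(unique(unlist(lapply(graph$objects, function(o) schedule_breaks(o$schedule)))))
  if (!is.null(output_grid)) {
    output_grid <- output_grid[output_grid >= t_span[1] & output_grid <= t_span[2]]
  }
  grid <- build_time_grid(t_span,
                          breaks = c(landscape_breaks(graph), release_breaks(scenario, t0),
                                     output_grid),
                          fine_points = c(sched_breaks, release_breaks(scenario, t0)),
                          max_step = max_step, fine_step = fine_step,
                          fine_window = fine_window)
  nT <- length(grid)

  sys0 <- assemble_system_matrix(graph, library, chain, grid[1])
  ns <- sys0$n_states; nmem <- sys0$n_members; n <- ns * nmem
  # auxiliary ledger states per chain member + one constant state carrying
  # the source term
  led_names <- as.vector(outer(c("decayed", "exp_w", "exp_a", "ingrown", "injected"),
                               chain, paste, sep = "|"))
  nled <- length(led_names)
  naug <- n + nled + 1L
  led_idx <- function(kind, m) n + (m - 1L) * 5L + match(kind, c("decayed", "exp_w", "exp_a", "ingrown", "injected"))

  # source distribution over states for the chain head
  targets <- scenario$targets
  if (is.null(targets)) targets <- stats::setNames(1, names(graph$objects)[1])
  if (!all(names(targets) %in% names(graph$objects)))
    stop("release targets reference unknown objects", call. = FALSE)
  src_states <- match(paste0(chain[1], "|", names(targets), ".REGOLITH_LOW"), sys0$state_names)
  src_frac <- as.numeric(targets)

  build_aug <- function(sys, rate) {
    M <- matrix(0, naug, naug)
    M[seq_len(n), seq_len(n)] <- sys$K
    for (m in seq_len(nmem)) {
      sel <- (m - 1L) * ns + seq_len(ns)
      M[led_idx("decayed", m), sel] <- sys$lambdas[m]
      M[led_idx("exp_w", m), sel] <- sys$exports_water[sel]
      M[led_idx("exp_a", m), sel] <- sys$exports_atm[sel]
    }
    for (ing in sys$ingrowth) {
      sel_p <- (ing$parent - 1L) * ns + seq_len(ns)
      M[led_idx("ingrown", ing$member), sel_p] <- M[led_idx("ingrown", ing$member), sel_p] + ing$coef
    }
    # the release rate enters through the constant state (set to the
    # segment's rate before each step), keeping the propagator matrix
    # identical across release rates: the solution is then linear in the
    # release to near machine precision
    M[src_states, naug] <- src_frac
    M[led_idx("injected", 1L), naug] <- 1
    M
  }

  states <- matrix(0, nT, naug)
  x <- c(rep(0, n + nled), 1)
  states[1, ] <- x
  sys_frozen <- if (is.null(freeze_at)) NULL else
    assemble_system_matrix(graph, library, chain, freeze_at)
  for (k in seq_len(nT - 1L)) {
    h <- grid[k + 1L] - grid[k]
    tm <- (grid[k] + grid[k + 1L]) / 2
    sys <- sys_frozen %||% assemble_system_matrix(graph, library, chain, tm)
    rate <- release_rate_at(scenario, tm, t0)
    M <- build_aug(sys)
    x[naug] <- rate
    x <- as.numeric(Matrix::expm(M * h) %*% x)
    tot <- sum(abs(x[seq_len(n)])) + sum(x[n + seq_len(nled)])
    neg <- x[seq_len(n)] < 0
    if (any(neg)) {
      if (any(x[seq_len(n)] < -nonneg_tol * max(tot, 1e-300)))
        stop(sprintf("negative inventory beyond tolerance at t = %g", grid[k + 1L]), call. = FALSE)
      x[seq_len(n)][neg] <- 0
    }
    states[k + 1L, ] <- x
  }

  ledger <- function(kind) {
    m <- states[, vapply(seq_len(nmem), function(m) led_idx(kind, m), integer(1)), drop = FALSE]
    colnames(m) <- chain
    m
  }
  inv <- states[, seq_len(n), drop = FALSE]
  colnames(inv) <- sys0$state_names
  structure(list(times = grid, inventories = inv,
                 decayed = ledger("decayed"), exported_water = ledger("exp_w"),
                 exported_atm = ledger("exp_a"), ingrown = ledger("ingrown"),
                 injected = ledger("injected"),
                 chain = chain, graph = graph, library = library,
                 scenario = scenario),
            class = "transport_result")
}

#' @export
print.transport_result <- function(x, ...) {
  cat(sprintf("<transport_result> %s release of %s: %d time(s) in [%g, %g], %d state(s)\n",
              x$scenario$mode, x$scenario$nuclide, length(x$times),
              min(x$times), max(x$times), ncol(x$inventories)))
  invisible(x)
}

#' Analytic decay-chain (Bateman) solution
#'
#' Activities of a linear decay chain under pure radioactive decay, from
#' arbitrary initial activities of each member. Used as an independent
#' oracle for the numerical solver. Tied decay constants are perturbed by
#' a relative 1e-9 to keep the classical partial-fraction form valid.
#'
#' @param lambdas decay constants, /a, one per chain member.
#' @param initial initial activities, Bq, one per member.
#' @param t numeric vector of elapsed times, years.
#' @param branching branching fractions between consecutive members
#'   (length `length(lambdas) - 1`), default all 1.
#' @return matrix `length(t)` x `length(lambdas)` of activities.
#' @export
bateman_solution <- function(lambdas, initial, t, branching = NULL) {
  nmem <- length(lambdas)
  stopifnot(length(initial) == nmem, all(lambdas > 0))
  if (is.null(branching)) branching <- rep(1, max(nmem - 1L, 0L))
  # perturb ties
  for (i in seq_len(nmem)) {
    while (any(abs(lambdas[-i] - lambdas[i]) < 1e-12 * lambdas[i])) {
      lambdas[i] <- lambdas[i] * (1 + 1e-9)
    }
  }
  A <- matrix(0, length(t), nmem)
  # superpose the solution from each initially present ancestor j
  for (j in seq_len(nmem)) {
    if (initial[j] == 0) next
    N0 <- initial[j] / lambdas[j]
    for (i in j:nmem) {
      prod_bl <- if (i > j) prod(branching[j:(i - 1L)] * lambdas[j:(i - 1L)]) else 1
      lam <- lambdas[j:i]
      s <- rep(0, length(t))
      for (k in seq_along(lam)) {
        denom <- prod(lam[-k] - lam[k])
        if (length(lam) == 1L) denom <- 1
        s <- s + exp(-lam[k] * t) / denom
      }
      A[, i] <- A[, i] + lambdas[i] * N0 * prod_bl * s
    }
  }
  colnames(A) <- names(lambdas)
  A
}

#' Steady-state inventories under a constant source
#'
#' Solves K A = -S for the equilibrium of the linear compartment system.
#'
#' @param K rate matrix (negative column sums = losses).
#' @param S source vector, Bq/a.
#' @return inventory vector, Bq (all entries >= 0 up to rounding).
#' @export
steady_state <- function(K, S) {
  stopifnot(is.matrix(K), nrow(K) == ncol(K), length(S) == nrow(K))
  A <- tryCatch(solve(K, -S), error = function(e) {
    loss <- -colSums(K)
    traps <- colnames(K)[loss <= 0]
    if (is.null(traps)) traps <- which(loss <= 0)
    stop(sprintf("rate matrix is singular; compartments with no loss path: %s",
                 paste(traps, collapse = ", ")), call. = FALSE)
  })
  tot <- sum(abs(A))
  A[A < 0 & A > -1e-9 * max(tot, 1e-300)] <- 0
  if (any(A < 0)) stop("negative steady-state inventory", call. = FALSE)
  A
}

#' Mass-balance audit of a transport simulation
#'
#' At every output time and for every chain member, compares what entered
#' the member's pool (external injection plus chain ingrowth) against
#' what is accounted for (current inventory plus cumulative decay plus
#' cumulative exports). A correct simulation keeps the relative error
#' below 1e-6 at all times, including across ecosystem transitions.
#'
#' @param result a `transport_result`.
#' @return maximum relative error (a single number); attribute `series`
#'   holds the per-time maximum over members.
#' @export
mass_balance_audit <- function(result) {
  chain <- result$chain
  err <- matrix(0, length(result$times), length(chain))
  for (m in seq_along(chain)) {
    sel <- startsWith(colnames(result$inventories), paste0(chain[m], "|"))
    inv <- rowSums(result$inventories[, sel, drop = FALSE])
    lhs <- result$injected[, m] + result$ingrown[, m]
    rhs <- inv + result$decayed[, m] + result$exported_water[, m] + result$exported_atm[, m]
    err[, m] <- abs(lhs - rhs) / pmax(lhs, .Machine$double.xmin)
    err[lhs == 0 & rhs == 0, m] <- 0
  }
  out <- max(err)
  attr(out, "series") <- apply(err, 1, max)
  out
}
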