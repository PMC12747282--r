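#' Intracellular virus concentration
#'
#' The concentration is normalized so that a newborn cell (volume \code{p0})
#' holding \code{Q_max} virions has concentration 1:
#' \code{rho = q * p0 / (Q_max * p)}. At fixed virion count the concentration
#' decreases with cell volume.
#'
#' @param p Cell volume in volume units, in [p0, 2*p0]. Vectorized.
#' @param q Intracellular virion count, >= 0. Vectorized.
#' @param params A \code{\link{chemostat_params}} object.
#' @return Concentration value(s) in [0, 1].
#' @examples
#' pars <- chemostat_params()
#' intracellular_concentration(pars$p0, 1000, pars)   # 1
#' intracellular_concentration(2 * pars$p0, 1000, pars) # 0.5
#' @export
intracellular_concentration <- function(p, q, params) {
  if (any(q < 0)) stop("virion count q must be nonnegative")
  if (any(p < params$p0 | p > 2 * params$p0))
    stop("cell volume p must lie in [p0, 2*p0]")
  if (any(q > params$Q_max * p / params$p0))
    stop("q exceeds the effective per-volume cap Q_max * p / p0")
  q * params$p0 / (params$Q_max * p)
}

#' Lysis hazard at a given intracellular virus concentration
#'
#' The lysis hazard is \code{(rho / (T - rho))^G}: zero for virus-free cells,
#' strictly increasing in \code{rho}, and diverging as \code{rho} approaches
#' the lethal threshold \code{T}, where lysis is certain. For concentrations
#' below \code{T/2}, larger \code{G} gives a smaller hazard.
#'
#' @param rho Intracellular virus concentration(s), in [0, T).
#' @param params A \code{\link{chemostat_params}} object.
#' @return Hazard per unit time; \code{Inf} for \code{rho >= T} (the certain
#'   lysis sentinel).
#' @examples
#' pars <- chemostat_params(G = 1, T = 1)
#' lysis_rate(0.5, pars)    # 1
#' lysis_rate(0, pars)      # 0: virus-free cells never lyse
#' @export
lysis_rate <- function(rho, params) {
  if (any(rho < 0)) stop("concentration rho must be nonnegative")
  out <- ifelse(rho >= params$T, Inf,
                ifelse(rho <= 0, 0, (rho / (params$T - rho))^params$G))
  as.numeric(out)
}

# Build an empty population state for a given strategy's lattice.
new_population_state <- function(params, a, control = sim_control()) {
  qg <- cpp_build_qgrid(q_cap(params, a), control$q_lin, control$q_ratio)
  n <- matrix(0, nrow = params$p0 + 1, ncol = length(qg),
              dimnames = list(p = params$p0:(2 * params$p0), q = qg))
  list(n = n, qgrid = qg, phi = params$phi0, psi = params$psi0, t = 0)
}

#' Advance the chemostat state by one integration step
#'
#' Applies, for every lattice state, the growth, division, virus replication,
#' immunity clearance, infection (virus-free cells only: superinfection
#' exclusion), dilution, lysis and PCD fluxes over one step \code{dt}, and
#' updates nutrient and free-virus concentrations. Mass reaching
#' concentration \code{>= 1 - a} is destroyed with its virions (PCD); lysed
#' mass releases all intracellular virions; diluted cells carry their virions
#' out of the system.
#'
#' @param state List with elements \code{n} (volume x virion-node matrix),
#'   \code{qgrid}, \code{phi}, \code{psi} as returned by
#'   \code{\link{run_to_equilibrium}} (field \code{state}) or built
#'   internally.
#' @param params A \code{\link{chemostat_params}} object.
#' @param strategy A \code{\link{defense_strategy}}.
#' @param dt Step size (time units).
#' @return The updated state, with step diagnostics in attribute
#'   \code{"fluxes"} (virions released, infections, divisions, PCD-destroyed
#'   and lysed mass, washout).
#' @export
chemostat_step <- function(state, params, strategy, dt) {
  strategy <- check_strategy(strategy, params)
  if (any(state$n < 0)) stop("state matrix has negative entries")
  out <- cpp_chemostat_step(state$n, as.integer(state$qgrid), state$phi,
                            state$psi, internal_params(params), strategy$a,
                            strategy$r * rate_scale(params), dt)
  if (any(!is.finite(out$n)) || any(out$n < 0) ||
      !is.finite(out$phi) || !is.finite(out$psi))
    stop("integration-stability error: non-finite or negative state after ",
         "step (offending update: lattice fluxes at dt = ", dt, ")")
  st <- list(n = out$n, qgrid = state$qgrid, phi = out$phi, psi = out$psi,
             t = (state$t %||% 0) + dt)
  dimnames(st$n) <- dimnames(state$n)
  attr(st, "fluxes") <- out[c("release", "infected", "divisions", "pcd",
                              "lysed", "washed", "burst")]
  st
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Integrate the chemostat to equilibrium
#'
#' Iterates the model until the relative change of population size, nutrient
#' and virus concentration per host generation falls below \code{tol}, or
#' \code{t_max} is reached. The run is deterministic given parameters,
#' strategy and discretization. An extinct population (total count below
#' 1e-9 of its initial value) is reported with fitness 0.
#'
#' @param params A \code{\link{chemostat_params}} object.
#' @param strategy A \code{\link{defense_strategy}}.
#' @param tol,t_max Convenience overrides of the corresponding
#'   \code{\link{sim_control}} fields.
#' @param init Optional warm-start state (a previous equilibrium object or
#'   its \code{state} field); mass is mapped onto the strategy's lattice.
#' @param control A \code{\link{sim_control}} list.
#' @return An object of class \code{"chemostat_equilibrium"}: fields
#'   \code{N} (total cell count; the fitness measure), \code{V} (total cell
#'   volume), \code{phi}, \code{psi}, \code{t}, \code{converged},
#'   \code{residual}, \code{extinct}, \code{fitness}, \code{burst}
#'   (lysis-flux-weighted burst histogram) and \code{state} (full lattice).
#' @examples
#' \donttest{
#' eq <- run_to_equilibrium(chemostat_params(psi0 = 0),
#'                          defense_strategy(0, 0))
#' eq$N
#' }
#' @export
run_to_equilibrium <- function(params, strategy, tol = NULL, t_max = NULL,
                               init = NULL, control = sim_control()) {
  strategy <- check_strategy(strategy, params)
  if (!is.null(tol)) control$tol <- tol
  if (!is.null(t_max)) control$t_max <- t_max
  if (control$tol <= 0) stop("tol must be > 0")
  if (is.null(init)) init <- default_init(params, strategy$a, control)
  if (inherits(init, "chemostat_equilibrium")) init <- init$state
  init_state <- list(n = init$n, qgrid = as.integer(init$qgrid),
                     phi = init$phi, psi = init$psi)
  raw <- cpp_run_chemostat(internal_params(params), strategy$a,
                           strategy$r * rate_scale(params),
                           unclass(control), init_state)
  qg <- raw$qgrid
  dimnames(raw$n) <- list(p = params$p0:(2 * params$p0), q = qg)
  burst_q <- c(qg, q_cap(params, strategy$a) + 1L)
  keep <- raw$burst > 0 & burst_q > 0
  structure(list(
    N = raw$N, V = raw$V * rate_scale(params),
    phi = raw$phi, psi = raw$psi, t = raw$t,
    steps = raw$steps, converged = raw$converged, residual = raw$residual,
    extinct = raw$extinct, fitness = if (raw$extinct) 0 else raw$N,
    burst = data.frame(q = burst_q[keep], flux = raw$burst[keep]),
    state = list(n = raw$n, qgrid = qg, phi = raw$phi, psi = raw$psi),
    params = params, strategy = strategy),
    class = "chemostat_equilibrium")
}

#' @exportS3Method base::print
print.chemostat_equilibrium <- function(x, ...) {
  cat("Chemostat equilibrium\n")
  cat(sprintf("  strategy a = %g, r = %g (r/E = %g)\n", x$strategy$a,
              x$strategy$r, if (x$params$E > 0) x$strategy$r / x$params$E
              else NA_real_))
  cat(sprintf("  N* = %.6g cells, V* = %.6g, phi* = %.4g, psi* = %.4g\n",
              x$N, x$V, x$phi, x$psi))
  cat(sprintf("  t = %.3g (%s, residual %.3g)%s\n", x$t,
              if (x$converged) "converged" else "NOT converged", x$residual,
              if (x$extinct) " [extinct]" else ""))
  invisible(x)
}

#' Burst size distribution at equilibrium
#'
#' The probability mass over virions released per lysis event, computed as
#' the lysis-flux-weighted histogram of intracellular virion counts at the
#' moment of lysis. PCD events release nothing and do not contribute. In
#' regimes where most of the population sits far below the lethal threshold
#' but lysing cells cluster near it, the distribution is two-peaked.
#'
#' @param equilibrium A \code{\link{run_to_equilibrium}} result.
#' @return A data frame with columns \code{q} (virions released) and
#'   \code{mass} (probability), or a zero-row frame with attribute
#'   \code{undefined = TRUE} when no lysis occurs (e.g. \code{a = 1}).
#' @export
burst_size_distribution <- function(equilibrium) {
  stopifnot(inherits(equilibrium, "chemostat_equilibrium"))
  b <- equilibrium$burst
  tot <- sum(b$flux)
  if (!is.finite(tot) || tot <= 0) {
    out <- data.frame(q = integer(0), mass = numeric(0))
    attr(out, "undefined") <- TRUE
    return(out)
  }
  out <- data.frame(q = b$q, mass = b$flux / tot)
  attr(out, "undefined") <- FALSE
  out
}
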