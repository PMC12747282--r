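#' Ecological parameters of the chemostat model
#'
#' Bundles the ecological degrees of freedom of the host-virus chemostat.
#' Time is measured in the units of the update equations; one host generation
#' at maximum nutrient corresponds to \code{log(2) / (A * phi0)} time units.
#'
#' @param A Baseline growth rate. Together with \code{phi0} it sets the
#'   generation timescale.
#' @param B Dilution rate: fraction of the chemostat volume replaced by
#'   influent media per unit time. Cell removal by dilution is extrinsic
#'   mortality; diluted infected cells carry their virions out of the system.
#' @param C Media uptake rate per unit cell volume. Also the virus encounter
#'   rate; \code{1/C} is proportional to the carrying capacity, and
#'   \code{C * psi0} is the MOI proxy of the environment.
#' @param E Maximum immunity investment. The growth-rate multiplier of a cell
#'   investing \code{r} in immunity is \code{1 - r/E}.
#' @param F Per-virion intracellular replication rate.
#' @param G Lysis-probability shape exponent; larger \code{G} lowers the lysis
#'   hazard far from the lethal threshold.
#' @param T Lethal intracellular virus concentration: lysis is certain at
#'   concentration \code{T}. Must lie in [0, 1].
#' @param phi0 Nutrient concentration in influent media.
#' @param psi0 Virus concentration in influent media (viral pressure).
#' @param p0 Cell birth volume in discrete volume units; cells divide on
#'   reaching volume \code{2 * p0}. Controls the volume-lattice resolution.
#' @param Q_max Maximum virion count in a newborn cell; the intracellular
#'   concentration is normalized so a newborn cell holding \code{Q_max}
#'   virions has concentration 1. Default 1000.
#'
#' @return An object of class \code{"chemostat_params"} (named list).
#' @examples
#' pars <- chemostat_params()                 # gut-microbiome-like ecology
#' pars <- chemostat_params(psi0 = 0)         # virus-free chemostat
#' @export
chemostat_params <- function(A = 28, B = 0.05, C = 1e-8, E = 0.0125,
                             F = 4.0, G = 1, T = 1, phi0 = 1, psi0 = 1e8,
                             p0 = 10L, Q_max = 1000L) {
  p <- list(A = A, B = B, C = C, E = E, F = F, G = G, T = T,
            phi0 = phi0, psi0 = psi0, p0 = as.integer(p0),
            Q_max = as.integer(Q_max))
  validate_chemostat_params(p)
  structure(p, class = "chemostat_params")
}

validate_chemostat_params <- function(p) {
  num <- vapply(p, is.numeric, logical(1))
  if (!all(num)) stop("all chemostat parameters must be numeric")
  rates <- c("A", "B", "C", "E", "F", "G", "phi0", "psi0")
  bad <- rates[vapply(rates, function(x) p[[x]] < 0, logical(1))]
  if (length(bad)) stop("negative rate parameter(s): ",
                        paste(bad, collapse = ", "))
  if (p$B <= 0) stop("dilution rate B must be > 0")
  if (p$C <= 0) stop("uptake rate C must be > 0 (1/C sets the carrying capacity)")
  if (p$T < 0 || p$T > 1) stop("lethal threshold T must lie in [0, 1]")
  if (p$p0 < 2) stop("birth volume p0 must be at least 2 volume units")
  if (p$Q_max < 1) stop("Q_max must be at least 1")
  invisible(p)
}

#' @exportS3Method base::print
print.chemostat_params <- function(x, ...) {
  cat("Chemostat ecology\n")
  cat(sprintf("  growth A = %g, dilution B = %g, uptake C = %g\n",
              x$A, x$B, x$C))
  cat(sprintf("  immunity cost scale E = %g, replication F = %g\n", x$E, x$F))
  cat(sprintf("  lysis G = %g, T = %g; influent phi0 = %g, psi0 = %g\n",
              x$G, x$T, x$phi0, x$psi0))
  cat(sprintf("  discretization p0 = %d, Q_max = %d; MOI proxy C*psi0 = %g\n",
              x$p0, x$Q_max, x$C * x$psi0))
  invisible(x)
}

#' Defense strategy of a genotype
#'
#' A genotype's strategy has two components: PCD investment \code{a} (the cell
#' self-destructs once its intracellular virus concentration reaches
#' \code{1 - a}; \code{a = 0} never, \code{a = 1} on the first virion) and
#' immunity investment \code{r} (intracellular virions are cleared at rate
#' \code{r * p} at growth cost \code{1 - r/E}).
#'
#' @param a PCD investment in [0, 1].
#' @param r Immunity rate, in [0, E] for the ecology it is used with.
#' @return An object of class \code{"defense_strategy"}.
#' @examples
#' defense_strategy(a = 0.95, r = 0.005)
#' defense_strategy(0, 0)    # undefended
#' @export
defense_strategy <- function(a, r) {
  stopifnot(is.numeric(a), length(a) == 1, is.numeric(r), length(r) == 1)
  if (a < 0 || a > 1) stop("PCD investment a must lie in [0, 1]")
  if (r < 0) stop("immunity investment r must be >= 0")
  structure(list(a = a, r = r), class = "defense_strategy")
}

#' @exportS3Method base::print
print.defense_strategy <- function(x, ...) {
  cat(sprintf("Defense strategy: a = %g (PCD threshold %g), r = %g\n",
              x$a, 1 - x$a, x$r))
  invisible(x)
}

check_strategy <- function(strategy, params) {
  if (!inherits(strategy, "defense_strategy"))
    strategy <- defense_strategy(strategy$a, strategy$r)
  if (strategy$r > params$E + 1e-12)
    stop("immunity investment r exceeds the ecology's maximum E = ", params$E)
  if (params$E == 0 && strategy$r > 0)
    stop("r > 0 requires E > 0")
  strategy
}

#' Integration control settings
#'
#' Numerical controls for the chemostat integrator. The integrator uses a
#' uniformization scheme: per-state outflow over a step is integrated exactly
#' and redistributed proportionally to destination rates, which preserves
#' positivity for any step size; the step size adapts to the largest outflow
#' rate among states carrying at least \code{floor_rel} of the population.
#' The virion axis is unit-spaced up to \code{q_lin} and geometric (factor
#' \code{q_ratio}) above, with transport rates scaled by node spacing.
#'
#' @param tol Convergence tolerance: maximum relative change of population
#'   size, nutrient and virus concentration per host generation.
#' @param t_max Maximum integration time (model time units).
#' @param t_min Minimum integration time before convergence may be declared.
#' @param eta Target per-step outflow fraction for rate-resolved states.
#' @param dt_max Hard upper bound on the step size.
#' @param check_every Interval (time units) between convergence checks.
#' @param recalc Steps between step-size / active-window re-estimation.
#' @param floor_rel Relative mass floor for states whose rates bound the step.
#' @param qtop_rel Relative mass floor for the active virion-axis window.
#' @param q_lin Last unit-spaced virion node.
#' @param q_ratio Geometric growth factor of virion-node spacing above
#'   \code{q_lin}.
#' @param record_burst Record the lysis-flux-weighted burst histogram at the
#'   end of an equilibrium run.
#' @return A named list of class \code{"sim_control"}.
#' @export
sim_control <- function(tol = 1e-6, t_max = 400, t_min = 5, eta = 0.3,
                        dt_max = 0.02, check_every = 0.25, recalc = 16L,
                        floor_rel = 1e-7, qtop_rel = 1e-14, q_lin = 48L,
                        q_ratio = 1.08, record_burst = TRUE) {
  structure(list(tol = tol, t_max = t_max, t_min = t_min, eta = eta,
                 dt_max = dt_max, check_every = check_every,
                 recalc = as.integer(recalc), floor_rel = floor_rel,
                 qtop_rel = qtop_rel, q_lin = as.integer(q_lin),
                 q_ratio = q_ratio, record_burst = record_burst),
            class = "sim_control")
}

# Cell volume is expressed in the same natural units as virion capacity
# (a newborn cell holds Q_max virions at concentration 1, so its volume is
# Q_max volume units). The lattice tracks volume in p0 substeps of the
# newborn volume; per-volume rates (uptake C, immunity r and its scale E)
# are converted by Q_max/p0 so that per-cell rates are independent of the
# lattice resolution. Division timing is scale-invariant by construction.
rate_scale <- function(params) params$Q_max / params$p0

internal_params <- function(params) {
  s <- rate_scale(params)
  p <- unclass(params)
  p$C <- p$C * s
  p$E <- p$E * s
  p
}

# Default initial condition: an established population at the virus-free
# carrying-capacity scale, all newborn, nutrient at its quasi-steady value,
# virus entering through the influent only (psi(0) = 0). Small inocula are
# not viable under strong viral pressure (the population must be large
# enough to suppress free virus by consumption), so equilibrium fitness is
# defined for established populations.
default_init <- function(params, a, control = sim_control()) {
  Ceff <- params$C * rate_scale(params)
  phig <- min(0.9 * params$phi0,
              params$B * log(2) / max(params$A, .Machine$double.xmin))
  V0 <- params$B * max(params$phi0 - phig, 0) / (Ceff * phig)
  st <- new_population_state(params, a, control)
  st$n[1, 1] <- V0 / params$p0
  st$phi <- params$phi0 * params$B / (params$B + Ceff * V0)
  st$psi <- 0
  st
}

# highest virion count admissible anywhere on the lattice for a strategy
q_cap <- function(params, a) {
  bound <- if (a > 0) min(params$T, 1 - a) else params$T
  max(1L, as.integer(ceiling(2 * bound * params$Q_max)) - 1L)
}

# host generation time at maximum nutrient, in model time units
generation_time <- function(params) log(2) / max(params$A * params$phi0,
                                                 .Machine$double.xmin)
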