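#' Scan the defense-strategy fitness landscape
#'
#' Evaluates equilibrium fitness (population size N*) over a grid of defense
#' strategies (PCD investment \code{a} by scaled immunity investment
#' \code{r/E}) for a fixed ecology. Within a column of constant \code{a},
#' successive grid points are warm-started from the previous equilibrium;
#' results are independent of evaluation order up to integration tolerance.
#'
#' @param params A \code{\link{chemostat_params}} object.
#' @param a_grid PCD-investment grid in [0, 1].
#' @param rE_grid Scaled immunity grid in [0, 1] (mapped to \code{r = rE * E}).
#' @param control A \code{\link{sim_control}}.
#' @param warm_start Reuse neighboring equilibria as initial states.
#' @return An object of class \code{"defense_landscape"}: \code{fitness}
#'   matrix (rows \code{a_grid}, columns \code{rE_grid}), \code{converged}
#'   logical matrix, the grid vectors, the grid optimum \code{a_opt},
#'   \code{r_opt}, \code{rE_opt}, its fitness, and the PCD-sensitivity
#'   \code{S} with classification \code{sensitive} (threshold 0.1) when the
#'   grid contains \code{a = 0}.
#' @seealso \code{\link{refine_optimum}}, \code{\link{pcd_sensitivity}}
#' @export
scan_landscape <- function(params, a_grid = seq(0, 1, length.out = 21),
                           rE_grid = seq(0, 1, length.out = 21),
                           control = sim_control(), warm_start = TRUE) {
  stopifnot(all(a_grid >= 0 & a_grid <= 1), all(rE_grid >= 0 & rE_grid <= 1))
  a_grid <- sort(unique(a_grid))
  rE_grid <- sort(unique(rE_grid))
  fitness <- matrix(NA_real_, length(a_grid), length(rE_grid),
                    dimnames = list(a = signif(a_grid, 6),
                                    rE = signif(rE_grid, 6)))
  conv <- matrix(NA, length(a_grid), length(rE_grid))
  col_init <- NULL
  for (ia in seq_along(a_grid)) {
    init <- col_init
    for (ir in seq_along(rE_grid)) {
      eq <- run_to_equilibrium(params,
                               defense_strategy(a_grid[ia],
                                                rE_grid[ir] * params$E),
                               init = if (warm_start) init else NULL,
                               control = control)
      fitness[ia, ir] <- eq$fitness
      conv[ia, ir] <- eq$converged || eq$extinct
      if (warm_start) {
        if (!eq$extinct) init <- eq else init <- NULL
        if (ir == 1 && !eq$extinct) col_init <- eq
      }
    }
  }
  opt <- grid_argmax(fitness)
  S <- NA_real_
  if (any(a_grid == 0) && fitness[opt[1], opt[2]] > 0)
    S <- 1 - min(1, fitness[which(a_grid == 0), opt[2]] /
                      fitness[opt[1], opt[2]])
  structure(list(fitness = fitness, converged = conv, a_grid = a_grid,
                 rE_grid = rE_grid, a_opt = a_grid[opt[1]],
                 rE_opt = rE_grid[opt[2]],
                 r_opt = rE_grid[opt[2]] * params$E,
                 f_opt = fitness[opt[1], opt[2]],
                 S = S, sensitive = if (is.na(S)) NA else S >= 0.1,
                 params = params),
            class = "defense_landscape")
}

# argmax with ties broken toward smaller a (row), then smaller r (column)
grid_argmax <- function(fitness) {
  best <- c(1L, 1L)
  fbest <- fitness[1, 1]
  for (ir in seq_len(ncol(fitness)))
    for (ia in seq_len(nrow(fitness))) {
      f <- fitness[ia, ir]
      if (is.na(f)) next
      if (is.na(fbest) || f > fbest ||
          (f == fbest && (ia < best[1] ||
                          (ia == best[1] && ir < best[2])))) {
        fbest <- f; best <- c(ia, ir)
      }
    }
  best
}

#' @exportS3Method base::print
print.defense_landscape <- function(x, ...) {
  cat(sprintf("Defense fitness landscape (%d x %d grid)\n",
              length(x$a_grid), length(x$rE_grid)))
  cat(sprintf("  optimum: a = %g, r/E = %g (fitness %.6g)\n",
              x$a_opt, x$rE_opt, x$f_opt))
  if (!is.na(x$S))
    cat(sprintf("  PCD-sensitivity S = %.4g (%s)\n", x$S,
                if (x$sensitive) "PCD-sensitive" else "PCD-insensitive"))
  if (any(!x$converged, na.rm = TRUE))
    cat(sprintf("  WARNING: %d grid point(s) not converged\n",
                sum(!x$converged, na.rm = TRUE)))
  invisible(x)
}

#' Refine a strategy optimum beyond grid resolution
#'
#' Nested grid refinement around an incumbent optimum: a local 5x5 grid with
#' half the previous spacing is evaluated around the incumbent, the incumbent
#' updated (ties toward smaller \code{a}, then smaller \code{r}), and the
#' spacing halved until both box widths fall below tolerance. Grids leaving
#' the unit box are clipped.
#'
#' @param params A \code{\link{chemostat_params}}.
#' @param landscape A \code{\link{scan_landscape}} result, or a list with
#'   fields \code{a_opt}, \code{rE_opt} (and optionally the grid spacings
#'   \code{da}, \code{drE}).
#' @param tol_a,tol_rE Target half-widths of the refinement box.
#' @param control A \code{\link{sim_control}}.
#' @param fitness_fn Fitness evaluator \code{function(a, rE, init)} returning
#'   a list with \code{fitness} (and optionally a warm-start state); defaults
#'   to the chemostat equilibrium. Supplying an analytic surface allows the
#'   refinement itself to be verified against a known maximum.
#' @return List with \code{a_opt}, \code{r_opt}, \code{rE_opt},
#'   \code{fitness} and the number of evaluations.
#' @export
refine_optimum <- function(params, landscape, tol_a = 1e-3, tol_rE = 1e-3,
                           control = sim_control(), fitness_fn = NULL) {
  a0 <- landscape$a_opt
  rE0 <- landscape$rE_opt
  da <- landscape$da %||%
    (if (length(landscape$a_grid) > 1) diff(landscape$a_grid[1:2]) else 0.05)
  drE <- landscape$drE %||%
    (if (length(landscape$rE_grid) > 1) diff(landscape$rE_grid[1:2]) else 0.05)
  if (is.null(fitness_fn)) {
    warm <- NULL
    fitness_fn <- function(a, rE, init) {
      eq <- run_to_equilibrium(params, defense_strategy(a, rE * params$E),
                               init = init, control = control)
      list(fitness = eq$fitness, state = if (!eq$extinct) eq else NULL)
    }
  }
  warm <- NULL
  fbest <- fitness_fn(a0, rE0, NULL)
  warm <- fbest$state
  fbest <- fbest$fitness
  evals <- 1L
  clip01 <- function(x) pmin(1, pmax(0, x))
  while (da > tol_a || drE > tol_rE) {
    da <- da / 2; drE <- drE / 2
    a_loc <- sort(unique(clip01(a0 + da * (-2:2))))
    rE_loc <- sort(unique(clip01(rE0 + drE * (-2:2))))
    for (rE in rE_loc) for (a in a_loc) {
      if (a == a0 && rE == rE0) next
      res <- fitness_fn(a, rE, warm)
      evals <- evals + 1L
      f <- res$fitness
      if (!is.null(res$state)) warm <- res$state
      if (f > fbest || (f == fbest && (a < a0 || (a == a0 && rE < rE0)))) {
        fbest <- f; a0 <- a; rE0 <- rE
      }
    }
  }
  list(a_opt = a0, rE_opt = rE0, r_opt = rE0 * params$E, fitness = fbest,
       evals = evals)
}

#' PCD-sensitivity of an ecology
#'
#' \code{S = 1 - N*(a = 0, r_opt) / N*(a_opt, r_opt)}: the fitness an optimal
#' population would lose if PCD were switched off at fixed immunity. An
#' ecology with \code{S >= 0.1} is classified PCD-sensitive (the landscape
#' shows a pronounced peak in the PCD axis); below the threshold the
#' landscape is a plateau along \code{a}.
#'
#' @param params A \code{\link{chemostat_params}}.
#' @param a_opt,r_opt Optimal strategy (from \code{\link{refine_optimum}}).
#' @param control A \code{\link{sim_control}}.
#' @param N_opt,N_0 Optional precomputed equilibrium fitness at
#'   \code{(a_opt, r_opt)} and \code{(0, r_opt)}; computed if missing.
#' @return List with \code{S} (clipped to [0, 1]; \code{NA} with
#'   \code{undefined = TRUE} when the optimum population is extinct),
#'   \code{sensitive} flag (threshold 0.1), and the two fitness values.
#' @export
pcd_sensitivity <- function(params, a_opt, r_opt, control = sim_control(),
                            N_opt = NULL, N_0 = NULL) {
  if (is.null(N_opt))
    N_opt <- run_to_equilibrium(params, defense_strategy(a_opt, r_opt),
                                control = control)$fitness
  if (is.null(N_0))
    N_0 <- run_to_equilibrium(params, defense_strategy(0, r_opt),
                              control = control)$fitness
  if (!is.finite(N_opt) || N_opt <= 0)
    return(list(S = NA_real_, sensitive = NA, undefined = TRUE,
                N_opt = N_opt, N_0 = N_0))
  S <- min(1, max(0, 1 - N_0 / N_opt))
  list(S = S, sensitive = S >= 0.1, undefined = FALSE,
       N_opt = N_opt, N_0 = N_0)
}

#' Track the optimal strategy along an ecological parameter sweep
#'
#' For each value of the swept parameter the fitness landscape is scanned,
#' the optimum refined, and the PCD-sensitivity computed. Neighboring value
#' pairs in which both ecologies are PCD-sensitive (S >= 0.1) are flagged;
#' optimal-investment trends are interpretable on those pairs, since on
#' insensitive plateaus the optimum location along \code{a} is imprecise.
#'
#' @param params Base \code{\link{chemostat_params}}.
#' @param which One of \code{"psi0"} (viral pressure), \code{"C"} (inverse
#'   carrying capacity), \code{"E"} (immunity cost scale), \code{"F"} (virus
#'   replication rate).
#' @param values Numeric vector (length >= 2) of parameter values.
#' @param a_grid,rE_grid Strategy grids for the coarse scan.
#' @param control A \code{\link{sim_control}}.
#' @param refine Refine each optimum beyond the grid (logical).
#' @param tol_a,tol_rE Refinement tolerances.
#' @return Data frame with one row per value: \code{value}, \code{a_opt},
#'   \code{r_opt}, \code{rE_opt}, \code{fitness}, \code{S},
#'   \code{sensitive}, and \code{pair_sensitive} (TRUE when this value and
#'   the next are both sensitive).
#' @export
sweep_parameter <- function(params, which = c("psi0", "C", "E", "F"), values,
                            a_grid = seq(0, 1, length.out = 11),
                            rE_grid = seq(0, 1, length.out = 11),
                            control = sim_control(), refine = TRUE,
                            tol_a = 2e-3, tol_rE = 2e-3) {
  which <- match.arg(which)
  if (length(values) < 1) stop("empty value list")
  if (length(values) < 2) stop("sweep needs at least 2 values")
  rows <- vector("list", length(values))
  for (i in seq_along(values)) {
    p <- params
    p[[which]] <- values[i]
    validate_chemostat_params(p)
    ls <- scan_landscape(p, a_grid, rE_grid, control = control)
    if (refine) {
      op <- refine_optimum(p, ls, tol_a = tol_a, tol_rE = tol_rE,
                           control = control)
    } else {
      op <- ls[c("a_opt", "rE_opt", "r_opt")]
      op$fitness <- ls$f_opt
    }
    sens <- pcd_sensitivity(p, op$a_opt, op$r_opt, control = control,
                            N_opt = op$fitness,
                            N_0 = if (any(ls$a_grid == 0) && !refine)
                              ls$fitness[1, match(op$rE_opt, ls$rE_grid)]
                            else NULL)
    rows[[i]] <- data.frame(value = values[i], a_opt = op$a_opt,
                            r_opt = op$r_opt, rE_opt = op$rE_opt,
                            fitness = op$fitness, S = sens$S,
                            sensitive = isTRUE(sens$sensitive))
  }
  out <- do.call(rbind, rows)
  out$pair_sensitive <- c(out$sensitive[-1] & out$sensitive[-nrow(out)], NA)
  out
}
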