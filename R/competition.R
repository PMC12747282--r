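#' Altruist-cheater competition in a shared chemostat
#'
#' Couples two genotypes through shared nutrient and virus pools: an altruist
#' (typically the ecology's optimal strategy, PCD-competent) and a cheater
#' (same immunity investment, no PCD). Both genotypes are seeded from the
#' altruist-strategy single-population equilibrium profile, scaled by the
#' initial fractions, and integrated deterministically.
#'
#' @param params A \code{\link{chemostat_params}}.
#' @param altruist,cheater \code{\link{defense_strategy}} objects. By
#'   convention the cheater has \code{a = 0}; any pair is accepted.
#' @param init_fraction Initial cheater fraction, in (0, 1).
#' @param t_max Duration of the competition (model time units).
#' @param record_every Sampling interval of the trajectory (time units);
#'   defaults to one host generation.
#' @param control A \code{\link{sim_control}}.
#' @param init Optional \code{\link{run_to_equilibrium}} object used as the
#'   seeding profile (computed if missing).
#' @return Object of class \code{"competition_run"}: \code{trajectory} data
#'   frame (t, N_altruist, N_cheater, cheater_fraction, phi, psi), final
#'   state, and a \code{joint_extinct} flag.
#' @export
run_competition <- function(params, altruist, cheater,
                            init_fraction = 0.5, t_max = 400,
                            record_every = NULL, control = sim_control(),
                            init = NULL) {
  altruist <- check_strategy(altruist, params)
  cheater <- check_strategy(cheater, params)
  if (init_fraction <= 0 || init_fraction >= 1)
    stop("init_fraction must lie strictly between 0 and 1")
  if (is.null(record_every)) record_every <- generation_time(params)
  if (is.null(init))
    init <- run_to_equilibrium(params, altruist, control = control)
  na <- init$state$n * (1 - init_fraction)
  nc <- init$state$n * init_fraction
  s <- rate_scale(params)
  raw <- cpp_advance_pair(na, as.integer(init$state$qgrid), altruist$a,
                          altruist$r * s, nc, as.integer(init$state$qgrid),
                          cheater$a, cheater$r * s, init$phi, init$psi,
                          internal_params(params), t_max, unclass(control),
                          record_every)
  tr <- as.data.frame(raw$trajectory)
  names(tr) <- c("t", "N_altruist", "N_cheater", "phi", "psi")
  tot <- tr$N_altruist + tr$N_cheater
  tr$cheater_fraction <- ifelse(tot > 0, tr$N_cheater / tot, NA_real_)
  structure(list(trajectory = tr, params = params, altruist = altruist,
                 cheater = cheater,
                 final = raw[c("n1", "n2", "qgrid1", "qgrid2", "phi", "psi",
                               "N1", "N2")],
                 joint_extinct = (raw$N1 + raw$N2) <= 0),
            class = "competition_run")
}

#' @exportS3Method base::print
print.competition_run <- function(x, ...) {
  tr <- x$trajectory
  cat(sprintf("Competition run: %d samples over t = [0, %.4g]\n",
              nrow(tr), max(tr$t)))
  cat(sprintf("  cheater fraction %.4f -> %.4f%s\n",
              tr$cheater_fraction[1], tr$cheater_fraction[nrow(tr)],
              if (x$joint_extinct) " [joint extinction]" else ""))
  invisible(x)
}

#' Classify the outcome of a competition trajectory
#'
#' Fits a linear trend to the cheater fraction over the final window of the
#' trajectory; the slope, expressed per host generation, decides between
#' neutrality (\code{|slope| < slope_tol}), cheater fixation (positive) and
#' altruist advantage (negative). A trajectory that has already saturated at
#' 0 or 1 is classified directly.
#'
#' @param trajectory Data frame with columns \code{t} and
#'   \code{cheater_fraction} (e.g. from \code{\link{run_competition}}), or a
#'   \code{"competition_run"} object.
#' @param window Fraction of the trajectory (from the end) used for the
#'   trend fit, in (0, 1].
#' @param slope_tol Neutrality tolerance on the slope, per generation.
#' @param params Optional \code{\link{chemostat_params}} used to convert the
#'   slope to per-generation units; taken from the run object when given,
#'   otherwise the trajectory's time unit is assumed to be generations.
#' @return List with \code{outcome} (one of \code{"cheater_fixation"},
#'   \code{"neutral"}, \code{"altruist_advantage"}) and \code{slope}
#'   (cheater-fraction change per generation).
#' @export
classify_outcome <- function(trajectory, window = 0.5, slope_tol = 1e-4,
                             params = NULL) {
  if (inherits(trajectory, "competition_run")) {
    params <- trajectory$params
    trajectory <- trajectory$trajectory
  }
  if (window <= 0 || window > 1) stop("window must lie in (0, 1]")
  tr <- trajectory[!is.na(trajectory$cheater_fraction), , drop = FALSE]
  n <- nrow(tr)
  if (n < 5) stop("trajectory too short to classify (need >= 5 samples)")
  keep <- tr$t >= max(tr$t) - window * (max(tr$t) - min(tr$t))
  tr <- tr[keep, , drop = FALSE]
  if (nrow(tr) < 3) stop("window leaves fewer than 3 samples")
  gen <- if (!is.null(params)) generation_time(params) else 1
  f <- tr$cheater_fraction
  if (all(f >= 1 - 1e-9)) return(list(outcome = "cheater_fixation", slope = 0))
  if (all(f <= 1e-9)) return(list(outcome = "altruist_advantage", slope = 0))
  slope <- unname(coef(lm(f ~ tr$t))[2]) * gen
  outcome <- if (abs(slope) < slope_tol) "neutral"
  else if (slope > 0) "cheater_fixation" else "altruist_advantage"
  list(outcome = outcome, slope = slope)
}

#' Expected progeny forfeited by committing PCD
#'
#' For each cell state (volume p, virion count q) the expected number of
#' future divisions of a single cell following the within-chemostat Markov
#' chain (growth, virus replication, immunity clearance, infection, lysis,
#' dilution) at fixed ambient nutrient and virus levels. States at or beyond
#' the PCD threshold are absorbing with value 0, so the value just below the
#' threshold is the expectation the committing cell forfeits. Computed by a
#' sparse linear solve over the (p, q) lattice.
#'
#' @param params A \code{\link{chemostat_params}}.
#' @param strategy A \code{\link{defense_strategy}}.
#' @param phi,psi Ambient nutrient and virus concentration (e.g. from an
#'   equilibrium).
#' @return Matrix of expected future divisions, rows p = p0..2*p0, columns
#'   q = 0..q_cap (unit spacing).
#' @export
expected_progeny_loss <- function(params, strategy, phi, psi) {
  strategy <- check_strategy(strategy, params)
  a <- strategy$a
  r <- strategy$r * rate_scale(params)   # per-lattice-volume clearance rate
  Ceff <- params$C * rate_scale(params)
  p0 <- params$p0
  np <- p0 + 1
  bound <- if (a > 0) min(params$T, 1 - a) else params$T
  nq <- q_cap(params, a) + 1L   # unit-spaced lattice: q = 0 .. qcap
  idx <- function(i, k) (k - 1L) * np + i    # i: 1..np (p = p0+i-1), k: 1..nq
  nst <- np * nq
  cap <- 7L * nst
  trip_i <- integer(cap); trip_j <- integer(cap); trip_x <- numeric(cap)
  ntrip <- 0L
  rhs <- numeric(nst)
  gm <- params$A *
    (1 - if (params$E > 0) strategy$r / params$E else 0) * phi
  add <- function(i, j, x) {
    ntrip <<- ntrip + 1L
    trip_i[ntrip] <<- i; trip_j[ntrip] <<- j; trip_x[ntrip] <<- x
  }
  active <- matrix(FALSE, np, nq)
  for (k in seq_len(nq)) for (i in seq_len(np)) {
    q <- k - 1L; p <- p0 + i - 1L
    active[i, k] <- (q * p0 / (params$Q_max * p)) < bound
  }
  for (k in seq_len(nq)) for (i in seq_len(np)) {
    s <- idx(i, k)
    if (!active[i, k]) { add(s, s, 1); next }   # absorbing: D = 0
    q <- k - 1L; p <- p0 + i - 1L
    rho <- q * p0 / (params$Q_max * p)
    g <- if (i < np || q == 0) gm * p else 0
    f <- if (q > 0) params$F * q else 0
    h <- if (q > 0) r * p else 0
    lam <- if (q > 0) lysis_rate(rho, params) else 0
    inf <- if (q == 0) Ceff * psi * p else 0
    R <- g + f + h + lam + inf + params$B
    if (R <= 0) { add(s, s, 1); next }
    add(s, s, R)
    if (g > 0) {
      if (i < np) add(s, idx(i + 1L, k), -g)
      else { add(s, idx(1L, 1L), -g); rhs[s] <- rhs[s] + g }  # division: +1
    }
    if (f > 0 && active[i, min(k + 1L, nq)] && k < nq)
      add(s, idx(i, k + 1L), -f)    # else absorbed (PCD/lysis): value 0
    if (h > 0) add(s, idx(i, k - 1L), -h)
    if (inf > 0) add(s, idx(i, 2L), -inf)
    # lysis and dilution absorb with value 0
  }
  A <- Matrix::sparseMatrix(i = trip_i[seq_len(ntrip)],
                            j = trip_j[seq_len(ntrip)],
                            x = trip_x[seq_len(ntrip)],
                            dims = c(nst, nst))
  D <- tryCatch(as.numeric(Matrix::solve(A, rhs)),
                error = function(e) rep(0, nst))
  matrix(pmax(D, 0), np, nq,
         dimnames = list(p = p0:(2 * p0), q = 0:(nq - 1L)))
}
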