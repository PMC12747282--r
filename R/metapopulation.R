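#' Parameters of the structured-metapopulation model
#'
#' A fully connected ensemble of chemostats ("patches": gut microbiomes,
#' biofilm pockets), each holding an altruist (PCD-competent) and a cheater
#' (PCD-incompetent) subpopulation coupled through shared local media.
#' Patches undergo a birth-death process (birth rate \code{b*(K-k)/K},
#' death rate \code{d} per patch); migration events occur with
#' exponentially distributed waiting times (mean \code{m}); the source patch
#' is chosen proportionally to its rounded population size (larger
#' populations send out more migrants, the engine of the Simpson's-paradox
#' effect), the destination uniformly among the other patches, and the
#' number of migrants is Binomial(N_source, f), split binomially between
#' genotypes.
#'
#' @param chemostat A \code{\link{chemostat_params}} object (per-patch
#'   ecology).
#' @param altruist Altruist \code{\link{defense_strategy}} (typically the
#'   ecology's optimum).
#' @param cheater Cheater strategy; defaults to \code{(0, r_altruist)}.
#' @param K Patch carrying capacity (maximum patch count).
#' @param b Patch birth-rate scale.
#' @param d Patch death rate (per patch).
#' @param m Mean waiting time between migration events. The equivalent
#'   migration rate \code{r_m = 1/m} is accepted via argument \code{r_m}.
#' @param f Per-individual migration probability.
#' @param k0 Initial number of occupied patches.
#' @param init_fraction Initial cheater fraction in occupied patches.
#' @param r_m Optional migration rate; if given, \code{m = 1/r_m}.
#' @return A \code{"metapop_params"} object.
#' @export
metapop_params <- function(chemostat = chemostat_params(),
                           altruist, cheater = NULL,
                           K = 20, b = 0.4, d = 0.01, m = 1.0, f = 1e-4,
                           k0 = 5, init_fraction = 0.5, r_m = NULL) {
  if (!is.null(r_m)) m <- 1 / r_m
  altruist <- check_strategy(altruist, chemostat)
  if (is.null(cheater)) cheater <- defense_strategy(0, altruist$r)
  cheater <- check_strategy(cheater, chemostat)
  stopifnot(K >= 1, b >= 0, d >= 0, m > 0, f >= 0, f <= 1,
            k0 >= 1, k0 <= K, init_fraction > 0, init_fraction < 1)
  structure(list(chemostat = chemostat, altruist = altruist,
                 cheater = cheater, K = as.integer(K), b = b, d = d, m = m,
                 f = f, k0 = as.integer(k0), init_fraction = init_fraction),
            class = "metapop_params")
}

# patch state: list(na, nc (lattice matrices), phi, psi, Na, Nc)
patch_sizes <- function(state) {
  vapply(state, function(ch) ch$Na + ch$Nc, numeric(1))
}

#' Draw and apply one migration event
#'
#' The source patch is drawn with probability proportional to its population
#' size rounded to the nearest whole individual; the destination is uniform
#' among the other patches; \code{n_m ~ Binomial(round(N_i), f)} individuals
#' migrate, of which \code{n_ma ~ Binomial(n_m, N_i^a / N_i)} are altruists
#' (the rest cheaters). Migrant mass is removed from the source lattices
#' proportionally and added to the destination.
#'
#' @param state List of patch states (internal representation as produced by
#'   \code{\link{simulate_metapopulation}}).
#' @param f Per-individual migration probability.
#' @return List with the updated \code{state} and an \code{event} record
#'   (source, destination, n_m, n_ma, n_mc), or \code{event = NULL} when no
#'   migration is possible (fewer than 2 patches or all empty).
#' @export
draw_migration_event <- function(state, f) {
  k <- length(state)
  if (k < 2) return(list(state = state, event = NULL))
  sizes <- round(patch_sizes(state))
  if (sum(sizes) <= 0) return(list(state = state, event = NULL))
  src <- sample.int(k, 1, prob = sizes / sum(sizes))
  # destination: uniform over patches other than the source
  others <- setdiff(seq_len(k), src)
  dst <- if (length(others) == 1) others else sample(others, 1)
  Ni <- sizes[src]
  n_m <- rbinom(1, Ni, f)
  Na <- state[[src]]$Na; Nc <- state[[src]]$Nc
  pa <- if (Na + Nc > 0) Na / (Na + Nc) else 0
  n_ma <- rbinom(1, n_m, pa)
  n_mc <- n_m - n_ma
  if (n_m > 0) {
    # remove proportional lattice slices from the source, add to destination
    if (n_ma > 0 && Na > 0) {
      fr <- min(1, n_ma / Na)
      slice <- state[[src]]$na * fr
      state[[src]]$na <- state[[src]]$na - slice
      state[[dst]]$na <- state[[dst]]$na + slice
      state[[src]]$Na <- sum(state[[src]]$na)
      state[[dst]]$Na <- sum(state[[dst]]$na)
    }
    if (n_mc > 0 && Nc > 0) {
      fr <- min(1, n_mc / Nc)
      slice <- state[[src]]$nc * fr
      state[[src]]$nc <- state[[src]]$nc - slice
      state[[dst]]$nc <- state[[dst]]$nc + slice
      state[[src]]$Nc <- sum(state[[src]]$nc)
      state[[dst]]$Nc <- sum(state[[dst]]$nc)
    }
  }
  list(state = state,
       event = list(source = src, destination = dst, n_m = n_m,
                    n_ma = n_ma, n_mc = n_mc))
}

#' Apply a patch birth or death event
#'
#' Births (propensity \code{b*(K-k)/K}) add an empty patch with fresh media
#' (\code{phi = phi0}, \code{psi = psi0}); deaths (propensity \code{d} per
#' patch) remove a uniformly chosen patch with all inhabitants.
#'
#' @param state List of patch states.
#' @param mp A \code{\link{metapop_params}} object.
#' @param type \code{"birth"} or \code{"death"}.
#' @return List with updated \code{state} and the \code{event} record.
#' @export
chemostat_birth_death <- function(state, mp, type = c("birth", "death")) {
  type <- match.arg(type)
  if (type == "birth") {
    if (length(state) >= mp$K) return(list(state = state, event = NULL))
    state[[length(state) + 1]] <- empty_patch(mp)
    return(list(state = state,
                event = list(type = "birth", patch = length(state))))
  }
  if (length(state) == 0) return(list(state = state, event = NULL))
  victim <- if (length(state) == 1) 1L else sample.int(length(state), 1)
  state[[victim]] <- NULL
  list(state = state, event = list(type = "death", patch = victim))
}

empty_patch <- function(mp, template = NULL) {
  p <- mp$chemostat
  ctl <- mp$control %||% sim_control()
  if (is.null(template)) {
    qa <- cpp_build_qgrid(q_cap(p, mp$altruist$a), ctl$q_lin, ctl$q_ratio)
    qc <- cpp_build_qgrid(q_cap(p, mp$cheater$a), ctl$q_lin, ctl$q_ratio)
  } else {
    qa <- template$qga; qc <- template$qgc
  }
  # born with fresh sterile media: virus arrives via the influent
  list(na = matrix(0, p$p0 + 1, length(qa)),
       nc = matrix(0, p$p0 + 1, length(qc)),
       qga = qa, qgc = qc, phi = p$phi0, psi = 0, Na = 0, Nc = 0)
}

#' Simulate the structured metapopulation
#'
#' Event-driven (Gillespie) simulation: migration, patch birth and patch
#' death compete as exponential clocks; between events every patch's
#' two-genotype chemostat dynamics advance deterministically. Population
#' sizes are converted to whole individuals (rounding) for migration draws;
#' a genotype falling below half an individual in a patch goes locally
#' extinct. The run stops at fixation of either genotype, global extinction,
#' or \code{t_max}.
#'
#' @param mp A \code{\link{metapop_params}} object.
#' @param t_max Simulation horizon (model time units).
#' @param seed Random seed (integer) for reproducibility.
#' @param control A \code{\link{sim_control}} for the within-patch
#'   integrator (a coarser-than-default volume lattice is typical here).
#' @param eps Fixation threshold on the global cheater fraction.
#' @param record_events Keep the full event log.
#' @return A \code{"metapop_run"}: \code{trajectory} data frame (t, k,
#'   N_total, cheater_fraction), \code{outcome} (one of
#'   \code{"altruist_fixation"}, \code{"cheater_fixation"}, \code{"ongoing"},
#'   \code{"extinct"}), \code{events} log, final \code{state}.
#' @export
simulate_metapopulation <- function(mp, t_max = 2000, seed = NULL,
                                    control = sim_control(), eps = 1e-3,
                                    record_events = TRUE) {
  stopifnot(inherits(mp, "metapop_params"))
  if (!is.null(seed)) set.seed(seed)
  p <- mp$chemostat
  mp$control <- control
  # seed patches from the altruist-strategy equilibrium
  eq <- run_to_equilibrium(p, mp$altruist, control = control)
  template <- empty_patch(mp)
  seedpatch <- template
  seedpatch$na <- map_to_grid(eq$state$n, eq$state$qgrid, template$qga)
  seedpatch$nc <- map_to_grid(eq$state$n, eq$state$qgrid, template$qgc)
  seedpatch$na <- seedpatch$na * (1 - mp$init_fraction)
  seedpatch$nc <- seedpatch$nc * mp$init_fraction
  seedpatch$Na <- sum(seedpatch$na); seedpatch$Nc <- sum(seedpatch$nc)
  seedpatch$phi <- eq$phi; seedpatch$psi <- eq$psi
  state <- replicate(mp$k0, seedpatch, simplify = FALSE)

  t <- 0
  traj <- list()
  events <- list()
  outcome <- "ongoing"
  ip <- internal_params(p)
  s <- rate_scale(p)
  record <- function() {
    Na <- sum(vapply(state, function(x) x$Na, numeric(1)))
    Nc <- sum(vapply(state, function(x) x$Nc, numeric(1)))
    traj[[length(traj) + 1]] <<- data.frame(
      t = t, k = length(state), N_total = Na + Nc,
      cheater_fraction = if (Na + Nc > 0) Nc / (Na + Nc) else NA_real_)
  }
  record()
  while (t < t_max) {
    k <- length(state)
    rate_mig <- if (k >= 2) 1 / mp$m else 0
    rate_birth <- mp$b * (mp$K - k) / mp$K
    rate_death <- mp$d * k
    total <- rate_mig + rate_birth + rate_death
    if (total <= 0) {
      # no events possible: advance deterministically to the horizon
      for (i in seq_along(state))
        state[[i]] <- advance_patch(state[[i]], mp, ip, s, t_max - t,
                                    control)
      t <- t_max
      record()
      break
    }
    tau <- rexp(1, total)
    tau <- min(tau, t_max - t)
    # advance all patches deterministically by tau
    for (i in seq_along(state)) state[[i]] <- advance_patch(state[[i]], mp,
                                                           ip, s, tau,
                                                           control)
    t <- t + tau
    if (t >= t_max) { record(); break }
    ev <- runif(1) * total
    if (ev < rate_mig) {
      res <- draw_migration_event(state, mp$f)
      state <- res$state
      if (record_events && !is.null(res$event))
        events[[length(events) + 1]] <- c(t = t, type = "migration",
                                          res$event)
    } else if (ev < rate_mig + rate_birth) {
      res <- chemostat_birth_death(state, mp, "birth")
      state <- res$state
      if (record_events && !is.null(res$event))
        events[[length(events) + 1]] <- c(t = t, res$event)
    } else {
      res <- chemostat_birth_death(state, mp, "death")
      state <- res$state
      if (record_events && !is.null(res$event))
        events[[length(events) + 1]] <- c(t = t, res$event)
    }
    record()
    Na <- sum(vapply(state, function(x) x$Na, numeric(1)))
    Nc <- sum(vapply(state, function(x) x$Nc, numeric(1)))
    if (length(state) == 0 || Na + Nc < 1) { outcome <- "extinct"; break }
    fr <- Nc / (Na + Nc)
    if (fr < eps) { outcome <- "altruist_fixation"; break }
    if (fr > 1 - eps) { outcome <- "cheater_fixation"; break }
  }
  traj <- do.call(rbind, traj)
  structure(list(trajectory = traj, outcome = outcome, events = events,
                 state = state, params = mp, t_end = t),
            class = "metapop_run")
}

# advance one patch by tau; culls genotypes below half an individual
advance_patch <- function(ch, mp, ip, s, tau, control) {
  if (ch$Na + ch$Nc <= 0) {
    # empty patch: media relax toward influent at rate B
    decay <- exp(-mp$chemostat$B * tau)
    ch$phi <- mp$chemostat$phi0 + (ch$phi - mp$chemostat$phi0) * decay
    ch$psi <- mp$chemostat$psi0 + (ch$psi - mp$chemostat$psi0) * decay
    return(ch)
  }
  raw <- cpp_advance_pair(ch$na, as.integer(ch$qga), mp$altruist$a,
                          mp$altruist$r * s, ch$nc, as.integer(ch$qgc),
                          mp$cheater$a, mp$cheater$r * s, ch$phi, ch$psi,
                          ip, tau, unclass(control), 0)
  ch$na <- raw$n1; ch$nc <- raw$n2
  ch$phi <- raw$phi; ch$psi <- raw$psi
  ch$Na <- raw$N1; ch$Nc <- raw$N2
  if (ch$Na < 0.5) { ch$na[] <- 0; ch$Na <- 0 }
  if (ch$Nc < 0.5) { ch$nc[] <- 0; ch$Nc <- 0 }
  ch
}

# map a lattice matrix onto another q-grid (largest node <= source q)
map_to_grid <- function(n, qg_from, qg_to) {
  out <- matrix(0, nrow(n), length(qg_to))
  j <- 1L
  for (k0 in seq_along(qg_from)) {
    while (j < length(qg_to) && qg_to[j + 1] <= qg_from[k0]) j <- j + 1L
    if (qg_to[j] <= qg_from[k0]) out[, j] <- out[, j] + n[, k0]
  }
  out
}

#' @exportS3Method base::print
print.metapop_run <- function(x, ...) {
  tr <- x$trajectory
  cat(sprintf("Metapopulation run: %s at t = %.4g (%d events)\n",
              x$outcome, x$t_end, length(x$events)))
  cat(sprintf("  final k = %d patches, global cheater fraction %.4g\n",
              tr$k[nrow(tr)], tr$cheater_fraction[nrow(tr)]))
  invisible(x)
}

#' Classify a metapopulation trajectory
#'
#' @param trajectory A \code{"metapop_run"} or its trajectory data frame
#'   with a \code{cheater_fraction} column.
#' @param eps Fixation threshold on the global cheater fraction.
#' @return \code{"altruist_fixation"}, \code{"cheater_fixation"},
#'   \code{"extinct"} or \code{"ongoing"}.
#' @export
detect_fixation <- function(trajectory, eps = 1e-3) {
  if (inherits(trajectory, "metapop_run")) {
    if (trajectory$outcome != "ongoing") return(trajectory$outcome)
    trajectory <- trajectory$trajectory
  }
  if (NROW(trajectory) == 0) stop("empty trajectory")
  last <- trajectory[nrow(trajectory), ]
  if (!is.finite(last$cheater_fraction)) return("extinct")
  if (last$cheater_fraction < eps) return("altruist_fixation")
  if (last$cheater_fraction > 1 - eps) return("cheater_fixation")
  "ongoing"
}
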