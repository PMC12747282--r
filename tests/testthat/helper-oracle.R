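# Shared fixtures and independent oracles for the test suite.

# A tiny, fast ecology for invariant tests: small lattice, mild rates.
tiny_params <- function(...) {
  defaults <- list(A = 4, B = 0.2, C = 1e-4, E = 0.05, F = 1, G = 1, T = 1,
                   phi0 = 1, psi0 = 100, p0 = 2L, Q_max = 3L)
  do.call(chemostat_params, utils::modifyList(defaults, list(...)))
}

# Term-by-term R oracle for one uniformization step of the chemostat
# lattice, written directly from the per-state rate definitions and kept
# independent of the C++ kernel. Unit-spaced q grid only.
oracle_step <- function(n, phi, psi, params, a, r, dt) {
  s <- params$Q_max / params$p0          # volume-unit conversion
  Ceff <- params$C * s
  Eeff <- params$E * s
  reff <- r * s
  p0 <- params$p0
  np <- p0 + 1
  nq <- ncol(n)
  bound <- if (a > 0) min(params$T, 1 - a) else params$T
  pcd_first <- a > 0 && (1 - a) <= params$T
  rho <- function(p, q) q * p0 / (params$Q_max * p)
  # clear PCD region (virus-bearing states only)
  for (k in seq_len(nq)) for (i in seq_len(np)) {
    if ((k - 1) > 0 && rho(p0 + i - 1, k - 1) >= bound) n[i, k] <- 0
  }
  V <- 0; P0 <- 0
  for (k in seq_len(nq)) for (i in seq_len(np)) {
    V <- V + n[i, k] * (p0 + i - 1)
    if (k == 1) P0 <- P0 + n[i, k] * (p0 + i - 1)
  }
  nn <- matrix(0, np, nq)
  release <- 0; infected <- 0; divisions <- 0; pcd <- 0; lysed <- 0
  gm <- params$A * (1 - if (Eeff > 0) reff / Eeff else 0) * phi
  for (k in seq_len(nq)) for (i in seq_len(np)) {
    m <- n[i, k]
    if (m <= 0) next
    p <- p0 + i - 1
    q <- k - 1
    g <- if (i < np || q == 0) gm * p else 0
    f <- if (q > 0) params$F * q else 0
    h <- if (q > 0) reff * p else 0
    lam <- if (q > 0) {
      rr <- rho(p, q)
      if (rr >= params$T) Inf else (rr / (params$T - rr))^params$G
    } else 0
    inf <- if (q == 0) Ceff * psi * p else 0
    R <- g + f + h + lam + inf + params$B
    if (R <= 0) { nn[i, k] <- nn[i, k] + m; next }
    outm <- m * (1 - exp(-R * dt))
    sh <- outm / R
    nn[i, k] <- nn[i, k] + m - outm
    if (g > 0) {
      if (i < np) nn[i + 1, k] <- nn[i + 1, k] + sh * g
      else { nn[1, 1] <- nn[1, 1] + 2 * sh * g; divisions <- divisions + sh * g }
    }
    if (f > 0) {
      qn <- q + 1
      if (k + 1 <= nq && rho(p, qn) < bound) {
        nn[i, k + 1] <- nn[i, k + 1] + sh * f
      } else if (pcd_first) pcd <- pcd + sh * f
      else { release <- release + sh * f * qn; lysed <- lysed + sh * f }
    }
    if (h > 0) nn[i, k - 1] <- nn[i, k - 1] + sh * h
    if (lam > 0) { release <- release + sh * lam * q; lysed <- lysed + sh * lam }
    if (inf > 0) {
      infected <- infected + sh * inf
      if (rho(p, 1) < bound) nn[i, 2] <- nn[i, 2] + sh * inf
      else pcd <- pcd + sh * inf
    }
  }
  Rphi <- params$B + Ceff * V
  phis <- params$phi0 * params$B / Rphi
  phi_new <- phis + (phi - phis) * exp(-Rphi * dt)
  Rpsi <- params$B + Ceff * P0
  psis <- (params$psi0 * params$B + release / dt) / Rpsi
  psi_new <- psis + (psi - psis) * exp(-Rpsi * dt)
  list(n = nn, phi = phi_new, psi = psi_new, release = release,
       infected = infected, divisions = divisions, pcd = pcd, lysed = lysed)
}

# build a state on a unit q grid for the tiny ecology
tiny_state <- function(params, a = 0, fill = 0) {
  qcap <- defenseEcology:::q_cap(params, a)
  qg <- 0:qcap
  n <- matrix(fill, params$p0 + 1, length(qg),
              dimnames = list(p = params$p0:(2 * params$p0), q = qg))
  list(n = n, qgrid = qg, phi = params$phi0, psi = params$psi0, t = 0)
}
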