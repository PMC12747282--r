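test_that("intracellular concentration follows the newborn normalization", {
  pars <- chemostat_params()
  expect_equal(intracellular_concentration(pars$p0, 1000, pars), 1.0)
  expect_equal(intracellular_concentration(2 * pars$p0, 1000, pars), 0.5)
  expect_equal(intracellular_concentration(15, 0, pars), 0)
  # decreasing in volume at fixed count
  rho <- intracellular_concentration(10:20, 500, pars)
  expect_true(all(diff(rho) < 0))
  expect_error(intracellular_concentration(5, 10, pars), "volume")
  expect_error(intracellular_concentration(10, -1, pars), "nonnegative")
})

test_that("lysis hazard has the stated limits and monotonicity", {
  pars <- chemostat_params(G = 1, T = 1)
  expect_equal(lysis_rate(0, pars), 0)
  expect_equal(lysis_rate(0.5, pars), 1.0)
  expect_equal(lysis_rate(0.25, chemostat_params(G = 2, T = 1)), 1 / 9)
  expect_identical(lysis_rate(1, pars), Inf)
  # strictly increasing on [0, T)
  rho <- seq(0, 0.99, by = 0.01)
  for (G in c(0.5, 1, 3)) {
    h <- lysis_rate(rho, chemostat_params(G = G))
    expect_true(all(diff(h) > 0))
  }
  # larger G lowers the hazard below T/2
  expect_true(all(lysis_rate(c(0.1, 0.3), chemostat_params(G = 4)) <
                  lysis_rate(c(0.1, 0.3), chemostat_params(G = 1))))
  expect_error(lysis_rate(-0.1, pars), "nonnegative")
})

test_that("one kernel step matches the term-by-term oracle", {
  pars <- tiny_params()
  set.seed(42)
  for (strat in list(c(0, 0.02), c(0.5, 0), c(0.8, 0.05), c(1, 0.01))) {
    st <- tiny_state(pars, a = strat[1])
    st$n[] <- runif(length(st$n), 0, 50)
    st$phi <- 0.7; st$psi <- 80
    got <- chemostat_step(st, pars, defense_strategy(strat[1], strat[2]),
                          dt = 0.01)
    exp_ <- oracle_step(st$n, st$phi, st$psi, pars, strat[1], strat[2], 0.01)
    expect_equal(unname(got$n), unname(exp_$n), tolerance = 1e-12)
    expect_equal(got$phi, exp_$phi, tolerance = 1e-12)
    expect_equal(got$psi, exp_$psi, tolerance = 1e-12)
    fl <- attr(got, "fluxes")
    expect_equal(fl$release, exp_$release, tolerance = 1e-12)
    expect_equal(fl$divisions, exp_$divisions, tolerance = 1e-12)
  }
})

test_that("states stay nonnegative across random parameter draws", {
  set.seed(7)
  for (rep in 1:5) {
    pars <- chemostat_params(A = runif(1, 2, 30), B = runif(1, 0.05, 0.2),
                             C = 10^runif(1, -6, -3), E = runif(1, 0.01, 1),
                             F = runif(1, 0.5, 6), G = runif(1, 0.5, 3),
                             T = runif(1, 0.5, 1), psi0 = 10^runif(1, 1, 5),
                             p0 = 4L, Q_max = 50L)
    a <- runif(1); r <- runif(1) * pars$E
    eq <- run_to_equilibrium(pars, defense_strategy(a, r),
                             control = sim_control(t_max = 30))
    expect_true(all(eq$state$n >= 0))
    expect_true(eq$phi >= 0 && eq$psi >= 0)
  }
})

test_that("virus-free equilibrium satisfies the chemostat flux balance", {
  pars <- chemostat_params(psi0 = 0)
  eq <- run_to_equilibrium(pars, defense_strategy(0, 0),
                           control = sim_control(tol = 1e-8))
  expect_true(eq$converged)
  lhs <- pars$B * (pars$phi0 - eq$phi)
  rhs <- pars$C * eq$phi * eq$V
  expect_lt(abs(lhs - rhs) / (pars$B * pars$phi0), 1e-5)
  # doubling C halves the virus-free carrying capacity (total cell volume)
  eq2 <- run_to_equilibrium(chemostat_params(psi0 = 0, C = 2e-8),
                            defense_strategy(0, 0),
                            control = sim_control(tol = 1e-8))
  expect_equal(eq$V / eq2$V, 2, tolerance = 1e-3)
})

test_that("empty chemostat relaxes to influent concentrations at rate B", {
  pars <- tiny_params()
  st <- tiny_state(pars, fill = 0)
  st$phi <- 0; st$psi <- 0
  dt <- 0.05
  st1 <- chemostat_step(st, pars, defense_strategy(0, 0), dt)
  expect_equal(st1$phi, pars$phi0 * (1 - exp(-pars$B * dt)), tolerance = 1e-12)
  expect_equal(st1$psi, pars$psi0 * (1 - exp(-pars$B * dt)), tolerance = 1e-12)
})

test_that("superinfection exclusion: no infection flux out of q >= 1", {
  # F = 0, r = 0: q can only change by infection; seed mass at q = 1 only
  pars <- tiny_params(F = 0)
  st <- tiny_state(pars, a = 0)
  st$n[, 2] <- 10   # all cells at q = 1
  st1 <- chemostat_step(st, pars, defense_strategy(0, 0), 0.02)
  expect_equal(sum(st1$n[, 3:ncol(st1$n)]), 0)
  expect_equal(attr(st1, "fluxes")$infected, 0)
  # whereas q = 0 cells are infected under identical conditions
  st$n[] <- 0; st$n[, 1] <- 10
  st2 <- chemostat_step(st, pars, defense_strategy(0, 0), 0.02)
  expect_gt(attr(st2, "fluxes")$infected, 0)
})

test_that("division conserves volume and adds one cell per event", {
  pars <- tiny_params(psi0 = 0)
  st <- tiny_state(pars)
  st$n[] <- 0
  st$n[nrow(st$n), 1] <- 100   # all cells at division size, uninfected
  st$psi <- 0
  st1 <- chemostat_step(st, pars, defense_strategy(0, 0), 0.01)
  div <- attr(st1, "fluxes")$divisions
  expect_gt(div, 0)
  # newborn mass is twice the divided mass, at half the volume
  expect_equal(st1$n[1, 1], 2 * div, tolerance = 1e-12)
  # total volume change is only dilution (B): division itself conserves it
  vol <- function(n) sum(n * (pars$p0:(2 * pars$p0)))
  drained <- vol(st$n) - vol(st1$n)
  # growth adds volume, dilution removes it; with growth the only other flux
  # here, check division bookkeeping via the exact oracle identity instead
  exp_ <- oracle_step(st$n, st$phi, st$psi, pars, 0, 0, 0.01)
  expect_equal(vol(st1$n), vol(exp_$n), tolerance = 1e-10)
})

test_that("full PCD (a = 1) removes infected mass without virion release", {
  pars <- tiny_params()
  st <- tiny_state(pars, a = 1)
  st$n[, 1] <- 50
  st$psi <- 1000
  st1 <- chemostat_step(st, pars, defense_strategy(1, 0), 0.05)
  fl <- attr(st1, "fluxes")
  expect_gt(fl$infected, 0)      # infections happen
  expect_equal(fl$pcd, fl$infected, tolerance = 1e-12)  # and all die at once
  expect_equal(fl$release, 0)    # PCD never releases virions
  expect_equal(sum(st1$n[, -1]), 0)  # no standing infected mass
})

test_that("PCD-cleared region stays empty and uninfected cells persist", {
  pars <- tiny_params()
  a <- 0.5
  st <- tiny_state(pars, a = 0)    # full grid, mass everywhere
  st$n[] <- 5
  st1 <- chemostat_step(st, pars, defense_strategy(a, 0.01), 0.01)
  rho <- outer(pars$p0:(2 * pars$p0), as.integer(colnames(st$n)),
               function(p, q) q * pars$p0 / (pars$Q_max * p))
  expect_true(all(st1$n[rho >= 1 - a & rho > 0] == 0))
  expect_true(all(st1$n[, 1] > 0))
})

test_that("exponential growth oracle holds in the virus-free linear regime", {
  # psi0 = 0, r = 0, fixed phi: V(t+dt) ~ V (1 + (A phi - B) dt), small dt
  pars <- tiny_params(psi0 = 0)
  st <- tiny_state(pars)
  st$n[] <- 0
  st$n[1, 1] <- 1    # far from capacity: phi ~ phi0 over one tiny step
  vol <- function(n) sum(n * (pars$p0:(2 * pars$p0)))
  dt <- 1e-4
  st1 <- chemostat_step(st, pars, defense_strategy(0, 0), dt)
  growth <- vol(st1$n) / vol(st$n)
  expect_equal(growth, 1 + (pars$A * st$phi - pars$B) * dt, tolerance = 1e-4)
})

test_that("equilibrium runs are deterministic", {
  pars <- tiny_params()
  e1 <- run_to_equilibrium(pars, defense_strategy(0.6, 0.01))
  e2 <- run_to_equilibrium(pars, defense_strategy(0.6, 0.01))
  expect_identical(e1$N, e2$N)
  expect_identical(e1$state$n, e2$state$n)
})

test_that("burst size distribution is normalized and empty under full PCD", {
  pars <- tiny_params()
  eq <- run_to_equilibrium(pars, defense_strategy(0, 0.01))
  b <- burst_size_distribution(eq)
  if (nrow(b) > 0) {
    expect_equal(sum(b$mass), 1, tolerance = 1e-12)
    expect_true(all(b$q >= 1))
  }
  eqa1 <- run_to_equilibrium(pars, defense_strategy(1, 0.01))
  b1 <- burst_size_distribution(eqa1)
  expect_true(isTRUE(attr(b1, "undefined")) || nrow(b1) == 0)
})

test_that("parameter validation rejects out-of-domain values", {
  expect_error(chemostat_params(T = 1.5), "T")
  expect_error(chemostat_params(B = 0), "B")
  expect_error(chemostat_params(p0 = 1), "p0")
  expect_error(chemostat_params(A = -1), "negative")
  expect_error(defense_strategy(1.2, 0), "a")
  expect_error(defense_strategy(0.5, -1), "r")
  expect_error(run_to_equilibrium(chemostat_params(E = 0.01),
                                  defense_strategy(0.5, 0.02)), "exceeds")
})
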