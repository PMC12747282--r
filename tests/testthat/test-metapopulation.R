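# metapopulation event machinery; within-patch dynamics are covered by the
# chemostat and competition suites

mk_state <- function(sizes_a, sizes_c, mp) {
  lapply(seq_along(sizes_a), function(i) {
    ch <- defenseEcology:::empty_patch(mp)
    ch$na[1, 1] <- sizes_a[i]; ch$Na <- sizes_a[i]
    ch$nc[1, 1] <- sizes_c[i]; ch$Nc <- sizes_c[i]
    ch
  })
}

test_params <- function() {
  mp <- metapop_params(tiny_params(), defense_strategy(0.8, 0.01),
                       K = 10, k0 = 2)
  mp$control <- sim_control()
  mp
}

test_that("migration conserves individuals and splits them binomially", {
  mp <- test_params()
  set.seed(11)
  state <- mk_state(c(200, 50), c(100, 25), mp)
  before_a <- sum(vapply(state, function(x) x$Na, 1))
  before_c <- sum(vapply(state, function(x) x$Nc, 1))
  res <- draw_migration_event(state, f = 0.2)
  ev <- res$event
  expect_equal(ev$n_ma + ev$n_mc, ev$n_m)
  after_a <- sum(vapply(res$state, function(x) x$Na, 1))
  after_c <- sum(vapply(res$state, function(x) x$Nc, 1))
  expect_equal(after_a, before_a, tolerance = 1e-9)
  expect_equal(after_c, before_c, tolerance = 1e-9)
  # source lost exactly what the destination gained
  expect_equal(res$state[[ev$source]]$Na + res$state[[ev$source]]$Nc,
               state[[ev$source]]$Na + state[[ev$source]]$Nc - ev$n_m,
               tolerance = 1e-6)
})

test_that("f = 0 sends no migrants; all-altruist sources send no cheaters", {
  mp <- test_params()
  set.seed(3)
  state <- mk_state(c(100, 100), c(50, 50), mp)
  for (i in 1:5) expect_equal(draw_migration_event(state, 0)$event$n_m, 0)
  state2 <- mk_state(c(120, 80), c(0, 0), mp)
  for (i in 1:10) expect_equal(draw_migration_event(state2, 0.5)$event$n_mc, 0)
})

test_that("sources are drawn proportionally to rounded patch size", {
  mp <- test_params()
  set.seed(21)
  state <- mk_state(c(70, 210), c(30, 90), mp)   # sizes 100 and 300
  n <- 4000
  src <- replicate(n, draw_migration_event(state, 0)$event$source)
  phat <- mean(src == 2)
  se <- sqrt(0.75 * 0.25 / n)
  expect_lt(abs(phat - 0.75), 4 * se)
})

test_that("patch birth-death respects the carrying capacity and empties", {
  mp <- test_params()
  state <- mk_state(rep(10, mp$K), rep(5, mp$K), mp)
  res <- chemostat_birth_death(state, mp, "birth")
  expect_null(res$event)            # k = K: birth propensity region empty
  expect_equal(length(res$state), mp$K)
  state2 <- mk_state(c(10, 20), c(5, 5), mp)
  res2 <- chemostat_birth_death(state2, mp, "birth")
  born <- res2$state[[length(res2$state)]]
  expect_equal(born$Na + born$Nc, 0)  # born empty
  expect_equal(born$phi, mp$chemostat$phi0)
  set.seed(5)
  res3 <- chemostat_birth_death(state2, mp, "death")
  expect_equal(length(res3$state), 1)
})

test_that("detect_fixation reads the global cheater fraction", {
  traj <- data.frame(t = 1, k = 3, N_total = 100, cheater_fraction = 0)
  expect_equal(detect_fixation(traj), "altruist_fixation")
  traj$cheater_fraction <- 1
  expect_equal(detect_fixation(traj), "cheater_fixation")
  traj$cheater_fraction <- 0.5
  expect_equal(detect_fixation(traj), "ongoing")
  traj$cheater_fraction <- NA_real_
  expect_equal(detect_fixation(traj), "extinct")
  expect_error(detect_fixation(traj[0, ]), "empty")
})

test_that("identical seeds reproduce identical runs", {
  mp <- metapop_params(tiny_params(), defense_strategy(0.8, 0.01),
                       K = 4, k0 = 2, m = 2)
  r1 <- simulate_metapopulation(mp, t_max = 30, seed = 42,
                                control = sim_control())
  r2 <- simulate_metapopulation(mp, t_max = 30, seed = 42,
                                control = sim_control())
  expect_identical(r1$trajectory, r2$trajectory)
  expect_identical(r1$outcome, r2$outcome)
  expect_identical(length(r1$events), length(r2$events))
})

test_that("d = 0 with b > 0 drives the patch count to K, which absorbs", {
  mp <- metapop_params(tiny_params(), defense_strategy(0.8, 0.01),
                       K = 6, k0 = 1, b = 5, d = 0, m = 1e6)
  r <- simulate_metapopulation(mp, t_max = 40, seed = 8,
                               control = sim_control())
  expect_equal(tail(r$trajectory$k, 1), mp$K)
})

test_that("a single patch without births reduces to plain competition", {
  pars <- tiny_params()
  alt <- defense_strategy(0.8, 0.01)
  mp <- metapop_params(pars, alt, K = 1, k0 = 1, b = 0, d = 0, m = 1e9,
                       init_fraction = 0.5)
  r <- simulate_metapopulation(mp, t_max = 25, seed = 1,
                               control = sim_control())
  cr <- run_competition(pars, alt, defense_strategy(0, alt$r),
                        init_fraction = 0.5, t_max = 25,
                        control = sim_control())
  fr_meta <- tail(r$trajectory$cheater_fraction, 1)
  fr_comp <- tail(cr$trajectory$cheater_fraction, 1)
  expect_equal(fr_meta, fr_comp, tolerance = 5e-3)
})
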