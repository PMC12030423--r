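test_that("first activation energy is 3/2 kB T", {
  expect_equal(activation_energy_first(295.15), 6.112e-21,
               tolerance = 1e-3)
  expect_equal(activation_energy_first(310.15), 6.423e-21,
               tolerance = 1e-3)
  expect_equal(activation_energy_first(2 * 295.15),
               2 * activation_energy_first(295.15))
  expect_error(activation_energy_first(-1))
})

test_that("second activation energy scales as Eact1 / P2", {
  e1 <- activation_energy_first(295.15)
  expect_identical(activation_energy_second(1, 295.15), e1)
  expect_equal(activation_energy_second(0.5, 295.15), 2 * e1)
  expect_equal(activation_energy_second(0.1, 295.15), 10 * e1)
  expect_equal(activation_energy_second(0.1, 295.15), 6.112e-20,
               tolerance = 1e-3)
  # strictly decreasing in P2
  p2 <- seq(0.05, 1, by = 0.05)
  expect_true(all(diff(activation_energy_second(p2, 295.15)) < 0))
  expect_error(activation_energy_second(0, 295.15), "0, 1")
  expect_error(activation_energy_second(1.2, 295.15), "0, 1")
})

test_that("AOD model constructor enforces domain and floor", {
  expect_silent(aod_survival_model(0.5))
  expect_error(aod_survival_model(0), "0, 1")
  expect_error(aod_survival_model(1.5), "0, 1")
  expect_error(aod_survival_model(1e-4), "floor")
  m <- aod_survival_model(c("295.15" = 0.1, "310.15" = 0.2))
  expect_identical(m$convention, "corrected")
})

test_that("k2 equals k1 at P2 = 1 under both conventions", {
  med <- medium_at_C(22)
  cond <- condition_at(22, 2.5)
  k1 <- stationary_rate_constant(pair_system_at(22, 2.5))
  for (conv in c("corrected", "printed")) {
    k2 <- second_rate_constant(cond, med, aod_survival_model(1, conv))
    expect_equal(k2, k1, tolerance = 1e-14)
  }
})

test_that("k2 carries the exact exponential factor per convention", {
  med <- medium_at_C(22)
  cond <- condition_at(22, 2.5)
  k1 <- stationary_rate_constant(pair_system_at(22, 2.5))
  # corrected: g = 3 (0.2 - 1) / (2 * 0.2) = -6
  k2c <- second_rate_constant(cond, med,
                              aod_survival_model(0.2, "corrected"))
  expect_equal(k2c, k1 * exp(-6), tolerance = 1e-12)
  k2p <- second_rate_constant(cond, med,
                              aod_survival_model(0.2, "printed"))
  expect_equal(k2p, k1 * exp(6), tolerance = 1e-12)
})

test_that("convention duality k2p * k2c = k1^2 holds across P2", {
  med <- medium_at_C(22)
  cond <- condition_at(22, 2.5)
  k1 <- stationary_rate_constant(pair_system_at(22, 2.5))
  for (p2 in exp(seq(log(1e-3), 0, length.out = 25))) {
    # log scale: the only representation that spans the whole P2 range
    # (the printed factor overflows a double below P2 ~ 2e-3)
    lk2c <- second_rate_constant(cond, med,
                                 aod_survival_model(p2, "corrected"),
                                 log = TRUE)
    lk2p <- second_rate_constant(cond, med,
                                 aod_survival_model(p2, "printed"),
                                 log = TRUE)
    expect_equal(lk2c + lk2p, 2 * log(k1), tolerance = 1e-12)
    if (p2 > 0.01) {   # value scale where both factors are representable
      expect_equal(exp(lk2c) * exp(lk2p), k1^2, tolerance = 1e-12)
    }
  }
})

test_that("k2 is increasing in P2 under corrected, decreasing under printed", {
  # the discriminating behaviour between the two sign conventions:
  # weaker antioxidant defense (higher P2) must accelerate death
  med <- medium_at_C(22)
  cond <- condition_at(22, 2.5)
  p2s <- seq(0.05, 1, by = 0.05)
  k2c <- vapply(p2s, function(p)
    second_rate_constant(cond, med, aod_survival_model(p, "corrected")),
    numeric(1))
  k2p <- vapply(p2s, function(p)
    second_rate_constant(cond, med, aod_survival_model(p, "printed")),
    numeric(1))
  expect_true(all(diff(k2c) > 0))
  expect_true(all(diff(k2p) < 0))
})

test_that("death ODE right-hand side factorises as a squared depletion", {
  cond <- condition_at(22, 2.5)
  ca0 <- cond$cell_density
  cb0 <- cond$nanoparticle_density
  k2 <- 1e-21
  expect_equal(death_ode_rhs(0, k2, cond), k2 * ca0 * cb0)
  expect_equal(death_ode_rhs(ca0, k2, cond), 0)
  expect_equal(death_ode_rhs(ca0 / 2, k2, cond), k2 * ca0 * cb0 / 4)
  expect_error(death_ode_rhs(1.1 * ca0, k2, cond), "CA0")
})

test_that("closed-form dead-cell count matches numerical integration", {
  # independent oracle: lsoda at tight tolerance on the fraction-scaled
  # balance, over a 6-decade grid of k2 and nanoparticle density
  cond0 <- condition_at(22, 2.5)
  times_s <- seq(0, 210 * 60, length.out = 22)
  for (k2 in 10^c(-22, -19.5, -17)) {
    for (cb0 in 10^c(14, 16.5, 19)) {
      cond <- experiment_condition(295.15, cb0,
                                   cell_density_per_m3 = cond0$cell_density,
                                   particle = default_particle(),
                                   cell = default_cell())
      rhs <- function(t, y, parms)
        list(death_ode_rhs(y[1] * cond$cell_density, k2, cond) /
               cond$cell_density)
      num <- deSolve::lsoda(c(f = 0), times_s, rhs, parms = NULL,
                            rtol = 1e-12, atol = 1e-16)[, "f"]
      ana <- damaged_count(times_s, k2, cond) / cond$cell_density
      rel <- abs(ana - num)[-1] / ana[-1]   # skip the exact zero at t = 0
      expect_lt(max(rel), 1e-8)
    }
  }
})

test_that("dead-cell count starts at zero and saturates at CA0", {
  cond <- condition_at(22, 2.5)
  k2 <- 1.3e-21
  expect_identical(damaged_count(0, k2, cond), 0)
  # half-saturation when CB0 k2 t = 1
  t_half <- 1 / (cond$nanoparticle_density * k2)
  expect_equal(damaged_count(t_half, k2, cond), cond$cell_density / 2)
  expect_equal(damaged_count(1e18, k2, cond), cond$cell_density,
               tolerance = 1e-6)
  # conservation: dead + surviving = CA0 exactly
  ts <- seq(0, 210 * 60, length.out = 10)
  n <- damaged_count(ts, k2, cond)
  expect_identical(n + (cond$cell_density - n),
                   rep(cond$cell_density, length(ts)))
})

test_that("damaged fraction is CA0-free and pins the 50%/86% pattern", {
  # fraction(10 min) = 0.5 forces CB0 k2 = 1/600, then
  # fraction(60 min) = 6/7 (the 37 C half-hyperbola pattern)
  cb0 <- 1e17
  k2 <- 1 / 600 / cb0
  expect_equal(damaged_fraction(600, k2, cb0), 0.5)
  expect_equal(damaged_fraction(3600, k2, cb0), 6 / 7)
  # independence of CA0 carried by the condition variant
  cond1 <- experiment_condition(295.15, cb0, cell_density_per_m3 = 5e11)
  cond2 <- experiment_condition(295.15, cb0, cell_density_per_m3 = 5e12)
  expect_identical(damaged_fraction(600, k2, cond1),
                   damaged_fraction(600, k2, cond2))
  expect_equal(damaged_fraction(1e15, k2, cb0), 1, tolerance = 1e-6)
  # strictly increasing in t, cb0 and k2
  expect_true(all(diff(damaged_fraction(10^(1:6), k2, cb0)) > 0))
  expect_true(all(diff(damaged_fraction(600, k2, cb0 * 10^(0:4))) > 0))
  expect_true(all(diff(damaged_fraction(600, k2 * 10^(0:4), cb0)) > 0))
})

test_that("timecourse prediction composes the full constant chain", {
  # no antioxidant defense: CB0 k1 ~ 16/s saturates within seconds --
  # the reason the printed sign convention cannot give hour-scale kinetics
  cond <- condition_at(22, 2.5)
  med <- medium_at_C(22)
  pred <- predict_timecourse(c(7 / 60, 1, 60), cond, med,
                             aod_survival_model(1))
  expect_true(all(pred$fraction_damaged > 0.99))
  # corrected convention at the reconstructed P2 reproduces ~50% at 150 min
  cond5 <- condition_at(22, 5)
  pred5 <- predict_timecourse(150, cond5, med, aod_survival_model(0.1064))
  expect_equal(pred5$fraction_damaged, 0.50, tolerance = 5e-3)
  # empty input gives an empty series
  empty <- predict_timecourse(numeric(0), cond, med, aod_survival_model(0.5))
  expect_identical(nrow(empty), 0L)
})

test_that("transient-k1 prediction converges to the stationary one", {
  cond <- condition_at(22, 5)
  med <- medium_at_C(22)
  mod <- aod_survival_model(0.1064)
  stat <- predict_timecourse(c(30, 150), cond, med, mod)
  trans <- predict_timecourse(c(30, 150), cond, med, mod,
                              transient_k1 = TRUE)
  # transient flux only adds encounters: predictions slightly above
  expect_true(all(trans$fraction_damaged >= stat$fraction_damaged))
  expect_equal(trans$fraction_damaged, stat$fraction_damaged,
               tolerance = 0.02)
})
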