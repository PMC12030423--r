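test_that("R-squared follows its defining identities", {
  obs <- c(0.2, 0.5, 0.8)
  expect_identical(r_squared(obs, obs), 1)
  expect_equal(r_squared(obs, rep(mean(obs), 3)), 0)
  # hand computation: SSres = 0.005, SStot = 0.18
  expect_equal(r_squared(obs, c(0.25, 0.45, 0.80)), 1 - 0.005 / 0.18,
               tolerance = 1e-12)
  # can be negative for a model worse than the mean
  expect_lt(r_squared(obs, c(0.9, 0.1, 0.2)), 0)
  expect_error(r_squared(obs, c(0.1, 0.2)), "equal length")
  expect_error(r_squared(0.5, 0.5), "two points")
  expect_error(r_squared(c(0.3, 0.3), c(0.1, 0.2)), "identical")
})

test_that("timecourse constructor validates counts and ordering", {
  tc <- damage_timecourse(c(10, 60), cells_counted = c(1500, 1600),
                          cells_damaged = c(750, 1440),
                          temperature_K = 310.15,
                          nanoparticle_density_per_m3 = 8e16)
  expect_equal(tc$fraction, c(0.5, 0.9))
  expect_error(
    damage_timecourse(c(60, 10), fraction = c(0.9, 0.5),
                      temperature_K = 310.15,
                      nanoparticle_density_per_m3 = 8e16),
    "increasing")
  expect_error(
    damage_timecourse(c(10, 60), cells_counted = c(100, 100),
                      cells_damaged = c(150, 50),
                      temperature_K = 310.15,
                      nanoparticle_density_per_m3 = 8e16),
    "exceed")
})

test_that("noise-free refit recovers the generating death probability", {
  med <- medium_at_C(22)
  cond <- condition_at(22, 5)
  for (true_p2 in c(0.02, 0.106, 0.5, 0.9)) {
    mod <- aod_survival_model(true_p2)
    times <- c(5, 15, 30, 60, 90, 120, 150, 210)
    tc <- damage_timecourse(
      times,
      fraction = predict_timecourse(times, cond, med, mod)$fraction_damaged,
      temperature_K = cond$temperature,
      nanoparticle_density_per_m3 = cond$nanoparticle_density)
    fit <- fit_p2(tc, med, cond)
    expect_lt(abs(fit$p2_hat - true_p2), 1e-3)
    expect_gt(fit$r_squared, 1 - 1e-10)
  }
})

test_that("fit is deterministic and matches the grid-search oracle", {
  med <- medium_at_C(22)
  cond <- condition_at(22, 5)
  times <- c(15, 30, 60, 90, 120, 150, 180, 210)
  set.seed(11)
  truef <- predict_timecourse(times, cond, med,
                              aod_survival_model(0.15))$fraction_damaged
  obs <- pmin(pmax(truef + rnorm(length(times), 0, 0.02), 0), 1)
  tc <- damage_timecourse(times, fraction = obs,
                          temperature_K = cond$temperature,
                          nanoparticle_density_per_m3 =
                            cond$nanoparticle_density)
  f1 <- fit_p2(tc, med, cond)
  f2 <- fit_p2(tc, med, cond)
  expect_identical(f1$p2_hat, f2$p2_hat)
  oracle <- grid_search_p2(tc, med, cond)
  expect_lt(abs(f1$p2_hat - oracle), 1e-4)
})

test_that("an exactly consistent two-point series is fit perfectly", {
  # (10 min, 0.5) and (60 min, 6/7) lie on one hyperbola
  tc <- hyperbola_timecourse(c(10, 60), 10, 0.5, 37, 5)
  expect_equal(tc$fraction[2], 6 / 7, tolerance = 1e-12)
  fit <- fit_p2(tc)
  expect_gt(fit$r_squared, 1 - 1e-9)
  expect_equal(fit$k2_hat,
               invert_single_point(10, 0.5, 37, 5)$k2, tolerance = 1e-6)
})

test_that("degenerate series are rejected or flagged", {
  cb0 <- mass_to_number_density(5, default_particle())
  one <- damage_timecourse(30, fraction = 0.2, temperature_K = 295.15,
                           nanoparticle_density_per_m3 = cb0)
  expect_error(fit_p2(one), "two points")
  zero <- damage_timecourse(c(30, 60), fraction = c(0, 0),
                            temperature_K = 295.15,
                            nanoparticle_density_per_m3 = cb0)
  expect_warning(f0 <- fit_p2(zero), "floor")
  expect_true(f0$at_boundary)
  expect_equal(f0$p2_hat, 1e-3)
})

test_that("time window restricts which points enter the fit", {
  med <- medium_at_C(22)
  cond <- condition_at(22, 5)
  mod <- aod_survival_model(0.106)
  times <- c(30, 60, 90, 120, 150, 180, 210)
  f <- predict_timecourse(times, cond, med, mod)$fraction_damaged
  # corrupt the late points (excess damage)
  f[times > 150] <- pmin(f[times > 150] + 0.25, 0.99)
  tc <- damage_timecourse(times, fraction = f,
                          temperature_K = cond$temperature,
                          nanoparticle_density_per_m3 =
                            cond$nanoparticle_density)
  full <- fit_p2(tc, med, cond)
  trunc <- fit_p2(tc, med, cond, time_window_min = c(0, 150))
  expect_identical(trunc$n_points, 5L)
  expect_gt(trunc$r_squared, full$r_squared)
  expect_lt(abs(trunc$p2_hat - 0.106), 1e-3)
})

test_that("activation-energy profile ranks temperatures correctly", {
  # 60-min damage fractions 0.40 / 0.10 / 0.30 at 4 / 22 / 37 C,
  # nanoparticle density for 2.5 ug/mL
  scenario <- list(c(4, 0.40), c(22, 0.10), c(37, 0.30))
  fits <- lapply(scenario, function(s)
    fit_p2(hyperbola_timecourse(c(30, 60, 120), 60, s[2], s[1], 2.5)))
  prof <- activation_energy_profile(fits)
  expect_identical(attr(prof, "argmax_K"), celsius_to_kelvin(22))
  expect_identical(attr(prof, "argmin_K"), celsius_to_kelvin(4))
  # closed-form inversion as the independent route to P2 and Eact2
  for (s in scenario) {
    ref <- invert_single_point(60, s[2], s[1], 2.5)
    row <- prof[prof$temperature_C == s[1], ]
    expect_equal(row$p2_hat, ref$p2, tolerance = 1e-4)
    expect_equal(row$eact2_hat_J, ref$eact2, tolerance = 1e-4)
  }
  # frozen reconstructions from the closed-form inversion
  expect_equal(prof$eact2_hat_J[prof$temperature_C == 4], 4.72e-20,
               tolerance = 5e-3)
  expect_equal(prof$eact2_hat_J[prof$temperature_C == 22], 5.98e-20,
               tolerance = 5e-3)
  expect_equal(prof$eact2_hat_J[prof$temperature_C == 37], 5.87e-20,
               tolerance = 5e-3)
})

test_that("profile rejects degenerate input and grows with T at fixed P2", {
  fits <- lapply(c(4, 22, 37), function(tC)
    fit_p2(hyperbola_timecourse(c(30, 60, 120), 60, 0.3, tC, 2.5)))
  expect_error(activation_energy_profile(fits[1]), "2")
  expect_error(activation_energy_profile(list(fits[[1]], fits[[1]])),
               "distinct")
  # shared P2 across temperatures: Eact2 = 1.5 kB T / P2 increasing in T
  same_p2 <- lapply(c(4, 22, 37), function(tC) {
    f <- fits[[1]]
    f$temperature <- celsius_to_kelvin(tC)
    f$eact2_hat <- activation_energy_second(f$p2_hat, f$temperature)
    f
  })
  prof <- activation_energy_profile(same_p2)
  expect_true(all(diff(prof$eact2_hat_J) > 0))
})
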