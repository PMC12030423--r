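# shared fixtures: default geometry and study conditions

default_particle <- function() particle_spec(35e-9, 350)
default_cell <- function() cell_spec(5e-6, cells_per_ml_to_per_m3(5e5))

medium_at_C <- function(tC) medium_state(celsius_to_kelvin(tC))

condition_at <- function(tC, conc_ug_ml) {
  experiment_condition(
    celsius_to_kelvin(tC),
    mass_to_number_density(conc_ug_ml, default_particle()),
    particle = default_particle(), cell = default_cell())
}

pair_system_at <- function(tC, conc_ug_ml) {
  pair_system_from_specs(default_particle(), default_cell(),
                         medium_at_C(tC),
                         mass_to_number_density(conc_ug_ml,
                                                default_particle()))
}

# brute-force oracle for the P2 fit: dense log-spaced grid, then local
# golden-section refinement inside the bracketing grid cells
grid_search_p2 <- function(timecourse, medium, condition,
                           convention = "corrected", n_grid = 1e4) {
  sys <- pair_system_from_specs(condition$particle, condition$cell,
                                medium, condition$nanoparticle_density)
  k1 <- stationary_rate_constant(sys)
  cb0 <- condition$nanoparticle_density
  t_s <- timecourse$time_min * 60
  obs <- timecourse$fraction
  expo <- function(p2, conv)
    if (conv == "corrected") 3 * (p2 - 1) / (2 * p2) else
      (3 - 3 * p2) / (2 * p2)
  sse <- function(p2)
    sum((obs - damaged_fraction(t_s, k1 * exp(expo(p2, convention)),
                                cb0))^2)
  grid <- exp(seq(log(1e-3), 0, length.out = n_grid))
  vals <- vapply(grid, sse, numeric(1))
  i <- which.min(vals)
  lo <- grid[max(1, i - 1)]
  hi <- grid[min(n_grid, i + 1)]
  stats::optimize(sse, c(lo, hi), tol = 1e-12)$minimum
}

# closed-form inversion of the hyperbola through a single (t, f) point:
# the k2 that reproduces fraction f at time t, and the implied P2 under the
# corrected convention
invert_single_point <- function(t_min, fraction, tC, conc_ug_ml) {
  cb0 <- mass_to_number_density(conc_ug_ml, default_particle())
  k2 <- fraction / (1 - fraction) / (cb0 * t_min * 60)
  k1 <- stationary_rate_constant(pair_system_at(tC, conc_ug_ml))
  g <- log(k2 / k1)
  p2 <- 1 / (1 - 2 * g / 3)
  list(k2 = k2, p2 = p2,
       eact2 = activation_energy_second(p2, celsius_to_kelvin(tC)))
}

# a noise-free time course lying exactly on the model hyperbola through
# (anchor_t_min, anchor_fraction)
hyperbola_timecourse <- function(times_min, anchor_t_min, anchor_fraction,
                                 tC, conc_ug_ml, label = "") {
  cb0 <- mass_to_number_density(conc_ug_ml, default_particle())
  k2 <- anchor_fraction / (1 - anchor_fraction) / (cb0 * anchor_t_min * 60)
  damage_timecourse(
    time_min = times_min,
    fraction = damaged_fraction(times_min * 60, k2, cb0),
    temperature_K = celsius_to_kelvin(tC),
    nanoparticle_density_per_m3 = cb0, label = label)
}
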