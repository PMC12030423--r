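#' Antioxidant-defense survival model
#'
#' Holds the death probability P2(T) — the probability that contact with
#' nanoparticles kills the cell despite its antioxidant defense (AOD) — and
#' the sign convention used for the effective second rate constant.
#'
#' \code{death_probability} may be a single value or a vector named by
#' temperature (kelvin, formatted with \code{format()}) when P2 varies
#' across conditions.
#'
#' Two conventions are supported for the Arrhenius exponent relating k2 to
#' the diffusion-limited k1 (see [second_rate_constant()]):
#' \describe{
#'   \item{corrected}{k2 = k1 exp(3 (P2 - 1) / (2 P2)), the thermodynamically
#'     consistent sign (k2 <= k1, increasing in P2). Default.}
#'   \item{printed}{k2 = k1 exp((3 - 3 P2) / (2 P2)), the reciprocal factor,
#'     retained for verbatim-faithfulness audits.}
#' }
#'
#' @param death_probability P2 in (0, 1]; scalar or named-by-temperature
#'   vector. Values below 1e-3 are rejected to keep the exponential finite.
#' @param convention \code{"corrected"} (default) or \code{"printed"}.
#' @param p2_floor lowest admissible P2 (default 1e-3).
#' @return An object of class \code{aod_survival_model}.
#' @export
aod_survival_model <- function(death_probability,
                               convention = c("corrected", "printed"),
                               p2_floor = 1e-3) {
  convention <- match.arg(convention)
  stopifnot(is.numeric(death_probability), length(death_probability) >= 1,
            all(is.finite(death_probability)))
  if (any(death_probability <= 0) || any(death_probability > 1))
    stop("death probability P2 must lie in (0, 1]", call. = FALSE)
  if (any(death_probability < p2_floor))
    stop("death probability P2 below the floor ", p2_floor,
         " (exponential overflow guard)", call. = FALSE)
  structure(list(death_probability = death_probability,
                 convention = convention, p2_floor = p2_floor),
            class = "aod_survival_model")
}

# look up P2 for a temperature from a scalar or named vector
p2_at_temperature <- function(model, temperature_K) {
  p2 <- model$death_probability
  if (length(p2) == 1 && is.null(names(p2))) return(unname(p2))
  key <- format(temperature_K)
  if (!is.null(names(p2)) && key %in% names(p2)) return(unname(p2[[key]]))
  stop("no death probability stored for temperature ", key, " K",
       call. = FALSE)
}

#' Experimental condition
#'
#' Temperature, reactant densities and geometry for one assay condition.
#'
#' @param temperature_K incubation temperature in kelvin.
#' @param nanoparticle_density_per_m3 initial nanoparticle number density
#'   CB0 (particles/m3).
#' @param cell_density_per_m3 initial cell number density CA0 (cells/m3);
#'   defaults to the cell spec's concentration.
#' @param particle a [particle_spec()].
#' @param cell a [cell_spec()].
#' @return An object of class \code{experiment_condition}.
#' @export
experiment_condition <- function(temperature_K, nanoparticle_density_per_m3,
                                 cell_density_per_m3 = cell$number_concentration,
                                 particle = particle_spec(),
                                 cell = cell_spec()) {
  stopifnot(inherits(particle, "particle_spec"), inherits(cell, "cell_spec"),
            length(temperature_K) == 1, is.finite(temperature_K),
            temperature_K > 0,
            length(nanoparticle_density_per_m3) == 1,
            is.finite(nanoparticle_density_per_m3),
            nanoparticle_density_per_m3 >= 0,
            length(cell_density_per_m3) == 1,
            is.finite(cell_density_per_m3), cell_density_per_m3 >= 0)
  structure(list(temperature = temperature_K,
                 nanoparticle_density = nanoparticle_density_per_m3,
                 cell_density = cell_density_per_m3,
                 particle = particle, cell = cell),
            class = "experiment_condition")
}

#' Activation energy of the defenseless death reaction
#'
#' The energy barrier to cell death when no antioxidant defense operates,
#' taken equal to the mean kinetic energy of a nanoparticle:
#' \eqn{E_{act1} = \frac{3}{2} k_B T}.
#'
#' @param temperature_K temperature in kelvin (vectorised).
#' @return Energy in joules.
#' @export
activation_energy_first <- function(temperature_K) {
  stopifnot(is.numeric(temperature_K), all(is.finite(temperature_K)),
            all(temperature_K > 0))
  1.5 * .kB * temperature_K
}

#' Effective activation energy of death under antioxidant defense
#'
#' \eqn{E_{act2} = E_{act1}(T) / P_2}: the energy barrier grows as the death
#' probability shrinks, with equality to Eact1 only at P2 = 1 (no defense).
#'
#' @param p2 death probability in (0, 1] (vectorised).
#' @param temperature_K temperature in kelvin.
#' @return Energy in joules.
#' @export
activation_energy_second <- function(p2, temperature_K) {
  stopifnot(is.numeric(p2), all(is.finite(p2)))
  if (any(p2 <= 0) || any(p2 > 1))
    stop("death probability P2 must lie in (0, 1]", call. = FALSE)
  activation_energy_first(temperature_K) / p2
}

# Arrhenius exponent relating k2 to k1 under each sign convention
convention_exponent <- function(p2, convention) {
  switch(convention,
         corrected = 3 * (p2 - 1) / (2 * p2),
         printed   = (3 - 3 * p2) / (2 * p2),
         stop("unknown convention: ", convention, call. = FALSE))
}

#' Effective rate constant of the death reaction
#'
#' The lumped rate constant of the death pathway, modulated by the
#' antioxidant defense through P2:
#' \deqn{k_2 = 4\pi R D \, e^{g(P_2)},}
#' where 4 pi R D is the stationary Smoluchowski constant for the cell +
#' nanoparticle pair at the condition's temperature, and g is the Arrhenius
#' exponent \eqn{(E_{act1} - E_{act2})/k_B T}. Under the default
#' \code{corrected} convention g = 3 (P2 - 1) / (2 P2), so k2 <= k1 and k2
#' increases with P2 (weaker defense, faster death); under \code{printed}
#' g = (3 - 3 P2) / (2 P2), the reciprocal factor. k2 = k1 exactly at
#' P2 = 1 under both. The identity k2(printed) * k2(corrected) = k1^2 holds
#' for every P2.
#'
#' @param condition an [experiment_condition()].
#' @param medium a [medium_state()] (must be at the condition temperature).
#' @param model an [aod_survival_model()].
#' @param log logical; return the natural logarithm of the rate constant.
#'   Under the printed convention with small P2 the exponential factor
#'   exceeds the double-precision range, so the log scale is the only one
#'   on which the value is representable.
#' @return Rate constant in m3/s (or its natural log).
#' @export
second_rate_constant <- function(condition, medium, model, log = FALSE) {
  stopifnot(inherits(condition, "experiment_condition"),
            inherits(medium, "medium_state"),
            inherits(model, "aod_survival_model"))
  p2 <- p2_at_temperature(model, condition$temperature)
  if (p2 < model$p2_floor)
    stop("P2 below floor ", model$p2_floor, call. = FALSE)
  sys <- pair_system_from_specs(condition$particle, condition$cell, medium,
                                max(condition$nanoparticle_density,
                                    .Machine$double.xmin))
  k1 <- stationary_rate_constant(sys)
  lk2 <- base::log(k1) + convention_exponent(p2, model$convention)
  if (log) lk2 else exp(lk2)
}

#' Right-hand side of the dead-cell balance equation
#'
#' \deqn{\frac{dN}{dt} = k_2 (C_{A0} - N)\left(C_{B0} -
#'   \frac{C_{B0}}{C_{A0}} N\right)
#'   = k_2 \frac{C_{B0}}{C_{A0}} (C_{A0} - N)^2,}
#' the rate of dead-cell formation when each dying cell removes a
#' proportional share of the nanoparticle pool.
#'
#' @param dead_count_per_m3 current dead-cell density N, in [0, CA0].
#' @param k2_m3_s effective rate constant.
#' @param condition an [experiment_condition()].
#' @return Rate in cells/(m3 s).
#' @export
death_ode_rhs <- function(dead_count_per_m3, k2_m3_s, condition) {
  stopifnot(inherits(condition, "experiment_condition"),
            is.numeric(dead_count_per_m3), all(is.finite(dead_count_per_m3)))
  ca0 <- condition$cell_density
  cb0 <- condition$nanoparticle_density
  if (any(dead_count_per_m3 < 0) || any(dead_count_per_m3 > ca0))
    stop("dead-cell count must lie in [0, CA0]", call. = FALSE)
  k2_m3_s * (ca0 - dead_count_per_m3) *
    (cb0 - (cb0 / ca0) * dead_count_per_m3)
}

#' Closed-form dead-cell time course
#'
#' The analytic solution of the dead-cell balance with N(0) = 0:
#' \deqn{N(t) = \frac{C_{A0} C_{B0} k_2 t}{C_{B0} k_2 t + 1},}
#' monotone non-decreasing from 0 to CA0.
#'
#' @param time_s time in seconds, >= 0 (vectorised).
#' @param k2_m3_s effective rate constant.
#' @param condition an [experiment_condition()].
#' @return Dead-cell density in cells/m3.
#' @export
damaged_count <- function(time_s, k2_m3_s, condition) {
  stopifnot(inherits(condition, "experiment_condition"),
            is.numeric(time_s), all(is.finite(time_s)), all(time_s >= 0))
  x <- condition$nanoparticle_density * k2_m3_s * time_s
  condition$cell_density * x / (x + 1)
}

#' Damaged-cell fraction
#'
#' N(t) / CA0 = CB0 k2 t / (CB0 k2 t + 1): the fraction of cells with a
#' damaged membrane. Independent of the cell density CA0.
#'
#' @param time_s time in seconds, >= 0 (vectorised).
#' @param k2_m3_s effective rate constant.
#' @param nanoparticle_density_per_m3 initial nanoparticle density CB0; an
#'   [experiment_condition()] may be passed instead.
#' @return Fraction in [0, 1).
#' @export
damaged_fraction <- function(time_s, k2_m3_s, nanoparticle_density_per_m3) {
  if (inherits(nanoparticle_density_per_m3, "experiment_condition"))
    nanoparticle_density_per_m3 <-
      nanoparticle_density_per_m3$nanoparticle_density
  stopifnot(is.numeric(time_s), all(is.finite(time_s)), all(time_s >= 0),
            is.numeric(nanoparticle_density_per_m3),
            all(nanoparticle_density_per_m3 >= 0))
  x <- nanoparticle_density_per_m3 * k2_m3_s * time_s
  x / (x + 1)
}

#' Predicted damage time course for an assay condition
#'
#' Composes the full model chain — viscosity law, Stokes-Einstein mutual
#' diffusion, stationary Smoluchowski constant, AOD-modulated k2 and the
#' closed-form time course — into the damaged fraction at each requested
#' time. With \code{transient_k1 = TRUE} the time-dependent rate constant
#' replaces its stationary limit and the balance equation is integrated
#' numerically (sensitivity studies only; the transient term is negligible
#' beyond about an hour for the default geometry).
#'
#' @param times_min times in minutes (the assay's native axis).
#' @param condition an [experiment_condition()].
#' @param medium a [medium_state()]; defaults to water at the condition
#'   temperature.
#' @param model an [aod_survival_model()].
#' @param transient_k1 logical; include the transient correction to k1.
#' @return A data.frame with columns \code{time_min} and
#'   \code{fraction_damaged}.
#' @export
predict_timecourse <- function(times_min, condition,
                               medium = medium_state(condition$temperature),
                               model, transient_k1 = FALSE) {
  stopifnot(inherits(condition, "experiment_condition"),
            is.numeric(times_min), all(is.finite(times_min)),
            all(times_min >= 0))
  if (length(times_min) == 0)
    return(data.frame(time_min = numeric(0), fraction_damaged = numeric(0)))
  times_s <- times_min * 60
  k2 <- second_rate_constant(condition, medium, model)
  if (!transient_k1) {
    frac <- damaged_fraction(times_s, k2, condition)
  } else {
    p2 <- p2_at_temperature(model, condition$temperature)
    sys <- pair_system_from_specs(condition$particle, condition$cell, medium,
                                  max(condition$nanoparticle_density,
                                      .Machine$double.xmin))
    g <- exp(convention_exponent(p2, model$convention))
    cb0 <- condition$nanoparticle_density
    rhs <- function(t, y, parms) {
      k2t <- transient_rate_constant(max(t, 1e-6), sys) * g
      list(k2t * (1 - y[1]) * cb0 * (1 - y[1]))
    }
    out_t <- sort(unique(c(0, times_s)))
    sol <- deSolve::lsoda(c(f = 0), out_t, rhs, parms = NULL,
                          rtol = 1e-10, atol = 1e-12)
    frac <- sol[match(times_s, out_t), "f"]
  }
  data.frame(time_min = times_min, fraction_damaged = as.numeric(frac))
}
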