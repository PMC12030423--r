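#' Physical constants
#'
#' Single source of the Boltzmann constant for the whole package
#' (2019 SI exact value).
#'
#' @return A list with element \code{boltzmann_constant} (J/K).
#' @export
#' @examples
#' physical_constants()$boltzmann_constant
physical_constants <- function() {
  list(boltzmann_constant = 1.380649e-23)
}

# internal shorthand; never reassigned
.kB <- 1.380649e-23

#' Convert degrees Celsius to kelvin
#'
#' @param temperature_C temperature in degrees Celsius.
#' @return Temperature in kelvin.
#' @export
celsius_to_kelvin <- function(temperature_C) {
  stopifnot(is.numeric(temperature_C), all(is.finite(temperature_C)))
  temperature_C + 273.15
}

#' Empirical water viscosity law
#'
#' Evaluates the three-constant Andrade-type law
#' \deqn{\eta(T) = A \cdot 10^{B/(T - C)}}
#' used for the incubation medium, whose viscosity is taken equal to that of
#' pure water. Default constants: A = 2.414e-5 Pa s, B = 247.8 K, C = 140 K.
#' The fit is an empirical description of liquid water; outside roughly
#' 273--320 K a warning is emitted but the value is still returned.
#'
#' @param temperature_K temperature in kelvin (vectorised).
#' @param A pre-factor, Pa s.
#' @param B exponent numerator, K.
#' @param C offset, K; \code{temperature_K} must exceed \code{C}.
#' @return Dynamic viscosity in Pa s.
#' @export
#' @examples
#' water_viscosity(293.15)   # ~1.002e-3 Pa s, handbook value at 20 C
water_viscosity <- function(temperature_K, A = 2.414e-5, B = 247.8, C = 140) {
  stopifnot(is.numeric(temperature_K), length(A) == 1, length(B) == 1,
            length(C) == 1, is.finite(A), is.finite(B), is.finite(C), A > 0)
  if (any(!is.finite(temperature_K)))
    stop("temperature must be finite", call. = FALSE)
  if (any(temperature_K <= C))
    stop("temperature must exceed the law's offset constant C = ", C, " K",
         call. = FALSE)
  if (any(temperature_K < 273 | temperature_K > 320))
    warning("temperature outside the 273-320 K validity window of the ",
            "viscosity law", call. = FALSE)
  A * 10^(B / (temperature_K - C))
}

#' Medium state at a given temperature
#'
#' Bundles temperature, the viscosity-law constants and the derived viscosity.
#'
#' @param temperature_K temperature in kelvin (scalar).
#' @param viscosity_A,viscosity_B,viscosity_C constants of the viscosity law,
#'   see [water_viscosity()].
#' @return An object of class \code{medium_state}: a list with fields
#'   \code{temperature}, \code{viscosity_A/B/C} and the derived
#'   \code{viscosity} (Pa s).
#' @export
#' @examples
#' m <- medium_state(celsius_to_kelvin(22))
#' m$viscosity
medium_state <- function(temperature_K, viscosity_A = 2.414e-5,
                         viscosity_B = 247.8, viscosity_C = 140) {
  stopifnot(length(temperature_K) == 1, is.finite(temperature_K),
            temperature_K > viscosity_C)
  eta <- water_viscosity(temperature_K, viscosity_A, viscosity_B, viscosity_C)
  stopifnot(eta > 0)
  structure(
    list(temperature = temperature_K,
         viscosity_A = viscosity_A, viscosity_B = viscosity_B,
         viscosity_C = viscosity_C, viscosity = eta),
    class = "medium_state")
}

#' @export
print.medium_state <- function(x, ...) {
  cat(sprintf("medium_state: T = %.2f K (%.2f C), eta = %.4g Pa s\n",
              x$temperature, x$temperature - 273.15, x$viscosity))
  invisible(x)
}

#' Nanoparticle specification
#'
#' @param radius_m particle radius in metres.
#' @param bulk_density_kg_m3 effective bulk density in kg/m3 used for
#'   mass-to-count conversion. The default 350 kg/m3 is the effective density
#'   of the suspended silver nanoparticles, far below solid silver
#'   (~10,490 kg/m3); it is a configurable field, never hard-coded elsewhere.
#' @return An object of class \code{particle_spec}.
#' @export
particle_spec <- function(radius_m = 35e-9, bulk_density_kg_m3 = 350) {
  stopifnot(length(radius_m) == 1, is.finite(radius_m), radius_m > 0,
            length(bulk_density_kg_m3) == 1, is.finite(bulk_density_kg_m3),
            bulk_density_kg_m3 > 0)
  structure(list(radius = radius_m, bulk_density = bulk_density_kg_m3),
            class = "particle_spec")
}

#' Cell specification
#'
#' @param radius_m cell radius in metres (default: macrophage, 5 um).
#' @param number_concentration_per_m3 cell number concentration in cells/m3
#'   (default: 5e5 cells/mL converted to SI).
#' @return An object of class \code{cell_spec}.
#' @export
cell_spec <- function(radius_m = 5e-6,
                      number_concentration_per_m3 = cells_per_ml_to_per_m3(5e5)) {
  stopifnot(length(radius_m) == 1, is.finite(radius_m), radius_m > 0,
            length(number_concentration_per_m3) == 1,
            is.finite(number_concentration_per_m3),
            number_concentration_per_m3 >= 0)
  structure(list(radius = radius_m,
                 number_concentration = number_concentration_per_m3),
            class = "cell_spec")
}

#' Mutual diffusion coefficient of a reacting pair (Stokes-Einstein)
#'
#' The relative diffusion coefficient of two independently diffusing spheres,
#' \deqn{D = \frac{k_B T}{6\pi\eta}\left(\frac{1}{r_A} + \frac{1}{r_B}\right),}
#' i.e. the sum of the two single-particle Stokes-Einstein coefficients.
#'
#' @param radius_a,radius_b radii of the two spheres in metres.
#' @param medium a [medium_state()].
#' @return Diffusion coefficient in m2/s.
#' @export
#' @examples
#' m <- medium_state(295.15)
#' mutual_diffusion_coefficient(5e-6, 35e-9, m)  # ~6.5e-12 m2/s
mutual_diffusion_coefficient <- function(radius_a, radius_b, medium) {
  stopifnot(inherits(medium, "medium_state"),
            is.numeric(radius_a), is.numeric(radius_b),
            all(is.finite(radius_a)), all(is.finite(radius_b)))
  if (any(radius_a <= 0) || any(radius_b <= 0))
    stop("radii must be positive", call. = FALSE)
  .kB * medium$temperature / (6 * pi * medium$viscosity) *
    (1 / radius_a + 1 / radius_b)
}

#' Hydrodynamic diameter from a diffusion coefficient
#'
#' Diameter of the sphere having the same diffusion coefficient as the
#' measured particle (the dynamic-light-scattering observable):
#' \deqn{d_H = \frac{k_B T}{3\pi\eta D}.}
#'
#' @param diffusion_coefficient_m2_s single-particle diffusion coefficient.
#' @param medium a [medium_state()].
#' @return Hydrodynamic diameter in metres.
#' @export
hydrodynamic_diameter <- function(diffusion_coefficient_m2_s, medium) {
  stopifnot(inherits(medium, "medium_state"),
            is.numeric(diffusion_coefficient_m2_s),
            all(is.finite(diffusion_coefficient_m2_s)))
  if (any(diffusion_coefficient_m2_s <= 0))
    stop("diffusion coefficient must be positive", call. = FALSE)
  .kB * medium$temperature /
    (3 * pi * medium$viscosity * diffusion_coefficient_m2_s)
}

#' Convert a mass concentration of nanoparticles to a number density
#'
#' Divides the mass per cubic metre by the mass of a single spherical
#' particle: \eqn{c \cdot 10^{-3} / (\rho \frac{4}{3}\pi r^3)} with c in
#' ug/mL (1 ug/mL = 1e-3 kg/m3). Exactly linear in the concentration and
#' scaling as r^-3.
#'
#' @param mass_ug_per_ml mass concentration in micrograms per millilitre.
#' @param particle a [particle_spec()].
#' @return Number density in particles/m3.
#' @export
#' @examples
#' mass_to_number_density(2.5, particle_spec())  # ~3.98e16 particles/m3
mass_to_number_density <- function(mass_ug_per_ml, particle) {
  stopifnot(inherits(particle, "particle_spec"),
            is.numeric(mass_ug_per_ml), all(is.finite(mass_ug_per_ml)))
  if (any(mass_ug_per_ml < 0))
    stop("mass concentration must be non-negative", call. = FALSE)
  mass_kg_per_m3 <- mass_ug_per_ml * 1e-3
  particle_mass <- particle$bulk_density * (4 / 3) * pi * particle$radius^3
  mass_kg_per_m3 / particle_mass
}

#' Convert cells/mL to cells/m3
#'
#' @param concentration_per_ml number concentration in cells per millilitre.
#' @return Number concentration in cells per cubic metre.
#' @export
cells_per_ml_to_per_m3 <- function(concentration_per_ml) {
  stopifnot(is.numeric(concentration_per_ml),
            all(is.finite(concentration_per_ml)))
  if (any(concentration_per_ml < 0))
    stop("concentration must be non-negative", call. = FALSE)
  concentration_per_ml * 1e6
}
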