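#' Pair-diffusion system for a diffusion-controlled reaction
#'
#' Describes the relative diffusion of one reactant species around an
#' absorbing spherical sink: the contact (reaction) radius R = rA + rB, the
#' mutual diffusion coefficient D = DA + DB and the far-field concentration
#' W0 of the diffusing species.
#'
#' @param reaction_radius_m contact radius R in metres, the sum of the two
#'   reactant radii.
#' @param diffusion_coefficient_m2_s mutual diffusion coefficient D.
#' @param far_field_concentration_per_m3 far-field number density W0.
#' @return An object of class \code{pair_diffusion_system}.
#' @seealso [pair_system_from_specs()] to build one from particle/cell specs.
#' @export
pair_diffusion_system <- function(reaction_radius_m,
                                  diffusion_coefficient_m2_s,
                                  far_field_concentration_per_m3) {
  stopifnot(length(reaction_radius_m) == 1, is.finite(reaction_radius_m),
            reaction_radius_m > 0,
            length(diffusion_coefficient_m2_s) == 1,
            is.finite(diffusion_coefficient_m2_s),
            diffusion_coefficient_m2_s > 0,
            length(far_field_concentration_per_m3) == 1,
            is.finite(far_field_concentration_per_m3),
            far_field_concentration_per_m3 > 0)
  structure(
    list(reaction_radius = reaction_radius_m,
         diffusion_coefficient = diffusion_coefficient_m2_s,
         far_field_concentration = far_field_concentration_per_m3),
    class = "pair_diffusion_system")
}

#' Build a pair-diffusion system from particle and cell specifications
#'
#' Convenience constructor: R = r_cell + r_particle, D from the
#' Stokes-Einstein mutual coefficient at the medium temperature, W0 the
#' nanoparticle number density.
#'
#' @param particle a [particle_spec()].
#' @param cell a [cell_spec()].
#' @param medium a [medium_state()].
#' @param nanoparticle_density_per_m3 far-field nanoparticle number density.
#' @return A [pair_diffusion_system()].
#' @export
pair_system_from_specs <- function(particle, cell, medium,
                                   nanoparticle_density_per_m3) {
  stopifnot(inherits(particle, "particle_spec"), inherits(cell, "cell_spec"))
  pair_diffusion_system(
    reaction_radius_m = cell$radius + particle$radius,
    diffusion_coefficient_m2_s =
      mutual_diffusion_coefficient(cell$radius, particle$radius, medium),
    far_field_concentration_per_m3 = nanoparticle_density_per_m3)
}

# complementary error function; exact via the normal CDF
erfc <- function(x) 2 * stats::pnorm(x * sqrt(2), lower.tail = FALSE)

#' Closed-form pair probability around an absorbing sphere
#'
#' The time-dependent concentration (pair-probability density) of the
#' diffusing species at distance r from the centre of an absorbing sphere of
#' radius R, for an initially uniform distribution W0:
#' \deqn{W(r,t) = W_0\left[1 - \frac{R}{r}\,
#'   \mathrm{Erfc}\!\left(\frac{r-R}{2\sqrt{Dt}}\right)\right].}
#' At t = 0 it returns W0 for r > R; at r = R it is 0 for all t > 0
#' (black-sphere absorbing boundary); as t grows it relaxes to the stationary
#' profile W0 (1 - R/r). Erfc arguments above 26 underflow; the value is then
#' clamped to W0 exactly.
#'
#' @param distance_m radial distance r >= R (vectorised).
#' @param time_s time since the initially uniform state, t >= 0 (vectorised;
#'   recycled against \code{distance_m}).
#' @param system a [pair_diffusion_system()].
#' @return Concentration in particles/m3, in [0, W0].
#' @export
pair_probability <- function(distance_m, time_s, system) {
  stopifnot(inherits(system, "pair_diffusion_system"),
            is.numeric(distance_m), is.numeric(time_s),
            all(is.finite(distance_m)), all(is.finite(time_s)),
            all(time_s >= 0))
  R <- system$reaction_radius
  D <- system$diffusion_coefficient
  W0 <- system$far_field_concentration
  if (any(distance_m < R * (1 - 1e-12)))
    stop("distance must be >= the reaction radius R", call. = FALSE)
  n <- max(length(distance_m), length(time_s))
  r <- rep_len(distance_m, n)
  t <- rep_len(time_s, n)
  arg <- ifelse(t > 0, (r - R) / (2 * sqrt(D * t)), Inf)
  w <- ifelse(arg > 26, W0, W0 * (1 - (R / r) * erfc(arg)))
  pmin(pmax(w, 0), W0)
}

#' Transient diffusion-limited rate constant
#'
#' The time-dependent Smoluchowski rate constant
#' \deqn{k_1(t) = 4\pi R D \left(1 + \frac{R}{\sqrt{\pi D t}}\right),}
#' strictly decreasing in t with limit 4 pi R D. The t -> 0 divergence is a
#' property of the initially uniform state and is not returned: t must be
#' positive.
#'
#' @param time_s time in seconds, > 0 (vectorised).
#' @param system a [pair_diffusion_system()].
#' @return Rate constant in m3/s.
#' @export
transient_rate_constant <- function(time_s, system) {
  stopifnot(inherits(system, "pair_diffusion_system"), is.numeric(time_s),
            all(is.finite(time_s)))
  if (any(time_s <= 0))
    stop("time must be positive (the t -> 0 limit diverges)", call. = FALSE)
  R <- system$reaction_radius
  D <- system$diffusion_coefficient
  4 * pi * R * D * (1 + R / sqrt(pi * D * time_s))
}

#' Stationary Smoluchowski rate constant
#'
#' The long-time limit \eqn{k_1 = 4\pi R D} of the diffusion-limited rate
#' constant; this is the value used in all downstream kinetics by default.
#'
#' @param system a [pair_diffusion_system()].
#' @return Rate constant in m3/s.
#' @export
#' @examples
#' s <- pair_diffusion_system(5.035e-6, 6.51e-12, 3.98e16)
#' stationary_rate_constant(s)  # ~4.12e-16 m3/s
stationary_rate_constant <- function(system) {
  stopifnot(inherits(system, "pair_diffusion_system"))
  4 * pi * system$reaction_radius * system$diffusion_coefficient
}

#' Logarithmically spaced radial grid
#'
#' Grid for the radial-diffusion oracle: nodes from the reaction radius R to
#' \code{outer_radius}, log-spaced so the thin depletion layer near R is
#' resolved without a huge grid.
#'
#' @param reaction_radius_m inner (absorbing) radius R.
#' @param outer_radius_m outer radius where the far-field condition is
#'   imposed; must be at least 20 R (default 50 R).
#' @param n_nodes number of nodes including both boundaries.
#' @param time_step_s reporting time step for the solver output.
#' @return An object of class \code{radial_grid} with fields
#'   \code{node_positions}, \code{outer_radius}, \code{time_step}.
#' @export
radial_grid <- function(reaction_radius_m,
                        outer_radius_m = 50 * reaction_radius_m,
                        n_nodes = 240, time_step_s) {
  stopifnot(length(reaction_radius_m) == 1, reaction_radius_m > 0,
            length(outer_radius_m) == 1, is.finite(outer_radius_m),
            n_nodes >= 10, length(time_step_s) == 1, is.finite(time_step_s),
            time_step_s > 0)
  if (outer_radius_m < 20 * reaction_radius_m)
    stop("outer radius must be at least 20 reaction radii", call. = FALSE)
  nodes <- exp(seq(log(reaction_radius_m), log(outer_radius_m),
                   length.out = n_nodes))
  nodes[1] <- reaction_radius_m
  nodes[n_nodes] <- outer_radius_m
  structure(list(node_positions = nodes, outer_radius = outer_radius_m,
                 time_step = time_step_s),
            class = "radial_grid")
}

#' Numerical radial-diffusion oracle
#'
#' Independently solves the radial diffusion equation around an absorbing
#' sphere by the method of lines, for validating the closed-form
#' [pair_probability()] and [transient_rate_constant()]. The substitution
#' omega = r W reduces the spherically symmetric problem to one-dimensional
#' diffusion \eqn{\partial\omega/\partial t = D\,\partial^2\omega/\partial r^2}
#' with omega(R, t) = 0 (absorbing) and omega(r_out, t) = r_out W0
#' (far field), discretised on the (non-uniform) grid with a three-point
#' stencil and integrated by \code{deSolve::lsoda} at tight tolerances.
#' The boundary flux \eqn{4\pi R^2 D\, \partial W/\partial r|_R =
#' 4\pi R D\, \omega'(R)} is recovered with a one-sided three-point
#' difference.
#'
#' @param system a [pair_diffusion_system()].
#' @param grid a [radial_grid()]; its \code{time_step} sets the output times.
#' @param horizon_s final time of the integration, in seconds.
#' @return A list of class \code{radial_oracle} with elements
#'   \code{times} (s), \code{r} (m), \code{W} (matrix, times x nodes,
#'   particles/m3), \code{flux} (particles/s into the sphere) and
#'   \code{rate_constant} (flux / W0, m3/s).
#' @export
radial_diffusion_oracle <- function(system, grid, horizon_s) {
  stopifnot(inherits(system, "pair_diffusion_system"),
            inherits(grid, "radial_grid"),
            length(horizon_s) == 1, is.finite(horizon_s), horizon_s > 0)
  R <- system$reaction_radius
  D <- system$diffusion_coefficient
  W0 <- system$far_field_concentration
  r <- grid$node_positions
  if (abs(r[1] - R) > 1e-12 * R)
    stop("grid must start at the reaction radius", call. = FALSE)
  n <- length(r)
  h <- diff(r)                       # n-1 spacings
  # interior nodes 2..(n-1); state is omega at the interior nodes
  hl <- h[seq_len(n - 2)]            # spacing to the left of node i
  hr <- h[2:(n - 1)]                 # spacing to the right of node i
  cl <- 2 / (hl * (hl + hr))
  cc <- -2 / (hl * hr)
  cr <- 2 / (hr * (hl + hr))
  omega_left <- 0                    # absorbing boundary, omega(R) = 0
  omega_right <- r[n] * W0           # far-field boundary
  rhs <- function(t, y, parms) {
    yl <- c(omega_left, y[-(n - 2)])
    yr <- c(y[-1], omega_right)
    list(D * (cl * yl + cc * y + cr * yr))
  }
  y0 <- r[2:(n - 1)] * W0            # initially uniform W = W0
  times <- unique(c(0, seq(0, horizon_s, by = grid$time_step), horizon_s))
  sol <- deSolve::lsoda(y0, times, rhs, parms = NULL,
                        rtol = 1e-9, atol = 1e-9 * max(abs(omega_right)),
                        jactype = "bandint", bandup = 1, banddown = 1)
  omega <- cbind(omega_left, sol[, -1, drop = FALSE], omega_right)
  W <- sweep(omega, 2, r, "/")
  W[, 1] <- 0
  if (any(!is.finite(W)) ||
      any(W < -1e-3 * W0) || any(W > W0 * (1 + 1e-3)))
    stop("radial solver instability: probability out of [0, W0]",
         call. = FALSE)
  # one-sided three-point derivative of omega at r = R (omega(R) = 0)
  x1 <- r[1]; x2 <- r[2]; x3 <- r[3]
  c2 <- (x1 - x3) / ((x2 - x1) * (x2 - x3))
  c3 <- (x1 - x2) / ((x3 - x1) * (x3 - x2))
  domega <- omega[, 2] * c2 + omega[, 3] * c3
  flux <- 4 * pi * R * D * domega
  structure(list(times = sol[, 1], r = r, W = W, flux = flux,
                 rate_constant = flux / W0),
            class = "radial_oracle")
}

#' Long-format profile of a radial oracle solution
#'
#' @param oracle result of [radial_diffusion_oracle()].
#' @return A data.frame with columns \code{r_m}, \code{t_s}, \code{W}.
#' @export
oracle_profile_long <- function(oracle) {
  stopifnot(inherits(oracle, "radial_oracle"))
  data.frame(r_m = rep(oracle$r, each = length(oracle$times)),
             t_s = rep(oracle$times, times = length(oracle$r)),
             W = as.vector(oracle$W))
}
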