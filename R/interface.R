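#' Default run configuration
#'
#' The physical parameter block and run options used across the analysis
#' scripts, with defaults equal to the study's parameter list: nanoparticle
#' radius 35 nm, bulk density 350 kg/m3, macrophage radius 5 um, cell
#' concentration 5e5 /mL, and the three water-viscosity constants.
#'
#' @return A named list of configuration values.
#' @export
default_run_config <- function() {
  list(
    particle_radius_m = 35e-9,
    particle_bulk_density_kg_m3 = 350,
    cell_radius_m = 5e-6,
    cell_concentration_per_ml = 5e5,
    viscosity_A = 2.414e-5,
    viscosity_B = 247.8,
    viscosity_C = 140,
    convention = "corrected",
    transient_k1 = FALSE,
    time_window_min = NULL,
    seed = 1L)
}

#' Read and validate a run configuration
#'
#' Reads a flat YAML key/value file, overlays it on the defaults and
#' validates it. Unknown keys are rejected so that typos never silently
#' fall back to a default.
#'
#' @param path path to a YAML file, or NULL for pure defaults.
#' @return A validated configuration list of class \code{run_config}.
#' @export
read_run_config <- function(path = NULL) {
  config <- default_run_config()
  if (!is.null(path)) {
    if (!file.exists(path))
      stop("config file not found: ", path, call. = FALSE)
    user <- yaml::read_yaml(path)
    if (!is.list(user)) stop("config must be a YAML mapping", call. = FALSE)
    unknown <- setdiff(names(user), names(config))
    if (length(unknown) > 0)
      stop("unknown config key(s): ", paste(unknown, collapse = ", "),
           call. = FALSE)
    config[names(user)] <- user
  }
  stopifnot(config$particle_radius_m > 0,
            config$particle_bulk_density_kg_m3 > 0,
            config$cell_radius_m > 0,
            config$cell_concentration_per_ml >= 0,
            config$viscosity_A > 0,
            config$convention %in% c("corrected", "printed"),
            is.logical(config$transient_k1))
  config$seed <- as.integer(config$seed)
  class(config) <- c("run_config", "list")
  config
}

#' Particle and cell specifications from a run configuration
#'
#' @param config a [read_run_config()] result.
#' @return A list with elements \code{particle} and \code{cell}.
#' @export
specs_from_config <- function(config) {
  stopifnot(inherits(config, "run_config"))
  list(particle = particle_spec(config$particle_radius_m,
                                config$particle_bulk_density_kg_m3),
       cell = cell_spec(config$cell_radius_m,
                        cells_per_ml_to_per_m3(
                          config$cell_concentration_per_ml)))
}

#' Transport and rate-constant table across temperatures
#'
#' For each requested temperature: water viscosity, the mutual
#' cell--nanoparticle diffusion coefficient, the stationary diffusion-limited
#' rate constant k1, and (if a death probability is supplied) the effective
#' death rate constant k2.
#'
#' @param temperatures_C temperatures in degrees Celsius (any order; output
#'   is sorted).
#' @param config a [read_run_config()] result (defaults used when NULL).
#' @param p2 optional death probability for the k2 column.
#' @return A data.frame with columns \code{temperature_C},
#'   \code{viscosity_Pa_s}, \code{diffusion_m2_s}, \code{k1_m3_s} and
#'   optionally \code{k2_m3_s}.
#' @export
rate_table <- function(temperatures_C, config = read_run_config(),
                       p2 = NULL) {
  stopifnot(is.numeric(temperatures_C), length(temperatures_C) >= 1)
  temperatures_C <- sort(temperatures_C)
  sp <- specs_from_config(config)
  rows <- lapply(temperatures_C, function(tC) {
    med <- medium_state(celsius_to_kelvin(tC), config$viscosity_A,
                        config$viscosity_B, config$viscosity_C)
    D <- mutual_diffusion_coefficient(sp$cell$radius, sp$particle$radius,
                                      med)
    sys <- pair_diffusion_system(sp$cell$radius + sp$particle$radius, D, 1)
    k1 <- stationary_rate_constant(sys)
    row <- data.frame(temperature_C = tC, viscosity_Pa_s = med$viscosity,
                      diffusion_m2_s = D, k1_m3_s = k1)
    if (!is.null(p2)) {
      model <- aod_survival_model(p2, config$convention)
      row$k2_m3_s <- k1 * exp(convention_exponent(p2, config$convention))
    }
    row
  })
  do.call(rbind, rows)
}

#' Serialise fit results to JSON
#'
#' Writes one record per fit: label, p2_hat, k2_hat_m3_per_s, eact2_hat_J,
#' r_squared, convention, n_points.
#'
#' @param fits a list of [fit_p2()] results.
#' @param path output path; when NULL the JSON string is returned.
#' @return The JSON string, invisibly if written to a file.
#' @export
write_fit_json <- function(fits, path = NULL) {
  if (inherits(fits, "p2_fit")) fits <- list(fits)
  stopifnot(all(vapply(fits, inherits, logical(1), "p2_fit")))
  records <- lapply(fits, function(f)
    list(label = f$label, p2_hat = f$p2_hat,
         k2_hat_m3_per_s = f$k2_hat, eact2_hat_J = f$eact2_hat,
         r_squared = f$r_squared, convention = f$convention,
         n_points = f$n_points))
  json <- jsonlite::toJSON(records, auto_unbox = TRUE, digits = NA,
                           pretty = TRUE, null = "null")
  if (is.null(path)) return(json)
  writeLines(json, path)
  invisible(json)
}

#' Export a predicted time course as CSV
#'
#' Columns: temperature_C, agnp_ug_per_ml, time_min, fraction_damaged_pred.
#'
#' @param prediction result of [predict_timecourse()].
#' @param temperature_C,agnp_ug_per_ml condition identifiers for the rows.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_prediction_csv <- function(prediction, temperature_C, agnp_ug_per_ml,
                                 path) {
  stopifnot(is.data.frame(prediction),
            all(c("time_min", "fraction_damaged") %in% names(prediction)))
  out <- data.frame(temperature_C = temperature_C,
                    agnp_ug_per_ml = agnp_ug_per_ml,
                    time_min = prediction$time_min,
                    fraction_damaged_pred = prediction$fraction_damaged)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}
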