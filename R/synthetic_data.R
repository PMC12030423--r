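#' Membrane-integrity assay design
#'
#' Design of a synthetic dual-fluorochrome membrane-integrity assay: cells
#' are scored damaged/intact over microscope fields of view, per temperature,
#' nanoparticle concentration and incubation time. The default field layout
#' (50 fields of ~30 cells) matches the counting protocol of scoring at
#' least 50 fields totalling at least 1500 cells per condition.
#'
#' @param temperatures_C incubation temperatures in degrees Celsius.
#' @param concentrations_ug_ml nanoparticle mass concentrations in ug/mL.
#' @param times_min observation times in minutes.
#' @param n_fields microscope fields per time point (default 50).
#' @param mean_cells_per_field mean cells per field (default 30).
#' @param baseline_damage spontaneous damage fraction in controls,
#'   in [0, 0.2] (default 0.02).
#' @param breakdown_time_min onset time of the late oxidative-stress excess
#'   regime, minutes, or NULL for none.
#' @param breakdown_factor hazard multiplier (>= 1) applied beyond
#'   \code{breakdown_time_min}.
#' @param seed integer seed; the whole dataset is a deterministic function
#'   of the design.
#' @return An object of class \code{assay_design}.
#' @export
assay_design <- function(temperatures_C, concentrations_ug_ml, times_min,
                         n_fields = 50, mean_cells_per_field = 30,
                         baseline_damage = 0.02,
                         breakdown_time_min = NULL, breakdown_factor = 1,
                         seed = 1L) {
  stopifnot(is.numeric(temperatures_C), length(temperatures_C) >= 1,
            is.numeric(concentrations_ug_ml),
            all(concentrations_ug_ml >= 0),
            is.numeric(times_min), all(times_min >= 0),
            n_fields >= 1, mean_cells_per_field > 0,
            baseline_damage >= 0, baseline_damage <= 0.2,
            breakdown_factor >= 1,
            length(seed) == 1, is.finite(seed))
  if (n_fields * mean_cells_per_field < 1500)
    warning("design yields fewer than 1500 cells per time point on ",
            "average; the counting protocol requires at least 50 fields ",
            "and 1500 cells", call. = FALSE)
  if (!is.null(breakdown_time_min))
    stopifnot(length(breakdown_time_min) == 1, breakdown_time_min > 0)
  structure(list(temperatures_C = temperatures_C,
                 concentrations_ug_ml = concentrations_ug_ml,
                 times_min = sort(times_min),
                 n_fields = as.integer(n_fields),
                 mean_cells_per_field = mean_cells_per_field,
                 baseline_damage = baseline_damage,
                 breakdown_time_min = breakdown_time_min,
                 breakdown_factor = breakdown_factor,
                 seed = as.integer(seed)),
            class = "assay_design")
}

#' True damage probability at a design point
#'
#' The per-cell probability of a damaged-membrane call: the kinetic model
#' fraction, optionally inflated after \code{breakdown_time_min} by
#' multiplying the cumulative hazard -log(1 - f) by
#' \code{breakdown_factor} (the late oxidative-stress excess), then mixed
#' with an independent baseline damage fraction b as
#' \eqn{f^* = b + (1 - b) f}. Reduces exactly to the model fraction when
#' b = 0 and the factor is 1.
#'
#' @param time_min time in minutes (vectorised).
#' @param model an [aod_survival_model()].
#' @param medium a [medium_state()].
#' @param condition an [experiment_condition()].
#' @param baseline_damage baseline damage fraction b.
#' @param breakdown_time_min onset of the excess regime, or NULL.
#' @param breakdown_factor hazard multiplier >= 1.
#' @return Probability in [0, 1).
#' @export
true_fraction <- function(time_min, model, medium, condition,
                          baseline_damage = 0, breakdown_time_min = NULL,
                          breakdown_factor = 1) {
  f <- predict_timecourse(time_min, condition, medium,
                          model)$fraction_damaged
  if (!is.null(breakdown_time_min) && breakdown_factor != 1) {
    late <- time_min > breakdown_time_min
    f[late] <- 1 - (1 - f[late])^breakdown_factor
  }
  baseline_damage + (1 - baseline_damage) * f
}

# run expr with a private RNG stream; restores the caller's state
with_private_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Simulate a membrane-integrity assay
#'
#' Generates per-field damaged/intact counts for every design point: the
#' number of cells in each field is Poisson around the design mean, and the
#' damaged count is binomial with the model's [true_fraction()] as success
#' probability. The same seed always regenerates the identical dataset.
#'
#' @param design an [assay_design()].
#' @param model an [aod_survival_model()]; \code{death_probability} may be
#'   named by temperature (kelvin) to vary P2 across conditions.
#' @param particle a [particle_spec()].
#' @param cell a [cell_spec()].
#' @return A data.frame of class \code{synthetic_assay} with columns
#'   \code{temperature_C}, \code{agnp_ug_per_ml}, \code{time_min},
#'   \code{field_id}, \code{cells_in_field}, \code{cells_damaged}, and a
#'   \code{provenance} attribute (true P2, convention, seed, baseline and
#'   breakdown settings).
#' @export
simulate_assay <- function(design, model, particle = particle_spec(),
                           cell = cell_spec()) {
  stopifnot(inherits(design, "assay_design"),
            inherits(model, "aod_survival_model"))
  grid <- expand.grid(temperature_C = design$temperatures_C,
                      agnp_ug_per_ml = design$concentrations_ug_ml,
                      time_min = design$times_min,
                      KEEP.OUT.ATTRS = FALSE)
  grid <- grid[order(grid$temperature_C, grid$agnp_ug_per_ml,
                     grid$time_min), , drop = FALSE]
  rows <- with_private_seed(design$seed, {
    out <- vector("list", nrow(grid))
    for (i in seq_len(nrow(grid))) {
      tC <- grid$temperature_C[i]
      conc <- grid$agnp_ug_per_ml[i]
      tmin <- grid$time_min[i]
      tK <- celsius_to_kelvin(tC)
      med <- medium_state(tK)
      cond <- experiment_condition(
        tK, mass_to_number_density(conc, particle),
        particle = particle, cell = cell)
      p <- true_fraction(tmin, model, med, cond,
                         baseline_damage = design$baseline_damage,
                         breakdown_time_min = design$breakdown_time_min,
                         breakdown_factor = design$breakdown_factor)
      n_cells <- stats::rpois(design$n_fields, design$mean_cells_per_field)
      n_dam <- stats::rbinom(design$n_fields, n_cells, p)
      out[[i]] <- data.frame(
        temperature_C = tC, agnp_ug_per_ml = conc, time_min = tmin,
        field_id = seq_len(design$n_fields),
        cells_in_field = n_cells, cells_damaged = n_dam)
    }
    out
  })
  ds <- do.call(rbind, rows)
  rownames(ds) <- NULL
  attr(ds, "provenance") <- list(
    death_probability = model$death_probability,
    convention = model$convention, seed = design$seed,
    baseline_damage = design$baseline_damage,
    breakdown_time_min = design$breakdown_time_min,
    breakdown_factor = design$breakdown_factor)
  class(ds) <- c("synthetic_assay", "data.frame")
  ds
}

#' Pool a synthetic assay into damage time courses
#'
#' Sums cells over fields per (temperature, concentration, time) and returns
#' one [damage_timecourse()] per (temperature, concentration) series.
#'
#' @param dataset a [simulate_assay()] result (or any data.frame with its
#'   columns).
#' @param particle a [particle_spec()] used to convert concentrations to
#'   number densities for the series attributes.
#' @return A named list of [damage_timecourse()] objects; names are
#'   "<T>C_<conc>ug".
#' @export
pool_assay <- function(dataset, particle = particle_spec()) {
  need <- c("temperature_C", "agnp_ug_per_ml", "time_min",
            "cells_in_field", "cells_damaged")
  stopifnot(all(need %in% names(dataset)))
  agg <- stats::aggregate(
    cbind(cells_in_field, cells_damaged) ~
      temperature_C + agnp_ug_per_ml + time_min,
    data = dataset, FUN = sum)
  split_key <- interaction(agg$temperature_C, agg$agnp_ug_per_ml,
                           drop = TRUE)
  out <- lapply(split(agg, split_key), function(g) {
    g <- g[order(g$time_min), , drop = FALSE]
    damage_timecourse(
      time_min = g$time_min,
      cells_counted = g$cells_in_field,
      cells_damaged = g$cells_damaged,
      temperature_K = celsius_to_kelvin(g$temperature_C[1]),
      nanoparticle_density_per_m3 =
        mass_to_number_density(g$agnp_ug_per_ml[1], particle),
      label = sprintf("%gC_%gug", g$temperature_C[1], g$agnp_ug_per_ml[1]))
  })
  names(out) <- vapply(out, attr, character(1), "label")
  out
}

#' Reported damage time courses (text-stated values)
#'
#' Small fixed time courses encoding the damage levels reported in the
#' source assay's narrative (not digitised from figures), tagged
#' approximate: at 5 ug/mL, the 22 C series reaches ~20% at 30 min and ~50%
#' at 150 min; the 37 C series ~50% at 10 min and ~90% at 60 min; at
#' 2.5 ug/mL and 4 C, ~40% (encoded at the 60-min observation).
#'
#' @param particle a [particle_spec()] for concentration conversion.
#' @return A named list of [damage_timecourse()] objects
#'   (\code{"22C"}, \code{"37C"}, \code{"4C"}).
#' @export
reported_damage_fixture <- function(particle = particle_spec()) {
  list(
    "22C" = damage_timecourse(
      time_min = c(30, 150), fraction = c(0.20, 0.50),
      temperature_K = celsius_to_kelvin(22),
      nanoparticle_density_per_m3 = mass_to_number_density(5, particle),
      label = "22C_5ug_reported"),
    "37C" = damage_timecourse(
      time_min = c(10, 60), fraction = c(0.50, 0.90),
      temperature_K = celsius_to_kelvin(37),
      nanoparticle_density_per_m3 = mass_to_number_density(5, particle),
      label = "37C_5ug_reported"),
    "4C" = damage_timecourse(
      time_min = 60, fraction = 0.40,
      temperature_K = celsius_to_kelvin(4),
      nanoparticle_density_per_m3 = mass_to_number_density(2.5, particle),
      label = "4C_2.5ug_reported"))
}

#' Write a synthetic assay (or time course) to CSV with provenance header
#'
#' Provenance (true P2, convention, seed, baseline/breakdown settings) is
#' written as "#"-prefixed comment lines before the header so the file
#' round-trips losslessly through [read_assay_csv()].
#'
#' @param dataset a [simulate_assay()] data.frame.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
write_assay_csv <- function(dataset, path) {
  stopifnot(is.data.frame(dataset))
  prov <- attr(dataset, "provenance")
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(prov)) {
    for (key in names(prov)) {
      val <- prov[[key]]
      ser <- if (is.null(val)) "NULL"
      else if (!is.null(names(val)))
        paste(names(val),
              format(unname(val), digits = 17, trim = TRUE),
              sep = "=", collapse = ",")
      else paste(format(val, digits = 17, trim = TRUE), collapse = ",")
      writeLines(sprintf("# %s: %s", key, ser), con)
    }
  }
  utils::write.csv(as.data.frame(dataset), con, row.names = FALSE)
  invisible(path)
}

#' Read a synthetic assay CSV written by [write_assay_csv()]
#'
#' @param path input file path.
#' @return A data.frame with the assay columns and, if present in the
#'   header, a \code{provenance} attribute.
#' @export
read_assay_csv <- function(path) {
  lines <- readLines(path)
  is_comment <- startsWith(lines, "#")
  prov <- NULL
  if (any(is_comment)) {
    prov <- list()
    for (ln in lines[is_comment]) {
      m <- regmatches(ln, regexec("^# ([^:]+): (.*)$", ln))[[1]]
      if (length(m) == 3) {
        val <- if (m[3] == "NULL") NULL else {
          parts <- strsplit(m[3], ",")[[1]]
          if (all(grepl("=", parts, fixed = TRUE))) {
            kv <- strsplit(parts, "=", fixed = TRUE)
            stats::setNames(as.numeric(vapply(kv, `[`, "", 2)),
                            vapply(kv, `[`, "", 1))
          } else {
            num <- suppressWarnings(as.numeric(parts))
            if (any(is.na(num))) m[3] else num
          }
        }
        prov[[m[2]]] <- val
      }
    }
  }
  body <- lines[!is_comment]
  if (length(body) < 2)
    stop("malformed assay CSV (no data rows): ", path, call. = FALSE)
  ds <- tryCatch(
    utils::read.csv(text = paste(body, collapse = "\n")),
    error = function(e)
      stop("malformed assay CSV at data line: ", conditionMessage(e),
           call. = FALSE))
  need <- c("temperature_C", "agnp_ug_per_ml", "time_min",
            "cells_in_field", "cells_damaged")
  missing_cols <- setdiff(need, names(ds))
  if (length(missing_cols) > 0)
    stop("assay CSV missing required column(s): ",
         paste(missing_cols, collapse = ", "),
         " (header at line ", which(!is_comment)[1], ")", call. = FALSE)
  if (!is.null(prov)) attr(ds, "provenance") <- prov
  class(ds) <- c("synthetic_assay", "data.frame")
  ds
}
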