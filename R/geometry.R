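#' Transwell experiment geometry
#'
#' Describes the physical set-up of a two-compartment insert experiment:
#' donor (apical) and receiver (basolateral) volumes, the membrane area of
#' the insert, and the sampling schedule. The basolateral/apical volume
#' factor is always derived from the volumes, never supplied.
#'
#' @param apical_volume Apical (donor) compartment volume in microlitres.
#' @param basolateral_volume Basolateral (receiver) compartment volume in
#'   microlitres.
#' @param insert_area Membrane area of the insert in cm^2.
#' @param sampling_times Strictly increasing sampling times in minutes; the
#'   receiver compartment is fully replaced at each of them.
#'
#' @return An object of class `experiment_geometry`: a list with the four
#'   arguments plus `volume_factor` (basolateral/apical, dimensionless).
#' @examples
#' geom <- experiment_geometry(300, 900, 0.336, c(60, 120, 180, 240))
#' geom$volume_factor  # 3
#' @export
experiment_geometry <- function(apical_volume, basolateral_volume,
                                insert_area, sampling_times) {
  stop_if_not_scalar_pos(apical_volume, "apical_volume")
  stop_if_not_scalar_pos(basolateral_volume, "basolateral_volume")
  stop_if_not_scalar_pos(insert_area, "insert_area")
  sampling_times <- as.numeric(sampling_times)
  if (length(sampling_times) < 1 || anyNA(sampling_times)) {
    stop("'sampling_times' must be a non-empty numeric vector", call. = FALSE)
  }
  if (sampling_times[1] <= 0) {
    stop("'sampling_times' must start after time zero", call. = FALSE)
  }
  if (is.unsorted(sampling_times, strictly = TRUE)) {
    stop("'sampling_times' must be strictly increasing", call. = FALSE)
  }
  structure(
    list(
      apical_volume = as.numeric(apical_volume),
      basolateral_volume = as.numeric(basolateral_volume),
      insert_area = as.numeric(insert_area),
      sampling_times = sampling_times,
      volume_factor = as.numeric(basolateral_volume) / as.numeric(apical_volume)
    ),
    class = "experiment_geometry"
  )
}

#' Default 24-well ThinCert geometry
#'
#' 300 uL apical / 900 uL basolateral, 0.336 cm^2 inserts, hourly sampling
#' for four hours with full basolateral media replacement.
#'
#' @return An [experiment_geometry()] object with volume factor 3.
#' @export
default_geometry <- function() {
  experiment_geometry(300, 900, 0.336, c(60, 120, 180, 240))
}

#' Read experiment geometry from a YAML config file
#'
#' Accepts either long key names (`apical_volume`, `basolateral_volume`,
#' `insert_area`, `sampling_times`) or the short forms `apical`, `baso`,
#' `area`, `times`. The volume factor is always computed from the volumes.
#'
#' @param path Path to a YAML file.
#' @return An [experiment_geometry()] object.
#' @export
read_experiment_config <- function(path) {
  if (!file.exists(path)) {
    stop("config file not found: ", path, call. = FALSE)
  }
  cfg <- yaml::read_yaml(path)
  pick <- function(...) {
    for (k in c(...)) if (!is.null(cfg[[k]])) return(cfg[[k]])
    stop("config is missing key '", ..1, "' (", path, ")", call. = FALSE)
  }
  experiment_geometry(
    apical_volume = pick("apical_volume", "apical"),
    basolateral_volume = pick("basolateral_volume", "baso", "basolateral"),
    insert_area = pick("insert_area", "area"),
    sampling_times = pick("sampling_times", "times")
  )
}

#' @export
print.experiment_geometry <- function(x, ...) {
  cat("Transwell geometry:\n")
  cat(sprintf("  apical %g uL / basolateral %g uL (volume factor %g)\n",
              x$apical_volume, x$basolateral_volume, x$volume_factor))
  cat(sprintf("  insert area %g cm^2\n", x$insert_area))
  cat("  sampling times [min]:", paste(x$sampling_times, collapse = ", "), "\n")
  invisible(x)
}

stop_if_not_scalar_pos <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x) || x <= 0) {
    stop("'", name, "' must be a single positive number", call. = FALSE)
  }
}
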