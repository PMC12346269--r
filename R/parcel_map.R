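#' Canonical order of the six dynamics parameters
#'
#' The fixed parameter order used when maps are stacked into matrices or
#' concatenated into subject vectors: aperiodic exponent, knee frequency,
#' aperiodic AUC, Hurst exponent, alpha power, alpha peak frequency.
#' @export
DYNAMICS_PARAMETERS <- c("exponent", "knee_frequency", "auc",
                         "hurst", "alpha_power", "alpha_frequency")

#' Construct a parcel map
#'
#' A `parcel_map` is a numeric vector with one value (or `NA`) per
#' parcel of a given geometry, carrying the parameter label and a
#' geometry reference. Missing values stay explicit; they are never
#' dropped silently.
#'
#' @param values numeric vector, one entry per parcel (`NA` allowed).
#' @param geometry the [parcel_geometry()] the map indexes.
#' @param parameter a label, typically one of [DYNAMICS_PARAMETERS].
#' @return numeric vector of class `parcel_map`.
#' @export
parcel_map <- function(values, geometry, parameter = "map") {
  values <- as.numeric(values)
  if (length(values) != n_parcels(geometry))
    stop_invalid("map length (", length(values),
                 ") != parcel count (", n_parcels(geometry), ")")
  structure(values, class = "parcel_map", parameter = parameter,
            geometry_ref = geometry_id(geometry))
}

#' @export
print.parcel_map <- function(x, ...) {
  cat(sprintf("<parcel_map> '%s', %d parcels, %d missing\n",
              attr(x, "parameter"), length(x), sum(is.na(x))))
  invisible(x)
}

# Cheap content hash identifying a geometry (for map/geometry checks).
geometry_id <- function(geometry) {
  v <- c(geometry$sphere_xyz)
  sprintf("geom-%d-%.6f", length(geometry$parcel_id),
          sum(v * seq_along(v)) %% 1e6)
}

map_values <- function(map) {
  v <- unclass(map)
  attributes(v) <- NULL
  v
}
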