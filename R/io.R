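#' Read / write parcel tables
#'
#' Maps, feature tables and geometries travel as tab-separated text
#' with a header row. A geometry table has columns `parcel_id`,
#' `sphere_x/y/z`, `anat_x/y/z`, `medial_wall` and optionally
#' `pair_left`/`pair_right` flags encoding the homotopic pairing.
#'
#' @param path file path.
#' @param x data.frame (or coercible) to write.
#' @name parcel_io
NULL

#' @rdname parcel_io
#' @export
read_parcel_table <- function(path) {
  as.data.frame(data.table::fread(path, sep = "\t"))
}

#' @rdname parcel_io
#' @export
write_parcel_table <- function(x, path) {
  data.table::fwrite(as.data.frame(x), path, sep = "\t", na = "NA")
  invisible(path)
}

#' @rdname parcel_io
#' @export
write_geometry <- function(geometry, path) {
  df <- data.frame(parcel_id = geometry$parcel_id,
                   sphere_x = geometry$sphere_xyz[, 1],
                   sphere_y = geometry$sphere_xyz[, 2],
                   sphere_z = geometry$sphere_xyz[, 3],
                   anat_x = geometry$anat_xyz[, 1],
                   anat_y = geometry$anat_xyz[, 2],
                   anat_z = geometry$anat_xyz[, 3],
                   medial_wall = geometry$medial_wall)
  if (!is.null(geometry$homotopic_pairs)) {
    hp <- geometry$homotopic_pairs
    pair <- integer(nrow(df))
    pair[hp$left] <- seq_len(nrow(hp))
    pair[hp$right] <- seq_len(nrow(hp))
    side <- character(nrow(df))
    side[hp$left] <- "L"; side[hp$right] <- "R"
    df$pair <- pair; df$side <- side
  }
  write_parcel_table(df, path)
}

#' @rdname parcel_io
#' @export
read_geometry <- function(path) {
  df <- read_parcel_table(path)
  hp <- NULL
  if (!is.null(df$pair)) {
    hp <- data.frame(
      left = order(df$pair[df$side == "L"]) |>
        (\(o) which(df$side == "L")[o])(),
      right = order(df$pair[df$side == "R"]) |>
        (\(o) which(df$side == "R")[o])())
  }
  parcel_geometry(df$parcel_id,
                  cbind(df$sphere_x, df$sphere_y, df$sphere_z),
                  cbind(df$anat_x, df$anat_y, df$anat_z),
                  medial_wall = df$medial_wall,
                  homotopic_pairs = hp)
}

#' Write a cohort's subject maps to a directory
#'
#' One `geometry.tsv` plus, per subject and condition, a tabular file
#' `maps_<subject>_<condition>.tsv` (parcel_id + six parameter
#' columns), and a `subjects.tsv` index with group labels and symptom
#' scores.
#'
#' @param cohort a [simulate_cohort()] result.
#' @param dir output directory (created if needed).
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_geometry(cohort$geometry, file.path(dir, "geometry.tsv"))
  idx <- lapply(cohort$subjects, function(s) {
    for (cond in names(s$maps)) {
      df <- data.frame(parcel_id = cohort$geometry$parcel_id,
                       s$maps[[cond]])
      write_parcel_table(df, file.path(
        dir, sprintf("maps_%s_%s.tsv", s$subject_id, cond)))
    }
    data.frame(subject_id = s$subject_id, group_label = s$group_label,
               conditions = paste(names(s$maps), collapse = ","),
               positive = s$symptoms[["positive"]] %||% NA_real_,
               negative = s$symptoms[["negative"]] %||% NA_real_)
  })
  write_parcel_table(do.call(rbind, idx), file.path(dir, "subjects.tsv"))
  invisible(dir)
}
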