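# Assembly of the full 30-variable measurement record.

measurement_units <- function() {
  c(Nasopharynx = "mm3", NasopharynxL = "mm", NasopharynxArea = "mm2",
    NasopharynxAPDist = "mm", NasopharynxWidth = "mm",
    Oropharynx = "mm3", OropharynxL = "mm", OropharynxArea = "mm2",
    OropharynxAPDist = "mm", OropharynxWidth = "mm",
    Laryngopharynx = "mm3", LaryngopharynxL = "mm",
    LaryngopharynxArea = "mm2", LaryngopharynxAPDist = "mm",
    LaryngopharynxWidth = "mm",
    PharynxVolume = "mm3", PharynxLength = "mm",
    GlottisArea = "mm2", GlottisAPDist = "mm", GlottisWidth = "mm",
    Subglottal = "mm3", SubglottalL = "mm", TracheaArea = "mm2",
    TracheaAPDist = "mm", TracheaWidth = "mm",
    VTLength_i = "mm", VelumLength = "mm", PSLengthLeft = "mm",
    PSLengthRight = "mm", AveragePSLength = "mm")
}

#' Names of the 30 measurement variables
#' @return character vector of length 30.
#' @export
measurement_variables <- function() names(measurement_units())

#' Assemble the full 30-variable measurement record
#'
#' Runs the region measurements plus the vocal-tract, velum and
#' piriform-sinus lengths and assembles one record for the scan. All
#' upstream artifacts must stem from the same scan (checked via their
#' `scan_id` when present). Only the piriform-sinus sides may be missing.
#'
#' @param volume a [ct_volume] (provenance only; may be NULL).
#' @param mask an `airway_mask` (provenance only; may be NULL).
#' @param mesh a watertight `airway_mesh`.
#' @param centerline a `centerline`.
#' @param sections list from [slice_orthogonal()].
#' @param landmarks a `landmark_set`.
#' @param partition optional precomputed `region_partition`.
#' @return A `measurement_record` with exactly 30 values and units.
#' @export
measure_all <- function(volume = NULL, mask = NULL, mesh, centerline,
                        sections, landmarks, partition = NULL) {
  ids <- unique(unlist(lapply(list(volume, mask, mesh$provenance),
                              function(x) x$scan_id %||% x$source)))
  ids <- ids[!is.null(ids) & !is.na(ids)]
  if (length(ids) > 1)
    stop("inconsistent provenance: scan ids ", paste(ids, collapse = " vs "))
  if (is.null(partition))
    partition <- partition_regions(centerline, landmarks)
  region <- measure_partition(mesh, centerline, sections, partition)
  ps <- piriform_lengths(landmarks)
  values <- c(region,
              list(VTLength_i = unname(vtl_incisor(centerline, partition,
                                                   landmarks)),
                   VelumLength = velum_length(landmarks),
                   PSLengthLeft = ps$left,
                   PSLengthRight = ps$right,
                   AveragePSLength = ps$average))
  units <- measurement_units()
  stopifnot(identical(names(values), names(units)))
  numeric_vals <- unlist(values)
  missing_ok <- c("PSLengthLeft", "PSLengthRight")
  bad <- names(numeric_vals)[is.na(numeric_vals) &
                               !names(numeric_vals) %in% missing_ok]
  if (length(bad)) stop("missing value for variable: ",
                        paste(bad, collapse = ", "))
  if (any(numeric_vals < 0, na.rm = TRUE))
    stop("negative measurement value; upstream geometry inconsistent")
  structure(list(values = as.list(numeric_vals), units = units,
                 scan_id = if (length(ids)) ids else NA_character_,
                 partition = partition),
            class = "measurement_record")
}

#' @export
print.measurement_record <- function(x, ...) {
  cat(sprintf("<measurement_record> scan %s, %d variables\n",
              x$scan_id, length(x$values)))
  df <- as.data.frame(x)
  print(df, row.names = FALSE, digits = 5)
  invisible(x)
}

#' @export
as.data.frame.measurement_record <- function(x, ...) {
  data.frame(scan_id = x$scan_id, variable = names(x$values),
             value = unlist(x$values), units = unname(x$units),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Write measurement records to CSV
#'
#' Writes the tidy long form (`scan_id`, `variable`, `value`, `units`), and
#' optionally a wide form with the 30 variable names as columns.
#'
#' @param records a `measurement_record` or list of them.
#' @param path output CSV path (tidy long form).
#' @param wide_path optional second path for the wide form.
#' @return `path`, invisibly.
#' @export
write_measurements <- function(records, path, wide_path = NULL) {
  if (inherits(records, "measurement_record")) records <- list(records)
  tidy <- do.call(rbind, lapply(records, as.data.frame))
  utils::write.csv(tidy, path, row.names = FALSE)
  if (!is.null(wide_path)) {
    wide <- do.call(rbind, lapply(records, function(r)
      as.data.frame(c(list(scan_id = r$scan_id), r$values))))
    utils::write.csv(wide, wide_path, row.names = FALSE)
  }
  invisible(path)
}
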