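#' Harmonize the CT reconstruction kernel
#'
#' Approximates the appearance of the standard reconstruction kernel.
#' Soft-kernel volumes are sharpened with a per-axial-slice 5x5 unsharp
#' enhancement (`out = in + amount * (in - boxmean5(in))`); bone-kernel
#' volumes are smoothed with a per-axial-slice 3x3 low-pass (uniform mean).
#' Both filters use reflective boundary handling. Standard-kernel volumes
#' pass through unchanged; the output kernel tag is always `"standard"`.
#'
#' @param volume a [ct_volume] with a known kernel tag.
#' @param amount unsharp gain for the soft-kernel branch (default 1).
#' @return A [ct_volume] tagged `"standard"`.
#' @export
harmonize_kernel <- function(volume, amount = 1) {
  stopifnot(inherits(volume, "ct_volume"))
  if (volume$kernel == "unknown")
    stop("kernel tag is unknown; set it explicitly before harmonizing")
  if (volume$kernel == "standard") return(volume)
  vox <- volume$voxels
  for (k in seq_len(dim(vox)[3])) {
    sl <- vox[, , k]
    if (volume$kernel == "soft") {
      vox[, , k] <- sl + amount * (sl - box_mean_2d(sl, 5L))
    } else {
      vox[, , k] <- box_mean_2d(sl, 3L)
    }
  }
  out <- volume
  out$voxels <- vox
  out$kernel <- "standard"
  out
}

# k x k uniform box mean of a matrix, reflective boundaries
box_mean_2d <- function(mat, k) {
  r <- (k - 1L) %/% 2L
  nr <- nrow(mat); nc <- ncol(mat)
  ri <- c(rev(seq_len(r) + 1L), seq_len(nr), nr - seq_len(r))
  ci <- c(rev(seq_len(r) + 1L), seq_len(nc), nc - seq_len(r))
  pad <- mat[ri, ci]
  acc <- matrix(0, nr, nc)
  for (dx in 0:(k - 1L)) for (dy in 0:(k - 1L))
    acc <- acc + pad[dx + seq_len(nr), dy + seq_len(nc)]
  acc / (k * k)
}

#' Image-specific airway threshold from the HU histogram
#'
#' Builds a histogram of the volume's HU values (10-HU bins with centres on
#' multiples of 10, smoothed with a 3-bin moving average), locates the air
#' peak and the soft-tissue peak as the modal bins inside their respective
#' search windows, and returns the arithmetic midpoint of the two peaks as
#' the upper threshold for airway segmentation.
#'
#' @param volume a [ct_volume].
#' @param roi optional list of index ranges `list(x=, y=, z=)` restricting
#'   the histogram to a sub-box.
#' @param air_window,tissue_window HU search windows for the two peaks.
#' @param bin_width histogram bin width, HU.
#' @return A `threshold_report`: list with `air_peak`, `tissue_peak`,
#'   `upper_threshold` (HU).
#' @export
compute_airway_threshold <- function(volume, roi = NULL,
                                     air_window = c(-1100, -900),
                                     tissue_window = c(50, 350),
                                     bin_width = 10) {
  stopifnot(inherits(volume, "ct_volume"))
  vox <- volume$voxels
  if (!is.null(roi))
    vox <- vox[roi$x %||% seq_len(dim(vox)[1]),
               roi$y %||% seq_len(dim(vox)[2]),
               roi$z %||% seq_len(dim(vox)[3])]
  v <- as.numeric(vox)
  lo <- min(air_window) - bin_width / 2
  hi <- max(tissue_window) + bin_width / 2
  centers <- seq(round(lo / bin_width) * bin_width,
                 round(hi / bin_width) * bin_width, by = bin_width)
  idx <- round((v - centers[1]) / bin_width) + 1L
  keep <- idx >= 1L & idx <= length(centers)
  counts <- tabulate(idx[keep], nbins = length(centers))
  sm <- (c(0, counts[-length(counts)]) + counts +
           c(counts[-1], 0)) / 3

  peak_in <- function(window, name) {
    inw <- which(centers >= window[1] & centers <= window[2])
    if (length(inw) == 0L || sum(counts[inw]) == 0L)
      stop("no voxels in the ", name, " search window [",
           window[1], ", ", window[2], "] HU")
    cand <- inw[sm[inw] == max(sm[inw])]
    cand <- cand[counts[cand] == max(counts[cand])]  # break ties on raw count
    centers[cand[1]]
  }
  air_peak <- peak_in(air_window, "air")
  tissue_peak <- peak_in(tissue_window, "soft-tissue")
  structure(list(air_peak = air_peak, tissue_peak = tissue_peak,
                 upper_threshold = (air_peak + tissue_peak) / 2),
            class = "threshold_report")
}

#' @export
print.threshold_report <- function(x, ...) {
  cat(sprintf(paste0("<threshold_report> air peak %g HU, tissue peak %g HU",
                     " -> upper threshold %g HU\n"),
              x$air_peak, x$tissue_peak, x$upper_threshold))
  invisible(x)
}

#' Segment the airway lumen
#'
#' Thresholds the volume at `HU <= threshold` (voxels exactly at the
#' threshold are included), clips to the axial region of interest
#' `[roi_inferior, roi_superior]` along the superior (z) axis, and keeps the
#' 26-connected component containing the seed voxel. Air that is not
#' connected to the seed inside the ROI (for example air outside the body,
#' or a second lumen) is excluded.
#'
#' @param volume a [ct_volume].
#' @param threshold upper HU threshold (e.g. from
#'   [compute_airway_threshold()]).
#' @param seed integer (i, j, k) voxel index inside the lumen.
#' @param roi_superior,roi_inferior axial bounds, mm in patient space
#'   (choanae level and first-tracheal-ring level).
#' @param connectivity 26 (default) or 6.
#' @return An `airway_mask`: logical voxel array plus geometry, seed and ROI.
#' @export
segment_airway <- function(volume, threshold, seed, roi_superior,
                           roi_inferior, connectivity = 26) {
  stopifnot(inherits(volume, "ct_volume"), length(seed) == 3L)
  if (roi_inferior >= roi_superior)
    stop("roi_inferior must be below roi_superior (mm, superior axis)")
  d <- dim(volume$voxels)
  seed <- as.integer(seed)
  if (any(seed < 1L) || any(seed > d)) stop("seed voxel index out of bounds")
  if (volume$voxels[seed[1], seed[2], seed[3]] > threshold)
    stop("seed voxel above threshold (",
         volume$voxels[seed[1], seed[2], seed[3]], " HU > ", threshold, " HU)")
  mask <- volume$voxels <= threshold
  z <- axis_coords(volume, 3)
  inroi <- z >= roi_inferior & z <= roi_superior
  mask[, , !inroi] <- FALSE
  if (!mask[seed[1], seed[2], seed[3]])
    stop("seed voxel lies outside the axial ROI")
  seed_lin <- (seed[1] - 1L) + d[1] * ((seed[2] - 1L) + d[2] * (seed[3] - 1L))
  comp <- .cc_from_seed(mask, d, seed_lin, as.integer(connectivity))
  if (!any(comp)) stop("airway component empty after ROI clipping")
  structure(
    list(voxels = comp, spacing = volume$spacing, origin = volume$origin,
         seed = seed, roi_superior = roi_superior,
         roi_inferior = roi_inferior, threshold = threshold,
         scan_id = volume$scan_id),
    class = "airway_mask")
}

#' @export
print.airway_mask <- function(x, ...) {
  cat(sprintf("<airway_mask> %d voxels (%.1f mm^3), ROI z in [%.1f, %.1f] mm\n",
              sum(x$voxels), sum(x$voxels) * prod(x$spacing),
              x$roi_inferior, x$roi_superior))
  invisible(x)
}

#' Voxel volume of a mask, mm^3
#' @param mask an `airway_mask`.
#' @return scalar mm^3.
#' @export
mask_volume <- function(mask) sum(mask$voxels) * prod(mask$spacing)
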