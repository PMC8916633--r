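# Minimal DICOM series reader: uncompressed little-endian transfer syntaxes
# (implicit or explicit VR), single-frame axial slices with identity in-plane
# orientation. Covers CT export from the common clinical scanners; anything
# else errors rather than guessing.

.dicom_needed_tags <- c(
  rows = "0028,0010", cols = "0028,0011",
  bits_allocated = "0028,0100", pixel_representation = "0028,0103",
  pixel_spacing = "0028,0030", ipp = "0020,0032", iop = "0020,0037",
  rescale_intercept = "0028,1052", rescale_slope = "0028,1053",
  kernel = "0018,1210", transfer_syntax = "0002,0010",
  pixel_data = "7fe0,0010")

.dicom_read_element <- function(con, explicit) {
  hdr <- readBin(con, "raw", n = 4L)
  if (length(hdr) < 4L) return(NULL)
  group <- readBin(hdr[1:2], "integer", size = 2, signed = FALSE, endian = "little")
  elem <- readBin(hdr[3:4], "integer", size = 2, signed = FALSE, endian = "little")
  tag <- sprintf("%04x,%04x", group, elem)
  explicit_here <- explicit || group == 2L  # file meta group is always explicit
  if (explicit_here) {
    vr <- rawToChar(readBin(con, "raw", n = 2L))
    if (vr %in% c("OB", "OW", "OF", "SQ", "UT", "UN")) {
      readBin(con, "raw", n = 2L)  # reserved
      len <- readBin(con, "integer", size = 4, endian = "little")
    } else {
      len <- readBin(con, "integer", size = 2, signed = FALSE, endian = "little")
    }
  } else {
    vr <- NA_character_
    len <- readBin(con, "integer", size = 4, endian = "little")
  }
  if (!is.na(len) && len == -1L)
    stop("undefined-length DICOM elements are not supported (tag ", tag, ")")
  value <- readBin(con, "raw", n = len)
  list(tag = tag, vr = vr, value = value)
}

.dicom_parse_file <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  preamble <- readBin(con, "raw", n = 132L)
  if (length(preamble) < 132L || rawToChar(preamble[129:132]) != "DICM")
    stop("not a DICOM part-10 file: ", path)
  elements <- list()
  explicit <- TRUE
  ts <- NULL
  repeat {
    el <- .dicom_read_element(con, explicit)
    if (is.null(el)) break
    if (el$tag %in% .dicom_needed_tags) elements[[el$tag]] <- el
    if (el$tag == "0002,0010") {
      ts <- sub("\\x00+$", "", rawToChar(el$value))
      ts <- trimws(ts)
      if (ts == "1.2.840.10008.1.2") {
        explicit <- FALSE
      } else if (ts != "1.2.840.10008.1.2.1") {
        stop("unsupported DICOM transfer syntax: ", ts)
      }
    }
    if (el$tag == "7fe0,0010") break  # pixel data is last in practice
  }
  elements
}

.dicom_string <- function(el) {
  if (is.null(el)) return(NULL)
  trimws(gsub("\\x00", "", rawToChar(el$value)))
}

.dicom_numeric <- function(el) {
  s <- .dicom_string(el)
  if (is.null(s)) return(NULL)
  as.numeric(strsplit(s, "\\\\")[[1]])
}

.dicom_uint16 <- function(el) {
  readBin(el$value, "integer", n = 1, size = 2, signed = FALSE,
          endian = "little")
}

.dicom_slice <- function(path) {
  els <- .dicom_parse_file(path)
  need <- function(tag, what) {
    if (is.null(els[[tag]])) stop("DICOM file ", basename(path),
                                  " lacks required element ", what)
    els[[tag]]
  }
  rows <- .dicom_uint16(need("0028,0010", "Rows"))
  cols <- .dicom_uint16(need("0028,0011", "Columns"))
  bits <- .dicom_uint16(need("0028,0100", "BitsAllocated"))
  if (bits != 16L) stop("only 16-bit DICOM pixel data is supported")
  signed <- !is.null(els[["0028,0103"]]) && .dicom_uint16(els[["0028,0103"]]) == 1L
  if (is.null(els[["0028,1052"]]) || is.null(els[["0028,1053"]]))
    stop("missing HU calibration metadata (rescale slope/intercept)")
  slope <- .dicom_numeric(els[["0028,1053"]])[1]
  intercept <- .dicom_numeric(els[["0028,1052"]])[1]
  ps <- .dicom_numeric(need("0028,0030", "PixelSpacing"))  # (row, col) mm
  ipp <- .dicom_numeric(need("0020,0032", "ImagePositionPatient"))
  iop <- .dicom_numeric(need("0020,0037", "ImageOrientationPatient"))
  if (max(abs(iop - c(1, 0, 0, 0, 1, 0))) > 1e-4)
    stop("only identity in-plane orientation (axial LPS) is supported")
  px <- readBin(need("7fe0,0010", "PixelData")$value, "integer",
                n = rows * cols, size = 2, signed = signed, endian = "little")
  hu <- slope * px + intercept
  kernel <- .dicom_string(els[["0018,1210"]])
  list(hu = matrix(hu, nrow = cols, ncol = rows),  # [col=x_lps, row=y_lps]
       rows = rows, cols = cols, dr = ps[1], dc = ps[2], ipp = ipp,
       kernel = kernel)
}

# Read a directory of single-frame axial DICOM files into a ct_volume (RAS).
load_dicom_series <- function(path, scan_id = NULL,
                              spacing_tolerance = 0.01) {
  files <- list.files(path, full.names = TRUE)
  files <- files[!dir.exists(files)]
  if (length(files) < 2L) stop("DICOM series needs at least 2 slices: ", path)
  slices <- lapply(files, .dicom_slice)
  z <- vapply(slices, function(s) s$ipp[3], numeric(1))
  ord <- order(z)
  slices <- slices[ord]
  z <- z[ord]
  dz <- diff(z)
  if (any(dz <= 0)) stop("duplicate slice positions in DICOM series")
  if (max(dz) - min(dz) > spacing_tolerance)
    stop(sprintf("inconsistent slice spacing: steps range %.4f-%.4f mm",
                 min(dz), max(dz)))
  s1 <- slices[[1]]
  same_geom <- vapply(slices, function(s)
    s$rows == s1$rows && s$cols == s1$cols &&
      isTRUE(all.equal(c(s$dr, s$dc), c(s1$dr, s1$dc))) &&
      max(abs(s$ipp[1:2] - s1$ipp[1:2])) < 1e-4, logical(1))
  if (!all(same_geom)) stop("DICOM slices have inconsistent in-plane geometry")

  nx <- s1$cols; ny <- s1$rows; nz <- length(slices)
  vox <- array(0, dim = c(nx, ny, nz))
  for (k in seq_len(nz)) {
    m <- slices[[k]]$hu              # [x_lps, y_lps]
    vox[, , k] <- m[nx:1, ny:1]      # LPS -> RAS: flip x and y
  }
  # RAS origin: voxel (1,1,1) is the corner with maximal x_lps and y_lps
  origin <- c(-(s1$ipp[1] + (nx - 1) * s1$dc),
              -(s1$ipp[2] + (ny - 1) * s1$dr),
              z[1])
  kern <- toupper(s1$kernel %||% "")
  kernel <- if (grepl("STANDARD", kern)) "standard"
    else if (grepl("SOFT", kern)) "soft"
    else if (grepl("BONE", kern)) "bone"
    else "unknown"
  ct_volume(vox, spacing = c(s1$dc, s1$dr, mean(dz)), origin = origin,
            kernel = kernel, scan_id = scan_id)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
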