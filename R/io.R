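#' Dual-wavelength reflectance stack
#'
#' Container for a time-ordered pair of image stacks, one per wavelength
#' (682 and 826 nm by default).  Frames are stored as 3-D arrays indexed
#' `[frame, row, col]` with intensities on a normalised `[0, 1]` scale.
#'
#' @param frames List of two 3-D arrays (one per wavelength), identical
#'   dimensions `T x H x W`.
#' @param paradigm The `bh_paradigm` the acquisition followed.
#' @param wavelengths_nm Ordered wavelengths, default `c(682, 826)`.
#' @param timestamps_s Per-frame acquisition times; regenerated from the
#'   paradigm when `NULL`.
#' @param valid Optional `T x H x W` logical array of per-pixel validity
#'   (all `TRUE` when `NULL`); pixels resampled from outside the frame during
#'   registration become invalid here and stay out of downstream statistics.
#' @param meta Free-form provenance list.
#' @return An object of class `bh_stack`.
#' @export
reflectance_stack <- function(frames, paradigm, wavelengths_nm = c(682, 826),
                              timestamps_s = NULL, valid = NULL, meta = list()) {
  stopifnot(inherits(paradigm, "bh_paradigm"))
  if (!is.list(frames) || length(frames) != 2) {
    stop("frames must be a list of two 3-D arrays (one per wavelength)", call. = FALSE)
  }
  d1 <- dim(frames[[1]]); d2 <- dim(frames[[2]])
  if (length(d1) != 3 || !identical(d1, d2)) {
    stop("wavelength stacks must be 3-D arrays of identical shape", call. = FALSE)
  }
  nf <- n_frames(paradigm)
  if (d1[1] != nf) {
    stop(sprintf("frame count mismatch: paradigm implies %d frames, found %d",
                 nf, d1[1]), call. = FALSE)
  }
  if (min(frames[[1]], na.rm = TRUE) < 0 || min(frames[[2]], na.rm = TRUE) < 0) {
    stop("reflectance intensities must be non-negative", call. = FALSE)
  }
  if (is.null(timestamps_s)) timestamps_s <- frame_times(paradigm)
  if (length(timestamps_s) != d1[1] || any(diff(timestamps_s) <= 0)) {
    stop("timestamps must match frame count and be strictly increasing", call. = FALSE)
  }
  if (is.null(valid)) valid <- array(TRUE, dim = d1)
  names(frames) <- paste0("w", wavelengths_nm)
  structure(
    list(frames = frames, wavelengths_nm = wavelengths_nm,
         timestamps_s = timestamps_s, paradigm = paradigm,
         valid = valid, meta = meta),
    class = "bh_stack"
  )
}

#' @export
print.bh_stack <- function(x, ...) {
  d <- dim(x$frames[[1]])
  cat(sprintf("Reflectance stack: %d frames of %d x %d px at %g/%g nm, %g-%g s\n",
              d[1], d[2], d[3], x$wavelengths_nm[1], x$wavelengths_nm[2],
              min(x$timestamps_s), max(x$timestamps_s)))
  invisible(x)
}

# quantise a [0,1] float image the way a 16-bit TIFF write/read cycle does
quantise16 <- function(x) round(pmin(pmax(x, 0), 1) * 65535) / 65535

#' Write a reflectance stack as multi-frame TIFF, one file per wavelength
#'
#' Intensities are clipped to `[0, 1]` and stored as 16-bit samples; frame
#' order is time order.  The write/read round trip is exact for data already
#' on the 16-bit grid (see [quantise_stack()]).
#'
#' @param stack A `bh_stack`.
#' @param paths Character vector of two file paths, same order as
#'   `stack$wavelengths_nm`.
#' @return `paths`, invisibly.
#' @export
write_stack <- function(stack, paths) {
  stopifnot(inherits(stack, "bh_stack"), length(paths) == 2)
  for (w in 1:2) {
    arr <- stack$frames[[w]]
    frames <- lapply(seq_len(dim(arr)[1]), function(i) pmin(pmax(arr[i, , ], 0), 1))
    tiff::writeTIFF(frames, paths[w], bits.per.sample = 16)
  }
  invisible(paths)
}

#' Read a dual-wavelength reflectance stack from multi-frame TIFFs
#'
#' @param paths Character vector of two multi-frame TIFF paths (682 nm file
#'   first).
#' @param paradigm The `bh_paradigm`; the frame count in each file must equal
#'   `n_frames(paradigm)`.
#' @param wavelengths_nm Wavelength labels for the two files.
#' @return A `bh_stack`.  Timestamps are regenerated from the paradigm.
#' @export
read_stack <- function(paths, paradigm, wavelengths_nm = c(682, 826)) {
  stopifnot(length(paths) == 2, inherits(paradigm, "bh_paradigm"))
  if (!all(file.exists(paths))) stop("stack file(s) not found", call. = FALSE)
  nf <- n_frames(paradigm)
  frames <- lapply(paths, function(p) {
    imgs <- tiff::readTIFF(p, all = TRUE)
    if (!is.list(imgs)) imgs <- list(imgs)
    if (length(imgs) != nf) {
      stop(sprintf("frame count mismatch in %s: expected %d frames (paradigm %g s at %g Hz), found %d",
                   p, nf, paradigm$total_s, paradigm$sampling_hz, length(imgs)),
           call. = FALSE)
    }
    arr <- array(0, dim = c(nf, nrow(imgs[[1]]), ncol(imgs[[1]])))
    for (i in seq_len(nf)) arr[i, , ] <- imgs[[i]]
    arr
  })
  reflectance_stack(frames, paradigm, wavelengths_nm,
                    meta = list(source = paths))
}

#' Snap a stack's intensities onto the 16-bit storage grid
#'
#' Useful before write/read round-trip comparisons.
#' @param stack A `bh_stack`.
#' @return The stack with every intensity quantised to `k / 65535`.
#' @export
quantise_stack <- function(stack) {
  stack$frames <- lapply(stack$frames, quantise16)
  stack
}

#' Write / read a single-frame calibration image
#'
#' The calibration frame is the reflectance of a uniformly diffusing white
#' sheet imaged before the study; it is the per-pixel reference intensity for
#' the attenuation computation.
#'
#' @param calibration List of two matrices (per wavelength) or a `bh_calibration`.
#' @param paths Two file paths.
#' @return For the reader, a list of two matrices with class `bh_calibration`.
#' @export
write_calibration <- function(calibration, paths) {
  stopifnot(length(paths) == 2)
  for (w in 1:2) tiff::writeTIFF(pmin(pmax(calibration[[w]], 0), 1),
                                 paths[w], bits.per.sample = 16)
  invisible(paths)
}

#' @rdname write_calibration
#' @export
read_calibration <- function(paths) {
  stopifnot(length(paths) == 2)
  cal <- lapply(paths, tiff::readTIFF)
  structure(cal, class = "bh_calibration")
}

#' Region-of-interest mask
#'
#' @param mask Logical matrix, same `H x W` shape as the image frames.
#' @param label Role of the region: `"foot"`, `"wound"`, a background label
#'   such as `"B1"`, or `"fiducial"`.
#' @return An object of class `bh_roi`.
#' @export
roi_mask <- function(mask, label = "foot") {
  mask <- mask > 0
  if (label == "foot" && !any(mask)) stop("foot mask must be non-empty", call. = FALSE)
  structure(list(mask = mask, label = label), class = "bh_roi")
}

#' Rectangular ROI constructor
#'
#' @param top_left `c(row, col)` of the rectangle's top-left pixel (1-based).
#' @param size Side length in pixels (scalar) or `c(height, width)`.
#' @param frame_shape `c(H, W)` of the frames.
#' @param label ROI label.
#' @return A `bh_roi` with exactly `prod(size)` selected pixels.
#' @examples
#' r <- make_rect_roi(c(10, 10), 50, c(400, 400), "B1")
#' sum(r$mask)  # 2500
#' @export
make_rect_roi <- function(top_left, size, frame_shape, label = "roi") {
  if (length(size) == 1) size <- c(size, size)
  r0 <- top_left[1]; c0 <- top_left[2]
  r1 <- r0 + size[1] - 1; c1 <- c0 + size[2] - 1
  if (r0 < 1 || c0 < 1 || r1 > frame_shape[1] || c1 > frame_shape[2]) {
    stop(sprintf("rectangle [%d:%d, %d:%d] out of bounds for %d x %d frame",
                 r0, r1, c0, c1, frame_shape[1], frame_shape[2]), call. = FALSE)
  }
  m <- matrix(FALSE, frame_shape[1], frame_shape[2])
  m[r0:r1, c0:c1] <- TRUE
  roi_mask(m, label)
}

#' Write / read a binary mask as PNG
#' @param roi A `bh_roi` (or logical matrix for `write_mask`).
#' @param path File path (`.png`).
#' @param label Label to attach on read.
#' @export
write_mask <- function(roi, path) {
  m <- if (inherits(roi, "bh_roi")) roi$mask else roi > 0
  png::writePNG(m * 1, path)
  invisible(path)
}

#' @rdname write_mask
#' @export
read_mask <- function(path, label = "foot") {
  img <- png::readPNG(path)
  if (length(dim(img)) == 3) img <- img[, , 1]
  roi_mask(img > 0.5, label)
}

#' Write / read a paradigm and run configuration as YAML
#' @param p A `bh_paradigm` (or the list returned by [bh_config()]).
#' @param path File path (`.yaml`).
#' @export
write_paradigm <- function(p, path) {
  yaml::write_yaml(unclass(p)[c("rest_s", "hold_s", "recovery_s", "sampling_hz")],
                   path)
  invisible(path)
}

#' @rdname write_paradigm
#' @export
read_paradigm <- function(path) {
  v <- yaml::read_yaml(path)
  paradigm(v$rest_s, v$hold_s, v$recovery_s, v$sampling_hz)
}

#' Export ROI concentration profiles as tidy CSV
#'
#' One row per (time, profile): columns `t_s`, `value`, `parameter`, `roi`,
#' `normalized`, plus optional identifier columns.
#'
#' @param profiles A `bh_profile` or list of them.
#' @param path CSV path.
#' @param ... Constant identifier columns (e.g. `subject = 1`).
#' @export
write_profiles_csv <- function(profiles, path, ...) {
  if (inherits(profiles, "bh_profile")) profiles <- list(profiles)
  rows <- lapply(profiles, function(p) {
    data.frame(t_s = p$t_s, value = p$values, parameter = p$parameter,
               roi = p$roi_label, normalized = p$normalized, ...)
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}
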