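#' Pearson's correlation coefficient between two series
#'
#' The oxygenation-flow synchrony statistic:
#' `PCC = sum((X - mean(X)) * (Y - mean(Y))) /
#'   sqrt(sum((X - mean(X))^2) * sum((Y - mean(Y))^2))`.
#' Returns `NA` (the invalid marker) when either series has zero variance or
#' contains non-finite values; never returns 0 for an undefined correlation.
#'
#' @param x,y Numeric vectors of equal length `>= 3`.
#' @return Scalar in `[-1, 1]`, or `NA` if undefined.
#' @examples
#' pearson_cc(c(1, 2, 3), c(1, 2, 4))  # 0.98198...
#' @export
pearson_cc <- function(x, y) {
  if (length(x) != length(y)) stop("series lengths differ", call. = FALSE)
  if (length(x) < 3) stop("need at least 3 time points", call. = FALSE)
  if (!all(is.finite(x)) || !all(is.finite(y))) return(NA_real_)
  xc <- x - mean(x); yc <- y - mean(y)
  den <- sqrt(sum(xc^2) * sum(yc^2))
  if (den == 0) return(NA_real_)
  min(max(sum(xc * yc) / den, -1), 1)
}

#' Build the reference oxygenation signal
#'
#' The comparator time-series for the correlation map: the mean `sto2` over
#' the whole foot (`mode = "global_mean"`, the convention for control feet
#' without wounds) or over a user-chosen background ROI away from the wound
#' (`mode = "roi"`, the convention for wound cases), restricted to the
#' analysis window.  The background ROI must be supplied explicitly — it is
#' never auto-selected — and its centroid is recorded in the result.
#'
#' @param maps A `bh_maps` object.
#' @param mode `"global_mean"` or `"roi"`.
#' @param foot_mask A `bh_roi` covering the imaged foot (required for
#'   `global_mean`).
#' @param roi Background `bh_roi` (required for `mode = "roi"`).
#' @param window_s `c(start_s, end_s)`; defaults to [analysis_window()] of
#'   the maps' paradigm.
#' @return An object of class `bh_reference`: `values` (one per window
#'   frame), `frames`, `window_s`, `source`, `centroid` (row, col; ROI mode).
#' @export
build_reference <- function(maps, mode = c("global_mean", "roi"),
                            foot_mask = NULL, roi = NULL, window_s = NULL) {
  mode <- match.arg(mode)
  stopifnot(inherits(maps, "bh_maps"))
  p <- maps$paradigm
  if (is.null(window_s)) window_s <- analysis_window(p)
  frames <- window_frames(p, window_s)
  src <- if (mode == "global_mean") {
    if (is.null(foot_mask)) stop("global_mean reference needs a foot mask", call. = FALSE)
    foot_mask
  } else {
    if (is.null(roi)) stop("ROI reference needs an explicit background ROI", call. = FALSE)
    roi
  }
  idx <- which(src$mask)
  if (length(idx) == 0) stop("reference pixel set is empty", call. = FALSE)
  d <- dim(maps$sto2)
  X <- matrix(maps$sto2, nrow = d[1])[frames, idx, drop = FALSE]
  vals <- rowMeans(X, na.rm = TRUE)
  if (any(!is.finite(vals))) {
    stop("reference signal has frames with no valid pixels", call. = FALSE)
  }
  if (stats::sd(vals) == 0) {
    stop("reference signal has zero variance over the window", call. = FALSE)
  }
  centroid <- c(row = mean((idx - 1) %% d[2] + 1),
                col = mean((idx - 1) %/% d[2] + 1))
  structure(list(values = vals, frames = frames, window_s = window_s,
                 source = if (mode == "roi") paste0("roi:", src$label) else "global_mean",
                 centroid = centroid),
            class = "bh_reference")
}

#' Pixel-wise oxygenation-flow correlation map
#'
#' Evaluates the Pearson correlation between every valid foot pixel's `sto2`
#' time-series and the reference signal over the analysis window.  Fiducial
#' and exclusion pixels, pixels outside the foot, pixels with any invalid
#' frame in the window, and zero-variance pixels are marked `NA` and never
#' enter downstream statistics.
#'
#' @param maps A `bh_maps` object.
#' @param reference A [build_reference()] result.
#' @param foot_mask A `bh_roi` covering the imaged foot.
#' @param exclusions Optional list of `bh_roi`s (e.g. fiducials) to mask out.
#' @return An object of class `bh_corrmap`: `pcc` (`H x W` matrix in
#'   `[-1, 1]` with `NA` invalids), `reference`, `window_s`, `parameter`.
#' @export
correlation_map <- function(maps, reference, foot_mask, exclusions = list()) {
  stopifnot(inherits(maps, "bh_maps"), inherits(reference, "bh_reference"))
  frames <- reference$frames
  if (length(frames) < 3) stop("analysis window shorter than 3 frames", call. = FALSE)
  d <- dim(maps$sto2)
  sel <- foot_mask$mask
  if (inherits(exclusions, "bh_roi")) exclusions <- list(exclusions)
  for (ex in exclusions) sel <- sel & !ex$mask
  idx <- which(sel)
  pcc <- matrix(NA_real_, d[2], d[3])
  if (length(idx) > 0) {
    Y <- matrix(maps$sto2, nrow = d[1])[frames, idx, drop = FALSE]
    complete <- colSums(!is.finite(Y)) == 0
    x <- reference$values
    xc <- x - mean(x)
    sx <- sum(xc^2)
    Yc <- sweep(Y, 2, colMeans(Y))
    num <- as.numeric(crossprod(Yc, xc))
    sy <- colSums(Yc^2)
    val <- rep(NA_real_, length(idx))
    ok <- complete & sy > 0 & sx > 0
    val[ok] <- pmin(pmax(num[ok] / sqrt(sx * sy[ok]), -1), 1)
    pcc[idx] <- val
  }
  structure(list(pcc = pcc, reference = reference,
                 window_s = reference$window_s, parameter = "sto2"),
            class = "bh_corrmap")
}

#' @export
print.bh_corrmap <- function(x, ...) {
  v <- x$pcc[!is.na(x$pcc)]
  cat(sprintf(
    "Oxygenation-flow correlation map: %d x %d px, %d valid; window %g-%g s; median PCC %.3f\n",
    nrow(x$pcc), ncol(x$pcc), length(v), x$window_s[1], x$window_s[2],
    stats::median(v)))
  invisible(x)
}

#' Plot a correlation map with a diverging palette
#'
#' Red = +1 (synchronous flow), blue = -1 (asynchronous); invalid pixels in
#' grey.
#' @param x A `bh_corrmap`.
#' @param ... Passed to [graphics::image()].
#' @export
plot.bh_corrmap <- function(x, ...) {
  pal <- grDevices::colorRampPalette(c("blue", "white", "red"))(101)
  z <- t(x$pcc[nrow(x$pcc):1, , drop = FALSE])
  graphics::image(z, zlim = c(-1, 1), col = pal, axes = FALSE,
                  main = "Oxygenation-flow correlation (PCC)", ...)
  invisible(x)
}

#' Write / read a correlation map as 32-bit TIFF
#'
#' PCC values are stored affinely rescaled, `(pcc + 1.5) / 3`, so the valid
#' `[-1, 1]` range maps into `(0, 1)`; invalid pixels are stored as exactly 0.
#' `read_corrmap()` undoes the mapping.
#'
#' @param cmap A `bh_corrmap`.
#' @param path TIFF path.
#' @export
write_corrmap <- function(cmap, path) {
  m <- (cmap$pcc + 1.5) / 3
  m[is.na(m)] <- 0
  tiff::writeTIFF(m, path, bits.per.sample = 32L, reduce = FALSE)
  invisible(path)
}

#' @rdname write_corrmap
#' @export
read_corrmap <- function(path) {
  m <- tiff::readTIFF(path)
  pcc <- 3 * m - 1.5
  pcc[m == 0] <- NA_real_
  structure(list(pcc = pcc, reference = NULL, window_s = NULL,
                 parameter = "sto2"),
            class = "bh_corrmap")
}

#' Pairwise ROI correlation table
#'
#' Pearson correlation between ROI-mean `sto2` profiles for every unordered
#' pair of ROIs over the analysis window, e.g. wound vs background regions.
#'
#' @param maps A `bh_maps` object.
#' @param rois List of `bh_roi`s (at least 2).
#' @param window_s Analysis window; defaults to [analysis_window()].
#' @return data.frame with columns `roi_a`, `roi_b`, `pcc`.
#' @export
pairwise_roi_correlations <- function(maps, rois, window_s = NULL) {
  stopifnot(length(rois) >= 2)
  p <- maps$paradigm
  if (is.null(window_s)) window_s <- analysis_window(p)
  frames <- window_frames(p, window_s)
  series <- lapply(rois, function(r) roi_profile(maps, r, "sto2")$values[frames])
  labels <- vapply(rois, function(r) r$label, character(1))
  pairs <- utils::combn(seq_along(rois), 2)
  data.frame(
    roi_a = labels[pairs[1, ]],
    roi_b = labels[pairs[2, ]],
    pcc = apply(pairs, 2, function(ij) pearson_cc(series[[ij[1]]], series[[ij[2]]]))
  )
}
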