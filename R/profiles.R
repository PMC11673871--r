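# Savitzky-Golay smoothing matrix with polynomial edge handling:
# interior rows carry the central FIR coefficients, the first/last
# half-windows use the corresponding rows of the local least-squares
# projection, exactly as signal::sgolayfilt applies them to a vector.
.sg_operator <- function(n_t, window, polyorder) {
  if (window %% 2 == 0) stop("Savitzky-Golay window must be odd", call. = FALSE)
  if (polyorder >= window) {
    stop("Savitzky-Golay polyorder must be smaller than the window", call. = FALSE)
  }
  if (window > n_t) stop("Savitzky-Golay window exceeds series length", call. = FALSE)
  FF <- signal::sgolay(p = polyorder, n = window)
  FF <- matrix(as.numeric(FF), window, window)
  k <- (window - 1) / 2
  S <- matrix(0, n_t, n_t)
  for (i in seq_len(k)) S[i, 1:window] <- FF[i, ]
  mid <- FF[k + 1, ]
  for (i in (k + 1):(n_t - k)) S[i, (i - k):(i + k)] <- mid
  for (j in seq_len(k)) S[n_t - k + j, (n_t - window + 1):n_t] <- FF[k + 1 + j, ]
  S
}

#' Savitzky-Golay smoothing of every pixel's time-series
#'
#' Applies a Savitzky-Golay filter along time at each pixel, preserving the
#' signal trend while suppressing frame-to-frame sensor noise.  The filter
#' reproduces polynomials up to `polyorder` exactly; edge frames use the
#' standard polynomial-fit edge handling rather than truncation.  Validity is
#' unchanged; pixels whose series contains invalid frames are left unsmoothed
#' (their valid frames keep their raw values).
#'
#' @param maps A `bh_maps` object, or a single `T x H x W` array.
#' @param window Odd window length in frames (default 11 at 1 Hz).
#' @param polyorder Polynomial order, `< window` (default 3).
#' @param parameters Which maps to filter when `maps` is a `bh_maps`
#'   (default all four).
#' @return The input with smoothed time-series.
#' @export
sg_smooth <- function(maps, window = 11, polyorder = 3,
                      parameters = c("hbo", "hbr", "hbt", "sto2")) {
  if (inherits(maps, "bh_maps")) {
    for (par in parameters) {
      maps[[par]] <- sg_smooth(maps[[par]], window, polyorder)
    }
    return(maps)
  }
  d <- dim(maps)
  S <- .sg_operator(d[1], window, polyorder)
  X <- matrix(maps, nrow = d[1])
  complete <- colSums(is.na(X)) == 0
  if (any(complete)) X[, complete] <- S %*% X[, complete, drop = FALSE]
  array(X, dim = d)
}

#' Smooth a single time-series (vector interface)
#' @inheritParams sg_smooth
#' @param x Numeric vector.
#' @return Smoothed vector of the same length.
#' @export
sg_smooth_series <- function(x, window = 11, polyorder = 3) {
  as.numeric(.sg_operator(length(x), window, polyorder) %*% x)
}

#' ROI-averaged concentration profile
#'
#' Per-frame mean of one hemodynamic parameter over the valid pixels of a
#' region of interest.
#'
#' @param maps A `bh_maps` object.
#' @param roi A `bh_roi`.
#' @param parameter One of `"hbo"`, `"hbr"`, `"hbt"`, `"sto2"`.
#' @return An object of class `bh_profile`: `values`, `t_s`, `parameter`,
#'   `roi_label`, `normalized` flag, `t0_s`, and per-frame contributing pixel
#'   counts `n_pixels`.
#' @export
roi_profile <- function(maps, roi, parameter = "sto2") {
  stopifnot(inherits(maps, "bh_maps"), inherits(roi, "bh_roi"))
  parameter <- match.arg(parameter, c("hbo", "hbr", "hbt", "sto2"))
  arr <- maps[[parameter]]
  d <- dim(arr)
  idx <- which(roi$mask)
  if (length(idx) == 0) stop("ROI is empty", call. = FALSE)
  X <- matrix(arr, nrow = d[1])[, idx, drop = FALSE]
  n_pix <- rowSums(!is.na(X))
  if (all(n_pix == 0)) {
    stop(sprintf("ROI '%s' has no valid pixels for parameter '%s'",
                 roi$label, parameter), call. = FALSE)
  }
  structure(
    list(values = rowMeans(X, na.rm = TRUE), t_s = maps$timestamps_s,
         parameter = parameter, roi_label = roi$label,
         normalized = FALSE, t0_s = NA_real_, n_pixels = n_pix),
    class = "bh_profile"
  )
}

#' @export
print.bh_profile <- function(x, ...) {
  cat(sprintf("%s profile over ROI '%s': %d frames%s\n",
              x$parameter, x$roi_label, length(x$values),
              if (x$normalized) sprintf(", %% change from t0 = %g s", x$t0_s) else ""))
  invisible(x)
}

#' Normalise a profile at breath-hold onset
#'
#' Retains the window from `t0 = rest_s` onwards and expresses the profile as
#' the percent change from its onset value:
#' `100 * (S(t) - S(t0)) / |S(t0)|`.  The absolute value in the denominator
#' keeps the sign convention stable for negative effective values.
#' Normalising an already-normalised profile at the same onset returns it
#' unchanged.
#'
#' @param profile A `bh_profile`.
#' @param paradigm A `bh_paradigm`; onset is `paradigm$rest_s`.
#' @return The normalised `bh_profile` (values in percent, starting at 0).
#' @export
normalize_at_onset <- function(profile, paradigm) {
  stopifnot(inherits(profile, "bh_profile"), inherits(paradigm, "bh_paradigm"))
  t0 <- paradigm$rest_s
  if (isTRUE(profile$normalized)) {
    if (isTRUE(all.equal(profile$t0_s, t0))) return(profile)
    stop("profile is already normalised at a different onset", call. = FALSE)
  }
  keep <- which(profile$t_s >= t0 - 1e-9)
  if (length(keep) == 0) stop("onset lies beyond the acquisition", call. = FALSE)
  i0 <- keep[1]
  s0 <- profile$values[i0]
  if (!is.finite(s0) || s0 == 0) {
    stop(sprintf("cannot normalise ROI '%s': onset value is %s",
                 profile$roi_label, format(s0)), call. = FALSE)
  }
  profile$values <- 100 * (profile$values[keep] - s0) / abs(s0)
  profile$t_s <- profile$t_s[keep]
  profile$n_pixels <- profile$n_pixels[keep]
  profile$normalized <- TRUE
  profile$t0_s <- t0
  profile
}

#' Grand average of concentration profiles
#'
#' Pointwise mean and standard error (sd / sqrt(n)) across profiles of the
#' same parameter and length, e.g. across subjects and repetitions.
#'
#' @param profiles List of `bh_profile` objects.
#' @return A list of class `bh_grand_average` with `mean`, `se` (both
#'   `bh_profile`-like vectors), `t_s`, `parameter`, `n`.
#' @export
grand_average <- function(profiles) {
  stopifnot(length(profiles) >= 1)
  pars <- vapply(profiles, function(p) p$parameter, character(1))
  if (length(unique(pars)) != 1) {
    stop("all profiles must share one parameter", call. = FALSE)
  }
  lens <- vapply(profiles, function(p) length(p$values), integer(1))
  if (length(unique(lens)) != 1) {
    stop("all profiles must share one length", call. = FALSE)
  }
  M <- do.call(cbind, lapply(profiles, function(p) p$values))
  n <- ncol(M)
  mu <- rowMeans(M)
  se <- if (n > 1) apply(M, 1, stats::sd) / sqrt(n) else rep(0, nrow(M))
  structure(list(mean = mu, se = se, t_s = profiles[[1]]$t_s,
                 parameter = pars[1], n = n),
            class = "bh_grand_average")
}

#' @export
plot.bh_grand_average <- function(x, shade_hold = NULL, ...) {
  graphics::plot(x$t_s, x$mean, type = "l", lwd = 2,
                 xlab = "time (s)", ylab = paste0(x$parameter, " (% change)"), ...)
  graphics::arrows(x$t_s, x$mean - x$se, x$t_s, x$mean + x$se,
                   length = 0.02, angle = 90, code = 3, col = "steelblue")
  if (!is.null(shade_hold)) {
    graphics::rect(shade_hold[1], graphics::par("usr")[3],
                   shade_hold[2], graphics::par("usr")[4],
                   col = grDevices::adjustcolor("grey", 0.3), border = NA)
  }
  invisible(x)
}
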