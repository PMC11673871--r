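#' Hemoglobin extinction-coefficient matrix
#'
#' 2 x 2 matrix of molar extinction coefficients, rows = wavelengths
#' (682, 826 nm), columns = chromophores (HbO, HbR).  The defaults are
#' approximate values from the standard compiled whole-blood hemoglobin
#' spectra (cm^-1 M^-1); they are configuration, not code — any invertible
#' pair is usable because the pipeline reports effective concentrations with
#' unit pathlength and all downstream statistics are scale-invariant.
#'
#' @param e_hbo,e_hbr Extinction coefficients of HbO and HbR at the two
#'   wavelengths (682 nm first).
#' @param wavelengths_nm Wavelength labels.
#' @return An `extinction_matrix` (classed 2 x 2 matrix).
#' @export
extinction_matrix <- function(e_hbo = c(300.8, 1004.2),
                              e_hbr = c(2480.5, 710.0),
                              wavelengths_nm = c(682, 826)) {
  E <- cbind(hbo = e_hbo, hbr = e_hbr)
  rownames(E) <- paste0("w", wavelengths_nm)
  if (!all(is.finite(E))) stop("extinction coefficients must be finite", call. = FALSE)
  if (abs(det(E)) < 1e-12 || !is.finite(kappa(E))) {
    stop("extinction matrix must be invertible with finite condition number",
         call. = FALSE)
  }
  structure(E, class = c("extinction_matrix", class(E)))
}

#' Optical attenuation relative to the calibration sheet
#'
#' Per wavelength, pixel and frame:
#' `dOD(lambda, x, y, t) = log10(I_cal(lambda, x, y) / I(lambda, x, y, t))`.
#' Pixels with non-positive tissue or calibration intensity are marked
#' invalid (`NA`).
#'
#' @param stack A `bh_stack` (registered if motion was present).
#' @param calibration A `bh_calibration` (one matrix per wavelength) or the
#'   per-frame aligned calibration (`T x H x W` arrays) from
#'   [register_stack()].
#' @return List of two `T x H x W` attenuation arrays (`NA` = invalid), with
#'   attribute `valid`.
#' @export
attenuation <- function(stack, calibration) {
  stopifnot(inherits(stack, "bh_stack"))
  d <- dim(stack$frames[[1]])
  per_frame_cal <- length(dim(calibration[[1]])) == 3
  if (!per_frame_cal && (max(calibration[[1]]) <= 0 || max(calibration[[2]]) <= 0)) {
    stop("calibration images are wholly non-positive", call. = FALSE)
  }
  valid <- stack$valid
  dod <- vector("list", 2)
  for (w in 1:2) {
    I <- stack$frames[[w]]
    cal <- if (per_frame_cal) calibration[[w]] else
      aperm(array(calibration[[w]], dim = c(d[2], d[3], d[1])), c(3, 1, 2))
    ok <- I > 0 & cal > 0
    out <- array(NA_real_, dim = d)
    out[ok] <- log10(cal[ok] / I[ok])
    valid <- valid & ok
    dod[[w]] <- out
  }
  names(dod) <- names(stack$frames)
  for (w in 1:2) dod[[w]][!valid] <- NA_real_
  attr(dod, "valid") <- valid
  attr(dod, "paradigm") <- stack$paradigm
  attr(dod, "timestamps_s") <- stack$timestamps_s
  dod
}

#' Invert the modified Beer-Lambert law
#'
#' Solves the 2 x 2 linear system `dOD = E %*% c(hbo, hbr)` at every valid
#' pixel and frame (unit effective pathlength), then derives total hemoglobin
#' `hbt = hbo + hbr` and oxygen saturation.  With `sto2_mode = "ratio"`
#' (default), `sto2 = hbo / hbt`, flagged invalid wherever
#' `|hbt| < sto2_guard` rather than clipped; with `sto2_mode = "difference"`
#' the oxygenation index `hbo - hbr` is stored instead (no guard needed).
#'
#' @param dod Attenuation stacks from [attenuation()].
#' @param E An [extinction_matrix()].
#' @param sto2_guard Minimum `|hbt|` (a.u.) for a defined saturation ratio.
#' @param sto2_mode `"ratio"` or `"difference"`.
#' @return An object of class `bh_maps`: list of `T x H x W` arrays `hbo`,
#'   `hbr`, `hbt`, `sto2`, logical `valid`, plus the paradigm and timestamps.
#' @export
invert_mbll <- function(dod, E = extinction_matrix(), sto2_guard = 1e-6,
                        sto2_mode = c("ratio", "difference")) {
  sto2_mode <- match.arg(sto2_mode)
  E <- unclass(E)
  if (abs(det(E)) < 1e-12) stop("singular extinction matrix", call. = FALSE)
  d <- dim(dod[[1]])
  valid <- attr(dod, "valid")
  if (is.null(valid)) valid <- !(is.na(dod[[1]]) | is.na(dod[[2]]))
  D <- rbind(as.vector(dod[[1]]), as.vector(dod[[2]]))
  D[is.na(D)] <- 0                     # placeholders; masked below
  C <- solve(E, D)
  hbo <- array(C[1, ], dim = d); hbr <- array(C[2, ], dim = d)
  hbo[!valid] <- NA_real_; hbr[!valid] <- NA_real_
  hbt <- hbo + hbr
  if (sto2_mode == "ratio") {
    sto2 <- hbo / hbt
    sto2[!is.na(hbt) & abs(hbt) < sto2_guard] <- NA_real_
  } else {
    sto2 <- hbo - hbr
  }
  structure(
    list(hbo = hbo, hbr = hbr, hbt = hbt, sto2 = sto2, valid = valid,
         paradigm = attr(dod, "paradigm"),
         timestamps_s = attr(dod, "timestamps_s"),
         sto2_mode = sto2_mode, sto2_guard = sto2_guard),
    class = "bh_maps"
  )
}

#' @export
print.bh_maps <- function(x, ...) {
  d <- dim(x$hbo)
  cat(sprintf(
    "Hemodynamic maps: %d frames of %d x %d px (hbo, hbr, hbt, sto2[%s]); %.1f%% pixels valid\n",
    d[1], d[2], d[3], x$sto2_mode, 100 * mean(x$valid)))
  invisible(x)
}

#' Compute hemodynamic maps from a registered stack
#'
#' Convenience wrapper: [attenuation()] followed by [invert_mbll()].
#'
#' @inheritParams attenuation
#' @inheritParams invert_mbll
#' @return A `bh_maps` object.
#' @export
mbll <- function(stack, calibration, E = extinction_matrix(),
                 sto2_guard = 1e-6, sto2_mode = "ratio") {
  invert_mbll(attenuation(stack, calibration), E,
              sto2_guard = sto2_guard, sto2_mode = sto2_mode)
}

#' Persist hemodynamic maps as 32-bit multi-frame TIFFs
#'
#' Each parameter is stored rescaled to `[0, 1]` over its finite range; the
#' per-parameter ranges are written to a `ranges.yaml` sidecar so values can
#' be restored, and the validity mask is stored as an 8-bit stack.
#'
#' @param maps A `bh_maps`.
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_maps <- function(maps, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ranges <- list()
  for (par in c("hbo", "hbr", "hbt", "sto2")) {
    arr <- maps[[par]]
    rng <- range(arr, finite = TRUE)
    if (diff(rng) == 0) rng[2] <- rng[1] + 1
    arr <- (arr - rng[1]) / (rng[2] - rng[1])
    arr[is.na(arr)] <- 0
    ranges[[par]] <- as.numeric(rng)
    frames <- lapply(seq_len(dim(arr)[1]), function(i) arr[i, , ])
    tiff::writeTIFF(frames, file.path(dir, paste0(par, ".tif")),
                    bits.per.sample = 32L, reduce = FALSE)
  }
  yaml::write_yaml(ranges, file.path(dir, "ranges.yaml"))
  vframes <- lapply(seq_len(dim(maps$valid)[1]), function(i) maps$valid[i, , ] * 1)
  tiff::writeTIFF(vframes, file.path(dir, "valid.tif"), bits.per.sample = 8)
  invisible(dir)
}
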