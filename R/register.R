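#' Rigid frame transform
#'
#' Rotation (degrees, about the frame centre) followed by a translation in
#' pixels.  `tx` shifts columns (x), `ty` shifts rows (y).  Identity is
#' `rigid_transform(0, 0, 0)`.
#'
#' @param rotation_deg Rotation in degrees (counter-clockwise in row/col
#'   coordinates).
#' @param tx,ty Translation in pixels along columns / rows.
#' @return An object of class `bh_transform`.
#' @export
rigid_transform <- function(rotation_deg = 0, tx = 0, ty = 0) {
  stopifnot(is.finite(rotation_deg), is.finite(tx), is.finite(ty))
  structure(list(rotation_deg = rotation_deg, tx = tx, ty = ty),
            class = "bh_transform")
}

#' @export
print.bh_transform <- function(x, ...) {
  cat(sprintf("Rigid transform: %.3f deg, tx = %.3f px, ty = %.3f px\n",
              x$rotation_deg, x$tx, x$ty))
  invisible(x)
}

.rotmat <- function(deg) {
  th <- deg * pi / 180
  matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
}

#' Compose and invert rigid transforms
#'
#' `compose_transforms(a, b)` is the transform equivalent to applying `b`
#' first, then `a`.  `invert_transform(a)` undoes `a`:
#' `compose_transforms(invert_transform(a), a)` is the identity.
#'
#' @param a,b `bh_transform` objects.
#' @return A `bh_transform`.
#' @export
compose_transforms <- function(a, b) {
  Ra <- .rotmat(a$rotation_deg)
  t <- Ra %*% c(b$tx, b$ty) + c(a$tx, a$ty)
  rigid_transform(a$rotation_deg + b$rotation_deg, t[1], t[2])
}

#' @rdname compose_transforms
#' @export
invert_transform <- function(a) {
  Rinv <- .rotmat(-a$rotation_deg)
  t <- -Rinv %*% c(a$tx, a$ty)
  rigid_transform(-a$rotation_deg, t[1], t[2])
}

#' Apply a rigid transform to an image
#'
#' Forward mapping: a point `p` (x = col, y = row) in the input lands at
#' `R (p - centre) + centre + (tx, ty)` in the output.  The output is sampled
#' by bilinear interpolation of the input at the inverse-mapped coordinates;
#' pixels mapped from outside the input are set to `fill` and flagged invalid.
#'
#' @param img Numeric matrix.
#' @param tf A [rigid_transform()].
#' @param fill Value for out-of-frame pixels.
#' @return List with `image` (matrix) and `valid` (logical matrix).
#' @export
warp_rigid <- function(img, tf, fill = 0) {
  H <- nrow(img); W <- ncol(img)
  if (tf$rotation_deg == 0 && tf$tx == 0 && tf$ty == 0) {
    return(list(image = img, valid = matrix(TRUE, H, W)))
  }
  cy <- (H + 1) / 2; cx <- (W + 1) / 2
  Rinv <- .rotmat(-tf$rotation_deg)
  # output pixel grid (x = col, y = row), inverse-mapped into the input
  xo <- rep(seq_len(W), each = H) - cx - tf$tx
  yo <- rep(seq_len(H), times = W) - cy - tf$ty
  xs <- Rinv[1, 1] * xo + Rinv[1, 2] * yo + cx
  ys <- Rinv[2, 1] * xo + Rinv[2, 2] * yo + cy
  x0 <- floor(xs); y0 <- floor(ys)
  fx <- xs - x0;  fy <- ys - y0
  ok <- x0 >= 1 & y0 >= 1 & x0 + 1 <= W & y0 + 1 <= H
  x0c <- pmin(pmax(x0, 1), W - 1); y0c <- pmin(pmax(y0, 1), H - 1)
  i00 <- (x0c - 1) * H + y0c            # [y0, x0] in column-major order
  v <- (1 - fx) * ((1 - fy) * img[i00]     + fy * img[i00 + 1]) +
       fx       * ((1 - fy) * img[i00 + H] + fy * img[i00 + H + 1])
  v[!ok] <- fill
  list(image = matrix(v, H, W), valid = matrix(ok, H, W))
}

# normalized cross-correlation over jointly valid pixels
.ncc <- function(a, b, valid) {
  a <- a[valid]; b <- b[valid]
  a <- a - mean(a); b <- b - mean(b)
  da <- sqrt(sum(a^2)); db <- sqrt(sum(b^2))
  if (da == 0 || db == 0) return(NA_real_)
  sum(a * b) / (da * db)
}

# integer translation estimate via unwindowed FFT cross-correlation
.xcorr_shift <- function(moving, fixed) {
  H <- nrow(fixed); W <- ncol(fixed)
  f <- stats::fft(fixed - mean(fixed))
  m <- stats::fft(moving - mean(moving))
  cc <- Re(stats::fft(f * Conj(m), inverse = TRUE))
  k <- which.max(cc)
  dy <- (k - 1) %% H; dx <- (k - 1) %/% H
  if (dy > H / 2) dy <- dy - H
  if (dx > W / 2) dx <- dx - W
  c(tx = dx, ty = dy)
}

# exact half of a rigid transform: h such that h o h = (rot, tx, ty)
.half_transform <- function(rot, tx, ty) {
  th <- rot / 2
  R <- .rotmat(th)
  t <- solve(diag(2) + R, c(tx, ty))
  rigid_transform(th, t[1], t[2])
}

# symmetric dissimilarity: warp both frames toward the midpoint so that
# interpolation blur affects them equally (removes the subpixel bias of
# one-sided resampling); returns 1 - NCC over jointly valid pixels
.sym_cost <- function(moving, fixed, par, moving_valid = NULL) {
  h <- .half_transform(par[1], par[2], par[3])
  a <- warp_rigid(moving, h)
  b <- warp_rigid(fixed, invert_transform(h))
  ok <- a$valid & b$valid
  if (!is.null(moving_valid)) {
    ok <- ok & (warp_rigid(moving_valid * 1, h)$image > 0.999)
  }
  v <- .ncc(a$image, b$image, ok)
  if (!is.finite(v)) 2 else 1 - v
}

#' Estimate the rigid transform aligning one frame to another
#'
#' Intensity-based rigid registration.  A coarse stage scans candidate
#' rotations, re-estimating the translation for each by FFT
#' cross-correlation; the best candidate seeds a Nelder-Mead refinement of
#' (rotation, tx, ty) that maximises the normalised cross-correlation
#' between the two frames resampled symmetrically toward their midpoint
#' (both sides suffer equal interpolation blur, which removes the subpixel
#' bias of one-sided resampling).  If the identity transform scores at least
#' as well as the refined fit it is returned exactly, so motion-free stacks
#' are left untouched bit-for-bit.
#'
#' @param moving,fixed Numeric matrices of identical shape; `fixed` must have
#'   non-zero variance.
#' @param moving_valid Optional logical matrix: pixels of `moving` that carry
#'   real signal (e.g. not fill values from a previous resampling); invalid
#'   pixels are excluded from the similarity metric.
#' @param rot_max Largest rotation magnitude searched, in degrees.
#' @param rot_step Coarse rotation grid step in degrees.
#' @return A [rigid_transform()] `tf` such that `warp_rigid(moving, tf)`
#'   aligns with `fixed`.  Attribute `ncc` carries the achieved similarity.
#' @export
register_frame <- function(moving, fixed, moving_valid = NULL,
                           rot_max = 5, rot_step = 1) {
  if (!identical(dim(moving), dim(fixed))) {
    stop("moving and fixed frames must share shape", call. = FALSE)
  }
  if (stats::sd(fixed) == 0) {
    stop("degenerate reference: fixed frame has zero intensity variance", call. = FALSE)
  }
  if (!is.null(moving_valid) && all(moving_valid)) moving_valid <- NULL
  mov_filled <- moving
  if (!is.null(moving_valid)) {
    mov_filled[!moving_valid] <- mean(moving[moving_valid])
  }
  ident_cost <- .sym_cost(moving, fixed, c(0, 0, 0), moving_valid)
  if (ident_cost < 1e-12) {
    tf <- rigid_transform(0, 0, 0)
    attr(tf, "ncc") <- 1 - ident_cost
    attr(tf, "converged") <- TRUE
    return(tf)
  }
  # coarse stage: translation solved per rotation candidate
  best <- NULL
  for (rot in seq(-rot_max, rot_max, by = rot_step)) {
    img <- if (rot == 0) mov_filled else
      warp_rigid(mov_filled, rigid_transform(rot, 0, 0))$image
    sh <- .xcorr_shift(img, fixed)
    # translation applies after rotation, matching the transform convention
    par <- c(rot, sh[["tx"]], sh[["ty"]])
    cost <- .sym_cost(moving, fixed, par, moving_valid)
    if (is.null(best) || cost < best$cost) best <- list(par = par, cost = cost)
  }
  obj <- function(par) .sym_cost(moving, fixed, par, moving_valid)
  fit <- stats::optim(best$par, obj, method = "Nelder-Mead",
                      control = list(reltol = 1e-10, maxit = 500))
  fit <- stats::optim(fit$par, obj, method = "Nelder-Mead",
                      control = list(reltol = 1e-10, maxit = 500))
  # snap estimates below the measurement resolution to the exact identity
  if (ident_cost <= fit$value + 1e-12 || max(abs(fit$par)) < 0.01) {
    tf <- rigid_transform(0, 0, 0)
    attr(tf, "ncc") <- 1 - ident_cost
    attr(tf, "converged") <- TRUE
    return(tf)
  }
  tf <- rigid_transform(fit$par[1], fit$par[2], fit$par[3])
  attr(tf, "ncc") <- 1 - fit$value
  attr(tf, "converged") <- TRUE   # iteration-capped refinements remain usable
  tf
}

#' Motion-correct a reflectance stack
#'
#' Registers every frame to the first frame of the acquisition.  The
#' transform is estimated on the second-wavelength (826 nm) channel — both
#' channels are acquired by the same camera and move together — and applied
#' to both channels.  The same per-frame transform is applied to the
#' calibration image so tissue/reference ratios stay co-located.  Pixels
#' resampled from outside the frame are flagged invalid and excluded from
#' all downstream statistics.
#'
#' @param stack A `bh_stack`.
#' @param calibration A `bh_calibration` (two matrices).
#' @param reference_channel Channel used for estimation (default 2 = 826 nm).
#' @return List with `stack` (aligned `bh_stack`, validity updated),
#'   `calibration` (per-frame aligned calibration: two `T x H x W` arrays),
#'   and `transforms` (data.frame `frame`, `rotation_deg`, `tx`, `ty`,
#'   `ncc`).  Frames that fail to converge keep the identity transform, with
#'   a warning.
#' @export
register_stack <- function(stack, calibration, reference_channel = 2) {
  stopifnot(inherits(stack, "bh_stack"))
  nf <- dim(stack$frames[[1]])[1]
  H <- dim(stack$frames[[1]])[2]; W <- dim(stack$frames[[1]])[3]
  fixed <- stack$frames[[reference_channel]][1, , ]
  out <- stack
  cal_out <- list(array(0, dim = c(nf, H, W)), array(0, dim = c(nf, H, W)))
  log <- data.frame(frame = seq_len(nf), rotation_deg = 0, tx = 0, ty = 0,
                    ncc = NA_real_)
  failed <- integer(0)
  for (i in seq_len(nf)) {
    tf <- tryCatch(
      register_frame(stack$frames[[reference_channel]][i, , ], fixed,
                     moving_valid = stack$valid[i, , ]),
      error = function(e) NULL)
    if (is.null(tf) || isFALSE(attr(tf, "converged"))) {
      failed <- c(failed, i)
      tf <- rigid_transform(0, 0, 0)
    }
    log$rotation_deg[i] <- tf$rotation_deg
    log$tx[i] <- tf$tx; log$ty[i] <- tf$ty
    log$ncc[i] <- if (is.null(attr(tf, "ncc"))) NA_real_ else attr(tf, "ncc")
    valid_i <- stack$valid[i, , ]
    for (w in 1:2) {
      wp <- warp_rigid(stack$frames[[w]][i, , ], tf)
      out$frames[[w]][i, , ] <- wp$image
      cw <- warp_rigid(calibration[[w]], tf)
      cal_out[[w]][i, , ] <- cw$image
      valid_i <- valid_i & wp$valid
    }
    out$valid[i, , ] <- valid_i
  }
  if (length(failed) > 0) {
    warning(sprintf("registration did not converge for %d frame(s) (%s); identity used",
                    length(failed), paste(utils::head(failed, 5), collapse = ", ")),
            call. = FALSE)
  }
  list(stack = out, calibration = cal_out, transforms = log)
}

#' Write per-frame registration transforms as CSV
#' @param transforms The `transforms` data.frame from [register_stack()].
#' @param path CSV path.
#' @export
write_transforms_csv <- function(transforms, path) {
  utils::write.csv(transforms, path, row.names = FALSE)
  invisible(path)
}
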