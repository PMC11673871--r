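#' Breath-hold hemodynamic response specification
#'
#' Parameterises the effective oxy-/deoxy-hemoglobin response of one tissue
#' region to the breath-hold stimulus.  The curve family is piecewise-linear
#' ramps with an exponential approach to a post-stimulus plateau: HbR ramps
#' up by `hold_hbr_rise` during the (possibly delayed) hold, then relaxes
#' below baseline by `recovery_hbr_undershoot`; HbO stays at baseline through
#' the hold, then overshoots by `recovery_hbo_overshoot` during recovery.
#' Both settle near `plateau_time_s` and drift slightly back toward baseline
#' afterwards, emulating the establishment of a new post-stimulus baseline.
#'
#' Negative fractional changes are allowed and produce an inverted
#' (asynchronous) response, used to emulate compromised wound-bed perfusion.
#'
#' @param baseline_hbo,baseline_hbr Baseline effective concentrations in
#'   arbitrary units; must be positive (the forward optical model takes
#'   attenuation relative to a white calibration sheet).  Defaults give a
#'   resting StO2 of 60%.
#' @param hold_hbr_rise Fractional HbR rise during the hold (default 0.02).
#' @param recovery_hbo_overshoot Fractional HbO overshoot peaking in recovery
#'   (default 0.02, the ~2% recovery change seen in control feet).
#' @param recovery_hbr_undershoot Fractional HbR undershoot in recovery
#'   (default 0.025).
#' @param response_delay_s Onset delay in seconds: 0 for control-like tissue;
#'   20-40 emulates the delayed recovery response of diabetic foot ulcers.
#' @param plateau_time_s Time (s) at which the recovery settles to its new
#'   baseline (default 100).
#' @param noise_sd Fractional standard deviation of multiplicative sensor
#'   noise applied when the region is rendered (not to the response itself).
#' @param seed Optional per-region seed recorded for provenance.
#' @return An object of class `bh_response_spec`.
#' @export
bh_response_spec <- function(baseline_hbo = 6e-4, baseline_hbr = 4e-4,
                             hold_hbr_rise = 0.02,
                             recovery_hbo_overshoot = 0.02,
                             recovery_hbr_undershoot = 0.025,
                             response_delay_s = 0, plateau_time_s = 100,
                             noise_sd = 0, seed = NULL) {
  if (!is.finite(baseline_hbo) || !is.finite(baseline_hbr) ||
      baseline_hbo <= 0 || baseline_hbr <= 0) {
    stop("baseline_hbo and baseline_hbr must be positive", call. = FALSE)
  }
  if (response_delay_s < 0) stop("response_delay_s must be >= 0", call. = FALSE)
  frac <- c(hold_hbr_rise, recovery_hbo_overshoot, recovery_hbr_undershoot)
  if (any(!is.finite(frac)) || any(frac <= -1)) {
    stop("fractional changes must be finite and > -1", call. = FALSE)
  }
  if (noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  structure(
    list(baseline_hbo = baseline_hbo, baseline_hbr = baseline_hbr,
         hold_hbr_rise = hold_hbr_rise,
         recovery_hbo_overshoot = recovery_hbo_overshoot,
         recovery_hbr_undershoot = recovery_hbr_undershoot,
         response_delay_s = response_delay_s,
         plateau_time_s = plateau_time_s,
         noise_sd = noise_sd, seed = seed),
    class = "bh_response_spec"
  )
}

# exponential approach from `from` to `to`, 95% complete after `span` seconds
.approach <- function(dt, from, to, span) {
  tau <- max(span, 1e-6) / 3
  to + (from - to) * exp(-dt / tau)
}

#' Simulate a breath-hold hemodynamic response
#'
#' Generates the noiseless effective (HbO, HbR) time-series of one region
#' under the paradigm, one sample per acquisition frame.  Deterministic:
#' sensor noise enters only at rendering time ([render_stack()]).
#'
#' @param spec A [bh_response_spec()].
#' @param paradigm A [paradigm()].
#' @return A data.frame with columns `t_s`, `hbo`, `hbr`.
#' @export
simulate_response <- function(spec, paradigm) {
  stopifnot(inherits(spec, "bh_response_spec"), inherits(paradigm, "bh_paradigm"))
  t <- frame_times(paradigm)
  d <- spec$response_delay_s
  hold_on  <- paradigm$rest_s + d
  hold_off <- paradigm$rest_s + paradigm$hold_s + d
  plateau  <- spec$plateau_time_s + d
  t_end <- max(t)
  if (hold_off >= t_end) {
    warning("response delay pushes the response past the acquisition end; truncated",
            call. = FALSE)
  }
  plateau <- min(plateau, t_end)
  span <- max(plateau - hold_off, 1e-6)

  b_o <- spec$baseline_hbo; b_r <- spec$baseline_hbr
  hbr_peak <- b_r * (1 + spec$hold_hbr_rise)
  hbr_low  <- b_r * (1 - spec$recovery_hbr_undershoot)
  hbo_high <- b_o * (1 + spec$recovery_hbo_overshoot)

  hbr <- numeric(length(t)); hbo <- numeric(length(t))
  # drift back toward baseline after the plateau: 20% of the excursion over 60 s
  drift <- function(val_at_plateau, baseline, dt) {
    val_at_plateau + (baseline - val_at_plateau) * 0.2 * pmin(dt / 60, 1)
  }
  for (i in seq_along(t)) {
    ti <- t[i]
    if (ti <= hold_on) {
      hbr[i] <- b_r; hbo[i] <- b_o
    } else if (ti <= hold_off) {
      f <- (ti - hold_on) / (hold_off - hold_on)
      hbr[i] <- b_r + f * (hbr_peak - b_r)
      hbo[i] <- b_o
    } else if (ti <= plateau) {
      hbr[i] <- .approach(ti - hold_off, hbr_peak, hbr_low, span)
      hbo[i] <- .approach(ti - hold_off, b_o, hbo_high, span)
    } else {
      hbr_pl <- .approach(plateau - hold_off, hbr_peak, hbr_low, span)
      hbo_pl <- .approach(plateau - hold_off, b_o, hbo_high, span)
      hbr[i] <- drift(hbr_pl, b_r, ti - plateau)
      hbo[i] <- drift(hbo_pl, b_o, ti - plateau)
    }
  }
  data.frame(t_s = t, hbo = hbo, hbr = hbr)
}

#' Synthetic scene specification
#'
#' A scene is a frame geometry plus labelled tissue regions, each with its own
#' breath-hold response and a static multiplicative melanin transmission
#' factor, optional near-zero fiducial marker squares, and optional per-frame
#' rigid motion.
#'
#' @param height,width Frame size in pixels.
#' @param regions List of regions, each a list with elements `label`
#'   (character), `mask` (logical `H x W` matrix), `response`
#'   (a [bh_response_spec()]), and `melanin` (transmission scalar in (0, 1],
#'   default 1; identical at both wavelengths).  Region masks must be
#'   disjoint and inside the frame.
#' @param fiducials Optional list of `list(top_left = c(r, c), size = s)`
#'   squares rendered near zero reflectance.
#' @param motion Optional list of per-frame [rigid_transform()]s (length =
#'   number of frames) applied after rendering.
#' @param texture_sd Standard deviation of a static, smooth, multiplicative
#'   spatial texture applied to tissue pixels at both wavelengths (default 0,
#'   none).  Like melanin it is time-invariant, so it cancels out of all
#'   temporal statistics; it emulates static skin structure and gives
#'   registration rotationally informative content.
#' @param paradigm A [paradigm()].
#' @return An object of class `bh_scene`.
#' @export
scene_spec <- function(height, width, regions, fiducials = list(),
                       motion = NULL, texture_sd = 0,
                       paradigm = oxyflow::paradigm()) {
  stopifnot(height >= 8, width >= 8, length(regions) >= 1,
            inherits(paradigm, "bh_paradigm"))
  cover <- matrix(0L, height, width)
  for (rg in regions) {
    if (is.null(rg$label) || is.null(rg$mask) || is.null(rg$response)) {
      stop("each region needs label, mask and response", call. = FALSE)
    }
    if (!identical(dim(rg$mask), as.integer(c(height, width)))) {
      stop("region mask shape must match the frame", call. = FALSE)
    }
    if (!inherits(rg$response, "bh_response_spec")) {
      stop("region response must be a bh_response_spec", call. = FALSE)
    }
    mel <- if (is.null(rg$melanin)) 1 else rg$melanin
    if (!is.finite(mel) || mel <= 0 || mel > 1) {
      stop("melanin_factor must lie in (0, 1]", call. = FALSE)
    }
    cover <- cover + (rg$mask > 0)
  }
  if (any(cover > 1L)) stop("region masks must be disjoint", call. = FALSE)
  if (!is.null(motion) && length(motion) != n_frames(paradigm)) {
    stop("motion must supply one rigid transform per frame", call. = FALSE)
  }
  if (texture_sd < 0) stop("texture_sd must be >= 0", call. = FALSE)
  structure(
    list(height = height, width = width, regions = regions,
         fiducials = fiducials, motion = motion, texture_sd = texture_sd,
         paradigm = paradigm),
    class = "bh_scene"
  )
}

#' Render a synthetic dual-wavelength reflectance stack
#'
#' Inverts the pipeline's attenuation model to produce frames whose mBLL
#' analysis recovers the programmed concentrations.  Per tissue pixel,
#' `I(lambda, t) = I_cal(lambda) * melanin * 10^-(eps_HbO * hbo(t) + eps_HbR * hbr(t))`
#' with optional multiplicative Gaussian noise; fiducials are rendered near
#' zero; per-frame rigid motion (if any) is applied after rendering.  The
#' calibration frame is spatially uniform per wavelength.
#'
#' @param scene A [scene_spec()].
#' @param optics An [extinction_matrix()]; must be invertible.
#' @param seed Integer seed controlling all sensor noise; identical seeds
#'   give bit-identical stacks.
#' @param cal_level Calibration-sheet reflectance on the `[0, 1]` scale.
#' @param background Reflectance of non-tissue background pixels.
#' @return A list with elements `stack` (`bh_stack`), `calibration`
#'   (`bh_calibration`), `masks` (named list of `bh_roi`: `foot`, `fiducial`,
#'   and one per region), `truth` (data.frame `t_s`, `region`, `hbo`, `hbr`
#'   of noiseless ground-truth series), and `motion` (the applied per-frame
#'   transforms, or `NULL`).
#' @export
render_stack <- function(scene, optics = extinction_matrix(), seed = NULL,
                         cal_level = 0.92, background = 0.04) {
  stopifnot(inherits(scene, "bh_scene"))
  E <- unclass(optics)
  if (abs(det(E)) < 1e-12) stop("extinction matrix must be invertible", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  p <- scene$paradigm
  nf <- n_frames(p); H <- scene$height; W <- scene$width

  flat <- list(matrix(background, nf, H * W), matrix(background, nf, H * W))
  foot <- matrix(FALSE, H, W)
  truth <- list()
  masks <- list()

  for (rg in scene$regions) {
    m <- rg$mask > 0
    mel <- if (is.null(rg$melanin)) 1 else rg$melanin
    resp <- simulate_response(rg$response, p)
    idx <- which(m)
    for (w in 1:2) {
      od <- E[w, 1] * resp$hbo + E[w, 2] * resp$hbr      # length nf
      series <- cal_level * mel * 10^(-od)
      block <- matrix(series, nrow = nf, ncol = length(idx))
      if (rg$response$noise_sd > 0) {
        block <- block * (1 + matrix(stats::rnorm(nf * length(idx),
                                                  sd = rg$response$noise_sd),
                                     nrow = nf))
        block[block < 0] <- 0
      }
      flat[[w]][, idx] <- block
    }
    foot <- foot | m
    truth[[rg$label]] <- data.frame(t_s = resp$t_s, region = rg$label,
                                    hbo = resp$hbo, hbr = resp$hbr)
    masks[[rg$label]] <- roi_mask(m, rg$label)
  }

  if (!is.null(scene$texture_sd) && scene$texture_sd > 0) {
    # static smooth multiplicative field over tissue pixels, shared by both
    # wavelengths (time-invariant, like melanin)
    x <- matrix(rep(seq(0, 1, length.out = W), each = H), H)
    y <- matrix(rep(seq(0, 1, length.out = H), times = W), H)
    field <- matrix(0, H, W)
    for (k in 1:6) {
      field <- field + stats::rnorm(1) *
        cos(2 * pi * (sample(1:3, 1) * x + sample(1:3, 1) * y) +
            stats::runif(1) * 2 * pi)
    }
    field <- field / stats::sd(field)
    tex <- pmax(1 + scene$texture_sd * field, 0.05)
    idx <- which(foot)
    for (w in 1:2) {
      flat[[w]][, idx] <- flat[[w]][, idx] *
        matrix(tex[idx], nrow = nf, ncol = length(idx), byrow = TRUE)
    }
  }

  fid <- matrix(FALSE, H, W)
  for (f in scene$fiducials) {
    r <- make_rect_roi(f$top_left, f$size, c(H, W), "fiducial")
    fid <- fid | r$mask
  }
  if (any(fid)) {
    for (w in 1:2) flat[[w]][, which(fid)] <- 0.005
  }
  arr <- lapply(flat, function(x) array(x, dim = c(nf, H, W)))

  if (!is.null(scene$motion)) {
    for (i in seq_len(nf)) {
      tf <- scene$motion[[i]]
      for (w in 1:2) {
        wp <- warp_rigid(arr[[w]][i, , ], tf, fill = background)
        arr[[w]][i, , ] <- wp$image
      }
    }
  }

  cal <- structure(list(matrix(cal_level, H, W), matrix(cal_level, H, W)),
                   class = "bh_calibration")
  stack <- reflectance_stack(arr, p,
                             meta = list(synthetic = TRUE, seed = seed))
  masks$foot <- roi_mask(foot, "foot")
  masks$fiducial <- roi_mask(fid, "fiducial")
  list(stack = stack, calibration = cal, masks = masks,
       truth = do.call(rbind, truth), motion = scene$motion)
}

#' Ready-made synthetic scenes
#'
#' `control_scene()` builds a fully synchronous foot: three background
#' regions sharing one control response but differing melanin factors, plus
#' two fiducial squares.  `dfu_scene()` adds a central wound region whose
#' response is delayed (`wound = "delayed"`) or sign-inverted
#' (`wound = "inverted"`, emulating asynchronous non-healing perfusion);
#' `wound_frac` controls the fraction of foot pixels it occupies.
#'
#' @param size Frame side length in pixels (square frames).
#' @param paradigm A [paradigm()].
#' @param noise_sd Fractional sensor noise shared by all regions.
#' @param melanin Numeric vector of 3 background melanin transmissions.
#' @param delay_s Wound response delay for `wound = "delayed"`.
#' @param wound `"delayed"` or `"inverted"`.
#' @param wound_frac Fraction of the foot area occupied by the wound.
#' @param motion Optional per-frame transforms (see [scene_spec()]).
#' @param texture_sd Static spatial texture level (see [scene_spec()]).
#' @return A `bh_scene`.
#' @export
control_scene <- function(size = 64, paradigm = oxyflow::paradigm(),
                          noise_sd = 0, melanin = c(0.95, 0.7, 0.5),
                          motion = NULL, texture_sd = 0) {
  g <- .scene_geometry(size)
  resp <- function() bh_response_spec(noise_sd = noise_sd)
  regions <- list(
    list(label = "B1", mask = g$b1, response = resp(), melanin = melanin[1]),
    list(label = "B2", mask = g$b2, response = resp(), melanin = melanin[2]),
    list(label = "B3", mask = g$b3, response = resp(), melanin = melanin[3])
  )
  scene_spec(size, size, regions, fiducials = g$fiducials,
             motion = motion, texture_sd = texture_sd, paradigm = paradigm)
}

#' @rdname control_scene
#' @export
dfu_scene <- function(size = 64, paradigm = oxyflow::paradigm(),
                      noise_sd = 0, melanin = c(0.95, 0.7, 0.5),
                      delay_s = 20, wound = c("delayed", "inverted"),
                      wound_frac = 0.3, motion = NULL, texture_sd = 0) {
  wound <- match.arg(wound)
  g <- .scene_geometry(size, wound_frac = wound_frac)
  resp <- function() bh_response_spec(noise_sd = noise_sd)
  wresp <- if (wound == "delayed") {
    bh_response_spec(response_delay_s = delay_s, noise_sd = noise_sd)
  } else {
    bh_response_spec(hold_hbr_rise = -0.02, recovery_hbo_overshoot = -0.02,
                     recovery_hbr_undershoot = -0.025, noise_sd = noise_sd)
  }
  regions <- list(
    list(label = "B1", mask = g$b1 & !g$wound, response = resp(), melanin = melanin[1]),
    list(label = "B2", mask = g$b2 & !g$wound, response = resp(), melanin = melanin[2]),
    list(label = "B3", mask = g$b3 & !g$wound, response = resp(), melanin = melanin[3]),
    list(label = "W",  mask = g$wound, response = wresp, melanin = melanin[2])
  )
  scene_spec(size, size, regions, fiducials = g$fiducials,
             motion = motion, texture_sd = texture_sd, paradigm = paradigm)
}

# foot occupies a central rectangle split into three background bands;
# the wound (if any) is a centred rectangle of the requested area fraction
.scene_geometry <- function(size, wound_frac = 0) {
  H <- size; W <- size
  pad <- max(2L, round(size / 10))
  foot_r <- (pad + 1):(H - pad); foot_c <- (pad + 1):(W - pad)
  foot <- matrix(FALSE, H, W); foot[foot_r, foot_c] <- TRUE
  thirds <- floor(length(foot_c) / 3)
  b1 <- b2 <- b3 <- matrix(FALSE, H, W)
  b1[foot_r, foot_c[seq_len(thirds)]] <- TRUE
  b2[foot_r, foot_c[(thirds + 1):(2 * thirds)]] <- TRUE
  b3[foot_r, foot_c[(2 * thirds + 1):length(foot_c)]] <- TRUE
  wound <- matrix(FALSE, H, W)
  if (wound_frac > 0) {
    area <- wound_frac * sum(foot)
    side <- max(3L, round(sqrt(area)))
    r0 <- max(foot_r[1], round(H / 2 - side / 2))
    c0 <- max(foot_c[1], round(W / 2 - side / 2))
    wound[r0:min(r0 + side - 1, max(foot_r)),
          c0:min(c0 + side - 1, max(foot_c))] <- TRUE
    wound <- wound & foot
  }
  fsz <- max(2L, round(size / 16))
  fiducials <- list(list(top_left = c(1, 1), size = fsz),
                    list(top_left = c(1, W - fsz + 1), size = fsz))
  list(foot = foot, b1 = b1, b2 = b2, b3 = b3, wound = wound,
       fiducials = fiducials)
}

#' Write a rendered scene to disk
#'
#' Persists the stack (two multi-frame TIFFs), calibration frames, masks
#' (PNG), ground-truth series (CSV) and the paradigm (YAML) under `dir`.
#'
#' @param rendered The list returned by [render_stack()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_scene <- function(rendered, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  wl <- rendered$stack$wavelengths_nm
  write_stack(rendered$stack,
              file.path(dir, sprintf("stack_%dnm.tif", wl)))
  write_calibration(rendered$calibration,
                    file.path(dir, sprintf("calibration_%dnm.tif", wl)))
  for (nm in names(rendered$masks)) {
    write_mask(rendered$masks[[nm]], file.path(dir, paste0("mask_", nm, ".png")))
  }
  utils::write.csv(rendered$truth, file.path(dir, "ground_truth.csv"),
                   row.names = FALSE)
  write_paradigm(rendered$stack$paradigm, file.path(dir, "paradigm.yaml"))
  invisible(dir)
}
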