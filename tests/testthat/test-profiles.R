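test_that("Savitzky-Golay smoothing matches the reference filter and is exact on polynomials", {
  set.seed(21)
  x <- rnorm(120)
  expect_equal(sg_smooth_series(x, 11, 3), signal::sgolayfilt(x, p = 3, n = 11),
               tolerance = 1e-12)
  # constants and polynomials up to the order are reproduced
  expect_equal(sg_smooth_series(rep(4, 50), 11, 3), rep(4, 50), tolerance = 1e-12)
  t <- seq_len(60)
  y <- 2 - 0.3 * t + 0.01 * t^2
  sm <- sg_smooth_series(y, 11, 2)
  expect_lt(max(abs(sm[6:55] - y[6:55])), 1e-9)
})

test_that("smoothing reduces residual variance on a seeded noisy ramp", {
  set.seed(7)
  t <- seq_len(120)
  truth <- t * 1.0
  noisy <- truth + rnorm(120, sd = 0.5)
  sm <- sg_smooth_series(noisy, 11, 3)
  expect_lt(stats::var(sm - truth), stats::var(noisy - truth))
})

test_that("filter configuration is validated", {
  expect_error(sg_smooth_series(rnorm(50), window = 10, polyorder = 3), "odd")
  expect_error(sg_smooth_series(rnorm(50), window = 5, polyorder = 5), "smaller")
  expect_error(sg_smooth_series(rnorm(9), window = 11, polyorder = 3), "exceeds")
})

test_that("array smoothing filters each pixel series and skips invalid ones", {
  set.seed(3)
  arr <- array(rnorm(40 * 3 * 3), dim = c(40, 3, 3))
  arr[5, 2, 2] <- NA
  sm <- sg_smooth(arr, 11, 3)
  expect_equal(sm[, 1, 1], sg_smooth_series(arr[, 1, 1], 11, 3))
  expect_identical(sm[, 2, 2], arr[, 2, 2])  # series with invalid frames untouched
})

test_that("ROI profiles average valid pixels per frame", {
  p <- short_paradigm()
  rd <- render_stack(control_scene(24, paradigm = p))
  maps <- mbll(rd$stack, rd$calibration)
  # single-pixel ROI equals that pixel's series
  px <- which(rd$masks$B1$mask, arr.ind = TRUE)[1, ]
  m1 <- matrix(FALSE, 24, 24); m1[px[1], px[2]] <- TRUE
  prof1 <- roi_profile(maps, roi_mask(m1, "one"), "sto2")
  expect_equal(prof1$values, maps$sto2[, px[1], px[2]])
  # two pixels with different series average to their mean
  maps2 <- maps
  maps2$sto2[, 1, 1] <- 1; maps2$sto2[, 1, 2] <- 3
  maps2$valid[, 1, 1] <- TRUE; maps2$valid[, 1, 2] <- TRUE
  m2 <- matrix(FALSE, 24, 24); m2[1, 1:2] <- TRUE
  expect_equal(unique(roi_profile(maps2, roi_mask(m2, "pair"), "sto2")$values), 2)
  # empty / all-invalid ROIs error
  expect_error(roi_profile(maps, roi_mask(matrix(FALSE, 24, 24), "none")), "empty")
})

test_that("ROI profile matches the simulator's ground truth", {
  p <- short_paradigm()
  rd <- render_stack(control_scene(32, paradigm = p, melanin = c(1, 1, 1),
                                   noise_sd = 0.005), seed = 8)
  maps <- mbll(rd$stack, rd$calibration)
  tr <- rd$truth[rd$truth$region == "B1", ]
  truth_sto2 <- tr$hbo / (tr$hbo + tr$hbr)
  prof <- roi_profile(maps, rd$masks$B1, "sto2")
  # ROI averaging beats single-pixel noise by ~sqrt(n); tolerance is noise-scaled
  expect_lt(max(abs(prof$values - truth_sto2)), 0.005)
})

test_that("onset normalisation yields percent change from t = rest_s", {
  p <- paradigm()
  prof <- structure(list(values = c(rep(10, 41), rep(11, 79)),
                         t_s = 0:119, parameter = "sto2", roi_label = "foot",
                         normalized = FALSE, t0_s = NA_real_,
                         n_pixels = rep(5L, 120)),
                    class = "bh_profile")
  norm <- normalize_at_onset(prof, p)
  expect_equal(norm$t_s[1], 40)
  expect_equal(norm$values[1], 0)
  expect_equal(norm$values[length(norm$values)], 10)  # 11 vs 10 -> +10%
  expect_length(norm$values, 80)
  # flat profile normalises to identically zero
  flat <- prof; flat$values <- rep(3, 120)
  expect_true(all(normalize_at_onset(flat, p)$values == 0))
  # idempotence at the same onset
  expect_identical(normalize_at_onset(norm, p), norm)
  # zero onset value is a normalisation error
  zero <- prof; zero$values[41] <- 0
  expect_error(normalize_at_onset(zero, p), "onset value")
})

test_that("the control StO2 profile recovers a ~2% post-hold plateau", {
  rd <- render_stack(control_scene(48), seed = 12)
  maps <- sg_smooth(mbll(rd$stack, rd$calibration))
  prof <- normalize_at_onset(roi_profile(maps, rd$masks$foot, "sto2"), paradigm())
  at <- function(t) prof$values[match(t, prof$t_s)]
  expect_gt(at(100), 1)              # rises ~2% above onset
  expect_lt(at(100), 3)
  expect_lt(abs(at(115) - at(100)), 0.5)   # plateaus near the 100th second
})

test_that("grand averages give pointwise mean and standard error", {
  mk <- function(v) structure(list(values = v, t_s = seq_along(v) - 1,
                                   parameter = "sto2", roi_label = "r",
                                   normalized = TRUE, t0_s = 0,
                                   n_pixels = rep(1L, length(v))),
                              class = "bh_profile")
  same <- grand_average(list(mk(c(1, 2, 3)), mk(c(1, 2, 3))))
  expect_equal(same$mean, c(1, 2, 3))
  expect_equal(same$se, c(0, 0, 0))
  # profiles at 0% and 2%: mean 1, sd sqrt(2), SE = sd/sqrt(2) = 1
  two <- grand_average(list(mk(rep(0, 4)), mk(rep(2, 4))))
  expect_equal(two$mean, rep(1, 4))
  expect_equal(two$se, rep(1, 4))
  expect_error(grand_average(list(mk(1:3), mk(1:4))), "length")
  bad <- mk(1:3); bad$parameter <- "hbo"
  expect_error(grand_average(list(mk(1:3), bad)), "parameter")
})

test_that("the grand-average SE band covers the true response", {
  # 3 synthetic subjects x 3 repetitions of the control response
  p <- paradigm()
  profs <- list()
  for (s in 1:9) {
    rd <- render_stack(control_scene(32, noise_sd = 0.01, melanin = c(1, 1, 1)),
                       seed = 100 + s)
    maps <- sg_smooth(mbll(rd$stack, rd$calibration))
    profs[[s]] <- normalize_at_onset(roi_profile(maps, rd$masks$foot, "sto2"), p)
  }
  ga <- grand_average(profs)
  tr <- render_stack(control_scene(32, melanin = c(1, 1, 1)))$truth
  tr <- tr[tr$region == "B1", ]
  # the fair comparator sees the same linear smoother as the data
  truth_sto2 <- sg_smooth_series(tr$hbo / (tr$hbo + tr$hbr), 11, 3)
  keep <- which(tr$t_s >= 40)
  truth_pct <- 100 * (truth_sto2[keep] - truth_sto2[keep[1]]) / abs(truth_sto2[keep[1]])
  covered <- abs(ga$mean - truth_pct) <= 3 * pmax(ga$se, 1e-3)
  expect_gte(mean(covered), 0.9)
})

test_that("ROI averaging commutes with the linear smoother", {
  p <- short_paradigm()
  rd <- render_stack(control_scene(24, paradigm = p, noise_sd = 0.02), seed = 9)
  maps <- mbll(rd$stack, rd$calibration)
  roi <- rd$masks$B2
  filtered_then_avg <- roi_profile(sg_smooth(maps, 7, 2), roi, "hbo")$values
  avg_then_filtered <- sg_smooth_series(roi_profile(maps, roi, "hbo")$values, 7, 2)
  expect_equal(filtered_then_avg, avg_then_filtered, tolerance = 1e-10)
})
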