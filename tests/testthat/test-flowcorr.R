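# literal two-pass evaluation of the correlation formula: explicit means,
# then explicit sums — the independent oracle for pearson_cc
pearson_oracle <- function(x, y) {
  n <- length(x)
  mx <- sum(x) / n; my <- sum(y) / n
  num <- 0; dx <- 0; dy <- 0
  for (i in seq_len(n)) {
    num <- num + (x[i] - mx) * (y[i] - my)
    dx <- dx + (x[i] - mx)^2
    dy <- dy + (y[i] - my)^2
  }
  num / sqrt(dx * dy)
}

test_that("pearson_cc implements the correlation formula", {
  x <- c(1, 2, 3)
  expect_equal(pearson_cc(x, x), 1)
  expect_equal(pearson_cc(x, -x + 7), -1)
  # hand case: numerator 3, denominator sqrt(2 * 14/3)
  expect_equal(pearson_cc(c(1, 2, 3), c(1, 2, 4)), 3 / sqrt(2 * 14 / 3),
               tolerance = 1e-12)
  expect_equal(pearson_cc(c(1, 2, 3), c(1, 2, 4)), 0.9819805, tolerance = 1e-7)
})

test_that("pearson_cc agrees with independent oracles on random series", {
  set.seed(31)
  for (i in 1:200) {
    n <- sample(3:60, 1)
    x <- rnorm(n); y <- rnorm(n)
    v <- pearson_cc(x, y)
    expect_lt(abs(v - pearson_oracle(x, y)), 1e-12)
    expect_lt(abs(v - stats::cor(x, y)), 1e-12)
  }
})

test_that("undefined correlations return the invalid marker, never zero", {
  expect_true(is.na(pearson_cc(rep(1, 5), rnorm(5))))
  expect_true(is.na(pearson_cc(rnorm(5), rep(2, 5))))
  expect_true(is.na(pearson_cc(c(1, NA, 3), c(1, 2, 3))))
  expect_error(pearson_cc(1:3, 1:4), "lengths")
  expect_error(pearson_cc(1:2, 2:3), "3 time points")
})

test_that("pearson_cc is invariant under positive affine maps and flips sign", {
  set.seed(5)
  x <- rnorm(20); y <- rnorm(20)
  v <- pearson_cc(x, y)
  expect_equal(pearson_cc(2.5 * x + 3, y), v, tolerance = 1e-12)
  expect_equal(pearson_cc(x, -0.5 * y + 1), -v, tolerance = 1e-12)
})

test_that("reference signals follow the declared pixel set and window", {
  p <- short_paradigm()
  rd <- render_stack(control_scene(24, paradigm = p, noise_sd = 0.01), seed = 4)
  maps <- mbll(rd$stack, rd$calibration)
  frames <- window_frames(p)
  # single-pixel ROI reference equals that pixel's windowed series
  px <- which(rd$masks$B2$mask, arr.ind = TRUE)[1, ]
  m1 <- matrix(FALSE, 24, 24); m1[px[1], px[2]] <- TRUE
  ref <- build_reference(maps, "roi", roi = roi_mask(m1, "B"),
                         foot_mask = rd$masks$foot)
  expect_equal(ref$values, maps$sto2[frames, px[1], px[2]])
  expect_equal(ref$frames, frames)
  # global mean over identical pixels equals the common series
  maps2 <- maps
  maps2$sto2[] <- rep(sin(seq_len(dim(maps$sto2)[1])), 24 * 24)
  refg <- build_reference(maps2, "global_mean", foot_mask = rd$masks$foot)
  expect_equal(refg$values, sin(frames), tolerance = 1e-12)
  # contract violations
  expect_error(build_reference(maps, "global_mean"), "foot mask")
  expect_error(build_reference(maps, "roi", foot_mask = rd$masks$foot),
               "explicit background ROI")
  flat <- maps; flat$sto2[] <- 1
  expect_error(build_reference(flat, "global_mean", foot_mask = rd$masks$foot),
               "zero variance")
})

test_that("correlation maps are 1 where pixels equal the reference and bounded", {
  p <- short_paradigm()
  rd <- render_stack(control_scene(24, paradigm = p, noise_sd = 0.01), seed = 6)
  maps <- mbll(rd$stack, rd$calibration)
  common <- cos(seq_len(dim(maps$sto2)[1]))
  maps$sto2[] <- rep(common, 24 * 24)
  ref <- build_reference(maps, "global_mean", foot_mask = rd$masks$foot)
  cm <- correlation_map(maps, ref, rd$masks$foot, list(rd$masks$fiducial))
  inside <- rd$masks$foot$mask & !rd$masks$fiducial$mask
  expect_true(all(abs(cm$pcc[inside] - 1) < 1e-12))
  expect_true(all(is.na(cm$pcc[!inside])))
  # a window below 3 frames is rejected
  ref$frames <- ref$frames[1:2]
  expect_error(correlation_map(maps, ref, rd$masks$foot), "3 frames")
})

test_that("synchronous backgrounds score high and inverted wounds negative", {
  rd <- render_stack(dfu_scene(48, noise_sd = 0.01, wound = "inverted"), seed = 13)
  maps <- sg_smooth(mbll(rd$stack, rd$calibration), parameters = "sto2")
  ref <- build_reference(maps, "roi", roi = rd$masks$B1,
                         foot_mask = rd$masks$foot)
  cm <- correlation_map(maps, ref, rd$masks$foot, list(rd$masks$fiducial))
  expect_lt(mean(cm$pcc[rd$masks$W$mask], na.rm = TRUE), 0)
  bg <- rd$masks$B2$mask | rd$masks$B3$mask
  expect_gt(mean(cm$pcc[bg], na.rm = TRUE), 0.8)
  # control scene against the global mean: high correlation across the foot
  rdc <- render_stack(control_scene(48, noise_sd = 0.01), seed = 13)
  mc <- sg_smooth(mbll(rdc$stack, rdc$calibration), parameters = "sto2")
  refc <- build_reference(mc, "global_mean", foot_mask = rdc$masks$foot)
  cmc <- correlation_map(mc, refc, rdc$masks$foot, list(rdc$masks$fiducial))
  v <- cmc$pcc[!is.na(cmc$pcc)]
  expect_gt(min(v), 0.8)
  expect_gt(mean(v >= 0.9), 0.99)
})

test_that("pairwise ROI correlations reproduce forced patterns", {
  p <- short_paradigm()
  rd <- render_stack(control_scene(24, paradigm = p), seed = 2)
  maps <- mbll(rd$stack, rd$calibration)
  # a ROI against itself correlates to 1
  tab_self <- pairwise_roi_correlations(maps, list(rd$masks$B1, rd$masks$B1))
  expect_equal(tab_self$pcc, 1, tolerance = 1e-12)
  # two identical series and one inverted: (1, -1, -1)
  maps2 <- maps
  s <- sin(seq_len(dim(maps$sto2)[1]))
  maps2$sto2[, , 1] <- s; maps2$sto2[, , 2] <- s; maps2$sto2[, , 3] <- -s
  col_roi <- function(j, lab) {
    m <- matrix(FALSE, 24, 24); m[, j] <- TRUE; roi_mask(m, lab)
  }
  tab <- pairwise_roi_correlations(
    maps2, list(col_roi(1, "a"), col_roi(2, "b"), col_roi(3, "c")))
  expect_equal(tab$pcc, c(1, -1, -1), tolerance = 1e-12)
  expect_error(pairwise_roi_correlations(maps, list(rd$masks$B1)), ">= 2")
})

test_that("delayed wounds weaken wound-background correlation, not background-background", {
  rd <- render_stack(dfu_scene(48, noise_sd = 0.01, wound = "delayed",
                               delay_s = 20), seed = 17)
  maps <- sg_smooth(mbll(rd$stack, rd$calibration), parameters = "sto2")
  rois <- list(rd$masks$B1, rd$masks$B2, rd$masks$W)
  tab <- pairwise_roi_correlations(maps, rois)
  b1b2 <- tab$pcc[tab$roi_a == "B1" & tab$roi_b == "B2"]
  wb <- tab$pcc[tab$roi_b == "W"]
  expect_gt(b1b2, 0.9)
  expect_true(all(wb < b1b2))
})

test_that("melanin differences do not break profile synchrony", {
  rd <- render_stack(control_scene(32, melanin = c(1, 0.4, 0.7)))
  maps <- mbll(rd$stack, rd$calibration)
  frames <- window_frames(paradigm())
  p1 <- roi_profile(maps, rd$masks$B1, "sto2")$values[frames]
  p2 <- roi_profile(maps, rd$masks$B2, "sto2")$values[frames]
  expect_gt(pearson_cc(p1, p2), 0.99)
})
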