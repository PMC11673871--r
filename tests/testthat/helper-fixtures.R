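# Shared fixtures, all generated in code.

# Elongated foot-like phantom with soft edges, internal blobs and two dark
# fiducial squares: smooth (band-limited) like real diffuse-reflectance
# frames, with enough angular structure to determine rotation.
reg_phantom <- function(n) {
  r <- matrix(rep(seq_len(n), n), n); cc <- t(r)
  sig <- function(x) 1 / (1 + exp(-x))
  u <- (r - n * 0.5) * cos(0.3) + (cc - n * 0.5) * sin(0.3)
  v <- -(r - n * 0.5) * sin(0.3) + (cc - n * 0.5) * cos(0.3)
  d <- sqrt((u / (n * 0.38))^2 + (v / (n * 0.18))^2)
  z <- 0.05 + 0.8 * sig((1 - d) * 12)
  z <- z + 0.12 * sig(((n * 0.07) - sqrt((r - n * 0.4)^2 + (cc - n * 0.62)^2)) / 2.5)
  z <- z - 0.10 * sig(((n * 0.06) - sqrt((r - n * 0.62)^2 + (cc - n * 0.38)^2)) / 2.5)
  f <- matrix(0, n, n); s <- max(3, round(n / 16))
  f[3:(2 + s), 3:(2 + s)] <- 1
  f[3:(2 + s), (n - 1 - s):(n - 2)] <- 1
  fs <- f
  for (i in 2:(n - 1)) for (j in 2:(n - 1)) {
    fs[i, j] <- mean(f[(i - 1):(i + 1), (j - 1):(j + 1)])
  }
  z * (1 - 0.95 * fs)
}

# binary erosion by k 4-neighbour steps
erode_mask <- function(m, k) {
  for (i in seq_len(k)) {
    m <- m & rbind(m[-1, ], FALSE) & rbind(FALSE, m[-nrow(m), ]) &
      cbind(m[, -1], FALSE) & cbind(FALSE, m[, -ncol(m)])
  }
  m
}

# short protocol used where only mechanics (not the 120 s response) matter
short_paradigm <- function() paradigm(rest_s = 10, hold_s = 5, recovery_s = 15)

# maximum translation/rotation residual of recovered vs programmed transforms
transform_residual <- function(recovered, programmed) {
  resid <- compose_transforms(recovered, programmed)
  c(trans = max(abs(c(resid$tx, resid$ty))), rot = abs(resid$rotation_deg))
}
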