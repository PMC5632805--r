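# Shared fixtures: reduced-resolution renders keep the suite fast while the
# scene stays geometrically identical to the platform's 2500 x 2000 frames.

TEST_W <- 640L
TEST_H <- 512L

test_truth <- function(layout, areas, ...) {
  ground_truth_plate(layout, areas, width = TEST_W, height = TEST_H, ...)
}

test_config <- function(truth, ...) {
  segmentation_config(crop_px_per_mm = truth$px_per_mm,
                      distortion_k = truth$distortion_k, ...)
}

# distortion coefficient with full-resolution-typical corner displacement,
# rescaled to the test raster
test_k <- function(k_full = 5e-9) k_full * (2500 / TEST_W)^2

random_areas <- function(layout, lo = 900, hi = 3000) {
  round(stats::runif(layout$wells_per_plate, lo, hi))
}

# Independent Conover-Iman oracle: direct transcription of the textbook
# formula with explicit loops, sharing no code with the implementation.
conover_oracle <- function(groups) {
  x <- unlist(groups, use.names = FALSE)
  g <- rep(seq_along(groups), lengths(groups))
  N <- length(x); k <- length(groups)
  r <- rank(x)
  Rsum <- tapply(r, g, sum)
  n <- lengths(groups)
  ties <- table(x)
  Hnum <- 12 / (N * (N + 1)) * sum(Rsum^2 / n) - 3 * (N + 1)
  C <- 1 - sum(ties^3 - ties) / (N^3 - N)
  H <- if (C > 0) Hnum / C else 0
  S2 <- (sum(r^2) - N * (N + 1)^2 / 4) / (N - 1)
  p <- matrix(1, k, k)
  for (i in 1:(k - 1)) for (j in (i + 1):k) {
    den <- sqrt(S2 * ((N - 1 - H) / (N - k)) * (1 / n[i] + 1 / n[j]))
    tij <- (Rsum[i] / n[i] - Rsum[j] / n[j]) / den
    p[i, j] <- p[j, i] <- 2 * stats::pt(-abs(tij), N - k)
  }
  p
}

# brute-force quartiles by linear interpolation on the sorted sample
quantile_oracle <- function(x, p) {
  s <- sort(x)
  h <- (length(s) - 1) * p + 1
  lo <- floor(h); hi <- ceiling(h)
  s[lo] + (h - lo) * (s[hi] - s[lo])
}
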