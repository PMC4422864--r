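# Fixtures are built in code; nothing binary ships with the package.

# tiny profile-mode dataset: Gaussian peaks at `peaks` on [lo, hi]
tiny_dataset <- function(peaks, heights = rep(100, length(peaks)),
                         lo = 100, hi = 110, step = 0.01, n_pixels = 2,
                         sigma = 0.05, meta = list()) {
  mz <- seq(lo, hi, by = step)
  spec <- rep(0, length(mz))
  for (i in seq_along(peaks))
    spec <- spec + heights[i] * exp(-(mz - peaks[i])^2 / (2 * sigma^2))
  ints <- matrix(rep(spec, n_pixels), ncol = n_pixels)
  coords <- cbind(x = seq_len(n_pixels) - 1L, y = 0L)
  meta <- modifyList(list(molecular_class = "metabolite", polarity = "-",
                          raster_um = 100, mass_range = c(lo, hi)), meta)
  msi_dataset(coords, mz, ints, meta)
}

# reduced design: n animals per genotype-condition cell (same 6 groups)
small_design <- function(n_per_group = 2) {
  g <- expand.grid(genotype = c("WT", "R192Q"),
                   condition = c("Naive", "Sham", "CSD"),
                   rep = seq_len(n_per_group), stringsAsFactors = FALSE)
  study_design(sprintf("A%02d", seq_len(nrow(g))), g$genotype, g$condition,
               postmortem_min = 7)
}

# narrow three-feature panel for fast phantom studies (three anchors is the
# minimum the linear recalibration accepts)
small_panel <- function() {
  data.frame(mz = c(144.80, 146.07, 147.60), class = "metabolite",
             region_pattern = c("uniform", "cortex", "uniform"),
             baseline = c(100, 150, 120))
}

# brute-force BH step-up: independent of bh_adjust's implementation
bh_brute <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- numeric(m)
  for (i in seq_len(m)) {
    js <- i:m
    q[o[i]] <- min(1, min(p[o[js]] * m / js))
  }
  q
}

# dense normalized-convolution oracle for Gaussian smoothing
conv_oracle <- function(x, kernel) {
  n <- length(x); k <- length(kernel); half <- (k - 1) / 2
  out <- numeric(n); denom <- numeric(n)
  for (i in seq_len(n)) {
    for (t in seq_len(k)) {
      j <- i + t - 1 - half
      if (j >= 1 && j <= n) {
        out[i] <- out[i] + x[j] * kernel[k - t + 1]
        denom[i] <- denom[i] + kernel[k - t + 1]
      }
    }
  }
  out / denom
}

# brute-force grayscale opening (erosion then dilation, truncated window)
opening_brute <- function(x, w) {
  half <- w %/% 2
  n <- length(x)
  er <- sapply(seq_len(n), function(i)
    min(x[max(1, i - half):min(n, i + half)]))
  sapply(seq_len(n), function(i)
    max(er[max(1, i - half):min(n, i + half)]))
}

# independent longest-row-run scan (cord length oracle)
cord_brute <- function(mask) {
  best <- 0
  for (r in seq_len(nrow(mask))) {
    run <- 0
    for (c in seq_len(ncol(mask))) {
      if (mask[r, c]) { run <- run + 1; best <- max(best, run) } else run <- 0
    }
  }
  best
}
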