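cfg <- preproc_config("metabolite")  # width 0.02 Da, 2 cycles, TopHat 0.5 Da

test_that("class presets follow the instrument settings", {
  expect_equal(cfg$gauss_width_da, 0.02)
  expect_equal(cfg$gauss_cycles, 2L)
  prot <- preproc_config("protein")
  expect_equal(prot$gauss_width_da, 2)
  expect_equal(prot$gauss_cycles, 4L)
  expect_error(preproc_config("lipid"), class = "atlasmsi_validation_error")
  expect_error(preproc_config("metabolite", tophat_window_da = 0.01),
               class = "atlasmsi_validation_error")
})

test_that("gaussian smoothing matches a dense-convolution oracle", {
  mz <- seq(100, 101, by = 0.005)
  # constant spectrum is unchanged (unit-mass kernel, normalized edges)
  expect_equal(gauss_smooth(rep(7, length(mz)), mz, cfg), rep(7, length(mz)),
               tolerance = 1e-12)
  # unit impulse spreads to a Gaussian of sigma = width and keeps mass
  one_cycle <- preproc_config("metabolite", gauss_cycles = 1)
  imp <- rep(0, length(mz)); imp[101] <- 1
  sm <- gauss_smooth(imp, mz, one_cycle)
  expect_equal(sum(sm), 1, tolerance = 1e-3)
  sigma_pts <- 0.02 / median(diff(mz))  # identical grid-spacing estimate
  expect_lt(max(abs(sm - conv_oracle(imp, atlasmsi:::gauss_kernel(sigma_pts)))),
            1e-12)
  expect_equal(which.max(sm), 101L)
  # two cycles at sigma equal one convolution at sigma*sqrt(2) away from the
  # renormalized edges (zero margins wider than both kernels)
  set.seed(1)
  x <- c(rep(0, 60), runif(81), rep(0, 60))
  two <- gauss_smooth(x, mz, cfg)
  once <- conv_oracle(x, atlasmsi:::gauss_kernel(sigma_pts * sqrt(2)))
  interior <- 40:160
  expect_lt(max(abs(two[interior] - once[interior])), 1e-6)
  # grid coarser than the kernel is refused
  expect_error(gauss_smooth(rep(1, 5), seq(100, 104), cfg),
               class = "atlasmsi_validation_error")
})

test_that("smoothing never increases the global maximum", {
  mz <- seq(100, 102, by = 0.005)
  set.seed(2)
  for (i in 1:20) {
    x <- rpois(length(mz), 20)
    expect_lte(max(gauss_smooth(x, mz, cfg)), max(x))
  }
})

test_that("TopHat subtracts the morphological opening", {
  mz <- seq(100, 103, by = 0.01)
  n <- length(mz)
  # constant spectrum -> all zeros; all-zero -> all zeros
  expect_equal(tophat_baseline(rep(10, n), mz, cfg), rep(0, n))
  expect_equal(tophat_baseline(rep(0, n), mz, cfg), rep(0, n))
  # flat baseline 10 + narrow peak of height 5: baseline removed, apex kept
  x <- rep(10, n)
  x[148:154] <- x[148:154] + 5 * exp(-((-3):3)^2 / 2)
  th <- tophat_baseline(x, mz, cfg)
  expect_equal(max(th), 5, tolerance = 1e-9)
  expect_equal(which.max(th), 151L)
  expect_equal(th[1:100], rep(0, 100))
  # agreement with a brute-force opening on random spectra, and the
  # pointwise-dominance invariant
  w <- as.integer(round(cfg$tophat_window_da / 0.01)) + 1L  # odd width used
  set.seed(3)
  for (i in 1:5) {
    x <- rpois(n, 30) + 20 * sin(seq(0, 3, length.out = n))^2
    th <- tophat_baseline(x, mz, cfg)
    expect_equal(th, x - opening_brute(x, w), tolerance = 1e-12)
    expect_true(all(th <= x + 1e-12))
    expect_true(all(th >= 0))
  }
  expect_error(tophat_baseline(rep(1, 10), seq(100, 100.09, by = 0.01), cfg),
               class = "atlasmsi_validation_error")
})

test_that("TIC normalization scales to unit sum and flags zero-TIC pixels", {
  expect_equal(tic_normalize(c(2, 3, 5)), c(0.2, 0.3, 0.5))
  set.seed(4)
  for (i in 1:10) {
    x <- runif(50)
    expect_equal(sum(tic_normalize(x)), 1, tolerance = 1e-12)
  }
  expect_error(tic_normalize(c(0, 0, 0)), class = "atlasmsi_zero_tic")
})

test_that("preprocess_dataset drops zero-TIC pixels instead of zero-filling", {
  d <- tiny_dataset(c(105), n_pixels = 3)
  d$intensities[, 2] <- 0
  pre <- preprocess_dataset(d, cfg)
  expect_identical(nrow(pre$coords), 2L)
  expect_identical(nrow(attr(pre, "dropped_pixels")), 1L)
  expect_equal(colSums(pre$intensities), c(1, 1), tolerance = 1e-12)
})

test_that("alignment of identical datasets is the identity", {
  ds <- lapply(1:3, function(i) tiny_dataset(c(101.5, 104, 107.5, 109)))
  al <- align_spectra(ds)
  expect_equal(unname(al$model$coefs[, "slope"]), rep(1, 3), tolerance = 1e-9)
  expect_equal(unname(al$model$coefs[, "offset"]), rep(0, 3), tolerance = 1e-7)
  expect_equal(al$datasets[[1]]$intensities, ds[[1]]$intensities,
               tolerance = 1e-9)
})

test_that("alignment recovers a planted +0.05 Da shift within 0.005 Da", {
  peaks <- c(101.5, 104, 107.5, 109)
  ds <- c(lapply(1:3, function(i) tiny_dataset(peaks)),
          list(tiny_dataset(peaks + 0.05)))
  al <- align_spectra(ds)
  expect_equal(unname(al$model$coefs[4, "offset"] +
                        (al$model$coefs[4, "slope"] - 1) * mean(peaks)),
               -0.05, tolerance = 0.005)
  # invariant: across-sample sd of each anchor's apex position shrinks
  apex_sd <- function(dats) {
    sapply(peaks, function(p) {
      pos <- sapply(dats, function(d) {
        m <- rowMeans(d$intensities)
        win <- abs(d$mz - p) < 0.3
        d$mz[win][which.max(m[win])]
      })
      sd(pos)
    })
  }
  expect_true(all(apex_sd(al$datasets) <= apex_sd(ds) + 1e-12))
})

test_that("anchor presence respects the 85% rule at the boundary", {
  peaks_all <- c(101.5, 104, 107.5, 109)
  extra <- 106
  make <- function(with_extra)
    tiny_dataset(if (with_extra) sort(c(peaks_all, extra)) else peaks_all)
  # present in 8 of 10: 0.8 < 0.85 -> excluded
  ds8 <- lapply(1:10, function(i) make(i <= 8))
  al8 <- align_spectra(ds8)
  expect_false(any(abs(al8$model$anchor_mzs - extra) < 0.2))
  # present in 9 of 10: 0.9 >= 0.85 -> included
  ds9 <- lapply(1:10, function(i) make(i <= 9))
  al9 <- align_spectra(ds9)
  expect_true(any(abs(al9$model$anchor_mzs - extra) < 0.2))
})

test_that("alignment refuses to fit with fewer than 3 anchors", {
  ds <- lapply(1:2, function(i) tiny_dataset(c(103, 107)))
  expect_error(align_spectra(ds), regexp = "anchor",
               class = "atlasmsi_alignment_error")
  expect_error(align_spectra(list(tiny_dataset(100.5))),
               class = "atlasmsi_validation_error")
})
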