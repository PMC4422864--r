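#' Global base peak mass spectrum
#'
#' Per-bin maximum intensity over every pixel of every dataset in a
#' study/class. Peaks are picked once on this summary spectrum so that the
#' same feature list applies to all animals.
#'
#' @param datasets list of recalibrated profile-mode [msi_dataset()]s sharing
#'   one m/z grid.
#' @return list of class `base_peak_spectrum` with `mz` and `values`.
#' @export
compute_base_peak_spectrum <- function(datasets) {
  if (!length(datasets)) abort("no datasets", "atlasmsi_validation_error")
  grid <- datasets[[1]]$mz
  for (d in datasets) {
    if (d$mode != "profile" || length(d$mz) != length(grid) ||
        max(abs(d$mz - grid)) > 1e-9)
      abort("datasets must share a resampled common m/z grid",
            "atlasmsi_validation_error")
  }
  v <- rep(-Inf, length(grid))
  for (d in datasets) v <- pmax(v, .row_max(d$intensities))
  structure(list(mz = grid, values = v), class = "base_peak_spectrum")
}

#' Peak picking on the base peak spectrum
#'
#' Local maxima with signal-to-noise at least `snr_min`, where the noise
#' level is 1.4826 times the median absolute deviation of the detrended
#' spectrum (running-median detrend). Each peak's integration window is the
#' contiguous run of bins above half its height, clipped to
#' `min_separation_da`; windows are made disjoint at the midpoint between
#' adjacent peaks.
#'
#' @param bps a `base_peak_spectrum`.
#' @param snr_min minimum SNR (default 3).
#' @param min_separation_da minimum apex separation; default 4x the class
#'   smoothing width via `gauss_width_da`.
#' @param gauss_width_da smoothing width used to derive the default
#'   separation.
#' @return a [feature_table()].
#' @export
pick_peaks <- function(bps, snr_min = 3, min_separation_da = NULL,
                       gauss_width_da = 0.02) {
  min_separation_da <- min_separation_da %||% (4 * gauss_width_da)
  mz <- bps$mz; y <- bps$values
  if (all(y <= 0)) return(feature_table(numeric(), numeric(), numeric()))
  pk <- find_local_maxima(mz, y, snr_min = snr_min,
                          min_separation_da = min_separation_da)
  if (!nrow(pk)) return(feature_table(numeric(), numeric(), numeric()))
  detrended <- y - runmed(y, min(length(y) - (1 - length(y) %% 2), 201))
  noise <- mad(detrended)
  apex <- pk$index
  spacing <- median(diff(mz))
  lo <- numeric(nrow(pk)); hi <- numeric(nrow(pk))
  for (i in seq_len(nrow(pk))) {
    half <- y[apex[i]] / 2
    l <- apex[i]; while (l > 1 && y[l - 1] >= half) l <- l - 1
    r <- apex[i]; while (r < length(y) && y[r + 1] >= half) r <- r + 1
    lo[i] <- max(mz[l] - spacing / 2, mz[apex[i]] - min_separation_da / 2)
    hi[i] <- min(mz[r] + spacing / 2, mz[apex[i]] + min_separation_da / 2)
  }
  # enforce disjoint windows: cut at the midpoint between adjacent apices
  if (nrow(pk) > 1) {
    for (i in seq_len(nrow(pk) - 1)) {
      if (hi[i] > lo[i + 1]) {
        mid <- (mz[apex[i]] + mz[apex[i + 1]]) / 2
        hi[i] <- min(hi[i], mid)
        lo[i + 1] <- max(lo[i + 1], mid + 1e-12)
      }
    }
  }
  snr <- if (noise > 0) pk$height / noise else rep(Inf, nrow(pk))
  feature_table(pk$mz, lo, hi, snr)
}

#' Distil a dataset into an image cube
#'
#' For each pixel and picked feature, sums the pixel's intensities within the
#' feature's integration window (area quantitation — robust to residual mass
#' error after recalibration). Centroid datasets are accepted: centroids
#' falling inside the window are summed.
#'
#' @param dataset an [msi_dataset()].
#' @param features a [feature_table()].
#' @return an [datacube()].
#' @export
extract_datacube <- function(dataset, features) {
  rng <- dataset$meta$mass_range
  tol <- if (dataset$mode == "profile") median(diff(dataset$mz)) else 0
  if (nrow(features) &&
      (min(features$lo) < rng[1] - tol - 1e-9 ||
       max(features$hi) > rng[2] + tol + 1e-9))
    abort("feature window outside the dataset mass range",
          "atlasmsi_validation_error")
  n_px <- nrow(dataset$coords)
  vals <- matrix(0, nrow = n_px, ncol = nrow(features))
  if (nrow(features)) {
    if (dataset$mode == "profile") {
      for (f in seq_len(nrow(features))) {
        rows <- which(dataset$mz >= features$lo[f] & dataset$mz <= features$hi[f])
        vals[, f] <- if (length(rows) == 1L) dataset$intensities[rows, ]
                     else colSums(dataset$intensities[rows, , drop = FALSE])
      }
    } else {
      for (p in seq_len(n_px)) {
        mzp <- dataset$mz[[p]]; ip <- dataset$intensities[[p]]
        for (f in seq_len(nrow(features)))
          vals[p, f] <- sum(ip[mzp >= features$lo[f] & mzp <= features$hi[f]])
      }
    }
  }
  datacube(dataset$coords, features, vals, meta = dataset$meta,
           provenance = sprintf("extract_datacube: %d features, window sums",
                                nrow(features)))
}

#' Variance-stabilizing transform
#'
#' Metabolite cubes get `log2(1 + c*x)` (default `c = 1`), damping the
#' mean-variance coupling of Poisson counts; peptide and protein cubes are
#' returned unchanged (the log transform was not applied to those classes),
#' with a provenance note. Strictly monotone, so pixel rank statistics are
#' preserved.
#'
#' @param cube an [datacube()].
#' @param molecular_class overrides the cube's class.
#' @param c scale inside the logarithm.
#' @param variant one of `"log2p1"`, `"log10p1"`, `"glog"`.
#' @return transformed cube.
#' @export
variance_stabilize <- function(cube, molecular_class = NULL, c = 1,
                               variant = c("log2p1", "log10p1", "glog")) {
  variant <- match.arg(variant)
  molecular_class <- molecular_class %||% cube$meta$molecular_class
  if (any(cube$values < 0, na.rm = TRUE))
    abort("variance stabilization requires nonnegative values",
          "atlasmsi_validation_error")
  if (molecular_class != "metabolite") {
    cube$provenance <- c(cube$provenance,
                         "variance_stabilize: skipped (non-metabolite class)")
    return(cube)
  }
  cube$values <- switch(variant,
    log2p1  = log2(1 + c * cube$values),
    log10p1 = log10(1 + c * cube$values),
    glog    = log2(c * cube$values + sqrt((c * cube$values)^2 + 1)))
  cube$provenance <- c(cube$provenance,
                       sprintf("variance_stabilize: %s, c=%g", variant, c))
  cube
}
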