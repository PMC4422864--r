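#' Preprocessing configuration
#'
#' Class presets follow the instrument-software settings used for each
#' molecular class: Gaussian smoothing width 0.02 Da with 2 cycles for
#' metabolites and peptides, width 2 Da with 4 cycles for proteins (lower
#' mass resolution in linear mode). The TopHat structuring-element width
#' defaults to 25x the smoothing width — wide enough to sit under unresolved
#' peak groups, narrow enough to follow curved baselines.
#'
#' @param molecular_class class whose presets to use.
#' @param gauss_width_da Gaussian kernel sigma in Da.
#' @param gauss_cycles number of smoothing passes.
#' @param tophat_window_da flat structuring-element width in Da.
#' @return list of class `preproc_config`.
#' @export
preproc_config <- function(molecular_class = "metabolite",
                           gauss_width_da = NULL, gauss_cycles = NULL,
                           tophat_window_da = NULL) {
  preset <- switch(molecular_class,
    metabolite = , peptide = list(width = 0.02, cycles = 2L),
    protein = list(width = 2, cycles = 4L),
    abort(sprintf("unknown molecular class '%s'", molecular_class),
          "atlasmsi_validation_error"))
  w <- gauss_width_da %||% preset$width
  cyc <- gauss_cycles %||% preset$cycles
  th <- tophat_window_da %||% (25 * w)
  if (w <= 0 || cyc < 1) abort("invalid smoothing parameters", "atlasmsi_validation_error")
  if (th <= w) abort("tophat window must exceed the smoothing width",
                     "atlasmsi_validation_error")
  structure(list(molecular_class = molecular_class, gauss_width_da = w,
                 gauss_cycles = as.integer(cyc), tophat_window_da = th),
            class = "preproc_config")
}

gauss_kernel <- function(sigma_pts, radius_sigmas = 6) {
  half <- max(1L, ceiling(radius_sigmas * sigma_pts))
  k <- dnorm(seq(-half, half), sd = sigma_pts)
  k / sum(k)
}

#' Gaussian smoothing of spectra
#'
#' Convolves each spectrum with a Gaussian kernel of sigma
#' `gauss_width_da`, repeated `gauss_cycles` times (equivalent to a single
#' pass at sigma*sqrt(cycles)). Total intensity is conserved away from the
#' spectrum ends.
#'
#' @param spectrum numeric vector, or a bins-by-pixels matrix to smooth
#'   column-wise.
#' @param mz the m/z grid the spectrum lives on (used for grid spacing).
#' @param config a [preproc_config()].
#' @return smoothed vector/matrix of the same shape.
#' @export
gauss_smooth <- function(spectrum, mz, config) {
  spacing <- median(diff(mz))
  if (spacing > config$gauss_width_da)
    abort("m/z grid coarser than the smoothing kernel", "atlasmsi_validation_error")
  k <- gauss_kernel(config$gauss_width_da / spacing)
  x <- if (is.matrix(spectrum)) spectrum else matrix(spectrum, ncol = 1)
  # normalized convolution: divide by the kernel mass inside the spectrum so
  # edges are not damped by the implicit zero padding
  denom <- .conv_cols(matrix(1, nrow(x), 1), k)[, 1]
  for (i in seq_len(config$gauss_cycles)) x <- .conv_cols(x, k) / denom
  if (is.matrix(spectrum)) x else x[, 1]
}

#' TopHat morphological baseline subtraction
#'
#' Subtracts the morphological opening (erosion then dilation with a flat
#' structuring element of width `tophat_window_da`) from each spectrum.
#' The result is nonnegative and pointwise no greater than the input.
#'
#' @inheritParams gauss_smooth
#' @return baseline-subtracted vector/matrix.
#' @export
tophat_baseline <- function(spectrum, mz, config) {
  spacing <- median(diff(mz))
  w <- as.integer(round(config$tophat_window_da / spacing))
  if (w %% 2L == 0L) w <- w + 1L
  if (w < 3L) abort("tophat window below 3 grid points", "atlasmsi_validation_error")
  n <- if (is.matrix(spectrum)) nrow(spectrum) else length(spectrum)
  if (w > n) abort("tophat window wider than the spectrum", "atlasmsi_validation_error")
  x <- if (is.matrix(spectrum)) spectrum else matrix(spectrum, ncol = 1)
  opened <- .dilate_cols(.erode_cols(x, w), w)
  out <- x - opened
  out[out < 0] <- 0  # guard against float round-off
  if (is.matrix(spectrum)) out else out[, 1]
}

#' Total-ion-count normalization
#'
#' Divides a spectrum by its summed intensity so that it sums to 1. A
#' zero-TIC spectrum cannot be normalized and raises a condition of class
#' `atlasmsi_zero_tic`; dataset-level preprocessing catches it and drops the
#' pixel (flagged in provenance) rather than zero-filling.
#'
#' @param spectrum numeric vector with at least one positive value.
#' @return normalized vector summing to 1.
#' @export
tic_normalize <- function(spectrum) {
  tic <- sum(spectrum)
  if (tic <= 0)
    abort("zero-TIC spectrum: pixel must be flagged and excluded",
          "atlasmsi_zero_tic")
  spectrum / tic
}

#' Preprocess every pixel of a dataset
#'
#' Applies, in order: Gaussian smoothing, TopHat baseline subtraction and
#' (optionally) TIC normalization. Zero-TIC pixels are removed from the pixel
#' list and recorded.
#'
#' @param dataset a profile-mode [msi_dataset()].
#' @param config a [preproc_config()]; defaults to the dataset's class preset.
#' @param tic apply TIC normalization after baseline subtraction?
#' @return the preprocessed dataset; dropped pixel coordinates (if any) are in
#'   `attr(, "dropped_pixels")`.
#' @export
preprocess_dataset <- function(dataset, config = NULL, tic = TRUE) {
  if (dataset$mode != "profile")
    abort("preprocessing operates on profile-mode data", "atlasmsi_validation_error")
  config <- config %||% preproc_config(dataset$meta$molecular_class)
  x <- gauss_smooth(dataset$intensities, dataset$mz, config)
  x <- tophat_baseline(x, dataset$mz, config)
  dropped <- integer(0)
  if (tic) {
    tics <- colSums(x)
    dropped <- which(tics <= 0)
    if (length(dropped)) {
      x <- x[, -dropped, drop = FALSE]
      tics <- tics[-dropped]
    }
    x <- sweep(x, 2, tics, "/")
  }
  coords <- if (length(dropped)) dataset$coords[-dropped, , drop = FALSE]
            else dataset$coords
  out <- msi_dataset(coords, dataset$mz, x, dataset$meta)
  attr(out, "dropped_pixels") <- if (length(dropped))
    dataset$coords[dropped, , drop = FALSE] else NULL
  out
}

# local maxima of a spectrum above an SNR threshold (MAD-based noise)
find_local_maxima <- function(mz, y, snr_min = 3, min_separation_da = 0) {
  n <- length(y)
  if (n < 3) return(data.frame(mz = numeric(), height = numeric()))
  is_max <- y[2:(n - 1)] > y[1:(n - 2)] & y[2:(n - 1)] >= y[3:n] & y[2:(n - 1)] > 0
  idx <- which(is_max) + 1L
  detrended <- y - runmed(y, min(n - (1 - n %% 2), 201))
  noise <- mad(detrended)
  if (noise > 0) idx <- idx[y[idx] / noise >= snr_min]
  if (min_separation_da > 0 && length(idx) > 1) {
    keep <- logical(length(idx))
    for (o in order(y[idx], decreasing = TRUE)) {
      if (!any(keep & abs(mz[idx] - mz[idx[o]]) < min_separation_da))
        keep[o] <- TRUE
    }
    idx <- sort(idx[keep])
  }
  data.frame(mz = mz[idx], height = y[idx], index = idx)
}

#' Cross-sample m/z alignment on common peaks
#'
#' Peak-picks each sample's mean spectrum, clusters peaks across samples
#' within `match_tol_da`, and keeps clusters present in at least
#' `presence_fraction` of the samples as anchors (when two sample peaks fall
#' in one cluster, the more intense one is kept). Each sample's linear
#' (slope, offset) recalibration is fitted by least squares from its observed
#' anchor positions to the cluster medians, applied to the m/z axis, and the
#' intensities are resampled back onto the shared grid.
#'
#' @param datasets list of profile-mode [msi_dataset()]s of one class on a
#'   common grid.
#' @param presence_fraction minimum fraction of samples a cluster must appear
#'   in to become an anchor (default 0.85).
#' @param match_tol_da peak-matching tolerance; class defaults 0.1 Da
#'   (metabolite), 0.3 Da (peptide), 2 Da (protein).
#' @param snr_min peak-picking SNR threshold on the mean spectra.
#' @param rel_height_min anchor candidates must reach this fraction of the
#'   tallest mean-spectrum peak; mean spectra of Poisson data carry dense
#'   low-amplitude ripple maxima that would otherwise form spurious
#'   high-presence clusters and corrupt the linear fit.
#' @return list with `model` (per-sample coefficients, anchor positions,
#'   presence) and `datasets` (recalibrated).
#' @export
align_spectra <- function(datasets, presence_fraction = 0.85,
                          match_tol_da = NULL, snr_min = 3,
                          rel_height_min = 0.05) {
  if (length(datasets) < 2)
    abort("alignment needs at least two datasets", "atlasmsi_validation_error")
  cls <- unique(vapply(datasets, function(d) d$meta$molecular_class, character(1)))
  if (length(cls) != 1)
    abort("alignment requires a single molecular class", "atlasmsi_validation_error")
  match_tol_da <- match_tol_da %||%
    switch(cls, metabolite = 0.1, peptide = 0.3, protein = 2)
  grid <- datasets[[1]]$mz

  peaks <- lapply(datasets, function(d) {
    m <- rowMeans(d$intensities)
    pk <- find_local_maxima(d$mz, m, snr_min = snr_min)
    pk[pk$height >= rel_height_min * max(pk$height, 0), , drop = FALSE]
  })
  all_pk <- do.call(rbind, Map(cbind, peaks,
                               sample = seq_along(peaks)))
  if (is.null(all_pk) || nrow(all_pk) == 0)
    abort("no peaks found for alignment", "atlasmsi_alignment_error")
  all_pk <- all_pk[order(all_pk$mz), ]
  # greedy clustering: break where the gap exceeds the tolerance
  cl <- cumsum(c(1, diff(all_pk$mz) > match_tol_da))
  anchors <- list()
  for (g in split(all_pk, cl)) {
    # one peak per sample: keep the most intense
    g <- g[order(-g$height), ]
    g <- g[!duplicated(g$sample), ]
    if (nrow(g) / length(datasets) >= presence_fraction)
      anchors[[length(anchors) + 1L]] <- g
  }
  if (length(anchors) < 3)
    abort(sprintf(
      "alignment refused: only %d anchor peak(s) found (>=3 needed for a linear recalibration)",
      length(anchors)), "atlasmsi_alignment_error")
  ref <- vapply(anchors, function(g) median(g$mz), numeric(1))

  coefs <- matrix(NA_real_, nrow = length(datasets), ncol = 2,
                  dimnames = list(NULL, c("slope", "offset")))
  out <- vector("list", length(datasets))
  for (s in seq_along(datasets)) {
    obs <- vapply(anchors, function(g) {
      r <- g$mz[g$sample == s]
      if (length(r)) r[1] else NA_real_
    }, numeric(1))
    ok <- !is.na(obs)
    fit <- if (sum(ok) >= 2) coef(lm(ref[ok] ~ obs[ok])) else c(0, 1)
    coefs[s, ] <- c(fit[2], fit[1])
    new_axis <- coefs[s, 1] * datasets[[s]]$mz + coefs[s, 2]
    out[[s]] <- resample_dataset(datasets[[s]], new_axis, grid)
  }
  list(
    model = list(anchor_mzs = ref, presence_fraction = presence_fraction,
                 match_tol_da = match_tol_da, coefs = coefs),
    datasets = out
  )
}

# resample a dataset whose true axis is `axis` onto `grid` (linear interp.)
resample_dataset <- function(dataset, axis, grid) {
  idx <- findInterval(grid, axis)
  idx[idx < 1L] <- 1L
  idx[idx >= length(axis)] <- length(axis) - 1L
  frac <- (grid - axis[idx]) / (axis[idx + 1L] - axis[idx])
  frac[frac < 0] <- 0; frac[frac > 1] <- 1
  x <- dataset$intensities
  newx <- x[idx, , drop = FALSE] * (1 - frac) + x[idx + 1L, , drop = FALSE] * frac
  msi_dataset(dataset$coords, grid, newx, dataset$meta)
}

#' Serialize an alignment model to JSON (provenance)
#'
#' @param model the `model` element returned by [align_spectra()].
#' @param path output JSON path.
#' @export
write_alignment_model <- function(model, path) {
  jsonlite::write_json(
    list(anchor_mzs = model$anchor_mzs,
         presence_fraction = model$presence_fraction,
         match_tol_da = model$match_tol_da,
         coefs = as.data.frame(model$coefs)),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
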