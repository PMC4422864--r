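# Intensity-based registration of a section ("moving") to an atlas frame
# ("fixed"): a multi-resolution affine stage minimizing the mean squared
# intensity difference, followed by a cubic-B-spline refinement optimized
# with L-BFGS-B and an analytic gradient.

block_downsample <- function(img, f) {
  if (f == 1) return(img)
  h <- floor(nrow(img) / f) * f
  w <- floor(ncol(img) / f) * f
  x <- img[seq_len(h), seq_len(w), drop = FALSE]
  # average f x f blocks
  x <- array(x, dim = c(f, h / f, f, w / f))
  apply(x, c(2, 4), mean)
}

image_gradients <- function(img) {
  h <- nrow(img); w <- ncol(img)
  gx <- (img[, c(2:w, w)] - img[, c(1, 1:(w - 1))]) / 2
  gy <- (img[c(2:h, h), ] - img[c(1, 1:(h - 1)), ]) / 2
  list(gx = gx, gy = gy)
}

affine_params_to_transform <- function(p, center) {
  affine_transform(translate_px = p[1:2], rotation_deg = p[3],
                   scale_x = exp(p[4]), scale_y = exp(p[5]), shear = p[6],
                   center = center)
}

mse_metric <- function(moving, fixed, transform) {
  pts <- grid_points(nrow(fixed), ncol(fixed))
  mapped <- transform_points(transform, pts)
  mv <- .bilinear_sample(moving, mapped[, 1], mapped[, 2])
  ok <- !is.na(mv)
  if (mean(ok) < 0.3) return(Inf)
  mean((mv[ok] - fixed[ok])^2)
}

#' Affine registration (translation, rotation, scaling, shearing)
#'
#' Minimizes the mean squared intensity difference between the fixed image
#' and the transformed moving image with Nelder-Mead over a 3-level
#' multi-resolution pyramid. Translation is initialized from the intensity
#' centroid difference, which gives a basin wide enough for the
#' +/-10 px / +/-10 degree / +/-10% deformations the phantom generator
#' produces.
#'
#' @param moving,fixed grayscale matrices on the same pixel size.
#' @param maxit Nelder-Mead iteration cap per pyramid level.
#' @return list with `transform` (a [section_transform()]) and `report`
#'   (metric before/after, converged flag).
#' @export
register_affine <- function(moving, fixed, maxit = 400) {
  if (!all(is.finite(moving)) || !all(is.finite(fixed)))
    abort("non-finite pixels", "atlasmsi_validation_error")
  centroid <- function(img) {
    w <- pmax(img - median(img), 0)
    s <- sum(w)
    if (s == 0) return(c((ncol(img) - 1) / 2, (nrow(img) - 1) / 2))
    c(sum(w * col(img) - w) / s, sum(w * row(img) - w) / s)
  }
  init_t <- centroid(moving) - centroid(fixed)
  p <- c(init_t[1], init_t[2], 0, 0, 0, 0)

  factors <- c(4, 2, 1)
  factors <- factors[pmin(nrow(fixed), ncol(fixed)) / factors >= 12]
  convergence <- 0
  for (f in factors) {
    mv <- block_downsample(moving, f)
    fx <- block_downsample(fixed, f)
    ctr <- c((ncol(fx) - 1) / 2, (nrow(fx) - 1) / 2)
    obj <- function(q) {
      tf <- affine_params_to_transform(q, ctr)
      m <- mse_metric(mv, fx, tf)
      if (!is.finite(m)) 1e6 else m
    }
    p_level <- c(p[1:2] / f, p[3:6])
    fit <- optim(p_level, obj, method = "Nelder-Mead",
                 control = list(maxit = maxit,
                                parscale = c(1, 1, 1, 0.05, 0.05, 0.05)))
    convergence <- fit$convergence
    p <- c(fit$par[1:2] * f, fit$par[3:6])
  }
  ctr <- c((ncol(fixed) - 1) / 2, (nrow(fixed) - 1) / 2)
  tf <- affine_params_to_transform(p, ctr)
  report <- list(
    metric_before = mse_metric(moving, fixed, section_transform(center = ctr)),
    metric_after = mse_metric(moving, fixed, tf),
    converged = convergence == 0
  )
  list(transform = tf, report = report)
}

#' B-spline refinement after affine registration
#'
#' Adds a cubic-B-spline displacement field (control spacing defaulting to
#' 1/8 of the image extent) on top of an affine initialization and minimizes
#' mean squared difference plus a small ridge penalty on the displacements
#' with L-BFGS-B and an analytic gradient. Starting from zero displacement
#' guarantees the final metric does not exceed the affine-only metric.
#'
#' @param moving,fixed grayscale matrices.
#' @param init affine-stage [section_transform()].
#' @param grid_spacing_px control-point spacing; default `extent / 8`.
#' @param lambda ridge weight on control displacements.
#' @param maxit L-BFGS-B iteration cap.
#' @param landmarks optional data.frame with `fixed_x, fixed_y, moving_x,
#'   moving_y` for TRE reporting.
#' @return list with `transform` (affine + B-spline) and `report`.
#' @export
register_bspline <- function(moving, fixed, init, grid_spacing_px = NULL,
                             lambda = 1e-3, maxit = 80, landmarks = NULL) {
  h <- nrow(fixed); w <- ncol(fixed)
  sx <- grid_spacing_px %||% ((w - 1) / 8)
  sy <- if (length(grid_spacing_px) == 2) grid_spacing_px[2] else
    grid_spacing_px %||% ((h - 1) / 8)
  if (sx >= w || sy >= h)
    abort("B-spline grid coarser than the image", "atlasmsi_validation_error")
  nx <- ceiling((w - 1) / sx) + 3L
  ny <- ceiling((h - 1) / sy) + 3L
  field <- bspline_field(nx, ny, c(sx, sy))

  pts <- grid_points(h, w)
  base <- transform_points(init, pts)  # affine part, fixed per iteration
  B <- bspline_basis(pts, field)
  fvals <- as.vector(fixed)
  gr <- image_gradients(moving)
  K <- nx * ny

  metric_affine <- mse_metric(moving, fixed, init)

  objective <- function(d) {
    dx <- B %*% d[1:K]; dy <- B %*% d[(K + 1):(2 * K)]
    px <- base[, 1] + dx; py <- base[, 2] + dy
    mv <- .bilinear_sample(moving, px, py)
    ok <- !is.na(mv)
    r <- mv - fvals
    r[!ok] <- 0
    nok <- max(sum(ok), 1)
    val <- sum(r^2) / nok + lambda * mean(d^2)
    gx <- .bilinear_sample(gr$gx, px, py); gx[!ok] <- 0
    gy <- .bilinear_sample(gr$gy, px, py); gy[!ok] <- 0
    grad <- c(crossprod(B, 2 * r * gx) / nok,
              crossprod(B, 2 * r * gy) / nok) +
      2 * lambda * d / (2 * K)
    attr(val, "gradient") <- grad
    val
  }
  fn <- function(d) as.numeric(objective(d))
  grfun <- function(d) attr(objective(d), "gradient")
  fit <- optim(rep(0, 2 * K), fn, grfun, method = "L-BFGS-B",
               control = list(maxit = maxit))
  field$dx <- matrix(fit$par[1:K], ny, nx, byrow = TRUE)
  field$dy <- matrix(fit$par[(K + 1):(2 * K)], ny, nx, byrow = TRUE)
  tf <- section_transform(init$affine, init$center, field)
  report <- list(metric_before = metric_affine,
                 metric_after = mse_metric(moving, fixed, tf),
                 converged = fit$convergence %in% c(0, 1))
  if (!is.null(landmarks)) {
    tre <- evaluate_registration(tf, landmarks)
    report$landmark_TRE_px <- tre$mean_px
  }
  list(transform = tf, report = report)
}

# longest horizontal run of TRUE in a logical mask
cord_length <- function(mask) {
  best <- 0L
  for (r in seq_len(nrow(mask))) {
    x <- mask[r, ]
    if (!any(x)) next
    runs <- rle(x)
    best <- max(best, max(runs$lengths[runs$values]))
  }
  best
}

#' Select the matching atlas section by hippocampus cord length
#'
#' The cord length is the longest run of hippocampus pixels along any single
#' row. The atlas section whose cord length is closest to the query
#' section's is returned; ties go to the more anterior section (larger
#' `ap_mm`) and are logged.
#'
#' @param section_labels integer label map of the section (or a logical
#'   hippocampus mask).
#' @param atlas list of [atlas_section()]s.
#' @param hippocampus_label region name looked up in each legend.
#' @return index into `atlas`.
#' @export
select_atlas_section <- function(section_labels, atlas,
                                 hippocampus_label = "hippocampus") {
  if (is.logical(section_labels)) {
    mask <- section_labels
  } else {
    lab <- as.integer(names(atlas[[1]]$legend)[
      atlas[[1]]$legend == hippocampus_label])
    mask <- section_labels == lab
  }
  if (!any(mask)) abort("empty hippocampus mask", "atlasmsi_validation_error")
  q <- cord_length(mask)
  cords <- vapply(atlas, function(a) {
    lab <- as.integer(names(a$legend)[a$legend == hippocampus_label])
    cord_length(a$labels == lab)
  }, integer(1))
  d <- abs(cords - q)
  cand <- which(d == min(d))
  if (length(cand) > 1) {
    ap <- vapply(atlas[cand], function(a) a$ap_mm, numeric(1))
    message(sprintf("atlas section tie (%s); choosing the more anterior",
                    paste(cand, collapse = ", ")))
    cand <- cand[which.max(ap)]
  }
  cand[1]
}

#' Landmark target registration error
#'
#' Maps the fixed-frame landmarks through the transform and measures the
#' Euclidean distance to their true moving-frame positions, in px and in
#' micrometres at the given raster pitch.
#'
#' @param transform a [section_transform()].
#' @param landmark_pairs data.frame with columns `fixed_x, fixed_y,
#'   moving_x, moving_y` (at least 3 rows).
#' @param raster_um pixel pitch in micrometres.
#' @return list with `mean_px`, `max_px`, `mean_um`, `max_um`, `n`.
#' @export
evaluate_registration <- function(transform, landmark_pairs, raster_um = 100) {
  if (nrow(landmark_pairs) < 3)
    abort("need at least 3 landmark pairs", "atlasmsi_validation_error")
  mapped <- transform_points(transform,
                             cbind(landmark_pairs$fixed_x, landmark_pairs$fixed_y))
  err <- sqrt((mapped[, 1] - landmark_pairs$moving_x)^2 +
              (mapped[, 2] - landmark_pairs$moving_y)^2)
  list(mean_px = mean(err), max_px = max(err),
       mean_um = mean(err) * raster_um, max_um = max(err) * raster_um,
       n = nrow(landmark_pairs))
}
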