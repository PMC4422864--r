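# Section-to-atlas geometry. A section_transform maps FIXED (atlas) frame
# coordinates to MOVING (section) frame coordinates — the resampling
# convention — as
#   T(p) = M (p - center) + center + t + D(p)
# with M a 2x2 (rotation/scale/shear), t a translation and D(p) a cubic
# B-spline displacement field evaluated on the fixed frame. Coordinates are
# 0-based (x = column, y = row).

#' Build a section transform
#'
#' @param affine 2x3 matrix `[M | t]`.
#' @param center rotation center `(x, y)` in px.
#' @param bspline optional B-spline displacement field from
#'   [bspline_field()].
#' @return object of class `section_transform`.
#' @export
section_transform <- function(affine = cbind(diag(2), c(0, 0)),
                              center = c(0, 0), bspline = NULL) {
  if (!all(dim(affine) == c(2, 3)))
    abort("affine must be 2x3", "atlasmsi_validation_error")
  if (abs(det(affine[, 1:2])) < 1e-12)
    abort("affine must be invertible", "atlasmsi_validation_error")
  if (!is.null(bspline) && !all(is.finite(c(bspline$dx, bspline$dy))))
    abort("B-spline displacements must be finite", "atlasmsi_validation_error")
  structure(list(affine = affine, center = center, bspline = bspline),
            class = "section_transform")
}

#' @rdname section_transform
#' @param translate_px translation `(tx, ty)` in px.
#' @param rotation_deg rotation angle (degrees, about `center`).
#' @param scale_x,scale_y axis scale factors.
#' @param shear shear coefficient (x displaced proportionally to y).
#' @export
affine_transform <- function(translate_px = c(0, 0), rotation_deg = 0,
                             scale_x = 1, scale_y = 1, shear = 0,
                             center = c(0, 0), bspline = NULL) {
  th <- rotation_deg * pi / 180
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  S <- matrix(c(scale_x, 0, shear, scale_y), 2, 2)
  section_transform(cbind(R %*% S, translate_px), center = center,
                    bspline = bspline)
}

#' Cubic B-spline displacement field on a control grid
#'
#' Control point `(i, j)` (0-based) sits at `((i - 1) * spacing_x,
#' (j - 1) * spacing_y)`, so the grid extends one spacing beyond the image on
#' every side as cubic B-splines require.
#'
#' @param nx,ny control grid size (at least 4 each).
#' @param spacing control point spacing `(sx, sy)` in px.
#' @param dx,dy ny-by-nx displacement matrices (px); default zero.
#' @export
bspline_field <- function(nx, ny, spacing, dx = NULL, dy = NULL) {
  if (nx < 4 || ny < 4)
    abort("B-spline grid needs at least 4x4 control points",
          "atlasmsi_validation_error")
  list(nx = nx, ny = ny, spacing = spacing,
       dx = dx %||% matrix(0, ny, nx), dy = dy %||% matrix(0, ny, nx))
}

# cubic B-spline weights for fractional offsets u in [0,1)
bspline_w <- function(u) {
  cbind((1 - u)^3 / 6,
        (3 * u^3 - 6 * u^2 + 4) / 6,
        (-3 * u^3 + 3 * u^2 + 3 * u + 1) / 6,
        u^3 / 6)
}

# dense basis matrix: n points x (nx*ny) control weights
bspline_basis <- function(pts, field) {
  n <- nrow(pts)
  tx <- pts[, 1] / field$spacing[1]
  ty <- pts[, 2] / field$spacing[2]
  ix <- pmin(pmax(floor(tx), 0), field$nx - 4)
  iy <- pmin(pmax(floor(ty), 0), field$ny - 4)
  wx <- bspline_w(tx - ix)
  wy <- bspline_w(ty - iy)
  B <- matrix(0, n, field$nx * field$ny)
  rows <- seq_len(n)
  for (b in 0:3) {
    for (a in 0:3) {
      col <- (iy + b) * field$nx + (ix + a) + 1L
      B[cbind(rows, col)] <- B[cbind(rows, col)] + wx[, a + 1] * wy[, b + 1]
    }
  }
  B
}

bspline_displacement <- function(pts, field, basis = NULL) {
  B <- basis %||% bspline_basis(pts, field)
  cbind(B %*% as.vector(t(field$dx)), B %*% as.vector(t(field$dy)))
}

#' Apply a section transform to points
#'
#' @param transform a [section_transform()].
#' @param pts n-by-2 matrix of fixed-frame `(x, y)` coordinates.
#' @return n-by-2 matrix of moving-frame coordinates.
#' @export
transform_points <- function(transform, pts) {
  pts <- matrix(as.numeric(pts), ncol = 2)
  M <- transform$affine[, 1:2]; t <- transform$affine[, 3]
  ctr <- transform$center
  out <- sweep(sweep(pts, 2, ctr) %*% t(M), 2, ctr + t, "+")
  if (!is.null(transform$bspline))
    out <- out + bspline_displacement(pts, transform$bspline)
  out
}

# numerically invert: find fixed-frame p with T(p) = q (moving-frame)
invert_transform_points <- function(transform, q, iters = 12, tol = 1e-6) {
  q <- matrix(as.numeric(q), ncol = 2)
  Minv <- solve(transform$affine[, 1:2])
  p <- sweep(sweep(q, 2, transform$center + transform$affine[, 3]) %*% t(Minv),
             2, transform$center, "+")
  for (i in seq_len(iters)) {
    r <- transform_points(transform, p) - q
    if (max(abs(r)) < tol) break
    p <- p - r %*% t(Minv)
  }
  p
}

grid_points <- function(h, w) {
  cbind(x = rep(seq_len(w) - 1, each = h), y = rep(seq_len(h) - 1, times = w))
}

#' Resample an image, label map or datacube through a section transform
#'
#' Every target (atlas-frame) pixel is mapped through the transform and the
#' moving object is sampled there: linear interpolation for images and cube
#' channels, nearest neighbour for label maps. Out-of-frame pixels become
#' `NA` (missing), never zero.
#'
#' @param obj numeric matrix (image), integer matrix (label map, pass
#'   `labels = TRUE`) or [datacube()].
#' @param transform a [section_transform()].
#' @param target_shape `(h, w)` of the atlas frame.
#' @param labels treat a matrix as an integer label map?
#' @return resampled object of the same kind.
#' @export
apply_transform <- function(obj, transform, target_shape, labels = FALSE) {
  h <- target_shape[1]; w <- target_shape[2]
  pts <- grid_points(h, w)
  mapped <- transform_points(transform, pts)
  if (inherits(obj, "msi_datacube")) {
    fs <- obj$meta$frame_shape %||% c(max(obj$coords[, 2]) + 1L,
                                      max(obj$coords[, 1]) + 1L)
    img_h <- fs[1]; img_w <- fs[2]
    vals <- matrix(NA_real_, nrow = h * w, ncol = ncol(obj$values))
    chan <- matrix(NA_real_, img_h, img_w)
    idx <- cbind(obj$coords[, 2] + 1L, obj$coords[, 1] + 1L)
    for (f in seq_len(ncol(obj$values))) {
      chan[] <- NA_real_
      chan[idx] <- obj$values[, f]
      vals[, f] <- .bilinear_sample(chan, mapped[, 1], mapped[, 2])
    }
    out <- datacube(pts, obj$features, vals, meta = obj$meta,
                    transform_applied = TRUE,
                    provenance = c(obj$provenance,
                                   "apply_transform: resampled to atlas grid"))
    return(out)
  }
  if (labels || is.integer(obj)) {
    storage.mode(obj) <- "integer"
    v <- .nearest_sample(obj, mapped[, 1], mapped[, 2])
    return(matrix(v, h, w)[])
  }
  if (!all(is.finite(obj)))
    abort("non-finite pixels in image", "atlasmsi_validation_error")
  matrix(.bilinear_sample(obj, mapped[, 1], mapped[, 2]), h, w)
}

#' Serialize / load a section transform (JSON)
#'
#' @param transform a [section_transform()].
#' @param path JSON file path.
#' @export
write_transform <- function(transform, path) {
  jsonlite::write_json(unclass_transform(transform), path,
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

unclass_transform <- function(transform) {
  list(affine = as.data.frame(transform$affine), center = transform$center,
       bspline = if (!is.null(transform$bspline)) list(
         nx = transform$bspline$nx, ny = transform$bspline$ny,
         spacing = transform$bspline$spacing,
         dx = as.data.frame(transform$bspline$dx),
         dy = as.data.frame(transform$bspline$dy)))
}

#' @rdname write_transform
#' @export
read_transform <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  transform_from_list(j)
}

transform_from_list <- function(j) {
  bs <- NULL
  if (!is.null(j$bspline))
    bs <- bspline_field(j$bspline$nx, j$bspline$ny, j$bspline$spacing,
                        dx = as.matrix(j$bspline$dx),
                        dy = as.matrix(j$bspline$dy))
  section_transform(as.matrix(j$affine), unlist(j$center), bs)
}
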