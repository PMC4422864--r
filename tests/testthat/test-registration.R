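# registration fixtures are generated phantoms; moderate deformations here,
# the full +/-10 px / +/-10 deg / +/-10% envelope runs in test-acceptance.R

test_that("atlas section selection follows the hippocampus cord length", {
  at <- generate_atlas(3, seed = 6)
  # a section identical to atlas k selects k
  for (k in 1:3)
    expect_identical(select_atlas_section(at[[k]]$labels, at), k)
  # a deformed phantom from the middle section still selects it
  s <- generate_section(at[[2]], deform_spec(rotation_deg = 4,
                                             translate_px = c(3, -2),
                                             bspline_amplitude_px = 1.5,
                                             seed = 3))
  expect_identical(select_atlas_section(s$labels, at), 2L)
  # ties go to the more anterior section and are logged
  twin <- list(at[[1]], at[[1]], at[[2]])
  twin[[1]]$ap_mm <- -1.9; twin[[2]]$ap_mm <- -1.2
  expect_message(k <- select_atlas_section(at[[1]]$labels, twin), "anterior")
  expect_identical(k, 2L)
  empty <- at[[1]]$labels; empty[empty == 3L] <- 5L
  expect_error(select_atlas_section(empty, at),
               class = "atlasmsi_validation_error")
})

test_that("affine registration of an image onto itself is the identity", {
  at <- generate_atlas(1, seed = 7)
  img <- at[[1]]$image
  res <- register_affine(img, img)
  expect_lt(max(abs(res$transform$affine[, 1:2] - diag(2))), 1e-3)
  expect_lt(max(abs(res$transform$affine[, 3])), 1e-3)
  expect_lt(res$report$metric_after, 1e-8)
  expect_true(res$report$metric_after <= res$report$metric_before)
})

test_that("affine registration recovers planted translation/rotation/scale", {
  at <- generate_atlas(1, seed = 8)
  # known translation (5, -3) px within 0.5 px
  s <- generate_section(at[[1]], deform_spec(translate_px = c(5, -3)))
  res <- register_affine(s$image, at[[1]]$image)
  expect_lt(abs(res$transform$affine[1, 3] - 5), 0.5)
  expect_lt(abs(res$transform$affine[2, 3] + 3), 0.5)
  # rotation 5 deg + scale 1.05 within 0.5 deg / 0.01
  s2 <- generate_section(at[[1]], deform_spec(rotation_deg = 5,
                                              scale_x = 1.05, scale_y = 1.05))
  res2 <- register_affine(s2$image, at[[1]]$image)
  M <- res2$transform$affine[, 1:2]
  expect_lt(abs(atan2(M[2, 1], M[1, 1]) * 180 / pi - 5), 0.5)
  expect_lt(abs(sqrt(sum(M[, 1]^2)) - 1.05), 0.01)
  # contraction on the metric
  expect_true(res2$report$metric_after <= res2$report$metric_before)
  expect_error(register_affine(matrix(c(NA, 1, 2, 3), 2), at[[1]]$image),
               class = "atlasmsi_validation_error")
})

test_that("B-spline refinement recovers local deformations", {
  at <- generate_atlas(1, seed = 9)
  img <- at[[1]]$image
  # null case: no local deformation in truth -> displacements stay < 0.5 px
  s0 <- generate_section(at[[1]], deform_spec(translate_px = c(2, 1),
                                              rotation_deg = 2))
  aff0 <- register_affine(s0$image, img)
  bsp0 <- register_bspline(s0$image, img, aff0$transform)
  disp <- atlasmsi:::bspline_displacement(
    atlasmsi:::grid_points(nrow(img), ncol(img)), bsp0$transform$bspline)
  expect_lt(max(abs(disp)), 0.5)
  expect_true(bsp0$report$metric_after <= bsp0$report$metric_before)

  # 3 px planted B-spline amplitude -> mean landmark TRE < 1 px
  s3 <- generate_section(at[[1]], deform_spec(translate_px = c(2, -1),
                                              rotation_deg = 3,
                                              bspline_amplitude_px = 3,
                                              seed = 13))
  aff3 <- register_affine(s3$image, img)
  bsp3 <- register_bspline(s3$image, img, aff3$transform,
                           landmarks = s3$landmarks)
  expect_lt(bsp3$report$landmark_TRE_px, 1)

  # identical images with identity init give ~zero metric
  ident <- register_bspline(img, img, section_transform())
  expect_lt(ident$report$metric_after, 1e-6)
  expect_error(register_bspline(img, img, section_transform(),
                                grid_spacing_px = 10 * ncol(img)),
               class = "atlasmsi_validation_error")
})

test_that("apply_transform resamples images, labels and cubes faithfully", {
  at <- generate_atlas(1, seed = 10)
  img <- at[[1]]$image
  shape <- dim(img)
  ident <- section_transform()
  expect_equal(apply_transform(img, ident, shape), img)
  expect_identical(apply_transform(at[[1]]$labels, ident, shape,
                                   labels = TRUE), at[[1]]$labels)

  # fractional translation of a one-hot channel conserves mass within 1%
  hot <- matrix(0, shape[1], shape[2])
  hot[20:25, 30:36] <- 1
  tr <- affine_transform(translate_px = c(3.5, -2.25))
  shifted <- apply_transform(hot, tr, shape)
  expect_equal(sum(shifted, na.rm = TRUE), sum(hot), tolerance = 0.01)

  # a rotated label map contains only labels present in the input
  rot <- affine_transform(rotation_deg = 45,
                          center = (rev(shape) - 1) / 2)
  lab45 <- apply_transform(at[[1]]$labels, rot, shape, labels = TRUE)
  expect_true(all(na.omit(unique(as.vector(lab45))) %in%
                    unique(as.vector(at[[1]]$labels))))

  # cube channels resample like images, with NA (not 0) off-frame
  d <- tiny_dataset(c(103), n_pixels = 4)
  d$coords <- cbind(x = c(0L, 1L, 0L, 1L), y = c(0L, 0L, 1L, 1L))
  d$meta$frame_shape <- c(2L, 2L)
  cube <- extract_datacube(d, feature_table(103, 102.5, 103.5))
  out <- apply_transform(cube, affine_transform(translate_px = c(5, 5)),
                         c(2, 2))
  expect_true(all(is.na(out$values)))
  expect_true(out$transform_applied)
})

test_that("landmark TRE is measured in px and um", {
  lm <- data.frame(fixed_x = c(10, 20, 30), fixed_y = c(5, 15, 25),
                   moving_x = c(10, 20, 30), moving_y = c(5, 15, 25))
  perfect <- evaluate_registration(section_transform(), lm)
  expect_equal(perfect$mean_px, 0)
  off <- lm; off$moving_x <- off$moving_x + 1
  tre <- evaluate_registration(section_transform(), off)
  expect_equal(tre$mean_px, 1)
  expect_equal(tre$mean_um, 100)  # 100 um raster
  expect_equal(tre$max_px, 1)
  expect_error(evaluate_registration(section_transform(), lm[1:2, ]),
               class = "atlasmsi_validation_error")
})
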