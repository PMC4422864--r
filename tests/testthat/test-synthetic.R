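test_that("atlas sections have strictly increasing hippocampus cord lengths", {
  at <- generate_atlas(3, seed = 1)
  truth <- attr(at, "truth")
  cords <- vapply(truth, `[[`, numeric(1), "cord_length")
  expect_length(unique(cords), 3L)
  expect_true(all(diff(cords) > 0))
  # cord length equals an independent row-run scan of the mask
  for (k in 1:3)
    expect_identical(cord_brute(at[[k]]$labels == 3L), as.numeric(cords[k]))
  # every section exposes >= 8 landmarks and the four ROIs
  for (k in 1:3) {
    expect_gte(nrow(truth[[k]]$landmarks), 8L)
    expect_setequal(unique(as.vector(at[[k]]$labels)), 0:5)
  }
  expect_error(generate_atlas(2, shape = c(20, 30)),
               class = "atlasmsi_validation_error")
})

test_that("atlas generation is deterministic in the seed", {
  a <- generate_atlas(2, seed = 9)
  b <- generate_atlas(2, seed = 9)
  expect_identical(a[[1]]$labels, b[[1]]$labels)
  expect_identical(a[[2]]$image, b[[2]]$image)
  c <- generate_atlas(2, seed = 10)
  expect_false(identical(a[[1]]$image, c[[1]]$image))
})

test_that("generate_section honors the deformation spec", {
  at <- generate_atlas(1, seed = 2)
  # identity deformation reproduces the atlas image
  s0 <- generate_section(at[[1]], deform_spec())
  expect_equal(s0$image, at[[1]]$image, tolerance = 1e-8)
  expect_identical(s0$labels, at[[1]]$labels)

  # pure translation displaces every landmark by exactly (5, -3)
  s1 <- generate_section(at[[1]], deform_spec(translate_px = c(5, -3)))
  expect_equal(s1$landmarks$moving_x - s1$landmarks$fixed_x,
               rep(5, nrow(s1$landmarks)))
  expect_equal(s1$landmarks$moving_y - s1$landmarks$fixed_y,
               rep(-3, nrow(s1$landmarks)))

  # composite affine + B-spline: landmark pairs match applying the
  # serialized transform to the atlas-side landmarks within 1e-6 px
  d <- deform_spec(rotation_deg = 4, scale_x = 1.03, scale_y = 0.98,
                   shear = 0.02, translate_px = c(3, 2),
                   bspline_amplitude_px = 2, seed = 21)
  s2 <- generate_section(at[[1]], d)
  path <- file.path(withr::local_tempdir(), "tf.json")
  write_transform(s2$transform, path)
  tf <- read_transform(path)
  mapped <- transform_points(tf, cbind(s2$landmarks$fixed_x,
                                       s2$landmarks$fixed_y))
  expect_lt(max(abs(mapped[, 1] - s2$landmarks$moving_x)), 1e-6)
  expect_lt(max(abs(mapped[, 2] - s2$landmarks$moving_y)), 1e-6)

  expect_error(generate_section(at[[1]], deform_spec(translate_px = c(60, 0))),
               class = "atlasmsi_validation_error")
})

test_that("noiseless effect-free studies give identical region means", {
  design <- small_design(1)[c(1, 3, 6), ]
  st <- generate_study(design, effects = list(),
                       noise = noise_model(poisson_scale = 0,
                                           mz_drift_ppm_sd = 0,
                                           baseline_amplitude = 0),
                       feature_panel = small_panel(), seed = 4,
                       shape = c(40, 56), deform_scale = 0)
  tm <- st$truth$region_means
  for (f in unique(tm$feature_mz)) {
    per_animal <- split(tm$expected_amp[tm$feature_mz == f],
                        tm$animal_id[tm$feature_mz == f])
    expect_true(all(vapply(per_animal, identical, logical(1),
                           per_animal[[1]])))
  }
  # and the actual generated cubes agree across animals (no noise, no deform)
  feats <- feature_table(146.07, 145.9, 146.25)
  cubes <- lapply(st$sections, function(s) extract_datacube(s$dataset, feats))
  expect_equal(cubes[[1]]$values, cubes[[2]]$values, tolerance = 1e-9)
})

test_that("a planted lfc -1 effect halves the affected hemisphere exactly", {
  design <- small_design(1)  # one animal per group incl. R192Q-CSD
  eff <- list(effect_spec(146.07, "cortex", "R", "R192Q-CSD", -1, 150))
  st <- generate_study(design, effects = eff,
                       noise = noise_model(poisson_scale = 0,
                                           mz_drift_ppm_sd = 0,
                                           baseline_amplitude = 0),
                       feature_panel = small_panel(), seed = 4,
                       shape = c(40, 56), deform_scale = 0)
  tm <- st$truth$region_means
  csd <- design$animal_id[design$group == "R192Q-CSD"]
  gl <- tm[tm$feature_mz == 146.07 & tm$roi == "cortex", ]
  for (an in design$animal_id) {
    l <- gl$expected_amp[gl$animal_id == an & gl$hemisphere == "L"]
    r <- gl$expected_amp[gl$animal_id == an & gl$hemisphere == "R"]
    if (an == csd) expect_equal(r, 0.5 * l) else expect_equal(r, l)
  }
  # verify on the generated pixels themselves for the affected animal
  s <- st$sections[[csd]]
  atl <- st$atlas[[st$atlas_index]]
  feats <- feature_table(146.07, 145.9, 146.25)
  cube <- extract_datacube(s$dataset, feats)
  lab <- atl$labels[cbind(cube$coords[, 2] + 1L, cube$coords[, 1] + 1L)]
  hemi <- ifelse(cube$coords[, 1] < atl$midline_col, "L", "R")
  ml <- mean(cube$values[lab == 1L & hemi == "L", 1])
  mr <- mean(cube$values[lab == 1L & hemi == "R", 1])
  expect_equal(mr / ml, 0.5, tolerance = 1e-9)
})

test_that("pixel counts are Poisson-dispersed at the declared scale", {
  design <- small_design(1)[1, , drop = FALSE]
  for (ps in c(1, 4)) {
    st <- generate_study(design, effects = list(),
                         noise = noise_model(poisson_scale = ps,
                                             mz_drift_ppm_sd = 0,
                                             baseline_amplitude = 0),
                         feature_panel = small_panel(), seed = 7,
                         shape = c(60, 80), deform_scale = 0)
    s <- st$sections[[1]]
    atl <- st$atlas[[st$atlas_index]]
    feats <- feature_table(147.60, 147.2, 148.0)  # uniform-pattern feature
    cube <- extract_datacube(s$dataset, feats)
    lab <- atl$labels[cbind(cube$coords[, 2] + 1L, cube$coords[, 1] + 1L)]
    v <- cube$values[lab > 0L, 1]  # uniform-pattern feature: whole tissue
    expect_gte(length(v), 1000L)
    expect_equal(var(v) / mean(v), ps, tolerance = 0.1)
  }
})

test_that("study generation is reproducible for a fixed seed", {
  design <- small_design(1)[c(1, 6), ]
  args <- list(design, effects = default_effects(),
               feature_panel = default_feature_panel(), seed = 42,
               shape = c(40, 56))
  a <- do.call(generate_study, args)
  b <- do.call(generate_study, args)
  expect_identical(a$sections[[1]]$dataset$intensities,
                   b$sections[[1]]$dataset$intensities)
  expect_identical(a$sections[[2]]$drift, b$sections[[2]]$drift)
  expect_equal(a$sections[[2]]$transform$bspline$dx,
               b$sections[[2]]$transform$bspline$dx)
})

test_that("write_study / read_study roundtrips the phantom", {
  design <- small_design(1)[c(1, 6), ]
  st <- generate_study(design,
                       effects = list(effect_spec(146.07, "cortex")),
                       feature_panel = small_panel(), seed = 8,
                       shape = c(40, 56))
  dir <- withr::local_tempdir()
  write_study(st, dir)
  back <- read_study(dir)
  an <- design$animal_id[1]
  expect_equal(back$sections[[an]]$dataset$intensities,
               st$sections[[an]]$dataset$intensities)
  expect_identical(back$sections[[an]]$labels, st$sections[[an]]$labels)
  expect_equal(back$sections[[an]]$landmarks$moving_x,
               st$sections[[an]]$landmarks$moving_x)
  m1 <- transform_points(back$sections[[an]]$transform, cbind(10, 12))
  m2 <- transform_points(st$sections[[an]]$transform, cbind(10, 12))
  expect_equal(as.numeric(m1), as.numeric(m2), tolerance = 1e-9)
  expect_equal(back$design$group, st$design$group)
})
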