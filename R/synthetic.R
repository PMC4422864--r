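# Synthetic phantom studies: a toy coronal atlas (four ROIs + hemisphere
# midline), per-animal deformed sections, and per-pixel Poisson spectra with
# planted group-by-hemisphere effects. Everything is seeded and
# byte-reproducible, and ground truth (transforms, landmarks, effects,
# expected region means) is returned alongside so every downstream stage can
# be tested against it.

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  force(code)
}

ATLAS_LEGEND <- c("0" = "background", "1" = "cortex", "2" = "striatum",
                  "3" = "hippocampus", "4" = "thalamus", "5" = "tissue")

#' Generate a toy coronal atlas
#'
#' Draws `n_sections` reference sections containing the four ROIs (cortex,
#' striatum, hippocampus, thalamus) inside an elliptical tissue outline with
#' a vertical hemisphere midline. The hippocampus maximum horizontal cord
#' length grows strictly with section index, so section selection by cord
#' length is identifiable; `ap_mm` spans the bregma window -1.22 to -1.94 mm.
#'
#' @param n_sections number of sections (>= 1).
#' @param shape `(h, w)` in pixels; at least 40 x 56.
#' @param seed RNG seed (drives the image texture).
#' @return list of [atlas_section()]s; per-section truth (cord lengths,
#'   landmarks) in `attr(, "truth")`.
#' @export
generate_atlas <- function(n_sections, shape = c(60, 80), seed = 1) {
  if (n_sections < 1) abort("n_sections must be >= 1", "atlasmsi_validation_error")
  h <- shape[1]; w <- shape[2]
  if (h < 40 || w < 56)
    abort("shape too small to draw all regions (need >= 40 x 56)",
          "atlasmsi_validation_error")
  cx <- (w - 1) / 2; cy <- (h - 1) / 2
  X <- matrix(rep(0:(w - 1), each = h), h, w)
  Y <- matrix(rep(0:(h - 1), times = w), h, w)
  rx <- 0.45 * w; ry <- 0.42 * h
  rell <- sqrt(((X - cx) / rx)^2 + ((Y - cy) / ry)^2)
  ap <- seq(-1.22, -1.94, length.out = max(n_sections, 1))
  sections <- vector("list", n_sections)
  truth <- vector("list", n_sections)
  for (k in seq_len(n_sections)) {
    labels <- matrix(0L, h, w)
    labels[rell <= 1] <- 5L                       # unlabeled tissue
    labels[rell <= 1 & rell > 0.74] <- 1L         # cortex band
    # striatum: two lateral blobs
    for (s in c(-1, 1)) {
      bx <- cx + s * 0.22 * w; by <- cy - 0.02 * h
      blob <- ((X - bx) / (0.08 * w))^2 + ((Y - by) / (0.11 * h))^2 <= 1
      labels[blob & rell <= 0.73] <- 2L
    }
    # thalamus: central ventral ellipse
    th <- ((X - cx) / (0.16 * w))^2 + ((Y - (cy + 0.14 * h)) / (0.12 * h))^2 <= 1
    labels[th & rell <= 0.73] <- 4L
    # hippocampus: horizontal bar whose width grows with section index
    half <- floor(0.08 * w) + (k - 1L) * max(1L, round(0.03 * w))
    y0 <- round(cy - 0.20 * h); y1 <- y0 + max(2L, round(0.05 * h))
    hip <- Y >= y0 & Y <= y1 & abs(X - cx) <= half
    labels[hip & rell <= 0.73] <- 3L

    base <- c(0.05, 0.55, 0.70, 0.90, 0.80, 0.35)[labels + 1L]
    img <- matrix(base, h, w) +
      0.06 * sin(2 * pi * X / w * 1.7) * cos(2 * pi * Y / h * 1.3)
    tex <- with_seed(seed + k, matrix(runif(h * w), h, w))
    kern <- gauss_kernel(1.2)
    tex <- .conv_cols(t(.conv_cols(t(tex), kern)), kern)
    img <- img + 0.08 * (tex - mean(tex))
    img[img < 0.02] <- 0.02; img[img > 1] <- 1

    sec <- atlas_section(img, labels, ATLAS_LEGEND, midline_col = cx,
                         ap_mm = ap[k], section_id = k)
    sections[[k]] <- sec
    truth[[k]] <- list(cord_length = cord_length(labels == 3L),
                       landmarks = atlas_landmarks(sec))
  }
  cords <- vapply(truth, `[[`, numeric(1), "cord_length")
  if (n_sections > 1 && any(diff(cords) <= 0))
    abort("hippocampus cord lengths not strictly increasing; enlarge shape",
          "atlasmsi_validation_error")
  attr(sections, "truth") <- truth
  sections
}

#' Region-boundary landmarks of an atlas section
#'
#' For each ROI, the leftmost, rightmost, topmost and bottommost mask pixels
#' (deterministic tie-break: first in column-major order), guaranteeing at
#' least 8 landmark pairs per section for registration evaluation.
#'
#' @param section an [atlas_section()].
#' @return data.frame with `x`, `y`, `region`.
#' @export
atlas_landmarks <- function(section) {
  out <- list()
  for (lab in c(1L, 2L, 3L, 4L)) {
    idx <- which(section$labels == lab, arr.ind = TRUE)
    if (!nrow(idx)) next
    x <- idx[, 2] - 1L; y <- idx[, 1] - 1L
    pick <- c(which.min(x), which.max(x), which.min(y), which.max(y))
    out[[length(out) + 1L]] <- data.frame(
      x = x[pick], y = y[pick],
      region = section$legend[as.character(lab)], row.names = NULL)
  }
  do.call(rbind, out)
}

#' Pad an atlas section with background margin
#'
#' Adds `margin` background pixels on every side (image padded with the
#' background intensity, labels with 0) so that large planted deformations
#' keep the tissue inside the frame. Landmark coordinates and the midline
#' shift by `margin`.
#'
#' @param section an [atlas_section()].
#' @param margin margin width in px.
#' @return padded [atlas_section()].
#' @export
pad_atlas_section <- function(section, margin) {
  h <- nrow(section$image); w <- ncol(section$image)
  img <- matrix(0.02, h + 2 * margin, w + 2 * margin)
  lab <- matrix(0L, h + 2 * margin, w + 2 * margin)
  img[margin + seq_len(h), margin + seq_len(w)] <- section$image
  lab[margin + seq_len(h), margin + seq_len(w)] <- section$labels
  atlas_section(img, lab, section$legend,
                midline_col = section$midline_col + margin,
                ap_mm = section$ap_mm, section_id = section$section_id)
}

#' Deformation specification for a phantom section
#'
#' @param rotation_deg,scale_x,scale_y,shear,translate_px affine components.
#' @param bspline_amplitude_px maximum local displacement (px).
#' @param bspline_grid control grid `(nx, ny)` before the +3 cubic margin.
#' @param seed seed for the random control displacements.
#' @return list of class `deform_spec`.
#' @export
deform_spec <- function(rotation_deg = 0, scale_x = 1, scale_y = 1, shear = 0,
                        translate_px = c(0, 0), bspline_amplitude_px = 0,
                        bspline_grid = c(5, 4), seed = 1) {
  if (scale_x <= 0 || scale_y <= 0)
    abort("scales must be positive", "atlasmsi_validation_error")
  if (bspline_amplitude_px < 0)
    abort("bspline amplitude must be >= 0", "atlasmsi_validation_error")
  structure(list(rotation_deg = rotation_deg, scale_x = scale_x,
                 scale_y = scale_y, shear = shear,
                 translate_px = translate_px,
                 bspline_amplitude_px = bspline_amplitude_px,
                 bspline_grid = bspline_grid, seed = seed),
            class = "deform_spec")
}

# truth transform (atlas frame -> section frame) from a deform spec
deform_to_transform <- function(deform, shape) {
  h <- shape[1]; w <- shape[2]
  bs <- NULL
  if (deform$bspline_amplitude_px > 0) {
    sx <- (w - 1) / (deform$bspline_grid[1] - 1)
    sy <- (h - 1) / (deform$bspline_grid[2] - 1)
    nx <- deform$bspline_grid[1] + 3L; ny <- deform$bspline_grid[2] + 3L
    disp <- with_seed(deform$seed,
                      matrix(runif(2 * nx * ny, -1, 1), ny * 2, nx)) *
      deform$bspline_amplitude_px
    bs <- bspline_field(nx, ny, c(sx, sy),
                        dx = disp[seq_len(ny), , drop = FALSE],
                        dy = disp[ny + seq_len(ny), , drop = FALSE])
  }
  affine_transform(translate_px = deform$translate_px,
                   rotation_deg = deform$rotation_deg,
                   scale_x = deform$scale_x, scale_y = deform$scale_y,
                   shear = deform$shear,
                   center = c((w - 1) / 2, (h - 1) / 2), bspline = bs)
}

#' Generate a deformed phantom section from an atlas section
#'
#' The serialized truth transform maps atlas coordinates to section
#' coordinates; the section image is rendered through its numerical inverse
#' (so that registering the section back onto the atlas should recover the
#' truth transform). Landmark pairs are the atlas landmarks and their exact
#' forward-mapped positions.
#'
#' @param atlas_section an [atlas_section()].
#' @param deform a [deform_spec()].
#' @return list with `image`, `labels`, `landmarks` (`fixed_*` = atlas frame,
#'   `moving_*` = section frame), `transform` (the truth
#'   [section_transform()]).
#' @export
generate_section <- function(atlas_section, deform) {
  shape <- dim(atlas_section$image)
  tf <- deform_to_transform(deform, shape)
  labeled <- which(atlas_section$labels > 0L, arr.ind = TRUE)
  fwd <- transform_points(tf, cbind(labeled[, 2] - 1, labeled[, 1] - 1))
  out_frac <- mean(fwd[, 1] < 0 | fwd[, 1] > shape[2] - 1 |
                   fwd[, 2] < 0 | fwd[, 2] > shape[1] - 1)
  if (out_frac > 0.10)
    abort(sprintf("deformation pushes %.0f%% of labeled pixels out of frame",
                  100 * out_frac), "atlasmsi_validation_error")
  pts <- grid_points(shape[1], shape[2])
  src <- invert_transform_points(tf, pts)
  img <- .bilinear_sample(atlas_section$image, src[, 1], src[, 2])
  img[is.na(img)] <- 0.02
  lab <- .nearest_sample(atlas_section$labels, src[, 1], src[, 2])
  lab[is.na(lab)] <- 0L
  lm <- atlas_landmarks(atlas_section)
  mv <- transform_points(tf, cbind(lm$x, lm$y))
  landmarks <- data.frame(fixed_x = lm$x, fixed_y = lm$y,
                          moving_x = mv[, 1], moving_y = mv[, 2],
                          region = lm$region)
  list(image = matrix(img, shape[1], shape[2]),
       labels = matrix(lab, shape[1], shape[2]),
       landmarks = landmarks, transform = tf)
}

#' Noise model for phantom spectra
#'
#' Pixel counts are drawn as `poisson_scale * Poisson(lambda /
#' poisson_scale)`, so the empirical variance-to-mean ratio equals
#' `poisson_scale` (0 disables noise entirely). The per-sample mass
#' calibration error is linear in m/z: a slope drawn with standard deviation
#' `mz_drift_ppm_sd` ppm plus a small constant offset.
#'
#' @param poisson_scale variance-to-mean ratio of pixel counts.
#' @param mz_drift_ppm_sd per-sample calibration slope sd (ppm).
#' @param baseline_amplitude amplitude (counts) of the smooth chemical
#'   baseline.
#' @param peak_width_da Gaussian peak sigma (Da).
#' @return list of class `noise_model`.
#' @export
noise_model <- function(poisson_scale = 1, mz_drift_ppm_sd = 30,
                        baseline_amplitude = 20, peak_width_da = 0.05) {
  if (any(c(poisson_scale, mz_drift_ppm_sd, baseline_amplitude,
            peak_width_da) < 0))
    abort("noise parameters must be >= 0", "atlasmsi_validation_error")
  structure(list(poisson_scale = poisson_scale,
                 mz_drift_ppm_sd = mz_drift_ppm_sd,
                 baseline_amplitude = baseline_amplitude,
                 peak_width_da = peak_width_da), class = "noise_model")
}

#' Planted effect specification
#'
#' @param feature_mz m/z of the affected panel feature (Da).
#' @param region ROI name (must be in the atlas legend).
#' @param hemisphere `"L"`, `"R"` or `"both"`.
#' @param group `genotype-condition` label, e.g. `"R192Q-CSD"`.
#' @param log2_fold_change planted log2 fold change (negative = decreased).
#' @param baseline_intensity expected counts at unaffected pixels.
#' @return list of class `effect_spec`.
#' @export
effect_spec <- function(feature_mz, region, hemisphere = "R",
                        group = "R192Q-CSD", log2_fold_change = -1,
                        baseline_intensity = 150) {
  if (baseline_intensity <= 0)
    abort("baseline_intensity must be positive", "atlasmsi_validation_error")
  structure(list(feature_mz = feature_mz, region = region,
                 hemisphere = hemisphere, group = group,
                 log2_fold_change = log2_fold_change,
                 baseline_intensity = baseline_intensity),
            class = "effect_spec")
}

#' Default phantom feature panel and effects
#'
#' Six metabolite-class features in a narrow m/z slice (the full 50-1000 Da
#' metabolite window at instrument pitch is deliberately not simulated at
#' desk scale), three of them carrying hemisphere effects confined to the
#' R192Q-CSD group, emulating the CSD-affected right hemisphere decreases;
#' planted |log2FC| lies in 0.5-1.
#'
#' @return `default_feature_panel()`: data.frame with `mz`, `class`,
#'   `region_pattern`, `baseline`; `default_effects()`: list of
#'   [effect_spec()]s.
#' @export
default_feature_panel <- function() {
  data.frame(
    mz = c(143.20, 144.40, 145.60, 146.07, 147.30, 148.50),
    class = "metabolite",
    region_pattern = c("uniform", "thalamus", "uniform", "cortex",
                       "uniform", "striatum"),
    baseline = c(120, 140, 100, 150, 110, 130)
  )
}

#' @rdname default_feature_panel
#' @export
default_effects <- function() {
  list(
    effect_spec(146.07, "cortex", "R", "R192Q-CSD", -1, 150),
    effect_spec(144.40, "thalamus", "R", "R192Q-CSD", -0.75, 140),
    effect_spec(148.50, "striatum", "R", "R192Q-CSD", -0.6, 130)
  )
}

#' Generate a complete synthetic study
#'
#' For each animal, a deformed phantom section is generated from the middle
#' atlas section and per-pixel spectra are synthesized on the class m/z grid:
#' sums of Gaussian peaks (sigma `peak_width_da`) at per-sample-drifted
#' feature positions, scaled by the region pattern and by `2^log2FC` where
#' the pixel's group/region/hemisphere matches a planted effect, plus a
#' smooth baseline, then Poisson-sampled.
#'
#' @param design a [study_design()]; default the 32-animal 6-group design.
#' @param effects list of [effect_spec()]s.
#' @param noise a [noise_model()].
#' @param feature_panel data.frame as in [default_feature_panel()].
#' @param seed master seed; every random draw derives from it.
#' @param shape atlas frame `(h, w)`.
#' @param grid_step m/z grid pitch (Da).
#' @param n_atlas_sections number of atlas sections.
#' @param deform_scale multiplier on the default per-animal deformation
#'   magnitudes (0 = perfectly aligned sections).
#' @return object of class `msi_study`: list with `design`, `atlas`,
#'   `atlas_index`, `sections` (per animal: `dataset`, `image`, `labels`,
#'   `landmarks`, `transform`, `drift`) and `truth` (effects, expected
#'   region-hemisphere mean table).
#' @export
generate_study <- function(design = default_study_design(),
                           effects = default_effects(),
                           noise = noise_model(),
                           feature_panel = default_feature_panel(),
                           seed = 1, shape = c(60, 80), grid_step = 0.01,
                           n_atlas_sections = 3, deform_scale = 1) {
  stopifnot(inherits(design, "study_design"))
  atlas <- generate_atlas(n_atlas_sections, shape = shape, seed = seed)
  sec_idx <- ceiling(n_atlas_sections / 2)
  asec <- atlas[[sec_idx]]
  cls <- unique(feature_panel$class)
  if (length(cls) != 1)
    abort("one molecular class per generated study", "atlasmsi_validation_error")
  rng <- c(min(feature_panel$mz) - 2, max(feature_panel$mz) + 2)
  grid <- seq(rng[1], rng[2], by = grid_step)
  region_labels <- setNames(names(ATLAS_LEGEND), ATLAS_LEGEND)
  for (e in effects) {
    if (!e$region %in% ATLAS_LEGEND)
      abort(sprintf("effect region '%s' not in atlas legend", e$region),
            "atlasmsi_validation_error")
    if (!any(abs(feature_panel$mz - e$feature_mz) < 1e-6))
      abort("effect feature not in panel", "atlasmsi_validation_error")
  }

  sections <- vector("list", nrow(design))
  names(sections) <- design$animal_id
  truth_means <- list()
  for (i in seq_len(nrow(design))) {
    an <- design$animal_id[i]
    group <- design$group[i]
    dseed <- seed * 1000L + i
    df <- with_seed(dseed, deform_spec(
      rotation_deg = runif(1, -5, 5) * deform_scale,
      scale_x = 1 + runif(1, -0.03, 0.03) * deform_scale,
      scale_y = 1 + runif(1, -0.03, 0.03) * deform_scale,
      shear = runif(1, -0.02, 0.02) * deform_scale,
      translate_px = runif(2, -4, 4) * deform_scale,
      bspline_amplitude_px = 1.5 * deform_scale,
      seed = dseed + 1L))
    sec <- generate_section(asec, df)
    tissue <- which(sec$labels > 0L, arr.ind = TRUE)
    coords <- cbind(x = tissue[, 2] - 1L, y = tissue[, 1] - 1L)
    labs <- sec$labels[tissue]
    hemi <- hemisphere_of(coords[, 1], asec$midline_col)

    drift <- with_seed(dseed + 2L, c(
      slope = 1 + rnorm(1) * noise$mz_drift_ppm_sd * 1e-6,
      offset = rnorm(1) * noise$mz_drift_ppm_sd * 1e-6 * mean(rng) * 0.5))

    lam <- matrix(0, nrow = length(grid), ncol = nrow(coords))
    for (f in seq_len(nrow(feature_panel))) {
      amp <- rep(feature_panel$baseline[f], nrow(coords))
      pat <- feature_panel$region_pattern[f]
      if (pat != "uniform")
        amp[labs == as.integer(region_labels[pat])] <- amp[labs == as.integer(region_labels[pat])] * 2
      for (e in effects) {
        if (abs(e$feature_mz - feature_panel$mz[f]) < 1e-6 && e$group == group) {
          hit <- labs == as.integer(region_labels[e$region]) &
            (e$hemisphere == "both" | hemi == e$hemisphere)
          amp[hit] <- amp[hit] * 2^e$log2_fold_change
        }
      }
      center <- feature_panel$mz[f] * drift["slope"] + drift["offset"]
      # peak support limited to +/- 6 sigma: the Gaussian is negligible beyond
      sup <- which(abs(grid - center) <= 6 * noise$peak_width_da)
      prof <- exp(-(grid[sup] - center)^2 / (2 * noise$peak_width_da^2))
      lam[sup, ] <- lam[sup, ] + prof %o% amp
      # truth: expected amplitude per region x hemisphere
      for (roi in c("cortex", "striatum", "hippocampus", "thalamus")) {
        for (hm in c("L", "R")) {
          a <- feature_panel$baseline[f] *
            (if (pat == roi) 2 else 1)
          for (e in effects)
            if (abs(e$feature_mz - feature_panel$mz[f]) < 1e-6 &&
                e$group == group && e$region == roi &&
                (e$hemisphere == "both" || e$hemisphere == hm))
              a <- a * 2^e$log2_fold_change
          truth_means[[length(truth_means) + 1L]] <- data.frame(
            animal_id = an, feature_mz = feature_panel$mz[f],
            roi = roi, hemisphere = hm, expected_amp = a)
        }
      }
    }
    if (noise$baseline_amplitude > 0)
      lam <- lam + noise$baseline_amplitude *
        exp(-(grid - rng[1]) / (0.4 * diff(rng)))
    ints <- if (noise$poisson_scale > 0) {
      with_seed(dseed + 3L, {
        x <- noise$poisson_scale * rpois(length(lam), lam / noise$poisson_scale)
        dim(x) <- dim(lam)
        x
      })
    } else lam
    meta <- list(molecular_class = cls, polarity = "-", raster_um = 100,
                 animal_id = an, section_id = paste0(an, "_", cls),
                 mass_range = rng, frame_shape = shape)
    sections[[i]] <- list(
      dataset = msi_dataset(coords, grid, ints, meta),
      image = sec$image, labels = sec$labels,
      landmarks = sec$landmarks, transform = sec$transform, drift = drift)
  }
  structure(list(design = design, atlas = atlas, atlas_index = sec_idx,
                 feature_panel = feature_panel, noise = noise, seed = seed,
                 sections = sections,
                 truth = list(effects = effects,
                              region_means = do.call(rbind, truth_means))),
            class = "msi_study")
}

#' @export
print.msi_study <- function(x, ...) {
  cat(sprintf("<msi_study> %d animals, %d panel features, seed %d\n",
              nrow(x$design), nrow(x$feature_panel), x$seed))
  invisible(x)
}

#' Write a study to disk / read it back
#'
#' Writes one imzML/ibd pair plus PGM image and label map per animal, the
#' atlas (PGM + JSON legends), truth JSONs (transforms, landmarks, effects)
#' and a `study.json` manifest compatible with the CLI.
#'
#' @param study an `msi_study`.
#' @param out_dir output directory (created).
#' @export
write_study <- function(study, out_dir) {
  dir.create(file.path(out_dir, "sections"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(out_dir, "atlas"), showWarnings = FALSE)
  dir.create(file.path(out_dir, "truth"), showWarnings = FALSE)
  for (k in seq_along(study$atlas))
    write_labelmap(study$atlas[[k]], file.path(out_dir, "atlas", paste0("section_", k)))
  tr <- list(); lms <- list()
  for (an in names(study$sections)) {
    s <- study$sections[[an]]
    write_imzml(s$dataset, file.path(out_dir, "sections", paste0(an, ".imzML")))
    write_pgm(round(s$image * 255), file.path(out_dir, "sections", paste0(an, "_image.pgm")), 255)
    write_pgm(s$labels, file.path(out_dir, "sections", paste0(an, "_labels.pgm")))
    tr[[an]] <- unclass_transform(s$transform)
    lms[[an]] <- s$landmarks
  }
  jsonlite::write_json(tr, file.path(out_dir, "truth", "transforms.json"),
                       auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(lms, file.path(out_dir, "truth", "landmarks.json"),
                       auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(lapply(study$truth$effects, unclass),
                       file.path(out_dir, "truth", "effects.json"),
                       auto_unbox = TRUE, digits = NA)
  write.table(study$truth$region_means,
              file.path(out_dir, "truth", "region_means.tsv"),
              sep = "\t", row.names = FALSE, quote = FALSE)
  write.table(as.data.frame(study$design), file.path(out_dir, "design.tsv"),
              sep = "\t", row.names = FALSE, quote = FALSE)
  jsonlite::write_json(
    list(atlas_sections = length(study$atlas), atlas_index = study$atlas_index,
         animals = names(study$sections), seed = study$seed,
         feature_panel = study$feature_panel),
    file.path(out_dir, "study.json"), auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}

#' @rdname write_study
#' @param dir a directory written by [write_study()].
#' @export
read_study <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "study.json"),
                                  simplifyVector = TRUE)
  design_df <- read.delim(file.path(dir, "design.tsv"), stringsAsFactors = FALSE)
  design <- study_design(design_df$animal_id, design_df$genotype,
                         design_df$condition, design_df$slide_id,
                         design_df$slide_position, design_df$acquisition_order,
                         design_df$postmortem_min)
  atlas <- lapply(seq_len(manifest$atlas_sections), function(k)
    read_labelmap(file.path(dir, "atlas", sprintf("section_%d.pgm", k)),
                  file.path(dir, "atlas", sprintf("section_%d_legend.json", k)),
                  labels_path = file.path(dir, "atlas", sprintf("section_%d_labels.pgm", k))))
  trs <- jsonlite::read_json(file.path(dir, "truth", "transforms.json"),
                             simplifyVector = TRUE)
  lms <- jsonlite::read_json(file.path(dir, "truth", "landmarks.json"),
                             simplifyVector = TRUE)
  sections <- list()
  for (an in manifest$animals) {
    ds <- read_imzml(file.path(dir, "sections", paste0(an, ".imzML")))
    img <- read_pgm(file.path(dir, "sections", paste0(an, "_image.pgm"))) / 255
    lab <- read_pgm(file.path(dir, "sections", paste0(an, "_labels.pgm")))
    sections[[an]] <- list(dataset = ds, image = img, labels = lab,
                           landmarks = as.data.frame(lms[[an]]),
                           transform = transform_from_list(trs[[an]]))
  }
  structure(list(design = design, atlas = atlas,
                 atlas_index = manifest$atlas_index,
                 feature_panel = manifest$feature_panel,
                 seed = manifest$seed, sections = sections,
                 truth = list(effects = jsonlite::read_json(
                   file.path(dir, "truth", "effects.json"), simplifyVector = FALSE),
                   region_means = read.delim(
                     file.path(dir, "truth", "region_means.tsv"),
                     stringsAsFactors = FALSE))),
            class = "msi_study")
}

#' Simulate null animal-level region profiles
#'
#' Draws per-animal ROI-by-hemisphere mean intensities under the generator's
#' Poisson pixel model with no planted effect: each mean is
#' `scale * Poisson(n_pixels * baseline / scale) / n_pixels`. Used for
#' type-I-error calibration of the paired hemisphere test at desk scale
#' without re-running image synthesis.
#'
#' @param design a [study_design()].
#' @param n_features number of features simulated.
#' @param rois ROI names.
#' @param n_pixels pixels averaged per ROI-hemisphere.
#' @param baseline expected counts per pixel.
#' @param poisson_scale variance-to-mean ratio.
#' @param seed RNG seed.
#' @return long data.frame compatible with [run_study_statistics()].
#' @export
simulate_null_profiles <- function(design, n_features = 10,
                                   rois = c("cortex", "striatum",
                                            "hippocampus", "thalamus"),
                                   n_pixels = 150, baseline = 100,
                                   poisson_scale = 1, seed = 1) {
  grid <- expand.grid(animal_id = design$animal_id, roi = rois,
                      hemisphere = c("L", "R"),
                      feature_id = seq_len(n_features),
                      stringsAsFactors = FALSE)
  grid$feature_mz <- 100 + grid$feature_id
  grid$value <- with_seed(seed,
    poisson_scale * rpois(nrow(grid), n_pixels * baseline / poisson_scale) / n_pixels)
  grid$n_pixels <- n_pixels
  grid
}
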