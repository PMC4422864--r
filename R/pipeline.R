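#' Run the full anatomy-driven analysis on a study
#'
#' Executes the pipeline end to end on an in-memory `msi_study` (from
#' [generate_study()] or [read_study()]): per-pixel preprocessing (Gaussian
#' smoothing, TopHat baseline, TIC normalization), cross-sample alignment on
#' common peaks, global base-peak-spectrum peak picking, image-cube
#' extraction with variance stabilization, registration of every section to
#' its atlas section (or import of externally supplied / truth transforms),
#' ROI-by-hemisphere profile extraction and the paired/unpaired comparison
#' plan with BH correction.
#'
#' @param study an `msi_study`.
#' @param transforms `"estimate"` (run affine + B-spline registration) or
#'   `"truth"` (import each section's serialized truth transform — the
#'   documented hook for externally computed transforms).
#' @param snr_min peak-picking SNR threshold.
#' @param alpha significance level on BH-adjusted q.
#' @param group_comparisons passed to [run_study_statistics()].
#' @param tic apply TIC normalization.
#' @param register_maxit iteration caps for the affine stage.
#' @return list with `stats`, `profiles`, `features`, `bps`, `alignment`,
#'   `transforms`, `registration_reports`, `atlas_choice`.
#' @export
run_pipeline <- function(study, transforms = c("estimate", "truth"),
                         snr_min = 3, alpha = 0.05,
                         group_comparisons = list(), tic = TRUE,
                         register_maxit = 300) {
  transforms <- match.arg(transforms)
  cls <- study$sections[[1]]$dataset$meta$molecular_class
  config <- preproc_config(cls)

  pre <- lapply(study$sections, function(s)
    preprocess_dataset(s$dataset, config, tic = tic))
  al <- align_spectra(pre)
  rm(pre)  # the recalibrated copies are what downstream stages consume
  bps <- compute_base_peak_spectrum(al$datasets)
  features <- pick_peaks(bps, snr_min = snr_min,
                         gauss_width_da = config$gauss_width_da)
  if (!nrow(features))
    abort("no features picked on the base peak spectrum", "atlasmsi_error")

  shape <- dim(study$atlas[[1]]$image)
  profiles <- list()
  tfs <- list(); reports <- list(); atlas_choice <- integer(0)
  for (an in names(study$sections)) {
    s <- study$sections[[an]]
    ds <- al$datasets[[match(an, names(study$sections))]]
    cube <- extract_datacube(ds, features)
    cube <- variance_stabilize(cube)
    k <- select_atlas_section(s$labels, study$atlas)
    atlas_choice[an] <- k
    if (transforms == "truth") {
      tf <- s$transform
      reports[[an]] <- list(imported = TRUE)
    } else {
      aff <- register_affine(s$image, study$atlas[[k]]$image,
                             maxit = register_maxit)
      bsp <- register_bspline(s$image, study$atlas[[k]]$image, aff$transform,
                              landmarks = s$landmarks)
      tf <- bsp$transform
      reports[[an]] <- list(affine = aff$report, bspline = bsp$report)
    }
    tfs[[an]] <- tf
    aligned <- apply_transform(cube, tf, shape)
    profiles[[an]] <- extract_region_profiles(aligned, study$atlas[[k]])
  }
  profiles <- do.call(rbind, profiles)
  stats <- run_study_statistics(profiles, study$design, alpha = alpha,
                                group_comparisons = group_comparisons)
  list(stats = stats, profiles = profiles, features = features, bps = bps,
       alignment = al$model, transforms = tfs,
       registration_reports = reports, atlas_choice = atlas_choice)
}

#' Match planted effects to picked features
#'
#' Maps each planted effect to the picked feature whose integration window
#' contains its m/z (the generator's truth is in true mass space; after
#' alignment the features are too).
#'
#' @param effects list of [effect_spec()]s.
#' @param features a [feature_table()].
#' @return data.frame with `feature_mz`, `feature_id`, `roi`, `group`,
#'   `hemisphere`, `log2_fold_change`; `feature_id` is `NA` when no window
#'   contains the planted m/z.
#' @export
match_effects_to_features <- function(effects, features) {
  do.call(rbind, lapply(effects, function(e) {
    hit <- which(features$lo <= e$feature_mz & features$hi >= e$feature_mz)
    data.frame(feature_mz = e$feature_mz,
               feature_id = if (length(hit)) hit[1] else NA_integer_,
               roi = e$region, group = e$group, hemisphere = e$hemisphere,
               log2_fold_change = e$log2_fold_change)
  }))
}
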