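#' Default mass range for a molecular class
#'
#' Metabolites 50-1000 Da, peptides 600-2000 Da, proteins 3000-20000 Da,
#' matching typical MALDI-TOF acquisition windows for each class.
#'
#' @param molecular_class one of `"metabolite"`, `"peptide"`, `"protein"`.
#' @return numeric length-2 vector `(lo, hi)` in Da.
#' @export
class_mass_range <- function(molecular_class) {
  switch(molecular_class,
    metabolite = c(50, 1000),
    peptide    = c(600, 2000),
    protein    = c(3000, 20000),
    abort(sprintf("unknown molecular class '%s'", molecular_class),
          "atlasmsi_validation_error")
  )
}

#' Construct an MSI dataset
#'
#' One tissue section's grid of mass spectra. Profile mode stores a shared
#' ascending m/z axis and a bins-by-pixels intensity matrix; centroid mode
#' stores per-pixel m/z and intensity lists.
#'
#' @param coords integer matrix (n_pixels x 2) of 0-based `(x, y)` grid
#'   coordinates; `x` is the column index (rightward), `y` the row index
#'   (downward).
#' @param mz shared ascending m/z grid (profile mode) or list of per-pixel
#'   m/z vectors (centroid mode).
#' @param intensities bins-by-pixels matrix (profile) or list of per-pixel
#'   intensity vectors (centroid); nonnegative.
#' @param meta list with `molecular_class`, `polarity` (`"+"` or `"-"`),
#'   `raster_um`, `animal_id`, `section_id` and optionally `mass_range`.
#' @param mode `"profile"` or `"centroid"`.
#' @return object of class `msi_dataset`.
#' @export
msi_dataset <- function(coords, mz, intensities, meta = list(),
                        mode = c("profile", "centroid")) {
  mode <- match.arg(mode)
  coords <- as.matrix(coords)
  storage.mode(coords) <- "integer"
  colnames(coords) <- c("x", "y")
  meta$molecular_class <- meta$molecular_class %||% "metabolite"
  meta$polarity <- meta$polarity %||% "-"
  meta$raster_um <- meta$raster_um %||% 100
  meta$mass_range <- meta$mass_range %||% class_mass_range(meta$molecular_class)
  obj <- structure(
    list(coords = coords, mz = mz, intensities = intensities,
         meta = meta, mode = mode),
    class = "msi_dataset"
  )
  validate_msi_dataset(obj)
  obj
}

validate_msi_dataset <- function(d) {
  if (anyDuplicated(paste(d$coords[, 1], d$coords[, 2])))
    abort("duplicate pixel coordinates", "atlasmsi_validation_error")
  if (!d$meta$polarity %in% c("+", "-"))
    abort("polarity must be '+' or '-'", "atlasmsi_validation_error")
  if (d$mode == "profile") {
    if (nrow(d$coords) != ncol(d$intensities))
      abort("one intensity column per pixel required", "atlasmsi_validation_error")
    if (length(d$mz) != nrow(d$intensities))
      abort("mz axis and intensity rows disagree", "atlasmsi_validation_error")
    if (length(d$mz) > 1 && any(diff(d$mz) <= 0))
      abort("mz axis must be strictly increasing", "atlasmsi_validation_error")
    if (any(d$intensities < 0))
      abort("intensities must be nonnegative", "atlasmsi_validation_error")
  } else {
    if (nrow(d$coords) != length(d$mz) || length(d$mz) != length(d$intensities))
      abort("centroid lists must have one entry per pixel", "atlasmsi_validation_error")
    for (i in seq_along(d$mz)) {
      if (length(d$mz[[i]]) > 1 && any(diff(d$mz[[i]]) <= 0))
        abort("centroid m/z lists must be strictly increasing", "atlasmsi_validation_error")
      if (any(d$intensities[[i]] < 0))
        abort("intensities must be nonnegative", "atlasmsi_validation_error")
    }
  }
  invisible(d)
}

#' @export
print.msi_dataset <- function(x, ...) {
  cat(sprintf("<msi_dataset> %s, %s mode, %d pixels, polarity %s\n",
              x$meta$molecular_class, x$mode, nrow(x$coords), x$meta$polarity))
  if (x$mode == "profile")
    cat(sprintf("  m/z %.4f..%.4f (%d bins)\n", min(x$mz), max(x$mz), length(x$mz)))
  invisible(x)
}

#' Construct a feature table
#'
#' @param center_mz peak apex positions (Da).
#' @param lo,hi integration window bounds (Da), `lo < center < hi`.
#' @param snr signal-to-noise ratio at the apex.
#' @return data.frame of class `msi_features`.
#' @export
feature_table <- function(center_mz, lo, hi, snr = NA_real_) {
  f <- data.frame(center_mz = center_mz, lo = lo, hi = hi,
                  snr = rep_len(snr, length(center_mz)))
  if (nrow(f)) {
    if (any(f$lo >= f$center_mz | f$hi <= f$center_mz))
      abort("feature windows must bracket the center", "atlasmsi_validation_error")
    o <- order(f$center_mz)
    if (any(f$lo[o][-1] < f$hi[o][-nrow(f)]))
      abort("feature windows must be disjoint", "atlasmsi_validation_error")
  }
  class(f) <- c("msi_features", "data.frame")
  f
}

#' Construct an image cube (pixels x features)
#'
#' @param coords pixel coordinates as in [msi_dataset()].
#' @param features an [feature_table()] object.
#' @param values n_pixels x n_features matrix; `NA` marks missing pixels
#'   after resampling.
#' @param meta metadata list carried over from the source dataset.
#' @param transform_applied has the cube been resampled onto the atlas grid?
#' @param provenance character vector of processing-log entries.
#' @return object of class `msi_datacube`.
#' @export
datacube <- function(coords, features, values, meta = list(),
                     transform_applied = FALSE, provenance = character()) {
  values <- as.matrix(values)
  if (nrow(values) != nrow(coords))
    abort("one cube row per pixel required", "atlasmsi_validation_error")
  if (ncol(values) != nrow(features))
    abort("one cube column per feature required", "atlasmsi_validation_error")
  structure(
    list(coords = as.matrix(coords), features = features, values = values,
         meta = meta, transform_applied = transform_applied,
         provenance = provenance),
    class = "msi_datacube"
  )
}

#' @export
print.msi_datacube <- function(x, ...) {
  cat(sprintf("<msi_datacube> %d pixels x %d features%s\n",
              nrow(x$values), ncol(x$values),
              if (x$transform_applied) " (atlas frame)" else ""))
  invisible(x)
}

#' Construct an atlas section
#'
#' A reference grayscale image plus an integer label map with a region
#' legend. Hemispheres are split at a vertical midline column.
#'
#' @param image numeric matrix (rows x cols), grayscale in `[0, 1]`.
#' @param labels integer matrix, same shape; 0 = background/unlabeled.
#' @param legend named character vector mapping label integers (names) to
#'   region names; must cover every label present.
#' @param midline_col 0-based x coordinate of the hemisphere midline;
#'   pixels with `x < midline_col` are left (L).
#' @param ap_mm anteroposterior position (mm from bregma).
#' @param section_id optional identifier.
#' @return object of class `atlas_section`.
#' @export
atlas_section <- function(image, labels, legend, midline_col,
                          ap_mm = NA_real_, section_id = NULL) {
  storage.mode(labels) <- "integer"
  if (!all(dim(image) == dim(labels)))
    abort("image and labels must have the same shape", "atlasmsi_validation_error")
  present <- sort(unique(as.integer(labels)))
  missing <- setdiff(present, as.integer(names(legend)))
  if (length(missing))
    abort(sprintf("label(s) %s present in image but absent from legend",
                  paste(missing, collapse = ", ")),
          "atlasmsi_validation_error")
  structure(
    list(image = image, labels = labels, legend = legend,
         midline_col = midline_col, ap_mm = ap_mm, section_id = section_id),
    class = "atlas_section"
  )
}

#' @export
print.atlas_section <- function(x, ...) {
  cat(sprintf("<atlas_section> %dx%d, ap %.2f mm, regions: %s\n",
              nrow(x$image), ncol(x$image), x$ap_mm,
              paste(x$legend[names(x$legend) != "0"], collapse = ", ")))
  invisible(x)
}

#' Construct a study design table
#'
#' @param animal_id unique animal identifiers.
#' @param genotype `"WT"` or `"R192Q"` per animal.
#' @param condition `"Naive"`, `"Sham"` or `"CSD"` per animal.
#' @param slide_id,slide_position,acquisition_order optional randomization
#'   columns (filled by [block_randomize()]).
#' @param postmortem_min post-mortem delay in minutes.
#' @return data.frame of class `study_design` with a `group` column
#'   (`genotype-condition`).
#' @export
study_design <- function(animal_id, genotype, condition,
                         slide_id = NA_integer_, slide_position = NA_integer_,
                         acquisition_order = NA_integer_,
                         postmortem_min = NA_real_) {
  if (anyDuplicated(animal_id))
    abort("animal_ids must be unique", "atlasmsi_validation_error")
  if (!all(genotype %in% c("WT", "R192Q")))
    abort("genotype must be WT or R192Q", "atlasmsi_validation_error")
  if (!all(condition %in% c("Naive", "Sham", "CSD")))
    abort("condition must be Naive, Sham or CSD", "atlasmsi_validation_error")
  d <- data.frame(animal_id = as.character(animal_id), genotype = genotype,
                  condition = condition,
                  group = paste(genotype, condition, sep = "-"),
                  slide_id = slide_id, slide_position = slide_position,
                  acquisition_order = acquisition_order,
                  postmortem_min = postmortem_min,
                  stringsAsFactors = FALSE)
  class(d) <- c("study_design", "data.frame")
  d
}

#' The study design used throughout: 32 animals in 6 genotype-by-condition
#' groups (WT and R192Q crossed with Naive, Sham, CSD; n = 5, 6, 5 per
#' genotype respectively).
#'
#' @param postmortem_min per-animal post-mortem delay (minutes); recycled.
#' @return a [study_design()] table with 32 rows.
#' @export
default_study_design <- function(postmortem_min = 7) {
  sizes <- c("WT-Naive" = 5, "WT-Sham" = 6, "WT-CSD" = 5,
             "R192Q-Naive" = 5, "R192Q-Sham" = 6, "R192Q-CSD" = 5)
  geno <- rep(sub("-.*", "", names(sizes)), sizes)
  cond <- rep(sub(".*-", "", names(sizes)), sizes)
  study_design(
    animal_id = sprintf("M%02d", seq_along(geno)),
    genotype = geno, condition = cond,
    postmortem_min = rep_len(postmortem_min, length(geno))
  )
}

# hemisphere of 0-based x coordinates relative to an atlas midline
hemisphere_of <- function(x, midline_col) ifelse(x < midline_col, "L", "R")
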