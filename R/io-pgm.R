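#' Read / write plain-text PGM (P2) images
#'
#' ASCII PGM is used for both grayscale section images (0-255, rescaled to
#' `[0, 1]` on read) and integer label maps. Arrays are `[row, col]` with the
#' origin at the top-left, matching the pixel-grid convention used across the
#' package (x = column, y = row, 0-based).
#'
#' @param path file path.
#' @return integer matrix of pixel values.
#' @export
read_pgm <- function(path) {
  if (!file.exists(path))
    abort(sprintf("file not found: %s", path), "atlasmsi_io_error")
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*#", lines)]
  tok <- scan(text = paste(lines, collapse = " "), what = character(),
              quiet = TRUE)
  if (tok[1] != "P2")
    abort("not a plain (P2) PGM file", "atlasmsi_io_error")
  w <- as.integer(tok[2]); h <- as.integer(tok[3])
  vals <- as.integer(tok[-(1:4)])
  if (length(vals) != w * h)
    abort("PGM pixel count does not match header", "atlasmsi_io_error")
  matrix(vals, nrow = h, ncol = w, byrow = TRUE)
}

#' @rdname read_pgm
#' @param img integer (or numeric, rounded) matrix to write.
#' @param maxval maximum pixel value declared in the header.
#' @export
write_pgm <- function(img, path, maxval = max(1L, max(img))) {
  img <- round(img)
  storage.mode(img) <- "integer"
  if (any(img < 0)) abort("PGM pixels must be nonnegative", "atlasmsi_io_error")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("P2", paste(ncol(img), nrow(img)), as.character(maxval)), con)
  writeLines(apply(img, 1, paste, collapse = " "), con)
  invisible(path)
}

#' Read an integer label map plus its JSON legend as an atlas section
#'
#' The legend JSON maps label integers to region names and may carry
#' `midline_col` (0-based hemisphere midline) and `ap_mm`. Every label present
#' in the image must be listed in the legend.
#'
#' @param image_path PGM label map (or grayscale image when `labels_path`
#'   is given separately).
#' @param legend_path JSON legend file.
#' @param labels_path optional separate PGM label map; when omitted,
#'   `image_path` is used as both the label map and (rescaled) display image.
#' @return an [atlas_section()].
#' @export
read_labelmap <- function(image_path, legend_path, labels_path = NULL) {
  img <- read_pgm(image_path)
  labels <- if (is.null(labels_path)) img else read_pgm(labels_path)
  leg <- jsonlite::read_json(legend_path, simplifyVector = TRUE)
  regions <- leg$regions %||% leg[setdiff(names(leg), c("midline_col", "ap_mm"))]
  legend <- setNames(as.character(unlist(regions)), names(regions))
  image <- if (is.null(labels_path)) img / max(1L, max(img)) else img / 255
  atlas_section(image = image, labels = labels, legend = legend,
                midline_col = leg$midline_col %||% (ncol(labels) / 2),
                ap_mm = leg$ap_mm %||% NA_real_)
}

#' @rdname read_labelmap
#' @param section an [atlas_section()] to write.
#' @param prefix output path prefix; writes `<prefix>.pgm` (grayscale),
#'   `<prefix>_labels.pgm` and `<prefix>_legend.json`.
#' @export
write_labelmap <- function(section, prefix) {
  write_pgm(round(section$image * 255), paste0(prefix, ".pgm"), maxval = 255)
  write_pgm(section$labels, paste0(prefix, "_labels.pgm"))
  jsonlite::write_json(
    list(regions = as.list(section$legend),
         midline_col = section$midline_col, ap_mm = section$ap_mm),
    paste0(prefix, "_legend.json"), auto_unbox = TRUE, digits = NA)
  invisible(prefix)
}

#' Write a region statistics table as TSV
#'
#' One row per feature x ROI x comparison with group means, effect
#' direction, raw p and BH-adjusted q.
#'
#' @param table a `region_stats` data.frame from [run_study_statistics()].
#' @param path output TSV path.
#' @export
write_stats_table <- function(table, path) {
  cols <- c("feature_mz", "roi", "comparison", "n", "mean_a", "mean_b",
            "estimate", "direction", "p_raw", "q_bh", "significant")
  out <- as.data.frame(table)[, cols, drop = FALSE]
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_stats_table
#' @export
read_stats_table <- function(path) {
  t <- read.delim(path, stringsAsFactors = FALSE)
  class(t) <- c("region_stats", "data.frame")
  t
}
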