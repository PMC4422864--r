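# Theoretical-mass annotation: monoisotopic masses from an embedded isotope
# table, adduct m/z with the proton-based charge-carrier convention
# (electron mass absorbed into the 1.007276 Da proton), PTM/adduct delta-pair
# detection with spatial-correlation support, and ppm matching against a
# small compound table.

# most-abundant-isotope masses (IUPAC/CODATA)
ISOTOPE_MASS <- c(
  H = 1.0078250319, C = 12.0, N = 14.0030740052, O = 15.9949146221,
  P = 30.97376151, S = 31.97207069, K = 38.9637069, Na = 22.98976928,
  Cl = 34.96885271, F = 18.99840320, Fe = 55.9349421, Mg = 23.98504190,
  Ca = 39.9625912, Zn = 63.9291466
)

PROTON_MASS <- 1.007276
K_CATION_MASS <- 38.963158    # 39K minus one electron
NA_CATION_MASS <- 22.989218   # 23Na minus one electron

#' Monoisotopic mass from an elemental formula
#'
#' Sums most-abundant-isotope masses over a Hill-style composition string
#' such as `"C6H14O12P2"` (multi-letter elements like `Na` supported).
#'
#' @param formula composition string.
#' @return neutral monoisotopic mass in Da.
#' @examples
#' monoisotopic_mass("H2O")      # 18.010565
#' monoisotopic_mass("C5H9NO4")  # glutamate, 147.053158
#' @export
monoisotopic_mass <- function(formula) {
  if (!is.character(formula) || length(formula) != 1 || !nzchar(formula))
    abort("empty or invalid formula", "atlasmsi_validation_error")
  m <- gregexpr("([A-Z][a-z]?)([0-9]*)", formula)[[1]]
  parts <- regmatches(formula, list(m))[[1]]
  if (!length(parts) || sum(nchar(parts)) != nchar(formula))
    abort(sprintf("unparseable formula '%s'", formula),
          "atlasmsi_validation_error")
  total <- 0
  for (p in parts) {
    el <- sub("[0-9]*$", "", p)
    cnt <- sub("^[A-Za-z]+", "", p)
    cnt <- if (nzchar(cnt)) as.integer(cnt) else 1L
    if (!el %in% names(ISOTOPE_MASS))
      abort(sprintf("unknown element '%s'", el), "atlasmsi_validation_error")
    total <- total + ISOTOPE_MASS[[el]] * cnt
  }
  total
}

#' Singly-charged adduct m/z from a neutral mass
#'
#' Charge-carrier convention: the ion m/z is the neutral mass plus/minus
#' proton(s) (1.007276 Da, electron mass absorbed) and/or alkali cations
#' (K+ 38.963158 Da, Na+ 22.989218 Da), so theoretical values reproduce
#' printed accurate masses to 4 decimals.
#'
#' @param neutral_mass neutral monoisotopic mass (Da, > 0).
#' @param adduct one of `"[M-H]-"`, `"[M+K-2H]-"`, `"[M+H]+"`, `"[M+K]+"`,
#'   `"[M+Na]+"` (unicode minus accepted).
#' @return ion m/z in Da.
#' @export
adduct_mz <- function(neutral_mass, adduct) {
  if (any(neutral_mass <= 0))
    abort("neutral mass must be positive", "atlasmsi_validation_error")
  adduct <- gsub("−", "-", adduct)
  switch(adduct,
    "[M-H]-"    = neutral_mass - PROTON_MASS,
    "[M+K-2H]-" = neutral_mass - 2 * PROTON_MASS + K_CATION_MASS,
    "[M+Na-2H]-" = neutral_mass - 2 * PROTON_MASS + NA_CATION_MASS,
    "[M+H]+"    = neutral_mass + PROTON_MASS,
    "[M+K]+"    = neutral_mass + K_CATION_MASS,
    "[M+Na]+"   = neutral_mass + NA_CATION_MASS,
    abort(sprintf("unknown adduct '%s'", adduct), "atlasmsi_validation_error"))
}

#' Known PTM / adduct-exchange mass-difference rules
#'
#' Methylation +14.01565, acetylation +42.01057, K-for-H exchange +37.95588,
#' Na-for-H exchange +21.98194 Da. The default tolerance (0.05 Da) suits
#' TOF-resolution peptide data, where a printed 14.00 Da spacing is
#' compatible with exact methylation (14.0157 Da).
#'
#' @param names subset of rules to return.
#' @param tolerance_da matching tolerance in Da.
#' @return data.frame with `name`, `delta_mass`, `tolerance`.
#' @export
delta_rules <- function(names = c("methylation", "acetylation", "K_for_H",
                                  "Na_for_H"), tolerance_da = 0.05) {
  all <- c(methylation = 14.01565, acetylation = 42.01057,
           K_for_H = 37.95588, Na_for_H = 21.98194)
  bad <- setdiff(names, names(all))
  if (length(bad))
    abort(sprintf("unknown delta rule(s): %s", paste(bad, collapse = ", ")),
          "atlasmsi_validation_error")
  data.frame(name = names, delta_mass = unname(all[names]),
             tolerance = tolerance_da, stringsAsFactors = FALSE)
}

#' Find feature pairs separated by a known PTM/adduct mass delta
#'
#' Reports every unordered feature pair (a < b by m/z) whose spacing matches
#' a rule within its tolerance and whose ion images are spatially correlated
#' (Pearson across shared non-missing pixels) at least `min_spatial_corr` —
#' the "same spatial distribution, separated by X Da" pattern used to flag
#' methylation pairs and K+ adducts.
#'
#' @param features a [feature_table()].
#' @param cube a [datacube()] containing those features (for images); may be
#'   `NULL`, in which case correlation support is skipped.
#' @param rules data.frame from [delta_rules()].
#' @param min_spatial_corr minimum Pearson correlation of the two images.
#' @return data.frame with `mz_a`, `mz_b`, `rule`, `observed_delta` (4
#'   decimals), `corr`; zero rows allowed.
#' @export
find_delta_pairs <- function(features, cube = NULL, rules = delta_rules(),
                             min_spatial_corr = 0.5) {
  out <- list()
  n <- nrow(features)
  if (n >= 2) {
    o <- order(features$center_mz)
    mz <- features$center_mz[o]
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) {
        dm <- mz[j] - mz[i]
        for (r in seq_len(nrow(rules))) {
          if (abs(dm - rules$delta_mass[r]) > rules$tolerance[r]) next
          corr <- NA_real_
          if (!is.null(cube)) {
            a <- cube$values[, o[i]]; b <- cube$values[, o[j]]
            ok <- !is.na(a) & !is.na(b)
            corr <- if (sum(ok) >= 3 && sd(a[ok]) > 0 && sd(b[ok]) > 0)
              cor(a[ok], b[ok]) else NA_real_
            if (is.na(corr) || corr < min_spatial_corr) next
          }
          out[[length(out) + 1L]] <- data.frame(
            mz_a = mz[i], mz_b = mz[j], rule = rules$name[r],
            observed_delta = round(dm, 4), corr = corr,
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (!length(out))
    return(data.frame(mz_a = numeric(), mz_b = numeric(), rule = character(),
                      observed_delta = numeric(), corr = numeric()))
  do.call(rbind, out)
}

#' Embedded compound panel
#'
#' A small CSD-relevant metabolite table (glutamate, fructose
#' 1,6-bisphosphate, AMP, ADP, ATP, lactate, pyruvate, glucose, creatine)
#' shipped as a plain CSV fixture; user tables use the same columns
#' (`name`, `formula`).
#'
#' @param path optional CSV path (defaults to the packaged table).
#' @return data.frame with `name`, `formula`, `neutral_monoisotopic_mass`.
#' @export
compound_table <- function(path = NULL) {
  path <- path %||% system.file("extdata", "compounds.csv",
                                package = "atlasmsi", mustWork = TRUE)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (is.null(tab$neutral_monoisotopic_mass))
    tab$neutral_monoisotopic_mass <- NA_real_
  miss <- is.na(tab$neutral_monoisotopic_mass)
  tab$neutral_monoisotopic_mass[miss] <-
    vapply(tab$formula[miss], monoisotopic_mass, numeric(1))
  tab
}

#' Match an observed m/z against a compound table
#'
#' Every (compound, adduct) whose theoretical ion m/z lies within `ppm_tol`
#' of the observation, ranked by absolute ppm error. Because isobars are
#' common at metabolite masses, the result is a ranked candidate list, never
#' a unique identity.
#'
#' @param observed_mz observed ion m/z (Da).
#' @param polarity `"+"` or `"-"`; selects which adducts are considered.
#' @param compounds data.frame from [compound_table()].
#' @param adducts adduct strings to try (defaults by polarity).
#' @param ppm_tol tolerance in ppm (default 10, FTICR-style accuracy).
#' @return data.frame `name`, `adduct`, `theoretical_mz`, `ppm_error`,
#'   sorted by `|ppm_error|`.
#' @export
match_compounds <- function(observed_mz, polarity = "-",
                            compounds = compound_table(), adducts = NULL,
                            ppm_tol = 10) {
  if (ppm_tol <= 0) abort("ppm_tol must be positive", "atlasmsi_validation_error")
  if (is.null(compounds) || !nrow(compounds))
    abort("empty compound table", "atlasmsi_validation_error")
  adducts <- adducts %||% if (polarity == "-")
    c("[M-H]-", "[M+K-2H]-", "[M+Na-2H]-") else c("[M+H]+", "[M+K]+", "[M+Na]+")
  out <- list()
  for (i in seq_len(nrow(compounds))) {
    for (ad in adducts) {
      th <- adduct_mz(compounds$neutral_monoisotopic_mass[i], ad)
      ppm <- (observed_mz - th) / th * 1e6
      if (abs(ppm) <= ppm_tol)
        out[[length(out) + 1L]] <- data.frame(
          name = compounds$name[i], adduct = ad, theoretical_mz = th,
          ppm_error = ppm, stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(name = character(), adduct = character(),
                      theoretical_mz = numeric(), ppm_error = numeric()))
  res <- do.call(rbind, out)
  res[order(abs(res$ppm_error)), , drop = FALSE]
}
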