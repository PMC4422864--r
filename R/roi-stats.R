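# Animal-level region statistics. The unit of analysis is the animal
# (per-animal ROI-by-hemisphere mean over retained pixels), never the pixel:
# with n = 5-6 animals per group, pixel-level testing would be
# pseudo-replication.

#' Extract per-animal region profiles from an atlas-aligned cube
#'
#' For every ROI-by-hemisphere cell, the mean feature vector over non-missing
#' cube pixels carrying that atlas label; pixel counts are recorded. Cells
#' with zero retained pixels are omitted (with a message).
#'
#' @param aligned_cube a [datacube()] resampled onto the atlas grid
#'   (`transform_applied` must be TRUE).
#' @param atlas_section the [atlas_section()] defining labels and midline.
#' @param rois region names to extract.
#' @return long data.frame: `animal_id`, `roi`, `hemisphere`, `feature_id`,
#'   `feature_mz`, `value`, `n_pixels`.
#' @export
extract_region_profiles <- function(aligned_cube, atlas_section,
                                    rois = c("cortex", "striatum",
                                             "hippocampus", "thalamus")) {
  if (!aligned_cube$transform_applied)
    abort("cube must be on the atlas grid", "atlasmsi_validation_error")
  labs <- atlas_section$labels
  px_label <- labs[cbind(aligned_cube$coords[, 2] + 1L,
                         aligned_cube$coords[, 1] + 1L)]
  hemi <- hemisphere_of(aligned_cube$coords[, 1], atlas_section$midline_col)
  animal <- aligned_cube$meta$animal_id %||% NA_character_
  out <- list()
  for (roi in rois) {
    lab <- as.integer(names(atlas_section$legend)[atlas_section$legend == roi])
    for (hm in c("L", "R")) {
      sel <- which(px_label == lab & hemi == hm)
      vals <- aligned_cube$values[sel, , drop = FALSE]
      keep <- rowSums(is.na(vals)) == 0
      if (!any(keep)) {
        message(sprintf("ROI %s/%s: no retained pixels for %s; row omitted",
                        roi, hm, animal))
        next
      }
      m <- colMeans(vals[keep, , drop = FALSE])
      out[[length(out) + 1L]] <- data.frame(
        animal_id = animal, roi = roi, hemisphere = hm,
        feature_id = seq_along(m),
        feature_mz = aligned_cube$features$center_mz,
        value = m, n_pixels = sum(keep), row.names = NULL)
    }
  }
  do.call(rbind, out)
}

#' Paired hemisphere t-test
#'
#' Two-sided paired Student t on per-animal left-minus-right differences
#' (df = n - 1). With zero variance the p-value is reported at its
#' df-appropriate limit: 0 for a nonzero mean difference, 1 otherwise.
#'
#' @param l,r per-animal left and right values (same animal order).
#' @return list with `t`, `df`, `p`, `estimate` (mean L - R).
#' @export
paired_hemisphere_test <- function(l, r) {
  if (length(l) != length(r) || length(l) < 2)
    abort("paired test needs >= 2 animals with both hemispheres",
          "atlasmsi_validation_error")
  d <- l - r
  n <- length(d)
  m <- mean(d); s <- sd(d)
  if (s == 0) {
    t <- if (m == 0) 0 else sign(m) * Inf
  } else {
    t <- m / (s / sqrt(n))
  }
  p <- 2 * pt(-abs(t), df = n - 1)
  list(t = t, df = n - 1, p = p, estimate = m)
}

#' Two-sample (non-paired) Student t-test
#'
#' Equal-variance by default, matching the plain Student test; Welch's
#' correction is available by flag.
#'
#' @param a,b the two groups' per-animal values.
#' @param welch use the Welch-Satterthwaite form?
#' @return list with `t`, `df`, `p`, `estimate` (mean(a) - mean(b)).
#' @export
group_test <- function(a, b, welch = FALSE) {
  if (length(a) < 2 || length(b) < 2)
    abort("group test needs >= 2 animals per group", "atlasmsi_validation_error")
  na <- length(a); nb <- length(b)
  est <- mean(a) - mean(b)
  if (welch) {
    va <- var(a) / na; vb <- var(b) / nb
    se <- sqrt(va + vb)
    df <- (va + vb)^2 / (va^2 / (na - 1) + vb^2 / (nb - 1))
  } else {
    sp2 <- ((na - 1) * var(a) + (nb - 1) * var(b)) / (na + nb - 2)
    se <- sqrt(sp2 * (1 / na + 1 / nb))
    df <- na + nb - 2
  }
  t <- if (se == 0) (if (est == 0) 0 else sign(est) * Inf) else est / se
  list(t = t, df = df, p = 2 * pt(-abs(t), df), estimate = est)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' `q_(i) = min_(j >= i) ( p_(j) * m / j )`, capped at 1, returned in input
#' order.
#'
#' @param p raw p-values in `[0, 1]`.
#' @return adjusted q-values.
#' @export
bh_adjust <- function(p) {
  if (!length(p)) return(numeric(0))
  if (any(is.na(p)) || any(p < 0 | p > 1))
    abort("p-values must lie in [0, 1]", "atlasmsi_validation_error")
  m <- length(p)
  o <- order(p)
  q_sorted <- pmin(1, rev(cummin(rev(p[o] * m / seq_len(m)))))
  q <- numeric(m)
  q[o] <- q_sorted
  q
}

#' Run the full study comparison plan
#'
#' For every feature and ROI: (a) a paired L-vs-R test within each
#' genotype-condition group; (b) optional unpaired between-group comparisons
#' on a matched hemisphere. BH adjustment is applied within each
#' (ROI x comparison) family across features (configurable via `bh_family`),
#' and rows are flagged significant at `q < alpha`.
#'
#' @param profiles long profile table from [extract_region_profiles()]
#'   (rows for all animals).
#' @param design the [study_design()].
#' @param alpha significance level on the BH-adjusted q.
#' @param group_comparisons list of `c(group_a, group_b, hemisphere)`
#'   triplets for unpaired tests (hemisphere `"L"`, `"R"` or `"mean"`).
#' @param welch use Welch's t for the unpaired comparisons?
#' @param bh_family `"roi_comparison"` (default), `"comparison"` or
#'   `"global"`.
#' @return data.frame of class `region_stats`: one row per feature x ROI x
#'   comparison with `mean_a`/`mean_b` (L/R or group means), `estimate`,
#'   `direction`, `p_raw`, `q_bh`, `significant`.
#' @export
run_study_statistics <- function(profiles, design, alpha = 0.05,
                                 group_comparisons = list(), welch = FALSE,
                                 bh_family = c("roi_comparison", "comparison",
                                               "global")) {
  bh_family <- match.arg(bh_family)
  missing_animals <- setdiff(design$animal_id, unique(profiles$animal_id))
  if (length(missing_animals))
    abort(sprintf("profiles missing animal(s): %s",
                  paste(missing_animals, collapse = ", ")),
          "atlasmsi_validation_error")
  rois <- unique(profiles$roi)
  feats <- unique(profiles[, c("feature_id", "feature_mz")])
  rows <- list()
  grp_of <- setNames(design$group, design$animal_id)

  for (roi in rois) {
    proi <- profiles[profiles$roi == roi, ]
    for (g in unique(design$group)) {
      animals <- design$animal_id[design$group == g]
      for (k in seq_len(nrow(feats))) {
        sub <- proi[proi$feature_id == feats$feature_id[k] &
                      proi$animal_id %in% animals, ]
        subl <- sub[sub$hemisphere == "L", ]
        subr <- sub[sub$hemisphere == "R", ]
        l <- subl$value[match(animals, subl$animal_id)]
        r <- subr$value[match(animals, subr$animal_id)]
        ok <- !is.na(l) & !is.na(r)
        if (sum(ok) < 2) next
        res <- paired_hemisphere_test(l[ok], r[ok])
        rows[[length(rows) + 1L]] <- data.frame(
          feature_mz = feats$feature_mz[k], feature_id = feats$feature_id[k],
          roi = roi, comparison = paste0(g, ":L-vs-R"), n = sum(ok),
          mean_a = mean(l[ok]), mean_b = mean(r[ok]),
          estimate = res$estimate,
          direction = ifelse(res$estimate > 0, "L>R",
                             ifelse(res$estimate < 0, "L<R", "none")),
          p_raw = res$p, stringsAsFactors = FALSE)
      }
    }
    for (cmp in group_comparisons) {
      ga <- cmp[1]; gb <- cmp[2]
      hm <- if (length(cmp) >= 3) cmp[3] else "mean"
      for (k in seq_len(nrow(feats))) {
        sub <- proi[proi$feature_id == feats$feature_id[k], ]
        pick <- function(g) {
          s <- sub[grp_of[sub$animal_id] == g, ]
          if (hm == "mean") {
            v <- tapply(s$value, s$animal_id, mean)
          } else {
            s <- s[s$hemisphere == hm, ]
            v <- setNames(s$value, s$animal_id)
          }
          as.numeric(v[!is.na(v)])
        }
        a <- pick(ga); b <- pick(gb)
        if (length(a) < 2 || length(b) < 2) next
        res <- group_test(a, b, welch = welch)
        rows[[length(rows) + 1L]] <- data.frame(
          feature_mz = feats$feature_mz[k], feature_id = feats$feature_id[k],
          roi = roi, comparison = sprintf("%s-vs-%s:%s", ga, gb, hm),
          n = length(a) + length(b),
          mean_a = mean(a), mean_b = mean(b), estimate = res$estimate,
          direction = ifelse(res$estimate > 0, paste0(ga, ">", gb),
                             ifelse(res$estimate < 0, paste0(ga, "<", gb),
                                    "none")),
          p_raw = res$p, stringsAsFactors = FALSE)
      }
    }
  }
  tab <- do.call(rbind, rows)
  if (is.null(tab)) {
    tab <- data.frame(feature_mz = numeric(), feature_id = integer(),
                      roi = character(), comparison = character(),
                      n = integer(), mean_a = numeric(), mean_b = numeric(),
                      estimate = numeric(), direction = character(),
                      p_raw = numeric())
  }
  fam <- switch(bh_family,
    roi_comparison = paste(tab$roi, tab$comparison),
    comparison = tab$comparison,
    global = rep("all", nrow(tab)))
  tab$q_bh <- NA_real_
  for (f in unique(fam)) {
    i <- fam == f
    tab$q_bh[i] <- bh_adjust(tab$p_raw[i])
  }
  tab$significant <- tab$q_bh < alpha
  class(tab) <- c("region_stats", "data.frame")
  tab
}

#' Semi-supervised block randomization of sections across slides
#'
#' Greedy seeded assignment maximizing group heterogeneity within each slide
#' (each slot takes an animal from the not-yet-represented group with the
#' largest remaining count, random tie-breaks), then randomizes within-slide
#' positions and the global acquisition order.
#'
#' @param design a [study_design()].
#' @param slots_per_slide sections per slide (4 in the emulated layout).
#' @param seed RNG seed.
#' @return the design with `slide_id`, `slide_position` and
#'   `acquisition_order` filled.
#' @export
block_randomize <- function(design, slots_per_slide = 4, seed = 1) {
  if (slots_per_slide < 1)
    abort("slots_per_slide must be >= 1", "atlasmsi_validation_error")
  n <- nrow(design)
  with_seed(seed, {
    remaining <- split(design$animal_id, design$group)
    remaining <- lapply(remaining, sample)
    slide_of <- setNames(integer(n), design$animal_id)
    pos_of <- setNames(integer(n), design$animal_id)
    slide <- 1L
    while (any(lengths(remaining) > 0)) {
      on_slide <- character(0)
      for (slot in seq_len(min(slots_per_slide, sum(lengths(remaining))))) {
        counts <- lengths(remaining)
        cand <- names(counts)[counts > 0 & !(names(counts) %in% on_slide)]
        if (!length(cand)) cand <- names(counts)[counts > 0]
        cand <- cand[counts[cand] == max(counts[cand])]
        g <- if (length(cand) > 1) sample(cand, 1) else cand
        a <- remaining[[g]][1]
        remaining[[g]] <- remaining[[g]][-1]
        on_slide <- c(on_slide, g)
        slide_of[a] <- slide
        pos_of[a] <- slot
      }
      # shuffle the physical positions within the slide
      placed <- names(slide_of)[slide_of == slide]
      pos_of[placed] <- sample(seq_along(placed))
      slide <- slide + 1L
    }
    design$slide_id <- slide_of[design$animal_id]
    design$slide_position <- pos_of[design$animal_id]
    design$acquisition_order <- sample(n)
  })
  design
}

#' Post-mortem degradation QC via a metabolite ratio
#'
#' Computes a per-animal whole-section ratio of two features (pixel-weighted
#' over all ROIs) and its Pearson correlation with post-mortem time —
#' emulating the AMP/ATP check for post-mortem degradation. Animals with a
#' nonpositive denominator are excluded (logged); if the ratios have zero
#' variance the correlation is reported as 0 with `degenerate = TRUE`.
#'
#' @param profiles long profile table covering all animals.
#' @param numerator_id,denominator_id `feature_id`s of the ratio.
#' @param times named vector of post-mortem minutes (names = animal ids).
#' @return list with `ratios` (data.frame), `r`, `p`, `degenerate`.
#' @export
qc_metabolite_ratio <- function(profiles, numerator_id, denominator_id, times) {
  animals <- unique(profiles$animal_id)
  ratio <- setNames(rep(NA_real_, length(animals)), animals)
  for (an in animals) {
    s <- profiles[profiles$animal_id == an, ]
    num <- s[s$feature_id == numerator_id, ]
    den <- s[s$feature_id == denominator_id, ]
    wnum <- sum(num$value * num$n_pixels) / sum(num$n_pixels)
    wden <- sum(den$value * den$n_pixels) / sum(den$n_pixels)
    if (!is.finite(wden) || wden <= 0) {
      message(sprintf("animal %s excluded from QC: nonpositive denominator", an))
      next
    }
    ratio[an] <- wnum / wden
  }
  ok <- !is.na(ratio)
  df <- data.frame(animal_id = names(ratio)[ok], ratio = ratio[ok],
                   postmortem_min = as.numeric(times[names(ratio)[ok]]),
                   row.names = NULL)
  if (sd(df$ratio) == 0 || sd(df$postmortem_min) == 0) {
    return(list(ratios = df, r = 0, p = NA_real_, degenerate = TRUE))
  }
  ct <- stats::cor.test(df$ratio, df$postmortem_min)
  list(ratios = df, r = unname(ct$estimate), p = ct$p.value,
       degenerate = FALSE)
}
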