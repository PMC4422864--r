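make_atlas_cube <- function(atl, fill) {
  # cube on the atlas grid with one feature painted via `fill(label, hemi)`
  h <- nrow(atl$labels); w <- ncol(atl$labels)
  pts <- atlasmsi:::grid_points(h, w)
  lab <- atl$labels[cbind(pts[, 2] + 1L, pts[, 1] + 1L)]
  hemi <- ifelse(pts[, 1] < atl$midline_col, "L", "R")
  vals <- matrix(fill(lab, hemi), ncol = 1)
  datacube(pts, feature_table(146, 145.5, 146.5), vals,
           meta = list(animal_id = "A1"), transform_applied = TRUE)
}

test_that("region profiles average the painted cube values", {
  atl <- generate_atlas(1, seed = 12)[[1]]
  uni <- make_atlas_cube(atl, function(lab, hemi) rep(7, length(lab)))
  prof <- extract_region_profiles(uni, atl)
  expect_identical(nrow(prof), 8L)  # 4 ROIs x 2 hemispheres
  expect_true(all(prof$value == 7))
  expect_true(all(prof$n_pixels > 0))

  lr <- make_atlas_cube(atl, function(lab, hemi)
    ifelse(lab == 1L & hemi == "L", 2, ifelse(lab == 1L & hemi == "R", 4, 0)))
  prof2 <- extract_region_profiles(lr, atl)
  expect_equal(prof2$value[prof2$roi == "cortex" & prof2$hemisphere == "L"], 2)
  expect_equal(prof2$value[prof2$roi == "cortex" & prof2$hemisphere == "R"], 4)

  # an all-missing ROI is omitted with a message
  holed <- make_atlas_cube(atl, function(lab, hemi) rep(1, length(lab)))
  holed$values[atl$labels[cbind(holed$coords[, 2] + 1L,
                                holed$coords[, 1] + 1L)] == 4L, ] <- NA
  expect_message(prof3 <- extract_region_profiles(holed, atl), "omitted")
  expect_false(any(prof3$roi == "thalamus"))
})

test_that("paired hemisphere t-test matches the closed form", {
  # differences (1.0, 1.2, 0.8): t = mean/ (sd/sqrt(3)) with df = 2
  res <- paired_hemisphere_test(c(2.0, 2.2, 1.8), c(1, 1, 1))
  expect_equal(res$t, 8.6603, tolerance = 1e-4)
  expect_equal(res$df, 2)
  expect_equal(res$p, 0.01307, tolerance = 1e-3)
  expect_equal(res$estimate, 1)
  # identical hemispheres: t = 0, p = 1
  same <- paired_hemisphere_test(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)
  # zero variance with nonzero mean: p at its df-appropriate limit
  lim <- paired_hemisphere_test(c(2, 3, 4), c(1, 2, 3))
  expect_identical(lim$t, Inf)
  expect_identical(lim$p, 0)
  expect_error(paired_hemisphere_test(1, 2), class = "atlasmsi_validation_error")
})

test_that("planted lfc -1 at low noise is detected at n = 5", {
  set.seed(31)
  hits <- replicate(20, {
    l <- rpois(5, 200 * 150) / 150
    r <- rpois(5, 100 * 150) / 150
    paired_hemisphere_test(l, r)$p < 0.05
  })
  expect_true(all(hits))
})

test_that("unpaired group test matches the pooled-variance closed form", {
  res <- group_test(c(1, 2, 3), c(2, 3, 4))
  expect_equal(res$t, -1.2247, tolerance = 1e-4)
  expect_equal(res$df, 4)
  expect_equal(res$p, 0.2878, tolerance = 1e-3)
  expect_equal(res$estimate, -1)
  same <- group_test(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)
  welch <- group_test(c(1, 2, 3), c(2, 4, 6, 8), welch = TRUE)
  expect_lt(welch$df, 5)  # Welch df below the pooled df
  expect_error(group_test(1, c(2, 3)), class = "atlasmsi_validation_error")
})

test_that("BH adjustment implements the step-up definition", {
  expect_equal(bh_adjust(0.03), 0.03)
  expect_equal(bh_adjust(c(0.01, 0.04, 0.03)), c(0.03, 0.04, 0.04))
  expect_equal(bh_adjust(rep(0.05, 3)), rep(0.05, 3))
  expect_error(bh_adjust(c(0.5, 1.2)), class = "atlasmsi_validation_error")
  # oracle equivalence + elementwise dominance + rank monotonicity
  set.seed(17)
  for (i in 1:200) {
    p <- runif(sample(1:50, 1))
    q <- bh_adjust(p)
    expect_lt(max(abs(q - bh_brute(p))), 1e-12)
    expect_true(all(q >= p))
    expect_true(all(diff(q[order(p)]) >= -1e-15))
  }
})

test_that("the study comparison plan produces the full table", {
  design <- small_design(2)
  profiles <- simulate_null_profiles(design, n_features = 3, seed = 23)
  tab <- run_study_statistics(profiles, design,
                              group_comparisons = list(
                                c("WT-CSD", "R192Q-CSD", "R")))
  # 3 features x 4 ROIs x (6 paired + 1 unpaired comparisons)
  expect_identical(nrow(tab), 3L * 4L * 7L)
  expect_true(all(tab$q_bh >= tab$p_raw - 1e-15))
  expect_true(all(tab$significant == (tab$q_bh < 0.05)))
  # alpha = 0 -> nothing significant
  tab0 <- run_study_statistics(profiles, design, alpha = 0)
  expect_identical(sum(tab0$significant), 0L)
  # missing animals are reported by id
  expect_error(run_study_statistics(profiles[profiles$animal_id != "A03", ],
                                    design),
               regexp = "A03", class = "atlasmsi_validation_error")
})

test_that("estimates of the L-R difference are unbiased on synthetic data", {
  true_diff <- 5
  set.seed(41)
  est <- replicate(200, {
    l <- rpois(6, 105 * 120) / 120
    r <- rpois(6, 100 * 120) / 120
    paired_hemisphere_test(l, r)$estimate
  })
  se <- sd(est) / sqrt(length(est))
  expect_lt(abs(mean(est) - true_diff), 2 * se + 1e-9)
})

test_that("block randomization maximizes within-slide group diversity", {
  design <- default_study_design()
  r1 <- block_randomize(design, slots_per_slide = 4, seed = 5)
  expect_identical(sort(unique(r1$slide_id)), 1:8)
  for (s in unique(r1$slide_id)) {
    g <- r1$group[r1$slide_id == s]
    expect_identical(length(unique(g)), 4L)  # 4 distinct groups per slide
    expect_setequal(r1$slide_position[r1$slide_id == s], 1:4)
  }
  expect_setequal(r1$acquisition_order, 1:32)
  # determinism
  r2 <- block_randomize(design, slots_per_slide = 4, seed = 5)
  expect_identical(r1, r2)
  # degenerate single-group design is still a valid assignment
  solo <- study_design(paste0("S", 1:4), rep("WT", 4), rep("CSD", 4))
  rs <- block_randomize(solo, 4, seed = 2)
  expect_identical(sort(rs$slide_position), 1:4)
  expect_error(block_randomize(design, 0), class = "atlasmsi_validation_error")
})

test_that("the post-mortem QC ratio behaves at its contract edges", {
  design <- small_design(2)
  profiles <- simulate_null_profiles(design, n_features = 2, seed = 29)
  times <- setNames(seq_len(nrow(design)) + 4, design$animal_id)
  # numerator == denominator -> all ratios exactly 1, degenerate r = 0
  qc1 <- qc_metabolite_ratio(profiles, 1, 1, times)
  expect_true(all(qc1$ratios$ratio == 1))
  expect_identical(qc1$r, 0)
  expect_true(qc1$degenerate)
  # independent ratio vs time: a correlation is estimable and |r| << 1
  qc2 <- qc_metabolite_ratio(profiles, 1, 2, times)
  expect_false(qc2$degenerate)
  expect_lt(abs(qc2$r), 0.9)
  expect_true(is.finite(qc2$p))
})
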