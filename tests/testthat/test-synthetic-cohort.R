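test_that("phantom shells are radial, labeled, and deterministic", {
  g <- make_phantom_geometry(400, 4, 12, 2.5)
  len <- sqrt(rowSums((g$pial - g$wm)^2))
  expect_true(all(abs(len - 2.5) < 1e-9))
  expect_identical(sort(unique(g$roi)), 1:4)
  expect_true(all(tabulate(g$roi, 4L) > 0))
  g2 <- make_phantom_geometry(400, 4, 12, 2.5)
  expect_identical(g$pial, g2$pial)
  expect_identical(g$wm, g2$wm)
  expect_identical(g$roi, g2$roi)
  # vertices map inside the voxel grid
  ijk <- rbind(g$pial, g$wm)
  ijk <- t(solve(g$affine) %*% rbind(t(ijk), 1))[, 1:3]
  expect_true(all(ijk >= 0 & ijk <= rep(g$shape - 1, each = nrow(ijk))))
  expect_error(
    make_phantom_geometry(100, 2, 12, 2.5,
                          grid_spec = list(shape = c(10, 10, 10))),
    "too small")
})

test_that("rd field matches the baseline profile at depth", {
  g <- small_phantom()
  base <- seq(1.1e-3, 0.7e-3, length.out = 21)
  vol <- make_rd_field(g, base)
  # midpoint of a vertex pair sits at 50% depth
  mid <- (g$pial[1, ] + g$wm[1, ]) / 2
  v <- sample_column_profile(vol, list(pial = mid, wm = mid))[1]
  expect_equal(v, base[11], tolerance = 0.02)

  flat <- make_rd_field(g, rep(1e-3, 21))
  expect_true(all(abs(flat[attr(flat, "ribbon")] - 1e-3) < 1e-15))
})

test_that("roi offsets shift the field by exactly the offset at depth", {
  g <- small_phantom()
  base <- rep(1e-3, 21)
  vol0 <- make_rd_field(g, base)
  vol1 <- make_rd_field(g, base, roi_offsets = c(0.1e-3, 0, 0, 0),
                        depth_weights = rep(1, 8))
  ribbon <- attr(vol0, "ribbon")
  delta <- vol1[ribbon] - vol0[ribbon]
  # recover each ribbon voxel's ROI by direct field evaluation: voxels
  # whose value moved carry ROI 1, the rest must be untouched
  expect_true(all(abs(delta) < 1e-15 | abs(delta - 0.1e-3) < 1e-15))
  expect_gt(sum(abs(delta - 0.1e-3) < 1e-15), 0)
})

test_that("dwi simulation follows the closed-form signal and the seed", {
  tf <- array(0, c(2, 2, 2, 6))
  tf[, , , 1:3] <- 1e-3 # isotropic, trace 3e-3
  attr(tf, "affine") <- diag(4)
  dwi <- make_dwi(tf, b_value = 800, n_b0 = 2, noise_sd = 0)
  dw <- dwi$volumes[, , , dwi$b_values > 0]
  expect_equal(as.vector(dw), rep(1000 * exp(-0.8), length(dw)),
               tolerance = 1e-12)
  d1 <- make_dwi(tf, noise_sd = 5, seed = 42)
  d2 <- make_dwi(tf, noise_sd = 5, seed = 42)
  expect_identical(d1$volumes, d2$volumes)
  d3 <- make_dwi(tf, noise_sd = 5, seed = 43)
  expect_false(identical(d1$volumes, d3$volumes))
})

test_that("non-positive-definite tensors warn but still produce signals", {
  tf <- array(0, c(1, 1, 1, 6))
  tf[, , , 1] <- -1e-3; tf[, , , 2:3] <- 1e-3
  attr(tf, "affine") <- diag(4)
  expect_warning(dwi <- make_dwi(tf), "non-positive-definite")
  expect_true(all(is.finite(dwi$volumes)))
})

test_that("simulated cohorts honor the group design and invariants", {
  spec <- cohort_spec(n_rois = 4, ad_roi_ids = 1:2, seed = 3)
  g <- small_phantom()
  coh <- simulate_cohort(spec, g)
  expect_equal(nrow(coh$participants), 60L)
  expect_equal(tabulate(coh$participants$group, 4L), c(17L, 16L, 15L, 12L))
  # amyloid invariant: group 1 above the cutoff, groups 2-4 below
  p <- coh$participants
  expect_true(all(p$abeta_ratio[p$group == 1] > spec$abeta_cutoff))
  expect_true(all(p$abeta_ratio[p$group > 1] < spec$abeta_cutoff,
                  na.rm = TRUE))
  # group-mean field value in AD ROIs increases with severity by
  # construction (zero-noise check)
  spec0 <- cohort_spec(group_sizes = c(3, 3, 3, 3), n_rois = 4,
                       ad_roi_ids = 1:2, between_subject_sd = 0,
                       measurement_sd = 0, seed = 3)
  coh0 <- simulate_cohort(spec0, g)
  ribbon <- attr(coh0$images[[1]], "ribbon")
  means <- vapply(1:4, function(grp) {
    idx <- which(coh0$participants$group == grp)
    mean(vapply(idx, function(i) mean(coh0$images[[i]][ribbon]),
                numeric(1)))
  }, numeric(1))
  expect_true(all(diff(means) > 0))
})

test_that("zero-severity zero-noise cohorts are identical across participants", {
  spec <- cohort_spec(group_sizes = c(2, 2, 2, 2), n_rois = 4,
                      group_severity = rep(0, 4), between_subject_sd = 0,
                      measurement_sd = 0, seed = 1)
  coh <- simulate_cohort(spec, small_phantom())
  for (i in 2:8) expect_identical(coh$images[[i]], coh$images[[1]])
})

test_that("table-level generator reproduces its construction formula", {
  spec0 <- cohort_spec(group_sizes = c(2, 2, 2, 2), n_rois = 6,
                       ad_roi_ids = 1:2, group_severity = rep(0, 4),
                       between_subject_sd = 0, measurement_sd = 0)
  tab0 <- make_depthbin_table(spec0)
  bb <- bin_profile(spec0$baseline_profile)
  for (p in 1:8) for (r in 1:6) {
    expect_equal(unname(tab0$values[p, r, ]), unname(bb))
  }

  sev <- c(0, 0.05e-3, 0.1e-3, 0.2e-3)
  spec1 <- cohort_spec(group_sizes = c(2, 2, 2, 2), n_rois = 6,
                       ad_roi_ids = 1:2, group_severity = sev,
                       between_subject_sd = 0, measurement_sd = 0)
  tab1 <- make_depthbin_table(spec1)
  g1 <- which(tab1$participants$group == 1)[1]
  g4 <- which(tab1$participants$group == 4)[1]
  for (b in 1:8) {
    expect_equal(tab1$values[g4, 1, b] - tab1$values[g1, 1, b],
                 0.2e-3 * spec1$depth_effect_weights[b], tolerance = 1e-12)
    expect_equal(tab1$values[g4, 5, b], tab1$values[g1, 5, b]) # null ROI
  }

  expect_identical(make_depthbin_table(spec1)$values, tab1$values)
})

test_that("image- and table-level paths agree at zero noise", {
  spec <- cohort_spec(group_sizes = c(3, 2, 2, 2), n_rois = 4,
                      ad_roi_ids = 1:2, between_subject_sd = 0,
                      measurement_sd = 0, seed = 5)
  tab <- make_depthbin_table(spec)
  g <- make_phantom_geometry(800, 4, 12, 2.5,
                             grid_spec = list(spacing_mm = 0.5))
  bp <- spec$baseline_profile
  coh <- simulate_cohort(spec, g, wm_value = bp[21], csf_value = bp[1])
  itab <- build_table(coh, "RD", "bins8")
  rel <- abs(itab$values - tab$values) / abs(tab$values)
  expect_lt(max(rel), 0.02)
})

test_that("planted decliners are group-2 members with extra AD elevation", {
  spec <- cohort_spec(n_rois = 6, ad_roi_ids = 1:2, n_decliners = 2L,
                      decliner_elevation = 2e-4, seed = 12)
  tab <- make_depthbin_table(spec)
  p <- tab$participants
  expect_equal(sum(p$ad_extra > 0), 2L)
  expect_true(all(p$group[p$ad_extra > 0] == 2L))
  expect_equal(p$true_elevation,
               spec$group_severity[p$group] + p$ad_extra + p$intercept)
  # planted elevation lands in AD ROIs only, depth-weighted like severity
  d <- which(p$ad_extra > 0)[1]
  ref <- which(p$group == 2L & p$ad_extra == 0)[1]
  spec0 <- spec; spec0$measurement_sd <- 0; spec0$between_subject_sd <- 0
  tab0 <- make_depthbin_table(spec0)
  expect_equal(tab0$values[d, 1, 3] - tab0$values[ref, 1, 3],
               2e-4 * spec$depth_effect_weights[3], tolerance = 1e-12)
  expect_equal(tab0$values[d, 5, 3], tab0$values[ref, 5, 3])
  expect_error(cohort_spec(group_sizes = c(2, 1, 2, 2), n_decliners = 2L),
               "n_decliners")
})

test_that("cohort spec validation rejects inconsistent designs", {
  expect_error(cohort_spec(group_severity = c(0.1e-3, 0, 0, 0)), "group 1")
  expect_error(cohort_spec(group_severity = c(0, 2e-4, 1e-4, 3e-4)),
               "non-decreasing")
  expect_error(cohort_spec(n_rois = 4, ad_roi_ids = 9), "subset")
  expect_error(cohort_spec(between_subject_sd = -1), "non-negative")
})
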