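test_that("logistic fit honors symmetry, separation, and the glm limit", {
  vals <- c(1, 2, 3, 7, 8, 9)
  labs <- c(1, 1, 1, 0, 0, 0)
  fit <- fit_logistic_ridge(vals, labs)
  expect_true(fit$converged)
  expect_equal(percentile_score(fit, 5), 50, tolerance = 1e-6)

  # complete separation: ridge keeps the slope finite
  expect_true(is.finite(fit$slope) && fit$slope < 0)

  # non-separable data: ridge -> 0 recovers the unpenalized ML fit
  set.seed(6)
  x <- c(rnorm(40, 0), rnorm(40, 1))
  y <- c(rep(0, 40), rep(1, 40))
  ours <- fit_logistic_ridge(x, y, ridge = 1e-10)
  ref <- glm(y ~ x, family = binomial())
  expect_equal(ours$intercept, unname(coef(ref)[1]), tolerance = 1e-6)
  expect_equal(ours$slope, unname(coef(ref)[2]), tolerance = 1e-6)

  expect_error(fit_logistic_ridge(1:4, rep(1, 4)), "both label classes")
})

test_that("percentiles follow the fitted sigmoid", {
  flat <- list(intercept = 0, slope = 0)
  expect_equal(percentile_score(flat, 123), 50)
  neg <- list(intercept = 2, slope = -1)
  expect_equal(percentile_score(neg, 2), 50)
  expect_equal(percentile_score(neg, 1e6), 0, tolerance = 1e-10)
  expect_equal(percentile_score(neg, -1e6), 100, tolerance = 1e-10)
  # strictly decreasing in the metric when the slope is negative
  grid <- seq(-5, 5, length.out = 101)
  expect_true(all(diff(percentile_score(neg, grid)) < 0))
})

scoring_fixture <- function(seed = 17) {
  spec <- cohort_spec(group_sizes = c(6, 4, 3, 5), n_rois = 6,
                      ad_roi_ids = 1:3,
                      group_severity = c(0, 0.5e-4, 1e-4, 2e-4),
                      seed = seed)
  tab <- make_depthbin_table(spec)
  res <- run_group_analysis(tab, group_ids(tab, 1), group_ids(tab, 4))
  list(tab = tab,
       m025 = select_significant(res, 0.025),
       m0025 = select_significant(res, 0.0025),
       ref_a = group_ids(tab, 1), ref_b = group_ids(tab, 4))
}

test_that("participant scoring combines masked percentiles with LOO", {
  f <- scoring_fixture()
  expect_gt(nrow(f$m0025), 0)
  pid <- group_ids(f$tab, 2)[1]
  rep1 <- score_participant(f$tab, pid, f$m025, f$m0025, f$ref_a, f$ref_b)
  expect_true(all(rep1$combos$percentile >= 0 &
                    rep1$combos$percentile <= 100))
  expect_equal(rep1$combined,
               mean(rep1$combos$percentile[rep1$combos$in_combined]))
  # non-reference participants use the full references
  expect_true(all(rep1$combos$n_a == length(f$ref_a)))
  # determinism
  rep2 <- score_participant(f$tab, pid, f$m025, f$m0025, f$ref_a, f$ref_b)
  expect_identical(rep1$combos, rep2$combos)

  # reference participants are excluded from their own fit
  repa <- score_participant(f$tab, f$ref_a[1], f$m025, f$m0025,
                            f$ref_a, f$ref_b)
  expect_true(all(repa$combos$n_a == length(f$ref_a) - 1L))
  expect_true(all(repa$combos$n_b == length(f$ref_b)))

  # single-combination combined mask
  one <- f$m0025[1, , drop = FALSE]
  rep3 <- score_participant(f$tab, pid, f$m025, one, f$ref_a, f$ref_b)
  i <- which(rep3$combos$roi == one$roi & rep3$combos$bin == one$bin)
  expect_equal(rep3$combined, rep3$combos$percentile[i])

  # combined percentile ignores the order of combinations
  shuf <- f$m025[sample(nrow(f$m025)), ]
  rep4 <- score_participant(f$tab, pid, shuf, f$m0025, f$ref_a, f$ref_b)
  expect_equal(rep4$combined, rep1$combined, tolerance = 1e-12)

  expect_error(score_participant(f$tab, f$ref_b[1], f$m025, f$m0025,
                                 f$ref_a, f$ref_b[1:2]), "below 2")
})

test_that("a participant at the normal reference mean scores above 50", {
  f <- scoring_fixture()
  tab <- f$tab
  pid <- group_ids(tab, 2)[1]
  pidx <- match(pid, tab$participants$id)
  aidx <- match(f$ref_a, tab$participants$id)
  for (i in seq_len(nrow(f$m025))) {
    r <- f$m025$roi[i]; b <- f$m025$bin[i]
    tab$values[pidx, r, b] <- mean(tab$values[aidx, r, b])
  }
  rep <- score_participant(tab, pid, f$m025, f$m0025, f$ref_a, f$ref_b)
  expect_gt(rep$combined, 50)
})

test_that("cohort scoring reproduces per-participant reports and summaries", {
  f <- scoring_fixture()
  sc <- score_cohort(f$tab, f$m025, f$m0025, f$ref_a, f$ref_b)
  expect_equal(nrow(sc$summary), nrow(f$tab$participants))
  pid <- group_ids(f$tab, 3)[2]
  direct <- score_participant(f$tab, pid, f$m025, f$m0025, f$ref_a, f$ref_b)
  cached <- sc$reports[[match(pid, sc$summary$id)]]
  expect_equal(cached$combined, direct$combined, tolerance = 1e-12)
  # monotone severity pushes group means down
  expect_true(all(diff(sc$group_summary$mean) < 0))
  # rank-based alternative stays in range and orders the groups too
  scr <- score_cohort(f$tab, f$m025, f$m0025, f$ref_a, f$ref_b,
                      method = "rank")
  expect_true(all(scr$summary$combined >= 0 & scr$summary$combined <= 100))
})

test_that("null cohorts give overlapping group ranges", {
  spec <- cohort_spec(group_sizes = c(8, 6, 6, 8), n_rois = 6,
                      ad_roi_ids = 1:3, group_severity = rep(0, 4),
                      seed = 23)
  tab <- make_depthbin_table(spec)
  res <- run_group_analysis(tab, group_ids(tab, 1), group_ids(tab, 4))
  # force a mask (nothing is truly significant under the null)
  mask <- select_significant(res, 1)
  sc <- score_cohort(tab, mask, mask, group_ids(tab, 1), group_ids(tab, 4))
  gs <- sc$group_summary
  expect_true(gs$min[gs$group == 1] < gs$max[gs$group == 4])
})

test_that("biomarker correlation is a squared Pearson coefficient", {
  x <- c(10, 20, 30, 40, 50)
  expect_equal(correlate_with_biomarker(x, 2 * x + 3), 1)
  expect_equal(correlate_with_biomarker(x, -0.5 * x + 1), 1)
  y <- c(0.04, 0.061, 0.052, 0.058, 0.049)
  hand <- (sum((x - mean(x)) * (y - mean(y))) /
             sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2)))^2
  expect_equal(correlate_with_biomarker(x, y), hand, tolerance = 1e-12)
  expect_equal(correlate_with_biomarker(x, y, subset = 1:4),
               correlate_with_biomarker(x[1:4], y[1:4]))
  expect_warning(r <- correlate_with_biomarker(x[1:2], y[1:2]), "fewer")
  expect_true(is.na(r))
  expect_warning(rz <- correlate_with_biomarker(x, rep(1, 5)), "variance")
  expect_true(is.na(rz))
  # missing ratios are dropped pairwise
  y2 <- y; y2[2] <- NA
  expect_equal(correlate_with_biomarker(x, y2),
               correlate_with_biomarker(x[-2], y[-2]))
})
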