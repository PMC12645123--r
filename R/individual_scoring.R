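#' Ridge-stabilized logistic regression on one metric value
#'
#' Fits `P(label = 1 | x) = plogis(intercept + slope * x)` by penalized
#' maximum likelihood with a small ridge penalty on the slope only, via
#' damped Newton iterations (fixed start at 0, tolerance 1e-10, at most
#' 200 iterations). The ridge guarantees finite coefficients when the two
#' reference groups are completely separated, which is likely at reference
#' sizes of ~16 vs ~11.
#'
#' @param values Numeric metric values of the reference participants.
#' @param labels 0/1 labels; 1 = cognitively normal reference (group 1),
#'   0 = dementia reference (group 4).
#' @param ridge Penalty on the slope (default 1e-4 on standardized scale
#'   applied to the raw slope; see vignette).
#' @return An object of class `logistic_fit`: `intercept`, `slope`,
#'   `ridge`, `converged`, `iterations`, `n_a` (label 1), `n_b` (label 0).
#' @export
fit_logistic_ridge <- function(values, labels, ridge = 1e-4) {
  stopifnot(length(values) == length(labels))
  labels <- as.numeric(labels)
  if (!all(labels %in% c(0, 1))) stop("labels must be 0/1")
  if (length(unique(labels)) < 2L) {
    stop("both label classes must be present")
  }
  # scale x for numerical conditioning; coefficients mapped back at exit
  mu <- mean(values); sdv <- stats::sd(values)
  if (sdv == 0) sdv <- 1
  x <- (values - mu) / sdv
  beta <- c(0, 0) # (intercept, slope) on standardized scale
  pen_loglik <- function(b) {
    eta <- b[1] + b[2] * x
    sum(labels * eta - log1p(exp(eta))) - ridge / 2 * b[2]^2
  }
  converged <- FALSE
  iter <- 0L
  for (iter in seq_len(200L)) {
    eta <- beta[1] + beta[2] * x
    p <- stats::plogis(eta)
    w <- p * (1 - p)
    grad <- c(sum(labels - p), sum((labels - p) * x) - ridge * beta[2])
    hess <- matrix(c(sum(w), sum(w * x),
                     sum(w * x), sum(w * x^2) + ridge), 2, 2)
    step <- tryCatch(solve(hess, grad), error = function(e) grad / max(diag(hess)))
    # damping: halve until the penalized log-likelihood does not decrease
    ll0 <- pen_loglik(beta)
    lam <- 1
    repeat {
      cand <- beta + lam * step
      if (pen_loglik(cand) >= ll0 - 1e-12 || lam < 1e-8) break
      lam <- lam / 2
    }
    beta <- beta + lam * step
    if (max(abs(lam * step)) < 1e-10) {
      converged <- TRUE
      break
    }
  }
  structure(
    list(intercept = beta[1] - beta[2] * mu / sdv, slope = beta[2] / sdv,
         ridge = ridge, converged = converged, iterations = iter,
         n_a = sum(labels == 1), n_b = sum(labels == 0)),
    class = "logistic_fit"
  )
}

#' @export
print.logistic_fit <- function(x, ...) {
  cat(sprintf("<logistic_fit> intercept %.4g, slope %.4g (n = %d vs %d, %s)\n",
              x$intercept, x$slope, x$n_a, x$n_b,
              if (x$converged) "converged" else "NOT converged"))
  invisible(x)
}

#' Percentile from a logistic reference fit
#'
#' Maps a participant's metric value through the fitted sigmoid:
#' `100 * plogis(intercept + slope * value)`. With label 1 = cognitively
#' normal reference, high percentiles indicate similarity to the normal
#' group and low percentiles similarity to the dementia group.
#'
#' @param fit A [fit_logistic_ridge()] result.
#' @param value Metric value(s) of the participant under test.
#' @return Percentile(s) in [0, 100].
#' @export
percentile_score <- function(fit, value) {
  100 * stats::plogis(fit$intercept + fit$slope * value)
}

# Rank-based alternative percentile: position of the participant's value
# within the pooled reference values, oriented so that values typical of
# the label-1 (normal) references score high.
rank_percentile <- function(values, labels, value) {
  pooled <- sort(values)
  r <- (sum(pooled < value) + 0.5 * sum(pooled == value)) / length(pooled)
  if (mean(values[labels == 1]) <= mean(values[labels == 0])) {
    100 * (1 - r)
  } else {
    100 * r
  }
}

#' Score one participant against the reference groups
#'
#' For every ROI x depth-bin combination in the screening mask
#' (q <= 0.025), fits the logistic reference model on groups 1 and 4 and
#' derives the participant's percentile; the combined percentile is the
#' unweighted mean over the combinations of the high-confidence mask
#' (q <= 0.0025). A participant belonging to a reference group is excluded
#' from that group before fitting (leave-one-out).
#'
#' @param table A [depthbin_table()].
#' @param participant_id Id of the participant under test.
#' @param mask_025 Screening [select_significant()] mask (q <= 0.025).
#' @param mask_0025 High-confidence mask (q <= 0.0025) over which the
#'   combined percentile is averaged.
#' @param reference_a_ids Ids of the cognitively normal references
#'   (label 1).
#' @param reference_b_ids Ids of the dementia references (label 0).
#' @param ridge Ridge penalty for [fit_logistic_ridge()].
#' @param method `"logistic"` (default) or `"rank"` (rank-based
#'   alternative percentile).
#' @param fits Optional precomputed list of fits (internal cache used by
#'   [score_cohort()] for non-reference participants).
#' @return An object of class `percentile_report`: `id`, `combos`
#'   (data.frame `roi`, `bin`, `percentile`, `in_combined`, `n_a`, `n_b`),
#'   and `combined`.
#' @export
score_participant <- function(table, participant_id, mask_025, mask_0025,
                              reference_a_ids, reference_b_ids,
                              ridge = 1e-4,
                              method = c("logistic", "rank"), fits = NULL) {
  method <- match.arg(method)
  if (nrow(mask_025) == 0L) stop("the screening mask is empty")
  ids <- table$participants$id
  pidx <- match(participant_id, ids)
  if (is.na(pidx)) stop(sprintf("participant '%s' not in table", participant_id))
  in_a <- participant_id %in% reference_a_ids
  in_b <- participant_id %in% reference_b_ids
  a_ids <- setdiff(reference_a_ids, participant_id)
  b_ids <- setdiff(reference_b_ids, participant_id)
  if (length(a_ids) < 2L || length(b_ids) < 2L) {
    stop("leave-one-out reduces a reference group below 2 participants")
  }
  use_cache <- !is.null(fits) && !in_a && !in_b
  a_idx <- match(a_ids, ids); b_idx <- match(b_ids, ids)

  key_0025 <- paste(mask_0025$roi, mask_0025$bin)
  n_comb <- nrow(mask_025)
  percentile <- numeric(n_comb)
  n_a_used <- integer(n_comb); n_b_used <- integer(n_comb)
  for (i in seq_len(n_comb)) {
    r <- mask_025$roi[i]; b <- mask_025$bin[i]
    value <- table$values[pidx, r, b]
    vals <- c(table$values[a_idx, r, b], table$values[b_idx, r, b])
    labs <- c(rep(1, length(a_idx)), rep(0, length(b_idx)))
    if (method == "rank") {
      percentile[i] <- rank_percentile(vals, labs, value)
      n_a_used[i] <- length(a_idx); n_b_used[i] <- length(b_idx)
    } else {
      fit <- if (use_cache) fits[[i]] else fit_logistic_ridge(vals, labs, ridge)
      percentile[i] <- percentile_score(fit, value)
      n_a_used[i] <- fit$n_a; n_b_used[i] <- fit$n_b
    }
  }
  in_combined <- paste(mask_025$roi, mask_025$bin) %in% key_0025
  combined <- if (any(in_combined)) mean(percentile[in_combined]) else NA_real_
  structure(
    list(id = participant_id,
         combos = data.frame(roi = mask_025$roi, bin = mask_025$bin,
                             percentile = percentile,
                             in_combined = in_combined,
                             n_a = n_a_used, n_b = n_b_used),
         combined = combined, method = method, metric = table$metric),
    class = "percentile_report"
  )
}

#' @export
print.percentile_report <- function(x, ...) {
  cat(sprintf("<percentile_report> %s: combined %.1f%% over %d of %d combinations\n",
              x$id, x$combined, sum(x$combos$in_combined), nrow(x$combos)))
  invisible(x)
}

#' Score every participant of a cohort
#'
#' Applies [score_participant()] to all participants, reusing one
#' reference fit per combination for participants outside the reference
#' groups (the fit only changes under leave-one-out).
#'
#' @inheritParams score_participant
#' @return List with `reports` (one [score_participant()] report per
#'   participant), `summary` (data.frame `id`, `group`, `combined`,
#'   `abeta_ratio`), and `group_summary` (per-group mean/min/max of the
#'   combined percentile).
#' @export
score_cohort <- function(table, mask_025, mask_0025,
                         reference_a_ids, reference_b_ids, ridge = 1e-4,
                         method = c("logistic", "rank")) {
  method <- match.arg(method)
  ids <- table$participants$id
  a_idx <- match(reference_a_ids, ids)
  b_idx <- match(reference_b_ids, ids)
  fits <- NULL
  if (method == "logistic" && nrow(mask_025) > 0L) {
    fits <- lapply(seq_len(nrow(mask_025)), function(i) {
      r <- mask_025$roi[i]; b <- mask_025$bin[i]
      fit_logistic_ridge(
        c(table$values[a_idx, r, b], table$values[b_idx, r, b]),
        c(rep(1, length(a_idx)), rep(0, length(b_idx))), ridge)
    })
  }
  reports <- lapply(ids, function(id) {
    score_participant(table, id, mask_025, mask_0025,
                      reference_a_ids, reference_b_ids, ridge, method,
                      fits = fits)
  })
  summary <- data.frame(
    id = ids,
    group = table$participants$group,
    combined = vapply(reports, function(r) r$combined, numeric(1)),
    abeta_ratio = if ("abeta_ratio" %in% names(table$participants)) {
      table$participants$abeta_ratio
    } else {
      NA_real_
    }
  )
  group_summary <- do.call(rbind, lapply(sort(unique(summary$group)), function(g) {
    v <- summary$combined[summary$group == g]
    data.frame(group = g, n = length(v), mean = mean(v, na.rm = TRUE),
               min = suppressWarnings(min(v, na.rm = TRUE)),
               max = suppressWarnings(max(v, na.rm = TRUE)))
  }))
  list(reports = reports, summary = summary, group_summary = group_summary)
}

#' Squared correlation between combined percentiles and a biomarker
#'
#' Squared Pearson correlation between the participants' combined
#' percentiles and their amyloid-beta 42/40 ratios (or any biomarker),
#' with pairwise deletion of missing values.
#'
#' @param combined_percentiles Numeric vector.
#' @param ratios Numeric vector, same length (may contain `NA`).
#' @param subset Optional logical or integer subset of participants (e.g.
#'   a single group).
#' @return R-squared, or `NA` (with a warning) if fewer than 3 complete
#'   pairs or zero variance.
#' @export
correlate_with_biomarker <- function(combined_percentiles, ratios,
                                     subset = NULL) {
  x <- combined_percentiles; y <- ratios
  if (!is.null(subset)) {
    x <- x[subset]; y <- y[subset]
  }
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3L) {
    warning("fewer than 3 complete pairs; correlation undefined")
    return(NA_real_)
  }
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warning("zero variance; correlation undefined")
    return(NA_real_)
  }
  stats::cor(x, y)^2
}
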