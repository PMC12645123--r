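#' One-tailed Welch two-sample t-test
#'
#' Welch's unequal-variance t statistic with Welch-Satterthwaite degrees
#' of freedom, returning the one-tailed p-value for the stated direction.
#' Directional testing is used so that a significant result carries the
#' sign of the group difference, not just its existence.
#'
#' @param sample_a,sample_b Numeric vectors (each n >= 2).
#' @param direction `"a_greater"` tests mean(a) > mean(b); `"b_greater"`
#'   tests mean(b) > mean(a).
#' @param var_equal Use the pooled-variance Student test instead of Welch.
#' @return List with `t`, `df`, `p`, and `degenerate` (TRUE when both
#'   samples have zero variance and equal means, in which case p = 0.5 by
#'   convention).
#' @export
welch_t_onetailed <- function(sample_a, sample_b,
                              direction = c("a_greater", "b_greater"),
                              var_equal = FALSE) {
  direction <- match.arg(direction)
  na <- length(sample_a); nb <- length(sample_b)
  if (na < 2L || nb < 2L) stop("each sample must contain at least 2 values")
  ma <- mean(sample_a); mb <- mean(sample_b)
  va <- stats::var(sample_a); vb <- stats::var(sample_b)
  if (va == 0 && vb == 0) {
    if (ma == mb) {
      return(list(t = 0, df = NA_real_, p = 0.5, degenerate = TRUE))
    }
    # deterministic separation: the directional p degenerates to 0 or 1
    t_inf <- sign(ma - mb) * Inf
    p <- if (direction == "a_greater") as.numeric(ma < mb) else
      as.numeric(ma > mb)
    return(list(t = t_inf, df = NA_real_, p = p, degenerate = FALSE))
  }
  if (var_equal) {
    sp2 <- ((na - 1) * va + (nb - 1) * vb) / (na + nb - 2)
    se <- sqrt(sp2 * (1 / na + 1 / nb))
    df <- na + nb - 2
  } else {
    se <- sqrt(va / na + vb / nb)
    df <- (va / na + vb / nb)^2 /
      ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  }
  t <- (ma - mb) / se
  p <- if (direction == "a_greater") {
    stats::pt(t, df, lower.tail = FALSE)
  } else {
    stats::pt(t, df, lower.tail = TRUE)
  }
  list(t = t, df = df, p = p, degenerate = FALSE)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false-discovery-rate adjustment (via [stats::p.adjust()]),
#' order-preserving and monotone.
#'
#' @param p_vector p-values in (0, 1].
#' @return q-values, same order and length.
#' @export
fdr_bh <- function(p_vector) {
  if (length(p_vector) == 0L) return(numeric(0))
  stats::p.adjust(p_vector, method = "BH")
}

#' Directional group comparison across all ROI x depth-bin combinations
#'
#' For every region and depth bin, tests group A against group B with
#' one-tailed tests in both directions, then applies Benjamini-Hochberg
#' FDR correction across all combinations. By default each direction forms
#' its own correction family (two one-tailed families); a single combined
#' family over both directions is available. Combinations with zero
#' variance in both groups and equal means are excluded from the FDR
#' family and reported.
#'
#' @param table A [depthbin_table()].
#' @param group_a_ids,group_b_ids Participant ids of the two groups (for
#'   the primary analysis: cognitively normal amyloid-negative vs AD
#'   dementia references).
#' @param test `"welch"` (default) or `"student"`.
#' @param fdr_family `"per_direction"` (default) or `"combined"`.
#' @return An object of class `group_test_result`: a data.frame with one
#'   row per combination (`roi`, `bin`, `t`, `df`, `mean_a`, `mean_b`,
#'   `n_a`, `n_b`, `p_a_greater`, `p_b_greater`, `q_a_greater`,
#'   `q_b_greater`, `degenerate`), plus metadata attributes.
#' @export
run_group_analysis <- function(table, group_a_ids, group_b_ids,
                               test = c("welch", "student"),
                               fdr_family = c("per_direction", "combined")) {
  stopifnot(inherits(table, "depthbin_table"))
  test <- match.arg(test)
  fdr_family <- match.arg(fdr_family)
  ids <- table$participants$id
  sel_a <- ids %in% group_a_ids
  sel_b <- ids %in% group_b_ids
  if (!any(sel_a) || !any(sel_b)) stop("both groups must be present in the table")
  d <- dim(table$values)
  n_roi <- d[2]; n_bin <- d[3]
  ncomb <- n_roi * n_bin
  # combinations x participants matrices
  flat <- matrix(aperm(table$values, c(2, 3, 1)), nrow = ncomb)
  a <- flat[, sel_a, drop = FALSE]
  b <- flat[, sel_b, drop = FALSE]
  skip <- rowSums(is.na(a)) > 0L | rowSums(is.na(b)) > 0L
  na <- ncol(a); nb <- ncol(b)
  ma <- rowMeans(a); mb <- rowMeans(b)
  va <- rowSums((a - ma)^2) / (na - 1)
  vb <- rowSums((b - mb)^2) / (nb - 1)
  degen <- !skip & va == 0 & vb == 0 & ma == mb
  if (test == "student") {
    sp2 <- ((na - 1) * va + (nb - 1) * vb) / (na + nb - 2)
    se <- sqrt(sp2 * (1 / na + 1 / nb))
    df <- rep(na + nb - 2, ncomb)
  } else {
    se <- sqrt(va / na + vb / nb)
    df <- (va / na + vb / nb)^2 /
      ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  }
  t <- (ma - mb) / se
  p_a <- stats::pt(t, df, lower.tail = FALSE)
  p_b <- stats::pt(t, df, lower.tail = TRUE)
  p_a[degen] <- 0.5; p_b[degen] <- 0.5
  t[degen] <- 0

  usable <- !skip & !degen
  q_a <- q_b <- rep(NA_real_, ncomb)
  if (fdr_family == "per_direction") {
    q_a[usable] <- fdr_bh(p_a[usable])
    q_b[usable] <- fdr_bh(p_b[usable])
  } else {
    qq <- fdr_bh(c(p_a[usable], p_b[usable]))
    q_a[usable] <- qq[seq_len(sum(usable))]
    q_b[usable] <- qq[sum(usable) + seq_len(sum(usable))]
  }

  res <- data.frame(
    roi = rep(seq_len(n_roi), times = n_bin),
    bin = rep(seq_len(n_bin), each = n_roi),
    t = t, df = df, mean_a = ma, mean_b = mb,
    n_a = na, n_b = nb,
    p_a_greater = p_a, p_b_greater = p_b,
    q_a_greater = q_a, q_b_greater = q_b,
    degenerate = degen, skipped = skip
  )
  res$t[skip] <- NA_real_
  res$p_a_greater[skip] <- NA_real_
  res$p_b_greater[skip] <- NA_real_
  structure(res,
            class = c("group_test_result", "data.frame"),
            bins = table$bins, roi_names = table$roi_names,
            lobe_map = table$lobe_map, metric = table$metric,
            test = test, fdr_family = fdr_family,
            n_degenerate = sum(degen), n_skipped = sum(skip))
}

#' Select significant ROI x depth-bin combinations
#'
#' @param result A [run_group_analysis()] result.
#' @param q_threshold FDR threshold (0.025 for screening, 0.0025 for the
#'   most significant combinations).
#' @param direction `"b_greater"` (metric higher in group B, the dementia
#'   reference — the direction of interest for diffusivity) or
#'   `"a_greater"`.
#' @return An object of class `selection_mask`: data.frame of selected
#'   (`roi`, `bin`) pairs with `q`, plus `threshold` and `direction`
#'   attributes.
#' @export
select_significant <- function(result, q_threshold,
                               direction = c("b_greater", "a_greater")) {
  direction <- match.arg(direction)
  q <- if (direction == "b_greater") result$q_b_greater else result$q_a_greater
  sel <- !is.na(q) & q <= q_threshold
  structure(
    data.frame(roi = result$roi[sel], bin = result$bin[sel], q = q[sel]),
    class = c("selection_mask", "data.frame"),
    threshold = q_threshold, direction = direction,
    n_possible = nrow(result),
    bins = attr(result, "bins"), lobe_map = attr(result, "lobe_map")
  )
}

#' Summarize a selection by lobe and depth bin
#'
#' Counts selected combinations per lobe (with percentages of the
#' possible combinations, one decimal) and per depth bin.
#'
#' @param mask A [select_significant()] mask.
#' @param lobe_map Character lobe per region id; defaults to the map
#'   carried by the mask.
#' @param n_bins Number of depth bins per region (default 8).
#' @return List with data.frames `by_lobe` (`lobe`, `selected`,
#'   `possible`, `percent`) and `by_bin` (`bin`, `selected`).
#' @export
summarize_selection <- function(mask, lobe_map = NULL, n_bins = 8L) {
  if (is.null(lobe_map)) lobe_map <- attr(mask, "lobe_map")
  if (is.null(lobe_map)) stop("a lobe map is required")
  if (nrow(mask) > 0 && any(mask$roi > length(lobe_map))) {
    stop("selection contains a region not covered by the lobe map")
  }
  lobes <- unique(lobe_map)
  by_lobe <- do.call(rbind, lapply(lobes, function(lb) {
    rois <- which(lobe_map == lb)
    selected <- sum(mask$roi %in% rois)
    possible <- length(rois) * n_bins
    data.frame(lobe = lb, selected = selected, possible = possible,
               percent = round(100 * selected / possible, 1))
  }))
  by_bin <- data.frame(
    bin = seq_len(n_bins),
    selected = vapply(seq_len(n_bins), function(b) sum(mask$bin == b),
                      integer(1))
  )
  list(by_lobe = by_lobe, by_bin = by_bin)
}
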