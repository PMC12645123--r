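#' Build cortical columns from matched surface vertex pairs
#'
#' Connects each index-matched pial / WM-interface vertex pair into a
#' straight cortical column oriented across the cortical sheet. Unlabeled
#' vertices (label 0) and pairs shorter than `min_length_mm` (including
#' degenerate coincident pairs) are dropped, with a message reporting the
#' count.
#'
#' @param surface_pair Either a `phantom_geometry` or a list with `pial`
#'   and `wm` (`n x 3` mm coordinate matrices, index-matched).
#' @param labels Integer ROI label per vertex (0 = unlabeled); defaults to
#'   the geometry's labels when `surface_pair` carries them.
#' @param min_length_mm Minimum column length retained (default 0.5).
#' @param transform Optional 4x4 matrix mapping column endpoints from the
#'   anatomical to the metric (diffusion) space before sampling.
#' @return An object of class `column_set` with `pial`, `wm`, `roi`, and
#'   `transform`.
#' @export
build_columns <- function(surface_pair, labels = NULL, min_length_mm = 0.5,
                          transform = NULL) {
  pial <- surface_pair$pial
  wm <- surface_pair$wm
  if (is.null(labels)) labels <- surface_pair$roi
  if (is.null(pial) || is.null(wm)) stop("surface_pair must carry pial and wm vertices")
  if (nrow(pial) != nrow(wm)) {
    stop("geometry error: pial and WM vertex counts differ")
  }
  if (length(labels) != nrow(pial)) {
    stop("geometry error: one label per vertex pair is required")
  }
  len <- sqrt(rowSums((pial - wm)^2))
  keep <- labels > 0 & len >= min_length_mm
  n_short <- sum(labels > 0 & len < min_length_mm)
  if (n_short > 0) {
    message(sprintf("dropped %d columns shorter than %.2f mm", n_short,
                    min_length_mm))
  }
  if (!any(keep)) warning("no columns retained")
  structure(
    list(pial = pial[keep, , drop = FALSE], wm = wm[keep, , drop = FALSE],
         roi = as.integer(labels[keep]), transform = transform,
         n_dropped = n_short),
    class = "column_set"
  )
}

#' @export
print.column_set <- function(x, ...) {
  cat(sprintf("<column_set> %d columns, %d ROIs, %d dropped\n",
              nrow(x$pial), length(unique(x$roi)), x$n_dropped))
  invisible(x)
}

#' Number of columns in a column set
#' @param column_set A [build_columns()] result.
#' @return Integer count.
#' @export
n_columns <- function(column_set) nrow(column_set$pial)

# Trilinear interpolation of a 3-D volume at continuous 0-based voxel
# coordinates (n x 3). Points outside the grid return NA.
trilinear <- function(volume, ijk) {
  d <- dim(volume)
  tol <- 1e-9
  inside <- ijk[, 1] >= -tol & ijk[, 1] <= d[1] - 1 + tol &
    ijk[, 2] >= -tol & ijk[, 2] <= d[2] - 1 + tol &
    ijk[, 3] >= -tol & ijk[, 3] <= d[3] - 1 + tol
  out <- rep(NA_real_, nrow(ijk))
  if (!any(inside)) return(out)
  p <- ijk[inside, , drop = FALSE]
  # clamp so that points on the upper face use the last cell with frac 1
  i0 <- pmin(pmax(floor(p[, 1]), 0), d[1] - 2); fx <- p[, 1] - i0
  j0 <- pmin(pmax(floor(p[, 2]), 0), d[2] - 2); fy <- p[, 2] - j0
  k0 <- pmin(pmax(floor(p[, 3]), 0), d[3] - 2); fz <- p[, 3] - k0
  fx <- pmin(pmax(fx, 0), 1); fy <- pmin(pmax(fy, 0), 1)
  fz <- pmin(pmax(fz, 0), 1)
  at <- function(di, dj, dk) {
    volume[cbind(i0 + di + 1, j0 + dj + 1, k0 + dk + 1)]
  }
  val <-
    at(0, 0, 0) * (1 - fx) * (1 - fy) * (1 - fz) +
    at(1, 0, 0) * fx * (1 - fy) * (1 - fz) +
    at(0, 1, 0) * (1 - fx) * fy * (1 - fz) +
    at(0, 0, 1) * (1 - fx) * (1 - fy) * fz +
    at(1, 1, 0) * fx * fy * (1 - fz) +
    at(1, 0, 1) * fx * (1 - fy) * fz +
    at(0, 1, 1) * (1 - fx) * fy * fz +
    at(1, 1, 1) * fx * fy * fz
  out[inside] <- val
  out
}

# The 21 fractional sampling depths (0 = pial, 1 = WM/GM interface).
sample_depths <- function() seq(0, 1, by = 0.05)

# Sample a volume along every column of a column set: returns an
# n_columns x 21 matrix (rows NA-flagged where any sample leaves the
# grid). `affine` defaults to the volume's own voxel-to-mm map.
sample_profiles <- function(volume, column_set, affine = NULL) {
  if (is.null(affine)) affine <- attr(volume, "affine")
  if (is.null(affine)) stop("volume carries no affine and none was supplied")
  n <- n_columns(column_set)
  depths <- sample_depths()
  pial <- apply_transform(column_set$pial, column_set$transform)
  wm <- apply_transform(column_set$wm, column_set$transform)
  # points for all columns at all depths: (n * 21) x 3
  f <- rep(depths, each = n)
  pts <- pial[rep(seq_len(n), times = 21L), , drop = FALSE] * (1 - f) +
    wm[rep(seq_len(n), times = 21L), , drop = FALSE] * f
  vals <- trilinear(volume, mm_to_voxel(pts, affine))
  prof <- matrix(vals, nrow = n, ncol = 21L)
  missing <- rowSums(is.na(prof)) > 0L
  prof[missing, ] <- NA_real_
  attr(prof, "missing") <- missing
  prof
}

#' Sample a cortical depth profile along one column
#'
#' Samples the volume at 21 equidistant cortical depths from 0% (pial
#' endpoint) to 100% (WM/GM-interface endpoint) by trilinear
#' interpolation. A column with any sample point outside the volume is
#' flagged missing (all-`NA` profile).
#'
#' @param volume 3-D array with an `affine` attribute (0-based voxel
#'   centers to mm).
#' @param column A list with `pial` and `wm` endpoints (length-3 mm
#'   coordinates) and optionally `transform`.
#' @return Numeric vector of 21 samples, pial to WM.
#' @export
sample_column_profile <- function(volume, column) {
  cs <- list(pial = matrix(column$pial, nrow = 1L),
             wm = matrix(column$wm, nrow = 1L),
             transform = column$transform)
  sample_profiles(volume, cs)[1L, ]
}

#' Mean depth profiles per region
#'
#' Averages the 21-point depth profiles of all non-missing columns within
#' each region (unweighted mean per depth). Regions with no usable column
#' are returned as all-`NA` rows.
#'
#' @param volume Scalar volume with `affine` attribute.
#' @param column_set A [build_columns()] result.
#' @param n_rois Number of regions (defaults to the maximum label).
#' @return `n_rois x 21` matrix with attribute `n_columns` (usable columns
#'   per region).
#' @export
roi_depth_profiles <- function(volume, column_set, n_rois = NULL) {
  if (is.null(n_rois)) n_rois <- max(column_set$roi)
  prof <- sample_profiles(volume, column_set)
  ok <- !attr(prof, "missing")
  out <- matrix(NA_real_, n_rois, 21L)
  counts <- integer(n_rois)
  for (r in seq_len(n_rois)) {
    rows <- column_set$roi == r & ok
    counts[r] <- sum(rows)
    if (counts[r] > 0L) out[r, ] <- colMeans(prof[rows, , drop = FALSE])
  }
  attr(out, "n_columns") <- counts
  out
}

#' Average a 21-depth profile into the eight 10% depth bins
#'
#' Bin k spans cortical depths `[10k, 10(k+1)]`% and averages the three
#' samples at depths 10k, 10k+5, and 10(k+1)% — boundary samples are
#' shared by adjacent bins. The 0-10% and 90-100% depths are never used,
#' excluding the samples most affected by partial-volume contamination
#' with CSF and white matter.
#'
#' @param profile21 Numeric vector of 21 depth samples (pial to WM).
#' @return Numeric vector of 8 bin means, named `"10-20%"` ... `"80-90%"`.
#' @export
bin_profile <- function(profile21) {
  stopifnot(length(profile21) == 21L)
  k <- 1:8
  out <- vapply(k, function(kk) {
    mean(profile21[(2 * kk + 1):(2 * kk + 3)])
  }, numeric(1))
  names(out) <- depth_bin_labels()
  out
}

# Mean of the 17 samples spanning 10-90% depth (single wide bin).
bin_10_90 <- function(profile21) {
  stopifnot(length(profile21) == 21L)
  mean(profile21[3:19])
}

#' Cortical thickness of columns
#'
#' Euclidean pial-to-WM endpoint distance in mm, before any
#' anatomical-to-diffusion transform.
#'
#' @param column_set A [build_columns()] result (or a single column list).
#' @return Numeric vector of lengths, one per column.
#' @export
column_thickness <- function(column_set) {
  if (is.null(dim(column_set$pial))) {
    return(sqrt(sum((column_set$pial - column_set$wm)^2)))
  }
  sqrt(rowSums((column_set$pial - column_set$wm)^2))
}

#' Voxel-based regional means
#'
#' The depth-agnostic voxel-based variant: the cortical ribbon is
#' rasterized by stepping along every column at `step_mm` spacing, each
#' touched voxel is assigned to the region of the nearest passing column
#' sample (ties resolved by smallest distance from the voxel center to the
#' column sample point), and the volume is averaged without weighting over
#' each region's member voxels.
#'
#' @param volume Scalar volume with `affine` attribute.
#' @param column_set A [build_columns()] result.
#' @param step_mm Rasterization step along each column (default 0.25).
#' @param n_rois Number of regions (defaults to the maximum label).
#' @return Numeric vector of per-region means (`NA` for regions with no
#'   member voxels), with attribute `n_voxels`.
#' @export
voxel_roi_mean <- function(volume, column_set, step_mm = 0.25,
                           n_rois = NULL) {
  if (is.null(n_rois)) n_rois <- max(column_set$roi)
  affine <- attr(volume, "affine")
  if (is.null(affine)) stop("volume carries no affine")
  pial <- apply_transform(column_set$pial, column_set$transform)
  wm <- apply_transform(column_set$wm, column_set$transform)
  n <- nrow(pial)
  len <- sqrt(rowSums((pial - wm)^2))
  n_steps <- pmax(1L, ceiling(len / step_mm))
  col_id <- rep(seq_len(n), times = n_steps + 1L)
  f <- unlist(lapply(seq_len(n), function(i) seq(0, 1, length.out = n_steps[i] + 1L)))
  pts <- pial[col_id, , drop = FALSE] * (1 - f) + wm[col_id, , drop = FALSE] * f
  ijk <- round(mm_to_voxel(pts, affine))
  d <- dim(volume)
  inside <- ijk[, 1] >= 0 & ijk[, 1] < d[1] & ijk[, 2] >= 0 &
    ijk[, 2] < d[2] & ijk[, 3] >= 0 & ijk[, 3] < d[3]
  ijk <- ijk[inside, , drop = FALSE]
  col_id <- col_id[inside]
  pts <- pts[inside, , drop = FALSE]
  if (nrow(ijk) == 0L) {
    out <- rep(NA_real_, n_rois)
    attr(out, "n_voxels") <- integer(n_rois)
    return(out)
  }
  lin <- ijk[, 1] + d[1] * (ijk[, 2] + d[2] * ijk[, 3])
  centers <- voxel_to_mm(ijk, affine)
  dist <- sqrt(rowSums((pts - centers)^2))
  # keep, per voxel, the sample closest to the voxel center
  ord <- order(lin, dist)
  first <- !duplicated(lin[ord])
  lin_keep <- lin[ord][first]
  roi_keep <- column_set$roi[col_id[ord][first]]
  vals <- volume[lin_keep + 1L]
  out <- rep(NA_real_, n_rois)
  counts <- integer(n_rois)
  for (r in seq_len(n_rois)) {
    sel <- roi_keep == r
    counts[r] <- sum(sel)
    if (counts[r] > 0L) out[r] <- mean(vals[sel])
  }
  attr(out, "n_voxels") <- counts
  out
}

#' Build the participant x ROI x depth-bin table from an image cohort
#'
#' Runs the column-sampling stage for every participant of an image-level
#' cohort and assembles the central depth-bin table. For cohorts simulated
#' at the `"dwi"` level the diffusion tensor is fitted per participant and
#' the requested metric map derived first; at the `"rd"` level the scalar
#' volumes are used directly (only `metric = "RD"` is then available,
#' except `"thickness"`).
#'
#' @param cohort A [simulate_cohort()] object (or a compatible list with
#'   `geometry`, `participants`, `images`, `level`).
#' @param metric `"RD"`, `"AD"`, `"MD"`, `"FA"`, or `"thickness"`.
#' @param mode Depth mode: `"bins8"` (primary), `"single_bin_k"` (one
#'   10% bin, see `k`), `"bin_10_90"` (one wide bin), `"voxel"`
#'   (voxel-based regional means), or `"thickness"` (implied by the
#'   thickness metric).
#' @param k Bin index 1-8 for `mode = "single_bin_k"`.
#' @param min_length_mm Column length threshold for [build_columns()].
#' @param columns Optional precomputed [build_columns()] result.
#' @return A [depthbin_table()].
#' @export
build_table <- function(cohort, metric = "RD",
                        mode = c("bins8", "single_bin_k", "bin_10_90",
                                 "voxel", "thickness"),
                        k = NULL, min_length_mm = 0.5, columns = NULL) {
  mode <- match.arg(mode)
  if (metric == "thickness") mode <- "thickness"
  if (mode == "single_bin_k" && (is.null(k) || !k %in% 1:8)) {
    stop("mode 'single_bin_k' requires k in 1..8")
  }
  if (is.null(columns)) {
    columns <- build_columns(cohort$geometry, min_length_mm = min_length_mm)
  }
  n_rois <- cohort$geometry$n_rois
  n <- nrow(cohort$participants)
  n_bins <- if (mode == "bins8") 8L else 1L
  vals <- array(NA_real_, dim = c(n, n_rois, n_bins))

  if (mode == "thickness") {
    th <- column_thickness(columns)
    per_roi <- vapply(seq_len(n_rois), function(r) {
      v <- th[columns$roi == r]
      if (length(v)) mean(v) else NA_real_
    }, numeric(1))
    for (p in seq_len(n)) vals[p, , 1L] <- per_roi
  } else {
    for (p in seq_len(n)) {
      vol <- participant_metric_volume(cohort, p, metric)
      if (mode == "voxel") {
        vals[p, , 1L] <- voxel_roi_mean(vol, columns, n_rois = n_rois)
      } else {
        prof <- roi_depth_profiles(vol, columns, n_rois = n_rois)
        for (r in seq_len(n_rois)) {
          if (anyNA(prof[r, ])) next
          vals[p, r, ] <- switch(mode,
            bins8 = bin_profile(prof[r, ]),
            single_bin_k = bin_profile(prof[r, ])[k],
            bin_10_90 = bin_10_90(prof[r, ]))
        }
      }
    }
  }
  bins <- switch(mode,
    bins8 = depth_bin_labels(),
    single_bin_k = depth_bin_labels()[k],
    bin_10_90 = "10-90%",
    voxel = "voxel",
    thickness = "thickness")
  depthbin_table(vals, cohort$participants, metric = metric, mode = mode,
                 bins = bins, lobe_map = default_lobe_map(n_rois))
}

# Metric volume for one participant of an image cohort.
participant_metric_volume <- function(cohort, p, metric) {
  img <- cohort$images[[p]]
  if (inherits(img, "dwi_dataset")) {
    tf <- fit_tensor_loglinear(img)
    vol <- tensor_metrics(tf, metric)
    # keep sampling defined across the whole grid: unfitted voxels carry
    # no signal information, fall back to 0
    vol[is.na(vol)] <- 0
    return(vol)
  }
  if (metric != "RD") {
    stop(sprintf("cohort stores scalar RD volumes; metric '%s' requires level = 'dwi'",
                 metric))
  }
  img
}
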