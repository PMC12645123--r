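#' Construct a participant x ROI x depth-bin table
#'
#' The central exchange object of the pipeline: a 3-dimensional numeric
#' array of metric values (participant x region x depth bin) together with
#' participant metadata (group, amyloid ratio) and the region/lobe scheme.
#' The primary analysis uses eight 10%-wide depth bins spanning 10-90%
#' cortical depth; secondary modes carry a single bin.
#'
#' @param values Numeric array `n_participants x n_rois x n_bins`.
#' @param participants data.frame with at least `id` and `group` (1-4);
#'   optionally `abeta_ratio` and generator bookkeeping columns.
#' @param metric Metric name (`"RD"`, `"AD"`, `"MD"`, `"FA"`, `"thickness"`).
#' @param mode Depth mode the table was built under (`"bins8"`,
#'   `"single_bin_k"`, `"bin_10_90"`, `"voxel"`, `"thickness"`).
#' @param bins Character labels of the depth bins; defaults to the eight
#'   bins `"10-20%"` ... `"80-90%"` when `n_bins` is 8.
#' @param roi_names Optional region names (default `roi_1` ...).
#' @param lobe_map Optional lobe per region (default [default_lobe_map()]).
#' @return An object of class `depthbin_table`.
#' @export
depthbin_table <- function(values, participants, metric = "RD",
                           mode = "bins8", bins = NULL, roi_names = NULL,
                           lobe_map = NULL) {
  stopifnot(is.array(values), length(dim(values)) == 3L)
  n_sub <- dim(values)[1]
  n_roi <- dim(values)[2]
  n_bin <- dim(values)[3]
  if (nrow(participants) != n_sub) {
    stop("participants table does not match first array dimension")
  }
  if (is.null(bins)) {
    bins <- if (n_bin == 8L) depth_bin_labels() else paste0("bin_", seq_len(n_bin))
  }
  if (length(bins) != n_bin) stop("bin labels do not match third dimension")
  if (is.null(roi_names)) {
    roi_names <- if (n_roi == 68L) dk_atlas()$name else paste0("roi_", seq_len(n_roi))
  }
  if (is.null(lobe_map)) lobe_map <- default_lobe_map(n_roi)
  if (length(lobe_map) != n_roi) stop("lobe_map must have one lobe per ROI")
  dimnames(values) <- list(participants$id, roi_names, bins)
  structure(
    list(values = values, participants = participants, metric = metric,
         mode = mode, bins = bins, roi_names = roi_names,
         lobe_map = lobe_map),
    class = "depthbin_table"
  )
}

#' Labels of the eight cortical depth bins
#' @return Character vector `"10-20%"` ... `"80-90%"`.
#' @export
depth_bin_labels <- function() {
  paste0(seq(10, 80, 10), "-", seq(20, 90, 10), "%")
}

#' @export
print.depthbin_table <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<depthbin_table> %s [%s]: %d participants x %d ROIs x %d bins\n",
              x$metric, x$mode, d[1], d[2], d[3]))
  cat("  groups:", paste(sprintf("%d (n=%d)", seq_along(tabulate(x$participants$group, 4L)),
                                 tabulate(x$participants$group, 4L)), collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.depthbin_table <- function(x) dim(x$values)

#' Participant ids belonging to one or more clinical groups
#' @param table A [depthbin_table()].
#' @param group Group number(s) in 1-4.
#' @return Character vector of participant ids.
#' @export
group_ids <- function(table, group) {
  table$participants$id[table$participants$group %in% group]
}
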