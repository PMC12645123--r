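# File interfaces: NIfTI volumes via RNifti, plain-text meshes and labels,
# bval/bvec gradient tables, and TSV exchange formats for the depth-bin
# table, test results, masks, and percentile reports. Voxel convention
# throughout: 0-based indices, affine maps voxel centers to mm.

#' Write a scalar volume as NIfTI-1
#' @param volume 3-D array with an `affine` attribute.
#' @param path Output `.nii` / `.nii.gz` path.
#' @return The path, invisibly.
#' @export
write_metric_nifti <- function(volume, path) {
  affine <- attr(volume, "affine") %||% diag(4)
  img <- RNifti::asNifti(unclass(array(as.numeric(volume), dim = dim(volume))))
  img <- RNifti::`sform<-`(img, structure(affine, code = 2L))
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a scalar volume from NIfTI-1
#' @param path Input path.
#' @return Array with `affine` attribute.
#' @export
read_metric_nifti <- function(path) {
  img <- RNifti::readNifti(path)
  vol <- array(as.numeric(img), dim = dim(img))
  attr(vol, "affine") <- unclass(RNifti::xform(img))
  vol
}

#' Write a DWI dataset (NIfTI + bval/bvec text files)
#'
#' Writes the 4-D volume series plus the conventional whitespace-separated
#' `bval` (one row) and `bvec` (three rows: x, y, z) files.
#'
#' @param dwi A [dwi_dataset()].
#' @param prefix Output path prefix; writes `<prefix>.nii.gz`,
#'   `<prefix>.bval`, `<prefix>.bvec`.
#' @return The three paths, invisibly.
#' @export
write_dwi <- function(dwi, prefix) {
  nii <- paste0(prefix, ".nii.gz")
  img <- RNifti::asNifti(unclass(dwi$volumes))
  img <- RNifti::`sform<-`(img, structure(dwi$affine, code = 2L))
  RNifti::writeNifti(img, nii)
  bval <- paste0(prefix, ".bval")
  writeLines(paste(format(dwi$b_values, trim = TRUE), collapse = " "), bval)
  bvec <- paste0(prefix, ".bvec")
  writeLines(apply(t(dwi$directions), 1, function(r) {
    paste(format(r, trim = TRUE, digits = 10), collapse = " ")
  }), bvec)
  invisible(c(nii, bval, bvec))
}

#' Read a DWI dataset from NIfTI + bval/bvec
#' @param nifti_path 4-D NIfTI path.
#' @param bval_path,bvec_path Gradient table paths; default to the NIfTI
#'   path with `.bval`/`.bvec` extensions.
#' @return A [dwi_dataset()].
#' @export
read_dwi <- function(nifti_path, bval_path = NULL, bvec_path = NULL) {
  stem <- sub("\\.nii(\\.gz)?$", "", nifti_path)
  if (is.null(bval_path)) bval_path <- paste0(stem, ".bval")
  if (is.null(bvec_path)) bvec_path <- paste0(stem, ".bvec")
  img <- RNifti::readNifti(nifti_path)
  b <- scan(bval_path, quiet = TRUE)
  g <- t(matrix(scan(bvec_path, quiet = TRUE), nrow = 3L, byrow = TRUE))
  dwi_dataset(array(as.numeric(img), dim = dim(img)), b, g,
              affine = unclass(RNifti::xform(img)))
}

#' Write a surface pair as plain-text mesh files
#'
#' Format: first line `<n_vertices> <n_faces>`, then one `x y z` line per
#' vertex (mm), then one `i j k` line per triangle (0-based vertex
#' indices). Labels are written one integer per vertex line.
#'
#' @param geometry A `phantom_geometry` (or list with `pial`, `wm`,
#'   `faces`, `roi`).
#' @param prefix Path prefix; writes `<prefix>_pial.txt`,
#'   `<prefix>_wm.txt`, `<prefix>_labels.txt`.
#' @return The paths, invisibly.
#' @export
write_mesh_txt <- function(geometry, prefix) {
  write_one <- function(vertices, faces, path) {
    con <- file(path, "w")
    on.exit(close(con))
    nf <- if (is.null(faces)) 0L else nrow(faces)
    writeLines(paste(nrow(vertices), nf), con)
    utils::write.table(format(vertices, digits = 10, trim = TRUE), con,
                       row.names = FALSE, col.names = FALSE,
                       quote = FALSE)
    if (nf > 0) {
      utils::write.table(faces - 1L, con, row.names = FALSE,
                         col.names = FALSE, quote = FALSE)
    }
  }
  p1 <- paste0(prefix, "_pial.txt")
  p2 <- paste0(prefix, "_wm.txt")
  p3 <- paste0(prefix, "_labels.txt")
  write_one(geometry$pial, geometry$faces, p1)
  write_one(geometry$wm, geometry$faces, p2)
  writeLines(as.character(geometry$roi), p3)
  invisible(c(p1, p2, p3))
}

#' Read a plain-text surface pair
#' @param pial_path,wm_path Mesh files in the [write_mesh_txt()] format.
#' @param labels_path Optional label file (one integer per vertex).
#' @return List with `pial`, `wm`, `faces` (1-based), and `roi`.
#' @export
read_mesh_txt <- function(pial_path, wm_path, labels_path = NULL) {
  read_one <- function(path) {
    head <- scan(path, n = 2L, quiet = TRUE)
    nv <- head[1]; nf <- head[2]
    dat <- scan(path, skip = 1L, quiet = TRUE)
    v <- matrix(dat[seq_len(nv * 3L)], ncol = 3L, byrow = TRUE)
    f <- NULL
    if (nf > 0) {
      f <- matrix(as.integer(dat[nv * 3L + seq_len(nf * 3L)]), ncol = 3L,
                  byrow = TRUE) + 1L
    }
    list(vertices = v, faces = f)
  }
  p <- read_one(pial_path)
  w <- read_one(wm_path)
  if (nrow(p$vertices) != nrow(w$vertices)) {
    stop("geometry error: pial and WM vertex counts differ")
  }
  roi <- if (!is.null(labels_path)) as.integer(readLines(labels_path)) else NULL
  list(pial = p$vertices, wm = w$vertices, faces = p$faces, roi = roi)
}

#' Read a 4x4 transform from a text file
#'
#' Whitespace-separated 4x4 matrix mapping anatomical to diffusion mm
#' coordinates, applied to column endpoints before sampling.
#'
#' @param path Text file with 16 numbers (row-major).
#' @return 4x4 matrix.
#' @export
read_affine_txt <- function(path) {
  m <- matrix(scan(path, quiet = TRUE), nrow = 4L, byrow = TRUE)
  stopifnot(all(dim(m) == c(4L, 4L)))
  m
}

#' Write / read the depth-bin table as TSV
#'
#' Long format with header: `participant`, `group`, `abeta_ratio`, `roi`,
#' `roi_name`, `bin`, `value`.
#'
#' @param table A [depthbin_table()].
#' @param path Output TSV path.
#' @return The path, invisibly.
#' @export
write_depthbin_tsv <- function(table, path) {
  d <- dim(table$values)
  long <- data.frame(
    participant = rep(table$participants$id, times = d[2] * d[3]),
    group = rep(table$participants$group, times = d[2] * d[3]),
    abeta_ratio = rep(table$participants$abeta_ratio %||% NA_real_,
                      times = d[2] * d[3]),
    roi = rep(rep(seq_len(d[2]), each = d[1]), times = d[3]),
    roi_name = rep(rep(table$roi_names, each = d[1]), times = d[3]),
    bin = rep(table$bins, each = d[1] * d[2]),
    value = as.vector(table$values)
  )
  utils::write.table(long, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' @rdname write_depthbin_tsv
#' @param metric,mode Metadata restored onto the read table.
#' @export
read_depthbin_tsv <- function(path, metric = "RD", mode = "bins8") {
  long <- utils::read.delim(path, check.names = FALSE)
  ids <- unique(long$participant)
  rois <- sort(unique(long$roi))
  bins <- unique(long$bin)
  vals <- array(NA_real_, dim = c(length(ids), length(rois), length(bins)))
  pi <- match(long$participant, ids)
  ri <- match(long$roi, rois)
  bi <- match(long$bin, bins)
  vals[cbind(pi, ri, bi)] <- long$value
  first <- !duplicated(long$participant)
  participants <- data.frame(id = long$participant[first],
                             group = long$group[first],
                             abeta_ratio = long$abeta_ratio[first])
  roi_names <- long$roi_name[match(rois, long$roi)]
  depthbin_table(vals, participants, metric = metric, mode = mode,
                 bins = bins, roi_names = roi_names)
}

#' Write group-analysis results as TSV
#' @param result A [run_group_analysis()] result.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_group_result_tsv <- function(result, path) {
  out <- as.data.frame(result)
  out$selected_025 <- !is.na(out$q_b_greater) & out$q_b_greater <= 0.025
  out$selected_0025 <- !is.na(out$q_b_greater) & out$q_b_greater <= 0.0025
  utils::write.table(out, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a selection mask as TSV
#' @param mask A [select_significant()] mask.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_mask_tsv <- function(mask, path) {
  utils::write.table(as.data.frame(mask), path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a selection mask from TSV
#' @param path TSV with `roi` and `bin` columns.
#' @return A data.frame usable as a selection mask.
#' @export
read_mask_tsv <- function(path) {
  utils::read.delim(path)
}

#' Write percentile reports as TSV
#'
#' Writes the per-combination percentiles (`participant`, `roi`, `bin`,
#' `percentile`, `in_combined`) and, alongside, a cohort summary
#' (`participant`, `group`, `combined_percentile`, `abeta_ratio`).
#'
#' @param scores A [score_cohort()] result.
#' @param prefix Path prefix; writes `<prefix>_percentiles.tsv` and
#'   `<prefix>_summary.tsv`.
#' @return The paths, invisibly.
#' @export
write_scores_tsv <- function(scores, prefix) {
  per <- do.call(rbind, lapply(scores$reports, function(r) {
    cbind(participant = r$id, r$combos)
  }))
  p1 <- paste0(prefix, "_percentiles.tsv")
  p2 <- paste0(prefix, "_summary.tsv")
  utils::write.table(per, p1, sep = "\t", row.names = FALSE, quote = FALSE)
  summ <- scores$summary
  names(summ) <- c("participant", "group", "combined_percentile",
                   "abeta_ratio")
  utils::write.table(summ, p2, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(c(p1, p2))
}
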