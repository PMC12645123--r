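#' Fit the diffusion tensor by log-linear least squares
#'
#' Per-voxel ordinary least squares of the log-signal against the six
#' unique tensor components plus log-S0, the standard log-linearized DTI
#' fit. Voxels containing non-positive signals are flagged and excluded.
#' Eigenvalues are computed in closed form per voxel and sorted
#' descending.
#'
#' @param dwi A [dwi_dataset()].
#' @param mask Optional logical volume; by default voxels whose mean b = 0
#'   signal exceeds an Otsu threshold are fitted.
#' @return An object of class `tensor_field`: `d6` (4-D array of xx, yy,
#'   zz, xy, xz, yz components, mm^2/s), `evals` (4-D array of descending
#'   eigenvalues), `s0`, `mask`, `affine`, and `n_excluded` (voxels
#'   flagged for non-positive signal).
#' @export
fit_tensor_loglinear <- function(dwi, mask = NULL) {
  stopifnot(inherits(dwi, "dwi_dataset"))
  shape <- dim(dwi$volumes)[1:3]
  nvol <- dim(dwi$volumes)[4]
  if (nvol < 7L) stop("at least 7 volumes are required for the tensor fit")
  b <- dwi$b_values
  g <- dwi$directions
  # design: log S = log S0 - b * (gx^2 Dxx + ... + 2 gy gz Dyz)
  x <- cbind(1,
             -b * g[, 1]^2, -b * g[, 2]^2, -b * g[, 3]^2,
             -2 * b * g[, 1] * g[, 2],
             -2 * b * g[, 1] * g[, 3],
             -2 * b * g[, 2] * g[, 3])
  nvox <- prod(shape)
  sig <- matrix(dwi$volumes, nrow = nvox, ncol = nvol)

  if (is.null(mask)) mask <- dwi$mask
  if (is.null(mask)) {
    s0_mean <- rowMeans(sig[, b == 0, drop = FALSE])
    mask <- s0_mean > otsu_threshold(s0_mean)
  }
  mask <- as.vector(mask)
  positive <- rowSums(sig <= 0) == 0L
  usable <- mask & positive
  n_excluded <- sum(mask & !positive)
  if (!any(usable)) stop("no usable voxels: all masked voxels contain non-positive signals")

  qr_x <- qr(x)
  coefs <- qr.coef(qr_x, t(log(sig[usable, , drop = FALSE])))

  d6 <- matrix(NA_real_, nvox, 6L)
  d6[usable, ] <- t(coefs[2:7, , drop = FALSE])
  s0 <- rep(NA_real_, nvox)
  s0[usable] <- exp(coefs[1, ])
  evals <- matrix(NA_real_, nvox, 3L)
  evals[usable, ] <- sym3_eigenvalues(d6[usable, , drop = FALSE])

  structure(
    list(d6 = array(d6, dim = c(shape, 6L)),
         evals = array(evals, dim = c(shape, 3L)),
         s0 = array(s0, dim = shape),
         mask = array(usable, dim = shape),
         affine = dwi$affine,
         n_excluded = n_excluded),
    class = "tensor_field"
  )
}

#' @export
print.tensor_field <- function(x, ...) {
  cat(sprintf("<tensor_field> %s, %d fitted voxels, %d excluded\n",
              paste(dim(x$s0), collapse = "x"), sum(x$mask), x$n_excluded))
  invisible(x)
}

#' Scalar maps from a fitted tensor field
#'
#' Derives the standard tensor-derived metrics from the per-voxel
#' eigenvalues: radial diffusivity `RD = (lambda2 + lambda3) / 2`, axial
#' diffusivity `AD = lambda1`, mean diffusivity
#' `MD = (lambda1 + lambda2 + lambda3) / 3`, and fractional anisotropy
#' `FA = sqrt(((l1-l2)^2 + (l2-l3)^2 + (l3-l1)^2) / (2 (l1^2+l2^2+l3^2)))`,
#' with FA defined as 0 where all eigenvalues vanish. Negative eigenvalues
#' from noisy voxels are used as-is (not clipped).
#'
#' @param tensor_field A [fit_tensor_loglinear()] result.
#' @param metric One of `"RD"`, `"AD"`, `"MD"`, `"FA"`.
#' @return 3-D numeric array with an `affine` attribute; `NA` outside the
#'   fitted mask.
#' @export
tensor_metrics <- function(tensor_field, metric = c("RD", "AD", "MD", "FA")) {
  if (is.character(metric) && length(metric) == 1L &&
      !metric %in% c("RD", "AD", "MD", "FA")) {
    stop(sprintf("unknown metric '%s'; expected RD, AD, MD, or FA", metric))
  }
  metric <- match.arg(metric)
  ev <- tensor_field$evals
  l1 <- ev[, , , 1]; l2 <- ev[, , , 2]; l3 <- ev[, , , 3]
  out <- switch(metric,
    RD = (l2 + l3) / 2,
    AD = l1,
    MD = (l1 + l2 + l3) / 3,
    FA = {
      num <- (l1 - l2)^2 + (l2 - l3)^2 + (l3 - l1)^2
      den <- 2 * (l1^2 + l2^2 + l3^2)
      fa <- sqrt(num / den)
      fa[den == 0] <- 0
      fa
    })
  out <- array(out, dim = dim(tensor_field$s0))
  attr(out, "affine") <- tensor_field$affine
  out
}
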