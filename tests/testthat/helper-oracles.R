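# Independent oracles and small fixtures shared across tests. Every
# oracle here is written from the definition, independently of the
# package's implementation path.

# Brute-force trilinear interpolation at one continuous 0-based voxel
# coordinate: explicit loop over the 8 cell corners.
oracle_trilinear <- function(volume, p) {
  d <- dim(volume)
  if (any(p < 0) || any(p > d - 1)) return(NA_real_)
  i0 <- pmin(floor(p), d - 2)
  f <- p - i0
  acc <- 0
  for (di in 0:1) for (dj in 0:1) for (dk in 0:1) {
    w <- (if (di == 1) f[1] else 1 - f[1]) *
      (if (dj == 1) f[2] else 1 - f[2]) *
      (if (dk == 1) f[3] else 1 - f[3])
    acc <- acc + w * volume[i0[1] + di + 1, i0[2] + dj + 1, i0[3] + dk + 1]
  }
  acc
}

# Welch's one-tailed test written out from the formula.
oracle_welch <- function(a, b, direction = "b_greater") {
  ma <- mean(a); mb <- mean(b)
  va <- var(a); vb <- var(b)
  na <- length(a); nb <- length(b)
  se <- sqrt(va / na + vb / nb)
  t <- (ma - mb) / se
  df <- (va / na + vb / nb)^2 /
    ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  p <- if (direction == "a_greater") 1 - pt(t, df) else pt(t, df)
  list(t = t, df = df, p = p)
}

# FA from the eigenvalue definition, scalar.
oracle_fa <- function(l) {
  sqrt(((l[1] - l[2])^2 + (l[2] - l[3])^2 + (l[3] - l[1])^2) /
         (2 * sum(l^2)))
}

# Small phantom reused by several files.
small_phantom <- function(n_rois = 4L, spacing = 1) {
  make_phantom_geometry(n_vertices = 400L, n_rois = n_rois,
                        inner_radius_mm = 12, thickness_mm = 2.5,
                        grid_spec = list(spacing_mm = spacing))
}

# A volume with an affine, filled from a function of mm coordinates.
volume_from_function <- function(shape, spacing, fn) {
  affine <- diag(c(spacing, spacing, spacing, 1))
  affine[1:3, 4] <- -(shape - 1) / 2 * spacing
  ijk <- as.matrix(expand.grid(i = 0:(shape[1] - 1), j = 0:(shape[2] - 1),
                               k = 0:(shape[3] - 1)))
  xyz <- cbind(ijk[, 1] * spacing + affine[1, 4],
               ijk[, 2] * spacing + affine[2, 4],
               ijk[, 3] * spacing + affine[3, 4])
  vol <- array(fn(xyz), dim = shape)
  attr(vol, "affine") <- affine
  vol
}
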