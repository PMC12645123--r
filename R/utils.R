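# Internal helpers shared across modules.

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's RNG state afterwards so generators are reproducible without
# clobbering the session stream.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else {
      NULL
    }
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  force(expr)
}

# Derive a per-stage seed from a root seed; keeps every stream inside the
# 32-bit integer range.
derive_seed <- function(seed, stage) {
  if (is.null(seed)) return(NULL)
  offsets <- c(simulate = 11L, dwi = 23L, noise = 37L, abeta = 53L,
               intercept = 71L, stats = 89L, scoring = 101L)
  off <- if (stage %in% names(offsets)) offsets[[stage]] else
    sum(utf8ToInt(stage)) %% 1000L
  # double arithmetic: products stay exact below 2^53, result < 2^31
  as.integer((as.numeric(seed) * 2654435 + off) %% 2147483399)
}

# Linear interpolation of a tabulated profile; x must be sorted increasing.
interp1 <- function(x, y, xout) {
  stats::approx(x, y, xout = xout, rule = 2)$y
}

# Otsu's threshold on a numeric vector (256-bin histogram); used for the
# default S0 brain mask.
otsu_threshold <- function(x) {
  x <- x[is.finite(x)]
  if (length(x) == 0L || diff(range(x)) == 0) return(-Inf)
  breaks <- seq(min(x), max(x), length.out = 257L)
  h <- graphics::hist(x, breaks = breaks, plot = FALSE)
  counts <- h$counts
  mids <- h$mids
  w <- cumsum(counts)
  mu <- cumsum(counts * mids)
  total <- w[length(w)]
  mu_t <- mu[length(mu)]
  w_b <- w
  w_f <- total - w
  between <- (mu_t * w_b - mu)^2 / (w_b * w_f)
  between[!is.finite(between)] <- -Inf
  mids[which.max(between)]
}

# 4x4 affine mapping 0-based voxel indices (voxel centers) to mm.
make_affine <- function(spacing, origin) {
  a <- diag(4)
  a[1, 1] <- spacing[1]; a[2, 2] <- spacing[2]; a[3, 3] <- spacing[3]
  a[1:3, 4] <- origin
  a
}

# Map mm coordinates (n x 3) to continuous 0-based voxel indices.
mm_to_voxel <- function(xyz, affine) {
  xyz <- rbind(t(xyz), 1)
  ijk <- solve(affine) %*% xyz
  t(ijk[1:3, , drop = FALSE])
}

voxel_to_mm <- function(ijk, affine) {
  ijk <- rbind(t(ijk), 1)
  xyz <- affine %*% ijk
  t(xyz[1:3, , drop = FALSE])
}

# Apply a 4x4 rigid/affine transform to n x 3 points (mm).
apply_transform <- function(xyz, transform) {
  if (is.null(transform)) return(xyz)
  out <- transform %*% rbind(t(xyz), 1)
  t(out[1:3, , drop = FALSE])
}

# Eigenvalues of symmetric 3x3 tensors, vectorized over rows of a n x 6
# component matrix (xx, yy, zz, xy, xz, yz). Returns n x 3, sorted
# descending. Closed-form (trigonometric) solution; eigenvectors are never
# needed downstream so this avoids n calls to eigen().
sym3_eigenvalues <- function(d6) {
  a11 <- d6[, 1]; a22 <- d6[, 2]; a33 <- d6[, 3]
  a12 <- d6[, 4]; a13 <- d6[, 5]; a23 <- d6[, 6]
  q <- (a11 + a22 + a33) / 3
  p1 <- a12^2 + a13^2 + a23^2
  p2 <- (a11 - q)^2 + (a22 - q)^2 + (a33 - q)^2 + 2 * p1
  p <- sqrt(p2 / 6)
  iso <- p <= .Machine$double.eps * pmax(abs(q), 1e-300)
  ps <- ifelse(iso, 1, p)
  b11 <- (a11 - q) / ps; b22 <- (a22 - q) / ps; b33 <- (a33 - q) / ps
  b12 <- a12 / ps; b13 <- a13 / ps; b23 <- a23 / ps
  detb <- b11 * (b22 * b33 - b23^2) -
    b12 * (b12 * b33 - b23 * b13) +
    b13 * (b12 * b23 - b22 * b13)
  r <- pmin(pmax(detb / 2, -1), 1)
  phi <- acos(r) / 3
  e1 <- q + 2 * p * cos(phi)
  e3 <- q + 2 * p * cos(phi + 2 * pi / 3)
  e2 <- 3 * q - e1 - e3
  out <- cbind(e1, e2, e3)
  out[iso, ] <- q[iso]
  colnames(out) <- c("lambda1", "lambda2", "lambda3")
  out
}
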