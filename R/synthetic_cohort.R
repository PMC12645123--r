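#' Specify a synthetic cohort
#'
#' Parameterizes the synthetic cohort generator. The defaults reproduce the
#' study design the analysis targets: four groups along the cognitive
#' decline spectrum with sizes 17/16/15/12 (cognitively normal
#' amyloid-negative, cognitively normal amyloid-positive, MCI, AD
#' dementia), 68 cortical regions, and a radial diffusivity elevation that
#' grows with group severity, is concentrated in AD-vulnerable temporal
#' regions, and peaks at middle cortical depths (30-40% bin).
#'
#' Severity values are additive diffusivity offsets in mm^2/s applied to
#' the AD regions before depth weighting. The defaults (0, 0.04, 0.09,
#' 0.15) x 1e-3 mm^2/s correspond to a roughly 4-17% elevation over a
#' cortical baseline of ~0.9e-3 mm^2/s, in line with the magnitude of
#' cortical diffusivity differences reported along the AD continuum; they
#' are free generator parameters, not estimates of any real cohort.
#'
#' @param group_sizes Four positive integers (groups 1-4).
#' @param n_rois Number of cortical regions.
#' @param ad_roi_ids Region ids receiving the group effect; defaults to the
#'   bilateral middle temporal/fusiform/parahippocampal/entorhinal set when
#'   `n_rois` is 68, otherwise region 1.
#' @param group_severity Four non-decreasing diffusivity offsets (mm^2/s),
#'   group 1 fixed at 0.
#' @param depth_effect_weights Eight non-negative weights scaling the
#'   severity per depth bin (10-20% ... 80-90%).
#' @param between_subject_sd SD (mm^2/s) of the per-participant random
#'   intercept added uniformly to all regions and depths.
#' @param measurement_sd SD (mm^2/s) of cell-level measurement noise.
#' @param baseline_profile 21 diffusivity values at depths 0%, 5%, ...,
#'   100% (pial to WM/GM interface); default decreases linearly from
#'   1.1e-3 to 0.7e-3 mm^2/s.
#' @param abeta_cutoff Amyloid-beta 42/40 ratio cutoff (default 0.058);
#'   group 1 is drawn above it, groups 2-4 below.
#' @param abeta_missing_rate Probability that a group-4 participant has no
#'   recorded amyloid ratio.
#' @param n_decliners Number of group-2 (stage-1 AD) participants planted
#'   as impending decliners: they receive `decliner_elevation` of extra
#'   AD-region diffusivity on top of their group severity (default 0,
#'   i.e. no planted decliners). Emulates asymptomatic participants whose
#'   AD-region microstructure already looks dementia-like and who convert
#'   at follow-up.
#' @param decliner_elevation Extra AD-region diffusivity offset (mm^2/s)
#'   for the planted decliners, depth-weighted like the group severity.
#' @param seed Integer root seed for all generator randomness.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(group_sizes = c(17L, 16L, 15L, 12L),
                        n_rois = 68L,
                        ad_roi_ids = NULL,
                        group_severity = c(0, 0.04e-3, 0.09e-3, 0.15e-3),
                        depth_effect_weights = c(0.6, 0.85, 1, 0.9, 0.75,
                                                 0.55, 0.35, 0.2),
                        between_subject_sd = 0.04e-3,
                        measurement_sd = 0.02e-3,
                        baseline_profile = seq(1.1e-3, 0.7e-3,
                                               length.out = 21L),
                        abeta_cutoff = 0.058,
                        abeta_missing_rate = 0,
                        n_decliners = 0L,
                        decliner_elevation = 0,
                        seed = 1L) {
  stopifnot(length(group_sizes) == 4L, all(group_sizes >= 1),
            n_rois >= 1, length(group_severity) == 4L,
            length(depth_effect_weights) == 8L,
            length(baseline_profile) == 21L)
  if (group_severity[1] != 0) stop("group 1 severity must be 0")
  if (any(diff(group_severity) < 0)) {
    stop("group_severity must be non-decreasing")
  }
  if (any(group_severity < 0) || any(depth_effect_weights < 0) ||
      between_subject_sd < 0 || measurement_sd < 0) {
    stop("severities, weights and SDs must be non-negative")
  }
  if (is.null(ad_roi_ids)) {
    ad_roi_ids <- if (n_rois == 68L) dk_ad_roi_ids() else 1L
  }
  if (!all(ad_roi_ids %in% seq_len(n_rois))) {
    stop("ad_roi_ids must be a subset of 1..n_rois")
  }
  if (n_decliners > group_sizes[2] || decliner_elevation < 0) {
    stop("n_decliners must fit in group 2 and decliner_elevation be >= 0")
  }
  structure(
    list(group_sizes = as.integer(group_sizes), n_rois = as.integer(n_rois),
         ad_roi_ids = as.integer(ad_roi_ids),
         group_severity = group_severity,
         depth_effect_weights = depth_effect_weights,
         between_subject_sd = between_subject_sd,
         measurement_sd = measurement_sd,
         baseline_profile = baseline_profile,
         abeta_cutoff = abeta_cutoff,
         abeta_missing_rate = abeta_missing_rate,
         n_decliners = as.integer(n_decliners),
         decliner_elevation = decliner_elevation,
         seed = as.integer(seed)),
    class = "cohort_spec"
  )
}

# Sector layout used to label both surface vertices and ribbon voxels:
# latitude bands x longitude sectors, clamped to n_rois.
sector_layout <- function(n_rois) {
  g1 <- max(1L, floor(sqrt(n_rois / 2)))
  g2 <- as.integer(ceiling(n_rois / g1))
  list(n_bands = g1, n_sectors = g2)
}

label_from_angles <- function(theta, phi, n_rois, layout) {
  band <- pmin(floor(theta / pi * layout$n_bands), layout$n_bands - 1L)
  sect <- pmin(floor((phi %% (2 * pi)) / (2 * pi) * layout$n_sectors),
               layout$n_sectors - 1L)
  as.integer(pmin(band * layout$n_sectors + sect + 1L, n_rois))
}

#' Build a spherical-shell phantom geometry
#'
#' Constructs two concentric spherical shells standing in for the pial and
#' white/gray-interface surfaces: index-matched vertices lie on shared
#' radial lines so that every cortical column is exactly radial with length
#' `thickness_mm`. Region labels are assigned by contiguous angular sectors
#' (latitude bands x longitude sectors). The construction is fully
#' deterministic.
#'
#' @param n_vertices Approximate number of vertices per shell (>= 4); the
#'   actual count is the nearest latitude x longitude grid.
#' @param n_rois Number of angular-sector regions.
#' @param inner_radius_mm Radius of the WM/GM interface shell.
#' @param thickness_mm Cortical thickness (pial radius minus inner radius).
#' @param grid_spec Optional list with `spacing_mm` (default 1) and either
#'   `shape` (3 integers) or `margin_mm` (default 2) from which a centered
#'   cubic grid is derived.
#' @return An object of class `phantom_geometry` with elements `pial`,
#'   `wm` (n x 3 mm coordinates), `faces` (triangle indices, 1-based),
#'   `roi` (label per vertex), `shape`, `affine`, and shell parameters.
#' @export
make_phantom_geometry <- function(n_vertices = 600L, n_rois = 4L,
                                  inner_radius_mm = 12, thickness_mm = 2.5,
                                  grid_spec = NULL) {
  stopifnot(n_vertices >= 4L, thickness_mm > 0, inner_radius_mm > 0)
  n_theta <- max(3L, round(sqrt(n_vertices / 2)))
  n_phi <- max(4L, as.integer(ceiling(n_vertices / n_theta)))
  theta <- pi * seq_len(n_theta) / (n_theta + 1)
  phi <- 2 * pi * (seq_len(n_phi) - 1) / n_phi
  grid <- expand.grid(phi = phi, theta = theta) # phi varies fastest
  dirs <- cbind(sin(grid$theta) * cos(grid$phi),
                sin(grid$theta) * sin(grid$phi),
                cos(grid$theta))
  r_out <- inner_radius_mm + thickness_mm
  pial <- dirs * r_out
  wm <- dirs * inner_radius_mm

  layout <- sector_layout(n_rois)
  roi <- label_from_angles(grid$theta, grid$phi, n_rois, layout)

  # quad grid between adjacent latitude rings, split into triangles
  idx <- function(i, j) (i - 1L) * n_phi + ((j - 1L) %% n_phi) + 1L
  faces <- NULL
  if (n_theta >= 2L) {
    i <- rep(seq_len(n_theta - 1L), each = n_phi)
    j <- rep(seq_len(n_phi), times = n_theta - 1L)
    faces <- rbind(
      cbind(idx(i, j), idx(i, j + 1L), idx(i + 1L, j)),
      cbind(idx(i, j + 1L), idx(i + 1L, j + 1L), idx(i + 1L, j))
    )
  }

  spacing <- if (!is.null(grid_spec$spacing_mm)) grid_spec$spacing_mm else 1
  if (!is.null(grid_spec$shape)) {
    shape <- as.integer(grid_spec$shape)
  } else {
    margin <- if (!is.null(grid_spec$margin_mm)) grid_spec$margin_mm else 2
    shape <- rep(as.integer(2 * ceiling((r_out + margin) / spacing) + 1L), 3L)
  }
  extent <- (shape - 1L) * spacing
  if (any(extent / 2 < r_out)) {
    stop("geometry error: voxel grid too small to contain the outer shell")
  }
  affine <- make_affine(rep(spacing, 3L), -(shape - 1L) / 2 * spacing)

  structure(
    list(pial = pial, wm = wm, faces = faces, roi = roi,
         shape = shape, affine = affine, n_rois = as.integer(n_rois),
         inner_radius_mm = inner_radius_mm, thickness_mm = thickness_mm,
         layout = layout),
    class = "phantom_geometry"
  )
}

#' @export
print.phantom_geometry <- function(x, ...) {
  cat(sprintf(paste0("<phantom_geometry> %d vertex pairs, %d ROIs, ",
                     "shells %.1f/%.1f mm, grid %s\n"),
              nrow(x$pial), x$n_rois, x$inner_radius_mm,
              x$inner_radius_mm + x$thickness_mm,
              paste(x$shape, collapse = "x")))
  invisible(x)
}

# Piecewise-constant depth weight: 10%-wide bins spanning 10-90% depth;
# depths outside [10%, 90%] take the nearest bin's weight.
depth_weight_at <- function(depth, weights8) {
  bin <- pmin(pmax(floor((depth - 0.1) / 0.1) + 1, 1), 8)
  weights8[bin]
}

#' Evaluate a depth-dependent radial diffusivity field on the phantom grid
#'
#' Fills the phantom's voxel grid with a scalar diffusivity field: inside
#' the cortical ribbon the value is the baseline profile evaluated at the
#' voxel's fractional depth (linear between the shells) plus a per-region
#' offset scaled by the depth-bin weight at that depth and a uniform
#' participant offset; voxels inside the WM shell and outside the pial
#' shell receive distinct constants so that partial-volume behavior can be
#' exercised.
#'
#' @param geometry A [make_phantom_geometry()] object.
#' @param baseline_profile 21 values at depths 0%, 5%, ..., 100%.
#' @param roi_offsets Additive offset (mm^2/s) per region, depth-weighted;
#'   recycled scalar allowed.
#' @param depth_weights Eight per-bin weights applied to `roi_offsets`.
#' @param global_offset Uniform additive offset (participant intercept).
#' @param wm_value,csf_value Constants outside the ribbon (mm^2/s).
#' @return 3-D numeric array with attributes `affine` and `ribbon`
#'   (logical mask of ribbon voxels).
#' @export
make_rd_field <- function(geometry, baseline_profile,
                          roi_offsets = 0, depth_weights = rep(1, 8),
                          global_offset = 0,
                          wm_value = 0.45e-3, csf_value = 2.5e-3) {
  stopifnot(length(baseline_profile) == 21L, length(depth_weights) == 8L)
  roi_offsets <- rep_len(roi_offsets, geometry$n_rois)
  shape <- geometry$shape
  ijk <- as.matrix(expand.grid(i = 0:(shape[1] - 1L), j = 0:(shape[2] - 1L),
                               k = 0:(shape[3] - 1L)))
  xyz <- voxel_to_mm(ijk, geometry$affine)
  r <- sqrt(rowSums(xyz^2))
  r_in <- geometry$inner_radius_mm
  r_out <- r_in + geometry$thickness_mm
  ribbon <- r >= r_in & r <= r_out

  vals <- numeric(nrow(xyz))
  vals[r < r_in] <- wm_value
  vals[r > r_out] <- csf_value
  if (any(ribbon)) {
    depth <- (r_out - r[ribbon]) / geometry$thickness_mm
    theta <- acos(pmin(pmax(xyz[ribbon, 3] / r[ribbon], -1), 1))
    phi <- atan2(xyz[ribbon, 2], xyz[ribbon, 1])
    lab <- label_from_angles(theta, phi, geometry$n_rois, geometry$layout)
    w <- depth_weight_at(depth, depth_weights)
    vals[ribbon] <- interp1(seq(0, 1, by = 0.05), baseline_profile, depth) +
      roi_offsets[lab] * w + global_offset
  }
  vol <- array(vals, dim = shape)
  attr(vol, "affine") <- geometry$affine
  attr(vol, "ribbon") <- array(ribbon, dim = shape)
  vol
}

#' Default 25-direction gradient scheme
#'
#' A deterministic spherical-Fibonacci spread of 25 unit vectors over the
#' hemisphere, matching the direction count of the acquisition protocol
#' the simulator emulates (25 directions at b = 800 s/mm^2).
#'
#' @param n Number of directions.
#' @return `n x 3` matrix of unit vectors.
#' @export
default_directions <- function(n = 25L) {
  i <- seq_len(n)
  z <- (i - 0.5) / n
  golden <- pi * (3 - sqrt(5))
  phi <- i * golden
  s <- sqrt(1 - z^2)
  unname(cbind(s * cos(phi), s * sin(phi), z))
}

#' Construct a diffusion-weighted dataset
#'
#' @param volumes 4-D intensity array (x, y, z, volume).
#' @param b_values Numeric b-value per volume (s/mm^2).
#' @param directions Matrix `n_volumes x 3`; rows for b = 0 volumes may be
#'   zero, all others must be unit-norm.
#' @param affine 4x4 voxel-to-mm map (0-based voxel centers).
#' @param mask Optional logical volume.
#' @return An object of class `dwi_dataset`.
#' @export
dwi_dataset <- function(volumes, b_values, directions, affine = diag(4),
                        mask = NULL) {
  stopifnot(length(dim(volumes)) == 4L,
            dim(volumes)[4] == length(b_values),
            nrow(directions) == length(b_values))
  nz <- b_values > 0
  if (sum(!nz) < 1L) stop("at least one b = 0 volume is required")
  if (sum(nz) < 6L) stop("at least six diffusion-weighted volumes are required")
  norms <- sqrt(rowSums(directions[nz, , drop = FALSE]^2))
  if (any(abs(norms - 1) > 1e-6)) {
    stop("directions for nonzero b-values must be unit-norm")
  }
  structure(list(volumes = volumes, b_values = b_values,
                 directions = directions, affine = affine, mask = mask),
            class = "dwi_dataset")
}

#' @export
print.dwi_dataset <- function(x, ...) {
  d <- dim(x$volumes)
  cat(sprintf("<dwi_dataset> %s, %d b=0 + %d DW volumes, b = %s s/mm^2\n",
              paste(d[1:3], collapse = "x"), sum(x$b_values == 0),
              sum(x$b_values > 0),
              paste(unique(x$b_values[x$b_values > 0]), collapse = "/")))
  invisible(x)
}

#' Simulate diffusion-weighted signals from a tensor field
#'
#' Generates the signal `S = S0 * exp(-b g' D g)` per voxel and direction,
#' preceded by `n_b0` unweighted volumes, with additive Gaussian noise.
#' Additive (rather than Rician) noise is a deliberate simplification
#' appropriate at the simulated signal-to-noise ratios; see the package
#' vignette.
#'
#' @param tensor_field 4-D array `x,y,z,6` of tensor components
#'   (xx, yy, zz, xy, xz, yz; mm^2/s), with an `affine` attribute.
#' @param b_value Diffusion weighting (s/mm^2), default 800.
#' @param directions Unit gradient directions (`n x 3`).
#' @param n_b0 Number of unweighted volumes, default 2.
#' @param noise_sd Additive Gaussian noise SD (signal units).
#' @param seed Optional seed for the noise stream.
#' @param s0 Noise-free unweighted signal.
#' @return A [dwi_dataset()].
#' @export
make_dwi <- function(tensor_field, b_value = 800,
                     directions = default_directions(), n_b0 = 2L,
                     noise_sd = 0, seed = NULL, s0 = 1000) {
  stopifnot(length(dim(tensor_field)) == 4L, dim(tensor_field)[4] == 6L,
            noise_sd >= 0)
  norms <- sqrt(rowSums(directions^2))
  if (any(abs(norms - 1) > 1e-6)) stop("directions must be unit-norm")
  shape <- dim(tensor_field)[1:3]
  nvox <- prod(shape)
  d6 <- matrix(tensor_field, nrow = nvox, ncol = 6L)
  ev <- sym3_eigenvalues(d6)
  if (any(ev[, 3] < -1e-12)) {
    warning(sprintf("%d voxels have non-positive-definite tensors; %s",
                    sum(ev[, 3] < -1e-12),
                    "signals computed from the quadratic form anyway"))
  }
  ndir <- nrow(directions)
  gq <- cbind(directions[, 1]^2, directions[, 2]^2, directions[, 3]^2,
              2 * directions[, 1] * directions[, 2],
              2 * directions[, 1] * directions[, 3],
              2 * directions[, 2] * directions[, 3])
  q <- d6 %*% t(gq) # nvox x ndir
  sig <- s0 * exp(-b_value * q)
  vols <- cbind(matrix(s0, nvox, n_b0), sig)
  if (noise_sd > 0) {
    vols <- vols + with_seed(seed, matrix(stats::rnorm(length(vols),
                                                       sd = noise_sd),
                                          nrow = nvox))
  }
  volumes <- array(vols, dim = c(shape, n_b0 + ndir))
  dwi_dataset(volumes,
              b_values = c(rep(0, n_b0), rep(b_value, ndir)),
              directions = rbind(matrix(0, n_b0, 3L), directions),
              affine = attr(tensor_field, "affine") %||% diag(4))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Radially oriented tensor field matching a radial-diffusivity volume
#'
#' Expands a scalar radial-diffusivity phantom volume into a full tensor
#' field: within the ribbon the principal axis is the radial (column)
#' direction with `lambda1 = RD + axial_excess` and the two transverse
#' eigenvalues equal to the voxel's RD value; outside the ribbon the tensor
#' is isotropic at the voxel's scalar value.
#'
#' @param geometry Phantom geometry.
#' @param rd_volume Scalar volume from [make_rd_field()].
#' @param axial_excess `lambda1 - RD` (mm^2/s), default 0.5e-3.
#' @return 4-D array `x,y,z,6` with the grid `affine` attribute.
#' @export
radial_tensor_field <- function(geometry, rd_volume, axial_excess = 0.5e-3) {
  shape <- geometry$shape
  ijk <- as.matrix(expand.grid(i = 0:(shape[1] - 1L), j = 0:(shape[2] - 1L),
                               k = 0:(shape[3] - 1L)))
  xyz <- voxel_to_mm(ijk, geometry$affine)
  r <- sqrt(rowSums(xyz^2))
  rhat <- xyz / ifelse(r > 0, r, 1)
  ribbon <- as.vector(attr(rd_volume, "ribbon"))
  if (is.null(ribbon)) {
    r_in <- geometry$inner_radius_mm
    ribbon <- r >= r_in & r <= r_in + geometry$thickness_mm
  }
  rd <- as.vector(rd_volume)
  ex <- ifelse(ribbon, axial_excess, 0)
  d6 <- cbind(rd + ex * rhat[, 1]^2,
              rd + ex * rhat[, 2]^2,
              rd + ex * rhat[, 3]^2,
              ex * rhat[, 1] * rhat[, 2],
              ex * rhat[, 1] * rhat[, 3],
              ex * rhat[, 2] * rhat[, 3])
  out <- array(d6, dim = c(shape, 6L))
  attr(out, "affine") <- geometry$affine
  out
}

# Draw participant metadata (group, amyloid ratio, random intercept) for a
# cohort spec; shared by the image-level and table-level generators so the
# two paths agree participant for participant.
draw_participants <- function(spec) {
  n <- sum(spec$group_sizes)
  group <- rep(1:4, times = spec$group_sizes)
  intercept <- with_seed(derive_seed(spec$seed, "intercept"),
                         stats::rnorm(n, 0, spec$between_subject_sd))
  cutoff <- spec$abeta_cutoff
  abeta <- with_seed(derive_seed(spec$seed, "abeta"), {
    u <- stats::runif(n)
    a <- ifelse(group == 1L, cutoff + u * 0.04, cutoff - (1 - u) * 0.04)
    miss <- group == 4L & stats::runif(n) < spec$abeta_missing_rate
    a[miss] <- NA_real_
    a
  })
  ad_extra <- numeric(n)
  if (spec$n_decliners > 0L) {
    g2 <- which(group == 2L)
    chosen <- with_seed(derive_seed(spec$seed, "decliners"),
                        sample(g2, spec$n_decliners))
    ad_extra[chosen] <- spec$decliner_elevation
  }
  data.frame(
    id = sprintf("sub-%02d", seq_len(n)),
    group = group,
    abeta_ratio = abeta,
    intercept = intercept,
    ad_extra = ad_extra,
    true_elevation = spec$group_severity[group] + ad_extra + intercept,
    stringsAsFactors = FALSE
  )
}

#' Simulate an image-level cohort on the phantom
#'
#' Generates one scalar radial-diffusivity volume (or a full simulated DWI
#' acquisition) per participant on a shared phantom geometry. Each
#' participant's field is the baseline depth profile plus the group
#' severity in the AD regions (depth-weighted) plus a participant random
#' intercept; at the `"rd"` level, voxel-wise Gaussian noise with
#' `measurement_sd` is added, while at the `"dwi"` level noise is applied
#' to the simulated signals via `dwi_noise_sd`.
#'
#' @param spec A [cohort_spec()]; its `n_rois` must match `geometry`.
#' @param geometry Optional phantom geometry; a default desk-scale phantom
#'   is built when omitted.
#' @param level `"rd"` for scalar volumes, `"dwi"` for simulated
#'   acquisitions (b = 800 s/mm^2, 25 directions, 2 b = 0 volumes).
#' @param dwi_noise_sd Signal noise SD for `level = "dwi"`.
#' @param axial_excess Axial minus radial diffusivity inside the ribbon.
#' @param wm_value,csf_value Field constants outside the ribbon, passed to
#'   [make_rd_field()]; set them to the baseline endpoints to obtain a
#'   partial-volume-free field.
#' @return An object of class `synthetic_cohort`: the geometry, the
#'   participant table, and one image per participant.
#' @export
simulate_cohort <- function(spec, geometry = NULL,
                            level = c("rd", "dwi"), dwi_noise_sd = 0,
                            axial_excess = 0.5e-3,
                            wm_value = 0.45e-3, csf_value = 2.5e-3) {
  stopifnot(inherits(spec, "cohort_spec"))
  level <- match.arg(level)
  if (is.null(geometry)) {
    geometry <- make_phantom_geometry(
      n_vertices = max(500L, 30L * spec$n_rois), n_rois = spec$n_rois)
  }
  if (geometry$n_rois != spec$n_rois) {
    stop("geometry and cohort spec disagree on the number of ROIs")
  }
  participants <- draw_participants(spec)
  n <- nrow(participants)
  ad_ind <- as.numeric(seq_len(spec$n_rois) %in% spec$ad_roi_ids)
  noise_seed <- derive_seed(spec$seed, "noise")
  images <- vector("list", n)
  for (p in seq_len(n)) {
    offsets <- ad_ind * (spec$group_severity[participants$group[p]] +
                           participants$ad_extra[p])
    vol <- make_rd_field(geometry, spec$baseline_profile,
                         roi_offsets = offsets,
                         depth_weights = spec$depth_effect_weights,
                         global_offset = participants$intercept[p],
                         wm_value = wm_value, csf_value = csf_value)
    if (level == "rd") {
      if (spec$measurement_sd > 0) {
        eps <- with_seed(noise_seed + p,
                         array(stats::rnorm(length(vol),
                                            sd = spec$measurement_sd),
                               dim = dim(vol)))
        att <- attributes(vol)
        vol <- vol + eps
        attributes(vol) <- att
      }
      images[[p]] <- vol
    } else {
      tf <- radial_tensor_field(geometry, vol, axial_excess = axial_excess)
      images[[p]] <- make_dwi(tf, noise_sd = dwi_noise_sd,
                              seed = if (is.null(noise_seed)) NULL else
                                noise_seed + p)
    }
  }
  structure(list(spec = spec, geometry = geometry,
                 participants = participants, images = images,
                 level = level),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("<synthetic_cohort> %d participants (%s), level = %s, %d ROIs\n",
              nrow(x$participants),
              paste(x$spec$group_sizes, collapse = "/"), x$level,
              x$spec$n_rois))
  invisible(x)
}

#' Generate a participant x ROI x depth-bin table directly
#'
#' Table-level fast path: produces the same depth-bin table the imaging
#' pipeline would, without simulating images. Cell values are the binned
#' baseline profile plus the group severity in AD regions scaled by the
#' bin's depth weight, plus the participant intercept and cell-level
#' Gaussian measurement noise. The effect parameterization and participant
#' draws are identical to [simulate_cohort()], so the two paths agree in
#' expectation.
#'
#' @param spec A [cohort_spec()].
#' @return A [depthbin_table()] with generator bookkeeping columns
#'   (`intercept`, `true_elevation`) in its participant table.
#' @export
make_depthbin_table <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  participants <- draw_participants(spec)
  n <- nrow(participants)
  bb <- bin_profile(spec$baseline_profile)
  ad_ind <- as.numeric(seq_len(spec$n_rois) %in% spec$ad_roi_ids)
  sev <- spec$group_severity[participants$group] + participants$ad_extra
  # n x roi x bin: baseline + severity * ad * weight + intercept + noise
  vals <- array(rep(bb, each = n * spec$n_rois),
                dim = c(n, spec$n_rois, 8L))
  effect <- outer(sev, ad_ind) # n x roi
  for (b in 1:8) {
    vals[, , b] <- vals[, , b] + effect * spec$depth_effect_weights[b] +
      participants$intercept
  }
  if (spec$measurement_sd > 0) {
    vals <- vals + with_seed(derive_seed(spec$seed, "noise"),
                             array(stats::rnorm(length(vals),
                                                sd = spec$measurement_sd),
                                   dim = dim(vals)))
  }
  depthbin_table(vals, participants, metric = "RD", mode = "bins8")
}
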