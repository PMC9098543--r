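#' Tissue compartment of the multi-tensor phantom
#'
#' @param label one of "GM", "WM", "CSF"
#' @param adc mean diffusivity in mm^2/s
#' @param axial_ratio for anisotropic (WM) compartments, the ratio of the
#'   axial to radial tensor eigenvalue at fixed trace `3*adc`
#' @return a `tissue_compartment` with derived eigenvalues and FA
#' @export
tissue_compartment <- function(label = c("GM", "WM", "CSF"), adc,
                               axial_ratio = 1) {
  label <- match.arg(label)
  stopifnot(adc > 0, axial_ratio >= 1)
  if (axial_ratio == 1) {
    lambda <- rep(adc, 3)
  } else {
    # axially symmetric, trace fixed at 3*adc
    l_par <- 3 * adc * axial_ratio / (axial_ratio + 2)
    l_perp <- 3 * adc / (axial_ratio + 2)
    lambda <- c(l_par, l_perp, l_perp)
  }
  lb <- mean(lambda)
  fa <- if (axial_ratio == 1) 0 else
    sqrt(1.5 * sum((lambda - lb)^2) / sum(lambda^2))
  structure(list(label = label, adc = adc, lambda = lambda, fa = fa,
                 axial_ratio = axial_ratio),
            class = "tissue_compartment")
}

# Ex vivo diffusivity modes of the three tissue classes (mm^2/s), with the
# white matter tensor axially symmetric at a 5:1 eigenvalue ratio.
default_compartments <- function() {
  list(GM = tissue_compartment("GM", 3.0e-4),
       WM = tissue_compartment("WM", 2.3e-4, axial_ratio = 5),
       CSF = tissue_compartment("CSF", 6.5e-4))
}

#' Ground-truth bundle geometry
#'
#' A tube of parallel fibers around a polyline centerline.
#'
#' @param name bundle name
#' @param centerline matrix `k x 3` of mm points, `k >= 2`
#' @param radius tube radius in mm
#' @param fiber_count number of ground-truth streamlines to plant
#' @param region one of "LH", "RH", "INT", "CBL" (metadata tag)
#' @export
bundle_geometry <- function(name, centerline, radius, fiber_count,
                            region = c("LH", "RH", "INT", "CBL")) {
  centerline <- as.matrix(centerline)
  stopifnot(nrow(centerline) >= 2, ncol(centerline) == 3,
            radius > 0, fiber_count >= 1)
  structure(list(name = name, centerline = centerline, radius = radius,
                 fiber_count = as.integer(fiber_count),
                 region = match.arg(region)),
            class = "bundle_geometry")
}

#' Phantom specification
#'
#' Defines the synthetic acquisition grid, tissue compartments, planted
#' bundles and noise level. Defaults mirror the ex vivo avian acquisition
#' the pipeline targets: 0.2 mm isotropic voxels, three-tissue diffusivity
#' modes, Rician noise defined at b = 0 in white matter.
#'
#' @param grid_shape integer vector of 3 voxel counts
#' @param voxel_size isotropic voxel size in mm
#' @param compartments named list of [tissue_compartment()]s (GM, WM, CSF)
#' @param bundles list of [bundle_geometry()]
#' @param snr signal-to-noise ratio at b = 0 (Inf for noiseless)
#' @param seed integer seed driving every random element of the phantom
#' @param s0 b = 0 signal level (arbitrary units)
#' @param csf_fraction fraction of the grid (lowest z slab) labeled CSF
#' @param cbl_fraction fraction of the grid (highest z slab) labeled
#'   cerebellum in the region-label volume
#' @export
phantom_spec <- function(grid_shape = c(32L, 32L, 32L), voxel_size = 0.2,
                         compartments = default_compartments(),
                         bundles = list(), snr = Inf, seed = 0L, s0 = 1000,
                         csf_fraction = 0.1, cbl_fraction = 0.25) {
  stopifnot(voxel_size > 0, length(grid_shape) == 3, all(grid_shape >= 4))
  extent <- grid_shape * voxel_size
  for (b in bundles) {
    if (any(b$centerline < 0) ||
        any(sweep(b$centerline, 2, extent, ">")))
      stop(sprintf("bundle '%s' centerline leaves the grid", b$name))
  }
  structure(list(grid_shape = as.integer(grid_shape), voxel_size = voxel_size,
                 compartments = compartments, bundles = bundles, snr = snr,
                 seed = as.integer(seed), s0 = s0,
                 csf_fraction = csf_fraction, cbl_fraction = cbl_fraction),
            class = "phantom_spec")
}

# resample a polyline at (approximately) fixed arc-length spacing, keeping
# endpoints; returns points and unit tangents
resample_polyline <- function(pts, spacing) {
  seg <- diff(pts)
  seg_len <- sqrt(rowSums(seg^2))
  s <- c(0, cumsum(seg_len))
  total <- s[length(s)]
  if (total <= 0) stop("degenerate polyline")
  n_out <- max(2L, ceiling(total / spacing) + 1L)
  si <- seq(0, total, length.out = n_out)
  out <- matrix(0, n_out, 3)
  tan_out <- matrix(0, n_out, 3)
  j <- 1L
  for (i in seq_len(n_out)) {
    while (j < length(seg_len) && si[i] > s[j + 1L]) j <- j + 1L
    f <- (si[i] - s[j]) / seg_len[j]
    out[i, ] <- pts[j, ] + f * seg[j, ]
    tan_out[i, ] <- seg[j, ] / seg_len[j]
  }
  list(points = out, tangents = tan_out, length = total)
}

# smallest-magnitude orthonormal frame transported along tangents
transport_frame <- function(tangents) {
  k <- nrow(tangents)
  e1 <- matrix(0, k, 3); e2 <- matrix(0, k, 3)
  t1 <- tangents[1, ]
  ref <- if (abs(t1[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  v <- ref - sum(ref * t1) * t1
  e1[1, ] <- unit(v)
  e2[1, ] <- pracma::cross(t1, e1[1, ])
  for (i in seq(2, k)) {
    ti <- tangents[i, ]
    v <- e1[i - 1, ] - sum(e1[i - 1, ] * ti) * ti
    e1[i, ] <- unit(v)
    e2[i, ] <- pracma::cross(ti, e1[i, ])
  }
  list(e1 = e1, e2 = e2)
}

#' Build the ground-truth phantom geometry
#'
#' Rasterizes each bundle tube into the white-matter compartment (recording
#' the local fiber direction per voxel; voxels claimed by several bundles
#' become crossing voxels carrying all directions), lays `fiber_count`
#' jittered parallel streamlines per bundle, and assigns tissue and region
#' labels to the remaining voxels.
#'
#' @param spec a [phantom_spec()]
#' @return a `ground_truth` list: `streamlines` (list of mm polylines),
#'   `bundle_of_streamline`, `region_labels` (int array, 1=LH 2=RH 3=INT
#'   4=CBL), `brain_mask` (logical array), `tissue_labels` (1=GM 2=WM
#'   3=CSF), `wm_voxels` (data.frame: voxel, bundle, ux, uy, uz), `spec`
#' @export
build_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  gs <- spec$grid_shape; vs <- spec$voxel_size
  nvox <- prod(gs)
  idx <- arrayInd(seq_len(nvox), gs)
  centers <- (idx - 0.5) * vs

  # --- rasterize bundles ---
  wm_list <- list()
  for (bi in seq_along(spec$bundles)) {
    b <- spec$bundles[[bi]]
    rs <- resample_polyline(b$centerline, vs / 4)
    S <- rs$points; Tn <- rs$tangents
    best_d2 <- rep(Inf, nvox); best_k <- rep(1L, nvox)
    for (k in seq_len(nrow(S))) {
      d2 <- (centers[, 1] - S[k, 1])^2 + (centers[, 2] - S[k, 2])^2 +
        (centers[, 3] - S[k, 3])^2
      upd <- d2 < best_d2
      best_d2[upd] <- d2[upd]; best_k[upd] <- k
    }
    inside <- which(best_d2 <= max(b$radius, vs / 2)^2)
    if (length(inside))
      wm_list[[bi]] <- data.frame(voxel = inside, bundle = bi,
                                  ux = Tn[best_k[inside], 1],
                                  uy = Tn[best_k[inside], 2],
                                  uz = Tn[best_k[inside], 3])
  }
  wm_voxels <- if (length(wm_list)) do.call(rbind, wm_list) else
    data.frame(voxel = integer(0), bundle = integer(0),
               ux = numeric(0), uy = numeric(0), uz = numeric(0))

  # --- tissue labels ---
  tissue <- array(1L, gs)                      # GM
  if (spec$csf_fraction > 0) {
    zc <- centers[, 3] / (gs[3] * vs)
    tissue[zc < spec$csf_fraction] <- 3L
  }
  tissue[wm_voxels$voxel] <- 2L

  # --- region labels: x halves -> LH/RH, top z slab -> CBL ---
  region <- array(0L, gs)
  xmid <- gs[1] * vs / 2
  region[seq_len(nvox)] <- ifelse(centers[, 1] < xmid, 1L, 2L)
  if (spec$cbl_fraction > 0) {
    zc <- centers[, 3] / (gs[3] * vs)
    region[zc >= 1 - spec$cbl_fraction] <- 4L
  }

  # --- brain mask: full grid minus a one-voxel border (air background) ---
  mask <- array(TRUE, gs)
  mask[c(1, gs[1]), , ] <- FALSE
  mask[, c(1, gs[2]), ] <- FALSE
  mask[, , c(1, gs[3])] <- FALSE

  # --- ground-truth streamlines ---
  streamlines <- list(); bundle_of <- integer(0)
  with_seed(derive_seed(spec$seed, "phantom_fibers"), {
    for (bi in seq_along(spec$bundles)) {
      b <- spec$bundles[[bi]]
      rs <- resample_polyline(b$centerline, vs / 2)
      fr <- transport_frame(rs$tangents)
      for (f in seq_len(b$fiber_count)) {
        repeat {                              # uniform offset in the disk
          a <- runif(2, -1, 1)
          if (sum(a^2) <= 1) break
        }
        off <- a * b$radius
        pts <- rs$points + off[1] * fr$e1 + off[2] * fr$e2
        streamlines[[length(streamlines) + 1L]] <- pts
        bundle_of <- c(bundle_of, bi)
      }
    }
  })

  structure(list(streamlines = streamlines, bundle_of_streamline = bundle_of,
                 region_labels = region, brain_mask = mask,
                 tissue_labels = tissue, wm_voxels = wm_voxels, spec = spec),
            class = "ground_truth")
}

#' Simulate the diffusion-weighted signal of a phantom
#'
#' Standard multi-tensor signal model: per voxel
#' `S(g, b) = S0 * sum_i f_i * exp(-b g' D_i g)` with equal volume fractions
#' over the compartments present in the voxel (crossing voxels mix one
#' tensor per planted direction). Rician noise is applied as the magnitude
#' of the complex-noised signal, `|S + n1 + i n2|` with
#' `n1, n2 ~ N(0, S0/snr)`; b = 0 volumes carry `S0` plus noise. Outside the
#' brain mask the noiseless signal is zero (air), so the noised background
#' is Rayleigh-distributed, as in magnitude MRI.
#'
#' @param truth a `ground_truth` from [build_phantom()]
#' @param spec the [phantom_spec()] used to build it
#' @param scheme a [gradient_scheme()]
#' @return 4D array `grid_shape x n_volumes`
#' @export
simulate_dwi <- function(truth, spec, scheme) {
  stopifnot(inherits(truth, "ground_truth"), inherits(scheme, "gradient_scheme"))
  if (!is.infinite(spec$snr) && spec$snr <= 0) stop("snr must be positive")
  gs <- spec$grid_shape
  nvox <- prod(gs)
  nvol <- length(scheme$bvals)
  ndw <- nrow(scheme$directions)
  b <- scheme$b
  sig <- matrix(0, nvox, nvol)               # voxel x volume
  inmask <- which(truth$brain_mask)
  sig[inmask, seq_len(scheme$n_b0)] <- spec$s0

  dw_cols <- scheme$n_b0 + seq_len(ndw)
  G <- scheme$directions

  # isotropic compartments: one attenuation per compartment, all directions
  for (ti in c(1L, 3L)) {
    comp <- spec$compartments[[c("GM", "WM", "CSF")[ti]]]
    vox <- intersect(which(truth$tissue_labels == ti), inmask)
    if (length(vox))
      sig[vox, dw_cols] <- spec$s0 * exp(-b * comp$adc)
  }

  # white matter: one axially symmetric tensor per planted direction
  wm <- truth$wm_voxels
  wm <- wm[wm$voxel %in% inmask, , drop = FALSE]
  comp <- spec$compartments$WM
  l_par <- comp$lambda[1]; l_perp <- comp$lambda[2]
  if (nrow(wm)) {
    U <- as.matrix(wm[, c("ux", "uy", "uz")])
    # attenuation per (wm row, direction): exp(-b (l_perp + (l_par-l_perp) (g.u)^2))
    gu2 <- (U %*% t(G))^2
    att <- exp(-b * (l_perp + (l_par - l_perp) * gu2))
    # average rows sharing a voxel (equal volume fractions)
    for (v in unique(wm$voxel)) {
      rows <- which(wm$voxel == v)
      a <- if (length(rows) == 1L) att[rows, ] else colMeans(att[rows, , drop = FALSE])
      sig[v, dw_cols] <- spec$s0 * a
    }
  }

  if (is.finite(spec$snr)) {
    sigma <- spec$s0 / spec$snr
    sig <- with_seed(derive_seed(spec$seed, "dwi_noise"), {
      n1 <- matrix(rnorm(length(sig), sd = sigma), nrow(sig))
      n2 <- matrix(rnorm(length(sig), sd = sigma), nrow(sig))
      sqrt((sig + n1)^2 + n2^2)
    })
  }
  array(sig, c(gs, nvol))
}
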