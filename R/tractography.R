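#' Streamline tracking parameters
#'
#' Defaults are the whole-brain SRD settings used for the ex vivo avian
#' acquisition this pipeline targets: eight seeds per mask voxel, a 30
#' degree aperture, a 50 um integration step, fiber lengths retained in
#' [0.1, 100] mm, and an anisotropy regularization factor of 0.12 (the
#' population 98% cumulative-GFA threshold).
#'
#' @param seeds_per_voxel seeds drawn uniformly inside each mask voxel
#' @param aperture_deg aperture half-angle (degrees) of the peak-selection
#'   cone around the previous direction
#' @param step integration step in mm (must be below the voxel size)
#' @param length_range retained fiber length range in mm
#' @param gfa_reg_threshold GFA value at which regularization vanishes
#' @param rng_seed seed for seed-point jitter
#' @param rel_peak_threshold relative ODF peak threshold
#' @export
tracking_params <- function(seeds_per_voxel = 8L, aperture_deg = 30,
                            step = 0.05, length_range = c(0.1, 100),
                            gfa_reg_threshold = 0.12, rng_seed = 0L,
                            rel_peak_threshold = 0.25) {
  stopifnot(step > 0, aperture_deg > 0, aperture_deg < 90,
            seeds_per_voxel >= 1, length_range[1] < length_range[2])
  structure(list(seeds_per_voxel = as.integer(seeds_per_voxel),
                 aperture_deg = aperture_deg, step = step,
                 length_range = length_range,
                 gfa_reg_threshold = gfa_reg_threshold,
                 rng_seed = as.integer(rng_seed),
                 rel_peak_threshold = rel_peak_threshold),
            class = "tracking_params")
}

#' Tractogram container
#' @param streamlines list of `n x 3` mm point matrices (each `n >= 2`)
#' @param voxel_size mm
#' @param subject subject identifier
#' @param params the [tracking_params()] used (or NULL)
#' @export
tractogram <- function(streamlines, voxel_size, subject = NA_character_,
                       params = NULL) {
  structure(list(streamlines = streamlines, voxel_size = voxel_size,
                 subject = subject, params = params),
            class = "tractogram")
}

#' @export
length.tractogram <- function(x) length(x$streamlines)

#' @export
print.tractogram <- function(x, ...) {
  cat(sprintf("tractogram: %d streamlines (subject %s)\n",
              length(x$streamlines), x$subject))
  invisible(x)
}

#' Streamline lengths in mm
#' @param x a [tractogram()] or list of point matrices
#' @export
streamline_lengths <- function(x) {
  sl <- if (inherits(x, "tractogram")) x$streamlines else x
  vapply(sl, function(p) sum(sqrt(rowSums(diff(p)^2))), numeric(1))
}

#' Draw seed points inside mask voxels
#'
#' Exactly `seeds_per_voxel` points uniformly inside each mask voxel's
#' half-open mm box, deterministic given `rng_seed`.
#'
#' @param mask logical 3D array
#' @param params a [tracking_params()]
#' @param voxel_size mm
#' @return matrix `n_seeds x 3` of mm points
#' @export
seed_voxels <- function(mask, params, voxel_size) {
  vox <- which(mask)
  if (length(vox) == 0) stop("empty mask")
  ijk <- arrayInd(vox, dim(mask))
  k <- params$seeds_per_voxel
  with_seed(params$rng_seed, {
    lo <- (ijk - 1) * voxel_size
    lo <- lo[rep(seq_len(nrow(lo)), each = k), , drop = FALSE]
    lo + matrix(runif(3 * nrow(lo)), ncol = 3) * voxel_size
  })
}

#' Streamline-regularized deterministic tractography
#'
#' From each seed, the streamline is integrated forward and backward. At
#' each step the candidate direction is the ODF peak (from trilinearly
#' interpolated SH coefficients) closest to the previous direction within
#' the aperture cone; the update blends it with the previous direction,
#' `d = normalize((1-w) d_odf + w d_prev)` with
#' `w = clamp(1 - GFA(x)/theta, 0, 1)`, so low-anisotropy regions propagate
#' inertially. Streamlines stop at the mask boundary, when no in-cone peak
#' exists, or past the maximum length; only lengths inside `length_range`
#' are kept. The first step from the seed follows the global ODF maximum.
#'
#' @param odf `sh_field` from [fit_aqbi()]
#' @param gfa GFA [scalar_map()]
#' @param mask logical 3D array
#' @param seeds matrix of mm seed points (see [seed_voxels()])
#' @param params a [tracking_params()]
#' @param subject subject tag for provenance
#' @return a [tractogram()]; dropped-seed count in attribute `n_dropped`
#' @export
track_srd <- function(odf, gfa, mask, seeds, params = tracking_params(),
                      subject = NA_character_) {
  stopifnot(inherits(odf, "sh_field"), inherits(params, "tracking_params"),
            params$step < odf$voxel_size)
  geo <- tess_geometry(order = odf$order)
  nb_len <- vapply(geo$neighbors, length, integer(1))
  nb_start <- c(0L, cumsum(nb_len))
  nb_idx <- unlist(geo$neighbors) - 1L
  res <- track_srd_cpp(
    as.vector(odf$coef), as.integer(dim(odf$coef)),
    as.vector(gfa$data), as.integer(mask), seeds,
    geo$points, geo$B, as.integer(nb_idx), as.integer(nb_start),
    odf$voxel_size, params$step, params$aperture_deg,
    params$gfa_reg_threshold, params$length_range[1],
    params$length_range[2], params$rel_peak_threshold)
  tg <- tractogram(res$streamlines, odf$voxel_size, subject, params)
  attr(tg, "n_dropped") <- res$n_dropped
  attr(tg, "seed_index") <- res$seed_index
  tg
}

#' Population fiber-length window
#'
#' Pools streamline lengths over all subjects and returns the low/high
#' percentiles of the cumulative length histogram (defaults 2% and 98%),
#' by linear interpolation of the empirical CDF. Applied over a cohort this
#' defines the length window used to discard aborted and implausible
#' streamlines before clustering.
#'
#' @param tractograms list of [tractogram()]s
#' @param lo_pct,hi_pct percentiles
#' @return numeric `c(l_min, l_max)` in mm
#' @export
population_length_window <- function(tractograms, lo_pct = 2, hi_pct = 98) {
  if (length(tractograms) == 0) stop("empty tractogram pool")
  lens <- unlist(lapply(tractograms, streamline_lengths))
  if (length(lens) == 0) stop("empty tractogram pool")
  c(interp_percentile(lens, lo_pct), interp_percentile(lens, hi_pct))
}
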