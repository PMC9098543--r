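# ---- end-to-end synthetic pipeline ----

#' Default planted bundle layout for a synthetic cohort
#'
#' Three well-separated tubes inside the grid: a straight left-hemisphere
#' tube along x, a straight right-hemisphere tube along y, and a
#' quarter-circle arc, exercising straight and curved tracking.
#'
#' @param grid_shape voxel counts
#' @param voxel_size mm
#' @param fiber_count ground-truth fibers per bundle
#' @export
default_bundles <- function(grid_shape = c(32L, 32L, 32L), voxel_size = 0.2,
                            fiber_count = 60L) {
  ext <- grid_shape * voxel_size
  margin <- 2.5 * voxel_size
  r <- 1.4 * voxel_size
  straight <- function(p0, p1) rbind(p0, p1)
  arc <- local({
    th <- seq(0, pi / 2, length.out = 25)
    rad <- 0.30 * min(ext)
    ctr <- c(0.62 * ext[1], 0.30 * ext[2], 0.72 * ext[3])
    cbind(ctr[1] + rad * (cos(th) - 1) + rad,
          ctr[2] + rad * sin(th) - rad / 2,
          ctr[3] + 0 * th)
  })
  arc[, 1] <- clamp(arc[, 1], margin, ext[1] - margin)
  arc[, 2] <- clamp(arc[, 2], margin, ext[2] - margin)
  list(
    bundle_geometry("straight_x_LH",
                    straight(c(margin, 0.30 * ext[2], 0.40 * ext[3]),
                             c(ext[1] - margin, 0.30 * ext[2], 0.40 * ext[3])),
                    radius = r, fiber_count = fiber_count, region = "INT"),
    bundle_geometry("straight_y_LH",
                    straight(c(0.28 * ext[1], margin, 0.62 * ext[3]),
                             c(0.28 * ext[1], ext[2] - margin, 0.62 * ext[3])),
                    radius = r, fiber_count = fiber_count, region = "LH"),
    bundle_geometry("arc_RH", arc,
                    radius = r, fiber_count = fiber_count, region = "RH"))
}

#' Pipeline configuration
#'
#' All stage parameters of the synthetic end-to-end pipeline, defaulting to
#' the acquisition and processing settings the package targets: a 75
#' direction + 5 b=0 shell at b = 4500 s/mm^2 on a 0.2 mm grid, SH order 8
#' with lambda = 0.006, SRD tracking (8 seeds/voxel, 30 degrees, 50 um
#' step, [0.1, 100] mm, regularization 0.12), the 2-98% population length
#' window in 8 ranges, 27-voxel parcels, the 31%/5-fiber cluster rules, and
#' the (nf, CAMD) = (4.0, 2.0) mm inter-subject setting with 50% presence.
#'
#' @param n_subjects cohort size
#' @param grid_shape phantom grid
#' @param voxel_size mm
#' @param snr Rician SNR at b = 0 (Inf = noiseless)
#' @param n_dirs,n_b0,b gradient scheme
#' @param bundles planted bundle list (NULL = [default_bundles()])
#' @param denoise run the NLM filter (skipped automatically when snr = Inf)
#' @param nlm_patch_radius,nlm_search_radius NLM window radii
#' @param sh_order,sh_lambda Q-ball fit settings
#' @param tracking a [tracking_params()]
#' @param window_pcts population length-window percentiles
#' @param intra an [intra_params()]
#' @param inter an [inter_params()]
#' @param seed root seed; every stage derives its own stream from it
#' @export
pipeline_config <- function(n_subjects = 6L,
                            grid_shape = c(32L, 32L, 32L),
                            voxel_size = 0.2,
                            snr = 30,
                            n_dirs = 75L, n_b0 = 5L, b = 4500,
                            bundles = NULL,
                            denoise = TRUE,
                            nlm_patch_radius = 1L, nlm_search_radius = 3L,
                            sh_order = 8L, sh_lambda = 0.006,
                            tracking = tracking_params(),
                            window_pcts = c(2, 98),
                            intra = intra_params(),
                            inter = inter_params(),
                            seed = 0L) {
  if (is.null(bundles)) bundles <- default_bundles(grid_shape, voxel_size)
  structure(list(n_subjects = as.integer(n_subjects),
                 grid_shape = as.integer(grid_shape),
                 voxel_size = voxel_size, snr = snr,
                 n_dirs = as.integer(n_dirs), n_b0 = as.integer(n_b0), b = b,
                 bundles = bundles, denoise = denoise,
                 nlm_patch_radius = nlm_patch_radius,
                 nlm_search_radius = nlm_search_radius,
                 sh_order = sh_order, sh_lambda = sh_lambda,
                 tracking = tracking, window_pcts = window_pcts,
                 intra = intra, inter = inter, seed = as.integer(seed)),
            class = "pipeline_config")
}

log_record <- function(log, stage, ...) {
  rec <- c(list(stage = stage), list(...))
  log[[length(log) + 1L]] <- rec
  log
}

#' Run the full synthetic pipeline
#'
#' phantom -> simulate -> (denoise) -> mask -> Q-ball + GFA -> SRD tracking
#' per subject; then population length window, intra-subject clustering,
#' inter-subject HDBSCAN clustering, and ROI-based bundle atlas assembly
#' (one ROI per planted bundle, derived from the ground-truth tubes).
#' Fully deterministic given `config$seed`.
#'
#' @param config a [pipeline_config()]
#' @param keep_tractograms keep per-subject tractograms in the result
#' @return list: `atlas` (a `bundle_atlas`), `inter_clusters`,
#'   `intra_clusters` (per subject), `window`, `gfa_thresholds`,
#'   `n_streamlines`, `centroids` (the [centroid_set()]), `log`, `config`
#' @export
run_pipeline <- function(config = pipeline_config(),
                         keep_tractograms = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  log <- list()
  scheme <- make_gradient_scheme(config$n_dirs, config$n_b0, config$b,
                                 seed = derive_seed(config$seed, "scheme"))
  tracts <- vector("list", config$n_subjects)
  gfa_thr <- numeric(config$n_subjects)
  truth0 <- NULL
  labels0 <- NULL
  mask0 <- NULL
  for (s in seq_len(config$n_subjects)) {
    spec <- phantom_spec(grid_shape = config$grid_shape,
                         voxel_size = config$voxel_size,
                         bundles = config$bundles, snr = config$snr,
                         seed = derive_seed(config$seed, paste0("subject", s)))
    truth <- build_phantom(spec)
    if (s == 1L) {
      truth0 <- truth; labels0 <- truth$region_labels; mask0 <- truth$brain_mask
    }
    vol <- simulate_dwi(truth, spec, scheme)
    dwi <- dwi_stack(vol, scheme, config$voxel_size, truth$brain_mask)
    if (config$denoise && is.finite(config$snr))
      dwi <- nlm_denoise(dwi, config$nlm_patch_radius,
                         config$nlm_search_radius)
    dwi <- apply_mask(dwi, truth$brain_mask)
    odf <- fit_aqbi(dwi, config$sh_order, config$sh_lambda)
    gfa <- gfa_map(odf)
    gfa_thr[s] <- percentile_threshold(gfa, truth$brain_mask, 98)
    tp <- config$tracking
    tp$rng_seed <- derive_seed(config$seed, paste0("seeds", s))
    seeds <- seed_voxels(truth$brain_mask, tp, config$voxel_size)
    tracts[[s]] <- track_srd(odf, gfa, truth$brain_mask, seeds, tp,
                             subject = paste0("S", s))
    log <- log_record(log, "track", subject = s,
                      n_seeds = nrow(seeds),
                      n_streamlines = length(tracts[[s]]),
                      n_dropped = attr(tracts[[s]], "n_dropped"))
  }
  window <- population_length_window(tracts, config$window_pcts[1],
                                     config$window_pcts[2])
  log <- log_record(log, "length_window", l_min = window[1], l_max = window[2])

  centroids <- list(); c_subj <- character(0); c_reg <- character(0)
  intra_all <- vector("list", config$n_subjects)
  for (s in seq_len(config$n_subjects)) {
    ip <- config$intra
    ip$seed <- derive_seed(config$seed, paste0("intra", s))
    cl <- cluster_subject(tracts[[s]], labels0, window, ip)
    intra_all[[s]] <- cl
    for (c in cl) {
      centroids[[length(centroids) + 1L]] <- c$centroid
      c_subj <- c(c_subj, paste0("S", s))
      c_reg <- c(c_reg, c$region)
    }
    log <- log_record(log, "cluster_intra", subject = s, n_clusters = length(cl))
  }
  if (length(centroids) == 0) stop("pipeline stage cluster_intra produced no clusters")
  cs <- centroid_set(centroids, c_subj, c_reg)
  inter <- cluster_inter_subject(cs, config$inter, config$n_subjects)
  log <- log_record(log, "cluster_inter", n_clusters = length(inter))

  # ROI label volume from the planted tubes: label 100 + bundle id
  roi_labels <- array(0L, config$grid_shape)
  wm <- truth0$wm_voxels
  for (bi in seq_along(config$bundles)) {
    vox <- wm$voxel[wm$bundle == bi]
    roi_labels[vox[roi_labels[vox] == 0L]] <- 100L + bi
  }
  bundles <- list()
  for (bi in seq_along(config$bundles)) {
    roi <- roi_constraint(config$bundles[[bi]]$name, include = 100L + bi)
    b <- suppressWarnings(
      select_bundle(inter, cs, roi, roi_labels, config$voxel_size))
    if (length(b$clusters) > 0) bundles[[length(bundles) + 1L]] <- b
  }
  atlas <- assemble_atlas(bundles)
  log <- log_record(log, "atlas", n_bundles = nrow(atlas$manifest))

  out <- list(atlas = atlas, inter_clusters = inter,
              intra_clusters = intra_all, window = window,
              gfa_thresholds = gfa_thr,
              n_streamlines = vapply(tracts, length, integer(1)),
              centroids = cs, region_labels = labels0, mask = mask0,
              log = log, config = config)
  if (keep_tractograms) out$tractograms <- tracts
  out
}
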