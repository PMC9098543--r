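# Shared fixtures, built once per test run and cached. All synthetic, all
# seeded: a 75+5 direction shell, straight / crossing / curved tube
# phantoms at 0.2 mm on a 32^3 grid, with their Q-ball fits.

.fx <- new.env(parent = emptyenv())

fx <- function(name, build) {
  if (is.null(.fx[[name]])) .fx[[name]] <- build()
  .fx[[name]]
}

fx_scheme <- function() fx("scheme", function()
  make_gradient_scheme(75, 5, 4500, seed = 0))

# WM tensor eigenvalues used by the phantom defaults
wm_lambdas <- function() {
  adc <- 2.3e-4
  c(3 * adc * 5 / 7, 3 * adc / 7, 3 * adc / 7)
}

# straight tube along x on voxel centers, spanning the whole mask
fx_straight_spec <- function(snr = Inf, seed = 1) {
  b <- bundle_geometry("tube_x",
                       rbind(c(0.2, 3.1, 3.1), c(6.19, 3.1, 3.1)),
                       radius = 0.15, fiber_count = 50, region = "LH")
  phantom_spec(grid_shape = c(32L, 32L, 32L), bundles = list(b), snr = snr,
               seed = seed, csf_fraction = 0, cbl_fraction = 0)
}

# fit the full local-model chain of a phantom spec
fit_phantom <- function(spec, scheme = fx_scheme()) {
  truth <- build_phantom(spec)
  vol <- simulate_dwi(truth, spec, scheme)
  dwi <- apply_mask(dwi_stack(vol, scheme, spec$voxel_size, truth$brain_mask),
                    truth$brain_mask)
  odf <- fit_aqbi(dwi)
  list(truth = truth, dwi = dwi, odf = odf, gfa = gfa_map(odf), spec = spec)
}

fx_straight <- function() fx("straight", function()
  fit_phantom(fx_straight_spec()))

fx_straight_noisy <- function() fx("straight_noisy", function() {
  b <- bundle_geometry("tube_x",
                       rbind(c(0.2, 3.1, 3.1), c(6.19, 3.1, 3.1)),
                       radius = 0.3, fiber_count = 50, region = "LH")
  fit_phantom(phantom_spec(grid_shape = c(32L, 32L, 32L), bundles = list(b),
                           snr = 30, seed = 3, csf_fraction = 0,
                           cbl_fraction = 0))
})

# two orthogonal tubes crossing at the grid center
fx_crossing <- function() fx("crossing", function() {
  b1 <- bundle_geometry("bx", rbind(c(0.2, 3.1, 3.1), c(6.19, 3.1, 3.1)),
                        radius = 0.3, fiber_count = 50, region = "LH")
  b2 <- bundle_geometry("by", rbind(c(3.1, 0.2, 3.1), c(3.1, 6.19, 3.1)),
                        radius = 0.3, fiber_count = 50, region = "LH")
  fit_phantom(phantom_spec(grid_shape = c(32L, 32L, 32L),
                           bundles = list(b1, b2), snr = Inf, seed = 1,
                           csf_fraction = 0, cbl_fraction = 0))
})

# quarter-circle arc from mask boundary to mask boundary
arc_centerline <- function() {
  th <- seq(0, pi / 2, length.out = 60)
  cbind(0.2 + 5.99 * (1 - cos(th)), 0.2 + 5.99 * sin(th), 3.1)
}

fx_curved <- function() fx("curved", function() {
  b <- bundle_geometry("arc", arc_centerline(), radius = 0.4,
                       fiber_count = 50, region = "LH")
  fit_phantom(phantom_spec(grid_shape = c(32L, 32L, 32L), bundles = list(b),
                           snr = Inf, seed = 1, csf_fraction = 0,
                           cbl_fraction = 0))
})

# purely isotropic phantom (no bundles)
fx_isotropic <- function() fx("isotropic", function()
  fit_phantom(phantom_spec(grid_shape = c(24L, 24L, 24L), bundles = list(),
                           snr = Inf, seed = 2, csf_fraction = 0,
                           cbl_fraction = 0)))

# seeds restricted to a set of voxels
seeds_in_voxels <- function(vox, dims, params, voxel_size) {
  m <- array(FALSE, dims)
  m[vox] <- TRUE
  seed_voxels(m, params, voxel_size)
}

# coefficient matrix (voxel-linear x ncoef) of an sh_field
coef_rows <- function(odf) {
  matrix(odf$coef, prod(dim(odf$coef)[1:3]), dim(odf$coef)[4])
}

angle_deg <- function(u, v) aviatract:::axis_angle_deg(u, v)

# planted 3-bundle synthetic tractogram for intra-subject clustering tests
make_planted_tractogram <- function(n_per = 60, seed = 5, jit = 0.1) {
  set.seed(seed)
  mk <- function(p0, p1, n) {
    lapply(seq_len(n), function(i) {
      o <- rnorm(3, 0, jit); o[1] <- 0
      t(vapply(seq(0, 1, length.out = 40),
               function(s) p0 + s * (p1 - p0) + o, numeric(3)))
    })
  }
  f1 <- mk(c(0.4, 1.1, 1.1), c(6.0, 1.1, 1.1), n_per)
  f2 <- mk(c(0.4, 3.1, 3.1), c(6.0, 3.1, 3.1), n_per)
  f3 <- mk(c(0.4, 5.1, 5.1), c(6.0, 5.1, 5.1), n_per)
  list(tractogram = tractogram(c(f1, f2, f3), 0.2, "S1"),
       planted = rep(1:3, each = n_per),
       labels = array(1L, c(32L, 32L, 32L)))
}

# synthetic multi-subject centroid cohort: 4 shared straight bundles with
# per-subject rigid jitter, plus one bundle present in `rare_subjects`
make_centroid_cohort <- function(n_subjects = 6, jit = 0.2, seed = 11,
                                 rare_subjects = 2) {
  set.seed(seed)
  mk <- function(p0, p1) {
    o <- rnorm(3, 0, jit)
    t(vapply(seq(0, 1, length.out = 21),
             function(s) p0 + s * (p1 - p0) + o, numeric(3)))
  }
  shared <- list(list(c(0, 0, 0), c(10, 0, 0)),
                 list(c(0, 5, 0), c(10, 5, 0)),
                 list(c(0, 0, 5), c(0, 10, 5)),
                 list(c(5, 0, 8), c(5, 10, 8)))
  rare <- list(c(10, 10, 0), c(10, 10, 10))
  cent <- list(); subj <- character(0); planted <- integer(0)
  for (s in seq_len(n_subjects)) {
    for (bi in seq_along(shared)) {
      cent[[length(cent) + 1L]] <- mk(shared[[bi]][[1]], shared[[bi]][[2]])
      subj <- c(subj, paste0("S", s)); planted <- c(planted, bi)
    }
    if (s <= rare_subjects) {
      cent[[length(cent) + 1L]] <- mk(rare[[1]], rare[[2]])
      subj <- c(subj, paste0("S", s)); planted <- c(planted, 5L)
    }
  }
  list(cs = centroid_set(cent, subj), planted = planted, subjects = subj)
}
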