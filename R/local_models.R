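#' Scalar map container
#' @param data 3D array
#' @param voxel_size mm
#' @param name map name ("ADC", "FA", "AD", "RD", "GFA")
#' @export
scalar_map <- function(data, voxel_size, name) {
  structure(list(data = data, voxel_size = voxel_size, name = name),
            class = "scalar_map")
}

dti_design_matrix <- function(scheme) {
  n <- length(scheme$bvals)
  G <- matrix(0, n, 3)
  G[scheme$bvals > 0, ] <- scheme$directions
  b <- scheme$bvals
  X <- cbind(1, -b * G[, 1]^2, -b * G[, 2]^2, -b * G[, 3]^2,
             -2 * b * G[, 1] * G[, 2], -2 * b * G[, 1] * G[, 3],
             -2 * b * G[, 2] * G[, 3])
  if (qr(X)$rank < 7)
    stop("rank-deficient DTI design matrix: need >= 6 distinct directions and a b=0 volume")
  X
}

#' Fit the diffusion tensor per voxel
#'
#' Log-linear least squares of `ln S = ln S0 - b g' D g` inside the mask;
#' non-positive signals are clamped at `1e-6 * max(S)` before the log.
#'
#' @param dwi a [dwi_stack()]
#' @return a `tensor_field`: `tensors` (n_mask x 6 matrix, columns Dxx, Dyy,
#'   Dzz, Dxy, Dxz, Dyz in mm^2/s), `ln_s0`, `mask`, `dims`, `voxel_size`
#' @export
fit_dti <- function(dwi) {
  stopifnot(inherits(dwi, "dwi_stack"))
  X <- dti_design_matrix(dwi$scheme)
  dims <- dim(dwi$data)
  vox <- which(dwi$mask)
  S <- matrix(dwi$data, prod(dims[1:3]), dims[4])[vox, , drop = FALSE]
  eps <- 1e-6 * max(S)
  lnS <- log(pmax(S, eps))
  beta <- solve(crossprod(X), crossprod(X, t(lnS)))   # 7 x n_mask
  structure(list(tensors = t(beta[2:7, , drop = FALSE]),
                 ln_s0 = beta[1, ], mask = dwi$mask, dims = dims[1:3],
                 voxel_size = dwi$voxel_size),
            class = "tensor_field")
}

tensor_eigvals <- function(tf) {
  n <- nrow(tf$tensors)
  ev <- matrix(0, n, 3)
  for (i in seq_len(n)) {
    d <- tf$tensors[i, ]
    D <- matrix(c(d[1], d[4], d[5], d[4], d[2], d[6], d[5], d[6], d[3]), 3, 3)
    # eigen() returns values in decreasing order: l1 >= l2 >= l3
    ev[i, ] <- eigen(D, symmetric = TRUE, only.values = TRUE)$values
  }
  ev
}

#' Rotationally invariant tensor maps
#'
#' From the sorted eigenvalues `l1 >= l2 >= l3`: ADC is their mean, AD = l1,
#' RD = (l2+l3)/2, and FA = sqrt(3/2) ||lambda - mean|| / ||lambda||.
#' Negative eigenvalues are clamped to zero (count recorded in the
#' `n_clamped` attribute of the result).
#'
#' @param tf a `tensor_field` from [fit_dti()]
#' @return named list of [scalar_map()]s ADC, FA, AD, RD
#' @export
tensor_maps <- function(tf) {
  ev <- tensor_eigvals(tf)
  n_clamped <- sum(ev < 0)
  ev[ev < 0] <- 0
  adc <- rowMeans(ev)
  ad <- ev[, 1]
  rd <- (ev[, 2] + ev[, 3]) / 2
  dev <- ev - adc
  nrm <- sqrt(rowSums(ev^2))
  fa <- ifelse(nrm > 0, sqrt(1.5 * rowSums(dev^2)) / nrm, 0)
  mk <- function(vals, name) {
    a <- array(0, tf$dims)
    a[tf$mask] <- vals
    scalar_map(a, tf$voxel_size, name)
  }
  out <- list(ADC = mk(adc, "ADC"), FA = mk(fa, "FA"),
              AD = mk(ad, "AD"), RD = mk(rd, "RD"))
  attr(out, "n_clamped") <- n_clamped
  out
}

#' Analytical Q-ball ODF reconstruction
#'
#' Per voxel: the diffusion signal normalized by the mean b = 0 volume is
#' fit onto the real symmetric spherical harmonic basis with
#' Laplace-Beltrami regularization,
#' `c = (B'B + lam L^2)^-1 B' s` with `L = diag(l(l+1))`, and the
#' Funk-Radon transform is applied analytically by scaling each degree-l
#' coefficient by `2 pi P_l(0)` to yield the ODF coefficients.
#'
#' @param dwi single-shell [dwi_stack()]
#' @param order even SH order (default 8, 45 coefficients)
#' @param lam Laplace-Beltrami regularization factor (L-curve optimum 0.006)
#' @return an `sh_field`: `coef` (4D array x,y,z,coef of ODF SH
#'   coefficients), `order`, `basis` tag, `mask`, `voxel_size`
#' @export
fit_aqbi <- function(dwi, order = 8L, lam = 0.006) {
  stopifnot(inherits(dwi, "dwi_stack"), order %% 2 == 0, lam >= 0)
  bnz <- unique(dwi$scheme$bvals[dwi$scheme$bvals > 0])
  if (length(bnz) != 1) stop("analytical Q-ball requires a single shell")
  nc <- n_sh_coef(order)
  ndir <- nrow(dwi$scheme$directions)
  if (ndir < nc)
    stop(sprintf("need >= %d directions for order %d (got %d)", nc, order, ndir))

  dims <- dim(dwi$data)
  vox <- which(dwi$mask)
  Smat <- matrix(dwi$data, prod(dims[1:3]), dims[4])[vox, , drop = FALSE]
  b0 <- rowMeans(Smat[, which(dwi$scheme$bvals == 0), drop = FALSE])
  b0[b0 <= 0] <- 1
  s <- Smat[, which(dwi$scheme$bvals > 0), drop = FALSE] / b0

  B <- sh_basis(dwi$scheme$directions, order)
  degs <- sh_degrees(order)
  L2 <- diag((degs * (degs + 1))^2)
  M <- solve(crossprod(B) + lam * L2, t(B))          # ncoef x ndir
  coef_sig <- s %*% t(M)                             # n_mask x ncoef
  frt <- 2 * pi * vapply(degs, legendre_p0, numeric(1))
  coef_odf <- sweep(coef_sig, 2, frt, "*")

  coef4 <- array(0, c(dims[1:3], nc))
  flat <- matrix(coef4, prod(dims[1:3]), nc)
  flat[vox, ] <- coef_odf
  structure(list(coef = array(flat, c(dims[1:3], nc)), order = order,
                 lam = lam, basis = "real_symmetric_lm", mask = dwi$mask,
                 voxel_size = dwi$voxel_size),
            class = "sh_field")
}

# GFA statistic of ODF samples (rows = voxels): std/rms with the sample
# (n-1) standard deviation; zero for an all-zero ODF
gfa_of_samples <- function(V) {
  if (is.null(dim(V))) V <- matrix(V, 1)
  n <- ncol(V)
  ss <- rowSums(V^2)
  varr <- (ss - n * rowMeans(V)^2) / (n - 1)
  ifelse(ss > 0, sqrt(pmax(n * varr, 0) / ss), 0)
}

# ODF samples on a tessellation for all masked voxels, chunked; values are
# min-shifted to be non-negative per voxel
odf_samples <- function(odf, geo, chunk = 2048L) {
  vox <- which(odf$mask)
  nc <- dim(odf$coef)[4]
  Cm <- matrix(odf$coef, prod(dim(odf$coef)[1:3]), nc)[vox, , drop = FALSE]
  out <- matrix(0, length(vox), geo$n)
  for (i0 in seq(1, length(vox), by = chunk)) {
    i1 <- min(i0 + chunk - 1L, length(vox))
    V <- Cm[i0:i1, , drop = FALSE] %*% t(geo$B)
    shift <- pmin(apply(V, 1, min), 0)
    out[i0:i1, ] <- V - shift
  }
  out
}

#' Generalized fractional anisotropy map
#'
#' GFA = std(ODF) / rms(ODF) over a dense tessellation (Tuch definition,
#' sample standard deviation); zero where the ODF vanishes.
#'
#' @param odf an `sh_field` from [fit_aqbi()]
#' @param geo tessellation geometry (>= 100 quasi-uniform points)
#' @return a [scalar_map()] named "GFA"
#' @export
gfa_map <- function(odf, geo = tess_geometry(order = odf$order)) {
  stopifnot(inherits(odf, "sh_field"), geo$n >= 100)
  V <- odf_samples(odf, geo)
  gfa <- gfa_of_samples(V)
  a <- array(0, dim(odf$coef)[1:3])
  a[odf$mask] <- clamp(gfa, 0, 1)
  scalar_map(a, odf$voxel_size, "GFA")
}

#' Color-encoded direction map
#'
#' RGB = |principal ODF direction| scaled by GFA per voxel.
#'
#' @param odf an `sh_field`
#' @param gfa the matching GFA [scalar_map()]
#' @param geo tessellation geometry
#' @return 4D array (x, y, z, 3) in [0, 1]
#' @export
ced_map <- function(odf, gfa, geo = tess_geometry(order = odf$order)) {
  V <- odf_samples(odf, geo)
  pk <- geo$points[max.col(V, ties.method = "first"), , drop = FALSE]
  vox <- which(odf$mask)
  rgb <- abs(pk) * gfa$data[vox]
  out <- array(0, c(dim(odf$coef)[1:3], 3))
  flat <- matrix(out, length(odf$mask), 3)
  flat[vox, ] <- rgb
  array(flat, dim(out))
}

#' Percentile threshold of a scalar map over a mask
#'
#' Value `v` such that `pct` percent of in-mask voxels fall at or below `v`,
#' by linear interpolation of the empirical CDF. Used for the 98% cumulative
#' GFA histogram threshold that sets the tracking regularization factor.
#'
#' @param map a [scalar_map()] (or plain array)
#' @param mask logical array
#' @param pct percentile in (0, 100)
#' @export
percentile_threshold <- function(map, mask, pct = 98) {
  vals <- if (inherits(map, "scalar_map")) map$data[mask] else map[mask]
  if (length(vals) == 0) stop("empty mask")
  interp_percentile(vals, pct)
}
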