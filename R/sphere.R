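#' Antipodally symmetric sphere tessellation
#'
#' Quasi-uniform unit vectors built from a golden-angle spiral on the upper
#' hemisphere plus the antipode of every point, so the set is exactly
#' symmetric under inversion (as required for sampling antipodally symmetric
#' ODFs). The default 724 points correspond to 362 axes.
#'
#' @param n even number of points (>= 100 for quadrature-grade uniformity)
#' @return matrix `n x 3` of unit row vectors
#' @export
sphere_tessellation <- function(n = 724L) {
  stopifnot(n %% 2 == 0, n >= 12)
  m <- n %/% 2
  i <- seq_len(m) - 0.5
  z <- i / m                       # (0, 1): open at pole and equator
  phi <- pi * (1 + sqrt(5)) * i
  r <- sqrt(pmax(1 - z^2, 0))
  up <- cbind(r * cos(phi), r * sin(phi), z)
  rbind(up, -up)
}

# number of even-degree real SH coefficients up to order L
n_sh_coef <- function(order) (order + 1L) * (order + 2L) / 2L

#' Real symmetric spherical harmonic basis
#'
#' Modified real SH basis restricted to even degrees (antipodal symmetry),
#' orthonormal on the sphere. Coefficients are ordered by degree `l`
#' (0, 2, ..., order) and within a degree by `m` ascending from `-l` to `l`;
#' negative orders carry the cosine azimuthal term, positive the sine.
#'
#' @param dirs matrix `n x 3` of unit vectors
#' @param order maximum (even) SH degree
#' @return matrix `n x (order+1)(order+2)/2`
#' @export
sh_basis <- function(dirs, order = 8L) {
  stopifnot(order %% 2 == 0, order >= 0)
  dirs <- as.matrix(dirs)
  z <- clamp(dirs[, 3], -1, 1)
  phi <- atan2(dirs[, 2], dirs[, 1])
  n <- nrow(dirs)
  B <- matrix(0, n, n_sh_coef(order))
  j <- 0L
  for (l in seq(0L, order, by = 2L)) {
    # pracma::legendre returns rows m = 0..l (Condon-Shortley included)
    P <- pracma::legendre(l, z)
    if (is.null(dim(P))) P <- matrix(P, nrow = l + 1L)
    for (m in seq(-l, l)) {
      j <- j + 1L
      am <- abs(m)
      nlm <- sqrt((2 * l + 1) / (4 * pi) *
                    exp(lgamma(l - am + 1) - lgamma(l + am + 1)))
      plm <- P[am + 1L, ]
      B[, j] <-
        if (m < 0) sqrt(2) * nlm * plm * cos(am * phi)
        else if (m == 0) nlm * plm
        else sqrt(2) * nlm * plm * sin(am * phi)
    }
  }
  B
}

# degree of each coefficient index, in basis ordering
sh_degrees <- function(order) {
  unlist(lapply(seq(0L, order, by = 2L), function(l) rep(l, 2L * l + 1L)))
}

# Legendre polynomial P_l(0), the Funk-Radon transform eigenvalue factor
legendre_p0 <- function(l) {
  if (l %% 2 == 1) return(0)
  k <- l / 2
  (-1)^k * exp(lgamma(l + 1) - 2 * lgamma(k + 1)) / 4^k
}

# cached tessellation geometry: points, SH sampling matrix per order,
# and the neighbor lists used for peak non-maximum suppression
.tess_cache <- new.env(parent = emptyenv())

tess_geometry <- function(n = 724L, order = 8L, nms_angle_deg = 25) {
  key <- paste(n, order, nms_angle_deg, sep = "_")
  if (!is.null(.tess_cache[[key]])) return(.tess_cache[[key]])
  pts <- sphere_tessellation(n)
  B <- sh_basis(pts, order)
  cth <- cos(nms_angle_deg * pi / 180)
  G <- tcrossprod(pts)
  nb <- lapply(seq_len(n), function(i) {
    which(G[i, ] >= cth & seq_len(n) != i)
  })
  geo <- list(points = pts, B = B, neighbors = nb, n = n, order = order,
              nms_angle_deg = nms_angle_deg)
  .tess_cache[[key]] <- geo
  geo
}

#' Extract ODF peaks on a dense tessellation
#'
#' The ODF is sampled on the tessellation, min-shifted to be non-negative,
#' and local maxima are extracted by non-maximum suppression within a fixed
#' angular neighborhood; peaks below `rel_threshold` of the global maximum
#' are dropped. Antipodal duplicates are collapsed to one axis each.
#'
#' @param coef SH coefficient vector (ODF, even-degree basis)
#' @param geo tessellation geometry from `tess_geometry()` (default 724
#'   points, 25 degree suppression radius)
#' @param rel_threshold relative peak threshold (fraction of global max)
#' @param refine refine each peak beyond the tessellation resolution by
#'   shrinking local ascent on the continuous SH expansion
#' @return list with `directions` (rows, strongest first) and `values`
#' @export
sh_peaks <- function(coef, geo = tess_geometry(order = sh_order_of(coef)),
                     rel_threshold = 0.25, refine = TRUE) {
  odf <- as.vector(geo$B %*% coef)
  odf <- odf - min(odf, 0)
  gmax <- max(odf)
  if (gmax <= 0) return(list(directions = matrix(0, 0, 3), values = numeric(0)))
  is_peak <- vapply(seq_len(geo$n), function(i) {
    odf[i] >= rel_threshold * gmax &&
      all(odf[i] >= odf[geo$neighbors[[i]]])
  }, logical(1))
  idx <- which(is_peak)
  idx <- idx[order(-odf[idx])]
  # collapse antipodal twins and near-duplicates within the NMS radius
  kept <- integer(0)
  cth <- cos(geo$nms_angle_deg * pi / 180)
  for (i in idx) {
    if (length(kept) == 0 ||
        all(abs(geo$points[kept, , drop = FALSE] %*% geo$points[i, ]) < cth))
      kept <- c(kept, i)
  }
  dirs <- geo$points[kept, , drop = FALSE]
  vals <- odf[kept]
  if (refine && length(kept)) {
    for (r in seq_len(nrow(dirs))) {
      ref <- refine_sh_max(coef, dirs[r, ], geo$order)
      dirs[r, ] <- ref$direction
      vals[r] <- ref$value - min(as.vector(geo$B %*% coef), 0)
    }
  }
  list(directions = dirs, values = vals)
}

# shrinking tangent-plane ascent of the SH expansion around a start axis
refine_sh_max <- function(coef, d0, order, start_deg = 4, n_iter = 6L) {
  d <- unit(d0)
  rad <- start_deg * pi / 180
  ring <- cbind(cos(seq(0, 2 * pi, length.out = 9)[-9]),
                sin(seq(0, 2 * pi, length.out = 9)[-9]))
  for (it in seq_len(n_iter)) {
    ref <- if (abs(d[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    e1 <- unit(ref - sum(ref * d) * d)
    e2 <- pracma::cross(d, e1)
    cand <- rbind(d, t(apply(ring, 1, function(ab)
      unit(d + rad * (ab[1] * e1 + ab[2] * e2)))))
    v <- as.vector(sh_basis(cand, order) %*% coef)
    best <- which.max(v)
    if (best == 1L) rad <- rad / 2 else d <- cand[best, ]
  }
  v <- as.vector(sh_basis(matrix(d, 1), order) %*% coef)
  list(direction = d, value = v)
}

# infer SH order from a coefficient count
sh_order_of <- function(coef) {
  nc <- if (is.matrix(coef)) ncol(coef) else length(coef)
  L <- (-3 + sqrt(1 + 8 * nc)) / 2
  if (abs(L - round(L)) > 1e-9) stop("invalid SH coefficient count")
  as.integer(round(L))
}
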