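#' @useDynLib aviatract, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats rnorm runif kmeans hclust cutree as.dist t.test sd mad quantile approx
NULL

# Run code with a temporary RNG state; restores the caller's stream.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  force(code)
}

# Derive a per-stage 31-bit seed from a root seed and a stage name, so each
# pipeline stage owns an independent reproducible stream.
derive_seed <- function(root_seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(root_seed) * 2654435761 + h) %% 2147483647)
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

vnorm <- function(v) sqrt(sum(v^2))

unit <- function(v) {
  n <- vnorm(v)
  if (n == 0) stop("cannot normalize zero vector")
  v / n
}

#' Linear-interpolation percentile of a sample
#'
#' Empirical quantile with linear interpolation between order statistics
#' (rank `1 + (n-1) p`), the convention used for both the cumulative GFA
#' histogram threshold and the population fiber-length window.
#'
#' @param x numeric vector (NA removed)
#' @param pct percentile in (0, 100)
#' @return the interpolated value
#' @export
interp_percentile <- function(x, pct) {
  stopifnot(pct > 0, pct < 100)
  x <- sort(x[!is.na(x)])
  n <- length(x)
  if (n == 0L) stop("empty sample")
  if (n == 1L) return(x[1L])
  r <- 1 + (n - 1) * pct / 100
  lo <- floor(r)
  frac <- r - lo
  if (lo >= n) return(x[n])
  x[lo] * (1 - frac) + x[lo + 1L] * frac
}

# mm point -> 1-based voxel index under half-open ownership [edge, edge+size)
mm_to_voxel <- function(p, voxel_size) {
  floor(p / voxel_size) + 1L
}

# 1-based voxel index -> center in mm
voxel_center <- function(ijk, voxel_size) {
  (ijk - 0.5) * voxel_size
}

# Angle in degrees between two axes (antipodally symmetric directions).
axis_angle_deg <- function(u, v) {
  d <- abs(sum(u * v)) / (vnorm(u) * vnorm(v))
  acos(clamp(d, -1, 1)) * 180 / pi
}
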