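#' Gradient scheme for a single-shell HARDI acquisition
#'
#' A gradient scheme holds the diffusion-encoding directions and b-values of
#' a single-shell acquisition: `n_b0` unweighted (b = 0) volumes followed by
#' `n_dirs` diffusion-weighted volumes on one shell.
#'
#' @param directions matrix `n_dirs x 3` of unit vectors
#' @param b shell b-value in s/mm^2
#' @param n_b0 number of b = 0 volumes (>= 1)
#' @return an object of class `gradient_scheme` with fields `directions`
#'   (unit rows), `bvals` (length `n_b0 + n_dirs`, b = 0 entries first) and
#'   `n_b0`
#' @export
gradient_scheme <- function(directions, b, n_b0 = 1L) {
  directions <- as.matrix(directions)
  stopifnot(ncol(directions) == 3, n_b0 >= 1, b > 0)
  nrm <- sqrt(rowSums(directions^2))
  if (any(abs(nrm - 1) > 1e-9))
    directions <- directions / nrm
  obj <- list(
    directions = directions,
    bvals = c(rep(0, n_b0), rep(b, nrow(directions))),
    b = b,
    n_b0 = as.integer(n_b0)
  )
  class(obj) <- "gradient_scheme"
  obj
}

#' @export
length.gradient_scheme <- function(x) length(x$bvals)

#' @export
print.gradient_scheme <- function(x, ...) {
  cat(sprintf("gradient_scheme: %d volumes (%d b=0, %d at b=%g s/mm^2)\n",
              length(x$bvals), x$n_b0, nrow(x$directions), x$b))
  invisible(x)
}

# Electrostatic energy of a direction set treating antipodal pairs as one
# axis: sum over pairs of 1/|xi-xj| + 1/|xi+xj|.
electrostatic_energy <- function(dirs) {
  n <- nrow(dirs)
  e <- 0
  for (i in seq_len(n - 1)) {
    di <- dirs[(i + 1):n, , drop = FALSE]
    dm <- sweep(di, 2, dirs[i, ])
    dp <- sweep(di, 2, -dirs[i, ])
    e <- e + sum(1 / sqrt(rowSums(dm^2))) + sum(1 / sqrt(rowSums(dp^2)))
  }
  e
}

# Quasi-uniform points on the sphere by the golden-angle (Fibonacci) spiral.
fibonacci_sphere <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- pi * (1 + sqrt(5)) * i
  z <- 1 - 2 * i / n
  r <- sqrt(pmax(1 - z^2, 0))
  cbind(r * cos(phi), r * sin(phi), z)
}

#' Build a quasi-uniform single-shell gradient scheme
#'
#' Directions are optimized by electrostatic-repulsion descent on the sphere,
#' treating antipodal directions as identical (charges interact with both the
#' point and its antipode), starting from a seeded jittered Fibonacci spiral.
#'
#' @param n_dirs number of diffusion-weighted directions (>= 6, the DTI
#'   minimum)
#' @param n_b0 number of b = 0 volumes
#' @param b shell b-value in s/mm^2
#' @param seed integer seed; the result is deterministic given the seed
#' @param n_iter descent iterations
#' @return a [gradient_scheme()]
#' @export
make_gradient_scheme <- function(n_dirs, n_b0 = 5L, b = 4500, seed = 0L,
                                 n_iter = 200L) {
  if (n_dirs < 6) stop("n_dirs must be >= 6 (diffusion tensor unfittable)")
  stopifnot(b > 0, n_b0 >= 1)
  dirs <- with_seed(seed, {
    # hemisphere start: no two initial points share an axis
    i <- seq_len(n_dirs) - 0.5
    z <- i / n_dirs
    phi <- pi * (1 + sqrt(5)) * i
    r <- sqrt(pmax(1 - z^2, 0))
    d0 <- cbind(r * cos(phi), r * sin(phi), z) +
      matrix(rnorm(3 * n_dirs, sd = 0.02), n_dirs, 3)
    d0 / sqrt(rowSums(d0^2))
  })
  # minimize the antipodal electrostatic energy over unconstrained 3n
  # coordinates (normalized inside the objective) with BFGS
  en <- function(y) {
    x <- matrix(y, n_dirs, 3)
    x <- x / sqrt(rowSums(x^2))
    electrostatic_energy(x)
  }
  gr <- function(y) {
    Y <- matrix(y, n_dirs, 3)
    ny <- sqrt(rowSums(Y^2))
    X <- Y / ny
    G <- matrix(0, n_dirs, 3)
    for (i in seq_len(n_dirs)) {
      dm <- sweep(X[-i, , drop = FALSE], 2, X[i, ], function(a, b) b - a)
      dp <- sweep(X[-i, , drop = FALSE], 2, X[i, ], "+")
      rm3 <- pmax(rowSums(dm^2), 1e-12)^1.5
      rp3 <- pmax(rowSums(dp^2), 1e-12)^1.5
      G[i, ] <- -colSums(dm / rm3) - colSums(dp / rp3)  # dE/dx_i
    }
    # chain rule through the normalization: (I - x x') / |y|
    (G - X * rowSums(G * X)) / ny
  }
  opt <- stats::optim(as.vector(dirs), en, function(y) as.vector(gr(y)),
                      method = "BFGS",
                      control = list(maxit = as.integer(n_iter), reltol = 1e-12))
  dirs <- matrix(opt$par, n_dirs, 3)
  dirs <- dirs / sqrt(rowSums(dirs^2))
  gradient_scheme(dirs, b = b, n_b0 = n_b0)
}

#' Minimum pairwise axis angle of a direction set
#'
#' Brute-force evaluation over all pairs, treating each direction and its
#' antipode as one axis.
#'
#' @param dirs matrix of unit row vectors
#' @return smallest pairwise angle in degrees
#' @export
min_pairwise_angle <- function(dirs) {
  g <- abs(tcrossprod(dirs))
  diag(g) <- 0
  acos(clamp(max(g[upper.tri(g)]), -1, 1)) * 180 / pi
}
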