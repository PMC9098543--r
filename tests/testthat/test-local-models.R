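# single-voxel DWI stack from a signal vector
one_voxel_stack <- function(S, scheme) {
  vol <- array(rep(S, each = 8), c(2, 2, 2, length(S)))
  dwi_stack(vol, scheme, 0.2)
}

wm_signal <- function(u, scheme, s0 = 1000) {
  lam <- wm_lambdas()
  gu2 <- (scheme$directions %*% unit(u))^2
  att <- exp(-scheme$b * (lam[2] + (lam[1] - lam[2]) * gu2))
  c(rep(s0, scheme$n_b0), s0 * att)
}

unit <- function(v) v / sqrt(sum(v^2))

test_that("DTI fit recovers planted tensors exactly on noiseless data", {
  sch <- fx_scheme()
  # isotropic voxel with D = d I
  d <- 3e-4
  S <- c(rep(1000, 5), rep(1000 * exp(-4500 * d), 75))
  tf <- fit_dti(one_voxel_stack(S, sch))
  expect_equal(unname(tf$tensors[1, 1:3]), rep(d, 3), tolerance = 1e-10 * d)
  expect_equal(unname(tf$tensors[1, 4:6]), rep(0, 3), tolerance = 1e-10 * d)
  # anisotropic voxel: eigenvector within 0.1 degree of the planted axis
  u <- unit(c(1, 2, 0.5))
  tfa <- fit_dti(one_voxel_stack(wm_signal(u, sch), sch))
  dm <- tfa$tensors[1, ]
  D <- matrix(c(dm[1], dm[4], dm[5], dm[4], dm[2], dm[6],
                dm[5], dm[6], dm[3]), 3, 3)
  v1 <- eigen(D, symmetric = TRUE)$vectors[, 1]
  expect_lt(angle_deg(v1, u), 0.1)
})

# Moore-Penrose pseudoinverse via SVD (independent of the fit path)
MASS_free_pinv <- function(X) {
  s <- svd(X)
  s$v %*% diag(1 / s$d) %*% t(s$u)
}

test_that("noisy DTI fit equals the brute-force pseudoinverse oracle", {
  sch <- fx_scheme()
  set.seed(30)
  S <- wm_signal(c(0, 1, 1), sch)
  S <- abs(S + rnorm(80, sd = 1000 / 30))
  dwi <- one_voxel_stack(S, sch)
  tf <- fit_dti(dwi)
  X <- aviatract:::dti_design_matrix(sch)
  beta <- MASS_free_pinv(X) %*% log(pmax(S, 1e-6 * max(S)))
  expect_equal(unname(tf$tensors[1, ]), unname(beta[2:7]), tolerance = 1e-10)
})

test_that("tensor maps match their closed forms", {
  mk_tf <- function(lam) {
    structure(list(tensors = matrix(c(lam, 0, 0, 0), 1),
                   ln_s0 = log(1000), mask = array(TRUE, c(1, 1, 1)),
                   dims = c(1L, 1L, 1L), voxel_size = 0.2),
              class = "tensor_field")
  }
  iso <- tensor_maps(mk_tf(c(2e-4, 2e-4, 2e-4)))
  expect_equal(iso$FA$data[1, 1, 1], 0)
  expect_equal(iso$ADC$data[1, 1, 1], 2e-4)
  expect_equal(iso$AD$data[1, 1, 1], 2e-4)
  expect_equal(iso$RD$data[1, 1, 1], 2e-4)
  stick <- tensor_maps(mk_tf(c(1, 0, 0)))
  expect_equal(stick$FA$data[1, 1, 1], 1)
  # formula vs independent numeric evaluation
  lam <- c(1.7, 0.3, 0.3) * 1e-4
  m <- tensor_maps(mk_tf(lam))
  fa_oracle <- sqrt(3 / 2) * sqrt(sum((lam - mean(lam))^2)) /
    sqrt(sum(lam^2))
  expect_equal(m$FA$data[1, 1, 1], fa_oracle, tolerance = 1e-12)
  expect_equal(m$AD$data[1, 1, 1], lam[1])
  expect_equal(m$RD$data[1, 1, 1], mean(lam[2:3]))
})

test_that("Q-ball fit matches brute-force regularized normal equations", {
  sch <- fx_scheme()
  set.seed(7)
  n <- 25
  S <- matrix(abs(1000 * exp(-runif(n * 75)) + rnorm(n * 75, 0, 20)), n, 75)
  vol <- array(0, c(n, 1, 1, 80))
  vol[, 1, 1, 1:5] <- 1000
  vol[, 1, 1, 6:80] <- S
  odf <- fit_aqbi(dwi_stack(vol, sch, 0.2), order = 8, lam = 0.006)
  # independent oracle: explicit solve of (B'B + lam L^2) c = B's, then FRT
  B <- sh_basis(sch$directions, 8)
  l <- aviatract:::sh_degrees(8)
  reg <- diag((l * (l + 1))^2)
  p0 <- vapply(l, aviatract:::legendre_p0, numeric(1))
  for (i in seq_len(n)) {
    cfit <- solve(crossprod(B) + 0.006 * reg) %*% crossprod(B, S[i, ] / 1000)
    oracle <- 2 * pi * p0 * as.vector(cfit)
    expect_equal(unname(odf$coef[i, 1, 1, ]), oracle, tolerance = 1e-10)
  }
})

test_that("Q-ball input contracts are enforced", {
  sch <- fx_scheme()
  multi <- sch; multi$bvals[6:10] <- 2000
  vol <- array(1000, c(2, 2, 2, 80))
  expect_error(fit_aqbi(dwi_stack(vol, multi, 0.2)), "single shell")
  few <- make_gradient_scheme(10, 1, 4500, seed = 0, n_iter = 20)
  expect_error(fit_aqbi(dwi_stack(array(1000, c(2, 2, 2, 11)), few, 0.2),
                        order = 8), "directions")
})

test_that("isotropic voxels yield a pure l=0 ODF; symmetry is exact", {
  sch <- fx_scheme()
  S <- c(rep(1000, 5), rep(1000 * exp(-1.0), 75))
  odf <- fit_aqbi(one_voxel_stack(S, sch))
  co <- odf$coef[1, 1, 1, ]
  expect_gt(abs(co[1]), 0)
  expect_lt(max(abs(co[-1])), 1e-8 * abs(co[1]))
  # antipodal symmetry of the even basis
  set.seed(8)
  d <- matrix(rnorm(30), 10); d <- d / sqrt(rowSums(d^2))
  expect_equal(sh_basis(d, 8), sh_basis(-d, 8), tolerance = 1e-12)
})

test_that("SH fit residual decreases monotonically as lambda decreases", {
  sch <- fx_scheme()
  set.seed(9)
  s <- exp(-runif(75))
  B <- sh_basis(sch$directions, 8)
  l <- aviatract:::sh_degrees(8)
  reg <- diag((l * (l + 1))^2)
  resid <- vapply(c(0.1, 0.01, 0.006, 0.001, 0), function(lam) {
    cf <- solve(crossprod(B) + lam * reg, crossprod(B, s))
    sum((s - B %*% cf)^2)
  }, numeric(1))
  expect_true(all(diff(resid) <= 1e-12))
})

test_that("GFA follows its definition on constructed samples", {
  # constant ODF -> zero variance -> GFA 0
  expect_equal(aviatract:::gfa_of_samples(matrix(3, 1, 100))[1], 0)
  # single nonzero sample of n: direct formula sqrt(n/(n-1)) sqrt(1-1/n)
  n <- 724
  v <- c(5, rep(0, n - 1))
  expect_equal(aviatract:::gfa_of_samples(matrix(v, 1)),
               sqrt(n / (n - 1)) * sqrt(1 - 1 / n), tolerance = 1e-12)
  # all-zero ODF -> 0
  expect_equal(aviatract:::gfa_of_samples(matrix(0, 1, 50))[1], 0)
})

test_that("planted WM voxels carry higher GFA than GM on the phantom", {
  fixt <- fx_straight()
  wmv <- intersect(fixt$truth$wm_voxels$voxel, which(fixt$truth$brain_mask))
  gm <- setdiff(which(fixt$truth$brain_mask), fixt$truth$wm_voxels$voxel)
  expect_gt(min(fixt$gfa$data[wmv]), max(fixt$gfa$data[gm]))
  expect_true(all(fixt$gfa$data >= 0 & fixt$gfa$data <= 1))
})

test_that("CED map encodes direction in the dominant channel, GFA in value", {
  fixt <- fx_straight()
  ced <- ced_map(fixt$odf, fixt$gfa)
  wmv <- intersect(fixt$truth$wm_voxels$voxel, which(fixt$truth$brain_mask))
  flat <- matrix(ced, prod(dim(ced)[1:3]), 3)
  # x-aligned fiber: red dominant
  expect_true(all(flat[wmv, 1] > flat[wmv, 2]))
  expect_true(all(flat[wmv, 1] > flat[wmv, 3]))
  # isotropic voxels: near-black
  gm <- setdiff(which(fixt$truth$brain_mask), fixt$truth$wm_voxels$voxel)
  expect_lt(max(flat[gm, ]), 0.05)
})

test_that("percentile threshold interpolates the empirical CDF", {
  set.seed(10)
  u <- array(runif(8000), c(20, 20, 20))
  m <- array(TRUE, c(20, 20, 20))
  expect_equal(percentile_threshold(u, m, 98), 0.98, tolerance = 0.02)
  expect_equal(percentile_threshold(array(0.4, dim(m)), m, 98), 0.4)
  # sort-and-index oracle on an arbitrary map
  x <- array(rnorm(1000), c(10, 10, 10))
  v <- percentile_threshold(x, array(TRUE, c(10, 10, 10)), 73)
  xs <- sort(as.vector(x))
  r <- 1 + (1000 - 1) * 0.73
  oracle <- xs[floor(r)] * (1 - (r - floor(r))) + xs[ceiling(r)] * (r - floor(r))
  expect_equal(v, oracle, tolerance = 1e-12)
  expect_error(percentile_threshold(x, array(FALSE, c(10, 10, 10)), 98),
               "empty")
})
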