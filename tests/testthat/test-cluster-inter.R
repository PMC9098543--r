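straight21 <- function(p0, p1, n = 21) {
  t(vapply(seq(0, 1, length.out = n), function(s) p0 + s * (p1 - p0),
           numeric(3)))
}

test_that("centroid resampling is arc-length uniform", {
  # straight 2-point segment -> 21 collinear equally spaced points
  r <- resample_centroid(rbind(c(0, 0, 0), c(10, 0, 0)), 21)
  expect_equal(r, straight21(c(0, 0, 0), c(10, 0, 0)), tolerance = 1e-12)
  # idempotence on an already equispaced polyline
  p <- straight21(c(1, 2, 3), c(4, 8, 3))
  expect_equal(resample_centroid(p, 21), p, tolerance = 1e-9)
  # quarter circle radius 10: spacing matches the analytic parametrization
  th <- seq(0, pi / 2, length.out = 400)
  arc <- cbind(10 * cos(th), 10 * sin(th), 0)
  r2 <- resample_centroid(arc, 21)
  seg <- sqrt(rowSums(diff(r2)^2))
  # analytic chord length for equal arc increments of (pi/2)/20
  chord <- 2 * 10 * sin((pi / 2) / 20 / 2)
  expect_equal(seg, rep(chord, 20), tolerance = 1e-4)
  expect_equal(sum(seg), pi / 2 * 10, tolerance = 0.01 * pi / 2 * 10)
  expect_error(resample_centroid(rbind(c(1, 1, 1), c(1, 1, 1))),
               "zero-length")
})

test_that("corrected distance: floor, monotone correction, flip handling", {
  p <- inter_params()
  a <- straight21(c(0, 0, 0), c(10, 0, 0))
  expect_equal(normalized_pairwise_distance(a, a, p), 0.01)
  # parallel centroids offset by delta: raw distance = delta, corrected
  # decreasing in length at fixed offset
  d_at_len <- vapply(c(2, 5, 10, 20, 40), function(L) {
    u <- straight21(c(0, 0, 0), c(L, 0, 0))
    v <- straight21(c(0, 1, 0), c(L, 1, 0))
    normalized_pairwise_distance(u, v, p)
  }, numeric(1))
  expect_true(all(diff(d_at_len) < 0))
  # flipped ordering gives the same distance
  b <- straight21(c(0, 1, 0), c(10, 1, 0))
  expect_equal(normalized_pairwise_distance(a, b[21:1, ], p),
               normalized_pairwise_distance(a, b, p))
  expect_error(normalized_pairwise_distance(a, straight21(c(0, 0, 0), c(1, 0, 0), 15), p),
               "point counts")
  # brute-force oracle over both orderings on random pairs
  set.seed(31)
  for (k in 1:10) {
    u <- straight21(runif(3, 0, 5), runif(3, 5, 15)) +
      matrix(rnorm(63, 0, 0.1), 21)
    v <- straight21(runif(3, 0, 5), runif(3, 5, 15)) +
      matrix(rnorm(63, 0, 0.1), 21)
    d_dir <- mean(sqrt(rowSums((u - v)^2)))
    d_fl <- mean(sqrt(rowSums((u - v[21:1, ])^2)))
    lu <- sum(sqrt(rowSums(diff(u)^2))); lv <- sum(sqrt(rowSums(diff(v)^2)))
    oracle <- max(0.01, min(d_dir, d_fl) * 4 / (4 + min(lu, lv)))
    expect_equal(normalized_pairwise_distance(u, v, p), oracle,
                 tolerance = 1e-12)
  }
})

test_that("affinity matrix: Gaussian kernel, camd cutoff, bounds", {
  p <- inter_params()
  expect_equal(exp(-0.01^2 / 1600), 1, tolerance = 1e-6)
  set.seed(32)
  cent <- lapply(1:50, function(i)
    straight21(runif(3, 0, 10), runif(3, 0, 10)))
  cs <- centroid_set(cent, paste0("S", rep(1:5, 10)))
  aff <- affinity_matrix(cs, p)
  expect_equal(aff$A, t(aff$A))
  expect_true(all(aff$A >= 0 & aff$A <= 1))
  expect_equal(diag(aff$A), rep(1, 50))
  # exhaustive: zero exactly where distance exceeds camd
  off <- !diag(50)
  expect_true(all((aff$A[off] == 0) == (aff$D[off] > p$camd)))
  expect_true(all(abs(aff$A[off & aff$D <= p$camd] -
                        exp(-aff$D[off & aff$D <= p$camd]^2 / p$sigma2)) < 1e-12))
})

test_that("planted cohort: 4 shared bundles survive, the rare one does not", {
  co <- make_centroid_cohort(n_subjects = 6, jit = 0.2, seed = 11,
                             rare_subjects = 2)
  cl <- cluster_inter_subject(co$cs, inter_params(), 6)
  expect_length(cl, 4)
  for (c in cl) {
    expect_equal(length(c$subjects), 6)
    expect_equal(c$presence_fraction, 1)
    expect_equal(length(unique(co$planted[c$members])), 1)
  }
  expect_false(5L %in% unlist(lapply(cl, function(c) co$planted[c$members])))
})

test_that("presence filter keeps >= 50% and preserves order", {
  p <- inter_params()
  mk <- function(subj) list(members = seq_along(subj), subjects = unique(subj),
                            presence_fraction = length(unique(subj)) / 6)
  cl <- list(mk(paste0("S", 1:3)), mk(paste0("S", 1:2)), mk(paste0("S", 1:6)))
  out <- presence_filter(cl, 6, p)
  expect_length(out, 2)
  expect_equal(out[[1]]$presence_fraction, 0.5)   # 3 of 6 kept (= 50%)
  expect_equal(out[[2]]$presence_fraction, 1)
})

test_that("clustering is invariant under a global rigid transform", {
  co <- make_centroid_cohort(n_subjects = 4, jit = 0.15, seed = 12,
                             rare_subjects = 0)
  th <- 0.7
  R <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  moved <- lapply(co$cs$points, function(pts)
    sweep(pts %*% t(R), 2, c(3, -2, 7), "+"))
  cs2 <- centroid_set(moved, co$cs$subjects)
  d1 <- aviatract:::centroid_raw_distances(co$cs)
  d2 <- aviatract:::centroid_raw_distances(cs2)
  expect_equal(d1$d_pw, d2$d_pw, tolerance = 1e-9)
  cl1 <- cluster_inter_subject(co$cs, inter_params(), 4)
  cl2 <- cluster_inter_subject(cs2, inter_params(), 4)
  expect_equal(lapply(cl1, `[[`, "members"), lapply(cl2, `[[`, "members"))
})

test_that("grid search returns the argmax of its own count surface", {
  co <- make_centroid_cohort(n_subjects = 4, jit = 0.15, seed = 13,
                             rare_subjects = 0)
  go <- grid_optimize(co$cs, nf_grid = seq(1, 100, length.out = 10),
                      camd_grid = seq(0.1, 4, length.out = 10))
  expect_equal(dim(go$surface), c(10, 10))
  best <- which(go$surface == max(go$surface), arr.ind = TRUE)[1, ]
  expect_equal(go$nf, seq(1, 100, length.out = 10)[best[1]])
  expect_equal(go$camd, seq(0.1, 4, length.out = 10)[best[2]])
  # camd below every corrected inter-centroid distance at this nf: zero
  # clusters there, while a permissive camd still finds them
  raw <- aviatract:::centroid_raw_distances(co$cs)
  Dn <- raw$d_pw * 4 / (4 + raw$minlen)   # unfloored corrected, nf = 4
  dmin <- min(Dn[upper.tri(Dn)])
  p_deg <- inter_params(d_floor = dmin / 10)
  tiny <- grid_optimize(co$cs, nf_grid = c(4), camd_grid = c(dmin / 2, 2),
                        p = p_deg)
  expect_equal(unname(tiny$surface[1, 1]), 0L)
  expect_gt(tiny$surface[1, 2], 0L)
  expect_error(grid_optimize(centroid_set(co$cs$points[1:4],
                                          rep("S1", 4))), ">= 2 subjects")
})
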