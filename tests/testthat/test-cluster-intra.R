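line_fiber <- function(p0, p1, n = 30) {
  t(vapply(seq(0, 1, length.out = n), function(s) p0 + s * (p1 - p0),
           numeric(3)))
}

test_that("region split follows the majority and interhemispheric rules", {
  labels <- array(1L, c(10, 10, 10))
  labels[6:10, , ] <- 2L
  tg <- tractogram(list(
    line_fiber(c(0.1, 0.5, 0.5), c(0.9, 0.5, 0.5)),   # all LH
    line_fiber(c(0.1, 0.5, 0.5), c(1.9, 0.5, 0.5)),   # spans LH and RH
    line_fiber(c(1.2, 0.5, 0.5), c(1.9, 0.5, 0.5))),  # all RH
    voxel_size = 0.2)
  part <- split_by_region(tg, labels)
  expect_equal(part$LH, 1L)
  expect_equal(part$INT, 2L)
  expect_equal(part$RH, 3L)
  # partition covers the tractogram
  set.seed(20)
  rnd <- tractogram(lapply(1:100, function(i) {
    p0 <- runif(3, 0.1, 1.9); line_fiber(p0, p0 + runif(3, -0.5, 0.5), 10)
  }), voxel_size = 0.2)
  part2 <- split_by_region(rnd, labels)
  expect_equal(sort(unname(unlist(part2))), 1:100)
})

test_that("length groups are equal-width, right-closed, window-filtered", {
  lens <- c(0.5, 1, 2.5, 4, 7.5, 8, 9)
  g <- split_by_length(lens, window = c(0, 8), n_ranges = 8)
  expect_equal(attr(g, "edges"), 0:8)
  expect_equal(attr(g, "n_discarded"), sum(lens < 0 | lens > 8))
  expect_equal(g[[8]], which(lens > 7 & lens <= 8))  # l = 8 in last bin
  expect_equal(g[[1]], which(lens > 0 & lens <= 1))
  # every kept fiber in exactly one bin
  expect_equal(sort(unlist(g)), which(lens >= 0 & lens <= 8))
})

test_that("density mask counts distinct fibers and applies the threshold", {
  f <- line_fiber(c(0.1, 0.1, 0.1), c(1.9, 0.1, 0.1))
  d5 <- density_mask(rep(list(f), 5), c(10, 10, 10), 0.2, min_fibers = 5)
  expect_true(all(d5[floor(f / 0.2) + 1]))
  d4 <- density_mask(rep(list(f), 4), c(10, 10, 10), 0.2, min_fibers = 5)
  expect_false(any(d4))
  # recount oracle on a random set
  set.seed(21)
  fibers <- lapply(1:20, function(i) {
    p0 <- runif(3, 0.2, 1.0); line_fiber(p0, p0 + runif(3, 0, 0.8), 15)
  })
  dm <- density_mask(fibers, c(10, 10, 10), 0.2, min_fibers = 2)
  counts <- attr(dm, "counts")
  oracle <- array(0L, c(10, 10, 10))
  for (f in fibers) {
    ijk <- pmin(pmax(floor(f / 0.2) + 1, 1), 10)
    lin <- unique(ijk[, 1] + 10 * (ijk[, 2] - 1) + 100 * (ijk[, 3] - 1))
    oracle[lin] <- oracle[lin] + 1L
  }
  expect_equal(as.vector(counts), as.vector(oracle))
})

test_that("parcellation hits the target parcel count and is a fixed point", {
  m <- array(FALSE, c(10, 10, 10))
  m[1:3, 1:3, 1:3] <- TRUE  # 27 voxels
  pm <- parcellate(m, 0.2, mean_parcel_size = 27, seed = 1)
  expect_equal(attr(pm, "k"), 1L)
  expect_true(all(pm[m] == 1L))
  m2 <- array(FALSE, c(12, 12, 12))
  m2[1:10, 1:9, 1:3] <- TRUE  # 270 voxels
  pm2 <- parcellate(m2, 0.2, mean_parcel_size = 27, seed = 2)
  expect_equal(attr(pm2, "k"), 10L)
  expect_equal(mean(tabulate(pm2[pm2 > 0])), 27)
  # brute-force nearest-center optimality
  vox <- which(m2)
  ctr <- (arrayInd(vox, dim(m2)) - 0.5) * 0.2
  lab <- pm2[vox]
  centers <- t(vapply(1:10, function(k) colMeans(ctr[lab == k, , drop = FALSE]),
                      numeric(3)))
  d2 <- as.matrix(ctr %*% t(centers))
  d2 <- outer(rowSums(ctr^2), rep(1, 10)) - 2 * d2 +
    outer(rep(1, length(vox)), rowSums(centers^2))
  expect_true(all(d2[cbind(seq_along(vox), lab)] <=
                    apply(d2, 1, min) + 1e-9))
  expect_error(parcellate(array(FALSE, c(3, 3, 3)), 0.2), "empty mask")
})

test_that("parcel connectivity equals the brute-force pair count", {
  pm <- array(0L, c(10, 10, 10))
  pm[1:3, 1, 1] <- 1L; pm[4:6, 1, 1] <- 2L; pm[7:9, 1, 1] <- 3L
  f <- line_fiber(c(0.1, 0.1, 0.1), c(1.7, 0.1, 0.1))
  M <- parcel_connectivity(list(f), pm, 0.2)
  expect_equal(M[1, 2], 1L); expect_equal(M[2, 3], 1L); expect_equal(M[1, 3], 1L)
  expect_equal(M, t(M))
  expect_true(all(diag(M) == 0))
  set.seed(22)
  fibers <- lapply(1:15, function(i) {
    p0 <- runif(3, 0.1, 1.0); line_fiber(p0, p0 + runif(3, 0, 0.9), 12)
  })
  pm2 <- array(sample(0:5, 1000, replace = TRUE), c(10, 10, 10))
  M2 <- parcel_connectivity(fibers, pm2, 0.2)
  oracle <- matrix(0L, 5, 5)
  for (f in fibers) {
    ijk <- pmin(pmax(floor(f / 0.2) + 1, 1), 10)
    lin <- unique(ijk[, 1] + 10 * (ijk[, 2] - 1) + 100 * (ijk[, 3] - 1))
    ps <- setdiff(unique(pm2[lin]), 0L)
    for (p in ps) for (q in ps) if (p != q)
      oracle[p, q] <- oracle[p, q] + 1L
  }
  expect_equal(unname(M2), unname(oracle) / 1L)
})

test_that("parcel clustering separates blocks and matches a naive oracle", {
  # two internally dense blocks, no cross connections
  M <- matrix(0L, 6, 6)
  M[1:3, 1:3] <- 10L; M[4:6, 4:6] <- 10L; diag(M) <- 0L
  cl <- cluster_parcels(M, cut = 0.9)
  expect_length(cl, 2)
  expect_setequal(cl[[1]], 1:3); expect_setequal(cl[[2]], 4:6)
  expect_equal(cluster_parcels(matrix(0L, 1, 1)), list(1L))
  # all-zero connectivity: singletons
  expect_length(cluster_parcels(matrix(0L, 4, 4)), 4)
  # naive average-linkage agglomeration oracle on a random 6-parcel matrix:
  # merge groups while the smallest mean cross-distance stays within the
  # cut, then compare the partitions
  set.seed(23)
  A <- matrix(runif(36, 0, 10), 6); A <- A + t(A); diag(A) <- 0
  cut <- 0.6
  got <- cluster_parcels(A, cut = cut)
  D <- 1 - A / max(A); diag(D) <- 0
  naive <- local({
    groups <- as.list(1:6)
    repeat {
      if (length(groups) == 1) break
      best <- NULL; bd <- Inf
      for (i in seq_along(groups)) for (j in seq_along(groups)) if (i < j) {
        d <- mean(D[groups[[i]], groups[[j]]])
        if (d < bd) { bd <- d; best <- c(i, j) }
      }
      if (bd > cut) break
      groups[[best[1]]] <- sort(c(groups[[best[1]]], groups[[best[2]]]))
      groups[[best[2]]] <- NULL
    }
    groups
  })
  canon <- function(g) unname(g[order(vapply(g, min, numeric(1)))])
  expect_equal(canon(lapply(got, as.integer)),
               canon(lapply(naive, as.integer)))
})

test_that("fiber assignment applies the 31% fraction and 5-member rules", {
  pm <- array(0L, c(10, 10, 10))
  pm[1:5, 1, 1] <- 1L; pm[6:10, 1, 1] <- 2L
  clusters <- list(1L, 2L)
  inside <- line_fiber(c(0.1, 0.1, 0.1), c(0.9, 0.1, 0.1), 20)
  # a fiber with exactly 30% of points in cluster 1, the rest outside any
  mixed <- rbind(matrix(rep(c(0.5, 0.1, 0.1), 3), 3, byrow = TRUE),
                 matrix(rep(c(0.5, 0.5, 0.5), 7), 7, byrow = TRUE))
  out <- assign_fibers(c(rep(list(inside), 5), list(mixed)),
                       clusters, pm, 0.2, min_frac = 0.31, min_members = 5)
  expect_length(out, 1)
  expect_setequal(out[[1]], 1:5)    # the 30% fiber is unassigned
  # below the 5-member minimum the cluster is dropped
  out4 <- assign_fibers(rep(list(inside), 4), clusters, pm, 0.2,
                        min_frac = 0.31, min_members = 5)
  expect_length(out4, 0)
  # fraction oracle on random fibers
  set.seed(24)
  fibers <- lapply(1:30, function(i) {
    p0 <- runif(3, 0.1, 1.4); line_fiber(p0, p0 + runif(3, 0, 0.5), 10)
  })
  pm3 <- array(sample(0:4, 1000, TRUE), c(10, 10, 10))
  cl3 <- list(c(1L, 2L), c(3L, 4L))
  got <- assign_fibers(fibers, cl3, pm3, 0.2, min_frac = 0.31,
                       min_members = 1)
  oracle <- lapply(seq_along(cl3), function(x) integer(0))
  for (fi in seq_along(fibers)) {
    ijk <- pmin(pmax(floor(fibers[[fi]] / 0.2) + 1, 1), 10)
    p <- pm3[ijk]
    frac <- vapply(cl3, function(cc) mean(p %in% cc), numeric(1))
    best <- which.max(frac)
    if (frac[best] >= 0.31)
      oracle[[best]] <- c(oracle[[best]], fi)
  }
  oracle <- oracle[vapply(oracle, length, integer(1)) >= 1]
  expect_equal(got, oracle)
})

test_that("centroid is the all-pairs argmin of mean MCP distance", {
  # three parallel fibers at offsets 0, 1, 2 mm: the middle one wins
  f <- lapply(c(0, 1, 2), function(o)
    line_fiber(c(0, o, 0), c(5, o, 0), 20))
  expect_equal(compute_centroid(f), 2L)
  # metric sanity
  D <- mcp_distance_matrix(f)
  expect_equal(diag(D), rep(0, 3))
  expect_equal(D, t(D))
  expect_equal(D[1, 2], 1, tolerance = 1e-9)
  # brute-force all-pairs oracle on 10 random fibers
  set.seed(25)
  fibers <- lapply(1:10, function(i) {
    p0 <- runif(3, 0, 2); line_fiber(p0, p0 + runif(3, 1, 3), 15)
  })
  mcp_pair <- function(A, B) {
    da <- mean(apply(A, 1, function(a) min(sqrt(colSums((t(B) - a)^2)))))
    db <- mean(apply(B, 1, function(b) min(sqrt(colSums((t(A) - b)^2)))))
    (da + db) / 2
  }
  Dor <- matrix(0, 10, 10)
  for (i in 1:9) for (j in (i + 1):10) {
    Dor[i, j] <- Dor[j, i] <- mcp_pair(fibers[[i]], fibers[[j]])
  }
  expect_equal(mcp_distance_matrix(fibers), Dor, tolerance = 1e-10)
  expect_equal(compute_centroid(fibers), which.min(rowSums(Dor)))
  expect_equal(compute_centroid(fibers[1]), 1L)
})

test_that("step-1 clustering recovers well-separated planted bundles", {
  pl <- make_planted_tractogram(n_per = 60, seed = 5)
  cl <- cluster_subject(pl$tractogram, pl$labels, window = c(0.64, 49.06),
                        intra_params(seed = 3))
  expect_gte(length(cl), 3)
  purities <- vapply(cl, function(c) {
    tab <- table(pl$planted[c$members]); max(tab) / sum(tab)
  }, numeric(1))
  expect_true(all(purities >= 0.9))
  majorities <- vapply(cl, function(c)
    names(which.max(table(pl$planted[c$members]))), character(1))
  expect_setequal(unique(majorities), c("1", "2", "3"))
  for (c in cl) {
    expect_gte(length(c$members), 5)
    expect_true(c$centroid_index %in% c$members)
  }
  # determinism
  cl2 <- cluster_subject(pl$tractogram, pl$labels, window = c(0.64, 49.06),
                         intra_params(seed = 3))
  expect_identical(lapply(cl, `[[`, "members"),
                   lapply(cl2, `[[`, "members"))
})
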