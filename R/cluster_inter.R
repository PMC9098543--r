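# ---- Step 2: inter-subject centroid clustering ----
# Centroids from all subjects (in a common/template space) are resampled to
# a fixed point count, compared with a length-corrected pairwise distance,
# turned into Gaussian affinities, and clustered with HDBSCAN; bundles must
# be present in at least half the cohort.

#' Resample a streamline to a fixed point count
#'
#' Equidistant points along arc length; endpoints preserved.
#'
#' @param c point matrix (`>= 2` rows)
#' @param n_points output point count (default 21)
#' @export
resample_centroid <- function(c, n_points = 21L) {
  c <- as.matrix(c)
  stopifnot(nrow(c) >= 2, n_points >= 2)
  seg <- diff(c)
  s <- c(0, cumsum(sqrt(rowSums(seg^2))))
  total <- s[length(s)]
  if (total <= 0) stop("zero-length streamline")
  si <- seq(0, total, length.out = n_points)
  out <- cbind(approx(s, c[, 1], xout = si, ties = "ordered")$y,
               approx(s, c[, 2], xout = si, ties = "ordered")$y,
               approx(s, c[, 3], xout = si, ties = "ordered")$y)
  out
}

#' Centroid set for inter-subject clustering
#'
#' @param centroids list of centroid streamlines (any point count; they are
#'   resampled to `n_points`)
#' @param subjects subject id per centroid
#' @param regions optional region tag per centroid
#' @param n_points fixed resampling count (default 21)
#' @return a `centroid_set`: `points` (list of `n_points x 3` matrices),
#'   `lengths` (mm, of the resampled polylines), `subjects`, `regions`
#' @export
centroid_set <- function(centroids, subjects, regions = NULL,
                         n_points = 21L) {
  stopifnot(length(centroids) == length(subjects))
  pts <- lapply(centroids, resample_centroid, n_points = n_points)
  lens <- vapply(pts, function(p) sum(sqrt(rowSums(diff(p)^2))), numeric(1))
  structure(list(points = pts, lengths = lens, subjects = subjects,
                 regions = regions, n_points = n_points,
                 space = "template"),
            class = "centroid_set")
}

#' @export
length.centroid_set <- function(x) length(x$points)

#' Inter-subject clustering parameters
#'
#' Defaults are the cohort-calibrated values: normalization factor nf =
#' 4.0 mm and maximum centroid affinity distance CAMD = 2.0 mm (grid
#' optimum), Gaussian affinity variance 1600 mm^2, minimum normalized
#' distance 0.01 mm, post-clustering exclusion distance 0.4 mm, and a 50%
#' minimum population presence.
#'
#' @param nf length-correction normalization factor, mm
#' @param camd maximum distance for a nonzero affinity, mm
#' @param sigma2 Gaussian affinity variance, mm^2
#' @param d_floor minimum normalized distance, mm
#' @param d_excl maximum member-to-medoid distance after exclusion, mm
#'   (NA disables the exclusion pass)
#' @param min_pop_frac minimum fraction of subjects per retained bundle
#' @export
inter_params <- function(nf = 4.0, camd = 2.0, sigma2 = 1600,
                         d_floor = 0.01, d_excl = 0.4,
                         min_pop_frac = 0.5) {
  stopifnot(nf > 0, camd > 0, sigma2 > 0, d_floor > 0, d_floor < camd,
            min_pop_frac > 0, min_pop_frac <= 1)
  structure(list(nf = nf, camd = camd, sigma2 = sigma2, d_floor = d_floor,
                 d_excl = d_excl, min_pop_frac = min_pop_frac),
            class = "inter_params")
}

#' Length-corrected normalized pairwise distance between two centroids
#'
#' Raw distance: the smaller, over the two point orderings (direct and
#' flipped), of the mean point-to-corresponding-point Euclidean distance.
#' Correction: `d = max(d_floor, d_raw * nf / (nf + min(len_a, len_b)))`,
#' releasing the constraint as the shorter centroid gets longer.
#'
#' @param a,b point matrices with the same (fixed) point count
#' @param p an [inter_params()]
#' @export
normalized_pairwise_distance <- function(a, b, p = inter_params()) {
  if (nrow(a) != nrow(b)) stop("centroid point counts differ")
  d_dir <- mean(sqrt(rowSums((a - b)^2)))
  d_flip <- mean(sqrt(rowSums((a - b[nrow(b):1, , drop = FALSE])^2)))
  d_pw <- min(d_dir, d_flip)
  len_a <- sum(sqrt(rowSums(diff(a)^2)))
  len_b <- sum(sqrt(rowSums(diff(b)^2)))
  max(p$d_floor, d_pw * p$nf / (p$nf + min(len_a, len_b)))
}

# raw (uncorrected) pairwise distances and pairwise minimum lengths,
# cached so the (nf, camd) grid search can rescale without recomputation
centroid_raw_distances <- function(cs) {
  n <- length(cs$points)
  d_pw <- matrix(0, n, n)
  for (i in seq_len(max(n - 1, 0))) {
    a <- cs$points[[i]]
    for (j in seq(i + 1, n)) {
      b <- cs$points[[j]]
      d <- min(mean(sqrt(rowSums((a - b)^2))),
               mean(sqrt(rowSums((a - b[nrow(b):1, ])^2))))
      d_pw[i, j] <- d; d_pw[j, i] <- d
    }
  }
  minlen <- outer(cs$lengths, cs$lengths, pmin)
  list(d_pw = d_pw, minlen = minlen)
}

corrected_distances <- function(raw, p) {
  D <- pmax(raw$d_pw * p$nf / (p$nf + raw$minlen), p$d_floor)
  diag(D) <- 0
  D
}

#' Gaussian affinity matrix between centroids
#'
#' `a_ij = exp(-d_ij^2 / sigma2)` where the corrected distance is at most
#' `camd`, zero beyond; unit diagonal.
#'
#' @param cs a [centroid_set()]
#' @param p an [inter_params()]
#' @return list with `A` (affinities) and `D` (corrected distances)
#' @export
affinity_matrix <- function(cs, p = inter_params()) {
  raw <- centroid_raw_distances(cs)
  D <- corrected_distances(raw, p)
  A <- ifelse(D <= p$camd, exp(-D^2 / p$sigma2), 0)
  diag(A) <- 1
  list(A = A, D = D)
}

#' HDBSCAN clustering of the centroid affinity structure
#'
#' HDBSCAN runs on the corrected distances, with pairs beyond `camd` (zero
#' affinity) set to a far sentinel so they can never bind; the minimum
#' cluster size is `max(2, ceiling(min_pop_frac * n_subjects))`. An
#' optional exclusion pass then removes members farther than `d_excl` from
#' their cluster's medoid centroid.
#'
#' @param aff output of [affinity_matrix()] (list A, D)
#' @param cs the [centroid_set()]
#' @param p an [inter_params()]
#' @param n_subjects cohort size
#' @return list of inter-clusters: `members` (centroid indices),
#'   `subjects`, `presence_fraction`
#' @export
hdbscan_interclusters <- function(aff, cs, p, n_subjects) {
  D <- aff$D
  sentinel <- 10 * p$camd + max(D[is.finite(D)], 0)
  D[aff$A == 0] <- sentinel
  diag(D) <- 0
  mcs <- max(2L, as.integer(ceiling(p$min_pop_frac * n_subjects)))
  res <- hdbscan_precomputed(D, min_cluster_size = mcs, min_samples = mcs)
  out <- list()
  for (ci in seq_len(res$n_clusters)) {
    mem <- which(res$labels == ci)
    if (!is.null(p$d_excl) && !is.na(p$d_excl) && length(mem) >= 2) {
      sub <- aff$D[mem, mem, drop = FALSE]
      medoid <- which.min(rowSums(sub))
      mem <- mem[sub[medoid, ] <= p$d_excl | seq_along(mem) == medoid]
    }
    if (length(mem) < 2) next
    subj <- unique(cs$subjects[mem])
    out[[length(out) + 1L]] <- list(
      members = mem, subjects = subj,
      presence_fraction = length(subj) / n_subjects)
  }
  out
}

#' Keep bundles present in enough of the cohort
#'
#' @param clusters inter-clusters from [hdbscan_interclusters()]
#' @param n_subjects cohort size
#' @param p an [inter_params()]
#' @export
presence_filter <- function(clusters, n_subjects, p = inter_params()) {
  Filter(function(cl) cl$presence_fraction >= p$min_pop_frac, clusters)
}

#' Full inter-subject clustering at one (nf, camd) setting
#'
#' @param cs a [centroid_set()]
#' @param p an [inter_params()]
#' @param n_subjects cohort size (defaults to distinct subjects in `cs`)
#' @param filter apply the population-presence filter
#' @export
cluster_inter_subject <- function(cs, p = inter_params(),
                                  n_subjects = length(unique(cs$subjects)),
                                  filter = TRUE) {
  aff <- affinity_matrix(cs, p)
  cl <- hdbscan_interclusters(aff, cs, p, n_subjects)
  if (filter) cl <- presence_filter(cl, n_subjects, p)
  cl
}

#' Grid search of the distance-correction parameters
#'
#' Runs the inter-subject clustering on every point of an (nf, CAMD) grid
#' and returns the setting maximizing the number of clusters produced by
#' the HDBSCAN stage, together with the full count surface.
#'
#' @param cs a [centroid_set()] (typically a small cohort subset)
#' @param nf_grid candidate normalization factors, mm
#' @param camd_grid candidate maximum affinity distances, mm
#' @param p base [inter_params()] (other fields reused)
#' @param n_subjects cohort size of the subset
#' @return list `nf`, `camd`, `surface` (matrix nf x camd of cluster
#'   counts)
#' @export
grid_optimize <- function(cs, nf_grid = seq(1, 100, length.out = 10),
                          camd_grid = seq(0.1, 4.0, length.out = 10),
                          p = inter_params(),
                          n_subjects = length(unique(cs$subjects))) {
  if (n_subjects < 2) stop("grid optimization needs >= 2 subjects")
  raw <- centroid_raw_distances(cs)
  surface <- matrix(0L, length(nf_grid), length(camd_grid),
                    dimnames = list(signif(nf_grid, 4), signif(camd_grid, 4)))
  for (i in seq_along(nf_grid)) {
    pi_ <- p; pi_$nf <- nf_grid[i]
    D <- corrected_distances(raw, pi_)
    for (j in seq_along(camd_grid)) {
      pij <- pi_; pij$camd <- camd_grid[j]
      if (pij$d_floor >= pij$camd) { surface[i, j] <- 0L; next }
      A <- ifelse(D <= pij$camd, exp(-D^2 / pij$sigma2), 0)
      diag(A) <- 1
      cl <- hdbscan_interclusters(list(A = A, D = D), cs, pij, n_subjects)
      surface[i, j] <- length(cl)
    }
  }
  best <- which(surface == max(surface), arr.ind = TRUE)[1, ]
  list(nf = nf_grid[best[1]], camd = camd_grid[best[2]], surface = surface)
}
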