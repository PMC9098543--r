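# ---- Step 1: intra-subject fiber clustering ----
# Partition the tractogram by region and length, build parcel connectivity
# matrices on fiber-density masks, cluster parcels hierarchically, assign
# fibers, and represent each retained cluster by a centroid fiber.

region_codes <- c(LH = 1L, RH = 2L, INT = 3L, CBL = 4L)

# unique voxel linear indices visited by a fiber's points (clamped to grid)
fiber_voxel_indices <- function(pts, voxel_size, dims) {
  ijk <- floor(pts / voxel_size) + 1
  for (a in 1:3) ijk[, a] <- clamp(ijk[, a], 1, dims[a])
  unique(ijk[, 1] + dims[1] * (ijk[, 2] - 1) + dims[1] * dims[2] * (ijk[, 3] - 1))
}

# region label at each fiber point
fiber_point_labels <- function(pts, labels, voxel_size) {
  dims <- dim(labels)
  ijk <- floor(pts / voxel_size) + 1
  for (a in 1:3) ijk[, a] <- clamp(ijk[, a], 1, dims[a])
  labels[cbind(ijk[, 1], ijk[, 2], ijk[, 3])]
}

#' Split a tractogram by anatomical region
#'
#' Each fiber goes to the region (left hemisphere, right hemisphere,
#' cerebellum) holding the majority of its points; fibers with points in
#' both hemispheres are interhemispheric (INT).
#'
#' @param t a [tractogram()]
#' @param region_labels integer array (1 = LH, 2 = RH, 3 = INT, 4 = CBL)
#' @return named list LH/RH/INT/CBL of fiber index vectors (disjoint,
#'   covering the tractogram)
#' @export
split_by_region <- function(t, region_labels) {
  out <- list(LH = integer(0), RH = integer(0), INT = integer(0),
              CBL = integer(0))
  for (i in seq_along(t$streamlines)) {
    lab <- fiber_point_labels(t$streamlines[[i]], region_labels, t$voxel_size)
    lab <- lab[lab > 0]
    if (length(lab) == 0) lab <- 1L   # unlabeled everywhere: arbitrary LH
    reg <- if (any(lab == 1L) && any(lab == 2L)) 3L else
      as.integer(names(which.max(table(lab))))
    nm <- names(region_codes)[reg]
    out[[nm]] <- c(out[[nm]], i)
  }
  out
}

#' Split fibers into equal-width length groups
#'
#' Fibers with lengths outside `window` are discarded; the window is cut
#' into `n_ranges` equal-width, right-closed bins.
#'
#' @param lengths fiber lengths in mm
#' @param window `c(l_min, l_max)` mm
#' @param n_ranges number of bins (default 8)
#' @return list of length `n_ranges` of fiber index vectors; discarded
#'   count in attribute `n_discarded`
#' @export
split_by_length <- function(lengths, window, n_ranges = 8L) {
  stopifnot(window[1] < window[2], n_ranges >= 1)
  keep <- lengths >= window[1] & lengths <= window[2]
  w <- (window[2] - window[1]) / n_ranges
  bin <- ceiling((lengths - window[1]) / w)
  bin[lengths == window[1]] <- 1L
  out <- lapply(seq_len(n_ranges), function(b) which(keep & bin == b))
  attr(out, "n_discarded") <- sum(!keep)
  attr(out, "edges") <- window[1] + w * (0:n_ranges)
  out
}

#' Fiber density mask
#'
#' Counts the distinct fibers traversing each voxel (a fiber counts once
#' per voxel) and thresholds at `min_fibers`.
#'
#' @param fibers list of fiber point matrices (mm)
#' @param dims grid dimensions
#' @param voxel_size mm
#' @param min_fibers minimum distinct-fiber count (default 5)
#' @return logical array; the raw counts in attribute `counts`
#' @export
density_mask <- function(fibers, dims, voxel_size, min_fibers = 5L) {
  counts <- array(0L, dims)
  for (f in fibers) {
    v <- fiber_voxel_indices(f, voxel_size, dims)
    counts[v] <- counts[v] + 1L
  }
  m <- counts >= min_fibers
  attr(m, "counts") <- counts
  m
}

#' K-means parcellation of a binary mask
#'
#' Subdivides the mask into random spatial parcels averaging
#' `mean_parcel_size` voxels: k = max(1, round(n/mean_parcel_size)) k-means
#' on voxel-center mm coordinates; every mask voxel is labeled by its
#' nearest final center.
#'
#' @param mask logical array
#' @param voxel_size mm
#' @param mean_parcel_size target mean parcel size in voxels (default 27)
#' @param seed integer seed
#' @return integer array of parcel labels (0 = background); parcel count in
#'   attribute `k`
#' @export
parcellate <- function(mask, voxel_size, mean_parcel_size = 27L, seed = 0L) {
  vox <- which(mask)
  if (length(vox) == 0) stop("empty mask")
  ctr <- (arrayInd(vox, dim(mask)) - 0.5) * voxel_size
  k <- max(1L, min(length(vox), as.integer(round(length(vox) / mean_parcel_size))))
  pm <- array(0L, dim(mask))
  if (k == 1L) {
    pm[vox] <- 1L
  } else {
    km <- with_seed(seed, stats::kmeans(ctr, centers = k, iter.max = 100L,
                                        nstart = 1L))
    # guarantee the fixed point: label by nearest final center
    d2 <- outer(rowSums(ctr^2), rep(1, k)) - 2 * ctr %*% t(km$centers) +
      outer(rep(1, nrow(ctr)), rowSums(km$centers^2))
    pm[vox] <- max.col(-d2, ties.method = "first")
  }
  attr(pm, "k") <- k
  pm
}

#' Parcel-to-parcel fiber connectivity matrix
#'
#' `M[p, q]` counts the fibers visiting both parcels p and q (p != q);
#' symmetric with a zero diagonal.
#'
#' @param fibers list of fiber point matrices
#' @param parcel_map integer label array from [parcellate()]
#' @param voxel_size mm
#' @export
parcel_connectivity <- function(fibers, parcel_map, voxel_size) {
  k <- max(parcel_map)
  M <- matrix(0L, k, k)
  dims <- dim(parcel_map)
  for (f in fibers) {
    v <- fiber_voxel_indices(f, voxel_size, dims)
    ps <- sort(unique(parcel_map[v]))
    ps <- ps[ps > 0]
    if (length(ps) >= 2) {
      pairs <- utils::combn(ps, 2)
      for (c in seq_len(ncol(pairs))) {
        M[pairs[1, c], pairs[2, c]] <- M[pairs[1, c], pairs[2, c]] + 1L
        M[pairs[2, c], pairs[1, c]] <- M[pairs[2, c], pairs[1, c]] + 1L
      }
    }
  }
  M
}

#' Hierarchical clustering of connected parcels
#'
#' Average-linkage agglomeration on the distance `1 - M/max(M)`, with the
#' dendrogram cut at a fixed height.
#'
#' @param M parcel connectivity matrix
#' @param cut dendrogram cut height in [0, 1] (default 0.9)
#' @return list of parcel-id vectors (one per cluster)
#' @export
cluster_parcels <- function(M, cut = 0.9) {
  k <- nrow(M)
  if (k == 1L) return(list(1L))
  mx <- max(M)
  if (mx == 0) return(as.list(seq_len(k)))
  D <- 1 - M / mx
  diag(D) <- 0
  hc <- stats::hclust(stats::as.dist(D), method = "average")
  # guard against floating-point non-monotonicity in the merge heights
  hc$height <- cummax(hc$height)
  grp <- stats::cutree(hc, h = cut)
  split(seq_len(k), grp)
}

#' Assign fibers to parcel clusters
#'
#' A fiber's trajectory fraction in a cluster is the share of its points
#' falling in that cluster's parcels; it joins the cluster of maximal
#' fraction when that fraction reaches `min_frac` (31%). Clusters keeping
#' fewer than `min_members` (5) fibers are discarded.
#'
#' @param fibers list of fiber point matrices
#' @param parcel_clusters list of parcel-id vectors from [cluster_parcels()]
#' @param parcel_map integer label array
#' @param voxel_size mm
#' @param min_frac minimum trajectory fraction (default 0.31)
#' @param min_members minimum cluster membership (default 5)
#' @return list of integer vectors of fiber indices (into `fibers`)
#' @export
assign_fibers <- function(fibers, parcel_clusters, parcel_map, voxel_size,
                          min_frac = 0.31, min_members = 5L) {
  dims <- dim(parcel_map)
  ncl <- length(parcel_clusters)
  cluster_of_parcel <- integer(max(parcel_map))
  for (ci in seq_len(ncl)) cluster_of_parcel[parcel_clusters[[ci]]] <- ci
  members <- vector("list", ncl)
  for (fi in seq_along(fibers)) {
    pts <- fibers[[fi]]
    ijk <- floor(pts / voxel_size) + 1
    for (a in 1:3) ijk[, a] <- clamp(ijk[, a], 1, dims[a])
    p <- parcel_map[cbind(ijk[, 1], ijk[, 2], ijk[, 3])]
    cl <- ifelse(p > 0, cluster_of_parcel[pmax(p, 1L)], 0L)
    cl <- cl[cl > 0]
    if (length(cl) == 0) next
    tab <- tabulate(cl, nbins = ncl) / nrow(pts)
    best <- which.max(tab)
    if (tab[best] >= min_frac)
      members[[best]] <- c(members[[best]], fi)
  }
  members[vapply(members, length, integer(1)) >= min_members]
}

#' Pairwise symmetric mean-closest-point distance matrix
#'
#' `d(A,B) = (mean_a min_b ||a-b|| + mean_b min_a ||b-a||) / 2` for every
#' pair of fibers.
#'
#' @param fibers list of fiber point matrices
#' @export
mcp_distance_matrix <- function(fibers) {
  mcp_dist_matrix_cpp(fibers)
}

#' Centroid fiber of a cluster
#'
#' The member fiber minimizing the mean symmetric mean-closest-point
#' distance to all other members; ties broken by lower index. A singleton
#' cluster returns its only member.
#'
#' @param fibers list of the cluster's member fiber point matrices
#' @return index (into `fibers`) of the centroid
#' @export
compute_centroid <- function(fibers) {
  n <- length(fibers)
  if (n == 0) stop("empty cluster")
  if (n == 1) return(1L)
  D <- mcp_dist_matrix_cpp(fibers)
  which.min(rowSums(D) / (n - 1))
}

#' Intra-subject clustering parameters
#' @param mean_parcel_size voxels per parcel (27)
#' @param min_fibers_mask density-mask threshold (5)
#' @param cut parcel-dendrogram cut height (0.9)
#' @param min_frac minimum trajectory fraction (0.31)
#' @param min_members minimum fibers per cluster (5)
#' @param n_ranges number of length groups (8)
#' @param seed integer seed for the parcellations
#' @export
intra_params <- function(mean_parcel_size = 27L, min_fibers_mask = 5L,
                         cut = 0.9, min_frac = 0.31, min_members = 5L,
                         n_ranges = 8L, seed = 0L) {
  structure(list(mean_parcel_size = mean_parcel_size,
                 min_fibers_mask = min_fibers_mask, cut = cut,
                 min_frac = min_frac, min_members = min_members,
                 n_ranges = n_ranges, seed = as.integer(seed)),
            class = "intra_params")
}

#' Cluster one subject's tractogram (Step 1)
#'
#' Runs the full intra-subject chain: region split, length-window split,
#' density mask, k-means parcellation, parcel connectivity, hierarchical
#' parcel clustering, fiber assignment, and centroid extraction, for every
#' (region, length range) unit.
#'
#' @param t a [tractogram()]
#' @param region_labels integer region array
#' @param window population length window `c(l_min, l_max)` mm
#' @param params an [intra_params()]
#' @return list of clusters, each a list with `members` (fiber indices into
#'   `t`), `region`, `length_range`, `centroid_index` (fiber index into
#'   `t`) and `centroid` (its point matrix)
#' @export
cluster_subject <- function(t, region_labels, window,
                            params = intra_params()) {
  dims <- dim(region_labels)
  lens <- streamline_lengths(t)
  by_region <- split_by_region(t, region_labels)
  clusters <- list()
  for (reg in names(by_region)) {
    ridx <- by_region[[reg]]
    if (length(ridx) == 0) next
    by_len <- split_by_length(lens[ridx], window, params$n_ranges)
    for (li in seq_along(by_len)) {
      gidx <- ridx[by_len[[li]]]
      if (length(gidx) < params$min_members) next
      fibers <- t$streamlines[gidx]
      dm <- density_mask(fibers, dims, t$voxel_size, params$min_fibers_mask)
      if (!any(dm)) next
      pm <- parcellate(dm, t$voxel_size, params$mean_parcel_size,
                       seed = params$seed + 131L * li +
                         7L * region_codes[[reg]])
      M <- parcel_connectivity(fibers, pm, t$voxel_size)
      pc <- cluster_parcels(M, params$cut)
      mem <- assign_fibers(fibers, pc, pm, t$voxel_size,
                           params$min_frac, params$min_members)
      for (m in mem) {
        ci <- compute_centroid(fibers[m])
        clusters[[length(clusters) + 1L]] <- list(
          members = gidx[m], region = reg, length_range = li,
          centroid_index = gidx[m][ci],
          centroid = fibers[[m[ci]]])
      }
    }
  }
  clusters
}
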