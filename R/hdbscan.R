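# HDBSCAN on a precomputed distance matrix.
#
# Density-based hierarchical clustering (Campello et al. style): core
# distances -> mutual reachability graph -> minimum spanning tree ->
# single-linkage hierarchy -> condensed tree at min_cluster_size ->
# excess-of-mass cluster selection. Points not in any selected cluster are
# noise (label 0). Conventions follow the scikit-learn implementation
# (min_samples counts the point itself; the root is never selected).

#' HDBSCAN clustering of a precomputed distance matrix
#'
#' @param D symmetric distance matrix
#' @param min_cluster_size smallest cluster size (>= 2)
#' @param min_samples neighborhood size for core distances (defaults to
#'   `min_cluster_size`; the point itself counts)
#' @return list with `labels` (integer, 0 = noise) and `n_clusters`
#' @export
hdbscan_precomputed <- function(D, min_cluster_size = 5L,
                                min_samples = min_cluster_size) {
  D <- as.matrix(D)
  n <- nrow(D)
  stopifnot(ncol(D) == n, min_cluster_size >= 2)
  if (n < min_cluster_size)
    return(list(labels = rep(0L, n), n_clusters = 0L))
  diag(D) <- 0

  # core distances (self counted among the min_samples neighbors)
  k <- min(min_samples, n)
  core <- vapply(seq_len(n), function(i) sort(D[i, ])[k], numeric(1))

  # mutual reachability
  MR <- pmax(D, outer(core, rep(1, n)), outer(rep(1, n), core))
  diag(MR) <- 0

  # Prim MST
  in_tree <- c(TRUE, rep(FALSE, n - 1))
  best_d <- MR[1, ]; best_from <- rep(1L, n)
  edges <- matrix(0, n - 1, 3)  # from, to, weight
  for (e in seq_len(n - 1)) {
    cand <- which(!in_tree)
    j <- cand[which.min(best_d[cand])]
    edges[e, ] <- c(best_from[j], j, best_d[j])
    in_tree[j] <- TRUE
    upd <- !in_tree & MR[j, ] < best_d
    best_d[upd] <- MR[j, upd]; best_from[upd] <- j
  }

  # single-linkage hierarchy via union-find over sorted MST edges
  edges <- edges[order(edges[, 3]), , drop = FALSE]
  parent_uf <- seq_len(2L * n - 1L)   # union-find over leaves + merge nodes
  find <- function(x) {
    while (parent_uf[x] != x) {
      parent_uf[x] <<- parent_uf[parent_uf[x]]
      x <- parent_uf[x]
    }
    x
  }
  child_l <- integer(n - 1); child_r <- integer(n - 1)
  height <- numeric(n - 1); sz <- integer(2L * n - 1L)
  sz[seq_len(n)] <- 1L
  for (e in seq_len(n - 1)) {
    ra <- find(as.integer(edges[e, 1])); rb <- find(as.integer(edges[e, 2]))
    node <- n + e
    child_l[e] <- ra; child_r[e] <- rb
    height[e] <- edges[e, 3]
    sz[node] <- sz[ra] + sz[rb]
    parent_uf[ra] <- node; parent_uf[rb] <- node
  }

  leaves_of <- function(node) {
    out <- integer(0); stack <- node
    while (length(stack)) {
      x <- stack[length(stack)]; stack <- stack[-length(stack)]
      if (x <= n) out <- c(out, x)
      else stack <- c(stack, child_l[x - n], child_r[x - n])
    }
    out
  }
  lam <- function(h) if (h <= 0) Inf else 1 / h

  # ---- condensed tree ----
  cl_parent <- integer(0); cl_birth <- numeric(0)
  cl_stab <- numeric(0); cl_children <- list()
  point_cluster <- integer(n); point_lambda <- numeric(n)
  new_cluster <- function(parent, birth) {
    cl_parent[length(cl_parent) + 1L] <<- parent
    cl_birth[length(cl_birth) + 1L] <<- birth
    cl_stab[length(cl_stab) + 1L] <<- 0
    cl_children[[length(cl_parent)]] <<- integer(0)
    if (parent > 0)
      cl_children[[parent]] <<- c(cl_children[[parent]], length(cl_parent))
    length(cl_parent)
  }
  root_cl <- new_cluster(0L, 0)
  fall_out <- function(cluster, node, lambda_val) {
    pts <- leaves_of(node)
    lv <- min(lambda_val, .Machine$double.xmax)
    point_cluster[pts] <<- cluster
    point_lambda[pts] <<- lv
    cl_stab[cluster] <<- cl_stab[cluster] +
      length(pts) * (lv - cl_birth[cluster])
  }
  # stack of (dendrogram node, condensed cluster)
  stack <- list(c(2L * n - 1L, root_cl))
  while (length(stack)) {
    top <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
    node <- top[1]; clus <- top[2]
    if (node <= n) { fall_out(clus, node, Inf); next }
    e <- node - n
    l <- child_l[e]; r <- child_r[e]
    lv <- lam(height[e])
    big_l <- sz[l] >= min_cluster_size
    big_r <- sz[r] >= min_cluster_size
    if (big_l && big_r) {
      # true split: current cluster dies, two children born
      cl_stab[clus] <- cl_stab[clus] +
        sz[node] * (min(lv, .Machine$double.xmax) - cl_birth[clus])
      cl_l <- new_cluster(clus, lv); cl_r <- new_cluster(clus, lv)
      stack[[length(stack) + 1L]] <- c(l, cl_l)
      stack[[length(stack) + 1L]] <- c(r, cl_r)
    } else if (big_l) {
      fall_out(clus, r, lv)
      stack[[length(stack) + 1L]] <- c(l, clus)
    } else if (big_r) {
      fall_out(clus, l, lv)
      stack[[length(stack) + 1L]] <- c(r, clus)
    } else {
      fall_out(clus, l, lv); fall_out(clus, r, lv)
    }
  }

  # ---- excess-of-mass selection (root excluded) ----
  ncl <- length(cl_parent)
  selected <- logical(ncl); subtree_stab <- numeric(ncl)
  # children always created after parents: reverse order is bottom-up
  for (c in rev(seq_len(ncl))) {
    kids <- cl_children[[c]]
    if (length(kids) == 0) {
      selected[c] <- c != root_cl
      subtree_stab[c] <- cl_stab[c]
    } else {
      kid_sum <- sum(subtree_stab[kids])
      if (c != root_cl && cl_stab[c] > kid_sum) {
        selected[c] <- TRUE
        # deselect all descendants
        desc <- kids
        while (length(desc)) {
          selected[desc] <- FALSE
          desc <- unlist(cl_children[desc])
        }
        subtree_stab[c] <- cl_stab[c]
      } else {
        subtree_stab[c] <- kid_sum
      }
    }
  }

  # ---- labels: selected ancestor (incl. own) of the fallout cluster ----
  labels <- integer(n)
  sel_ids <- which(selected)
  relabel <- integer(ncl)
  relabel[sel_ids] <- seq_along(sel_ids)
  for (p in seq_len(n)) {
    c <- point_cluster[p]
    while (c > 0 && !selected[c]) c <- cl_parent[c]
    labels[p] <- if (c > 0) relabel[c] else 0L
  }
  list(labels = labels, n_clusters = length(sel_ids))
}
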