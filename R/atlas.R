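# ---- Step 3: ROI-constrained bundle selection and group comparison ----

#' ROI constraint for bundle selection
#'
#' @param name bundle name
#' @param include label ids the bundle must pass through (all of them)
#' @param exclude label ids the bundle must avoid entirely
#' @export
roi_constraint <- function(name, include, exclude = integer(0)) {
  if (length(intersect(include, exclude)))
    stop("include and exclude regions overlap")
  structure(list(name = name, include = as.integer(include),
                 exclude = as.integer(exclude)),
            class = "roi_constraint")
}

#' Select inter-subject clusters into a named bundle
#'
#' A cluster is selected when its centroid passes through every include
#' region (at least one point in each) and touches no exclude region.
#'
#' @param clusters inter-clusters (list with `members`, `subjects`)
#' @param cs the [centroid_set()] the clusters index into
#' @param roi a [roi_constraint()]
#' @param labels integer label volume in template space
#' @param voxel_size mm
#' @return a `bundle`: `name`, `clusters` (indices into `clusters`),
#'   `members`, `subjects`
#' @export
select_bundle <- function(clusters, cs, roi, labels, voxel_size) {
  cluster_labels <- function(cl) {
    unique(unlist(lapply(cs$points[cl$members], function(p)
      fiber_point_labels(p, labels, voxel_size))))
  }
  sel <- integer(0)
  for (ci in seq_along(clusters)) {
    labs <- cluster_labels(clusters[[ci]])
    if (all(roi$include %in% labs) && !any(roi$exclude %in% labs))
      sel <- c(sel, ci)
  }
  if (length(sel) == 0)
    warning(sprintf("bundle '%s': no cluster matched its ROI constraint", roi$name))
  members <- unlist(lapply(clusters[sel], `[[`, "members"))
  subjects <- unique(unlist(lapply(clusters[sel], `[[`, "subjects")))
  structure(list(name = roi$name, clusters = sel, members = members,
                 subjects = subjects),
            class = "bundle")
}

#' Assemble selected bundles into a population atlas
#'
#' @param bundles list of `bundle`s (unique names)
#' @return a `bundle_atlas`: `bundles` plus a manifest data.frame (name,
#'   n_clusters, n_members, n_subjects)
#' @export
assemble_atlas <- function(bundles) {
  nms <- vapply(bundles, `[[`, character(1), "name")
  if (anyDuplicated(nms)) stop("duplicate bundle names")
  manifest <- data.frame(
    name = nms,
    n_clusters = vapply(bundles, function(b) length(b$clusters), integer(1)),
    n_members = vapply(bundles, function(b) length(b$members), integer(1)),
    n_subjects = vapply(bundles, function(b) length(b$subjects), integer(1)),
    stringsAsFactors = FALSE)
  structure(list(bundles = bundles, manifest = manifest),
            class = "bundle_atlas")
}

#' @export
print.bundle_atlas <- function(x, ...) {
  cat(sprintf("bundle_atlas: %d bundles\n", nrow(x$manifest)))
  print(x$manifest)
  invisible(x)
}

#' Per-region fiber density of a subject
#'
#' Fibers per in-mask voxel in each region: the fiber count assigned to the
#' region divided by the region's in-mask voxel count.
#'
#' @param t a [tractogram()]
#' @param region_labels integer region array
#' @param mask logical array
#' @return named numeric vector (LH, RH, INT, CBL)
#' @export
region_fiber_density <- function(t, region_labels, mask) {
  part <- split_by_region(t, region_labels)
  vox <- vapply(names(region_codes), function(r)
    sum(region_labels[mask] == region_codes[[r]]), numeric(1))
  cnt <- vapply(part, length, numeric(1))
  ifelse(vox > 0, cnt / vox, NA_real_)
}

#' Compare fiber densities between two lines
#'
#' Welch two-sample t-test per region between the two groups (e.g. short
#' vs long tonic immobility lines), two-sided, flagged at `alpha`.
#'
#' @param densities matrix or data.frame, subjects in rows, regions in
#'   columns
#' @param lines factor/character of group labels per subject (2 levels)
#' @param alpha significance level (default 0.05)
#' @return data.frame: region, t, df, p, significant
#' @export
compare_lines <- function(densities, lines, alpha = 0.05) {
  densities <- as.matrix(densities)
  lines <- as.factor(lines)
  if (nlevels(lines) != 2) stop("exactly two lines required")
  g1 <- lines == levels(lines)[1]
  if (sum(g1) < 2 || sum(!g1) < 2) stop("each group needs >= 2 subjects")
  res <- lapply(seq_len(ncol(densities)), function(j) {
    x <- densities[g1, j]; y <- densities[!g1, j]
    if (stats::sd(x) == 0 && stats::sd(y) == 0 && mean(x) == mean(y))
      return(data.frame(t = 0, df = NA_real_, p = 1))
    tt <- stats::t.test(x, y, var.equal = FALSE)
    data.frame(t = unname(tt$statistic), df = unname(tt$parameter),
               p = tt$p.value)
  })
  out <- do.call(rbind, res)
  out <- cbind(region = colnames(densities) %||% as.character(seq_len(ncol(densities))),
               out)
  out$significant <- out$p < alpha
  rownames(out) <- NULL
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
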