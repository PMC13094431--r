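# Unsupervised spatial segmentation: bisecting k-means on pixel spectra
# under a correlation distance, plus cluster-vs-mask agreement scoring.

#' Correlation distance between two spectra
#'
#' `1 - Pearson correlation`, the scale-invariant spectral metric used for
#' segmentation. Zero-variance vectors are defined to be at distance 1 from
#' everything except an identical zero-variance vector (distance 0).
#'
#' @param u,v numeric vectors of equal length >= 2.
#' @return distance in \[0, 2\].
#' @export
correlation_distance <- function(u, v) {
  if (length(u) != length(v)) stop("length mismatch")
  stopifnot(length(u) >= 2)
  su <- stats::sd(u); sv <- stats::sd(v)
  if (su == 0 || sv == 0) {
    if (su == 0 && sv == 0 && all(u == v)) return(0)
    return(1)
  }
  1 - stats::cor(u, v)
}

# z-score the columns of a matrix (spectra); zero-variance columns -> 0,
# so their correlation with anything is 0 (distance 1), matching
# correlation_distance().
zscore_cols <- function(m) {
  mu <- colMeans(m)
  s <- sqrt(colSums((m - rep(mu, each = nrow(m)))^2) / (nrow(m) - 1))
  z <- (m - rep(mu, each = nrow(m))) / rep(ifelse(s == 0, Inf, s),
                                           each = nrow(m))
  z
}

# 2-means under correlation distance on z-scored spectra Z (features x
# pixels). Centroids are re-standardized every iteration so assignment by
# Euclidean distance on standardized vectors equals assignment by
# correlation distance. Returns assignment (1/2) and total dispersion.
two_means_correlation <- function(Z, init, max_iter = 100) {
  p <- ncol(Z); nf <- nrow(Z)
  cent <- Z[, init, drop = FALSE]
  assign_old <- rep(0L, p)
  for (it in seq_len(max_iter)) {
    corr <- crossprod(Z, cent) / (nf - 1)   # p x 2 Pearson correlations
    assignment <- max.col(corr, ties.method = "first")
    if (all(assignment == assign_old)) break
    assign_old <- assignment
    for (k in 1:2) {
      members <- which(assignment == k)
      if (length(members) == 0) next
      cm <- rowMeans(Z[, members, drop = FALSE])
      s <- stats::sd(cm)
      cent[, k] <- if (s == 0) 0 else (cm - mean(cm)) / s
    }
  }
  corr <- crossprod(Z, cent) / (nf - 1)
  assignment <- max.col(corr, ties.method = "first")
  d <- 1 - corr[cbind(seq_len(p), assignment)]
  list(assignment = assignment, dispersion = sum(d))
}

# Dispersion of one pixel set around its correlation-space centroid.
node_dispersion <- function(Z, members) {
  if (length(members) < 2) return(0)
  cm <- rowMeans(Z[, members, drop = FALSE])
  s <- stats::sd(cm)
  if (s == 0) return(sum(rep(1, length(members))))
  zc <- (cm - mean(cm)) / s
  sum(1 - crossprod(Z[, members, drop = FALSE], zc) / (nrow(Z) - 1))
}

#' Bisecting k-means segmentation
#'
#' Divisive clustering of pixel spectra: starting from all tissue pixels as
#' one leaf, repeatedly splits the leaf with the largest total
#' within-cluster dispersion by 2-means under the correlation distance
#' (best of `n_restarts` random centroid initializations), until `n_leaves`
#' leaves exist or no leaf can be split. Background pixels (TIC below
#' `background_frac` of the median pixel TIC) are excluded before
#' clustering and carry cluster id `NA`.
#'
#' @param table a TIC-normalized `feature_table`.
#' @param n_leaves target number of leaves (>= 2; default 8).
#' @param seed RNG seed for centroid initialization.
#' @param n_restarts random restarts per split (default 10).
#' @param background_frac background TIC threshold as a fraction of the
#'   median pixel TIC (default 0.05).
#' @return A `cluster_map`: per-pixel `cluster` ids (NA for background),
#'   `tree` (list of nodes with members, dispersion, children), `n_leaves`
#'   achieved, grid geometry.
#' @export
bisecting_kmeans <- function(table, n_leaves = 8, seed = 1,
                             n_restarts = 10, background_frac = 0.05) {
  stopifnot(inherits(table, "feature_table"), n_leaves >= 2)
  tic <- colSums(table$intensities)
  tissue <- which(tic > background_frac * stats::median(tic[tic > 0]))
  Z <- zscore_cols(table$intensities[, tissue, drop = FALSE])
  n <- length(tissue)
  tree <- list(list(id = 1L, members = seq_len(n), parent = NA_integer_,
                    children = NULL,
                    dispersion = node_dispersion(Z, seq_len(n))))
  leaves <- 1L
  with_local_seed(seed, {
    while (length(leaves) < n_leaves) {
      splittable <- leaves[vapply(leaves, function(i) {
        # dispersion 0 means all member spectra are perfectly correlated
        length(tree[[i]]$members) >= 2 && tree[[i]]$dispersion > 1e-12
      }, logical(1))]
      if (length(splittable) == 0) break
      target <- splittable[which.max(
        vapply(splittable, function(i) tree[[i]]$dispersion, numeric(1)))]
      members <- tree[[target]]$members
      Zm <- Z[, members, drop = FALSE]
      best <- NULL
      for (r in seq_len(n_restarts)) {
        init <- sample(length(members), 2)
        fit <- two_means_correlation(Zm, init)
        if (length(unique(fit$assignment)) < 2) next
        if (is.null(best) || fit$dispersion < best$dispersion) best <- fit
      }
      if (is.null(best)) {
        # no restart produced a genuine split; stop early
        break
      }
      for (k in 1:2) {
        child_members <- members[best$assignment == k]
        tree[[length(tree) + 1]] <- list(
          id = length(tree) + 1L, members = child_members,
          parent = tree[[target]]$id, children = NULL,
          dispersion = node_dispersion(Z, child_members))
      }
      kids <- c(length(tree) - 1L, length(tree))
      tree[[target]]$children <- kids
      leaves <- c(setdiff(leaves, target), kids)
    }
  })
  cluster <- rep(NA_integer_, ncol(table$intensities))
  for (j in seq_along(leaves))
    cluster[tissue[tree[[leaves[j]]]$members]] <- j
  structure(list(cluster = cluster, tree = tree,
                 leaf_nodes = leaves, n_leaves = length(leaves),
                 width = table$width, height = table$height,
                 tissue_pixels = tissue), class = "cluster_map")
}

#' @export
print.cluster_map <- function(x, ...) {
  cat("Cluster map: ", x$n_leaves, " leaves over ",
      length(x$tissue_pixels), " tissue pixels (",
      sum(is.na(x$cluster)), " background)\n", sep = "")
  invisible(x)
}

dice_coefficient <- function(a, b) {
  if (sum(a) + sum(b) == 0) return(NaN)
  2 * sum(a & b) / (sum(a) + sum(b))
}

#' Score cluster-vs-mask agreement
#'
#' Per leaf: the mask label maximizing the Dice coefficient, with Dice and
#' Jaccard reported; globally: the adjusted Rand index over tissue pixels
#' (background excluded on both sides).
#'
#' @param clusters a `cluster_map`.
#' @param mask a `tissue_mask` of matching dimensions.
#' @return An `overlap_report`: data.frame `per_leaf` (leaf, best_label,
#'   dice, jaccard, n_pixels) and scalar `ari`.
#' @export
score_overlap <- function(clusters, mask) {
  stopifnot(inherits(clusters, "cluster_map"), inherits(mask, "tissue_mask"))
  if (clusters$width != mask$width || clusters$height != mask$height)
    stop("dimension mismatch between cluster map and mask")
  tissue <- !is.na(clusters$cluster) & mask$labels != "background"
  labels <- setdiff(unique(mask$labels[tissue]), "background")
  per_leaf <- do.call(rbind, lapply(seq_len(clusters$n_leaves), function(k) {
    in_k <- clusters$cluster == k & tissue
    scores <- vapply(labels, function(l)
      dice_coefficient(in_k[tissue], (mask$labels == l)[tissue]), numeric(1))
    best <- which.max(scores)
    inter <- sum(in_k & mask$labels == labels[best])
    uni <- sum(in_k | (mask$labels == labels[best] & tissue))
    data.frame(leaf = k, best_label = labels[best], dice = scores[best],
               jaccard = inter / uni, n_pixels = sum(in_k))
  }))
  ari <- mclust::adjustedRandIndex(clusters$cluster[tissue],
                                   mask$labels[tissue])
  structure(list(per_leaf = per_leaf, ari = ari), class = "overlap_report")
}

#' @export
print.overlap_report <- function(x, ...) {
  cat("Cluster/mask overlap (ARI = ", sprintf("%.3f", x$ari), "):\n",
      sep = "")
  print(x$per_leaf, row.names = FALSE)
  invisible(x)
}

#' Select the adipose cluster
#'
#' Picks the leaf with the highest Dice coefficient against the adipose
#' mask label (ties: lower leaf id) and merges the remaining leaves into
#' one non-adipose pixel set, the contrast used for enrichment testing.
#' Background pixels are excluded from both sides.
#'
#' @param clusters a `cluster_map`.
#' @param mask a `tissue_mask`.
#' @return list with `adipose_leaf`, `adipose_pixels`, `nonadipose_pixels`
#'   (pixel indices) and the leaf's `dice`.
#' @export
select_adipose_cluster <- function(clusters, mask) {
  stopifnot(inherits(clusters, "cluster_map"))
  tissue <- !is.na(clusters$cluster) & mask$labels != "background"
  is_adipose <- (mask$labels == "adipose") & tissue
  if (!any(is_adipose)) stop("mask contains no adipose pixels")
  dices <- vapply(seq_len(clusters$n_leaves), function(k)
    dice_coefficient(clusters$cluster == k & tissue, is_adipose),
    numeric(1))
  if (all(dices == 0 | is.nan(dices)))
    stop("no cluster overlaps the adipose label (best Dice ",
         sprintf("%.3f", max(dices, na.rm = TRUE)), ")")
  leaf <- which.max(dices)   # which.max takes the first (lowest id) on ties
  adipose_pixels <- which(clusters$cluster == leaf & tissue)
  nonadipose_pixels <- which(!is.na(clusters$cluster) &
                             clusters$cluster != leaf & tissue)
  list(adipose_leaf = leaf, adipose_pixels = adipose_pixels,
       nonadipose_pixels = nonadipose_pixels, dice = dices[leaf])
}
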