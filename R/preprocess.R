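# Preprocessing chain: TIC normalization, baseline correction, feature
# picking, cross-replicate alignment, deisotoping and interday rescaling.

#' Feature table
#'
#' Aligned centroided features (rows) by pixels (columns) for one replicate,
#' the working container downstream of peak picking.
#'
#' @param replicate_id replicate identifier.
#' @param polarity ionization mode.
#' @param mz centroid m/z per feature, strictly increasing.
#' @param intensities features x pixels matrix, non-negative.
#' @param width,height pixel grid geometry carried over from the dataset.
#' @param feature_ids optional feature identifiers (default `F<mz>`).
#' @param removed_isotopologues bookkeeping data.frame from [deisotope()].
#' @return A `feature_table`.
#' @export
feature_table <- function(replicate_id, polarity, mz, intensities,
                          width, height, feature_ids = NULL,
                          removed_isotopologues = NULL) {
  intensities <- as.matrix(intensities)
  mz <- as.numeric(mz)
  if (length(mz) > 1 && any(diff(mz) <= 0))
    stop("feature centroids must be strictly increasing")
  if (nrow(intensities) != length(mz))
    stop("intensity matrix rows must match the feature list")
  if (any(intensities < 0)) stop("negative intensities")
  if (is.null(feature_ids))
    feature_ids <- sprintf("F%.4f", mz)
  structure(list(replicate_id = as.character(replicate_id),
                 polarity = polarity, mz = mz, intensities = intensities,
                 feature_ids = feature_ids,
                 width = as.integer(width), height = as.integer(height),
                 removed_isotopologues = removed_isotopologues),
            class = "feature_table")
}

#' @export
print.feature_table <- function(x, ...) {
  cat("Feature table '", x$replicate_id, "': ", length(x$mz),
      " features x ", ncol(x$intensities), " pixels (", x$polarity,
      " mode)\n", sep = "")
  invisible(x)
}

#' Total ion current normalization
#'
#' Scales every pixel spectrum so its summed intensity is 1. Pixels with
#' zero TIC are left untouched and recorded in
#' `metadata$zero_tic_pixels`.
#'
#' @param dataset an `msi_dataset`.
#' @return The normalized `msi_dataset` (idempotent).
#' @export
tic_normalize <- function(dataset) {
  validate_msi_dataset(dataset)
  tic <- rowSums(dataset$intensities)
  nz <- tic > 0
  dataset$intensities[nz, ] <- dataset$intensities[nz, , drop = FALSE] / tic[nz]
  dataset$metadata$tic_normalized <- TRUE
  dataset$metadata$zero_tic_pixels <- which(!nz)
  dataset
}

# Rolling minimum of y over an m/z window (Da) centered on each axis point.
rolling_min_baseline <- function(mz, y, window_da) {
  n <- length(mz)
  half <- window_da / 2
  lo <- findInterval(mz - half, mz) + 1L
  lo <- pmax(lo, 1L)
  # findInterval gives the last index <= bound; adjust for exact hits
  lo <- vapply(seq_len(n), function(i) {
    j <- lo[i]
    while (j > 1 && mz[j - 1] >= mz[i] - half) j <- j - 1L
    j
  }, integer(1))
  hi <- findInterval(mz + half, mz)
  vapply(seq_len(n), function(i) min(y[lo[i]:hi[i]]), numeric(1))
}

#' Baseline correction by rolling minimum
#'
#' Per pixel, subtracts a rolling-minimum baseline estimated over a sliding
#' m/z window and clips at zero. When the window exceeds the full axis span
#' the baseline degenerates to the global per-pixel minimum.
#'
#' @param dataset an `msi_dataset`.
#' @param window_da window width in Da (default 5).
#' @return The corrected `msi_dataset`.
#' @export
baseline_correct <- function(dataset, window_da = 5) {
  validate_msi_dataset(dataset)
  stopifnot(window_da > 0)
  span <- diff(range(dataset$mz_axis))
  if (length(dataset$mz_axis) < 2 || window_da >= span) {
    base <- apply(dataset$intensities, 1, min)
    dataset$intensities <- pmax(dataset$intensities - base, 0)
    return(dataset)
  }
  mz <- dataset$mz_axis
  dataset$intensities <- t(apply(dataset$intensities, 1, function(y)
    pmax(y - rolling_min_baseline(mz, y, window_da), 0)))
  dataset
}

#' Pick features from the mean spectrum
#'
#' Features are local maxima of the mean (across pixels) spectrum: an axis
#' point beats every neighbor within `adjacency_da`; isolated centroids (no
#' neighbor that close) are peaks by themselves. Peaks below
#' `min_rel_intensity` of the strongest mean signal are dropped, the rest
#' ranked by mean intensity and truncated to `top_n`; per-pixel intensities
#' are sampled at the centroid bin.
#'
#' @param dataset a TIC-normalized `msi_dataset`.
#' @param min_rel_intensity minimum mean intensity as a fraction of the
#'   maximum mean intensity (default 0.001).
#' @param top_n maximum number of features to keep (default 200, the
#'   working depth of the published negative-mode analysis).
#' @param adjacency_da spacing under which neighboring axis points compete
#'   as one profile (default 0.02 Da).
#' @return A `feature_table` (possibly with zero features).
#' @export
pick_features <- function(dataset, min_rel_intensity = 0.001, top_n = 200,
                          adjacency_da = 0.02) {
  validate_msi_dataset(dataset)
  mz <- dataset$mz_axis
  avg <- colMeans(dataset$intensities)
  n <- length(mz)
  is_peak <- vapply(seq_len(n), function(i) {
    if (avg[i] <= 0) return(FALSE)
    left_ok <- i == 1 || mz[i] - mz[i - 1] > adjacency_da ||
      avg[i] > avg[i - 1]
    right_ok <- i == n || mz[i + 1] - mz[i] > adjacency_da ||
      avg[i] > avg[i + 1]
    left_ok && right_ok
  }, logical(1))
  is_peak <- is_peak & avg >= min_rel_intensity * max(avg, 0)
  idx <- which(is_peak)
  if (length(idx) > top_n)
    idx <- sort(idx[order(avg[idx], decreasing = TRUE)[seq_len(top_n)]])
  feature_table(dataset$replicate_id, dataset$polarity, mz[idx],
                t(dataset$intensities[, idx, drop = FALSE]),
                width = dataset$width, height = dataset$height)
}

#' Align features across replicates
#'
#' Greedy nearest-neighbor grouping of centroids across replicate feature
#' tables, seeded from the most intense remaining feature downward (which
#' makes the result independent of input table order; ties broken toward
#' lower m/z). Each consensus feature takes at most one member per
#' replicate, within `tol_da` of the seed centroid.
#'
#' @param tables list of `feature_table`s of one polarity.
#' @param tol_da matching tolerance in Da (default 0.02).
#' @return An `aligned_features` object: data.frame `consensus` with
#'   `avg_mz`, `ppm_deviation` (max pairwise deviation), `n_replicates`,
#'   and member row indices per replicate (`idx_<replicate_id>`), plus the
#'   input tables.
#' @export
align_features <- function(tables, tol_da = 0.02) {
  stopifnot(length(tables) >= 1, tol_da > 0)
  pol <- unique(vapply(tables, `[[`, character(1), "polarity"))
  if (length(pol) != 1) stop("mixed polarity feature tables")
  reps <- vapply(tables, `[[`, character(1), "replicate_id")
  if (anyDuplicated(reps)) stop("duplicate replicate ids")
  pool <- do.call(rbind, lapply(seq_along(tables), function(k)
    data.frame(rep = k, idx = seq_along(tables[[k]]$mz),
               mz = tables[[k]]$mz,
               mean_int = rowMeans(tables[[k]]$intensities))))
  pool <- pool[order(-pool$mean_int, pool$mz), ]
  taken <- rep(FALSE, nrow(pool))
  groups <- list()
  for (i in seq_len(nrow(pool))) {
    if (taken[i]) next
    seed <- pool[i, ]
    member <- integer(length(tables))
    member[seed$rep] <- seed$idx
    taken[i] <- TRUE
    for (k in seq_along(tables)) {
      if (k == seed$rep) next
      cand <- which(!taken & pool$rep == k &
                    abs(pool$mz - seed$mz) <= tol_da)
      if (length(cand) == 0) next
      best <- cand[order(abs(pool$mz[cand] - seed$mz), pool$mz[cand])][1]
      member[k] <- pool$idx[best]
      taken[best] <- TRUE
    }
    mzs <- vapply(which(member > 0), function(k)
      tables[[k]]$mz[member[k]], numeric(1))
    avg <- mean(mzs)
    ppm <- if (length(mzs) > 1) max(dist(mzs)) / avg * 1e6 else 0
    groups[[length(groups) + 1]] <- list(avg_mz = avg, ppm = ppm,
                                         member = member)
  }
  consensus <- data.frame(
    avg_mz = vapply(groups, `[[`, numeric(1), "avg_mz"),
    ppm_deviation = vapply(groups, `[[`, numeric(1), "ppm"),
    n_replicates = vapply(groups, function(g) sum(g$member > 0), integer(1)))
  for (k in seq_along(tables))
    consensus[[paste0("idx_", reps[k])]] <-
      vapply(groups, function(g) g$member[k], integer(1))
  ord <- order(consensus$avg_mz)
  consensus <- consensus[ord, , drop = FALSE]
  rownames(consensus) <- NULL
  structure(list(consensus = consensus, replicate_ids = reps,
                 polarity = pol, tables = tables, tol_da = tol_da),
            class = "aligned_features")
}

#' @export
print.aligned_features <- function(x, ...) {
  full <- sum(x$consensus$n_replicates == length(x$replicate_ids))
  cat("Aligned features: ", nrow(x$consensus), " consensus features over ",
      length(x$replicate_ids), " replicates (", full,
      " covering all replicates)\n", sep = "")
  invisible(x)
}

#' Remove isotopologue satellites
#'
#' Drops feature B when a feature A sits `delta_da` (within `tol_da`) below
#' it with a larger mean intensity - the M+1 satellite pattern. Removed
#' features are recorded with their parent in
#' `removed_isotopologues`.
#'
#' @param table a `feature_table` (sorted by m/z, as constructed).
#' @param delta_da isotopologue spacing (default 1.00336 Da).
#' @param tol_da spacing tolerance (default 0.01 Da).
#' @return The deisotoped `feature_table`.
#' @export
deisotope <- function(table, delta_da = 1.00336, tol_da = 0.01) {
  stopifnot(inherits(table, "feature_table"))
  mz <- table$mz
  mean_int <- rowMeans(table$intensities)
  removed <- logical(length(mz))
  parent <- integer(0); child <- integer(0)
  for (b in seq_along(mz)) {
    a <- which(abs((mz[b] - mz) - delta_da) <= tol_da &
               mean_int > mean_int[b])
    if (length(a) > 0) {
      removed[b] <- TRUE
      parent <- c(parent, a[which.max(mean_int[a])])
      child <- c(child, b)
    }
  }
  if (!any(removed)) return(table)
  log <- data.frame(removed_mz = mz[child], parent_mz = mz[parent],
                    removed_id = table$feature_ids[child],
                    parent_id = table$feature_ids[parent])
  feature_table(table$replicate_id, table$polarity, mz[!removed],
                table$intensities[!removed, , drop = FALSE],
                width = table$width, height = table$height,
                feature_ids = table$feature_ids[!removed],
                removed_isotopologues = log)
}

#' Interday intensity rescaling
#'
#' Matches a target replicate's absolute intensity scale to a reference by
#' the ratio of mean TIC over matched regions of interest, the
#' source-realignment drift correction applied between acquisition days.
#'
#' @param reference,target `feature_table`s.
#' @param reference_roi,target_roi pixel index vectors of matched ROIs
#'   (same tissue, same size).
#' @return list with `scale` and the rescaled `target` table.
#' @export
interday_rescale <- function(reference, target, reference_roi, target_roi) {
  stopifnot(inherits(reference, "feature_table"),
            inherits(target, "feature_table"),
            length(reference_roi) == length(target_roi))
  ref_tic <- mean(colSums(reference$intensities[, reference_roi,
                                                drop = FALSE]))
  tgt_tic <- mean(colSums(target$intensities[, target_roi, drop = FALSE]))
  if (tgt_tic == 0) stop("zero TIC in target ROI")
  scale <- ref_tic / tgt_tic
  target$intensities <- target$intensities * scale
  list(scale = scale, target = target)
}
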