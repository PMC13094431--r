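# Two-tier adipose-enrichment selection: per-replicate FDR-filtered Welch
# tests (tier 1), then replicate-level ROC AUC thresholding (tier 2), and
# the summary statistics of the adipose-lipid report.

#' Rank-based ROC AUC
#'
#' Area under the receiver operating characteristic curve with the adipose
#' group as positive class, computed from ranks (Mann-Whitney form): ties
#' contribute half a win, so AUC = (wins + 0.5 ties) / (n1 * n2).
#'
#' @param adipose,nonadipose numeric vectors (non-empty).
#' @return AUC in \[0, 1\].
#' @export
roc_auc <- function(adipose, nonadipose) {
  n1 <- length(adipose); n2 <- length(nonadipose)
  if (n1 == 0 || n2 == 0) stop("empty group")
  r <- rank(c(adipose, nonadipose))
  (sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2) / (n1 * n2)
}

# Per-row AUC for features x pixels matrices of the two groups.
auc_many <- function(a, b) {
  n1 <- ncol(a); n2 <- ncol(b)
  vapply(seq_len(nrow(a)), function(i) {
    r <- rank(c(a[i, ], b[i, ]))
    (sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2) / (n1 * n2)
  }, numeric(1))
}

# Matrix of per-replicate intensities for the consensus features of an
# aligned_features object: rows = consensus features, NA-padded where a
# replicate lacks the feature. Returns list of per-replicate matrices
# subset to the given pixels.
consensus_intensities <- function(aligned, replicate, pixels) {
  k <- match(replicate, aligned$replicate_ids)
  idx <- aligned$consensus[[paste0("idx_", replicate)]]
  out <- matrix(NA_real_, nrow = nrow(aligned$consensus),
                ncol = length(pixels))
  has <- idx > 0
  out[has, ] <- aligned$tables[[k]]$intensities[idx[has], pixels,
                                                drop = FALSE]
  out
}

#' Tier-1 enrichment filter
#'
#' Per replicate and consensus feature, a Welch t-test of adipose versus
#' merged non-adipose pixel intensities, Benjamini-Hochberg adjusted within
#' the replicate's feature family. A feature is a candidate when it is
#' significant (q < `alpha`) with the adipose mean above the non-adipose
#' mean in at least one replicate (enrichment is one-directional).
#'
#' @param aligned an `aligned_features` object.
#' @param partitions list (one per replicate, in `aligned$replicate_ids`
#'   order) with `adipose_pixels` and `nonadipose_pixels` index vectors
#'   (e.g. from [select_adipose_cluster()]).
#' @param alpha FDR level (default 0.05).
#' @return list with matrices `p`, `q`, `mean_adipose`, `mean_nonadipose`
#'   (consensus features x replicates) and logical `candidate`.
#' @export
tier1_filter <- function(aligned, partitions, alpha = 0.05) {
  stopifnot(inherits(aligned, "aligned_features"),
            length(partitions) == length(aligned$replicate_ids))
  reps <- aligned$replicate_ids
  nf <- nrow(aligned$consensus)
  p <- q <- ma <- mn <- matrix(NA_real_, nf, length(reps),
                               dimnames = list(NULL, reps))
  for (k in seq_along(reps)) {
    part <- partitions[[k]]
    if (length(part$adipose_pixels) < 2 ||
        length(part$nonadipose_pixels) < 2)
      stop("degenerate partition in replicate ", reps[k])
    A <- consensus_intensities(aligned, reps[k], part$adipose_pixels)
    B <- consensus_intensities(aligned, reps[k], part$nonadipose_pixels)
    has <- !is.na(A[, 1])
    w <- welch_many(A[has, , drop = FALSE], B[has, , drop = FALSE])
    p[has, k] <- w$p
    q[has, k] <- bh_adjust(w$p)
    ma[has, k] <- w$mean_a
    mn[has, k] <- w$mean_b
  }
  candidate <- rowSums(q < alpha & ma > mn, na.rm = TRUE) >= 1
  list(p = p, q = q, mean_adipose = ma, mean_nonadipose = mn,
       candidate = candidate, alpha = alpha)
}

#' Tier-2 ROC filter and enrichment results
#'
#' Computes the per-replicate ROC AUC (adipose positive) for every
#' consensus feature and applies the replicate-consistency rule: a feature
#' passes tier 2 when its AUC exceeds `auc_threshold` in at least
#' `ceiling(replicate_fraction * n_replicates)` replicates. A feature is
#' adipose-enriched when it passes both tiers.
#'
#' @param aligned an `aligned_features` object.
#' @param partitions as in [tier1_filter()].
#' @param tier1 output of [tier1_filter()].
#' @param auc_threshold AUC cutoff (default 0.7).
#' @param replicate_fraction required fraction of replicates (default 0.5).
#' @return An `enrichment_result` data.frame: `avg_mz`, `polarity`,
#'   per-replicate `p_`/`q_`/`auc_` columns, `pass_tier1`, `pass_tier2`,
#'   `enriched`, `avg_intensity_adipose`, `avg_intensity_nonadipose`,
#'   `avg_fold_change`, `avg_auc`.
#' @export
tier2_roc <- function(aligned, partitions, tier1, auc_threshold = 0.7,
                      replicate_fraction = 0.5) {
  reps <- aligned$replicate_ids
  nf <- nrow(aligned$consensus)
  auc <- matrix(NA_real_, nf, length(reps), dimnames = list(NULL, reps))
  for (k in seq_along(reps)) {
    part <- partitions[[k]]
    A <- consensus_intensities(aligned, reps[k], part$adipose_pixels)
    B <- consensus_intensities(aligned, reps[k], part$nonadipose_pixels)
    has <- !is.na(A[, 1])
    auc[has, k] <- auc_many(A[has, , drop = FALSE], B[has, , drop = FALSE])
  }
  need <- ceiling(replicate_fraction * length(reps))
  pass_tier2 <- rowSums(auc > auc_threshold, na.rm = TRUE) >= need
  out <- data.frame(avg_mz = aligned$consensus$avg_mz,
                    polarity = aligned$polarity,
                    ppm_deviation = aligned$consensus$ppm_deviation)
  for (k in seq_along(reps)) {
    out[[paste0("p_", reps[k])]] <- tier1$p[, k]
    out[[paste0("q_", reps[k])]] <- tier1$q[, k]
    out[[paste0("auc_", reps[k])]] <- auc[, k]
  }
  out$pass_tier1 <- tier1$candidate
  out$pass_tier2 <- pass_tier2
  out$enriched <- out$pass_tier1 & out$pass_tier2
  out$avg_intensity_adipose <- rowMeans(tier1$mean_adipose, na.rm = TRUE)
  out$avg_intensity_nonadipose <- rowMeans(tier1$mean_nonadipose,
                                           na.rm = TRUE)
  out$avg_fold_change <- out$avg_intensity_adipose /
    out$avg_intensity_nonadipose
  out$avg_auc <- rowMeans(auc, na.rm = TRUE)
  class(out) <- c("enrichment_result", "data.frame")
  out
}

#' Run both enrichment tiers
#'
#' Convenience wrapper: [tier1_filter()] followed by [tier2_roc()].
#'
#' @inheritParams tier1_filter
#' @inheritParams tier2_roc
#' @return An `enrichment_result` (see [tier2_roc()]).
#' @export
enrichment_analysis <- function(aligned, partitions, alpha = 0.05,
                                auc_threshold = 0.7,
                                replicate_fraction = 0.5) {
  t1 <- tier1_filter(aligned, partitions, alpha = alpha)
  tier2_roc(aligned, partitions, t1, auc_threshold = auc_threshold,
            replicate_fraction = replicate_fraction)
}

#' Summarize enrichment results in report form
#'
#' Per-feature cross-replicate averages in the layout of the published
#' adipose-lipid table: average adipose and non-adipose intensity (mean of
#' per-replicate means), fold change as the ratio of the averages, and
#' average AUC, the latter two rounded to 2 decimals for reporting. With
#' `from_printed = TRUE` the fold change is recomputed from
#' printed-precision (3 significant digits) intensity averages, matching
#' how the published table's columns relate.
#'
#' @param result an `enrichment_result` (or data.frame with
#'   `avg_intensity_adipose` / `avg_intensity_nonadipose` / `avg_auc`).
#' @param enriched_only keep only features passing both tiers
#'   (default TRUE when the column is present).
#' @param from_printed round intensities to 3 significant digits before
#'   taking the ratio (default FALSE).
#' @return data.frame with `avg_mz` (when present), intensities, the
#'   rounded `avg_fold_change` and `avg_auc`.
#' @export
summarize_enrichment <- function(result, enriched_only = TRUE,
                                 from_printed = FALSE) {
  df <- as.data.frame(result)
  if (enriched_only && "enriched" %in% names(df))
    df <- df[df$enriched, , drop = FALSE]
  ia <- df$avg_intensity_adipose
  ib <- df$avg_intensity_nonadipose
  if (from_printed) {
    ia <- signif(ia, 3)
    ib <- signif(ib, 3)
  }
  out <- data.frame(avg_intensity_adipose = ia,
                    avg_intensity_nonadipose = ib,
                    avg_fold_change = round(ia / ib, 2))
  if ("avg_mz" %in% names(df)) out <- cbind(avg_mz = df$avg_mz, out)
  if ("avg_auc" %in% names(df)) out$avg_auc <- round(df$avg_auc, 2)
  rownames(out) <- NULL
  out
}
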