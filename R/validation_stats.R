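# Technical-validation statistics: ROI selection, CV summaries, ANOVA,
# Welch t-tests and Benjamini-Hochberg adjustment.

#' Select regions of interest
#'
#' Samples `n_rois` disjoint 3x3 pixel blocks lying fully inside one tissue
#' label (the 150 um x 150 um ROI aggregation unit at 50 um pixels).
#' Sampling is uniform over feasible block positions and deterministic per
#' seed.
#'
#' @param mask a `tissue_mask`.
#' @param label tissue label to sample within.
#' @param n_rois number of ROIs.
#' @param seed RNG seed.
#' @return list of ROIs; each has `label`, `pixels` (9 row-major pixel
#'   indices) and `center` (x, y).
#' @export
select_rois <- function(mask, label, n_rois, seed = 1) {
  stopifnot(inherits(mask, "tissue_mask"), n_rois >= 1)
  w <- mask$width; h <- mask$height
  lab <- matrix(mask$labels == label, nrow = h, ncol = w, byrow = TRUE)
  centers <- which(vapply(seq_len(w * h), function(px) {
    x <- (px - 1) %% w + 1; y <- (px - 1) %/% w + 1
    if (x < 2 || x > w - 1 || y < 2 || y > h - 1) return(FALSE)
    all(lab[(y - 1):(y + 1), (x - 1):(x + 1)])
  }, logical(1)))
  block_pixels <- function(px) {
    x <- (px - 1) %% w + 1; y <- (px - 1) %/% w + 1
    as.vector(outer((x - 1):(x + 1), (y - 2):y * w, `+`))
  }
  chosen <- with_local_seed(seed, {
    picked <- integer(0)
    used <- logical(w * h)
    for (cand in centers[sample.int(length(centers))]) {
      bp <- block_pixels(cand)
      if (any(used[bp])) next
      used[bp] <- TRUE
      picked <- c(picked, cand)
      if (length(picked) == n_rois) break
    }
    picked
  })
  if (length(chosen) < n_rois)
    stop("region too small: only ", length(chosen),
         " disjoint 3x3 block(s) of '", label, "' available, need ", n_rois)
  lapply(chosen, function(px) {
    x <- (px - 1) %% w + 1; y <- (px - 1) %/% w + 1
    list(label = label, pixels = sort(block_pixels(px)),
         center = c(x = x - 1, y = y - 1))
  })
}

#' Coefficient of variation in percent
#'
#' @param values numeric vector (n >= 2, positive mean).
#' @return `100 * sd(values) / mean(values)` (sample SD, n-1 denominator).
#' @export
cv_percent <- function(values) {
  if (length(values) < 2) stop("need at least 2 values")
  m <- mean(values)
  if (m <= 0) stop("mean must be positive")
  100 * stats::sd(values) / m
}

#' Per-feature CV summary over ROIs
#'
#' For every feature, the CV across ROI-mean intensities of one tissue, and
#' the fractions of features under the conventional 20% and 25%
#' reproducibility cutoffs.
#'
#' @param table a `feature_table`.
#' @param rois list of ROIs sharing one tissue label
#'   (see [select_rois()]).
#' @return list with `cv` (per-feature CV, %), `fraction_below_20`,
#'   `fraction_below_25`, `label`.
#' @export
cv_summary <- function(table, rois) {
  stopifnot(inherits(table, "feature_table"))
  if (length(rois) < 2) stop("need at least 2 ROIs")
  labels <- unique(vapply(rois, `[[`, character(1), "label"))
  if (length(labels) != 1) stop("ROIs must share one tissue label")
  roi_means <- matrix(vapply(rois, function(r)
    rowMeans(table$intensities[, r$pixels, drop = FALSE]),
    numeric(length(table$mz))), nrow = length(table$mz))
  cv <- apply(roi_means, 1, function(v)
    if (mean(v) > 0) cv_percent(v) else NA_real_)
  list(cv = stats::setNames(cv, table$feature_ids),
       fraction_below_20 = mean(cv < 20, na.rm = TRUE),
       fraction_below_25 = mean(cv < 25, na.rm = TRUE),
       label = labels)
}

#' One-way ANOVA
#'
#' Standard fixed-effects one-way analysis of variance (between/within mean
#' squares with k-1 and N-k degrees of freedom), e.g. for TIC variation
#' between tissues.
#'
#' @param groups list of numeric vectors (>= 2 groups, each n >= 2).
#' @return list with `F`, `p`, `df`.
#' @export
one_way_anova <- function(groups) {
  stopifnot(length(groups) >= 2, all(lengths(groups) >= 2))
  values <- unlist(groups)
  g <- factor(rep(seq_along(groups), lengths(groups)))
  if (stats::var(values) == 0)
    stop("zero between-group and within-group variance: F undefined")
  fit <- stats::anova(stats::aov(values ~ g))
  list(F = fit$`F value`[1], p = fit$`Pr(>F)`[1],
       df = c(fit$Df[1], fit$Df[2]))
}

#' Two-way ANOVA with interaction
#'
#' Balanced fixed-effects two-way analysis of variance, e.g. tissue type x
#' lipid with replicate ROI values per cell.
#'
#' @param values numeric vector of replicate observations.
#' @param factor_a,factor_b factors of the same length as `values` (e.g.
#'   tissue and lipid). The design must be balanced.
#' @return data.frame with one row per term (`a`, `b`, `a:b`): `F`, `p`.
#' @export
two_way_anova <- function(values, factor_a, factor_b) {
  factor_a <- factor(factor_a); factor_b <- factor(factor_b)
  stopifnot(length(values) == length(factor_a),
            length(values) == length(factor_b),
            nlevels(factor_a) >= 2, nlevels(factor_b) >= 2)
  cell_n <- table(factor_a, factor_b)
  if (length(unique(as.vector(cell_n))) != 1 || any(cell_n < 2))
    stop("unbalanced design: equal replicates per cell required")
  if (stats::var(values) == 0)   # all cells identical: no effects anywhere
    return(data.frame(term = c("a", "b", "a:b"), F = 0, p = 1))
  fit <- suppressWarnings(
    stats::anova(stats::aov(values ~ factor_a * factor_b)))
  out <- data.frame(term = c("a", "b", "a:b"),
                    F = fit$`F value`[1:3], p = fit$`Pr(>F)`[1:3])
  out$F[is.na(out$F)] <- 0
  out$p[is.na(out$p)] <- 1
  out
}

# Vectorized Welch t-test over feature rows: a, b are features x pixels
# matrices of the two groups. Returns t, df, p (two-sided).
welch_many <- function(a, b) {
  n1 <- ncol(a); n2 <- ncol(b)
  m1 <- rowMeans(a); m2 <- rowMeans(b)
  v1 <- rowSums((a - m1)^2) / (n1 - 1)
  v2 <- rowSums((b - m2)^2) / (n2 - 1)
  se2 <- v1 / n1 + v2 / n2
  t <- (m1 - m2) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  p <- 2 * stats::pt(-abs(t), df)
  # both groups constant and equal: no evidence against the null
  degenerate <- se2 == 0
  t[degenerate & m1 == m2] <- 0
  p[degenerate & m1 == m2] <- 1
  list(t = t, df = df, p = p, mean_a = m1, mean_b = m2)
}

#' Welch's unequal-variance t-test
#'
#' Welch statistic with Satterthwaite degrees of freedom and two-sided p,
#' the unpaired-comparison test of the pipeline. A pooled-variance variant
#' is available via `pooled = TRUE`.
#'
#' @param a,b numeric vectors (each n >= 2).
#' @param pooled use the pooled-variance (Student) form instead.
#' @return list with `t`, `df`, `p`.
#' @export
welch_t_test <- function(a, b, pooled = FALSE) {
  stopifnot(length(a) >= 2, length(b) >= 2)
  if (pooled) {
    if (stats::var(a) == 0 && stats::var(b) == 0) {
      if (mean(a) == mean(b)) return(list(t = 0, df = length(a) +
                                            length(b) - 2, p = 1))
    }
    ht <- stats::t.test(a, b, var.equal = TRUE)
    return(list(t = unname(ht$statistic), df = unname(ht$parameter),
                p = ht$p.value))
  }
  r <- welch_many(matrix(a, nrow = 1), matrix(b, nrow = 1))
  list(t = r$t, df = r$df, p = r$p)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjusted p-values (capped at 1,
#' order-preserving).
#'
#' @param pvals numeric vector of p-values in \[0, 1\].
#' @return adjusted q-values.
#' @export
bh_adjust <- function(pvals) {
  if (any(pvals < 0 | pvals > 1, na.rm = TRUE))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(pvals, method = "BH")
}
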