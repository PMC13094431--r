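# Independent oracles and shared fixtures for the suite.

# Brute-force ROC AUC by pair enumeration (wins + half ties).
auc_brute <- function(a, b) {
  s <- 0
  for (x in a) for (y in b) s <- s + (x > y) + 0.5 * (x == y)
  s / (length(a) * length(b))
}

# Step-up BH adjustment written directly from the definition.
bh_brute <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- numeric(m)
  prev <- 1
  for (i in m:1) {
    prev <- min(prev, p[o[i]] * m / i)
    q[o[i]] <- prev
  }
  q
}

# Match consensus features of an enrichment result back to planted panel
# features by nearest m/z; returns planted ids (NA where unmatched).
match_to_truth <- function(avg_mz, truth, tol = 0.01) {
  vapply(avg_mz, function(m) {
    d <- abs(truth$feature_mz - m)
    i <- which.min(d)
    if (d[i] < tol) truth$panel$feature_id[i] else NA_character_
  }, character(1))
}

# Sensitivity/specificity of an enrichment result against phantom truth.
recovery_rates <- function(enrichment, truth) {
  planted <- match_to_truth(enrichment$avg_mz, truth)
  detected <- planted[enrichment$enriched & !is.na(planted)]
  list(sensitivity = mean(truth$enriched_ids %in% detected),
       specificity = mean(!(truth$null_ids %in% detected)))
}

# Mask-based adipose/non-adipose pixel partition (bypasses segmentation
# where only the statistical tiers are under test).
mask_partitions <- function(mask, n_replicates) {
  part <- list(adipose_pixels = which(mask$labels == "adipose"),
               nonadipose_pixels = which(!mask$labels %in%
                                           c("adipose", "background")))
  rep(list(part), n_replicates)
}

# Preprocess phantom replicates to an aligned feature set.
phantom_aligned <- function(sim, top_n = 2000) {
  tabs <- lapply(sim$datasets, function(d)
    deisotope(pick_features(tic_normalize(d), top_n = top_n)))
  align_features(tabs)
}
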