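# Correlation distance, bisecting k-means, and cluster-mask overlap.

test_that("correlation distance matches hand-computed Pearson values", {
  u <- c(1, 2, 3, 4)
  expect_equal(correlation_distance(u, u), 0)
  expect_equal(correlation_distance(u, -u + 10), 2)
  expect_equal(correlation_distance(u, c(1, 3, 2, 4)), 0.2)  # r = 0.8
  # zero-variance conventions
  z <- rep(5, 4)
  expect_equal(correlation_distance(z, z), 0)
  expect_equal(correlation_distance(z, u), 1)
  expect_equal(correlation_distance(z, rep(7, 4)), 1)
  expect_error(correlation_distance(u, c(1, 2)), "length mismatch")
})

two_signature_table <- function(n_per = 50, seed = 2) {
  # two blocks of pixels with orthogonal spectral signatures plus noise
  old <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  sig1 <- c(10, 1, 8, 1, 6, 1)
  sig2 <- c(1, 9, 1, 7, 1, 5)
  ints <- cbind(
    matrix(rep(sig1, n_per), 6) * matrix(rlnorm(6 * n_per, 0, 0.1), 6),
    matrix(rep(sig2, n_per), 6) * matrix(rlnorm(6 * n_per, 0, 0.1), 6))
  list(table = feature_table("two", "negative",
                             mz = seq(200, 700, length.out = 6),
                             ints, width = 2 * n_per, height = 1),
       mask = tissue_mask(matrix(rep(c("muscle", "adipose"),
                                     each = n_per), 1)))
}

test_that("two well-separated signatures are recovered exactly (ARI = 1)", {
  fx <- two_signature_table()
  cm <- bisecting_kmeans(fx$table, n_leaves = 2, seed = 1)
  expect_identical(cm$n_leaves, 2L)
  rep_ <- score_overlap(cm, fx$mask)
  expect_equal(rep_$ari, 1.0)
  expect_true(all(rep_$per_leaf$dice == 1.0))
})

test_that("identical spectra cannot be split: single leaf, early stop", {
  ints <- matrix(rep(c(5, 1, 3), 40), 3)
  tab <- feature_table("const", "negative", c(200, 300, 400), ints,
                       width = 40, height = 1)
  cm <- bisecting_kmeans(tab, n_leaves = 4, seed = 1)
  expect_identical(cm$n_leaves, 1L)
})

test_that("bisection is deterministic and dispersion-monotone", {
  sim <- simulate_dataset(phantom_spec(seed = 2, n_replicates = 1))
  tab <- pick_features(tic_normalize(sim$datasets[[1]]), top_n = 200)
  cm1 <- bisecting_kmeans(tab, n_leaves = 6, seed = 3)
  cm2 <- bisecting_kmeans(tab, n_leaves = 6, seed = 3)
  expect_identical(cm1$cluster, cm2$cluster)
  # every child's dispersion is bounded by its parent's
  for (node in cm1$tree) {
    if (is.null(node$children)) next
    for (ch in node$children)
      expect_lte(cm1$tree[[ch]]$dispersion, node$dispersion + 1e-9)
  }
})

test_that("segmentation accuracy increases with signature separation", {
  ari_at <- function(contrast) {
    panel <- default_lipid_panel()
    # shrink marker contrast toward 1 to blur the tissue signatures
    mcols <- c(paste0("mult_", c("muscle", "liver", "brain", "eye", "gill")),
               "mult_adipose")
    for (cc in mcols) panel[[cc]] <- 1 + contrast * (panel[[cc]] - 1)
    sim <- simulate_dataset(phantom_spec(seed = 4, panel = panel,
                                         n_replicates = 1))
    tab <- pick_features(tic_normalize(sim$datasets[[1]]), top_n = 200)
    cm <- bisecting_kmeans(tab, n_leaves = 8, seed = 1)
    score_overlap(cm, sim$truth$mask)$ari
  }
  aris <- vapply(c(0.1, 0.5, 1.0), ari_at, numeric(1))
  expect_true(all(diff(aris) >= -1e-9))
  expect_gt(aris[3], aris[1])
})

test_that("overlap scoring: identity, half-split Dice and permutation null", {
  fx <- two_signature_table()
  cm <- bisecting_kmeans(fx$table, n_leaves = 2, seed = 1)
  # one cluster covering everything vs an equal two-label mask: Dice 2/3
  one <- cm
  one$cluster[] <- 1L
  one$n_leaves <- 1L
  rep1 <- score_overlap(one, fx$mask)
  expect_equal(rep1$per_leaf$dice, 2 / 3)
  expect_error(score_overlap(cm, tissue_mask(matrix("muscle", 3, 3))),
               "dimension mismatch")
  # random label permutation of a large mask: |ARI| ~ 0
  old <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(99)
  n <- 1600
  big <- bisecting_kmeans(feature_table("big", "negative",
    mz = seq(200, 500, length.out = 4),
    matrix(rlnorm(4 * n, 0, 0.5), 4) +
      rbind(rep(c(5, 0), each = n / 2), rep(c(0, 5), each = n / 2), 1, 1),
    width = n, height = 1), n_leaves = 2, seed = 1)
  perm <- tissue_mask(matrix(sample(rep(c("muscle", "liver", "adipose"),
                                        length.out = n)), 1))
  expect_lt(abs(score_overlap(big, perm)$ari), 0.05)
})

test_that("adipose cluster selection maximizes Dice and merges the rest", {
  sim <- simulate_dataset(phantom_spec(seed = 1, n_replicates = 1))
  tab <- pick_features(tic_normalize(sim$datasets[[1]]), top_n = 200)
  cm <- bisecting_kmeans(tab, n_leaves = 8, seed = 1)
  sel <- select_adipose_cluster(cm, sim$truth$mask)
  expect_gte(sel$dice, 0.9)
  # merged non-adipose set spans at least two distinct tissue labels
  labs <- unique(sim$truth$mask$labels[sel$nonadipose_pixels])
  expect_gte(length(setdiff(labs, c("adipose", "background"))), 2)
  # no pixel in both sets
  expect_length(intersect(sel$adipose_pixels, sel$nonadipose_pixels), 0)
  # ties break to the lower leaf id
  fx <- two_signature_table()
  cm2 <- bisecting_kmeans(fx$table, n_leaves = 2, seed = 1)
  half <- tissue_mask(matrix(rep("adipose", 100), 1))
  sel2 <- select_adipose_cluster(cm2, half)   # both leaves Dice 2/3
  expect_identical(sel2$adipose_leaf, 1L)
})
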