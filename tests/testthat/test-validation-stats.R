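# ROI selection, CV machinery, ANOVA, Welch tests and BH adjustment.

test_that("ROI selection returns disjoint 3x3 blocks inside the label", {
  m <- build_layout(phantom_spec(seed = 1))
  rois <- select_rois(m, "liver", 3, seed = 1)
  px <- unlist(lapply(rois, `[[`, "pixels"))
  expect_length(px, 27)
  expect_identical(anyDuplicated(px), 0L)
  expect_true(all(m$labels[px] == "liver"))
  # each block is a contiguous 3x3 square
  for (r in rois) {
    xs <- (r$pixels - 1) %% m$width
    ys <- (r$pixels - 1) %/% m$width
    expect_equal(sort(unique(xs)), min(xs) + 0:2)
    expect_equal(sort(unique(ys)), min(ys) + 0:2)
  }
  # a 3x3 region admits exactly one ROI
  tiny <- tissue_mask(matrix(c(rep("background", 25)), 5, 5))
  tm <- mask_matrix(tiny); tm[2:4, 2:4] <- "liver"
  tiny <- tissue_mask(tm)
  one <- select_rois(tiny, "liver", 1, seed = 1)
  expect_length(one, 1)
  expect_error(select_rois(tiny, "liver", 2, seed = 1), "region too small")
})

test_that("cv_percent matches the closed form", {
  expect_equal(cv_percent(c(7, 7, 7)), 0)
  expect_equal(cv_percent(c(8, 10, 12)), 20.0)
  expect_equal(cv_percent(c(5, 10, 15)), 50.0)
  expect_error(cv_percent(c(5)), "at least 2")
  expect_error(cv_percent(c(-1, 1)), "mean must be positive")
})

test_that("ROI CV fractions respond monotonically to the planted noise CV", {
  # ROI means aggregate 9 pixels, so ROI-level CV is ~ pixel CV / 3: the
  # low-reproducibility regime needs pixel CV well past the 20% cutoff
  frac_below_20 <- vapply(c(0.10, 0.40, 0.70), function(cv) {
    sim <- simulate_dataset(phantom_spec(seed = 2, noise_cv = cv,
                                         n_replicates = 1,
                                         panel = null_panel(60)))
    tab <- pick_features(tic_normalize(sim$datasets[[1]]), top_n = 100)
    rois <- select_rois(sim$truth$mask, "muscle", 8, seed = 3)
    cv_summary(tab, rois)$fraction_below_20
  }, numeric(1))
  expect_true(all(diff(frac_below_20) <= 0))
  expect_gte(frac_below_20[1], 0.9)   # low-noise regime: >= 90% under 20%
  expect_lt(frac_below_20[3], 0.5)    # high-noise regime: < 50% under 20%
  # single-feature summary arithmetic
  tab1 <- feature_table("r", "negative", 300,
                        matrix(c(90, 100, 110, 100, 100, 100, 95, 105, 100),
                               1, 9), width = 9, height = 1)
  rois1 <- list(list(label = "muscle", pixels = 1:3),
                list(label = "muscle", pixels = 4:6),
                list(label = "muscle", pixels = 7:9))
  s <- cv_summary(tab1, rois1)
  expect_equal(unname(s$cv), 0)       # ROI means all 100
  expect_equal(s$fraction_below_20, 1)
})

test_that("one-way ANOVA matches hand computation and the t-test square", {
  same <- one_way_anova(list(c(1, 2, 3), c(1, 2, 3)))
  expect_equal(same$F, 0)
  expect_equal(same$p, 1)
  hand <- one_way_anova(list(c(1, 2), c(5, 6), c(9, 10)))
  expect_equal(hand$F, 64)                     # MSB 32 / MSW 0.5
  expect_equal(hand$p, stats::pf(64, 2, 3, lower.tail = FALSE))
  expect_equal(hand$p, 0.0035, tolerance = 0.01)
  expect_error(one_way_anova(list(c(1, 1), c(1, 1))), "undefined")
  # for two groups, F equals the squared pooled t statistic
  a <- c(3.1, 2.9, 3.5, 3.0); b <- c(2.2, 2.6, 2.1, 2.4)
  f2 <- one_way_anova(list(a, b))
  tt <- stats::t.test(a, b, var.equal = TRUE)
  expect_equal(f2$F, unname(tt$statistic)^2, tolerance = 1e-10)
  expect_equal(f2$p, tt$p.value, tolerance = 1e-10)
})

test_that("phantom TIC separates tissues by one-way ANOVA", {
  sim <- simulate_dataset(phantom_spec(seed = 5, n_replicates = 1))
  d <- sim$datasets[[1]]
  tic <- pixel_tic(d)
  groups <- lapply(c("muscle", "liver", "adipose"), function(lab)
    tic[sim$truth$mask$labels == lab])
  expect_lt(one_way_anova(groups)$p, 0.001)
})

test_that("two-way ANOVA: degenerate cells, null interaction, planted interaction", {
  g <- expand.grid(a = c("x", "y"), b = c("u", "v"), r = 1:3)
  flat <- two_way_anova(rep(1, nrow(g)), g$a, g$b)
  expect_true(all(flat$F == 0))
  expect_error(two_way_anova(rnorm(7), rep(c("x", "y"), c(3, 4)),
                             rep("u", 7)), "unbalanced|levels")
  old <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(21)
  # additive (no interaction) tables rarely flag the interaction term
  null_p <- replicate(100, {
    eff_a <- c(x = 0, y = 1)[g$a]
    eff_b <- c(u = 0, v = 2)[g$b]
    two_way_anova(eff_a + eff_b + rnorm(nrow(g)), g$a, g$b)$p[3]
  })
  expect_gte(mean(null_p > 0.05), 0.9)
  # a 2-SD planted interaction is detected
  power_p <- replicate(100, {
    inter <- ifelse(g$a == "y" & g$b == "v", 4, 0)
    two_way_anova(inter + rnorm(nrow(g), sd = 1), g$a, g$b)$p[3]
  })
  expect_gte(mean(power_p < 0.05), 0.8)
})

test_that("Welch test matches stats::t.test and handles degenerate input", {
  w <- welch_t_test(c(2.1, 2.5, 2.3), c(1.1, 1.4, 1.2))
  tt <- stats::t.test(c(2.1, 2.5, 2.3), c(1.1, 1.4, 1.2))
  expect_equal(w$t, unname(tt$statistic), tolerance = 1e-10)
  expect_equal(w$t, 7.3413, tolerance = 1e-4)
  expect_equal(w$p, tt$p.value, tolerance = 1e-10)
  expect_equal(w$df, unname(tt$parameter), tolerance = 1e-10)
  same <- welch_t_test(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)
  shift <- welch_t_test(c(1, 2, 3), c(101, 102, 103))
  expect_lt(shift$p, 1e-4)
  flat <- welch_t_test(c(2, 2, 2), c(2, 2))
  expect_equal(flat$p, 1)
  pooled <- welch_t_test(c(1, 2, 3, 4), c(2, 3, 4, 8), pooled = TRUE)
  ttp <- stats::t.test(c(1, 2, 3, 4), c(2, 3, 4, 8), var.equal = TRUE)
  expect_equal(pooled$t, unname(ttp$statistic))
})

test_that("vectorized Welch agrees with per-feature t.test calls", {
  old <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(7)
  a <- matrix(rnorm(20 * 8, mean = 1), 20)
  b <- matrix(rnorm(20 * 12), 20)
  many <- lipidmsi:::welch_many(a, b)
  for (i in c(1, 5, 20)) {
    tt <- stats::t.test(a[i, ], b[i, ])
    expect_equal(many$t[i], unname(tt$statistic), tolerance = 1e-10)
    expect_equal(many$p[i], tt$p.value, tolerance = 1e-10)
  }
})

test_that("BH adjustment matches the step-up definition and its properties", {
  expect_equal(bh_adjust(0.03), 0.03)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(c(0.005, 0.9)), c(0.01, 0.9))
  expect_error(bh_adjust(c(0.5, 1.2)), "0, 1")
  old <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(11)
  for (i in 1:20) {
    p <- runif(50)^2
    q <- bh_adjust(p)
    expect_equal(q, bh_brute(p), tolerance = 1e-12)   # oracle equivalence
    expect_true(all(q >= p - 1e-12))
    expect_true(!is.unsorted(q[order(p)]))            # order-preserving
  }
})

test_that("the two-tier filter controls FDR on uniform-null features", {
  # direct check on the BH tier with 1000 independent null features
  old <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(13)
  p <- runif(1000)
  q <- bh_adjust(p)
  se <- sqrt(0.05 * 0.95 / 1000)
  expect_lte(mean(q < 0.05), 0.05 + 2 * se)
})
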