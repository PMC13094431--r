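# TIC normalization, baseline correction, feature picking, alignment,
# deisotoping and interday rescaling.

test_that("TIC normalization sums pixels to one, flags zero pixels, idempotent", {
  ints <- rbind(c(2, 3, 5), c(0, 0, 0), c(10, 0, 0))
  d <- msi_dataset("t", "negative", 3, 1, c(200, 300, 400), ints)
  n <- tic_normalize(d)
  expect_equal(n$intensities[1, ], c(0.2, 0.3, 0.5))
  expect_equal(n$intensities[2, ], c(0, 0, 0))
  expect_identical(n$metadata$zero_tic_pixels, 2L)
  n2 <- tic_normalize(n)
  expect_equal(n2$intensities, n$intensities)
  # every nonzero pixel of a phantom sums to 1
  sim <- simulate_dataset(phantom_spec(seed = 2, width = 16, height = 16,
                                       n_replicates = 1))
  tn <- tic_normalize(sim$datasets[[1]])
  tic <- pixel_tic(tn)
  expect_true(all(abs(tic[tic > 0] - 1) < 1e-9))
})

test_that("rolling-minimum baseline removes offsets and preserves peaks", {
  mz <- seq(200, 210, by = 0.05)   # dense profile-like axis
  flat <- msi_dataset("f", "negative", 1, 1, mz,
                      matrix(3, 1, length(mz)))
  expect_true(all(baseline_correct(flat, 2)$intensities == 0))
  # single Gaussian peak of height 8 on offset 2
  peak <- 8 * exp(-(mz - 205)^2 / (2 * 0.1^2))
  d <- msi_dataset("p", "negative", 1, 1, mz,
                   matrix(peak + 2, 1, length(mz)))
  corr <- baseline_correct(d, 2)
  expect_equal(max(corr$intensities), 8, tolerance = 0.01 * 8)
  # already baseline-free spectra are unchanged
  d0 <- msi_dataset("z", "negative", 1, 1, mz, matrix(peak, 1, length(mz)))
  expect_equal(baseline_correct(d0, 2)$intensities, d0$intensities,
               tolerance = 1e-6)
  # window wider than the axis falls back to global minimum subtraction
  wide <- baseline_correct(d, 100)
  expect_equal(min(wide$intensities), 0)
  expect_equal(max(wide$intensities), 8, tolerance = 0.08)
})

test_that("feature picking recovers planted peaks and ranks by intensity", {
  sim <- simulate_dataset(phantom_spec(seed = 1, n_replicates = 1))
  d <- tic_normalize(sim$datasets[[1]])
  tab <- pick_features(d, top_n = 200)
  expect_identical(length(tab$mz), nrow(sim$truth$panel))
  expect_true(all(vapply(sim$truth$panel$mz, function(m)
    min(abs(tab$mz - m)) < 1e-9, logical(1))))
  # top_n = 1 keeps the single most intense planted feature
  top1 <- pick_features(d, top_n = 1)
  means <- colMeans(d$intensities)
  expect_equal(top1$mz, d$mz_axis[which.max(means)])
  # flat (all-zero) spectra give an empty table
  flat <- msi_dataset("f", "negative", 2, 2, c(200, 300),
                      matrix(0, 4, 2))
  expect_identical(length(pick_features(tic_normalize(flat))$mz), 0L)
})

test_that("alignment groups centroids within tolerance and splits beyond it", {
  mk <- function(id, mz, ints) feature_table(id, "negative", mz,
                                             matrix(ints, length(mz), 4),
                                             width = 2, height = 2)
  a <- align_features(list(mk("r1", 295.228, 10), mk("r2", 295.232, 12)),
                      tol_da = 0.02)
  expect_identical(nrow(a$consensus), 1L)
  expect_equal(a$consensus$avg_mz, 295.230)
  expect_equal(a$consensus$ppm_deviation, 0.004 / 295.230 * 1e6,
               tolerance = 1e-6)
  b <- align_features(list(mk("r1", 295.23, 10), mk("r2", 295.30, 12)),
                      tol_da = 0.02)
  expect_identical(nrow(b$consensus), 2L)
  expect_error(align_features(list(
    mk("r1", 295.23, 1),
    feature_table("r2", "positive", 295.23, matrix(1, 1, 4), 2, 2))),
    "mixed polarity")
})

test_that("alignment output is independent of replicate input order", {
  sim <- simulate_dataset(phantom_spec(seed = 3))
  tabs <- lapply(sim$datasets, function(d)
    pick_features(tic_normalize(d), top_n = 200))
  a12 <- align_features(tabs)
  a21 <- align_features(rev(tabs))
  expect_equal(sort(a12$consensus$avg_mz), sort(a21$consensus$avg_mz))
  # every planted lipid yields exactly one consensus feature over 3 replicates
  expect_identical(nrow(a12$consensus), nrow(sim$truth$panel))
  expect_true(all(a12$consensus$n_replicates == 3L))
})

test_that("deisotoping applies the spacing and intensity-order rules", {
  mk <- function(mz, means) feature_table("r", "negative", mz,
                                          matrix(rep(means, 5), length(mz), 5),
                                          width = 5, height = 1)
  # satellite pattern: Delta = 1.0034, smaller intensity -> removed
  t1 <- deisotope(mk(c(255.2330, 256.2364), c(100, 17.3)))
  expect_identical(length(t1$mz), 1L)
  expect_equal(t1$mz, 255.2330)
  expect_identical(t1$removed_isotopologues$parent_mz, 255.2330)
  # wrong spacing -> both kept
  t2 <- deisotope(mk(c(255.2330, 255.7330), c(100, 17.3)))
  expect_identical(length(t2$mz), 2L)
  # higher peak above is not a satellite -> both kept
  t3 <- deisotope(mk(c(255.2330, 256.2364), c(10, 100)))
  expect_identical(length(t3$mz), 2L)
})

test_that("deisotoping removes exactly the planted satellites, never the base peak", {
  sim <- simulate_dataset(phantom_spec(seed = 3, isotope_satellites = TRUE,
                                       n_replicates = 1))
  tab <- pick_features(tic_normalize(sim$datasets[[1]]), top_n = 200)
  out <- deisotope(tab)
  expect_identical(nrow(out$removed_isotopologues),
                   length(sim$truth$satellite_mz))
  expect_true(all(vapply(out$removed_isotopologues$removed_mz, function(m)
    min(abs(sim$truth$satellite_mz - m)) < 1e-9, logical(1))))
  top_mz <- tab$mz[which.max(rowMeans(tab$intensities))]
  expect_true(top_mz %in% out$mz)
})

test_that("interday rescaling recovers planted replicate scale factors", {
  mk <- function(ints) feature_table("r", "negative", c(200, 300),
                                     ints, width = 2, height = 2)
  ref <- mk(matrix(c(1, 2, 3, 4, 5, 6, 7, 8), 2, 4))
  same <- interday_rescale(ref, ref, 1:4, 1:4)
  expect_equal(same$scale, 1.0)
  halved <- mk(ref$intensities * 0.5)
  r <- interday_rescale(ref, halved, 1:4, 1:4)
  expect_equal(r$scale, 2.0)
  expect_equal(r$target$intensities, ref$intensities)
  # phantom replicates with planted factors {0.8, 1.25}
  s <- phantom_spec(seed = 8, n_replicates = 2, scale_factors = c(0.8, 1.25))
  sim <- simulate_dataset(s)
  tabs <- lapply(sim$datasets, function(d) pick_features(d, top_n = 100))
  roi <- which(sim$truth$mask$labels == "liver")
  rec <- interday_rescale(tabs[[1]], tabs[[2]], roi, roi)
  expect_equal(rec$scale, 0.8 / 1.25, tolerance = 0.02)
  zero <- mk(matrix(0, 2, 4))
  expect_error(interday_rescale(ref, zero, 1:4, 1:4), "zero TIC")
})
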