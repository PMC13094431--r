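# Dataset container invariants, continuous-mode imzML roundtrips, label
# masks and the packaged adipose-lipid reference table.

make_grid <- function(w = 2, h = 2, mz = c(200.1, 300.2, 400.3),
                      polarity = "negative", seed = 42) {
  ints <- with_seed_matrix(seed, w * h, length(mz))
  msi_dataset("unit", polarity, w, h, mz, ints)
}

with_seed_matrix <- function(seed, nr, nc) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  matrix(runif(nr * nc, 0, 100), nr, nc)
}

test_that("dataset invariants are enforced", {
  expect_error(msi_dataset("x", "negative", 2, 2, c(300, 200, 400),
                           matrix(1, 4, 3)), "strictly increasing")
  expect_error(msi_dataset("x", "negative", 2, 2, c(50, 200), matrix(1, 4, 2)),
               "acquisition range")
  expect_error(msi_dataset("x", "negative", 2, 2, c(200, 300),
                           matrix(-1, 4, 2)), "negative intensities")
  expect_error(msi_dataset("x", "upward", 2, 2, c(200, 300), matrix(1, 4, 2)),
               "polarity")
  expect_error(msi_dataset("x", "negative", 2, 2, c(200, 300), matrix(1, 3, 2)),
               "rows")
})

test_that("imzML roundtrip preserves the grid bit-for-bit at storage precision", {
  d <- make_grid()
  path <- file.path(tempdir(), "roundtrip.imzML")
  write_imzml(d, path)
  d2 <- read_imzml(path)
  expect_identical(d2$mz_axis, d$mz_axis)          # m/z stored as float64
  expect_equal(d2$intensities, d$intensities, tolerance = 1e-6)  # float32
  expect_identical(d2$polarity, d$polarity)
  expect_identical(d2$replicate_id, d$replicate_id)
  expect_identical(c(d2$width, d2$height), c(d$width, d$height))
  expect_equal(pixel_tic(d2), pixel_tic(d), tolerance = 1e-5)
})

test_that("positive polarity and a 1x1 single-peak grid survive the roundtrip", {
  d <- msi_dataset("tiny", "positive", 1, 1, 500.5, matrix(7.25, 1, 1))
  path <- file.path(tempdir(), "tiny.imzML")
  write_imzml(d, path)
  d2 <- read_imzml(path)
  expect_identical(d2$polarity, "positive")
  expect_equal(d2$intensities[1, 1], 7.25)
})

test_that("phantom grids written to imzML reread with the declared layout", {
  sim <- simulate_dataset(phantom_spec(seed = 1, width = 20, height = 20,
                                       n_replicates = 1))
  d <- sim$datasets[[1]]
  path <- file.path(tempdir(), "phantom.imzML")
  write_imzml(d, path)
  d2 <- read_imzml(path)
  expect_identical(nrow(d2$intensities), 400L)
  expect_identical(length(d2$mz_axis), nrow(sim$truth$panel))
  expect_equal(d2$intensities, d$intensities, tolerance = 1e-6)
})

test_that("missing ibd companion and processed-mode files are rejected", {
  d <- make_grid()
  path <- file.path(tempdir(), "broken.imzML")
  write_imzml(d, path)
  file.remove(sub("imzML$", "ibd", path))
  expect_error(read_imzml(path), "ibd companion")
  # forge a processed-mode declaration
  path2 <- file.path(tempdir(), "processed.imzML")
  write_imzml(d, path2)
  txt <- readLines(path2)
  txt <- gsub('name="continuous"', 'name="processed"', txt)
  writeLines(txt, path2)
  expect_error(read_imzml(path2), "processed")
})

test_that("the written imzML is parseable by an independent reader", {
  # pyimzML (Python) serves as the external format oracle
  d <- make_grid(w = 3, h = 2, seed = 7)
  path <- file.path(tempdir(), "oracle.imzML")
  write_imzml(d, path)
  script <- tempfile(fileext = ".py")
  writeLines(c(
    "from pyimzml.ImzMLParser import ImzMLParser",
    sprintf("p = ImzMLParser(r'%s')", path),
    "print(len(p.coordinates))",
    "mz, ints = p.getspectrum(0)",
    "print(len(mz)); print(round(float(mz[0]), 6))",
    "print(round(float(ints.sum()), 4))"), script)
  out <- suppressWarnings(system2("python", script, stdout = TRUE,
                                  stderr = FALSE))
  vals <- as.numeric(utils::tail(out, 4))
  expect_identical(vals[1], 6)                       # pixels
  expect_identical(vals[2], 3)                       # axis length
  expect_equal(vals[3], d$mz_axis[1], tolerance = 1e-6)
  expect_equal(vals[4], sum(d$intensities[1, ]), tolerance = 1e-3)
})

test_that("CSV masks read with label normalization and dimension checks", {
  path <- tempfile(fileext = ".csv")
  writeLines(c("adipose,adipose,adipose",
               "adipose,liver ,adipose",      # trailing space normalized
               "adipose,adipose,adipose"), path)
  m <- read_mask(path)
  expect_identical(c(m$width, m$height), c(3L, 3L))
  expect_identical(sum(m$labels == "adipose"), 8L)
  expect_identical(sum(m$labels == "liver"), 1L)
  expect_error(read_mask(path, expected_dim = c(4, 4)), "do not match")
  writeLines(c("adipose,spleen", "muscle,muscle"), path)
  expect_error(read_mask(path), "unknown tissue label")
})

test_that("mask CSV roundtrip and PNG-with-legend reading agree", {
  sim_mask <- build_layout(phantom_spec(seed = 1))
  path <- tempfile(fileext = ".csv")
  write_mask(sim_mask, path)
  m2 <- read_mask(path)
  expect_identical(m2$labels, sim_mask$labels)
  # indexed PNG with a legend sidecar
  png_path <- tempfile(fileext = ".png")
  labs <- c("background", "muscle", "adipose")
  idx <- matrix(c(0L, 1L, 2L, 1L), 2, 2)
  png::writePNG(idx / 255, png_path)
  writeLines(paste(0:2, labs, sep = "\t"), paste0(png_path, ".legend"))
  m3 <- read_mask(png_path)
  expect_identical(m3$labels, as.vector(t(matrix(labs[idx + 1L], 2, 2))))
  file.remove(paste0(png_path, ".legend"))
  expect_error(read_mask(png_path), "legend sidecar")
})

test_that("the packaged reference table loads 52 records with parsed adducts", {
  tb <- load_table1()
  expect_identical(nrow(tb), 52L)
  expect_identical(sum(tb$polarity == "positive"), 35L)
  expect_identical(sum(tb$polarity == "negative"), 17L)
  # the oxidized linoleic-acid row
  row <- tb[abs(tb$desi_avg_mz - 295.23) < 1e-6, ]
  expect_identical(row$annotation, "FA (18:2;O)")
  expect_identical(row$desi_adduct, "[M-H]-")
  # the DG(32:1) row with scientific-notation intensities
  dg <- tb[tb$annotation == "DG(32:1)", ]
  expect_equal(dg$avg_intensity_adipose, 1.71e4)
  expect_equal(dg$avg_intensity_nonadipose, 9.09e3)
  expect_identical(dg$desi_adduct, "[M+H-H2O]+")
  expect_identical(dg$other_adducts_enriched[[1]], "[M+H]+")
  # empty adduct lists parse to empty vectors
  fa <- tb[tb$annotation == "FA (16:0)", ]
  expect_length(fa$other_adducts_enriched[[1]], 0)
})
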