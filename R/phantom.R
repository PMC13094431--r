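# Synthetic full-body MSI phantoms with known ground truth: multi-tissue
# layout, planted adipose enrichment, lognormal pixel noise, per-replicate
# intensity scale drift, optional M+1 isotopologue satellites, and synthetic
# surface-extraction MS2 spectra.

# Run code under a seed without disturbing the caller's RNG stream.
with_local_seed <- function(seed, code) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

PHANTOM_TISSUES <- c("muscle", "liver", "brain", "eye", "gill")

#' Default phantom lipid panel
#'
#' A negative-mode panel of 40 species emulating a full-body section:
#' \itemize{
#'   \item 12 adipose-enriched neutral-lipid features (free and oxidized
#'     fatty acids plus LPE(16:0)) at planted fold changes 1.5-2.8, uniform
#'     across non-adipose tissues;
#'   \item 12 null fatty-acid features (fold 1.0 everywhere);
#'   \item 16 glycerophospholipid tissue markers (PE/PI/PEe/PG/PS), each
#'     3.5x enriched in a home tissue, 0.65x elsewhere and 0.3x in adipose
#'     tissue, which carry the between-tissue signature that drives
#'     segmentation and count as nulls for adipose enrichment.
#' }
#' Base intensities are fixed so that expected adipose TIC slightly exceeds
#' the other tissues, as in lipid-rich fat depots.
#'
#' @return data.frame with `feature_id`, `mz`, `base_intensity`,
#'   per-tissue multipliers `mult_muscle` ... `mult_gill`, `mult_adipose`,
#'   `adduct` and logical `enriched`.
#' @export
default_lipid_panel <- function() {
  mz_neg <- function(sh) adduct_mz(parse_shorthand(sh), "[M-H]-")
  enr_sh <- c("FA(12:0)", "FA(14:0)", "FA(16:1)", "FA(16:0)", "FA(17:0)",
              "FA(18:0)", "FA(18:2;O)", "FA(18:1;O)", "FA(20:0)",
              "FA(22:0)", "FA(24:0)", "LPE(16:0)")
  enr_base <- c(30, 25, 20, 40, 15, 45, 12, 18, 35, 25, 20, 15)
  enr_fold <- seq(1.5, 2.8, length.out = length(enr_sh))
  nul_sh <- c("FA(13:0)", "FA(15:0)", "FA(16:2)", "FA(17:1)", "FA(16:0;O)",
              "FA(16:2;O)", "FA(18:2)", "FA(18:1)", "FA(19:0)", "FA(20:4)",
              "FA(22:6)", "FA(22:6;O)")
  nul_base <- c(20, 25, 15, 30, 20, 15, 80, 90, 25, 60, 70, 50)
  mark <- data.frame(
    shorthand = c("PE(34:1)", "PE(36:2)", "PE(38:4)",
                  "PI(34:1)", "PI(36:2)", "PI(38:4)",
                  "PEe(34:1)", "PEe(36:4)", "PEe(38:4)", "PEe(40:6)",
                  "PG(34:1)", "PG(36:2)", "PG(38:4)",
                  "PS(36:1)", "PS(38:1)", "PS(40:7)"),
    home = c(rep("liver", 3), rep("muscle", 3), rep("gill", 4),
             rep("brain", 3), rep("eye", 3)),
    stringsAsFactors = FALSE
  )
  mark_base <- rep(20, nrow(mark))
  n <- length(enr_sh) + length(nul_sh) + nrow(mark)
  panel <- data.frame(
    feature_id = c(enr_sh, nul_sh, mark$shorthand),
    mz = c(vapply(enr_sh, mz_neg, numeric(1)),
           vapply(nul_sh, mz_neg, numeric(1)),
           vapply(mark$shorthand, mz_neg, numeric(1))),
    base_intensity = c(enr_base, nul_base, mark_base),
    adduct = "[M-H]-",
    enriched = c(rep(TRUE, length(enr_sh)), rep(FALSE, length(nul_sh)),
                 rep(FALSE, nrow(mark))),
    stringsAsFactors = FALSE
  )
  for (t in PHANTOM_TISSUES) panel[[paste0("mult_", t)]] <- 1
  panel$mult_adipose <- c(enr_fold, rep(1, length(nul_sh)),
                          rep(0.3, nrow(mark)))
  for (i in seq_len(nrow(mark))) {
    j <- length(enr_sh) + length(nul_sh) + i
    for (t in PHANTOM_TISSUES)
      panel[[paste0("mult_", t)]][j] <- if (t == mark$home[i]) 3.5 else 0.65
  }
  rownames(panel) <- NULL
  panel
}

#' Null phantom panel
#'
#' `n_features` features uniform across every tissue including adipose
#' (planted fold 1.0), for false-discovery-rate calibration runs.
#'
#' @param n_features number of features.
#' @return panel data.frame as in [default_lipid_panel()].
#' @export
null_panel <- function(n_features) {
  mz <- seq(200, 1100, length.out = n_features)
  panel <- data.frame(
    feature_id = sprintf("null_%04d", seq_len(n_features)),
    mz = mz,
    base_intensity = rep(c(10, 20, 50, 100, 200), length.out = n_features),
    adduct = "[M-H]-",
    enriched = FALSE,
    stringsAsFactors = FALSE
  )
  for (t in PHANTOM_TISSUES) panel[[paste0("mult_", t)]] <- 1
  panel$mult_adipose <- 1
  panel
}

#' Phantom specification
#'
#' Bundles the study conditions of a simulated experiment: grid size,
#' replicate count, planted lipid panel, within-tissue lognormal noise CV,
#' per-replicate global intensity scale drift, additive baseline level, and
#' whether M+1 isotopologue satellites are planted.
#'
#' @param seed integer seed; every stochastic choice of the generator flows
#'   from it.
#' @param width,height grid size in pixels (>= 16 each; default 40 x 50,
#'   about 2000 pixels).
#' @param n_replicates number of serial-section replicates (default 3).
#' @param panel lipid panel data.frame (default [default_lipid_panel()]).
#' @param noise_cv within-tissue coefficient of variation of the lognormal
#'   pixel noise (default 0.15, within the 10-20% reproducibility band of
#'   the imaging platform).
#' @param scale_range per-replicate global intensity scale factor range
#'   (default 0.8-1.25, mimicking interday source-realignment drift).
#' @param scale_factors optional explicit per-replicate scale factors
#'   overriding `scale_range`.
#' @param baseline_level additive baseline noise level (default 0.2
#'   intensity units).
#' @param isotope_satellites plant M+1 satellites at +1.00336 Da with
#'   relative abundance 0.0107 x carbons / 0.9893 (default FALSE).
#' @param polarity ionization mode of the phantom (default "negative").
#' @return A `phantom_spec` list.
#' @export
phantom_spec <- function(seed = 1, width = 40, height = 50,
                         n_replicates = 3, panel = default_lipid_panel(),
                         noise_cv = 0.15, scale_range = c(0.8, 1.25),
                         scale_factors = NULL, baseline_level = 0.2,
                         isotope_satellites = FALSE, polarity = "negative") {
  stopifnot(width >= 16, height >= 16, n_replicates >= 1,
            noise_cv > 0, noise_cv < 1,
            all(panel$mult_adipose > 0), all(panel$base_intensity > 0))
  if (!is.null(scale_factors)) stopifnot(length(scale_factors) == n_replicates)
  structure(list(seed = as.integer(seed), width = as.integer(width),
                 height = as.integer(height),
                 n_replicates = as.integer(n_replicates), panel = panel,
                 noise_cv = noise_cv, scale_range = scale_range,
                 scale_factors = scale_factors,
                 baseline_level = baseline_level,
                 isotope_satellites = isotope_satellites,
                 polarity = polarity),
            class = "phantom_spec")
}

# Paint an ellipse (cx, cy, rx, ry in pixels) onto a label grid.
paint_ellipse <- function(lab, width, height, cx, cy, rx, ry, value) {
  xs <- rep(seq_len(width), times = height)
  ys <- rep(seq_len(height), each = width)
  inside <- ((xs - cx) / rx)^2 + ((ys - cy) / ry)^2 <= 1
  lab[inside] <- value
  lab
}

#' Build the phantom tissue layout
#'
#' Deterministic (per seed) sagittal-section-like mask: a muscle body with
#' an eye disc, brain and liver blobs, a gill band, a visceral adipose blob
#' and a subepidermal adipose ribbon, surrounded by background. Region
#' centers are jittered by up to 2% of the grid per seed. Geometry is
#' axis-aligned and schematic, not anatomically realistic.
#'
#' @param spec a `phantom_spec` (only seed/width/height used).
#' @return A `tissue_mask`.
#' @export
build_layout <- function(spec) {
  w <- spec$width; h <- spec$height
  if (w < 16 || h < 16) stop("grid too small to place all regions")
  jit <- with_local_seed(spec$seed, stats::runif(8, -0.02, 0.02))
  lab <- rep("background", w * h)
  xs <- rep(seq_len(w), times = h)
  ys <- rep(seq_len(h), each = w)
  # muscle body: inner rectangle with a 5% margin
  body <- xs > 0.05 * w & xs <= 0.95 * w & ys > 0.05 * h & ys <= 0.95 * h
  lab[body] <- "muscle"
  lab <- paint_ellipse(lab, w, h, (0.15 + jit[1]) * w, (0.30 + jit[2]) * h,
                       max(1.2, 0.06 * w), max(1.2, 0.05 * h), "eye")
  lab <- paint_ellipse(lab, w, h, (0.28 + jit[3]) * w, (0.22 + jit[4]) * h,
                       max(1.2, 0.07 * w), max(1.2, 0.06 * h), "brain")
  gill <- xs >= (0.36 + jit[5]) * w & xs <= (0.43 + jit[5]) * w &
    ys >= 0.15 * h & ys <= 0.60 * h
  lab[gill] <- "gill"
  lab <- paint_ellipse(lab, w, h, (0.56 + jit[6]) * w, (0.55 + jit[7]) * h,
                       max(1.5, 0.09 * w), max(1.5, 0.08 * h), "liver")
  lab <- paint_ellipse(lab, w, h, (0.74 + jit[8]) * w, (0.48 + jit[7]) * h,
                       max(1.5, 0.10 * w), max(1.5, 0.09 * h), "adipose")
  ribbon <- xs >= 0.25 * w & xs <= 0.85 * w & ys >= 0.84 * h & ys <= 0.90 * h
  lab[ribbon] <- "adipose"
  counts <- table(factor(lab, levels = TISSUE_LABELS))
  needed <- c("muscle", "liver", "brain", "eye", "gill", "adipose")
  if (any(counts[needed] == 0))
    stop("grid too small to place all regions: empty ",
         paste(needed[counts[needed] == 0], collapse = ", "))
  tissue_mask(lab, width = w, height = h)
}

# Planted per-tissue mean matrix (features x tissues incl. adipose), given
# the realized mask pixel counts. Adipose mean of a feature is
# mult_adipose x the pixel-weighted mean over non-adipose tissues.
planted_means <- function(panel, mask) {
  counts <- table(factor(mask$labels, levels = TISSUE_LABELS))
  nt <- counts[PHANTOM_TISSUES]
  mult <- as.matrix(panel[, paste0("mult_", PHANTOM_TISSUES)])
  nonadipose <- mult * rep(panel$base_intensity, times = ncol(mult))
  wmean <- as.vector(nonadipose %*% as.numeric(nt)) / sum(nt)
  means <- cbind(nonadipose, adipose = panel$mult_adipose * wmean)
  colnames(means) <- c(PHANTOM_TISSUES, "adipose")
  rownames(means) <- panel$feature_id
  means
}

#' Simulate a multi-replicate phantom experiment
#'
#' For every pixel of tissue t and feature l, intensity is
#' `mean[l, t] * LN(cv) * s_r + |N(0, baseline)|` where `LN(cv)` is a
#' unit-mean lognormal with the target coefficient of variation and `s_r`
#' the replicate's global scale factor. Adipose means are the planted fold
#' times the pixel-weighted non-adipose mean. Background pixels carry only
#' baseline noise. With `isotope_satellites`, every feature gains an M+1
#' companion at +1.00336 Da whose intensity is a fixed fraction
#' `0.0107 * C / 0.9893` (C = molecular carbon count, or the nearest
#' integer to m/z / 14 for abstract features) of the monoisotopic pixel
#' intensity.
#'
#' @param spec a `phantom_spec`.
#' @return list with `datasets` (list of `msi_dataset`) and `truth`: the
#'   `mask`, planted per-tissue `means`, `enriched_ids`, `null_ids`,
#'   `scale_factors`, `panel`, and `satellite_mz` (when planted).
#' @export
simulate_dataset <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  mask <- build_layout(spec)
  panel <- spec$panel
  means <- planted_means(panel, mask)
  cv <- spec$noise_cv
  sigma <- sqrt(log(1 + cv^2))
  scale_factors <- if (!is.null(spec$scale_factors)) spec$scale_factors else
    with_local_seed(spec$seed + 1000L,
                    stats::runif(spec$n_replicates, spec$scale_range[1],
                                 spec$scale_range[2]))
  ord <- order(panel$mz)
  mz_axis <- panel$mz[ord]
  if (any(diff(mz_axis) <= 0)) stop("panel m/z values must be distinct")

  sat_ratio <- NULL
  if (spec$isotope_satellites) {
    carbons <- vapply(seq_len(nrow(panel)), function(i) {
      rec <- tryCatch(parse_shorthand(panel$feature_id[i]),
                      error = function(e) NULL)
      if (!is.null(rec)) as.integer(rec$formula[["C"]])
      else as.integer(round(panel$mz[i] / 14))
    }, integer(1))
    sat_ratio <- C13_ABUNDANCE * carbons / (1 - C13_ABUNDANCE)
  }

  npx <- mask$width * mask$height
  datasets <- vector("list", spec$n_replicates)
  truth_sat_mz <- NULL
  for (r in seq_len(spec$n_replicates)) {
    ints <- with_local_seed(spec$seed + r, {
      m <- matrix(0, nrow = npx, ncol = nrow(panel))
      for (t in colnames(means)) {
        px <- which(mask$labels == t)
        if (length(px) == 0) next
        noise <- matrix(stats::rlnorm(length(px) * nrow(panel),
                                      meanlog = -sigma^2 / 2, sdlog = sigma),
                        nrow = length(px))
        m[px, ] <- noise * rep(means[, t], each = length(px)) *
          scale_factors[r]
      }
      m + abs(matrix(stats::rnorm(npx * nrow(panel), 0,
                                  spec$baseline_level), nrow = npx))
    })
    ints <- ints[, ord, drop = FALSE]
    axis <- mz_axis
    if (spec$isotope_satellites) {
      sat_mz <- mz_axis + C13_DELTA_DA
      sat_int <- ints * rep(sat_ratio[ord], each = npx)
      axis <- c(mz_axis, sat_mz)
      o2 <- order(axis)
      ints <- cbind(ints, sat_int)[, o2, drop = FALSE]
      axis <- axis[o2]
      if (any(diff(axis) <= 0)) stop("satellite m/z collides with a feature")
      truth_sat_mz <- sort(sat_mz)
    }
    datasets[[r]] <- msi_dataset(
      replicate_id = paste0("phantom_", spec$seed, "_rep", r),
      polarity = spec$polarity, width = mask$width, height = mask$height,
      mz_axis = axis, intensities = ints,
      metadata = list(seed = spec$seed, replicate = r,
                      scale_factor = scale_factors[r]))
  }
  truth <- list(mask = mask, means = means,
                enriched_ids = panel$feature_id[panel$enriched],
                null_ids = panel$feature_id[!panel$enriched],
                feature_mz = panel$mz,
                scale_factors = scale_factors, panel = panel,
                satellite_mz = truth_sat_mz)
  list(datasets = datasets, truth = truth)
}

#' Simulate a diagnostic MS2 spectrum
#'
#' Emits the precursor and every class-diagnostic rule fragment for the
#' lipid/adduct pair (exact rule m/z), plus low-level random noise peaks.
#'
#' @param lipid a `lipid_record` (chain-resolved where the class rule needs
#'   acyl compositions).
#' @param adduct adduct name or spec.
#' @param seed RNG seed for fragment intensities and noise peaks.
#' @param n_noise number of random noise peaks (default 5).
#' @param chains optional acyl composition override.
#' @return An `ms2_spectrum`.
#' @export
simulate_ms2 <- function(lipid, adduct, seed = 1, n_noise = 5,
                         chains = NULL) {
  if (is.character(adduct)) adduct <- adduct_spec(adduct)
  rules <- fragment_rules(lipid, adduct, chains = chains)
  prec <- adduct_mz(lipid, adduct)
  with_local_seed(seed, {
    frag_int <- stats::runif(length(rules), 20, 60)
    noise_mz <- stats::runif(n_noise, 100, max(100.1, prec - 1))
    noise_int <- stats::runif(n_noise, 0.5, 3)
    peaks <- rbind(cbind(mz = prec, intensity = 100),
                   cbind(mz = unname(rules), intensity = frag_int),
                   cbind(mz = noise_mz, intensity = noise_int))
    peaks <- peaks[order(peaks[, "mz"]), , drop = FALSE]
    ms2_spectrum(prec, adduct$polarity, peaks)
  })
}

#' Simulate surface-extraction (LESA-like) spot spectra
#'
#' Samples `n_sites` extraction sites inside adipose tissue and returns one
#' spot spectrum per site: spiked internal standards at their nominal
#' intensity under lognormal CV 13%, plus tissue lipids drawn from the
#' adipose signature of the panel under the phantom noise CV.
#'
#' @param mask a `tissue_mask` with at least `n_sites` adipose pixels.
#' @param n_sites number of extraction sites (0 allowed; returns an empty
#'   list).
#' @param standards data.frame with `mz` and `nominal_intensity` (may have
#'   zero rows).
#' @param seed RNG seed.
#' @param panel lipid panel providing the tissue signature (default
#'   [default_lipid_panel()]); pass `NULL` to omit tissue lipids.
#' @param standard_cv lognormal CV of the spiked standards (default 0.13).
#' @param tissue_cv lognormal CV of tissue lipids (default 0.15).
#' @return list of extracts: each has `site` (pixel x, y) and `peaks`
#'   (mz/intensity matrix).
#' @export
simulate_lesa_extracts <- function(mask, n_sites, standards, seed = 1,
                                   panel = default_lipid_panel(),
                                   standard_cv = 0.13, tissue_cv = 0.15) {
  stopifnot(inherits(mask, "tissue_mask"), n_sites >= 0)
  if (n_sites == 0) return(list())
  adipose_px <- which(mask$labels == "adipose")
  if (length(adipose_px) < n_sites)
    stop("insufficient adipose area: ", length(adipose_px),
         " pixels for ", n_sites, " sites")
  sig_ln <- function(cv) sqrt(log(1 + cv^2))
  tissue_mean <- NULL
  if (!is.null(panel)) {
    means <- planted_means(panel, mask)
    tissue_mean <- cbind(mz = panel$mz, intensity = means[, "adipose"])
  }
  with_local_seed(seed, {
    sites <- sample(adipose_px, n_sites)
    lapply(sites, function(px) {
      peaks <- NULL
      if (nrow(standards) > 0) {
        s <- sig_ln(standard_cv)
        peaks <- cbind(mz = standards$mz,
                       intensity = standards$nominal_intensity *
                         stats::rlnorm(nrow(standards), -s^2 / 2, s))
      }
      if (!is.null(tissue_mean)) {
        s <- sig_ln(tissue_cv)
        tp <- cbind(mz = tissue_mean[, "mz"],
                    intensity = tissue_mean[, "intensity"] *
                      stats::rlnorm(nrow(tissue_mean), -s^2 / 2, s))
        peaks <- rbind(peaks, tp)
      }
      peaks <- peaks[order(peaks[, "mz"]), , drop = FALSE]
      x <- (px - 1) %% mask$width
      y <- (px - 1) %/% mask$width
      list(site = c(x = x, y = y), peaks = peaks)
    })
  })
}
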