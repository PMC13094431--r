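# End-to-end orchestration: simulate -> preprocess -> segment -> validate
# -> enrich -> annotate, with a parameter manifest and TSV artifacts.

#' Pipeline configuration
#'
#' All stage parameters in one structured list; every default mirrors the
#' corresponding module default and all randomness flows from `seed`.
#'
#' @param seed master seed (phantom simulation and segmentation restarts).
#' @param simulate simulate a phantom experiment (`TRUE`) or read imzML
#'   inputs from `input_paths` with a mask from `mask_path`.
#' @param phantom a `phantom_spec` used when `simulate = TRUE`.
#' @param input_paths character vector of imzML paths (ignored when
#'   simulating).
#' @param mask_path tissue mask path (ignored when simulating).
#' @param baseline_window baseline-correction window in Da, or `NULL` to
#'   skip the step (the default: centroided axes carry no baseline to
#'   estimate; set a window for profile-like data).
#' @param top_n feature-picking depth (default 200).
#' @param align_tol_da cross-replicate alignment tolerance (default 0.02).
#' @param deisotope_tol_da isotopologue spacing tolerance (default 0.01).
#' @param n_leaves segmentation leaves (default 8).
#' @param n_restarts 2-means restarts per split (default 10).
#' @param alpha tier-1 FDR level (default 0.05).
#' @param auc_threshold tier-2 AUC cutoff (default 0.7).
#' @param replicate_fraction tier-2 replicate consistency (default 0.5).
#' @param annotation_tol_da accurate-mass search tolerance (default 0.05).
#' @param out_dir artifact directory (default a fresh tempdir subfolder).
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(seed = 1, simulate = TRUE,
                            phantom = phantom_spec(seed = seed),
                            input_paths = NULL, mask_path = NULL,
                            baseline_window = NULL, top_n = 200,
                            align_tol_da = 0.02, deisotope_tol_da = 0.01,
                            n_leaves = 8, n_restarts = 10, alpha = 0.05,
                            auc_threshold = 0.7, replicate_fraction = 0.5,
                            annotation_tol_da = 0.05,
                            out_dir = file.path(tempfile("lipidmsi_run_"))) {
  stopifnot(alpha > 0, alpha < 1, auc_threshold >= 0, auc_threshold <= 1,
            replicate_fraction > 0, replicate_fraction <= 1,
            annotation_tol_da > 0, n_leaves >= 2)
  structure(as.list(environment()), class = "pipeline_config")
}

#' Run the full pipeline
#'
#' Executes the stages in order (simulate or load, preprocess, segment,
#' validate, enrich, annotate), writes every artifact as TSV/CSV into
#' `config$out_dir` together with a JSON manifest of all parameters and
#' per-stage feature counts, and returns the in-memory results. Reruns
#' with an identical config are bit-identical.
#'
#' @param config a `pipeline_config`.
#' @return list with `datasets`, `truth` (when simulated), `tables`,
#'   `aligned`, `cluster_maps`, `overlaps`, `partitions`, `cv`,
#'   `enrichment`, `annotation`, `manifest`, `out_dir`.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  counts <- list()
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  # --- simulate / load ---
  truth <- NULL
  if (isTRUE(config$simulate)) {
    sim <- stage("simulate", simulate_dataset(config$phantom))
    datasets <- sim$datasets
    truth <- sim$truth
    mask <- truth$mask
    write_mask(mask, file.path(config$out_dir, "mask.csv"))
  } else {
    if (is.null(config$input_paths) || is.null(config$mask_path))
      stop("stage 'load' failed: no inputs and simulation disabled",
           call. = FALSE)
    datasets <- stage("load", lapply(config$input_paths, read_imzml))
    mask <- stage("load", read_mask(config$mask_path))
  }
  counts$n_replicates <- length(datasets)
  counts$n_axis_points <- length(datasets[[1]]$mz_axis)

  # --- preprocess ---
  tables <- stage("preprocess", lapply(datasets, function(d) {
    if (!is.null(config$baseline_window))
      d <- baseline_correct(d, window_da = config$baseline_window)
    d <- tic_normalize(d)
    tab <- pick_features(d, top_n = config$top_n)
    deisotope(tab, tol_da = config$deisotope_tol_da)
  }))
  counts$n_features_per_replicate <- vapply(tables, function(t)
    length(t$mz), integer(1))
  aligned <- stage("preprocess",
                   align_features(tables, tol_da = config$align_tol_da))
  counts$n_consensus_features <- nrow(aligned$consensus)

  # --- segment ---
  cluster_maps <- stage("segment", lapply(tables, function(t)
    bisecting_kmeans(t, n_leaves = config$n_leaves, seed = config$seed,
                     n_restarts = config$n_restarts)))
  overlaps <- stage("segment", lapply(cluster_maps, score_overlap, mask))
  partitions <- stage("segment", lapply(cluster_maps,
                                        select_adipose_cluster, mask))
  counts$adipose_cluster_dice <- vapply(partitions, `[[`, numeric(1),
                                        "dice")

  # --- validate ---
  cv <- stage("validate", {
    lapply(stats::setNames(nm = c("muscle", "liver", "adipose")),
           function(lab) {
      rois <- tryCatch(select_rois(mask, lab, n_rois = 3,
                                   seed = config$seed),
                       error = function(e) NULL)
      if (is.null(rois)) return(NULL)
      cv_summary(tables[[1]], rois)
    })
  })

  # --- enrich ---
  enrichment <- stage("enrich",
    enrichment_analysis(aligned, partitions, alpha = config$alpha,
                        auc_threshold = config$auc_threshold,
                        replicate_fraction = config$replicate_fraction))
  counts$n_tier1_candidates <- sum(enrichment$pass_tier1)
  counts$n_enriched <- sum(enrichment$enriched)

  # --- annotate ---
  database <- stage("annotate", build_lipid_database())
  polarity <- datasets[[1]]$polarity
  annotation <- stage("annotate", {
    enr <- enrichment[enrichment$enriched, , drop = FALSE]
    if (nrow(enr) == 0) return(enr[0, c("avg_mz", "polarity")])
    do.call(rbind, lapply(enr$avg_mz, function(m) {
      hits <- accurate_mass_search(m, polarity, database,
                                   tol_da = config$annotation_tol_da)
      utils::head(hits, 3)
    }))
  })
  counts$n_annotated_features <- length(unique(annotation$query_mz))

  # --- report ---
  write_tsv <- function(df, name)
    utils::write.table(df, file.path(config$out_dir, name), sep = "\t",
                       row.names = FALSE, quote = FALSE)
  write_tsv(as.data.frame(enrichment), "enrichment.tsv")
  write_tsv(summarize_enrichment(enrichment), "enrichment_summary.tsv")
  if (nrow(annotation) > 0) write_tsv(annotation, "annotation.tsv")
  write_tsv(do.call(rbind, lapply(seq_along(overlaps), function(i)
    cbind(replicate = i, overlaps[[i]]$per_leaf))), "overlap.tsv")
  cfg <- config
  cfg$phantom <- if (isTRUE(config$simulate))
    cfg$phantom[setdiff(names(cfg$phantom), "panel")] else NULL
  manifest <- list(parameters = cfg, stage_counts = counts,
                   stages_completed = c("simulate", "preprocess", "segment",
                                        "validate", "enrich", "annotate"))
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, force = TRUE,
                       digits = NA)
  list(datasets = datasets, truth = truth, tables = tables,
       aligned = aligned, cluster_maps = cluster_maps, overlaps = overlaps,
       partitions = partitions, cv = cv, enrichment = enrichment,
       annotation = annotation, manifest = manifest,
       out_dir = config$out_dir)
}

#' Render an ion image
#'
#' Per-pixel intensity of one feature (summed over axis points within
#' `tol_da`), scaled to percent of the maximum, with pixels below
#' `floor_percent` masked to `NA` - the display convention of superimposed
#' ion images (signal scaled 20%-100% of maximum, sub-threshold pixels
#' omitted).
#'
#' @param dataset an `msi_dataset`.
#' @param feature_mz feature m/z (must lie within the axis range).
#' @param tol_da half-width of the extraction window (default 0.01).
#' @param floor_percent masking threshold in percent of maximum
#'   (default 20).
#' @return height x width numeric matrix of percentages (NA = masked).
#' @export
render_ion_image <- function(dataset, feature_mz, tol_da = 0.01,
                             floor_percent = 20) {
  validate_msi_dataset(dataset)
  if (feature_mz < min(dataset$mz_axis) - tol_da ||
      feature_mz > max(dataset$mz_axis) + tol_da)
    stop("feature m/z outside the dataset axis")
  cols <- which(abs(dataset$mz_axis - feature_mz) <= tol_da)
  if (length(cols) == 0) stop("no axis point within tolerance of feature")
  v <- rowSums(dataset$intensities[, cols, drop = FALSE])
  pct <- 100 * v / max(v)
  pct[pct < floor_percent] <- NA_real_
  matrix(pct, nrow = dataset$height, ncol = dataset$width, byrow = TRUE)
}
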