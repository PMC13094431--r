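# MSI dataset container and the standard formats the pipeline touches:
# continuous-mode imzML 1.1 (.imzML + .ibd), label masks (CSV / indexed PNG
# with a legend sidecar) and the packaged adipose-lipid reference table.

TISSUE_LABELS <- c("background", "muscle", "liver", "brain", "eye", "gill",
                   "adipose", "other")

#' MSI dataset
#'
#' A pixel grid of centroided spectra sharing one m/z axis, the in-memory
#' representation of a continuous-mode imzML file. Pixels are stored
#' row-major (0-based x = column, y = row; pixel index `y * width + x + 1`).
#'
#' @param replicate_id replicate identifier.
#' @param polarity `"positive"` or `"negative"`.
#' @param width,height grid dimensions in pixels.
#' @param mz_axis strictly increasing m/z values within the acquisition
#'   range 100-1200 Da.
#' @param intensities numeric matrix, `width * height` rows (pixels) by
#'   `length(mz_axis)` columns, all values >= 0.
#' @param pixel_size_um pixel edge length in micrometers (default 50).
#' @param metadata free-form named list (e.g. the ammonium-acetate
#'   pretreatment flag for positive mode).
#' @return A validated `msi_dataset`.
#' @export
msi_dataset <- function(replicate_id, polarity, width, height, mz_axis,
                        intensities, pixel_size_um = 50, metadata = list()) {
  x <- structure(list(
    replicate_id = as.character(replicate_id),
    polarity = polarity,
    pixel_size_um = pixel_size_um,
    width = as.integer(width),
    height = as.integer(height),
    mz_axis = as.numeric(mz_axis),
    intensities = as.matrix(intensities),
    metadata = metadata
  ), class = "msi_dataset")
  validate_msi_dataset(x)
}

validate_msi_dataset <- function(x) {
  stopifnot(inherits(x, "msi_dataset"))
  if (!x$polarity %in% c("positive", "negative"))
    stop("polarity must be 'positive' or 'negative'")
  if (x$width < 1 || x$height < 1) stop("width x height must be >= 1")
  n <- length(x$mz_axis)
  if (n == 0) stop("empty m/z axis")
  if (any(diff(x$mz_axis) <= 0)) stop("m/z axis must be strictly increasing")
  if (min(x$mz_axis) < 100 || max(x$mz_axis) > 1200)
    stop("m/z axis outside the acquisition range [100, 1200] Da")
  if (nrow(x$intensities) != x$width * x$height)
    stop("intensity matrix must have width*height rows")
  if (ncol(x$intensities) != n)
    stop("intensity matrix must have one column per m/z axis point")
  if (any(x$intensities < 0)) stop("negative intensities")
  x
}

#' @export
print.msi_dataset <- function(x, ...) {
  cat("MSI dataset '", x$replicate_id, "': ", x$width, " x ", x$height,
      " px (", x$pixel_size_um, " um), ", length(x$mz_axis),
      " m/z points [", sprintf("%.2f", min(x$mz_axis)), "-",
      sprintf("%.2f", max(x$mz_axis)), "], ", x$polarity, " mode\n",
      sep = "")
  invisible(x)
}

#' Per-pixel total ion current
#'
#' @param dataset an `msi_dataset`.
#' @return numeric vector of pixel TICs (row sums of the intensity matrix).
#' @export
pixel_tic <- function(dataset) {
  rowSums(dataset$intensities)
}

#' Tissue label mask
#'
#' @param labels character vector (length `width * height`, row-major) or
#'   matrix (`height` rows x `width` columns) of labels from
#'   `r paste(TISSUE_LABELS, collapse = ", ")`.
#' @param width,height grid dimensions; inferred when `labels` is a matrix.
#' @return A `tissue_mask` (list with `width`, `height`, `labels` vector).
#' @export
tissue_mask <- function(labels, width = NULL, height = NULL) {
  if (is.matrix(labels)) {
    height <- nrow(labels); width <- ncol(labels)
    labels <- as.vector(t(labels))   # row-major
  }
  labels <- trimws(as.character(labels))
  stopifnot(length(labels) == width * height)
  bad <- setdiff(unique(labels), TISSUE_LABELS)
  if (length(bad) > 0)
    stop("unknown tissue label(s): ", paste(bad, collapse = ", "))
  structure(list(width = as.integer(width), height = as.integer(height),
                 labels = labels), class = "tissue_mask")
}

#' @export
print.tissue_mask <- function(x, ...) {
  tab <- table(x$labels)
  cat("Tissue mask ", x$width, " x ", x$height, " px: ",
      paste(names(tab), tab, sep = "=", collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Mask labels as a height x width matrix
#' @param mask a `tissue_mask`.
#' @export
mask_matrix <- function(mask) {
  matrix(mask$labels, nrow = mask$height, ncol = mask$width, byrow = TRUE)
}

## ---- imzML ---------------------------------------------------------------

imzml_paths <- function(path) {
  base <- sub("\\.imzML$", "", path, ignore.case = TRUE)
  list(imzml = paste0(base, ".imzML"), ibd = paste0(base, ".ibd"))
}

#' Write a continuous-mode imzML file pair
#'
#' Serializes an `msi_dataset` as imzML 1.1 continuous mode: the shared m/z
#' axis stored once as 64-bit floats, per-pixel intensities as 32-bit
#' floats, coordinates converted to the 1-based imzML convention.
#'
#' @param dataset an `msi_dataset`.
#' @param path output path (`.imzML`; the `.ibd` companion is written next
#'   to it).
#' @return The imzML path, invisibly.
#' @export
write_imzml <- function(dataset, path) {
  validate_msi_dataset(dataset)
  p <- imzml_paths(path)
  nmz <- length(dataset$mz_axis)
  npx <- dataset$width * dataset$height
  uuid <- paste0(sprintf("%08x", as.integer(sum(utf8ToInt(
    dataset$replicate_id)) %% .Machine$integer.max)),
    "-0000-0000-0000-000000000000")

  # ibd: 16-byte identifier, m/z axis once (float64), then intensities
  # (float32) pixel by pixel in row-major order.
  ibd <- file(p$ibd, "wb")
  writeBin(as.raw(rep(0L, 16)), ibd)
  writeBin(dataset$mz_axis, ibd, size = 8, endian = "little")
  for (i in seq_len(npx))
    writeBin(as.numeric(dataset$intensities[i, ]), ibd, size = 4,
             endian = "little")
  close(ibd)

  mz_offset <- 16
  int_offsets <- 16 + 8 * nmz + 4 * nmz * (seq_len(npx) - 1)
  pol_cv <- if (dataset$polarity == "positive")
    '<cvParam cvRef="MS" accession="MS:1000130" name="positive scan"/>'
  else
    '<cvParam cvRef="MS" accession="MS:1000129" name="negative scan"/>'

  spectra <- vapply(seq_len(npx), function(i) {
    x1 <- (i - 1) %% dataset$width + 1        # imzML is 1-based
    y1 <- (i - 1) %/% dataset$width + 1
    paste0(
      '<spectrum id="spectrum=', i, '" index="', i - 1,
      '" defaultArrayLength="0">', pol_cv,
      '<scanList count="1"><scan>',
      '<cvParam cvRef="IMS" accession="IMS:1000050" name="position x" value="',
      x1, '"/>',
      '<cvParam cvRef="IMS" accession="IMS:1000051" name="position y" value="',
      y1, '"/>',
      '</scan></scanList>',
      '<binaryDataArrayList count="2">',
      '<binaryDataArray encodedLength="0">',
      '<referenceableParamGroupRef ref="mzArray"/>',
      '<cvParam cvRef="IMS" accession="IMS:1000103" name="external array length" value="', nmz, '"/>',
      '<cvParam cvRef="IMS" accession="IMS:1000102" name="external offset" value="', mz_offset, '"/>',
      '<cvParam cvRef="IMS" accession="IMS:1000104" name="external encoded length" value="', 8 * nmz, '"/>',
      '<binary/></binaryDataArray>',
      '<binaryDataArray encodedLength="0">',
      '<referenceableParamGroupRef ref="intensityArray"/>',
      '<cvParam cvRef="IMS" accession="IMS:1000103" name="external array length" value="', nmz, '"/>',
      '<cvParam cvRef="IMS" accession="IMS:1000102" name="external offset" value="',
      format(int_offsets[i], scientific = FALSE), '"/>',
      '<cvParam cvRef="IMS" accession="IMS:1000104" name="external encoded length" value="', 4 * nmz, '"/>',
      '<binary/></binaryDataArray>',
      '</binaryDataArrayList></spectrum>')
  }, character(1))

  xml <- paste0(
    '<?xml version="1.0" encoding="UTF-8"?>\n',
    '<mzML xmlns="http://psi.hupo.org/ms/mzml" version="1.1">',
    '<cvList count="3">',
    '<cv id="MS" fullName="Proteomics Standards Initiative Mass Spectrometry Ontology" URI="http://psidev.info/ms/mzML/psi-ms.obo"/>',
    '<cv id="UO" fullName="Unit Ontology" URI="http://obo.cvs.sourceforge.net/obo/obo/ontology/phenotype/unit.obo"/>',
    '<cv id="IMS" fullName="Imaging MS Ontology" URI="http://www.maldi-msi.org/download/imzml/imagingMS.obo"/>',
    '</cvList>',
    '<fileDescription><fileContent>',
    '<cvParam cvRef="IMS" accession="IMS:1000030" name="continuous"/>',
    '<cvParam cvRef="IMS" accession="IMS:1000080" name="universally unique identifier" value="{', uuid, '}"/>',
    '<userParam name="replicate_id" value="', dataset$replicate_id, '"/>',
    '</fileContent></fileDescription>',
    '<referenceableParamGroupList count="2">',
    '<referenceableParamGroup id="mzArray">',
    '<cvParam cvRef="MS" accession="MS:1000514" name="m/z array" unitCvRef="MS" unitAccession="MS:1000040" unitName="m/z"/>',
    '<cvParam cvRef="MS" accession="MS:1000523" name="64-bit float"/>',
    '<cvParam cvRef="MS" accession="MS:1000576" name="no compression"/>',
    '<cvParam cvRef="IMS" accession="IMS:1000101" name="external data" value="true"/>',
    '</referenceableParamGroup>',
    '<referenceableParamGroup id="intensityArray">',
    '<cvParam cvRef="MS" accession="MS:1000515" name="intensity array" unitCvRef="MS" unitAccession="MS:1000131" unitName="number of detector counts"/>',
    '<cvParam cvRef="MS" accession="MS:1000521" name="32-bit float"/>',
    '<cvParam cvRef="MS" accession="MS:1000576" name="no compression"/>',
    '<cvParam cvRef="IMS" accession="IMS:1000101" name="external data" value="true"/>',
    '</referenceableParamGroup>',
    '</referenceableParamGroupList>',
    '<softwareList count="1"><software id="lipidmsi" version="0.1.0"/></softwareList>',
    '<scanSettingsList count="1"><scanSettings id="scanSettings1">',
    '<cvParam cvRef="IMS" accession="IMS:1000042" name="max count of pixels x" value="', dataset$width, '"/>',
    '<cvParam cvRef="IMS" accession="IMS:1000043" name="max count of pixels y" value="', dataset$height, '"/>',
    '<cvParam cvRef="IMS" accession="IMS:1000046" name="pixel size (x)" value="', dataset$pixel_size_um, '"/>',
    '</scanSettings></scanSettingsList>',
    '<instrumentConfigurationList count="1"><instrumentConfiguration id="IC1"/></instrumentConfigurationList>',
    '<dataProcessingList count="1"><dataProcessing id="export">',
    '<processingMethod order="1" softwareRef="lipidmsi">',
    '<cvParam cvRef="MS" accession="MS:1000544" name="Conversion to mzML"/>',
    '</processingMethod></dataProcessing></dataProcessingList>',
    '<run id="run1" defaultInstrumentConfigurationRef="IC1">',
    '<spectrumList count="', npx, '" defaultDataProcessingRef="export">',
    paste(spectra, collapse = ""),
    '</spectrumList></run></mzML>')
  writeLines(xml, p$imzml)
  invisible(p$imzml)
}

#' Read a continuous-mode imzML file pair
#'
#' @param path path to the `.imzML` file (its `.ibd` companion must sit next
#'   to it).
#' @param replicate_id replicate identifier for the returned dataset;
#'   defaults to the stored `replicate_id` user parameter or the file stem.
#' @return An `msi_dataset`. Processed-mode files are rejected.
#' @export
read_imzml <- function(path, replicate_id = NULL) {
  p <- imzml_paths(path)
  if (!file.exists(p$imzml)) stop("imzML file not found: ", p$imzml)
  if (!file.exists(p$ibd))
    stop("format error: missing .ibd companion for ", p$imzml)
  doc <- xml2::read_xml(p$imzml)
  xml2::xml_ns_strip(doc)

  fc <- xml2::xml_find_all(doc, ".//fileDescription/fileContent/cvParam")
  modes <- xml2::xml_attr(fc, "name")
  if ("processed" %in% modes)
    stop("unsupported imzML dialect: processed mode (continuous mode required)")
  if (!"continuous" %in% modes)
    stop("format error: imzML file declares neither continuous nor processed mode")

  if (is.null(replicate_id)) {
    up <- xml2::xml_find_first(doc,
      ".//fileDescription/fileContent/userParam[@name='replicate_id']")
    replicate_id <- if (!inherits(up, "xml_missing"))
      xml2::xml_attr(up, "value")
    else sub("\\.imzML$", "", basename(p$imzml), ignore.case = TRUE)
  }

  px_size <- xml2::xml_find_first(doc,
    ".//scanSettings/cvParam[@accession='IMS:1000046']")
  pixel_size_um <- if (!inherits(px_size, "xml_missing"))
    as.numeric(xml2::xml_attr(px_size, "value")) else 50

  spectra <- xml2::xml_find_all(doc, ".//run/spectrumList/spectrum")
  if (length(spectra) == 0) stop("format error: no spectra in ", p$imzml)
  attr1 <- function(nodes, xpath, what = "value")
    xml2::xml_attr(xml2::xml_find_first(nodes, xpath), what)
  xs <- as.integer(vapply(spectra, attr1,
    ".//cvParam[@accession='IMS:1000050']", FUN.VALUE = character(1)))
  ys <- as.integer(vapply(spectra, attr1,
    ".//cvParam[@accession='IMS:1000051']", FUN.VALUE = character(1)))
  pol <- if (length(xml2::xml_find_all(spectra[[1]],
    ".//cvParam[@accession='MS:1000130']")) > 0 ||
    !inherits(xml2::xml_find_first(spectra[[1]],
      "cvParam[@accession='MS:1000130']"), "xml_missing"))
    "positive" else "negative"

  get_arrays <- function(sp) {
    bdas <- xml2::xml_find_all(sp, ".//binaryDataArray")
    out <- lapply(bdas, function(b) {
      ref <- xml2::xml_attr(
        xml2::xml_find_first(b, "referenceableParamGroupRef"), "ref")
      list(ref = ref,
           len = as.integer(attr1(b, "cvParam[@accession='IMS:1000103']")),
           offset = as.numeric(attr1(b, "cvParam[@accession='IMS:1000102']")))
    })
    names(out) <- vapply(out, `[[`, character(1), "ref")
    out
  }
  first <- get_arrays(spectra[[1]])
  nmz <- first$mzArray$len

  ibd <- file(p$ibd, "rb")
  on.exit(close(ibd))
  seek(ibd, first$mzArray$offset)
  mz_axis <- readBin(ibd, numeric(), n = nmz, size = 8, endian = "little")
  if (any(diff(mz_axis) <= 0))
    stop("validation error: stored m/z axis is not strictly increasing")

  width <- max(xs); height <- max(ys)
  ints <- matrix(0, nrow = width * height, ncol = nmz)
  for (i in seq_along(spectra)) {
    arr <- get_arrays(spectra[[i]])$intensityArray
    seek(ibd, arr$offset)
    v <- readBin(ibd, numeric(), n = arr$len, size = 4, endian = "little")
    ints[(ys[i] - 1) * width + xs[i], ] <- v   # 1-based imzML -> row-major
  }
  msi_dataset(replicate_id, pol, width, height, mz_axis, ints,
              pixel_size_um = pixel_size_um)
}

## ---- masks ---------------------------------------------------------------

#' Read a tissue label mask
#'
#' CSV masks hold one label name per cell (no header); labels are
#' whitespace-normalized. Indexed PNG masks need a legend sidecar
#' (`<path>.legend`, tab-separated `index<TAB>label` rows mapping 0-255
#' gray values to label names).
#'
#' @param path mask file (`.csv` or `.png`).
#' @param expected_dim optional `c(width, height)` to validate against.
#' @return A `tissue_mask`.
#' @export
read_mask <- function(path, expected_dim = NULL) {
  if (grepl("\\.png$", path, ignore.case = TRUE)) {
    img <- png::readPNG(path)
    if (length(dim(img)) == 3) img <- img[, , 1]
    legend_path <- paste0(path, ".legend")
    if (!file.exists(legend_path))
      stop("missing legend sidecar for PNG mask: ", legend_path)
    leg <- utils::read.delim(legend_path, header = FALSE,
                             col.names = c("index", "label"))
    idx <- round(img * 255)
    lab <- leg$label[match(as.vector(idx), leg$index)]
    if (anyNA(lab)) stop("PNG gray value missing from legend sidecar")
    m <- matrix(trimws(lab), nrow = nrow(img), ncol = ncol(img))
  } else {
    rows <- utils::read.csv(path, header = FALSE, stringsAsFactors = FALSE,
                            strip.white = TRUE, colClasses = "character")
    m <- as.matrix(rows)
  }
  mask <- tissue_mask(m)
  if (!is.null(expected_dim)) {
    if (mask$width != expected_dim[1] || mask$height != expected_dim[2])
      stop("mask dimensions ", mask$width, "x", mask$height,
           " do not match expected ", expected_dim[1], "x", expected_dim[2])
  }
  mask
}

#' Write a tissue label mask as CSV
#'
#' @param mask a `tissue_mask`.
#' @param path output CSV path.
#' @export
write_mask <- function(mask, path) {
  stopifnot(inherits(mask, "tissue_mask"))
  utils::write.table(mask_matrix(mask), path, sep = ",", row.names = FALSE,
                     col.names = FALSE, quote = FALSE)
  invisible(path)
}

## ---- reference table -----------------------------------------------------

#' Load the packaged adipose-enriched lipid reference table
#'
#' Parses the tab-separated transcription of the published table of
#' high-confidence adipose-enriched lipids (52 species identified by
#' integrated imaging and surface-extraction MS2). Adduct strings are
#' canonicalized and the comma-separated adduct lists split into list
#' columns.
#'
#' @param path TSV path; defaults to the copy shipped with the package.
#' @return data.frame with one row per lipid: `polarity` (`"positive"` /
#'   `"negative"`), `desi_avg_mz`, `desi_between_rep_ppm`, `annotation`,
#'   `desi_adduct`, `other_adducts_enriched` (list), intensity/fold/AUC
#'   summaries, `lesa_observed_ms1`, `dominant_fa_composition`,
#'   `lesa_adduct`, `other_adducts_detected` (list), `lipid_class`,
#'   `lesa_delta_ppm`.
#' @export
load_table1 <- function(path = system.file("extdata",
                                           "table1_adipose_lipids.tsv",
                                           package = "lipidmsi")) {
  raw <- utils::read.delim(path, stringsAsFactors = FALSE,
                           colClasses = "character")
  num <- function(col) {
    v <- suppressWarnings(as.numeric(raw[[col]]))
    if (anyNA(v)) stop("non-numeric value in column ", col)
    v
  }
  split_adducts <- function(col) {
    lapply(raw[[col]], function(s) {
      s <- trimws(s)
      if (s == "-" || s == "") return(character(0))
      canonical_adduct(trimws(strsplit(s, ",")[[1]]))
    })
  }
  out <- data.frame(
    polarity = ifelse(raw$polarity == "+", "positive", "negative"),
    desi_avg_mz = num("desi_avg_mz"),
    desi_between_rep_ppm = num("desi_between_rep_ppm"),
    annotation = trimws(raw$annotation),
    desi_adduct = canonical_adduct(trimws(raw$desi_adduct)),
    avg_intensity_adipose = num("avg_intensity_adipose"),
    avg_intensity_nonadipose = num("avg_intensity_nonadipose"),
    avg_fold_change = num("avg_fold_change"),
    avg_roc = num("avg_roc"),
    lesa_observed_ms1 = num("lesa_observed_ms1"),
    dominant_fa_composition = trimws(raw$dominant_fa_composition),
    lesa_adduct = canonical_adduct(trimws(raw$lesa_adduct)),
    lipid_class = trimws(raw$lipid_class),
    lesa_delta_ppm = num("lesa_delta_ppm"),
    stringsAsFactors = FALSE
  )
  out$other_adducts_enriched <- split_adducts("other_adducts_enriched")
  out$other_adducts_detected <- split_adducts("other_adducts_detected")
  stopifnot(all(out$avg_fold_change > 0),
            all(out$avg_roc >= 0 & out$avg_roc <= 1),
            all(out$desi_avg_mz >= 100 & out$desi_avg_mz <= 1200),
            all(out$lesa_observed_ms1 >= 100 & out$lesa_observed_ms1 <= 1200))
  out
}
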