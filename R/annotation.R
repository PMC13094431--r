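# Accurate-mass annotation against a combinatorial lipid database, MS2
# diagnostic-fragment rules and the cross-modal Level-2 identification rule.

# Default class grid: wide enough to cover every adipose-enriched species
# reported for the zebrafish sections (FA 12-24, DG 28-40, TG 40-60, PC/PE/
# PEe/PI 30-44, LPE 14-22) at biologically plausible unsaturation.
default_database_grid <- function() {
  list(
    FA  = list(carbons = 12:24, double_bonds = 0:6,  oxygens = 0:1),
    DG  = list(carbons = 28:40, double_bonds = 0:6,  oxygens = 0),
    TG  = list(carbons = 40:60, double_bonds = 0:10, oxygens = 0),
    PC  = list(carbons = 30:44, double_bonds = 0:10, oxygens = 0),
    PE  = list(carbons = 30:44, double_bonds = 0:10, oxygens = 0),
    PEe = list(carbons = 30:44, double_bonds = 0:10, oxygens = 0),
    PI  = list(carbons = 30:44, double_bonds = 0:10, oxygens = 0),
    LPE = list(carbons = 14:22, double_bonds = 0:2,  oxygens = 0)
  )
}

#' Build a combinatorial lipid annotation database
#'
#' Enumerates lipid species over per-class carbon/double-bond/extra-oxygen
#' grids and precomputes every adduct m/z. The packaged default grid covers
#' all species reported enriched in zebrafish adipose tissue and serves as a
#' self-contained stand-in for an online lipid database query.
#'
#' @param grid named list (class -> list(carbons, double_bonds, oxygens));
#'   defaults to `default_database_grid()`.
#' @param adducts character vector of adduct names to precompute; defaults
#'   to all supported adducts.
#' @return A `lipid_database`: data.frame with one row per (species, adduct):
#'   `shorthand`, `lipid_class`, `carbons`, `double_bonds`, `oxygen_extra`,
#'   `mass`, `adduct`, `polarity`, `mz`.
#' @export
build_lipid_database <- function(grid = default_database_grid(),
                                 adducts = ADDUCTS$name) {
  if (length(grid) == 0) stop("empty class grid")
  stopifnot(!is.null(names(grid)))
  adducts <- canonical_adduct(adducts)
  ad <- ADDUCTS[match(adducts, ADDUCTS$name), ]
  species <- do.call(rbind, lapply(names(grid), function(cls) {
    g <- grid[[cls]]
    ox <- if (is.null(g$oxygens)) 0L else g$oxygens
    expand.grid(lipid_class = cls, carbons = g$carbons,
                double_bonds = g$double_bonds, oxygen_extra = ox,
                stringsAsFactors = FALSE)
  }))
  species$mass <- mapply(function(cls, c0, d, x)
    formula_mass(lipid_formula(cls, c0, d, x)),
    species$lipid_class, species$carbons, species$double_bonds,
    species$oxygen_extra)
  species$shorthand <- paste0(
    species$lipid_class, "(", species$carbons, ":", species$double_bonds,
    ifelse(species$oxygen_extra == 1, ";O",
           ifelse(species$oxygen_extra > 1,
                  paste0(";O", species$oxygen_extra), "")), ")")
  db <- do.call(rbind, lapply(seq_len(nrow(ad)), function(i) {
    out <- species
    out$adduct <- ad$name[i]
    out$polarity <- ad$polarity[i]
    out$mz <- out$mass + ad$mass_shift[i]
    out
  }))
  rownames(db) <- NULL
  class(db) <- c("lipid_database", "data.frame")
  db
}

#' Accurate-mass search
#'
#' Finds all (lipid, adduct) pairs of the requested polarity whose
#' theoretical m/z lies within `tol_da` of the query, the putative
#' annotation step of the imaging workflow.
#'
#' @param query_mz query m/z in Da.
#' @param polarity `"positive"` or `"negative"`.
#' @param database a `lipid_database`.
#' @param tol_da search half-width in Da (default 0.05).
#' @return data.frame of hits sorted by |delta_ppm| (ties: lipid class, then
#'   carbons): `query_mz`, `shorthand`, `lipid_class`, `carbons`,
#'   `double_bonds`, `oxygen_extra`, `mass`, `adduct`, `theoretical_mz`,
#'   `delta_da`, `delta_ppm`. Zero rows when nothing matches.
#' @export
accurate_mass_search <- function(query_mz, polarity, database,
                                 tol_da = 0.05) {
  stopifnot(tol_da > 0, length(query_mz) == 1,
            polarity %in% c("positive", "negative"))
  hit <- database[database$polarity == polarity &
                  abs(database$mz - query_mz) <= tol_da, , drop = FALSE]
  if (nrow(hit) == 0) {
    out <- data.frame(query_mz = numeric(), shorthand = character(),
                      lipid_class = character(), carbons = integer(),
                      double_bonds = integer(), oxygen_extra = integer(),
                      mass = numeric(), adduct = character(),
                      theoretical_mz = numeric(), delta_da = numeric(),
                      delta_ppm = numeric(), stringsAsFactors = FALSE)
    return(out)
  }
  out <- data.frame(
    query_mz = query_mz,
    shorthand = hit$shorthand,
    lipid_class = hit$lipid_class,
    carbons = hit$carbons,
    double_bonds = hit$double_bonds,
    oxygen_extra = hit$oxygen_extra,
    mass = hit$mass,
    adduct = hit$adduct,
    theoretical_mz = hit$mz,
    stringsAsFactors = FALSE
  )
  out$delta_da <- query_mz - out$theoretical_mz
  out$delta_ppm <- ppm_deviation(query_mz, out$theoretical_mz)
  ord <- order(abs(out$delta_ppm), out$lipid_class, out$carbons)
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Neutral monoisotopic mass of a free fatty acid chain c:d.
fa_neutral_mass <- function(carbons, double_bonds) {
  formula_mass(lipid_formula("FA", carbons, double_bonds, 0))
}

#' Class-diagnostic MS2 fragment rules
#'
#' Returns the diagnostic fragment m/z expected for a lipid/adduct pair:
#' \itemize{
#'   \item FA (incl. oxidized) as `[M-H]-`: water loss and CO2 loss from the
#'     deprotonated precursor.
#'   \item TG as `[M+Na]+`: neutral loss of each distinct fatty acyl as the
#'     free acid; as `[M+NH4]+`: the same losses plus NH3.
#'   \item DG as `[M+H-H2O]+`: loss of each distinct acyl as the free acid.
#'   \item PC, positive adducts: the phosphocholine head-group ion 184.0733.
#'   \item PE/PEe/PI/PG/PS as `[M-H]-`: fatty acyl carboxylate anions.
#'   \item LPE as `[M-H]-`: the carboxylate anion of its single chain.
#' }
#' Chain-resolved rules need acyl compositions: either stored on the
#' `lipid_record` (chain-resolved shorthand) or passed via `chains`.
#'
#' @param lipid a `lipid_record`.
#' @param adduct adduct name or spec.
#' @param chains optional list of `c(carbons, double_bonds)` overriding the
#'   record's chains (e.g. the dominant composition from MS2).
#' @return named numeric vector of fragment m/z.
#' @export
fragment_rules <- function(lipid, adduct, chains = NULL) {
  stopifnot(inherits(lipid, "lipid_record"))
  if (is.character(adduct)) adduct <- adduct_spec(adduct)
  prec <- adduct_mz(lipid, adduct)
  cls <- lipid$lipid_class
  if (is.null(chains)) chains <- lipid$chains
  need_chains <- function() {
    if (is.null(chains))
      stop("fragment rules for ", cls, " need acyl chain compositions")
    unique(lapply(chains, function(ch) as.integer(ch[1:2])))
  }
  if (cls == "FA" && adduct$name == "[M-H]-") {
    return(c(water_loss = prec - WATER_MASS, co2_loss = prec - CO2_MASS))
  }
  if (cls == "TG" && adduct$name %in% c("[M+Na]+", "[M+NH4]+")) {
    ch <- need_chains()
    losses <- vapply(ch, function(x) fa_neutral_mass(x[1], x[2]), numeric(1))
    extra <- if (adduct$name == "[M+NH4]+") NH3_MASS else 0
    out <- prec - losses - extra
    names(out) <- vapply(ch, function(x)
      paste0("acyl_loss_", x[1], ":", x[2]), character(1))
    return(out)
  }
  if (cls == "DG" && adduct$name == "[M+H-H2O]+") {
    ch <- need_chains()
    out <- prec - vapply(ch, function(x) fa_neutral_mass(x[1], x[2]),
                         numeric(1))
    names(out) <- vapply(ch, function(x)
      paste0("acyl_loss_", x[1], ":", x[2]), character(1))
    return(out)
  }
  if (cls == "PC" && adduct$polarity == "positive") {
    return(c(phosphocholine_head = PC_HEAD_FRAGMENT))
  }
  if (cls %in% c("PE", "PEe", "PI", "PG", "PS") &&
      adduct$name == "[M-H]-") {
    ch <- need_chains()
    out <- vapply(ch, function(x)
      fa_neutral_mass(x[1], x[2]) - PROTON_MASS, numeric(1))
    names(out) <- vapply(ch, function(x)
      paste0("carboxylate_", x[1], ":", x[2]), character(1))
    return(out)
  }
  if (cls == "LPE" && adduct$name == "[M-H]-") {
    ch <- if (!is.null(chains)) unique(lapply(chains, function(x)
      as.integer(x[1:2])))
      else list(c(lipid$total_carbons, lipid$total_double_bonds))
    out <- vapply(ch, function(x)
      fa_neutral_mass(x[1], x[2]) - PROTON_MASS, numeric(1))
    names(out) <- vapply(ch, function(x)
      paste0("carboxylate_", x[1], ":", x[2]), character(1))
    return(out)
  }
  stop("no fragment rule for class ", cls, " with adduct ", adduct$name)
}

#' Construct an MS2 spectrum object
#'
#' @param precursor_mz precursor m/z.
#' @param polarity `"positive"` or `"negative"`.
#' @param fragments two-column matrix/data.frame (mz, intensity).
#' @return An `ms2_spectrum` object.
#' @export
ms2_spectrum <- function(precursor_mz, polarity, fragments) {
  fragments <- as.matrix(fragments)
  colnames(fragments) <- c("mz", "intensity")
  stopifnot(precursor_mz > 0, polarity %in% c("positive", "negative"),
            all(fragments[, "intensity"] >= 0),
            all(fragments[, "mz"] < precursor_mz + 1))
  structure(list(precursor_mz = precursor_mz, polarity = polarity,
                 fragments = fragments), class = "ms2_spectrum")
}

#' @export
print.ms2_spectrum <- function(x, ...) {
  cat("MS2 spectrum: precursor m/z ", sprintf("%.4f", x$precursor_mz),
      " (", x$polarity, "), ", nrow(x$fragments), " fragments\n", sep = "")
  invisible(x)
}

#' Match an MS2 spectrum against annotation candidates
#'
#' For each candidate hit whose theoretical precursor lies within the 1-Da
#' isolation window (`precursor_tol_da` half-width 0.5), counts the
#' class-diagnostic rule fragments found in the spectrum within `tol_ppm`.
#' The best candidate has the most matched fragments (ties broken by
#' precursor |delta ppm|); candidates with zero matched fragments are
#' rejected. Candidates whose class/adduct has no applicable rule (e.g. no
#' chain information) contribute no evidence and are likewise rejected.
#'
#' @param spectrum an `ms2_spectrum`.
#' @param candidates data.frame of annotation hits
#'   (`accurate_mass_search()` output), optionally with a `chains` list
#'   column of acyl compositions.
#' @param tol_ppm fragment match tolerance in ppm (default 5).
#' @param precursor_tol_da precursor window half-width (default 0.5).
#' @return data.frame with the winning candidate and `n_matched`, or zero
#'   rows when no candidate has fragment evidence.
#' @export
match_ms2 <- function(spectrum, candidates, tol_ppm = 5,
                      precursor_tol_da = 0.5) {
  stopifnot(inherits(spectrum, "ms2_spectrum"))
  if (nrow(candidates) == 0) return(candidates)
  keep <- abs(spectrum$precursor_mz - candidates$theoretical_mz) <=
    precursor_tol_da
  candidates <- candidates[keep, , drop = FALSE]
  if (nrow(candidates) == 0) return(candidates)
  frag_mz <- spectrum$fragments[, "mz"]
  n_matched <- vapply(seq_len(nrow(candidates)), function(i) {
    rec <- parse_shorthand(candidates$shorthand[i])
    ch <- if ("chains" %in% names(candidates)) candidates$chains[[i]] else NULL
    rules <- tryCatch(fragment_rules(rec, candidates$adduct[i], chains = ch),
                      error = function(e) numeric(0))
    if (length(rules) == 0) return(0L)
    sum(vapply(rules, function(f)
      any(abs(frag_mz - f) / f * 1e6 <= tol_ppm), logical(1)))
  }, integer(1))
  prec_ppm <- abs(ppm_deviation(spectrum$precursor_mz,
                                candidates$theoretical_mz))
  ok <- n_matched > 0
  if (!any(ok)) return(candidates[0, , drop = FALSE])
  idx <- which(ok)[order(-n_matched[ok], prec_ppm[ok])][1]
  out <- candidates[idx, , drop = FALSE]
  out$n_matched <- n_matched[idx]
  rownames(out) <- NULL
  out
}

#' Cross-modal Level-2 identification
#'
#' Applies the integration rule of the workflow: a lipid counts as a Level-2
#' identification when the imaging experiment and the surface-extraction
#' MS2 experiment detect the same lipid annotation as the same adduct.
#'
#' @param desi data.frame of imaging-side annotations with columns
#'   `annotation` (shorthand) and `adduct`, plus any identifier columns.
#' @param lesa data.frame of MS2-side identifications with columns
#'   `annotation` and `adduct`.
#' @return data.frame of matched records, one row per (desi row, lipid,
#'   adduct) pair, with columns from both sides (lesa columns prefixed
#'   `lesa_` where they collide).
#' @export
level2_crossmatch <- function(desi, lesa) {
  stopifnot(all(c("annotation", "adduct") %in% names(desi)),
            all(c("annotation", "adduct") %in% names(lesa)))
  norm_ann <- function(x) vapply(x, function(s)
    parse_shorthand(s)$shorthand, character(1), USE.NAMES = FALSE)
  dkey <- paste(norm_ann(desi$annotation), canonical_adduct(desi$adduct))
  lkey <- paste(norm_ann(lesa$annotation), canonical_adduct(lesa$adduct))
  idx <- match(dkey, lkey)
  hit <- !is.na(idx)
  if (!any(hit)) return(desi[0, , drop = FALSE])
  out <- desi[hit, , drop = FALSE]
  lsub <- lesa[idx[hit], , drop = FALSE]
  clash <- intersect(names(lsub), names(out))
  names(lsub)[match(clash, names(lsub))] <- paste0("lesa_", clash)
  out <- cbind(out, lsub)
  out$level <- 2L
  rownames(out) <- NULL
  out
}

#' Read / write a centroided peak list
#'
#' Plain-text two-column (m/z, intensity) format with `# key: value` header
#' lines carrying the precursor m/z and polarity.
#'
#' @param path file path.
#' @return `read_ms2()` returns an `ms2_spectrum`.
#' @export
read_ms2 <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  get <- function(key) {
    m <- grep(paste0("^#\\s*", key, "\\s*:"), hdr, value = TRUE)
    if (length(m) == 0) stop("missing header '", key, "' in ", path)
    trimws(sub("^[^:]*:", "", m[1]))
  }
  body <- lines[!grepl("^#", lines) & nzchar(trimws(lines))]
  peaks <- do.call(rbind, lapply(strsplit(body, "[\t ]+"), as.numeric))
  ms2_spectrum(as.numeric(get("precursor_mz")), get("polarity"),
               matrix(peaks, ncol = 2,
                      dimnames = list(NULL, c("mz", "intensity"))))
}

#' @rdname read_ms2
#' @param spectrum an `ms2_spectrum`.
#' @export
write_ms2 <- function(spectrum, path) {
  stopifnot(inherits(spectrum, "ms2_spectrum"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    paste0("# precursor_mz: ", format(spectrum$precursor_mz, digits = 10)),
    paste0("# polarity: ", spectrum$polarity),
    paste(format(spectrum$fragments[, "mz"], digits = 10, trim = TRUE),
          format(spectrum$fragments[, "intensity"], digits = 8, trim = TRUE),
          sep = "\t")), con)
  invisible(path)
}
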