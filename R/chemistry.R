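# Monoisotopic atomic masses (IUPAC/CODATA), Da.
ATOMIC_MASS <- c(
  C  = 12.0,
  H  = 1.0078250319,
  N  = 14.0030740052,
  O  = 15.9949146221,
  P  = 30.97376151,
  Na = 22.98976928,
  K  = 38.9637064864,
  Cl = 34.96885268
)
ELECTRON_MASS <- 0.00054857990907
PROTON_MASS   <- ATOMIC_MASS[["H"]] - ELECTRON_MASS   # 1.0072765
WATER_MASS    <- 2 * ATOMIC_MASS[["H"]] + ATOMIC_MASS[["O"]]
CO2_MASS      <- ATOMIC_MASS[["C"]] + 2 * ATOMIC_MASS[["O"]]
NH3_MASS      <- ATOMIC_MASS[["N"]] + 3 * ATOMIC_MASS[["H"]]
# Phosphocholine head-group fragment ion of PC species, positive mode.
PC_HEAD_FRAGMENT <- 5 * ATOMIC_MASS[["C"]] + 15 * ATOMIC_MASS[["H"]] +
  ATOMIC_MASS[["N"]] + 4 * ATOMIC_MASS[["O"]] + ATOMIC_MASS[["P"]] -
  ELECTRON_MASS
# C-13 excess spacing and natural abundance used for M+1 satellites.
C13_DELTA_DA <- 1.00336
C13_ABUNDANCE <- 0.0107

LIPID_CLASSES <- c("FA", "DG", "TG", "PC", "PE", "PEe", "PI", "PG", "PA",
                   "PS", "LPC", "LPE", "LPG", "LPS", "SM", "Cer")

#' Mass of a molecular formula
#'
#' @param formula named integer vector of element counts, e.g.
#'   `c(C = 16, H = 32, O = 2)`.
#' @return Monoisotopic mass in Da.
#' @examples
#' formula_mass(c(C = 16, H = 32, O = 2))  # palmitic acid
#' @export
formula_mass <- function(formula) {
  stopifnot(length(formula) > 0, !is.null(names(formula)))
  unknown <- setdiff(names(formula), names(ATOMIC_MASS))
  if (length(unknown) > 0)
    stop("unknown element(s): ", paste(unknown, collapse = ", "))
  sum(formula * ATOMIC_MASS[names(formula)])
}

# Element counts for a lipid class given total acyl carbons c, total double
# bonds d and x extra oxygens. Glycerolipid rules follow from glycerol +
# acyls - n(H2O); glycerophospholipids add the respective head group; SM/Cer
# rules include the two backbone oxygens of the standard ;O2 sphingoid base.
lipid_formula <- function(lipid_class, carbons, double_bonds, oxygen_extra = 0) {
  c0 <- carbons; d <- double_bonds; x <- oxygen_extra
  h <- 2 * c0 - 2 * d
  f <- switch(lipid_class,
    FA  = c(C = c0,     H = h,      O = 2 + x),
    DG  = c(C = c0 + 3, H = h + 4,  O = 5 + x),
    TG  = c(C = c0 + 3, H = h + 2,  O = 6 + x),
    PC  = c(C = c0 + 8, H = h + 16, N = 1, O = 8 + x,  P = 1),
    PE  = c(C = c0 + 5, H = h + 10, N = 1, O = 8 + x,  P = 1),
    PEe = c(C = c0 + 5, H = h + 12, N = 1, O = 7 + x,  P = 1),
    PI  = c(C = c0 + 9, H = h + 15, O = 13 + x, P = 1),
    PG  = c(C = c0 + 6, H = h + 11, O = 10 + x, P = 1),
    PA  = c(C = c0 + 3, H = h + 5,  O = 8 + x,  P = 1),
    PS  = c(C = c0 + 6, H = h + 10, N = 1, O = 10 + x, P = 1),
    LPC = c(C = c0 + 8, H = h + 18, N = 1, O = 7 + x,  P = 1),
    LPE = c(C = c0 + 5, H = h + 12, N = 1, O = 7 + x,  P = 1),
    LPG = c(C = c0 + 6, H = h + 13, O = 9 + x,  P = 1),
    LPS = c(C = c0 + 6, H = h + 12, N = 1, O = 9 + x,  P = 1),
    SM  = c(C = c0 + 5, H = h + 13, N = 2, O = 6 + x,  P = 1),
    Cer = c(C = c0,     H = h + 1,  N = 1, O = 3 + x),
    stop("unsupported lipid class: ", lipid_class)
  )
  f
}

#' Parse lipid shorthand notation
#'
#' Accepts the common `Class(C:D)`, `Class(C:D;O)` and chain-resolved
#' `Class C1:D1_C2:D2` (or `/`-separated) spellings, e.g. `"FA (18:2;O)"`,
#' `"DG(32:1)"`, `"TG (53:4)"`, `"PEe-16:1_22:6"`, `"PG 17:0/17:0"`.
#' `DAG`/`TAG` are accepted as aliases of `DG`/`TG`. Sphingolipid hydroxyl
#' counts (`18:1;2`) are interpreted against the standard two backbone
#' oxygens of SM/Cer.
#'
#' @param text lipid shorthand string.
#' @return A `lipid_record`: list with `shorthand` (canonical form),
#'   `lipid_class`, `total_carbons`, `total_double_bonds`, `oxygen_extra`,
#'   `chains` (list of `c(carbons, double_bonds)` or `NULL` when only class
#'   totals are given), `formula`, `monoisotopic_mass`.
#' @examples
#' parse_shorthand("FA (18:2;O)")$monoisotopic_mass  # 296.2351
#' parse_shorthand("TG(48:1)")$formula               # C51 H96 O6
#' @export
parse_shorthand <- function(text) {
  stopifnot(is.character(text), length(text) == 1)
  s <- trimws(text)
  # alias long-hand class names
  s <- sub("^DAG\\b", "DG", s)
  s <- sub("^TAG\\b", "TG", s)
  # class prefix: longest match first so PEe beats PE, LPC beats PC etc.
  classes <- LIPID_CLASSES[order(nchar(LIPID_CLASSES), decreasing = TRUE)]
  cls <- NA_character_
  for (k in classes) {
    if (grepl(paste0("^", k, "($|[^A-Za-z])"), s)) { cls <- k; break }
  }
  if (is.na(cls)) stop("unknown lipid class prefix in: ", text)
  rest <- sub(paste0("^", cls), "", s)
  rest <- gsub("[()\\-]", " ", rest)
  rest <- trimws(gsub("\\s+", " ", rest))
  if (!nzchar(rest)) stop("missing carbon:double-bond token in: ", text)
  tokens <- strsplit(rest, "[_/ ]+")[[1]]
  parse_token <- function(tok) {
    m <- regmatches(tok, regexec("^([0-9]+):([0-9]+)(;O([0-9]*)|;([0-9]+))?$", tok))[[1]]
    if (length(m) == 0) stop("malformed carbon:double-bond token '", tok,
                             "' in: ", text)
    oxy <- 0L
    if (nzchar(m[4])) oxy <- if (nzchar(m[5])) as.integer(m[5]) else 1L
    if (nzchar(m[6])) oxy <- as.integer(m[6])
    c(carbons = as.integer(m[2]), double_bonds = as.integer(m[3]), oxy = oxy)
  }
  parsed <- lapply(tokens, parse_token)
  carbons <- sum(vapply(parsed, `[[`, integer(1), "carbons"))
  dbs     <- sum(vapply(parsed, `[[`, integer(1), "double_bonds"))
  oxy     <- sum(vapply(parsed, `[[`, integer(1), "oxy"))
  # SM/Cer shorthand counts the two backbone hydroxyls explicitly (";2")
  if (cls %in% c("SM", "Cer")) oxy <- max(0L, oxy - 2L)
  if (carbons <= 0) stop("total carbons must be positive in: ", text)
  chains <- NULL
  if (length(parsed) > 1)
    chains <- lapply(parsed, function(p) p[c("carbons", "double_bonds")])
  f <- lipid_formula(cls, carbons, dbs, oxy)
  canonical <- paste0(cls, "(", carbons, ":", dbs,
                      if (oxy == 1) ";O" else if (oxy > 1) paste0(";O", oxy) else "",
                      ")")
  structure(list(
    shorthand = canonical,
    lipid_class = cls,
    total_carbons = carbons,
    total_double_bonds = dbs,
    oxygen_extra = oxy,
    chains = chains,
    formula = f,
    monoisotopic_mass = formula_mass(f)
  ), class = "lipid_record")
}

#' @export
print.lipid_record <- function(x, ...) {
  cat(x$shorthand, " [", paste0(names(x$formula), x$formula, collapse = " "),
      "]  M = ", sprintf("%.4f", x$monoisotopic_mass), " Da\n", sep = "")
  if (!is.null(x$chains))
    cat("  chains:", paste(vapply(x$chains, function(ch)
      paste0(ch[1], ":", ch[2]), character(1)), collapse = ", "), "\n")
  invisible(x)
}

# Adduct table: electron-mass-corrected shifts for singly charged species.
ADDUCTS <- local({
  A <- ATOMIC_MASS; e <- ELECTRON_MASS
  data.frame(
    name = c("[M-H]-", "[M+Cl]-", "[M+HCOO]-", "[M+OAc]-",
             "[M+H]+", "[M+H-H2O]+", "[M+Na]+", "[M+NH4]+", "[M+K]+"),
    polarity = c(rep("negative", 4), rep("positive", 5)),
    charge = c(rep(-1L, 4), rep(1L, 5)),
    mass_shift = c(
      -(A[["H"]] - e),
      A[["Cl"]] + e,
      A[["C"]] + A[["H"]] + 2 * A[["O"]] + e,
      2 * A[["C"]] + 3 * A[["H"]] + 2 * A[["O"]] + e,
      A[["H"]] - e,
      A[["H"]] - e - (2 * A[["H"]] + A[["O"]]),
      A[["Na"]] - e,
      A[["N"]] + 4 * A[["H"]] - e,
      A[["K"]] - e
    ),
    stringsAsFactors = FALSE
  )
})

#' Canonicalize an adduct name
#'
#' Strips whitespace so the printed variants `[M + H-H2O]+`, `[M + NH4]+`
#' collapse to the canonical spellings used throughout the package.
#'
#' @param name adduct string(s).
#' @return Canonical adduct name(s); error on unknown adducts.
#' @export
canonical_adduct <- function(name) {
  out <- gsub("\\s+", "", name)
  bad <- setdiff(unique(out), c(ADDUCTS$name, "-", ""))
  if (length(bad) > 0)
    stop("unknown adduct token(s): ", paste(bad, collapse = ", "))
  out
}

#' Adduct specification
#'
#' @param name canonical (or spaced) adduct name, one of
#'   `[M-H]-`, `[M+Cl]-`, `[M+HCOO]-`, `[M+OAc]-`, `[M+H]+`, `[M+H-H2O]+`,
#'   `[M+Na]+`, `[M+NH4]+`, `[M+K]+`.
#' @return list with `name`, `polarity`, `charge`, `mass_shift` (Da).
#' @export
adduct_spec <- function(name) {
  nm <- canonical_adduct(name)
  i <- match(nm, ADDUCTS$name)
  if (is.na(i)) stop("unknown adduct: ", name)
  as.list(ADDUCTS[i, ])
}

#' Theoretical m/z of a lipid adduct
#'
#' @param mass neutral monoisotopic mass in Da (> 0), or a `lipid_record`.
#' @param adduct adduct name or `adduct_spec()` result.
#' @return m/z in Da (singly charged throughout).
#' @examples
#' adduct_mz(parse_shorthand("FA (16:0)"), "[M-H]-")   # 255.2330
#' adduct_mz(parse_shorthand("TG(48:1)"), "[M+Na]+")   # 827.7099
#' @export
adduct_mz <- function(mass, adduct) {
  if (inherits(mass, "lipid_record")) mass <- mass$monoisotopic_mass
  stopifnot(is.numeric(mass), all(mass > 0))
  if (is.character(adduct)) adduct <- adduct_spec(adduct)
  mass + adduct$mass_shift
}

#' Mass deviation in parts per million
#'
#' @param observed observed m/z.
#' @param theoretical theoretical m/z (> 0).
#' @return `1e6 * (observed - theoretical) / theoretical`.
#' @export
ppm_deviation <- function(observed, theoretical) {
  stopifnot(all(theoretical > 0))
  1e6 * (observed - theoretical) / theoretical
}
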