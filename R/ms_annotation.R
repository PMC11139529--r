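# Monoisotopic-mass annotation of negative-mode LC-MS peaks.
#
# Ion masses follow the electron-inclusive convention: deprotonation removes
# a proton (1.007276 Da), not a hydrogen atom, and the formate adduct adds
# the formate anion mass (44.998203 Da). Only singly-charged negative-mode
# adducts are supported; isotopologues are not modeled.

#' Tabulated monoisotopic atomic masses (Da)
#'
#' IUPAC monoisotopic masses for the elements occurring in the supported
#' compound classes (gallotannins, phenolic acids, amino acids, flavonoids).
#'
#' @format Named numeric vector, Da per atom.
#' @keywords internal
.monoisotopic_masses <- c(
  C = 12.000000,
  H = 1.0078250319,
  N = 14.0030740052,
  O = 15.9949146221,
  S = 31.97207069
)

# Mass shift (Da, electron-inclusive) and charge per supported adduct.
.adducts <- list(
  "[M-H]-"    = list(name = "[M-H]-",    mass_shift = -1.007276,  charge = -1L),
  "[M+HCOO]-" = list(name = "[M+HCOO]-", mass_shift = +44.998203, charge = -1L)
)

#' Parse an elemental formula string
#'
#' Parses a Hill-order style formula such as `"C7H6O5"` into a named integer
#' vector of element counts. An omitted count means 1.
#'
#' @param text Non-empty formula string, e.g. `"C4H7NO4"`.
#' @return Named integer vector of element counts (class
#'   `"element_formula"`); every count is >= 1.
#' @examples
#' parse_formula("C7H6O5")
#' parse_formula("H2O")
#' @export
parse_formula <- function(text) {
  if (!is.character(text) || length(text) != 1L || is.na(text) || !nzchar(text))
    stop("formula must be a single non-empty string")
  pat <- "([A-Z][a-z]?)([0-9]*)"
  m <- gregexpr(pat, text, perl = TRUE)[[1]]
  tokens <- regmatches(text, list(m))[[1]]
  if (sum(attr(m, "match.length")) != nchar(text))
    stop("malformed formula: ", text)
  sym <- sub(pat, "\\1", tokens)
  cnt <- sub(pat, "\\2", tokens)
  cnt <- ifelse(cnt == "", 1L, suppressWarnings(as.integer(cnt)))
  if (anyNA(cnt) || any(cnt < 1L))
    stop("malformed count in formula: ", text)
  bad <- setdiff(sym, names(.monoisotopic_masses))
  if (length(bad))
    stop("unrecognized element symbol(s): ", paste(bad, collapse = ", "))
  counts <- tapply(cnt, factor(sym, levels = unique(sym)), sum)
  out <- as.integer(counts)
  names(out) <- names(counts)
  class(out) <- "element_formula"
  out
}

#' @export
format.element_formula <- function(x, ...) {
  paste0(names(x), ifelse(unclass(x) == 1L, "", unclass(x)), collapse = "")
}

#' @export
print.element_formula <- function(x, ...) {
  cat(format(x), "\n")
  invisible(x)
}

#' Monoisotopic mass of a formula
#'
#' @param formula An `element_formula` (from [parse_formula()]) or a formula
#'   string, or an empty vector for mass 0.
#' @return Neutral monoisotopic mass in Da.
#' @examples
#' monoisotopic_mass("C7H6O5") # gallic acid, 170.0215 Da
#' @export
monoisotopic_mass <- function(formula) {
  if (is.character(formula)) formula <- parse_formula(formula)
  if (length(formula) == 0L) return(0)
  bad <- setdiff(names(formula), names(.monoisotopic_masses))
  if (length(bad))
    stop("no tabulated monoisotopic mass for: ", paste(bad, collapse = ", "))
  sum(.monoisotopic_masses[names(formula)] * as.numeric(formula))
}

#' Supported negative-mode adducts
#'
#' @return Character vector of adduct names.
#' @export
supported_adducts <- function() names(.adducts)

adduct_spec <- function(adduct) {
  if (is.list(adduct) && all(c("name", "mass_shift") %in% names(adduct)))
    return(adduct)
  spec <- .adducts[[adduct]]
  if (is.null(spec)) stop("unsupported adduct: ", adduct)
  spec
}

#' Theoretical adduct m/z
#'
#' Computes the theoretical m/z of a singly-charged negative-mode adduct
#' ion under the electron-inclusive convention.
#'
#' @param formula An `element_formula` or formula string (neutral molecule).
#' @param adduct `"[M-H]-"` or `"[M+HCOO]-"` (or an adduct spec list).
#' @return Theoretical m/z in Th.
#' @examples
#' adduct_mz("C8H8O5", "[M-H]-") # methyl gallate, 183.0299
#' @export
adduct_mz <- function(formula, adduct) {
  monoisotopic_mass(formula) + adduct_spec(adduct)$mass_shift
}

#' Mass error in mDa
#'
#' @param observed,theoretical m/z values in Th (both positive).
#' @param digits Decimals for reporting; `NULL` for unrounded.
#' @return `(observed - theoretical) * 1000`, in mDa.
#' @export
mass_error_mda <- function(observed, theoretical, digits = 1) {
  err <- (observed - theoretical) * 1000
  if (is.null(digits)) err else round(err, digits)
}

#' Annotate observed peaks against candidate compounds
#'
#' Each peak is matched to the candidate whose theoretical adduct m/z is
#' nearest in absolute mass error and within `tolerance_mda`; ties are broken
#' by candidate order. Unmatched peaks are kept with `matched = FALSE`.
#'
#' @param peaks data.frame with columns `observed_mz` and `adduct`
#'   (optionally `peak_no`, `rt_min`).
#' @param candidates data.frame with columns `name`, `formula` and
#'   optionally `class`.
#' @param tolerance_mda Match tolerance in mDa (> 0), default 5.
#' @return data.frame of annotated peaks with `theoretical_mz`,
#'   `mass_error_mda`, `name`, `class`, `formula`, `matched`.
#' @export
annotate_table <- function(peaks, candidates, tolerance_mda = 5) {
  stopifnot(is.data.frame(peaks), is.data.frame(candidates))
  if (nrow(candidates) == 0L) stop("empty candidate list")
  if (!is.numeric(tolerance_mda) || tolerance_mda <= 0)
    stop("tolerance must be > 0")
  out <- peaks
  out$theoretical_mz <- NA_real_
  out$mass_error_mda <- NA_real_
  out$name <- NA_character_
  out$formula_matched <- NA_character_
  out$class <- NA_character_
  out$matched <- FALSE
  cand_mass <- vapply(candidates$formula, monoisotopic_mass, numeric(1))
  for (i in seq_len(nrow(peaks))) {
    shift <- adduct_spec(peaks$adduct[i])$mass_shift
    theo <- cand_mass + shift
    err <- (peaks$observed_mz[i] - theo) * 1000
    j <- which.min(abs(err)) # which.min takes the first on ties
    if (abs(err[j]) <= tolerance_mda) {
      out$theoretical_mz[i] <- theo[j]
      out$mass_error_mda[i] <- round(err[j], 1)
      out$name[i] <- as.character(candidates$name[j])
      out$formula_matched[i] <- as.character(candidates$formula[j])
      if (!is.null(candidates$class))
        out$class[i] <- as.character(candidates$class[j])
      out$matched[i] <- TRUE
    }
  }
  out
}

#' Annotate a compound-table CSV
#'
#' Reads a CSV with columns
#' `peak_no,rt_min,observed_mz,adduct,formula,name,class`, scores each row
#' against its own stated formula, and adds
#' `theoretical_mz,mass_error_mda,matched`.
#'
#' @param path Input CSV path.
#' @param out Optional output CSV path; written when non-`NULL`.
#' @param tolerance_mda Tolerance in mDa for the `matched` flag.
#' @return The augmented data.frame, invisibly when `out` is given.
#' @export
annotate_compound_csv <- function(path, out = NULL, tolerance_mda = 5) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("observed_mz", "adduct", "formula")
  if (!all(need %in% names(tab)))
    stop("compound table needs columns: ", paste(need, collapse = ", "))
  tab$theoretical_mz <- mapply(adduct_mz, tab$formula, tab$adduct)
  tab$mass_error_mda <- mass_error_mda(tab$observed_mz, tab$theoretical_mz)
  tab$matched <- abs((tab$observed_mz - tab$theoretical_mz) * 1000) <= tolerance_mda
  if (!is.null(out)) {
    utils::write.csv(tab, out, row.names = FALSE)
    return(invisible(tab))
  }
  tab
}
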