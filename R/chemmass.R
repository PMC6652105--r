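# Monoisotopic atomic masses (Da), most abundant isotope per element.
# 12C defines the scale exactly; others at IUPAC values.
MONOISOTOPIC_MASS <- c(
  C = 12.0,
  H = 1.00782503207,
  N = 14.0030740048,
  O = 15.9949146196,
  S = 31.97207100,
  P = 30.97376163,
  Na = 22.9897692809
)

# Singly charged ESI cation masses (electron-corrected).
ADDUCT_MASS <- c("M+H" = 1.007276, "M+Na" = 22.989218)

#' Parse a Hill-style molecular formula
#'
#' `"C29H33N3O9S"` -> `c(C = 29, H = 33, N = 3, O = 9, S = 1)`; an omitted
#' count means 1.
#'
#' @param text Formula string (element symbols from the packaged mass
#'   table, each optionally followed by a count).
#' @return Named integer vector of class `molecular_formula`.
#' @export
parse_formula <- function(text) {
  stopifnot(is.character(text), length(text) == 1)
  if (!nzchar(text)) stop("parse_formula: empty formula")
  m <- gregexpr("([A-Z][a-z]?)([0-9]*)", text)[[1]]
  if (m[1] == -1) stop("parse_formula: malformed token at position 1 of '",
                       text, "'")
  tokens <- regmatches(text, gregexpr("([A-Z][a-z]?)([0-9]*)", text))[[1]]
  if (sum(attr(m, "match.length")) != nchar(text)) {
    covered <- rep(FALSE, nchar(text))
    for (i in seq_along(m))
      covered[m[i]:(m[i] + attr(m, "match.length")[i] - 1)] <- TRUE
    stop("parse_formula: malformed token at position ", which(!covered)[1],
         " of '", text, "'")
  }
  sym <- sub("[0-9]*$", "", tokens)
  cnt <- as.integer(sub("^[A-Za-z]+", "", paste0(tokens, "")))
  cnt[is.na(cnt)] <- 1L
  unknown <- setdiff(sym, names(MONOISOTOPIC_MASS))
  if (length(unknown) > 0)
    stop("parse_formula: unknown element '", unknown[1], "' at position ",
         m[match(unknown[1], sym)])
  if (any(cnt < 1)) stop("parse_formula: element counts must be >= 1")
  out <- tapply(cnt, factor(sym, levels = unique(sym)), sum)
  structure(setNames(as.integer(out), names(out)),
            class = "molecular_formula")
}

#' Format a formula in Hill order (C, H, then alphabetical)
#'
#' @param formula A `molecular_formula` (or named count vector).
#' @return Character string.
#' @export
format_formula <- function(formula) {
  f <- unclass(formula)
  ord <- c(intersect(c("C", "H"), names(f)),
           sort(setdiff(names(f), c("C", "H"))))
  paste0(ord, ifelse(f[ord] > 1, f[ord], ""), collapse = "")
}

#' Monoisotopic mass of a molecular formula
#'
#' @param formula A `molecular_formula` from [parse_formula()] (a plain
#'   formula string is accepted and parsed).
#' @return Mass in Da.
#' @export
monoisotopic_mass <- function(formula) {
  if (is.character(formula)) formula <- parse_formula(formula)
  f <- unclass(formula)
  if (length(f) == 0) stop("monoisotopic_mass: empty formula")
  missing <- setdiff(names(f), names(MONOISOTOPIC_MASS))
  if (length(missing) > 0)
    stop("monoisotopic_mass: no mass for element '", missing[1], "'")
  sum(f * MONOISOTOPIC_MASS[names(f)])
}

#' m/z of a singly charged ESI adduct
#'
#' @inheritParams monoisotopic_mass
#' @param adduct `"M+H"` or `"M+Na"`.
#' @return m/z value.
#' @export
adduct_mz <- function(formula, adduct) {
  if (!adduct %in% names(ADDUCT_MASS))
    stop("adduct_mz: unsupported adduct '", adduct, "'; supported: ",
         paste(names(ADDUCT_MASS), collapse = ", "))
  monoisotopic_mass(formula) + ADDUCT_MASS[[adduct]]
}
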