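# Elemental formulas are named numeric vectors (element symbol -> count).
# An unknown formula is represented by NA (scalar); count 0 entries are dropped.

.ELEMENT_SYMBOLS <- c(
  "H", "He", "Li", "Be", "B", "C", "N", "O", "F", "Ne", "Na", "Mg", "Al",
  "Si", "P", "S", "Cl", "Ar", "K", "Ca", "Sc", "Ti", "V", "Cr", "Mn", "Fe",
  "Co", "Ni", "Cu", "Zn", "Ga", "Ge", "As", "Se", "Br", "Kr", "Rb", "Sr",
  "Y", "Zr", "Nb", "Mo", "Tc", "Ru", "Rh", "Pd", "Ag", "Cd", "In", "Sn",
  "Sb", "Te", "I", "Xe", "Cs", "Ba", "La", "Ce", "Pr", "Nd", "Pm", "Sm",
  "Eu", "Gd", "Tb", "Dy", "Ho", "Er", "Tm", "Yb", "Lu", "Hf", "Ta", "W",
  "Re", "Os", "Ir", "Pt", "Au", "Hg", "Tl", "Pb", "Bi", "Po", "At", "Rn",
  "Fr", "Ra", "Ac", "Th", "Pa", "U"
)

#' Parse an elemental formula string
#'
#' Parses Hill-style formula strings such as `"C2H4O2"` or `"CH3COOH"` into a
#' named count vector. Element symbols must be valid one/two-letter chemical
#' symbols; an omitted count means 1.
#'
#' @param text Formula string, or `NA` for an unknown formula.
#' @return Named numeric vector of element counts (class `elemental_formula`),
#'   or `NA` if `text` is `NA` or empty.
#' @examples
#' parse_formula("C2H4O2")
#' parse_formula("H2O")
#' @export
parse_formula <- function(text) {
  if (length(text) != 1L) stop("parse_formula() expects a single string")
  if (is.na(text) || !nzchar(trimws(text))) return(NA)
  text <- trimws(text)
  m <- gregexpr("[A-Z][a-z]?[0-9]*", text)[[1]]
  parts <- regmatches(text, list(m))[[1]]
  if (sum(attr(m, "match.length")) != nchar(text) || length(parts) == 0L) {
    stop(sprintf("malformed formula string: '%s'", text))
  }
  sym <- sub("[0-9]*$", "", parts)
  cnt <- sub("^[A-Za-z]+", "", parts)
  cnt <- ifelse(nzchar(cnt), as.numeric(cnt), 1)
  bad <- setdiff(sym, .ELEMENT_SYMBOLS)
  if (length(bad) > 0L) {
    stop(sprintf("unknown element symbol(s) %s in formula '%s'",
                 paste(sQuote(bad), collapse = ", "), text))
  }
  out <- tapply(cnt, sym, sum)
  formula_counts(stats::setNames(as.numeric(out), names(out)))
}

#' Construct an elemental formula from counts
#'
#' @param counts Named numeric vector of non-negative element counts.
#' @return Normalised count vector of class `elemental_formula` (zeros
#'   dropped, names sorted).
#' @export
formula_counts <- function(counts) {
  if (length(counts) == 0L) {
    return(structure(stats::setNames(numeric(0), character(0)),
                     class = "elemental_formula"))
  }
  stopifnot(!is.null(names(counts)), all(nzchar(names(counts))))
  bad <- setdiff(names(counts), .ELEMENT_SYMBOLS)
  if (length(bad) > 0L) {
    stop(sprintf("unknown element symbol(s): %s",
                 paste(sQuote(bad), collapse = ", ")))
  }
  if (any(counts < 0)) stop("element counts must be non-negative")
  counts <- counts[counts != 0]
  counts <- counts[order(names(counts))]
  structure(counts, class = "elemental_formula")
}

# Signed elemental sums (used for balance deltas; negatives allowed).
formula_zero <- function() {
  stats::setNames(numeric(0), character(0))
}

# delta <- delta + k * formula  (plain named-vector arithmetic)
formula_axpy <- function(delta, k, formula) {
  if (length(formula) == 0L) return(delta)
  els <- union(names(delta), names(formula))
  out <- stats::setNames(numeric(length(els)), els)
  out[names(delta)] <- delta
  out[names(formula)] <- out[names(formula)] + k * as.numeric(formula)
  out
}

#' Add two formulas or signed element maps
#' @param a,b Named numeric vectors (element -> count).
#' @return Named numeric vector of summed counts.
#' @export
formula_add <- function(a, b) {
  formula_axpy(as_element_map(a), 1, as_element_map(b))
}

#' Scale a formula or signed element map
#' @param a Named numeric vector (element -> count).
#' @param k Scalar multiplier.
#' @return Named numeric vector of scaled counts.
#' @export
formula_scale <- function(a, k) {
  v <- as_element_map(a)
  stats::setNames(as.numeric(v) * k, names(v))
}

as_element_map <- function(x) {
  if (length(x) == 1L && is.na(x[[1]]) && is.null(names(x))) {
    stop("cannot do arithmetic with an unknown formula")
  }
  stats::setNames(as.numeric(x), names(x))
}

#' Render a formula to a string
#' @param x `elemental_formula` or named count vector.
#' @return Single string such as `"C2H4O2"`, or `NA` for unknown.
#' @export
render_formula <- function(x) {
  if (is_unknown_formula(x)) return(NA_character_)
  if (length(x) == 0L) return("")
  # Hill order: C, H, then alphabetical
  els <- names(x)
  ord <- order(match(els, c("C", "H"), nomatch = 3L), els)
  paste0(els[ord], ifelse(x[ord] == 1, "", format(x[ord], trim = TRUE,
                                                  scientific = FALSE)),
         collapse = "")
}

#' Test whether a formula is unknown
#' @param x Formula value as stored on a metabolite.
#' @return `TRUE` if the formula is the unknown marker `NA`.
#' @export
is_unknown_formula <- function(x) {
  length(x) == 1L && is.null(names(x)) && is.na(x[[1]])
}

#' Number of atoms of one element in a formula
#' @param x Formula (named counts) or `NA`.
#' @param element Element symbol, e.g. `"C"`.
#' @return Count (0 if absent), or `NA` if the formula is unknown.
#' @export
element_count <- function(x, element = "C") {
  if (is_unknown_formula(x)) return(NA_real_)
  v <- as_element_map(x)
  if (element %in% names(v)) unname(v[[element]]) else 0
}

#' @export
print.elemental_formula <- function(x, ...) {
  cat("<formula>", render_formula(x), "\n")
  invisible(x)
}
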