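# Reaction-equation strings: "2 A + B => C", "A[e] <=> A[c]".
# "<=>" marks a reversible reaction, "=>" irreversible; omitted coefficient
# means 1; metabolite tokens may carry a "[compartment]" suffix which is kept
# as part of the metabolite id.

#' Parse a reaction-equation string
#'
#' @param text Equation such as `"2 A + B => C"`. One side may be empty
#'   (exchange notation, e.g. `"A =>"`).
#' @return List with `stoichiometry` (named numeric; negative = consumed) and
#'   `reversible` (logical).
#' @export
parse_equation <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  arrow <- if (grepl("<=>", text, fixed = TRUE)) "<=>"
           else if (grepl("=>", text, fixed = TRUE)) "=>"
           else stop(sprintf("equation '%s' lacks an arrow ('=>' or '<=>')", text))
  sides <- strsplit(text, arrow, fixed = TRUE)[[1]]
  if (length(sides) == 1L) sides <- c(sides, "")
  if (length(sides) != 2L) stop(sprintf("equation '%s' has multiple arrows", text))
  parse_side <- function(s, sign) {
    s <- trimws(s)
    if (!nzchar(s)) return(stats::setNames(numeric(0), character(0)))
    terms <- trimws(strsplit(s, "+", fixed = TRUE)[[1]])
    if (any(!nzchar(terms))) {
      stop(sprintf("empty term in equation side '%s'", s))
    }
    coeffs <- numeric(0)
    for (term in terms) {
      parts <- strsplit(term, "[[:space:]]+")[[1]]
      if (length(parts) == 1L) {
        cf <- 1; met <- parts[1]
      } else if (length(parts) == 2L &&
                 grepl("^[0-9.]+([eE][+-]?[0-9]+)?$", parts[1])) {
        cf <- as.numeric(parts[1]); met <- parts[2]
      } else {
        stop(sprintf("cannot parse equation term '%s'", term))
      }
      if (is.na(cf) || cf <= 0) stop(sprintf("bad coefficient in term '%s'", term))
      coeffs[met] <- (if (met %in% names(coeffs)) coeffs[[met]] else 0) + sign * cf
    }
    coeffs
  }
  lhs <- parse_side(sides[1], -1)
  rhs <- parse_side(sides[2], +1)
  stoich <- stats::setNames(numeric(0), character(0))
  for (m in union(names(lhs), names(rhs))) {
    v <- (if (m %in% names(lhs)) lhs[[m]] else 0) +
         (if (m %in% names(rhs)) rhs[[m]] else 0)
    if (v != 0) stoich[m] <- v
  }
  list(stoichiometry = stoich, reversible = arrow == "<=>")
}

#' Render stoichiometry as an equation string
#'
#' Inverse of [parse_equation()]: `parse_equation(render_equation(s, rev))`
#' reproduces stoichiometry and reversibility exactly.
#'
#' @param stoichiometry Named numeric vector (negative = consumed).
#' @param reversible Logical.
#' @return Equation string.
#' @export
render_equation <- function(stoichiometry, reversible = FALSE) {
  fmt_side <- function(v) {
    if (length(v) == 0L) return("")
    v <- v[order(names(v))]
    paste(ifelse(v == 1, names(v),
                 paste(format(unname(v), trim = TRUE, scientific = FALSE,
                              digits = 15), names(v))),
          collapse = " + ")
  }
  lhs <- -stoichiometry[stoichiometry < 0]
  rhs <- stoichiometry[stoichiometry > 0]
  paste(fmt_side(lhs), if (reversible) "<=>" else "=>", fmt_side(rhs))
}
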