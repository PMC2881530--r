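# Gene-protein-reaction (GPR) logic: boolean trees over gene identifiers.
# AND encodes enzyme complexes (all subunits required), OR isoenzymes.
# Representation: leaf = list(op = "GENE", gene = "NP4044A");
# node = list(op = "AND"/"OR", args = list(...)); empty logic = list(op = "EMPTY").

#' Empty gene logic
#'
#' Marks a reaction without genetic support. Evaluates to `FALSE` under any
#' gene set.
#' @return A `gene_logic` object.
#' @export
empty_gene_logic <- function() {
  structure(list(op = "EMPTY"), class = "gene_logic")
}

gl_node <- function(op, args) {
  structure(list(op = op, args = args), class = "gene_logic")
}

gl_leaf <- function(gene) {
  structure(list(op = "GENE", gene = gene), class = "gene_logic")
}

#' Parse a gene-logic expression
#'
#' Grammar: gene identifiers, `AND`, `OR` (case-insensitive keywords) and
#' parentheses; `AND` binds tighter than `OR`. The empty string yields the
#' empty logic.
#'
#' @param text Expression string, e.g. `"NP4044A AND NP4046A"`.
#' @return A `gene_logic` tree.
#' @examples
#' parse_gene_logic("a OR b AND c")   # OR(a, AND(b, c))
#' @export
parse_gene_logic <- function(text) {
  if (length(text) != 1L) stop("parse_gene_logic() expects a single string")
  if (is.na(text) || !nzchar(trimws(text))) return(empty_gene_logic())
  toks <- gl_tokenize(text)
  st <- new.env(parent = emptyenv())
  st$toks <- toks
  st$pos <- 1L
  node <- gl_parse_or(st, text)
  if (st$pos <= length(st$toks)) {
    stop(sprintf("gene-logic syntax error near token %d ('%s') in '%s'",
                 st$pos, st$toks[st$pos], text))
  }
  node
}

gl_tokenize <- function(text) {
  m <- gregexpr("\\(|\\)|[^()[:space:]]+", text)[[1]]
  regmatches(text, list(m))[[1]]
}

gl_peek <- function(st) if (st$pos <= length(st$toks)) st$toks[st$pos] else NA_character_

gl_parse_or <- function(st, text) {
  args <- list(gl_parse_and(st, text))
  while (!is.na(gl_peek(st)) && toupper(gl_peek(st)) == "OR") {
    st$pos <- st$pos + 1L
    args <- c(args, list(gl_parse_and(st, text)))
  }
  if (length(args) == 1L) args[[1]] else gl_node("OR", args)
}

gl_parse_and <- function(st, text) {
  args <- list(gl_parse_atom(st, text))
  while (!is.na(gl_peek(st)) && toupper(gl_peek(st)) == "AND") {
    st$pos <- st$pos + 1L
    args <- c(args, list(gl_parse_atom(st, text)))
  }
  if (length(args) == 1L) args[[1]] else gl_node("AND", args)
}

gl_parse_atom <- function(st, text) {
  tok <- gl_peek(st)
  if (is.na(tok)) {
    stop(sprintf("gene-logic syntax error: unexpected end of '%s'", text))
  }
  if (tok == "(") {
    st$pos <- st$pos + 1L
    node <- gl_parse_or(st, text)
    if (is.na(gl_peek(st)) || gl_peek(st) != ")") {
      stop(sprintf("gene-logic syntax error: unbalanced '(' at token %d in '%s'",
                   st$pos, text))
    }
    st$pos <- st$pos + 1L
    return(node)
  }
  if (tok == ")" || toupper(tok) %in% c("AND", "OR")) {
    stop(sprintf("gene-logic syntax error at token %d ('%s') in '%s'",
                 st$pos, tok, text))
  }
  st$pos <- st$pos + 1L
  gl_leaf(tok)
}

#' Evaluate gene logic against a set of present genes
#'
#' Standard boolean semantics: `AND` requires all children, `OR` any. The
#' empty logic is `FALSE` under every gene set (no genetic support).
#'
#' @param logic A `gene_logic` tree.
#' @param present_genes Character vector of gene identifiers considered present.
#' @return Logical scalar.
#' @export
evaluate_gene_logic <- function(logic, present_genes) {
  stopifnot(inherits(logic, "gene_logic"))
  switch(logic$op,
    EMPTY = FALSE,
    GENE = logic$gene %in% present_genes,
    AND = all(vapply(logic$args, evaluate_gene_logic, logical(1), present_genes)),
    OR = any(vapply(logic$args, evaluate_gene_logic, logical(1), present_genes)),
    stop(sprintf("malformed gene-logic node with op '%s'", logic$op))
  )
}

#' Render gene logic back to its string form
#'
#' `parse_gene_logic(render_gene_logic(x))` reproduces `x` structurally.
#' @param logic A `gene_logic` tree.
#' @return Expression string; `""` for the empty logic.
#' @export
render_gene_logic <- function(logic) {
  stopifnot(inherits(logic, "gene_logic"))
  switch(logic$op,
    EMPTY = "",
    GENE = logic$gene,
    AND = paste(vapply(logic$args, function(a) {
      s <- render_gene_logic(a)
      if (a$op == "OR") paste0("(", s, ")") else s
    }, character(1)), collapse = " AND "),
    OR = paste(vapply(logic$args, render_gene_logic, character(1)),
               collapse = " OR "),
    stop(sprintf("malformed gene-logic node with op '%s'", logic$op))
  )
}

#' Genes referenced by a gene-logic tree
#' @param logic A `gene_logic` tree.
#' @return Character vector of distinct gene identifiers.
#' @export
gene_logic_genes <- function(logic) {
  stopifnot(inherits(logic, "gene_logic"))
  switch(logic$op,
    EMPTY = character(0),
    GENE = logic$gene,
    unique(unlist(lapply(logic$args, gene_logic_genes)))
  )
}

#' @export
print.gene_logic <- function(x, ...) {
  cat("<gene_logic>", render_gene_logic(x), "\n")
  invisible(x)
}
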