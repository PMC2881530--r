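# Tabular (CSV/TSV) and SBML network serialization.
#
# The tabular dialect mirrors a spreadsheet export of a curated
# reconstruction: one reaction per row (id, name, equation string, EC,
# gene-logic string, evidence flags, category), optionally accompanied by a
# metabolite table carrying formulas/charges/compartments. Column names are
# remappable so real exports with different headers can be consumed.

.default_reaction_cols <- function() {
  c(id = "id", name = "name", equation = "equation", ec = "ec",
    genes = "genes", genetic_class = "genetic_class",
    literature = "literature", gap_fill = "gap_fill",
    category = "category", kind = "kind")
}

#' Read a network from tabular files
#'
#' @param path Reaction table (CSV or TSV by extension; `sep` overrides).
#' @param metabolites_path Optional metabolite table with columns
#'   `id, name, formula, charge, compartment`; metabolites absent from it (or
#'   when it is omitted) get unknown formula/charge.
#' @param col_map Named character vector remapping the logical reaction
#'   columns (`id`, `equation`, and optionally `name`, `ec`, `genes`,
#'   `genetic_class`, `literature`, `gap_fill`, `category`, `kind`) to the
#'   file's headers.
#' @param sep Field separator; default from file extension.
#' @return A `metabolic_network`. Unparseable rows are collected into the
#'   `rejects` attribute (data.frame of row, id, message), never silently
#'   dropped.
#' @export
read_network_table <- function(path, metabolites_path = NULL,
                               col_map = character(0), sep = NULL) {
  cols <- .default_reaction_cols()
  cols[names(col_map)] <- col_map
  if (is.null(sep)) sep <- if (grepl("\\.tsv$", path)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep, quote = "\"",
                          stringsAsFactors = FALSE, check.names = FALSE,
                          comment.char = "")
  for (need in c("id", "equation")) {
    if (!cols[[need]] %in% names(df)) {
      stop(sprintf("reaction table lacks mandatory column '%s' (mapped from '%s')",
                   cols[[need]], need))
    }
  }
  getcol <- function(logical_name, default) {
    cn <- cols[[logical_name]]
    if (cn %in% names(df)) df[[cn]] else rep(default, nrow(df))
  }
  ids <- as.character(df[[cols[["id"]]]])
  eqs <- as.character(df[[cols[["equation"]]]])
  nms <- as.character(getcol("name", NA_character_))
  genes <- as.character(getcol("genes", ""))
  gclass <- as.character(getcol("genetic_class", "NONE"))
  lit <- as.logical(getcol("literature", FALSE))
  gap <- as.logical(getcol("gap_fill", FALSE))
  categ <- as.character(getcol("category", ""))
  kind <- as.character(getcol("kind", NA_character_))

  rejects <- data.frame(row = integer(0), id = character(0),
                        message = character(0), stringsAsFactors = FALSE)
  rxns <- list()
  met_ids <- character(0)
  for (i in seq_len(nrow(df))) {
    res <- tryCatch({
      eq <- parse_equation(eqs[i])
      k <- kind[i]
      if (is.na(k) || !nzchar(k)) {
        k <- if (length(eq$stoichiometry) == 1L) "EXCHANGE" else "INTERNAL"
      }
      ev <- evidence(genetic_class = if (nzchar(gclass[i])) gclass[i] else "NONE",
                     literature = isTRUE(lit[i]), gap_fill = isTRUE(gap[i]))
      reaction(id = ids[i], stoichiometry = eq$stoichiometry,
               name = if (is.na(nms[i])) ids[i] else nms[i],
               reversible = eq$reversible, kind = k,
               gene_logic = parse_gene_logic(genes[i]),
               evidence = ev, category = categ[i])
    }, error = function(e) e)
    if (inherits(res, "error")) {
      rejects <- rbind(rejects, data.frame(row = i, id = ids[i],
                                           message = conditionMessage(res),
                                           stringsAsFactors = FALSE))
    } else {
      rxns[[length(rxns) + 1L]] <- res
      met_ids <- union(met_ids, names(res$stoichiometry))
    }
  }

  met_info <- NULL
  if (!is.null(metabolites_path)) {
    msep <- if (grepl("\\.tsv$", metabolites_path)) "\t" else ","
    met_info <- utils::read.table(metabolites_path, header = TRUE, sep = msep,
                                  quote = "\"", stringsAsFactors = FALSE,
                                  comment.char = "")
    met_ids <- union(met_ids, as.character(met_info$id))
  }
  mets <- lapply(met_ids, function(mid) {
    if (!is.null(met_info) && mid %in% met_info$id) {
      row <- met_info[match(mid, met_info$id), ]
      f <- if ("formula" %in% names(row) && !is.na(row$formula) &&
               nzchar(row$formula)) row$formula else NA
      metabolite(mid,
                 name = if ("name" %in% names(row) && !is.na(row$name)) row$name else mid,
                 formula = f,
                 charge = if ("charge" %in% names(row)) row$charge else NA_integer_,
                 compartment = if ("compartment" %in% names(row) &&
                                   !is.na(row$compartment)) row$compartment else "c")
    } else {
      metabolite(mid, compartment = if (grepl("\\[e\\]$", mid)) "e" else "c")
    }
  })
  net <- metabolic_network(mets, rxns, validate = FALSE)
  attr(net, "rejects") <- rejects
  net
}

#' Write a network to tabular files
#'
#' @param network A `metabolic_network`.
#' @param path Reaction table destination (TSV when the extension is `.tsv`).
#' @param metabolites_path Optional metabolite table destination.
#' @return `path`, invisibly.
#' @export
write_network_table <- function(network, path, metabolites_path = NULL) {
  stopifnot(inherits(network, "metabolic_network"))
  rxns <- network$reactions
  df <- data.frame(
    id = vapply(rxns, function(r) r$id, character(1)),
    name = vapply(rxns, function(r) r$name, character(1)),
    equation = vapply(rxns, function(r)
      render_equation(r$stoichiometry, r$reversible), character(1)),
    ec = "",
    genes = vapply(rxns, function(r) render_gene_logic(r$gene_logic), character(1)),
    genetic_class = vapply(rxns, function(r) r$evidence$genetic_class, character(1)),
    literature = vapply(rxns, function(r) r$evidence$literature, logical(1)),
    gap_fill = vapply(rxns, function(r) r$evidence$gap_fill, logical(1)),
    category = vapply(rxns, function(r) r$category, character(1)),
    kind = vapply(rxns, function(r) r$kind, character(1)),
    stringsAsFactors = FALSE)
  sep <- if (grepl("\\.tsv$", path)) "\t" else ","
  utils::write.table(df, path, sep = sep, row.names = FALSE, quote = TRUE)
  if (!is.null(metabolites_path)) {
    mets <- network$metabolites
    mdf <- data.frame(
      id = vapply(mets, function(m) m$id, character(1)),
      name = vapply(mets, function(m) m$name, character(1)),
      formula = vapply(mets, function(m) {
        f <- render_formula(m$formula); if (is.na(f)) "" else f
      }, character(1)),
      charge = vapply(mets, function(m)
        if (is.na(m$charge)) NA_integer_ else m$charge, integer(1)),
      compartment = vapply(mets, function(m) m$compartment, character(1)),
      stringsAsFactors = FALSE)
    msep <- if (grepl("\\.tsv$", metabolites_path)) "\t" else ","
    utils::write.table(mdf, metabolites_path, sep = msep, row.names = FALSE,
                       quote = TRUE)
  }
  invisible(path)
}

# ---------------------------------------------------------------------------
# SBML. Level 2/3 core subset; formula/charge/GPR and our reaction
# annotations travel in <notes> "KEY: value" paragraphs, the convention used
# by constraint-based modelling tools of the flat-SBML era.

sbml_notes <- function(kv) {
  kv <- kv[!is.na(kv) & nzchar(kv)]
  if (length(kv) == 0L) return(NULL)
  paste0("<notes><body xmlns=\"http://www.w3.org/1999/xhtml\">",
         paste0("<p>", names(kv), ": ", kv, "</p>", collapse = ""),
         "</body></notes>")
}

parse_sbml_notes <- function(node) {
  notes <- xml2::xml_find_first(node, "./*[local-name()='notes']")
  out <- character(0)
  if (inherits(notes, "xml_missing")) return(out)
  ps <- xml2::xml_find_all(notes, ".//*[local-name()='p']")
  for (p in ps) {
    txt <- xml2::xml_text(p)
    m <- regmatches(txt, regexec("^\\s*([A-Z_]+)\\s*:\\s*(.*)\\s*$", txt))[[1]]
    if (length(m) == 3L) out[m[2]] <- m[3]
  }
  out
}

#' Write a network as SBML
#'
#' Emits an SBML Level 3 Version 1 document. Formulas, charges, gene
#' associations, evidence flags and reaction kinds are stored in `<notes>`
#' elements so that [read_sbml_network()] round-trips the network exactly;
#' unknown formulas/charges simply omit the corresponding note.
#'
#' @param network A `metabolic_network`.
#' @param path Destination file.
#' @return `path`, invisibly.
#' @export
write_sbml_network <- function(network, path) {
  stopifnot(inherits(network, "metabolic_network"))
  esc <- function(x) {
    x <- gsub("&", "&amp;", x, fixed = TRUE)
    x <- gsub("<", "&lt;", x, fixed = TRUE)
    gsub(">", "&gt;", x, fixed = TRUE)
  }
  compartments <- unique(vapply(network$metabolites, function(m) m$compartment,
                                character(1)))
  if (length(compartments) == 0L) compartments <- "c"
  lines <- c(
    "<?xml version=\"1.0\" encoding=\"UTF-8\"?>",
    "<sbml xmlns=\"http://www.sbml.org/sbml/level3/version1/core\" level=\"3\" version=\"1\">",
    "<model id=\"model\">",
    "<listOfCompartments>",
    sprintf("<compartment id=\"%s\" constant=\"true\"/>", compartments),
    "</listOfCompartments>",
    "<listOfSpecies>")
  for (m in network$metabolites) {
    kv <- c(FORMULA = if (is_unknown_formula(m$formula)) NA_character_
                      else render_formula(m$formula),
            CHARGE = if (is.na(m$charge)) NA_character_ else as.character(m$charge))
    notes <- sbml_notes(kv)
    open <- sprintf(paste0("<species id=\"%s\" name=\"%s\" compartment=\"%s\"",
                           " hasOnlySubstanceUnits=\"false\" boundaryCondition=\"%s\"",
                           " constant=\"false\""),
                    esc(m$id), esc(m$name), esc(m$compartment),
                    if (m$compartment == "e") "true" else "false")
    lines <- c(lines, if (is.null(notes)) paste0(open, "/>")
                      else paste0(open, ">", notes, "</species>"))
  }
  lines <- c(lines, "</listOfSpecies>", "<listOfReactions>")
  for (r in network$reactions) {
    kv <- c(GENE_ASSOCIATION = render_gene_logic(r$gene_logic),
            KIND = r$kind,
            CATEGORY = r$category,
            GENETIC_CLASS = r$evidence$genetic_class,
            LITERATURE = if (r$evidence$literature) "true" else NA_character_,
            GAP_FILL = if (r$evidence$gap_fill) "true" else NA_character_)
    notes <- sbml_notes(kv)
    sref <- function(ids, coeffs) {
      if (length(ids) == 0L) return(character(0))
      sprintf("<speciesReference species=\"%s\" stoichiometry=\"%s\" constant=\"true\"/>",
              esc(ids), format(coeffs, trim = TRUE, scientific = FALSE, digits = 15))
    }
    s <- r$stoichiometry
    reac <- s[s < 0]; prod <- s[s > 0]
    lines <- c(lines,
      sprintf("<reaction id=\"%s\" name=\"%s\" reversible=\"%s\" fast=\"false\">",
              esc(r$id), esc(r$name), if (r$reversible) "true" else "false"),
      if (!is.null(notes)) notes,
      if (length(reac)) c("<listOfReactants>", sref(names(reac), -unname(reac)),
                          "</listOfReactants>"),
      if (length(prod)) c("<listOfProducts>", sref(names(prod), unname(prod)),
                          "</listOfProducts>"),
      "</reaction>")
  }
  lines <- c(lines, "</listOfReactions>", "</model>", "</sbml>")
  writeLines(lines, path)
  invisible(path)
}

#' Read a network from SBML
#'
#' Accepts SBML Level 2 or 3 (core). Species formula/charge and reaction
#' gene associations are taken from `<notes>` `KEY: value` paragraphs when
#' present (absent means unknown/empty). Species flagged
#' `boundaryCondition="true"` are placed in the `"e"` compartment. Reaction
#' kind comes from a `KIND` note when present, otherwise single-metabolite
#' reactions are classified as EXCHANGE and the rest as INTERNAL.
#'
#' @param path SBML file.
#' @param drop_boundary_species Remove boundary species (and their
#'   stoichiometric entries) instead of keeping them as extracellular
#'   metabolites. This is the counting convention under which the distinct
#'   metabolites of a reconstruction are tallied. Default `FALSE`.
#' @return A `metabolic_network`.
#' @export
read_sbml_network <- function(path, drop_boundary_species = FALSE) {
  doc <- xml2::read_xml(path)  # malformed XML raises here
  root <- xml2::xml_name(doc)
  if (root != "sbml") stop(sprintf("not an SBML document (root <%s>)", root))
  level <- xml2::xml_attr(doc, "level")
  if (!level %in% c("2", "3")) {
    stop(sprintf("unsupported SBML level '%s' (only Level 2/3 core is read)",
                 level))
  }
  sp_nodes <- xml2::xml_find_all(doc, ".//*[local-name()='listOfSpecies']/*[local-name()='species']")
  boundary_ids <- character(0)
  mets <- list()
  for (sp in sp_nodes) {
    id <- xml2::xml_attr(sp, "id")
    boundary <- identical(xml2::xml_attr(sp, "boundaryCondition"), "true")
    if (boundary) boundary_ids <- c(boundary_ids, id)
    kv <- parse_sbml_notes(sp)
    comp <- xml2::xml_attr(sp, "compartment")
    if (boundary) comp <- "e"
    if (is.na(comp) || !nzchar(comp)) comp <- "c"
    mets[[length(mets) + 1L]] <- metabolite(
      id,
      name = {
        nm <- xml2::xml_attr(sp, "name"); if (is.na(nm)) id else nm
      },
      formula = if ("FORMULA" %in% names(kv)) kv[["FORMULA"]] else NA,
      charge = if ("CHARGE" %in% names(kv)) as.integer(kv[["CHARGE"]])
               else NA_integer_,
      compartment = comp)
  }
  rx_nodes <- xml2::xml_find_all(doc, ".//*[local-name()='listOfReactions']/*[local-name()='reaction']")
  rxns <- list()
  for (rx in rx_nodes) {
    id <- xml2::xml_attr(rx, "id")
    rev_attr <- xml2::xml_attr(rx, "reversible")
    reversible <- if (is.na(rev_attr)) TRUE else identical(rev_attr, "true")
    kv <- parse_sbml_notes(rx)
    stoich <- stats::setNames(numeric(0), character(0))
    for (side in c("listOfReactants", "listOfProducts")) {
      sign <- if (side == "listOfReactants") -1 else 1
      refs <- xml2::xml_find_all(rx, sprintf(
        "./*[local-name()='%s']/*[local-name()='speciesReference']", side))
      for (ref in refs) {
        sid <- xml2::xml_attr(ref, "species")
        st <- xml2::xml_attr(ref, "stoichiometry")
        cf <- if (is.na(st)) 1 else as.numeric(st)
        stoich[sid] <- (if (sid %in% names(stoich)) stoich[[sid]] else 0) + sign * cf
      }
    }
    if (drop_boundary_species) {
      stoich <- stoich[!names(stoich) %in% boundary_ids]
    }
    kind <- if ("KIND" %in% names(kv)) kv[["KIND"]]
            else if (length(stoich) == 1L) "EXCHANGE" else "INTERNAL"
    ev <- evidence(
      genetic_class = if ("GENETIC_CLASS" %in% names(kv)) kv[["GENETIC_CLASS"]] else "NONE",
      literature = identical(unname(kv["LITERATURE"]), "true"),
      gap_fill = identical(unname(kv["GAP_FILL"]), "true"))
    rxns[[length(rxns) + 1L]] <- reaction(
      id,
      stoichiometry = stoich,
      name = {
        nm <- xml2::xml_attr(rx, "name"); if (is.na(nm)) id else nm
      },
      reversible = reversible, kind = kind,
      gene_logic = parse_gene_logic(
        if ("GENE_ASSOCIATION" %in% names(kv)) kv[["GENE_ASSOCIATION"]] else ""),
      evidence = ev,
      category = if ("CATEGORY" %in% names(kv)) kv[["CATEGORY"]] else "")
  }
  if (drop_boundary_species) {
    mets <- Filter(function(m) !m$id %in% boundary_ids, mets)
  }
  metabolic_network(mets, rxns, validate = FALSE)
}

#' Write a phenotype sweep as TSV
#'
#' Fixed column order (`maintenance`, `acetate_fraction`, `status`,
#' `growth`), one row per grid cell, maintenance-major, for bit-exact
#' diffing.
#'
#' @param sweep A `sweep_result` from [sweep_phenotype()].
#' @param path Destination TSV.
#' @return `path`, invisibly.
#' @export
write_sweep_table <- function(sweep, path) {
  stopifnot(inherits(sweep, "sweep_result"))
  g <- sweep$growth
  df <- data.frame(
    maintenance = rep(sweep$grid$maintenance_values,
                      each = length(sweep$grid$acetate_fractions)),
    acetate_fraction = rep(sweep$grid$acetate_fractions,
                           times = length(sweep$grid$maintenance_values)),
    status = as.character(ifelse(is.na(as.vector(t(g))), "INFEASIBLE",
                                 "OPTIMAL")),
    growth = as.numeric(t(g)),
    stringsAsFactors = FALSE)
  df$growth <- ifelse(is.na(df$growth), "",
                      format(df$growth, trim = TRUE, scientific = FALSE,
                             digits = 12))
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
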