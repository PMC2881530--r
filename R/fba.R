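# Flux balance core: stoichiometric matrix, reaction-class constraint
# construction, LP solution and diagnostics.
#
# The LP solved is the classical one: choose a flux vector v maximizing an
# objective c'v subject to steady state S v = 0, with reversible internal
# reactions free in sign, irreversible ones bounded below by zero, exchange
# fluxes of ubiquitous compounds free, exchange fluxes of parameterized
# compounds fixed to their uptake values, one-way (secretion-only) exchanges
# signed outward, and abundant compounds free for uptake only.

#' Build the stoichiometric matrix of a network
#'
#' @param network A `metabolic_network`.
#' @return Sparse `Matrix` (metabolites x reactions) with dimnames; entry
#'   (i, j) is reaction j's signed coefficient for metabolite i.
#' @export
build_stoichiometric_matrix <- function(network) {
  stopifnot(inherits(network, "metabolic_network"))
  met_ids <- names(network$metabolites)
  rxn_ids <- names(network$reactions)
  ii <- integer(0); jj <- integer(0); xx <- numeric(0)
  for (j in seq_along(network$reactions)) {
    s <- network$reactions[[j]]$stoichiometry
    if (length(s) == 0L) next
    idx <- match(names(s), met_ids)
    if (anyNA(idx)) {
      stop(sprintf("reaction '%s' references undeclared metabolite(s): %s",
                   rxn_ids[j],
                   paste(names(s)[is.na(idx)], collapse = ", ")))
    }
    ii <- c(ii, idx); jj <- c(jj, rep(j, length(s))); xx <- c(xx, unname(s))
  }
  Matrix::sparseMatrix(i = ii, j = jj, x = xx,
                       dims = c(length(met_ids), length(rxn_ids)),
                       dimnames = list(met_ids, rxn_ids))
}

#' Exchange specification for the flux LP
#'
#' @param ubiquitous Metabolite ids with free two-way exchange (CO2, water,
#'   major ions of the brine).
#' @param parameterized Named numeric vector: metabolite id -> fixed uptake
#'   (positive = into the cell); these enter the LP as equalities.
#' @param secretion_only Metabolite ids with one-way outflow (overflow
#'   metabolites that cells may accumulate in the medium).
#' @param abundant Metabolite ids freely available for uptake (sulfate,
#'   orthophosphate, trace ions) but not secreted.
#' @return An `exchange_spec`; the four sets must be pairwise disjoint.
#' @export
exchange_spec <- function(ubiquitous = character(0),
                          parameterized = stats::setNames(numeric(0), character(0)),
                          secretion_only = character(0),
                          abundant = character(0)) {
  stopifnot(is.numeric(parameterized))
  sets <- list(ubiquitous = ubiquitous, parameterized = names(parameterized),
               secretion_only = secretion_only, abundant = abundant)
  all_ids <- unlist(sets, use.names = FALSE)
  if (anyDuplicated(all_ids)) {
    stop(sprintf("exchange_spec sets must be pairwise disjoint; duplicated: %s",
                 paste(unique(all_ids[duplicated(all_ids)]), collapse = ", ")))
  }
  structure(list(ubiquitous = ubiquitous, parameterized = parameterized,
                 secretion_only = secretion_only, abundant = abundant),
            class = "exchange_spec")
}

# map: metabolite id -> (exchange reaction id, orientation s) where s is the
# coefficient of the metabolite in that exchange column (s * v = net import).
exchange_orientation <- function(reactions) {
  out <- list()
  for (r in reactions) {
    if (r$kind == "EXCHANGE" && length(r$stoichiometry) == 1L) {
      out[[names(r$stoichiometry)]] <- list(id = r$id,
                                            s = unname(r$stoichiometry[[1]]))
    }
  }
  out
}

#' Build a flux balance problem
#'
#' Classifies every reaction exactly once (reversible/irreversible internal,
#' growth, or one of the four exchange classes), synthesizing exchange
#' columns for metabolites named in `exchanges` that lack one. Exchange
#' reactions present in the network but not named in the spec are closed
#' (flux fixed to 0).
#'
#' @param network A `metabolic_network` (must pass [validate_network()]).
#' @param exchanges An [exchange_spec()].
#' @param objective A reaction id, or a named numeric weight vector over
#'   reaction ids.
#' @param extra_reactions Optional list of [reaction()] objects appended
#'   before building (e.g. a freshly assembled growth reaction).
#' @return A `flux_problem` with the sparse matrix `S`, objective `obj`, and
#'   bounds `lb`/`ub` over the (possibly augmented) reaction set.
#' @export
build_flux_problem <- function(network, exchanges, objective,
                               extra_reactions = list()) {
  stopifnot(inherits(network, "metabolic_network"),
            inherits(exchanges, "exchange_spec"))
  reactions <- c(network$reactions, stats::setNames(
    extra_reactions, vapply(extra_reactions, function(r) r$id, character(1))))
  met_ids <- names(network$metabolites)
  spec_mets <- c(exchanges$ubiquitous, names(exchanges$parameterized),
                 exchanges$secretion_only, exchanges$abundant)
  missing <- setdiff(spec_mets, met_ids)
  if (length(missing) > 0L) {
    stop(sprintf("exchange_spec names metabolites absent from the network: %s",
                 paste(missing, collapse = ", ")))
  }
  exch <- exchange_orientation(reactions)
  for (m in setdiff(spec_mets, names(exch))) {
    rid <- paste0("EX_", m)
    while (rid %in% names(reactions)) rid <- paste0(rid, "_x")
    reactions[[rid]] <- reaction(rid, stats::setNames(1, m),
                                 name = paste("exchange of", m),
                                 reversible = TRUE, kind = "EXCHANGE")
    exch[[m]] <- list(id = rid, s = 1)
  }
  net2 <- structure(list(metabolites = network$metabolites,
                         reactions = reactions),
                    class = "metabolic_network")
  S <- build_stoichiometric_matrix(net2)
  rxn_ids <- names(reactions)
  n <- length(rxn_ids)
  lb <- stats::setNames(rep(-Inf, n), rxn_ids)
  ub <- stats::setNames(rep(Inf, n), rxn_ids)
  class_of <- stats::setNames(character(n), rxn_ids)
  for (r in reactions) {
    if (r$kind == "GROWTH") {
      lb[r$id] <- 0; class_of[r$id] <- "growth"
    } else if (r$kind == "INTERNAL") {
      if (!r$reversible) lb[r$id] <- 0
      class_of[r$id] <- if (r$reversible) "reversible" else "irreversible"
    }
  }
  for (r in reactions) {
    if (r$kind != "EXCHANGE") next
    m <- names(r$stoichiometry)
    s <- unname(r$stoichiometry[[1]])
    if (m %in% exchanges$ubiquitous) {
      lb[r$id] <- -Inf; ub[r$id] <- Inf; class_of[r$id] <- "ubiquitous"
    } else if (m %in% names(exchanges$parameterized)) {
      v <- exchanges$parameterized[[m]] / s
      lb[r$id] <- v; ub[r$id] <- v; class_of[r$id] <- "parameterized"
    } else if (m %in% exchanges$secretion_only) {
      if (s > 0) { lb[r$id] <- -Inf; ub[r$id] <- 0 } else { lb[r$id] <- 0 }
      class_of[r$id] <- "secretion_only"
    } else if (m %in% exchanges$abundant) {
      if (s > 0) { lb[r$id] <- 0 } else { lb[r$id] <- -Inf; ub[r$id] <- 0 }
      class_of[r$id] <- "abundant"
    } else {
      lb[r$id] <- 0; ub[r$id] <- 0; class_of[r$id] <- "closed"
    }
  }
  obj <- stats::setNames(numeric(n), rxn_ids)
  if (is.character(objective)) {
    if (!all(objective %in% rxn_ids)) {
      stop(sprintf("objective reaction(s) not in network: %s",
                   paste(setdiff(objective, rxn_ids), collapse = ", ")))
    }
    obj[objective] <- 1
  } else if (is.numeric(objective) && !is.null(names(objective))) {
    if (!all(names(objective) %in% rxn_ids)) {
      stop("objective weights name unknown reactions")
    }
    obj[names(objective)] <- objective
  } else stop("objective must be a reaction id or a named weight vector")
  structure(list(S = S, obj = obj, lb = lb, ub = ub,
                 reaction_ids = rxn_ids, metabolite_ids = met_ids,
                 class_of = class_of, exchanges = exchanges,
                 exchange_map = exch, network = net2),
            class = "flux_problem")
}

#' Solve a flux balance problem
#'
#' @param problem A `flux_problem`.
#' @param feas_tol Steady-state residual tolerance, absolute after scaling
#'   each row to unit maximum coefficient.
#' @return A `flux_solution`: `status` (`"OPTIMAL"`, `"INFEASIBLE"`,
#'   `"UNBOUNDED"`, `"NUMERICAL"`), `v` (named flux vector) and
#'   `objective_value`.
#' @export
solve_flux_problem <- function(problem, feas_tol = 1e-7) {
  stopifnot(inherits(problem, "flux_problem"))
  res <- solve_lp(problem$obj, problem$S, rep(0, nrow(problem$S)),
                  lb = problem$lb, ub = problem$ub, sense = "max")
  if (res$status != "OPTIMAL") {
    return(structure(list(status = res$status, v = NULL,
                          objective_value = NA_real_),
                     class = "flux_solution"))
  }
  v <- stats::setNames(res$x, problem$reaction_ids)
  resid <- as.numeric(problem$S %*% v)
  rscale <- apply(abs(as.matrix(problem$S)), 1, max)
  rscale[rscale == 0] <- 1
  if (max(abs(resid) / rscale) > feas_tol) {
    return(structure(list(status = "NUMERICAL", v = v,
                          objective_value = NA_real_,
                          residual = max(abs(resid) / rscale)),
                     class = "flux_solution"))
  }
  structure(list(status = "OPTIMAL", v = v, objective_value = res$objective),
            class = "flux_solution")
}

#' @export
print.flux_solution <- function(x, ...) {
  cat(sprintf("<flux_solution> %s, objective %s\n", x$status,
              format(x$objective_value)))
  invisible(x)
}

#' Carbon closure ledger of a flux solution
#'
#' Audits where exchanged carbon goes: uptake across parameterized/abundant
#' exchanges, CO2 outflow, other secreted carbon, and carbon incorporated
#' through growth reactions (summed over their known-formula participants).
#'
#' @param solution An OPTIMAL `flux_solution`.
#' @param problem The `flux_problem` it solved.
#' @param tol Fluxes below `tol` are treated as zero.
#' @return List: `uptake_C`, `co2_C`, `secreted_C`, `incorporated_C`,
#'   `residual_C` (uptake - co2 - secreted - incorporated), `unverifiable`
#'   (ids of carbon-carrying exchanges with unknown formula and nonzero
#'   flux).
#' @export
carbon_closure_check <- function(solution, problem, tol = 1e-9) {
  stopifnot(inherits(solution, "flux_solution"),
            inherits(problem, "flux_problem"))
  if (solution$status != "OPTIMAL") stop("carbon closure requires an OPTIMAL solution")
  v <- solution$v
  mets <- problem$network$metabolites
  uptake <- 0; co2 <- 0; secreted <- 0
  unverifiable <- character(0)
  for (m in names(problem$exchange_map)) {
    e <- problem$exchange_map[[m]]
    rate <- e$s * v[[e$id]]          # + = import
    if (abs(rate) <= tol) next
    f <- mets[[m]]$formula
    if (is_unknown_formula(f)) {
      unverifiable <- c(unverifiable, e$id)
      next
    }
    nc <- element_count(f, "C")
    if (nc == 0) next
    is_co2 <- identical(render_formula(f), "CO2")
    if (rate > 0) uptake <- uptake + rate * nc
    else if (is_co2) co2 <- co2 - rate * nc
    else secreted <- secreted - rate * nc
  }
  incorporated <- 0
  for (r in problem$network$reactions) {
    if (r$kind != "GROWTH") next
    g <- v[[r$id]]
    if (abs(g) <= tol) next
    for (mid in names(r$stoichiometry)) {
      f <- mets[[mid]]$formula
      if (is_unknown_formula(f)) next   # the biomass unit itself
      incorporated <- incorporated - g * r$stoichiometry[[mid]] *
        element_count(f, "C")
    }
  }
  list(uptake_C = uptake, co2_C = co2, secreted_C = secreted,
       incorporated_C = incorporated,
       residual_C = uptake - co2 - secreted - incorporated,
       unverifiable = unverifiable)
}

#' Remove reactions that can never carry flux
#'
#' Iteratively deletes internal reactions touching a dead-end metabolite
#' (one with no possible producer or no possible consumer, counting
#' reversible reactions in both directions and treating exchanged
#' metabolites as always producible/consumable). Standard preprocessing
#' that shrinks the LP without changing its optimum.
#'
#' @param network A `metabolic_network`.
#' @param exchanges An [exchange_spec()]; its metabolites (plus any touched
#'   by EXCHANGE reactions) are protected.
#' @param drop_orphan_metabolites Remove metabolites left untouched by any
#'   reaction. Default `TRUE`.
#' @return The pruned `metabolic_network`.
#' @export
prune_blocked_reactions <- function(network, exchanges,
                                    drop_orphan_metabolites = TRUE) {
  stopifnot(inherits(network, "metabolic_network"),
            inherits(exchanges, "exchange_spec"))
  reactions <- network$reactions
  open_mets <- unique(c(exchanges$ubiquitous, names(exchanges$parameterized),
                        exchanges$secretion_only, exchanges$abundant,
                        names(exchange_orientation(reactions))))
  repeat {
    producers <- list(); consumers <- list()
    for (r in reactions) {
      for (mid in names(r$stoichiometry)) {
        cf <- r$stoichiometry[[mid]]
        if (cf > 0 || r$reversible) producers[[mid]] <- c(producers[[mid]], r$id)
        if (cf < 0 || r$reversible) consumers[[mid]] <- c(consumers[[mid]], r$id)
      }
    }
    blocked <- character(0)
    for (r in reactions) {
      if (r$kind == "EXCHANGE") next
      for (mid in names(r$stoichiometry)) {
        if (mid %in% open_mets) next
        touching <- union(producers[[mid]], consumers[[mid]])
        if (is.null(producers[[mid]]) || is.null(consumers[[mid]]) ||
            length(touching) == 1L) {
          blocked <- c(blocked, r$id)
          break
        }
      }
    }
    if (length(blocked) == 0L) break
    reactions <- reactions[!names(reactions) %in% blocked]
  }
  mets <- network$metabolites
  if (drop_orphan_metabolites) {
    used <- unique(unlist(lapply(reactions, function(r) names(r$stoichiometry))))
    mets <- mets[names(mets) %in% union(used, open_mets)]
  }
  structure(list(metabolites = mets, reactions = reactions),
            class = "metabolic_network")
}

#' Dump a flux problem as a plain-text LP file
#'
#' CPLEX-LP-style text export for audit purposes.
#' @param problem A `flux_problem`.
#' @param path Destination file.
#' @return `path`, invisibly.
#' @export
write_lp_file <- function(problem, path) {
  stopifnot(inherits(problem, "flux_problem"))
  term <- function(coef, var) {
    sprintf("%s %s %s", ifelse(coef < 0, "-", "+"),
            format(abs(coef), trim = TRUE, scientific = FALSE), var)
  }
  lines <- c("Maximize",
             paste(" obj:",
                   paste(term(problem$obj[problem$obj != 0],
                              names(problem$obj)[problem$obj != 0]),
                         collapse = " ")),
             "Subject To")
  Sm <- as.matrix(problem$S)
  for (i in seq_len(nrow(Sm))) {
    nz <- which(Sm[i, ] != 0)
    if (length(nz) == 0L) next
    lines <- c(lines, paste0(" ", rownames(Sm)[i], ": ",
                             paste(term(Sm[i, nz], colnames(Sm)[nz]),
                                   collapse = " "), " = 0"))
  }
  lines <- c(lines, "Bounds")
  for (j in seq_along(problem$lb)) {
    lines <- c(lines, sprintf(" %s <= %s <= %s",
                              format(problem$lb[j]), names(problem$lb)[j],
                              format(problem$ub[j])))
  }
  lines <- c(lines, "End")
  writeLines(lines, path)
  invisible(path)
}
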