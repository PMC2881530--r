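# Phenotype plane: maximal growth over the acetate:oxygen uptake ratio and
# the maintenance energy, with feasibility walls and the optimality curve.
#
# The ratio is parameterized as the acetate fraction f = acetate /
# (acetate + O2) of a fixed total uptake; by LP scale invariance the total
# only scales the growth surface, so the phenotype is a function of
# (f, maintenance) alone.

#' Define a sweep grid
#'
#' @param acetate_fractions Ascending fractions strictly inside (0, 1);
#'   default 0.10 ... 0.90 step 0.01 (the 1:9 to 9:1 quotient range).
#' @param maintenance_values Ascending maintenance energies, umol ATP per
#'   delta-OD*ml; default 0 ... 100 step 5.
#' @param total_uptake Total acetate + O2 uptake (arbitrary positive scale).
#' @return A `sweep_grid`.
#' @export
sweep_grid <- function(acetate_fractions = seq(0.10, 0.90, by = 0.01),
                       maintenance_values = seq(0, 100, by = 5),
                       total_uptake = 10) {
  stopifnot(all(acetate_fractions > 0), all(acetate_fractions < 1),
            !is.unsorted(acetate_fractions, strictly = TRUE),
            all(maintenance_values >= 0),
            !is.unsorted(maintenance_values, strictly = TRUE),
            total_uptake > 0)
  structure(list(acetate_fractions = acetate_fractions,
                 maintenance_values = maintenance_values,
                 total_uptake = total_uptake),
            class = "sweep_grid")
}

#' Maximal growth at one uptake setting
#'
#' Solves the flux LP with the growth reaction as objective and acetate/O2
#' uptakes fixed as parameters.
#'
#' @param network A `metabolic_network` (without a growth reaction, or with
#'   one that `growth_reaction` replaces).
#' @param growth_reaction A GROWTH [reaction()] (e.g. from
#'   [assemble_growth_reaction()], already carrying the maintenance term).
#' @param exchanges Base [exchange_spec()]; acetate and O2 are added/overridden
#'   as parameterized uptakes.
#' @param acetate_uptake,o2_uptake Fixed uptakes (> 0).
#' @param acetate_id,o2_id Metabolite ids.
#' @return List `status` (`"OPTIMAL"`, `"INFEASIBLE"`, ...) and `growth`
#'   (flux through the growth reaction; `NA` unless OPTIMAL).
#' @export
max_growth <- function(network, growth_reaction, exchanges,
                       acetate_uptake, o2_uptake,
                       acetate_id = "ace", o2_id = "o2") {
  stopifnot(acetate_uptake > 0, o2_uptake > 0)
  ex <- merge_parameterized(exchanges,
                            stats::setNames(c(acetate_uptake, o2_uptake),
                                            c(acetate_id, o2_id)))
  net <- drop_growth_reactions(network)
  problem <- build_flux_problem(net, ex, objective = growth_reaction$id,
                                extra_reactions = list(growth_reaction))
  sol <- solve_flux_problem(problem)
  list(status = sol$status,
       growth = if (sol$status == "OPTIMAL") sol$objective_value else NA_real_,
       solution = sol, problem = problem)
}

merge_parameterized <- function(exchanges, values) {
  stopifnot(inherits(exchanges, "exchange_spec"))
  p <- exchanges$parameterized
  p <- p[setdiff(names(p), names(values))]
  p <- c(p, values)
  drop <- names(values)
  exchange_spec(ubiquitous = setdiff(exchanges$ubiquitous, drop),
                parameterized = p,
                secretion_only = setdiff(exchanges$secretion_only, drop),
                abundant = setdiff(exchanges$abundant, drop))
}

drop_growth_reactions <- function(network) {
  keep <- Filter(function(r) r$kind != "GROWTH", network$reactions)
  structure(list(metabolites = network$metabolites, reactions = keep),
            class = "metabolic_network")
}

#' Sweep maximal growth over the phenotype plane
#'
#' One LP per grid cell; the growth reaction is rebuilt for every
#' maintenance value. Deterministic for fixed inputs.
#'
#' @param network A `metabolic_network`.
#' @param growth_builder Function `maintenance -> GROWTH reaction`, with
#'   maintenance in umol ATP per delta-OD*ml (builders for the generated
#'   networks are attached to them as the `"growth_builder"` attribute).
#' @param grid A [sweep_grid()].
#' @param exchanges Base [exchange_spec()] (without acetate/O2, which the
#'   sweep parameterizes).
#' @param acetate_id,o2_id Metabolite ids for the swept exchanges.
#' @param prune Prune never-flux reactions once per maintenance value before
#'   solving (identical optima, smaller LPs).
#' @return A `sweep_result`: `grid`, `growth` (maintenance x fraction
#'   matrix; `NA` = infeasible) and `status` (matching character matrix;
#'   numerical failures are marked `"NUMERICAL"`, never silently
#'   infeasible).
#' @export
sweep_phenotype <- function(network, growth_builder, grid, exchanges,
                            acetate_id = "ace", o2_id = "o2", prune = TRUE) {
  stopifnot(inherits(grid, "sweep_grid"), is.function(growth_builder))
  nf <- length(grid$acetate_fractions)
  nm <- length(grid$maintenance_values)
  growth <- matrix(NA_real_, nm, nf,
                   dimnames = list(maintenance = grid$maintenance_values,
                                   fraction = grid$acetate_fractions))
  status <- matrix("INFEASIBLE", nm, nf, dimnames = dimnames(growth))
  base_net <- drop_growth_reactions(network)
  for (im in seq_len(nm)) {
    m <- grid$maintenance_values[im]
    rxn_g <- growth_builder(m)
    stopifnot(inherits(rxn_g, "reaction"), rxn_g$kind == "GROWTH")
    ex <- merge_parameterized(exchanges, stats::setNames(c(1, 1),
                                                         c(acetate_id, o2_id)))
    net_m <- base_net
    net_m$reactions[[rxn_g$id]] <- rxn_g
    if (prune) net_m <- prune_blocked_reactions(net_m, ex)
    if (!rxn_g$id %in% names(net_m$reactions)) {
      # growth itself blocked: every cell infeasible at this maintenance
      next
    }
    net_m$reactions[[rxn_g$id]] <- NULL
    problem <- build_flux_problem(net_m, ex, objective = rxn_g$id,
                                  extra_reactions = list(rxn_g))
    for (jf in seq_len(nf)) {
      f <- grid$acetate_fractions[jf]
      vals <- c(f, 1 - f) * grid$total_uptake
      p2 <- set_parameterized_uptakes(problem,
                                      stats::setNames(vals, c(acetate_id, o2_id)))
      sol <- solve_flux_problem(p2)
      status[im, jf] <- sol$status
      if (sol$status == "OPTIMAL") growth[im, jf] <- sol$objective_value
    }
  }
  structure(list(grid = grid, growth = growth, status = status),
            class = "sweep_result")
}

# retarget the fixed-uptake bounds of an already built problem
set_parameterized_uptakes <- function(problem, values) {
  stopifnot(inherits(problem, "flux_problem"))
  for (m in names(values)) {
    e <- problem$exchange_map[[m]]
    if (is.null(e)) stop(sprintf("no exchange column for metabolite '%s'", m))
    v <- values[[m]] / e$s
    problem$lb[e$id] <- v
    problem$ub[e$id] <- v
  }
  problem
}

#' @export
print.sweep_result <- function(x, ...) {
  cat(sprintf("<sweep_result> %d maintenance x %d fraction cells, %d feasible\n",
              nrow(x$growth), ncol(x$growth), sum(!is.na(x$growth))))
  invisible(x)
}

#' Feasibility bounds of a sweep
#'
#' First/last feasible acetate fraction per maintenance row, plus the
#' envelope (min/max over rows). All-infeasible sweeps yield an explicit
#' empty result.
#'
#' @param sweep A `sweep_result`.
#' @return List: `per_maintenance` (data.frame maintenance, min_fraction,
#'   max_fraction, n_feasible) and `envelope` (named numeric
#'   `c(min_fraction, max_fraction)`, `NA` when nothing is feasible).
#' @export
feasibility_bounds <- function(sweep) {
  stopifnot(inherits(sweep, "sweep_result"))
  fr <- sweep$grid$acetate_fractions
  rows <- lapply(seq_len(nrow(sweep$growth)), function(im) {
    ok <- which(!is.na(sweep$growth[im, ]))
    data.frame(maintenance = sweep$grid$maintenance_values[im],
               min_fraction = if (length(ok)) fr[min(ok)] else NA_real_,
               max_fraction = if (length(ok)) fr[max(ok)] else NA_real_,
               n_feasible = length(ok))
  })
  per <- do.call(rbind, rows)
  feas <- per[per$n_feasible > 0, , drop = FALSE]
  envelope <- if (nrow(feas) > 0) {
    c(min_fraction = min(feas$min_fraction),
      max_fraction = max(feas$max_fraction))
  } else c(min_fraction = NA_real_, max_fraction = NA_real_)
  list(per_maintenance = per, envelope = envelope)
}

#' Optimality curve of a sweep
#'
#' Per maintenance row, the acetate fraction maximizing growth. Ties
#' (within `tie_tol` relative) are reported as a plateau interval with its
#' midpoint as the scalar representative. All-infeasible rows are omitted
#' (noted in the `omitted` field).
#'
#' @param sweep A `sweep_result`.
#' @param tie_tol Relative tie tolerance on the row maximum.
#' @return An `optimality_curve`: data.frame `curve` (maintenance,
#'   optimal_fraction, plateau_lo, plateau_hi, optimal_growth) and
#'   `omitted` (maintenance values with no feasible cell).
#' @export
optimality_curve <- function(sweep, tie_tol = 1e-6) {
  stopifnot(inherits(sweep, "sweep_result"))
  fr <- sweep$grid$acetate_fractions
  rows <- list(); omitted <- numeric(0)
  for (im in seq_len(nrow(sweep$growth))) {
    g <- sweep$growth[im, ]
    if (all(is.na(g))) {
      omitted <- c(omitted, sweep$grid$maintenance_values[im])
      next
    }
    gmax <- max(g, na.rm = TRUE)
    at <- which(!is.na(g) & g >= gmax - tie_tol * max(1, abs(gmax)))
    rows[[length(rows) + 1L]] <- data.frame(
      maintenance = sweep$grid$maintenance_values[im],
      optimal_fraction = (fr[min(at)] + fr[max(at)]) / 2,
      plateau_lo = fr[min(at)], plateau_hi = fr[max(at)],
      optimal_growth = gmax)
  }
  structure(list(curve = do.call(rbind, rows), omitted = omitted),
            class = "optimality_curve")
}

#' Near-optimality of an observed uptake ratio
#'
#' Ratio of the growth attainable at the observed acetate fraction to the
#' row optimum, at the nearest maintenance row (or linearly interpolated).
#' 0 when the observed cell is infeasible.
#'
#' @param sweep A `sweep_result`.
#' @param observed_fraction Observed acetate fraction (within the grid
#'   span).
#' @param maintenance Maintenance energy (within the grid span).
#' @param interpolate Linear interpolation across the two bracketing
#'   maintenance rows instead of nearest-row lookup.
#' @return Ratio in [0, 1].
#' @export
near_optimality <- function(sweep, observed_fraction, maintenance,
                            interpolate = FALSE) {
  stopifnot(inherits(sweep, "sweep_result"))
  fr <- sweep$grid$acetate_fractions
  mv <- sweep$grid$maintenance_values
  stopifnot(observed_fraction >= min(fr), observed_fraction <= max(fr),
            maintenance >= min(mv), maintenance <= max(mv))
  jf <- which.min(abs(fr - observed_fraction))
  ratio_at <- function(im) {
    g <- sweep$growth[im, ]
    if (all(is.na(g))) return(NA_real_)
    gobs <- g[[jf]]
    if (is.na(gobs)) return(0)
    gobs / max(g, na.rm = TRUE)
  }
  if (!interpolate || maintenance %in% mv) {
    return(ratio_at(which.min(abs(mv - maintenance))))
  }
  i0 <- max(which(mv <= maintenance))
  i1 <- min(which(mv >= maintenance))
  w <- (maintenance - mv[i0]) / (mv[i1] - mv[i0])
  (1 - w) * ratio_at(i0) + w * ratio_at(i1)
}

#' Estimate maintenance energy from respiration
#'
#' Oxygen consumed per unit biomass increase, converted to ATP through the
#' P:O ratio (ATP per oxygen *atom* reduced by the respiratory chain; set
#' `atoms_per_o2 = 1` for a per-O2 reading of the ratio).
#'
#' @param o2_per_biomass umol O2 consumed per delta-OD*ml (>= 0).
#' @param p_o_ratio ATP per oxygen atom (default 1, the halophile value).
#' @param atoms_per_o2 Oxygen atoms credited per O2 (default 2).
#' @return Maintenance energy, umol ATP per delta-OD*ml.
#' @export
estimate_maintenance_energy <- function(o2_per_biomass, p_o_ratio = 1,
                                        atoms_per_o2 = 2) {
  stopifnot(o2_per_biomass >= 0, p_o_ratio >= 0, atoms_per_o2 > 0)
  o2_per_biomass * atoms_per_o2 * p_o_ratio
}
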