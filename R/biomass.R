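# Biomass (growth reaction) construction from composition measurements.
#
# The growth pseudo-reaction consumes biomass precursors in measured ratios
# (umol per OD*L of culture) and produces one unit of population. Its
# coefficient pipeline: a total-organic-carbon (TOC) slope against optical
# density fixes the bulk carbon; per-amino-acid slopes fix the protein
# fraction; combined analyser pools (Asp+Asn, Glu+Gln) are split by
# proteome abundance; cysteine and tryptophan (not measurable on the
# analyser) are estimated from proteome frequencies; nucleotides take a
# configurable share of the TOC and are allocated across base pairs by the
# genomic A+T : G+C proportion; minor components (lipids, S-layer sugars,
# cofactor ATP) are scaled from a reference organism; a maintenance-ATP
# term proportional to growth closes the energy demand.

#' Least-squares slope through the origin
#'
#' Fits `amount = slope * od` (no intercept): zero biomass at zero optical
#' density. Optionally an intercept model for sensitivity work.
#'
#' @param od Optical densities (> 0, length >= 2).
#' @param amount Measured amounts (same length).
#' @param intercept Fit an intercept instead of forcing the origin.
#' @return A `linear_fit`: `slope`, `stderr` (of the slope), `n`,
#'   `intercept` (0 unless requested).
#' @export
fit_through_origin <- function(od, amount, intercept = FALSE) {
  stopifnot(length(od) == length(amount), length(od) >= 2)
  if (all(od == 0)) stop("degenerate input: all optical densities are zero")
  # stderr computed directly from the residuals so that exact fits report a
  # clean zero instead of a perfect-fit warning
  if (intercept) {
    fit <- stats::lm(amount ~ od)
    sigma2 <- sum(stats::residuals(fit)^2) / max(fit$df.residual, 1)
    xc <- od - mean(od)
    se <- sqrt(sigma2 / sum(xc^2))
    return(structure(list(slope = unname(stats::coef(fit)[["od"]]),
                          stderr = se,
                          intercept = unname(stats::coef(fit)[["(Intercept)"]]),
                          n = length(od)),
                     class = "linear_fit"))
  }
  fit <- stats::lm(amount ~ od + 0)
  sigma2 <- sum(stats::residuals(fit)^2) / max(fit$df.residual, 1)
  structure(list(slope = unname(stats::coef(fit)[["od"]]),
                 stderr = sqrt(sigma2 / sum(od^2)),
                 intercept = 0, n = length(od)),
            class = "linear_fit")
}

#' @export
print.linear_fit <- function(x, ...) {
  cat(sprintf("<linear_fit> slope %.6g +/- %.3g (n = %d)\n",
              x$slope, x$stderr, x$n))
  invisible(x)
}

#' Create a composition sample
#'
#' @param od Optical density of the culture sample (> 0).
#' @param values Named numeric vector, analyte -> amount (per litre of
#'   culture, in the configured unit).
#' @return A `composition_sample`.
#' @export
composition_sample <- function(od, values) {
  stopifnot(is.numeric(od), length(od) == 1L, od > 0,
            is.numeric(values), !is.null(names(values)), all(values >= 0))
  structure(list(od = od, values = values), class = "composition_sample")
}

#' Per-analyte slopes from composition samples
#'
#' One origin-constrained fit per analyte across samples. Pooled analytes
#' (e.g. `"Asp+Asn"`) are single keys here and are split downstream.
#'
#' @param samples List of [composition_sample()]s reporting identical
#'   analyte sets.
#' @param intercept Passed to [fit_through_origin()].
#' @return Named list of `linear_fit`s.
#' @export
fit_amino_acid_slopes <- function(samples, intercept = FALSE) {
  stopifnot(length(samples) >= 2)
  analytes <- names(samples[[1]]$values)
  for (s in samples) {
    if (!identical(sort(names(s$values)), sort(analytes))) {
      stop("inconsistent analyte sets across composition samples")
    }
  }
  od <- vapply(samples, function(s) s$od, numeric(1))
  out <- lapply(analytes, function(a) {
    fit_through_origin(od, vapply(samples, function(s) s$values[[a]], numeric(1)),
                       intercept = intercept)
  })
  stats::setNames(out, analytes)
}

#' Split a combined analyte pool by proteome abundance
#'
#' Divides a pooled total (amino-acid analysers report Asp+Asn and Glu+Gln
#' jointly) across its members in proportion to their relative abundance in
#' all protein-coding genes. Shares sum to the pool total exactly.
#'
#' @param pool_total Pooled coefficient (umol per OD*L).
#' @param member_freqs Named relative abundances (>= 0, not all zero).
#' @return Named numeric vector of member coefficients.
#' @export
split_combined_pool <- function(pool_total, member_freqs) {
  stopifnot(is.numeric(pool_total), length(pool_total) == 1L,
            is.numeric(member_freqs), !is.null(names(member_freqs)),
            all(member_freqs >= 0))
  tot <- sum(member_freqs)
  if (tot == 0) stop("all member frequencies are zero; cannot split pool")
  pool_total * member_freqs / tot
}

#' Estimate unmeasured amino acids from proteome frequencies
#'
#' For amino acids that the analyser cannot quantify (cysteine,
#' tryptophan), the coefficient is the total of the measured ones scaled by
#' the target's proteome frequency relative to the measured set's summed
#' frequency.
#'
#' @param measured Named coefficients of measured amino acids (umol/OD*L).
#' @param proteome_freqs Named frequencies covering measured and target
#'   amino acids (one copy per gene convention).
#' @param targets Character vector of amino acids to estimate.
#' @return Named numeric vector over `targets`.
#' @export
estimate_unmeasured_aa <- function(measured, proteome_freqs,
                                   targets = c("Cys", "Trp")) {
  stopifnot(length(measured) > 0, !is.null(names(measured)))
  if (any(targets %in% names(measured))) {
    stop("targets must be disjoint from measured amino acids")
  }
  miss <- setdiff(c(targets, names(measured)), names(proteome_freqs))
  if (length(miss) > 0L) {
    stop(sprintf("proteome_freqs lacks: %s", paste(miss, collapse = ", ")))
  }
  denom <- sum(proteome_freqs[names(measured)])
  if (denom == 0) stop("measured amino acids have zero total proteome frequency")
  stats::setNames(sum(measured) * proteome_freqs[targets] / denom, targets)
}

#' Allocate a nucleotide pool across base pairs
#'
#' Splits the total (d)NMP pool across the four pairs by the genomic base
#' composition: the A pair and the T/U pair each get half the A+T share, the
#' G and C pairs each half of the remainder. Note that in the reference
#' composition the larger share (63.4%) sits on the A/T pairs; the split
#' fraction is therefore an explicit parameter rather than a hard-coded
#' "GC content" (see the methods vignette for the discrepancy discussion).
#'
#' @param nucleotide_pool Total pool over the four NMP+dNMP pairs
#'   (umol/OD*L, >= 0).
#' @param split_fraction_AT Fraction allocated to the A and T/U pairs
#'   jointly; default 0.634.
#' @return Named vector over `AMP+dAMP`, `UMP+dTMP`, `GMP+dGMP`,
#'   `CMP+dCMP`; sums to the pool exactly.
#' @export
allocate_nucleotides <- function(nucleotide_pool, split_fraction_AT = 0.634) {
  stopifnot(length(nucleotide_pool) == 1L)
  if (nucleotide_pool < 0) stop("nucleotide pool must be non-negative")
  stopifnot(split_fraction_AT >= 0, split_fraction_AT <= 1)
  at <- nucleotide_pool * split_fraction_AT / 2
  gc <- nucleotide_pool * (1 - split_fraction_AT) / 2
  c("AMP+dAMP" = at, "UMP+dTMP" = at, "GMP+dGMP" = gc, "CMP+dCMP" = gc)
}

#' Size the nucleotide pool from the TOC budget
#'
#' Two modes. `"fraction"`: the pool carries a fixed fraction (default 20%)
#' of the total organic carbon. `"residual"`: the pool absorbs whatever
#' carbon the other components leave unclaimed, closing the carbon balance
#' exactly.
#'
#' @param toc_slope Total organic carbon, mmol C per OD*L.
#' @param composition_carbon Carbon already claimed by other components,
#'   umol C per OD*L (used by `"residual"` mode).
#' @param carbon_per_nucleotide Mean C atoms per (d)NMP (default 9.66, the
#'   GC-weighted mean of the four pairs).
#' @param mode `"fraction"` or `"residual"`.
#' @param fraction TOC share for `"fraction"` mode.
#' @return Pool size in umol/OD*L.
#' @export
residual_nucleotide_pool <- function(toc_slope, composition_carbon = 0,
                                     carbon_per_nucleotide = 9.66,
                                     mode = c("fraction", "residual"),
                                     fraction = 0.2) {
  mode <- match.arg(mode)
  stopifnot(toc_slope >= 0, carbon_per_nucleotide > 0)
  toc_umol <- toc_slope * 1000
  carbon <- if (mode == "fraction") toc_umol * fraction
            else toc_umol - composition_carbon
  if (carbon < -1e-9) {
    stop(sprintf(paste0("negative nucleotide carbon residual (%.3f umol C): ",
                        "other components exceed the TOC budget"), carbon))
  }
  max(carbon, 0) / carbon_per_nucleotide
}

#' Scale reference-organism component coefficients
#'
#' Minor components (lipids, S-layer sugars, cofactors) lacking direct
#' measurements are taken from a reference organism's composition and
#' scaled by the ratio of measured amino-acid content between the two
#' organisms.
#'
#' @param reference Named coefficients (umol/OD*L) in the reference
#'   organism; defaults to the halophile reference set.
#' @param aa_ratio Measured amino-acid content ratio (this organism /
#'   reference), > 0.
#' @return Scaled named coefficients.
#' @export
scale_reference_components <- function(reference = reference_minor_components(),
                                       aa_ratio = 1) {
  stopifnot(aa_ratio > 0, is.numeric(reference), !is.null(names(reference)))
  reference * aa_ratio
}

#' Reference minor-component coefficients
#'
#' The default minor-component set (umol/OD*L): ether lipid archaeol, the
#' S-layer glyco moieties, and a free-ATP pool.
#' @return Named numeric vector.
#' @export
reference_minor_components <- function() {
  c(Archaeol = 20.0, GalNAc = 2.2, GlcNAc = 2.2, Gal = 9.6, Glc = 9.6,
    ATP = 2.0)
}

#' Assemble a biomass composition
#'
#' @param coefficients Named numeric vector, component -> umol per OD*L
#'   (all >= 0).
#' @param provenance Named character vector over the same components; each
#'   one of `MEASURED`, `SPLIT_FROM_POOL`, `PROTEOME_ESTIMATED`,
#'   `GC_ALLOCATED`, `REFERENCE_SCALED`, `FIXED`.
#' @return A `biomass_composition`.
#' @export
biomass_composition <- function(coefficients, provenance) {
  stopifnot(is.numeric(coefficients), !is.null(names(coefficients)),
            all(coefficients >= 0))
  ok <- c("MEASURED", "SPLIT_FROM_POOL", "PROTEOME_ESTIMATED", "GC_ALLOCATED",
          "REFERENCE_SCALED", "FIXED")
  if (!identical(sort(names(coefficients)), sort(names(provenance)))) {
    stop("every coefficient needs a provenance entry (and vice versa)")
  }
  if (!all(provenance %in% ok)) {
    stop(sprintf("unknown provenance value(s): %s",
                 paste(setdiff(provenance, ok), collapse = ", ")))
  }
  structure(list(coefficients = coefficients,
                 provenance = provenance[names(coefficients)]),
            class = "biomass_composition")
}

#' @export
print.biomass_composition <- function(x, ...) {
  cat(sprintf("<biomass_composition> %d components, total %.1f umol/OD*L\n",
              length(x$coefficients), sum(x$coefficients)))
  invisible(x)
}

#' Growth-reaction specification
#'
#' @param composition A [biomass_composition()].
#' @param maintenance_atp Maintenance energy, umol ATP per delta-OD*ml
#'   (>= 0). Folded into the growth reaction as ATP hydrolysis proportional
#'   to growth flux.
#' @param biomass_unit Canonical biomass unit of the coefficients
#'   (informational); 1 OD*L = 1000 delta-OD*ml.
#' @return A `growth_reaction_spec`.
#' @export
growth_reaction_spec <- function(composition, maintenance_atp = 0,
                                 biomass_unit = "OD*L") {
  stopifnot(inherits(composition, "biomass_composition"),
            maintenance_atp >= 0)
  structure(list(composition = composition, maintenance_atp = maintenance_atp,
                 biomass_unit = biomass_unit),
            class = "growth_reaction_spec")
}

#' Assemble the growth pseudo-reaction
#'
#' Builds a GROWTH-kind, irreversible reaction consuming the composition's
#' components (mapped onto network metabolites) plus hydrolysed maintenance
#' ATP and water, and producing ADP, orthophosphate and one biomass unit.
#' The maintenance term converts from umol ATP per delta-OD*ml to the OD*L
#' coefficient scale (x 1000).
#'
#' @param spec A [growth_reaction_spec()].
#' @param network A `metabolic_network` providing the metabolites.
#' @param component_map Named character vector, component id -> network
#'   metabolite id. Components missing from it raise an error listing them.
#' @param atp,adp,pi,h2o,biomass Metabolite ids of the energy/water species
#'   and the biomass unit.
#' @param id Reaction id.
#' @return A GROWTH [reaction()].
#' @export
assemble_growth_reaction <- function(spec, network, component_map,
                                     atp = "atp", adp = "adp", pi = "pi",
                                     h2o = "h2o", biomass = "biomass",
                                     id = "GROWTH") {
  stopifnot(inherits(spec, "growth_reaction_spec"),
            inherits(network, "metabolic_network"))
  comps <- names(spec$composition$coefficients)
  unmapped <- setdiff(comps, names(component_map))
  if (length(unmapped) > 0L) {
    stop(sprintf("no metabolite mapping for component(s): %s",
                 paste(unmapped, collapse = ", ")))
  }
  needed <- unique(c(unname(component_map[comps]), atp, adp, pi, h2o, biomass))
  absent <- setdiff(needed, names(network$metabolites))
  if (length(absent) > 0L) {
    stop(sprintf("network lacks metabolite(s): %s", paste(absent, collapse = ", ")))
  }
  stoich <- stats::setNames(numeric(0), character(0))
  add <- function(mid, v) {
    stoich[mid] <<- (if (mid %in% names(stoich)) stoich[[mid]] else 0) + v
  }
  for (comp in comps) {
    add(component_map[[comp]], -spec$composition$coefficients[[comp]])
  }
  maint <- spec$maintenance_atp * 1000     # umol per OD*L
  if (maint > 0) {
    add(atp, -maint); add(h2o, -maint)
    add(adp, maint); add(pi, maint)
  }
  add(biomass, 1)
  reaction(id, stoich, name = "growth (biomass) reaction",
           reversible = FALSE, kind = "GROWTH")
}

#' Carbon carried by a composition
#'
#' @param composition A [biomass_composition()].
#' @param carbon_per_component Named numeric vector, component -> C atoms.
#'   Components absent from it count zero carbon.
#' @return Total umol C per OD*L.
#' @export
composition_carbon <- function(composition, carbon_per_component) {
  stopifnot(inherits(composition, "biomass_composition"))
  co <- composition$coefficients
  nc <- stats::setNames(rep(0, length(co)), names(co))
  hit <- intersect(names(co), names(carbon_per_component))
  nc[hit] <- carbon_per_component[hit]
  sum(co * nc)
}

#' Write a composition report
#'
#' TSV with fixed columns `component`, `coefficient`, `provenance`.
#' @param composition A [biomass_composition()].
#' @param path Destination TSV.
#' @return `path`, invisibly.
#' @export
write_composition_table <- function(composition, path) {
  stopifnot(inherits(composition, "biomass_composition"))
  df <- data.frame(component = names(composition$coefficients),
                   coefficient = unname(composition$coefficients),
                   provenance = unname(composition$provenance),
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
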