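# Synthetic-data generators: balanced toy networks with closed-form optima,
# a full-scale synthetic reference network emulating a curated archaeal
# reconstruction, and simulated growth/composition data with known ground
# truth. Everything here is generated, deterministic under a seed, and
# auditable by the same balance machinery as real networks.

# evaluate expr under a temporary RNG seed, restoring global state after
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Toy-network specification
#'
#' Stylized acetate energetics: activating one acetate into the acetyl pool
#' costs ATP; fully oxidizing one acetyl consumes O2 and regenerates ATP;
#' building one biomass unit consumes acetyl units and ATP. An explicit
#' ATP-hydrolysis sink keeps surplus-energy states feasible so the closed
#' forms hold.
#'
#' @param activation_atp_cost ATP per acetate activated (default 1).
#' @param atp_per_acetyl_oxidation ATP per acetyl fully oxidized (default 4).
#' @param o2_per_acetyl O2 per acetyl oxidized (default 2).
#' @param co2_per_acetyl CO2 per acetyl oxidized (default 2).
#' @param biomass_acetyl Acetyl units per biomass (default 1).
#' @param biomass_atp ATP per biomass (default 2).
#' @param include_atp_sink Include the ATP sink (default `TRUE`).
#' @return A `toy_network_spec`.
#' @export
toy_network_spec <- function(activation_atp_cost = 1,
                             atp_per_acetyl_oxidation = 4,
                             o2_per_acetyl = 2, co2_per_acetyl = 2,
                             biomass_acetyl = 1, biomass_atp = 2,
                             include_atp_sink = TRUE) {
  vals <- c(activation_atp_cost, atp_per_acetyl_oxidation, o2_per_acetyl,
            co2_per_acetyl, biomass_acetyl, biomass_atp)
  stopifnot(all(vals > 0))
  structure(list(activation_atp_cost = activation_atp_cost,
                 atp_per_acetyl_oxidation = atp_per_acetyl_oxidation,
                 o2_per_acetyl = o2_per_acetyl,
                 co2_per_acetyl = co2_per_acetyl,
                 biomass_acetyl = biomass_acetyl, biomass_atp = biomass_atp,
                 include_atp_sink = include_atp_sink),
            class = "toy_network_spec")
}

# ATP/ADP are a conserved moiety pair whose formulas differ by HPO3, so
# ATP + H2O -> ADP + Pi is elementally neutral and energy bookkeeping never
# disturbs the balance audit.
.moiety_mets <- function() {
  list(
    metabolite("atp", "ATP", "C10H16N5O13P3", 0L),
    metabolite("adp", "ADP", "C10H15N5O10P2", 0L),
    metabolite("pi", "orthophosphate", "H3PO4", 0L),
    metabolite("h2o", "water", "H2O", 0L, compartment = "e"))
}

# hydrolyse k ATP inside a stoichiometry map
.atp_hydrolysis <- function(stoich, k) {
  for (pair in list(c("atp", -k), c("h2o", -k), c("adp", k), c("pi", k))) {
    mid <- pair[1]; v <- as.numeric(pair[2])
    stoich[mid] <- (if (mid %in% names(stoich)) stoich[[mid]] else 0) + v
  }
  stoich
}

#' Generate the AC-CORE toy network
#'
#' A minimal, elementally balanced acetate-oxidation network: exchanges for
#' acetate, O2 and CO2; an activation reaction (acetate + ATP -> acetyl);
#' a lumped oxidation (acetyl + q O2 -> q CO2 + y ATP); a growth reaction
#' (acetyl + ATP -> biomass); and optionally an ATP sink. With the default
#' spec and total uptake T = a + w, the closed forms are: growth
#' g = a - w/2 (forced), feasible iff `a >= w/2` and `2w >= a + (2+m) g`,
#' maximal growth (3a - T)/2, and optimal acetate uptake
#' a* = T (6+m) / (12+3m).
#'
#' The returned network carries attributes used by the sweep machinery:
#' `"exchanges"` (base [exchange_spec()]), `"growth_builder"` (maintenance
#' -> GROWTH reaction; toy maintenance is ATP per biomass unit, applied
#' directly), `"acetate_id"`, `"o2_id"`.
#'
#' @param spec A [toy_network_spec()].
#' @return A `metabolic_network` of 7 reactions (6 without the sink).
#' @export
generate_toy_network <- function(spec = toy_network_spec()) {
  stopifnot(inherits(spec, "toy_network_spec"))
  n <- spec$co2_per_acetyl
  q <- spec$o2_per_acetyl
  # acetyl carrier formula C_n H_h O_o chosen so oxidation balances:
  # C_nH_hO_o + q O2 -> n CO2 + (h/2) H2O
  h <- max(4, 4 * (q - n) + 4)
  if (h %% 2 != 0) h <- h + 1
  o <- 2 * n + h / 2 - 2 * q
  if (o < 0) stop("toy spec not balanceable: too much O2 per acetyl")
  fac <- formula_counts(c(C = n, H = h, O = o)[c(n, h, o) > 0])
  mets <- c(list(
    metabolite("ace", "acetate (carrier form)", fac, 0L, compartment = "e"),
    metabolite("acu", "acetyl pool", fac, 0L),
    metabolite("o2", "dioxygen", "O2", 0L, compartment = "e"),
    metabolite("co2", "carbon dioxide", "CO2", 0L, compartment = "e"),
    metabolite("biomass", "biomass unit", NA, NA_integer_)),
    .moiety_mets())
  y <- spec$atp_per_acetyl_oxidation
  cact <- spec$activation_atp_cost
  rxns <- list(
    reaction("EX_ace", c(ace = 1), "acetate exchange", reversible = TRUE,
             kind = "EXCHANGE"),
    reaction("EX_o2", c(o2 = 1), "oxygen exchange", reversible = TRUE,
             kind = "EXCHANGE"),
    reaction("EX_co2", c(co2 = -1), "CO2 outflow", reversible = FALSE,
             kind = "EXCHANGE"),
    reaction("ACT", .atp_hydrolysis(c(ace = -1, acu = 1), cact),
             "acetate activation", kind = "INTERNAL",
             gene_logic = "NPT001A",
             evidence = evidence("SPECIFIC"), category = "central metabolism"),
    reaction("OX",
             {
               s <- c(acu = -1, o2 = -q, co2 = n)
               s["h2o"] <- h / 2
               .atp_hydrolysis(s, -y)   # negative hydrolysis = ATP synthesis
             },
             "lumped acetyl oxidation + respiration", kind = "INTERNAL",
             gene_logic = "NPT002A AND NPT003A",
             evidence = evidence("SPECIFIC", literature = TRUE),
             category = "central metabolism"))
  if (spec$include_atp_sink) {
    rxns <- c(rxns, list(
      reaction("SINK", .atp_hydrolysis(stats::setNames(numeric(0), character(0)), 1),
               "ATP-hydrolysis sink (toy-only surplus-energy outlet)",
               kind = "INTERNAL", category = "energy dissipation")))
  }
  builder <- function(maintenance) {
    stopifnot(maintenance >= 0)
    reaction("BIO",
             .atp_hydrolysis(c(acu = -spec$biomass_acetyl, biomass = 1),
                             spec$biomass_atp + maintenance),
             "toy growth reaction", kind = "GROWTH")
  }
  rxns <- c(rxns, list(builder(0)))
  net <- metabolic_network(mets, rxns)
  attr(net, "exchanges") <- exchange_spec(
    ubiquitous = "h2o", secretion_only = c("co2", "biomass"))
  attr(net, "growth_builder") <- builder
  attr(net, "acetate_id") <- "ace"
  attr(net, "o2_id") <- "o2"
  net
}

#' Synthetic per-analyte amino-acid slopes
#'
#' A synthetic measured-slope table (umol per OD*L) for the 16 individually
#' measurable amino acids plus the two analyser pools (`Asp+Asn`,
#' `Glu+Gln`); cysteine and tryptophan are absent (estimated downstream).
#' The relative pattern is a plausible acidic-proteome profile; the scale
#' puts the amino-acid carbon near 80% of the synthetic TOC budget. These
#' are generator ground truths, not measurements.
#'
#' @return Named numeric vector of 18 analyte slopes.
#' @export
synthetic_aa_slopes <- function() {
  f <- synthetic_proteome_freqs()
  pooled <- c(f[setdiff(names(f), c("Asp", "Asn", "Glu", "Gln", "Cys", "Trp"))],
              "Asp+Asn" = unname(f[["Asp"]] + f[["Asn"]]),
              "Glu+Gln" = unname(f[["Glu"]] + f[["Gln"]]))
  round(pooled * 3700, 1)
}

#' Synthetic proteome amino-acid frequencies
#'
#' Relative molar frequencies over the 20 amino acids (one copy per gene
#' convention), synthetic but shaped like an acidic halophilic proteome.
#'
#' @return Named numeric vector (sums to ~1).
#' @export
synthetic_proteome_freqs <- function() {
  c(Ala = 0.110, Arg = 0.055, Asp = 0.062, Asn = 0.022, Cys = 0.009,
    Gln = 0.023, Glu = 0.075, Gly = 0.082, His = 0.021, Ile = 0.048,
    Leu = 0.092, Lys = 0.033, Met = 0.020, Phe = 0.038, Pro = 0.046,
    Ser = 0.060, Thr = 0.056, Trp = 0.012, Tyr = 0.030, Val = 0.082)
}

# carbon (and lumped-synthesis size) of the synthetic components: each
# organic component has formula C_{2k} H_k O_k and is built from k acetyl
# units (k acu -> comp + k/2 red + k h2o, elementally balanced).
.component_k <- function() {
  aa <- stats::setNames(rep(2, 20), paste0("aa_", tolower(names(synthetic_proteome_freqs()))))
  nuc <- stats::setNames(rep(5, 4), c("nuc_a", "nuc_u", "nuc_g", "nuc_c"))
  sug <- stats::setNames(rep(3, 4), c("galnac", "glcnac", "gal", "glc"))
  c(aa, nuc, sug, archaeol = 10)
}

#' Synthetic-reference biomass composition
#'
#' Runs the full composition pipeline on the synthetic ground-truth tables:
#' measured single amino acids, pool splitting (Asp+Asn, Glu+Gln) by
#' proteome frequency, Cys/Trp estimation, reference-scaled minor
#' components, and a residual-mode nucleotide pool allocated by the A+T
#' split so the composition's carbon closes exactly on the TOC budget.
#' Components are named after the synthetic-reference network's metabolites.
#'
#' @param toc_slope mmol C per OD*L (default 18.2).
#' @param split_fraction_AT A+T allocation share (default 0.634).
#' @param aa_slopes Named analyte slopes (default [synthetic_aa_slopes()]).
#' @param aa_ratio Scaling of the reference minor components (default 1).
#' @return A [biomass_composition()] whose total carbon (with the synthetic
#'   component formulas) equals `toc_slope` exactly.
#' @export
synthetic_reference_composition <- function(toc_slope = 18.2,
                                            split_fraction_AT = 0.634,
                                            aa_slopes = synthetic_aa_slopes(),
                                            aa_ratio = 1) {
  freqs <- synthetic_proteome_freqs()
  singles <- aa_slopes[!grepl("\\+", names(aa_slopes))]
  aa <- stats::setNames(as.numeric(singles), names(singles))
  prov <- stats::setNames(rep("MEASURED", length(aa)), names(aa))
  for (pool in list(c("Asp+Asn", "Asp", "Asn"), c("Glu+Gln", "Glu", "Gln"))) {
    shares <- split_combined_pool(aa_slopes[[pool[1]]], freqs[pool[2:3]])
    aa[names(shares)] <- shares
    prov[names(shares)] <- "SPLIT_FROM_POOL"
  }
  est <- estimate_unmeasured_aa(aa, freqs, targets = c("Cys", "Trp"))
  aa[names(est)] <- est
  prov[names(est)] <- "PROTEOME_ESTIMATED"

  minors_all <- scale_reference_components(reference_minor_components(),
                                           aa_ratio = aa_ratio)
  minors <- minors_all[setdiff(names(minors_all), "ATP")]  # free-ATP pool folded
  k <- .component_k()
  comp_names <- c(paste0("aa_", tolower(names(aa))), names(minors))
  coeffs <- c(stats::setNames(as.numeric(aa), paste0("aa_", tolower(names(aa)))),
              stats::setNames(as.numeric(minors),
                              c("galnac", "glcnac", "gal", "glc", "archaeol")))
  prov2 <- c(stats::setNames(unname(prov), paste0("aa_", tolower(names(prov)))),
             stats::setNames(rep("REFERENCE_SCALED", length(minors)),
                             c("galnac", "glcnac", "gal", "glc", "archaeol")))
  carbon_so_far <- sum(coeffs * 2 * k[names(coeffs)])
  pool <- residual_nucleotide_pool(toc_slope, composition_carbon = carbon_so_far,
                                   carbon_per_nucleotide = 10,
                                   mode = "residual")
  alloc <- allocate_nucleotides(pool, split_fraction_AT)
  nuc_ids <- c("AMP+dAMP" = "nuc_a", "UMP+dTMP" = "nuc_u",
               "GMP+dGMP" = "nuc_g", "CMP+dCMP" = "nuc_c")
  coeffs[unname(nuc_ids)] <- as.numeric(alloc[names(nuc_ids)])
  prov2[unname(nuc_ids)] <- "GC_ALLOCATED"
  coeffs[c("na1", "cl1")] <- 2813.4
  prov2[c("na1", "cl1")] <- "FIXED"
  biomass_composition(coeffs, prov2)
}

#' Generate the synthetic reference network
#'
#' A full-scale stand-in for a curated haloarchaeal reconstruction,
#' generated in code (no real reconstruction data is shipped). Its summary
#' statistics are construction parameters chosen to emulate the published
#' reconstruction it stands in for: 683 reactions, 597 metabolites, 654
#' distinct (non-transport) genes, 10 reactions that cannot be balance-
#' checked because a reactant's formula is unknown (7 in cofactor
#' biosynthesis, 3 in amino-acid degradation), and 168 literature-supported
#' reactions.
#'
#' The metabolic core is a lumped acetate machinery whose energetics were
#' calibrated once so the phenotype plane reproduces the published
#' feasibility envelope: complete oxidation of the C2 carrier needs 2 O2
#' (elemental fact, acetate fraction wall at 1/3) and the lumped activation
#' cost of 6/7 ATP per acetate puts the energy wall at fraction
#' 2/(2 + 6/7) = 0.70. Around the core, prunable decorative pathways
#' (isomerase chains and isoenzyme duplicates in self-contained metabolite
#' groups) pad the network to full scale without changing any optimum.
#'
#' Attributes mirror [generate_toy_network()]: `"exchanges"`,
#' `"growth_builder"` (maintenance in umol ATP per delta-OD*ml),
#' `"acetate_id"`, `"o2_id"`, plus `"composition"` (the
#' [synthetic_reference_composition()]) and `"component_map"`.
#'
#' @param n_reactions,n_metabolites,n_genes,n_literature,n_unverifiable
#'   Target summary statistics.
#' @param toc_slope mmol C per OD*L for the composition (default 18.2).
#' @param seed RNG seed for the decorative padding and annotation draws.
#' @return A `metabolic_network`.
#' @export
synthetic_reference_network <- function(n_reactions = 683,
                                        n_metabolites = 597,
                                        n_genes = 654,
                                        n_literature = 168,
                                        n_unverifiable = 10,
                                        toc_slope = 18.2,
                                        seed = 20100625) {
  with_seed(seed, {
    comp <- synthetic_reference_composition(toc_slope = toc_slope)
    k <- .component_k()
    mets <- c(list(
      metabolite("ace", "acetate (carrier form)", "C2H4O2", 0L, compartment = "e"),
      metabolite("acu", "acetyl pool", "C2H4O2", 0L),
      metabolite("o2", "dioxygen", "O2", 0L, compartment = "e"),
      metabolite("co2", "carbon dioxide", "CO2", 0L, compartment = "e"),
      metabolite("red", "reduced electron carrier (H2 equivalent)", "H2", 0L),
      metabolite("na1", "sodium ion", "Na", 1L, compartment = "e"),
      metabolite("cl1", "chloride ion", "Cl", -1L, compartment = "e"),
      metabolite("k1", "potassium ion", "K", 1L, compartment = "e"),
      metabolite("h1", "proton", "H", 1L, compartment = "e"),
      metabolite("so4", "sulfate", "O4S", -2L, compartment = "e"),
      metabolite("biomass", "biomass unit", NA, NA_integer_)),
      .moiety_mets())
    for (comp_id in names(k)) {
      kk <- k[[comp_id]]
      mets[[length(mets) + 1L]] <- metabolite(
        comp_id, paste("biomass component", comp_id),
        formula_counts(c(C = 2 * kk, H = kk, O = kk)), charge = 0L)
    }
    core_rxns <- list(
      reaction("EX_ace", c(ace = 1), "acetate exchange", reversible = TRUE,
               kind = "EXCHANGE", category = "transport"),
      reaction("EX_o2", c(o2 = 1), "oxygen exchange", reversible = TRUE,
               kind = "EXCHANGE", category = "transport"),
      reaction("EX_co2", c(co2 = -1), "CO2 outflow", kind = "EXCHANGE",
               category = "transport"),
      reaction("EX_h2o", c(h2o = 1), "water exchange", reversible = TRUE,
               kind = "EXCHANGE", category = "transport"),
      reaction("EX_na", c(na1 = 1), "sodium exchange", reversible = TRUE,
               kind = "EXCHANGE", category = "transport"),
      reaction("EX_cl", c(cl1 = 1), "chloride exchange", reversible = TRUE,
               kind = "EXCHANGE", category = "transport"),
      reaction("EX_k", c(k1 = 1), "potassium exchange", reversible = TRUE,
               kind = "EXCHANGE", category = "transport"),
      reaction("EX_h", c(h1 = 1), "proton exchange", reversible = TRUE,
               kind = "EXCHANGE", category = "transport"),
      reaction("EX_so4", c(so4 = 1), "sulfate exchange", reversible = TRUE,
               kind = "EXCHANGE", category = "transport"),
      reaction("ACT", .atp_hydrolysis(c(ace = -1, acu = 1), 6 / 7),
               "lumped acetate uptake + activation", kind = "INTERNAL",
               evidence = evidence("SPECIFIC", literature = TRUE),
               category = "central metabolism"),
      reaction("OX", c(acu = -1, h2o = -2, co2 = 2, red = 4),
               "lumped acetyl oxidation (citric acid cycle)",
               kind = "INTERNAL",
               gene_logic = "NP4044A AND NP4046A",
               evidence = evidence("SPECIFIC", literature = TRUE),
               category = "central metabolism"),
      reaction("RESP", .atp_hydrolysis(c(red = -1, o2 = -0.5, h2o = 1), -1),
               "respiratory chain (P:O = 1 per O atom)", kind = "INTERNAL",
               evidence = evidence("SPECIFIC", literature = TRUE),
               category = "energy metabolism"),
      reaction("NGAM",
               .atp_hydrolysis(stats::setNames(numeric(0), character(0)), 1),
               "non-growth-associated ATP hydrolysis", kind = "INTERNAL",
               category = "energy metabolism"))
    for (comp_id in names(k)) {
      kk <- k[[comp_id]]
      core_rxns[[length(core_rxns) + 1L]] <- reaction(
        paste0("SYN_", comp_id),
        stats::setNames(c(-kk, 1, kk / 2, kk), c("acu", comp_id, "red", "h2o")),
        paste("lumped biosynthesis of", comp_id), kind = "INTERNAL",
        evidence = evidence("SPECIFIC"), category = "biosynthesis")
    }
    component_map <- stats::setNames(names(comp$coefficients),
                                     names(comp$coefficients))
    builder <- function(maintenance) {
      assemble_growth_reaction(
        growth_reaction_spec(comp, maintenance_atp = maintenance),
        net_env$net, component_map, id = "GROWTH")
    }
    # placeholder growth (maintenance 0) included in the network proper
    n_core <- length(core_rxns) + 1L          # + GROWTH
    n_core_mets <- length(mets)

    # ---- decorative padding -------------------------------------------
    n_dec_mets <- n_metabolites - n_core_mets - n_unverifiable
    n_dec_rxns <- n_reactions - n_core
    n_groups <- 40L
    stopifnot(n_dec_mets > n_groups, n_dec_rxns > n_dec_mets - n_groups)
    categories <- c("amino acid metabolism", "cofactor biosynthesis",
                    "nucleotide metabolism", "lipid metabolism",
                    "sugar metabolism", "amino acid degradation",
                    "transport", "miscellaneous")
    grp_of <- sort(rep_len(seq_len(n_groups), n_dec_mets))
    grp_formula <- lapply(seq_len(n_groups), function(g) {
      cc <- sample(3:18, 1); hh <- 2 * sample(2:12, 1); oo <- sample(1:8, 1)
      formula_counts(c(C = cc, H = hh, O = oo))
    })
    grp_category <- sample(categories[categories != "transport"],
                           n_groups, replace = TRUE)
    dec_met_ids <- sprintf("dm%04d", seq_len(n_dec_mets))
    for (i in seq_len(n_dec_mets)) {
      mets[[length(mets) + 1L]] <- metabolite(
        dec_met_ids[i], paste("pathway intermediate", dec_met_ids[i]),
        grp_formula[[grp_of[i]]], charge = 0L)
    }
    unk_ids <- sprintf("unk%02d", seq_len(n_unverifiable))
    for (u in unk_ids) {
      mets[[length(mets) + 1L]] <- metabolite(
        u, paste("uncharacterized reactant", u), NA, NA_integer_)
    }
    dec_rxns <- list()
    chain_edges <- list()
    for (g in seq_len(n_groups)) {
      members <- dec_met_ids[grp_of == g]
      if (length(members) < 2L) next
      for (i in seq_len(length(members) - 1L)) {
        chain_edges[[length(chain_edges) + 1L]] <-
          list(from = members[i], to = members[i + 1L], group = g)
      }
    }
    n_chain <- length(chain_edges)
    n_extra <- n_dec_rxns - n_chain - n_unverifiable
    stopifnot(n_extra >= 0)
    rev_flag <- stats::runif(n_chain) < 0.35
    # isoenzyme duplicates only of irreversible edges, same direction,
    # so no decorative cycle can ever circulate flux
    dup_pool <- which(!rev_flag)
    dup_sel <- sample(dup_pool, n_extra, replace = FALSE)
    mk_dec <- function(id, from, to, reversible, group, extra_stoich = NULL) {
      s <- stats::setNames(c(-1, 1), c(from, to))
      use_atp <- !reversible && stats::runif(1) < 0.25
      if (use_atp) s <- .atp_hydrolysis(s, 1)
      if (!is.null(extra_stoich)) s <- c(s, extra_stoich)
      reaction(id, s, paste("conversion", from, "to", to),
               reversible = reversible, kind = "INTERNAL",
               category = grp_category[group])
    }
    for (i in seq_len(n_chain)) {
      e <- chain_edges[[i]]
      dec_rxns[[length(dec_rxns) + 1L]] <- mk_dec(
        sprintf("R%04d", i), e$from, e$to, rev_flag[i], e$group)
    }
    for (j in seq_along(dup_sel)) {
      e <- chain_edges[[dup_sel[j]]]
      dec_rxns[[length(dec_rxns) + 1L]] <- mk_dec(
        sprintf("R%04d", n_chain + j), e$from, e$to, FALSE, e$group)
    }
    # the n_unverifiable reactions involve an unknown reactant: the audit
    # can only mark them UNVERIFIABLE (7 cofactor, 3 degradation)
    unk_cat <- c(rep("cofactor biosynthesis", 7),
                 rep("amino acid degradation", 3))
    unk_cat <- rep_len(unk_cat, n_unverifiable)
    host_edges <- sample(seq_len(n_chain), n_unverifiable)
    for (j in seq_len(n_unverifiable)) {
      e <- chain_edges[[host_edges[j]]]
      r <- mk_dec(sprintf("CFX%02d", j), e$from, e$to, FALSE, e$group,
                  extra_stoich = stats::setNames(1, unk_ids[j]))
      r$category <- unk_cat[j]
      dec_rxns[[length(dec_rxns) + 1L]] <- r
    }

    # ---- evidence + gene annotation -----------------------------------
    all_rxns <- c(core_rxns, dec_rxns)
    n_all <- length(all_rxns) + 1L        # + GROWTH
    idx_dec <- seq(length(core_rxns) + 1L, length(all_rxns))
    # genetic classes: decorative reactions split SPECIFIC / GENERAL_ONLY /
    # NONE; transporters (exchanges) are GENERAL_ONLY with a separate,
    # uncounted transporter gene pool
    core_gene_ids <- c("NP4044A", "NP4046A")
    pool <- setdiff(sprintf("NP%04dA", seq(2, 2 + 2 * (n_genes + 50), by = 2)),
                    core_gene_ids)
    pool <- c(core_gene_ids, pool[seq_len(n_genes - length(core_gene_ids))])
    stopifnot(length(pool) == n_genes, !anyDuplicated(pool))
    transporter_pool <- sprintf("NPT%03dA", seq_len(30))
    cursor <- 3L   # NP4044A/NP4046A already on OX
    shuffled <- sample(idx_dec)
    class_draw <- sample(c("SPECIFIC", "GENERAL_ONLY", "NONE"),
                         length(idx_dec), replace = TRUE,
                         prob = c(0.60, 0.20, 0.20))
    for (pos in seq_along(shuffled)) {
      i <- shuffled[pos]
      cls <- class_draw[pos]
      r <- all_rxns[[i]]
      if (cls == "SPECIFIC" && cursor <= n_genes) {
        ng <- min(sample(1:3, 1, prob = c(0.6, 0.3, 0.1)), n_genes - cursor + 1L)
        gs <- pool[cursor:(cursor + ng - 1L)]
        cursor <- cursor + ng
        r$gene_logic <- parse_gene_logic(paste(
          gs, collapse = if (ng > 1 && stats::runif(1) < 0.5) " AND " else " OR "))
        r$evidence <- evidence("SPECIFIC")
      } else if (cls == "SPECIFIC") {
        r$gene_logic <- gl_leaf(sample(pool, 1))
        r$evidence <- evidence("SPECIFIC")
      } else if (cls == "GENERAL_ONLY") {
        r$gene_logic <- gl_leaf(sample(transporter_pool, 1))
        r$evidence <- evidence("GENERAL_ONLY")
      } else {
        r$evidence <- evidence("NONE", gap_fill = stats::runif(1) < 0.4)
      }
      all_rxns[[i]] <- r
    }
    # sweep any unassigned genes onto extra SPECIFIC reactions (OR'd in)
    while (cursor <= n_genes) {
      i <- sample(idx_dec, 1)
      r <- all_rxns[[i]]
      if (r$evidence$genetic_class != "SPECIFIC") next
      r$gene_logic <- gl_node("OR", list(r$gene_logic, gl_leaf(pool[cursor])))
      cursor <- cursor + 1L
      all_rxns[[i]] <- r
    }
    # exchanges: GENERAL_ONLY transporters
    for (i in seq_along(all_rxns)) {
      if (all_rxns[[i]]$kind == "EXCHANGE") {
        all_rxns[[i]]$evidence <- evidence("GENERAL_ONLY")
        all_rxns[[i]]$gene_logic <- gl_leaf(sample(transporter_pool, 1))
      }
    }
    # literature flags: exactly n_literature reactions, never on gap fills
    lit_now <- vapply(all_rxns, function(r) r$evidence$literature, logical(1))
    eligible <- which(!lit_now &
                        !vapply(all_rxns, function(r) r$evidence$gap_fill,
                                logical(1)))
    need <- n_literature - sum(lit_now)
    stopifnot(need >= 0, need <= length(eligible))
    for (i in sample(eligible, need)) {
      all_rxns[[i]]$evidence$literature <- TRUE
    }

    net_env <- new.env(parent = emptyenv())
    net_env$net <- metabolic_network(mets, all_rxns, validate = FALSE)
    growth0 <- builder(0)
    all_rxns[[length(all_rxns) + 1L]] <- growth0
    net <- metabolic_network(mets, all_rxns)
    net_env$net <- net
    stopifnot(length(net$reactions) == n_reactions,
              length(net$metabolites) == n_metabolites)
    attr(net, "exchanges") <- exchange_spec(
      ubiquitous = c("co2", "h2o", "na1", "cl1", "k1", "h1"),
      secretion_only = "biomass",
      abundant = "so4")
    attr(net, "growth_builder") <- builder
    attr(net, "acetate_id") <- "ace"
    attr(net, "o2_id") <- "o2"
    attr(net, "composition") <- comp
    attr(net, "component_map") <- component_map
    net
  })
}

#' Experiment parameters for the growth-series simulator
#'
#' @param toc_slope mmol C per OD*L (default 18.2).
#' @param incorporation_fraction Fraction of consumed carbon incorporated
#'   (default 0.35).
#' @param respiration_fraction Fraction respired as CO2 (default 0.63).
#' @param rer Respiratory exchange ratio (default 1).
#' @param od0 Initial optical density.
#' @param growth_rate Exponential OD growth rate (per hour).
#' @param sample_times Sampling times (hours).
#' @param volume_ml Culture volume.
#' @param acetate0_mM Initial acetate concentration.
#' @param noise_sd Named vector of Gaussian noise SDs for channels `od`,
#'   `acetate` (mM) and `o2` (umol, applied to increments, truncated at 0
#'   to keep the cumulative channel monotone).
#' @param seed RNG seed (`NULL` = use current RNG state).
#' @return An `experiment_params` list.
#' @export
experiment_params <- function(toc_slope = 18.2,
                              incorporation_fraction = 0.35,
                              respiration_fraction = 0.63,
                              rer = 1.0, od0 = 0.10, growth_rate = 0.023,
                              sample_times = seq(0, 100, by = 10),
                              volume_ml = 35, acetate0_mM = 40,
                              noise_sd = c(od = 0, acetate = 0, o2 = 0),
                              seed = NULL) {
  stopifnot(incorporation_fraction >= 0, respiration_fraction >= 0,
            incorporation_fraction + respiration_fraction <= 1,
            rer > 0, od0 > 0, growth_rate > 0, volume_ml > 0,
            acetate0_mM > 0, all(noise_sd >= 0))
  structure(list(toc_slope = toc_slope,
                 incorporation_fraction = incorporation_fraction,
                 respiration_fraction = respiration_fraction,
                 rer = rer, od0 = od0, growth_rate = growth_rate,
                 sample_times = sample_times, volume_ml = volume_ml,
                 acetate0_mM = acetate0_mM, noise_sd = noise_sd, seed = seed),
            class = "experiment_params")
}

#' Simulate a growth experiment with known carbon fates
#'
#' Builds an OD curve, then sets acetate disappearance and cumulative O2 so
#' that, per interval, incorporated carbon (delta-OD x volume x TOC slope)
#' is exactly `incorporation_fraction` of carbon uptake and respired carbon
#' is `respiration_fraction` of it at the given RER. With zero noise,
#' [carbon_fate_accounting()] recovers the fractions exactly; Gaussian
#' noise is added per channel afterwards (O2 noise on increments, truncated
#' at zero so the cumulative series stays monotone).
#'
#' @param params An [experiment_params()].
#' @return A [growth_experiment()].
#' @export
simulate_growth_experiment <- function(params = experiment_params()) {
  stopifnot(inherits(params, "experiment_params"))
  with_seed(params$seed, {
    t <- params$sample_times
    n <- length(t)
    stopifnot(n >= 2)
    od <- params$od0 * exp(params$growth_rate * t)
    vol_l <- params$volume_ml / 1000
    inc_C <- incorporated_carbon(diff(od), vol_l, params$toc_slope)
    uptake_C <- inc_C / params$incorporation_fraction
    resp_C <- params$respiration_fraction * uptake_C
    d_acetate_umol <- uptake_C / 2
    acetate <- params$acetate0_mM - cumsum(c(0, d_acetate_umol)) / params$volume_ml
    if (any(acetate < 0)) {
      stop("simulated acetate went negative; raise acetate0_mM or shorten the run")
    }
    o2_inc <- resp_C / params$rer
    sd <- params$noise_sd
    gn <- function(name) if (name %in% names(sd)) sd[[name]] else 0
    od_n <- od + stats::rnorm(n, 0, gn("od"))
    od_n <- pmax(od_n, 1e-6)
    acetate_n <- pmax(acetate + stats::rnorm(n, 0, gn("acetate")), 0)
    o2_inc_n <- pmax(o2_inc + stats::rnorm(n - 1, 0, gn("o2")), 0)
    growth_experiment(t, od_n, acetate_n, cumsum(c(0, o2_inc_n)),
                      params$volume_ml)
  })
}

#' Simulate composition-vs-OD samples
#'
#' `value = slope x od + Gaussian noise`, truncated at zero.
#'
#' @param slopes Named true slopes (analyte -> amount per OD*L).
#' @param ods Optical densities of the samples.
#' @param sd Gaussian noise SD (single value, all analytes).
#' @param seed RNG seed (`NULL` = current state).
#' @return List of [composition_sample()]s.
#' @export
simulate_composition_samples <- function(slopes, ods, sd = 0, seed = NULL) {
  stopifnot(is.numeric(slopes), !is.null(names(slopes)), all(ods > 0), sd >= 0)
  with_seed(seed, {
    lapply(ods, function(od) {
      vals <- pmax(slopes * od + stats::rnorm(length(slopes), 0, sd), 0)
      composition_sample(od, vals)
    })
  })
}
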