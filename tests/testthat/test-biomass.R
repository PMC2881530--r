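test_that("origin-constrained fits recover exact and degenerate slopes", {
  f <- fit_through_origin(c(1, 2), c(18.2, 36.4))
  expect_equal(f$slope, 18.2)
  expect_equal(f$stderr, 0, tolerance = 1e-10)
  expect_equal(fit_through_origin(c(1, 2), c(0, 0))$slope, 0)
  expect_error(fit_through_origin(c(0, 0), c(1, 2)), "degenerate")
  fi <- fit_through_origin(c(1, 2, 3), c(2.5, 4.5, 6.5), intercept = TRUE)
  expect_equal(fi$slope, 2, tolerance = 1e-9)
  expect_equal(fi$intercept, 0.5, tolerance = 1e-9)
})

test_that("noisy slope recovery lands within three standard errors", {
  ods <- seq(0.1, 1.2, length.out = 20)
  samples <- simulate_composition_samples(c(TOC = 18.2), ods, sd = 1,
                                          seed = 11)
  f <- fit_amino_acid_slopes(samples)$TOC
  expect_lte(abs(f$slope - 18.2), 3 * f$stderr)
})

test_that("multi-analyte panels are fitted per analyte with pools as keys", {
  slopes <- c(Ala = 120, Gly = 80, "Asp+Asn" = 60)
  samples <- simulate_composition_samples(slopes, seq(0.2, 1, by = 0.2))
  fits <- fit_amino_acid_slopes(samples)
  expect_setequal(names(fits), names(slopes))
  for (a in names(slopes)) expect_equal(fits[[a]]$slope, slopes[[a]])
  bad <- c(samples, list(composition_sample(1.2, c(Ala = 1, Gly = 1, Trp = 1))))
  expect_error(fit_amino_acid_slopes(bad), "inconsistent analyte")
})

test_that("pool splitting is proportional and conserves the total", {
  expect_equal(split_combined_pool(100, c(Asp = 1, Asn = 1)),
               c(Asp = 50, Asn = 50))
  expect_equal(split_combined_pool(100, c(Asp = 3, Asn = 1)),
               c(Asp = 75, Asn = 25))
  expect_error(split_combined_pool(10, c(a = 0, b = 0)), "zero")
  set.seed(5)
  for (i in 1:20) {
    fr <- stats::runif(sample(2:5, 1))
    names(fr) <- paste0("m", seq_along(fr))
    tot <- stats::runif(1, 1, 500)
    expect_equal(sum(split_combined_pool(tot, fr)), tot, tolerance = 1e-12)
  }
})

test_that("unmeasured amino acids scale with the measured total", {
  est <- estimate_unmeasured_aa(c(Ala = 100),
                                c(Ala = 0.1, Cys = 0.01), targets = "Cys")
  expect_equal(unname(est), 10)
  expect_equal(unname(estimate_unmeasured_aa(
    c(Ala = 100), c(Ala = 0.1, Cys = 0), targets = "Cys")), 0)
  expect_error(estimate_unmeasured_aa(c(Cys = 1), c(Cys = 0.1),
                                      targets = "Cys"), "disjoint")
  set.seed(6)
  freqs <- c(Ala = 0.1, Gly = 0.08, Cys = 0.01, Trp = 0.012)
  for (k in c(0.5, 1, 2, 7)) {
    base <- c(Ala = 100, Gly = 60)
    e1 <- estimate_unmeasured_aa(base, freqs)
    e2 <- estimate_unmeasured_aa(base * k, freqs)
    expect_equal(e2, e1 * k, tolerance = 1e-12)  # linear in the measured total
  }
})

test_that("nucleotide allocation follows the A+T split and conserves the pool", {
  even <- allocate_nucleotides(100, 0.5)
  expect_true(all(even == 25))
  alloc <- allocate_nucleotides(257.4, 0.634)
  # the A pair : G pair ratio must be 63.4 : 36.6, the published 81.6 : 47.1
  expect_equal(alloc[["AMP+dAMP"]] / alloc[["GMP+dGMP"]], 81.6 / 47.1,
               tolerance = 2e-3)
  expect_equal(alloc[["AMP+dAMP"]], alloc[["UMP+dTMP"]])
  set.seed(8)
  for (s in stats::runif(10)) {
    a <- allocate_nucleotides(123.4, s)
    expect_equal(sum(a), 123.4, tolerance = 1e-12)
  }
  expect_error(allocate_nucleotides(-1), "non-negative")
})

test_that("nucleotide pool sizing supports fraction and residual modes", {
  # 20% of 18.2 mmol C at 9.66 C per nucleotide
  pool <- residual_nucleotide_pool(18.2, mode = "fraction", fraction = 0.2)
  expect_equal(pool, 18.2 * 1000 * 0.2 / 9.66, tolerance = 1e-12)
  expect_equal(residual_nucleotide_pool(18.2, mode = "fraction", fraction = 0),
               0)
  expect_equal(residual_nucleotide_pool(18.2, composition_carbon = 18200,
                                        mode = "residual"), 0)
  expect_error(residual_nucleotide_pool(18.2, composition_carbon = 20000,
                                        mode = "residual"), "negative")
})

test_that("reference components scale multiplicatively and ship defaults", {
  ref <- reference_minor_components()
  expect_equal(ref[["Archaeol"]], 20.0)
  expect_equal(ref[["GalNAc"]], 2.2)
  expect_equal(ref[["Gal"]], 9.6)
  expect_equal(ref[["ATP"]], 2.0)
  expect_equal(scale_reference_components(ref, 1), ref)
  expect_equal(scale_reference_components(ref, 2), ref * 2)
})

test_that("growth reactions convert maintenance units and demand mappings", {
  net <- generate_toy_network()
  comp <- biomass_composition(c(X = 1), c(X = "MEASURED"))
  rx <- assemble_growth_reaction(growth_reaction_spec(comp, 0), net,
                                 component_map = c(X = "acu"))
  expect_equal(rx$kind, "GROWTH")
  expect_false(rx$reversible)
  expect_equal(rx$stoichiometry[["acu"]], -1)
  expect_equal(rx$stoichiometry[["biomass"]], 1)
  expect_false("atp" %in% names(rx$stoichiometry))
  # 10 umol ATP per delta-OD*ml -> 10,000 umol per OD*L
  rx10 <- assemble_growth_reaction(growth_reaction_spec(comp, 10), net,
                                   component_map = c(X = "acu"))
  expect_equal(rx10$stoichiometry[["atp"]], -10000)
  expect_equal(rx10$stoichiometry[["adp"]], 10000)
  expect_error(assemble_growth_reaction(growth_reaction_spec(comp, 0), net,
                                        component_map = c(Y = "acu")),
               "no metabolite mapping")
})

test_that("the synthetic composition closes its carbon on the TOC budget", {
  comp <- synthetic_reference_composition()
  k <- haloflux:::.component_k()
  carbon <- sum(comp$coefficients[names(k)] * 2 * k)
  expect_equal(carbon, 18.2 * 1000, tolerance = 1e-9)
  # sodium and chloride carried at the fixed brine coefficients
  expect_equal(comp$coefficients[["na1"]], 2813.4)
  expect_equal(comp$coefficients[["cl1"]], 2813.4)
  expect_setequal(unique(comp$provenance),
                  c("MEASURED", "SPLIT_FROM_POOL", "PROTEOME_ESTIMATED",
                    "GC_ALLOCATED", "REFERENCE_SCALED", "FIXED"))
  p <- withr::local_tempfile(fileext = ".tsv")
  write_composition_table(comp, p)
  tab <- utils::read.delim(p)
  expect_equal(nrow(tab), length(comp$coefficients))
})
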