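test_that("generated toy networks validate and audit clean", {
  net <- generate_toy_network()
  expect_length(validate_network(net), 0)
  aud <- network_balance_audit(net)
  expect_equal(unname(aud$counts["UNBALANCED"]), 0)
  expect_equal(unname(aud$counts["UNVERIFIABLE"]), 0)
  # non-default spec still balances (formulas are derived from the spec)
  net2 <- generate_toy_network(toy_network_spec(o2_per_acetyl = 3,
                                                co2_per_acetyl = 2))
  aud2 <- network_balance_audit(net2)
  expect_equal(unname(aud2$counts["UNBALANCED"]), 0)
})

test_that("toy spec rejects non-positive parameters", {
  expect_error(toy_network_spec(activation_atp_cost = 0))
  expect_error(toy_network_spec(o2_per_acetyl = -1))
})

test_that("growth simulators are bit-reproducible under a fixed seed", {
  p <- experiment_params(noise_sd = c(od = 0.01, acetate = 0.2, o2 = 10),
                         seed = 123)
  e1 <- simulate_growth_experiment(p)
  e2 <- simulate_growth_experiment(p)
  expect_identical(e1, e2)
  f1 <- withr::local_tempfile(fileext = ".csv")
  f2 <- withr::local_tempfile(fileext = ".csv")
  write_growth_series(e1, f1); write_growth_series(e2, f2)
  expect_identical(readLines(f1), readLines(f2))   # byte-identical
  s1 <- simulate_composition_samples(c(A = 2), c(0.5, 1), sd = 0.1, seed = 4)
  s2 <- simulate_composition_samples(c(A = 2), c(0.5, 1), sd = 0.1, seed = 4)
  expect_identical(s1, s2)
})

test_that("simulators respect their parameter constraints", {
  expect_error(experiment_params(incorporation_fraction = 0.7,
                                 respiration_fraction = 0.7), "<= 1")
  expect_error(experiment_params(rer = 0))
  # noiseless composition samples reproduce slopes exactly
  s <- simulate_composition_samples(c(A = 3.5, B = 1.2), c(0.2, 0.6, 1.1))
  fits <- fit_amino_acid_slopes(s)
  expect_equal(fits$A$slope, 3.5)
  expect_equal(fits$B$slope, 1.2)
})

test_that("the synthetic reference network reproduces its target statistics", {
  net <- synthetic_reference_network()
  expect_equal(length(net$reactions), 683)
  expect_equal(length(net$metabolites), 597)
  expect_equal(length(network_genes(net)), 654)
  expect_length(validate_network(net), 0)
  aud <- network_balance_audit(net)
  expect_equal(unname(aud$counts["UNBALANCED"]), 0)
  expect_equal(unname(aud$counts["UNVERIFIABLE"]), 10)
  expect_length(aud$offenders, 10)
  # the ten all involve an unknown reactant, split 7 cofactor / 3 degradation
  cats <- vapply(aud$offenders, function(id) net$reactions[[id]]$category,
                 character(1))
  expect_equal(sum(cats == "cofactor biosynthesis"), 7)
  expect_equal(sum(cats == "amino acid degradation"), 3)
  ev <- evidence_summary(net)
  expect_gte(ev$literature, 168)
  expect_equal(sum(ev$genetic_class), 683)
})

test_that("reference-network generation is deterministic per seed", {
  n1 <- synthetic_reference_network(seed = 7)
  n2 <- synthetic_reference_network(seed = 7)
  expect_identical(names(n1$reactions), names(n2$reactions))
  expect_identical(
    lapply(n1$reactions, function(r) r$stoichiometry),
    lapply(n2$reactions, function(r) r$stoichiometry))
  expect_identical(
    vapply(n1$reactions, function(r) render_gene_logic(r$gene_logic),
           character(1)),
    vapply(n2$reactions, function(r) render_gene_logic(r$gene_logic),
           character(1)))
})

test_that("the oracle refuses oversized problems instead of guessing", {
  net <- synthetic_reference_network()
  ex <- haloflux:::merge_parameterized(attr(net, "exchanges"),
                                       c(ace = 10, o2 = 10))
  pr <- build_flux_problem(haloflux:::drop_growth_reactions(net), ex,
                           objective = "OX")
  expect_error(brute_force_lp(pr, max_dims = 8), "refused")
})
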