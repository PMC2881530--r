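test_that("validate_network reports violations as data", {
  expect_length(validate_network(metabolic_network()), 0)
  net <- metabolic_network(
    list(metabolite("A", formula = "C", charge = 0L)),
    list(reaction("R1", c(A = -1, X = 1))),
    validate = FALSE)
  v <- validate_network(net)
  expect_length(v, 1)
  expect_equal(v[[1]]$type, "dangling_metabolite")
  bad_ex <- metabolic_network(
    list(metabolite("A"), metabolite("B")),
    list(reaction("EX", c(A = 1, B = -1), kind = "EXCHANGE")),
    validate = FALSE)
  expect_equal(validate_network(bad_ex)[[1]]$type, "malformed_exchange")
})

test_that("the AC-CORE toy satisfies every structural invariant", {
  expect_length(validate_network(generate_toy_network()), 0)
})

test_that("balance verdicts distinguish balanced, unbalanced and unverifiable", {
  net <- tiny_balanced_network()
  rep1 <- check_reaction_balance(net, "R1")
  expect_equal(rep1$verdict, "BALANCED")
  expect_equal(rep1$charge_delta, 0)

  net2 <- metabolic_network(
    list(metabolite("A", formula = "CH4", charge = 0L),
         metabolite("B", formula = "CH3", charge = -1L)),
    list(reaction("R1", c(A = -1, B = 1))))
  rep2 <- check_reaction_balance(net2, "R1")
  expect_equal(rep2$verdict, "UNBALANCED")
  expect_equal(rep2$element_deltas[["H"]], -1)
  expect_equal(rep2$charge_delta, -1)

  net3 <- metabolic_network(
    list(metabolite("A", formula = "CH4", charge = 0L),
         metabolite("U", formula = NA)),
    list(reaction("R1", c(A = -1, U = 1))))
  rep3 <- check_reaction_balance(net3, "R1")
  expect_equal(rep3$verdict, "UNVERIFIABLE")
  expect_equal(rep3$unknown_participants, "U")
  # exchange and growth reactions are exempt
  expect_true(check_reaction_balance(net, "EX_A")$skipped)
})

test_that("balance verdict is invariant under reversal and positive rescaling", {
  base <- tiny_balanced_network()
  flip <- metabolic_network(base$metabolites,
                            list(reaction("R1", -base$reactions$R1$stoichiometry),
                                 base$reactions$EX_A))
  scaled <- metabolic_network(base$metabolites,
                              list(reaction("R1", 2.5 * base$reactions$R1$stoichiometry),
                                   base$reactions$EX_A))
  for (net in list(base, flip, scaled)) {
    expect_equal(check_reaction_balance(net, "R1")$verdict, "BALANCED")
  }
  # same invariance for an unbalanced reaction: verdict stays UNBALANCED
  ub <- metabolic_network(
    list(metabolite("A", formula = "CH4", charge = 0L),
         metabolite("B", formula = "CH3", charge = -1L)),
    list(reaction("R1", c(A = -1, B = 1))))
  ubf <- metabolic_network(ub$metabolites,
                           list(reaction("R1", c(A = 1, B = -1))))
  expect_equal(check_reaction_balance(ubf, "R1")$verdict, "UNBALANCED")
  expect_equal(check_reaction_balance(ubf, "R1")$element_deltas[["H"]], 1)
})

test_that("element deltas are linear over reaction sums", {
  net <- metabolic_network(
    list(metabolite("A", formula = "C2H4O2", charge = 0L),
         metabolite("B", formula = "CO2", charge = 0L),
         metabolite("C", formula = "H2O", charge = 0L)),
    list(reaction("R1", c(A = -1, B = 2)),           # drops H4, O0 -> delta
         reaction("R2", c(B = -2, C = 2)),
         reaction("R12", c(A = -1, C = 2))))
  d1 <- check_reaction_balance(net, "R1")$element_deltas
  d2 <- check_reaction_balance(net, "R2")$element_deltas
  d12 <- check_reaction_balance(net, "R12")$element_deltas
  combined <- formula_add(d1, d2)
  combined <- combined[combined != 0]
  expect_equal(combined[order(names(combined))],
               d12[order(names(d12))])
})

test_that("balance audit counts partition the internal reactions", {
  net <- tiny_balanced_network()
  aud <- network_balance_audit(net)
  expect_equal(sum(aud$counts), 1)  # one INTERNAL reaction
  expect_equal(unname(aud$counts["BALANCED"]), 1)
  expect_length(aud$offenders, 0)
  toy_aud <- network_balance_audit(generate_toy_network())
  expect_equal(unname(toy_aud$counts["UNBALANCED"]), 0)
  expect_equal(unname(toy_aud$counts["UNVERIFIABLE"]), 0)
})

test_that("evidence summary tallies classes, literature and gap fills", {
  expect_equal(evidence_summary(metabolic_network())$n_reactions, 0L)
  net <- metabolic_network(
    list(metabolite("A", formula = "C", charge = 0L)),
    list(reaction("R1", c(A = 1), evidence = evidence("SPECIFIC"),
                  category = "x"),
         reaction("R2", c(A = -1), evidence = evidence("SPECIFIC",
                                                       literature = TRUE),
                  category = "x"),
         reaction("R3", c(A = -1), evidence = evidence("NONE", gap_fill = TRUE),
                  category = "y")))
  ev <- evidence_summary(net)
  expect_equal(unname(ev$genetic_class), c(2, 0, 1))
  expect_equal(ev$literature, 1)
  expect_equal(ev$gap_fill, 1)
  expect_equal(sum(ev$genetic_class), ev$n_reactions)
})

test_that("evidence invariants are enforced", {
  expect_error(evidence("SPECIFIC", gap_fill = TRUE), "gap_fill")
  expect_error(evidence("NONE", literature = TRUE, gap_fill = TRUE), "gap_fill")
})

test_that("gene counting can include or exclude general-annotation-only genes", {
  net <- metabolic_network(
    list(metabolite("A", formula = "C", charge = 0L)),
    list(reaction("R1", c(A = 1), gene_logic = "g1 AND g2",
                  evidence = evidence("SPECIFIC")),
         reaction("R2", c(A = -1), gene_logic = "t1",
                  evidence = evidence("GENERAL_ONLY"))))
  expect_equal(network_genes(net), c("g1", "g2"))
  expect_equal(network_genes(net, include_general_only = TRUE),
               c("g1", "g2", "t1"))
})
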