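test_that("stoichiometric matrix mirrors reaction definitions", {
  net <- metabolic_network(
    list(metabolite("A", formula = "C", charge = 0L),
         metabolite("B", formula = "C", charge = 0L)),
    list(reaction("R", c(A = -1, B = 1))))
  S <- build_stoichiometric_matrix(net)
  expect_equal(dim(S), c(2L, 1L))
  expect_equal(as.numeric(S[, "R"]), c(-1, 1))

  toy <- generate_toy_network()
  St <- build_stoichiometric_matrix(toy)
  expect_equal(ncol(St), 7L)   # 3 exchanges + ACT + OX + SINK + BIO
  expect_equal(as.numeric(St["acu", "ACT"]), 1)
  expect_equal(as.numeric(St["o2", "OX"]), -2)
})

test_that("elementally weighted column sums vanish for balanced internal reactions", {
  toy <- generate_toy_network()
  S <- as.matrix(build_stoichiometric_matrix(toy))
  for (el in c("C", "H", "O", "P", "N")) {
    w <- vapply(toy$metabolites[rownames(S)], function(m) {
      if (is_unknown_formula(m$formula)) 0 else element_count(m$formula, el)
    }, numeric(1))
    for (r in names(toy$reactions)) {
      if (toy$reactions[[r]]$kind != "INTERNAL") next
      if ("biomass" %in% names(toy$reactions[[r]]$stoichiometry)) next
      expect_equal(sum(w * S[, r]), 0, tolerance = 1e-9,
                   info = paste(el, r))
    }
  }
})

test_that("exchange classes map to the right bounds and disjointness is enforced", {
  net <- chain_network()
  pr <- build_flux_problem(net, chain_exchanges(2), objective = "BIO")
  # parameterized exchange is an equality at the uptake value
  expect_equal(unname(pr$lb["EX_A"]), 2)
  expect_equal(unname(pr$ub["EX_A"]), 2)
  # synthesized secretion exchange for the biomass unit is one-way out
  bid <- pr$exchange_map$biomass$id
  expect_equal(unname(pr$ub[bid] * sign(pr$exchange_map$biomass$s)), 0)
  expect_error(exchange_spec(ubiquitous = "X", secretion_only = "X"),
               "disjoint")
  expect_error(build_flux_problem(net, exchange_spec(parameterized = c(Z = 1)),
                                  objective = "BIO"),
               "absent from the network")
  expect_error(build_flux_problem(net, chain_exchanges(1), objective = "nope"),
               "not in network")
})

test_that("optimal solutions satisfy steady state and irreversibility", {
  ctx <- toy_with_context()
  res <- max_growth(ctx$net, ctx$builder(0), ctx$exchanges, 5, 5)
  expect_equal(res$status, "OPTIMAL")
  sol <- res$solution; pr <- res$problem
  resid <- as.numeric(pr$S %*% sol$v)
  expect_lt(max(abs(resid)), 1e-7)
  irr <- names(pr$lb)[pr$lb == 0 & is.infinite(pr$ub)]
  expect_true(all(sol$v[irr] >= -1e-9))
})

test_that("scaling the parameterized uptakes scales the optimum", {
  ctx <- toy_with_context()
  base <- max_growth(ctx$net, ctx$builder(0), ctx$exchanges, 5, 5)$growth
  for (k in c(0.1, 1, 10)) {
    g <- max_growth(ctx$net, ctx$builder(0), ctx$exchanges, 5 * k, 5 * k)$growth
    expect_equal(g, base * k, tolerance = 1e-7)
  }
})

test_that("carbon closure balances uptake against CO2 and biomass carbon", {
  ctx <- toy_with_context()
  res <- max_growth(ctx$net, ctx$builder(0), ctx$exchanges, 5, 5)
  ledger <- carbon_closure_check(res$solution, res$problem)
  expect_equal(ledger$uptake_C, 10)           # 5 acetate x 2 C
  expect_equal(ledger$residual_C, 0, tolerance = 1e-7)
  expect_equal(ledger$uptake_C, ledger$co2_C + ledger$incorporated_C,
               tolerance = 1e-7)
  # at (5,5), m=0: growth 2.5 incorporates 5 C, oxidation releases 5 C
  expect_equal(ledger$incorporated_C, 5, tolerance = 1e-7)
  expect_equal(ledger$co2_C, 5, tolerance = 1e-7)
})

test_that("carbon closure holds along the whole feasible segment", {
  ctx <- toy_with_context()
  for (f in c(0.35, 0.40, 0.45, 0.50)) {
    res <- max_growth(ctx$net, ctx$builder(0), ctx$exchanges, 10 * f,
                      10 * (1 - f))
    expect_equal(res$status, "OPTIMAL")
    ledger <- carbon_closure_check(res$solution, res$problem)
    expect_equal(ledger$residual_C, 0, tolerance = 1e-6)
  }
})

test_that("pruning removes dead-end pathways without changing the optimum", {
  ctx <- toy_with_context()
  net <- ctx$net
  # graft a dead-end appendage (reversible, so naive in/out counting misses it)
  net$metabolites$dead1 <- metabolite("dead1", formula = "C2H4O2", charge = 0L)
  net$metabolites$dead2 <- metabolite("dead2", formula = "C2H4O2", charge = 0L)
  net$reactions$D1 <- reaction("D1", c(acu = -1, dead1 = 1), reversible = TRUE)
  net$reactions$D2 <- reaction("D2", c(dead1 = -1, dead2 = 1), reversible = TRUE)
  ex <- haloflux:::merge_parameterized(ctx$exchanges, c(ace = 5, o2 = 5))
  pruned <- prune_blocked_reactions(net, ex)
  expect_false("D1" %in% names(pruned$reactions))
  expect_false("D2" %in% names(pruned$reactions))
  g1 <- max_growth(net, ctx$builder(0), ctx$exchanges, 5, 5)$growth
  g2 <- max_growth(pruned, ctx$builder(0), ctx$exchanges, 5, 5)$growth
  expect_equal(g1, g2, tolerance = 1e-9)
})

test_that("LP text export lists objective, constraints and bounds", {
  net <- chain_network()
  pr <- build_flux_problem(net, chain_exchanges(1), objective = "BIO")
  p <- withr::local_tempfile(fileext = ".lp")
  write_lp_file(pr, p)
  txt <- readLines(p)
  expect_true(any(grepl("Maximize", txt)))
  expect_true(any(grepl("BIO", txt)))
  expect_true(any(grepl("Bounds", txt)))
})
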