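test_that("simplex solves textbook LPs exactly", {
  # max x + y s.t. x + 2y <= 4, 3x + y <= 6 (slacks s1, s2) -> 14/5
  A <- rbind(c(1, 2, 1, 0), c(3, 1, 0, 1))
  r <- solve_lp(c(1, 1, 0, 0), A, c(4, 6))
  expect_equal(r$status, "OPTIMAL")
  expect_equal(r$objective, 14 / 5, tolerance = 1e-9)
  expect_equal(r$x[1:2], c(8 / 5, 6 / 5), tolerance = 1e-9)
})

test_that("simplex handles free variables, fixed variables and infeasibility", {
  # free y: max -|structure|: max y s.t. y + z = 1, z >= 0 -> y = 1
  r <- solve_lp(c(1, 0), rbind(c(1, 1)), 1, lb = c(-Inf, 0))
  expect_equal(r$status, "OPTIMAL")
  expect_equal(r$objective, 1)
  # fixed variable via lb == ub
  r2 <- solve_lp(c(0, 1), rbind(c(1, 1)), 5, lb = c(2, 0), ub = c(2, Inf))
  expect_equal(r2$x, c(2, 3))
  # infeasible: x >= 0, x = -1
  r3 <- solve_lp(1, rbind(1), -1, lb = 0)
  expect_equal(r3$status, "INFEASIBLE")
  # unbounded: max x, no constraints binding
  r4 <- solve_lp(c(1, -1), rbind(c(1, 1)), 1, lb = c(0, 0))
  expect_equal(r4$status, "OPTIMAL")  # x <= 1 via equality
  r5 <- solve_lp(1, matrix(0, 1, 1), 0, lb = 0)
  expect_equal(r5$status, "UNBOUNDED")
})

test_that("finite upper bounds are respected", {
  r <- solve_lp(c(1, 1), rbind(c(1, -1)), 0, lb = c(0, 0), ub = c(3, Inf))
  expect_equal(r$status, "OPTIMAL")
  expect_equal(r$x, c(3, 3))
})

test_that("forced-flux chain yields unit growth and matches the oracle", {
  net <- chain_network()
  pr <- build_flux_problem(net, chain_exchanges(1), objective = "BIO")
  sol <- solve_flux_problem(pr)
  expect_equal(sol$status, "OPTIMAL")
  expect_equal(sol$objective_value, 1)
  bf <- brute_force_lp(pr)
  expect_equal(bf$status, "OPTIMAL")
  expect_equal(bf$objective_value, sol$objective_value, tolerance = 1e-9)
})

test_that("a fixed uptake with no consumer is infeasible", {
  net <- metabolic_network(
    list(metabolite("A", formula = "C", charge = 0L),
         metabolite("B", formula = "C", charge = 0L)),
    list(reaction("EX_A", c(A = 1), kind = "EXCHANGE", reversible = TRUE),
         reaction("AB", c(A = -1, B = 1), kind = "INTERNAL")))
  pr <- build_flux_problem(net, exchange_spec(parameterized = c(A = 1)),
                           objective = "AB")
  expect_equal(solve_flux_problem(pr)$status, "INFEASIBLE")
  expect_equal(brute_force_lp(pr)$status, "INFEASIBLE")
})

test_that("solver and vertex-enumeration oracle agree on random small LPs", {
  set.seed(2024)
  agree <- 0
  for (i in 1:40) {
    n <- sample(3:6, 1); m <- sample(1:3, 1)
    A <- matrix(stats::rnorm(m * n), m, n)
    x0 <- stats::runif(n)          # feasible witness keeps many cases feasible
    b <- as.numeric(A %*% x0)
    cc <- stats::rnorm(n)
    ub <- rep(stats::runif(1, 1, 5), n)  # compact box -> bounded
    r <- solve_lp(cc, A, b, lb = rep(0, n), ub = ub)
    # independent enumeration over the raw polyhedron {A v = b, 0 <= v <= ub}
    bf <- brute_force_oracle_raw(A, b, cc, rep(0, n), ub)
    expect_equal(r$status, bf$status)
    if (r$status == "OPTIMAL") {
      expect_equal(r$objective, bf$objective, tolerance = 1e-6)
      agree <- agree + 1
    }
  }
  expect_gte(agree, 20)  # most random instances should be feasible
})
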