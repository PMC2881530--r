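test_that("the elementary carbon conversions are linear", {
  expect_equal(total_carbon_uptake(0), 0)
  expect_equal(total_carbon_uptake(10), 20)
  set.seed(3)
  x <- stats::runif(5, 0, 50)
  expect_equal(total_carbon_uptake(sum(x)), sum(total_carbon_uptake(x)))
  expect_equal(incorporated_carbon(0, 1), 0)
  expect_equal(incorporated_carbon(1, 1, 18.2), 18200)
  expect_equal(incorporated_carbon(1, 0.5, 18.2),
               incorporated_carbon(1, 1, 18.2) / 2)
  expect_equal(incorporated_carbon(-0.1, 1, 18.2), -1820)  # lysis keeps sign
  expect_equal(respired_carbon(100, 1), 100)
  expect_equal(respired_carbon(100, 0.8), 80)
  expect_equal(respired_carbon(sum(x)), sum(respired_carbon(x)))
})

test_that("a lossless experiment has zero delta everywhere", {
  # constructed so respiration + incorporation = uptake exactly
  times <- 0:5
  od <- seq(0.1, 0.6, by = 0.1)
  vol <- 1000                                   # 1 L
  inc <- incorporated_carbon(diff(od), 1, 18.2) # umol C per interval
  uptake <- inc / 0.4
  resp <- 0.6 * uptake
  acet <- 50 - cumsum(c(0, uptake / 2)) / vol
  o2 <- cumsum(c(0, resp))
  exp0 <- growth_experiment(times, od, acet, o2, vol)
  res <- carbon_fate_accounting(exp0, toc_slope = 18.2, rer = 1)
  expect_equal(max(abs(res$intervals$delta_C)), 0, tolerance = 1e-9)
  expect_equal(unname(res$fractions), c(0.4, 0.6, 0), tolerance = 1e-12)
})

test_that("the ledger identity holds exactly per interval and cumulatively", {
  p <- experiment_params(noise_sd = c(od = 0.01, acetate = 0.2, o2 = 10),
                         seed = 21)
  res <- carbon_fate_accounting(simulate_growth_experiment(p))
  with(res$intervals, {
    expect_equal(delta_C, uptake_C - incorporated_C - respired_C)
    expect_equal(cum_delta_C, cum_uptake_C - cum_incorporated_C - cum_respired_C)
  })
  expect_equal(unname(res$totals["delta_C"]),
               unname(res$totals["uptake_C"] - res$totals["incorporated_C"] -
                        res$totals["respired_C"]))
  expect_equal(sum(res$fractions), 1, tolerance = 1e-12)
})

test_that("acetate increases are flagged and excluded from uptake", {
  exp0 <- growth_experiment(0:2, c(0.1, 0.2, 0.3), c(40, 41, 39),
                            c(0, 5, 10), 35)
  expect_warning(res <- carbon_fate_accounting(exp0), "excluded")
  expect_true(res$intervals$excluded_from_uptake[1])
  expect_equal(res$intervals$uptake_C[1], 0)
})

test_that("outputs scale with the extensive quantities", {
  times <- 0:4; od <- seq(0.1, 0.5, by = 0.1)
  mk <- function(vol) {
    inc <- incorporated_carbon(diff(od), vol / 1000, 18.2)
    up <- inc / 0.35
    growth_experiment(times, od, 40 - cumsum(c(0, up / 2)) / vol,
                      cumsum(c(0, 0.63 * up)), vol)
  }
  r1 <- carbon_fate_accounting(mk(35))
  r2 <- carbon_fate_accounting(mk(70))
  expect_equal(r2$totals, 2 * r1$totals, tolerance = 1e-9)
  expect_equal(r2$fractions, r1$fractions, tolerance = 1e-12)
})

test_that("FBA carbon closure and experiment accounting agree on respiration", {
  # complete oxidation (zero growth): all carbon respired at RER 1, so the
  # LP ledger's CO2 equals the experiment ledger's respired carbon
  ctx <- toy_with_context()
  a <- 5; w <- 10                       # f = 1/3: g = 0, pure oxidation
  res <- max_growth(ctx$net, ctx$builder(0), ctx$exchanges, a, w)
  ledger <- carbon_closure_check(res$solution, res$problem)
  expect_equal(ledger$incorporated_C, 0, tolerance = 1e-8)
  expect_equal(ledger$co2_C, respired_carbon(w, rer = 1), tolerance = 1e-8)
})
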