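# closed forms for the AC-CORE toy (total uptake T = a + w):
#   forced growth  g = a - w/2
#   ATP feasibility  2w >= a + (2+m) g
#   optimal uptake  a* = T (6+m) / (12+3m)

test_that("max growth reproduces the toy closed forms", {
  ctx <- toy_with_context()
  r <- max_growth(ctx$net, ctx$builder(0), ctx$exchanges, 5, 5)
  expect_equal(r$growth, 2.5, tolerance = 1e-8)
  expect_equal(max_growth(ctx$net, ctx$builder(0), ctx$exchanges, 2, 8)$status,
               "INFEASIBLE")   # a < w/2: oxygen cannot be consumed
  expect_equal(max_growth(ctx$net, ctx$builder(0), ctx$exchanges, 8, 2)$status,
               "INFEASIBLE")   # ATP deficit
})

test_that("sweeps are deterministic, contiguous and scale-invariant", {
  ctx <- toy_with_context()
  grid <- sweep_grid(seq(0.10, 0.90, by = 0.02), c(0, 6, 30), total_uptake = 10)
  sw <- sweep_phenotype(ctx$net, ctx$builder, grid, ctx$exchanges)
  sw2 <- sweep_phenotype(ctx$net, ctx$builder, grid, ctx$exchanges)
  expect_identical(sw$growth, sw2$growth)
  expect_false(any(sw$status == "NUMERICAL"))
  # contiguity: feasible cells of each row form one interval
  for (im in seq_len(nrow(sw$growth))) {
    ok <- unname(which(!is.na(sw$growth[im, ])))
    if (length(ok) > 1) expect_equal(ok, seq(min(ok), max(ok)))
  }
  # doubling total uptake doubles every feasible cell
  grid2 <- sweep_grid(grid$acetate_fractions, grid$maintenance_values,
                      total_uptake = 20)
  swd <- sweep_phenotype(ctx$net, ctx$builder, grid2, ctx$exchanges)
  expect_equal(swd$growth, 2 * sw$growth, tolerance = 1e-7)
})

test_that("growth is non-increasing in maintenance at fixed ratio", {
  ctx <- toy_with_context()
  grid <- sweep_grid(seq(0.34, 0.50, by = 0.02), c(0, 5, 10, 20, 40),
                     total_uptake = 10)
  sw <- sweep_phenotype(ctx$net, ctx$builder, grid, ctx$exchanges)
  g <- sw$growth
  g[is.na(g)] <- -Inf   # infeasible counts as no growth
  for (jf in seq_len(ncol(g))) {
    d <- diff(g[, jf])
    expect_true(all(d[!is.nan(d)] <= 1e-9), info = paste("fraction", jf))
  }
})

test_that("feasibility bounds match the closed-form interval at m = 0", {
  ctx <- toy_with_context()
  grid <- sweep_grid(seq(0.10, 0.90, by = 0.01), 0, total_uptake = 10)
  sw <- sweep_phenotype(ctx$net, ctx$builder, grid, ctx$exchanges)
  fb <- feasibility_bounds(sw)
  expect_lt(abs(fb$envelope[["min_fraction"]] - 1 / 3), 0.011)
  expect_lt(abs(fb$envelope[["max_fraction"]] - 1 / 2), 0.011)
  # single-cell row: both bounds collapse onto that fraction
  g1 <- sweep_grid(0.45, 0, total_uptake = 10)
  s1 <- sweep_phenotype(ctx$net, ctx$builder, g1, ctx$exchanges)
  fb1 <- feasibility_bounds(s1)
  expect_equal(fb1$per_maintenance$min_fraction, 0.45)
  expect_equal(fb1$per_maintenance$max_fraction, 0.45)
  # all-infeasible sweep: explicit empty envelope
  g0 <- sweep_grid(0.15, c(0, 10), total_uptake = 10)
  s0 <- sweep_phenotype(ctx$net, ctx$builder, g0, ctx$exchanges)
  expect_true(all(is.na(feasibility_bounds(s0)$envelope)))
})

test_that("the optimality curve follows a* = T(6+m)/(12+3m) and is monotone", {
  ctx <- toy_with_context()
  grid <- sweep_grid(seq(0.30, 0.55, by = 0.0025), c(0, 6, 30),
                     total_uptake = 10)
  sw <- sweep_phenotype(ctx$net, ctx$builder, grid, ctx$exchanges)
  oc <- optimality_curve(sw)
  expected <- (6 + c(0, 6, 30)) / (12 + 3 * c(0, 6, 30))
  expect_true(all(abs(oc$curve$optimal_fraction - expected) <= 0.003))
  expect_true(all(diff(oc$curve$optimal_fraction) <= 1e-12))
  # constant surface ties: plateau spans the whole row, midpoint reported
  flat <- sw
  flat$growth[] <- 1
  ocf <- optimality_curve(flat)
  expect_equal(ocf$curve$plateau_lo, rep(0.30, 3))
  expect_equal(ocf$curve$plateau_hi, rep(0.55, 3))
  expect_equal(ocf$curve$optimal_fraction, rep(0.425, 3))
})

test_that("near-optimality compares observed against optimal growth", {
  ctx <- toy_with_context()
  grid <- sweep_grid(seq(0.10, 0.90, by = 0.01), c(0, 10), total_uptake = 10)
  sw <- sweep_phenotype(ctx$net, ctx$builder, grid, ctx$exchanges)
  # observed = optimal
  oc <- optimality_curve(sw)
  expect_equal(near_optimality(sw, oc$curve$optimal_fraction[1], 0), 1.0)
  # closed form: at f = 0.4, g = 1.0 against g* = 2.5
  expect_equal(near_optimality(sw, 0.40, 0), 0.4, tolerance = 1e-6)
  # infeasible observed ratio scores zero
  expect_equal(near_optimality(sw, 0.20, 0), 0)
  # interpolation between rows stays within the bracketing ratios
  r0 <- near_optimality(sw, 0.40, 0); r10 <- near_optimality(sw, 0.40, 10)
  ri <- near_optimality(sw, 0.40, 5, interpolate = TRUE)
  expect_gte(ri, min(r0, r10)); expect_lte(ri, max(r0, r10))
})

test_that("bounds and argmax are stable under grid refinement", {
  ctx <- toy_with_context()
  coarse <- sweep_phenotype(ctx$net, ctx$builder,
                            sweep_grid(seq(0.30, 0.55, by = 0.02), 0,
                                       total_uptake = 10), ctx$exchanges)
  fine <- sweep_phenotype(ctx$net, ctx$builder,
                          sweep_grid(seq(0.30, 0.55, by = 0.01), 0,
                                     total_uptake = 10), ctx$exchanges)
  fc <- optimality_curve(coarse)$curve$optimal_fraction
  ff <- optimality_curve(fine)$curve$optimal_fraction
  expect_lte(abs(fc - ff), 0.02)  # within one coarse step
})

test_that("maintenance estimation multiplies O2, atoms and the P:O ratio", {
  expect_equal(estimate_maintenance_energy(0), 0)
  expect_equal(estimate_maintenance_energy(5, p_o_ratio = 1, atoms_per_o2 = 2),
               10)
  expect_equal(estimate_maintenance_energy(5, p_o_ratio = 1, atoms_per_o2 = 1),
               5)
})
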