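test_that("the population transform is log(X + 1)", {
  expect_equal(population_transform(0), 0)
  expect_equal(population_transform(exp(1) - 1), 1)
  expect_equal(population_transform(exp(2) - 1), 2)
  expect_error(population_transform(-1), "non-negative")
})

test_that("growth rates follow the proliferation-removal balance", {
  p <- circuit_params(p_FF = 1, r_F = 0.3, K_F = 6, K_M = 6, r_M = 0.1)
  # the origin is always a fixed point
  g0 <- growth_rates(data.frame(F = 0, M = 0), p)
  expect_equal(c(g0$dF, g0$dM), c(0, 0))
  # at carrying capacity the proliferation factor vanishes
  p2 <- circuit_params(p_FF = 5, r_F = 0.1, K_F = 2, K_M = 2)
  gc <- growth_rates(data.frame(F = exp(2) - 1, M = 0), p2)
  expect_equal(gc$dF, -0.1 * (exp(2) - 1))
  # direct arithmetic: p_FF = 1, f(F) = 1
  g1 <- growth_rates(data.frame(F = exp(1) - 1, M = 0), p)
  expect_equal(g1$dF, (1 * 1 * (1 - 1 / 6) - 0.3) * (exp(1) - 1))
})

test_that("parameter validation enforces the sign constraints", {
  expect_error(circuit_params(r_F = -0.1), "non-negative")
  expect_error(circuit_params(K_F = 0), "positive")
  expect_silent(circuit_params(p_FF = -2, K_F = 1, K_M = 1))
  expect_error(as_circuit_params(list(p_FF = 1)), "missing")
})

test_that("simulation handles fixed points and pure decay exactly", {
  p0 <- circuit_params(r_F = 0.25, r_M = 0.25, K_F = 5, K_M = 5)
  tr <- simulate_circuit(p0, 0, 0, t_end = 5)
  expect_true(all(tr$F == 0) && all(tr$M == 0))
  # all p = 0: closed-form exponential decay
  tr2 <- simulate_circuit(p0, 100, 100, t_end = 4, dt_out = 4)
  expect_equal(tr2$F[nrow(tr2)], 100 * exp(-1), tolerance = 1e-6)
  expect_equal(tr2$M[nrow(tr2)], 100 * exp(-1), tolerance = 1e-6)
  expect_error(simulate_circuit(p0, 10, 10, t_end = 0), "t_end")
})

test_that("trajectories from the control regime converge to the ON state", {
  p <- preset_params("control")
  fp <- find_fixed_points(p)
  on <- fp[fp$class == "ON", ]
  expect_equal(nrow(on), 1)
  tr <- simulate_circuit(p, F0 = 2e4, M0 = 2e4, t_end = 120, dt_out = 120)
  expect_equal(log(tr$F[nrow(tr)] + 1), on$fF, tolerance = 1e-4)
  expect_equal(log(tr$M[nrow(tr)] + 1), on$fM, tolerance = 1e-4)
})

test_that("trajectories stay non-negative for random parameter draws", {
  set.seed(14)
  for (i in 1:10) {
    p <- circuit_params(p_FF = runif(1, -1, 1), p_MF = runif(1, -1, 1),
                        p_FM = runif(1, -1, 1), p_MM = runif(1, -1, 1),
                        r_F = runif(1, 0, 1), r_M = runif(1, 0, 1),
                        K_F = runif(1, 2, 10), K_M = runif(1, 2, 10))
    # seed within capacity: beyond f = K an inhibitory (negative) autocrine
    # coefficient turns the logistic factor into unbounded growth
    F0 <- runif(1, 0, exp(0.9 * p$K_F))
    M0 <- runif(1, 0, exp(0.9 * p$K_M))
    tr <- simulate_circuit(p, F0, M0, t_end = 30)
    expect_true(all(tr$F >= 0) && all(tr$M >= 0))
  }
})

test_that("the discrete map reduces to decay with the +1 convention", {
  p0 <- circuit_params(r_F = 0.25, r_M = 0.3, K_F = 5, K_M = 5)
  out <- discrete_map(data.frame(F3 = 100, M3 = 0), p0)
  expect_equal(out$F7, 101 * exp(-1) - 1)
  expect_equal(out$M7, 0)   # log(0+1) - 4*0.3 inverts below zero, clamped
  out0 <- discrete_map(data.frame(F3 = 0, M3 = 0), p0)
  expect_equal(c(out0$F7, out0$M7), c(0, 0))
  # continuous counterpart: F(t) = F0 exp(-r t); discrete uses (F0 + 1)
  expect_equal(out$F7 + 1, (100 + 1) * exp(-0.25 * 4))
})

test_that("the collapse threshold is 4 r_F / K_F with maximum at K_F / 2", {
  expect_equal(autocrine_collapse_threshold(r_F = 1, K_F = 4), 1)
  expect_equal(autocrine_collapse_threshold(r_F = 0, K_F = 3), 0)
  expect_error(autocrine_collapse_threshold(1, 0), "positive")
  # the net-growth quadratic is maximized at f = K/2, and the maximum is
  # zero exactly at the threshold
  r <- 0.37; K <- 6.2
  thr <- autocrine_collapse_threshold(r, K)
  g <- function(f, pFF) pFF * f * (1 - f / K) - r
  opt <- optimize(g, c(0, K), pFF = thr, maximum = TRUE)
  expect_equal(opt$maximum, K / 2, tolerance = 1e-4)
  expect_equal(opt$objective, 0, tolerance = 1e-10)
})

test_that("simulations collapse below the threshold and persist above", {
  r_F <- 0.4; K_F <- 7
  thr <- autocrine_collapse_threshold(r_F, K_F)
  final_max <- function(p_FF) {
    p <- circuit_params(p_FF = p_FF, r_F = r_F, r_M = 1, K_F = K_F, K_M = K_F)
    F0 <- exp(seq(log(1), log(1e5), length.out = 20)) - 1
    max(vapply(F0, function(f0) {
      simulate_circuit(p, f0, 0, t_end = 400, dt_out = 400)$F[2]
    }, numeric(1)))
  }
  expect_lt(final_max(0.99 * thr), 1)
  expect_gt(final_max(1.01 * thr), 1)
})

test_that("the origin linearization has eigenvalues (-r_F, -r_M)", {
  p <- circuit_params(p_FF = 2, p_MF = 1, p_FM = 0.5, p_MM = 0.2,
                      r_F = 0.31, r_M = 0.77, K_F = 6, K_M = 8)
  fp <- classify_fixed_point(0, 0, p)
  expect_equal(sort(Re(c(fp$eig1, fp$eig2))), sort(c(-0.31, -0.77)))
  expect_equal(fp$class, "OFF")
})
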