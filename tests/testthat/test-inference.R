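test_that("noiseless round-trip recovers all eight parameters", {
  for (regime in c("control", "cancer_cm")) {
    p <- preset_params(regime)
    arrows <- generate_arrows(p, n_grid = 5, include_axes = FALSE,
                              noise_cv = 0)
    fit <- fit_circuit(arrows)
    expect_rel_equal(unlist(fit$params), unlist(p), 1e-4)
    q <- fit$quality
    expect_equal(q$r2_F, 1, tolerance = 1e-6)
    expect_equal(q$r2_M, 1, tolerance = 1e-6)
    expect_equal(q$direction_error_rate, 0)
  }
})

test_that("pure-decay arrows identify the removal rate", {
  p0 <- circuit_params(r_F = 0.25, r_M = 0.25, K_F = 8, K_M = 8)
  arrows <- generate_arrows(p0, n_grid = 5, include_axes = FALSE,
                            noise_cv = 0)
  fit <- fit_circuit(arrows)
  expect_equal(fit$params$r_F, 0.25, tolerance = 1e-6)
  expect_equal(fit$params$r_M, 0.25, tolerance = 1e-6)
  expect_lt(max(abs(c(fit$params$p_FF, fit$params$p_MF,
                      fit$params$p_FM, fit$params$p_MM))), 1e-6)
})

test_that("underdetermined datasets are rejected with clear errors", {
  arrows <- generate_arrows(preset_params("control"), noise_cv = 0)
  expect_error(fit_circuit(arrows[1:2, ]), "underdetermined")
  # enough rows, but macrophages never seeded
  a2 <- generate_arrows(preset_params("control"), n_grid = 7, noise_cv = 0)
  a2 <- a2[a2$M3 == 0, ]
  expect_gte(nrow(a2), 8)
  expect_error(fit_circuit(a2), "underdetermined")
})

test_that("variance explained matches a hand-computed SS ratio", {
  p <- circuit_params(p_FF = 0.5, p_FM = 0.2, r_F = 0.2, r_M = 0.1,
                      K_F = 8, K_M = 8)
  toy <- tibble::tibble(F3 = c(100, 1000, 5000), M3 = c(0, 100, 1000),
                        F7 = c(150, 2000, 4000), M7 = c(10, 300, 2000))
  pred <- discrete_map(toy[, c("F3", "M3")], p)
  y <- log(toy$F7 + 1)
  yhat <- log(pred$F7 + 1)
  r2_hand <- 1 - sum((y - yhat)^2) / sum((y - mean(y))^2)
  expect_equal(fit_quality(p, toy)$r2_F, r2_hand)
  # constant observations: R^2 undefined, not 1
  toy2 <- dplyr::mutate(toy, F7 = 500)
  expect_true(is.na(fit_quality(p, toy2)$r2_F))
})

test_that("direction errors count sign mismatches of the log change", {
  p <- circuit_params(p_FF = 0.5, r_F = 0.2, K_F = 8, K_M = 8, r_M = 0.5)
  toy <- tibble::tibble(F3 = c(100, 100), M3 = c(0, 0),
                        F7 = c(1, 1), M7 = c(0, 0))
  # model predicts fibroblast growth at f(100) = 4.6 < K/2 region; observed
  # shrinkage on both arrows; M has zero observed change -> matched
  q <- fit_quality(p, toy)
  pred <- discrete_map(toy[, c("F3", "M3")], p)
  expect_true(all(pred$F7 > toy$F3))
  expect_equal(q$direction_error_rate, 0.5)
})

test_that("estimation error shrinks as noise vanishes", {
  p <- preset_params("control")
  truth <- unlist(p)
  well_identified <- c("p_FF", "p_FM", "r_F", "K_F", "K_M")
  mean_err <- function(cv) {
    errs <- vapply(1:5, function(s) {
      a <- generate_arrows(p, noise_cv = cv, seed = 1000 + s)
      est <- unlist(fit_circuit(a)$params)
      mean(abs(est[well_identified] - truth[well_identified]) /
             abs(truth[well_identified]))
    }, numeric(1))
    mean(errs)
  }
  errs <- vapply(c(0.2, 0.1, 0.05, 0), mean_err, numeric(1))
  expect_lt(errs[4], 1e-6)
  expect_lt(errs[3], errs[1])
  expect_lt(errs[4], errs[2])
})

test_that("bootstrap of a degenerate dataset has zero-width intervals", {
  p <- preset_params("control")
  one <- generate_arrows(p, n_grid = 3, include_axes = TRUE, noise_cv = 0)
  fit <- bootstrap_fit(one, n_boot = 50, seed = 3)
  s <- tidy(fit)
  expect_true(is.data.frame(s))
  # noiseless data: every resample is fitted by the same (true) parameters
  expect_lt(max(s$conf_high - s$conf_low), 1e-5)
  expect_rel_equal(s$median, unlist(p)[s$parameter], 1e-5)
})

test_that("bootstrap is reproducible and summaries are ordered", {
  p <- preset_params("control")
  a <- generate_arrows(p, noise_cv = 0.1, seed = 2)
  f1 <- bootstrap_fit(a, n_boot = 60, seed = 9)
  f2 <- bootstrap_fit(a, n_boot = 60, seed = 9)
  expect_equal(f1$boot$draws, f2$boot$draws)
  s <- tidy(f1)
  expect_true(all(s$conf_low <= s$median & s$median <= s$conf_high))
  expect_true(all(s$q25 <= s$median & s$median <= s$q75))
  g <- glance(f1)
  expect_equal(g$n_boot, 60)
})

test_that("contrasts follow the percentile-of-zero rule", {
  fake_fit <- function(draws) {
    structure(list(boot = list(draws = draws)), class = "circuit_fit")
  }
  nm <- c("p_FF", "p_MF", "p_FM", "p_MM", "r_F", "r_M", "K_F", "K_M")
  m <- matrix(rep(1:50, 8), ncol = 8, dimnames = list(NULL, nm))
  a <- fake_fit(m)
  # identical draws: p = 1
  expect_true(all(contrast_fits(a, fake_fit(m))$p_value == 1))
  # full separation: p = 2 / n_boot
  expect_true(all(contrast_fits(fake_fit(m + 100), a)$p_value == 2 / 50))
  # partial overlap: p matches a direct sign count
  set.seed(4)
  d <- matrix(rnorm(50 * 8, mean = 0.5), ncol = 8, dimnames = list(NULL, nm))
  ct <- contrast_fits(fake_fit(m + d), a)
  for (i in seq_along(nm)) {
    x <- d[, i]
    expect_equal(ct$p_value[i],
                 min(max(2 * min(mean(x <= 0), mean(x >= 0)), 2 / 50), 1))
  }
  expect_error(contrast_fits(a, fake_fit(m[1:10, ])), "paired")
})
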