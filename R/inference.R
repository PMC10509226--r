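#' Read an arrow dataset of paired co-culture counts
#'
#' An "arrow" is one paired observation of fibroblast and macrophage counts
#' at day 3 (tail) and day 7 (head) in one well. The CSV carries columns
#' `condition`, `replicate`, `F_day3`, `M_day3`, `F_day7`, `M_day7` (the
#' short names `F3`, `M3`, `F7`, `M7` are also accepted).
#'
#' @param path CSV file path.
#' @return A tibble with columns `condition`, `replicate`, `F3`, `M3`, `F7`,
#'   `M7`.
#' @export
read_arrows <- function(path) {
  d <- readr::read_csv(path, show_col_types = FALSE)
  long <- c(F3 = "F_day3", M3 = "M_day3", F7 = "F_day7", M7 = "M_day7")
  for (short in names(long)) {
    if (!short %in% names(d) && long[[short]] %in% names(d)) {
      d[[short]] <- d[[long[[short]]]]
      d[[long[[short]]]] <- NULL
    }
  }
  need <- c("F3", "M3", "F7", "M7")
  miss <- setdiff(need, names(d))
  if (length(miss) > 0) {
    stop("arrow data is missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (!"condition" %in% names(d)) d$condition <- "unlabeled"
  if (!"replicate" %in% names(d)) d$replicate <- seq_len(nrow(d))
  validate_arrows(d)
  dplyr::select(d, "condition", "replicate", dplyr::all_of(need))
}

validate_arrows <- function(data) {
  counts <- as.matrix(data[c("F3", "M3", "F7", "M7")])
  if (any(!is.finite(counts)) || any(counts < 0)) {
    stop("arrow counts must be finite and non-negative", call. = FALSE)
  }
  invisible(data)
}

# Residuals of one population's discrete-map equation on the log scale.
# theta = (p_self, p_other, r, K); x1 = f(own day-3), x2 = f(other day-3),
# y = f(own day-7). The prediction is floored at 0 exactly as discrete_map
# clamps inverted counts at zero, so observed clamped zeros are consistent.
eq_residuals <- function(theta, x1, x2, y, delta_t) {
  pred <- delta_t * ((theta[1] * x1 + theta[2] * x2) *
                       (1 - x1 / theta[4]) - theta[3]) + x1
  pmax(pred, 0) - y
}

fit_one_equation <- function(x1, x2, y, delta_t, starts = NULL) {
  lower <- c(-Inf, -Inf, 0, 1e-3)
  upper <- rep(Inf, 4)
  if (is.null(starts)) {
    k0 <- max(x1) + 1
    ps <- rbind(c(0, 0), c(0, 0.5), c(0.5, 0), c(0.5, 0.5), c(0.25, 0.25))
    starts <- lapply(seq_len(nrow(ps)), function(i) {
      c(ps[i, 1], ps[i, 2], 0.1, k0)
    })
  }
  best <- NULL
  for (s in starts) {
    fit <- tryCatch(
      minpack.lm::nls.lm(par = s, lower = lower, upper = upper,
                         fn = eq_residuals, x1 = x1, x2 = x2, y = y,
                         delta_t = delta_t,
                         control = minpack.lm::nls.lm.control(
                           maxiter = 500, ftol = 1e-14, ptol = 1e-14)),
      error = function(e) NULL)
    if (is.null(fit)) next
    if (is.null(best) || fit$deviance < best$deviance) best <- fit
  }
  if (is.null(best)) stop("nonlinear least-squares fit failed", call. = FALSE)
  best$par
}

#' Fit the circuit parameters to an arrow dataset
#'
#' Least-squares inference of the eight effective circuit rates from paired
#' day-3/day-7 counts via the discrete map: for each population the observed
#' `log(X7 + 1)` is regressed on its one-step prediction from the day-3
#' state. The fibroblast equation (parameters `p_FF`, `p_MF`, `r_F`, `K_F`)
#' and the macrophage equation (`p_FM`, `p_MM`, `r_M`, `K_M`) decouple and
#' are fitted independently by bounded Levenberg-Marquardt nonlinear least
#' squares (removal rates constrained to be non-negative, capacities to at
#' least 1e-3; proliferation coefficients unbounded, negative values reading
#' as inhibition). Each equation is fitted from five deterministic starting
#' points and the best objective is kept.
#'
#' @param data An arrow tibble with columns `F3`, `M3`, `F7`, `M7` (see
#'   [read_arrows()]); at least 8 arrows, of which at least 4 with `F3 > 0`
#'   and 4 with `M3 > 0`.
#' @param delta_t Interval between the paired counts in days (default 4).
#' @return A `circuit_fit` object: list with elements `params`
#'   ([circuit_params()]), `data`, `delta_t` and `quality` (see
#'   [fit_quality()]).
#' @export
#' @examples
#' arrows <- generate_arrows(preset_params("control"), noise_cv = 0, seed = 1)
#' fit <- fit_circuit(arrows)
#' tidy(fit)
fit_circuit <- function(data, delta_t = 4) {
  data <- tibble::as_tibble(data)
  validate_arrows(data)
  if (nrow(data) < 8) {
    stop("underdetermined dataset: at least 8 arrows are required to fit ",
         "8 parameters", call. = FALSE)
  }
  if (sum(data$F3 > 0) < 4 || sum(data$M3 > 0) < 4) {
    stop("underdetermined dataset: need at least 4 arrows with F3 > 0 and ",
         "4 with M3 > 0", call. = FALSE)
  }
  x1 <- population_transform(data$F3)
  x2 <- population_transform(data$M3)
  thF <- fit_one_equation(x1, x2, population_transform(data$F7), delta_t)
  thM <- fit_one_equation(x2, x1, population_transform(data$M7), delta_t)
  params <- circuit_params(p_FF = thF[1], p_MF = thF[2], r_F = thF[3],
                           K_F = thF[4],
                           p_MM = thM[1], p_FM = thM[2], r_M = thM[3],
                           K_M = thM[4])
  structure(list(params = params, data = data, delta_t = delta_t,
                 quality = fit_quality(params, data, delta_t),
                 boot = NULL),
            class = "circuit_fit")
}

#' Goodness of fit of circuit parameters on arrow data
#'
#' Variance explained is the coefficient of determination
#' `1 - SS_res / SS_tot` of observed versus predicted `log(X7 + 1)`,
#' computed per cell type (reported as `NA` when the observed outcomes are
#' constant). The direction error rate is the fraction of arrows where the
#' predicted sign of the log change between day 3 and day 7 differs from the
#' observed sign; arrows with zero observed change always count as matched.
#'
#' @param params A [circuit_params()] object.
#' @param data An arrow tibble.
#' @param delta_t Interval in days.
#' @return A tibble with one row: `r2_F`, `r2_M`, `direction_error_rate`.
#' @export
fit_quality <- function(params, data, delta_t = 4) {
  params <- as_circuit_params(params)
  pred <- discrete_map(data[c("F3", "M3")], params, delta_t)
  r2 <- function(obs, hat) {
    y <- log(obs + 1)
    yhat <- log(hat + 1)
    ss_tot <- sum((y - mean(y))^2)
    if (ss_tot == 0) return(NA_real_)
    1 - sum((y - yhat)^2) / ss_tot
  }
  dir_err <- function(obs3, obs7, hat7) {
    d_obs <- log(obs7 + 1) - log(obs3 + 1)
    d_hat <- log(hat7 + 1) - log(obs3 + 1)
    mean(d_obs != 0 & sign(d_obs) != sign(d_hat))
  }
  tibble::tibble(
    r2_F = r2(data$F7, pred$F7),
    r2_M = r2(data$M7, pred$M7),
    direction_error_rate = mean(c(
      dir_err(data$F3, data$F7, pred$F7),
      dir_err(data$M3, data$M7, pred$M7))))
}

#' Bootstrap uncertainty of the circuit fit
#'
#' Resamples the arrows with replacement `n_boot` times and refits the
#' circuit for each draw (restarting from the point estimate; multi-start on
#' the original data). Summaries per parameter are the bootstrap median,
#' interquartile range and percentile 95% confidence interval. Failed draws
#' are excluded when they make up less than 1% of the requested draws and
#' are an error otherwise.
#'
#' @param data An arrow tibble (see [fit_circuit()]).
#' @param n_boot Number of bootstrap draws (default 5000).
#' @param seed RNG seed for reproducibility.
#' @param delta_t Interval in days.
#' @return A `circuit_fit` object whose `boot` element holds the draw matrix
#'   (`n_boot` rows, one column per parameter), the per-parameter summary
#'   tibble and the failure count. `tidy()` returns the summary table.
#' @export
bootstrap_fit <- function(data, n_boot = 5000, seed = NULL, delta_t = 4) {
  if (!is.null(seed)) set.seed(seed)
  fit <- fit_circuit(data, delta_t)
  data <- fit$data
  x1 <- population_transform(data$F3)
  x2 <- population_transform(data$M3)
  yF <- population_transform(data$F7)
  yM <- population_transform(data$M7)
  p <- fit$params
  startF <- list(c(p$p_FF, p$p_MF, p$r_F, p$K_F))
  startM <- list(c(p$p_MM, p$p_FM, p$r_M, p$K_M))
  par_names <- c("p_FF", "p_MF", "p_FM", "p_MM", "r_F", "r_M", "K_F", "K_M")
  draws <- matrix(NA_real_, n_boot, 8, dimnames = list(NULL, par_names))
  n_fail <- 0
  for (b in seq_len(n_boot)) {
    idx <- sample.int(nrow(data), nrow(data), replace = TRUE)
    res <- tryCatch({
      thF <- fit_one_equation(x1[idx], x2[idx], yF[idx], delta_t, startF)
      thM <- fit_one_equation(x2[idx], x1[idx], yM[idx], delta_t, startM)
      c(thF[1], thF[2], thM[2], thM[1], thF[3], thM[3], thF[4], thM[4])
    }, error = function(e) NULL)
    if (is.null(res)) n_fail <- n_fail + 1 else draws[b, ] <- res
  }
  if (n_fail > 0.01 * n_boot) {
    stop("bootstrap failed in ", n_fail, " of ", n_boot,
         " draws (more than the 1% tolerance)", call. = FALSE)
  }
  ok <- stats::complete.cases(draws)
  qs <- apply(draws[ok, , drop = FALSE], 2, stats::quantile,
              probs = c(0.025, 0.25, 0.5, 0.75, 0.975))
  summary <- tibble::tibble(
    parameter = par_names,
    estimate = unlist(p)[par_names],
    median = qs[3, ], q25 = qs[2, ], q75 = qs[4, ],
    conf_low = qs[1, ], conf_high = qs[5, ])
  fit$boot <- list(draws = draws[ok, , drop = FALSE], summary = summary,
                   n_boot = n_boot, n_fail = n_fail, seed = seed)
  fit
}

#' @export
print.circuit_fit <- function(x, ...) {
  cat("<circuit_fit>", nrow(x$data), "arrows, delta_t =", x$delta_t, "days\n")
  print(x$params)
  cat(sprintf("  variance explained: F %.3f, M %.3f; direction error %.3f\n",
              x$quality$r2_F, x$quality$r2_M,
              x$quality$direction_error_rate))
  if (!is.null(x$boot)) {
    cat("  bootstrap:", x$boot$n_boot, "draws,", x$boot$n_fail, "failed\n")
  }
  invisible(x)
}

#' Tidy and glance methods for circuit fits
#'
#' `tidy()` returns one row per parameter (with bootstrap median, IQR and
#' 95% CI when available); `glance()` returns one row of fit-quality
#' summaries.
#'
#' @param x A `circuit_fit` object.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.circuit_fit <- function(x, ...) {
  if (!is.null(x$boot)) return(x$boot$summary)
  v <- unlist(x$params)
  tibble::tibble(parameter = names(v), estimate = unname(v))
}

#' @rdname tidy.circuit_fit
#' @export
glance.circuit_fit <- function(x, ...) {
  dplyr::mutate(x$quality, n_arrows = nrow(x$data), delta_t = x$delta_t,
                n_boot = if (is.null(x$boot)) NA_integer_ else x$boot$n_boot)
}

#' Contrast circuit parameters between two conditions
#'
#' Pairs the bootstrap draws of two fitted conditions by index and forms the
#' per-parameter difference distribution `a - b`. The two-sided p-value is
#' twice the smaller tail fraction of zero within the contrast distribution,
#' floored at `2 / n_boot` and capped at 1.
#'
#' @param a,b `circuit_fit` objects from [bootstrap_fit()] with equal
#'   numbers of retained draws.
#' @return A tibble with columns `parameter`, `median_diff`, `conf_low`,
#'   `conf_high` (95% interval of the difference) and `p_value`.
#' @export
contrast_fits <- function(a, b) {
  if (is.null(a$boot) || is.null(b$boot)) {
    stop("both fits need bootstrap draws; run bootstrap_fit()", call. = FALSE)
  }
  da <- a$boot$draws
  db <- b$boot$draws
  if (nrow(da) != nrow(db)) {
    stop("bootstrap sample counts differ (", nrow(da), " vs ", nrow(db),
         "); draws are paired by index", call. = FALSE)
  }
  d <- da - db
  n <- nrow(d)
  purrr::map_dfr(colnames(d), function(pn) {
    x <- d[, pn]
    p <- 2 * min(mean(x <= 0), mean(x >= 0))
    tibble::tibble(parameter = pn,
                   median_diff = stats::median(x),
                   conf_low = stats::quantile(x, 0.025, names = FALSE),
                   conf_high = stats::quantile(x, 0.975, names = FALSE),
                   p_value = min(max(p, 2 / n), 1))
  })
}
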