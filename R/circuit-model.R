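#' Log population-size transform
#'
#' Cell-cell interaction terms in the circuit act through `f(X) = log(X + 1)`
#' (natural log), a diminishing-returns transform of population size that is
#' finite at zero cells. Carrying capacities are expressed on this scale.
#'
#' @param x Cell counts, non-negative numeric vector.
#' @return `log(x + 1)`.
#' @export
#' @examples
#' population_transform(c(0, exp(1) - 1, exp(2) - 1))
population_transform <- function(x) {
  if (any(!is.finite(x)) || any(x < 0)) {
    stop("population counts must be finite and non-negative", call. = FALSE)
  }
  log(x + 1)
}

# Per-capita net growth rates in f-space (f = log(count + 1)).
# Vectorized over fF, fM. Returns list(gF, gM) in 1/day.
per_capita_rates <- function(fF, fM, p) {
  gF <- (p$p_FF * fF + p$p_MF * fM) * (1 - fF / p$K_F) - p$r_F
  gM <- (p$p_FM * fF + p$p_MM * fM) * (1 - fM / p$K_M) - p$r_M
  list(gF = gF, gM = gM)
}

# Partial derivatives of the per-capita rates with respect to (fF, fM).
per_capita_rate_grad <- function(fF, fM, p) {
  list(
    gF_fF = p$p_FF * (1 - fF / p$K_F) - (p$p_FF * fF + p$p_MF * fM) / p$K_F,
    gF_fM = p$p_MF * (1 - fF / p$K_F),
    gM_fF = p$p_FM * (1 - fM / p$K_M),
    gM_fM = p$p_MM * (1 - fM / p$K_M) - (p$p_FM * fF + p$p_MM * fM) / p$K_M
  )
}

#' Instantaneous growth rates of the circuit
#'
#' Right-hand side of the continuous model
#' `dX/dt = X * (proliferation - removal)`: for fibroblasts,
#' `dF/dt = F * ((p_FF f(F) + p_MF f(M)) (1 - f(F)/K_F) - r_F)` and
#' analogously for macrophages, with `f = log(X + 1)`.
#'
#' @param data A data frame with columns `F` and `M` (cell counts), or a
#'   numeric vector `c(F, M)`.
#' @param params A [circuit_params()] object.
#' @return A tibble with columns `F`, `M`, `dF`, `dM` (counts per day).
#' @export
#' @examples
#' p <- preset_params("control")
#' growth_rates(data.frame(F = c(0, 100), M = c(0, 100)), p)
growth_rates <- function(data, params) {
  params <- as_circuit_params(params)
  if (is.numeric(data) && length(data) == 2) {
    data <- data.frame(F = data[[1]], M = data[[2]])
  }
  F <- data[["F"]]
  M <- data[["M"]]
  g <- per_capita_rates(population_transform(F), population_transform(M),
                        params)
  tibble::tibble(F = F, M = M, dF = F * g$gF, dM = M * g$gM)
}

# deSolve right-hand side; states clamped so populations at (or below) zero
# stay at zero.
circuit_rhs <- function(t, y, parms) {
  y <- pmax(y, 0)
  g <- per_capita_rates(log(y[[1]] + 1), log(y[[2]] + 1), parms)
  list(c(y[[1]] * g$gF, y[[2]] * g$gM))
}

#' Simulate the continuous circuit
#'
#' Integrates the two-population model with an adaptive stiff-capable solver
#' (`deSolve::ode`, lsoda) at relative tolerance 1e-8 and absolute tolerance
#' 1e-10. Populations are clamped at zero: a population that reaches zero
#' stays there, and sub-1e-6-cell values at output times are set to exactly 0.
#'
#' @param params A [circuit_params()] object.
#' @param F0,M0 Initial cell counts at time zero (non-negative scalars).
#' @param t_end End time in days.
#' @param dt_out Output grid spacing in days.
#' @return A tibble with columns `time`, `F`, `M`.
#' @export
#' @examples
#' simulate_circuit(preset_params("control"), F0 = 1e4, M0 = 1e4, t_end = 10)
simulate_circuit <- function(params, F0, M0, t_end, dt_out = 0.25) {
  params <- as_circuit_params(params)
  if (!is.finite(t_end) || t_end <= 0) stop("t_end must be > 0", call. = FALSE)
  if (F0 < 0 || M0 < 0) {
    stop("initial counts must be non-negative", call. = FALSE)
  }
  times <- unique(c(seq(0, t_end, by = dt_out), t_end))
  # fall back to a looser absolute tolerance, then to an explicit RK method,
  # when lsoda cannot hold 1e-10 near an absorbing zero state
  attempts <- list(list(method = "lsoda", atol = 1e-10),
                   list(method = "lsoda", atol = 1e-8),
                   list(method = "ode45", atol = 1e-8))
  sol <- NULL
  for (a in attempts) {
    cand <- tryCatch(
      suppressWarnings(deSolve::ode(y = c(F = F0, M = M0), times = times,
                                    func = circuit_rhs, parms = params,
                                    method = a$method, rtol = 1e-8,
                                    atol = a$atol)),
      error = function(e) NULL)
    if (!is.null(cand) && nrow(cand) == length(times) &&
        all(is.finite(cand))) {
      sol <- cand
      break
    }
  }
  if (is.null(sol)) {
    stop("ODE integration failed for F0 = ", F0, ", M0 = ", M0,
         " with all solver settings", call. = FALSE)
  }
  out <- tibble::tibble(time = sol[, "time"],
                        F = pmax(sol[, "F"], 0),
                        M = pmax(sol[, "M"], 0))
  out$F[out$F < 1e-6] <- 0
  out$M[out$M < 1e-6] <- 0
  out
}

#' Discrete day-3 to day-7 map of the circuit
#'
#' One-step prediction of day-7 counts from day-3 counts, obtained by
#' approximating the logarithmic derivative over the experimental interval:
#' `log(F7 + 1) = dt * ((p_FF f(F3) + p_MF f(M3)) (1 - f(F3)/K_F) - r_F)
#'  + log(F3 + 1)` (and analogously for M), with `f = log(X + 1)` used
#' uniformly so that zero counts are representable. Predictions are inverted
#' from the log scale and clamped at zero.
#'
#' @param data A data frame with day-3 counts in columns `F3` and `M3`.
#' @param params A [circuit_params()] object.
#' @param delta_t Interval length in days (default 4, day 3 to day 7).
#' @return The input tibble with predicted columns `F7` and `M7` appended.
#' @export
#' @examples
#' # pure decay: all p = 0
#' p <- circuit_params(r_F = 0.25, r_M = 0.25, K_F = 6, K_M = 6)
#' discrete_map(data.frame(F3 = 100, M3 = 0), p)  # F7 = 101 / e - 1
discrete_map <- function(data, params, delta_t = 4) {
  params <- as_circuit_params(params)
  fF <- population_transform(data[["F3"]])
  fM <- population_transform(data[["M3"]])
  g <- per_capita_rates(fF, fM, params)
  tibble::as_tibble(data) |>
    dplyr::mutate(F7 = pmax(exp(delta_t * g$gF + fF) - 1, 0),
                  M7 = pmax(exp(delta_t * g$gM + fM) - 1, 0))
}

#' Autocrine threshold for population collapse
#'
#' For the single-population (fibroblast-only) circuit
#' `dF/dt = F * (p_FF f (1 - f/K_F) - r_F)`, the net per-capita growth is a
#' downward parabola in `f` maximized at `f = K_F / 2`. The population
#' collapses from every initial condition exactly when that maximum is
#' negative, i.e. when `p_FF < 4 r_F / K_F`. This function returns the
#' threshold value `4 r_F / K_F`.
#'
#' @param r_F Removal rate (per day), non-negative.
#' @param K_F Carrying capacity (log-count units), strictly positive.
#' @return The critical autocrine coefficient `4 * r_F / K_F`.
#' @export
#' @examples
#' autocrine_collapse_threshold(r_F = 1, K_F = 4)  # 1
autocrine_collapse_threshold <- function(r_F, K_F) {
  if (any(K_F <= 0)) stop("K_F must be strictly positive", call. = FALSE)
  if (any(r_F < 0)) stop("r_F must be non-negative", call. = FALSE)
  4 * r_F / K_F
}
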