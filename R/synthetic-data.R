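#' Preset circuit parameter regimes
#'
#' Documented numeric presets reproducing the qualitative circuit structure
#' of the two growth conditions. The fitted values behind the published
#' portraits are not reprinted anywhere accessible, so these presets are
#' this package's own, version-pinned stand-ins constrained by the stated
#' qualitative structure:
#'
#' * `"control"`: both populations are removed (`r_F = 0.3`, `r_M = 0.8`
#'   per day); fibroblasts sustain themselves through a strong autocrine
#'   loop (`p_FF = 0.6`, far above the collapse threshold `4 r_F / K_F`)
#'   and support macrophages through a strong paracrine arm (`p_FM = 0.3`),
#'   while the reverse paracrine arm and the macrophage autocrine loop are
#'   weak (`p_MF = 0.05`, `p_MM = 0.02`). The portrait is bistable: stable
#'   OFF and ON states plus a semi-stable ON-OFF point on the fibroblast
#'   axis.
#' * `"cancer_cm"`: cancer-conditioned medium sets the macrophage removal
#'   rate to zero (enhanced survival), raises macrophage self-sufficiency
#'   (`p_MM = 0.4`), reduces their dependence on fibroblasts (`p_FM = 0.1`)
#'   and removes the macrophage effect on fibroblasts (`p_MF = 0`). The
#'   origin becomes semi-stable and a stable OFF-ON state appears on the
#'   macrophage axis.
#'
#' Carrying capacities are `K_F = 9` and `K_M = 9 + log(10)` log-count
#' units in both regimes, i.e. roughly a 10-fold higher macrophage count
#' capacity.
#'
#' @param regime `"control"` or `"cancer_cm"`.
#' @return A [circuit_params()] object.
#' @export
#' @examples
#' preset_params("control")
preset_params <- function(regime = c("control", "cancer_cm")) {
  regime <- match.arg(regime)
  switch(regime,
    control = circuit_params(p_FF = 0.6, p_MF = 0.05, p_FM = 0.3,
                             p_MM = 0.02, r_F = 0.3, r_M = 0.8,
                             K_F = 9, K_M = 9 + log(10)),
    cancer_cm = circuit_params(p_FF = 0.6, p_MF = 0, p_FM = 0.1,
                               p_MM = 0.4, r_F = 0.3, r_M = 0,
                               K_F = 9, K_M = 9 + log(10)))
}

#' Generate a synthetic arrow dataset from a known circuit
#'
#' Emulates the co-culture phase-portrait experiment: day-3 seeding counts
#' are laid out on a log-spaced grid spanning the experimental range
#' (0 to 1e5 cells per well), including the axes (fibroblasts alone and
#' macrophages alone), and day-7 counts are the model prediction for each
#' seeding, corrupted by multiplicative lognormal noise with mean 1 and
#' coefficient of variation `noise_cv` (counting error scales with
#' abundance). Predictions come from the discrete day-3 to day-7 map or from
#' integrating the continuous model over `delta_t` days.
#'
#' @param params A [circuit_params()] object.
#' @param n_grid Number of log-spaced interior seeding levels per axis
#'   (default 6).
#' @param count_min,count_max Range of the interior seeding levels.
#' @param include_axes Include zero-seeding rows/columns? (default TRUE)
#' @param noise_cv Coefficient of variation of the multiplicative lognormal
#'   noise on day-7 counts (default 0.1; 0 = noiseless).
#' @param mode `"discrete"` (the day-3 to day-7 map) or `"continuous"`
#'   (ODE integration).
#' @param delta_t Interval in days.
#' @param condition Condition label stored in the output.
#' @param seed RNG seed; the dataset is deterministic given the seed.
#' @return An arrow tibble with columns `condition`, `replicate`, `F3`,
#'   `M3`, `F7`, `M7`.
#' @export
#' @examples
#' arrows <- generate_arrows(preset_params("control"), noise_cv = 0.1,
#'                           seed = 7)
generate_arrows <- function(params, n_grid = 6, count_min = 10,
                            count_max = 1e5, include_axes = TRUE,
                            noise_cv = 0.1, mode = c("discrete", "continuous"),
                            delta_t = 4, condition = "synthetic",
                            seed = NULL) {
  params <- as_circuit_params(params)
  mode <- match.arg(mode)
  if (noise_cv < 0) stop("noise_cv must be non-negative", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  levels <- exp(seq(log(count_min), log(count_max), length.out = n_grid))
  if (include_axes) levels <- c(0, levels)
  grid <- expand.grid(F3 = levels, M3 = levels)
  if (mode == "discrete") {
    pred <- discrete_map(grid, params, delta_t)
  } else {
    pred <- purrr::pmap_dfr(grid, function(F3, M3) {
      tr <- simulate_circuit(params, F0 = F3, M0 = M3, t_end = delta_t,
                             dt_out = delta_t)
      tibble::tibble(F3 = F3, M3 = M3,
                     F7 = tr$F[nrow(tr)], M7 = tr$M[nrow(tr)])
    })
  }
  n <- nrow(pred)
  if (noise_cv > 0) {
    sdlog <- sqrt(log(1 + noise_cv^2))
    fac <- function() stats::rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
    pred$F7 <- pred$F7 * fac()
    pred$M7 <- pred$M7 * fac()
  }
  tibble::tibble(condition = condition, replicate = seq_len(n),
                 F3 = pred$F3, M3 = pred$M3,
                 F7 = pmax(pred$F7, 0), M7 = pmax(pred$M7, 0))
}

#' Generate a random weighted directed cell network
#'
#' Erdos-Renyi-style random digraph: every ordered node pair, self-loops
#' included, carries an edge independently with probability `p_edge`;
#' weights are i.i.d. lognormal with the given median and log-scale sigma.
#' Optionally a motif instance is planted by forcing the edges of a chosen
#' two-node pattern between the first two nodes and multiplying their
#' weights by `mult`, so that detection power of the weighted census can be
#' measured.
#'
#' @param n_nodes Number of nodes.
#' @param p_edge Edge probability in (0, 1].
#' @param w_median Median edge weight of the lognormal weight distribution.
#' @param w_sigma Log-scale standard deviation of the weights.
#' @param plant `NULL`, `"mutual"` (reciprocal edges) or `"mutual_loops"`
#'   (reciprocal edges plus both autocrine loops).
#' @param mult Weight multiplier applied to the planted edges (>= 1).
#' @param seed RNG seed.
#' @return A `cell_network` with nodes `C1 ... Cn`.
#' @export
#' @examples
#' net <- generate_random_network(7, p_edge = 0.4, plant = "mutual_loops",
#'                                mult = 10, seed = 3)
generate_random_network <- function(n_nodes, p_edge = 0.4, w_median = 1,
                                    w_sigma = 0.5, plant = NULL, mult = 1,
                                    seed = NULL) {
  if (p_edge <= 0 || p_edge > 1) {
    stop("p_edge must be in (0, 1]", call. = FALSE)
  }
  if (mult < 1) stop("mult must be >= 1", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  nodes <- paste0("C", seq_len(n_nodes))
  A <- matrix(stats::runif(n_nodes^2) < p_edge, n_nodes, n_nodes)
  W <- matrix(0, n_nodes, n_nodes)
  W[A] <- stats::rlnorm(sum(A), meanlog = log(w_median), sdlog = w_sigma)
  if (!is.null(plant)) {
    plant <- match.arg(plant, c("mutual", "mutual_loops"))
    cells <- rbind(c(1, 2), c(2, 1))
    if (plant == "mutual_loops") cells <- rbind(cells, c(1, 1), c(2, 2))
    for (r in seq_len(nrow(cells))) {
      i <- cells[r, 1]; j <- cells[r, 2]
      if (W[i, j] == 0) {
        W[i, j] <- stats::rlnorm(1, meanlog = log(w_median), sdlog = w_sigma)
      }
      W[i, j] <- W[i, j] * mult
    }
  }
  idx <- which(W > 0, arr.ind = TRUE)
  as_cell_network(
    tibble::tibble(sender = nodes[idx[, 1]], receiver = nodes[idx[, 2]],
                   weight = W[idx]),
    nodes = nodes)
}
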