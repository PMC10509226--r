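#' Run the full network-to-motifs analysis
#'
#' Chains the network half of the workflow: read the interaction-strength
#' matrix, prune weak interactions, compute node strengths and the root,
#' census the requested pattern sizes, and score them against the
#' degree-preserving null. If `out_dir` is given, writes `network_edges.csv`,
#' `node_strengths.json`, `motifs.csv` and `motifs.json`; the JSON embeds
#' the fully resolved configuration (including the seed) so every report is
#' reproducible from its own metadata.
#'
#' @param matrix_input Path to an interaction-matrix CSV, or a matrix.
#' @param k Pattern sizes (default `c(2, 3)`).
#' @param weak_fraction Weak-interaction pruning budget (default 0.10).
#' @param n_random Number of null networks (default 10000).
#' @param z_threshold Significance threshold (default 1.65).
#' @param seed RNG seed (required for a reproducible report).
#' @param out_dir Optional output directory.
#' @param progress Log null-model progress?
#' @return Invisibly, a list with `network`, `strengths`, `enrichment` and
#'   `config`.
#' @export
run_motif_pipeline <- function(matrix_input, k = c(2, 3),
                               weak_fraction = 0.10, n_random = 10000,
                               z_threshold = 1.65, seed = 1, out_dir = NULL,
                               progress = FALSE) {
  W <- if (is.character(matrix_input)) {
    read_interaction_matrix(matrix_input)
  } else {
    validate_interaction_matrix(as.matrix(matrix_input))
  }
  net <- build_cell_network(W, weak_fraction)
  strengths <- node_strengths(net)
  enr <- motif_significance(net, k = k, n_random = n_random,
                            z_threshold = z_threshold, seed = seed,
                            progress = progress)
  config <- list(
    matrix_input = if (is.character(matrix_input)) matrix_input else
      "in-memory matrix",
    k = k, weak_fraction = weak_fraction, n_random = n_random,
    z_threshold = z_threshold, seed = seed)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    readr::write_csv(tibble::as_tibble(net),
                     file.path(out_dir, "network_edges.csv"))
    jsonlite::write_json(strengths, file.path(out_dir, "node_strengths.json"),
                         dataframe = "rows", digits = NA, pretty = TRUE)
    readr::write_csv(tibble::as_tibble(enr), file.path(out_dir, "motifs.csv"))
    jsonlite::write_json(
      list(config = config, motifs = tibble::as_tibble(enr)),
      file.path(out_dir, "motifs.json"),
      dataframe = "rows", auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(list(network = net, strengths = strengths, enrichment = enr,
                 config = config))
}

#' Run the arrows-to-circuit analysis
#'
#' Chains the dynamics half of the workflow for each requested condition:
#' fit the circuit, bootstrap it, and compute the phase portrait of the
#' point estimate; optionally contrasts the first two conditions. With
#' `out_dir` set, writes per-condition parameter tables
#' (`fit_<condition>.csv`), a contrast table and one JSON bundle
#' (`circuit.json`) embedding the resolved configuration and seed.
#'
#' @param arrows Path to an arrows CSV (see [read_arrows()]) or an arrow
#'   tibble with a `condition` column.
#' @param conditions Conditions to analyze; default all present. An unknown
#'   label is an error naming the available ones.
#' @param n_boot Bootstrap draws per condition (default 5000).
#' @param seed RNG seed.
#' @param delta_t Interval in days.
#' @param contrast Contrast the first two conditions? (default TRUE when two
#'   or more are analyzed)
#' @param basins Compute basins of attraction in the portraits?
#' @param out_dir Optional output directory.
#' @return Invisibly, a list with `fits` (named list of `circuit_fit`),
#'   `portraits` (named list of `phase_portrait`), `contrast` (tibble or
#'   NULL) and `config`.
#' @export
run_circuit_pipeline <- function(arrows, conditions = NULL, n_boot = 5000,
                                 seed = 1, delta_t = 4, contrast = NULL,
                                 basins = FALSE, out_dir = NULL) {
  data <- if (is.character(arrows)) read_arrows(arrows) else
    tibble::as_tibble(arrows)
  if (!"condition" %in% names(data)) data$condition <- "unlabeled"
  available <- unique(data$condition)
  if (is.null(conditions)) conditions <- available
  missing <- setdiff(conditions, available)
  if (length(missing) > 0) {
    stop("condition(s) not present: ", paste(missing, collapse = ", "),
         "; available: ", paste(available, collapse = ", "), call. = FALSE)
  }
  fits <- list()
  portraits <- list()
  for (i in seq_along(conditions)) {
    cond <- conditions[i]
    sub <- dplyr::filter(data, .data$condition == cond)
    fits[[cond]] <- bootstrap_fit(sub, n_boot = n_boot, seed = seed + i - 1,
                                  delta_t = delta_t)
    portraits[[cond]] <- phase_portrait(fits[[cond]]$params, basins = basins)
  }
  if (is.null(contrast)) contrast <- length(conditions) >= 2
  contrast_tbl <- if (contrast && length(conditions) >= 2) {
    contrast_fits(fits[[conditions[1]]], fits[[conditions[2]]])
  } else {
    NULL
  }
  config <- list(conditions = conditions, n_boot = n_boot, seed = seed,
                 delta_t = delta_t, basins = basins)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    for (cond in conditions) {
      readr::write_csv(tidy(fits[[cond]]),
                       file.path(out_dir, paste0("fit_", cond, ".csv")))
    }
    if (!is.null(contrast_tbl)) {
      readr::write_csv(contrast_tbl, file.path(out_dir, "contrasts.csv"))
    }
    bundle <- list(
      config = config,
      fits = lapply(fits, function(f) {
        list(params = unclass(f$params), quality = f$quality,
             summary = f$boot$summary)
      }),
      fixed_points = lapply(portraits, function(pp) {
        dplyr::mutate(pp$fixed_points,
                      eig1 = as.character(.data$eig1),
                      eig2 = as.character(.data$eig2))
      }),
      contrast = contrast_tbl)
    jsonlite::write_json(bundle, file.path(out_dir, "circuit.json"),
                         dataframe = "rows", auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  }
  invisible(list(fits = fits, portraits = portraits,
                 contrast = contrast_tbl, config = config))
}
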