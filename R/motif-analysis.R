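# Precompute, for every k-subset of n nodes, the column-major linear indices
# of the tracked cells in the full n x n adjacency matrix. Rows = subsets.
motif_subset_index <- function(n, k, with_self_loops) {
  subsets <- utils::combn(n, k)
  cells <- pattern_cells(k, with_self_loops)
  k2 <- matrix(seq_len(k * k), k, k)
  ij <- cbind(row(k2)[cells], col(k2)[cells])
  idx <- matrix(0L, ncol(subsets), length(cells))
  for (s in seq_len(ncol(subsets))) {
    nodes <- subsets[, s]
    idx[s, ] <- (nodes[ij[, 2]] - 1L) * n + nodes[ij[, 1]]
  }
  list(subsets = subsets, idx = idx,
       pow2 = 2^(seq_len(length(cells)) - 1))
}

# Classify every node subset by induced configuration and compute the mean
# weight of the pattern's edges per instance. Returns per-subset pattern row
# (NA = no class) and mean weight.
classify_subsets <- function(A, W, six, code_map) {
  B <- matrix(A[six$idx], nrow(six$idx), ncol(six$idx))
  codes <- as.integer(B %*% six$pow2)
  rows <- code_map[codes + 1]
  Wm <- matrix(W[six$idx], nrow(six$idx), ncol(six$idx))
  mw <- rowSums(Wm * B) / pmax(rowSums(B), 1)
  list(rows = rows, mean_weight = mw)
}

#' Find all instances of a circuit pattern in a network
#'
#' Induced-subgraph matching: a set of k network nodes is an instance of a
#' pattern exactly when its induced edge configuration (inter-node edges, and
#' self-loops when the pattern family tracks them) is isomorphic to the
#' pattern. Each distinct node set is counted once; automorphic re-mappings
#' are not multiplied (the raw mapping count is `n_automorphisms` times
#' larger and is reported by [count_motifs()]).
#'
#' @param net A `cell_network` (see [build_cell_network()]).
#' @param patterns A `motif_patterns` table from [enumerate_patterns()].
#' @return A tibble with one row per instance: `pattern_id`,
#'   `canonical_key`, `nodes` (list-column of node name vectors) and
#'   `mean_weight` (mean weight of the mapped edges).
#' @export
#' @examples
#' net <- as_cell_network(data.frame(sender = c("A", "B"),
#'                                   receiver = c("B", "A"),
#'                                   weight = c(2, 4)))
#' find_motif_instances(net, enumerate_patterns(2, with_self_loops = TRUE))
find_motif_instances <- function(net, patterns) {
  mats <- network_matrices(net)
  k <- patterns$k[1]
  if (k > length(mats$nodes)) {
    return(tibble::tibble(pattern_id = character(), canonical_key = character(),
                          nodes = list(), mean_weight = numeric()))
  }
  six <- motif_subset_index(length(mats$nodes), k,
                            attr(patterns, "with_self_loops"))
  cl <- classify_subsets(mats$A, mats$W, six, pattern_code_map(patterns))
  hit <- which(!is.na(cl$rows))
  tibble::tibble(
    pattern_id = patterns$pattern_id[cl$rows[hit]],
    canonical_key = patterns$canonical_key[cl$rows[hit]],
    nodes = lapply(hit, function(s) mats$nodes[six$subsets[, s]]),
    mean_weight = cl$mean_weight[hit]) |>
    dplyr::arrange(.data$pattern_id)
}

#' Score a set of motif instances
#'
#' The class score of a pattern is the sum over its instances of the
#' instance mean edge weight; an empty instance set scores 0.
#'
#' @param instances A tibble from [find_motif_instances()] (or any data
#'   frame with a `mean_weight` column).
#' @return The summed weight score (a scalar).
#' @export
score_pattern <- function(instances) {
  if (NROW(instances) == 0) return(0)
  sum(instances$mean_weight)
}

#' Count and score all patterns of one size in a network
#'
#' @param net A `cell_network`.
#' @param k Pattern size (number of nodes).
#' @param with_self_loops Do self-loops distinguish classes? Defaults to
#'   TRUE for k = 2 (the 7 two-cell circuit patterns) and FALSE for k >= 3
#'   (inter-edge classes, e.g. the 13 three-cell patterns).
#' @return A tibble with one row per pattern: `k`, `pattern_id`,
#'   `canonical_key`, `n_instances` (distinct node sets), `n_mappings`
#'   (instances times pattern automorphisms) and `score`.
#' @export
count_motifs <- function(net, k, with_self_loops = (k == 2)) {
  patterns <- enumerate_patterns(k, with_self_loops)
  mats <- network_matrices(net)
  if (k > length(mats$nodes)) {
    return(summarize_classes(patterns,
                             list(rows = integer(), mean_weight = numeric())))
  }
  six <- motif_subset_index(length(mats$nodes), k, with_self_loops)
  cl <- classify_subsets(mats$A, mats$W, six, pattern_code_map(patterns))
  summarize_classes(patterns, cl)
}

summarize_classes <- function(patterns, cl) {
  rows <- cl$rows[!is.na(cl$rows)]
  mw <- cl$mean_weight[!is.na(cl$rows)]
  n_inst <- tabulate(rows, nbins = nrow(patterns))
  score <- rep(0, nrow(patterns))
  if (length(rows) > 0) {
    agg <- tapply(mw, factor(rows, levels = seq_len(nrow(patterns))), sum,
                  default = 0)
    score <- as.numeric(agg)
  }
  tibble::tibble(k = patterns$k, pattern_id = patterns$pattern_id,
                 canonical_key = patterns$canonical_key,
                 n_instances = n_inst,
                 n_mappings = n_inst * patterns$n_automorphisms,
                 score = score)
}

#' Degree-preserving rewiring of a cell network
#'
#' Randomizes a network by repeated double-edge swaps: two edges
#' `(a -> b, c -> d)` are replaced by `(a -> d, c -> b)` when this creates no
#' duplicate edge. Every node's in-degree and out-degree are preserved
#' exactly; self-loops may be created or destroyed. Edge weights are then
#' randomly permuted over the rewired edges. Networks admitting no swap are
#' returned unchanged (degenerate null).
#'
#' @param net A `cell_network`.
#' @param swap_factor Swap attempts per edge (default 10).
#' @param seed Optional RNG seed.
#' @return A rewired `cell_network` on the same node set.
#' @export
rewire_network <- function(net, swap_factor = 10, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  mats <- network_matrices(net)
  res <- rewire_matrices(mats$A, net$weight, swap_factor)
  nodes <- mats$nodes
  idx <- which(res$A, arr.ind = TRUE)
  as_cell_network(
    tibble::tibble(sender = nodes[idx[, 1]], receiver = nodes[idx[, 2]],
                   weight = res$W[idx]),
    nodes = nodes)
}

# Core swap routine on a logical adjacency matrix; returns the rewired A and
# a weight matrix with the weight multiset randomly permuted over edges.
rewire_matrices <- function(A, weights, swap_factor = 10) {
  edges <- which(A, arr.ind = TRUE)
  m <- nrow(edges)
  if (m >= 2) {
    attempts <- ceiling(swap_factor * m)
    pick <- matrix(sample.int(m, 2 * attempts, replace = TRUE), ncol = 2)
    for (t in seq_len(attempts)) {
      i <- pick[t, 1]; j <- pick[t, 2]
      if (i == j) next
      a <- edges[i, 1]; b <- edges[i, 2]
      c <- edges[j, 1]; d <- edges[j, 2]
      if (a == c || b == d) next
      if (A[a, d] || A[c, b]) next
      A[a, b] <- FALSE; A[c, d] <- FALSE
      A[a, d] <- TRUE;  A[c, b] <- TRUE
      edges[i, 2] <- d; edges[j, 2] <- b
    }
  }
  W <- matrix(0, nrow(A), ncol(A))
  if (m > 0) W[which(A)] <- weights[sample.int(m)]
  list(A = A, W = W)
}

#' Motif enrichment against a degree-preserving null model
#'
#' Full weighted motif census: enumerates the pattern classes for each
#' requested size, counts induced instances and their weight scores in the
#' network, and compares each class score with its distribution over
#' `n_random` degree-preserving rewired networks with permuted weights. The
#' z-score is `(score - null_mean) / null_sd` (defined as 0 when the null is
#' degenerate and the score equals its mean, and +/-Inf otherwise);
#' significance is one-sided enrichment, `z > z_threshold` strictly.
#'
#' @param net A `cell_network`.
#' @param k Pattern sizes to analyze (subset of 1:4; default `c(2, 3)`).
#' @param n_random Number of randomized networks (default 10000).
#' @param z_threshold Significance threshold on the z-score (default 1.65,
#'   one-sided 5%).
#' @param seed Optional RNG seed for reproducibility.
#' @param swap_factor Swap attempts per edge in each rewiring.
#' @param progress Print progress every 1000 null networks?
#' @return A `motif_enrichment` tibble with per-pattern columns `k`,
#'   `pattern_id`, `canonical_key`, `n_instances`, `n_mappings`, `score`,
#'   `null_mean`, `null_sd`, `z`, `significant`. Attributes `n_random`,
#'   `z_threshold` and `null_scores` (matrix of null class scores) are
#'   attached.
#' @export
#' @examples
#' net <- generate_random_network(n_nodes = 6, p_edge = 0.4, seed = 1)
#' motif_significance(net, k = 2, n_random = 200, seed = 1)
motif_significance <- function(net, k = c(2, 3), n_random = 10000,
                               z_threshold = 1.65, seed = NULL,
                               swap_factor = 10, progress = FALSE) {
  if (n_random < 2) stop("n_random must be at least 2", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  mats <- network_matrices(net)
  n <- length(mats$nodes)
  ks <- sort(unique(k))
  setup <- lapply(ks, function(kk) {
    with_loops <- kk == 2
    patterns <- enumerate_patterns(kk, with_self_loops = with_loops)
    list(patterns = patterns, feasible = kk <= n,
         six = if (kk <= n) motif_subset_index(n, kk, with_loops),
         code_map = pattern_code_map(patterns))
  })
  empty_cl <- list(rows = integer(), mean_weight = numeric())
  real <- dplyr::bind_rows(lapply(setup, function(s) {
    cl <- if (s$feasible) {
      classify_subsets(mats$A, mats$W, s$six, s$code_map)
    } else {
      empty_cl
    }
    summarize_classes(s$patterns, cl)
  }))
  null_scores <- matrix(0, n_random, nrow(real))
  for (r in seq_len(n_random)) {
    rw <- rewire_matrices(mats$A, net$weight, swap_factor)
    null_scores[r, ] <- unlist(lapply(setup, function(s) {
      cl <- if (s$feasible) {
        classify_subsets(rw$A, rw$W, s$six, s$code_map)
      } else {
        empty_cl
      }
      summarize_classes(s$patterns, cl)$score
    }))
    if (progress && r %% 1000 == 0) {
      message("null networks: ", r, " / ", n_random)
    }
  }
  null_mean <- colMeans(null_scores)
  null_sd <- apply(null_scores, 2, stats::sd)
  diff <- real$score - null_mean
  z <- ifelse(null_sd > 0, diff / null_sd,
              ifelse(abs(diff) < 1e-12, 0, sign(diff) * Inf))
  out <- dplyr::mutate(real, null_mean = null_mean, null_sd = null_sd,
                       z = z, significant = z > z_threshold)
  attr(out, "n_random") <- n_random
  attr(out, "z_threshold") <- z_threshold
  attr(out, "null_scores") <- null_scores
  class(out) <- c("motif_enrichment", class(out))
  out
}

#' @rdname motif_significance
#' @param x A `motif_enrichment` object.
#' @param ... Unused.
#' @export
tidy.motif_enrichment <- function(x, ...) {
  tibble::as_tibble(x)
}

#' z-scores of real pattern scores against null samples
#'
#' Standalone scoring step of the motif census: compares per-pattern real
#' scores with columns of a null-sample matrix. Degenerate nulls (zero
#' standard deviation) give z = 0 when the real score equals the null mean
#' and a signed infinity otherwise.
#'
#' @param real_scores Named numeric vector of per-pattern scores.
#' @param null_samples Matrix of null scores, one column per pattern in the
#'   same order (>= 2 rows).
#' @param z_threshold One-sided significance threshold (default 1.65).
#' @return A tibble with columns `pattern`, `score`, `null_mean`, `null_sd`,
#'   `z`, `significant`.
#' @export
motif_zscores <- function(real_scores, null_samples, z_threshold = 1.65) {
  null_samples <- as.matrix(null_samples)
  if (length(real_scores) != ncol(null_samples)) {
    stop("pattern sets of real scores and null samples do not match",
         call. = FALSE)
  }
  if (nrow(null_samples) < 2) {
    stop("need at least 2 null samples per pattern", call. = FALSE)
  }
  mu <- colMeans(null_samples)
  sdv <- apply(null_samples, 2, stats::sd)
  diff <- unname(real_scores) - mu
  z <- ifelse(sdv > 0, diff / sdv,
              ifelse(abs(diff) < 1e-12, 0, sign(diff) * Inf))
  tibble::tibble(
    pattern = if (!is.null(names(real_scores))) names(real_scores)
              else paste0("pattern_", seq_along(real_scores)),
    score = unname(real_scores), null_mean = mu, null_sd = sdv,
    z = z, significant = z > z_threshold)
}
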