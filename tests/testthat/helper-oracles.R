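# Independent brute-force oracles. These deliberately avoid the package's
# canonicalization and matching code paths: orbits are computed by explicit
# permutation of full adjacency matrices, and subgraph matching by explicit
# enumeration of injective node mappings.

oracle_perms <- function(k) {
  if (k == 1) return(list(1L))
  unlist(lapply(seq_len(k), function(i) {
    lapply(oracle_perms(k - 1), function(p) c(i, seq_len(k)[-i][p]))
  }), recursive = FALSE)
}

oracle_weak_conn <- function(adj) {
  k <- nrow(adj)
  if (k == 1) return(TRUE)
  u <- (adj | t(adj))
  diag(u) <- FALSE
  reach <- u
  for (i in seq_len(k)) reach <- reach | (reach %*% u > 0)
  all(reach[1, -1] | FALSE)
}

# Count isomorphism classes of k-node digraphs, connected via inter-node
# edges, by collecting one representative per permutation orbit.
oracle_count_patterns <- function(k, with_self_loops) {
  cells <- which(if (with_self_loops) matrix(TRUE, k, k) else
    row(diag(k)) != col(diag(k)))
  perms <- oracle_perms(k)
  seen <- character(0)
  count <- 0
  for (code in 0:(2^length(cells) - 1)) {
    adj <- matrix(0L, k, k)
    adj[cells] <- as.integer(intToBits(code))[seq_along(cells)]
    if (k >= 2 && sum(adj) - sum(diag(adj)) == 0) next
    if (!oracle_weak_conn(adj)) next
    orbit <- vapply(perms, function(p) {
      paste(adj[p, p], collapse = "")
    }, character(1))
    rep_key <- min(orbit)
    if (!rep_key %in% seen) {
      seen <- c(seen, rep_key)
      count <- count + 1
    }
  }
  count
}

# All induced instances of a pattern in a weighted digraph, by exhaustive
# injective mappings; distinct node sets deduplicated. Returns a data frame
# with sorted node-set keys and mean mapped-edge weight.
oracle_find_instances <- function(W, pattern_adj, loops_matter) {
  n <- nrow(W)
  k <- nrow(pattern_adj)
  A <- (W > 0) * 1L
  if (k > n) return(data.frame(key = character(0), mean_w = numeric(0)))
  subsets <- utils::combn(n, k, simplify = FALSE)
  perms <- oracle_perms(k)
  out <- list()
  for (nodes in subsets) {
    for (p in perms) {
      mapped <- nodes[p]
      ok <- TRUE
      ws <- numeric(0)
      for (i in seq_len(k)) {
        for (j in seq_len(k)) {
          if (i == j && !loops_matter) next
          if (A[mapped[i], mapped[j]] != pattern_adj[i, j]) {
            ok <- FALSE
            break
          }
          if (pattern_adj[i, j] == 1) ws <- c(ws, W[mapped[i], mapped[j]])
        }
        if (!ok) break
      }
      if (ok) {
        key <- paste(sort(nodes), collapse = "-")
        if (is.null(out[[key]])) out[[key]] <- mean(ws)
        break   # one match per node set is enough (dedup automorphisms)
      }
    }
  }
  data.frame(key = names(out), mean_w = unname(unlist(out)),
             stringsAsFactors = FALSE)
}

# Weighted random adjacency for oracle cross-checks.
oracle_random_W <- function(n, p_edge = 0.4, seed = 1) {
  set.seed(seed)
  A <- matrix(runif(n * n) < p_edge, n, n)
  W <- matrix(0, n, n)
  W[A] <- round(runif(sum(A), 0.5, 5), 2)
  dimnames(W) <- list(paste0("N", 1:n), paste0("N", 1:n))
  W
}

net_from_W <- function(W) {
  idx <- which(W > 0, arr.ind = TRUE)
  nodes <- rownames(W)
  as_cell_network(
    data.frame(sender = nodes[idx[, 1]], receiver = nodes[idx[, 2]],
               weight = W[idx]),
    nodes = nodes)
}

# Relative error with a small absolute floor so exactly-zero true values
# (e.g. r_M = 0 in the cancer regime) are compared on a sensible scale.
expect_rel_equal <- function(actual, expected, tol) {
  expect_lt(max(abs(actual - expected) / pmax(abs(expected), 1e-2)), tol)
}
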