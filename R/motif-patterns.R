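# All permutations of 1:k (k small).
perms_of <- function(k) {
  if (k == 1) return(list(1L))
  out <- list()
  for (i in seq_len(k)) {
    for (p in perms_of(k - 1)) {
      rest <- seq_len(k)[-i]
      out[[length(out) + 1]] <- c(i, rest[p])
    }
  }
  out
}

# Label-invariant canonical key of a k x k binary adjacency matrix
# (diagonal = self-loops): lexicographically smallest column-major bit string
# over all node permutations.
pattern_canonical_key <- function(adj) {
  k <- nrow(adj)
  keys <- vapply(perms_of(k), function(p) {
    paste(as.integer(adj[p, p, drop = FALSE]), collapse = "")
  }, character(1))
  paste0("k", k, ":", min(keys))
}

pattern_automorphisms <- function(adj) {
  k <- nrow(adj)
  sum(vapply(perms_of(k), function(p) {
    identical(as.integer(adj[p, p, drop = FALSE]), as.integer(adj))
  }, logical(1)))
}

# Weak connectivity via inter-node edges only (self-loops ignored).
weakly_connected <- function(adj) {
  k <- nrow(adj)
  if (k == 1) return(TRUE)
  u <- (adj | t(adj))
  diag(u) <- FALSE
  seen <- c(TRUE, rep(FALSE, k - 1))
  repeat {
    new <- seen | apply(u[seen, , drop = FALSE], 2, any)
    if (all(new == seen)) break
    seen <- new
  }
  all(seen)
}

# Cell positions (column-major linear indices into a k x k matrix) tracked by
# a pattern family: off-diagonal cells first, then the diagonal if self-loops
# are part of the pattern classes.
pattern_cells <- function(k, with_self_loops) {
  m <- matrix(seq_len(k * k), k, k)
  cells <- m[row(m) != col(m)]
  if (with_self_loops) cells <- c(cells, diag(m))
  cells
}

#' Enumerate directed circuit patterns
#'
#' Exhaustively enumerates the isomorphism classes of k-node directed
#' patterns that are weakly connected through their inter-node edges. When
#' `with_self_loops = TRUE` the autocrine self-loop configuration is part of
#' the class (for two-cell circuits this yields the 7 possible patterns);
#' when `FALSE` classes are defined by inter-node edge structure alone (13
#' classes of three-cell circuits).
#'
#' @param k Number of nodes (1 to 4).
#' @param with_self_loops Do self-loops distinguish pattern classes?
#' @param connected_only Keep only patterns weakly connected via inter-node
#'   edges (default TRUE).
#' @return A `motif_patterns` tibble with columns `k`, `pattern_id`,
#'   `canonical_key`, `n_inter_edges`, `n_self_loops`, `n_automorphisms` and
#'   a list-column `adj` of binary adjacency matrices (diagonal =
#'   self-loops). Rows are in deterministic canonical-key order. The
#'   `with_self_loops` flag is carried as an attribute.
#' @export
#' @examples
#' nrow(enumerate_patterns(2, with_self_loops = TRUE))   # 7
#' nrow(enumerate_patterns(3, with_self_loops = FALSE))  # 13
enumerate_patterns <- function(k, with_self_loops, connected_only = TRUE) {
  if (!k %in% 1:4) stop("k must be 1, 2, 3 or 4", call. = FALSE)
  cells <- pattern_cells(k, with_self_loops)
  n_cells <- length(cells)
  seen <- new.env(parent = emptyenv())
  reps <- list()
  for (code in 0:(2^n_cells - 1)) {
    bits <- as.integer(intToBits(code))[seq_len(max(n_cells, 1))]
    adj <- matrix(0L, k, k)
    adj[cells] <- bits[seq_len(n_cells)]
    if (connected_only && !weakly_connected(adj)) next
    if (k >= 2 && connected_only && sum(adj) - sum(diag(adj)) == 0) next
    key <- pattern_canonical_key(adj)
    if (is.null(seen[[key]])) {
      seen[[key]] <- TRUE
      reps[[length(reps) + 1]] <- list(key = key, adj = adj)
    }
  }
  keys <- vapply(reps, `[[`, character(1), "key")
  ord <- order(keys)
  reps <- reps[ord]
  out <- tibble::tibble(
    k = k,
    pattern_id = paste0("k", k, "_", sprintf("%02d", seq_along(reps))),
    canonical_key = vapply(reps, `[[`, character(1), "key"),
    n_inter_edges = vapply(reps, function(r) {
      sum(r$adj) - sum(diag(r$adj))
    }, numeric(1)),
    n_self_loops = vapply(reps, function(r) sum(diag(r$adj)), numeric(1)),
    n_automorphisms = vapply(reps, function(r) {
      pattern_automorphisms(r$adj)
    }, numeric(1)),
    adj = lapply(reps, `[[`, "adj"))
  attr(out, "with_self_loops") <- with_self_loops
  class(out) <- c("motif_patterns", class(out))
  out
}

# Map every raw configuration code (bits over pattern_cells in order, bit i
# weighted 2^(i-1)) to its pattern row index, or NA for configurations that
# belong to no enumerated class. Used for O(1) classification of induced
# subgraph configurations.
pattern_code_map <- function(patterns) {
  k <- patterns$k[1]
  with_self_loops <- attr(patterns, "with_self_loops")
  cells <- pattern_cells(k, with_self_loops)
  n_cells <- length(cells)
  map <- rep(NA_integer_, 2^n_cells)
  key_to_row <- stats::setNames(seq_len(nrow(patterns)),
                                patterns$canonical_key)
  for (code in 0:(2^n_cells - 1)) {
    bits <- as.integer(intToBits(code))[seq_len(n_cells)]
    adj <- matrix(0L, k, k)
    adj[cells] <- bits
    row <- key_to_row[pattern_canonical_key(adj)]
    if (!is.na(row)) map[code + 1] <- row
  }
  map
}
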