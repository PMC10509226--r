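#' Read a cell-cell interaction-strength matrix
#'
#' Reads a square CSV matrix of cumulative ligand-receptor interaction
#' scores: first row and first column carry the cell-type labels, the body is
#' numeric, rows are senders, columns receivers, and the diagonal holds
#' autocrine strengths. Empty cells are treated as zero.
#'
#' @param path Path to a CSV file.
#' @return A numeric matrix with identical row and column names (the
#'   validated interaction matrix).
#' @export
read_interaction_matrix <- function(path) {
  raw <- utils::read.csv(path, row.names = 1, check.names = FALSE)
  W <- as.matrix(raw)
  if (!is.numeric(W)) {
    stop("interaction matrix body must be numeric", call. = FALSE)
  }
  W[is.na(W)] <- 0
  validate_interaction_matrix(W)
}

#' Validate an interaction matrix
#'
#' @param W A square numeric matrix with matching row/column cell-type
#'   labels; entries are non-negative interaction strengths.
#' @return The matrix, invisibly validated.
#' @export
validate_interaction_matrix <- function(W) {
  if (!is.matrix(W) || nrow(W) != ncol(W)) {
    stop("interaction matrix must be square", call. = FALSE)
  }
  if (is.null(rownames(W)) || is.null(colnames(W))) {
    stop("interaction matrix must carry cell-type labels", call. = FALSE)
  }
  if (anyDuplicated(rownames(W)) || anyDuplicated(colnames(W))) {
    stop("cell-type labels must be unique", call. = FALSE)
  }
  if (!identical(rownames(W), colnames(W))) {
    stop("row and column labels must match (senders = receivers)",
         call. = FALSE)
  }
  if (any(!is.finite(W)) || any(W < 0)) {
    stop("interaction strengths must be finite and non-negative",
         call. = FALSE)
  }
  W
}

#' Build the filtered weighted directed cell network
#'
#' Turns an interaction matrix into a weighted directed graph (self-loops
#' represent autocrine signaling) and excludes the weak interactions that
#' collectively contribute up to `weak_fraction` of the total interaction
#' weight: candidate edges are sorted by ascending weight (ties broken by
#' lexicographic (sender, receiver) order) and removed greedily while the
#' cumulative removed weight stays within the budget
#' `weak_fraction * total weight`. Zero cells never become edges.
#'
#' @param W A validated interaction matrix (see
#'   [validate_interaction_matrix()]), or a data frame convertible to one.
#' @param weak_fraction Fraction of total weight to prune, in `[0, 1)`
#'   (default 0.10).
#' @return A `cell_network`: a tibble with columns `sender`, `receiver`,
#'   `weight` (> 0) and a `nodes` attribute holding all cell-type labels
#'   (isolated nodes included).
#' @export
#' @examples
#' W <- matrix(c(4.5, 0.5, 0.5, 4.5), 2, 2,
#'             dimnames = list(c("A", "B"), c("A", "B")))
#' build_cell_network(W)  # the two 0.5 edges fall inside the 10% budget
build_cell_network <- function(W, weak_fraction = 0.10) {
  if (is.data.frame(W)) W <- as.matrix(W)
  W <- validate_interaction_matrix(W)
  if (!is.numeric(weak_fraction) || length(weak_fraction) != 1 ||
      weak_fraction < 0 || weak_fraction >= 1) {
    stop("weak_fraction must be in [0, 1)", call. = FALSE)
  }
  labels <- rownames(W)
  idx <- which(W > 0, arr.ind = TRUE)
  edges <- tibble::tibble(sender = labels[idx[, 1]],
                          receiver = labels[idx[, 2]],
                          weight = W[idx])
  if (nrow(edges) > 0) {
    edges <- dplyr::arrange(edges, .data$weight, .data$sender, .data$receiver)
    budget <- weak_fraction * sum(edges$weight)
    removable <- cumsum(edges$weight) <= budget
    edges <- edges[!removable, , drop = FALSE]
    edges <- dplyr::arrange(edges, .data$sender, .data$receiver)
  }
  as_cell_network(edges, nodes = labels)
}

#' Construct a cell network from an edge table
#'
#' @param edges A data frame with columns `sender`, `receiver`, `weight`.
#' @param nodes Character vector of node names; defaults to the nodes seen in
#'   `edges`. Isolated nodes are allowed.
#' @return A `cell_network` tibble (see [build_cell_network()]).
#' @export
as_cell_network <- function(edges, nodes = NULL) {
  edges <- tibble::as_tibble(edges)[c("sender", "receiver", "weight")]
  if (is.null(nodes)) nodes <- sort(unique(c(edges$sender, edges$receiver)))
  if (anyDuplicated(paste(edges$sender, edges$receiver, sep = "\r"))) {
    stop("duplicate (sender, receiver) pairs are not allowed", call. = FALSE)
  }
  if (any(edges$weight <= 0) || any(!is.finite(edges$weight))) {
    stop("edge weights must be finite and strictly positive", call. = FALSE)
  }
  if (!all(c(edges$sender, edges$receiver) %in% nodes)) {
    stop("edge endpoints must belong to the node set", call. = FALSE)
  }
  structure(edges, nodes = as.character(nodes),
            class = c("cell_network", class(edges)))
}

#' Nodes of a cell network
#' @param net A `cell_network`.
#' @return Character vector of node names.
#' @export
network_nodes <- function(net) attr(net, "nodes")

#' Weighted node strengths and the network root
#'
#' Weighted out-degree and in-degree per node (self-loops count in both),
#' with the root flagged as the node of highest weighted out-degree (ties
#' broken lexicographically) -- the apex of the signaling hierarchy.
#'
#' @param net A `cell_network`.
#' @return A tibble with columns `node`, `out_strength`, `in_strength`,
#'   `is_root`, sorted by decreasing `out_strength`.
#' @export
node_strengths <- function(net) {
  nodes <- network_nodes(net)
  if (length(nodes) == 0) stop("network has no nodes", call. = FALSE)
  out_s <- tapply(net$weight, factor(net$sender, levels = nodes), sum,
                  default = 0)
  in_s <- tapply(net$weight, factor(net$receiver, levels = nodes), sum,
                 default = 0)
  res <- tibble::tibble(node = nodes,
                        out_strength = as.numeric(out_s),
                        in_strength = as.numeric(in_s))
  root <- res$node[order(-res$out_strength, res$node)][1]
  res$is_root <- res$node == root
  dplyr::arrange(res, -.data$out_strength, .data$node)
}

# adjacency (logical) and weight matrices of a network, nodes in fixed order
network_matrices <- function(net) {
  nodes <- network_nodes(net)
  n <- length(nodes)
  W <- matrix(0, n, n, dimnames = list(nodes, nodes))
  W[cbind(match(net$sender, nodes), match(net$receiver, nodes))] <- net$weight
  list(nodes = nodes, W = W, A = W > 0)
}
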