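#' @useDynLib netbackbone, .registration = TRUE
#' @importFrom Rcpp evalCpp
NULL

# ---------------------------------------------------------------------------
# Network: an undirected graph with optional nonnegative edge weights.
# Stored as an ordered node-label vector plus a canonical edge table
# (i < j, sorted), so identical graphs always have identical internal
# representations regardless of input order.
# ---------------------------------------------------------------------------

new_network <- function(nodes, i, j, w, loops_dropped = 0L) {
  nodes <- as.character(nodes)
  i <- as.integer(i)
  j <- as.integer(j)
  w <- as.numeric(w)
  stopifnot(length(i) == length(j), length(w) == length(i))
  flip <- i > j
  if (any(flip)) {
    tmp <- i[flip]
    i[flip] <- j[flip]
    j[flip] <- tmp
  }
  ord <- order(i, j)
  edges <- data.frame(i = i[ord], j = j[ord], w = w[ord])
  rownames(edges) <- NULL
  structure(
    list(
      nodes = nodes,
      edges = edges,
      weighted = nrow(edges) > 0 && !all(edges$w == 1 | edges$w == 0),
      loops_dropped = as.integer(loops_dropped)
    ),
    class = "nbb_network"
  )
}

#' Construct an undirected network from edge endpoints
#'
#' Builds the package's network container. Edges are undirected and stored
#' once with endpoints in canonical order; self-loops are dropped (their
#' count is kept in the load report); duplicate edges are deduplicated and
#' must carry identical weights. The network is considered weighted when at
#' least one weight lies outside \{0, 1\}.
#'
#' @param from,to vectors of node labels (coerced to character).
#' @param weight optional numeric vector of nonnegative edge weights;
#'   omitted means an unweighted network (all weights 1).
#' @param nodes optional character vector fixing the node set and its order,
#'   e.g. to preserve isolated nodes. Defaults to first-appearance order in
#'   the edge list.
#' @return An object of class `nbb_network` with fields `nodes`, `edges`
#'   (data frame of index pairs `i < j` and weight `w`), `weighted`, and
#'   `loops_dropped`.
#' @export
network <- function(from, to, weight = NULL, nodes = NULL) {
  from <- as.character(from)
  to <- as.character(to)
  if (length(from) != length(to)) stop("'from' and 'to' must have equal length")
  if (is.null(weight)) weight <- rep(1, length(from))
  weight <- as.numeric(weight)
  if (length(weight) != length(from)) stop("'weight' has wrong length")
  if (any(is.na(weight)) || any(weight < 0)) stop("negative or missing edge weight")
  if (is.null(nodes)) {
    nodes <- unique(as.vector(rbind(from, to)))
  } else {
    nodes <- as.character(nodes)
    if (!all(c(from, to) %in% nodes)) stop("edge endpoint not in supplied node set")
  }
  i <- match(from, nodes)
  j <- match(to, nodes)
  loops <- i == j
  n_loops <- sum(loops)
  i <- i[!loops]
  j <- j[!loops]
  weight <- weight[!loops]
  # deduplicate unordered pairs; duplicate weights must agree
  lo <- pmin(i, j)
  hi <- pmax(i, j)
  key <- paste(lo, hi)
  if (anyDuplicated(key)) {
    agree <- tapply(weight, key, function(v) all(v == v[1]))
    if (!all(agree)) stop("duplicate edge with conflicting weights")
    keep <- !duplicated(key)
    lo <- lo[keep]
    hi <- hi[keep]
    weight <- weight[keep]
  }
  new_network(nodes, lo, hi, weight, loops_dropped = n_loops)
}

#' @export
print.nbb_network <- function(x, ...) {
  cat(sprintf(
    "<network: %d nodes, %d edges, %s%s>\n",
    length(x$nodes), nrow(x$edges),
    if (x$weighted) "weighted" else "unweighted",
    if (x$loops_dropped > 0) sprintf(", %d loops dropped on load", x$loops_dropped) else ""
  ))
  invisible(x)
}

n_nodes <- function(net) length(net$nodes)
n_edges <- function(net) nrow(net$edges)

is_network <- function(x) inherits(x, "nbb_network")
is_incidence <- function(x) inherits(x, "nbb_incidence")

#' Node degrees and strengths
#'
#' `degrees()` counts incident edges; `strengths()` sums incident edge
#' weights (for an unweighted network the two coincide).
#' @param net an `nbb_network`.
#' @return numeric vector aligned with `net$nodes`.
#' @export
degrees <- function(net) {
  stopifnot(is_network(net))
  tabulate(c(net$edges$i, net$edges$j), nbins = n_nodes(net))
}

#' @rdname degrees
#' @export
strengths <- function(net) {
  stopifnot(is_network(net))
  s <- numeric(n_nodes(net))
  e <- net$edges
  for (col in c("i", "j")) {
    add <- tapply(e$w, e[[col]], sum)
    idx <- as.integer(names(add))
    s[idx] <- s[idx] + as.numeric(add)
  }
  s
}

# dense 0/1 adjacency matrix (integer), no dimnames
adjacency_of <- function(net) {
  n <- n_nodes(net)
  A <- matrix(0L, n, n)
  e <- net$edges
  A[cbind(e$i, e$j)] <- 1L
  A[cbind(e$j, e$i)] <- 1L
  A
}

#' Convert between the package network container and igraph
#'
#' @param net an `nbb_network`.
#' @return an igraph object with a `weight` edge attribute when the network
#'   is weighted.
#' @export
as_igraph <- function(net) {
  stopifnot(is_network(net))
  e <- net$edges
  g <- igraph::graph_from_data_frame(
    data.frame(from = net$nodes[e$i], to = net$nodes[e$j]),
    directed = FALSE,
    vertices = data.frame(name = net$nodes)
  )
  if (net$weighted) igraph::E(g)$weight <- e$w
  g
}

# ---------------------------------------------------------------------------
# BipartiteIncidence: binary agents x artifacts matrix.
# ---------------------------------------------------------------------------

#' Construct a bipartite incidence matrix
#'
#' Wraps a binary agents-by-artifacts matrix \eqn{B}. Row marginals
#' \eqn{r_i}, column marginals \eqn{c_k} and the fill \eqn{f = \sum B_{ik}}
#' satisfy \eqn{\sum r_i = \sum c_k = f} by construction.
#'
#' @param B matrix (or `Matrix`) with cells in \{0, 1\}.
#' @param agents,artifacts optional row/column labels; default to existing
#'   dimnames or positional labels.
#' @return An object of class `nbb_incidence`.
#' @export
bipartite_incidence <- function(B, agents = NULL, artifacts = NULL) {
  B <- as.matrix(B)
  storage.mode(B) <- "double"
  if (any(is.na(B)) || !all(B == 0 | B == 1)) {
    stop("non-binary incidence matrix")
  }
  agents <- as.character(agents %||% rownames(B) %||% paste0("a", seq_len(nrow(B))))
  artifacts <- as.character(artifacts %||% colnames(B) %||% paste0("t", seq_len(ncol(B))))
  stopifnot(length(agents) == nrow(B), length(artifacts) == ncol(B))
  B <- matrix(as.integer(B), nrow(B), ncol(B))
  dimnames(B) <- list(agents, artifacts)
  structure(list(B = B), class = "nbb_incidence")
}

#' @export
print.nbb_incidence <- function(x, ...) {
  cat(sprintf(
    "<bipartite incidence: %d agents x %d artifacts, fill %d>\n",
    nrow(x$B), ncol(x$B), sum(x$B)
  ))
  invisible(x)
}

incidence_matrix <- function(B) {
  stopifnot(is_incidence(B))
  B$B
}

row_marginals <- function(B) rowSums(incidence_matrix(B))
col_marginals <- function(B) colSums(incidence_matrix(B))

#' Detect the type of a source network
#'
#' Classifies an input as `"bipartite"` (an incidence matrix), `"weighted"`
#' (a network with at least one weight outside \{0,1\}) or `"unweighted"`.
#' This is the dispatch rule used by [backbone()].
#'
#' @param net an `nbb_network` or `nbb_incidence`.
#' @return one of `"bipartite"`, `"weighted"`, `"unweighted"`.
#' @export
detect_network_type <- function(net) {
  if (is_incidence(net)) return("bipartite")
  if (is_network(net)) return(if (net$weighted) "weighted" else "unweighted")
  stop("cannot detect network type: expected an nbb_network or nbb_incidence")
}

#' Project a bipartite network onto its agents
#'
#' Two agents are connected if they share at least one artifact and the edge
#' weight counts their shared artifacts: \eqn{P_{ij} = \sum_k B_{ik} B_{jk}}
#' (the off-diagonal of \eqn{B B^T}). Zero-weight pairs and the diagonal are
#' omitted; agents sharing no artifacts remain as isolated nodes.
#'
#' @param B an `nbb_incidence` with at least 2 agents.
#' @return a weighted `nbb_network` on the agents.
#' @export
project_bipartite <- function(B) {
  Bm <- incidence_matrix(B)
  if (nrow(Bm) < 2) stop("projection requires at least 2 agents")
  P <- tcrossprod(Bm)
  idx <- which(upper.tri(P) & P > 0, arr.ind = TRUE)
  new_network(rownames(Bm), idx[, 1], idx[, 2], P[idx])
}
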