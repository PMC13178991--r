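# ---------------------------------------------------------------------------
# File input/output. Edge lists are whitespace/TAB separated with an
# optional third weight column and '#' comments; matrices come in as dense
# whitespace tables or Matrix Market files; GraphML goes through igraph.
# ---------------------------------------------------------------------------

#' Read a network or bipartite incidence matrix from a file
#'
#' @param path path to an existing file.
#' @param format one of `"edgelist"`, `"adjacency"` (dense whitespace-
#'   delimited), `"mtx"` (Matrix Market), `"graphml"`.
#' @param bipartite if `TRUE` the input is interpreted as an agents-by-
#'   artifacts incidence structure (matrix formats: rows are agents;
#'   edge lists: first column agents, second artifacts) and must be binary.
#' @return an [network()] object, or a [bipartite_incidence()] when
#'   `bipartite = TRUE`. Self-loops are dropped and counted in the
#'   `loops_dropped` field; duplicate edges must agree on weight.
#' @details A square matrix input that is not symmetric (tolerance 1e-12)
#'   raises "directed input unsupported"; negative weights are rejected.
#' @export
read_network <- function(path,
                         format = c("edgelist", "adjacency", "mtx", "graphml"),
                         bipartite = FALSE) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  switch(format,
    edgelist = read_edgelist(path, bipartite),
    adjacency = {
      M <- as.matrix(utils::read.table(path, header = FALSE))
      dimnames(M) <- NULL
      if (bipartite) bipartite_incidence(M) else matrix_to_network(M)
    },
    mtx = {
      M <- as.matrix(Matrix::readMM(path))
      if (bipartite) bipartite_incidence(M) else matrix_to_network(M)
    },
    graphml = read_graphml(path, bipartite)
  )
}

read_edgelist <- function(path, bipartite = FALSE) {
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) stop("empty edge list")
  parts <- strsplit(lines, "[ \t]+")
  nf <- lengths(parts)
  if (!all(nf %in% c(2L, 3L))) stop("edge list rows must have 2 or 3 fields")
  from <- vapply(parts, `[[`, "", 1L)
  to <- vapply(parts, `[[`, "", 2L)
  w <- rep(1, length(parts))
  has_w <- nf == 3L
  if (any(has_w)) {
    w[has_w] <- as.numeric(vapply(parts[has_w], `[[`, "", 3L))
    if (any(is.na(w))) stop("non-numeric edge weight")
  }
  if (any(w < 0)) stop("negative edge weight")
  if (bipartite) {
    if (!all(w == 1)) stop("non-binary incidence when bipartite")
    agents <- unique(from)
    artifacts <- unique(to)
    B <- matrix(0L, length(agents), length(artifacts),
                dimnames = list(agents, artifacts))
    B[cbind(match(from, agents), match(to, artifacts))] <- 1L
    bipartite_incidence(B)
  } else {
    network(from, to, weight = w)
  }
}

matrix_to_network <- function(M) {
  if (nrow(M) != ncol(M)) {
    stop("adjacency matrix must be square (use bipartite = TRUE for incidence input)")
  }
  if (any(M < 0)) stop("negative edge weight")
  if (max(abs(M - t(M))) > 1e-12) stop("directed input unsupported")
  n_loops <- sum(diag(M) != 0)
  diag(M) <- 0
  nodes <- rownames(M) %||% as.character(seq_len(nrow(M)))
  idx <- which(upper.tri(M) & M != 0, arr.ind = TRUE)
  net <- new_network(nodes, idx[, 1], idx[, 2], M[idx], loops_dropped = n_loops)
  net
}

read_graphml <- function(path, bipartite = FALSE) {
  g <- igraph::read_graph(path, format = "graphml")
  if (bipartite) {
    if (!("type" %in% igraph::vertex_attr_names(g))) {
      stop("bipartite graphml requires a logical 'type' vertex attribute")
    }
    B <- as.matrix(igraph::as_biadjacency_matrix(g, types = igraph::V(g)$type))
    if (!all(B %in% c(0, 1))) stop("non-binary incidence when bipartite")
    return(bipartite_incidence(B))
  }
  el <- igraph::as_edgelist(g, names = TRUE)
  nodes <- igraph::V(g)$name %||% as.character(seq_len(igraph::vcount(g)))
  w <- if ("weight" %in% igraph::edge_attr_names(g)) igraph::E(g)$weight else NULL
  if (nrow(el) == 0) {
    return(new_network(nodes, integer(0), integer(0), numeric(0)))
  }
  network(el[, 1], el[, 2], weight = w, nodes = nodes)
}

#' Write a backbone to disk
#'
#' Edge-list output has one line per edge (`from<TAB>to`), with a third
#' `sign` column in \{+1, -1\} when the backbone is signed. GraphML output
#' carries the sign as an edge attribute. A write/read round trip returns an
#' identical edge set.
#'
#' @param result a [backbone()] result (`nbb_backbone`).
#' @param path output file path.
#' @param format `"edgelist"` or `"graphml"`.
#' @return `path`, invisibly.
#' @export
write_backbone <- function(result, path, format = c("edgelist", "graphml")) {
  format <- match.arg(format)
  stopifnot(inherits(result, "nbb_backbone"))
  bb <- result$backbone
  e <- bb$edges
  labels_from <- bb$nodes[e$i]
  labels_to <- bb$nodes[e$j]
  sgn <- result$signs
  if (format == "edgelist") {
    df <- data.frame(from = labels_from, to = labels_to)
    if (result$signed) df$sign <- sgn
    utils::write.table(df, path,
      sep = "\t", quote = FALSE,
      row.names = FALSE, col.names = FALSE
    )
  } else {
    g <- as_igraph(bb)
    if (result$signed) igraph::E(g)$sign <- sgn
    igraph::write_graph(g, path, format = "graphml")
  }
  invisible(path)
}

#' Write a network as a plain edge list / an incidence as Matrix Market
#'
#' Plain writers used by the CLI `simulate` subcommand: tab-separated
#' `from to [weight]` lines (weight column only for weighted networks), and
#' sparse Matrix Market for incidence matrices.
#'
#' @param net an `nbb_network`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_edgelist <- function(net, path) {
  stopifnot(is_network(net))
  e <- net$edges
  df <- data.frame(from = net$nodes[e$i], to = net$nodes[e$j])
  if (net$weighted) df$w <- e$w
  utils::write.table(df, path,
    sep = "\t", quote = FALSE,
    row.names = FALSE, col.names = FALSE
  )
  invisible(path)
}

#' @rdname write_edgelist
#' @param B a [bipartite_incidence()].
#' @export
write_incidence_mtx <- function(B, path) {
  Matrix::writeMM(Matrix::Matrix(incidence_matrix(B), sparse = TRUE), path)
  invisible(path)
}
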