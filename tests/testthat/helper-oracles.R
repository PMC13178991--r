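# Independent oracles and small random-input generators used across the
# suite. Everything here is deliberately naive (enumeration, set algebra,
# Monte Carlo) and shares no code with the implementation paths it checks.

# -- random inputs ----------------------------------------------------------

rand_graph <- function(n, p, seed) {
  gen_sbm(n_per_block = n, blocks = 1, p_in = p, p_out = 0, seed = seed)$network
}

rand_weighted_graph <- function(n, p, seed, wmax = 10) {
  net <- rand_graph(n, p, seed)
  ne <- nrow(net$edges)
  set.seed(seed + 1)
  net$edges$w <- stats::runif(ne, 0.1, wmax)
  net$weighted <- TRUE
  net
}

rand_incidence <- function(m, n, p, seed) {
  set.seed(seed)
  B <- matrix(as.integer(stats::runif(m * n) < p), m, n)
  bipartite_incidence(B)
}

edge_key_set <- function(net) {
  a <- net$nodes[net$edges$i]
  b <- net$nodes[net$edges$j]
  paste(pmin(a, b), pmax(a, b), sep = "~") # label-canonical unordered pairs
}

# -- Poisson-binomial by exhaustive enumeration (n <= 12) -------------------

oracle_pb_tail <- function(probs, obs, tail = "upper") {
  n <- length(probs)
  stopifnot(n <= 12)
  conf <- as.matrix(expand.grid(rep(list(0:1), n)))
  pr <- apply(conf, 1, function(x) prod(ifelse(x == 1, probs, 1 - probs)))
  tot <- rowSums(conf)
  if (tail == "upper") sum(pr[tot >= obs]) else sum(pr[tot <= obs])
}

# -- hypergeometric overlap by subset enumeration (small n) -----------------

oracle_hyper_upper <- function(n, ri, rj, obs) {
  sets_i <- utils::combn(n, ri, simplify = FALSE)
  ref_j <- seq_len(rj) # WLOG j's artifacts are 1..rj
  hits <- vapply(sets_i, function(s) length(intersect(s, ref_j)) >= obs, logical(1))
  mean(hits)
}

# -- naive per-edge structural scores ---------------------------------------

neighborhoods <- function(net) {
  n <- length(net$nodes)
  nb <- vector("list", n)
  for (r in seq_len(nrow(net$edges))) {
    i <- net$edges$i[r]
    j <- net$edges$j[r]
    nb[[i]] <- c(nb[[i]], j)
    nb[[j]] <- c(nb[[j]], i)
  }
  nb
}

oracle_escore_edge <- function(net, metric, i, j) {
  nb <- neighborhoods(net)
  n <- length(net$nodes)
  Ni <- nb[[i]]
  Nj <- nb[[j]]
  ki <- length(Ni)
  kj <- length(Nj)
  ci <- union(Ni, i)
  cj <- union(Nj, j)
  switch(metric,
    jaccard = length(intersect(ci, cj)) / length(union(ci, cj)),
    triangles = length(intersect(Ni, Nj)),
    meetmin = length(intersect(ci, cj)) / min(ki, kj),
    geometric = length(intersect(ci, cj))^2 / (ki * kj),
    hyper = {
      o <- length(intersect(Ni, Nj))
      1 - sum(stats::dhyper(o:min(ki, kj), kj, n - kj, ki))
    },
    degree_from = kj,
    quad_raw = {
      cnt <- 0
      for (u in setdiff(Ni, j)) {
        for (v in setdiff(Nj, i)) {
          if (u != v && v %in% nb[[u]]) cnt <- cnt + 1
        }
      }
      cnt
    }
  )
}

oracle_simmelian_edge <- function(net, i, j) {
  nb <- neighborhoods(net)
  tri <- function(a, b) length(intersect(nb[[a]], nb[[b]]))
  ranked <- function(a) {
    nbrs <- sort(nb[[a]])
    s <- vapply(nbrs, function(b) tri(a, b), numeric(1))
    nbrs[order(-s, nbrs)]
  }
  li <- setdiff(ranked(i), j)
  lj <- setdiff(ranked(j), i)
  kmax <- max(length(li), length(lj))
  if (kmax == 0) return(0)
  best <- 0
  for (k in seq_len(kmax)) {
    ti <- li[seq_len(min(k, length(li)))]
    tj <- lj[seq_len(min(k, length(lj)))]
    best <- max(best, length(intersect(ti, tj)) / length(union(ti, tj)))
  }
  best
}

# -- fixed-marginal matrix enumeration (small) ------------------------------

enumerate_fixed_margin <- function(r, cc) {
  m <- length(r)
  n <- length(cc)
  stopifnot(m * n <= 16)
  conf <- as.matrix(expand.grid(rep(list(0:1), m * n)))
  out <- list()
  for (row in seq_len(nrow(conf))) {
    M <- matrix(conf[row, ], m, n)
    if (all(rowSums(M) == r) && all(colSums(M) == cc)) out[[length(out) + 1]] <- M
  }
  out
}

matrix_key <- function(M) paste(as.vector(M), collapse = "")

# -- community agreement ----------------------------------------------------

ari_vs_blocks <- function(res, blocks) {
  g <- as_igraph(res$backbone)
  cl <- igraph::membership(igraph::cluster_fast_greedy(g))
  igraph::compare(cl, blocks, method = "adjusted.rand")
}
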