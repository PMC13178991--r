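# ---------------------------------------------------------------------------
# Seeded toy-network generators. Each generator reproduces one of the
# archetypal inputs the backbone models are meant for: a blocky dense
# unweighted graph, a bipartite network with embedded communities, a
# two-scale weighted hub-and-spoke system, and a hub-dominated
# preferential-attachment graph.
# ---------------------------------------------------------------------------

#' Generate a stochastic block model graph
#'
#' Every within-block pair is an edge independently with probability
#' `p_in`, every between-block pair with probability `p_out`. Defaults give
#' the classic 60-node, three-block community toy (blocks of 20,
#' p_in = 0.75, p_out = 0.25).
#'
#' @param n_per_block nodes per block.
#' @param blocks number of blocks.
#' @param p_in,p_out edge probabilities in \[0, 1\].
#' @param seed optional integer seed.
#' @return list with `network` (unweighted) and `blocks` (integer labels).
#' @export
gen_sbm <- function(n_per_block = 20, blocks = 3, p_in = 0.75, p_out = 0.25,
                    seed = NULL) {
  if (any(c(p_in, p_out) < 0) || any(c(p_in, p_out) > 1)) {
    stop("probabilities must be in [0, 1]")
  }
  n <- n_per_block * blocks
  lab <- rep(seq_len(blocks), each = n_per_block)
  idx <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  pvec <- ifelse(lab[idx[, 1]] == lab[idx[, 2]], p_in, p_out)
  hit <- with_seed(seed, stats::runif(length(pvec)) < pvec)
  net <- new_network(paste0("n", seq_len(n)), idx[hit, 1], idx[hit, 2],
                     rep(1, sum(hit)))
  list(network = net, blocks = lab)
}

#' Generate a bipartite network with embedded communities
#'
#' Agents and artifacts are split into matching blocks; agent i holds
#' artifact k with probability `p_in` inside its block and `p_out` outside.
#' The defaults (30 agents, 75 artifacts, 3 blocks, p_in = 0.65,
#' p_out = 0.04) were calibrated by pilot simulation so that the SDSM and
#' FDSM projection backbones at alpha = 0.05 recover the three planted
#' communities essentially always; they are a package choice, tunable
#' through the arguments.
#'
#' @param agents,artifacts counts (must be divisible by `blocks`).
#' @param blocks number of communities.
#' @param p_in,p_out within/between membership probabilities, `p_in > p_out`.
#' @param seed optional integer seed.
#' @return list with `incidence`, `agent_blocks`, `artifact_blocks`.
#' @export
gen_bipartite_blocks <- function(agents = 30, artifacts = 75, blocks = 3,
                                 p_in = 0.65, p_out = 0.04, seed = NULL) {
  if (agents < 1 || artifacts < 1 || agents %% blocks || artifacts %% blocks) {
    stop("agents and artifacts must be positive multiples of blocks")
  }
  if (!(p_in > p_out)) stop("p_in must exceed p_out")
  ab <- rep(seq_len(blocks), each = agents / blocks)
  tb <- rep(seq_len(blocks), each = artifacts / blocks)
  pmat <- ifelse(outer(ab, tb, `==`), p_in, p_out)
  B <- with_seed(seed, (matrix(stats::runif(agents * artifacts), agents, artifacts) < pmat) * 1L)
  dimnames(B) <- list(paste0("a", seq_len(agents)), paste0("t", seq_len(artifacts)))
  list(
    incidence = bipartite_incidence(B),
    agent_blocks = ab, artifact_blocks = tb
  )
}

#' Generate a two-scale weighted hub-and-spoke network
#'
#' Two hubs joined by a bridge edge of weight `(high_weight + low_weight)/2`;
#' hub A serves `spokes_per_hub` spokes at around `high_weight`, hub B at
#' around `low_weight` (one region carries much more volume). Spoke weights
#' get a small positive multiplicative jitter (up to `jitter`), which keeps
#' the mean edge weight strictly above the bridge weight so the
#' mean-threshold backbone is exactly the high-volume region.
#'
#' @param spokes_per_hub spokes per hub.
#' @param high_weight,low_weight regional weight scales (> 0).
#' @param jitter maximum relative jitter (>= 0).
#' @param seed optional integer seed.
#' @return a weighted network with `2 * spokes_per_hub + 2` nodes.
#' @export
gen_hub_spoke <- function(spokes_per_hub = 4, high_weight = 10, low_weight = 1,
                          jitter = 0.05, seed = NULL) {
  if (high_weight <= 0 || low_weight <= 0) stop("weights must be positive")
  ns <- spokes_per_hub
  from <- c("hubA", rep("hubA", ns), rep("hubB", ns))
  to <- c("hubB", paste0("a", seq_len(ns)), paste0("b", seq_len(ns)))
  jit <- with_seed(seed, 1 + stats::runif(2 * ns, 0, jitter))
  w <- c(
    (high_weight + low_weight) / 2,
    high_weight * jit[seq_len(ns)],
    low_weight * jit[ns + seq_len(ns)]
  )
  network(from, to, weight = w)
}

#' Generate a preferential-attachment graph
#'
#' Barabasi-Albert-style growth: starting from a complete seed graph on
#' `m_per_step + 1` nodes, each new node attaches `m_per_step` edges to
#' distinct existing nodes with probability proportional to their current
#' degree. With `m_per_step = 1` the result is a tree with n - 1 edges.
#'
#' @param n total nodes (> `m_per_step`).
#' @param m_per_step edges added per new node (>= 1). The default 3 gives
#'   the dense hub-dominated toy used for the local-degree model.
#' @param seed optional integer seed.
#' @return an unweighted network.
#' @export
gen_preferential_attachment <- function(n = 60, m_per_step = 3, seed = NULL) {
  m_per_step <- as.integer(m_per_step)
  if (m_per_step < 1 || n <= m_per_step) stop("need n > m_per_step >= 1")
  with_seed(seed, {
    n0 <- m_per_step + 1L
    fr <- utils::combn(n0, 2)
    ei <- fr[1, ]
    ej <- fr[2, ]
    deg <- rep(n0 - 1L, n0)
    for (v in seq.int(n0 + 1L, n)) {
      targets <- integer(0)
      deg_v <- c(deg, 0L)
      w <- deg_v[seq_len(v - 1L)]
      for (t in seq_len(m_per_step)) {
        pick <- sample.int(v - 1L, 1L, prob = w)
        targets <- c(targets, pick)
        w[pick] <- 0 # distinct targets
      }
      ei <- c(ei, rep(v, m_per_step))
      ej <- c(ej, targets)
      deg <- c(deg, m_per_step)
      deg[targets] <- deg[targets] + 1L
    }
    new_network(paste0("n", seq_len(n)), ei, ej, rep(1, length(ei)))
  })
}
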