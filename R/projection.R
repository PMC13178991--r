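# ---------------------------------------------------------------------------
# Statistical backbones of bipartite projections. Each model evaluates the
# observed number of shared artifacts P_ij of every agent pair against a
# null over random incidence matrices; models differ in which marginals of
# B they constrain (on average or exactly).
#
# All *_pvalues functions return statistics for every agent pair (not just
# pairs with positive projection weight): with signed retention, a pair
# sharing suspiciously *few* artifacts can enter the backbone negatively.
# ---------------------------------------------------------------------------

check_incidence <- function(B, min_agents = 2) {
  if (!is_incidence(B)) {
    stop("bipartite incidence input required (weighted/unipartite input unsupported here)")
  }
  if (nrow(B$B) < min_agents) stop("need at least ", min_agents, " agents")
  invisible(B)
}

all_pairs <- function(m) {
  idx <- which(upper.tri(matrix(0, m, m)), arr.ind = TRUE)
  list(i = idx[, 1], j = idx[, 2])
}

pair_stats <- function(B, pu, pl, model, obs) {
  m <- nrow(B$B)
  pr <- all_pairs(m)
  df <- data.frame(
    from = pr$i, to = pr$j,
    weight = obs[cbind(pr$i, pr$j)],
    p_upper = pu, p_lower = pl
  )
  new_edge_stats(df, rownames(B$B), model)
}

#' Stochastic degree sequence model (SDSM) p-values
#'
#' The null constrains the marginals of B on average: cells are independent
#' Bernoulli with the bipartite-configuration-model probabilities
#' \eqn{p_{ik}} from [bicm_fit()]. The shared-artifact count of agents
#' i and j is then Poisson-binomial with per-artifact success probability
#' \eqn{p_{ik} p_{jk}}, and the inclusive tails at the observed count are
#' the p-values.
#'
#' @param B a [bipartite_incidence()].
#' @param tol,max_iter passed to [bicm_fit()].
#' @return edge statistics over all agent pairs with columns `weight`
#'   (observed shared artifacts), `p_upper`, `p_lower`.
#' @export
sdsm_pvalues <- function(B, tol = 1e-8, max_iter = 10000) {
  check_incidence(B)
  fit <- bicm_fit(B, tol = tol, max_iter = max_iter)
  Bm <- incidence_matrix(B)
  obs <- tcrossprod(Bm)
  pr <- all_pairs(nrow(Bm))
  np <- length(pr$i)
  pu <- numeric(np)
  pl <- numeric(np)
  for (r in seq_len(np)) {
    probs <- fit$p[pr$i[r], ] * fit$p[pr$j[r], ]
    tails <- pb_tails(probs, obs[pr$i[r], pr$j[r]])
    pu[r] <- tails[["upper"]]
    pl[r] <- tails[["lower"]]
  }
  pair_stats(B, pu, pl, "sdsm", obs)
}

#' Sample a fixed-marginal matrix by curveball trades
#'
#' Runs `trades` curveball trades starting from `B`: two distinct rows are
#' chosen uniformly, the symmetric difference of their one-sets is
#' redistributed uniformly at random, preserving both row sums (and hence
#' all column sums). This is the "fastball" randomization step used by the
#' fixed degree sequence model.
#'
#' @param B a [bipartite_incidence()] with at least 2 rows.
#' @param trades number of trades (>= 1).
#' @param seed optional integer; fixing it makes the sample reproducible.
#' @return a new [bipartite_incidence()] with identical marginals.
#' @export
fastball_sample <- function(B, trades, seed = NULL) {
  check_incidence(B)
  stopifnot(trades >= 1)
  Bm <- incidence_matrix(B)
  out <- with_seed(seed, fastball_trades(Bm, as.integer(trades)))
  dimnames(out) <- dimnames(Bm)
  bipartite_incidence(out)
}

#' Fixed degree sequence model (FDSM) p-values
#'
#' The null constrains both marginals of B exactly: matrices with the
#' observed row and column sums are sampled by a serial curveball/fastball
#' Markov chain (the observed matrix is a valid state, so no separate
#' burn-in), with `trades_per_sample` trades between retained samples.
#' Add-one p-values avoid zeros:
#' \deqn{p_{upper} = (1 + \#\{P^*_{ij} \ge P_{ij}\}) / (1 + trials).}
#'
#' @param B a [bipartite_incidence()].
#' @param trials number of sampled matrices (>= 1).
#' @param seed optional integer seed; fixing it fixes the p-values exactly.
#' @param trades_per_sample trades between consecutive samples; default
#'   `max(100, 5 * nrow(B))`.
#' @return edge statistics over all agent pairs.
#' @export
fdsm_pvalues <- function(B, trials = 1000, seed = NULL, trades_per_sample = NULL) {
  check_incidence(B)
  stopifnot(trials >= 1)
  Bm <- incidence_matrix(B)
  m <- nrow(Bm)
  tps <- as.integer(trades_per_sample %||% max(100, 5 * m))
  obs <- tcrossprod(Bm)
  ge <- matrix(0L, m, m)
  le <- matrix(0L, m, m)
  with_seed(seed, {
    M <- Bm
    for (t in seq_len(trials)) {
      M <- fastball_trades(M, tps)
      Ps <- tcrossprod(M)
      ge <- ge + (Ps >= obs)
      le <- le + (Ps <= obs)
    }
  })
  pr <- all_pairs(m)
  pu <- (1 + ge[cbind(pr$i, pr$j)]) / (1 + trials)
  pl <- (1 + le[cbind(pr$i, pr$j)]) / (1 + trials)
  pair_stats(B, pu, pl, "fdsm", obs)
}

#' Fixed row model p-values
#'
#' Conditions on the row marginals only: holding agent j's artifact set
#' fixed, agent i's \eqn{r_i} artifacts are drawn uniformly without
#' replacement from the n artifacts, so the shared count is hypergeometric.
#' The model is symmetric in the pair because the hypergeometric is
#' symmetric in (draws, successes).
#'
#' @param B a [bipartite_incidence()].
#' @return edge statistics over all agent pairs.
#' @export
fixedrow_pvalues <- function(B) {
  check_incidence(B)
  Bm <- incidence_matrix(B)
  n <- ncol(Bm)
  r <- rowSums(Bm)
  obs <- tcrossprod(Bm)
  pr <- all_pairs(nrow(Bm))
  o <- obs[cbind(pr$i, pr$j)]
  ri <- r[pr$i]
  rj <- r[pr$j]
  pu <- stats::phyper(o - 1, rj, n - rj, ri, lower.tail = FALSE)
  pl <- stats::phyper(o, rj, n - rj, ri)
  pair_stats(B, pu, pl, "fixedrow", obs)
}

#' Fixed column model p-values
#'
#' Conditions on the column marginals only: artifact k, held by \eqn{c_k}
#' of the m agents, is shared by a specific pair with probability
#' \eqn{c_k (c_k - 1) / (m (m - 1))}; artifacts contribute independently,
#' giving Poisson-binomial tails (the same per-artifact probabilities for
#' every pair).
#'
#' @param B a [bipartite_incidence()] with at least 2 agents.
#' @return edge statistics over all agent pairs.
#' @export
fixedcol_pvalues <- function(B) {
  check_incidence(B)
  Bm <- incidence_matrix(B)
  m <- nrow(Bm)
  cc <- colSums(Bm)
  probs <- cc * (cc - 1) / (m * (m - 1))
  obs <- tcrossprod(Bm)
  pr <- all_pairs(m)
  o <- obs[cbind(pr$i, pr$j)]
  # one DP per distinct observed value, shared across pairs
  pu <- numeric(length(o))
  pl <- numeric(length(o))
  for (v in unique(o)) {
    tails <- pb_tails(probs, v)
    hit <- o == v
    pu[hit] <- tails[["upper"]]
    pl[hit] <- tails[["lower"]]
  }
  pair_stats(B, pu, pl, "fixedcol", obs)
}

#' Fixed fill model p-values
#'
#' Constrains only the total fill \eqn{f}: every cell is an independent
#' Bernoulli with probability \eqn{f/(mn)}, so a pair shares a given
#' artifact with probability \eqn{(f/(mn))^2} and the shared count is
#' Binomial(n, (f/(mn))^2), inclusive tails.
#'
#' @param B a [bipartite_incidence()].
#' @return edge statistics over all agent pairs.
#' @export
fixedfill_pvalues <- function(B) {
  check_incidence(B)
  Bm <- incidence_matrix(B)
  m <- nrow(Bm)
  n <- ncol(Bm)
  p2 <- (sum(Bm) / (m * n))^2
  obs <- tcrossprod(Bm)
  pr <- all_pairs(m)
  o <- obs[cbind(pr$i, pr$j)]
  pu <- stats::pbinom(o - 1, n, p2, lower.tail = FALSE)
  pl <- stats::pbinom(o, n, p2)
  pair_stats(B, pu, pl, "fixedfill", obs)
}

#' Extract the backbone of a bipartite projection
#'
#' The source network is the bipartite incidence matrix B, not its
#' projection: the projection is computed internally and the retained
#' backbone lives on the agents only. The SDSM is the default (efficient
#' and usually adequate); the FDSM is more powerful but far more
#' computationally intensive; fixedrow/fixedcol/fixedfill are included for
#' methodological comparison and generally perform worse.
#'
#' @param B a [bipartite_incidence()].
#' @param model one of `"sdsm"`, `"fdsm"`, `"fixedrow"`, `"fixedcol"`,
#'   `"fixedfill"`.
#' @param alpha significance level (default 0.05).
#' @param mtc multiple-test correction, see [adjust_pvalues()].
#' @param signed retain significantly weak pairs as negative edges.
#' @param trials,seed,trades_per_sample FDSM sampling controls, see
#'   [fdsm_pvalues()].
#' @return a `nbb_backbone` result; `edges_removed_pct` is relative to the
#'   positive-weight edges of the projection.
#' @export
backbone_from_projection <- function(B, model = c("sdsm", "fdsm", "fixedrow", "fixedcol", "fixedfill"),
                                     alpha = 0.05, mtc = "none", signed = FALSE,
                                     trials = 1000, seed = NULL,
                                     trades_per_sample = NULL) {
  model <- match.arg(model)
  check_incidence(B)
  stats <- switch(model,
    sdsm = sdsm_pvalues(B),
    fdsm = fdsm_pvalues(B, trials = trials, seed = seed, trades_per_sample = trades_per_sample),
    fixedrow = fixedrow_pvalues(B),
    fixedcol = fixedcol_pvalues(B),
    fixedfill = fixedfill_pvalues(B)
  )
  retained <- retain_edges(stats, alpha, mtc = mtc, signed = signed)
  denom <- sum(stats$weight > 0) # edges of the weighted projection
  new_backbone_result(
    retained = retained, nodes = rownames(incidence_matrix(B)), denom = denom,
    original = original_summary(B), family = "projection",
    model = model, alpha = alpha, mtc = mtc, signed = signed,
    seed = if (model == "fdsm") seed else NULL,
    trials = if (model == "fdsm") trials else NULL
  )
}
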