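# ---------------------------------------------------------------------------
# Backbones of weighted networks: one structural model (global threshold)
# and three statistical models (disparity filter, locally adaptive network
# sparsification, marginal likelihood filter).
#
# Statistical models evaluate each edge from the perspective of both of its
# endpoints; the edge-level p-value is the minimum of the two endpoint
# p-values ("retain if significant from at least one side"), with the max
# rule available as an option.
# ---------------------------------------------------------------------------

check_weighted <- function(net) {
  if (!is_network(net)) stop("expected a network")
  if (!net$weighted) stop("unweighted input: weighted-network models need edge weights")
}

combine_endpoint <- function(a, b, rule = c("min", "max")) {
  rule <- match.arg(rule)
  if (rule == "min") pmin(a, b) else pmax(a, b)
}

#' Global threshold backbone of a weighted network
#'
#' Retains exactly the edges with weight strictly larger than `threshold`
#' (ties are excluded). A structural model: the same cut is applied to every
#' edge, so multiscale structure is ignored.
#'
#' @param net a weighted network.
#' @param threshold numeric cut value.
#' @return a `nbb_backbone` result (unweighted backbone).
#' @export
global_threshold <- function(net, threshold) {
  check_weighted(net)
  stopifnot(is.numeric(threshold), length(threshold) == 1)
  e <- net$edges
  keep <- e$w > threshold
  retained <- data.frame(from = e$i[keep], to = e$j[keep], sign = rep(1L, sum(keep)))
  new_backbone_result(
    retained = retained, nodes = net$nodes, denom = n_edges(net),
    original = original_summary(net), family = "weighted",
    model = "global", parameter = threshold
  )
}

#' Disparity filter p-values
#'
#' Under the disparity null a node's strength \eqn{s_i} is split uniformly
#' at random among its \eqn{k_i} edges, so the fractional weight
#' \eqn{f_{ij} = w_{ij}/s_i} of one edge has the distribution of the minimum
#' spacing beta law, giving the endpoint upper-tail p-value
#' \deqn{p = (1 - f_{ij})^{k_i - 1}.}
#' A degree-1 endpoint carries no information (\eqn{0^0} convention):
#' its p-value is 1, so pendant edges are never retained on statistical
#' grounds alone. The null is continuous, so the endpoint lower tail is
#' \eqn{1 - p}.
#'
#' @param net a weighted network with strictly positive weights.
#' @param rule endpoint combination rule, `"min"` (default) or `"max"`.
#' @return edge statistics with per-endpoint columns (`p_upper_from`,
#'   `p_upper_to`, ...) and combined `p_upper` / `p_lower`.
#' @export
disparity_pvalues <- function(net, rule = "min") {
  check_weighted(net)
  e <- net$edges
  if (any(e$w <= 0)) stop("disparity filter requires strictly positive weights")
  k <- degrees(net)
  s <- strengths(net)
  endpoint <- function(idx) {
    ki <- k[idx]
    f <- e$w / s[idx]
    ifelse(ki <= 1, 1, (1 - f)^(ki - 1))
  }
  pu_i <- endpoint(e$i)
  pu_j <- endpoint(e$j)
  df <- data.frame(
    from = e$i, to = e$j, weight = e$w,
    p_upper_from = pu_i, p_upper_to = pu_j,
    p_lower_from = 1 - pu_i, p_lower_to = 1 - pu_j,
    p_upper = combine_endpoint(pu_i, pu_j, rule),
    p_lower = combine_endpoint(1 - pu_i, 1 - pu_j, rule)
  )
  new_edge_stats(df, net$nodes, "disparity")
}

#' Locally adaptive network sparsification p-values
#'
#' The endpoint p-value is the inclusive empirical upper tail of the
#' fractional edge weight among the endpoint's own edges:
#' \eqn{p = \#\{l : f_{il} \ge f_{ij}\} / k_i} (which includes the edge
#' itself, so \eqn{p \ge 1/k_i}). The lower tail counts \eqn{\le} instead.
#'
#' @inheritParams disparity_pvalues
#' @return edge statistics as in [disparity_pvalues()].
#' @export
lans_pvalues <- function(net, rule = "min") {
  check_weighted(net)
  e <- net$edges
  k <- degrees(net)
  s <- strengths(net)
  ne <- nrow(e)
  # fractional weight of each edge from each endpoint's perspective
  f_i <- e$w / s[e$i]
  f_j <- e$w / s[e$j]
  # incidence lists: for each node, the fractional weights of its edges
  node_of <- c(e$i, e$j)
  f_of <- c(f_i, f_j)
  fracs <- split(f_of, node_of)
  tail_count <- function(idx, f, op) {
    vapply(seq_len(ne), function(r) {
      v <- fracs[[as.character(idx[r])]]
      sum(op(v, f[r]))
    }, numeric(1))
  }
  pu_i <- tail_count(e$i, f_i, `>=`) / k[e$i]
  pu_j <- tail_count(e$j, f_j, `>=`) / k[e$j]
  pl_i <- tail_count(e$i, f_i, `<=`) / k[e$i]
  pl_j <- tail_count(e$j, f_j, `<=`) / k[e$j]
  df <- data.frame(
    from = e$i, to = e$j, weight = e$w,
    p_upper_from = pu_i, p_upper_to = pu_j,
    p_lower_from = pl_i, p_lower_to = pl_j,
    p_upper = combine_endpoint(pu_i, pu_j, rule),
    p_lower = combine_endpoint(pl_i, pl_j, rule)
  )
  new_edge_stats(df, net$nodes, "lans")
}

#' Marginal likelihood filter p-values
#'
#' The total integer weight \eqn{T = \sum_{(i,j)} w_{ij}} is treated as T
#' independent weight units, each joining nodes i and j with probability
#' \eqn{q_{ij} = s_i s_j / (2 T^2)}. The edge weight is then
#' \eqn{X \sim \mathrm{Binomial}(T, q_{ij})} under the null, and the
#' inclusive tails \eqn{P(X \ge w_{ij})} / \eqn{P(X \le w_{ij})} are the
#' p-values (no endpoint split: the null is already a property of the pair).
#'
#' @param net a weighted network with positive integer weights. Non-integer
#'   weights raise an error instructing the user to rescale; no silent
#'   rounding is performed.
#' @return edge statistics with `p_upper` / `p_lower`.
#' @export
mlf_pvalues <- function(net) {
  # unlike disparity/lans, all-unit weights are meaningful here (each edge
  # carries an integer number of weight units), so only the integer
  # constraint is enforced
  if (!is_network(net)) stop("expected a network")
  e <- net$edges
  if (any(e$w != round(e$w)) || any(e$w < 1)) {
    stop("mlf requires positive integer weights; rescale your weights to integers first")
  }
  s <- strengths(net)
  T_ <- sum(e$w)
  q <- pmin(1, s[e$i] * s[e$j] / (2 * T_^2))
  df <- data.frame(
    from = e$i, to = e$j, weight = e$w,
    p_upper = stats::pbinom(e$w - 1, T_, q, lower.tail = FALSE),
    p_lower = stats::pbinom(e$w, T_, q)
  )
  new_edge_stats(df, net$nodes, "mlf")
}

#' Extract the backbone of a weighted network
#'
#' Dispatches to one of the four weighted-network models and then applies
#' the retention rule. `"global"` is structural and takes `parameter` (the
#' threshold); the statistical models take `alpha` (default 0.05).
#' Supplying the wrong control argument for the model is an error.
#'
#' @param net a weighted network.
#' @param model `"disparity"` (default), `"global"`, `"lans"`, or `"mlf"`.
#' @param alpha significance level for the statistical models.
#' @param parameter threshold for the global model.
#' @param mtc multiple-test correction, see [adjust_pvalues()].
#' @param signed retain significantly weak edges as negative (statistical
#'   models only).
#' @return a `nbb_backbone` result.
#' @export
backbone_from_weighted <- function(net, model = c("disparity", "global", "lans", "mlf"),
                                   alpha = NULL, parameter = NULL,
                                   mtc = "none", signed = FALSE) {
  model <- match.arg(model)
  check_weighted(net)
  if (model == "global") {
    if (!is.null(alpha)) stop("'alpha' does not apply to the structural global model; use 'parameter'")
    if (is.null(parameter)) stop("global threshold model needs 'parameter'")
    if (signed) stop("the global threshold model has no lower tail; signed = TRUE unsupported")
    return(global_threshold(net, parameter))
  }
  if (!is.null(parameter)) stop("'parameter' applies to structural models only; use 'alpha'")
  alpha <- alpha %||% 0.05
  stats <- switch(model,
    disparity = disparity_pvalues(net),
    lans = lans_pvalues(net),
    mlf = mlf_pvalues(net)
  )
  retained <- retain_edges(stats, alpha, mtc = mtc, signed = signed)
  new_backbone_result(
    retained = retained, nodes = net$nodes, denom = n_edges(net),
    original = original_summary(net), family = "weighted",
    model = model, alpha = alpha, mtc = mtc, signed = signed
  )
}

original_summary <- function(x) {
  if (is_incidence(x)) {
    list(
      type = "bipartite", agents = nrow(x$B), artifacts = ncol(x$B),
      nodes = nrow(x$B) + ncol(x$B), edges = sum(x$B)
    )
  } else {
    list(type = detect_network_type(x), nodes = n_nodes(x), edges = n_edges(x))
  }
}
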