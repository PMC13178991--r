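# ---------------------------------------------------------------------------
# Structural backbones of unweighted networks: a four-step framework
# (edge scoring -> optional local rank normalization -> filtering ->
# optional union of maximum spanning trees), with the named models as
# preset combinations of the steps.
#
# Conventions (documented, switchable only by editing the metric):
#  * jaccard/meetmin/geometric use CLOSED neighborhoods N[i] = N(i) u {i},
#    so edges inside a clique score 1 under jaccard;
#  * the hypergeometric metric uses OPEN-neighborhood overlap with
#    population = total node count;
#  * local ranks are 1..k_i with ties broken by neighbor position in the
#    node order (determinism over hash order).
# ---------------------------------------------------------------------------

check_unweighted <- function(net) {
  if (!is_network(net)) stop("expected a network")
  if (net$weighted) stop("weighted input: unweighted-network models need a binary network")
}

#' Score the edges of an unweighted network
#'
#' Assigns each edge a structural score, the first step of the unweighted
#' backbone framework. Most metrics are symmetric; `degree` is directional
#' (the score of edge i-j seen from i is the neighbor's degree k_j), so
#' per-endpoint columns `score_from` / `score_to` are returned alongside
#' the symmetric summary `score` (their maximum).
#'
#' Metrics: `jaccard` = closed-neighborhood intersection over union;
#' `triangles` = common-neighbor count; `degree` = neighbor degree
#' (directional); `meetmin` = closed intersection / min(k_i, k_j);
#' `geometric` = closed intersection squared / (k_i k_j); `hyper` = one
#' minus the inclusive upper hypergeometric tail of the open-neighborhood
#' overlap (population = node count, successes = k_j, draws = k_i);
#' `quadrangles` = 4-cycle support \eqn{Q_{ij}/\sqrt{Q_i Q_j}} where
#' \eqn{Q_{ij}} counts 4-cycles through the edge and
#' \eqn{Q_i = \sum_j Q_{ij}}; `random` = i.i.d. Uniform(0,1) per edge
#' (seeded).
#'
#' @param net an unweighted network.
#' @param metric one of the names above.
#' @param seed optional seed for `metric = "random"`.
#' @return edge statistics with `score_from`, `score_to`, `score`.
#' @export
escore <- function(net,
                   metric = c("jaccard", "triangles", "degree", "meetmin",
                              "geometric", "hyper", "quadrangles", "random"),
                   seed = NULL) {
  metric <- match.arg(metric)
  check_unweighted(net)
  e <- net$edges
  n <- n_nodes(net)
  ne <- nrow(e)
  A <- adjacency_of(net)
  k <- rowSums(A)
  ki <- k[e$i]
  kj <- k[e$j]
  cn <- if (metric %in% c("jaccard", "triangles", "meetmin", "geometric", "hyper", "quadrangles")) {
    CN <- A %*% A
    CN[cbind(e$i, e$j)] # open common-neighbor count per edge
  }
  s_from <- s_to <- switch(metric,
    jaccard = {
      inter <- cn + 2 # closed: both endpoints join the intersection
      uni <- ki + kj - cn # |N[i] u N[j]|
      inter / uni
    },
    triangles = cn,
    meetmin = (cn + 2) / pmin(ki, kj),
    geometric = (cn + 2)^2 / (ki * kj),
    hyper = 1 - stats::phyper(cn - 1, kj, n - kj, ki, lower.tail = FALSE),
    quadrangles = {
      A3 <- A %*% A %*% A
      Qij <- A3[cbind(e$i, e$j)] - ki - kj + 1 # 4-cycles through the edge
      Qi <- numeric(n)
      for (col in c("i", "j")) {
        add <- tapply(Qij, e[[col]], sum)
        idx <- as.integer(names(add))
        Qi[idx] <- Qi[idx] + as.numeric(add)
      }
      ifelse(Qi[e$i] * Qi[e$j] > 0, Qij / sqrt(Qi[e$i] * Qi[e$j]), 0)
    },
    random = with_seed(seed, stats::runif(ne)),
    degree = NULL
  )
  if (metric == "degree") {
    s_from <- kj
    s_to <- ki
  }
  df <- data.frame(
    from = e$i, to = e$j,
    score_from = s_from, score_to = s_to,
    score = pmax(s_from, s_to)
  )
  st <- new_edge_stats(df, net$nodes, paste0("escore:", metric))
  attr(st, "metric") <- metric
  st
}

#' Locally rank edge scores
#'
#' With `method = "rank"`, each node sorts its incident edges by score
#' (from its own perspective) in decreasing order and assigns ranks
#' 1..k_i; ties are broken by the neighbor's position in the node order.
#' `method = "none"` is the identity.
#'
#' @param stats edge statistics from [escore()].
#' @param method `"rank"` or `"none"`.
#' @return `stats`, with `rank_from` / `rank_to` columns when ranked.
#' @export
normalize_scores <- function(stats, method = c("none", "rank")) {
  method <- match.arg(method)
  if (method == "none") return(stats)
  if (!all(c("score_from", "score_to") %in% names(stats))) stop("scores absent")
  ne <- nrow(stats)
  long <- data.frame(
    node = c(stats$from, stats$to),
    nb = c(stats$to, stats$from),
    s = c(stats$score_from, stats$score_to),
    row = rep(seq_len(ne), 2L),
    side = rep(c(1L, 2L), each = ne)
  )
  ord <- order(long$node, -long$s, long$nb)
  long <- long[ord, ]
  rk <- stats::ave(seq_len(nrow(long)), long$node, FUN = seq_along)
  stats$rank_from <- NA_integer_
  stats$rank_to <- NA_integer_
  from_side <- long$side == 1L
  stats$rank_from[long$row[from_side]] <- rk[from_side]
  stats$rank_to[long$row[!from_side]] <- rk[!from_side]
  stats
}

#' Filter edges by score
#'
#' `threshold` keeps edges with `score >= parameter`; `proportion` keeps
#' the top `floor(parameter * |E|)` edges globally (ties broken by stable
#' edge order); `degree` lets node i nominate its `ceiling(k_i^parameter)`
#' best-ranked edges, and keeps an edge nominated by at least one endpoint
#' (which guarantees minimum degree >= 1 on non-isolated nodes).
#'
#' @param stats edge statistics ([normalize_scores()] output with
#'   `method = "rank"` is required for the degree filter).
#' @param method `"threshold"`, `"proportion"`, or `"degree"`.
#' @param parameter threshold value, retained fraction in \[0, 1\], or
#'   degree exponent in \[0, 1\].
#' @return data frame of kept edges (`from`, `to`).
#' @export
filter_edges <- function(stats, method = c("threshold", "proportion", "degree"),
                         parameter) {
  method <- match.arg(method)
  if (missing(parameter) || is.null(parameter)) stop("parameter missing")
  keep <- switch(method,
    threshold = stats$score >= parameter,
    proportion = {
      if (parameter < 0 || parameter > 1) stop("proportion parameter must be in [0, 1]")
      nkeep <- floor(parameter * nrow(stats))
      ord <- order(-stats$score, seq_len(nrow(stats)))
      out <- logical(nrow(stats))
      out[ord[seq_len(nkeep)]] <- TRUE
      out
    },
    degree = {
      if (parameter < 0 || parameter > 1) stop("degree parameter must be in [0, 1]")
      if (!all(c("rank_from", "rank_to") %in% names(stats))) {
        stop("degree filter expects per-node ranks; run normalize_scores(method = 'rank')")
      }
      nodes <- attr(stats, "nodes")
      k <- tabulate(c(stats$from, stats$to), nbins = length(nodes))
      quota <- ceiling(k^parameter)
      stats$rank_from <= quota[stats$from] | stats$rank_to <= quota[stats$to]
    }
  )
  out <- data.frame(from = stats$from[keep], to = stats$to[keep])
  rownames(out) <- NULL
  out
}

#' Union of maximum spanning trees
#'
#' An edge belongs to some maximum spanning tree/forest exactly when its
#' endpoints lie in different components of the subgraph of strictly
#' higher-scoring edges. Adding this set to a filtered backbone keeps the
#' backbone connected whenever the input is connected.
#'
#' @param net the unweighted network the scores live on.
#' @param stats edge statistics with a `score` column, aligned with
#'   `net$edges`.
#' @return data frame of UMST edges (`from`, `to`).
#' @export
umst <- function(net, stats) {
  check_unweighted(net)
  stopifnot(nrow(stats) == n_edges(net))
  n <- n_nodes(net)
  parent <- seq_len(n)
  find <- function(x) {
    while (parent[x] != x) {
      parent[x] <<- parent[parent[x]]
      x <- parent[x]
    }
    x
  }
  keep <- logical(nrow(stats))
  for (s in sort(unique(stats$score), decreasing = TRUE)) {
    idx <- which(stats$score == s)
    # test all edges at this level against the strictly-greater forest...
    keep[idx] <- vapply(idx, function(r) find(stats$from[r]) != find(stats$to[r]), logical(1))
    # ...then merge the level into the forest
    for (r in idx) {
      ra <- find(stats$from[r])
      rb <- find(stats$to[r])
      if (ra != rb) parent[ra] <- rb
    }
  }
  out <- data.frame(from = stats$from[keep], to = stats$to[keep])
  rownames(out) <- NULL
  out
}

#' Simmelian redundancy of edges
#'
#' Ties are weighted by an embeddedness strength (triangle count by
#' default; the quadrangle coefficient for the quadrilateral variant), each
#' node ranks its neighbors by strength (ties broken by node order), and
#' the redundancy of edge i-j is the maximum over prefix sizes k >= 1 of
#' the Jaccard coefficient between i's and j's top-k neighbor sets, with
#' each endpoint excluded from the other's list.
#'
#' @param net an unweighted network.
#' @param strength `"triangles"` or `"quadrangles"`.
#' @return edge statistics with the redundancy in `score` (in \[0, 1\]).
#' @export
simmelian_redundancy <- function(net, strength = c("triangles", "quadrangles")) {
  strength <- match.arg(strength)
  check_unweighted(net)
  e <- net$edges
  st <- escore(net, metric = strength)
  # per-node neighbor list ordered by (strength desc, neighbor index asc)
  long <- data.frame(
    node = c(e$i, e$j),
    nb = c(e$j, e$i),
    s = rep(st$score, 2L)
  )
  ord <- order(long$node, -long$s, long$nb)
  long <- long[ord, ]
  ranked <- split(long$nb, long$node)
  red <- vapply(seq_len(nrow(e)), function(r) {
    i <- e$i[r]
    j <- e$j[r]
    li <- setdiff(ranked[[as.character(i)]], j)
    lj <- setdiff(ranked[[as.character(j)]], i)
    kmax <- max(length(li), length(lj))
    if (kmax == 0) return(0)
    best <- 0
    for (kk in seq_len(kmax)) {
      ti <- li[seq_len(min(kk, length(li)))]
      tj <- lj[seq_len(min(kk, length(lj)))]
      u <- length(union(ti, tj))
      if (u > 0) best <- max(best, length(intersect(ti, tj)) / u)
    }
    best
  }, numeric(1))
  df <- data.frame(
    from = e$i, to = e$j,
    score_from = red, score_to = red, score = red
  )
  out <- new_edge_stats(df, net$nodes, paste0("simmelian:", strength))
  attr(out, "metric") <- paste0("simmelian_", strength)
  out
}

unweighted_presets <- list(
  lspar = list(escore = "jaccard", normalize = "rank", filter = "degree", umst = FALSE, default = 0.5),
  degree = list(escore = "degree", normalize = "rank", filter = "degree", umst = FALSE, default = 0.5),
  gspar = list(escore = "jaccard", normalize = "none", filter = "proportion", umst = FALSE, default = NULL),
  skeleton = list(escore = "random", normalize = "none", filter = "proportion", umst = FALSE, default = NULL),
  jaccard = list(escore = "jaccard", normalize = "none", filter = "threshold", umst = FALSE, default = NULL),
  meetmin = list(escore = "meetmin", normalize = "none", filter = "threshold", umst = FALSE, default = NULL),
  geometric = list(escore = "geometric", normalize = "none", filter = "threshold", umst = FALSE, default = NULL),
  hyper = list(escore = "hyper", normalize = "none", filter = "threshold", umst = FALSE, default = NULL),
  simmelian = list(escore = "simmelian", normalize = "none", filter = "threshold", umst = FALSE, default = NULL),
  quadrilateral = list(escore = "quadrilateral", normalize = "none", filter = "threshold", umst = FALSE, default = NULL)
)

#' Extract the backbone of an unweighted network
#'
#' Runs the four-step framework. Named presets fix the steps: `lspar`
#' (local sparsification, the default: jaccard scores, local ranks, degree
#' filter), `degree` (local degree: neighbor-degree scores, local ranks,
#' degree filter), `gspar` (global sparsification: jaccard scores,
#' proportion filter -- `parameter` is the fraction of edges RETAINED),
#' `skeleton` (seeded random scores + proportion filter; yields
#' non-reproducible backbones without a seed, and a warning reminds you of
#' that), `jaccard`/`meetmin`/`geometric` (score threshold), `hyper`
#' (retain when the hypergeometric p-value is below `parameter`),
#' `simmelian` and `quadrilateral` (redundancy threshold on triangle or
#' quadrangle strengths). `model = "custom"` takes the steps from the
#' `escore`/`normalize`/`filter`/`umst` arguments.
#'
#' @param net an unweighted network.
#' @param model preset name or `"custom"`.
#' @param parameter sparsification parameter; default 0.5 for the
#'   rank/degree presets, required otherwise.
#' @param seed seed for stochastic scores (`random`).
#' @param escore,normalize,filter,umst custom pipeline steps (see
#'   [escore()], [normalize_scores()], [filter_edges()], [umst()]).
#'   `umst = TRUE` adds the union of maximum spanning trees on the raw
#'   scores to the filtered edge set.
#' @return a `nbb_backbone` result.
#' @export
backbone_from_unweighted <- function(net,
                                     model = c("lspar", "degree", "gspar", "skeleton",
                                               "jaccard", "meetmin", "geometric", "hyper",
                                               "simmelian", "quadrilateral", "custom"),
                                     parameter = NULL, seed = NULL,
                                     escore = NULL, normalize = NULL, filter = NULL,
                                     umst = FALSE) {
  model <- match.arg(model)
  check_unweighted(net)
  if (model == "custom") {
    if (is.null(escore) || is.null(normalize) || is.null(filter)) {
      stop("custom model needs escore, normalize and filter")
    }
    steps <- list(escore = escore, normalize = normalize, filter = filter, umst = umst, default = NULL)
  } else {
    steps <- unweighted_presets[[model]]
    if (umst) steps$umst <- TRUE
  }
  parameter <- parameter %||% steps$default
  if (is.null(parameter)) stop("parameter missing for model '", model, "'")
  if (model == "skeleton" && is.null(seed)) {
    warning("skeleton backbones are random; supply a seed for reproducibility")
  }
  st <- switch(steps$escore,
    simmelian = simmelian_redundancy(net, "triangles"),
    quadrilateral = simmelian_redundancy(net, "quadrangles"),
    escore(net, metric = steps$escore, seed = seed)
  )
  stn <- normalize_scores(st, steps$normalize)
  if (model == "hyper") {
    # threshold applied to the p-value: retain when p < parameter
    keep <- (1 - stn$score) < parameter
    kept <- data.frame(from = stn$from[keep], to = stn$to[keep])
  } else {
    kept <- filter_edges(stn, steps$filter, parameter)
  }
  if (isTRUE(steps$umst)) {
    extra <- umst(net, st)
    kept <- unique(rbind(kept, extra))
  }
  retained <- data.frame(from = kept$from, to = kept$to, sign = rep(1L, nrow(kept)))
  new_backbone_result(
    retained = retained, nodes = net$nodes, denom = n_edges(net),
    original = original_summary(net), family = "unweighted",
    model = model, parameter = parameter,
    seed = seed,
    steps = steps[c("escore", "normalize", "filter", "umst")]
  )
}
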