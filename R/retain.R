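# ---------------------------------------------------------------------------
# Turning edgewise p-values into a retained (optionally signed) edge set.
# ---------------------------------------------------------------------------

# edge-statistics container: a data frame of edges (integer endpoint indices
# into a node vector kept as an attribute) plus either a score column or
# p_upper / p_lower columns.
new_edge_stats <- function(df, nodes, model) {
  stopifnot(is.data.frame(df), all(c("from", "to") %in% names(df)))
  structure(df,
    nodes = as.character(nodes), model = model,
    class = c("nbb_edge_stats", "data.frame")
  )
}

#' Multiple-test correction for edge p-values
#'
#' Thin wrapper around the standard step-up/step-down adjustments, fixed to
#' the methods used for backbone extraction. `"bh"` controls the false
#' discovery rate (the `mtc = "fdr"` spelling is accepted as an alias);
#' `"by"` is its dependency-robust variant.
#'
#' @param p numeric vector of p-values in \[0, 1\].
#' @param method one of `"none"`, `"bonferroni"`, `"holm"`, `"bh"`, `"by"`
#'   (or `"fdr"`, an alias for `"bh"`).
#' @return adjusted p-values in \[0, 1\], in input order.
#' @export
adjust_pvalues <- function(p, method = c("none", "bonferroni", "holm", "bh", "by", "fdr")) {
  method <- match.arg(method)
  if (any(is.na(p)) || any(p < 0) || any(p > 1)) stop("p-values must be in [0, 1]")
  key <- switch(method,
    none = "none", bonferroni = "bonferroni", holm = "holm",
    bh = "BH", fdr = "BH", by = "BY"
  )
  stats::p.adjust(p, method = key)
}

#' Retain significant edges, optionally with signs
#'
#' In unsigned mode an edge is retained (sign +1) when its adjusted upper-
#' tail p-value is below `alpha`. In signed mode the two-tailed test is
#' split as `alpha/2` per tail: significantly strong edges are retained as
#' +1 and significantly weak edges as -1. For discrete null models both
#' inclusive tails sum to at least 1, so an edge can receive at most one
#' sign.
#'
#' @param stats an edge-statistics object (or data frame) with `p_upper`
#'   and, for signed retention, `p_lower` columns.
#' @param alpha significance level in (0, 1).
#' @param mtc multiple-test correction passed to [adjust_pvalues()].
#' @param signed logical; retain significantly weak edges as negative.
#' @return data frame with columns `from`, `to`, `sign`.
#' @export
retain_edges <- function(stats, alpha, mtc = "none", signed = FALSE) {
  if (!is.numeric(alpha) || length(alpha) != 1 || alpha <= 0 || alpha >= 1) {
    stop("alpha must be a single value in (0, 1)")
  }
  if (!("p_upper" %in% names(stats))) stop("edge statistics lack p_upper")
  if (signed && !("p_lower" %in% names(stats))) {
    stop("signed retention requested but p_lower absent")
  }
  if (!signed) {
    keep <- adjust_pvalues(stats$p_upper, mtc) < alpha
    out <- data.frame(
      from = stats$from[keep], to = stats$to[keep],
      sign = rep(1L, sum(keep))
    )
  } else {
    pos <- adjust_pvalues(stats$p_upper, mtc) < alpha / 2
    neg <- adjust_pvalues(stats$p_lower, mtc) < alpha / 2
    neg <- neg & !pos # ties impossible for valid tails; belt and braces
    keep <- pos | neg
    out <- data.frame(
      from = stats$from[keep], to = stats$to[keep],
      sign = ifelse(pos[keep], 1L, -1L)
    )
  }
  rownames(out) <- NULL
  out
}
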