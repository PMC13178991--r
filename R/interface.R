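# ---------------------------------------------------------------------------
# BackboneResult: retained backbone + model metadata + narrative text.
# ---------------------------------------------------------------------------

model_labels <- list(
  global = "a global threshold",
  disparity = "the disparity filter",
  lans = "locally adaptive network sparsification",
  mlf = "the marginal likelihood filter",
  sdsm = "the stochastic degree sequence model (SDSM)",
  fdsm = "the fixed degree sequence model (FDSM)",
  fixedrow = "the fixed row model",
  fixedcol = "the fixed column model",
  fixedfill = "the fixed fill model",
  lspar = "Local Sparsification",
  gspar = "Global Sparsification",
  degree = "Local Degree",
  skeleton = "a Skeleton backbone",
  simmelian = "Simmelian sparsification",
  quadrilateral = "Quadrilateral Simmelian sparsification",
  jaccard = "Jaccard sparsification",
  meetmin = "Meetmin sparsification",
  geometric = "Geometric sparsification",
  hyper = "Hypergeometric sparsification",
  custom = "a custom score-and-filter model"
)

model_citations <- list(
  disparity = "Serrano, Boguna, & Vespignani, 2009",
  lans = "Foti, Hughes, & Rockmore, 2011",
  mlf = "Dianati, 2016",
  sdsm = "Neal, Domagalski, & Sagan, 2021",
  fdsm = "Zweig & Kaufmann, 2011",
  fixedrow = "Neal, Domagalski, & Sagan, 2021",
  fixedcol = "Neal, Domagalski, & Sagan, 2021",
  fixedfill = "Neal, Domagalski, & Sagan, 2021",
  lspar = "Satuluri, Parthasarathy, & Ruan, 2011",
  gspar = "Satuluri, Parthasarathy, & Ruan, 2011",
  degree = "Hamann, Lindner, Meyerhenke, Staudt, & Wagner, 2016",
  skeleton = "Karger, 1999",
  simmelian = "Nick, Lee, Cunningham, & Brandes, 2013",
  quadrilateral = "Nocaj, Ortmann, & Brandes, 2015",
  jaccard = "Goldberg & Roth, 2003",
  meetmin = "Goldberg & Roth, 2003",
  geometric = "Goldberg & Roth, 2003",
  hyper = "Goldberg & Roth, 2003"
)

new_backbone_result <- function(retained, nodes, denom, original, family, model,
                                alpha = NULL, parameter = NULL, mtc = "none",
                                signed = FALSE, seed = NULL, trials = NULL,
                                steps = NULL) {
  bb <- new_network(nodes, retained$from, retained$to, rep(1, nrow(retained)))
  # carry the signs in the backbone's canonical edge order
  key_in <- paste(pmin(retained$from, retained$to), pmax(retained$from, retained$to))
  key_bb <- paste(bb$edges$i, bb$edges$j)
  signs <- as.integer(retained$sign[match(key_bb, key_in)])
  pct <- if (denom > 0) 100 * (1 - nrow(retained) / denom) else 0
  res <- structure(
    list(
      backbone = bb, signs = signs, original = original,
      family = family, model = model,
      alpha = alpha, parameter = parameter, mtc = mtc, signed = signed,
      seed = seed, trials = trials, steps = steps,
      edges_removed_pct = pct, narrative = NULL
    ),
    class = "nbb_backbone"
  )
  res$narrative <- render_narrative(res)
  res
}

#' Narrative summary of a backbone extraction
#'
#' Renders deterministic narrative text from the stored metadata: which
#' model was used (with its citation), at which alpha or filtering
#' parameter, and what percentage of edges it removed. Percentages are
#' rounded half-even to two decimals with trailing zeros trimmed.
#' Regenerating the narrative from the same result is byte-identical.
#'
#' @param result a `nbb_backbone`.
#' @return a character scalar.
#' @export
render_narrative <- function(result) {
  stopifnot(inherits(result, "nbb_backbone"))
  o <- result$original
  src <- switch(o$type,
    bipartite = sprintf(
      "the weighted projection of a bipartite network containing %d agents and %d artifacts",
      o$agents, o$artifacts
    ),
    weighted = sprintf("a weighted network containing %d nodes", o$nodes),
    unweighted = sprintf("an unweighted network containing %d nodes", o$nodes)
  )
  head <- sprintf(
    "The netbackbone package for R (v%s) was used to extract the unweighted backbone of %s.",
    as.character(utils::packageVersion("netbackbone")), src
  )
  label <- model_labels[[result$model]] %||% result$model
  cite <- model_citations[[result$model]]
  label_cited <- if (is.null(cite)) {
    label
  } else if (grepl("\\)$", label)) {
    sub("\\)$", paste0("; ", cite, ")"), label) # "... (SDSM; Neal, ...)"
  } else {
    sprintf("%s (%s)", label, cite)
  }
  pct <- format_pct(result$edges_removed_pct)
  body <- if (result$family %in% c("weighted", "projection") && result$model != "global") {
    sig <- sprintf(
      "An edge was retained in the backbone if its weight was statistically significant (alpha = %s) using %s, which reduced the number of edges by %s%%.",
      format_num(result$alpha), label_cited, pct
    )
    if (result$signed) {
      sig <- paste(
        sig,
        "Statistically significantly strong edges were retained as positive and significantly weak edges as negative (two-tailed test)."
      )
    }
    if (!identical(result$mtc, "none")) {
      sig <- paste(sig, sprintf("P-values were adjusted for multiple testing (%s).", result$mtc))
    }
    sig
  } else if (result$model == "global") {
    sprintf(
      "Edges were selected for retention in the backbone using %s (threshold = %s), which removed %s%% of the edges.",
      label, format_num(result$parameter), pct
    )
  } else {
    sprintf(
      "Edges were selected for retention in the backbone using %s with filtering parameter = %s, which removed %s%% of the edges.",
      label_cited, format_num(result$parameter), pct
    )
  }
  paste(head, body)
}

#' @export
print.nbb_backbone <- function(x, ...) {
  cat(x$narrative, "\n", sep = "")
  cat(sprintf(
    "backbone: %d nodes, %d edges%s\n",
    length(x$backbone$nodes), nrow(x$backbone$edges),
    if (x$signed) sprintf(" (%d negative)", sum(x$signs < 0)) else ""
  ))
  invisible(x)
}

#' Extract a backbone, auto-detecting the source network type
#'
#' Wrapper that inspects the input and dispatches: a bipartite incidence
#' goes to [backbone_from_projection()] with the SDSM at alpha 0.05; a
#' weighted network goes to [backbone_from_weighted()] with the disparity
#' filter at alpha 0.05; an unweighted network goes to
#' [backbone_from_unweighted()] with local sparsification at parameter 0.5.
#' The narrative summary is printed unless `quiet = TRUE`.
#'
#' @param x a network or bipartite incidence.
#' @param alpha,parameter optional overrides of the model defaults.
#' @param model optional model override for the detected family.
#' @param mtc,signed,trials,seed passed through to the core functions.
#' @param quiet suppress narrative printing.
#' @return a `nbb_backbone` result.
#' @export
backbone <- function(x, alpha = NULL, parameter = NULL, model = NULL,
                     mtc = "none", signed = FALSE, trials = 1000,
                     seed = NULL, quiet = FALSE) {
  type <- detect_network_type(x)
  res <- switch(type,
    bipartite = backbone_from_projection(x,
      model = model %||% "sdsm", alpha = alpha %||% 0.05,
      mtc = mtc, signed = signed, trials = trials, seed = seed
    ),
    weighted = backbone_from_weighted(x,
      model = model %||% "disparity", alpha = alpha,
      parameter = parameter, mtc = mtc, signed = signed
    ),
    unweighted = backbone_from_unweighted(x,
      model = model %||% "lspar", parameter = parameter %||% 0.5,
      seed = seed
    )
  )
  if (!quiet) cat(res$narrative, "\n", sep = "")
  res
}

#' Serialize / restore a backbone result
#'
#' Writes the retained edges, signs, metadata and narrative as JSON so a
#' result can be re-loaded losslessly (requires the jsonlite package).
#'
#' @param result a `nbb_backbone`.
#' @param path JSON file path.
#' @return `backbone_to_json` returns `path` invisibly;
#'   `backbone_from_json` returns the restored `nbb_backbone`.
#' @export
backbone_to_json <- function(result, path) {
  stopifnot(inherits(result, "nbb_backbone"))
  if (!requireNamespace("jsonlite", quietly = TRUE)) stop("jsonlite not installed")
  bb <- result$backbone
  payload <- list(
    nodes = bb$nodes,
    edges = data.frame(
      from = bb$nodes[bb$edges$i], to = bb$nodes[bb$edges$j],
      sign = result$signs
    ),
    original = result$original,
    family = result$family, model = result$model,
    alpha = result$alpha, parameter = result$parameter,
    mtc = result$mtc, signed = result$signed,
    seed = result$seed, trials = result$trials,
    edges_removed_pct = result$edges_removed_pct,
    narrative = result$narrative
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname backbone_to_json
#' @param path JSON file path.
#' @export
backbone_from_json <- function(path) {
  if (!requireNamespace("jsonlite", quietly = TRUE)) stop("jsonlite not installed")
  d <- jsonlite::read_json(path, simplifyVector = TRUE)
  retained <- data.frame(
    from = match(d$edges$from, d$nodes),
    to = match(d$edges$to, d$nodes),
    sign = d$edges$sign
  )
  if (nrow(retained) == 0) retained <- data.frame(from = integer(0), to = integer(0), sign = integer(0))
  denom_pct <- d$edges_removed_pct
  res <- new_backbone_result(
    retained = retained, nodes = d$nodes,
    denom = if (denom_pct < 100) round(nrow(retained) / (1 - denom_pct / 100)) else 0,
    original = d$original, family = d$family, model = d$model,
    alpha = d$alpha, parameter = d$parameter, mtc = d$mtc %||% "none",
    signed = isTRUE(d$signed), seed = d$seed, trials = d$trials
  )
  # trust the stored percentage over the denominator back-computation
  res$edges_removed_pct <- denom_pct
  res$narrative <- render_narrative(res)
  res
}
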