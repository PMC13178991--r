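# ---------------------------------------------------------------------------
# Poisson-binomial tail probabilities: the distribution of a sum of
# independent, non-identical Bernoulli variables. This is the edge-weight
# null for the SDSM and fixed-column models. Exact dynamic-programming
# convolution up to 8192 terms; a refined (skewness-corrected) normal
# approximation beyond that.
# ---------------------------------------------------------------------------

PB_EXACT_LIMIT <- 8192L

#' Poisson-binomial tail probability
#'
#' Computes the inclusive tail probability \eqn{P(X \ge \mathrm{obs})}
#' (upper) or \eqn{P(X \le \mathrm{obs})} (lower) for
#' \eqn{X = \sum_k \mathrm{Bernoulli}(p_k)}. The exact method is a
#' dynamic-programming convolution with the count axis capped at the
#' observed value (mass beyond it is absorbed), which keeps the cost at
#' O(length(probs) * observed). Beyond 8192 terms a continuity-corrected
#' normal approximation with a first-order skewness term is used.
#'
#' @param probs numeric vector of success probabilities in \[0, 1\].
#' @param observed integer in \[0, length(probs)\].
#' @param tail `"upper"` or `"lower"` (both inclusive).
#' @param method `"auto"` (default: exact up to 8192 terms), `"dp"`, or
#'   `"rna"` (refined normal approximation).
#' @return a single probability.
#' @export
poisson_binomial_tail <- function(probs, observed, tail = c("upper", "lower"),
                                  method = c("auto", "dp", "rna")) {
  tail <- match.arg(tail)
  both <- pb_tails(probs, observed, method = match.arg(method))
  if (tail == "upper") both[["upper"]] else both[["lower"]]
}

# both inclusive tails at once
pb_tails <- function(probs, observed, method = "auto") {
  probs <- as.numeric(probs)
  if (any(is.na(probs)) || any(probs < 0) || any(probs > 1)) {
    stop("probabilities must be in [0, 1]")
  }
  observed <- as.integer(observed)
  if (observed < 0 || observed > length(probs)) stop("observed out of range")
  if (method == "auto") {
    method <- if (length(probs) <= PB_EXACT_LIMIT) "dp" else "rna"
  }
  if (method == "dp") {
    v <- pb_tails_dp(probs, observed)
    c(upper = v[1], lower = v[2])
  } else {
    pb_tails_rna(probs, observed)
  }
}

pb_tails_rna <- function(probs, observed) {
  mu <- sum(probs)
  s2 <- sum(probs * (1 - probs))
  if (s2 == 0) {
    # degenerate: X is the constant sum of the 0/1 probabilities
    return(c(upper = as.numeric(observed <= mu), lower = as.numeric(observed >= mu)))
  }
  sg <- sqrt(s2)
  gamma <- sum(probs * (1 - probs) * (1 - 2 * probs)) / sg^3
  cdf <- function(k) {
    x <- (k + 0.5 - mu) / sg
    min(1, max(0, stats::pnorm(x) + gamma * (1 - x^2) * stats::dnorm(x) / 6))
  }
  c(upper = 1 - cdf(observed - 1), lower = cdf(observed))
}
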