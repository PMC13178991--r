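# ---------------------------------------------------------------------------
# Bipartite configuration model (BiCM): maximum-entropy cell probabilities
# p_ik = x_i y_k / (1 + x_i y_k) whose expected row and column sums match
# the observed marginals. Solved by fixed-point iteration on the reduced
# system of distinct degrees; boundary rows/columns (empty or full) are
# peeled off first and get exact probabilities 0/1.
# ---------------------------------------------------------------------------

#' Fit the bipartite configuration model
#'
#' @param B a [bipartite_incidence()] object (or binary matrix).
#' @param tol convergence tolerance on the maximum absolute difference
#'   between expected and observed marginals.
#' @param max_iter maximum number of fixed-point sweeps.
#' @return an object of class `nbb_bicm`: list with `p` (m x n cell
#'   probability matrix), `x`, `y` (row/column factors; `NA` for degenerate
#'   rows/columns handled exactly), `residual`, `iterations`.
#' @export
bicm_fit <- function(B, tol = 1e-8, max_iter = 10000) {
  if (!is_incidence(B)) B <- bipartite_incidence(B)
  Bm <- incidence_matrix(B)
  m <- nrow(Bm)
  n <- ncol(Bm)
  r <- rowSums(Bm)
  cc <- colSums(Bm)
  p <- matrix(NA_real_, m, n, dimnames = dimnames(Bm))
  row_active <- rep(TRUE, m)
  col_active <- rep(TRUE, n)
  r_eff <- r
  c_eff <- cc
  # peel degenerate rows/columns one class at a time: a full row forces
  # p = 1 across it and reduces every remaining column's effective marginal
  repeat {
    na_ <- sum(col_active)
    ma_ <- sum(row_active)
    full_r <- row_active & (r_eff == na_)
    zero_r <- row_active & (r_eff == 0)
    full_c <- col_active & (c_eff == ma_)
    zero_c <- col_active & (c_eff == 0)
    if (any(full_r)) {
      p[full_r, col_active] <- 1
      c_eff[col_active] <- c_eff[col_active] - sum(full_r)
      row_active[full_r] <- FALSE
    } else if (any(zero_r)) {
      p[zero_r, col_active] <- 0
      row_active[zero_r] <- FALSE
    } else if (any(full_c)) {
      p[row_active, full_c] <- 1
      r_eff[row_active] <- r_eff[row_active] - sum(full_c)
      col_active[full_c] <- FALSE
    } else if (any(zero_c)) {
      p[row_active, zero_c] <- 0
      col_active[zero_c] <- FALSE
    } else {
      break
    }
    if (!any(row_active) || !any(col_active)) break
  }
  x_full <- rep(NA_real_, m)
  y_full <- rep(NA_real_, n)
  iterations <- 0L
  residual <- 0
  if (any(row_active) && any(col_active)) {
    rv <- r_eff[row_active]
    cv <- c_eff[col_active]
    rd <- sort(unique(rv)) # distinct active row degrees
    cd <- sort(unique(cv))
    mr <- as.numeric(table(factor(rv, levels = rd)))
    qc <- as.numeric(table(factor(cv, levels = cd)))
    fa <- sum(rv)
    x <- rd / sqrt(fa)
    y <- cd / sqrt(fa)
    resid_of <- function(x, y) {
      XY <- outer(x, y)
      P <- XY / (1 + XY)
      max(
        max(abs(as.vector(P %*% qc) - rd)),
        max(abs(as.vector(crossprod(P, mr)) - cd))
      )
    }
    for (it in seq_len(max_iter)) {
      XY <- outer(x, y)
      x <- rd / as.vector((1 / (1 + XY)) %*% (qc * y))
      XY <- outer(x, y)
      y <- cd / as.vector(crossprod(1 / (1 + XY), mr * x))
      iterations <- it
      if (it %% 10 == 0 || it == max_iter) {
        residual <- resid_of(x, y)
        if (residual <= tol) break
      }
    }
    residual <- resid_of(x, y)
    if (residual > tol) {
      stop(sprintf(
        "bicm did not converge in %d iterations (residual %.3e > tol %.3e)",
        max_iter, residual, tol
      ))
    }
    xi <- x[match(rv, rd)]
    yk <- y[match(cv, cd)]
    x_full[row_active] <- xi
    y_full[col_active] <- yk
    XYf <- outer(xi, yk)
    p[row_active, col_active] <- XYf / (1 + XYf)
  }
  # overall residual including exactly-handled degenerate rows/columns
  residual_all <- max(
    max(abs(rowSums(p) - r)),
    max(abs(colSums(p) - cc))
  )
  structure(
    list(
      p = p, x = x_full, y = y_full,
      residual = residual_all, iterations = iterations
    ),
    class = "nbb_bicm"
  )
}

#' @export
print.nbb_bicm <- function(x, ...) {
  cat(sprintf(
    "<bicm fit: %d x %d, residual %.2e, %d iterations>\n",
    nrow(x$p), ncol(x$p), x$residual, x$iterations
  ))
  invisible(x)
}
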