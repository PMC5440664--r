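test_that("joint CTMC likelihood matches a dense matrix-exponential oracle", {
  skip_if_not_installed("Matrix")
  set.seed(14)
  for (rep in 1:5) {
    len <- runif(1, 0.5, 3)
    tr <- tree2(len)
    r8 <- runif(8, 0.02, 0.8)
    Q <- dependent_Q(r8)
    P <- as.matrix(Matrix::expm(Q * len))
    pi0 <- qr.solve(rbind(t(Q), rep(1, 4)), c(0, 0, 0, 0, 1))
    a <- c(A = sample(0:1, 1), B = sample(0:1, 1))
    b <- c(A = sample(0:1, 1), B = sample(0:1, 1))
    sA <- 2 * a[1] + b[1] + 1; sB <- 2 * a[2] + b[2] + 1
    oracle <- log(sum(pi0 * P[, sA] * P[, sB]))
    expect_equal(ctmc_loglik(tr, a, b, r8), oracle, tolerance = 1e-8)
  }
})

test_that("zero rates with identical tips give the root-state probability", {
  tr <- tree2()
  ll <- ctmc_loglik(tr, c(A = 1, B = 1), c(A = 0, B = 0), rep(0, 8))
  expect_equal(ll, log(0.25)) # uniform root convention for a null chain
})

test_that("the independent model is the constrained dependent model", {
  tr <- sim_tree(16)
  set.seed(15)
  m <- simulate_mk(tr, nchar = 2, k_states = 2, rate = 0.05)
  a <- setNames(m$data[, 1], rownames(m$data))
  b <- setNames(m$data[, 2], rownames(m$data))
  r4 <- c(0.1, 0.3, 0.2, 0.15)
  expect_equal(ctmc_loglik(tr, a, b, r4, independent = TRUE),
               ctmc_loglik(tr, a, b, r4[c(1, 1, 2, 2, 3, 3, 4, 4)]),
               tolerance = 1e-12)
})

test_that("swapping the characters with permuted rates leaves the
           likelihood unchanged", {
  tr <- sim_tree(16)
  set.seed(16)
  m <- simulate_mk(tr, nchar = 2, k_states = 2, rate = 0.05)
  a <- setNames(m$data[, 1], rownames(m$data))
  b <- setNames(m$data[, 2], rownames(m$data))
  r8 <- runif(8, 0.05, 0.5)
  expect_equal(ctmc_loglik(tr, a, b, r8),
               ctmc_loglik(tr, b, a, r8[c(5, 6, 7, 8, 1, 2, 3, 4)]),
               tolerance = 1e-10)
})

test_that("a very long branch drives tips to the stationary distribution", {
  tr <- tree2(5000)
  r8 <- c(0.2, 0.4, 0.3, 0.1, 0.25, 0.15, 0.3, 0.2)
  Q <- dependent_Q(r8)
  pi0 <- qr.solve(rbind(t(Q), rep(1, 4)), c(0, 0, 0, 0, 1))
  # tips become independent draws from pi
  ll <- ctmc_loglik(tr, c(A = 0, B = 1), c(A = 1, B = 0), r8)
  expect_equal(ll, unname(log(pi0[2]) + log(pi0[3])), tolerance = 1e-6)
})

test_that("perfectly coupled characters are detected, and the LR is
           non-negative", {
  set.seed(17)
  sig <- 0
  for (r in 1:10) {
    tr <- simulate_tree(64, lambda = 0.12, seed = 600 + r)
    m <- simulate_mk(tr, nchar = 1, k_states = 2, rate = 0.05)
    x <- setNames(m$data[, 1], rownames(m$data))
    if (length(unique(x)) < 2) next
    pt <- pair_lrt(tr, x, x, seed = r)
    expect_gte(pt$lr, -1e-6)
    sig <- sig + isTRUE(pt$significant)
  }
  expect_gte(sig, 9) # >= 90% power at perfect coupling
})

test_that("degenerate pairs are flagged and excluded from summaries", {
  tr <- sim_tree(16)
  const <- setNames(rep(0, 16), tr$tip.label)
  vary <- setNames(rep(c(0, 1), 8), tr$tip.label)
  pt <- pair_lrt(tr, const, vary)
  expect_true(pt$degenerate)
  res <- data.frame(significant = c(TRUE, FALSE, NA),
                    p = c(0.01, 0.5, NA),
                    degenerate = c(FALSE, FALSE, TRUE))
  s <- summarize_pairs(res)
  expect_equal(s$n_total, 2)
  expect_equal(s$n_significant, 1)
})

test_that("pair summaries reproduce printed-percentage arithmetic", {
  res <- data.frame(significant = rep(c(TRUE, FALSE), c(318, 4255 - 318)))
  expect_equal(summarize_pairs(res)$percent, 7.5)
  expect_equal(summarize_pairs(
    data.frame(significant = rep(FALSE, 100)))$percent, 0.0)
  expect_equal(summarize_pairs(
    data.frame(significant = rep(TRUE, 100)))$percent, 100.0)
  # BH q-values appended when p is present
  res2 <- data.frame(significant = c(TRUE, FALSE), p = c(0.01, 0.8))
  s2 <- summarize_pairs(res2)
  expect_equal(s2$results$q, p.adjust(res2$p, "BH"))
})

test_that("the all-pairs driver runs over small matrices", {
  tr <- sim_tree(24)
  set.seed(18)
  ma <- simulate_mk(tr, nchar = 2, k_states = 3, rate = 0.06)
  mb <- simulate_mk(tr, nchar = 2, k_states = 2, rate = 0.06)
  res <- pairwise_lrt_all(tr, ma, mb, seed = 5)
  expect_equal(nrow(res), 4)
  ok <- !res$degenerate
  expect_true(all(res$lr[ok] >= -1e-6))
  s <- summarize_pairs(res)
  expect_equal(s$n_total, sum(ok))
})
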