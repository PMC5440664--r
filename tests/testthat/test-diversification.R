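test_that("pure-birth likelihood matches the closed-form Yule density", {
  # crown-conditioned Yule: logL = (n-2) log(lambda) - lambda * total length
  tr <- tree3()
  for (lam in c(0.1, 0.5, 1.7)) {
    closed <- (3 - 2) * log(lam) - lam * sum(tr$edge.length)
    expect_equal(bd_loglik(tr, 1, c(lambda0 = lam)), closed, tolerance = 1e-8)
  }
  tr2 <- sim_tree(30)
  lam <- 0.3
  closed <- (30 - 2) * log(lam) - lam * sum(tr2$edge.length)
  expect_equal(bd_loglik(tr2, 1, c(lambda0 = lam)), closed, tolerance = 1e-8)
})

test_that("nested models coincide at their boundary parameters", {
  tr <- sim_tree(30)
  l1 <- bd_loglik(tr, 1, c(lambda0 = 0.25))
  expect_equal(bd_loglik(tr, 2, c(lambda0 = 0.25, mu0 = 0)), l1,
               tolerance = 1e-10)
  expect_equal(bd_loglik(tr, 3, c(lambda0 = 0.25, a = 0)), l1,
               tolerance = 1e-10)
  expect_equal(bd_loglik(tr, 6, c(lambda0 = 0.25, a = 0, mu0 = 0, b = 0)),
               l1, tolerance = 1e-10)
})

test_that("analytic Yule gradient matches finite differences", {
  tr <- sim_tree(30)
  lam <- 0.31
  # d logL / d lambda = (n-2)/lambda - total length
  g_analytic <- (30 - 2) / lam - sum(tr$edge.length)
  h <- 1e-5
  g_fd <- (bd_loglik(tr, 1, c(lambda0 = lam + h)) -
             bd_loglik(tr, 1, c(lambda0 = lam - h))) / (2 * h)
  expect_equal(g_fd, g_analytic, tolerance = 1e-4 * abs(g_analytic))
})

test_that("likelihood is invariant under tip-label permutation", {
  tr <- sim_tree(20)
  tr2 <- tr
  tr2$tip.label <- sample(tr$tip.label)
  p <- c(lambda0 = 0.4, a = 0.2, mu0 = 0.05)
  expect_equal(bd_loglik(tr, 4, p), bd_loglik(tr2, 4, p))
})

test_that("fitting respects nesting and finds the Yule MLE", {
  tr <- sim_tree(40)
  fits <- fit_bd_models(tr, starts = 4, seed = 3)
  ll <- vapply(fits, `[[`, 0, "logL")
  expect_gte(ll[2], ll[1] - 1e-6)
  expect_gte(ll[3], ll[1] - 1e-6)
  expect_gte(ll[4], ll[3] - 1e-6)
  expect_gte(ll[4], ll[2] - 1e-6)
  expect_gte(ll[6], ll[4] - 1e-6)
  expect_gte(ll[6], ll[5] - 1e-6)
  # Yule MLE has closed form (n-2)/TL
  expect_equal(unname(fits[[1]]$params["lambda0"]),
               (40 - 2) / sum(tr$edge.length), tolerance = 1e-4)
})

test_that("AICc arithmetic and selection table ranking are exact", {
  mk <- function(logL, K, n, model = 1)
    structure(list(model = model, description = "x", logL = logL, K = K,
                   AICc = -2 * logL + 2 * K + 2 * K * (K + 1) / (n - K - 1),
                   n = n), class = "bd_fit")
  f <- mk(-10, 2, 10)
  expect_equal(f$AICc, 20 + 4 + 12 / 7)
  expect_equal(f$AICc, 25.7143, tolerance = 1e-4)
  tb <- selection_table(list(mk(-5, 1, 10, model = 1), mk(-4, 1, 10, model = 2)))
  expect_equal(tb$dAICc, c(0, 2))
  expect_equal(tb$Model, c(2, 1))
  # identical AICc: both deltas 0, input order preserved
  tb2 <- selection_table(list(mk(-5, 1, 10, 1), mk(-5, 1, 10, 2)))
  expect_equal(tb2$dAICc, c(0, 0))
  expect_equal(tb2$Model, c(1, 2))
})

test_that("declining-speciation trees prefer the exponential model", {
  set.seed(21)
  wins <- 0
  for (r in 1:20) {
    tr <- simulate_tree(200, lambda = 0.8, decline = 0.1)
    f1 <- fit_bd_model(tr, 1, starts = 2, seed = r)
    f3 <- fit_bd_model(tr, 3, starts = 2, seed = r,
                       extra_starts = list(f1$params))
    wins <- wins + (f3$AICc < f1$AICc)
  }
  expect_gte(wins, 16) # >= 80% of 20 replicates
})

test_that("domain violations are rejected", {
  tr <- tree3()
  expect_error(bd_loglik(tr, 1, c(lambda0 = -1)), "lambda0")
  expect_error(bd_loglik(tr, 2, c(lambda0 = 1, mu0 = -0.1)), "mu0")
  expect_error(bd_loglik(tr, 1, c(mu0 = 1)), "needs parameters")
  ntr <- ape::read.tree(text = "((A:1,B:2):1,C:2);")
  expect_error(bd_loglik(ntr, 1, c(lambda0 = 1)), "ultrametric")
})
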