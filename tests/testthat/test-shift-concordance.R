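test_that("the shared-shift ratio follows its definition", {
  tr <- sim_tree(20)
  e <- plant_shifts(tr, 4, min_clade = 2, disjoint = FALSE)
  sa <- shift_set(tr, e, "adult")
  expect_equal(shared_shift_ratio(sa, sa), 1)
  # disjoint node sets
  all_e <- seq_len(nrow(tr$edge))
  nodes_of <- function(ed) unique(tr$edge[ed, 1])
  eb <- setdiff(all_e, which(tr$edge[, 1] %in% nodes_of(e)))[1:4]
  sb <- shift_set(tr, eb, "tadpole")
  expect_equal(shared_shift_ratio(sa, sb), 0)
  expect_error(shared_shift_ratio(shift_set(tr, integer(0)), sa), "empty")
  # plain arithmetic: 7 shared of larger set 20
  fake_a <- structure(data.frame(node = 1:20, child = 1:20),
                      class = c("shift_set", "data.frame"))
  fake_b <- structure(data.frame(node = c(1:7, 101:109), child = 1:16),
                      class = c("shift_set", "data.frame"))
  expect_equal(shared_shift_ratio(fake_a, fake_b), 0.35)
})

test_that("identical shift sets give the smallest attainable p-value", {
  tr <- sim_tree(32)
  e <- plant_shifts(tr, 5, min_clade = 2, disjoint = FALSE)
  sa <- shift_set(tr, e)
  out <- node_concordance_test(tr, sa, sa, nreps = 200, seed = 3)
  expect_equal(out$statistic, 1)
  expect_equal(out$p, 1 / 201)
})

test_that("single-shift null matches exhaustive enumeration", {
  # one shift per phase on m eligible nodes: P(overlap) = 1/m exactly
  tr <- tree_with <- ape::read.tree(text = "(((A:1,B:1):1,C:2):1,D:3);")
  m <- length(setdiff(seq_len(4 + tr$Nnode), 5)[
    setdiff(seq_len(4 + tr$Nnode), 5) > 4]) # internal non-root nodes
  sa <- shift_set(tr, 2) # some internal edge
  out <- node_concordance_test(tr, sa, sa, nreps = 4000, seed = 8)
  expect_equal(mean(out$null), 1 / m, tolerance = 0.15)
  expect_setequal(unique(out$null), c(0, 1))
})

test_that("concordance p-values are conservative under the matched null", {
  tr <- sim_tree(64)
  internal <- setdiff(seq_len(64 + tr$Nnode), 65)
  internal <- internal[internal > 64]
  set.seed(17)
  ps <- vapply(1:200, function(r) {
    # generate shift nodes exactly as the null does: uniform internal nodes
    na <- 15; nb <- 17
    fake <- function(n) structure(
      data.frame(node = sample(internal, n), child = NA_integer_),
      class = c("shift_set", "data.frame"))
    node_concordance_test(tr, fake(na), fake(nb), nreps = 99,
                          seed = 5000 + r)$p
  }, numeric(1))
  for (t0 in c(0.05, 0.1, 0.25))
    expect_lte(mean(ps <= t0), t0 + 0.06)
  expect_gt(min(ps), 0)
})

test_that("direction concordance scores shared nodes and enumerates its
           null", {
  tr <- sim_tree(24)
  e <- plant_shifts(tr, 4, min_clade = 2, disjoint = FALSE)
  sa <- shift_set(tr, e)
  out <- direction_concordance_test(tr, sa, sa, nreps = 500, seed = 2)
  expect_equal(out$statistic, 1) # same child everywhere by construction
  expect_true(all(out$null >= 0 & out$null <= 1))
  # a single shared bifurcating node: null is Bernoulli(1/2)
  one <- shift_set(tr, e[1])
  out1 <- direction_concordance_test(tr, one, one, nreps = 2000, seed = 3)
  expect_setequal(unique(out1$null), c(0, 1))
  expect_equal(mean(out1$null), 0.5, tolerance = 0.1)
  sb <- shift_set(tr, setdiff(seq_len(nrow(tr$edge)),
                              which(tr$edge[, 1] %in% tr$edge[e, 1]))[1])
  expect_error(direction_concordance_test(tr, sa, sb), "shared")
})

test_that("shift histograms conserve counts and place ages correctly", {
  tr <- sim_tree(40)
  e <- plant_shifts(tr, 6, min_clade = 2, disjoint = FALSE)
  ss <- shift_set(tr, e)
  h <- bin_shifts_by_time(tr, ss, width = 4)
  expect_equal(sum(h$n_shifts), nrow(ss))
  ages <- node_ages(tr)[ss$node]
  for (i in seq_len(nrow(h)))
    expect_equal(h$n_shifts[i],
                 sum(ages >= h$age_from[i] & ages < h$age_to[i]))
  # a shift at age 22 lands in [20, 24)
  fake <- structure(data.frame(node = 1L, child = 2L),
                    class = c("shift_set", "data.frame"))
  tr2 <- ape::read.tree(text = "(A:30,B:30);")
  ages2 <- node_ages(tr2)
  # place it via a constructed tree is awkward: check the binning rule directly
  expect_equal(findInterval(22, seq(0, 32, 4)), 6) # 6th bin = [20, 24)
  h0 <- bin_shifts_by_time(tr, shift_set(tr, integer(0)), width = 4)
  expect_true(all(h0$n_shifts == 0))
})

test_that("interval correlations drop incomplete pairs and match cor()", {
  expect_equal(interval_correlation(1:10, 1:10)$r, 1)
  expect_equal(interval_correlation(1:10, -(1:10))$r, -1)
  a <- c(1, 2, NA, 4, 5); b <- c(2, 1, 3, NA, 4)
  out <- interval_correlation(a, b)
  expect_equal(out$n, 3)
  expect_equal(out$r, cor(c(1, 2, 5), c(2, 1, 4)))
  expect_error(interval_correlation(1:2, 1:3), "lengths")
  expect_error(interval_correlation(c(1, NA, 3), c(NA, 2, 3)), "complete")
  # null calibration at the 5% critical value for n = 10
  set.seed(21)
  crit <- qnorm(0.975) / sqrt(10 - 3 + 1) # ~0.62 via Fisher approximation
  inside <- mean(replicate(500, {
    abs(interval_correlation(rpois(10, 3), rpois(10, 3))$r) < 0.632
  }))
  expect_gte(inside, 0.90)
})
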