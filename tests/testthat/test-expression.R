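test_that("FPKM arithmetic is exact and proportional", {
  expect_equal(compute_fpkm(100, 1000, 1e6), 100)
  expect_equal(compute_fpkm(0, 1000, 1e6), 0)
  expect_equal(compute_fpkm(50, 2000, 2e6), compute_fpkm(50, 2000, 1e6) / 2)
  expect_error(compute_fpkm(1, 0, 1e6), "transcript_length")
  expect_error(compute_fpkm(1, 100, 0), "total_mapped")
})

test_that("ratio thresholds classify genes as published", {
  tb <- data.frame(gene = paste0("g", 1:6),
                   fpkm_adult = c(8, 1, 5, 0.1, 0.2, 3),
                   fpkm_tadpole = c(4, 4, 5, 0.3, 7, 2))
  cl <- classify_phase_bias(tb)
  expect_equal(as.character(cl$table$class),
               c("adult-biased",    # ratio 2 > 1.6
                 "tadpole-biased",  # ratio 0.25 < 0.4
                 "even",            # ratio 1
                 "unclassifiable",  # both under the floor
                 "tadpole-biased",  # adult under floor only
                 "even"))           # ratio 1.5 inside (0.4, 1.6)
  expect_equal(sum(cl$counts), nrow(tb)) # classes partition the table
})

test_that("tightening thresholds never increases the biased count", {
  set.seed(19)
  tb <- simulate_expression(n_genes = 500, seed = 20)
  n_biased <- function(hi, lo) {
    cl <- classify_phase_bias(tb, hi = hi, lo = lo)
    sum(cl$counts[c("adult-biased", "tadpole-biased")])
  }
  expect_lte(n_biased(2.0, 0.4), n_biased(1.6, 0.4))
  expect_lte(n_biased(1.6, 0.3), n_biased(1.6, 0.4))
})

test_that("keyword flags match an independent regex-scan oracle", {
  terms <- c("osteoclast", "keratin", "limb morphogenesis")
  set.seed(20)
  tb <- simulate_expression(n_genes = 300, seed = 21)
  got <- keyword_flag(tb$annotation, terms)
  oracle <- vapply(tb$annotation, function(a) {
    any(vapply(terms, function(t)
      regexpr(t, a, ignore.case = TRUE, fixed = FALSE) > 0, logical(1)))
  }, logical(1), USE.NAMES = FALSE)
  expect_identical(got, oracle)
  expect_true(keyword_flag("Osteoclast differentiation", "osteoclast"))
  expect_false(keyword_flag("", terms))
  expect_error(keyword_flag("x", character(0)), "nonempty")
})

test_that("proportion z-tests follow the pooled formula", {
  z0 <- proportion_ztest(10, 100, 10, 100)
  expect_equal(z0$z, 0)
  expect_equal(z0$p, 1)
  # hand-evaluated pooled formula
  k1 <- 50; n1 <- 100; k2 <- 10; n2 <- 100
  pool <- (k1 + k2) / (n1 + n2)
  z_hand <- (k1 / n1 - k2 / n2) / sqrt(pool * (1 - pool) * (1 / n1 + 1 / n2))
  zt <- proportion_ztest(k1, n1, k2, n2)
  expect_equal(zt$z, z_hand, tolerance = 1e-12)
  expect_equal(zt$p, 2 * pnorm(-abs(z_hand)))
  # swapping groups negates z, p unchanged
  zs <- proportion_ztest(k2, n2, k1, n1)
  expect_equal(zs$z, -zt$z)
  expect_equal(zs$p, zt$p)
  # degenerate pooled proportions
  expect_equal(proportion_ztest(0, 10, 0, 20), list(z = 0, p = 1, p1 = 0, p2 = 0))
})

test_that("planted expression classes are recovered at calibrated rates", {
  tb0 <- simulate_expression(n_genes = 2000, frac_adult = 0, frac_tadpole = 0,
                             frac_low = 0, seed = 22)
  cl0 <- classify_phase_bias(tb0)
  fp <- sum(cl0$counts[c("adult-biased", "tadpole-biased")]) / 2000
  expect_lt(fp, 0.05) # false-positive calls under pure noise
  tb1 <- simulate_expression(n_genes = 2000, frac_adult = 0.3,
                             frac_tadpole = 0.1, seed = 23)
  cl1 <- classify_phase_bias(tb1)
  rec <- cl1$counts[["adult-biased"]] / 2000
  expect_lt(abs(rec - 0.30), 0.05) # within +-5 points of the planted 30%
  # determinism
  expect_identical(simulate_expression(n_genes = 50, seed = 9),
                   simulate_expression(n_genes = 50, seed = 9))
})
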