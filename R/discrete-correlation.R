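# Likelihood test of correlated evolution between binary characters of
# the two life-history phases: a dependent 8-rate joint Markov model
# against the 4-rate independent model, compared by likelihood ratio.

#' Joint rate matrix of the dependent two-character model
#'
#' Joint states are ordered 00, 01, 10, 11 (character A first). The 8
#' rates are, in order: A 0->1 | B=0, A 0->1 | B=1, A 1->0 | B=0,
#' A 1->0 | B=1, B 0->1 | A=0, B 0->1 | A=1, B 1->0 | A=0, B 1->0 | A=1.
#' Double transitions have rate 0. The independent model is the special
#' case with rates 1=2, 3=4, 5=6, 7=8.
#'
#' @param rates8 numeric vector of 8 non-negative rates (events/Myr).
#' @return 4x4 rate matrix with zero row sums.
#' @export
dependent_Q <- function(rates8) {
  stopifnot(length(rates8) == 8, all(rates8 >= 0))
  r <- rates8
  Q <- matrix(0, 4, 4, dimnames = list(c("00", "01", "10", "11"),
                                       c("00", "01", "10", "11")))
  Q["00", "10"] <- r[1]; Q["01", "11"] <- r[2]
  Q["10", "00"] <- r[3]; Q["11", "01"] <- r[4]
  Q["00", "01"] <- r[5]; Q["10", "11"] <- r[6]
  Q["01", "00"] <- r[7]; Q["11", "10"] <- r[8]
  diag(Q) <- -rowSums(Q)
  Q
}

independent_rates8 <- function(rates4) {
  stopifnot(length(rates4) == 4)
  rates4[c(1, 1, 2, 2, 3, 3, 4, 4)]
}

# Stationary distribution of a CTMC rate matrix (left null vector).
stationary_dist <- function(Q) {
  A <- rbind(t(Q), rep(1, 4))
  pi <- tryCatch(as.numeric(qr.solve(A, c(0, 0, 0, 0, 1))),
                 error = function(e) rep(0.25, 4))
  pi <- pmax(pi, 0)
  if (sum(pi) <= 0) return(rep(0.25, 4))
  pi / sum(pi)
}

#' Log-likelihood of a pair of binary characters under a joint CTMC
#'
#' Felsenstein pruning over the 4-state joint chain, with per-branch
#' transition probabilities from the matrix exponential of `Q * length`
#' and the root weighted by the stationary distribution of `Q` (or
#' user-supplied weights).
#'
#' @param tree a `phylo` object.
#' @param char_a,char_b named 0/1 tip vectors (no missing values; prune
#'   missing tips per pair before calling).
#' @param rates8 the 8 dependent-model rates (see [dependent_Q()]); for
#'   the independent model pass `independent = TRUE` with 4 rates.
#' @param independent interpret `rates8` as the 4 independent-model rates.
#' @param root_probs optional root state weights (default: stationary
#'   distribution of the fitted Q).
#' @return log-likelihood.
#' @export
ctmc_loglik <- function(tree, char_a, char_b, rates8, independent = FALSE,
                        root_probs = NULL) {
  if (independent) rates8 <- independent_rates8(rates8)
  Q <- dependent_Q(rates8)
  ctx <- tree_context(tree)
  a <- char_a[ctx$tree$tip.label]; b <- char_b[ctx$tree$tip.label]
  if (anyNA(a) || anyNA(b)) stop("characters must cover all tips; prune missing")
  if (!all(c(a, b) %in% 0:1)) stop("characters must be binary 0/1")
  joint <- as.integer(2 * a + b) # 0..3 == states 00,01,10,11
  if (is.null(root_probs)) root_probs <- stationary_dist(Q)
  len_po <- ctx$len[ctx$po]
  .ctmc_pruning_cpp(ctx$edge_po, len_po, ctx$ntip, ctx$nnode, joint, Q,
                    root_probs)
}

fit_ctmc <- function(tree, a, b, independent, n_starts = 3, seed = 1,
                     extra_starts = list()) {
  npar <- if (independent) 4 else 8
  lb <- log(1e-6); ub <- log(100)
  obj <- function(lr) {
    ll <- tryCatch(ctmc_loglik(tree, a, b, exp(lr), independent = independent),
                   error = function(e) -Inf)
    if (!is.finite(ll)) 1e10 else -ll
  }
  # moment-style start: observed flip fraction over total tree length
  base <- max(0.5 / sum(tree$edge.length) * ape::Ntip(tree) / 4, 1e-4)
  starts <- c(list(rep(log(base), npar)),
              lapply(seq_len(n_starts - 1), function(i)
                log(base) + rnorm(npar, 0, 1.5)),
              extra_starts)
  best <- NULL
  for (s in starts) {
    f <- tryCatch(nlminb(pmin(pmax(s, lb), ub), obj, lower = lb, upper = ub,
                         control = list(rel.tol = 1e-8)),
                  error = function(e) NULL)
    if (!is.null(f) && is.finite(f$objective) &&
        (is.null(best) || f$objective < best$objective)) best <- f
  }
  if (is.null(best)) stop("CTMC optimizer failed from every start")
  list(rates = exp(best$par), logL = -best$objective,
       convergence = best$convergence)
}

#' Likelihood-ratio test of correlated evolution for one character pair
#'
#' Fits the independent (4-rate) and dependent (8-rate) models by
#' maximum likelihood (multi-start, dependent fit seeded with the
#' expanded independent solution) and compares them with a likelihood
#' ratio referred to chi-square with 4 degrees of freedom.
#'
#' @param tree a `phylo` object.
#' @param char_a,char_b named 0/1 tip vectors; tips missing in either are
#'   pruned for this pair.
#' @param n_starts random starts per model fit.
#' @param seed RNG seed.
#' @param alpha significance level for the `significant` flag.
#' @return object of class `pair_test`: `logL_indep`, `logL_dep`, `lr`,
#'   `df`, `p`, `significant`, `degenerate`, `n_tips`, fitted `rates_*`.
#' @export
pair_lrt <- function(tree, char_a, char_b, n_starts = 3, seed = 1,
                     alpha = 0.05) {
  set.seed(seed)
  keep <- intersect(names(char_a)[!is.na(char_a)],
                    names(char_b)[!is.na(char_b)])
  keep <- intersect(keep, tree$tip.label)
  degenerate <- FALSE
  if (length(keep) < 3) degenerate <- TRUE
  if (!degenerate) {
    tr <- ape::keep.tip(tree, keep)
    a <- char_a[tr$tip.label]; b <- char_b[tr$tip.label]
    if (length(unique(a)) < 2 || length(unique(b)) < 2) degenerate <- TRUE
  }
  if (degenerate)
    return(structure(list(logL_indep = NA_real_, logL_dep = NA_real_,
                          lr = NA_real_, df = 4, p = NA_real_,
                          significant = NA, degenerate = TRUE,
                          n_tips = length(keep)),
                     class = "pair_test"))
  fi <- fit_ctmc(tr, a, b, independent = TRUE, n_starts = n_starts)
  fd <- fit_ctmc(tr, a, b, independent = FALSE, n_starts = n_starts,
                 extra_starts = list(log(independent_rates8(fi$rates))))
  lr <- 2 * (fd$logL - fi$logL)
  p <- pchisq(max(lr, 0), df = 4, lower.tail = FALSE)
  structure(list(logL_indep = fi$logL, logL_dep = fd$logL, lr = lr, df = 4,
                 p = p, significant = p < alpha, degenerate = FALSE,
                 n_tips = length(keep), rates_indep = fi$rates,
                 rates_dep = fd$rates),
            class = "pair_test")
}

#' @export
print.pair_test <- function(x, ...) {
  if (x$degenerate) cat("Pair LRT: degenerate pair (excluded)\n")
  else cat(sprintf("Pair LRT: LR = %.3f (df 4), p = %.4g%s\n", x$lr, x$p,
                   if (x$significant) " *" else ""))
  invisible(x)
}

#' Test all adult x tadpole character pairs for correlated evolution
#'
#' Binarizes both matrices (state 0 vs > 0), prunes missing tips per
#' pair, and runs [pair_lrt()] for every pair of one character from each
#' phase. Invariant or too-sparse pairs are flagged degenerate and
#' excluded from the summary.
#'
#' @param tree a `phylo` object.
#' @param mat_a,mat_b [char_matrix()] objects for the two phases.
#' @param n_starts,seed,alpha passed to [pair_lrt()].
#' @return data.frame with one row per pair (`char_a`, `char_b`,
#'   `logL_indep`, `logL_dep`, `lr`, `p`, `significant`, `degenerate`).
#' @export
pairwise_lrt_all <- function(tree, mat_a, mat_b, n_starts = 3, seed = 1,
                             alpha = 0.05) {
  ba <- recode_characters(mat_a, "binary")$data
  bb <- recode_characters(mat_b, "binary")$data
  grid <- expand.grid(char_a = seq_len(ncol(ba)), char_b = seq_len(ncol(bb)))
  res <- lapply(seq_len(nrow(grid)), function(i) {
    ca <- setNames(ba[, grid$char_a[i]], rownames(ba))
    cb <- setNames(bb[, grid$char_b[i]], rownames(bb))
    r <- pair_lrt(tree, ca, cb, n_starts = n_starts,
                  seed = seed + i, alpha = alpha)
    data.frame(char_a = grid$char_a[i], char_b = grid$char_b[i],
               logL_indep = r$logL_indep, logL_dep = r$logL_dep,
               lr = r$lr, p = r$p, significant = r$significant,
               degenerate = r$degenerate)
  })
  do.call(rbind, res)
}

#' Summarize pairwise correlated-evolution tests
#'
#' Counts significant pairs, reports the percentage (one decimal), and
#' appends Benjamini-Hochberg adjusted q-values when raw p-values are
#' available. Degenerate pairs are excluded from the totals.
#'
#' @param results data.frame with a logical `significant` column and
#'   optionally `p` and `degenerate` columns (e.g. from
#'   [pairwise_lrt_all()]).
#' @param alpha significance level used for the FDR count.
#' @return list with `n_significant`, `n_total`, `percent` (1 decimal),
#'   `n_significant_fdr` (if p available) and the augmented `results`.
#' @export
summarize_pairs <- function(results, alpha = 0.05) {
  if (!NROW(results)) stop("need at least one result")
  if (!is.null(results$degenerate))
    results <- results[!results$degenerate, , drop = FALSE]
  n_total <- nrow(results)
  n_sig <- sum(results$significant, na.rm = TRUE)
  out <- list(n_significant = n_sig, n_total = n_total,
              percent = round(100 * n_sig / n_total, 1))
  if (!is.null(results$p)) {
    results$q <- p.adjust(results$p, method = "BH")
    out$n_significant_fdr <- sum(results$q < alpha, na.rm = TRUE)
  }
  out$results <- results
  out
}
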