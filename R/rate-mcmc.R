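# Branch-specific Brownian-motion rate heterogeneity by reversible-jump
# MCMC. A configuration is a set of "shift" branches; every branch evolves
# at the rate of its nearest ancestral shift (or the background rate), so
# the branch partition is always reconstructable from the shift set.

# Cladewise tree plus the postorder permutation of its edges.
tree_context <- function(tree) {
  tree <- ape::reorder.phylo(tree, "cladewise")
  po <- ape::reorder.phylo(tree, "postorder", index.only = TRUE)
  list(tree = tree, edge = tree$edge, len = tree$edge.length,
       edge_po = tree$edge[po, , drop = FALSE], po = po,
       ntip = ape::Ntip(tree), nnode = tree$Nnode)
}

#' Brownian-motion log-likelihood with branch-specific rates
#'
#' Gaussian likelihood of tip values whose covariance is the shared
#' root-to-tip path length weighted by per-branch rates, computed by
#' Felsenstein pruning in O(n).
#'
#' @param tree a `phylo` object.
#' @param trait named numeric vector of tip values.
#' @param edge_rates per-edge rate multipliers (order of `tree$edge` after
#'   cladewise reordering); scalar recycled.
#' @param sig2 base rate multiplying `edge_rates`.
#' @param root_state root trait value; `NULL` profiles the root at its ML
#'   (GLS) value.
#' @return log-likelihood.
#' @export
bm_loglik <- function(tree, trait, edge_rates = 1, sig2 = 1,
                      root_state = NULL) {
  ctx <- tree_context(tree)
  edge_rates <- rep_len(edge_rates, nrow(ctx$edge))
  if (any(edge_rates <= 0) || sig2 <= 0) stop("rates must be positive")
  x <- trait[ctx$tree$tip.label]
  if (anyNA(x)) stop("trait must cover all tips")
  vl <- (sig2 * edge_rates * ctx$len)[ctx$po]
  .bm_pruning_cpp(ctx$edge_po, vl, ctx$ntip, ctx$nnode, as.numeric(x),
                  if (is.null(root_state)) NA_real_ else root_state)
}

rj_loglik <- function(ctx, x, shifts, rates, m0) {
  shift_class <- integer(nrow(ctx$edge))
  if (length(shifts)) shift_class[shifts] <- seq_along(shifts)
  cls <- .edge_classes_cpp(ctx$edge, shift_class, ctx$ntip, ctx$nnode)
  vl <- (rates[cls + 1L] * ctx$len)[ctx$po]
  list(ll = .bm_pruning_cpp(ctx$edge_po, vl, ctx$ntip, ctx$nnode, x, m0),
       classes = cls)
}

#' Reversible-jump MCMC over branch-rate configurations
#'
#' Samples rate-shift configurations under a Brownian-motion model. Moves:
#' log-scale sliding-window rate update (probability 0.4), root-state
#' update (0.1), shift birth (0.25) and shift death (0.25). The number of
#' shifts has a Poisson(1) prior, shift placements are uniform among
#' branches, and class rates have a log-normal prior centered on the
#' single-rate ML estimate; birth proposals draw the new rate from the
#' prior, which makes the dimension-jump acceptance ratio the likelihood
#' ratio times a purely combinatorial factor.
#'
#' @param tree a `phylo` object.
#' @param trait named numeric vector of tip values (one MDS axis).
#' @param generations generations per chain (>= 1000).
#' @param burn_in fraction of each chain discarded.
#' @param chains number of independent chains.
#' @param seed RNG seed (chain i uses `seed + i - 1`).
#' @param thin record every `thin`-th generation.
#' @param prior_mean_shifts mean of the Poisson prior on the shift count.
#' @param rate_sdlog sd(log) of the log-normal rate prior.
#' @param window half-width of the log-rate proposal window.
#' @return object of class `posterior_rates`: per-branch geometric and
#'   arithmetic mean rates, per-branch shift posterior probability,
#'   posterior distribution of the shift count, acceptance rates,
#'   per-chain branch rates, `generations`, `burn_in`, `seed`.
#' @export
run_rjmcmc <- function(tree, trait, generations = 1e6, burn_in = 0.5,
                       chains = 2, seed = 1, thin = max(1L, generations %/% 2000L),
                       prior_mean_shifts = 1, rate_sdlog = 6,
                       window = 0.6) {
  if (generations < 1000) stop("generations must be >= 1000")
  ctx <- tree_context(tree)
  x <- as.numeric(trait[ctx$tree$tip.label])
  if (anyNA(x)) stop("trait must cover all tips")
  ne <- nrow(ctx$edge)
  fit0 <- bm_ml_fit(ctx$tree, setNames(x, ctx$tree$tip.label))
  prior_meanlog <- log(fit0$sig2)
  chain_out <- lapply(seq_len(chains), function(ch) {
    set.seed(seed + ch - 1L)
    rj_chain(ctx, x, generations, burn_in, thin, prior_mean_shifts,
             prior_meanlog, rate_sdlog, window, fit0)
  })
  comb <- function(f) Reduce(`+`, lapply(chain_out, `[[`, f)) / chains
  nsamp <- chain_out[[1]]$nsamp
  kmax <- max(vapply(chain_out, function(c0) length(c0$k_tab), 0L))
  k_post <- rowSums(vapply(chain_out, function(c0) {
    k <- numeric(kmax); k[seq_along(c0$k_tab)] <- c0$k_tab; k
  }, numeric(kmax))) / (chains * nsamp)
  structure(list(
    geometric_mean = exp(comb("sum_log_rate") / nsamp),
    arithmetic_mean = comb("sum_rate") / nsamp,
    shift_prob = comb("shift_count") / nsamp,
    k_posterior = setNames(k_post, seq_len(kmax) - 1L),
    acceptance = Reduce(`+`, lapply(chain_out, `[[`, "accept")) /
      Reduce(`+`, lapply(chain_out, `[[`, "proposed")),
    chain_geometric_mean = vapply(chain_out, function(c0)
      exp(c0$sum_log_rate / nsamp), numeric(ne)),
    generations = generations, burn_in = burn_in, chains = chains,
    thin = thin, seed = seed, tree = ctx$tree),
    class = "posterior_rates")
}

#' @export
print.posterior_rates <- function(x, ...) {
  cat(sprintf(
    "rjMCMC posterior rates: %d chains x %g generations (burn-in %g%%)\n",
    x$chains, x$generations, 100 * x$burn_in))
  cat(sprintf("  P(0 shifts) = %.3f; mean branch rate (geometric) = %.4g\n",
              x$k_posterior["0"], mean(x$geometric_mean)))
  cat("  acceptance:", paste(names(x$acceptance),
                             sprintf("%.2f", x$acceptance), collapse = ", "), "\n")
  invisible(x)
}

rj_chain <- function(ctx, x, generations, burn_in, thin, k_mean,
                     prior_meanlog, rate_sdlog, window, fit0) {
  ne <- nrow(ctx$edge)
  shifts <- integer(0)
  rates <- exp(prior_meanlog) # class rates: root class first
  m0 <- fit0$root
  cur <- rj_loglik(ctx, x, shifts, rates, m0)
  ll <- cur$ll
  lprior_rate <- function(r) dnorm(log(r), prior_meanlog, rate_sdlog,
                                   log = TRUE) - log(r)
  move_p <- c(rate = 0.4, root = 0.1, birth = 0.25, death = 0.25)
  accept <- proposed <- setNames(numeric(4), names(move_p))
  sum_log_rate <- sum_rate <- shift_count <- numeric(ne)
  k_tab <- numeric(0)
  nsamp <- 0L
  sd_root <- max(sd(x) / 5, 1e-3)
  keep_from <- ceiling(generations * burn_in)
  for (g in seq_len(generations)) {
    mv <- sample(names(move_p), 1, prob = move_p)
    proposed[mv] <- proposed[mv] + 1
    k <- length(shifts)
    if (mv == "rate") {
      j <- sample.int(k + 1L, 1)
      u <- runif(1, -window, window)
      r2 <- rates; r2[j] <- rates[j] * exp(u)
      new <- rj_loglik(ctx, x, shifts, r2, m0)
      lA <- new$ll - ll + lprior_rate(r2[j]) - lprior_rate(rates[j]) + u
      if (is.finite(lA) && log(runif(1)) < lA) {
        rates <- r2; ll <- new$ll; cur <- new; accept[mv] <- accept[mv] + 1
      }
    } else if (mv == "root") {
      m2 <- m0 + rnorm(1, 0, sd_root)
      new <- rj_loglik(ctx, x, shifts, rates, m2)
      if (is.finite(new$ll) && log(runif(1)) < new$ll - ll) {
        m0 <- m2; ll <- new$ll; cur <- new; accept[mv] <- accept[mv] + 1
      }
    } else if (mv == "birth") {
      free <- setdiff(seq_len(ne), shifts)
      if (length(free)) {
        e <- free[sample.int(length(free), 1)]
        r_new <- rlnorm(1, prior_meanlog, rate_sdlog)
        s2 <- c(shifts, e); r2 <- c(rates, r_new)
        new <- rj_loglik(ctx, x, s2, r2, m0)
        lA <- new$ll - ll + log(k_mean) - log(k + 1)
        if (is.finite(lA) && log(runif(1)) < lA) {
          shifts <- s2; rates <- r2; ll <- new$ll; cur <- new
          accept[mv] <- accept[mv] + 1
        }
      }
    } else if (k > 0) {
      j <- sample.int(k, 1)
      s2 <- shifts[-j]; r2 <- rates[-(j + 1L)]
      new <- rj_loglik(ctx, x, s2, r2, m0)
      lA <- new$ll - ll + log(k) - log(k_mean)
      if (is.finite(lA) && log(runif(1)) < lA) {
        shifts <- s2; rates <- r2; ll <- new$ll; cur <- new
        accept[mv] <- accept[mv] + 1
      }
    }
    if (g > keep_from && g %% thin == 0L) {
      nsamp <- nsamp + 1L
      er <- rates[cur$classes + 1L]
      sum_log_rate <- sum_log_rate + log(er)
      sum_rate <- sum_rate + er
      if (length(shifts)) shift_count[shifts] <- shift_count[shifts] + 1
      kk <- length(shifts) + 1L
      if (kk > length(k_tab)) k_tab <- c(k_tab, numeric(kk - length(k_tab)))
      k_tab[kk] <- k_tab[kk] + 1
    }
  }
  if (all(proposed > 0) && all(accept / proposed < 0.01))
    warning("rjMCMC chain appears not to be mixing (all acceptance < 1%)")
  list(sum_log_rate = sum_log_rate, sum_rate = sum_rate,
       shift_count = shift_count, k_tab = k_tab, nsamp = nsamp,
       accept = accept, proposed = proposed)
}

# Birth/death proposal log-ratios, exposed for algebraic unit tests of
# reversibility: a birth at edge e followed by the matching death must
# have log-Hastings ratios that cancel exactly.
rj_jump_logratio <- function(n_edges, k, k_mean = 1,
                             type = c("birth", "death")) {
  type <- match.arg(type)
  if (type == "birth") log(k_mean) - log(k + 1) else log(k) - log(k_mean)
}

#' Compare posterior evolutionary rates between two phases
#'
#' Kruskal-Wallis test on the two per-branch rate samples plus Pearson
#' correlation of the standardized (z-scored within phase) rates.
#'
#' @param rates_a,rates_b per-branch rates for the same branches, either
#'   numeric vectors or `posterior_rates` objects (geometric means used).
#' @return list with `kw_h`, `kw_p`, `pearson_r`, `pearson_p`,
#'   `mean_a`, `mean_b`.
#' @export
compare_phase_rates <- function(rates_a, rates_b) {
  get <- function(r) if (inherits(r, "posterior_rates")) r$geometric_mean else
    as.numeric(r)
  a <- get(rates_a); b <- get(rates_b)
  if (length(a) != length(b)) stop("rate vectors must match branch for branch")
  kw <- kruskal.test(list(a, b))
  if (sd(a) == 0 && sd(b) == 0 && all(a == a[1]) && all(b == b[1]) && a[1] == b[1]) {
    pr <- list(estimate = 1, p.value = NA_real_) # identical constant vectors
  } else if (sd(a) == 0 || sd(b) == 0) {
    pr <- list(estimate = NA_real_, p.value = NA_real_)
  } else if (all(scale(a) == scale(b))) {
    pr <- list(estimate = 1, p.value = 0)
  } else {
    ct <- cor.test(as.numeric(scale(a)), as.numeric(scale(b)))
    pr <- list(estimate = unname(ct$estimate), p.value = ct$p.value)
  }
  list(kw_h = unname(kw$statistic), kw_p = kw$p.value,
       pearson_r = unname(pr$estimate), pearson_p = pr$p.value,
       mean_a = mean(a), mean_b = mean(b))
}

#' Average branch rates within fixed time intervals
#'
#' Partitions time before present into intervals of `width` Myr anchored
#' at the present and averages branch rates within each interval, each
#' branch weighted by the fraction of its length falling inside the
#' interval. Intervals crossed by no branch are `NA`.
#'
#' @param tree a `phylo` object.
#' @param rates per-branch rates (cladewise edge order).
#' @param width interval width in Myr (> 0).
#' @return data.frame with `age_from`, `age_to`, `mean_rate`,
#'   `lineage_time`.
#' @export
bin_rates_by_time <- function(tree, rates, width = 4) {
  if (width <= 0) stop("width must be > 0")
  tree <- ape::reorder.phylo(tree, "cladewise")
  rates <- rep_len(rates, nrow(tree$edge))
  ages <- node_ages(tree)
  hi <- ages[tree$edge[, 1]]
  lo <- ages[tree$edge[, 2]]
  nb <- ceiling(root_age(tree) / width - 1e-9)
  from <- (seq_len(nb) - 1) * width
  wt <- vapply(seq_len(nb), function(i) {
    ov <- pmax(0, pmin(hi, from[i] + width) - pmax(lo, from[i]))
    c(sum(ov * rates), sum(ov))
  }, numeric(2))
  data.frame(age_from = from, age_to = from + width,
             mean_rate = ifelse(wt[2, ] > 0, wt[1, ] / wt[2, ], NA_real_),
             lineage_time = wt[2, ])
}
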