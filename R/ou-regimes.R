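# Multi-optimum Ornstein-Uhlenbeck regime-shift detection: stepwise
# forward addition of shifts by AICc, backward collapse of convergent
# regimes, and a parametric-bootstrap convergence test.
#
# Model: per axis, dX = alpha (theta_regime - X) dt + sqrt(sig2) dW, with
# the root state at the root-regime optimum. For an ultrametric tree the
# tip mean is a weighted sum of regime optima along the root-to-tip path,
#   E[X_i] = theta_root e^{-aT} +
#            sum_segments theta_r (e^{-a(T - t_end)} - e^{-a(T - t_start)}),
# and the covariance is
#   V_ij = sig2/(2a) * e^{-a d_ij} * (1 - e^{-2a s_ij}),
# with s_ij the shared time from the root and d_ij the patristic distance.

ou_context <- function(tree) {
  tree <- validate_tree(tree)
  tree <- ape::reorder.phylo(tree, "cladewise")
  dep <- node_depths(tree)
  s <- shared_time_matrix(tree)
  ntip <- ape::Ntip(tree)
  T <- root_age(tree)
  tip_sets <- edge_tip_sets(tree)
  ne <- nrow(tree$edge)
  inc <- matrix(0, ne, ntip) # edge x tip incidence (tip below edge)
  for (e in seq_len(ne)) inc[e, tip_sets[[e]]] <- 1
  list(tree = tree, ntip = ntip, T = T, dep = dep, s = s,
       d = outer(dep[1:ntip], dep[1:ntip], "+") - 2 * s,
       tip_sets = tip_sets, inc = inc,
       e_top = dep[tree$edge[, 1]], e_bot = pmin(dep[tree$edge[, 2]], T))
}

# Mean design matrix W (tips x regimes) so that E[X] = W theta.
ou_weights <- function(ctx, painting, alpha) {
  contrib <- exp(-alpha * (ctx$T - ctx$e_bot)) - exp(-alpha * (ctx$T - ctx$e_top))
  W0 <- rowsum(ctx$inc * contrib, painting$edge_regime)
  W <- matrix(0, ctx$ntip, painting$n_regimes)
  W[, as.integer(rownames(W0))] <- t(W0)
  W[, painting$root_regime] <- W[, painting$root_regime] + exp(-alpha * ctx$T)
  W
}

# Unit-sig2 covariance; sig2 and theta are profiled out analytically.
ou_corr <- function(ctx, alpha) {
  exp(-alpha * ctx$d) * (1 - exp(-2 * alpha * ctx$s)) / (2 * alpha)
}

# Profile log-likelihood (theta by GLS, sig2 analytic) for one axis at a
# given alpha. Returns -Inf for numerically singular designs.
ou_profile <- function(ctx, painting, alpha, x) {
  C <- ou_corr(ctx, alpha)
  if (!all(is.finite(C))) return(list(logL = -Inf))
  ch <- tryCatch(chol(C), error = function(e) NULL)
  if (is.null(ch)) return(list(logL = -Inf))
  W <- ou_weights(ctx, painting, alpha)
  n <- ctx$ntip
  Wt <- backsolve(ch, W, transpose = TRUE)
  xt <- backsolve(ch, x, transpose = TRUE)
  qrW <- qr(Wt)
  if (qrW$rank < ncol(W)) return(list(logL = -Inf))
  theta <- qr.coef(qrW, xt)
  r <- xt - Wt %*% theta
  sig2 <- sum(r^2) / n
  if (sig2 <= 0) return(list(logL = -Inf))
  logL <- -n / 2 * log(2 * pi * sig2) - sum(log(diag(ch))) - n / 2
  list(logL = logL, theta = as.numeric(theta), sig2 = sig2)
}

# Optimize alpha for one axis (bounded 1-D search on log alpha). The
# tolerance is on log alpha; 0.01 resolves AICc to well under 0.1 units.
ou_fit_axis <- function(ctx, painting, x, alpha_range = c(1e-5, 50),
                        tol = 0.01) {
  f <- function(la) {
    ll <- ou_profile(ctx, painting, exp(la), x)$logL
    if (!is.finite(ll)) 1e10 else -ll
  }
  opt <- optimize(f, log(alpha_range), tol = tol)
  alpha <- exp(opt$minimum)
  c(list(alpha = alpha), ou_profile(ctx, painting, alpha, x))
}

#' Fit a multi-optimum OU model under a fixed regime painting
#'
#' For each trait axis, selection strength `alpha` and diffusion `sig2`
#' are optimized (theta profiled out by GLS); axes share the painting but
#' have independent parameters. The AICc parameter count is
#' `K = n_regimes * n_axes + 2 * n_axes + n_shifts` (optima, alpha and
#' sig2 per axis, plus shift placements), with effective sample size
#' `n_tips * n_axes`.
#'
#' @param tree ultrametric `phylo` object.
#' @param traits named vector or matrix (tips x axes) of trait values.
#' @param painting a [paint_from_shifts()] regime painting.
#' @return object of class `ou_fit`.
#' @export
fit_ou_model <- function(tree, traits, painting) {
  ctx <- ou_context(tree)
  fit_ou_painting(ctx, as_trait_matrix(traits, ctx$tree), painting)
}

as_trait_matrix <- function(traits, tree) {
  X <- as.matrix(traits)
  if (is.null(rownames(X))) stop("traits must be named by species")
  if (!all(tree$tip.label %in% rownames(X))) stop("traits must cover all tips")
  X[tree$tip.label, , drop = FALSE]
}

fit_ou_painting <- function(ctx, X, painting, n_shifts = length(painting$shift_edges)) {
  axes <- lapply(seq_len(ncol(X)), function(j)
    ou_fit_axis(ctx, painting, X[, j]))
  logL <- vapply(axes, `[[`, 0, "logL")
  k <- ncol(X)
  K <- painting$n_regimes * k + 2 * k + n_shifts
  neff <- ctx$ntip * k
  aicc <- if (neff - K - 1 <= 0) Inf else
    -2 * sum(logL) + 2 * K + 2 * K * (K + 1) / (neff - K - 1)
  structure(list(
    painting = painting, n_regimes = painting$n_regimes,
    shift_edges = painting$shift_edges, n_shifts = n_shifts,
    alpha = vapply(axes, `[[`, 0, "alpha"),
    sig2 = vapply(axes, `[[`, 0, "sig2"),
    theta = do.call(cbind, lapply(axes, `[[`, "theta")),
    logL = logL, K = K, AICc = aicc, n = ctx$ntip, k_axes = k),
    class = "ou_fit")
}

#' @export
print.ou_fit <- function(x, ...) {
  cat(sprintf("OU fit: %d regime(s), %d shift(s), %d axis/axes\n",
              x$n_regimes, x$n_shifts, x$k_axes))
  cat(sprintf("  logL = %.4f, K = %d, AICc = %.4f\n", sum(x$logL), x$K, x$AICc))
  cat(sprintf("  alpha = %s (half-life %s Myr)\n",
              paste(signif(x$alpha, 4), collapse = ", "),
              paste(signif(half_life(x$alpha), 4), collapse = ", ")))
  invisible(x)
}

#' Dense-matrix OU (Hansen) log-likelihood
#'
#' Direct multivariate-normal evaluation for one trait axis under an
#' explicit regime painting and parameters; the reference form of the
#' likelihood that the profile machinery optimizes.
#'
#' @param tree ultrametric `phylo` object.
#' @param painting a regime painting.
#' @param alpha,sig2 OU parameters (> 0).
#' @param theta optimum per regime.
#' @param trait named tip values, one axis.
#' @return log-likelihood.
#' @export
hansen_loglik <- function(tree, painting, alpha, sig2, theta, trait) {
  if (alpha <= 0) stop("alpha must be > 0")
  if (sig2 <= 0) stop("sig2 must be > 0")
  ctx <- ou_context(tree)
  x <- as_trait_matrix(trait, ctx$tree)[, 1]
  mu <- as.numeric(ou_weights(ctx, painting, alpha) %*% theta)
  V <- sig2 * ou_corr(ctx, alpha)
  ch <- chol(V)
  r <- backsolve(ch, x - mu, transpose = TRUE)
  -ctx$ntip / 2 * log(2 * pi) - sum(log(diag(ch))) - sum(r^2) / 2
}

#' Forward stepwise search for OU regime shifts
#'
#' Starts from a single-regime model and repeatedly adds the one shift
#' (a new regime on the clade subtended by a branch, until overridden by
#' nested shifts) that most decreases the across-axes AICc, stopping when
#' no candidate decreases it. Ties break to the earliest branch in
#' preorder. Terminal branches are eligible.
#'
#' @param tree ultrametric `phylo` object.
#' @param traits named vector or matrix (tips x axes).
#' @param max_shifts optional cap on the number of shifts.
#' @param trace print progress.
#' @return an `ou_fit` with extra fields `aicc_trace` (AICc after each
#'   accepted step, starting with the single-regime model) and `tree`.
#' @export
surface_forward <- function(tree, traits, max_shifts = Inf, trace = FALSE) {
  ctx <- ou_context(tree)
  X <- as_trait_matrix(traits, ctx$tree)
  shifts <- integer(0)
  cur <- fit_ou_painting(ctx, X, paint_from_shifts(ctx$tree, shifts))
  aicc_trace <- cur$AICc
  ne <- nrow(ctx$tree$edge)
  while (length(shifts) < max_shifts) {
    best <- NULL
    for (e in setdiff(seq_len(ne), shifts)) {
      fit <- tryCatch(
        fit_ou_painting(ctx, X, paint_from_shifts(ctx$tree, c(shifts, e))),
        error = function(err) NULL)
      if (is.null(fit) || !is.finite(fit$AICc)) next
      if (is.null(best) || fit$AICc < best$AICc - 1e-12) {
        best <- fit
        best_e <- e
      }
    }
    if (is.null(best) || best$AICc >= cur$AICc) break
    shifts <- sort(c(shifts, best_e))
    cur <- best
    aicc_trace <- c(aicc_trace, cur$AICc)
    if (trace)
      message("added shift at edge ", best_e, ", AICc = ",
              format(cur$AICc, digits = 8))
  }
  cur$aicc_trace <- aicc_trace
  cur$tree <- ctx$tree
  cur$trait_matrix <- X
  cur
}

# Merge regime `s` into regime `r` of a painting, renumbering regimes
# contiguously (preorder of first appearance). Shift edges are retained:
# after a collapse two regimes separated by a shift may share an optimum,
# which is exactly the "convergence" structure the backward phase scores.
collapse_regimes <- function(painting, r, s) {
  er <- painting$edge_regime
  er[er == s] <- r
  root <- if (painting$root_regime == s) r else painting$root_regime
  ids <- unique(c(root, er))
  map <- match(seq_len(max(er)), ids)
  structure(list(edge_regime = map[er], root_regime = map[root],
                 shift_edges = painting$shift_edges,
                 n_regimes = length(ids)),
            class = "regime_painting")
}

#' Backward collapse of convergent OU regimes
#'
#' Iteratively merges the pair of regimes whose collapse (shared optimum
#' across all axes) most decreases AICc, stopping when no merge improves
#' it. The drop in the number of distinct regimes is the convergence
#' measure used by [convergence_pvalue()].
#'
#' @param fit an `ou_fit` from [surface_forward()] (must carry its tree).
#' @return an `ou_fit` with fields `delta_k` (regimes collapsed) and
#'   `tree`.
#' @export
surface_backward <- function(fit) {
  stopifnot(inherits(fit, "ou_fit"), !is.null(fit$tree))
  ctx <- ou_context(fit$tree)
  X <- fit$trait_matrix
  if (is.null(X)) stop("fit lacks trait data; refit with surface_forward()")
  cur <- fit
  painting <- fit$painting
  repeat {
    k <- painting$n_regimes
    if (k < 2) break
    best <- NULL
    for (r in seq_len(k - 1)) for (s in (r + 1):k) {
      p2 <- collapse_regimes(painting, r, s)
      f2 <- tryCatch(fit_ou_painting(ctx, X, p2, n_shifts = cur$n_shifts),
                     error = function(err) NULL)
      if (is.null(f2) || !is.finite(f2$AICc)) next
      if (is.null(best) || f2$AICc < best$fit$AICc - 1e-12)
        best <- list(fit = f2, painting = p2)
    }
    if (is.null(best) || best$fit$AICc >= cur$AICc) break
    cur <- best$fit
    painting <- best$painting
  }
  cur$tree <- fit$tree
  cur$trait_matrix <- X
  cur$delta_k <- fit$n_regimes - cur$n_regimes
  cur
}

#' Parametric-bootstrap test for phenotypic convergence
#'
#' Compares the observed amount of regime collapse with a null of
#' non-convergent evolution: `nrep` datasets are simulated under the
#' forward fit's shift structure, `alpha` and `sig2`, but with every
#' regime stepping to its *own* optimum (offsets from the parent regime
#' redrawn as Gaussian with the root-mean-square step size of the fitted
#' optima, so the null preserves the scale of divergence while making
#' exact convergence a measure-zero event). The forward search and
#' backward collapse are rerun on each simulated dataset and
#' `p = (1 + #(sim delta_k >= observed delta_k)) / (nrep + 1)`.
#'
#' @param tree ultrametric `phylo` object.
#' @param fit forward `ou_fit` (from [surface_forward()]).
#' @param nrep number of bootstrap replicates (>= 10).
#' @param seed RNG seed.
#' @return list with `p`, `delta_k_obs`, `delta_k_sim`, `nrep`, `seed`.
#' @export
convergence_pvalue <- function(tree, fit, nrep = 100, seed = 1) {
  if (nrep < 10) stop("nrep must be >= 10")
  stopifnot(inherits(fit, "ou_fit"))
  bwd <- surface_backward(fit)
  dk_obs <- bwd$delta_k
  if (!is.null(fit$tree)) tree <- fit$tree # painting indexes this edge order
  parents <- regime_parents(tree, fit$painting)
  step_sd <- vapply(seq_len(fit$k_axes), function(j) {
    if (fit$painting$n_regimes < 2)
      return(sqrt(fit$sig2[j] / (2 * fit$alpha[j])))
    steps <- fit$theta[-1, j] - fit$theta[parents[-1], j]
    max(sqrt(mean(steps^2)), 1e-8)
  }, numeric(1))
  set.seed(seed)
  dk_sim <- vapply(seq_len(nrep), function(i) {
    X <- vapply(seq_len(fit$k_axes), function(j) {
      th <- numeric(fit$painting$n_regimes)
      th[1] <- fit$theta[1, j]
      for (r in seq_len(fit$painting$n_regimes)[-1])
        th[r] <- th[parents[r]] + rnorm(1, 0, step_sd[j])
      sim_ou(tree, fit$painting, fit$alpha[j], fit$sig2[j], th)
    }, numeric(fit$n))
    rownames(X) <- tree$tip.label
    f <- surface_forward(tree, X)
    surface_backward(f)$delta_k
  }, numeric(1))
  list(p = (1 + sum(dk_sim >= dk_obs)) / (nrep + 1),
       delta_k_obs = dk_obs, delta_k_sim = dk_sim, nrep = nrep, seed = seed)
}

#' Phylogenetic half-life of an OU process
#'
#' The expected time to evolve halfway toward a new optimum, `ln(2) /
#' alpha`, in Myr.
#'
#' @param alpha selection strength (1/Myr, > 0); vectorized.
#' @return numeric vector of half-lives.
#' @export
half_life <- function(alpha) {
  if (any(alpha <= 0)) stop("alpha must be > 0")
  log(2) / alpha
}
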