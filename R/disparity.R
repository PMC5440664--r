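# Disparity-through-time curves and the morphological disparity index
# (MDI): the signed area between the observed relative-disparity curve and
# the median curve of Brownian-motion simulations on the same tree.
# Negative MDI means subclades partition morphospace early, the classic
# signature of adaptive radiation.

#' Average squared pairwise distance among points
#'
#' The disparity metric: mean squared Euclidean distance over all
#' unordered pairs of points.
#'
#' @param x numeric vector (one trait) or matrix (points in rows).
#' @return scalar disparity.
#' @export
disparity <- function(x) {
  x <- as.matrix(x)
  m <- nrow(x)
  if (m < 2) stop("need at least 2 points")
  # sum_{i<j} |xi - xj|^2 = m sum|xi|^2 - |sum xi|^2
  tot <- m * sum(x^2) - sum(colSums(x)^2)
  2 * tot / (m * (m - 1))
}

#' Disparity-through-time curve and MDI for one trait axis
#'
#' Computes, at the age of each internal node (root first), the mean
#' relative disparity of the subclades whose ancestral lineage crosses
#' that age (subclade disparity divided by whole-tree disparity; the root
#' point is 1 by construction). The observed curve is compared with
#' `nsim` Brownian-motion simulations whose rate is the ML estimate from
#' the data; MDI is the trapezoid integral, over relative time
#' (0 = root, 1 = most recent internal node), of observed minus the
#' pointwise median simulated curve.
#'
#' @param tree ultrametric `phylo` object.
#' @param trait named numeric vector covering all tips (one MDS axis).
#' @param nsim number of BM simulations (>= 2).
#' @param seed RNG seed.
#' @return object of class `dtt_result`: `times` (relative), `ages`
#'   (Myr), `observed`, `sim` (matrix, one column per simulation),
#'   `median_sim`, `mdi`, `sig2_ml`, `nsim`, `seed`.
#' @export
dtt_curve <- function(tree, trait, nsim = 1000, seed = 1) {
  if (nsim < 2) stop("nsim must be >= 2")
  tree <- validate_tree(tree)
  if (!all(tree$tip.label %in% names(trait)))
    stop("trait must cover all tips")
  x <- trait[tree$tip.label]
  fit <- bm_ml_fit(tree, x)
  set.seed(seed)
  C <- ape::vcv(tree)
  L <- chol(fit$sig2 * C)
  sims <- fit$root + t(L) %*% matrix(rnorm(nrow(C) * nsim), nrow(C))
  rownames(sims) <- rownames(C)
  obs <- dtt_profiles(tree, matrix(x, ncol = 1,
                                   dimnames = list(tree$tip.label, NULL)))
  sim <- dtt_profiles(tree, sims)
  med <- apply(sim$curves, 1, median)
  rel <- obs$rel_times
  mdi <- trapezoid(rel, obs$curves[, 1] - med)
  structure(list(times = rel, ages = obs$ages, observed = obs$curves[, 1],
                 sim = sim$curves, median_sim = med, mdi = mdi,
                 sig2_ml = fit$sig2, nsim = nsim, seed = seed),
            class = "dtt_result")
}

#' @export
print.dtt_result <- function(x, ...) {
  cat(sprintf("DTT: %d node ages, MDI = %.4f (%d BM simulations, seed %d)\n",
              length(x$times), x$mdi, x$nsim, x$seed))
  invisible(x)
}

#' @rdname dtt_curve
#' @param x a `dtt_result`.
#' @export
mdi <- function(x) {
  stopifnot(inherits(x, "dtt_result"))
  x$mdi
}

trapezoid <- function(x, y) sum(0.5 * diff(x) * (y[-1] + y[-length(y)]))

# Relative-disparity profiles for one or many datasets at once. X is an
# ntip x nset matrix; returns curves (ntimes x nset) on the shared grid of
# internal-node ages. Vectorized across datasets: per-clade sums of x and
# x^2 are accumulated postorder, giving each clade's average squared
# pairwise difference in O(edges) per dataset.
dtt_profiles <- function(tree, X) {
  tree <- ape::reorder.phylo(tree, "postorder")
  ntip <- ape::Ntip(tree)
  nn <- ntip + tree$Nnode
  nset <- ncol(X)
  X <- X[tree$tip.label, , drop = FALSE]
  S1 <- matrix(0, nn, nset); S2 <- matrix(0, nn, nset); M <- integer(nn)
  S1[1:ntip, ] <- X; S2[1:ntip, ] <- X^2; M[1:ntip] <- 1L
  for (e in seq_len(nrow(tree$edge))) {
    p <- tree$edge[e, 1]; ch <- tree$edge[e, 2]
    S1[p, ] <- S1[p, ] + S1[ch, ]
    S2[p, ] <- S2[p, ] + S2[ch, ]
    M[p] <- M[p] + M[ch]
  }
  disp <- matrix(0, nn, nset)
  big <- M > 1
  disp[big, ] <- 2 * (M[big] * S2[big, , drop = FALSE] -
                        S1[big, , drop = FALSE]^2) /
    (M[big] * (M[big] - 1))
  total <- disp[ntip + 1L, ]
  if (any(total <= 0)) stop("zero total disparity")
  ages <- node_ages(tree)
  int_ages <- sort(ages[(ntip + 1L):nn], decreasing = TRUE)
  parent_of <- rep(nn + 1L, nn) # sentinel for the root
  parent_of[tree$edge[, 2]] <- tree$edge[, 1]
  parent_age <- c(ages, Inf)[parent_of]
  curves <- matrix(0, length(int_ages), nset)
  curves[1, ] <- 1
  for (i in seq_along(int_ages)[-1]) {
    t_k <- int_ages[i]
    cross <- which(ages <= t_k + 1e-12 & parent_age > t_k + 1e-12 &
                     seq_len(nn) != ntip + 1L)
    curves[i, ] <- colMeans(disp[cross, , drop = FALSE]) / total
  }
  T <- root_age(tree)
  list(rel_times = (T - int_ages) / T, ages = int_ages, curves = curves)
}

# ML fit of single-rate BM (mean and rate) via the tree covariance.
bm_ml_fit <- function(tree, x) {
  C <- ape::vcv(tree)
  x <- x[rownames(C)]
  n <- length(x)
  Ci <- solve(C)
  one <- rep(1, n)
  root <- as.numeric((one %*% Ci %*% x) / (one %*% Ci %*% one))
  r <- x - root
  sig2 <- as.numeric(r %*% Ci %*% r) / n
  list(root = root, sig2 = sig2)
}
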