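# Non-metric multidimensional scaling of the transformation-distance
# matrix into a small number of phenotypic summary axes ("MDS variables").

#' Non-metric multidimensional scaling of a distance matrix
#'
#' Embeds the species in `k` dimensions by NMDS (Kruskal stress-1, global
#' monotone regression), taking the best of `restarts` random starting
#' configurations plus a classical-scaling start. The optimization engine
#' is \code{\link[vegan]{monoMDS}}; restarts and the deterministic seed
#' contract are handled here. Coordinates are returned column-centered.
#'
#' @param D a `phase_dist`, `dist`, or symmetric matrix of dissimilarities.
#' @param k number of ordination axes.
#' @param seed RNG seed governing the random restarts.
#' @param restarts number of random initial configurations (default 20).
#' @param maxit maximum iterations per start.
#' @return object of class `nmds_fit`: `points` (n x k, centered),
#'   `stress` (Kruskal stress-1 in [0, 1]), `k`, `seed`, `restarts`,
#'   `converged`.
#' @export
fit_nmds <- function(D, k, seed = 1, restarts = 20, maxit = 500) {
  if (inherits(D, "phase_dist")) D <- D$dist
  if (!inherits(D, "dist")) {
    D <- as.matrix(D)
    if (!isSymmetric(unname(D))) stop("distance matrix must be symmetric")
    D <- stats::as.dist(D)
  }
  n <- attr(D, "Size")
  if (n < k + 2) stop("need at least k + 2 species")
  if (all(D == 0)) stop("degenerate distance matrix (all zeros)")
  set.seed(seed)
  init <- c(list(cmdscale_start(D, k)),
            lapply(seq_len(restarts), function(i) matrix(rnorm(n * k), n, k)))
  best <- NULL
  for (y in init) {
    fit <- tryCatch(
      vegan::monoMDS(D, y = y, k = k, model = "global", maxit = maxit,
                     weakties = FALSE, # tied counts must get equal fits
                     smin = 1e-6, sfgrmin = 1e-9, sratmax = 0.999999),
      error = function(e) NULL)
    if (!is.null(fit) && (is.null(best) || fit$stress < best$stress))
      best <- fit
  }
  if (is.null(best)) stop("NMDS failed from every starting configuration")
  pts <- scale(best$points, center = TRUE, scale = FALSE)
  attr(pts, "scaled:center") <- NULL
  rownames(pts) <- labels(D)
  colnames(pts) <- paste0("MDS", seq_len(k))
  structure(list(points = pts, stress = best$stress, k = k, seed = seed,
                 restarts = restarts, converged = best$maxits > best$iters,
                 iters = best$iters),
            class = "nmds_fit")
}

cmdscale_start <- function(D, k) {
  y <- suppressWarnings(stats::cmdscale(D, k = k))
  if (ncol(y) < k) y <- cbind(y, matrix(0, nrow(y), k - ncol(y)))
  y + matrix(rnorm(length(y), sd = 1e-4), nrow(y)) # break exact ties
}

#' @export
print.nmds_fit <- function(x, ...) {
  cat(sprintf("NMDS fit: %d points, k = %d, stress-1 = %.4g (seed %d, %d restarts)\n",
              nrow(x$points), x$k, x$stress, x$seed, x$restarts))
  invisible(x)
}

#' Reorder ordination axes by decreasing variance
#'
#' Axes are reindexed so that coordinate variance is non-increasing (ties
#' keep their original order), giving a deterministic "MDS1 carries the
#' most variation" convention. Each axis is also given a deterministic
#' sign: the coordinate of largest magnitude on the axis is made positive.
#'
#' @param fit an `nmds_fit`.
#' @return the fit with reordered, sign-fixed `points`.
#' @export
axis_variance_order <- function(fit) {
  stopifnot(inherits(fit, "nmds_fit"))
  v <- apply(fit$points, 2, var)
  ord <- order(-v) # stable: ties keep original order
  pts <- fit$points[, ord, drop = FALSE]
  for (j in seq_len(ncol(pts))) {
    i <- which.max(abs(pts[, j]))
    if (pts[i, j] < 0) pts[, j] <- -pts[, j]
  }
  colnames(pts) <- paste0("MDS", seq_len(ncol(pts)))
  fit$points <- pts
  fit
}
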