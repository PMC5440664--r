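# Pairwise character-state transformation distances between species, the
# single morphology metric that feeds the ordination.

#' Pairwise character-state transformation distances
#'
#' For every pair of species, sums over all characters scored in both the
#' number of state transformations separating them: `|i - j|` for ordered
#' characters, 1 for unordered characters with differing states, 0
#' otherwise. Missing data are handled by pairwise deletion: a character
#' contributes to a pair only when both species are scored.
#'
#' @param x a [char_matrix()].
#' @param normalize if `TRUE`, divide each pairwise count by the number of
#'   characters comparable for that pair (useful under unequal
#'   missingness). Default is the raw transformation count.
#' @param zero_comparable what to do when a pair shares no scored
#'   character: `"error"` (default) or `"skip-pair"` (distance set `NA`).
#' @return object of class `phase_dist`: list with `dist` (symmetric
#'   matrix, zero diagonal), `n_comparable` (per-pair character counts) and
#'   `normalized`.
#' @export
pairwise_transformations <- function(x, normalize = FALSE,
                                     zero_comparable = c("error", "skip-pair")) {
  stopifnot(inherits(x, "char_matrix"))
  zero_comparable <- match.arg(zero_comparable)
  m <- x$data
  n <- nrow(m)
  if (n < 2) stop("need at least 2 species")
  D <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  N <- matrix(0L, n, n, dimnames = dimnames(D))
  for (j in seq_len(ncol(m))) {
    v <- m[, j]
    ok <- !is.na(v)
    comp <- outer(ok, ok, "&")
    d <- if (x$ordered[j]) abs(outer(v, v, "-")) else (outer(v, v, "!=")) * 1
    d[!comp] <- 0
    D <- D + d
    N <- N + comp
  }
  diag(N) <- ncol(m) - rowSums(is.na(m))
  off <- upper.tri(N)
  if (any(N[off] == 0)) {
    if (zero_comparable == "error")
      stop("species pair(s) with zero comparable characters; ",
           'use zero_comparable = "skip-pair" to mark them NA')
    D[N == 0 & row(N) != col(N)] <- NA
  }
  if (normalize) {
    D <- D / N
    diag(D) <- 0
  }
  structure(list(dist = D, n_comparable = N, normalized = normalize),
            class = "phase_dist")
}

#' @export
print.phase_dist <- function(x, ...) {
  cat("Transformation distance matrix:", nrow(x$dist), "species",
      if (x$normalized) "(normalized)" else "(raw counts)", "\n")
  invisible(x)
}

#' @export
as.matrix.phase_dist <- function(x, ...) x$dist

#' Recode a character matrix under an alternative coding scheme
#'
#' `"as-is"` returns the matrix unchanged; `"all-unordered"` clears all
#' ordered flags; `"binary"` maps state 0 to 0 and any state > 0 to 1
#' (flags cleared, since a two-state character carries no order).
#'
#' @param x a [char_matrix()].
#' @param scheme one of `"as-is"`, `"all-unordered"`, `"binary"`.
#' @return a recoded `char_matrix`.
#' @export
recode_characters <- function(x, scheme = c("as-is", "all-unordered", "binary")) {
  stopifnot(inherits(x, "char_matrix"))
  scheme <- match.arg(scheme)
  switch(scheme,
    "as-is" = x,
    "all-unordered" = char_matrix(x$data, ordered = FALSE),
    "binary" = char_matrix((x$data > 0L) * 1L, ordered = FALSE))
}

#' Drop-k character jackknife of the distance matrix
#'
#' Resampling helper for assessing robustness of the distance matrix to
#' character sampling: repeatedly drops `k` randomly chosen characters and
#' recomputes [pairwise_transformations()].
#'
#' @param x a [char_matrix()].
#' @param k number of characters to drop per replicate.
#' @param nrep number of replicates.
#' @param seed RNG seed.
#' @param ... passed to [pairwise_transformations()].
#' @return list of `phase_dist` objects, one per replicate, each carrying a
#'   `dropped` attribute with the dropped character indices.
#' @export
jackknife_distances <- function(x, k = 1, nrep = 100, seed = 1, ...) {
  stopifnot(inherits(x, "char_matrix"), k >= 1, k < ncol(x$data))
  set.seed(seed)
  lapply(seq_len(nrep), function(i) {
    drop <- sample.int(ncol(x$data), k)
    xi <- char_matrix(x$data[, -drop, drop = FALSE], x$ordered[-drop])
    out <- pairwise_transformations(xi, ...)
    attr(out, "dropped") <- drop
    out
  })
}
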