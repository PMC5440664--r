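# Shared fixtures and independent oracles used across the suite.

# Small fixed trees.
tree3 <- function() ape::read.tree(text = "((A:1,B:1):1,C:2);")
tree2 <- function(len = 1.5) ape::read.tree(
  text = sprintf("(A:%.15g,B:%.15g);", len, len))

# A reproducible simulated tree cached per size.
.sim_tree_cache <- new.env(parent = emptyenv())
sim_tree <- function(n, lambda = 0.12, seed = 5) {
  key <- paste(n, lambda, seed)
  if (is.null(.sim_tree_cache[[key]]))
    .sim_tree_cache[[key]] <- simulate_tree(n, lambda = lambda, seed = seed)
  .sim_tree_cache[[key]]
}

# Dense multivariate-normal log-density oracle.
dmvnorm_log <- function(x, mu, V) {
  r <- x - mu
  ch <- chol(V)
  z <- backsolve(ch, r, transpose = TRUE)
  -length(x) / 2 * log(2 * pi) - sum(log(diag(ch))) - sum(z^2) / 2
}

# Brute-force transformation distance between two species rows.
brute_pair_dist <- function(vi, vj, ordered) {
  d <- 0; n <- 0
  for (k in seq_along(vi)) {
    if (is.na(vi[k]) || is.na(vj[k])) next
    n <- n + 1
    d <- d + if (ordered[k]) abs(vi[k] - vj[k]) else (vi[k] != vj[k]) * 1
  }
  c(d = d, n = n)
}

# Edge, its parent edge, and the child edges of its child node: the
# "immediate neighborhood" used to score shift recovery.
edge_neighborhood <- function(tree, e) {
  pn <- tree$edge[e, 1]; cn <- tree$edge[e, 2]
  unique(c(e, which(tree$edge[, 2] == pn), which(tree$edge[, 1] == cn)))
}

random_char_matrix <- function(n_sp = 6, n_ch = 8, k = 3, p_missing = 0.1,
                               p_ordered = 0.5) {
  m <- matrix(sample(0:(k - 1), n_sp * n_ch, replace = TRUE), n_sp,
              dimnames = list(paste0("s", seq_len(n_sp)), NULL))
  m[runif(length(m)) < p_missing] <- NA
  char_matrix(m, ordered = runif(n_ch) < p_ordered)
}
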