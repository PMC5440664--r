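# Shared tree helpers. All modules use the same time convention: node ages
# are measured backwards from the present (tips at age 0, root at age T).

#' Node heights and ages of an ultrametric tree
#'
#' `node_depths()` returns the time elapsed from the root for every node
#' (tips first, then internal nodes, in ape's numbering). `node_ages()`
#' returns time before present, i.e. `root_age(tree) - node_depths(tree)`.
#'
#' @param tree a rooted `phylo` object with branch lengths in Myr.
#' @return numeric vector of length `Ntip + Nnode`.
#' @export
node_depths <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  ape::node.depth.edgelength(tree)
}

#' @rdname node_depths
#' @export
node_ages <- function(tree) {
  d <- node_depths(tree)
  max(d[seq_len(ape::Ntip(tree))]) - d
}

#' @rdname node_depths
#' @export
root_age <- function(tree) {
  max(node_depths(tree)[seq_len(ape::Ntip(tree))])
}

# Tip indices descending from the child node of every edge.
edge_tip_sets <- function(tree) {
  phangorn::Descendants(tree, tree$edge[, 2], type = "tips")
}

# Root node id (ape convention: Ntip + 1 for rooted trees).
root_node <- function(tree) ape::Ntip(tree) + 1L

is_ultrametric_tol <- function(tree, tol_factor = 1e-6) {
  d <- node_depths(tree)[seq_len(ape::Ntip(tree))]
  T <- max(d)
  (max(d) - min(d)) <= tol_factor * T
}

# Force exact ultrametricity by absorbing small rounding into terminal edges.
renormalize_depths <- function(tree) {
  d <- node_depths(tree)
  ntip <- ape::Ntip(tree)
  T <- mean(d[seq_len(ntip)])
  term <- match(seq_len(ntip), tree$edge[, 2])
  tree$edge.length[term] <- tree$edge.length[term] + (T - d[seq_len(ntip)])
  if (any(tree$edge.length <= 0))
    stop("renormalization produced non-positive terminal branch lengths")
  tree
}

#' Paint branches into selective regimes from a set of shift edges
#'
#' A regime painting assigns every branch of the tree to a regime. Regime 1
#' is the root (background) regime; each shift edge starts a new regime that
#' applies to the whole clade it subtends, until overridden by a nested
#' shift. Shift edges are numbered in preorder so regime ids are contiguous
#' and deterministic.
#'
#' @param tree a `phylo` object.
#' @param shift_edges integer vector of edge indices (rows of `tree$edge`)
#'   where a new regime begins. May be empty.
#' @return object of class `regime_painting`: list with `edge_regime`
#'   (integer per edge), `root_regime` (always 1), `shift_edges` (in
#'   preorder order) and `n_regimes`.
#' @export
paint_from_shifts <- function(tree, shift_edges = integer(0)) {
  tree <- ape::reorder.phylo(tree, "cladewise")
  ne <- nrow(tree$edge)
  shift_edges <- sort(unique(as.integer(shift_edges)))
  if (length(shift_edges) && (min(shift_edges) < 1 || max(shift_edges) > ne))
    stop("shift edge index out of range")
  regime_of_node <- integer(ape::Ntip(tree) + tree$Nnode)
  regime_of_node[root_node(tree)] <- 1L
  edge_regime <- integer(ne)
  next_id <- 1L
  for (e in seq_len(ne)) { # cladewise order guarantees parent before child
    r <- regime_of_node[tree$edge[e, 1]]
    if (e %in% shift_edges) {
      next_id <- next_id + 1L
      r <- next_id
    }
    edge_regime[e] <- r
    regime_of_node[tree$edge[e, 2]] <- r
  }
  structure(list(edge_regime = edge_regime, root_regime = 1L,
                 shift_edges = shift_edges, n_regimes = next_id),
            class = "regime_painting")
}

#' @export
print.regime_painting <- function(x, ...) {
  cat("Regime painting:", x$n_regimes, "regime(s),",
      length(x$shift_edges), "shift edge(s)\n")
  invisible(x)
}

# Shared-time (mrca depth) matrix among tips; used by the OU machinery.
shared_time_matrix <- function(tree) {
  ntip <- ape::Ntip(tree)
  dep <- node_depths(tree)
  m <- ape::mrca(tree)
  s <- matrix(dep[m], ntip, ntip,
              dimnames = list(tree$tip.label, tree$tip.label))
  diag(s) <- dep[seq_len(ntip)]
  s
}
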