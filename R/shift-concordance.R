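# Randomization tests for whether regime shifts in the two life-history
# phases fall on the same nodes of the phylogeny, and whether shifts at
# shared nodes proceed into the same descendant sublineage.

#' Construct a shift set for one life-history phase
#'
#' A shift set records, for one phase, the nodes at which its selective
#' regime shifts, and for each such node the child ("descendant
#' sublineage") that carries the new optimum. Given an `ou_fit`, the shift
#' edges are converted to (parent node, child node) pairs.
#'
#' @param tree a `phylo` object.
#' @param x an `ou_fit`, or an integer vector of shift edge indices
#'   (cladewise order).
#' @param phase label for the phase (e.g. `"adult"`, `"tadpole"`).
#' @return object of class `shift_set`: data.frame with columns `node`
#'   and `child`, plus attributes `phase` and `n`.
#' @export
shift_set <- function(tree, x, phase = "phase") {
  tree <- ape::reorder.phylo(tree, "cladewise")
  edges <- if (inherits(x, "ou_fit")) x$shift_edges else as.integer(x)
  if (!length(edges))
    return(structure(data.frame(node = integer(0), child = integer(0)),
                     phase = phase, class = c("shift_set", "data.frame")))
  if (min(edges) < 1 || max(edges) > nrow(tree$edge))
    stop("shift edge index out of range")
  out <- data.frame(node = tree$edge[edges, 1], child = tree$edge[edges, 2])
  if (anyDuplicated(out$node))
    out <- out[!duplicated(out$node), , drop = FALSE] # one shift per node
  structure(out, phase = phase, class = c("shift_set", "data.frame"))
}

#' Fraction of shift nodes shared between two phases
#'
#' The number of shift nodes common to both phases divided by the larger
#' phase-specific shift count (in the frog study, tadpoles, the phase
#' with more shifts).
#'
#' @param shifts_a,shifts_b `shift_set` objects.
#' @return the shared-shift ratio in [0, 1].
#' @export
shared_shift_ratio <- function(shifts_a, shifts_b) {
  a <- shifts_a$node; b <- shifts_b$node
  if (!length(a) || !length(b)) stop("empty shift set")
  length(intersect(a, b)) / max(length(a), length(b))
}

rand_p <- function(null, observed) (1 + sum(null >= observed)) / (length(null) + 1)

#' Randomization test for concordance of shift nodes between phases
#'
#' Places the observed numbers of shifts uniformly (without replacement)
#' on the eligible nodes of the tree, independently for the two phases,
#' and recomputes the shared-shift ratio each time;
#' `p = (1 + #(null >= observed)) / (nreps + 1)`.
#'
#' @param tree a `phylo` object.
#' @param shifts_a,shifts_b `shift_set` objects.
#' @param nreps number of randomizations.
#' @param seed RNG seed.
#' @param eligible `"internal"` (internal non-root nodes, the default:
#'   shift nodes are parents of shift branches and hence always internal,
#'   so placing null shifts on tips would bias the test) or `"all"`
#'   (every non-root node).
#' @return object of class `randomization_result`: `statistic`, `null`
#'   (length `nreps`), `p`, `nreps`, `seed`.
#' @export
node_concordance_test <- function(tree, shifts_a, shifts_b, nreps = 1000,
                                  seed = 1, eligible = c("internal", "all")) {
  eligible <- match.arg(eligible)
  ntip <- ape::Ntip(tree)
  nodes <- setdiff(seq_len(ntip + tree$Nnode), ntip + 1L)
  if (eligible == "internal") nodes <- nodes[nodes > ntip]
  na <- length(shifts_a$node); nb <- length(shifts_b$node)
  if (max(na, nb) > length(nodes)) stop("more shifts than eligible nodes")
  obs <- shared_shift_ratio(shifts_a, shifts_b)
  set.seed(seed)
  null <- vapply(seq_len(nreps), function(i) {
    ra <- sample(nodes, na); rb <- sample(nodes, nb)
    length(intersect(ra, rb)) / max(na, nb)
  }, numeric(1))
  structure(list(statistic = obs, null = null, p = rand_p(null, obs),
                 nreps = nreps, seed = seed, test = "node concordance"),
            class = "randomization_result")
}

#' @export
print.randomization_result <- function(x, ...) {
  cat(sprintf("%s randomization: statistic = %.4g, p = %.4g (%d reps, seed %d)\n",
              x$test, x$statistic, x$p, x$nreps, x$seed))
  invisible(x)
}

#' Randomization test for concordance of shift direction at shared nodes
#'
#' Restricted to nodes at which both phases shift: the statistic is the
#' fraction of those nodes whose recorded descendant sublineage is the
#' same in both phases (a shift is "unidirectional" when the adult and
#' tadpole optima change in the same daughter lineage). The null
#' redraws, at each shared node and independently per phase, the
#' descendant sublineage uniformly among the node's children.
#'
#' @inheritParams node_concordance_test
#' @return a `randomization_result`.
#' @export
direction_concordance_test <- function(tree, shifts_a, shifts_b,
                                       nreps = 1000, seed = 1) {
  shared <- intersect(shifts_a$node, shifts_b$node)
  if (!length(shared)) stop("no shared shift nodes")
  ca <- shifts_a$child[match(shared, shifts_a$node)]
  cb <- shifts_b$child[match(shared, shifts_b$node)]
  obs <- mean(ca == cb)
  kids <- lapply(shared, function(nd) tree$edge[tree$edge[, 1] == nd, 2])
  set.seed(seed)
  null <- vapply(seq_len(nreps), function(i) {
    mean(vapply(kids, function(k)
      sample(k, 1) == sample(k, 1), logical(1)))
  }, numeric(1))
  structure(list(statistic = obs, null = null, p = rand_p(null, obs),
                 n_shared = length(shared), nreps = nreps, seed = seed,
                 test = "shift direction"),
            class = "randomization_result")
}

#' Histogram of shift ages in fixed time intervals
#'
#' Assigns each shift to the 4-Myr (by default) interval containing its
#' node's age; intervals are anchored at the present: [0, 4), [4, 8), ...
#'
#' @param tree a `phylo` object.
#' @param shifts a `shift_set`.
#' @param width interval width in Myr (> 0).
#' @return data.frame with `age_from`, `age_to`, `n_shifts`.
#' @export
bin_shifts_by_time <- function(tree, shifts, width = 4) {
  if (width <= 0) stop("width must be > 0")
  ages <- node_ages(tree)[shifts$node]
  nb <- max(1, ceiling(root_age(tree) / width - 1e-9))
  idx <- pmin(floor(ages / width), nb - 1) + 1
  data.frame(age_from = (seq_len(nb) - 1) * width,
             age_to = seq_len(nb) * width,
             n_shifts = tabulate(idx, nbins = nb))
}

#' Correlation between two per-interval series
#'
#' Pearson correlation of paired interval values (e.g. shift counts or
#' binned rates for the two phases); intervals missing in either series
#' are dropped pairwise.
#'
#' @param series_a,series_b equal-length numeric vectors.
#' @return list with `r`, `p`, `n` (complete pairs).
#' @export
interval_correlation <- function(series_a, series_b) {
  if (length(series_a) != length(series_b)) stop("series lengths differ")
  ok <- !is.na(series_a) & !is.na(series_b)
  if (sum(ok) < 3) stop("fewer than 3 complete interval pairs")
  a <- series_a[ok]; b <- series_b[ok]
  if (sd(a) == 0 || sd(b) == 0)
    return(list(r = NA_real_, p = NA_real_, n = sum(ok)))
  ct <- suppressWarnings(cor.test(a, b))
  list(r = unname(ct$estimate), p = ct$p.value, n = sum(ok))
}
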