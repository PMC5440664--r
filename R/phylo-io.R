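# Reading and writing of trees and categorical character matrices, and the
# shared validation rules all downstream modules rely on.

#' Read a time-calibrated ultrametric tree from a Newick file
#'
#' Parses a rooted Newick tree with branch lengths (Myr), validates it
#' (unique tip labels, positive branch lengths, ultrametric within a
#' relative tolerance of `tol * T` where `T` is the root age) and then
#' re-normalizes terminal branches so that all tips sit at age exactly 0.
#'
#' @param path path to a Newick file.
#' @param tol relative ultrametricity tolerance (default `1e-6`); empirical
#'   time trees carry rounding error of this order.
#' @return a `phylo` object, exactly ultrametric.
#' @export
read_newick <- function(path, tol = 1e-6) {
  tree <- tryCatch(ape::read.tree(path),
                   error = function(e) stop("malformed Newick file: ",
                                            conditionMessage(e)))
  if (is.null(tree)) stop("malformed Newick file: no tree found")
  validate_tree(tree, tol = tol)
}

#' Validate a phylogeny for use in downstream analyses
#'
#' @param tree a `phylo` object.
#' @param tol relative ultrametricity tolerance.
#' @return the tree, re-normalized to exact ultrametricity.
#' @export
validate_tree <- function(tree, tol = 1e-6) {
  if (!inherits(tree, "phylo")) stop("not a phylo object")
  if (is.null(tree$edge.length) || anyNA(tree$edge.length))
    stop("missing branch lengths")
  if (any(tree$edge.length <= 0)) stop("branch lengths must be positive")
  if (anyDuplicated(tree$tip.label)) stop("duplicate tip labels")
  if (!ape::is.rooted(tree)) stop("tree must be rooted")
  if (!is_ultrametric_tol(tree, tol))
    stop("tree is not ultrametric within tolerance ", tol, " * root age")
  renormalize_depths(tree)
}

#' Write a tree to a Newick file
#'
#' @param tree a `phylo` object.
#' @param path output path.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path, digits = 15)
  invisible(path)
}

#' Construct a categorical character matrix
#'
#' The container for phase-specific morphology data: species in rows,
#' categorical characters (small non-negative integer states, `NA` for
#' missing) in columns, plus a per-character flag saying whether the states
#' form an ordered series (mensural characters coded as a continuum).
#'
#' @param data integer matrix (species x characters) with `NA` for missing
#'   entries; rownames are species, states must be in 0..9. An ordered
#'   character's declared state space is a contiguous integer range, but
#'   intermediate states need not be observed (two species may show only
#'   states 0 and 2, at distance 2).
#' @param ordered logical vector, one flag per character (recycled if
#'   length 1).
#' @return object of class `char_matrix`.
#' @export
char_matrix <- function(data, ordered = FALSE) {
  data <- as.matrix(data)
  storage.mode(data) <- "integer"
  if (is.null(rownames(data))) stop("species names (rownames) required")
  if (anyDuplicated(rownames(data))) stop("duplicate species in matrix")
  vals <- data[!is.na(data)]
  if (length(vals) && (min(vals) < 0L || max(vals) > 9L))
    stop("states must be integers in 0..9")
  ordered <- rep_len(as.logical(ordered), ncol(data))
  structure(list(data = data, ordered = ordered), class = "char_matrix")
}

#' @export
print.char_matrix <- function(x, ...) {
  cat("Character matrix:", nrow(x$data), "species x", ncol(x$data),
      "characters (", sum(x$ordered), "ordered,",
      sum(is.na(x$data)), "missing cells )\n")
  invisible(x)
}

#' @export
dim.char_matrix <- function(x) dim(x$data)

#' Species of a character matrix
#' @param x a `char_matrix`.
#' @return character vector of species names.
#' @export
species <- function(x) rownames(x$data)

#' Read a categorical character matrix from a NEXUS file
#'
#' Accepts both DATA and CHARACTERS blocks with SYMBOLS and MISSING
#' declared in the FORMAT line. State symbols are limited to the digits
#' 0--9. Polymorphic (bracketed) entries are treated as missing data.
#' Symbols present in the matrix but not declared in SYMBOLS are rejected.
#'
#' @param path path to a NEXUS file.
#' @param ordered per-character ordered flags (logical, recycled); the
#'   ordered/unordered assignment typically lives outside the NEXUS file,
#'   so it is supplied here rather than parsed from a TYPESET block.
#' @return a [char_matrix()].
#' @export
read_nexus_matrix <- function(path, ordered = FALSE) {
  raw <- readLines(path, warn = FALSE)
  txt <- paste(raw, collapse = "\n")
  fmt <- regmatches(txt, regexpr("(?i)FORMAT[^;]*;", txt, perl = TRUE))
  symbols <- as.character(0:9)
  missing_char <- "?"
  if (length(fmt)) {
    sm <- regmatches(fmt, regexpr('(?i)SYMBOLS\\s*=\\s*"[^"]*"', fmt, perl = TRUE))
    if (length(sm)) {
      s <- sub('"$', "", sub('(?i)SYMBOLS\\s*=\\s*"', "", sm, perl = TRUE))
      symbols <- strsplit(gsub("\\s", "", s), "")[[1]]
    }
    mm <- regmatches(fmt, regexpr("(?i)MISSING\\s*=\\s*\\S", fmt, perl = TRUE))
    if (length(mm)) missing_char <- substr(mm, nchar(mm), nchar(mm))
  }
  if (!all(grepl("^[0-9]$", symbols)))
    stop("only digit state symbols 0-9 are supported")
  rows <- tryCatch(ape::read.nexus.data(path),
                   error = function(e) stop("malformed NEXUS file: ",
                                            conditionMessage(e)))
  if (anyDuplicated(names(rows))) stop("duplicate taxon in NEXUS matrix")
  nc <- unique(lengths(rows))
  if (length(nc) != 1) stop("row length mismatch in NEXUS matrix")
  cells <- t(vapply(rows, as.character, character(nc)))
  out <- matrix(NA_integer_, nrow(cells), ncol(cells),
                dimnames = list(names(rows), NULL))
  plain <- !grepl("/", cells, fixed = TRUE) # ape encodes polymorphic as "a/b"
  is_missing <- cells == missing_char | cells == "-"
  bad <- plain & !is_missing & !(cells %in% symbols)
  if (any(bad))
    stop("undeclared symbol(s) in matrix: ",
         paste(unique(cells[bad]), collapse = ", "))
  keep <- plain & !is_missing
  out[keep] <- as.integer(cells[keep])
  char_matrix(out, ordered = ordered)
}

#' Write a character matrix to a NEXUS DATA block
#'
#' Missing cells are written as `?`. The SYMBOLS declaration covers exactly
#' the states present, so files round-trip through [read_nexus_matrix()].
#'
#' @param x a `char_matrix`.
#' @param path output path.
#' @export
write_nexus_matrix <- function(x, path) {
  stopifnot(inherits(x, "char_matrix"))
  m <- x$data
  st <- sort(unique(m[!is.na(m)]))
  if (!length(st)) st <- 0L
  chr <- matrix(as.character(m), nrow(m))
  chr[is.na(chr)] <- "?"
  nm <- format(rownames(m))
  lines <- c(
    "#NEXUS",
    "BEGIN DATA;",
    sprintf("  DIMENSIONS NTAX=%d NCHAR=%d;", nrow(m), ncol(m)),
    sprintf('  FORMAT DATATYPE=STANDARD SYMBOLS="%s" MISSING=? GAP=-;',
            paste(st, collapse = "")),
    "  MATRIX",
    sprintf("    %s  %s", nm, apply(chr, 1, paste, collapse = "")),
    "  ;",
    "END;")
  writeLines(lines, path)
  invisible(path)
}

#' Restrict a tree and one or more character matrices to shared species
#'
#' Taxa lacking morphological data in any matrix are pruned from the tree,
#' and each matrix is restricted (and reordered) to the tips retained.
#' Degree-2 nodes created by pruning are merged, so patristic distances
#' among retained tips are preserved exactly.
#'
#' @param tree a `phylo` object.
#' @param matrices a single `char_matrix` or a list of them.
#' @return list with elements `tree` and `matrices` (a list).
#' @export
prune_to_common <- function(tree, matrices) {
  if (inherits(matrices, "char_matrix")) matrices <- list(matrices)
  shared <- Reduce(intersect, c(list(tree$tip.label), lapply(matrices, species)))
  if (length(shared) < 3) stop("fewer than 3 shared species")
  tree2 <- ape::keep.tip(tree, shared)
  mats <- lapply(matrices, function(m)
    char_matrix(m$data[tree2$tip.label, , drop = FALSE], m$ordered))
  list(tree = tree2, matrices = mats)
}
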