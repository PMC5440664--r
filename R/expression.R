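# Phase-biased gene expression: FPKM normalization, ratio-threshold
# classification of genes into adult-biased / tadpole-biased / even,
# keyword flagging of morphology-associated annotations, and two-sided
# proportion z-tests.

#' Fragments per kilobase of exon per million mapped reads
#'
#' `counts * 1e9 / (transcript_length * total_mapped)`; vectorized.
#'
#' @param counts read (fragment) counts.
#' @param transcript_length exon length in bp (> 0).
#' @param total_mapped total mapped reads in the sample (> 0).
#' @return FPKM values.
#' @export
compute_fpkm <- function(counts, transcript_length, total_mapped) {
  if (any(transcript_length <= 0)) stop("transcript_length must be > 0")
  if (any(total_mapped <= 0)) stop("total_mapped must be > 0")
  counts * 1e9 / (transcript_length * total_mapped)
}

#' Classify genes as phase-biased or evenly expressed
#'
#' A gene's adult/tadpole FPKM ratio above `hi` calls it adult-biased,
#' below `lo` tadpole-biased, otherwise even. Genes below `min_fpkm` in
#' both phases are unclassifiable; genes below the floor in exactly one
#' phase are assigned to the other phase's biased class (this avoids
#' ratios against a denominator of ~0, which the thresholds were not
#' designed for). The default thresholds 1.6 and 0.4 are the published
#' cutoffs for unevenly expressed transcripts, implemented exactly as
#' printed (they are deliberately not reciprocal).
#'
#' @param table data.frame with columns `gene`, `fpkm_adult`,
#'   `fpkm_tadpole` and optionally `morph_flag` (logical).
#' @param hi,lo ratio thresholds (`hi > lo > 0`).
#' @param min_fpkm expression floor.
#' @return object of class `phase_classification`: the input with a
#'   `class` column (factor: adult-biased, tadpole-biased, even,
#'   unclassifiable), plus a `counts` table and, when `morph_flag` is
#'   present, `morph_fraction` per class.
#' @export
classify_phase_bias <- function(table, hi = 1.6, lo = 0.4, min_fpkm = 1.0) {
  stopifnot(hi > lo, lo > 0)
  fa <- table$fpkm_adult; ft <- table$fpkm_tadpole
  if (any(fa < 0) || any(ft < 0)) stop("FPKM must be >= 0")
  cls <- rep("even", nrow(table))
  low_a <- fa < min_fpkm; low_t <- ft < min_fpkm
  ratio <- fa / ft
  cls[ratio > hi] <- "adult-biased"
  cls[ratio < lo] <- "tadpole-biased"
  cls[low_a & !low_t] <- "tadpole-biased"
  cls[low_t & !low_a] <- "adult-biased"
  cls[low_a & low_t] <- "unclassifiable"
  lev <- c("adult-biased", "tadpole-biased", "even", "unclassifiable")
  table$class <- factor(cls, levels = lev)
  out <- list(table = table, counts = table(table$class),
              hi = hi, lo = lo, min_fpkm = min_fpkm)
  if (!is.null(table$morph_flag))
    out$morph_fraction <- tapply(table$morph_flag, table$class, mean)
  structure(out, class = "phase_classification")
}

#' @export
print.phase_classification <- function(x, ...) {
  cat("Phase-bias classification (ratio >", x$hi, "adult, <", x$lo,
      "tadpole; floor", x$min_fpkm, "FPKM):\n")
  print(x$counts)
  if (!is.null(x$morph_fraction)) {
    cat("Morphology-associated fraction per class:\n")
    print(round(x$morph_fraction, 3))
  }
  invisible(x)
}

#' Flag genes whose annotation matches morphology-associated terms
#'
#' Case-insensitive fixed-substring match of any search term against each
#' gene's free-text annotation.
#'
#' @param annotations character vector of annotation texts.
#' @param terms nonempty character vector of search terms.
#' @return logical vector of flags.
#' @export
keyword_flag <- function(annotations, terms) {
  if (!length(terms)) stop("term list must be nonempty")
  annotations[is.na(annotations)] <- ""
  low <- tolower(annotations)
  flags <- rep(FALSE, length(annotations))
  for (tm in tolower(terms))
    flags <- flags | grepl(tm, low, fixed = TRUE)
  flags
}

#' Two-sided two-proportion z-test
#'
#' Pooled-proportion z statistic for H0: p1 = p2, with
#' `p = 2 * (1 - Phi(|z|))`. Degenerate pooled proportions (0 or 1)
#' return `z = 0, p = 1` by convention.
#'
#' @param k1,n1 successes and trials in group 1.
#' @param k2,n2 successes and trials in group 2.
#' @return list with `z`, `p`, `p1`, `p2`.
#' @export
proportion_ztest <- function(k1, n1, k2, n2) {
  stopifnot(n1 > 0, n2 > 0, k1 >= 0, k2 >= 0, k1 <= n1, k2 <= n2)
  p1 <- k1 / n1; p2 <- k2 / n2
  pool <- (k1 + k2) / (n1 + n2)
  if (pool <= 0 || pool >= 1)
    return(list(z = 0, p = 1, p1 = p1, p2 = p2))
  z <- (p1 - p2) / sqrt(pool * (1 - pool) * (1 / n1 + 1 / n2))
  list(z = z, p = 2 * pnorm(-abs(z)), p1 = p1, p2 = p2)
}
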