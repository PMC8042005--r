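# Expression breadth across tissues: per-tissue medians, expressed calls
# at a TPM threshold, binned breadth distributions and set-vs-set
# abundance comparisons.

#' Per-tissue median expression
#'
#' @param m An `expression_matrix` (typically TPM).
#' @return Numeric gene x tissue matrix of medians over each tissue's
#'   samples (midpoint of central order statistics for even counts).
#' @export
median_by_tissue <- function(m) {
  stopifnot(inherits(m, "expression_matrix"))
  tiss <- tissues_of(m)
  out <- vapply(tiss, function(t) {
    cols <- names(m$sample_tissue)[m$sample_tissue == t]
    apply(m$values[, cols, drop = FALSE], 1, stats::median)
  }, numeric(nrow(m$values)))
  if (is.null(dim(out))) out <- matrix(out, ncol = length(tiss),
                                       dimnames = list(rownames(m$values), tiss))
  out
}

#' Expression breadth profile
#'
#' Calls a gene expressed in a tissue when its median expression is at or
#' above `threshold` (inclusive), and counts expressing tissues per gene.
#'
#' @param medians Gene x tissue median matrix from [median_by_tissue()].
#' @param threshold TPM cut (> 0); 1 by default, with 5 and 10 as the
#'   usual sensitivity settings.
#' @return A `breadth_profile`: list with `threshold`, logical `expressed`
#'   matrix and integer `breadth` per gene.
#' @export
breadth_profile <- function(medians, threshold = 1) {
  if (threshold <= 0) stop("threshold must be positive")
  expressed <- medians >= threshold
  structure(list(threshold = threshold,
                 expressed = expressed,
                 breadth = rowSums(expressed)),
            class = "breadth_profile")
}

#' Binned breadth histogram
#'
#' Bins genes by the number of tissues expressing them: with the default
#' width 2 the first bin counts genes expressed in one or two tissues,
#' the second in three or four, and so on. Genes expressed nowhere are
#' excluded from the bins and reported separately.
#'
#' @param profile A [breadth_profile()].
#' @param bin_width Bin width in tissues (>= 1).
#' @return List with `counts` (named bin counts), `breaks` and
#'   `n_unexpressed`.
#' @export
binned_breadth_histogram <- function(profile, bin_width = 2) {
  stopifnot(inherits(profile, "breadth_profile"))
  if (bin_width < 1) stop("bin_width must be >= 1")
  b <- profile$breadth
  n0 <- sum(b == 0)
  b <- b[b > 0]
  n_tissues <- ncol(profile$expressed)
  upper <- seq(bin_width, n_tissues + bin_width - 1, by = bin_width)
  bin_of <- ceiling(b / bin_width)
  counts <- tabulate(bin_of, nbins = length(upper))
  labels <- vapply(seq_along(upper), function(i) {
    lo <- (i - 1) * bin_width + 1
    hi <- min(i * bin_width, n_tissues)
    if (lo == hi) as.character(lo) else paste0(lo, "-", hi)
  }, character(1))
  names(counts) <- labels
  list(counts = counts, breaks = upper, n_unexpressed = n0)
}

#' Compare breadth distributions of two gene sets
#'
#' Two-sided Kolmogorov-Smirnov comparison of tissue-breadth values
#' between two disjoint gene sets.
#'
#' @param profile A [breadth_profile()] covering both sets.
#' @param setA,setB Character vectors of gene ids (disjoint).
#' @param alternative Passed to [ks_test()]; two-sided by default.
#' @return A `chap_test` result.
#' @export
compare_breadth <- function(profile, setA, setB, alternative = "two.sided") {
  stopifnot(inherits(profile, "breadth_profile"))
  if (length(intersect(setA, setB)) > 0) {
    stop("gene sets must be disjoint for a breadth comparison")
  }
  bA <- profile$breadth[intersect(setA, names(profile$breadth))]
  bB <- profile$breadth[intersect(setB, names(profile$breadth))]
  if (length(bA) == 0 || length(bB) == 0) stop("both sets must be non-empty")
  ks_test(bA, bB, alternative = alternative)
}

#' Per-tissue abundance comparison between two gene sets
#'
#' For each tissue, restricts to genes whose median expression in that
#' tissue is at or above `threshold`, compares the two sets' medians by a
#' rank test (default one-sided: set A higher), and adjusts across
#' tissues by Benjamini-Hochberg. Tissues where either restricted set is
#' empty are flagged not-testable and excluded from the adjustment family.
#'
#' @param medians Gene x tissue median matrix.
#' @param setA,setB Disjoint gene-id vectors.
#' @param threshold TPM cut for inclusion per tissue.
#' @param alternative `"greater"` (default: A above B), `"less"` or
#'   `"two.sided"`.
#' @return Data frame with one row per tissue: `tissue`, `n_A`, `n_B`,
#'   `U`, `p`, `adj_p`, `testable`.
#' @export
per_tissue_abundance_comparison <- function(medians, setA, setB, threshold = 1,
                                            alternative = "greater") {
  if (length(intersect(setA, setB)) > 0) stop("gene sets must be disjoint")
  tiss <- colnames(medians)
  rows <- lapply(tiss, function(t) {
    v <- medians[, t]
    keep <- v >= threshold
    a <- v[keep & rownames(medians) %in% setA]
    b <- v[keep & rownames(medians) %in% setB]
    if (length(a) == 0 || length(b) == 0) {
      data.frame(tissue = t, n_A = length(a), n_B = length(b),
                 U = NA_real_, p = NA_real_, testable = FALSE,
                 stringsAsFactors = FALSE)
    } else {
      res <- mw_test(a, b, alternative = alternative)
      data.frame(tissue = t, n_A = length(a), n_B = length(b),
                 U = res$statistic, p = res$p, testable = TRUE,
                 stringsAsFactors = FALSE)
    }
  })
  out <- do.call(rbind, rows)
  out$adj_p <- NA_real_
  out$adj_p[out$testable] <- bh_adjust(out$p[out$testable])
  out
}
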