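# Count filtering and TMM (trimmed mean of M-values) scaling factors,
# implemented from the definition: precision-weighted mean of gene-wise
# log-ratios against a reference sample after two-sided trimming on M
# and on A.

#' Filter lowly-expressed genes from a count matrix
#'
#' Default rule (`mode = "all"`): a gene is removed when its count is at
#' most `count_cut` in every sample, i.e. retained if any sample exceeds
#' the cut. The stricter `mode = "any"` removes a gene when any sample is
#' at or below the cut.
#'
#' @param counts An `expression_matrix` with `units == "counts"`.
#' @param count_cut Count threshold (default 10, inclusive).
#' @param mode `"all"` (default) or `"any"`; see above.
#' @return The filtered `expression_matrix`.
#' @export
filter_low_counts <- function(counts, count_cut = 10, mode = c("all", "any")) {
  stopifnot(inherits(counts, "expression_matrix"))
  mode <- match.arg(mode)
  if (counts$units != "counts") {
    stop("low-count filtering applies to raw counts, not ", counts$units)
  }
  low <- counts$values <= count_cut
  drop <- if (mode == "all") rowSums(low) == ncol(counts$values)
          else rowSums(low) > 0
  message(sprintf("filter_low_counts: removed %d of %d genes (mode '%s')",
                  sum(drop), length(drop), mode))
  counts$values <- counts$values[!drop, , drop = FALSE]
  counts
}

# weighted trimmed mean of M-values for one sample against the reference;
# obs and ref are count vectors, n_obs/n_ref their library sizes
tmm_pair <- function(obs, ref, n_obs, n_ref, m_trim, a_trim) {
  keep <- obs > 0 & ref > 0
  obs <- obs[keep]; ref <- ref[keep]
  if (length(obs) == 0) return(1)
  p_o <- obs / n_obs
  p_r <- ref / n_ref
  M <- log2(p_o / p_r)
  A <- 0.5 * log2(p_o * p_r)
  # asymptotic (delta-method) variance of M; inverse used as weight
  w <- (n_obs - obs) / (n_obs * obs) + (n_ref - ref) / (n_ref * ref)
  finite <- is.finite(M) & is.finite(A)
  M <- M[finite]; A <- A[finite]; w <- w[finite]
  n <- length(M)
  if (n == 0) return(1)
  lo_m <- floor(n * m_trim) + 1; hi_m <- n + 1 - lo_m
  lo_a <- floor(n * a_trim) + 1; hi_a <- n + 1 - lo_a
  rM <- rank(M, ties.method = "first")
  rA <- rank(A, ties.method = "first")
  keep2 <- rM >= lo_m & rM <= hi_m & rA >= lo_a & rA <= hi_a
  if (!any(keep2)) return(1)
  f <- sum(M[keep2] / w[keep2]) / sum(1 / w[keep2])
  if (!is.finite(f)) 1 else 2^f
}

#' TMM normalization factors
#'
#' Between-sample scaling factors: the reference sample is the one whose
#' upper-quartile count fraction is closest to the mean across samples;
#' each sample's factor is two to the precision-weighted mean of gene-wise
#' M-values (log2 ratios of count fractions against the reference) after
#' two-sided trimming of the most extreme `m_trim` of M-values and
#' `a_trim` of A-values, over genes nonzero in both samples. Factors are
#' rescaled to geometric mean 1.
#'
#' @param counts Filtered `expression_matrix` of raw counts.
#' @param m_trim Two-sided trim fraction on M (default 0.30).
#' @param a_trim Two-sided trim fraction on A (default 0.05).
#' @return A `norm_factors` object: list with `factors` (named, geometric
#'   mean 1), `lib_size`, `ref_sample`, and the trim settings.
#' @export
tmm_factors <- function(counts, m_trim = 0.30, a_trim = 0.05) {
  stopifnot(inherits(counts, "expression_matrix"))
  x <- counts$values
  if (ncol(x) < 2) stop("TMM needs at least 2 samples")
  lib <- colSums(x)
  if (any(lib == 0)) {
    stop("sample(s) with all-zero counts: ",
         paste(colnames(x)[lib == 0], collapse = ", "))
  }
  uq <- apply(x, 2, function(col) stats::quantile(col / sum(col), 0.75))
  ref_i <- which.min(abs(uq - mean(uq)))
  f <- vapply(seq_len(ncol(x)), function(j) {
    if (j == ref_i) 1
    else tmm_pair(x[, j], x[, ref_i], lib[j], lib[ref_i], m_trim, a_trim)
  }, numeric(1))
  f <- f / exp(mean(log(f)))
  structure(list(factors = stats::setNames(f, colnames(x)),
                 lib_size = lib,
                 ref_sample = colnames(x)[ref_i],
                 m_trim = m_trim, a_trim = a_trim),
            class = "norm_factors")
}

#' @export
print.norm_factors <- function(x, ...) {
  cat(sprintf("TMM factors for %d samples (ref %s), range [%.3f, %.3f]\n",
              length(x$factors), x$ref_sample, min(x$factors), max(x$factors)))
  invisible(x)
}
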