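# Gene essentiality summaries across CRISPR screens: the per-gene
# minimal score and growth-impact distribution comparisons.

#' Read a gene x cell-line CRISPR score table
#'
#' @param path CSV with gene ids in the first column and one column per
#'   cell line; empty cells are missing scores.
#' @return Numeric matrix (genes x cell lines) with NAs for missing.
#' @export
read_scores <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- df[[1]]
  m
}

#' Minimal CRISPR score per gene
#'
#' Summarizes each gene by its minimum score over non-missing cell lines
#' (the most growth-reducing screen); genes measured nowhere are flagged
#' absent rather than set to zero. `summary = "mean"` is available for
#' sensitivity analysis.
#'
#' @param scores Gene x cell-line numeric matrix (NAs allowed).
#' @param summary `"min"` (default) or `"mean"`.
#' @return An `essentiality_profile` data frame: `gene_id`, `score`,
#'   `n_cell_lines`, `measured`.
#' @export
min_score_per_gene <- function(scores, summary = c("min", "mean")) {
  summary <- match.arg(summary)
  if (ncol(scores) < 1) stop("need at least one cell line")
  n_meas <- rowSums(!is.na(scores))
  val <- apply(scores, 1, function(v) {
    v <- v[!is.na(v)]
    if (length(v) == 0) NA_real_
    else if (summary == "min") min(v) else mean(v)
  })
  out <- data.frame(gene_id = rownames(scores), score = unname(val),
                    n_cell_lines = unname(n_meas), measured = n_meas > 0,
                    stringsAsFactors = FALSE, row.names = NULL)
  class(out) <- c("essentiality_profile", "data.frame")
  out
}

#' Compare growth impact between two gene sets
#'
#' One-sided Kolmogorov-Smirnov comparison of summarized scores: the
#' default direction tests whether set A is stochastically lower (more
#' growth-reducing) than set B.
#'
#' @param profile A [min_score_per_gene()] result.
#' @param setA,setB Disjoint gene-id vectors.
#' @param alternative `"greater"` (default; A lower — A's CDF above B's),
#'   `"less"` or `"two.sided"`.
#' @return A `chap_test` result.
#' @export
compare_growth_impact <- function(profile, setA, setB,
                                  alternative = "greater") {
  stopifnot(inherits(profile, "essentiality_profile"))
  if (length(intersect(setA, setB)) > 0) stop("gene sets must be disjoint")
  sc <- stats::setNames(profile$score, profile$gene_id)
  a <- sc[intersect(setA, profile$gene_id[profile$measured])]
  b <- sc[intersect(setB, profile$gene_id[profile$measured])]
  if (length(a) == 0 || length(b) == 0) {
    stop("both sets need at least one measured gene")
  }
  ks_test(a, b, alternative = alternative)
}
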