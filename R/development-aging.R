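# Development and aging comparisons: specificity-score group tests,
# developmental-module versus adult-correlation tests, adult-vs-aging
# high-correlation pair overlap, and age-trend group comparisons.

#' Compare specificity scores between two gene groups per context
#'
#' One-sided Mann-Whitney test per context (default direction: group A
#' more non-specific, i.e. lower scores), Benjamini-Hochberg adjusted
#' across contexts. Contexts where either group is empty are flagged and
#' excluded from the adjustment family.
#'
#' @param scores Data frame `gene_id`, `context`, `score` (scores in
#'   `[0, 1]`).
#' @param groupA,groupB Disjoint gene-id vectors.
#' @param alternative `"less"` (default: A lower), `"greater"` or
#'   `"two.sided"`.
#' @return Data frame per context: `context`, `n_A`, `n_B`, `U`, `p`,
#'   `adj_p`, `testable`.
#' @export
compare_specificity <- function(scores, groupA, groupB,
                                alternative = "less") {
  need <- c("gene_id", "context", "score")
  if (!all(need %in% names(scores))) {
    stop("scores needs columns: ", paste(need, collapse = ", "))
  }
  if (any(scores$score < 0 | scores$score > 1, na.rm = TRUE)) {
    stop("specificity scores must lie in [0, 1]")
  }
  if (length(intersect(groupA, groupB)) > 0) stop("groups must be disjoint")
  rows <- lapply(split(scores, scores$context), function(d) {
    a <- d$score[d$gene_id %in% groupA]
    b <- d$score[d$gene_id %in% groupB]
    if (length(a) == 0 || length(b) == 0) {
      data.frame(context = d$context[1], n_A = length(a), n_B = length(b),
                 U = NA_real_, p = NA_real_, testable = FALSE,
                 stringsAsFactors = FALSE)
    } else {
      res <- mw_test(a, b, alternative = alternative)
      data.frame(context = d$context[1], n_A = length(a), n_B = length(b),
                 U = res$statistic, p = res$p, testable = TRUE,
                 stringsAsFactors = FALSE)
    }
  })
  out <- do.call(rbind, c(rows, make.row.names = FALSE))
  out$adj_p <- NA_real_
  out$adj_p[out$testable] <- bh_adjust(out$p[out$testable])
  out
}

#' Test whether same-module pairs are more correlated in the adult tissue
#'
#' Partitions the tensor's chaperone pairs by whether both members share
#' a developmental module in the given organ, then runs a one-sided
#' Mann-Whitney test on the adult correlation values (same-module
#' greater).
#'
#' @param adult A [coexpression_tensor()] whose columns include `organ`.
#' @param modules Data frame `organ`, `gene_id`, `module`.
#' @param organ Organ/tissue label present in both structures.
#' @return A `chap_test` result with counts attached (`n_same`,
#'   `n_other`).
#' @export
module_pair_correlation_test <- function(adult, modules, organ) {
  stopifnot(inherits(adult, "coexpression_tensor"))
  if (!organ %in% colnames(adult$r)) {
    stop("organ '", organ, "' absent from the adult tensor")
  }
  mo <- modules[modules$organ == organ, , drop = FALSE]
  if (nrow(mo) == 0) stop("organ '", organ, "' absent from the module map")
  mod_of <- stats::setNames(mo$module, mo$gene_id)
  ma <- mod_of[adult$pairs$gene_a]
  mb <- mod_of[adult$pairs$gene_b]
  same <- !is.na(ma) & !is.na(mb) & ma == mb
  rvals <- adult$r[, organ]
  ok <- !is.na(rvals)
  a <- rvals[same & ok]
  b <- rvals[!same & ok]
  if (length(a) == 0) stop("no same-module pairs in organ '", organ, "'")
  if (length(b) == 0) stop("no cross-module pairs in organ '", organ, "'")
  res <- mw_test(a, b, alternative = "greater")
  res$n_same <- length(a)
  res$n_other <- length(b)
  res
}

#' Overlap of highly correlated pairs between two conditions
#'
#' One-sided Fisher test on the overlap between the set of pairs highly
#' correlated in condition A (r strictly above `r_threshold` in the given
#' tissue of the tensor) and a second pair set (e.g. pairs highly
#' correlated in aging brain), over an explicit pair universe. For the
#' overlapping pairs, reports in how many other tissues each exceeds the
#' threshold (the tissue-specificity breakdown).
#'
#' @param tensorA Adult [coexpression_tensor()].
#' @param tissue Tissue of `tensorA` defining set A.
#' @param setB Character vector of pair keys `"a|b"` (order-normalized
#'   internally).
#' @param universe Total number of pairs in the comparison universe.
#' @param r_threshold Threshold for "highly correlated" (default 0.8).
#' @return List with `test` (a `chap_test`), `overlap_pairs`, and
#'   `other_tissue_counts` (per overlapping pair, tissues other than
#'   `tissue` above the threshold).
#' @export
high_corr_pair_overlap <- function(tensorA, tissue, setB, universe,
                                   r_threshold = 0.8) {
  stopifnot(inherits(tensorA, "coexpression_tensor"))
  if (!tissue %in% colnames(tensorA$r)) stop("unknown tissue: ", tissue)
  norm_key <- function(keys) {
    parts <- strsplit(keys, "|", fixed = TRUE)
    vapply(parts, function(p) paste(sort(p), collapse = "|"), character(1))
  }
  rvals <- tensorA$r[, tissue]
  setA <- norm_key(rownames(tensorA$r)[!is.na(rvals) & rvals > r_threshold])
  setB <- unique(norm_key(setB))
  if (universe < max(length(setA), length(setB))) {
    stop("universe smaller than a pair set")
  }
  k <- length(intersect(setA, setB))
  test <- fisher_exact_2x2(a = k,
                           b = length(setA) - k,
                           c = length(setB) - k,
                           d = universe - length(setA) - length(setB) + k,
                           alternative = "greater")
  overlap <- intersect(setA, setB)
  other <- tensorA$r[match(overlap, norm_key(rownames(tensorA$r))),
                     setdiff(colnames(tensorA$r), tissue), drop = FALSE]
  counts <- if (length(overlap)) rowSums(other > r_threshold, na.rm = TRUE)
            else integer(0)
  list(test = test, overlap_pairs = overlap,
       other_tissue_counts = stats::setNames(as.integer(counts), overlap))
}

#' Compare age trends between variable-chaperone subsets
#'
#' Splits genes into core, brain-upregulated variable (variable label and
#' log2fc at or above `fc_threshold` in the brain tissue of the adult DE
#' table) and other variable, then runs a one-sided Mann-Whitney test of
#' whether brain-upregulated variable chaperones have lower age
#' correlations than the other variable chaperones.
#'
#' @param trends Data frame `gene_id`, `age_correlation` in `[-1, 1]`.
#' @param classification A [classify_core_variable()] result.
#' @param de_table A [build_de_table()] result.
#' @param brain_tissue Tissue label used as "brain" in the DE table.
#' @param fc_threshold Upregulation cut on log2fc (default 1).
#' @return List with `test` (a `chap_test`), `groups` (gene ids per
#'   group) and `summaries` (median age correlation per group).
#' @export
age_trend_group_comparison <- function(trends, classification, de_table,
                                       brain_tissue, fc_threshold = 1) {
  if (any(abs(trends$age_correlation) > 1, na.rm = TRUE)) {
    stop("age correlations must lie in [-1, 1]")
  }
  lab <- stats::setNames(classification$label, classification$gene_id)
  brain <- de_table[de_table$tissue == brain_tissue, ]
  if (nrow(brain) == 0) stop("brain tissue '", brain_tissue,
                             "' absent from the DE table")
  up <- brain$gene_id[brain$log2fc >= fc_threshold]
  gid <- trends$gene_id
  matched <- gid[gid %in% names(lab)]
  n_unmatched <- sum(!gid %in% names(lab))
  if (n_unmatched > 0) {
    message(sprintf("age trends: %d gene(s) not in the classification",
                    n_unmatched))
  }
  groups <- list(
    core = matched[lab[matched] == "core"],
    brain_up_variable = matched[lab[matched] == "variable" & matched %in% up],
    other_variable = matched[lab[matched] == "variable" & !matched %in% up])
  if (any(lengths(groups) == 0)) {
    stop("empty group(s): ",
         paste(names(groups)[lengths(groups) == 0], collapse = ", "))
  }
  tr <- stats::setNames(trends$age_correlation, trends$gene_id)
  res <- mw_test(tr[groups$brain_up_variable], tr[groups$other_variable],
                 alternative = "less")
  list(test = res, groups = groups,
       summaries = vapply(groups, function(g)
         stats::median(tr[g], na.rm = TRUE), numeric(1)))
}
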