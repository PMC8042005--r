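# Per-tissue Spearman co-expression among chaperones: the pair x tissue
# correlation tensor, pair-class labels, the tissues-correlated-count
# statistic and node-link network export.

spearman_matrix <- function(x) {
  # x: samples x genes; midrank transform then product-moment correlation
  r <- apply(x, 2, rank, ties.method = "average")
  const <- apply(x, 2, function(v) length(unique(v)) == 1)
  cc <- suppressWarnings(stats::cor(r))
  cc[const, ] <- NA
  cc[, const] <- NA
  cc
}

#' Pairwise Spearman correlations within one tissue
#'
#' @param m An `expression_matrix`.
#' @param genes Character vector (or [gene_set()]) of genes to correlate.
#' @param tissue Tissue label.
#' @param min_samples Minimum samples required (default 5).
#' @return Data frame `gene_a`, `gene_b`, `r` (NA when either gene is
#'   constant in the tissue) for all unordered pairs, plus `n_samples`.
#' @export
tissue_correlations <- function(m, genes, tissue, min_samples = 5) {
  stopifnot(inherits(m, "expression_matrix"))
  if (inherits(genes, "gene_set")) genes <- genes$members
  genes <- intersect(genes, rownames(m$values))
  if (length(genes) < 2) stop("need at least 2 genes present in the matrix")
  cols <- names(m$sample_tissue)[m$sample_tissue == tissue]
  if (length(cols) < 2) stop("tissue '", tissue, "' has < 2 samples")
  if (length(cols) < min_samples) {
    stop("tissue '", tissue, "' has fewer than ", min_samples, " samples")
  }
  x <- t(m$values[genes, cols, drop = FALSE])
  cc <- spearman_matrix(x)
  idx <- which(upper.tri(cc), arr.ind = TRUE)
  data.frame(gene_a = genes[idx[, 1]], gene_b = genes[idx[, 2]],
             r = cc[idx], n_samples = length(cols),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Build the pair x tissue co-expression tensor
#'
#' @param m An `expression_matrix`.
#' @param genes Genes (or a [gene_set()]) to correlate.
#' @param min_samples Minimum samples per included tissue (default 5).
#' @return A `coexpression_tensor`: list with `r` (pair x tissue matrix,
#'   rownames `"a|b"`), `pairs` (data frame `gene_a`, `gene_b`) and
#'   `n_samples` per tissue. Tissues below the sample floor are skipped.
#' @export
coexpression_tensor <- function(m, genes, min_samples = 5) {
  stopifnot(inherits(m, "expression_matrix"))
  if (inherits(genes, "gene_set")) genes <- genes$members
  tiss <- tissues_of(m)
  n_per <- vapply(tiss, function(t) sum(m$sample_tissue == t), integer(1))
  tiss <- tiss[n_per[tiss] >= min_samples]
  if (length(tiss) == 0) stop("no tissue reaches ", min_samples, " samples")
  slices <- lapply(tiss, function(t)
    tissue_correlations(m, genes, t, min_samples = min_samples))
  pairs <- slices[[1]][, c("gene_a", "gene_b")]
  r <- vapply(slices, function(s) s$r, numeric(nrow(pairs)))
  if (is.null(dim(r))) r <- matrix(r, nrow = nrow(pairs))
  dimnames(r) <- list(paste(pairs$gene_a, pairs$gene_b, sep = "|"), tiss)
  structure(list(r = r, pairs = pairs,
                 n_samples = stats::setNames(
                   vapply(slices, function(s) s$n_samples[1], numeric(1)),
                   tiss)),
            class = "coexpression_tensor")
}

#' @export
print.coexpression_tensor <- function(x, ...) {
  cat(sprintf("coexpression tensor: %d pairs x %d tissues (%d undefined r)\n",
              nrow(x$r), ncol(x$r), sum(is.na(x$r))))
  invisible(x)
}

#' Label pairs as core-core, mixed, or variable-variable
#'
#' @param tensor A [coexpression_tensor()].
#' @param classification A [classify_core_variable()] result.
#' @return Character vector per pair, in tensor row order.
#' @export
pair_classes <- function(tensor, classification) {
  lab <- stats::setNames(classification$label, classification$gene_id)
  a <- lab[tensor$pairs$gene_a]
  b <- lab[tensor$pairs$gene_b]
  out <- ifelse(a == "core" & b == "core", "core-core",
         ifelse(a == "variable" & b == "variable", "variable-variable",
                "mixed"))
  out[is.na(a) | is.na(b)] <- NA
  stats::setNames(out, rownames(tensor$r))
}

#' Number of tissues in which each pair is highly correlated
#'
#' Counts, per pair, tissues with a defined correlation strictly greater
#' than `r_threshold` (positive correlations only; undefined values are
#' omitted, not treated as zero).
#'
#' @param tensor A [coexpression_tensor()].
#' @param r_threshold Correlation threshold in (0, 1) (default 0.7).
#' @param absolute Use `|r|` instead of signed r (default FALSE).
#' @return Named integer vector per pair.
#' @export
count_correlated_tissues <- function(tensor, r_threshold = 0.7,
                                     absolute = FALSE) {
  stopifnot(inherits(tensor, "coexpression_tensor"))
  if (r_threshold <= 0 || r_threshold >= 1) {
    stop("r_threshold must lie in (0, 1)")
  }
  v <- if (absolute) abs(tensor$r) else tensor$r
  rowSums(v > r_threshold, na.rm = TRUE)
}

#' Compare tissues-correlated counts between two pair classes
#'
#' Two-sided Kolmogorov-Smirnov comparison of the per-pair
#' tissues-correlated counts of two pair classes (e.g. core-core vs
#' mixed).
#'
#' @param counts Named counts from [count_correlated_tissues()].
#' @param classes Pair labels from [pair_classes()].
#' @param classA,classB Class labels to compare.
#' @return A `chap_test` result.
#' @export
compare_pair_class_distributions <- function(counts, classes, classA, classB) {
  a <- counts[!is.na(classes) & classes == classA]
  b <- counts[!is.na(classes) & classes == classB]
  if (length(a) == 0 || length(b) == 0) {
    stop("both pair classes must be non-empty")
  }
  ks_test(a, b, alternative = "two.sided")
}

#' Export one tissue's co-expression network as a node-link document
#'
#' Nodes carry symbol, family, core flag and disease annotations from the
#' registry and classification; edges carry the Spearman r and are
#' emitted only when r strictly exceeds the threshold.
#'
#' @param tensor A [coexpression_tensor()].
#' @param tissue Tissue label present in the tensor.
#' @param r_threshold Edge threshold (strict).
#' @param registry A `chap_registry` (optional annotations).
#' @param classification A `gene_classification` (optional core flags).
#' @param path Optional path; when given the JSON is written there.
#' @return The node-link list (`nodes`, `links`, `tissue`, `r_threshold`),
#'   invisibly when written to `path`.
#' @export
export_network <- function(tensor, tissue, r_threshold = 0.7,
                           registry = NULL, classification = NULL,
                           path = NULL) {
  stopifnot(inherits(tensor, "coexpression_tensor"))
  if (!tissue %in% colnames(tensor$r)) {
    stop("unknown tissue '", tissue, "' (tensor has: ",
         paste(colnames(tensor$r), collapse = ", "), ")")
  }
  rvals <- tensor$r[, tissue]
  keep <- !is.na(rvals) & rvals > r_threshold
  links <- data.frame(source = tensor$pairs$gene_a[keep],
                      target = tensor$pairs$gene_b[keep],
                      r = unname(rvals[keep]),
                      stringsAsFactors = FALSE, row.names = NULL)
  node_ids <- sort(unique(c(tensor$pairs$gene_a, tensor$pairs$gene_b)))
  nodes <- data.frame(id = node_ids, stringsAsFactors = FALSE)
  if (!is.null(registry)) {
    i <- match(node_ids, registry$gene_id)
    nodes$symbol <- registry$symbol[i]
    nodes$family <- registry$family[i]
    nodes$diseases <- vapply(registry$diseases[i], function(d)
      paste(d, collapse = ";"), character(1))
  }
  if (!is.null(classification)) {
    lab <- stats::setNames(classification$label, classification$gene_id)
    nodes$core <- unname(lab[node_ids] == "core")
  }
  doc <- list(tissue = tissue, r_threshold = r_threshold,
              nodes = nodes, links = links)
  if (!is.null(path)) {
    jsonlite::write_json(doc, path, dataframe = "rows", auto_unbox = TRUE,
                         digits = NA, na = "null")
    return(invisible(doc))
  }
  doc
}

#' Read a node-link network document written by [export_network()]
#' @param path JSON path.
#' @return The node-link list.
#' @export
read_network <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  doc$nodes <- as.data.frame(doc$nodes, stringsAsFactors = FALSE)
  doc$links <- as.data.frame(doc$links, stringsAsFactors = FALSE)
  doc
}
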