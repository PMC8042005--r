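# Expression-matrix container and I/O (GCT 1.2 and TSV), with the
# sample -> tissue attribute table and tissue aggregation maps.

#' Construct an expression matrix
#'
#' A gene x sample matrix of non-negative values (raw counts or TPM) plus
#' a total map from sample to tissue label.
#'
#' @param values Numeric matrix, genes in rows (rownames = gene ids),
#'   samples in columns (colnames = sample ids).
#' @param sample_tissue Named character vector mapping every sample id to
#'   a tissue label.
#' @param units `"counts"` or `"tpm"`.
#' @param min_samples Tissues with fewer samples are dropped with a warning.
#' @return An `expression_matrix` object.
#' @export
expression_matrix <- function(values, sample_tissue, units = c("counts", "tpm"),
                              min_samples = 1) {
  units <- match.arg(units)
  if (!is.matrix(values)) values <- as.matrix(values)
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop("values must carry gene ids as rownames and sample ids as colnames")
  }
  if (anyDuplicated(rownames(values)) || anyDuplicated(colnames(values))) {
    stop("gene and sample ids must be unique")
  }
  if (any(!is.finite(values))) stop("values must be finite")
  if (any(values < 0)) stop("negative expression value found")
  missing_samp <- setdiff(colnames(values), names(sample_tissue))
  if (length(missing_samp) > 0) {
    stop("samples absent from the attribute table: ",
         paste(missing_samp, collapse = ", "))
  }
  sample_tissue <- sample_tissue[colnames(values)]
  tissue_n <- table(sample_tissue)
  drop_t <- names(tissue_n)[tissue_n < min_samples]
  if (length(drop_t) > 0) {
    warning(sprintf("dropping %d tissue(s) with < %d samples: %s",
                    length(drop_t), min_samples,
                    paste(drop_t, collapse = ", ")))
    keep <- !(sample_tissue %in% drop_t)
    values <- values[, keep, drop = FALSE]
    sample_tissue <- sample_tissue[keep]
  }
  structure(list(values = values,
                 sample_tissue = sample_tissue,
                 units = units),
            class = "expression_matrix")
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("expression matrix (%s): %d genes x %d samples, %d tissues\n",
              x$units, nrow(x$values), ncol(x$values),
              length(unique(x$sample_tissue))))
  invisible(x)
}

#' @export
dim.expression_matrix <- function(x) dim(x$values)

#' Tissues of an expression matrix
#' @param m An `expression_matrix`.
#' @return Sorted unique tissue labels.
#' @export
tissues_of <- function(m) sort(unique(m$sample_tissue))

#' Read a GCT 1.2 expression file
#'
#' @param path GCT path (`#1.2` header, dimensions line, then a matrix with
#'   `Name`/`Description` columns).
#' @return Numeric matrix with gene rownames and sample colnames.
#' @export
read_gct <- function(path) {
  if (!file.exists(path)) stop("GCT file not found: ", path)
  lines <- readLines(path)
  if (length(lines) < 3 || trimws(lines[1]) != "#1.2") {
    stop("not a GCT 1.2 file (line 1 must be '#1.2'): ", path)
  }
  dims <- as.integer(strsplit(trimws(lines[2]), "\t")[[1]])
  if (length(dims) < 2 || any(is.na(dims))) {
    stop("malformed GCT dimensions at line 2")
  }
  body <- utils::read.delim(text = lines[-(1:2)], check.names = FALSE,
                            stringsAsFactors = FALSE)
  if (nrow(body) != dims[1]) {
    stop(sprintf(
      "GCT header declares %d data rows but body has %d (first body line is line 4)",
      dims[1], nrow(body)))
  }
  if (ncol(body) - 2 != dims[2]) {
    stop(sprintf("GCT header declares %d samples but body has %d",
                 dims[2], ncol(body) - 2))
  }
  vals <- as.matrix(body[, -(1:2), drop = FALSE])
  rownames(vals) <- body[[1]]
  vals
}

#' Write a matrix as GCT 1.2
#'
#' @param values Numeric matrix with gene rownames and sample colnames.
#' @param path Output path.
#' @param descriptions Optional `Description` column (defaults to gene ids).
#' @return `path`, invisibly.
#' @export
write_gct <- function(values, path, descriptions = rownames(values)) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("#1.2", paste(nrow(values), ncol(values), sep = "\t")), con)
  df <- data.frame(Name = rownames(values), Description = descriptions,
                   values, check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Load an expression matrix with its sample attributes
#'
#' @param path Matrix file: GCT 1.2 (`.gct`) or TSV (genes x samples,
#'   first column gene id).
#' @param attributes Path to a sample-attribute TSV with columns
#'   `sample_id`, `tissue` (optionally `united_tissue`), or a data frame.
#' @param units `"counts"` or `"tpm"`.
#' @param min_samples Minimum samples per retained tissue (default 5, the
#'   smallest group size at which per-tissue medians and correlations are
#'   considered).
#' @return An `expression_matrix`.
#' @export
load_matrix <- function(path, attributes, units = c("counts", "tpm"),
                        min_samples = 5) {
  units <- match.arg(units)
  vals <- if (grepl("\\.gct$", path, ignore.case = TRUE)) {
    read_gct(path)
  } else {
    df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
    m <- as.matrix(df[, -1, drop = FALSE])
    rownames(m) <- df[[1]]
    m
  }
  attr_df <- if (is.character(attributes)) {
    utils::read.delim(attributes, stringsAsFactors = FALSE)
  } else {
    as.data.frame(attributes, stringsAsFactors = FALSE)
  }
  if (!all(c("sample_id", "tissue") %in% names(attr_df))) {
    stop("attribute table needs columns sample_id and tissue")
  }
  st <- stats::setNames(attr_df$tissue, attr_df$sample_id)
  expression_matrix(vals, st, units = units, min_samples = min_samples)
}

#' Aggregate sub-tissues into united tissues
#'
#' Relabels each sample's tissue by a total map from tissue to
#' united-tissue label (e.g. collapsing brain sub-regions, or uniting
#' adipose depots), pooling samples before any downstream statistic.
#'
#' @param m An `expression_matrix`.
#' @param map Named character vector `tissue -> united label`; must cover
#'   every tissue present.
#' @return The relabelled `expression_matrix`.
#' @export
aggregate_tissues <- function(m, map) {
  stopifnot(inherits(m, "expression_matrix"))
  present <- unique(m$sample_tissue)
  uncovered <- setdiff(present, names(map))
  if (length(uncovered) > 0) {
    stop("aggregation map does not cover tissue(s): ",
         paste(uncovered, collapse = ", "))
  }
  m$sample_tissue <- stats::setNames(unname(map[m$sample_tissue]),
                                     names(m$sample_tissue))
  m
}

#' Subset an expression matrix by gene and/or sample
#' @param m An `expression_matrix`.
#' @param genes Optional gene ids to keep.
#' @param samples Optional sample ids to keep.
#' @return The subsetted `expression_matrix`.
#' @export
subset_matrix <- function(m, genes = NULL, samples = NULL) {
  stopifnot(inherits(m, "expression_matrix"))
  if (!is.null(genes)) {
    missing_g <- setdiff(genes, rownames(m$values))
    if (length(missing_g) > 0) {
      stop("genes absent from matrix: ", paste(missing_g, collapse = ", "))
    }
    m$values <- m$values[genes, , drop = FALSE]
  }
  if (!is.null(samples)) {
    m$values <- m$values[, samples, drop = FALSE]
    m$sample_tissue <- m$sample_tissue[samples]
  }
  m
}
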