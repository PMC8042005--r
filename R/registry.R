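# Curated chaperone annotation registry: loading, validation, subsetting.
# The canonical on-disk form is a TSV with one row per gene and
# semicolon-joined tokens for list-valued fields.

CHAPERONE_FAMILIES <- c("sHSP", "HSP40", "HSP60/HSP10", "HSP70", "HSP90",
                        "coHSP90", "NEF", "prefoldin", "folding enzyme",
                        "other")

REGISTRY_COLUMNS <- c("gene_id", "symbol", "family", "stress_induced",
                      "diseases", "disease_tissues", "orthologs_celegans",
                      "orthologs_mouse")

split_tokens <- function(x) {
  lapply(x, function(s) {
    if (is.na(s) || !nzchar(trimws(s))) character(0)
    else trimws(strsplit(s, ";", fixed = TRUE)[[1]])
  })
}

join_tokens <- function(lst) {
  vapply(lst, function(v) paste(v, collapse = ";"), character(1))
}

#' Load a chaperone annotation registry
#'
#' Reads the curated chaperone table (gene id, symbol, family,
#' stress-induced flag, disease annotations, orthologs) from its canonical
#' tab-separated form, validating identifiers and the closed family
#' vocabulary.
#'
#' @param path Path to a TSV with columns `gene_id`, `symbol`, `family`,
#'   `stress_induced`, `diseases`, `disease_tissues`, `orthologs_celegans`,
#'   `orthologs_mouse`. List-valued fields are semicolon-joined.
#' @return A `chap_registry` data frame with list-columns for diseases,
#'   disease tissues and orthologs.
#' @export
load_registry <- function(path) {
  if (!file.exists(path)) stop("registry file not found: ", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = "character")
  missing_cols <- setdiff(REGISTRY_COLUMNS, names(df))
  if (length(missing_cols) > 0) {
    stop("registry is missing required columns: ",
         paste(missing_cols, collapse = ", "))
  }
  dup <- df$gene_id[duplicated(df$gene_id)]
  if (length(dup) > 0) {
    stop("duplicate gene_id in registry: ", paste(unique(dup), collapse = ", "))
  }
  bad_fam <- setdiff(unique(df$family), CHAPERONE_FAMILIES)
  if (length(bad_fam) > 0) {
    stop("unknown chaperone family label: ", paste(bad_fam, collapse = ", "),
         " (allowed: ", paste(CHAPERONE_FAMILIES, collapse = ", "), ")")
  }
  stress <- tolower(trimws(df$stress_induced))
  if (!all(stress %in% c("true", "false", "0", "1"))) {
    stop("stress_induced must be TRUE/FALSE")
  }
  out <- data.frame(gene_id = df$gene_id, symbol = df$symbol,
                    family = df$family,
                    stress_induced = stress %in% c("true", "1"),
                    stringsAsFactors = FALSE)
  out$diseases <- split_tokens(df$diseases)
  out$disease_tissues <- split_tokens(df$disease_tissues)
  out$orthologs_celegans <- split_tokens(df$orthologs_celegans)
  out$orthologs_mouse <- split_tokens(df$orthologs_mouse)
  class(out) <- c("chap_registry", "data.frame")
  message(sprintf("loaded registry with %d chaperone records", nrow(out)))
  out
}

#' Write a registry to its canonical TSV form
#'
#' @param registry A `chap_registry`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_registry <- function(registry, path) {
  stopifnot(inherits(registry, "chap_registry"))
  df <- data.frame(gene_id = registry$gene_id, symbol = registry$symbol,
                   family = registry$family,
                   stress_induced = registry$stress_induced,
                   diseases = join_tokens(registry$diseases),
                   disease_tissues = join_tokens(registry$disease_tissues),
                   orthologs_celegans = join_tokens(registry$orthologs_celegans),
                   orthologs_mouse = join_tokens(registry$orthologs_mouse),
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Construct a gene set
#'
#' @param name Set label.
#' @param members Character vector of gene ids.
#' @param universe_hint Optional size of the population the set came from.
#' @return A `gene_set` object.
#' @export
gene_set <- function(name, members, universe_hint = NULL) {
  structure(list(name = name, members = unique(as.character(members)),
                 universe_hint = universe_hint),
            class = "gene_set")
}

#' @export
print.gene_set <- function(x, ...) {
  cat(sprintf("gene set '%s': %d members%s\n", x$name, length(x$members),
              if (is.null(x$universe_hint)) ""
              else sprintf(" (universe %d)", x$universe_hint)))
  invisible(x)
}

#' Select a registry subset by a named predicate
#'
#' Supported predicates: `"family=<label>"` (one of the closed family
#' vocabulary), `"stress_induced"`, `"has_disease"`, and
#' `"has_ortholog(celegans)"` / `"has_ortholog(mouse)"`.
#'
#' @param registry A `chap_registry`.
#' @param predicate Predicate string.
#' @return A [gene_set()] with `universe_hint` set to the registry size.
#' @export
select_subset <- function(registry, predicate) {
  stopifnot(inherits(registry, "chap_registry"))
  supported <- c("family=<label>", "stress_induced", "has_disease",
                 "has_ortholog(celegans)", "has_ortholog(mouse)")
  keep <- if (grepl("^family=", predicate)) {
    fam <- sub("^family=", "", predicate)
    if (!fam %in% CHAPERONE_FAMILIES) {
      stop("unknown family '", fam, "'; allowed: ",
           paste(CHAPERONE_FAMILIES, collapse = ", "))
    }
    registry$family == fam
  } else if (predicate == "stress_induced") {
    registry$stress_induced
  } else if (predicate == "has_disease") {
    lengths(registry$diseases) > 0
  } else if (grepl("^has_ortholog\\((celegans|mouse)\\)$", predicate)) {
    sp <- sub("^has_ortholog\\((.*)\\)$", "\\1", predicate)
    lengths(registry[[paste0("orthologs_", sp)]]) > 0
  } else {
    stop("unknown predicate '", predicate, "'; supported: ",
         paste(supported, collapse = ", "))
  }
  if (!any(keep)) {
    warning("predicate '", predicate, "' selected no genes")
  }
  gene_set(predicate, registry$gene_id[keep], universe_hint = nrow(registry))
}

#' Path to the packaged synthetic fixture registry
#'
#' A ~20-gene synthetic annotation table spanning every chaperone family,
#' for examples and desk-scale tests. It is constructed, not curated:
#' symbols are real chaperone gene names but annotations are illustrative.
#'
#' @return File path of the fixture TSV.
#' @export
example_registry_path <- function() {
  system.file("extdata", "chaperone_registry_synthetic.tsv",
              package = "chapatlas", mustWork = TRUE)
}
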