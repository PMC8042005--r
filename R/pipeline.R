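# Configuration-driven orchestration: a YAML config selects either a
# simulated dataset or on-disk inputs, stages run in dependency order
# under a single seed, and a consolidated JSON report records statuses,
# thresholds and input fingerprints.

pipeline_defaults <- function() {
  list(
    tpm_threshold = 1,
    fc_threshold = 1,
    alpha = 0.05,
    significance_required = FALSE,
    r_threshold = 0.7,
    r_threshold_aging = 0.8,
    min_samples = 5,
    stages = c("simulate", "breadth", "de", "classify", "coexpression",
               "essentiality")
  )
}

# deterministic per-stage seed derived from the global seed; kept below
# 2^31 so it stays a valid R integer
stage_seed <- function(seed, stage) {
  offs <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 1009 + offs) %% .Machine$integer.max)
}

#' Validate a pipeline configuration
#'
#' Reads a YAML config (or takes an equivalent list), fills defaults,
#' checks thresholds and verifies that every referenced input file
#' exists and every enabled stage's prerequisites are enabled.
#'
#' @param config Path to a YAML file, or a list.
#' @return A normalized `pipeline_config` list.
#' @export
validate_config <- function(config) {
  cfg <- if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config)
    yaml::read_yaml(config)
  } else config
  def <- pipeline_defaults()
  for (k in names(def)) if (is.null(cfg[[k]])) cfg[[k]] <- def[[k]]
  if (is.null(cfg$seed)) cfg$seed <- 7
  if (cfg$fc_threshold <= 0) stop("fc_threshold must be positive")
  if (cfg$alpha <= 0 || cfg$alpha > 1) stop("alpha must lie in (0, 1]")
  if (cfg$tpm_threshold <= 0) stop("tpm_threshold must be positive")
  for (thr in c("r_threshold", "r_threshold_aging")) {
    if (cfg[[thr]] <= 0 || cfg[[thr]] >= 1) stop(thr, " must lie in (0, 1)")
  }
  simulate_on <- "simulate" %in% cfg$stages
  if (!simulate_on) {
    for (p in c("counts_path", "tpm_path", "samples_path")) {
      if (is.null(cfg[[p]])) {
        stop("without a simulate stage the config must set ", p)
      }
      if (!file.exists(cfg[[p]])) stop("input file not found: ", cfg[[p]])
    }
  }
  deps <- list(classify = "de", coexpression = "classify")
  for (s in names(deps)) {
    if (s %in% cfg$stages && !deps[[s]] %in% cfg$stages) {
      stop("stage '", s, "' requires stage '", deps[[s]], "' to be enabled")
    }
  }
  structure(cfg, class = "pipeline_config")
}

fingerprint <- function(path) {
  # content hash without external tools: size plus a simple checksum
  raw <- readBin(path, "raw", file.info(path)$size)
  sprintf("%d-%08x", length(raw),
          sum(as.integer(raw) * (seq_along(raw) %% 97 + 1)) %% 0xFFFFFFFF)
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Run the configured pipeline
#'
#' Executes the enabled stages in dependency order (simulate/load ->
#' breadth -> DE -> classification -> co-expression -> essentiality),
#' writing each stage's tables under a stage-named subdirectory of
#' `out_dir` and a consolidated `report.json`. Identical (config, inputs,
#' seed) give identical outputs.
#'
#' @param config A [validate_config()] result, YAML path, or list.
#' @param out_dir Output directory (created if needed).
#' @return The run report list, invisibly.
#' @export
run_pipeline <- function(config, out_dir) {
  cfg <- if (inherits(config, "pipeline_config")) config
         else validate_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  report <- list(seed = cfg$seed,
                 version = as.character(utils::packageVersion("chapatlas")),
                 thresholds = cfg[c("tpm_threshold", "fc_threshold", "alpha",
                                    "r_threshold", "r_threshold_aging")],
                 stages = list())
  mark <- function(stage, status, detail = NULL) {
    report$stages[[stage]] <<- list(status = status, detail = detail)
  }
  state <- new.env(parent = emptyenv())

  run_stage <- function(stage, fun) {
    if (!stage %in% cfg$stages && stage != "load") return(invisible())
    dir.create(file.path(out_dir, stage), showWarnings = FALSE)
    ok <- tryCatch({ fun(); TRUE },
                   error = function(e) {
                     mark(stage, "failed", conditionMessage(e))
                     jsonlite::write_json(report,
                                          file.path(out_dir, "report.json"),
                                          auto_unbox = TRUE, digits = NA,
                                          na = "null")
                     stop("stage '", stage, "' failed: ",
                          conditionMessage(e), call. = FALSE)
                   })
    invisible(ok)
  }

  if ("simulate" %in% cfg$stages) {
    run_stage("simulate", function() {
      sim_args <- cfg$simulate %||% list()
      sim_args$seed <- stage_seed(cfg$seed, "simulate")
      sc <- do.call(simulation_config, sim_args)
      sim <- simulate_dataset(sc)
      state$counts <- sim$counts
      state$tpm <- sim$tpm
      state$truth <- sim$truth
      write_gct(sim$counts$values, file.path(out_dir, "simulate", "counts.gct"))
      write_tsv(data.frame(sample_id = names(sim$counts$sample_tissue),
                           tissue = unname(sim$counts$sample_tissue)),
                file.path(out_dir, "simulate", "samples.tsv"))
      write_tsv(data.frame(gene_id = names(sim$truth$labels),
                           label = unname(sim$truth$labels)),
                file.path(out_dir, "simulate", "truth_labels.tsv"))
      mark("simulate", "ok", sprintf("%d genes x %d samples",
                                     nrow(sim$counts$values),
                                     ncol(sim$counts$values)))
    })
  } else {
    report$inputs <- list(counts = fingerprint(cfg$counts_path),
                          tpm = fingerprint(cfg$tpm_path),
                          samples = fingerprint(cfg$samples_path))
    state$counts <- load_matrix(cfg$counts_path, cfg$samples_path,
                                units = "counts",
                                min_samples = cfg$min_samples)
    state$tpm <- load_matrix(cfg$tpm_path, cfg$samples_path, units = "tpm",
                             min_samples = cfg$min_samples)
    mark("load", "ok")
  }

  if (!is.null(cfg$tissue_map)) {
    map <- unlist(cfg$tissue_map)
    state$counts <- aggregate_tissues(state$counts, map)
    state$tpm <- aggregate_tissues(state$tpm, map)
  }

  run_stage("breadth", function() {
    med <- median_by_tissue(state$tpm)
    prof <- breadth_profile(med, threshold = cfg$tpm_threshold)
    state$medians <- med
    state$breadth <- prof
    write_tsv(data.frame(gene_id = names(prof$breadth),
                         breadth = unname(prof$breadth)),
              file.path(out_dir, "breadth", "breadth.tsv"))
    hist <- binned_breadth_histogram(prof)
    write_tsv(data.frame(bin = names(hist$counts),
                         count = unname(hist$counts)),
              file.path(out_dir, "breadth", "histogram.tsv"))
    mark("breadth", "ok",
         sprintf("threshold %g TPM, %d genes unexpressed",
                 cfg$tpm_threshold, hist$n_unexpressed))
  })

  run_stage("de", function() {
    state$de <- build_de_table(state$counts)
    write_tsv(state$de, file.path(out_dir, "de", "de_table.tsv"))
    mark("de", "ok", sprintf("%d genes x %d tissues",
                             length(attr(state$de, "genes")),
                             length(unique(state$de$tissue))))
  })

  run_stage("classify", function() {
    state$classification <- classify_core_variable(
      state$de, fc_threshold = cfg$fc_threshold, alpha = cfg$alpha,
      significance_required = cfg$significance_required)
    write_tsv(state$classification,
              file.path(out_dir, "classify", "classification.tsv"))
    mark("classify", "ok",
         sprintf("%d core / %d variable",
                 sum(state$classification$label == "core"),
                 sum(state$classification$label == "variable")))
  })

  run_stage("coexpression", function() {
    genes <- if (!is.null(state$truth)) {
      names(state$truth$labels)[state$truth$labels != "background"]
    } else if (!is.null(cfg$gene_set_path)) {
      utils::read.delim(cfg$gene_set_path)$gene_id
    } else {
      stop("coexpression needs a simulated truth or a gene_set_path")
    }
    tens <- coexpression_tensor(state$tpm, genes,
                                min_samples = cfg$min_samples)
    state$tensor <- tens
    counts <- count_correlated_tissues(tens, cfg$r_threshold)
    classes <- pair_classes(tens, state$classification)
    write_tsv(data.frame(pair = rownames(tens$r),
                         class = unname(classes),
                         n_tissues_correlated = unname(counts)),
              file.path(out_dir, "coexpression", "pair_counts.tsv"))
    for (t in colnames(tens$r)) {
      export_network(tens, t, cfg$r_threshold,
                     classification = state$classification,
                     path = file.path(out_dir, "coexpression",
                                      paste0("network_", t, ".json")))
    }
    mark("coexpression", "ok", sprintf("%d pairs x %d tissues",
                                       nrow(tens$r), ncol(tens$r)))
  })

  run_stage("essentiality", function() {
    scores <- if (!is.null(state$truth)) {
      simulate_essentiality(state$truth,
                            seed = stage_seed(cfg$seed, "essentiality"))
    } else if (!is.null(cfg$scores_path)) {
      read_scores(cfg$scores_path)
    } else {
      stop("essentiality needs a simulated truth or a scores_path")
    }
    prof <- min_score_per_gene(scores)
    write_tsv(prof, file.path(out_dir, "essentiality", "min_scores.tsv"))
    state$essentiality <- prof
    mark("essentiality", "ok", sprintf("%d genes x %d cell lines",
                                       nrow(scores), ncol(scores)))
  })

  report$stages <- report$stages
  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, na = "null")
  invisible(report)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
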