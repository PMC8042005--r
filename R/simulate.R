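# Seeded multi-tissue negative-binomial simulator with planted
# core/variable chaperones, per-tissue latent co-expression modules,
# library-size variation, and companion essentiality and
# development/aging tables consistent with the planted structure.

#' Simulation configuration
#'
#' Defines the study conditions for the synthetic multi-tissue dataset:
#' counts are negative binomial around gene base means with planted
#' tissue effects for variable chaperones, log-normal library-size
#' factors, and a per-tissue latent factor loading shared by module
#' genes that induces within-tissue co-expression.
#'
#' @param n_tissues Number of tissues (default 12).
#' @param samples_per_tissue Samples per tissue (>= 5; default 10).
#' @param n_genes Total genes (default 6000).
#' @param n_chaperones Planted chaperones among them (default 150).
#' @param n_core Planted core chaperones (all-zero effects; default 30).
#' @param effect_log2 Planted log2 effect for each variable chaperone in
#'   its single upregulated tissue (|effect| >= 1; default 2).
#' @param nb_dispersion Negative-binomial dispersion (default 0.2).
#' @param library_size_log_sd SD of log-normal library factors (default 0.2).
#' @param module_size Genes per planted co-expression module (default 15,
#'   drawn from the core chaperones so module pairs exist in every tissue).
#' @param module_loading Latent-factor loading on log2 mean for module
#'   genes (default 0.8).
#' @param module_tissues Number of tissues in which the module is active
#'   (default all).
#' @param frac_restricted Fraction of background genes with
#'   tissue-restricted expression, giving the bimodal breadth profile
#'   (default 0.35).
#' @param seed Integer seed (default 7).
#' @return A `sim_config` list.
#' @export
simulation_config <- function(n_tissues = 12, samples_per_tissue = 10,
                              n_genes = 6000, n_chaperones = 150,
                              n_core = 30, effect_log2 = 2,
                              nb_dispersion = 0.2,
                              library_size_log_sd = 0.2,
                              module_size = 15, module_loading = 0.8,
                              module_tissues = n_tissues,
                              frac_restricted = 0.35, seed = 7) {
  cfg <- list(n_tissues = n_tissues, samples_per_tissue = samples_per_tissue,
              n_genes = n_genes, n_chaperones = n_chaperones, n_core = n_core,
              effect_log2 = effect_log2, nb_dispersion = nb_dispersion,
              library_size_log_sd = library_size_log_sd,
              module_size = module_size, module_loading = module_loading,
              module_tissues = module_tissues,
              frac_restricted = frac_restricted, seed = as.integer(seed))
  if (cfg$samples_per_tissue < 2) {
    stop("samples_per_tissue must be >= 2 (correlations undefined below)")
  }
  if (cfg$n_core > cfg$n_chaperones || cfg$n_chaperones > cfg$n_genes) {
    stop("need n_core <= n_chaperones <= n_genes")
  }
  if (cfg$n_chaperones > cfg$n_core && abs(cfg$effect_log2) < 1) {
    stop("planted |log2 effect| for variable genes must be >= 1")
  }
  if (cfg$nb_dispersion <= 0 || cfg$library_size_log_sd < 0) {
    stop("dispersion must be positive and library_size_log_sd non-negative")
  }
  if (cfg$module_size > cfg$n_core) {
    stop("module_size cannot exceed the number of core chaperones")
  }
  structure(cfg, class = "sim_config")
}

#' Simulate a multi-tissue expression dataset with planted truth
#'
#' @param config A [simulation_config()].
#' @return List with `counts` and `tpm` (both `expression_matrix`) and
#'   `truth`: `labels` (gene -> core/variable/background),
#'   `effect_matrix` (gene x tissue planted log2 effects),
#'   `module_membership` (tissue -> gene ids), `essential_set`,
#'   and `base_mean_matrix` (the model mean per gene x tissue before
#'   library scaling, for generator-level checks).
#' @export
simulate_dataset <- function(config = simulation_config()) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  G <- config$n_genes; Tn <- config$n_tissues; S <- config$samples_per_tissue
  n_samp <- Tn * S
  genes <- sprintf("GENE%05d", seq_len(G))
  chap_idx <- seq_len(config$n_chaperones)
  core_idx <- seq_len(config$n_core)
  var_idx <- setdiff(chap_idx, core_idx)
  genes[chap_idx] <- sprintf("CHAP%04d", chap_idx)
  tissues <- sprintf("tissue%02d", seq_len(Tn))
  sample_ids <- paste0(rep(tissues, each = S), "_s", rep(seq_len(S), Tn))
  sample_tissue <- stats::setNames(rep(tissues, each = S), sample_ids)

  # base mean (log2 scale): chaperones high-ish and ubiquitous;
  # background bimodal in breadth: ubiquitous mass + tissue-restricted mass
  base_log2 <- stats::rnorm(G, mean = 6, sd = 1.5)
  labels <- rep("background", G)
  labels[chap_idx] <- "variable"
  labels[core_idx] <- "core"
  names(labels) <- genes

  effect <- matrix(0, G, Tn, dimnames = list(genes, tissues))
  # each variable chaperone upregulated in one tissue, round-robin
  if (length(var_idx) > 0) {
    up_tissue <- ((seq_along(var_idx) - 1) %% Tn) + 1
    effect[cbind(var_idx, up_tissue)] <- config$effect_log2
  }
  # tissue-restricted background genes: expressed in 1-3 tissues only
  n_bg <- G - config$n_chaperones
  bg_idx <- setdiff(seq_len(G), chap_idx)
  restricted <- sample(bg_idx, round(config$frac_restricted * n_bg))
  low_log2 <- -4   # below the expressed threshold after TPM scaling
  base_log2[restricted] <- low_log2
  for (g in restricted) {
    k <- sample(1:3, 1)
    on_t <- sample(Tn, k)
    effect[g, on_t] <- stats::rnorm(k, mean = 10, sd = 1)  # lifts above cut
  }

  # per-tissue latent modules: the first module_size core chaperones, so
  # module membership is a deterministic function of the configuration
  # and datasets simulated under different seeds share their modules
  module_genes <- genes[core_idx[seq_len(config$module_size)]]
  module_tiss <- tissues[seq_len(config$module_tissues)]
  module_membership <- stats::setNames(
    lapply(tissues, function(t) if (t %in% module_tiss) module_genes
           else character(0)),
    tissues)

  mu_log2 <- matrix(base_log2, G, n_samp) +
    effect[, sample_tissue[sample_ids]]
  # latent factor per sample enters module genes' log-mean additively;
  # centered within each tissue so it induces within-tissue correlation
  # without shifting tissue means (which would fake differential
  # expression for module genes)
  z <- stats::rnorm(n_samp)
  z <- z - stats::ave(z, sample_tissue[sample_ids])
  mod_rows <- match(module_genes, genes)
  active <- sample_tissue[sample_ids] %in% module_tiss
  mu_log2[mod_rows, active] <- mu_log2[mod_rows, active] +
    config$module_loading * rep(z[active], each = length(mod_rows))

  lib_factor <- exp(stats::rnorm(n_samp, 0, config$library_size_log_sd))
  mu <- t(t(2^mu_log2) * lib_factor)
  size <- 1 / config$nb_dispersion
  counts <- matrix(stats::rnbinom(G * n_samp, mu = mu, size = size),
                   G, n_samp, dimnames = list(genes, sample_ids))

  # TPM: length-free normalization of expected expression plus noise
  rel <- 2^(mu_log2 + stats::rnorm(G * n_samp, 0, 0.1))
  tpm <- t(t(rel) / colSums(rel)) * 1e6
  dimnames(tpm) <- list(genes, sample_ids)

  essential_set <- genes[core_idx]
  truth <- list(labels = labels, effect_matrix = effect,
                module_membership = module_membership,
                essential_set = essential_set,
                base_mean_matrix = t(t(2^mu_log2) * lib_factor))
  list(counts = expression_matrix(counts, sample_tissue, units = "counts"),
       tpm = expression_matrix(tpm, sample_tissue, units = "tpm"),
       truth = truth)
}

#' Simulate a gene x cell-line essentiality score table
#'
#' Scores are standard normal per cell line; genes in the planted
#' essential set have their mean shifted by `shift` (negative for
#' growth-reducing).
#'
#' @param truth Truth list from [simulate_dataset()] (or any list with
#'   `labels` and `essential_set`).
#' @param n_cell_lines Number of cell lines (>= 1).
#' @param shift Mean shift for planted-essential genes (<= 0).
#' @param seed Integer seed.
#' @return Numeric gene x cell-line matrix.
#' @export
simulate_essentiality <- function(truth, n_cell_lines = 500, shift = -1,
                                  seed = 7) {
  if (n_cell_lines < 1) stop("n_cell_lines must be >= 1")
  if (shift > 0) stop("shift must be <= 0 for planted-essential genes")
  set.seed(seed)
  genes <- names(truth$labels)
  scores <- matrix(stats::rnorm(length(genes) * n_cell_lines),
                   length(genes), n_cell_lines,
                   dimnames = list(genes,
                                   sprintf("cellline%03d",
                                           seq_len(n_cell_lines))))
  ess <- genes %in% truth$essential_set
  scores[ess, ] <- scores[ess, ] + shift
  scores
}

#' Simulate development specificity scores and organ module maps
#'
#' Specificity scores lie in `[0, 1]` (0 = uniform across organs or time
#' points, 1 = most specific): planted core genes draw from a
#' low-specificity Beta, variable chaperones from a high-specificity
#' Beta, background in between. The organ module map reuses the planted
#' co-expression module membership.
#'
#' @param truth Truth list from [simulate_dataset()].
#' @param seed Integer seed.
#' @param organs Organ labels (defaults to the truth's tissues).
#' @return List with `specificity` (data frame gene/context/score) and
#'   `modules` (data frame organ/gene/module).
#' @export
simulate_development_tables <- function(truth, seed = 7, organs = NULL) {
  set.seed(seed)
  genes <- names(truth$labels)
  if (is.null(organs)) organs <- names(truth$module_membership)
  shape <- function(lbl) switch(lbl,
    core = c(1.2, 8),        # mean ~0.13
    variable = c(4, 3),      # mean ~0.57
    background = c(2, 4))    # mean ~0.33
  spec <- do.call(rbind, lapply(organs, function(org) {
    sc <- vapply(truth$labels, function(l) {
      p <- shape(l); stats::rbeta(1, p[1], p[2])
    }, numeric(1))
    data.frame(gene_id = genes, context = org,
               score = pmin(pmax(sc, 0), 1),
               stringsAsFactors = FALSE, row.names = NULL)
  }))
  mods <- do.call(rbind, lapply(organs, function(org) {
    members <- truth$module_membership[[org]]
    if (is.null(members) || length(members) == 0) return(NULL)
    data.frame(organ = org, gene_id = members,
               module = paste0(org, "_m1"),
               stringsAsFactors = FALSE, row.names = NULL)
  }))
  list(specificity = spec, modules = mods)
}
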