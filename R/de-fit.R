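# Weighted two-group fits per gene with empirical-Bayes variance
# moderation, the one-vs-rest tissue DE table, and the core/variable
# classification rule.

# invert the trigamma function by Newton iteration on 1/trigamma
trigamma_inverse <- function(x) {
  if (!is.finite(x)) return(0)
  if (x <= 0) return(Inf)
  if (x > 1e7) return(1 / sqrt(x))
  if (x < 1e-6) return(1 / x)
  y <- 0.5 + 1 / x
  for (i in 1:50) {
    tri <- trigamma(y)
    dif <- tri * (1 - tri / x) / psigamma(y, 2)
    y <- y + dif
    if (abs(dif / y) < 1e-10) break
  }
  y
}

#' Estimate variance-moderation hyperparameters
#'
#' Fits a scaled-F model to gene-wise residual variances by matching the
#' mean and variance of log residual variances: the prior degrees of
#' freedom d0 come from inverting the trigamma relation for the excess
#' variance of log s^2 over what the residual degrees of freedom explain,
#' and the prior variance s0^2 from the corrected mean. When the observed
#' spread of log s^2 does not exceed its sampling spread, d0 is infinite.
#'
#' @param sigma2 Gene-wise residual variances (positive).
#' @param df Residual degrees of freedom (scalar or per gene).
#' @return A `moderation_params` list: `prior_df` (d0, possibly `Inf`)
#'   and `prior_var` (s0^2).
#' @export
estimate_moderation <- function(sigma2, df) {
  ok <- is.finite(sigma2) & sigma2 > 0
  s2 <- sigma2[ok]
  if (length(s2) < 2) stop("need at least 2 positive residual variances")
  df <- rep(df, length.out = length(sigma2))[ok]
  e <- log(s2) - digamma(df / 2) + log(df / 2)
  emean <- mean(e)
  evar <- stats::var(e) * (length(e) - 1) / length(e) -
    mean(trigamma(df / 2))
  if (evar > 0) {
    d0 <- 2 * trigamma_inverse(evar)
    s02 <- exp(emean + digamma(d0 / 2) - log(d0 / 2))
  } else {
    d0 <- Inf
    s02 <- exp(emean)
  }
  structure(list(prior_df = d0, prior_var = s02),
            class = "moderation_params")
}

# posterior (moderated) variances given hyperparameters
posterior_var <- function(sigma2, df, params) {
  d0 <- params$prior_df; s02 <- params$prior_var
  if (!is.finite(d0)) return(rep(s02, length(sigma2)))
  if (d0 == 0) return(sigma2)
  (d0 * s02 + df * sigma2) / (d0 + df)
}

#' One-vs-rest weighted fit with moderated t-statistics for one tissue
#'
#' Compares the target tissue's samples against the pooled samples of all
#' other tissues, gene by gene, using a weighted two-group least-squares
#' fit on the precision-weighted log-CPM. Residual variances are shrunk
#' toward a prior fitted across genes ([estimate_moderation()]), and the
#' t-statistic gains the prior degrees of freedom.
#'
#' @param v A [voom_transform()] result.
#' @param tissues Named character vector mapping sample id to tissue.
#' @param target Target tissue label.
#' @param moderation Optional `moderation_params` to reuse; also accepts
#'   `0` (no shrinkage) or `Inf` (full shrinkage to the prior variance)
#'   as a forced prior df.
#' @return Data frame per gene: `gene_id`, `log2fc`, `t`, `p`,
#'   `sigma2`, `df_total`; hyperparameters in attributes.
#' @export
fit_one_vs_rest <- function(v, tissues, target, moderation = NULL) {
  stopifnot(inherits(v, "voom_result"))
  samp <- colnames(v$log_cpm)
  tissues <- tissues[samp]
  if (!target %in% tissues) stop("target tissue not present: ", target)
  grp <- as.numeric(tissues == target)
  if (sum(grp) < 2 || sum(1 - grp) < 2) {
    stop("both target and background need >= 2 samples")
  }
  y <- v$log_cpm
  w <- v$weights
  # closed-form weighted two-group fit per gene, vectorized over genes
  w1 <- w * rep(grp, each = nrow(w))
  w0 <- w * rep(1 - grp, each = nrow(w))
  W1 <- rowSums(w1); W0 <- rowSums(w0)
  m1 <- rowSums(w1 * y) / W1
  m0 <- rowSums(w0 * y) / W0
  beta <- m1 - m0
  fitted <- outer(m0, rep(1, ncol(y))) + outer(beta, grp)
  rss <- rowSums(w * (y - fitted)^2)
  df <- ncol(y) - 2
  sigma2 <- rss / df
  se_unscaled <- sqrt(1 / W1 + 1 / W0)
  params <- if (inherits(moderation, "moderation_params")) {
    moderation
  } else if (is.numeric(moderation)) {
    # forced prior df; prior variance from the fitted model (or mean s2)
    est <- estimate_moderation(sigma2, df)
    structure(list(prior_df = moderation, prior_var = est$prior_var),
              class = "moderation_params")
  } else {
    estimate_moderation(sigma2, df)
  }
  s2_post <- posterior_var(sigma2, df, params)
  df_total <- df + if (is.finite(params$prior_df)) params$prior_df else Inf
  tval <- beta / (se_unscaled * sqrt(s2_post))
  p <- 2 * stats::pt(-abs(tval), df_total)
  out <- data.frame(gene_id = rownames(y), log2fc = beta, t = tval, p = p,
                    sigma2 = sigma2, df_total = df_total,
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "moderation") <- params
  out
}

#' One-vs-rest differential expression across all tissues
#'
#' Full pipeline from raw counts: low-count filter, TMM factors, log-CPM
#' with precision weights, a weighted two-group moderated fit of every
#' tissue against the rest, and Benjamini-Hochberg adjustment within each
#' tissue's family of genes.
#'
#' @param counts `expression_matrix` of raw counts (unfiltered).
#' @param count_cut,filter_mode Passed to [filter_low_counts()].
#' @param m_trim,a_trim Passed to [tmm_factors()].
#' @param span,iter Passed to [voom_transform()].
#' @return A `de_table` data frame: `gene_id`, `tissue`, `log2fc`, `t`,
#'   `p`, `adj_p`, with the retained gene ids in `attr(,"genes")`.
#' @export
build_de_table <- function(counts, count_cut = 10, filter_mode = "all",
                           m_trim = 0.30, a_trim = 0.05,
                           span = 0.5, iter = 2) {
  stopifnot(inherits(counts, "expression_matrix"))
  filtered <- filter_low_counts(counts, count_cut = count_cut,
                                mode = filter_mode)
  nf <- tmm_factors(filtered, m_trim = m_trim, a_trim = a_trim)
  v <- voom_transform(filtered, nf, span = span, iter = iter)
  tiss <- tissues_of(filtered)
  if (length(tiss) < 2) stop("one-vs-rest DE needs >= 2 tissues")
  pieces <- lapply(tiss, function(t) {
    fit <- fit_one_vs_rest(v, filtered$sample_tissue, t)
    fit$adj_p <- bh_adjust(fit$p)
    fit$tissue <- t
    fit[, c("gene_id", "tissue", "log2fc", "t", "p", "adj_p")]
  })
  out <- do.call(rbind, pieces)
  attr(out, "genes") <- rownames(filtered$values)
  class(out) <- c("de_table", "data.frame")
  out
}

#' Classify genes as core or variable
#'
#' A gene is `variable` when some tissue shows `|log2fc| >= fc_threshold`
#' (by default irrespective of significance, matching a fold-change-only
#' core definition; set `significance_required = TRUE` to additionally
#' demand adjusted p <= alpha in that tissue). Retained genes that are
#' not variable are `core`.
#'
#' @param table A [build_de_table()] result.
#' @param fc_threshold Absolute log2 fold-change cut (default 1).
#' @param alpha Adjusted-p cut when `significance_required` (default 0.05).
#' @param significance_required Whether variability also requires an
#'   adjusted p at or below `alpha` (default FALSE).
#' @return A `gene_classification` data frame: `gene_id`, `label`,
#'   `max_abs_log2fc`; thresholds in attributes.
#' @export
classify_core_variable <- function(table, fc_threshold = 1, alpha = 0.05,
                                   significance_required = FALSE) {
  stopifnot(inherits(table, "de_table") || is.data.frame(table))
  need <- c("gene_id", "tissue", "log2fc", "adj_p")
  if (!all(need %in% names(table))) {
    stop("DE table needs columns: ", paste(need, collapse = ", "))
  }
  n_tiss <- length(unique(table$tissue))
  cnt <- table(table$gene_id)
  incomplete <- names(cnt)[cnt != n_tiss]
  if (length(incomplete) > 0) {
    stop("gene(s) missing tissue entries: ",
         paste(utils::head(incomplete, 5), collapse = ", "))
  }
  hit <- abs(table$log2fc) >= fc_threshold
  if (significance_required) hit <- hit & table$adj_p <= alpha
  agg <- tapply(hit, table$gene_id, any)
  fc <- tapply(abs(table$log2fc), table$gene_id, max)
  out <- data.frame(gene_id = names(agg),
                    label = ifelse(agg, "variable", "core"),
                    max_abs_log2fc = as.numeric(fc[names(agg)]),
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "fc_threshold") <- fc_threshold
  attr(out, "alpha") <- alpha
  attr(out, "significance_required") <- significance_required
  class(out) <- c("gene_classification", "data.frame")
  message(sprintf("classification: %d core, %d variable of %d genes",
                  sum(out$label == "core"), sum(out$label == "variable"),
                  nrow(out)))
  out
}
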