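# Low-count filtering, TMM factors, precision weights and the moderated
# two-group fit, against direct-formula oracles and the established
# reference implementations.

test_that("low-count filter removes genes at or below the cut in every sample", {
  x <- rbind(all10 = rep(10, 4), one11 = c(10, 11, 10, 10),
             high = rep(100, 4))
  colnames(x) <- paste0("s", 1:4)
  em <- expression_matrix(x, setNames(rep(c("a", "b"), 2), colnames(x)),
                          units = "counts")
  f <- suppressMessages(filter_low_counts(em))
  expect_setequal(rownames(f$values), c("one11", "high"))
  # strict any-sample mode drops genes with any low sample
  f2 <- suppressMessages(filter_low_counts(em, mode = "any"))
  expect_equal(rownames(f2$values), "high")
  tpm <- expression_matrix(x, setNames(rep(c("a", "b"), 2), colnames(x)),
                           units = "tpm")
  expect_error(filter_low_counts(tpm), "raw counts")
})

test_that("filtered retained set matches an exhaustive row-max oracle", {
  em <- make_counts(G = 200, n_per = 5, seed = 21, size = 1)
  f <- suppressMessages(filter_low_counts(em))
  keep_oracle <- apply(em$values, 1, function(v) any(v > 10))
  expect_setequal(rownames(f$values),
                  rownames(em$values)[keep_oracle])
})

test_that("TMM factors are unit for identical and depth-scaled libraries", {
  set.seed(22)
  base <- rnbinom(300, mu = 2^runif(300, 3, 10), size = 5) + 1
  x <- cbind(s1 = base, s2 = base, s3 = base)
  rownames(x) <- paste0("g", seq_along(base))
  em <- expression_matrix(x, setNames(rep("a", 3), colnames(x)), "counts")
  expect_equal(unname(tmm_factors(em)$factors), rep(1, 3))
  # doubling every count leaves M-values, hence factors, at 1
  x2 <- cbind(s1 = base, s2 = 2 * base)
  rownames(x2) <- paste0("g", seq_along(base))
  em2 <- expression_matrix(x2, setNames(rep("a", 2), colnames(x2)), "counts")
  expect_equal(unname(tmm_factors(em2)$factors), c(1, 1), tolerance = 1e-12)
})

test_that("TMM factors match the trim-and-weight oracle to 1e-10", {
  set.seed(23)
  for (i in 1:10) {
    G <- 10
    x <- matrix(rpois(G * 3, lambda = 2^runif(G * 3, 2, 9)) + 1, G, 3,
                dimnames = list(paste0("g", 1:G), paste0("s", 1:3)))
    em <- expression_matrix(x, setNames(rep("a", 3), colnames(x)), "counts")
    nf <- tmm_factors(em)
    ref_j <- which(colnames(x) == nf$ref_sample)
    raw <- vapply(1:3, function(j) {
      if (j == ref_j) 1 else tmm_oracle_pair(x[, j], x[, ref_j])
    }, numeric(1))
    raw <- raw / exp(mean(log(raw)))
    expect_equal(unname(nf$factors), raw, tolerance = 1e-10)
  }
})

test_that("TMM agrees closely with edgeR on random count matrices", {
  skip_if_not_installed("edgeR")
  em <- make_counts(G = 400, n_per = 4, seed = 24)
  nf <- tmm_factors(em)
  ref <- edgeR::calcNormFactors(edgeR::DGEList(em$values), method = "TMM")
  expect_equal(unname(nf$factors), ref$samples$norm.factors,
               tolerance = 0.02)
})

test_that("all-zero samples are rejected by name", {
  x <- cbind(s1 = c(5, 6), s2 = c(0, 0))
  rownames(x) <- c("g1", "g2")
  em <- expression_matrix(x, c(s1 = "a", s2 = "a"), "counts")
  expect_error(tmm_factors(em), "s2")
})

test_that("precision weights are strictly positive with a decreasing trend", {
  set.seed(25)
  G <- 1500; n <- 16
  mu <- 2^runif(G, 2, 10)
  x <- matrix(rnbinom(G * n, mu = mu, size = 1 / 0.2), G, n,
              dimnames = list(paste0("g", 1:G), paste0("s", 1:n)))
  em <- expression_matrix(x, setNames(rep(c("a", "b"), each = 8),
                                      colnames(x)), "counts")
  v <- voom_transform(em, tmm_factors(em))
  expect_true(all(v$weights > 0))
  expect_true(all(is.finite(v$log_cpm)))
  # evaluate the fitted trend across the central 80% of the mean range:
  # decreasing at every step of a 25-point grid, up to smoothing noise
  # (the true NB sqrt-sd curve flattens toward its dispersion floor, so
  # upticks bounded by 2% of the total drop are estimation noise)
  qs <- quantile(v$trend$x, c(0.1, 0.9))
  grid <- seq(qs[1], qs[2], length.out = 25)
  trend_fun <- approxfun(v$trend$x, v$trend$y, rule = 2, ties = mean)
  yg <- trend_fun(grid)
  drop_total <- yg[1] - yg[length(yg)]
  expect_gt(drop_total, 0)
  expect_true(all(diff(yg) < 0.02 * drop_total))
})

test_that("identical count rows receive identical weights", {
  em <- make_counts(G = 40, n_per = 5, seed = 26)
  em$values[2, ] <- em$values[1, ]
  v <- voom_transform(em)
  expect_equal(v$weights[1, ], v$weights[2, ])
  expect_equal(v$log_cpm[1, ], v$log_cpm[2, ])
})

test_that("weight agreement with limma voom on matched settings", {
  skip_if_not_installed("limma")
  skip_if_not_installed("edgeR")
  em <- make_counts(G = 600, n_per = 8, seed = 27)
  nf <- tmm_factors(em)
  v <- voom_transform(em, nf)
  dge <- edgeR::DGEList(em$values)
  dge$samples$norm.factors <- unname(nf$factors)
  design <- stats::model.matrix(~1, data.frame(row.names = colnames(em$values)))
  ref <- limma::voom(dge, design)
  expect_gt(cor(as.vector(v$weights), as.vector(ref$weights)), 0.99)
  expect_equal(v$log_cpm, ref$E, tolerance = 1e-10)
})

test_that("forcing the prior df recovers the ordinary and fixed-variance t", {
  em <- make_counts(G = 80, n_per = 6, seed = 28)
  v <- voom_transform(em, tmm_factors(em))
  st <- em$sample_tissue
  f0 <- fit_one_vs_rest(v, st, "a", moderation = 0)
  fI <- fit_one_vs_rest(v, st, "a", moderation = Inf)
  grp <- as.numeric(st[colnames(v$log_cpm)] == "a")
  s02 <- attr(fI, "moderation")$prior_var
  for (g in sample(nrow(v$log_cpm), 15)) {
    w <- v$weights[g, ]; y <- v$log_cpm[g, ]
    W1 <- sum(w * grp); W0 <- sum(w * (1 - grp))
    m1 <- sum(w * grp * y) / W1; m0 <- sum(w * (1 - grp) * y) / W0
    beta <- m1 - m0
    res <- y - (m0 + beta * grp)
    s2 <- sum(w * res^2) / (length(y) - 2)
    se <- sqrt(1 / W1 + 1 / W0)
    expect_equal(f0$t[g], beta / (se * sqrt(s2)), tolerance = 1e-8)
    expect_equal(fI$t[g], beta / (se * sqrt(s02)), tolerance = 1e-8)
  }
})

test_that("moderated t matches the closed-form posterior oracle to 1e-8", {
  em <- make_counts(G = 50, n_per = 7, seed = 29)
  v <- voom_transform(em, tmm_factors(em))
  st <- em$sample_tissue
  fit <- fit_one_vs_rest(v, st, "b")
  params <- attr(fit, "moderation")
  grp <- as.numeric(st[colnames(v$log_cpm)] == "b")
  df <- ncol(v$log_cpm) - 2
  for (g in seq_len(nrow(v$log_cpm))) {
    w <- v$weights[g, ]; y <- v$log_cpm[g, ]
    W1 <- sum(w * grp); W0 <- sum(w * (1 - grp))
    m1 <- sum(w * grp * y) / W1; m0 <- sum(w * (1 - grp) * y) / W0
    beta <- m1 - m0
    s2 <- sum(w * (y - (m0 + beta * grp))^2) / df
    s2_post <- if (is.finite(params$prior_df)) {
      (params$prior_df * params$prior_var + df * s2) /
        (params$prior_df + df)
    } else params$prior_var
    t_oracle <- beta / (sqrt(1 / W1 + 1 / W0) * sqrt(s2_post))
    expect_equal(fit$t[g], t_oracle, tolerance = 1e-8)
  }
})

test_that("moderated t tracks limma's empirical-Bayes fit", {
  skip_if_not_installed("limma")
  skip_if_not_installed("edgeR")
  em <- make_counts(G = 500, n_per = 10, seed = 30)
  nf <- tmm_factors(em)
  v <- voom_transform(em, nf)
  mine <- fit_one_vs_rest(v, em$sample_tissue, "a")
  dge <- edgeR::DGEList(em$values)
  dge$samples$norm.factors <- unname(nf$factors)
  grp <- as.numeric(em$sample_tissue[colnames(em$values)] == "a")
  design <- cbind(1, grp)
  ref <- limma::eBayes(limma::lmFit(limma::voom(dge, design), design))
  expect_gt(cor(mine$t, ref$t[, 2]), 0.999)
  expect_equal(mine$log2fc, unname(ref$coefficients[, 2]), tolerance = 0.05)
})

test_that("common depth scaling leaves log2fc essentially unchanged", {
  em <- make_counts(G = 300, n_per = 6, seed = 31)
  em_scaled <- em
  em_scaled$values <- em$values * 4
  de1 <- suppressMessages(build_de_table(em))
  de2 <- suppressMessages(build_de_table(em_scaled))
  shared <- intersect(attr(de1, "genes"), attr(de2, "genes"))
  big <- shared[rowMeans(em$values[shared, ]) >= 50]
  a <- de1[de1$gene_id %in% big & de1$tissue == "a", "log2fc"]
  b <- de2[de2$gene_id %in% big & de2$tissue == "a", "log2fc"]
  expect_equal(a, b, tolerance = 0.01)
})

test_that("sample order does not affect the DE table", {
  em <- make_counts(G = 100, n_per = 5, seed = 32)
  perm <- sample(ncol(em$values))
  em2 <- em
  em2$values <- em$values[, perm]
  em2$sample_tissue <- em$sample_tissue[perm]
  de1 <- suppressMessages(build_de_table(em))
  de2 <- suppressMessages(build_de_table(em2))
  expect_equal(de1, de2)
})

test_that("BH-adjusted p within a tissue is monotone in raw p", {
  em <- make_counts(G = 150, n_per = 6, seed = 33)
  de <- suppressMessages(build_de_table(em))
  for (t in unique(de$tissue)) {
    d <- de[de$tissue == t, ]
    o <- order(d$p)
    expect_true(all(diff(d$adj_p[o]) >= -1e-15))
    expect_true(all(d$adj_p >= d$p - 1e-15))
  }
})

test_that("classification applies the fold-change rule inclusively", {
  tab <- data.frame(
    gene_id = rep(c("flat", "edge", "signif"), each = 2),
    tissue = rep(c("t1", "t2"), 3),
    log2fc = c(0, 0, 1.0, 0.2, 3, 0.1),
    t = 0, p = 0.5,
    adj_p = c(0.9, 0.9, 0.01, 0.8, 0.8, 0.9))
  class(tab) <- c("de_table", "data.frame")
  cl <- suppressMessages(classify_core_variable(tab))
  lab <- setNames(cl$label, cl$gene_id)
  expect_equal(unname(lab["flat"]), "core")
  expect_equal(unname(lab["edge"]), "variable")   # threshold inclusive
  # significance-qualified variant demands adjusted p too
  cl2 <- suppressMessages(classify_core_variable(tab,
                                                 significance_required = TRUE))
  lab2 <- setNames(cl2$label, cl2$gene_id)
  expect_equal(unname(lab2["edge"]), "variable")
  expect_equal(unname(lab2["signif"]), "core")  # big fc but adj_p > alpha
  # incomplete gene x tissue grids are rejected
  expect_error(suppressMessages(classify_core_variable(tab[-1, ])),
               "missing tissue")
})
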