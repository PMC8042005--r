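# Per-tissue Spearman correlations, pair statistics and network export.

make_tpm_fixture <- function(seed = 44) {
  set.seed(seed)
  n <- 8
  s <- rnorm(n)                      # shared latent signal
  x <- rbind(mono_a = 1:n,           # strictly monotone pair
             mono_b = (1:n)^2,
             corr_a = s + rnorm(n, 0, 0.1),
             corr_b = s + rnorm(n, 0, 0.1),
             noise = rnorm(n),
             const = rep(3, n))
  colnames(x) <- paste0("s", 1:n)
  x <- x - min(x)                    # keep values non-negative
  expression_matrix(x, setNames(rep("t1", n), colnames(x)), units = "tpm")
}

test_that("monotone pairs reach r = 1 and constant genes are flagged", {
  m <- make_tpm_fixture()
  tc <- tissue_correlations(m, rownames(m$values), "t1")
  get_r <- function(a, b) tc$r[(tc$gene_a == a & tc$gene_b == b) |
                               (tc$gene_a == b & tc$gene_b == a)]
  expect_equal(get_r("mono_a", "mono_b"), 1)
  expect_true(is.na(get_r("const", "noise")))
  expect_gt(get_r("corr_a", "corr_b"), 0.8)
})

test_that("tied samples match the midrank covariance oracle exactly", {
  set.seed(45)
  for (i in 1:50) {
    x <- sample(1:5, 8, replace = TRUE)   # heavy ties
    y <- sample(1:5, 8, replace = TRUE)
    if (length(unique(x)) == 1 || length(unique(y)) == 1) next
    m <- expression_matrix(rbind(g1 = x, g2 = y,
                                 dummy = 1:8) |>
                             (\(v) {colnames(v) <- paste0("s", 1:8); v})(),
                           setNames(rep("t", 8), paste0("s", 1:8)), "tpm")
    tc <- tissue_correlations(m, c("g1", "g2"), "t")
    expect_equal(tc$r[1], spearman_oracle(x, y), tolerance = 1e-12)
  }
})

test_that("Spearman is invariant to strictly increasing transforms", {
  set.seed(46)
  x <- rnorm(9); y <- rnorm(9)
  build <- function(a, b) {
    v <- rbind(g1 = a - min(a), g2 = b - min(b))
    colnames(v) <- paste0("s", 1:9)
    expression_matrix(v, setNames(rep("t", 9), colnames(v)), "tpm")
  }
  r0 <- tissue_correlations(build(x, y), c("g1", "g2"), "t")$r
  r1 <- tissue_correlations(build(exp(x), y), c("g1", "g2"), "t")$r
  r2 <- tissue_correlations(build(x, y^3 + 5 * y), c("g1", "g2"), "t")$r
  expect_identical(r0, r1)
  expect_identical(r0, r2)
})

test_that("tensor respects symmetry, range and the sample floor", {
  s <- simulate_dataset(simulation_config(n_tissues = 3,
                                          samples_per_tissue = 6,
                                          n_genes = 100, n_chaperones = 10,
                                          n_core = 5, module_size = 3,
                                          seed = 47))
  genes <- names(s$truth$labels)[s$truth$labels != "background"]
  tens <- coexpression_tensor(s$tpm, genes)
  expect_equal(nrow(tens$r), choose(length(genes), 2))
  expect_true(all(abs(tens$r) <= 1 + 1e-12, na.rm = TRUE))
  # pair order does not matter: r computed once per unordered pair
  expect_equal(anyDuplicated(t(apply(tens$pairs, 1, sort))), 0)
  expect_error(tissue_correlations(s$tpm, genes, "tissue01",
                                   min_samples = 10), "fewer than 10")
})

test_that("tissues-correlated counts use strict positive thresholding", {
  r <- matrix(c(0.7, 0.7, 0.7,     # exactly at threshold: never counted
                1, 1, 1,
                0.9, -0.9, NA),
              3, 3, byrow = TRUE,
              dimnames = list(c("a|b", "a|c", "b|c"),
                              c("t1", "t2", "t3")))
  tens <- structure(list(r = r,
                         pairs = data.frame(gene_a = c("a", "a", "b"),
                                            gene_b = c("b", "c", "c")),
                         n_samples = c(t1 = 6, t2 = 6, t3 = 6)),
                    class = "coexpression_tensor")
  cnt <- count_correlated_tissues(tens, 0.7)
  expect_equal(unname(cnt), c(0, 3, 1))
  # negative correlations count only in absolute mode
  expect_equal(unname(count_correlated_tissues(tens, 0.7,
                                               absolute = TRUE)), c(0, 3, 2))
  expect_error(count_correlated_tissues(tens, 1.2), "\\(0, 1\\)")
  # monotone non-increasing in the threshold
  c5 <- count_correlated_tissues(tens, 0.5)
  c8 <- count_correlated_tissues(tens, 0.8)
  expect_true(all(c8 <= c5))
})

test_that("planted module pairs are correlated in more tissues than background", {
  s <- simulate_dataset(simulation_config(n_tissues = 6,
                                          samples_per_tissue = 8,
                                          n_genes = 300, n_chaperones = 30,
                                          n_core = 12, module_size = 6,
                                          seed = 48))
  genes <- names(s$truth$labels)[s$truth$labels != "background"]
  tens <- coexpression_tensor(s$tpm, genes)
  cnt <- count_correlated_tissues(tens, 0.7)
  mod <- s$truth$module_membership[[1]]
  in_mod <- tens$pairs$gene_a %in% mod & tens$pairs$gene_b %in% mod
  expect_gt(min(cnt[in_mod]), median(cnt[!in_mod]))
})

test_that("pair classes derive from the two member labels", {
  cl <- data.frame(gene_id = c("a", "b", "c"),
                   label = c("core", "core", "variable"))
  tens <- structure(list(r = matrix(0.5, 3, 1,
                                    dimnames = list(c("a|b", "a|c", "b|c"),
                                                    "t1")),
                         pairs = data.frame(gene_a = c("a", "a", "b"),
                                            gene_b = c("b", "c", "c"))),
                    class = "coexpression_tensor")
  pc <- pair_classes(tens, cl)
  expect_equal(unname(pc), c("core-core", "mixed", "mixed"))
  counts <- setNames(c(5, 1, 0), names(pc))
  expect_error(compare_pair_class_distributions(counts, pc, "core-core",
                                                "variable-variable"),
               "non-empty")
  res <- compare_pair_class_distributions(counts, pc, "core-core", "mixed")
  expect_s3_class(res, "chap_test")
})

test_that("network export thresholds edges and round-trips through JSON", {
  s <- simulate_dataset(simulation_config(n_tissues = 3,
                                          samples_per_tissue = 6,
                                          n_genes = 120, n_chaperones = 12,
                                          n_core = 6, module_size = 4,
                                          seed = 49))
  genes <- names(s$truth$labels)[s$truth$labels != "background"]
  tens <- coexpression_tensor(s$tpm, genes)
  # a threshold of 1 leaves no edges (strict inequality)
  empty <- export_network(tens, "tissue01", r_threshold = 1)
  expect_equal(nrow(empty$links), 0)
  # a threshold just below a known pair's r keeps that edge with its r
  known <- which.max(tens$r[, "tissue01"])
  rv <- tens$r[known, "tissue01"]
  doc <- export_network(tens, "tissue01", r_threshold = rv - 1e-6)
  key <- paste(doc$links$source, doc$links$target, sep = "|")
  expect_true(rownames(tens$r)[known] %in% key)
  expect_equal(doc$links$r[key == rownames(tens$r)[known]], rv)
  expect_error(export_network(tens, "nowhere"), "unknown tissue")
  tmp <- withr::local_tempfile(fileext = ".json")
  export_network(tens, "tissue01", r_threshold = 0.5, path = tmp)
  back <- read_network(tmp)
  full <- export_network(tens, "tissue01", r_threshold = 0.5)
  expect_equal(back$links$r, full$links$r)
  expect_setequal(back$nodes$id, full$nodes$id)
  expect_equal(back$tissue, "tissue01")
})
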