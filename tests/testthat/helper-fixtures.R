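# Shared fixture builders and independent brute-force oracles.

# small two-tissue count matrix
make_counts <- function(G = 50, n_per = 6, seed = 1, tissues = c("a", "b"),
                        size = 5) {
  set.seed(seed)
  n <- n_per * length(tissues)
  mu <- 2^stats::runif(G, 3, 9)
  x <- matrix(stats::rnbinom(G * n, mu = mu, size = size), G, n,
              dimnames = list(sprintf("g%03d", 1:G),
                              sprintf("s%02d", 1:n)))
  st <- stats::setNames(rep(tissues, each = n_per), colnames(x))
  expression_matrix(x, st, units = "counts")
}

# registry fixture path
fixture_registry <- function() {
  system.file("extdata", "chaperone_registry_synthetic.tsv",
              package = "chapatlas")
}

# exhaustive two-sample KS p by enumerating all label assignments
ks_enum_p <- function(x, y, alternative = "two.sided") {
  m <- length(x); n <- length(y)
  pooled <- c(x, y)
  stat <- function(xi) {
    a <- pooled[xi]; b <- pooled[-xi]
    grid <- sort(unique(pooled))
    Fa <- vapply(grid, function(v) mean(a <= v), numeric(1))
    Fb <- vapply(grid, function(v) mean(b <= v), numeric(1))
    switch(alternative,
           two.sided = max(abs(Fa - Fb)),
           greater = max(Fa - Fb),
           less = max(Fb - Fa))
  }
  obs <- stat(seq_len(m))
  combos <- utils::combn(m + n, m)
  ds <- apply(combos, 2, stat)
  mean(ds >= obs - 1e-12)
}

# exhaustive Mann-Whitney p by enumerating all subsets
mw_enum_p <- function(x, y, alternative = "two.sided") {
  m <- length(x); n <- length(y)
  pooled <- c(x, y)
  r <- rank(pooled)
  u_of <- function(xi) sum(r[xi]) - m * (m + 1) / 2
  obs <- u_of(seq_len(m))
  combos <- utils::combn(m + n, m)
  us <- apply(combos, 2, u_of)
  p_ge <- mean(us >= obs - 1e-12)
  p_le <- mean(us <= obs + 1e-12)
  switch(alternative,
         greater = p_ge, less = p_le,
         two.sided = min(1, 2 * min(p_ge, p_le)))
}

# Spearman with midranks via explicit covariance formula
spearman_oracle <- function(x, y) {
  midrank <- function(v) {
    s <- sort(v)
    vapply(v, function(a) mean(which(s == a)), numeric(1))
  }
  rx <- midrank(x); ry <- midrank(y)
  num <- sum((rx - mean(rx)) * (ry - mean(ry)))
  den <- sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
  num / den
}

# hypergeometric tail by direct (non-log) summation of choose() terms
hyper_tail_oracle <- function(N, K, n, k, alternative = "greater") {
  lo <- max(0, K + n - N); hi <- min(K, n)
  pmf <- vapply(lo:hi, function(i)
    choose(K, i) * choose(N - K, n - i) / choose(N, n), numeric(1))
  supp <- lo:hi
  if (alternative == "greater") sum(pmf[supp >= k]) else sum(pmf[supp <= k])
}

# step-up FDR oracle: sort, scale, cumulative-min, unsort
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  sorted <- p[o] * m / seq_len(m)
  for (i in (m - 1):1) sorted[i] <- min(sorted[i], sorted[i + 1])
  out <- numeric(m)
  out[o] <- pmin(sorted, 1)
  out
}

# TMM factor for one sample against a reference, re-derived from the
# trim-and-weight definition with order()-based selection
tmm_oracle_pair <- function(obs, ref, m_trim = 0.30, a_trim = 0.05) {
  n_obs <- sum(obs); n_ref <- sum(ref)
  keep <- obs > 0 & ref > 0
  o <- obs[keep] / n_obs; r <- ref[keep] / n_ref
  M <- log2(o / r); A <- 0.5 * log2(o * r)
  w <- (n_obs - obs[keep]) / (n_obs * obs[keep]) +
    (n_ref - ref[keep]) / (n_ref * ref[keep])
  n <- length(M)
  lo_m <- floor(n * m_trim) + 1; hi_m <- n + 1 - lo_m
  lo_a <- floor(n * a_trim) + 1; hi_a <- n + 1 - lo_a
  keep_m <- order(M)[lo_m:hi_m]
  keep_a <- order(A)[lo_a:hi_a]
  sel <- intersect(keep_m, keep_a)
  2^(sum(M[sel] / w[sel]) / sum(1 / w[sel]))
}
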