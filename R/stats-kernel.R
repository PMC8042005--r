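# Exact overlap tests, rank tests and FDR adjustment used throughout the
# pipeline. Tail probabilities are accumulated in log space so that the
# very small p-values arising in genome-scale comparisons (down to ~1e-32)
# do not underflow.

#' Construct a 2x2 overlap design
#'
#' Describes the overlap between two gene sets drawn from a common universe:
#' `N` genes in the universe, `K` in the first set, `n` in the second and
#' `k` in the intersection.
#'
#' @param N Universe size.
#' @param K Size of the first set.
#' @param n Size of the second set.
#' @param k Observed overlap.
#' @return An object of class `overlap_table`.
#' @export
overlap_table <- function(N, K, n, k) {
  vals <- c(N = N, K = K, n = n, k = k)
  if (any(vals < 0) || any(vals != round(vals))) {
    stop("overlap_table entries must be non-negative integers")
  }
  if (K > N) stop("infeasible table: K > N (set 1 larger than universe)")
  if (n > N) stop("infeasible table: n > N (set 2 larger than universe)")
  if (k > min(K, n)) {
    stop("infeasible table: k > min(K, n) (overlap exceeds a set)")
  }
  if (k < max(0L, K + n - N)) {
    stop("infeasible table: k < max(0, K + n - N) (sets must overlap more)")
  }
  structure(list(N = N, K = K, n = n, k = k), class = "overlap_table")
}

#' @export
print.overlap_table <- function(x, ...) {
  cat(sprintf("overlap table: universe %d, sets %d and %d, overlap %d\n",
              x$N, x$K, x$n, x$k))
  invisible(x)
}

# log of sum(exp(lx)) without leaving log space
logsumexp <- function(lx) {
  m <- max(lx)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(lx - m)))
}

# log hypergeometric pmf at each value of x
log_hyper_pmf <- function(x, N, K, n) {
  lchoose(K, x) + lchoose(N - K, n - x) - lchoose(N, n)
}

new_test_result <- function(statistic, p, alternative, method, exact = FALSE,
                            extra = NULL) {
  out <- c(list(statistic = unname(statistic), p = min(max(p, 0), 1),
                alternative = alternative, method = method, exact = exact),
           extra)
  structure(out, class = "chap_test")
}

#' @export
print.chap_test <- function(x, ...) {
  cat(sprintf("%s\n  statistic = %.6g, p = %.4g (%s%s)\n",
              x$method, x$statistic, x$p, x$alternative,
              if (isTRUE(x$exact)) ", exact" else ""))
  invisible(x)
}

#' Hypergeometric overlap test
#'
#' Exact tail probability of the observed overlap between two gene sets
#' under sampling without replacement. `alternative = "greater"` returns
#' the enrichment tail P(X >= k); `"less"` the depletion tail P(X <= k).
#' The probability mass function is summed exactly via log-gamma terms.
#'
#' @param t An [overlap_table()].
#' @param alternative One of `"greater"`, `"less"`, `"two.sided"`.
#' @return A `chap_test` result with the overlap as statistic.
#' @export
hypergeom_overlap <- function(t, alternative = c("greater", "less", "two.sided")) {
  stopifnot(inherits(t, "overlap_table"))
  alternative <- match.arg(alternative)
  lo <- max(0L, t$K + t$n - t$N)
  hi <- min(t$K, t$n)
  support <- lo:hi
  lp <- log_hyper_pmf(support, t$N, t$K, t$n)
  p <- switch(alternative,
    greater = exp(logsumexp(lp[support >= t$k])),
    less = exp(logsumexp(lp[support <= t$k])),
    two.sided = {
      obs <- lp[support == t$k]
      # include all tables at most as probable as the observed one
      exp(logsumexp(lp[lp <= obs + 1e-7]))
    })
  new_test_result(t$k, p, alternative, "hypergeometric overlap test",
                  exact = TRUE)
}

#' Fisher exact test on a 2x2 table
#'
#' One-sided tails equal the hypergeometric tails on the induced overlap
#' table (`a` as the overlap cell); the two-sided p-value sums all tables
#' with point probability at most that of the observed table. `"greater"`
#' tests enrichment of the overlap cell `a`, `"less"` its depletion.
#'
#' @param a,b,c,d Non-negative integer cell counts, row-wise
#'   (`a` = in both sets, `b` = set 1 only, `c` = set 2 only, `d` = neither).
#' @param alternative One of `"greater"`, `"less"`, `"two.sided"`.
#' @return A `chap_test` result; statistic is the sample odds ratio.
#' @export
fisher_exact_2x2 <- function(a, b, c, d,
                             alternative = c("greater", "less", "two.sided")) {
  alternative <- match.arg(alternative)
  cells <- c(a, b, c, d)
  if (any(cells < 0) || any(cells != round(cells))) {
    stop("cell counts must be non-negative integers")
  }
  if (a + b == 0 || c + d == 0 || a + c == 0 || b + d == 0) {
    stop("degenerate table: a margin is zero")
  }
  tab <- overlap_table(N = a + b + c + d, K = a + b, n = a + c, k = a)
  res <- hypergeom_overlap(tab, alternative)
  odds <- (a * d) / (b * c)
  new_test_result(odds, res$p, alternative, "Fisher exact test", exact = TRUE)
}

# number of monotone lattice paths (0,0) -> (m,n) whose empirical-CDF
# deviation stays strictly below d at every node; used for the exact
# two-sample KS tail by complement counting
ks_paths_inside <- function(m, n, d, one_sided = FALSE) {
  u <- matrix(0, m + 1, n + 1)
  u[1, 1] <- 1
  tol <- 1e-9
  inside <- function(i, j) {
    dev <- i / m - j / n
    if (one_sided) dev < d - tol else abs(dev) < d - tol
  }
  for (i in 0:m) {
    for (j in 0:n) {
      if (i == 0 && j == 0) next
      if (!inside(i, j)) { u[i + 1, j + 1] <- 0; next }
      acc <- 0
      if (i > 0) acc <- acc + u[i, j + 1]
      if (j > 0) acc <- acc + u[i + 1, j]
      u[i + 1, j + 1] <- acc
    }
  }
  u[m + 1, n + 1]
}

#' Two-sample Kolmogorov-Smirnov test
#'
#' The statistic is the supremum difference between the two empirical
#' CDFs; for one-sided alternatives it is the signed deviation
#' (`"greater"`: CDF of `x` lies above that of `y`, i.e. `x`
#' stochastically smaller). For tie-free samples with both sizes at most
#' `exact_max` the p-value is exact, obtained by counting lattice paths;
#' otherwise the asymptotic Smirnov formula is used.
#'
#' @param x,y Numeric samples.
#' @param alternative One of `"two.sided"`, `"greater"`, `"less"`.
#' @param exact_max Largest per-sample size at which the exact tail is used.
#' @return A `chap_test` result with the D statistic.
#' @export
ks_test <- function(x, y, alternative = c("two.sided", "greater", "less"),
                    exact_max = 10) {
  alternative <- match.arg(alternative)
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (length(x) < 1 || length(y) < 1) stop("both samples must be non-empty")
  m <- length(x); n <- length(y)
  pooled <- c(x, y)
  ord <- order(pooled)
  steps <- ifelse(ord <= m, 1 / m, -1 / n)
  dev <- cumsum(steps)               # F_x - F_y after each pooled point
  # with ties, only deviations at distinct values count
  keep <- c(diff(sort(pooled)) != 0, TRUE)
  dev <- dev[keep]
  D <- switch(alternative,
    two.sided = max(abs(dev)),
    greater = max(dev),
    less = -min(dev))
  D <- max(D, 0)
  ties <- anyDuplicated(pooled) > 0
  use_exact <- !ties && m <= exact_max && n <= exact_max
  if (use_exact) {
    total <- choose(m + n, m)
    inside <- ks_paths_inside(m, n, D, one_sided = alternative != "two.sided")
    p <- 1 - inside / total
  } else {
    n_eff <- m * n / (m + n)
    if (D <= 0) {
      p <- 1
    } else if (alternative == "two.sided") {
      lambda <- sqrt(n_eff) * D
      j <- 1:100
      p <- 2 * sum((-1)^(j - 1) * exp(-2 * j^2 * lambda^2))
    } else {
      p <- exp(-2 * n_eff * D^2)
    }
  }
  new_test_result(D, p, alternative, "two-sample Kolmogorov-Smirnov test",
                  exact = use_exact)
}

# frequency table of the Wilcoxon rank-sum W (sum of ranks of the size-m
# sample minus its minimum) over all C(m+n, m) assignments, by
# subset-sum counting over ranks 1..m+n
mw_exact_freq <- function(m, n) {
  N <- m + n
  maxU <- m * n
  # f[j+1, u+1] = number of j-subsets of ranks seen so far with U value u
  f <- matrix(0, m + 1, maxU + 1)
  f[1, 1] <- 1
  for (r in 1:N) {
    for (j in min(m, r):1) {
      for (u in maxU:0) {
        # adding rank r as the j-th chosen element contributes r - j to U
        add <- r - j
        if (u - add >= 0) {
          f[j + 1, u + 1] <- f[j + 1, u + 1] + f[j, u - add + 1]
        }
      }
    }
  }
  f[m + 1, ]
}

#' Mann-Whitney U test
#'
#' Rank-sum comparison with midrank ties. `alternative = "greater"` tests
#' whether `x` tends to exceed `y`. For tie-free samples with both sizes
#' at most `exact_max`, the null distribution of U is enumerated exactly;
#' otherwise a normal approximation with tie and continuity corrections
#' is used.
#'
#' @param x,y Numeric samples.
#' @param alternative One of `"two.sided"`, `"greater"`, `"less"`.
#' @param exact_max Largest per-sample size at which the exact tail is used.
#' @return A `chap_test` result with the U statistic (for `x`).
#' @export
mw_test <- function(x, y, alternative = c("two.sided", "greater", "less"),
                    exact_max = 8) {
  alternative <- match.arg(alternative)
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (length(x) < 1 || length(y) < 1) stop("both samples must be non-empty")
  m <- length(x); n <- length(y)
  r <- rank(c(x, y), ties.method = "average")
  U <- sum(r[seq_len(m)]) - m * (m + 1) / 2
  ties <- anyDuplicated(c(x, y)) > 0
  use_exact <- !ties && m <= exact_max && n <= exact_max
  if (use_exact) {
    freq <- mw_exact_freq(m, n)
    total <- choose(m + n, m)
    support <- 0:(m * n)
    p_ge <- sum(freq[support >= U]) / total
    p_le <- sum(freq[support <= U]) / total
    p <- switch(alternative,
      greater = p_ge,
      less = p_le,
      two.sided = min(1, 2 * min(p_ge, p_le)))
  } else {
    mu <- m * n / 2
    Nn <- m + n
    tie_tab <- table(r)
    sigma2 <- m * n / 12 * ((Nn + 1) - sum(tie_tab^3 - tie_tab) / (Nn * (Nn - 1)))
    sigma <- sqrt(sigma2)
    z <- U - mu
    p <- switch(alternative,
      greater = stats::pnorm((z - 0.5) / sigma, lower.tail = FALSE),
      less = stats::pnorm((z + 0.5) / sigma),
      two.sided = {
        zc <- (z - sign(z) * 0.5) / sigma
        min(1, 2 * min(stats::pnorm(zc), stats::pnorm(zc, lower.tail = FALSE)))
      })
  }
  new_test_result(U, p, alternative, "Mann-Whitney U test", exact = use_exact)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment: sorted p-values are scaled by
#' m/rank, a running minimum is taken from the largest down, and results
#' are returned in the input order, capped at 1.
#'
#' @param pvals Numeric vector of p-values in `[0, 1]` (NA allowed).
#' @return Adjusted p-values in the input order.
#' @export
bh_adjust <- function(pvals) {
  ok <- !is.na(pvals)
  p <- pvals[ok]
  if (any(p < 0 | p > 1)) stop("p-values must lie in [0, 1]")
  m <- length(p)
  if (m == 0) return(pvals)
  o <- order(p, decreasing = TRUE)
  scaled <- p[o] * m / (m:1)
  adj <- pmin(1, cummin(scaled))
  out <- pvals
  out[ok][o] <- adj
  out
}

#' Pearson correlation with t-based p-value
#'
#' @param x,y Numeric vectors of equal length >= 3, neither constant.
#' @return A `chap_test` result; statistic is r, with `df` attached.
#' @export
pearson_corr <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  ok <- !(is.na(x) | is.na(y))
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3) stop("need at least 3 paired observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) stop("constant vector")
  xc <- x - mean(x); yc <- y - mean(y)
  r <- sum(xc * yc) / sqrt(sum(xc^2) * sum(yc^2))
  r <- max(-1, min(1, r))
  df <- n - 2
  if (abs(r) >= 1) {
    p <- 0
  } else {
    tval <- r * sqrt(df / (1 - r^2))
    p <- 2 * stats::pt(-abs(tval), df)
  }
  new_test_result(r, p, "two.sided", "Pearson correlation",
                  extra = list(df = df, n = n))
}
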