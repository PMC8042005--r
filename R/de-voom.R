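# Mean-variance precision weights for log-CPM, estimated from a locally
# weighted regression of sqrt residual standard deviation on mean
# log-count, evaluated at each observation's fitted count.

# gene-wise least-squares fit of y (genes x samples) on design
# (samples x p); returns coefficients, fitted values and residual sd
ls_fit_genes <- function(y, design, weights = NULL) {
  n <- ncol(y); p <- qr(design)$rank
  if (p < ncol(design)) stop("design matrix is not full rank")
  if (n - ncol(design) < 1) stop("residual degrees of freedom must be >= 1")
  if (is.null(weights)) {
    qrd <- qr(design)
    coef <- t(qr.coef(qrd, t(y)))
    fitted <- coef %*% t(design)
    res <- y - fitted
    df <- n - ncol(design)
    sigma <- sqrt(rowSums(res^2) / df)
    list(coef = coef, fitted = fitted, sigma = sigma, df = rep(df, nrow(y)))
  } else {
    # per-gene weighted LS; weights is genes x samples
    out_coef <- matrix(NA_real_, nrow(y), ncol(design))
    fitted <- matrix(NA_real_, nrow(y), n)
    sigma <- numeric(nrow(y))
    df <- n - ncol(design)
    for (g in seq_len(nrow(y))) {
      w <- weights[g, ]
      sw <- sqrt(w)
      fit <- stats::lm.fit(design * sw, y[g, ] * sw)
      out_coef[g, ] <- fit$coefficients
      fitted[g, ] <- drop(design %*% fit$coefficients)
      sigma[g] <- sqrt(sum(fit$residuals^2) / df)
    }
    list(coef = out_coef, fitted = fitted, sigma = sigma,
         df = rep(df, nrow(y)))
  }
}

#' Log-CPM transform with mean-variance precision weights
#'
#' Computes `log2((count + 0.5) / (effective library size + 1) * 1e6)`,
#' fits each gene's log-CPM on the design by least squares, models the
#' mean-variance trend by a locally weighted regression of the square
#' root of the residual standard deviation on mean log-count, and assigns
#' each observation the inverse fourth power of the trend value at its
#' fitted count as a precision weight.
#'
#' @param counts Filtered `expression_matrix` of raw counts.
#' @param factors [tmm_factors()] result (or NULL for library size only).
#' @param design Sample x coefficient model matrix; defaults to an
#'   intercept-only design.
#' @param span Lowess span for the trend (default 0.5).
#' @param iter Lowess robustness iterations (default 2).
#' @return A `voom_result`: list with `log_cpm`, `weights` (both genes x
#'   samples), `trend` (x = mean log2 count, y = sqrt sd) and `lib_size`.
#' @export
voom_transform <- function(counts, factors = NULL, design = NULL,
                           span = 0.5, iter = 2) {
  stopifnot(inherits(counts, "expression_matrix"))
  x <- counts$values
  n <- ncol(x)
  lib <- colSums(x)
  eff_lib <- if (is.null(factors)) lib else lib * factors$factors[colnames(x)]
  if (is.null(design)) design <- matrix(1, n, 1)
  y <- t(log2(t(x + 0.5) / (eff_lib + 1) * 1e6))
  fit <- ls_fit_genes(y, design)
  # mean log2 count per gene, on the count scale of an average library
  sx <- rowMeans(y) + mean(log2(eff_lib + 1)) - log2(1e6)
  sy <- sqrt(fit$sigma)
  ok <- is.finite(sx) & is.finite(sy)
  lo <- stats::lowess(sx[ok], sy[ok], f = span, iter = iter)
  trend_fun <- stats::approxfun(lo$x, lo$y, rule = 2, ties = mean)
  fitted_cpm <- 2^fit$fitted
  fitted_count <- log2(t(t(fitted_cpm) * (eff_lib + 1)) / 1e6)
  w <- 1 / pmax(trend_fun(fitted_count), 1e-6)^4
  dim(w) <- dim(y)
  dimnames(w) <- dimnames(y)
  structure(list(log_cpm = y, weights = w,
                 trend = list(x = lo$x, y = lo$y),
                 lib_size = eff_lib, design = design),
            class = "voom_result")
}

#' @export
print.voom_result <- function(x, ...) {
  cat(sprintf("voom transform: %d genes x %d samples; weight range [%.3g, %.3g]\n",
              nrow(x$log_cpm), ncol(x$log_cpm), min(x$weights), max(x$weights)))
  invisible(x)
}
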