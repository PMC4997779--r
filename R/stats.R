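#' Statistical kernel
#'
#' Self-contained implementations of the tests used throughout the pipeline:
#' the empirical-Bayes moderated t-statistic (variance shrinkage with a
#' scaled inverse chi-square prior), the Wilcoxon rank-sum test (exact by
#' enumeration for small samples, normal approximation with tie correction
#' otherwise), the one-tailed Fisher exact test, Fisher's combined-probability
#' method, and Benjamini-Hochberg adjustment.
#'
#' @name stats-kernel
#' @keywords internal
NULL

## ---- trigamma inversion -----------------------------------------------

#' Invert the trigamma function
#'
#' Solves `trigamma(x) = y` for `x > 0` by a monotone Newton iteration on
#' `1/trigamma` with a bisection fallback. Tolerance 1e-8 (relative).
#'
#' @param y positive target value.
#' @return the solution `x`; `Inf` when `y <= 0`.
#' @keywords internal
trigamma_inverse <- function(y) {
  if (!is.finite(y) || y <= 0) return(Inf)
  if (y > 1e7) return(1 / sqrt(y))
  if (y < 1e-6) return(1 / y)
  x <- 0.5 + 1 / y
  ok <- FALSE
  for (i in seq_len(100)) {
    tri <- trigamma(x)
    dif <- tri * (1 - tri / y) / psigamma(x, deriv = 2L)
    x_new <- x + dif
    if (!is.finite(x_new) || x_new <= 0) break
    x <- x_new
    if (abs(dif / x) < 1e-8) { ok <- TRUE; break }
  }
  if (ok) return(x)
  # bisection fallback: trigamma is strictly decreasing on (0, Inf)
  lo <- 1e-8; hi <- 1e8
  for (i in seq_len(200)) {
    mid <- sqrt(lo * hi)
    if (trigamma(mid) > y) lo <- mid else hi <- mid
    if (hi / lo - 1 < 1e-8) break
  }
  sqrt(lo * hi)
}

## ---- empirical Bayes variance model -----------------------------------

#' Fit the empirical-Bayes variance prior
#'
#' Estimates the prior degrees of freedom `d0` and prior variance `s0_sq` of
#' the scaled inverse chi-square prior on gene-wise variances by the method
#' of moments on log sample variances: with `s^2 ~ s0_sq * d0/chisq(d0) *
#' chisq(d)/d`, `log(s^2)` has known digamma/trigamma moments, so the excess
#' dispersion of `log(s^2)` over `trigamma(d/2)` identifies `d0`.
#'
#' @param variances numeric vector of gene-wise sample variances; at least 10
#'   positive values are required. Non-positive variances are dropped with a
#'   message.
#' @param residual_df residual degrees of freedom (`n_a + n_b - 2` for a
#'   two-group comparison), a single value `>= 1`.
#' @return an object of class `eb_params`: a list with elements `d0`,
#'   `s0_sq`, `residual_df` and `n_genes`. `d0` is `Inf` when the log
#'   variances show no excess dispersion (e.g. all variances equal), in which
#'   case `s0_sq` is the mean variance.
#' @export
fit_empirical_bayes <- function(variances, residual_df) {
  stopifnot(is.numeric(variances), length(residual_df) == 1L,
            is.finite(residual_df), residual_df >= 1)
  keep <- is.finite(variances) & variances > 0
  if (any(!keep)) {
    message(sum(!keep), " non-positive or non-finite variances dropped from the prior fit")
  }
  v <- variances[keep]
  if (length(v) < 10L) {
    stop("fit_empirical_bayes() needs at least 10 genes with positive variance")
  }
  d <- residual_df
  e <- log(v) - digamma(d / 2) + log(d / 2)
  emean <- mean(e)
  evar <- sum((e - emean)^2) / (length(e) - 1) - trigamma(d / 2)
  if (is.finite(evar) && evar > 0) {
    d0 <- 2 * trigamma_inverse(evar)
    s0_sq <- exp(emean + digamma(d0 / 2) - log(d0 / 2))
  } else {
    d0 <- Inf
    s0_sq <- mean(v)
  }
  structure(list(d0 = d0, s0_sq = s0_sq, residual_df = d,
                 n_genes = length(v)),
            class = "eb_params")
}

#' @export
print.eb_params <- function(x, ...) {
  cat("Empirical-Bayes variance prior\n")
  cat("  prior df (d0):      ", format(x$d0), "\n")
  cat("  prior variance s0^2:", format(x$s0_sq), "\n")
  cat("  fitted on", x$n_genes, "genes with residual df", x$residual_df, "\n")
  invisible(x)
}

#' Moderated t-statistics for a two-group comparison
#'
#' Computes, per gene, the pooled sample variance `s^2`, the posterior
#' variance `s2_post = (d0 * s0_sq + d * s^2) / (d0 + d)` with
#' `d = n_a + n_b - 2`, the moderated t-statistic
#' `(mean_a - mean_b) / sqrt(s2_post * (1/n_a + 1/n_b))` and its two-sided
#' p-value on `d0 + d` degrees of freedom. With `d0 = 0` this is the
#' classical pooled two-sample t-test; with `d0 = Inf` every gene uses the
#' prior variance `s0_sq`.
#'
#' @param a,b numeric matrices (genes x samples) with identical row names, or
#'   numeric vectors for a single gene. Each group needs `>= 2` samples.
#' @param params an [fit_empirical_bayes()] result, or a list with elements
#'   `d0` and `s0_sq`.
#' @return a data frame with columns `gene`, `log2_fc` (`mean_a - mean_b`),
#'   `t_mod`, `p` and `df_total`.
#' @export
moderated_t <- function(a, b, params) {
  if (is.null(params) || is.null(params$d0) || is.null(params$s0_sq)) {
    stop("moderated_t() needs fitted empirical-Bayes parameters; ",
         "call fit_empirical_bayes() first (or supply d0 = 0 explicitly)")
  }
  if (is.vector(a)) a <- matrix(a, nrow = 1, dimnames = list("gene1", NULL))
  if (is.vector(b)) b <- matrix(b, nrow = 1, dimnames = list("gene1", NULL))
  stopifnot(nrow(a) == nrow(b))
  if (is.null(rownames(a))) rownames(a) <- paste0("gene", seq_len(nrow(a)))
  n_a <- ncol(a); n_b <- ncol(b)
  if (n_a < 2L || n_b < 2L) stop("each group needs at least 2 samples")
  d0 <- params$d0; s0 <- params$s0_sq
  mean_a <- rowMeans(a); mean_b <- rowMeans(b)
  ss <- rowSums((a - mean_a)^2) + rowSums((b - mean_b)^2)
  d <- n_a + n_b - 2
  s2 <- ss / d
  s2_post <- if (is.infinite(d0)) rep(s0, length(s2)) else (d0 * s0 + d * s2) / (d0 + d)
  se <- sqrt(s2_post * (1 / n_a + 1 / n_b))
  diff <- mean_a - mean_b
  t_mod <- ifelse(se > 0, diff / se, ifelse(diff == 0, 0, sign(diff) * Inf))
  df_total <- d0 + d
  p <- 2 * stats::pt(-abs(t_mod), df = df_total)
  data.frame(gene = rownames(a), log2_fc = diff, t_mod = t_mod, p = p,
             df_total = df_total, row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Differential statistics between two sample groups
#'
#' Convenience wrapper fitting the empirical-Bayes prior on the pooled
#' gene-wise variances and returning the full moderated-t table with
#' Benjamini-Hochberg adjusted p-values. The sign convention is
#' `positive = higher in group a`.
#'
#' @param mat numeric genes x samples matrix.
#' @param group_a,group_b character or integer indices of the two sample
#'   groups (columns of `mat`); must be disjoint, each of size `>= 2`.
#' @param params optional pre-fitted [fit_empirical_bayes()] result; fitted
#'   from the data when `NULL`.
#' @return a data frame with columns `gene`, `log2_fc`, `t_mod`, `p`,
#'   `p_adj`, `df_total`, with the fitted `eb_params` attached as attribute
#'   `"eb_params"`.
#' @export
diff_expression <- function(mat, group_a, group_b, params = NULL) {
  a <- mat[, group_a, drop = FALSE]
  b <- mat[, group_b, drop = FALSE]
  if (length(intersect(colnames(a), colnames(b))) > 0)
    stop("group_a and group_b must be disjoint")
  if (is.null(params)) {
    n_a <- ncol(a); n_b <- ncol(b)
    ss <- rowSums((a - rowMeans(a))^2) + rowSums((b - rowMeans(b))^2)
    d <- n_a + n_b - 2
    params <- fit_empirical_bayes(ss / d, residual_df = d)
  }
  out <- moderated_t(a, b, params)
  out$p_adj <- bh_adjust(out$p)
  attr(out, "eb_params") <- params
  out
}

## ---- rank-sum test ----------------------------------------------------

#' Wilcoxon rank-sum test
#'
#' Exact p-values by full enumeration of rank assignments (mid-ranks for
#' ties) when `length(x) + length(y) <= max_exact`; otherwise the normal
#' approximation with tie-corrected variance and continuity correction 0.5.
#' `alternative = "less"` tests whether `x` tends to be smaller than `y`.
#'
#' @param x,y non-empty numeric vectors.
#' @param alternative one of `"less"`, `"greater"`, `"two_sided"`.
#' @param max_exact total-sample-size bound for the enumeration branch.
#' @return the p-value.
#' @export
rank_sum_test <- function(x, y, alternative = c("less", "greater", "two_sided"),
                          max_exact = 12L) {
  alternative <- match.arg(alternative)
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) == 0L || length(y) == 0L) stop("rank_sum_test() needs non-empty inputs")
  if (anyNA(x) || anyNA(y)) stop("rank_sum_test() does not accept missing values")
  n_x <- length(x); n_y <- length(y); n <- n_x + n_y
  r <- rank(c(x, y), ties.method = "average")
  w <- sum(r[seq_len(n_x)])
  eps <- 1e-8
  if (n <= max_exact) {
    sets <- utils::combn(n, n_x)
    ws <- colSums(matrix(r[sets], nrow = n_x))
    p_less <- mean(ws <= w + eps)
    p_greater <- mean(ws >= w - eps)
  } else {
    mu <- n_x * (n + 1) / 2
    ties <- table(r)
    sigma2 <- n_x * n_y / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
    sigma <- sqrt(sigma2)
    p_less <- stats::pnorm((w - mu + 0.5) / sigma)
    p_greater <- stats::pnorm((w - mu - 0.5) / sigma, lower.tail = FALSE)
  }
  switch(alternative,
         less = p_less,
         greater = p_greater,
         two_sided = min(1, 2 * min(p_less, p_greater)))
}

## ---- Fisher exact test (one-tailed) -----------------------------------

#' One-tailed Fisher exact test for enrichment
#'
#' For the 2x2 table `(a, b; c, d)` with fixed margins, computes the
#' hypergeometric tail probability of observing `a` or more counts in the
#' top-left cell, i.e. the enrichment direction in which the table
#' `(2, 0; 0, 2)` gives `p = 1/6`. Tables as or more extreme are summed
#' explicitly.
#'
#' @param a,b,c,d non-negative integer cell counts.
#' @return the one-tailed p-value (`1` for the all-zero table).
#' @export
fisher_exact_one_tailed <- function(a, b, c, d) {
  cells <- c(a, b, c, d)
  if (any(!is.finite(cells)) || any(cells < 0) || any(cells != round(cells)))
    stop("cell counts must be non-negative integers")
  m <- a + b          # white balls: row 1
  n2 <- c + d         # black balls: row 2
  k <- a + c          # draws: column 1
  hi <- min(k, m)
  xs <- seq(from = a, to = hi)
  sum(stats::dhyper(xs, m = m, n = n2, k = k))
}

## ---- Fisher's combined-probability method -----------------------------

#' Combine p-values with Fisher's method
#'
#' `X = -2 * sum(log(p))` is referred to the upper tail of a chi-square
#' distribution with `2k` degrees of freedom. Exact zeros are floored at the
#' smallest positive representable double with a warning rather than
#' propagated as `-Inf`.
#'
#' @param p numeric vector of p-values in `(0, 1]`, length `>= 1`.
#' @return the combined p-value.
#' @export
combine_fisher <- function(p) {
  if (length(p) < 1L) stop("combine_fisher() needs at least one p-value")
  if (anyNA(p)) stop("combine_fisher() does not accept missing values")
  if (any(p == 0)) {
    warning("p-values of exactly 0 floored at .Machine$double.xmin")
    p[p == 0] <- .Machine$double.xmin
  }
  if (any(p < 0 | p > 1)) stop("p-values must lie in (0, 1]")
  X <- -2 * sum(log(p))
  stats::pchisq(X, df = 2 * length(p), lower.tail = FALSE)
}

## ---- Benjamini-Hochberg -----------------------------------------------

#' Benjamini-Hochberg step-up adjustment
#'
#' @param p numeric vector of p-values in `[0, 1]`.
#' @return adjusted p-values, capped at 1, in the input order.
#' @export
bh_adjust <- function(p) {
  if (length(p) == 0L) return(numeric(0))
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]")
  n <- length(p)
  o <- order(p, decreasing = TRUE)
  ro <- order(o)
  pmin(1, cummin(n / (n:1) * p[o]))[ro]
}
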