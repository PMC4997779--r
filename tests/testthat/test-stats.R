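# Empirical-Bayes variance model ------------------------------------------

test_that("empirical-Bayes fit recovers planted prior parameters", {
  set.seed(101)
  d0 <- 4; s0 <- 1; d <- 6; n <- 5000
  sigma2 <- s0 * d0 / rchisq(n, d0)
  s2 <- sigma2 * rchisq(n, d) / d
  fit <- fit_empirical_bayes(s2, d)
  expect_lt(abs(fit$d0 - d0) / d0, 0.2)
  expect_lt(abs(fit$s0_sq - s0) / s0, 0.1)
})

test_that("empirical-Bayes fit matches limma's moment estimator", {
  set.seed(102)
  s2 <- 0.8 * 5 / rchisq(300, 5) * rchisq(300, 8) / 8
  fit <- fit_empirical_bayes(s2, 8)
  ref <- limma::fitFDist(s2, df1 = 8)
  expect_equal(fit$d0, ref$df2, tolerance = 1e-6)
  expect_equal(fit$s0_sq, ref$scale, tolerance = 1e-6)
})

test_that("degenerate and equivariant cases of the prior fit", {
  expect_equal(fit_empirical_bayes(rep(2.5, 50), 4)$d0, Inf)
  expect_equal(fit_empirical_bayes(rep(2.5, 50), 4)$s0_sq, 2.5)
  set.seed(103)
  s2 <- rchisq(500, 5) / 5
  f1 <- fit_empirical_bayes(s2, 5)
  f2 <- fit_empirical_bayes(2 * s2, 5)
  expect_equal(f2$d0, f1$d0, tolerance = 1e-8)
  expect_equal(f2$s0_sq, 2 * f1$s0_sq, tolerance = 1e-8)
  expect_error(fit_empirical_bayes(rep(1, 5), 4), "at least 10")
})

# Moderated t --------------------------------------------------------------

test_that("moderated t with d0 = 0 equals the classical pooled t", {
  p0 <- list(d0 = 0, s0_sq = 1)
  row <- moderated_t(c(1, 2, 3), c(4, 5, 6), p0)
  expect_equal(row$t_mod, -3 / sqrt(1 * (2 / 3)), tolerance = 1e-12)
  expect_equal(row$df_total, 4)
  # against t.test on random data
  set.seed(104)
  a <- rnorm(7); b <- rnorm(5, 1)
  row <- moderated_t(a, b, p0)
  ref <- t.test(a, b, var.equal = TRUE)
  expect_equal(row$t_mod, unname(ref$statistic), tolerance = 1e-12)
  expect_equal(row$p, ref$p.value, tolerance = 1e-12)
})

test_that("moderated t limit cases and shrinkage endpoint", {
  expect_equal(moderated_t(c(1, 2, 3), c(1, 3, 2), list(d0 = 0, s0_sq = 1))$t_mod, 0)
  expect_equal(moderated_t(c(1, 2, 3), c(1, 3, 2), list(d0 = 0, s0_sq = 1))$p, 1)
  # d0 = Inf: posterior variance is exactly s0_sq
  a <- c(5, 6, 7); b <- c(1, 2, 3)
  row <- moderated_t(a, b, list(d0 = Inf, s0_sq = 4))
  expect_equal(row$t_mod, 4 / sqrt(4 * (2 / 3)), tolerance = 1e-12)
  expect_error(moderated_t(a, b, NULL), "fit")
  expect_error(moderated_t(matrix(1:2, ncol = 1), matrix(3:4, ncol = 1),
                           list(d0 = 0, s0_sq = 1)),
               "at least 2")
})

test_that("moderated t matches limma end to end", {
  set.seed(105)
  m <- matrix(rnorm(200 * 12, sd = rep(sqrt(rchisq(200, 4) / 4), 12)), 200)
  rownames(m) <- paste0("g", 1:200); colnames(m) <- paste0("s", 1:12)
  grp <- rep(c("A", "B"), each = 6)
  m[1:20, grp == "A"] <- m[1:20, grp == "A"] + 2
  ours <- diff_expression(m, colnames(m)[grp == "A"], colnames(m)[grp == "B"])
  design <- stats::model.matrix(~ 0 + grp)
  colnames(design) <- c("A", "B")
  fit <- limma::eBayes(limma::contrasts.fit(
    limma::lmFit(m, design),
    limma::makeContrasts(A - B, levels = design)))
  expect_equal(attr(ours, "eb_params")$d0, fit$df.prior, tolerance = 1e-8)
  expect_equal(ours$t_mod, unname(fit$t[, 1]), tolerance = 1e-8)
  expect_equal(ours$p, unname(fit$p.value[, 1]), tolerance = 1e-8)
})

test_that("moderated-t p-values are uniform under the null", {
  set.seed(106)
  m <- matrix(rnorm(2000 * 20), 2000,
              dimnames = list(paste0("g", 1:2000), paste0("s", 1:20)))
  res <- diff_expression(m, paste0("s", 1:10), paste0("s", 11:20))
  ks <- max(abs(sort(res$p) - (seq_len(2000) - 0.5) / 2000))
  expect_lt(ks, 0.05)
})

# Rank-sum test ------------------------------------------------------------

test_that("exact rank-sum branch equals the enumeration oracle for n <= 8", {
  expect_equal(rank_sum_test(c(1, 2), c(3, 4), "less"), 1 / 6)
  expect_equal(rank_sum_test(c(1, 2), c(1, 2), "two_sided"), 1)
  set.seed(107)
  for (rep in 1:25) {
    n <- sample(3:8, 1)
    n_x <- sample(seq_len(n - 1), 1)
    vals <- sample(1:4, n, replace = TRUE)  # heavy ties on purpose
    x <- vals[seq_len(n_x)]; y <- vals[-seq_len(n_x)]
    for (alt in c("less", "greater", "two_sided")) {
      expect_equal(rank_sum_test(x, y, alt), oracle_rank_sum(x, y, alt),
                   info = paste("rep", rep, alt))
    }
  }
})

test_that("rank-sum approximation matches wilcox.test and the exact branch", {
  set.seed(108)
  x <- rnorm(10); y <- rnorm(10, 0.5)
  approx_p <- rank_sum_test(x, y, "less", max_exact = 0L)
  ref <- stats::wilcox.test(x, y, alternative = "less", exact = FALSE,
                            correct = TRUE)$p.value
  expect_equal(approx_p, ref, tolerance = 1e-10)
  # branches agree on moderate samples
  exact_p <- rank_sum_test(x, y, "less", max_exact = 20L)
  expect_lt(abs(approx_p - exact_p), 0.02)
  # swapping the sets maps 'less' to 'greater' exactly
  expect_equal(rank_sum_test(x, y, "less", max_exact = 0L),
               rank_sum_test(y, x, "greater", max_exact = 0L))
  expect_error(rank_sum_test(numeric(0), y), "non-empty")
})

# Fisher exact (one-tailed) ------------------------------------------------

test_that("one-tailed Fisher exact matches hypergeometric tails and fisher.test", {
  expect_equal(fisher_exact_one_tailed(2, 0, 0, 2), 1 / 6)
  expect_equal(fisher_exact_one_tailed(0, 2, 2, 0), 1)
  expect_equal(fisher_exact_one_tailed(0, 0, 0, 0), 1)
  # doubling all cells strengthens the enrichment
  expect_lt(fisher_exact_one_tailed(4, 0, 0, 4), fisher_exact_one_tailed(2, 0, 0, 2))
  set.seed(109)
  for (rep in 1:20) {
    cells <- rpois(4, 5)
    ref <- stats::fisher.test(matrix(cells, 2, byrow = TRUE),
                              alternative = "greater")$p.value
    expect_equal(fisher_exact_one_tailed(cells[1], cells[2], cells[3], cells[4]),
                 ref, tolerance = 1e-10)
  }
  expect_error(fisher_exact_one_tailed(1.5, 0, 0, 1), "integer")
})

# Fisher's method ----------------------------------------------------------

test_that("Fisher combination matches the closed form and its properties", {
  expect_equal(combine_fisher(c(0.5, 0.5)),
               exp(-2.772589 / 2) * (1 + 2.772589 / 2), tolerance = 1e-6)
  expect_equal(combine_fisher(c(1, 1, 1)), 1)
  expect_equal(combine_fisher(0.123), 0.123, tolerance = 1e-12)
  # exchangeable and monotone
  p <- c(0.2, 0.8, 0.5)
  expect_equal(combine_fisher(p), combine_fisher(rev(p)))
  expect_lt(combine_fisher(c(0.1, 0.8, 0.5)), combine_fisher(p))
  expect_warning(res <- combine_fisher(c(0, 0.5)), "floored")
  expect_gt(res, 0)
  expect_error(combine_fisher(c(0.5, 1.2)), "0, 1")
})

# BH adjustment ------------------------------------------------------------

test_that("BH step-up matches the hand computation and p.adjust", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_adjust(0.2), 0.2)
  expect_equal(bh_adjust(rep(1, 4)), rep(1, 4))
  set.seed(110)
  p <- runif(200)^2
  expect_equal(bh_adjust(p), stats::p.adjust(p, method = "BH"))
  expect_true(all(bh_adjust(p) >= p))
})
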