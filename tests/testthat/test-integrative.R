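test_that("Z-scores use the normal-sample mean and n-1 standard deviation", {
  normal <- matrix(c(8, 10, 12, 5, 5, 5), nrow = 2, byrow = TRUE,
                   dimnames = list(c("gA", "gFlat"), paste0("n", 1:3)))
  tumour <- matrix(c(5, 10, 5, 5), nrow = 2, byrow = TRUE,
                   dimnames = list(c("gA", "gFlat"), paste0("t", 1:2)))
  expect_message(zs <- compute_zscores(tumour, normal), "zero normal variance")
  expect_equal(zs$mu[["gA"]], 10)
  expect_equal(zs$sigma[["gA"]], 2)
  expect_equal(zs$z["gA", "t1"], -2.5)
  expect_equal(zs$z["gA", "t2"], 0)
  expect_false("gFlat" %in% rownames(zs$z))
  expect_error(compute_zscores(tumour, normal[, 1:2]), "at least 3")
})

test_that("call thresholds are strict at the boundary", {
  expect_false(call_underexpression(matrix(-2))[1])
  expect_true(call_underexpression(matrix(-2.01))[1])
  expect_false(call_underexpression(matrix(0))[1])
  expect_false(call_cnv_loss(-0.35))
  expect_true(call_cnv_loss(-0.36))
  expect_false(call_cnv_loss(0))
  tb <- matrix(c(0.75, 0.70, 0.55, 0.50), 1,
               dimnames = list("g", paste0("t", 1:4)))
  nb <- matrix(c(0.40, 0.40), 1, dimnames = list("g", c("n1", "n2")))
  hy <- call_hypermethylation(tb, nb)
  expect_equal(unname(hy$delta_beta[1, ]), c(0.35, 0.30, 0.15, 0.10))
  expect_equal(unname(hy$call[1, ]), c(TRUE, FALSE, FALSE, FALSE))
  expect_equal(unname(hy$call_relaxed[1, ]), c(TRUE, TRUE, TRUE, FALSE))
})

test_that("segments map to genes by maximal overlap with deterministic ties", {
  coords <- data.frame(gene_id = c("gIn", "gSplit", "gOff"),
                       chrom = c("chr1", "chr1", "chr2"),
                       start = c(100, 300, 100), end = c(200, 400, 200))
  segs <- data.frame(sample_id = "S1", chrom = "chr1",
                     start = c(0, 380, 0), end = c(380, 1000, 1000),
                     segval = c(-0.5, 0.2, 0.9))
  # gSplit overlaps the first segment by 80 and the second by 20
  segs <- segs[1:2, ]
  m <- map_segments_to_genes(segs, coords)
  expect_equal(m["gIn", "S1"], -0.5)
  expect_equal(m["gSplit", "S1"], -0.5)
  expect_true(is.na(m["gOff", "S1"]))
  # exact tie: two segments overlap the gene by 50 each -> smaller start wins
  tie <- data.frame(sample_id = "S1", chrom = "chr1",
                    start = c(100, 150), end = c(150, 250),
                    segval = c(1, 2))
  coords2 <- data.frame(gene_id = "g", chrom = "chr1", start = 100, end = 200)
  expect_equal(map_segments_to_genes(tie, coords2)["g", "S1"], 1)
  # brute-force overlap oracle on a random instance
  set.seed(501)
  coords3 <- data.frame(gene_id = paste0("g", 1:20), chrom = "chr1",
                        start = seq(0, 1900, by = 100), end = seq(60, 1960, by = 100))
  starts <- sort(sample(0:1900, 8))
  segs3 <- data.frame(sample_id = "S1", chrom = "chr1", start = starts,
                      end = starts + sample(50:400, 8, replace = TRUE),
                      segval = rnorm(8))
  got <- map_segments_to_genes(segs3, coords3)
  for (i in 1:20) {
    ov <- pmin(segs3$end, coords3$end[i]) - pmax(segs3$start, coords3$start[i])
    if (all(ov <= 0)) {
      expect_true(is.na(got[i, 1]))
    } else {
      best <- which(ov == max(ov))
      best <- best[which.min(segs3$start[best])]
      expect_equal(got[i, 1], segs3$segval[best])
    }
  }
})

test_that("inactivating-mutation calls collapse duplicates and ignore Other", {
  rec <- data.frame(sample_id = c("S1", "S1", "S2", "S2"),
                    gene_id = c("gA", "gA", "gA", "gB"),
                    variant_class = c("Missense", "Missense", "Other", "Deletion"))
  m <- call_inactivating_mutation(rec, genes = c("gA", "gB", "gC"),
                                  samples = c("S1", "S2"))
  expect_true(m["gA", "S1"])    # two missense records -> one call
  expect_false(m["gA", "S2"])   # Other class does not count
  expect_true(m["gB", "S2"])
  expect_false(any(m["gC", ]))  # no records -> false everywhere
})

test_that("mechanism frequencies and classes follow the cutoffs", {
  calls <- data.frame(
    gene = rep("tf1", 6), sample = paste0("t", 1:6),
    underexpressed = c(TRUE, TRUE, TRUE, TRUE, FALSE, FALSE),
    segval = 0, cnv_loss = c(TRUE, FALSE, FALSE, FALSE, TRUE, TRUE),
    delta_beta = 0, hypermeth = c(TRUE, TRUE, FALSE, FALSE, FALSE, FALSE),
    hypermeth_relaxed = TRUE, mutated = FALSE)
  fq <- mechanism_frequencies(calls)
  expect_equal(fq$n_under, 4L)          # only underexpressed tumours count
  expect_equal(fq$f_loss, 0.25)
  expect_equal(fq$f_hyper, 0.5)
  expect_equal(fq$mechanism_class, "Both")
  # no alterations -> Neither
  calls2 <- within(calls, { cnv_loss <- FALSE; hypermeth <- FALSE })
  expect_equal(mechanism_frequencies(calls2)$mechanism_class, "Neither")
  expect_equal(mechanism_frequencies(calls2)$f_loss, 0)
  # dominant classes
  calls3 <- within(calls, cnv_loss <- FALSE)
  expect_equal(mechanism_frequencies(calls3)$mechanism_class, "DNAmDominant")
  calls4 <- within(calls, hypermeth <- FALSE)
  expect_equal(mechanism_frequencies(calls4)$mechanism_class, "CNVDominant")
  # genes never underexpressed are excluded
  calls5 <- calls; calls5$underexpressed <- FALSE
  expect_message(fq5 <- mechanism_frequencies(calls5), "never underexpressed")
  expect_equal(nrow(fq5), 0L)
})

test_that("channel comparison of silenced TFs is one-tailed per channel", {
  set.seed(502)
  genes <- c(paste0("tf", 1:20), paste0("u", 1:200))
  gs <- data.frame(gene = genes,
                   dnam_t = c(rnorm(20, 2.5), rnorm(200)),
                   cnv_mean = c(rnorm(20, 0, 0.05), rnorm(200, -0.2, 0.1)),
                   mut_freq = rep(0.01, 220))
  ps <- compare_silenced_vs_underexpressed(gs, paste0("tf", 1:20), genes)
  expect_lt(ps[["p_dnam"]], 0.01)       # TFs shifted up in DNAm statistics
  expect_gt(ps[["p_cnv"]], 0.5)         # background has more loss than TFs
  # identical distributions give unremarkable p-values (uniformity spot check)
  nulls <- replicate(20, {
    gs2 <- data.frame(gene = genes, dnam_t = rnorm(220),
                      cnv_mean = rnorm(220), mut_freq = rnorm(220))
    compare_silenced_vs_underexpressed(gs2, paste0("tf", 1:20), genes)[["p_dnam"]]
  })
  expect_gt(mean(nulls), 0.25)
  expect_lt(mean(nulls), 0.75)
  # missing-channel genes are dropped channel-wise, not row-wise
  gs$dnam_t[1:20] <- NA
  ps3 <- compare_silenced_vs_underexpressed(gs, paste0("tf", 1:20), genes)
  expect_true(is.na(ps3[["p_dnam"]]))
  expect_false(is.na(ps3[["p_cnv"]]))
  expect_error(compare_silenced_vs_underexpressed(gs, "absent", genes), "subset")
})

test_that("meta-analysis combines channels with Fisher's method", {
  tab <- data.frame(p_dnam = c(0.5, 0.5), p_cnv = c(1, 1), p_mut = c(0.2, 0.8))
  meta <- meta_combine(tab)
  expect_equal(meta[["p_dnam"]], combine_fisher(c(0.5, 0.5)))
  expect_equal(meta[["p_cnv"]], 1)
  # lowering any input lowers the combination
  tab2 <- tab; tab2$p_mut[1] <- 0.05
  expect_lt(meta_combine(tab2)[["p_mut"]], meta[["p_mut"]])
  expect_error(meta_combine(tab[1, ]), "at least 2")
})

test_that("null-draw expected counts cover a null TF set and flag enrichment", {
  set.seed(503)
  counts <- stats::setNames(rbinom(400, 30, 0.05), paste0("g", 1:400))
  null_set <- sample(names(counts), 40)
  res <- expected_counts_null(counts, null_set, n_draws = 500, seed = 7)
  expect_true(res$covered)
  # planted enrichment: inflate the chosen genes' counts
  counts2 <- counts
  counts2[null_set] <- counts2[null_set] + 10
  res2 <- expected_counts_null(counts2, null_set, n_draws = 500, seed = 7)
  expect_gt(res2$observed, res2$upper)
  # degenerate single draw collapses the interval and is flagged
  res3 <- expected_counts_null(counts, null_set, n_draws = 1, seed = 7)
  expect_true(res3$degenerate)
  expect_equal(res3$lower, res3$upper)
})

test_that("tertile exclusivity detects planted anti-correlated mechanisms", {
  set.seed(504)
  freqs <- data.frame(gene = paste0("tf", 1:30),
                      f_loss = c(runif(15, 0.3, 0.7), rep(0, 15)),
                      f_hyper = c(rep(0, 15), runif(15, 0.3, 0.7)))
  ps <- tertile_exclusivity(freqs)
  expect_lt(ps[["p_hyper_low_vs_top_cnv"]], 0.05)
  expect_lt(ps[["p_cnv_low_vs_top_hyper"]], 0.05)
  # equal frequencies: no evidence in either direction
  flat <- data.frame(gene = paste0("tf", 1:9), f_loss = 0.3, f_hyper = 0.3)
  suppressWarnings(ps_flat <- tertile_exclusivity(flat))
  expect_true(all(is.na(ps_flat) | ps_flat >= 0.5))
  expect_error(tertile_exclusivity(freqs[1:5, ]), "at least 6")
})

test_that("per-TF exclusivity flags planted mutually exclusive alterations", {
  set.seed(505)
  n <- 40
  mk_calls <- function(delta_noloss) {
    loss <- c(rep(TRUE, 15), rep(FALSE, 25))
    data.frame(gene = "tf1", sample = paste0("t", 1:n), underexpressed = TRUE,
               segval = ifelse(loss, -0.5, 0), cnv_loss = loss,
               delta_beta = ifelse(loss, rnorm(n, 0, 0.02), rnorm(n, delta_noloss, 0.05)),
               hypermeth = FALSE, hypermeth_relaxed = FALSE)
  }
  calls <- mk_calls(0.4)
  calls$hypermeth_relaxed <- calls$delta_beta > 0.1
  res <- per_tf_exclusivity(calls)
  expect_equal(res$gene, "tf1")
  expect_lt(res$p, 0.05)
  # below the frequency gate in the methylation channel -> excluded
  calls2 <- mk_calls(0)
  calls2$hypermeth_relaxed <- FALSE
  expect_equal(nrow(per_tf_exclusivity(calls2)), 0L)
  # identical delta-beta distributions: no signal
  calls3 <- mk_calls(0)
  calls3$delta_beta <- rnorm(n, 0.2, 0.05)
  calls3$hypermeth_relaxed <- TRUE
  expect_gt(per_tf_exclusivity(calls3)$p, 0.05)
})

test_that("cross-cancer concordance is 1 for identical and ~0 for independent frequencies", {
  fq <- function(hyper, loss) data.frame(gene = paste0("tf", seq_along(hyper)),
                                         f_hyper = hyper, f_loss = loss)
  set.seed(506)
  h <- runif(30); l <- runif(30)
  same <- cross_cancer_concordance(list(a = fq(h, l), b = fq(h, l)))
  expect_equal(same$pairs$r2_dnam, 1)
  expect_equal(same$pairs$r2_cnv, 1)
  indep <- cross_cancer_concordance(list(a = fq(runif(30), runif(30)),
                                         b = fq(runif(30), runif(30))))
  expect_lt(indep$pairs$r2_dnam, 0.2)
  # zero-variance channel is skipped (NA), the other channel survives
  degen <- cross_cancer_concordance(list(a = fq(h, rep(0.1, 30)),
                                         b = fq(h, rep(0.2, 30))))
  expect_true(is.na(degen$pairs$r2_cnv))
  expect_equal(degen$pairs$r2_dnam, 1)
})
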