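#' Per-tumour Z-scores relative to the normal reference
#'
#' For each gene, `Z_ts = (X_ts - mu_t) / sigma_t` where `mu_t` and `sigma_t`
#' are the mean and (n-1 denominator) standard deviation of expression over
#' the normal tissue samples. Genes with zero normal standard deviation are
#' dropped with a message.
#'
#' @param tumour_expr,normal_expr numeric genes x samples matrices sharing
#'   row names; `>= 3` normal samples required.
#' @return list with `z` (genes x tumours), `mu`, `sigma`.
#' @export
compute_zscores <- function(tumour_expr, normal_expr) {
  stopifnot(is.matrix(tumour_expr), is.matrix(normal_expr))
  if (ncol(normal_expr) < 3L) stop("compute_zscores() needs at least 3 normal samples")
  genes <- intersect(rownames(tumour_expr), rownames(normal_expr))
  tumour_expr <- tumour_expr[genes, , drop = FALSE]
  normal_expr <- normal_expr[genes, , drop = FALSE]
  mu <- rowMeans(normal_expr)
  sigma <- sqrt(rowSums((normal_expr - mu)^2) / (ncol(normal_expr) - 1))
  keep <- sigma > 0 & is.finite(sigma)
  if (any(!keep)) message(sum(!keep), " genes with zero normal variance dropped from Z-scores")
  z <- (tumour_expr[keep, , drop = FALSE] - mu[keep]) / sigma[keep]
  list(z = z, mu = mu[keep], sigma = sigma[keep])
}

#' Call per-tumour underexpression from Z-scores
#'
#' Strict inequality: a Z-score exactly at the threshold is not a call.
#'
#' @param z numeric Z-score matrix (genes x tumours).
#' @param threshold default -2.
#' @return logical matrix of the same shape.
#' @export
call_underexpression <- function(z, threshold = -2) {
  z < threshold
}

#' Map CNV segments to genes by maximal overlap
#'
#' For every gene and sample, assigns the segment value of the segment with
#' the largest overlap with the gene locus; ties go to the segment with the
#' smaller start; genes with no overlapping segment are missing.
#'
#' @param segments data frame as returned by [read_seg()] (0-based half-open).
#' @param coords gene coordinates as returned by [read_bed()].
#' @return numeric genes x samples matrix of segment values (NA = no
#'   overlapping segment).
#' @export
map_segments_to_genes <- function(segments, coords) {
  samples <- sort(unique(segments$sample_id))
  out <- matrix(NA_real_, nrow = nrow(coords), ncol = length(samples),
                dimnames = list(coords$gene_id, samples))
  if (nrow(segments) == 0L) return(out)
  gene_gr <- GenomicRanges::GRanges(coords$chrom,
                                    IRanges::IRanges(coords$start + 1, coords$end))
  seg_gr <- GenomicRanges::GRanges(segments$chrom,
                                   IRanges::IRanges(segments$start + 1, segments$end))
  hits <- GenomicRanges::findOverlaps(gene_gr, seg_gr)
  if (length(hits) == 0L) return(out)
  q <- S4Vectors::queryHits(hits); s <- S4Vectors::subjectHits(hits)
  ov <- GenomicRanges::width(GenomicRanges::pintersect(gene_gr[q], seg_gr[s]))
  df <- data.frame(gene = q, sample = segments$sample_id[s], width = ov,
                   seg_start = segments$start[s], segval = segments$segval[s])
  df <- df[order(df$gene, df$sample, -df$width, df$seg_start), , drop = FALSE]
  df <- df[!duplicated(df[, c("gene", "sample")]), , drop = FALSE]
  out[cbind(df$gene, match(df$sample, samples))] <- df$segval
  out
}

#' Call copy-number loss from segment values
#'
#' Strict inequality (`segval < threshold`); missing segment values yield no
#' call (NA).
#'
#' @param segval numeric vector or matrix of segment values.
#' @param threshold default -0.35, the conservative one-copy-loss bound.
#' @return logical object of the same shape (NA where `segval` is missing).
#' @export
call_cnv_loss <- function(segval, threshold = -0.35) {
  segval < threshold
}

#' Call promoter hypermethylation per tumour
#'
#' `delta_beta = beta_tumour - mean(normal betas)` per gene; the strict call
#' requires `delta_beta > threshold` (default 0.3), the relaxed call uses
#' `relaxed_threshold` (default 0.1). Missing promoter values yield no call.
#'
#' @param tumour_betas numeric genes x tumours matrix of promoter betas.
#' @param normal_betas numeric genes x normals matrix of promoter betas.
#' @param threshold strict delta-beta threshold (default 0.3).
#' @param relaxed_threshold relaxed threshold (default 0.1).
#' @return list with `call`, `call_relaxed` (logical matrices) and
#'   `delta_beta`.
#' @export
call_hypermethylation <- function(tumour_betas, normal_betas,
                                  threshold = 0.3, relaxed_threshold = 0.1) {
  genes <- intersect(rownames(tumour_betas), rownames(normal_betas))
  tumour_betas <- tumour_betas[genes, , drop = FALSE]
  normal_betas <- normal_betas[genes, , drop = FALSE]
  normal_mean <- rowMeans(normal_betas, na.rm = TRUE)
  delta <- tumour_betas - normal_mean
  list(call = delta > threshold,
       call_relaxed = delta > relaxed_threshold,
       delta_beta = delta)
}

#' Binary inactivating-mutation matrix
#'
#' A gene/sample pair is called mutated when it carries at least one record
#' with variant class nonsense, missense or deletion; multiple inactivating
#' mutations in the same gene and sample count as one.
#'
#' @param records mutation data frame from [read_mutations()].
#' @param genes,samples row/column universes of the output matrix.
#' @return logical genes x samples matrix.
#' @export
call_inactivating_mutation <- function(records, genes, samples) {
  out <- matrix(FALSE, nrow = length(genes), ncol = length(samples),
                dimnames = list(genes, samples))
  hit <- records$variant_class %in% c("Nonsense", "Missense", "Deletion") &
    records$gene_id %in% genes & records$sample_id %in% samples
  if (any(hit)) {
    out[cbind(match(records$gene_id[hit], genes),
              match(records$sample_id[hit], samples))] <- TRUE
  }
  out
}

#' Assemble the per-(TF, tumour) alteration call table
#'
#' Joins the underexpression, CNV, methylation and mutation channels on a
#' common set of genes and tumour samples. Calls are defined only where the
#' underlying datum is non-missing.
#'
#' @param z_calls logical genes x tumours underexpression matrix.
#' @param segval numeric genes x tumours segment-value matrix (NA allowed).
#' @param hyper result of [call_hypermethylation()].
#' @param mutated logical genes x tumours mutation matrix.
#' @param genes optional restriction of the gene universe (e.g. the silenced
#'   TFs).
#' @param cnv_threshold,hyper_threshold,relaxed_threshold call thresholds.
#' @return data frame of class `alteration_calls` with one row per (gene,
#'   tumour): `gene`, `sample`, `underexpressed`, `segval`, `cnv_loss`,
#'   `delta_beta`, `hypermeth`, `hypermeth_relaxed`, `mutated`.
#' @export
build_alteration_calls <- function(z_calls, segval, hyper, mutated, genes = NULL,
                                   cnv_threshold = -0.35, hyper_threshold = 0.3,
                                   relaxed_threshold = 0.1) {
  if (is.null(genes)) genes <- rownames(z_calls)
  genes <- Reduce(intersect, list(genes, rownames(z_calls), rownames(segval),
                                  rownames(hyper$delta_beta), rownames(mutated)))
  samples <- Reduce(intersect, list(colnames(z_calls), colnames(segval),
                                    colnames(hyper$delta_beta), colnames(mutated)))
  grid <- expand.grid(gene = genes, sample = samples, stringsAsFactors = FALSE,
                      KEEP.OUT.ATTRS = FALSE)
  idx <- cbind(match(grid$gene, genes), match(grid$sample, samples))
  sv <- segval[genes, samples, drop = FALSE][idx]
  db <- hyper$delta_beta[genes, samples, drop = FALSE][idx]
  out <- data.frame(
    gene = grid$gene, sample = grid$sample,
    underexpressed = z_calls[genes, samples, drop = FALSE][idx],
    segval = sv,
    cnv_loss = call_cnv_loss(sv, cnv_threshold),
    delta_beta = db,
    hypermeth = db > hyper_threshold,
    hypermeth_relaxed = db > relaxed_threshold,
    mutated = mutated[genes, samples, drop = FALSE][idx],
    stringsAsFactors = FALSE)
  class(out) <- c("alteration_calls", class(out))
  out
}

#' Per-TF mechanism frequencies among underexpressed tumours
#'
#' For each gene, computed over the tumours where the gene is called
#' underexpressed and the respective channel is non-missing: the fractions of
#' tumours with CNV loss, promoter hypermethylation and inactivating
#' mutation. Genes never underexpressed are excluded with a message. The
#' mechanism class uses configurable cutoffs (defaults: DNAm-dominant when
#' `f_hyper >= major_cut` and `f_loss < minor_cut`; CNV-dominant symmetric;
#' Both when both `>= major_cut`; otherwise Neither).
#'
#' @param calls an [build_alteration_calls()] table.
#' @param major_cut,minor_cut mechanism-class cutoffs (defaults 0.2 / 0.1).
#' @return data frame with `gene`, `n_under`, `f_loss`, `f_hyper`, `f_mut`,
#'   denominators `n_loss_obs`, `n_hyper_obs`, `n_mut_obs`, and
#'   `mechanism_class`.
#' @export
mechanism_frequencies <- function(calls, major_cut = 0.2, minor_cut = 0.1) {
  under <- calls[calls$underexpressed %in% TRUE, , drop = FALSE]
  all_genes <- unique(calls$gene)
  skipped <- setdiff(all_genes, unique(under$gene))
  if (length(skipped) > 0)
    message(length(skipped), " genes never underexpressed excluded from mechanism frequencies")
  if (nrow(under) == 0L) {
    return(data.frame(gene = character(0), n_under = integer(0), f_loss = numeric(0),
                      f_hyper = numeric(0), f_mut = numeric(0),
                      n_loss_obs = integer(0), n_hyper_obs = integer(0),
                      n_mut_obs = integer(0), mechanism_class = character(0)))
  }
  frac <- function(x) if (all(is.na(x))) NA_real_ else mean(x, na.rm = TRUE)
  agg <- do.call(rbind, lapply(split(under, under$gene), function(g) {
    data.frame(gene = g$gene[1L], n_under = nrow(g),
               f_loss = frac(g$cnv_loss), f_hyper = frac(g$hypermeth),
               f_mut = frac(g$mutated),
               n_loss_obs = sum(!is.na(g$cnv_loss)),
               n_hyper_obs = sum(!is.na(g$hypermeth)),
               n_mut_obs = sum(!is.na(g$mutated)),
               stringsAsFactors = FALSE)
  }))
  rownames(agg) <- NULL
  cls <- function(fh, fl) {
    if (is.na(fh) || is.na(fl)) return("Neither")
    if (fh >= major_cut && fl >= major_cut) return("Both")
    if (fh >= major_cut && fl < minor_cut) return("DNAmDominant")
    if (fl >= major_cut && fh < minor_cut) return("CNVDominant")
    "Neither"
  }
  agg$mechanism_class <- mapply(cls, agg$f_hyper, agg$f_loss)
  agg
}

#' Compare alteration statistics of silenced TFs against all underexpressed genes
#'
#' Per molecular channel, a one-tailed rank-sum test of the silenced TFs'
#' per-gene statistics against those of all other underexpressed genes:
#' differential-methylation t-statistics (alternative: TFs greater), mean
#' segment value (TFs smaller, i.e. more loss) and inactivating-mutation
#' frequency (TFs greater). Genes missing a channel are excluded from that
#' channel only.
#'
#' @param gene_stats data frame with columns `gene`, `dnam_t`, `cnv_mean`,
#'   `mut_freq` (NA allowed per channel).
#' @param silenced_tfs character vector, a subset of `all_under`.
#' @param all_under character vector of all genes underexpressed in the
#'   cancer type.
#' @return named numeric vector `c(p_dnam, p_cnv, p_mut)`.
#' @export
compare_silenced_vs_underexpressed <- function(gene_stats, silenced_tfs, all_under) {
  if (!all(silenced_tfs %in% all_under))
    stop("silenced_tfs must be a subset of all_under")
  bg <- setdiff(all_under, silenced_tfs)
  one <- function(col, alternative) {
    x <- gene_stats[[col]][match(silenced_tfs, gene_stats$gene)]
    y <- gene_stats[[col]][match(bg, gene_stats$gene)]
    x <- x[!is.na(x)]; y <- y[!is.na(y)]
    if (length(x) == 0L || length(y) == 0L) return(NA_real_)
    rank_sum_test(x, y, alternative = alternative)
  }
  c(p_dnam = one("dnam_t", "greater"),
    p_cnv = one("cnv_mean", "less"),
    p_mut = one("mut_freq", "greater"))
}

#' Meta-analysis across cancer types
#'
#' Applies Fisher's combined-probability method per molecular channel to the
#' per-cancer p-values.
#'
#' @param per_cancer data frame with one row per cancer type and columns
#'   `p_dnam`, `p_cnv`, `p_mut` (`>= 2` rows).
#' @return named numeric vector of combined p-values.
#' @export
meta_combine <- function(per_cancer) {
  if (nrow(per_cancer) < 2L) stop("meta_combine() needs at least 2 cancer types")
  vapply(c("p_dnam", "p_cnv", "p_mut"), function(col) {
    p <- per_cancer[[col]]
    combine_fisher(p[!is.na(p)])
  }, numeric(1))
}

#' Expected alteration-event counts under random gene draws
#'
#' Repeatedly draws `|silenced set|` genes from the underexpressed-gene
#' universe (without replacement, seeded) and records the total number of
#' alteration events (e.g. hypermethylation calls summed over tumours)
#' carried by each draw, yielding a null distribution for the observed count
#' at the silenced TFs.
#'
#' @param event_counts named numeric vector: per underexpressed gene, its
#'   total event count across tumours.
#' @param silenced_tfs character vector (subset of `names(event_counts)`).
#' @param n_draws number of random draws (`>= 100` recommended; a single draw
#'   is flagged as degenerate).
#' @param seed integer seed.
#' @return list with `observed`, `expected_mean`, `lower`, `upper` (2.5/97.5
#'   percentiles), `n_draws`, `degenerate`, `covered`.
#' @export
expected_counts_null <- function(event_counts, silenced_tfs, n_draws = 1000L, seed) {
  stopifnot(!is.null(names(event_counts)))
  if (!all(silenced_tfs %in% names(event_counts)))
    stop("silenced_tfs must be covered by event_counts")
  set.seed(as.integer(seed))
  k <- length(silenced_tfs)
  draws <- vapply(seq_len(n_draws), function(i) {
    sum(event_counts[sample.int(length(event_counts), k)])
  }, numeric(1))
  observed <- sum(event_counts[silenced_tfs])
  qs <- stats::quantile(draws, c(0.025, 0.975), names = FALSE)
  degenerate <- n_draws < 2L
  list(observed = observed, expected_mean = mean(draws),
       lower = qs[1L], upper = qs[2L], n_draws = n_draws,
       degenerate = degenerate,
       covered = observed >= qs[1L] && observed <= qs[2L])
}

#' Tertile-based mutual-exclusivity test
#'
#' Ranks genes by CNV-loss frequency and tests (one-tailed rank-sum) whether
#' hypermethylation frequency is higher in the lowest tertile than in the top
#' tertile; the reverse direction ranks by hypermethylation frequency and
#' compares CNV-loss frequency. Tertile boundaries are taken on mid-ranks so
#' tied frequencies stay together.
#'
#' @param freqs [mechanism_frequencies()] table (`>= 6` genes).
#' @return named numeric vector:
#'   `p_hyper_low_vs_top_cnv` (hypermethylation higher where CNV loss is
#'   rare) and `p_cnv_low_vs_top_hyper` (CNV loss higher where
#'   hypermethylation is rare). NA when a tertile is empty after the tie
#'   rule.
#' @export
tertile_exclusivity <- function(freqs) {
  n <- nrow(freqs)
  if (n < 6L) stop("tertile_exclusivity() needs at least 6 genes")
  one_direction <- function(rank_on, compare) {
    r <- rank(freqs[[rank_on]], ties.method = "average")
    low <- r <= n / 3
    top <- r > 2 * n / 3
    if (!any(low) || !any(top)) {
      warning("empty tertile after keeping ties together; no test performed")
      return(NA_real_)
    }
    rank_sum_test(freqs[[compare]][low], freqs[[compare]][top],
                  alternative = "greater")
  }
  c(p_hyper_low_vs_top_cnv = one_direction("f_loss", "f_hyper"),
    p_cnv_low_vs_top_hyper = one_direction("f_hyper", "f_loss"))
}

#' Per-TF mutual exclusivity of hypermethylation and CNV loss
#'
#' For each gene with at least `min_freq` frequency of both CNV loss and
#' relaxed hypermethylation among its underexpressed tumours, tests
#' (one-tailed rank-sum) whether delta-beta is higher in the tumours without
#' CNV loss than in those with CNV loss. Genes with an empty group are
#' excluded with a message.
#'
#' @param calls an [build_alteration_calls()] table.
#' @param min_freq eligibility frequency for both channels (default 0.01).
#' @return data frame with `gene`, `n_loss`, `n_noloss`, `f_loss`,
#'   `f_hyper_relaxed`, `p`.
#' @export
per_tf_exclusivity <- function(calls, min_freq = 0.01) {
  under <- calls[calls$underexpressed %in% TRUE &
                   !is.na(calls$cnv_loss) & !is.na(calls$delta_beta), , drop = FALSE]
  res <- lapply(split(under, under$gene), function(g) {
    f_loss <- mean(g$cnv_loss)
    f_hyper_rel <- mean(g$hypermeth_relaxed)
    if (f_loss < min_freq || f_hyper_rel < min_freq) return(NULL)
    loss <- g$delta_beta[g$cnv_loss]
    noloss <- g$delta_beta[!g$cnv_loss]
    if (length(loss) == 0L || length(noloss) == 0L) {
      message("gene ", g$gene[1L], ": one CNV group empty; exclusivity test skipped")
      return(NULL)
    }
    data.frame(gene = g$gene[1L], n_loss = length(loss), n_noloss = length(noloss),
               f_loss = f_loss, f_hyper_relaxed = f_hyper_rel,
               p = rank_sum_test(noloss, loss, alternative = "greater"),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  if (is.null(out)) {
    out <- data.frame(gene = character(0), n_loss = integer(0), n_noloss = integer(0),
                      f_loss = numeric(0), f_hyper_relaxed = numeric(0), p = numeric(0))
  }
  rownames(out) <- NULL
  out
}

#' Cross-cancer concordance of mechanism frequencies
#'
#' For every pair of cancer types, the squared Pearson correlation of the
#' per-gene hypermethylation frequencies (and, separately, CNV-loss
#' frequencies) over the genes silenced in both cancers; pairs with fewer
#' than `min_shared` shared genes, or with a zero-variance frequency vector
#' in a channel, are skipped for that channel. The aggregate comparison is a
#' one-tailed paired Wilcoxon signed-rank test that the methylation R-squared
#' exceeds the CNV R-squared across pairs.
#'
#' @param freq_list named list of [mechanism_frequencies()] tables, one per
#'   cancer type.
#' @param min_shared minimum number of shared genes per pair (default 3).
#' @return list with `pairs` (data frame: `cancer_a`, `cancer_b`, `n_shared`,
#'   `r2_dnam`, `r2_cnv`), `mean_r2_dnam`, `mean_r2_cnv` and `p_paired`.
#' @export
cross_cancer_concordance <- function(freq_list, min_shared = 3L) {
  stopifnot(length(freq_list) >= 2L, !is.null(names(freq_list)))
  combos <- utils::combn(names(freq_list), 2L)
  r2 <- function(x, y) {
    if (stats::sd(x) == 0 || stats::sd(y) == 0) return(NA_real_)
    stats::cor(x, y)^2
  }
  rows <- lapply(seq_len(ncol(combos)), function(i) {
    a <- freq_list[[combos[1L, i]]]; b <- freq_list[[combos[2L, i]]]
    shared <- intersect(a$gene, b$gene)
    if (length(shared) < min_shared) return(NULL)
    ia <- match(shared, a$gene); ib <- match(shared, b$gene)
    data.frame(cancer_a = combos[1L, i], cancer_b = combos[2L, i],
               n_shared = length(shared),
               r2_dnam = r2(a$f_hyper[ia], b$f_hyper[ib]),
               r2_cnv = r2(a$f_loss[ia], b$f_loss[ib]),
               stringsAsFactors = FALSE)
  })
  pairs <- do.call(rbind, rows)
  if (is.null(pairs) || nrow(pairs) == 0L) stop("no cancer pair shares enough silenced genes")
  ok <- stats::complete.cases(pairs[, c("r2_dnam", "r2_cnv")])
  p_paired <- if (sum(ok) >= 2L) {
    stats::wilcox.test(pairs$r2_dnam[ok], pairs$r2_cnv[ok], paired = TRUE,
                       alternative = "greater", exact = FALSE)$p.value
  } else NA_real_
  list(pairs = pairs,
       mean_r2_dnam = mean(pairs$r2_dnam, na.rm = TRUE),
       mean_r2_cnv = mean(pairs$r2_cnv, na.rm = TRUE),
       p_paired = p_paired)
}
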