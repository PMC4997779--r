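#' Default analysis thresholds
#'
#' The call thresholds of the integrative analysis: Z < -2 for per-tumour
#' underexpression, segment value < -0.35 for one-copy loss, delta-beta > 0.3
#' for promoter hypermethylation (0.1 for the relaxed regime used by the
#' per-TF exclusivity analysis), BH-adjusted p < 0.05 for differential
#' expression, 1000 random genes for the up/down fraction comparison.
#'
#' @param seed integer seed used for the seeded sub-analyses (random gene
#'   draws, null-count draws).
#' @return named list of thresholds.
#' @export
default_thresholds <- function(seed = 1L) {
  list(alpha = 0.05, z_threshold = -2, cnv_threshold = -0.35,
       hyper_threshold = 0.3, relaxed_threshold = 0.1,
       n_random = 1000L, n_null_draws = 1000L,
       svd_k = 5L, svd_alpha = 0.05,
       expressed_filter = TRUE, seed = as.integer(seed))
}

#' Run the full TF-silencing analysis on a cohort
#'
#' Executes every stage on an in-memory cohort (from [generate_cohort()] or
#' [read_cohort()]): quantile normalization of the stem-cell compendium
#' expression and per-tissue identification of upregulated candidate TFs;
#' per cancer type, log2 regularization and SVD QC, differential expression
#' against normal-adjacent samples, silenced-TF selection (up in tissue, down
#' in cancer), expression-matched non-housekeeping controls and the
#' preferential-silencing rank-sum test, per-tumour Z-score underexpression
#' calls, promoter methylation assignment and hypermethylation calls, CNV
#' segment mapping and loss calls, inactivating-mutation calls, mechanism
#' frequencies and classes, channel-wise comparison of silenced TFs against
#' all underexpressed genes, and the exclusivity analyses; finally the Fisher
#' meta-analysis and the cross-cancer concordance of mechanism frequencies.
#'
#' @param cohort a [generate_cohort()] or [read_cohort()] object.
#' @param thresholds a [default_thresholds()] list.
#' @return object of class `tfsilence_result`; see the per-element
#'   documentation in the returned list (`selections`, `exclusive`,
#'   `per_cancer`, `channel_table`, `meta`, `concordance`).
#' @export
run_pipeline <- function(cohort, thresholds = default_thresholds()) {
  th <- utils::modifyList(default_thresholds(), thresholds)
  gl <- cohort$gene_lists
  candidates <- intersect(gl$tf_genes, union(gl$bivalent_genes, gl$prc2_genes))

  ## ---- stage 1: tissue vs hESC on the stem-cell compendium ----
  scm2 <- quantile_normalize(cohort$scm2$expr)
  pheno <- cohort$scm2$pheno
  hesc_cols <- pheno$sample[pheno$phenotype == "hESC"]
  selections <- list()
  tissue_diffs <- list()
  rnd_comparisons <- list()
  for (i in seq_along(cohort$tissues)) {
    ti <- cohort$tissues[i]
    tissue_cols <- pheno$sample[pheno$tissue == ti]
    diff_t <- diff_expression(scm2, tissue_cols, hesc_cols)
    selections[[ti]] <- identify_up_tfs(diff_t, candidates, tissue = ti,
                                        alpha = th$alpha)
    tissue_diffs[[ti]] <- diff_t
    rnd_comparisons[[ti]] <- fraction_comparison_vs_random(
      selections[[ti]], diff_t, n_random = min(th$n_random, nrow(diff_t)),
      seed = th$seed + i)
  }
  exclusive <- exclusive_sets(selections)

  ## ---- stages 2-3 per cancer type ----
  per_cancer <- list()
  for (i in seq_len(nrow(cohort$cancers))) {
    ct <- cohort$cancers$cancer[i]
    ti <- cohort$cancers$tissue[i]
    dat <- cohort$cancer_data[[ct]]
    ph <- dat$pheno
    normal_cols <- ph$sample[ph$phenotype == "NormalAdjacent"]
    tumour_cols <- ph$sample[ph$phenotype == "Tumour"]

    expr <- log2_regularize(dat$counts)
    qc <- svd_qc(expr, ph$phenotype[match(colnames(expr), ph$sample)],
                 k = th$svd_k, alpha = th$svd_alpha)
    diff_c <- diff_expression(expr, tumour_cols, normal_cols)
    all_under <- diff_c$gene[diff_c$p_adj < th$alpha & diff_c$t_mod < 0]
    up_tfs <- intersect(selections[[ti]]$up_tfs, rownames(expr))
    silenced <- intersect(up_tfs, all_under)

    ## expression-matched controls for the preferential-silencing test
    normal_means <- rowMeans(expr[, normal_cols, drop = FALSE])
    expressed_tfs <- if (isTRUE(th$expressed_filter)) {
      up_tfs[normal_means[up_tfs] > stats::median(normal_means)]
    } else up_tfs
    control <- NULL; pref_p <- NA_real_
    if (length(expressed_tfs) >= 2L) {
      control <- match_control_genes(expressed_tfs, normal_means,
                                     gl$housekeeping_genes)
      pref_p <- test_preferential_silencing(diff_c, expressed_tfs, control)
    }
    cgi_p <- if (length(silenced) > 0)
      cgi_enrichment(silenced, rownames(expr), gl$cgi_genes) else NA_real_

    ## per-tumour underexpression calls
    zs <- compute_zscores(expr[, tumour_cols, drop = FALSE],
                          expr[, normal_cols, drop = FALSE])
    z_calls <- call_underexpression(zs$z, threshold = th$z_threshold)

    ## promoter methylation
    gm <- assign_promoter_dnam(dat$betas, cohort$probe_manifest)
    hyper <- call_hypermethylation(gm$values[, tumour_cols, drop = FALSE],
                                   gm$values[, normal_cols, drop = FALSE],
                                   threshold = th$hyper_threshold,
                                   relaxed_threshold = th$relaxed_threshold)
    dnam_diff <- diff_expression(gm$values, tumour_cols, normal_cols)

    ## CNV and mutations
    segval <- map_segments_to_genes(dat$segments, cohort$genes)
    segval <- segval[, intersect(colnames(segval), tumour_cols), drop = FALSE]
    mut_records <- standardize_mutation_records(dat$mutations)
    mutated <- call_inactivating_mutation(mut_records, rownames(expr), tumour_cols)

    ## alteration calls and mechanism attribution for the silenced TFs
    calls <- build_alteration_calls(z_calls, segval, hyper, mutated,
                                    genes = silenced,
                                    cnv_threshold = th$cnv_threshold,
                                    hyper_threshold = th$hyper_threshold,
                                    relaxed_threshold = th$relaxed_threshold)
    freqs <- mechanism_frequencies(calls)

    ## per-gene channel statistics over the whole universe
    cnv_mean <- rowMeans(segval, na.rm = TRUE)
    cnv_mean[!is.finite(cnv_mean)] <- NA_real_
    gene_stats <- data.frame(
      gene = rownames(expr),
      dnam_t = dnam_diff$t_mod[match(rownames(expr), dnam_diff$gene)],
      cnv_mean = cnv_mean[match(rownames(expr), names(cnv_mean))],
      mut_freq = rowMeans(mutated)[rownames(expr)],
      stringsAsFactors = FALSE)
    channel_p <- compare_silenced_vs_underexpressed(gene_stats, silenced, all_under)

    ## exclusivity analyses
    tertile_p <- if (nrow(freqs) >= 6L) tertile_exclusivity(freqs) else
      c(p_hyper_low_vs_top_cnv = NA_real_, p_cnv_low_vs_top_hyper = NA_real_)
    excl_tf <- per_tf_exclusivity(calls, min_freq = 0.01)

    ## expected hypermethylation-event counts under null gene draws
    under_meth <- intersect(all_under, rownames(gm$values))
    event_counts <- rowSums(z_calls[under_meth, , drop = FALSE] &
                              hyper$call[under_meth, colnames(z_calls), drop = FALSE],
                            na.rm = TRUE)
    expected_null <- if (length(intersect(silenced, under_meth)) > 0) {
      expected_counts_null(event_counts, intersect(silenced, under_meth),
                           n_draws = th$n_null_draws, seed = th$seed + 100L + i)
    } else NULL

    per_cancer[[ct]] <- list(
      cancer = ct, tissue = ti, qc = qc, diff = diff_c,
      gene_universe = rownames(expr),
      all_under = all_under, up_tfs = up_tfs, silenced_tfs = silenced,
      expressed_tfs = expressed_tfs, control = control,
      preferential_silencing_p = pref_p, cgi_p = cgi_p,
      z = zs$z, calls = calls, mechanism_freqs = freqs,
      gene_stats = gene_stats, channel_p = channel_p,
      tertile_p = tertile_p, per_tf_exclusivity = excl_tf,
      expected_null = expected_null)
  }

  channel_table <- data.frame(
    cancer = names(per_cancer),
    p_dnam = vapply(per_cancer, function(x) x$channel_p[["p_dnam"]], numeric(1)),
    p_cnv = vapply(per_cancer, function(x) x$channel_p[["p_cnv"]], numeric(1)),
    p_mut = vapply(per_cancer, function(x) x$channel_p[["p_mut"]], numeric(1)),
    row.names = NULL, stringsAsFactors = FALSE)
  meta <- if (nrow(channel_table) >= 2L) meta_combine(channel_table) else NULL

  freq_list <- lapply(per_cancer, function(x) x$mechanism_freqs)
  concordance <- tryCatch(cross_cancer_concordance(freq_list),
                          error = function(e) NULL)

  structure(list(selections = selections, exclusive = exclusive,
                 tissue_random_comparisons = rnd_comparisons,
                 per_cancer = per_cancer, channel_table = channel_table,
                 meta = meta, concordance = concordance, thresholds = th),
            class = "tfsilence_result")
}

#' @export
print.tfsilence_result <- function(x, ...) {
  cat("TF-silencing analysis across", length(x$per_cancer), "cancer types\n")
  for (ct in names(x$per_cancer)) {
    pc <- x$per_cancer[[ct]]
    cat(sprintf("  %-16s %3d silenced TFs; preferential-silencing p = %.3g\n",
                ct, length(pc$silenced_tfs), pc$preferential_silencing_p))
  }
  if (!is.null(x$meta)) {
    cat(sprintf("  meta-analysis (Fisher): p_dnam = %.3g, p_cnv = %.3g, p_mut = %.3g\n",
                x$meta[["p_dnam"]], x$meta[["p_cnv"]], x$meta[["p_mut"]]))
  }
  invisible(x)
}

# map raw MAF-style records (sample, gene, classification) to the internal
# variant-class vocabulary; pass-through if already standardized
standardize_mutation_records <- function(df, class_map = default_variant_class_map()) {
  if ("variant_class" %in% names(df)) return(df)
  vc <- unname(class_map[as.character(df[[3L]])])
  unknown <- is.na(vc)
  if (any(unknown)) {
    warning(sum(unknown), " mutation records with unmapped classification assigned 'Other'")
    vc[unknown] <- "Other"
  }
  data.frame(sample_id = as.character(df[[1L]]), gene_id = as.character(df[[2L]]),
             variant_class = vc, stringsAsFactors = FALSE)
}
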