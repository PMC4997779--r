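#' Configuration for the synthetic multi-omic cohort
#'
#' Builds and validates the parameter set of the seeded cohort generator. The
#' defaults describe the package's reference study design: 2000 genes of
#' which 200 are bivalent/PRC2-marked TFs and 200 housekeeping genes; 4
#' normal tissues each with 20 stem-cell-compendium normals; 6 cancer types
#' (2 lung-like, 2 kidney-like, 1 bladder-like, 1 colon-like) each with 20
#' normal-adjacent and 60 tumour samples; per cancer, 40 silenced TFs with
#' mechanism proportions 50% hypermethylation, 25% CNV loss, 12.5% both
#' (mutually exclusive within tumours), 12.5% neither.
#'
#' @param seed integer RNG seed; every random draw in the generator flows
#'   from it.
#' @param n_genes,n_tfs,n_housekeeping gene-universe sizes.
#' @param n_tissues number of normal tissues.
#' @param cancers_per_tissue integer vector (length `n_tissues`): matched
#'   cancer types per tissue.
#' @param n_hesc,n_normal,n_tumour sample sizes (hESC lines; normals per
#'   tissue and normal-adjacent per cancer; tumours per cancer).
#' @param n_common_dev,n_exclusive_dev developmental-TF structure: TFs
#'   upregulated in every tissue vs the ones upregulated in exactly one.
#' @param frac_silenced_tfs fraction of a tissue's developmental TFs silenced
#'   in each matched cancer.
#' @param mechanism_mix named proportions over
#'   `c(DNAm, CNV, Both, Neither, Mutation)`; must sum to 1.
#' @param frac_affected_tumours fraction of tumours in which a planted gene's
#'   expression is dropped.
#' @param hyper_frac_range per-TF range (uniform) for the fraction of a
#'   DNAm-mechanism TF's affected tumours that receive the methylation gain;
#'   drawn once per TF so the hypermethylation programme is shared across
#'   cancer types.
#' @param cnv_frac_range per-(TF, cancer) range for the fraction of affected
#'   tumours with planted copy-number loss; drawn independently per cancer,
#'   making CNV frequencies idiosyncratic across cancer types.
#' @param both_event_frac event fraction (each channel) for both-mechanism
#'   TFs; the two channels are planted in disjoint tumour subsets.
#' @param mut_event_frac event fraction for mutation-mechanism TFs.
#' @param tf_up_log2 hESC-to-tissue upregulation of developmental TFs (log2).
#' @param silencing_log2 tissue-to-tumour expression drop (log2).
#' @param delta_beta_effect planted promoter beta gain in hypermethylated
#'   tumours.
#' @param cnv_loss_value planted segment value at lost loci.
#' @param mutation_rate background per-(gene, tumour) mutation probability.
#' @param expression_sd per-sample expression noise (log2 scale).
#' @param beta_noise_sd additive truncated-Gaussian probe noise.
#' @param n_bg_down background cancer-downregulated genes per cancer.
#' @param bg_driver_mix named proportions over `c(CNV, Mutation, None)` for
#'   the drivers of background downregulated genes.
#' @param frac_other_only_genes fraction of non-TF, non-housekeeping genes
#'   whose probes all fall outside the three promoter classes (absent from
#'   the gene-level methylation matrix, exercising channel-wise missingness).
#' @param gene_length,gene_spacing,n_chroms synthetic genome layout (bp).
#' @return validated list of class `cohort_config`.
#' @export
cohort_config <- function(seed = 1L,
                          n_genes = 2000L, n_tfs = 200L, n_housekeeping = 200L,
                          n_tissues = 4L, cancers_per_tissue = c(2L, 2L, 1L, 1L),
                          n_hesc = 20L, n_normal = 20L, n_tumour = 60L,
                          n_common_dev = 24L, n_exclusive_dev = 24L,
                          frac_silenced_tfs = 5 / 6,
                          mechanism_mix = c(DNAm = 0.5, CNV = 0.25, Both = 0.125,
                                            Neither = 0.125, Mutation = 0),
                          frac_affected_tumours = 0.6,
                          hyper_frac_range = c(0.45, 0.75),
                          cnv_frac_range = c(0.25, 0.7),
                          both_event_frac = 0.4,
                          mut_event_frac = 0.6,
                          tf_up_log2 = 2, silencing_log2 = 2,
                          delta_beta_effect = 0.4, cnv_loss_value = -0.5,
                          mutation_rate = 0.01,
                          expression_sd = 0.5, beta_noise_sd = 0.05,
                          n_bg_down = 300L,
                          bg_driver_mix = c(CNV = 0.4, Mutation = 0.2, None = 0.4),
                          frac_other_only_genes = 0.02,
                          gene_length = 5000L, gene_spacing = 10000L,
                          n_chroms = 4L) {
  cfg <- as.list(environment())
  counts <- c(n_genes, n_tfs, n_housekeeping, n_tissues, n_hesc, n_normal,
              n_tumour, n_common_dev, n_exclusive_dev, n_bg_down,
              gene_length, gene_spacing, n_chroms, cancers_per_tissue)
  if (any(counts <= 0) || any(counts != round(counts)))
    stop("all counts in the cohort config must be positive integers")
  if (length(cancers_per_tissue) != n_tissues)
    stop("cancers_per_tissue must have one entry per tissue")
  if (abs(sum(mechanism_mix) - 1) > 1e-8) stop("mechanism_mix must sum to 1")
  if (!setequal(names(mechanism_mix), c("DNAm", "CNV", "Both", "Neither", "Mutation")))
    stop("mechanism_mix must be named over DNAm, CNV, Both, Neither, Mutation")
  if (abs(sum(bg_driver_mix) - 1) > 1e-8) stop("bg_driver_mix must sum to 1")
  if (n_tfs + n_housekeeping >= n_genes)
    stop("n_genes must exceed n_tfs + n_housekeeping")
  if (n_common_dev + n_tissues * n_exclusive_dev > n_tfs)
    stop("developmental-TF structure does not fit inside n_tfs")
  if (frac_silenced_tfs <= 0 || frac_silenced_tfs > 1)
    stop("frac_silenced_tfs must lie in (0, 1]")
  effects <- c(tf_up_log2, silencing_log2, delta_beta_effect, cnv_loss_value,
               expression_sd, beta_noise_sd)
  if (any(!is.finite(effects))) stop("effect sizes and noise levels must be finite")
  if (n_bg_down > n_genes - n_tfs - n_housekeeping)
    stop("n_bg_down exceeds the non-TF, non-housekeeping gene pool")
  if (gene_length >= gene_spacing) stop("gene_length must be smaller than gene_spacing")
  structure(cfg, class = "cohort_config")
}

# largest-remainder allocation of n items to named proportions
alloc_counts <- function(n, props) {
  raw <- n * props
  base <- floor(raw)
  rem <- n - sum(base)
  if (rem > 0) {
    o <- order(raw - base, decreasing = TRUE)
    base[o[seq_len(rem)]] <- base[o[seq_len(rem)]] + 1
  }
  stats::setNames(as.integer(base), names(props))
}

# assign labels to a shuffled gene vector following proportions exactly
assign_by_mix <- function(genes, mix) {
  counts <- alloc_counts(length(genes), mix)
  labels <- rep(names(counts), counts)
  stats::setNames(labels, sample(genes))
}

#' Generate a synthetic multi-omic cohort with planted ground truth
#'
#' Produces, entirely in memory, every input the pipeline consumes: a
#' stem-cell-compendium-style log2 expression matrix (hESC + tissue normals)
#' in which each tissue's developmental TFs are upregulated; per cancer type,
#' a tumour + normal-adjacent RNA-seq-like count matrix with planted TF
#' silencing and background downregulated genes, a probe-level beta matrix
#' (promoter gains planted only in the tumours where expression was dropped),
#' a per-tumour CNV segmentation with planted losses at the affected loci,
#' and a mutation table; plus gene coordinates, gene lists and the truth
#' tables needed for recovery testing. Identical seeds give identical
#' cohorts.
#'
#' @param config a [cohort_config()].
#' @return list of class `synthetic_cohort` with elements `config`, `genes`
#'   (coordinates + roles), `gene_lists`, `tissues`, `cancers`, `scm2`,
#'   `probe_manifest`, `cancer_data` (per cancer: `counts`, `pheno`, `betas`,
#'   `segments`, `mutations`) and `truth`.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  cfg <- config
  set.seed(cfg$seed)

  ## ---- genome layout and gene roles ----
  gene_ids <- sprintf("g%04d", seq_len(cfg$n_genes))
  per_chrom <- ceiling(cfg$n_genes / cfg$n_chroms)
  chrom_idx <- rep(seq_len(cfg$n_chroms), each = per_chrom)[seq_len(cfg$n_genes)]
  pos_in_chrom <- stats::ave(seq_len(cfg$n_genes), chrom_idx, FUN = seq_along)
  coords <- data.frame(gene_id = gene_ids,
                       chrom = paste0("chr", chrom_idx),
                       start = (pos_in_chrom - 1) * cfg$gene_spacing,
                       end = (pos_in_chrom - 1) * cfg$gene_spacing + cfg$gene_length,
                       stringsAsFactors = FALSE)
  chrom_len <- (per_chrom + 1) * cfg$gene_spacing

  tf_genes <- sort(sample(gene_ids, cfg$n_tfs))
  hk_genes <- sort(sample(setdiff(gene_ids, tf_genes), cfg$n_housekeeping))
  other_genes <- setdiff(gene_ids, c(tf_genes, hk_genes))

  tissues <- c("lung", "kidney", "bladder", "colon",
               paste0("tissue", seq_len(max(0, cfg$n_tissues - 4))))[seq_len(cfg$n_tissues)]
  cancers <- data.frame(
    cancer = unlist(lapply(seq_len(cfg$n_tissues), function(i) {
      paste0(tissues[i], "_cancer", seq_len(cfg$cancers_per_tissue[i]))
    })),
    tissue = rep(tissues, cfg$cancers_per_tissue),
    stringsAsFactors = FALSE)

  ## ---- developmental TFs and mechanisms ----
  common_dev <- sample(tf_genes, cfg$n_common_dev)
  remaining <- setdiff(tf_genes, common_dev)
  exclusive_dev <- list()
  for (ti in tissues) {
    exclusive_dev[[ti]] <- sample(remaining, cfg$n_exclusive_dev)
    remaining <- setdiff(remaining, exclusive_dev[[ti]])
  }
  dev_by_tissue <- lapply(exclusive_dev, function(e) c(common_dev, e))
  dev_all <- unique(unlist(dev_by_tissue))

  mechanism <- c(assign_by_mix(common_dev, cfg$mechanism_mix),
                 unlist(unname(lapply(exclusive_dev, assign_by_mix, mix = cfg$mechanism_mix))))
  hyper_frac_tf <- stats::setNames(
    stats::runif(length(dev_all), cfg$hyper_frac_range[1], cfg$hyper_frac_range[2]),
    dev_all)

  ## ---- gene lists ----
  bivalent <- unique(c(dev_all,
                       sample(setdiff(tf_genes, dev_all),
                              min(30L, length(setdiff(tf_genes, dev_all)))),
                       sample(other_genes, min(100L, length(other_genes)))))
  prc2 <- unique(c(sample(tf_genes, round(0.5 * cfg$n_tfs)),
                   sample(other_genes, min(100L, length(other_genes)))))
  cgi <- unique(c(tf_genes, sample(other_genes, round(0.3 * length(other_genes)))))
  gene_lists <- list(tf_genes = tf_genes, bivalent_genes = sort(bivalent),
                     prc2_genes = sort(prc2), housekeeping_genes = hk_genes,
                     cgi_genes = sort(cgi))

  ## ---- baseline expression and methylation ----
  base_mean <- pmin(pmax(stats::rnorm(cfg$n_genes, 7, 2), 3), 13)
  names(base_mean) <- gene_ids
  base_mean[hk_genes] <- pmin(pmax(stats::rnorm(length(hk_genes), 9, 0.5), 3), 13)
  base_beta <- stats::setNames(stats::rbeta(cfg$n_genes, 2, 8), gene_ids)

  tissue_mean <- sapply(tissues, function(ti) {
    m <- base_mean
    m[dev_by_tissue[[ti]]] <- m[dev_by_tissue[[ti]]] + cfg$tf_up_log2
    m
  })

  ## ---- stem-cell compendium expression (log2 array scale) ----
  hesc_cols <- paste0("hESC_", seq_len(cfg$n_hesc))
  normal_cols <- lapply(tissues, function(ti) paste0(ti, "_N", seq_len(cfg$n_normal)))
  names(normal_cols) <- tissues
  scm2_samples <- c(hesc_cols, unlist(normal_cols, use.names = FALSE))
  scm2_mean <- cbind(matrix(base_mean, cfg$n_genes, cfg$n_hesc),
                     do.call(cbind, lapply(tissues, function(ti) {
                       matrix(tissue_mean[, ti], cfg$n_genes, cfg$n_normal)
                     })))
  scm2 <- scm2_mean + matrix(stats::rnorm(length(scm2_mean), 0, cfg$expression_sd),
                             nrow = cfg$n_genes)
  dimnames(scm2) <- list(gene_ids, scm2_samples)
  scm2_pheno <- data.frame(
    sample = scm2_samples,
    phenotype = c(rep("hESC", cfg$n_hesc),
                  rep("NormalFetal", cfg$n_tissues * cfg$n_normal)),
    tissue = c(rep("hESC", cfg$n_hesc), rep(tissues, each = cfg$n_normal)),
    stringsAsFactors = FALSE)

  ## ---- probe manifest (global) ----
  other_only <- sample(other_genes, round(cfg$frac_other_only_genes * length(other_genes)))
  manifest_rows <- lapply(gene_ids, function(g) {
    if (g %in% other_only) {
      return(data.frame(gene_id = g, region_group = rep("Body", sample(1:2, 1)),
                        stringsAsFactors = FALSE))
    }
    regions <- c(if (stats::runif(1) < 0.65) rep("TSS200", sample(1:3, 1)),
                 if (stats::runif(1) < 0.5) rep("1stExon", sample(1:2, 1)),
                 if (stats::runif(1) < 0.9) rep("TSS1500", sample(1:4, 1)),
                 if (stats::runif(1) < 0.5) rep("Body", sample(1:3, 1)))
    if (!any(regions %in% c("TSS200", "1stExon", "TSS1500")))
      regions <- c(regions, rep("TSS1500", sample(1:2, 1)))
    data.frame(gene_id = g, region_group = regions, stringsAsFactors = FALSE)
  })
  manifest <- do.call(rbind, manifest_rows)
  internal_vocab <- c(TSS200 = "TSS200", `1stExon` = "FirstExon",
                      TSS1500 = "TSS1500", Body = "Other")
  manifest <- data.frame(probe_id = sprintf("cg%06d", seq_len(nrow(manifest))),
                         gene_id = manifest$gene_id,
                         region_group = unname(internal_vocab[manifest$region_group]),
                         stringsAsFactors = FALSE)

  ## ---- per-cancer data with planted mechanisms ----
  n_sil <- round(cfg$frac_silenced_tfs * (cfg$n_common_dev + cfg$n_exclusive_dev))
  bg_pool <- setdiff(other_genes, character(0))
  cancer_data <- list()
  truth_silenced <- list()
  truth_events <- list()
  truth_bg <- list()

  for (i in seq_len(nrow(cancers))) {
    ct <- cancers$cancer[i]; ti <- cancers$tissue[i]
    dev <- dev_by_tissue[[ti]]
    # stratified silenced-TF selection keeps the mechanism mix exact
    mech_dev <- mechanism[dev]
    sil_counts <- alloc_counts(n_sil, cfg$mechanism_mix)
    silenced <- unlist(lapply(names(sil_counts), function(m) {
      pool <- dev[mech_dev == m]
      if (sil_counts[[m]] > length(pool))
        stop("mechanism stratum '", m, "' too small for the requested silenced count")
      sample(pool, sil_counts[[m]])
    }))
    bg_down <- sample(bg_pool, cfg$n_bg_down)
    bg_driver <- assign_by_mix(bg_down, cfg$bg_driver_mix)

    normal_cols_ct <- paste0(ct, "_N", seq_len(cfg$n_normal))
    tumour_cols_ct <- paste0(ct, "_T", seq_len(cfg$n_tumour))
    samples_ct <- c(normal_cols_ct, tumour_cols_ct)
    n_aff <- round(cfg$frac_affected_tumours * cfg$n_tumour)

    planted <- c(silenced, bg_down)
    dropped <- hyper_ev <- loss_ev <- mut_ev <- list()
    for (g in planted) {
      aff <- sample(tumour_cols_ct, n_aff)
      dropped[[g]] <- aff
      if (g %in% silenced) {
        m <- mechanism[[g]]
        if (m == "DNAm") {
          hyper_ev[[g]] <- sample(aff, round(hyper_frac_tf[[g]] * n_aff))
        } else if (m == "CNV") {
          f <- stats::runif(1, cfg$cnv_frac_range[1], cfg$cnv_frac_range[2])
          loss_ev[[g]] <- sample(aff, round(f * n_aff))
        } else if (m == "Both") {
          # mutually exclusive tumour subsets for the two channels
          shuffled <- sample(aff)
          nh <- round(cfg$both_event_frac * n_aff)
          nl <- round(cfg$both_event_frac * n_aff)
          hyper_ev[[g]] <- shuffled[seq_len(nh)]
          loss_ev[[g]] <- shuffled[nh + seq_len(nl)]
        } else if (m == "Mutation") {
          mut_ev[[g]] <- sample(aff, round(cfg$mut_event_frac * n_aff))
        }
      } else {
        drv <- bg_driver[[g]]
        if (drv == "CNV") loss_ev[[g]] <- aff
        if (drv == "Mutation") mut_ev[[g]] <- aff
      }
    }

    ## expression counts
    mean_mat <- matrix(tissue_mean[, ti], cfg$n_genes, length(samples_ct),
                       dimnames = list(gene_ids, samples_ct))
    for (g in planted) {
      mean_mat[g, dropped[[g]]] <- mean_mat[g, dropped[[g]]] - cfg$silencing_log2
    }
    vals <- mean_mat + matrix(stats::rnorm(length(mean_mat), 0, cfg$expression_sd),
                              nrow = cfg$n_genes)
    counts <- round(pmax(2^vals - 1, 0))
    pheno <- data.frame(sample = samples_ct,
                        phenotype = c(rep("NormalAdjacent", cfg$n_normal),
                                      rep("Tumour", cfg$n_tumour)),
                        stringsAsFactors = FALSE)

    ## promoter betas -> probe matrix
    beta_gene <- matrix(base_beta, cfg$n_genes, length(samples_ct),
                        dimnames = list(gene_ids, samples_ct))
    for (g in names(hyper_ev)) {
      beta_gene[g, hyper_ev[[g]]] <-
        pmin(0.98, beta_gene[g, hyper_ev[[g]]] + cfg$delta_beta_effect)
    }
    betas <- beta_gene[manifest$gene_id, , drop = FALSE] +
      matrix(stats::rnorm(nrow(manifest) * length(samples_ct), 0, cfg$beta_noise_sd),
             nrow = nrow(manifest))
    betas <- pmin(pmax(betas, 0), 1)
    rownames(betas) <- manifest$probe_id

    ## CNV segmentation (tumours only)
    loss_long <- if (length(loss_ev) > 0) {
      data.frame(gene = rep(names(loss_ev), lengths(loss_ev)),
                 sample = unlist(loss_ev), stringsAsFactors = FALSE)
    } else data.frame(gene = character(0), sample = character(0))
    segments <- make_segmentation(loss_long, coords, tumour_cols_ct, chrom_len,
                                  margin = 1000, loss_value = cfg$cnv_loss_value)

    ## mutations
    bg_hits <- which(matrix(stats::runif(cfg$n_genes * cfg$n_tumour), cfg$n_genes) <
                       cfg$mutation_rate, arr.ind = TRUE)
    bg_classes <- sample(c("Missense_Mutation", "Silent", "Nonsense_Mutation",
                           "Frame_Shift_Del"),
                         nrow(bg_hits), replace = TRUE, prob = c(0.5, 0.3, 0.1, 0.1))
    mut_rows <- data.frame(sample = tumour_cols_ct[bg_hits[, 2]],
                           gene = gene_ids[bg_hits[, 1]],
                           variant_classification = bg_classes,
                           stringsAsFactors = FALSE)
    if (length(mut_ev) > 0) {
      planted_mut <- data.frame(
        sample = unlist(mut_ev),
        gene = rep(names(mut_ev), lengths(mut_ev)),
        variant_classification = sample(c("Missense_Mutation", "Nonsense_Mutation",
                                          "Frame_Shift_Del"),
                                        sum(lengths(mut_ev)), replace = TRUE),
        stringsAsFactors = FALSE)
      mut_rows <- rbind(mut_rows, planted_mut)
    }
    mut_rows <- mut_rows[order(mut_rows$sample, mut_rows$gene), , drop = FALSE]
    rownames(mut_rows) <- NULL

    cancer_data[[ct]] <- list(counts = counts, pheno = pheno, betas = betas,
                              segments = segments, mutations = mut_rows)
    truth_silenced[[ct]] <- data.frame(cancer = ct, gene = silenced,
                                       mechanism = unname(mechanism[silenced]),
                                       stringsAsFactors = FALSE)
    truth_events[[ct]] <- list(dropped = dropped, hyper = hyper_ev,
                               loss = loss_ev, mut = mut_ev)
    truth_bg[[ct]] <- data.frame(cancer = ct, gene = bg_down,
                                 driver = unname(bg_driver[bg_down]),
                                 stringsAsFactors = FALSE)
  }

  truth <- list(dev_by_tissue = dev_by_tissue,
                mechanism = mechanism,
                hyper_frac = hyper_frac_tf,
                silenced = do.call(rbind, truth_silenced),
                events = truth_events,
                bg_down = do.call(rbind, truth_bg))
  rownames(truth$silenced) <- NULL
  rownames(truth$bg_down) <- NULL

  structure(list(config = cfg,
                 genes = coords,
                 gene_lists = gene_lists,
                 tissues = tissues,
                 cancers = cancers,
                 scm2 = list(expr = scm2, pheno = scm2_pheno),
                 probe_manifest = manifest,
                 cancer_data = cancer_data,
                 truth = truth),
            class = "synthetic_cohort")
}

# per-sample segmentation: planted loss intervals (gene locus +/- margin)
# carved out of per-chromosome background segments; internal 0-based
# half-open coordinates
make_segmentation <- function(loss_long, coords, samples, chrom_len,
                              margin = 1000, loss_value = -0.5, noise_sd = 0.05) {
  chroms <- unique(coords$chrom)
  rows <- vector("list", length(samples) * length(chroms))
  k <- 0L
  for (s in samples) {
    sg <- loss_long$gene[loss_long$sample == s]
    for (ch in chroms) {
      g <- coords[coords$gene_id %in% sg & coords$chrom == ch, , drop = FALSE]
      g <- g[order(g$start), , drop = FALSE]
      starts <- pmax(0, g$start - margin)
      ends <- pmin(chrom_len, g$end + margin)
      # background = complement of the planted intervals
      bg_start <- c(0, ends)
      bg_end <- c(starts, chrom_len)
      keep <- bg_start < bg_end
      k <- k + 1L
      rows[[k]] <- data.frame(
        sample_id = s, chrom = ch,
        start = c(starts, bg_start[keep]),
        end = c(ends, bg_end[keep]),
        segval = c(stats::rnorm(length(starts), loss_value, noise_sd),
                   stats::rnorm(sum(keep), 0, noise_sd)),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$sample_id, out$chrom, out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat("Synthetic multi-omic cohort (seed ", x$config$seed, ")\n", sep = "")
  cat("  ", x$config$n_genes, " genes, ", x$config$n_tfs, " TFs, ",
      length(x$tissues), " tissues, ", nrow(x$cancers), " cancer types\n", sep = "")
  invisible(x)
}

#' Confusion summaries of pipeline output against the planted truth
#'
#' @param truth the `truth` element of a [generate_cohort()] result.
#' @param result a [run_pipeline()] result on the same cohort.
#' @return list with `silencing` (pooled detection counts across cancers:
#'   `tp`, `fp`, `fn`, `sensitivity`, `fdr`) and `mechanism` (confusion
#'   `table` truth x predicted over detected planted TFs, plus `accuracy`).
#' @export
truth_confusion <- function(truth, result) {
  mech_map <- c(DNAm = "DNAmDominant", CNV = "CNVDominant", Both = "Both",
                Neither = "Neither", Mutation = "Neither")
  tp <- fp <- fn <- 0L
  truth_lab <- pred_lab <- character(0)
  for (ct in names(result$per_cancer)) {
    ts <- truth$silenced[truth$silenced$cancer == ct, , drop = FALSE]
    if (nrow(ts) == 0L) stop("cancer type ", ct, " absent from the truth table")
    res_ct <- result$per_cancer[[ct]]
    if (!all(ts$gene %in% res_ct$gene_universe))
      stop("gene universes of truth and pipeline output do not match")
    detected <- res_ct$silenced_tfs
    tp <- tp + length(intersect(detected, ts$gene))
    fp <- fp + length(setdiff(detected, ts$gene))
    fn <- fn + length(setdiff(ts$gene, detected))
    hit <- intersect(intersect(detected, ts$gene), res_ct$mechanism_freqs$gene)
    truth_lab <- c(truth_lab, mech_map[ts$mechanism[match(hit, ts$gene)]])
    pred_lab <- c(pred_lab,
                  res_ct$mechanism_freqs$mechanism_class[
                    match(hit, res_ct$mechanism_freqs$gene)])
  }
  lev <- c("DNAmDominant", "CNVDominant", "Both", "Neither")
  tab <- table(factor(truth_lab, lev), factor(pred_lab, lev), dnn = c("truth", "predicted"))
  list(silencing = list(tp = tp, fp = fp, fn = fn,
                        sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
                        fdr = if (tp + fp > 0) fp / (tp + fp) else 0),
       mechanism = list(table = tab,
                        accuracy = if (length(truth_lab) > 0)
                          sum(diag(tab)) / sum(tab) else NA_real_))
}
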