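# shared fixtures, memoised so expensive cohorts are built once per session

.fixtures <- new.env(parent = emptyenv())

# the package's reference study design (2000 genes, 6 cancer types), seed 1
default_run <- function() {
  if (is.null(.fixtures$default)) {
    cohort <- generate_cohort(cohort_config(seed = 1))
    result <- suppressMessages(run_pipeline(cohort, default_thresholds(seed = 1)))
    .fixtures$default <- list(cohort = cohort, result = result)
  }
  .fixtures$default
}

# a reduced cohort for fast structural tests
small_config <- function(seed = 11, ...) {
  cohort_config(seed = seed, n_genes = 300L, n_tfs = 60L, n_housekeeping = 40L,
                n_tissues = 2L, cancers_per_tissue = c(1L, 1L),
                n_hesc = 10L, n_normal = 10L, n_tumour = 30L,
                n_common_dev = 8L, n_exclusive_dev = 8L,
                frac_silenced_tfs = 0.75, n_bg_down = 60L, n_chroms = 2L, ...)
}

small_run <- function() {
  if (is.null(.fixtures$small)) {
    cohort <- generate_cohort(small_config())
    result <- suppressWarnings(suppressMessages(
      run_pipeline(cohort, default_thresholds(seed = 11))))
    .fixtures$small <- list(cohort = cohort, result = result)
  }
  .fixtures$small
}

# independent rank-sum oracle: enumerate all group assignments and count by
# the pair-comparison (Mann-Whitney U) formulation rather than rank sums
oracle_rank_sum <- function(x, y, alternative) {
  pooled <- c(x, y)
  n <- length(pooled); n_x <- length(x)
  u_stat <- function(xs, ys) {
    sum(outer(xs, ys, "<")) + 0.5 * sum(outer(xs, ys, "=="))
  }
  u_obs <- u_stat(x, y)
  sets <- utils::combn(n, n_x)
  us <- apply(sets, 2, function(ix) u_stat(pooled[ix], pooled[-ix]))
  eps <- 1e-9
  p_less <- mean(us >= u_obs - eps)     # x smaller <=> many x < y pairs
  p_greater <- mean(us <= u_obs + eps)
  switch(alternative,
         less = p_less, greater = p_greater,
         two_sided = min(1, 2 * min(p_less, p_greater)))
}

# independent brute-force recursive promoter model: plain double loop
oracle_promoter_dnam <- function(probe_mat, annotation) {
  genes <- sort(unique(annotation$gene_id))
  res <- list()
  for (g in genes) {
    ann_g <- annotation[annotation$gene_id == g, ]
    probes <- NULL
    for (region in c("TSS200", "FirstExon", "TSS1500")) {
      cand <- unique(ann_g$probe_id[ann_g$region_group == region])
      cand <- cand[cand %in% rownames(probe_mat)]
      if (length(cand) > 0) { probes <- cand; break }
    }
    if (is.null(probes)) next
    vals <- probe_mat[probes, , drop = FALSE]
    res[[g]] <- apply(vals, 2, function(col) {
      if (all(is.na(col))) NA_real_ else mean(col, na.rm = TRUE)
    })
  }
  do.call(rbind, res)
}

# random probe manifest + beta matrix for oracle comparisons
random_dnam_instance <- function(n_genes = 30, n_samples = 6, p_missing = 0) {
  genes <- sprintf("g%02d", seq_len(n_genes))
  rows <- lapply(genes, function(g) {
    regions <- sample(c("TSS200", "FirstExon", "TSS1500", "Other"),
                      size = sample(1:5, 1), replace = TRUE)
    data.frame(gene_id = g, region_group = regions, stringsAsFactors = FALSE)
  })
  ann <- do.call(rbind, rows)
  ann$probe_id <- sprintf("cg%03d", seq_len(nrow(ann)))
  mat <- matrix(runif(nrow(ann) * n_samples), nrow = nrow(ann),
                dimnames = list(ann$probe_id, paste0("s", seq_len(n_samples))))
  if (p_missing > 0) mat[runif(length(mat)) < p_missing] <- NA
  list(mat = mat, annotation = ann[, c("probe_id", "gene_id", "region_group")])
}
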