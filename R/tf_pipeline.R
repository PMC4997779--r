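#' Identify transcription factors up/downregulated in a tissue
#'
#' Selects, among a candidate TF set, the genes significantly differentially
#' expressed in a tissue relative to the embryonic stem-cell ground state.
#' The direction convention of the differential table is positive = higher in
#' the tissue. No fold-change filter is applied; log2 fold changes are
#' reported for audit.
#'
#' @param diff differential table from [diff_expression()] (tissue vs hESC).
#' @param candidate_tfs character vector of candidate (bivalent/PRC2-marked)
#'   TF gene IDs. Candidates absent from `diff` are skipped with a message.
#' @param tissue tissue label stored in the result.
#' @param alpha BH-adjusted significance level (default 0.05).
#' @return an object of class `tf_selection`: list with `tissue`, `up_tfs`,
#'   `down_tfs`, `fold_changes` (named log2 FC for all scored candidates) and
#'   `alpha`.
#' @export
identify_up_tfs <- function(diff, candidate_tfs, tissue = "tissue", alpha = 0.05) {
  candidate_tfs <- unique(as.character(candidate_tfs))
  present <- candidate_tfs %in% diff$gene
  if (any(!present)) {
    message(sum(!present), " candidate TFs absent from the differential table were skipped")
  }
  sub <- diff[match(candidate_tfs[present], diff$gene), , drop = FALSE]
  up <- sub$gene[sub$p_adj < alpha & sub$t_mod > 0]
  down <- sub$gene[sub$p_adj < alpha & sub$t_mod < 0]
  fc <- stats::setNames(sub$log2_fc, sub$gene)
  structure(list(tissue = tissue, up_tfs = up, down_tfs = down,
                 fold_changes = fc, alpha = alpha),
            class = "tf_selection")
}

#' @export
print.tf_selection <- function(x, ...) {
  cat("TF selection for tissue '", x$tissue, "': ", length(x$up_tfs), " up, ",
      length(x$down_tfs), " down (alpha = ", x$alpha, ")\n", sep = "")
  invisible(x)
}

#' Tissue-exclusive and common upregulated TF sets
#'
#' @param selections named list of [identify_up_tfs()] results (`>= 2`
#'   tissues).
#' @return list with `exclusive` (named list: TFs up in exactly that tissue)
#'   and `common` (TFs up in every tissue).
#' @export
exclusive_sets <- function(selections) {
  if (length(selections) < 2L) stop("exclusive_sets() needs at least 2 tissues")
  ups <- lapply(selections, function(s) s$up_tfs)
  if (is.null(names(ups))) names(ups) <- vapply(selections, `[[`, "", "tissue")
  all_up <- unlist(ups, use.names = FALSE)
  counts <- table(all_up)
  exclusive <- lapply(ups, function(u) u[counts[u] == 1L])
  common <- Reduce(intersect, ups)
  list(exclusive = exclusive, common = common)
}

#' Compare up/down fractions of TFs against randomly selected genes
#'
#' Draws `n_random` genes (without replacement, seeded) from the full
#' differential table, classifies them with the same significance rule as the
#' TF selection, and performs a one-tailed Fisher exact test for the TFs
#' being skewed towards upregulation relative to the random draw.
#'
#' @param selection an [identify_up_tfs()] result.
#' @param diff full differential table (all genes).
#' @param n_random number of random genes (default 1000).
#' @param seed integer seed for the draw.
#' @return list with the 2x2 `table` (rows TF/random, columns up/down) and
#'   the one-tailed Fisher `p` for TF up-enrichment.
#' @export
fraction_comparison_vs_random <- function(selection, diff, n_random = 1000L, seed) {
  if (n_random > nrow(diff)) stop("n_random exceeds the number of scored genes")
  set.seed(as.integer(seed))
  rnd <- diff[sample.int(nrow(diff), n_random), , drop = FALSE]
  rnd_up <- sum(rnd$p_adj < selection$alpha & rnd$t_mod > 0)
  rnd_down <- sum(rnd$p_adj < selection$alpha & rnd$t_mod < 0)
  tf_up <- length(selection$up_tfs); tf_down <- length(selection$down_tfs)
  tab <- matrix(c(tf_up, tf_down, rnd_up, rnd_down), nrow = 2, byrow = TRUE,
                dimnames = list(c("TF", "random"), c("up", "down")))
  p <- fisher_exact_one_tailed(tf_up, tf_down, rnd_up, rnd_down)
  list(table = tab, p = p)
}

#' Match expression-level controls for a TF set
#'
#' Builds a 1:1 control gene set with expression levels matched to the TFs in
#' normal(-adjacent) tissue. Candidates are all genes minus TFs minus
#' housekeeping genes. Matching is greedy nearest-neighbour on mean log2
#' expression, processing TFs in decreasing expression order, consuming
#' candidates without replacement; distance ties are broken by lexicographic
#' gene ID.
#'
#' @param tf_set character vector of TF gene IDs.
#' @param normal_means named numeric vector of mean log2 expression in the
#'   normal(-adjacent) samples, covering TFs and the candidate pool.
#' @param housekeeping character vector of housekeeping gene IDs (excluded
#'   from the pool).
#' @return an object of class `control_gene_set`: list with `genes` (the
#'   matched controls) and `match_map` (named character vector TF -> control).
#' @export
match_control_genes <- function(tf_set, normal_means, housekeeping) {
  tf_set <- unique(as.character(tf_set))
  missing_tf <- setdiff(tf_set, names(normal_means))
  if (length(missing_tf) > 0)
    stop("TFs without a normal expression value: ", paste(utils::head(missing_tf, 5), collapse = ", "))
  pool <- setdiff(names(normal_means), union(tf_set, housekeeping))
  if (length(pool) < length(tf_set)) stop("candidate pool smaller than the TF set")
  pool <- pool[order(pool)]  # lexicographic, so ties resolve deterministically
  pool_means <- normal_means[pool]
  tf_order <- tf_set[order(normal_means[tf_set], decreasing = TRUE)]
  match_map <- character(0)
  for (tf in tf_order) {
    dist <- abs(pool_means - normal_means[[tf]])
    best <- which(dist == min(dist))[1L]  # pool is sorted: first hit = lexicographic winner
    match_map[[tf]] <- pool[best]
    pool <- pool[-best]; pool_means <- pool_means[-best]
  }
  structure(list(genes = unname(match_map), match_map = match_map),
            class = "control_gene_set")
}

#' @export
print.control_gene_set <- function(x, ...) {
  cat("Control gene set:", length(x$genes), "expression-matched non-housekeeping genes\n")
  invisible(x)
}

#' Test preferential silencing of TFs in cancer
#'
#' One-tailed rank-sum test that the cancer-vs-normal moderated t-statistics
#' of the TF set are smaller (more negative, i.e. stronger downregulation in
#' cancer) than those of the expression-matched control set.
#'
#' @param cancer_diff differential table (cancer vs normal; negative t =
#'   lower in cancer).
#' @param tf_set,control_set disjoint character vectors of gene IDs.
#' @return the one-tailed p-value.
#' @export
test_preferential_silencing <- function(cancer_diff, tf_set, control_set) {
  if (inherits(control_set, "control_gene_set")) control_set <- control_set$genes
  if (length(intersect(tf_set, control_set)) > 0)
    stop("TF set and control set must be disjoint")
  t_tf <- cancer_diff$t_mod[match(tf_set, cancer_diff$gene)]
  t_ctl <- cancer_diff$t_mod[match(control_set, cancer_diff$gene)]
  t_tf <- t_tf[!is.na(t_tf)]; t_ctl <- t_ctl[!is.na(t_ctl)]
  rank_sum_test(t_tf, t_ctl, alternative = "less")
}

#' CpG-island enrichment of silenced TFs
#'
#' One-tailed Fisher exact test for silenced TFs being more likely to map to
#' a CpG-island promoter than background genes.
#'
#' @param silenced_tfs,background character vectors of gene IDs (background
#'   excludes the silenced TFs internally).
#' @param cgi_genes character vector of genes with CpG-island promoters.
#' @return the one-tailed p-value.
#' @export
cgi_enrichment <- function(silenced_tfs, background, cgi_genes) {
  background <- setdiff(background, silenced_tfs)
  if (length(silenced_tfs) == 0L || length(background) == 0L)
    stop("cgi_enrichment() needs non-empty gene sets")
  a <- sum(silenced_tfs %in% cgi_genes)
  b <- length(silenced_tfs) - a
  c_ <- sum(background %in% cgi_genes)
  d <- length(background) - c_
  fisher_exact_one_tailed(a, b, c_, d)
}
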