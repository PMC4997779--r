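#' Quantile normalization
#'
#' Forces every column (sample) onto the common reference distribution
#' obtained as the row-wise mean of the column-sorted input. Tied entries
#' within a column receive the mean of their tied reference quantiles
#' (mid-rank rule), which makes the transform idempotent.
#'
#' @param mat numeric genes x samples matrix with `>= 2` samples and no
#'   missing values.
#' @return matrix of the same shape; each column has identical sorted values.
#' @export
quantile_normalize <- function(mat) {
  stopifnot(is.matrix(mat))
  if (ncol(mat) < 2L) stop("quantile normalization needs at least 2 samples")
  if (anyNA(mat)) stop("missing values present; filter or impute before quantile normalization")
  ref <- rowMeans(apply(mat, 2L, sort))
  out <- apply(mat, 2L, function(col) {
    r <- rank(col, ties.method = "average")
    (ref[floor(r)] + ref[ceiling(r)]) / 2
  })
  dimnames(out) <- dimnames(mat)
  out
}

#' Average probe rows into gene rows
#'
#' One output row per gene, the unweighted arithmetic mean of its probe
#' rows. Probes absent from the map (or mapped to no gene) are dropped.
#'
#' @param probe_mat numeric probes x samples matrix with probe row names.
#' @param probe_map data frame with columns `probe_id` and `gene_id`
#'   (many-to-one and one-to-many both allowed).
#' @return numeric genes x samples matrix.
#' @export
collapse_probes_to_genes <- function(probe_mat, probe_map) {
  stopifnot(is.matrix(probe_mat), !is.null(rownames(probe_mat)))
  if (is.null(probe_map) || nrow(probe_map) == 0L) stop("empty probe-to-gene map")
  map <- probe_map[probe_map$probe_id %in% rownames(probe_mat) &
                     nzchar(probe_map$gene_id), , drop = FALSE]
  if (nrow(map) == 0L) stop("no probes in the matrix are covered by the map")
  rows <- probe_mat[map$probe_id, , drop = FALSE]
  sums <- rowsum(rows, group = map$gene_id)
  counts <- as.vector(table(map$gene_id)[rownames(sums)])
  sums / counts
}

#' Log2 regularization of a count matrix
#'
#' Removes genes with zero counts in all samples or with no variation across
#' samples (sample variance exactly 0 on the raw scale), then applies
#' `log2(count + 1)`.
#'
#' @param counts numeric genes x samples matrix of non-negative counts.
#' @return log2-scale matrix restricted to the retained genes.
#' @export
log2_regularize <- function(counts) {
  stopifnot(is.matrix(counts))
  if (anyNA(counts)) stop("missing values are not allowed in the count matrix")
  if (any(counts < 0)) stop("negative counts are not allowed")
  all_zero <- rowSums(counts) == 0
  m <- rowMeans(counts)
  no_var <- rowSums((counts - m)^2) == 0
  keep <- !(all_zero | no_var)
  log2(counts[keep, , drop = FALSE] + 1)
}

#' SVD-based quality control of the top components of variation
#'
#' Computes the right singular vectors of the row-centred matrix and, for
#' each of the top `k` components, the association of the sample loadings
#' with the phenotype labels (rank-sum test for 2 classes, Kruskal-Wallis for
#' more). The data set is flagged when the top component does not associate
#' with phenotype at level `alpha` -- the signature of dominant confounding
#' variation.
#'
#' @param mat numeric genes x samples matrix with `>= 3` samples.
#' @param phenotype character/factor vector of per-sample labels with `>= 2`
#'   classes.
#' @param k number of top components to report (default 5, truncated to the
#'   matrix rank).
#' @param alpha significance level for the flag rule (default 0.05).
#' @return data frame (`component_index`, `variance_explained`, `assoc_p`,
#'   `flagged`); `flagged` is `TRUE` only on row 1 and only when its
#'   association p-value exceeds `alpha`.
#' @export
svd_qc <- function(mat, phenotype, k = 5L, alpha = 0.05) {
  stopifnot(is.matrix(mat))
  if (ncol(mat) < 3L) stop("svd_qc() needs at least 3 samples")
  phenotype <- as.factor(phenotype)
  if (length(phenotype) != ncol(mat)) stop("one phenotype label per sample is required")
  if (nlevels(droplevels(phenotype)) < 2L) stop("svd_qc() needs at least 2 phenotype classes")
  centred <- mat - rowMeans(mat)
  k <- min(k, nrow(mat), ncol(mat) - 1L)
  sv <- svd(centred, nu = 0, nv = k)
  var_explained <- sv$d[seq_len(k)]^2 / sum(sv$d^2)
  assoc_p <- vapply(seq_len(k), function(i) {
    v <- sv$v[, i]
    if (nlevels(droplevels(phenotype)) == 2L) {
      groups <- split(v, droplevels(phenotype))
      rank_sum_test(groups[[1L]], groups[[2L]], alternative = "two_sided")
    } else {
      stats::kruskal.test(v, phenotype)$p.value
    }
  }, numeric(1))
  data.frame(component_index = seq_len(k),
             variance_explained = var_explained,
             assoc_p = assoc_p,
             flagged = seq_len(k) == 1L & assoc_p > alpha)
}
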