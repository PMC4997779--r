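#' Recursive promoter methylation model
#'
#' Assigns one promoter DNA methylation (beta) value per gene per sample from
#' probe-level betas, following a strict region priority: the average over
#' probes within 200 bp upstream of the TSS (`TSS200`); if none exist, first
#' exon probes (`FirstExon`); if none, probes within 1500 bp upstream
#' (`TSS1500`). Genes whose probes all fall outside these three classes are
#' omitted. The region class is decided gene-wise from the manifest (not per
#' sample); a probe annotated to several region groups for the same gene
#' counts once, at its highest-priority group.
#'
#' Missing betas for individual probes are averaged over the non-missing
#' probes of the selected class per sample; a cell is missing only when all
#' probes of the class are missing for that sample.
#'
#' @param probe_mat numeric probes x samples matrix of betas in `[0, 1]`
#'   (missing values allowed).
#' @param annotation probe manifest as returned by [read_probe_manifest()]:
#'   columns `probe_id`, `gene_id`, `region_group` with `region_group` in
#'   `{TSS200, FirstExon, TSS1500, Other}`.
#' @return an object of class `gene_dnam`: list with `values` (genes x
#'   samples beta matrix), `region_used` (named character vector) and
#'   `n_probes_used` (named integer vector).
#' @export
assign_promoter_dnam <- function(probe_mat, annotation) {
  stopifnot(is.matrix(probe_mat), !is.null(rownames(probe_mat)))
  rng <- range(probe_mat, na.rm = TRUE)
  if (rng[1] < 0 || rng[2] > 1) stop("beta values must lie in [0, 1]")
  priority <- c(TSS200 = 1L, FirstExon = 2L, TSS1500 = 3L)
  ann <- annotation[annotation$region_group %in% names(priority) &
                      annotation$probe_id %in% rownames(probe_mat), , drop = FALSE]
  if (nrow(ann) == 0L) {
    return(structure(list(values = probe_mat[0, , drop = FALSE],
                          region_used = character(0),
                          n_probes_used = integer(0)),
                     class = "gene_dnam"))
  }
  ann$prio <- priority[ann$region_group]
  # a probe listed under several groups for the same gene counts once,
  # at its highest-priority group
  ann <- ann[order(ann$gene_id, ann$probe_id, ann$prio), , drop = FALSE]
  ann <- ann[!duplicated(ann[, c("gene_id", "probe_id")]), , drop = FALSE]
  best <- tapply(ann$prio, ann$gene_id, min)
  ann <- ann[ann$prio == best[ann$gene_id], , drop = FALSE]

  vals <- probe_mat[ann$probe_id, , drop = FALSE]
  present <- !is.na(vals)
  vals[!present] <- 0
  sums <- rowsum(vals, group = ann$gene_id)
  counts <- rowsum(present + 0, group = ann$gene_id)
  out <- sums / counts          # 0/0 -> NaN when all probes missing
  out[counts == 0] <- NA_real_
  genes <- rownames(out)
  region_used <- names(priority)[best[genes]]
  names(region_used) <- genes
  n_probes <- as.integer(table(ann$gene_id)[genes])
  names(n_probes) <- genes
  structure(list(values = out, region_used = region_used,
                 n_probes_used = n_probes),
            class = "gene_dnam")
}

#' @export
print.gene_dnam <- function(x, ...) {
  cat("Gene-level promoter methylation:", nrow(x$values), "genes x",
      ncol(x$values), "samples\n")
  print(table(x$region_used))
  invisible(x)
}
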