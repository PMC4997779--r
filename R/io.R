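#' Readers and writers for the pipeline's external formats
#'
#' All genomic coordinates inside the package are 0-based half-open; readers
#' are the only place where conversion from on-disk conventions happens (SEG
#' is read as 1-based inclusive, BED as 0-based half-open).
#'
#' @name io-formats
#' @keywords internal
NULL

#' Read a labelled numeric matrix from TSV
#'
#' Expects one header row of sample IDs and one leading row-label column.
#' Values are parsed as numeric; empty cells and `NA` become missing values.
#'
#' @param path file path.
#' @param orientation `"genes_by_samples"` (default, returned as-is) or
#'   `"samples_by_genes"` (transposed on read so the result is always genes
#'   by samples).
#' @return numeric matrix with row and column names.
#' @export
read_matrix <- function(path, orientation = c("genes_by_samples", "samples_by_genes")) {
  orientation <- match.arg(orientation)
  df <- utils::read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                          colClasses = "character")
  if (ncol(df) < 2L) stop("matrix TSV needs a label column plus at least one sample column: ", path)
  labels <- df[[1L]]
  if (anyDuplicated(labels)) {
    stop("duplicate row labels in ", path, ": ",
         paste(unique(labels[duplicated(labels)]), collapse = ", "))
  }
  samples <- colnames(df)[-1L]
  if (anyDuplicated(samples)) {
    stop("duplicate sample IDs in ", path, ": ",
         paste(unique(samples[duplicated(samples)]), collapse = ", "))
  }
  vals <- as.matrix(df[, -1L, drop = FALSE])
  suppressWarnings(num <- matrix(as.numeric(vals), nrow = nrow(vals)))
  bad <- which(is.na(num) & !(is.na(vals) | vals == "" | vals == "NA"), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stop("non-numeric cell in ", path, " at row '", labels[bad[1, 1]],
         "', column '", samples[bad[1, 2]], "': '", vals[bad[1, , drop = FALSE]], "'")
  }
  dimnames(num) <- list(labels, samples)
  if (orientation == "samples_by_genes") num <- t(num)
  num
}

#' Write a labelled numeric matrix as TSV
#'
#' @param mat numeric matrix with row and column names.
#' @param path output file path.
#' @param label_name header for the row-label column.
#' @export
write_matrix <- function(mat, path, label_name = "gene_id") {
  stopifnot(is.matrix(mat), !is.null(rownames(mat)), !is.null(colnames(mat)))
  df <- data.frame(rownames(mat), mat, check.names = FALSE, stringsAsFactors = FALSE)
  colnames(df) <- c(label_name, colnames(mat))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read CNV segments (SEG format)
#'
#' Columns: sample, chromosome, start, end, optional number of markers, and
#' segment mean. On-disk coordinates are taken as 1-based inclusive (the
#' common SEG dialect) and converted to 0-based half-open (`start - 1`,
#' `end`). Records are returned sorted by (sample, chrom, start).
#'
#' @param path file path.
#' @return data frame with columns `sample_id`, `chrom`, `start`, `end`,
#'   `segval` (0-based half-open coordinates).
#' @export
read_seg <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                          stringsAsFactors = FALSE)
  if (ncol(df) == 6L) df <- df[, -5L]  # drop num_mark if present
  if (ncol(df) != 5L) stop("SEG file must have 5 or 6 columns: ", path)
  colnames(df) <- c("sample_id", "chrom", "start", "end", "segval")
  df$sample_id <- as.character(df$sample_id)
  df$chrom <- as.character(df$chrom)
  df$start <- as.numeric(df$start); df$end <- as.numeric(df$end)
  df$segval <- as.numeric(df$segval)
  if (nrow(df) == 0L) return(df)
  if (any(is.na(df$segval))) stop("missing segment value in ", path)
  if (any(is.na(df$start) | is.na(df$end))) stop("non-numeric coordinates in ", path)
  df$start <- df$start - 1  # 1-based inclusive -> 0-based half-open
  if (any(df$start >= df$end)) stop("segment with start >= end in ", path)
  df <- df[order(df$sample_id, df$chrom, df$start), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Write CNV segments (SEG format)
#'
#' Inverse of [read_seg()]: internal 0-based half-open coordinates are
#' written as 1-based inclusive.
#'
#' @param segments data frame as returned by [read_seg()].
#' @param path output file path.
#' @export
write_seg <- function(segments, path) {
  out <- data.frame(sample = segments$sample_id, chrom = segments$chrom,
                    start = segments$start + 1, end = segments$end,
                    seg_mean = segments$segval)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Default mapping from MAF variant-classification strings to variant classes
#'
#' The dictionary can be replaced (e.g. loaded from a YAML config) to support
#' other MAF dialects without code changes. Unlisted strings map to `Other`.
#'
#' @return named character vector: names are MAF classification strings,
#'   values are one of `Nonsense`, `Missense`, `Deletion`.
#' @export
default_variant_class_map <- function() {
  c(Nonsense_Mutation = "Nonsense",
    Missense_Mutation = "Missense",
    Frame_Shift_Del   = "Deletion",
    In_Frame_Del      = "Deletion",
    Silent            = "Other")
}

#' Read somatic mutations (minimal MAF)
#'
#' Expects a TSV with at least three columns: sample, gene and variant
#' classification. Classification strings are mapped to the variant-class
#' vocabulary `{Nonsense, Missense, Deletion, Other}` via `class_map`;
#' unknown strings map to `Other` with a warning. Duplicate records are kept
#' (they are collapsed downstream when building the mutation-call matrix).
#'
#' @param path file path.
#' @param class_map named character vector, see [default_variant_class_map()].
#' @return data frame with columns `sample_id`, `gene_id`, `variant_class`.
#' @export
read_mutations <- function(path, class_map = default_variant_class_map()) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                          stringsAsFactors = FALSE)
  if (ncol(df) < 3L) stop("mutation table needs sample, gene and classification columns: ", path)
  standardize_mutation_records(df, class_map = class_map)
}

#' Read gene coordinates (BED4)
#'
#' BED is natively 0-based half-open, so no conversion is applied. One record
#' per gene is enforced.
#'
#' @param path file path (chrom, start, end, gene_id; no header).
#' @return data frame with columns `gene_id`, `chrom`, `start`, `end`.
#' @export
read_bed <- function(path) {
  df <- utils::read.delim(path, header = FALSE, sep = "\t", stringsAsFactors = FALSE)
  if (ncol(df) < 4L) stop("BED4 file needs chrom, start, end, name columns: ", path)
  out <- data.frame(gene_id = as.character(df[[4L]]), chrom = as.character(df[[1L]]),
                    start = as.numeric(df[[2L]]), end = as.numeric(df[[3L]]),
                    stringsAsFactors = FALSE)
  if (any(out$start >= out$end)) stop("gene with start >= end in ", path)
  if (anyDuplicated(out$gene_id)) stop("duplicate gene records in ", path)
  out
}

#' Write gene coordinates (BED4)
#'
#' @param coords data frame as returned by [read_bed()].
#' @param path output file path.
#' @export
write_bed <- function(coords, path) {
  out <- data.frame(coords$chrom, coords$start, coords$end, coords$gene_id)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a one-gene-per-line list
#'
#' @param path file path.
#' @return character vector of gene IDs; empty lines are an error.
#' @export
read_gene_list <- function(path) {
  x <- readLines(path)
  x <- trimws(x)
  x <- x[nzchar(x) | seq_along(x) < length(x)]  # allow one trailing newline
  if (any(!nzchar(x))) stop("empty gene identifier in ", path)
  x
}

#' Write a one-gene-per-line list
#' @param genes character vector.
#' @param path output file path.
#' @export
write_gene_list <- function(genes, path) {
  writeLines(as.character(genes), path)
  invisible(path)
}

#' Read the 450k-style probe manifest
#'
#' TSV with columns `probe_id`, `gene_id`, `region_group` where the region
#' vocabulary follows the 450k manifest: `TSS200`, `1stExon`, `TSS1500`;
#' anything else (gene body, 3'UTR, ...) becomes `Other`. A probe may map to
#' several genes (one row each).
#'
#' @param path file path.
#' @return data frame with columns `probe_id`, `gene_id`, `region_group`
#'   where `region_group` is one of `TSS200`, `FirstExon`, `TSS1500`,
#'   `Other`.
#' @export
read_probe_manifest <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  if (ncol(df) < 3L) stop("probe manifest needs probe_id, gene_id, region_group columns: ", path)
  out <- data.frame(probe_id = as.character(df[[1L]]), gene_id = as.character(df[[2L]]),
                    region_group = as.character(df[[3L]]), stringsAsFactors = FALSE)
  vocab <- c(TSS200 = "TSS200", `1stExon` = "FirstExon", TSS1500 = "TSS1500")
  mapped <- unname(vocab[out$region_group])
  mapped[is.na(mapped)] <- "Other"
  out$region_group <- mapped
  if (anyDuplicated(out[, c("probe_id", "gene_id")]))
    stop("duplicate (probe_id, gene_id) pairs in ", path)
  out
}

#' Read a pipeline config (YAML)
#'
#' @param path YAML file naming inputs, thresholds and seeds.
#' @return named list.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  yaml::read_yaml(path)
}

#' Write a pipeline config (YAML)
#' @param config named list.
#' @param path output file path.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}
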