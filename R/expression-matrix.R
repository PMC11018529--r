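#' Expression matrix with per-sample metadata
#'
#' The central container of the package: a genes x samples numeric matrix
#' together with a per-sample metadata table and a unit flag. Counts and TPM
#' matrices must be nonnegative; `"log"`-unit matrices (e.g. latent-factor
#' simulations or log-ratio summaries) may contain negative values.
#'
#' @param values numeric matrix, genes in rows (rownames = gene ids),
#'   samples in columns (colnames = sample ids).
#' @param meta data.frame with columns `sample_id`, `species`, `tissue`,
#'   `replicate`; one row per sample.
#' @param unit one of `"counts"`, `"TPM"`, `"log2TPM"`, `"log"`.
#' @return an object of class `ExpressionMatrix`: a list with elements
#'   `values`, `meta`, `unit`.
#' @export
expression_matrix <- function(values, meta, unit = c("counts", "TPM", "log2TPM", "log")) {
  unit <- match.arg(unit)
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop_fmt("expression matrix needs gene rownames and sample colnames")
  if (anyDuplicated(rownames(values)))
    stop_fmt("duplicate gene id: %s",
             rownames(values)[duplicated(rownames(values))][1])
  if (anyDuplicated(colnames(values)))
    stop_fmt("duplicate sample id: %s",
             colnames(values)[duplicated(colnames(values))][1])
  if (unit %in% c("counts", "TPM") && any(values < 0, na.rm = TRUE)) {
    bad <- which(values < 0, arr.ind = TRUE)[1, ]
    stop_fmt("negative value for gene '%s', sample '%s'",
             rownames(values)[bad[1]], colnames(values)[bad[2]])
  }
  meta <- as.data.frame(meta, stringsAsFactors = FALSE)
  req <- c("sample_id", "species", "tissue", "replicate")
  miss <- setdiff(req, names(meta))
  if (length(miss))
    stop_fmt("metadata lacks column(s): %s", paste(miss, collapse = ", "))
  absent <- setdiff(colnames(values), meta$sample_id)
  if (length(absent))
    stop_fmt("sample(s) without metadata: %s", paste(absent, collapse = ", "))
  meta <- meta[match(colnames(values), meta$sample_id), req, drop = FALSE]
  rownames(meta) <- NULL
  structure(list(values = values, meta = meta, unit = unit),
            class = "ExpressionMatrix")
}

#' @export
print.ExpressionMatrix <- function(x, ...) {
  cat(sprintf("ExpressionMatrix: %d genes x %d samples [%s]\n",
              nrow(x$values), ncol(x$values), x$unit))
  cat(sprintf("tissues: %s\n",
              paste(unique(x$meta$tissue), collapse = ", ")))
  invisible(x)
}

#' @export
dim.ExpressionMatrix <- function(x) dim(x$values)

#' Read an expression table and its sample metadata
#'
#' Both files are tab-separated with a header row; lines starting with `#`
#' are ignored. The expression table has gene ids in the first column and
#' one column per sample. The metadata table has columns `sample_id`,
#' `species`, `tissue`, `replicate` and `unit`; the unit must be identical
#' for all samples and becomes the matrix unit.
#'
#' @param table_path path to the genes x samples TSV.
#' @param meta_path path to the sample metadata TSV.
#' @return an [expression_matrix()].
#' @export
read_expression <- function(table_path, meta_path) {
  tab <- utils::read.delim(table_path, header = TRUE, sep = "\t",
                           comment.char = "#", check.names = FALSE,
                           stringsAsFactors = FALSE)
  if (ncol(tab) < 2) stop_fmt("expression table '%s' has no sample columns", table_path)
  gene_ids <- as.character(tab[[1]])
  if (anyDuplicated(gene_ids))
    stop_fmt("duplicate gene id in '%s': %s", table_path,
             gene_ids[duplicated(gene_ids)][1])
  values <- as.matrix(tab[, -1, drop = FALSE])
  storage.mode(values) <- "double"
  rownames(values) <- gene_ids
  meta <- utils::read.delim(meta_path, header = TRUE, sep = "\t",
                            comment.char = "#", stringsAsFactors = FALSE)
  if (!"unit" %in% names(meta))
    stop_fmt("metadata '%s' lacks required 'unit' column", meta_path)
  unit <- unique(meta$unit)
  if (length(unit) != 1)
    stop_fmt("metadata '%s' has inconsistent units: %s", meta_path,
             paste(unit, collapse = ", "))
  expression_matrix(values, meta, unit = unit)
}

#' Write an expression matrix and its metadata to TSV
#'
#' Values are written with 6 significant digits; integers (counts) are
#' written exactly.
#'
#' @param m an [expression_matrix()].
#' @param table_path,meta_path output paths.
#' @return invisibly, `m`.
#' @export
write_expression <- function(m, table_path, meta_path = NULL) {
  stopifnot(inherits(m, "ExpressionMatrix"))
  v <- m$values
  out <- data.frame(gene_id = rownames(v), signif(v, 6),
                    check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(out, table_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (!is.null(meta_path)) {
    meta <- m$meta
    meta$unit <- m$unit
    utils::write.table(meta, meta_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(m)
}

#' Convert raw counts to TPM
#'
#' Per sample, each gene's count is divided by its length in kilobases to
#' give a rate; rates are scaled so every sample column sums to one million
#' (transcripts per million).
#'
#' @param m an [expression_matrix()] with unit `"counts"`.
#' @param lengths named numeric vector of gene lengths in bp covering every
#'   gene of `m`; all positive.
#' @return an [expression_matrix()] with unit `"TPM"`.
#' @export
counts_to_tpm <- function(m, lengths) {
  stopifnot(inherits(m, "ExpressionMatrix"))
  if (m$unit != "counts") stop_fmt("counts_to_tpm needs unit 'counts', got '%s'", m$unit)
  genes <- rownames(m$values)
  miss <- setdiff(genes, names(lengths))
  if (length(miss))
    stop_fmt("no length for gene(s): %s", paste(utils::head(miss, 5), collapse = ", "))
  len <- as.numeric(lengths[genes])
  if (any(len <= 0)) stop_fmt("gene lengths must be positive")
  rate <- m$values / (len / 1000)
  tot <- colSums(rate)
  if (any(tot == 0))
    stop_fmt("sample '%s' has all-zero counts; TPM undefined",
             colnames(m$values)[which(tot == 0)[1]])
  tpm <- sweep(rate, 2, tot, "/") * 1e6
  expression_matrix(tpm, m$meta, unit = "TPM")
}

#' Filter to expressed genes
#'
#' Retains genes with TPM at or above `min_tpm` in at least `min_samples`
#' samples (boundary inclusive); gene order is preserved. The filter is
#' idempotent.
#'
#' @param m an [expression_matrix()] with unit `"TPM"`.
#' @param min_tpm expression threshold (default 1).
#' @param min_samples minimum number of samples at or above the threshold
#'   (default 2).
#' @return the filtered [expression_matrix()].
#' @export
filter_expressed <- function(m, min_tpm = 1, min_samples = 2) {
  stopifnot(inherits(m, "ExpressionMatrix"))
  if (m$unit != "TPM") stop_fmt("filter_expressed needs unit 'TPM', got '%s'", m$unit)
  keep <- rowSums(m$values >= min_tpm) >= min_samples
  expression_matrix(m$values[keep, , drop = FALSE], m$meta, unit = m$unit)
}

#' Average biological replicates within tissue
#'
#' Per gene and tissue, the arithmetic mean over that tissue's replicate
#' samples. The output has one pseudo-sample per tissue, named after the
#' tissue, in order of first appearance in the metadata.
#'
#' @param m an [expression_matrix()].
#' @return an [expression_matrix()] with one column per tissue.
#' @export
average_replicates <- function(m) {
  stopifnot(inherits(m, "ExpressionMatrix"))
  tissues <- unique(m$meta$tissue)
  cols <- vapply(tissues, function(tt) {
    idx <- which(m$meta$tissue == tt)
    if (!length(idx)) stop_fmt("tissue '%s' has no samples", tt)
    rowMeans(m$values[, idx, drop = FALSE])
  }, numeric(nrow(m$values)))
  cols <- matrix(cols, nrow = nrow(m$values),
                 dimnames = list(rownames(m$values), tissues))
  meta <- data.frame(sample_id = tissues,
                     species = m$meta$species[match(tissues, m$meta$tissue)],
                     tissue = tissues, replicate = NA_integer_,
                     stringsAsFactors = FALSE)
  expression_matrix(cols, meta, unit = m$unit)
}

#' log2(TPM + 1) transform
#'
#' @param m an [expression_matrix()] with unit `"TPM"`.
#' @return an [expression_matrix()] with unit `"log2TPM"`.
#' @export
log_transform <- function(m) {
  stopifnot(inherits(m, "ExpressionMatrix"))
  if (m$unit != "TPM") stop_fmt("log_transform needs unit 'TPM', got '%s'", m$unit)
  expression_matrix(log2(m$values + 1), m$meta, unit = "log2TPM")
}

#' Flag outlier replicates by correlation to tissue-mates
#'
#' A replicate is flagged when the Pearson correlation between its profile
#' and the centroid (mean profile) of the other replicates of the same
#' tissue falls below `min_cor`. This is an optional quality step standing
#' in for visual hierarchical-clustering checks; tissues with fewer than
#' two replicates are never flagged.
#'
#' @param m an [expression_matrix()].
#' @param min_cor correlation threshold (default 0.8).
#' @return character vector of flagged sample ids (possibly empty).
#' @export
flag_outlier_replicates <- function(m, min_cor = 0.8) {
  stopifnot(inherits(m, "ExpressionMatrix"))
  flagged <- character(0)
  for (tt in unique(m$meta$tissue)) {
    idx <- which(m$meta$tissue == tt)
    if (length(idx) < 2) next
    for (i in idx) {
      centroid <- rowMeans(m$values[, setdiff(idx, i), drop = FALSE])
      r <- suppressWarnings(stats::cor(m$values[, i], centroid))
      if (!is.na(r) && r < min_cor)
        flagged <- c(flagged, colnames(m$values)[i])
    }
  }
  flagged
}
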