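#' Read a gene-level count table
#'
#' Reads a tab-separated file with columns `gene_id`, `length` (bp) and
#' one column per sample, as written by [write_counts()].
#'
#' @param path file path.
#' @return A [count_matrix()].
#' @export
read_counts <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  miss <- setdiff(c("gene_id", "length"), names(df))
  if (length(miss))
    stop("count file ", path, " is missing column(s): ",
         paste(miss, collapse = ", "))
  sample_cols <- setdiff(names(df), c("gene_id", "length"))
  if (!length(sample_cols)) stop("count file has no sample columns")
  m <- as.matrix(df[, sample_cols, drop = FALSE])
  if (!is.numeric(m)) {
    bad <- sample_cols[!vapply(df[sample_cols], is.numeric, logical(1))]
    stop("non-numeric counts in column(s): ", paste(bad, collapse = ", "))
  }
  neg <- which(m < 0, arr.ind = TRUE)
  if (nrow(neg))
    stop("negative count at gene ", df$gene_id[neg[1, 1]], ", sample ",
         sample_cols[neg[1, 2]])
  rownames(m) <- df$gene_id
  count_matrix(m, stats::setNames(df$length, df$gene_id))
}

#' Write a count matrix as a tab-separated table
#'
#' @param cm a [count_matrix()].
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
write_counts <- function(cm, path) {
  stopifnot(inherits(cm, "count_matrix"))
  df <- data.frame(gene_id = rownames(cm$counts),
                   length = unname(cm$gene_lengths),
                   cm$counts, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read sample metadata
#'
#' Reads a tab-separated file with columns `sample_id`, `diet`, `tissue`.
#'
#' @param path file path.
#' @return A data.frame with those three character columns.
#' @export
read_metadata <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  miss <- setdiff(c("sample_id", "diet", "tissue"), names(df))
  if (length(miss))
    stop("metadata file ", path, " is missing column(s): ",
         paste(miss, collapse = ", "))
  df[, c("sample_id", "diet", "tissue")]
}

#' Write sample metadata as a tab-separated table
#'
#' @param metadata data.frame with `sample_id`, `diet`, `tissue`.
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
write_metadata <- function(metadata, path) {
  utils::write.table(metadata[, c("sample_id", "diet", "tissue")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Compute FPKM from counts and gene lengths
#'
#' FPKM (fragments per kilobase of exon per million mapped fragments) is
#' `counts * 1e9 / (library_size * gene_length_bp)`, with the library size
#' taken as each sample's total assigned counts.
#'
#' @param cm a [count_matrix()].
#' @return Numeric matrix of FPKM values, genes x samples.
#' @examples
#' cm <- count_matrix(matrix(c(10, 90), 2, 1,
#'                    dimnames = list(c("a", "b"), "s1")),
#'                    c(a = 1000, b = 1000))
#' compute_fpkm(cm)  # library size 100
#' @export
compute_fpkm <- function(cm) {
  stopifnot(inherits(cm, "count_matrix"))
  libsize <- colSums(cm$counts)
  if (any(libsize == 0))
    stop("zero library size for sample(s): ",
         paste(colnames(cm$counts)[libsize == 0], collapse = ", "))
  sweep(cm$counts * 1e9 / cm$gene_lengths, 2, libsize, "/")
}

#' Filter genes with low mean expression
#'
#' Removes a gene when its arithmetic mean FPKM across all samples is
#' strictly below `threshold`; a gene whose mean equals the threshold is
#' kept.
#'
#' @param fpkm FPKM matrix from [compute_fpkm()], genes x samples.
#' @param threshold mean-FPKM cutoff (default 5).
#' @return A list with `fpkm` (the kept rows), `removed` (ids of filtered
#'   genes) and `means` (mean FPKM of every input gene). Warns if nothing
#'   survives.
#' @export
filter_low_expression <- function(fpkm, threshold = 5) {
  if (!is.matrix(fpkm) || nrow(fpkm) == 0)
    stop("`fpkm` must be a non-empty matrix")
  means <- rowMeans(fpkm)
  drop <- means < threshold
  if (all(drop)) warning("no gene passes the mean-FPKM filter")
  list(fpkm = fpkm[!drop, , drop = FALSE],
       removed = rownames(fpkm)[drop],
       means = means)
}

#' Assemble the mined samples x features table
#'
#' Builds the table handed to the attribute-weighting models: one row per
#' sample, one numeric FPKM feature per kept gene (sorted by gene id), a
#' categorical `tissue` feature, and the binary `diet` class label in the
#' last column.
#'
#' @param fpkm FPKM matrix (genes x samples), typically after
#'   [filter_low_expression()].
#' @param metadata data.frame with `sample_id`, `diet`, `tissue` covering
#'   exactly the samples of `fpkm`.
#' @return A data.frame of class `mined_table` with attribute
#'   `feature_cols` (the gene ids plus `"tissue"`); `diet` is a factor
#'   with levels control, CR.
#' @export
assemble_mined_table <- function(fpkm, metadata) {
  if (!setequal(colnames(fpkm), metadata$sample_id))
    stop("samples of `fpkm` and `metadata` differ: ",
         paste(union(setdiff(colnames(fpkm), metadata$sample_id),
                     setdiff(metadata$sample_id, colnames(fpkm))),
               collapse = ", "))
  metadata <- metadata[match(colnames(fpkm), metadata$sample_id), ]
  genes <- sort(rownames(fpkm))
  tab <- as.data.frame(t(fpkm[genes, , drop = FALSE]))
  tab$tissue <- factor(metadata$tissue)
  tab$diet <- factor(metadata$diet, levels = c("control", "CR"))
  rownames(tab) <- metadata$sample_id
  if (nlevels(tab$tissue) < 2L)
    message("single-tissue table: the tissue feature is constant")
  structure(tab, feature_cols = c(genes, "tissue"), class =
              c("mined_table", "data.frame"))
}

#' Feature columns of a mined table
#' @param table a `mined_table` from [assemble_mined_table()].
#' @return Character vector of feature column names (genes plus tissue).
#' @export
feature_cols <- function(table) {
  fc <- attr(table, "feature_cols")
  if (is.null(fc)) setdiff(names(table), "diet") else fc
}
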