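#' Gene-level count matrix with gene lengths
#'
#' Container for a genes x samples matrix of non-negative integer read
#' counts together with per-gene exon lengths (bp). This is the raw input
#' of the pipeline: FPKM computation needs the lengths, differential
#' expression needs the counts.
#'
#' @param counts integer matrix, genes in rows and samples in columns, with
#'   unique row and column names.
#' @param gene_lengths numeric vector of gene lengths in bp, one per gene,
#'   named by gene id (or in row order of `counts`).
#' @return An object of class `count_matrix`: a list with elements
#'   `counts` (integer matrix) and `gene_lengths` (named numeric vector).
#' @examples
#' cm <- count_matrix(matrix(0:5, 2, 3, dimnames = list(c("g1", "g2"),
#'                    c("s1", "s2", "s3"))), c(g1 = 1000, g2 = 2000))
#' dim(cm$counts)
#' @export
count_matrix <- function(counts, gene_lengths) {
  if (!is.matrix(counts)) stop("`counts` must be a matrix")
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("`counts` must have gene row names and sample column names")
  if (anyDuplicated(rownames(counts)))
    stop("duplicate gene ids: ",
         paste(unique(rownames(counts)[duplicated(rownames(counts))]),
               collapse = ", "))
  if (anyDuplicated(colnames(counts)))
    stop("duplicate sample ids: ",
         paste(unique(colnames(counts)[duplicated(colnames(counts))]),
               collapse = ", "))
  if (any(!is.finite(counts)) || any(counts < 0))
    stop("counts must be finite and non-negative")
  if (any(counts != round(counts)))
    stop("counts must be integers")
  if (length(gene_lengths) != nrow(counts))
    stop("need one gene length per gene")
  if (is.null(names(gene_lengths))) {
    names(gene_lengths) <- rownames(counts)
  } else if (!setequal(names(gene_lengths), rownames(counts))) {
    stop("gene length names do not match gene ids")
  }
  gene_lengths <- gene_lengths[rownames(counts)]
  if (any(!is.finite(gene_lengths)) || any(gene_lengths <= 0))
    stop("gene lengths must be positive")
  storage.mode(counts) <- "double"
  structure(list(counts = counts, gene_lengths = gene_lengths),
            class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat("count_matrix:", nrow(x$counts), "genes x", ncol(x$counts),
      "samples\n")
  cat("gene lengths:", round(min(x$gene_lengths)), "-",
      round(max(x$gene_lengths)), "bp\n")
  invisible(x)
}

#' @export
dim.count_matrix <- function(x) dim(x$counts)

#' Validate sample metadata against a count matrix
#'
#' Checks that every sample in the count matrix has exactly one metadata
#' row, that diet and tissue are from the expected label sets, and that
#' both diets are present within every tissue (the design needs a
#' within-tissue contrast).
#'
#' @param cm a [count_matrix()].
#' @param metadata data.frame with columns `sample_id`, `diet`
#'   (control/CR) and `tissue`.
#' @return `metadata`, row-ordered to match the count matrix columns,
#'   with `diet` and `tissue` as factors (control is the diet reference
#'   level). Errors name any offending samples.
#' @export
validate_metadata <- function(cm, metadata) {
  stopifnot(inherits(cm, "count_matrix"))
  req <- c("sample_id", "diet", "tissue")
  miss <- setdiff(req, names(metadata))
  if (length(miss))
    stop("metadata is missing column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(metadata$sample_id))
    stop("duplicate metadata rows for sample(s): ",
         paste(unique(metadata$sample_id[duplicated(metadata$sample_id)]),
               collapse = ", "))
  absent <- setdiff(colnames(cm$counts), metadata$sample_id)
  if (length(absent))
    stop("metadata missing for sample(s): ", paste(absent, collapse = ", "))
  bad_diet <- setdiff(unique(metadata$diet), c("control", "CR"))
  if (length(bad_diet))
    stop("unknown diet label(s): ", paste(bad_diet, collapse = ", "))
  metadata <- metadata[match(colnames(cm$counts), metadata$sample_id), ,
                       drop = FALSE]
  rownames(metadata) <- NULL
  metadata$diet <- factor(metadata$diet, levels = c("control", "CR"))
  metadata$tissue <- factor(metadata$tissue)
  one_diet <- tapply(metadata$diet, metadata$tissue,
                     function(d) length(unique(d)) < 2L)
  if (any(one_diet))
    stop("tissue(s) without both diets: ",
         paste(names(one_diet)[one_diet], collapse = ", "))
  metadata
}
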