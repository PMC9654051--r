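#' PCA on the correlation matrix of per-tissue fold changes
#'
#' Principal component analysis of a genes x tissues fold-change matrix
#' using the column correlation matrix (i.e. columns are centred and
#' scaled to unit variance), the convention of classical multivariate
#' packages. Component signs follow a deterministic rule: the
#' largest-magnitude loading of each component is made positive.
#'
#' @param m numeric matrix (rows = genes, columns = tissues) with no
#'   missing entries and at least 2 rows and columns.
#' @return List with `loadings` (columns x components), `scores`
#'   (rows x components, from the standardised data), `explained`
#'   (variance fractions summing to 1) and `correlation` (the column
#'   correlation matrix).
#' @export
pca_correlation <- function(m) {
  m <- as.matrix(m)
  if (nrow(m) < 2 || ncol(m) < 2)
    stop("need at least 2 rows and 2 columns")
  if (any(!is.finite(m))) stop("matrix has missing or infinite entries")
  sds <- apply(m, 2, stats::sd)
  if (any(sds == 0))
    stop("constant column(s): ",
         paste(colnames(m)[sds == 0], collapse = ", "))
  z <- scale(m)
  p <- stats::prcomp(z, center = FALSE, scale. = FALSE)
  ev <- p$sdev^2
  k <- ncol(p$rotation)
  flip <- vapply(seq_len(k), function(j) {
    v <- p$rotation[, j]
    sign(v[which.max(abs(v))])
  }, numeric(1))
  flip[flip == 0] <- 1
  loadings <- sweep(p$rotation, 2, flip, "*")
  scores <- sweep(p$x, 2, flip, "*")
  list(loadings = loadings, scores = scores,
       explained = ev / sum(ev), correlation = stats::cor(m))
}

#' Hierarchical clustering with percent-similarity merge levels
#'
#' Agglomerative clustering of the tissue columns of a fold-change
#' matrix on Euclidean distance, reporting each merge on the
#' percent-similarity scale `100 * (1 - d / d_max)` where `d_max` is the
#' final merge distance — so the last merge sits at similarity 0% and
#' identical columns join at 100%.
#'
#' @param m numeric matrix with >= 2 columns (columns are clustered).
#' @param linkage one of `"complete"` (default), `"single"`,
#'   `"average"`.
#' @return List with `merges` (data.frame: `step`, `distance`,
#'   `similarity`, `members` — the labels joined at that step) and
#'   `hclust` (the underlying [stats::hclust] tree).
#' @export
cluster_similarity <- function(m, linkage = c("complete", "single",
                                              "average")) {
  linkage <- match.arg(linkage)
  m <- as.matrix(m)
  if (ncol(m) < 2) stop("need at least 2 columns to cluster")
  d <- stats::dist(t(m), method = "euclidean")
  hc <- stats::hclust(d, method = linkage)
  d_max <- hc$height[length(hc$height)]
  sim <- if (d_max == 0) rep(100, length(hc$height))
         else 100 * (1 - hc$height / d_max)
  members <- vapply(seq_along(hc$height), function(i) {
    leaves <- function(node) {
      if (node < 0) return(hc$labels[-node])
      unlist(lapply(hc$merge[node, ], leaves))
    }
    paste(sort(leaves(i)), collapse = "+")
  }, character(1))
  list(merges = data.frame(step = seq_along(hc$height),
                           distance = hc$height,
                           similarity = sim,
                           members = members,
                           stringsAsFactors = FALSE),
       hclust = hc)
}

#' Build a genes x tissues signed fold-change matrix from DE results
#'
#' Selects the top `n` genes by smallest Wald p-value anywhere and casts
#' their signed fold changes into a genes x tissues matrix; genes not
#' expressed in a tissue are imputed with fold change 1 (no change).
#'
#' @param de output of [run_diffexp()].
#' @param top_n number of genes to keep (default 40).
#' @return Numeric matrix, rows = gene ids, columns = tissues.
#' @export
fold_change_matrix <- function(de, top_n = 40) {
  best <- tapply(de$wald_p, de$gene_id, min, na.rm = TRUE)
  best <- best[is.finite(best)]
  keep <- names(sort(best))[seq_len(min(top_n, length(best)))]
  sub <- de[de$gene_id %in% keep, ]
  tissues <- unique(sub$tissue)
  m <- matrix(1, length(keep), length(tissues),
              dimnames = list(keep, tissues))
  idx <- cbind(match(sub$gene_id, keep), match(sub$tissue, tissues))
  fc <- ifelse(is.na(sub$signed_fc), 1, sub$signed_fc)
  m[idx] <- fc
  m
}
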