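#' Equal-frequency discretization
#'
#' Bins a numeric feature at its quantile edges (type-7 quantiles,
#' right-closed intervals) so bins are as equally populated as ties
#' allow. Heavily tied values collapse edges, so the effective number of
#' bins can be below `n_bins`; a constant feature yields a single bin.
#' The assignment is fully deterministic.
#'
#' @param values numeric vector.
#' @param n_bins requested number of bins (>= 2).
#' @return Integer bin labels in `1..n_bins` (without gaps).
#' @examples
#' table(discretize_equal_frequency(1:40, 4))  # four bins of 10
#' @export
discretize_equal_frequency <- function(values, n_bins = 5) {
  if (length(n_bins) != 1L || !is.finite(n_bins) || n_bins < 2)
    stop("`n_bins` must be an integer >= 2")
  if (any(!is.finite(values))) stop("`values` must be finite")
  edges <- unique(stats::quantile(values, probs = seq(0, 1,
                                                      length.out = n_bins + 1),
                                  names = FALSE, type = 7))
  if (length(edges) < 2L) return(rep(1L, length(values)))
  b <- .bincode(values, breaks = edges, right = TRUE,
                include.lowest = TRUE)
  # relabel in case tie-collapsed edges left unused codes
  as.integer(factor(b))
}

#' Feature x class contingency table
#'
#' Numeric features are discretized with [discretize_equal_frequency()]
#' first; factor/character features use their categories as bins.
#'
#' @param feature numeric or categorical vector.
#' @param class_labels class vector of the same length.
#' @param n_bins bins for numeric features.
#' @return A bins x classes contingency table (class `table`).
#' @export
contingency <- function(feature, class_labels, n_bins = 5) {
  if (length(feature) != length(class_labels))
    stop("`feature` and `class_labels` lengths differ")
  bins <- if (is.numeric(feature)) {
    discretize_equal_frequency(feature, n_bins)
  } else {
    factor(feature)
  }
  table(bin = bins, class = factor(class_labels))
}

# base-2 entropy of a count vector (0 log 0 = 0)
entropy2 <- function(counts) {
  p <- counts[counts > 0] / sum(counts)
  -sum(p * log2(p))
}

# Gini impurity of a count vector
gini_imp <- function(counts) {
  p <- counts / sum(counts)
  1 - sum(p^2)
}

#' Contingency-based attribute weights
#'
#' Computes one of the five contingency-table relevance scores used by
#' the weighting ensemble:
#' \describe{
#'   \item{info_gain}{`H(class) - sum_b p(b) H(class | b)` in bits;}
#'   \item{info_gain_ratio}{info gain divided by the bin entropy
#'     `H(bins)`; defined as 0 when `H(bins) = 0`;}
#'   \item{uncertainty}{symmetric uncertainty
#'     `2 IG / (H(class) + H(bins))` (0 when the denominator is 0);}
#'   \item{gini_index}{Gini impurity reduction
#'     `Gini(class) - sum_b p(b) Gini(class | b)`;}
#'   \item{chi_squared}{Pearson statistic `sum (O - E)^2 / E` over cells
#'     with positive expectation.}
#' }
#'
#' @param ct contingency table from [contingency()] (bins x classes).
#' @param model one of `"info_gain"`, `"info_gain_ratio"`,
#'   `"chi_squared"`, `"gini_index"`, `"uncertainty"`.
#' @return Non-negative raw weight.
#' @examples
#' ct <- as.table(matrix(c(20, 0, 0, 20), 2, 2))
#' weight_from_contingency(ct, "info_gain")   # 1 bit
#' weight_from_contingency(ct, "chi_squared") # 40
#' @export
weight_from_contingency <- function(ct,
                                    model = c("info_gain",
                                              "info_gain_ratio",
                                              "chi_squared", "gini_index",
                                              "uncertainty")) {
  model <- match.arg(model)
  ct <- as.matrix(ct)
  n <- sum(ct)
  if (n == 0) stop("empty contingency table")
  row_n <- rowSums(ct)
  col_n <- colSums(ct)
  if (model == "chi_squared") {
    e <- outer(row_n, col_n) / n
    keep <- e > 0
    return(sum((ct[keep] - e[keep])^2 / e[keep]))
  }
  if (model == "gini_index") {
    cond <- sum((row_n[row_n > 0] / n) *
                  apply(ct[row_n > 0, , drop = FALSE], 1, gini_imp))
    return(gini_imp(col_n) - cond)
  }
  ig <- entropy2(col_n) -
    sum((row_n[row_n > 0] / n) *
          apply(ct[row_n > 0, , drop = FALSE], 1, entropy2))
  switch(model,
         info_gain = ig,
         info_gain_ratio = {
           hb <- entropy2(row_n)
           if (hb == 0) 0 else ig / hb
         },
         uncertainty = {
           denom <- entropy2(col_n) + entropy2(row_n)
           if (denom == 0) 0 else 2 * ig / denom
         })
}

#' OneR-style rule weight
#'
#' Builds the single-feature rule that maps each bin of the feature to
#' its majority class and scores the feature by the rule's training
#' accuracy above the majority-class baseline, floored at zero. A
#' perfectly separating feature on balanced classes scores 0.5; a
#' constant feature scores 0.
#'
#' @inheritParams contingency
#' @return Raw weight in `[0, 1)`.
#' @export
weight_rule <- function(feature, class_labels, n_bins = 5) {
  ct <- contingency(feature, class_labels, n_bins)
  n <- sum(ct)
  rule_acc <- sum(apply(ct, 1, max)) / n
  baseline <- max(colSums(ct)) / n
  max(0, rule_acc - baseline)
}

# min-max scale the mined features for Relief distances: numeric columns
# to [0,1] (constant -> all 0); factors passed through.
relief_scale <- function(x) {
  lapply(x, function(col) {
    if (is.numeric(col)) {
      r <- range(col)
      if (r[1] == r[2]) rep(0, length(col))
      else (col - r[1]) / (r[2] - r[1])
    } else factor(col)
  })
}

#' ReliefF attribute weights
#'
#' Scores every feature of a mined table by the ReliefF criterion: a
#' feature is relevant when it differs more between a sample and its
#' nearest misses (other class) than between the sample and its nearest
#' hits (same class). Numeric features are min-max scaled to `[0, 1]`;
#' `diff` is the absolute scaled difference for numeric features and the
#' 0/1 indicator for categorical ones. Distances between samples are the
#' sum of per-feature diffs (Manhattan). With `n_iterations = NULL`
#' every sample is visited once and the result is deterministic;
#' otherwise `n_iterations` samples are drawn with the given seed.
#' Neighbour ties are broken by sample order.
#'
#' For each visited sample `i`,
#' `W(f) <- W(f) + sum_misses diff(f, i, m) / (k n) -
#'                 sum_hits diff(f, i, h) / (k n)`.
#'
#' @param x data.frame of features only (numeric and/or factor columns).
#' @param class_labels class vector (two classes expected).
#' @param k_neighbors neighbours per class (default 5).
#' @param n_iterations number of sampled instances, or `NULL` for a full
#'   deterministic pass over all samples.
#' @param seed seed used only when `n_iterations` is given.
#' @return Named numeric vector of raw Relief weights (one per feature).
#' @export
relief_weights <- function(x, class_labels, k_neighbors = 5,
                           n_iterations = NULL, seed = 1) {
  cl <- factor(class_labels)
  n <- nrow(x)
  if (length(cl) != n) stop("class labels do not match table rows")
  cls_sizes <- table(cl)
  if (any(cls_sizes < k_neighbors + 1))
    stop("every class needs more than `k_neighbors` samples; ",
         "reduce k_neighbors (smallest class has ", min(cls_sizes),
         " samples)")
  scaled <- relief_scale(x)
  num <- vapply(scaled, is.numeric, logical(1))
  zn <- if (any(num)) do.call(cbind, scaled[num]) else
    matrix(0, n, 0)
  fac <- scaled[!num]

  # pairwise Manhattan distance over all features
  d <- if (ncol(zn)) as.matrix(stats::dist(zn, method = "manhattan"))
       else matrix(0, n, n)
  for (f in fac) d <- d + outer(f, f, "!=")

  visit <- if (is.null(n_iterations)) seq_len(n) else {
    set.seed(seed)
    sample(n, n_iterations, replace = n_iterations > n)
  }
  k <- k_neighbors
  hit_i <- hit_j <- miss_i <- miss_j <- integer(0)
  for (i in visit) {
    same <- setdiff(which(cl == cl[i]), i)
    other <- which(cl != cl[i])
    hits <- same[order(d[i, same])[seq_len(k)]]
    misses <- other[order(d[i, other])[seq_len(k)]]
    hit_i <- c(hit_i, rep(i, k)); hit_j <- c(hit_j, hits)
    miss_i <- c(miss_i, rep(i, k)); miss_j <- c(miss_j, misses)
  }
  m <- length(visit)
  w_num <- if (ncol(zn)) {
    colSums(abs(zn[miss_i, , drop = FALSE] - zn[miss_j, , drop = FALSE])) /
      (k * m) -
      colSums(abs(zn[hit_i, , drop = FALSE] - zn[hit_j, , drop = FALSE])) /
      (k * m)
  } else numeric(0)
  w_fac <- vapply(fac, function(f) {
    sum(f[miss_i] != f[miss_j]) / (k * m) -
      sum(f[hit_i] != f[hit_j]) / (k * m)
  }, numeric(1))
  w <- numeric(ncol(x))
  names(w) <- names(x)
  w[num] <- w_num
  w[!num] <- w_fac
  w
}

#' Min-max normalise raw weights to \[0, 1\]
#'
#' `(w - min) / (max - min)` per model, so 0 marks the least and 1 the
#' most important feature. A constant raw vector maps to all zeros with a
#' warning.
#'
#' @param raw numeric vector of raw weights.
#' @return Normalised weights in `[0, 1]`.
#' @export
normalize_weights <- function(raw) {
  if (!length(raw)) stop("no weights to normalise")
  r <- range(raw)
  if (r[1] == r[2]) {
    warning("constant raw weights; normalised weights set to 0")
    return(stats::setNames(rep(0, length(raw)), names(raw)))
  }
  (raw - r[1]) / (r[2] - r[1])
}

#' The seven attribute-weighting model names
#' @return Character vector in report order.
#' @export
weighting_models <- function() {
  c("info_gain_ratio", "rule", "chi_squared", "gini_index",
    "uncertainty", "relief", "info_gain")
}

#' Run the full attribute-weighting ensemble
#'
#' Applies all seven weighting models — information gain ratio, rule
#' (OneR), chi-squared, Gini index, symmetric uncertainty, ReliefF and
#' information gain — to every feature of a mined table (per-gene FPKM
#' plus the categorical tissue feature) against the binary diet class,
#' and min-max normalises each model's weights across features.
#'
#' @param table a `mined_table` from [assemble_mined_table()], or any
#'   data.frame whose last column `diet` is the class and whose other
#'   columns are features.
#' @param n_bins bins for the discretization behind the contingency
#'   models (default 5).
#' @param relief_k ReliefF neighbours per class (default 5).
#' @param relief_iterations `NULL` for a full deterministic Relief pass,
#'   or a number of sampled instances.
#' @param seed seed for sampled Relief iterations.
#' @return A data.frame of class `weight_matrix`: `feature`, the seven
#'   normalised weight columns (in [weighting_models()] order) and the
#'   seven raw weights as `raw_<model>` columns.
#' @export
run_all_models <- function(table, n_bins = 5, relief_k = 5,
                           relief_iterations = NULL, seed = 1) {
  if (!"diet" %in% names(table)) stop("`table` must have a diet class column")
  cl <- factor(table$diet)
  if (nlevels(droplevels(cl)) != 2L)
    stop("the diet class must have exactly two levels")
  feats <- table[, feature_cols(table), drop = FALSE]
  if (ncol(feats) < 2L) stop("need at least two features")

  cts <- lapply(feats, contingency, class_labels = cl, n_bins = n_bins)
  raw <- data.frame(
    info_gain_ratio = vapply(cts, weight_from_contingency, numeric(1),
                             model = "info_gain_ratio"),
    rule = vapply(feats, weight_rule, numeric(1), class_labels = cl,
                  n_bins = n_bins),
    chi_squared = vapply(cts, weight_from_contingency, numeric(1),
                         model = "chi_squared"),
    gini_index = vapply(cts, weight_from_contingency, numeric(1),
                        model = "gini_index"),
    uncertainty = vapply(cts, weight_from_contingency, numeric(1),
                         model = "uncertainty"),
    relief = relief_weights(feats, cl, k_neighbors = relief_k,
                            n_iterations = relief_iterations, seed = seed),
    info_gain = vapply(cts, weight_from_contingency, numeric(1),
                       model = "info_gain"))
  norm <- as.data.frame(lapply(raw, normalize_weights))
  names(raw) <- paste0("raw_", names(raw))
  out <- cbind(data.frame(feature = names(feats),
                          stringsAsFactors = FALSE),
               norm, raw)
  rownames(out) <- NULL
  structure(out, class = c("weight_matrix", "data.frame"))
}
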