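#' Sum of the seven normalised weights per feature
#'
#' The ranking statistic of the signature: the arithmetic sum of the
#' seven min-max normalised model weights, so every feature scores in
#' `[0, 7]`.
#'
#' @param wm a `weight_matrix` from [run_all_models()], or any data.frame
#'   with a `feature` column and the seven model columns.
#' @return Named numeric vector of sums, one per feature.
#' @examples
#' sum_weights(data.frame(feature = "C1qa", info_gain_ratio = 0.6,
#'   rule = 0.9, chi_squared = 0.8, gini_index = 0.6, uncertainty = 0.7,
#'   relief = 0.5, info_gain = 0.5))  # 4.6
#' @export
sum_weights <- function(wm) {
  miss <- setdiff(weighting_models(), names(wm))
  if (length(miss))
    stop("weight matrix is missing model column(s): ",
         paste(miss, collapse = ", "))
  s <- rowSums(as.matrix(wm[, weighting_models()]))
  stats::setNames(s, wm$feature)
}

#' Rank features by sum of weights and extract the top-k signature
#'
#' Orders features by decreasing sum of the seven normalised weights;
#' ties are broken lexicographically by feature id so the ranking is
#' deterministic. Ranks run 1..N without gaps.
#'
#' @param wm a `weight_matrix` from [run_all_models()].
#' @param k signature size (default 20).
#' @return A list with `signature` (the top-`k` rows) and `ranking` (all
#'   features); both are data.frames with `rank`, `feature`, the seven
#'   normalised weights, `sum_of_weights` and a logical `tied` marking
#'   rows whose sum equals another feature's sum.
#' @export
rank_and_top_k <- function(wm, k = 20) {
  if (length(k) != 1L || !is.finite(k) || k != round(k) || k <= 0)
    stop("`k` must be a positive integer")
  if (k > nrow(wm)) stop("`k` exceeds the number of features")
  s <- sum_weights(wm)
  ord <- order(-s, wm$feature)
  ranking <- data.frame(rank = seq_along(ord),
                        feature = wm$feature[ord],
                        wm[ord, weighting_models()],
                        sum_of_weights = s[ord],
                        stringsAsFactors = FALSE)
  ranking$tied <- duplicated(ranking$sum_of_weights) |
    duplicated(ranking$sum_of_weights, fromLast = TRUE)
  rownames(ranking) <- NULL
  list(signature = ranking[seq_len(k), ], ranking = ranking)
}

#' Tissue-independence diagnostic of a ranking
#'
#' A signature is tissue-independent when the diet signal, not the
#' tissue of origin, drives the ranking — i.e. the categorical tissue
#' feature itself lands near the bottom. Reports the tissue feature's
#' rank and sum of weights and whether it falls in the bottom decile of
#' ranks; warns when it does not (diet effects confined to one tissue
#' produce exactly that failure).
#'
#' @param ranking the full `ranking` from [rank_and_top_k()].
#' @param tissue_feature name of the tissue feature (default
#'   `"tissue"`).
#' @return List with `tissue_rank`, `tissue_sum`, `n_features`,
#'   `tissue_in_bottom_decile`.
#' @export
tissue_independence_check <- function(ranking, tissue_feature = "tissue") {
  i <- match(tissue_feature, ranking$feature)
  if (is.na(i))
    stop("feature `", tissue_feature, "` not found in the ranking")
  n <- nrow(ranking)
  ok <- ranking$rank[i] / n >= 0.9
  if (!ok)
    warning("tissue feature ranks ", ranking$rank[i], " of ", n,
            ": the signature is not tissue-independent")
  list(tissue_rank = ranking$rank[i],
       tissue_sum = ranking$sum_of_weights[i],
       n_features = n,
       tissue_in_bottom_decile = ok)
}

#' Write a signature table
#'
#' Writes the ranked signature as a tab-separated table with the seven
#' normalised weights additionally rounded to one decimal for display
#' (sums stay computed from the unrounded weights, so a printed sum can
#' differ from the sum of the printed one-decimal weights by up to 0.1
#' per column).
#'
#' @param signature data.frame from [rank_and_top_k()] (`signature` or
#'   `ranking` element).
#' @param path output path.
#' @param digits decimals for the displayed weights.
#' @return Invisibly, `path`.
#' @export
write_signature <- function(signature, path, digits = 1) {
  out <- signature
  for (mcol in weighting_models()) out[[mcol]] <- round(out[[mcol]], digits)
  out$sum_of_weights <- round(out$sum_of_weights, digits)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
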