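fake_wm <- function(features, weights) {
  # weights: matrix n x 7 in weighting_models() order
  df <- data.frame(feature = features, stringsAsFactors = FALSE)
  for (j in seq_along(weighting_models()))
    df[[weighting_models()[j]]] <- weights[, j]
  structure(df, class = c("weight_matrix", "data.frame"))
}

test_that("sum of weights reproduces printed signature rows", {
  rows <- rbind(
    AC134224.2 = c(0.8, 0.5, 0.9, 0.9, 0.8, 0.9, 0.8),  # 5.6
    Plcg1      = c(0.6, 1.0, 0.8, 0.6, 0.7, 0.9, 0.6),  # 5.2
    Mcoln1     = c(0.6, 0.6, 1.0, 0.6, 0.9, 0.8, 0.6),  # 5.1
    C1qa       = c(0.6, 0.9, 0.8, 0.6, 0.7, 0.5, 0.5),  # 4.6
    tissue     = c(0.0, 0.0, 0.0, 0.0, 0.0, 0.7, 0.0))  # 0.7
  wm <- fake_wm(rownames(rows), rows)
  s <- sum_weights(wm)
  expect_equal(unname(s), c(5.6, 5.2, 5.1, 4.6, 0.7), tolerance = 1e-12)
  expect_equal(unname(sum_weights(fake_wm("z", matrix(0, 1, 7)))), 0)
  expect_error(sum_weights(wm[, -2]), "missing model")
})

test_that("sum of weights ignores model column order", {
  set.seed(2)
  w <- matrix(runif(21), 3, 7)
  wm <- fake_wm(c("a", "b", "c"), w)
  shuffled <- wm[, c("feature", sample(weighting_models()))]
  expect_equal(sum_weights(shuffled), sum_weights(wm))
})

test_that("ranking orders by sum with deterministic lexicographic ties", {
  w <- matrix(0, 3, 7)
  w[1, 1] <- 6.1 / 1  # encode sums via first model
  w[2, 1] <- 5.6
  w[3, 1] <- 0.7
  wm <- fake_wm(c("a", "b", "c"), w)
  res <- rank_and_top_k(wm, k = 2)
  expect_equal(res$signature$feature, c("a", "b"))
  expect_equal(res$ranking$rank, 1:3)
  expect_true(all(diff(res$ranking$sum_of_weights) <= 0))
  # exact ties resolved lexicographically and flagged
  wtie <- fake_wm(c("zz", "aa", "mm"), matrix(0.5, 3, 7))
  res <- rank_and_top_k(wtie, k = 3)
  expect_equal(res$ranking$feature, c("aa", "mm", "zz"))
  expect_true(all(res$ranking$tied))
  expect_error(rank_and_top_k(wm, k = 0), "positive")
  expect_error(rank_and_top_k(wm, k = 9), "exceeds")
})

test_that("every ranked sum lies in [0, 7] and ranks have no gaps", {
  d <- generate_counts(synthetic_config(n_genes = 80, seed = 3))
  mt <- assemble_mined_table(filter_low_expression(compute_fpkm(d$counts))$fpkm,
                             d$metadata)
  res <- rank_and_top_k(run_all_models(mt), k = 10)
  expect_equal(res$ranking$rank, seq_len(nrow(res$ranking)))
  expect_true(all(res$ranking$sum_of_weights >= 0 &
                    res$ranking$sum_of_weights <= 7))
  # stored sum equals the sum of the stored weights
  recomputed <- rowSums(res$ranking[, weighting_models()])
  expect_equal(unname(recomputed), res$ranking$sum_of_weights,
               tolerance = 1e-12)
})

test_that("tissue-independence diagnostic flags both regimes", {
  # diet effect everywhere but tissue-independent: tissue sinks
  d <- generate_counts(synthetic_config(n_genes = 150, frac_signature = 0.06,
                                        frac_tissue_dep = 0,
                                        effect_fold = 3, seed = 41))
  mt <- assemble_mined_table(filter_low_expression(compute_fpkm(d$counts))$fpkm,
                             d$metadata)
  res <- rank_and_top_k(run_all_models(mt), k = 10)
  diag <- tissue_independence_check(res$ranking)
  expect_true(diag$tissue_in_bottom_decile)
  expect_equal(diag$n_features, nrow(res$ranking))
  expect_error(tissue_independence_check(res$ranking, "no_such"),
               "not found")
})

test_that("a mid-ranked tissue feature triggers the warning path", {
  w <- matrix(0, 20, 7)
  w[, 1] <- seq(7, 0.5, length.out = 20)
  feats <- c(sprintf("g%02d", 1:10), "tissue", sprintf("g%02d", 11:19))
  res <- rank_and_top_k(fake_wm(feats, w), k = 5)
  expect_warning(diag <- tissue_independence_check(res$ranking),
                 "not tissue-independent")
  expect_false(diag$tissue_in_bottom_decile)
  expect_equal(diag$tissue_rank, 11)
})

test_that("diet effects confined to one tissue lift the tissue feature", {
  # adversarial design: tissues share baselines and every effect lives in
  # the hypothalamus, so Relief's nearest misses cross tissues and the
  # tissue attribute climbs off the very bottom of the ranking
  d <- generate_counts(synthetic_config(n_genes = 150, frac_signature = 0,
                                        frac_tissue_dep = 0,
                                        sd_log_tissue = 0, seed = 43))
  hypo_cr <- d$metadata$tissue == "hypothalamus" & d$metadata$diet == "CR"
  boosted <- d$counts$counts
  boosted[1:30, hypo_cr] <- round(boosted[1:30, hypo_cr] * 8)
  cm <- count_matrix(boosted, d$counts$gene_lengths)
  mt <- assemble_mined_table(filter_low_expression(compute_fpkm(cm))$fpkm,
                             d$metadata)
  wm <- run_all_models(mt)
  res <- rank_and_top_k(wm, k = 10)
  adv <- suppressWarnings(tissue_independence_check(res$ranking))
  # Relief now ranks tissue at the top of its column ...
  expect_equal(wm$relief[wm$feature == "tissue"], 1)
  # ... and the tissue feature is no longer at (or near) the very bottom
  expect_lt(adv$tissue_rank, adv$n_features - 5)
  # contrast: the same design with tissue-independent effects pins the
  # tissue feature to the last rank
  d2 <- generate_counts(synthetic_config(n_genes = 150,
                                         frac_signature = 0.06,
                                         frac_tissue_dep = 0,
                                         sd_log_tissue = 0,
                                         effect_fold = 3, seed = 43))
  mt2 <- assemble_mined_table(
    filter_low_expression(compute_fpkm(d2$counts))$fpkm, d2$metadata)
  res2 <- rank_and_top_k(run_all_models(mt2), k = 10)
  ind <- tissue_independence_check(res2$ranking)
  expect_gt(adv$n_features - adv$tissue_rank,
            ind$n_features - ind$tissue_rank)
})

test_that("signature files print one-decimal weights", {
  w <- matrix(c(0.84, 0.52, 0.91, 0.88, 0.77, 0.93, 0.79), 1, 7)
  wm <- fake_wm("geneA", w)
  res <- rank_and_top_k(wm, k = 1)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_signature(res$signature, path)
  out <- read.delim(path)
  expect_equal(out$info_gain_ratio, 0.8)
  expect_equal(out$sum_of_weights, round(sum(w), 1))
})
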