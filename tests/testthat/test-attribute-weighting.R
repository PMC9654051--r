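test_that("equal-frequency discretization is deterministic and tie-safe", {
  expect_error(discretize_equal_frequency(1:10, 1), "n_bins")
  b <- discretize_equal_frequency(1:40, 4)
  expect_equal(as.vector(table(b)), rep(10L, 4))
  expect_equal(discretize_equal_frequency(rep(3.2, 15), 5), rep(1L, 15))
  # 50% ties at one value: no empty bins, deterministic labels
  v <- c(rep(1, 10), 2, 3, 4, 5, 6, 7, 8, 9, 10, 11)
  b1 <- discretize_equal_frequency(v, 4)
  b2 <- discretize_equal_frequency(v, 4)
  expect_identical(b1, b2)
  expect_true(all(tabulate(b1) > 0))
  expect_lte(max(b1), 4)
  # all ties fall in one bin
  expect_equal(length(unique(b1[v == 1])), 1)
})

test_that("contingency tables equal a brute-force tally", {
  tissue <- factor(rep(c("hy", "am", "pi", "ad"), each = 10))
  diet <- factor(rep(rep(c("control", "CR"), each = 5), 4))
  ct <- contingency(tissue, diet)
  expect_true(all(ct == 5))
  expect_equal(dim(ct), c(4L, 2L))
  # perfectly separating binary feature gives a diagonal table
  f <- c(rep(0, 20), rep(1, 20))
  cl <- rep(c("a", "b"), each = 20)
  ct <- contingency(f, cl, n_bins = 2)
  expect_equal(as.vector(ct), c(20, 0, 0, 20))
  # numeric fixture vs independent tally
  set.seed(3)
  x <- rnorm(40)
  cl <- sample(c("a", "b"), 40, TRUE)
  ct <- contingency(x, cl, n_bins = 5)
  bins <- discretize_equal_frequency(x, 5)
  manual <- matrix(0, max(bins), 2)
  for (i in seq_along(x))
    manual[bins[i], (cl[i] == "b") + 1] <-
      manual[bins[i], (cl[i] == "b") + 1] + 1
  expect_equal(unclass(ct), manual, ignore_attr = TRUE)
  expect_error(contingency(1:5, 1:4), "lengths differ")
})

test_that("contingency weights reproduce closed forms", {
  perfect <- as.table(matrix(c(20, 0, 0, 20), 2, 2))
  expect_equal(weight_from_contingency(perfect, "info_gain"), 1)
  expect_equal(weight_from_contingency(perfect, "gini_index"), 0.5)
  expect_equal(weight_from_contingency(perfect, "chi_squared"), 40)
  expect_equal(weight_from_contingency(perfect, "info_gain_ratio"), 1)
  expect_equal(weight_from_contingency(perfect, "uncertainty"), 1)
  indep <- as.table(matrix(10, 2, 2))
  for (m in c("info_gain", "info_gain_ratio", "chi_squared",
              "gini_index", "uncertainty"))
    expect_equal(weight_from_contingency(indep, m), 0)
  # hand-derived: IG = H(1/2) - H(1/4) = 1 - 0.811278...
  skewed <- as.table(matrix(c(3, 1, 1, 3), 2, 2))
  expect_equal(weight_from_contingency(skewed, "info_gain"),
               1 - (-0.25 * log2(0.25) - 0.75 * log2(0.75)),
               tolerance = 1e-12)
  expect_error(weight_from_contingency(as.table(matrix(0, 2, 2)),
                                       "info_gain"), "empty")
})

test_that("contingency weights match the brute-force oracle on random tables", {
  set.seed(5)
  for (i in 1:50) {
    ct <- matrix(rpois(8, 4), 4, 2)
    if (sum(ct) == 0) next
    oracle <- oracle_contingency_weights(ct)
    for (m in names(oracle))
      expect_equal(weight_from_contingency(as.table(ct), m),
                   unname(oracle[m]), tolerance = 1e-12)
  }
})

test_that("contingency weights are invariant to label permutations", {
  set.seed(6)
  ct <- matrix(rpois(8, 5) + 1, 4, 2)
  for (m in c("info_gain", "info_gain_ratio", "chi_squared",
              "gini_index", "uncertainty")) {
    w <- weight_from_contingency(as.table(ct), m)
    expect_equal(weight_from_contingency(as.table(ct[sample(4), ]), m), w)
    expect_equal(weight_from_contingency(as.table(ct[, 2:1]), m), w)
  }
})

test_that("information-theoretic weights respect their bounds", {
  set.seed(8)
  for (i in 1:25) {
    ct <- matrix(rpois(8, 3), 4, 2)
    if (any(colSums(ct) == 0) || sum(ct) == 0) next
    ig <- weight_from_contingency(as.table(ct), "info_gain")
    expect_lte(ig, oracle_entropy(colSums(ct)) + 1e-12)
    u <- weight_from_contingency(as.table(ct), "uncertainty")
    expect_gte(u, -1e-12)
    expect_lte(u, 1 + 1e-12)
  }
})

test_that("rule weight is OneR accuracy above baseline", {
  cl <- rep(c("a", "b"), each = 20)
  # perfect separation on balanced classes: 1.0 - 0.5
  expect_equal(weight_rule(c(rep(0, 20), rep(1, 20)), cl, 2), 0.5)
  expect_equal(weight_rule(rep(1, 40), cl), 0)
  # 75% single-bin purity, balanced classes -> 0.25
  f <- c(rep(0, 20), rep(1, 20))
  cl2 <- c(rep("a", 15), rep("b", 5), rep("b", 15), rep("a", 5))
  expect_equal(weight_rule(f, cl2, 2), 0.75 - 0.5)
})

test_that("ReliefF matches the O(n^2) reference and orders relevance", {
  tab <- toy_mined_table(n_per_cell = 3, n_noise = 2, seed = 101)
  feats <- tab[, setdiff(names(tab), "diet")]
  w <- relief_weights(feats, tab$diet, k_neighbors = 2)
  ref <- oracle_relief(feats, tab$diet, k = 2)
  expect_equal(w, ref, tolerance = 1e-12)
  expect_gt(w["relevant"], max(w[c("noise1", "noise2")]))
  # constant feature scores 0
  feats$flat <- 1
  expect_equal(relief_weights(feats, tab$diet, k_neighbors = 2)[["flat"]], 0)
  # determinism of the full pass
  expect_identical(relief_weights(feats, tab$diet, 2),
                   relief_weights(feats, tab$diet, 2))
  expect_error(relief_weights(feats, tab$diet, k_neighbors = 10),
               "k_neighbors")
})

test_that("ReliefF reference agreement holds across random small tables", {
  for (s in 1:5) {
    set.seed(200 + s)
    n <- 16
    feats <- data.frame(a = rnorm(n), b = runif(n),
                        f = factor(sample(c("x", "y", "z"), n, TRUE)))
    cl <- factor(sample(c("c1", "c2"), n, TRUE, prob = c(0.5, 0.5)))
    if (min(table(cl)) < 4) next
    expect_equal(relief_weights(feats, cl, k_neighbors = 3),
                 oracle_relief(feats, cl, k = 3), tolerance = 1e-12)
  }
})

test_that("weight normalization maps to [0, 1] with degenerate warning", {
  expect_equal(unname(normalize_weights(c(2, 4, 6))), c(0, 0.5, 1))
  expect_warning(res <- normalize_weights(c(3, 3, 3)), "constant")
  expect_equal(unname(res), c(0, 0, 0))
  set.seed(9)
  w <- normalize_weights(rnorm(50))
  expect_equal(range(w), c(0, 1))
})

test_that("the seven-model ensemble scores a perfect separator at 1", {
  tab <- toy_mined_table(n_per_cell = 5, n_noise = 3, seed = 33)
  tab$relevant <- ifelse(tab$diet == "CR", 1, 0)  # exact indicator
  wm <- run_all_models(tab, n_bins = 2, relief_k = 3)
  expect_s3_class(wm, "weight_matrix")
  expect_equal(nrow(wm), 5)  # relevant + 3 noise + tissue
  norm <- as.matrix(wm[, weighting_models()])
  expect_true(all(norm >= 0 & norm <= 1))
  rel <- wm[wm$feature == "relevant", weighting_models()]
  expect_true(all(rel == 1))
})

test_that("ensemble output is deterministic and permutation degrades sums", {
  d <- generate_counts(synthetic_config(n_genes = 500, frac_signature = 0.02,
                                        frac_tissue_dep = 0,
                                        effect_fold = 3, seed = 55))
  mt <- assemble_mined_table(filter_low_expression(compute_fpkm(d$counts))$fpkm,
                             d$metadata)
  wm1 <- run_all_models(mt)
  wm2 <- run_all_models(mt)
  expect_identical(wm1, wm2)
  planted <- d$truth$gene_id[d$truth$class == "signature"]
  sums <- sum_weights(wm1)
  planted_sums <- sums[names(sums) %in% planted]
  # seeded class permutation: the null 95th percentile of sums falls
  # below the planted genes' sums from the unpermuted run
  set.seed(77)
  perm <- mt
  perm$diet <- perm$diet[sample(nrow(perm))]
  null_sums <- sum_weights(run_all_models(perm))
  expect_gt(min(planted_sums), quantile(null_sums, 0.95))
})
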