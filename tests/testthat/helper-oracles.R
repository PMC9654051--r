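# Independent brute-force references. Everything here is written as
# plainly (and slowly) as possible, with explicit loops over cells and
# samples, so it shares no code path with the package implementation.

oracle_entropy <- function(counts) {
  n <- sum(counts)
  h <- 0
  for (c_i in counts) {
    if (c_i > 0) {
      p <- c_i / n
      h <- h - p * (log(p) / log(2))
    }
  }
  h
}

oracle_gini <- function(counts) {
  n <- sum(counts)
  g <- 1
  for (c_i in counts) g <- g - (c_i / n)^2
  g
}

# all five contingency scores from first principles, looping over rows/cells
oracle_contingency_weights <- function(ct) {
  ct <- as.matrix(ct)
  n <- sum(ct)
  h_class <- oracle_entropy(colSums(ct))
  h_bins <- oracle_entropy(rowSums(ct))
  g_class <- oracle_gini(colSums(ct))
  cond_h <- 0
  cond_g <- 0
  for (b in seq_len(nrow(ct))) {
    nb <- sum(ct[b, ])
    if (nb > 0) {
      cond_h <- cond_h + (nb / n) * oracle_entropy(ct[b, ])
      cond_g <- cond_g + (nb / n) * oracle_gini(ct[b, ])
    }
  }
  ig <- h_class - cond_h
  chi <- 0
  for (b in seq_len(nrow(ct))) {
    for (j in seq_len(ncol(ct))) {
      e <- sum(ct[b, ]) * sum(ct[, j]) / n
      if (e > 0) chi <- chi + (ct[b, j] - e)^2 / e
    }
  }
  c(info_gain = ig,
    info_gain_ratio = if (h_bins == 0) 0 else ig / h_bins,
    uncertainty = if (h_class + h_bins == 0) 0 else
      2 * ig / (h_class + h_bins),
    gini_index = g_class - cond_g,
    chi_squared = chi)
}

# O(n^2) ReliefF reference: full pass, k nearest hits/misses by explicit
# sorting, Manhattan distance over min-max scaled numerics + 0/1 factors.
oracle_relief <- function(x, class_labels, k) {
  n <- nrow(x)
  p <- ncol(x)
  cl <- as.character(class_labels)
  z <- matrix(0, n, p)
  is_num <- logical(p)
  for (j in seq_len(p)) {
    col <- x[[j]]
    if (is.numeric(col)) {
      is_num[j] <- TRUE
      lo <- min(col); hi <- max(col)
      z[, j] <- if (hi > lo) (col - lo) / (hi - lo) else 0
    }
  }
  diff_f <- function(j, a, b) {
    if (is_num[j]) abs(z[a, j] - z[b, j])
    else as.numeric(!identical(as.character(x[[j]][a]),
                               as.character(x[[j]][b])))
  }
  dist_ab <- function(a, b) {
    s <- 0
    for (j in seq_len(p)) s <- s + diff_f(j, a, b)
    s
  }
  w <- numeric(p)
  for (i in seq_len(n)) {
    d_i <- sapply(seq_len(n), function(b) dist_ab(i, b))
    hits <- setdiff(which(cl == cl[i]), i)
    misses <- which(cl != cl[i])
    hits <- hits[order(d_i[hits])][seq_len(k)]
    misses <- misses[order(d_i[misses])][seq_len(k)]
    for (j in seq_len(p)) {
      for (m in misses) w[j] <- w[j] + diff_f(j, i, m) / (k * n)
      for (h in hits) w[j] <- w[j] - diff_f(j, i, h) / (k * n)
    }
  }
  names(w) <- names(x)
  w
}

# BH step-up computed literally from the definition
oracle_bh <- function(p) {
  m <- length(p)
  ord <- order(p)
  q <- numeric(m)
  running_min <- 1
  for (i in rev(seq_len(m))) {
    val <- p[ord[i]] * m / i
    running_min <- min(running_min, val)
    q[ord[i]] <- running_min
  }
  q
}

# small helper: a balanced mined table with one planted diet feature,
# one tissue-like factor and noise features
toy_mined_table <- function(n_per_cell = 5, n_noise = 3, seed = 11) {
  set.seed(seed)
  tissues <- c("t1", "t2")
  md <- expand.grid(rep = seq_len(n_per_cell), diet = c("control", "CR"),
                    tissue = tissues, stringsAsFactors = FALSE)
  n <- nrow(md)
  tab <- data.frame(relevant = ifelse(md$diet == "CR", 1, 0) +
                      rnorm(n, 0, 0.05))
  for (j in seq_len(n_noise)) tab[[paste0("noise", j)]] <- rnorm(n)
  tab$tissue <- factor(md$tissue)
  tab$diet <- factor(md$diet, levels = c("control", "CR"))
  structure(tab, feature_cols = setdiff(names(tab), "diet"),
            class = c("mined_table", "data.frame"))
}

# enumerate all non-degenerate r x 2 tables with cells in 0..max_cell
enumerate_tables <- function(nrow_ct, max_cell) {
  cells <- expand.grid(rep(list(0:max_cell), nrow_ct * 2))
  cells <- cells[rowSums(cells) > 0, , drop = FALSE]
  lapply(seq_len(nrow(cells)), function(i)
    matrix(as.numeric(cells[i, ]), nrow = nrow_ct))
}
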