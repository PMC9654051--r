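#' Median-of-ratios size factors
#'
#' DESeq-style normalisation: each sample's factor is the median of its
#' count ratios to the per-gene geometric-mean reference, computed over
#' genes with nonzero counts in every sample. When no such gene exists
#' the upper-quartile of nonzero counts is used instead (scaled to
#' geometric mean 1).
#'
#' @param cm a [count_matrix()] or a counts matrix.
#' @return Named positive numeric vector, one factor per sample.
#' @export
size_factors <- function(cm) {
  m <- if (inherits(cm, "count_matrix")) cm$counts else cm
  if (all(m == 0)) stop("cannot normalise an all-zero count matrix")
  everywhere <- rowSums(m == 0) == 0
  if (any(everywhere)) {
    logref <- rowMeans(log(m[everywhere, , drop = FALSE]))
    sf <- apply(log(m[everywhere, , drop = FALSE]), 2,
                function(col) exp(stats::median(col - logref)))
  } else {
    uq <- apply(m, 2, function(col) {
      nz <- col[col > 0]
      if (!length(nz)) stop("sample with all-zero counts")
      stats::quantile(nz, 0.75, names = FALSE)
    })
    sf <- uq / exp(mean(log(uq)))
  }
  stats::setNames(sf, colnames(m))
}

#' Method-of-moments NB dispersion for one gene
#'
#' Estimates the negative-binomial dispersion phi in
#' `Var = mu + phi * mu^2` from size-factor-normalised counts, pooling the
#' within-group sample variances so planted group differences do not
#' inflate the estimate: `phi = max(0, (s2 - m) / m^2)` with `s2` the
#' mean within-group variance and `m` the overall normalised mean.
#'
#' @param counts integer vector of raw counts for one gene.
#' @param groups factor of group labels (two groups expected).
#' @param factors per-sample size factors (default all 1).
#' @return Non-negative dispersion estimate; `NA` for an all-zero gene.
#' @export
estimate_dispersion <- function(counts, groups,
                                factors = rep(1, length(counts))) {
  if (length(counts) != length(groups))
    stop("`counts` and `groups` lengths differ")
  if (all(counts == 0)) return(NA_real_)
  y <- counts / factors
  if (any(tabulate(factor(groups)) < 2L))
    stop("need at least 2 samples per group")
  s2 <- mean(tapply(y, groups, stats::var))
  m <- mean(y)
  max(0, (s2 - m) / m^2)
}

#' Two-group negative-binomial Wald test
#'
#' Fits the two-group NB generalised linear model with log link and
#' log-size-factor offsets, `log mu = beta0 + beta * diet + log sf`, at a
#' fixed plug-in dispersion, and tests `beta = 0` with a Wald statistic.
#' Because the dispersion is a small-sample plug-in estimate, the p-value
#' uses the quasi-likelihood convention (Pearson-scaled standard error, t
#' reference with residual degrees of freedom) rather than a plain normal
#' reference, which is markedly anticonservative at n = 5 per group.
#' `phi = 0` reduces to a Poisson-based fit. When one group has all-zero
#' counts the GLM estimate diverges, so the log-ratio and its standard
#' error fall back to a 0.5 pseudo-count on the normalised group means
#' (delta-method SE, same t reference); such genes are flagged.
#'
#' @param counts integer count vector for one gene.
#' @param design factor with two levels; the second level is the
#'   numerator of the ratio (use levels control, CR).
#' @param factors per-sample size factors.
#' @param phi NB dispersion (from [estimate_dispersion()]).
#' @return List with `log_ratio` (natural log), `se`, `wald_p`, `ratio`
#'   and `flag` (`"ok"` or `"pseudocount"`).
#' @export
nb_wald_test <- function(counts, design, factors = rep(1, length(counts)),
                         phi = 0) {
  design <- droplevels(factor(design))
  if (nlevels(design) != 2L)
    stop("`design` must have exactly two groups")
  if (is.na(phi)) stop("dispersion is NA (all-zero gene?)")
  y <- counts / factors
  gmean <- tapply(y, design, mean)
  n_g <- tabulate(design)
  df_r <- length(counts) - 2L
  if (any(gmean == 0)) {
    m <- gmean + 0.5
    log_ratio <- log(m[2] / m[1])
    se <- sqrt(sum((m + phi * m^2) / (n_g * m^2)))
    z <- log_ratio / se
    return(list(log_ratio = unname(log_ratio), se = unname(se),
                wald_p = 2 * stats::pt(-abs(z), df = df_r),
                ratio = unname(m[2] / m[1]), flag = "pseudocount"))
  }
  fam <- if (phi < 1e-10) stats::poisson()
         else MASS::negative.binomial(theta = 1 / phi)
  fit <- suppressWarnings(
    stats::glm(counts ~ design + offset(log(factors)), family = fam))
  # force the quasi-likelihood convention (Pearson-estimated dispersion,
  # t reference) regardless of the family's declared dispersion
  disp <- sum(stats::residuals(fit, type = "pearson")^2) / df_r
  co <- summary(fit, dispersion = disp)$coefficients
  log_ratio <- co[2, 1]
  se <- co[2, 2]
  z <- log_ratio / se
  list(log_ratio = log_ratio, se = se,
       wald_p = 2 * stats::pt(-abs(z), df = df_r),
       ratio = unname(gmean[2] / gmean[1]), flag = "ok")
}

#' Signed fold change
#'
#' Reports a CR/control expression ratio `r` in the signed convention
#' used for differential-expression tables: `r` itself when `r >= 1`
#' (upregulation) and `-1/r` when `r < 1`, so a halving becomes -2 and
#' negative values read as downregulation under calorie restriction.
#'
#' @param ratio positive expression ratio(s).
#' @return Signed fold change(s) with `|signed_fc| >= 1`.
#' @examples
#' signed_fold_change(c(2, 0.5, 1))  #  2 -2  1
#' @export
signed_fold_change <- function(ratio) {
  if (any(!is.finite(ratio)) || any(ratio <= 0))
    stop("`ratio` must be positive and finite")
  ifelse(ratio >= 1, ratio, -1 / ratio)
}

#' Benjamini-Hochberg q-values
#'
#' Step-up false-discovery-rate adjustment (via [stats::p.adjust()]),
#' with input validation.
#'
#' @param pvalues numeric vector of p-values in \[0, 1\].
#' @return q-values in the original order.
#' @export
bh_fdr <- function(pvalues) {
  if (any(!is.finite(pvalues)) || any(pvalues < 0) || any(pvalues > 1))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(pvalues, method = "BH")
}

#' Per-tissue differential expression between CR and control
#'
#' For each tissue, normalises the tissue's libraries with
#' [size_factors()], estimates a per-gene method-of-moments dispersion,
#' runs the NB Wald test CR vs control, and adjusts p-values with
#' [bh_fdr()] within the tissue. Genes with zero counts in every library
#' of a tissue are reported as `not_expressed` there.
#'
#' @param cm a [count_matrix()].
#' @param metadata sample metadata (validated with [validate_metadata()]).
#' @param shared_dispersion if `TRUE`, use the median per-gene dispersion
#'   of the tissue for every gene instead of gene-wise estimates.
#' @return A data.frame with one row per gene x tissue: `gene_id`,
#'   `tissue`, `ratio`, `signed_fc`, `wald_p`, `fdr_q`, `status`
#'   (tested / not_expressed), `flag`.
#' @export
run_diffexp <- function(cm, metadata, shared_dispersion = FALSE) {
  metadata <- validate_metadata(cm, metadata)
  res <- lapply(levels(metadata$tissue), function(tt) {
    sel <- metadata$tissue == tt
    m <- cm$counts[, metadata$sample_id[sel], drop = FALSE]
    diet <- droplevels(metadata$diet[sel])
    sf <- size_factors(m)
    expressed <- rowSums(m) > 0
    out <- data.frame(gene_id = rownames(m), tissue = tt,
                      ratio = NA_real_, signed_fc = NA_real_,
                      wald_p = NA_real_, fdr_q = NA_real_,
                      status = ifelse(expressed, "tested", "not_expressed"),
                      flag = NA_character_, stringsAsFactors = FALSE)
    phis <- vapply(which(expressed), function(g)
      estimate_dispersion(m[g, ], diet, sf), numeric(1))
    if (shared_dispersion) phis[] <- stats::median(phis)
    k <- 0L
    for (g in which(expressed)) {
      k <- k + 1L
      w <- nb_wald_test(m[g, ], diet, sf, phis[k])
      out$ratio[g] <- w$ratio
      out$signed_fc[g] <- signed_fold_change(w$ratio)
      out$wald_p[g] <- w$wald_p
      out$flag[g] <- w$flag
    }
    out$fdr_q[expressed] <- bh_fdr(out$wald_p[expressed])
    out
  })
  do.call(rbind, res)
}

#' Wide differential-expression table with significance stars
#'
#' Casts the long output of [run_diffexp()] into one row per gene with a
#' signed-fold-change column per tissue, annotated with the conventional
#' significance stars (p <= 0.05 `*`, <= 0.01 `**`, <= 0.001 `***`) and
#' `NE` for genes not expressed in a tissue.
#'
#' @param de output of [run_diffexp()].
#' @param alpha star thresholds, largest first.
#' @param use_fdr annotate stars from `fdr_q` instead of raw `wald_p`.
#' @return data.frame `gene_id` plus one character column per tissue.
#' @export
de_wide_table <- function(de, alpha = c(0.05, 0.01, 0.001),
                          use_fdr = FALSE) {
  p <- if (use_fdr) de$fdr_q else de$wald_p
  stars <- vapply(p, function(pp) {
    if (is.na(pp)) "" else strrep("*", sum(pp <= alpha))
  }, character(1))
  cell <- ifelse(de$status == "not_expressed", "NE",
                 trimws(paste(sprintf("%.2f", de$signed_fc), stars)))
  wide <- stats::reshape(
    data.frame(gene_id = de$gene_id, tissue = de$tissue, cell = cell,
               stringsAsFactors = FALSE),
    idvar = "gene_id", timevar = "tissue", direction = "wide")
  names(wide) <- sub("^cell\\.", "", names(wide))
  rownames(wide) <- NULL
  wide
}
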