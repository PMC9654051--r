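#' Configuration for the synthetic RNA-seq generator
#'
#' Describes a balanced two-diet (control vs calorie restriction) by
#' four-tissue RNA-seq experiment with negative-binomial counts, planted
#' diet effects and known ground truth. Defaults emulate the study design
#' the package targets: 5 animals per diet per tissue (40 libraries in
#' total) across hypothalamus, amygdala, pituitary and adrenal glands.
#'
#' Genes fall in three classes. *Signature* genes carry a
#' tissue-independent diet effect: one multiplicative fold (up or down,
#' one sign per gene) applied in every tissue. *Tissue-dependent* genes
#' carry an independent effect direction per tissue, mimicking genes such
#' as growth hormone that respond up in one tissue and down in others.
#' The remaining *null* genes have fold change 1 everywhere.
#'
#' @param n_genes number of genes.
#' @param n_per_cell samples per diet x tissue cell (default 5, the study
#'   design).
#' @param tissues character vector of tissue labels.
#' @param mean_log_baseline,sd_log_baseline log-normal parameters of the
#'   per-gene baseline expression rate (reads per kb at unit library
#'   scale).
#' @param sd_log_tissue log-sd of the per-gene, per-tissue baseline
#'   multiplier; 0 gives identical baselines across tissues.
#' @param dispersion negative-binomial dispersion phi (Var = mu + phi*mu^2);
#'   0 gives Poisson counts.
#' @param frac_signature fraction of genes with a tissue-independent diet
#'   effect.
#' @param frac_tissue_dep fraction of genes with a tissue-dependent diet
#'   effect.
#' @param effect_fold multiplicative diet effect (> 0); planted genes get
#'   this fold (or its reciprocal) in CR relative to control.
#' @param plant_min_fpkm planted classes are assigned only to genes whose
#'   expected pooled mean FPKM is at least this value (conservatively
#'   assuming the gene is down-regulated), because the emulated design
#'   mines the signature from the post-filter expressed gene set — an
#'   effect planted on an unexpressed gene is unrecoverable by
#'   construction. Set 0 to plant on arbitrary genes.
#' @param gene_length_range bp interval gene lengths are drawn from
#'   (uniform).
#' @param depth expected total fragments per library; the per-gene rates
#'   are scaled so the average library has this many counts. FPKM values
#'   are depth-invariant, but count noise is not: realistic depths keep
#'   the NB dispersion, not shot noise, as the dominant variance source.
#' @param libsize_sdlog log-sd of per-sample library size factors
#'   (log-normal, mean log 0) so normalisation is exercised non-trivially.
#' @param seed integer seed; identical configurations give bit-identical
#'   data.
#' @return A validated list of class `synthetic_config`.
#' @seealso [generate_counts()]
#' @export
synthetic_config <- function(n_genes = 2000,
                             n_per_cell = 5,
                             tissues = c("hypothalamus", "amygdala",
                                         "pituitary", "adrenal"),
                             mean_log_baseline = 1,
                             sd_log_baseline = 1.5,
                             sd_log_tissue = 0.5,
                             dispersion = 0.3,
                             frac_signature = 0.005,
                             frac_tissue_dep = 0.01,
                             effect_fold = 2,
                             gene_length_range = c(500, 5000),
                             plant_min_fpkm = 5,
                             depth = 2e6,
                             libsize_sdlog = 0.1,
                             seed = 1) {
  cfg <- list(n_genes = n_genes, n_per_cell = n_per_cell, tissues = tissues,
              mean_log_baseline = mean_log_baseline,
              sd_log_baseline = sd_log_baseline,
              sd_log_tissue = sd_log_tissue,
              dispersion = dispersion, frac_signature = frac_signature,
              frac_tissue_dep = frac_tissue_dep, effect_fold = effect_fold,
              gene_length_range = gene_length_range,
              plant_min_fpkm = plant_min_fpkm, depth = depth,
              libsize_sdlog = libsize_sdlog, seed = seed)
  for (nm in c("n_genes", "n_per_cell", "seed")) {
    v <- cfg[[nm]]
    if (length(v) != 1L || !is.finite(v) || v != round(v))
      stop("`", nm, "` must be a single integer")
  }
  if (cfg$n_genes < 1 || cfg$n_per_cell < 1)
    stop("`n_genes` and `n_per_cell` must be positive")
  if (length(cfg$tissues) < 1 || anyDuplicated(cfg$tissues))
    stop("`tissues` must be distinct labels")
  for (nm in c("sd_log_baseline", "sd_log_tissue", "dispersion",
               "frac_signature", "frac_tissue_dep", "libsize_sdlog",
               "plant_min_fpkm")) {
    v <- cfg[[nm]]
    if (length(v) != 1L || !is.finite(v) || v < 0)
      stop("`", nm, "` must be a single non-negative number")
  }
  if (cfg$frac_signature + cfg$frac_tissue_dep > 1)
    stop("frac_signature + frac_tissue_dep must not exceed 1")
  if (!is.finite(cfg$effect_fold) || cfg$effect_fold <= 0)
    stop("`effect_fold` must be > 0")
  if (length(cfg$depth) != 1L || !is.finite(cfg$depth) || cfg$depth <= 0)
    stop("`depth` must be a single positive number")
  if (length(cfg$gene_length_range) != 2L ||
      any(cfg$gene_length_range <= 0) ||
      diff(cfg$gene_length_range) < 0)
    stop("`gene_length_range` must be an increasing positive bp interval")
  structure(cfg, class = "synthetic_config")
}

#' Generate a synthetic count matrix with known planted truth
#'
#' Draws a negative-binomial genes x samples count matrix under the design
#' described by a [synthetic_config()]. The mean model is
#' `mu(g, s) = q_g * t(g, tissue_s) * (L_g / 1000) * f(g, tissue_s, diet_s)
#' * size_s`, where `q_g` is the log-normal per-gene baseline rate,
#' `t(g, tissue)` a log-normal tissue multiplier, `L_g` the gene length in
#' bp, `f` the planted diet fold (1 for control samples and for null
#' genes) and `size_s` a log-normal library size factor. Counts are
#' NB(mu, phi) with `Var = mu + phi * mu^2` (Poisson if `phi = 0`).
#'
#' @param config a [synthetic_config()].
#' @return A list of class `synthetic_dataset` with elements:
#'   \describe{
#'     \item{counts}{a [count_matrix()] (genes x samples, with lengths);}
#'     \item{metadata}{data.frame `sample_id`, `diet`, `tissue`;}
#'     \item{truth}{data.frame with `gene_id`, `class` (null / signature /
#'       tissue_dependent) and one `fold_<tissue>` column per tissue
#'       giving the true CR/control mean ratio;}
#'     \item{size_factors}{the simulated per-sample library size factors;}
#'     \item{mu}{the expected count matrix the draws came from (for
#'       convergence diagnostics);}
#'     \item{config}{the configuration used.}
#'   }
#'   The same configuration (including seed) returns bit-identical output.
#' @examples
#' d <- generate_counts(synthetic_config(n_genes = 50, seed = 7))
#' table(d$truth$class)
#' @export
generate_counts <- function(config) {
  if (!inherits(config, "synthetic_config"))
    stop("`config` must come from synthetic_config()")
  cfg <- config
  n_t <- length(cfg$tissues)
  n_samp <- 2L * cfg$n_per_cell * n_t
  gene_ids <- sprintf("gene%05d", seq_len(cfg$n_genes))

  set.seed(cfg$seed)
  lengths_bp <- round(stats::runif(cfg$n_genes, cfg$gene_length_range[1],
                                   cfg$gene_length_range[2]))
  q <- stats::rlnorm(cfg$n_genes, cfg$mean_log_baseline, cfg$sd_log_baseline)
  tissue_mult <- matrix(stats::rlnorm(cfg$n_genes * n_t, 0,
                                      cfg$sd_log_tissue),
                        cfg$n_genes, n_t,
                        dimnames = list(gene_ids, cfg$tissues))

  n_sig <- round(cfg$frac_signature * cfg$n_genes)
  n_dep <- round(cfg$frac_tissue_dep * cfg$n_genes)
  if (n_sig + n_dep > cfg$n_genes) n_dep <- cfg$n_genes - n_sig

  # planted classes go to expressed genes: expected pooled mean FPKM
  # (conservatively treating the gene as down-regulated) must clear
  # plant_min_fpkm; fall back to the highest-expressed genes if needed
  exp_fpkm <- q * 1e6 / sum(q * lengths_bp / 1000)
  pooled <- exp_fpkm * (1 + 1 / cfg$effect_fold) / 2
  eligible <- which(pooled >= cfg$plant_min_fpkm)
  n_plant <- n_sig + n_dep
  if (length(eligible) < n_plant)
    eligible <- order(pooled, decreasing = TRUE)[seq_len(n_plant)]
  planted <- if (n_plant > 0) sort(sample(eligible, n_plant)) else integer(0)

  cls <- rep("null", cfg$n_genes)
  sig_idx <- planted[seq_len(n_sig)]
  dep_idx <- planted[n_sig + seq_len(n_dep)]
  cls[sig_idx] <- "signature"
  cls[dep_idx] <- "tissue_dependent"

  # true CR/control fold per gene and tissue; one sign per signature gene,
  # independent signs per tissue for tissue-dependent genes
  fold <- matrix(1, cfg$n_genes, n_t,
                 dimnames = list(gene_ids, cfg$tissues))
  if (n_sig > 0) {
    sgn <- sample(c(1, -1), n_sig, replace = TRUE)
    fold[sig_idx, ] <- cfg$effect_fold^sgn
  }
  if (n_dep > 0) {
    sgn <- matrix(sample(c(1, -1), n_dep * n_t, replace = TRUE), n_dep, n_t)
    fold[dep_idx, ] <- cfg$effect_fold^sgn
  }

  metadata <- expand.grid(rep = seq_len(cfg$n_per_cell),
                          diet = c("control", "CR"),
                          tissue = cfg$tissues,
                          KEEP.OUT.ATTRS = FALSE,
                          stringsAsFactors = FALSE)
  metadata$sample_id <- sprintf("%s_%s_%d",
                                abbreviate(metadata$tissue, 4),
                                metadata$diet, metadata$rep)
  metadata <- metadata[, c("sample_id", "diet", "tissue")]

  size_fac <- stats::rlnorm(n_samp, 0, cfg$libsize_sdlog)
  names(size_fac) <- metadata$sample_id

  t_idx <- match(metadata$tissue, cfg$tissues)
  diet_mult <- ifelse(rep(metadata$diet == "CR", each = cfg$n_genes),
                      fold[, t_idx], 1)
  rate <- q * tissue_mult[, t_idx] * (lengths_bp / 1000) * diet_mult
  # scale rates so the average library carries `depth` fragments
  mu <- rate * (cfg$depth * n_samp / sum(rate)) *
    rep(size_fac, each = cfg$n_genes)
  counts <- if (cfg$dispersion > 0) {
    stats::rnbinom(length(mu), mu = mu, size = 1 / cfg$dispersion)
  } else {
    stats::rpois(length(mu), mu)
  }
  counts <- matrix(counts, cfg$n_genes, n_samp,
                   dimnames = list(gene_ids, metadata$sample_id))

  truth <- data.frame(gene_id = gene_ids, class = cls,
                      stringsAsFactors = FALSE)
  for (tt in cfg$tissues) truth[[paste0("fold_", tt)]] <- fold[, tt]

  structure(list(counts = count_matrix(counts,
                                       stats::setNames(lengths_bp, gene_ids)),
                 metadata = metadata, truth = truth,
                 size_factors = size_fac,
                 mu = matrix(mu, cfg$n_genes, n_samp,
                             dimnames = dimnames(counts)),
                 config = cfg),
            class = "synthetic_dataset")
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat("synthetic_dataset:", nrow(x$counts$counts), "genes,",
      ncol(x$counts$counts), "samples (",
      length(x$config$tissues), "tissues x 2 diets x",
      x$config$n_per_cell, "reps )\n")
  print(table(gene_class = x$truth$class))
  invisible(x)
}

#' Generate seeded posterior draws for effect reporting
#'
#' Produces a reproducible vector of normal posterior draws, used as
#' fixtures for the posterior-summary (SEXIT-style) reporting functions,
#' which consume draw vectors rather than fitting models themselves.
#'
#' @param location,scale normal mean and standard deviation (`scale > 0`).
#' @param n_draws number of draws (at least 2).
#' @param seed integer seed.
#' @return Numeric vector of length `n_draws`.
#' @examples
#' d <- generate_posterior_draws(-95.9, 40, 4000, seed = 1)
#' median(d)
#' @export
generate_posterior_draws <- function(location, scale, n_draws, seed) {
  if (length(scale) != 1L || !is.finite(scale) || scale <= 0)
    stop("`scale` must be a single positive number")
  if (length(n_draws) != 1L || !is.finite(n_draws) ||
      n_draws != round(n_draws) || n_draws < 2)
    stop("`n_draws` must be an integer >= 2")
  set.seed(seed)
  stats::rnorm(n_draws, location, scale)
}

#' Write a synthetic dataset to plain-text files
#'
#' Writes counts and metadata as tab-separated files and the ground truth
#' as JSON, in the formats read back by [read_counts()] and
#' [read_metadata()].
#'
#' @param dataset a `synthetic_dataset` from [generate_counts()].
#' @param dir output directory (created if needed).
#' @return Invisibly, the named vector of file paths written.
#' @export
write_synthetic_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "synthetic_dataset"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(counts = file.path(dir, "counts.tsv"),
             metadata = file.path(dir, "metadata.tsv"),
             truth = file.path(dir, "truth.json"))
  write_counts(dataset$counts, paths[["counts"]])
  write_metadata(dataset$metadata, paths[["metadata"]])
  jsonlite::write_json(dataset$truth, paths[["truth"]], digits = NA)
  invisible(paths)
}
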