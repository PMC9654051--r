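#' Pipeline configuration
#'
#' Validated configuration for [run_pipeline()]. Unknown keys are
#' rejected so typos fail fast, before any stage runs.
#'
#' @param out_dir output directory for all artifacts.
#' @param seed master seed; each stage derives its own stream from it by
#'   stage name, so toggling one stage does not perturb another.
#' @param simulate if `TRUE` generate inputs with [generate_counts()];
#'   otherwise read `counts_path`/`metadata_path`.
#' @param counts_path,metadata_path input files when `simulate = FALSE`.
#' @param n_genes,n_per_cell,effect_fold,frac_signature,frac_tissue_dep
#'   generator settings (see [synthetic_config()]).
#' @param fpkm_threshold mean-FPKM filter cutoff (default 5).
#' @param n_bins,relief_k attribute-weighting settings.
#' @param top_k signature size (default 20).
#' @param top_n_multivariate genes in the fold-change matrix (default
#'   40).
#' @param linkage clustering linkage (default complete).
#' @param stages character vector of stages to run, a subset of
#'   `c("simulate", "fpkm", "de", "weights", "signature",
#'   "multivariate")` in that order.
#' @param ... rejected; present so unknown keys raise an error.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir = "crsignature_out", seed = 1,
                            simulate = TRUE, counts_path = NULL,
                            metadata_path = NULL, n_genes = 500,
                            n_per_cell = 5, effect_fold = 2,
                            frac_signature = 0.01, frac_tissue_dep = 0.01,
                            fpkm_threshold = 5, n_bins = 5, relief_k = 5,
                            top_k = 20, top_n_multivariate = 40,
                            linkage = "complete",
                            stages = c("simulate", "fpkm", "de", "weights",
                                       "signature", "multivariate"), ...) {
  extra <- list(...)
  if (length(extra))
    stop("unknown configuration key(s): ",
         paste(names(extra), collapse = ", "))
  known <- c("simulate", "fpkm", "de", "weights", "signature",
             "multivariate")
  bad <- setdiff(stages, known)
  if (length(bad))
    stop("unknown stage(s): ", paste(bad, collapse = ", "))
  if (!simulate && !("simulate" %in% stages) &&
      (is.null(counts_path) || is.null(metadata_path)))
    stop("without simulation, `counts_path` and `metadata_path` are required")
  structure(list(out_dir = out_dir, seed = seed, simulate = simulate,
                 counts_path = counts_path, metadata_path = metadata_path,
                 n_genes = n_genes, n_per_cell = n_per_cell,
                 effect_fold = effect_fold,
                 frac_signature = frac_signature,
                 frac_tissue_dep = frac_tissue_dep,
                 fpkm_threshold = fpkm_threshold, n_bins = n_bins,
                 relief_k = relief_k, top_k = top_k,
                 top_n_multivariate = top_n_multivariate,
                 linkage = linkage,
                 stages = known[known %in% stages]),
            class = "pipeline_config")
}

# deterministic per-stage seed derived from the master seed and stage name
stage_seed <- function(master, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  (as.integer(master) + h * 7919L) %% 2147483647L
}

#' Run the signature-discovery pipeline end to end
#'
#' Executes the enabled stages in dependency order: simulate (or read)
#' counts, FPKM + low-expression filter, per-tissue differential
#' expression, the seven-model attribute weighting, sum-of-weights
#' signature with tissue-independence diagnostic, and fold-change
#' PCA/clustering. Every output is written under `config$out_dir`
#' together with a resolved copy of the configuration, a plain-text log
#' and a checksum manifest; the same configuration and seed reproduce
#' identical checksums.
#'
#' @param config a [pipeline_config()].
#' @return Invisibly, a list with `manifest` (data.frame `file`, `md5`),
#'   `results` (in-memory stage outputs) and `log_path`.
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "pipeline_config"))
    stop("`config` must come from pipeline_config()")
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(config$out_dir, "pipeline.log")
  logf <- function(...) cat(sprintf(...), "\n", sep = "",
                            file = log_path, append = TRUE)
  cat(sprintf("crsignature %s | master seed %d\n",
              as.character(utils::packageVersion("crsignature")),
              config$seed),
      file = log_path)
  cfg_copy <- unclass(config)
  # provenance copy; not in the manifest because it records out_dir,
  # whose checksum would differ between otherwise identical runs
  jsonlite::write_json(cfg_copy[!vapply(cfg_copy, is.null, logical(1))],
                       file.path(config$out_dir, "config.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  outputs <- character(0)
  results <- list()
  stage <- "none"
  ok <- TRUE
  tryCatch({
    if ("simulate" %in% config$stages || config$simulate) {
      stage <- "simulate"
      logf("stage simulate (seed %d)", stage_seed(config$seed, stage))
      sim <- generate_counts(synthetic_config(
        n_genes = config$n_genes, n_per_cell = config$n_per_cell,
        effect_fold = config$effect_fold,
        frac_signature = config$frac_signature,
        frac_tissue_dep = config$frac_tissue_dep,
        seed = stage_seed(config$seed, stage)))
      write_synthetic_dataset(sim, config$out_dir)
      outputs <- c(outputs, "counts.tsv", "metadata.tsv", "truth.json")
      cm <- sim$counts; metadata <- sim$metadata
      results$simulate <- sim
    } else {
      cm <- read_counts(config$counts_path)
      metadata <- read_metadata(config$metadata_path)
    }
    metadata <- validate_metadata(cm, metadata)

    if ("fpkm" %in% config$stages) {
      stage <- "fpkm"
      logf("stage fpkm (threshold %g)", config$fpkm_threshold)
      fpkm <- compute_fpkm(cm)
      filt <- filter_low_expression(fpkm, config$fpkm_threshold)
      mined <- assemble_mined_table(filt$fpkm, metadata)
      utils::write.table(
        data.frame(gene_id = rownames(filt$fpkm),
                   round(filt$fpkm, 4), check.names = FALSE),
        file.path(config$out_dir, "fpkm_filtered.tsv"), sep = "\t",
        quote = FALSE, row.names = FALSE)
      jsonlite::write_json(list(threshold = config$fpkm_threshold,
                                removed = filt$removed),
                           file.path(config$out_dir, "filtered_genes.json"),
                           auto_unbox = TRUE, digits = NA)
      outputs <- c(outputs, "fpkm_filtered.tsv", "filtered_genes.json")
      logf("  kept %d of %d genes", nrow(filt$fpkm), nrow(fpkm))
      results$fpkm <- filt
      results$mined_table <- mined
    }

    if ("de" %in% config$stages) {
      stage <- "de"
      logf("stage de")
      de <- run_diffexp(cm, metadata)
      utils::write.table(de, file.path(config$out_dir, "diffexp_long.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      utils::write.table(de_wide_table(de),
                         file.path(config$out_dir, "diffexp_wide.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      outputs <- c(outputs, "diffexp_long.tsv", "diffexp_wide.tsv")
      results$de <- de
    }

    if ("weights" %in% config$stages) {
      stage <- "weights"
      if (is.null(results$mined_table))
        stop("the weights stage needs the fpkm stage")
      logf("stage weights (seed %d)", stage_seed(config$seed, stage))
      wm <- run_all_models(results$mined_table, n_bins = config$n_bins,
                           relief_k = config$relief_k,
                           seed = stage_seed(config$seed, stage))
      utils::write.table(wm, file.path(config$out_dir, "weights.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      outputs <- c(outputs, "weights.tsv")
      results$weights <- wm
    }

    if ("signature" %in% config$stages) {
      stage <- "signature"
      if (is.null(results$weights))
        stop("the signature stage needs the weights stage")
      logf("stage signature (top %d)", config$top_k)
      sig <- rank_and_top_k(results$weights,
                            k = min(config$top_k, nrow(results$weights)))
      diag <- tryCatch(tissue_independence_check(sig$ranking),
                       warning = function(w) {
                         logf("  warning: %s", conditionMessage(w))
                         suppressWarnings(
                           tissue_independence_check(sig$ranking))
                       })
      write_signature(sig$signature,
                      file.path(config$out_dir, "signature.tsv"))
      write_signature(sig$ranking,
                      file.path(config$out_dir, "ranking.tsv"))
      jsonlite::write_json(diag,
                           file.path(config$out_dir,
                                     "tissue_independence.json"),
                           auto_unbox = TRUE, digits = NA)
      outputs <- c(outputs, "signature.tsv", "ranking.tsv",
                   "tissue_independence.json")
      results$signature <- sig
      results$tissue_diagnostic <- diag
    }

    if ("multivariate" %in% config$stages) {
      stage <- "multivariate"
      if (is.null(results$de))
        stop("the multivariate stage needs the de stage")
      logf("stage multivariate (top %d genes, %s linkage)",
           config$top_n_multivariate, config$linkage)
      fcm <- fold_change_matrix(results$de, config$top_n_multivariate)
      pca <- pca_correlation(fcm)
      clus <- cluster_similarity(fcm, config$linkage)
      utils::write.table(
        data.frame(component = seq_along(pca$explained),
                   explained = pca$explained),
        file.path(config$out_dir, "pca_explained.tsv"), sep = "\t",
        quote = FALSE, row.names = FALSE)
      utils::write.table(
        data.frame(tissue = rownames(pca$loadings), pca$loadings),
        file.path(config$out_dir, "pca_loadings.tsv"), sep = "\t",
        quote = FALSE, row.names = FALSE)
      utils::write.table(clus$merges,
                         file.path(config$out_dir, "cluster_merges.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      outputs <- c(outputs, "pca_explained.tsv", "pca_loadings.tsv",
                   "cluster_merges.tsv")
      results$multivariate <- list(fold_changes = fcm, pca = pca,
                                   clustering = clus)
    }
  }, error = function(e) {
    logf("FAILED at stage %s: %s", stage, conditionMessage(e))
    ok <<- FALSE
    results$error <<- conditionMessage(e)
  })

  paths <- file.path(config$out_dir, outputs)
  manifest <- data.frame(file = outputs,
                         md5 = unname(tools::md5sum(paths)),
                         stringsAsFactors = FALSE)
  utils::write.table(manifest, file.path(config$out_dir, "manifest.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  logf(if (ok) "pipeline complete (%d artifacts)" else
    "pipeline failed (%d artifacts written)", length(outputs))
  if (!ok) stop("pipeline failed at stage ", stage, ": ", results$error)
  invisible(list(manifest = manifest, results = results,
                 log_path = log_path))
}
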