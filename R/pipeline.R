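#' Run the RNA-seq interaction-contrast chain on a count matrix
#'
#' Convenience wrapper chaining [precision_weighted_logcpm()],
#' [fit_gene_models()], [empirical_bayes_moderate()], the per-timepoint
#' heat-versus-control contrasts of every genotype and the heat-by-genotype
#' interaction contrasts of every non-reference genotype, and
#' [decide_global()].
#'
#' @param counts genes x samples count matrix.
#' @param samples sample sheet (sample_id, genotype, condition, timepoint).
#' @param alpha,lfc decision thresholds for [decide_global()].
#' @param reference_genotype the wild-type label (first genotype level by
#'   default).
#' @return list with `we`, `fit`, `mod`, `decisions`, `cube`.
#' @export
run_interaction_pipeline <- function(counts, samples, alpha = 0.05, lfc = 0,
                                     reference_genotype = NULL) {
  counts <- counts[, samples$sample_id, drop = FALSE]
  design <- make_design(samples)
  we <- precision_weighted_logcpm(counts, design)
  fit <- fit_gene_models(we)
  mod <- empirical_bayes_moderate(fit$sigma2, fit$df_resid)

  genotypes <- unique(samples$genotype)
  wt <- reference_genotype %||% genotypes[1L]
  tps <- unique(samples$timepoint)
  conditions <- unique(samples$condition)

  res <- list()
  for (g in genotypes) {
    for (tp in tps) {
      res[[paste("heat", g, tp, sep = ".")]] <-
        heat_contrast(fit, mod, g, tp, conditions = conditions)
    }
  }
  for (g in setdiff(genotypes, wt)) {
    for (tp in tps) {
      res[[paste("int", g, tp, sep = ".")]] <-
        interaction_contrast(fit, mod, g, wt, tp, conditions = conditions)
    }
  }
  decisions <- decide_global(res, alpha = alpha, lfc = lfc)
  list(we = we, fit = fit, mod = mod, decisions = decisions,
       cube = build_decision_cube(decisions))
}

#' End-to-end planted-target recovery from a simulation configuration
#'
#' Generates a complete synthetic data set, writes and re-parses the gene
#' models and peaks through the annotation module, runs the
#' interaction-contrast pipeline, applies the discordance, promoter-binding
#' and commonality filters, and scores the recovered candidate list against
#' the planted direct targets.
#'
#' @param config a [sim_config()].
#' @param alpha,lfc decision thresholds.
#' @param min_timepoints commonality threshold (default 2 of 3).
#' @return list with `candidates` (the filtered table), `n_candidates`,
#'   `precision`, `recall`, `f1`, `truth`, `pipeline`, `bound_genes`.
#' @export
recover_targets <- function(config, alpha = 0.05, lfc = 0,
                            min_timepoints = 2L) {
  truth <- plant_truth(config)
  cm <- simulate_counts(config, truth)

  td <- tempfile("simanno")
  dir.create(td)
  on.exit(unlink(td, recursive = TRUE), add = TRUE)
  gff <- file.path(td, "genes.gff3")
  npk <- file.path(td, "peaks.narrowPeak")
  simulate_annotation_and_peaks(config, truth, gff, npk)
  genes <- parse_gene_models(gff)
  peaks <- parse_peaks(npk)
  bound <- promoter_bound_genes(peaks, genes, window = config$promoter_window)

  pl <- run_interaction_pipeline(cm$counts, cm$samples,
                                 alpha = alpha, lfc = lfc,
                                 reference_genotype = config$genotypes[1L])
  tps <- unique(cm$samples$timepoint)
  disc <- lapply(tps, function(tp) {
    discordant_by_genotype(pl$cube, tp, oe = config$genotypes[2L],
                           ko = config$genotypes[3L])
  })
  names(disc) <- tps
  cand <- candidate_direct_targets(disc, bound)
  common <- commonality_filter(cand, min_timepoints = min_timepoints,
                               n_timepoints = length(tps))

  predicted <- unique(common$gene_id)
  planted <- truth$targets$gene_id
  tp_ <- length(intersect(predicted, planted))
  precision <- if (length(predicted) > 0L) tp_ / length(predicted) else NA_real_
  recall <- if (length(planted) > 0L) tp_ / length(planted) else NA_real_
  f1 <- if (!is.na(precision) && !is.na(recall) && precision + recall > 0) {
    2 * precision * recall / (precision + recall)
  } else 0

  list(candidates = common, n_candidates = length(predicted),
       precision = precision, recall = recall, f1 = f1,
       truth = truth, pipeline = pl, bound_genes = bound)
}
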