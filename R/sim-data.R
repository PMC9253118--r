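#' Simulate the RNA-seq count matrix and sample sheet
#'
#' Draws negative-binomial gene-level counts for the full factorial design
#' (genotype x condition x timepoint x replicate; 3 x 2 x 3 x 3 = 54
#' samples under the default configuration). The log2 mean of gene g in
#' sample s is
#' `log2(baseline_g * libsize_s)` plus, where applicable: the generic heat
#' effect (heat samples), a constitutive genotype effect (cancels in the
#' interaction contrast), the planted heat-by-genotype interaction of direct
#' targets (`+lfc` in the overexpressor / `-lfc` in the knockout for
#' activated targets, mirrored for repressed, only at affected timepoints and
#' only under heat), and the shared module latent factor that induces
#' within-module correlation.
#'
#' @param config a [sim_config()].
#' @param truth the matching [plant_truth()] output.
#' @return list with `counts` (integer matrix, genes x samples) and
#'   `samples` (data.frame: sample_id, genotype, condition, timepoint,
#'   replicate).
#' @export
simulate_counts <- function(config, truth) {
  stopifnot(inherits(truth, "planted_truth"))
  with_seed(config$seed + 1L, simulate_counts_impl(config, truth))
}

simulate_counts_impl <- function(cfg, truth) {
  genes <- truth$genes
  n <- nrow(genes)
  samples <- expand.grid(
    replicate = seq_len(cfg$replicates),
    timepoint = cfg$timepoints,
    condition = cfg$conditions,
    genotype = cfg$genotypes,
    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE
  )[, c("genotype", "condition", "timepoint", "replicate")]
  samples$sample_id <- with(samples, paste(genotype, condition, timepoint,
                                           paste0("r", replicate), sep = "_"))
  ns <- nrow(samples)

  lib <- stats::rlnorm(ns, log(cfg$lib_size_mean), cfg$lib_size_sdlog)
  baseline <- exp(stats::rnorm(n, log(1 / n), 1))
  baseline <- baseline / sum(baseline)

  ## constitutive genotype effects (additive over conditions)
  geno_eff <- matrix(0, n, length(cfg$genotypes),
                     dimnames = list(genes$gene_id, cfg$genotypes))
  for (g in setdiff(cfg$genotypes, cfg$genotypes[1L])) {
    pick <- stats::runif(n) < 0.1
    geno_eff[pick, g] <- stats::rnorm(sum(pick), 0, 0.3)
  }

  ## module latent factors, scaled to the target within-module correlation of
  ## log-expression against the NB log-scale noise
  sigma_log2 <- sqrt(cfg$nb_dispersion) / log(2)
  lat_sd <- if (cfg$module_cor > 0) {
    sigma_log2 * sqrt(cfg$module_cor / (1 - cfg$module_cor))
  } else 0
  latent <- matrix(stats::rnorm(cfg$n_modules * ns), cfg$n_modules, ns)

  tp_list <- strsplit(genes$affected_timepoints, ";", fixed = TRUE)
  heat_cond <- cfg$conditions[2L]
  wt <- cfg$genotypes[1L]
  oe <- cfg$genotypes[2L]
  ko <- cfg$genotypes[3L]

  log2mu <- matrix(0, n, ns, dimnames = list(genes$gene_id, samples$sample_id))
  for (s in seq_len(ns)) {
    sm <- samples[s, ]
    eff <- geno_eff[, sm$genotype]
    if (sm$condition == heat_cond) {
      eff <- eff + truth$heat_lfc[, sm$timepoint]
      if (sm$genotype %in% c(oe, ko)) {
        sgn <- ifelse(genes$direction == "activated", 1, -1) *
          ifelse(sm$genotype == oe, 1, -1)
        affected <- genes$is_target &
          vapply(tp_list, function(x) sm$timepoint %in% x, logical(1))
        eff[affected] <- eff[affected] +
          cfg$target_interaction_lfc * sgn[affected]
      }
    }
    if (lat_sd > 0 && cfg$n_modules > 0L) {
      inmod <- genes$module > 0L
      eff[inmod] <- eff[inmod] + lat_sd * latent[genes$module[inmod], s]
    }
    log2mu[, s] <- log2(baseline * lib[s]) + eff
  }

  mu <- 2^log2mu
  counts <- matrix(
    stats::rnbinom(length(mu), mu = mu, size = 1 / cfg$nb_dispersion),
    n, ns, dimnames = dimnames(mu)
  )
  list(counts = counts,
       samples = samples[, c("sample_id", "genotype", "condition",
                             "timepoint", "replicate")])
}

#' Simulate a long-format qPCR Ct table
#'
#' Emulates the comparative-Ct screen: a comparator arm at baseline
#' expression and a case arm whose genes follow the planted log2
#' fold-change trajectories. Ct values are
#' `ct_base + (40 - base expression) - log2(relative expression) + noise`;
#' the reference gene sits at `ct_base` in every sample, and planted
#' undetectable genes sit above the detection ceiling everywhere.
#'
#' @param config a [sim_config()].
#' @param truth the matching [plant_truth()] output.
#' @param case_arm,comparator_arm treatment-arm labels (e.g. "primed" vs
#'   "control", or "primed+triggered" vs "triggered").
#' @param tech_reps technical replicates per (sample, gene).
#' @return data.frame with columns sample_id, arm, timepoint, bio_rep,
#'   gene_id, tech_rep, ct.
#' @export
simulate_ct_table <- function(config, truth,
                              case_arm = "primed",
                              comparator_arm = "control",
                              tech_reps = 2L) {
  stopifnot(inherits(truth, "planted_truth"))
  with_seed(config$seed + 2L, {
    cfg <- config
    ct <- truth$ct
    tps <- cfg$timepoints
    arms <- c(comparator_arm, case_arm)
    grid <- expand.grid(
      tech_rep = seq_len(tech_reps),
      gene_id = ct$panel,
      bio_rep = seq_len(cfg$replicates),
      timepoint = tps,
      arm = arms,
      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE
    )
    grid$sample_id <- with(grid, paste(arm, timepoint,
                                       paste0("r", bio_rep), sep = "_"))
    is_ref <- grid$gene_id == ct$reference_gene
    is_undet <- grid$gene_id %in% ct$undetectable

    base_ct <- rep(NA_real_, nrow(grid))
    base_ct[is_ref] <- cfg$ct_base
    assayed <- !is_ref & !is_undet
    base_ct[assayed] <- cfg$ct_base +
      (40 - ct$base_expression[grid$gene_id[assayed]])

    lfc <- rep(0, nrow(grid))
    case_rows <- assayed & grid$arm == case_arm
    lfc[case_rows] <- ct$trajectories[
      cbind(grid$gene_id[case_rows], grid$timepoint[case_rows])
    ]

    noise <- if (cfg$ct_noise_sd > 0) {
      stats::rnorm(nrow(grid), 0, cfg$ct_noise_sd)
    } else rep(0, nrow(grid))
    ctval <- base_ct - lfc + noise
    ctval[is_undet] <- pmax(cfg$ct_ceiling + 0.5,
                            cfg$ct_ceiling + 1 + noise[is_undet])
    grid$ct <- ctval
    grid[, c("sample_id", "arm", "timepoint", "bio_rep",
             "gene_id", "tech_rep", "ct")]
  })
}
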