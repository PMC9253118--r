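#' Simulation configuration for the synthetic thermomemory data set
#'
#' Bundles every knob of the synthetic-data generator. The defaults emulate
#' the study design the pipeline targets: 3 genotypes (wild type, a
#' transcription-factor overexpressor, a knockout) x 2 conditions (control,
#' heat priming) x 3 timepoints (0h, 1h, 4h of the memory phase) x 3
#' biological replicates of RNA-seq; a 104-gene qPCR panel of NAC
#' transcription factors with 29 undetectable members; planted direct-target
#' genes whose heat-by-genotype interaction effects have opposite sign in the
#' overexpressor and the knockout; planted co-expression modules; and binding
#' peaks placed inside (targets) or well away from (decoys) the 1-kb upstream
#' promoter windows.
#'
#' @param n_genes number of simulated genes.
#' @param n_direct_targets number of planted direct-target genes.
#' @param n_modules number of planted co-expression modules.
#' @param module_sizes integer vector of module sizes
#'   (default `n_genes %/% 20` genes each); must sum to at most `n_genes`.
#' @param genotypes,conditions,timepoints,replicates factorial design labels
#'   and biological replicate count.
#' @param lib_size_mean mean sequencing library size (reads); libraries are
#'   drawn log-normal around it.
#' @param lib_size_sdlog log-scale standard deviation of library sizes.
#' @param nb_dispersion negative-binomial dispersion (1/size); > 0.
#' @param heat_effect_sd standard deviation (log2) of generic heat-response
#'   effects among heat-responsive genes.
#' @param prop_heat_responsive proportion of genes with a generic (genotype-
#'   independent) heat response.
#' @param target_interaction_lfc magnitude (log2) of the planted
#'   heat-by-genotype interaction effect of direct targets.
#' @param p_all_timepoints probability a planted target is affected at all
#'   three timepoints (otherwise at a random two), so the two-of-three
#'   commonality rule has positives.
#' @param module_cor target within-module correlation of log-expression
#'   induced by the shared latent factor.
#' @param n_bound_nontargets number of non-target genes that also receive a
#'   promoter-proximal binding peak (binding without regulation).
#' @param ct_panel_size qPCR panel size (including the reference gene).
#' @param ct_n_undetectable number of panel genes planted as undetectable
#'   (cycle threshold above the detection ceiling everywhere).
#' @param ct_n_clusters number of planted qPCR trajectory clusters.
#' @param ct_noise_sd Gaussian noise on simulated Ct values (cycles).
#' @param ct_reference_gene name of the stable reference gene in the panel.
#' @param ct_base baseline Ct of the reference gene (cycles).
#' @param ct_ceiling detection ceiling (cycles); undetectable genes sit above.
#' @param gene_length,intergenic gene-model length and intergenic spacing (bp)
#'   of the synthetic chromosome.
#' @param n_decoy_peaks number of decoy binding peaks placed at least
#'   `promoter_window + 1` bp from every TSS.
#' @param peak_width width (bp) of simulated binding peaks.
#' @param promoter_window promoter window (bp upstream of the TSS; default
#'   1000, the rule applied to DAP-seq peaks).
#' @param seed integer seed; every generator call is deterministic given it.
#' @return an object of class `sim_config` (a validated list).
#' @export
sim_config <- function(n_genes = 2000,
                       n_direct_targets = 50,
                       n_modules = 5,
                       module_sizes = NULL,
                       genotypes = c("WT", "OE", "KO"),
                       conditions = c("control", "heat"),
                       timepoints = c("0h", "1h", "4h"),
                       replicates = 3,
                       lib_size_mean = 2e6,
                       lib_size_sdlog = 0.1,
                       nb_dispersion = 0.05,
                       heat_effect_sd = 1,
                       prop_heat_responsive = 0.3,
                       target_interaction_lfc = 2,
                       p_all_timepoints = 0.4,
                       module_cor = 0.6,
                       n_bound_nontargets = 200,
                       ct_panel_size = 104,
                       ct_n_undetectable = 29,
                       ct_n_clusters = 5,
                       ct_noise_sd = 0.25,
                       ct_reference_gene = "REFG",
                       ct_base = 20,
                       ct_ceiling = 38,
                       gene_length = 2000,
                       intergenic = 8000,
                       n_decoy_peaks = 300,
                       peak_width = 200,
                       promoter_window = 1000,
                       seed = 1) {
  if (is.null(module_sizes)) {
    module_sizes <- rep(max(3L, n_genes %/% 20L), n_modules)
  }
  cfg <- list(
    n_genes = as.integer(n_genes),
    n_direct_targets = as.integer(n_direct_targets),
    n_modules = as.integer(n_modules),
    module_sizes = as.integer(module_sizes),
    genotypes = genotypes, conditions = conditions, timepoints = timepoints,
    replicates = as.integer(replicates),
    lib_size_mean = lib_size_mean, lib_size_sdlog = lib_size_sdlog,
    nb_dispersion = nb_dispersion,
    heat_effect_sd = heat_effect_sd,
    prop_heat_responsive = prop_heat_responsive,
    target_interaction_lfc = target_interaction_lfc,
    p_all_timepoints = p_all_timepoints,
    module_cor = module_cor,
    n_bound_nontargets = as.integer(n_bound_nontargets),
    ct_panel_size = as.integer(ct_panel_size),
    ct_n_undetectable = as.integer(ct_n_undetectable),
    ct_n_clusters = as.integer(ct_n_clusters),
    ct_noise_sd = ct_noise_sd,
    ct_reference_gene = ct_reference_gene,
    ct_base = ct_base, ct_ceiling = ct_ceiling,
    gene_length = as.integer(gene_length),
    intergenic = as.integer(intergenic),
    n_decoy_peaks = as.integer(n_decoy_peaks),
    peak_width = as.integer(peak_width),
    promoter_window = as.integer(promoter_window),
    seed = as.integer(seed)
  )
  validate_sim_config(cfg)
  class(cfg) <- "sim_config"
  cfg
}

validate_sim_config <- function(cfg) {
  if (cfg$n_genes < 1L) stop("configuration error: n_genes must be >= 1")
  if (cfg$n_direct_targets < 0L || cfg$n_direct_targets > cfg$n_genes) {
    stop("configuration error: n_direct_targets must be in [0, n_genes]")
  }
  if (length(cfg$module_sizes) != cfg$n_modules) {
    stop("configuration error: module_sizes must have length n_modules")
  }
  if (cfg$n_modules > 0L && sum(cfg$module_sizes) > cfg$n_genes) {
    stop("configuration error: sum(module_sizes) must be <= n_genes")
  }
  if (cfg$nb_dispersion <= 0) {
    stop("configuration error: nb_dispersion must be > 0")
  }
  if (cfg$replicates < 1L) {
    stop("configuration error: replicates must be >= 1")
  }
  if (cfg$module_cor < 0 || cfg$module_cor >= 1) {
    stop("configuration error: module_cor must be in [0, 1)")
  }
  if (cfg$promoter_window <= 0L) {
    stop("configuration error: promoter_window must be > 0")
  }
  if (cfg$peak_width + 100L >= cfg$promoter_window) {
    stop("configuration error: peak_width must leave room inside the promoter window")
  }
  if (cfg$intergenic < 2L * (cfg$promoter_window + cfg$peak_width + 2L)) {
    stop("configuration error: intergenic spacing too small for decoy placement")
  }
  if (cfg$ct_n_undetectable + 1L > cfg$ct_panel_size) {
    stop("configuration error: ct_n_undetectable must leave detectable panel genes")
  }
  invisible(cfg)
}
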