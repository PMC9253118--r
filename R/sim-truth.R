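#' Plant the ground truth of a synthetic thermomemory data set
#'
#' Lays out a single synthetic chromosome of non-overlapping gene models on
#' both strands, chooses the direct-target genes (with activation/repression
#' direction and the timepoints at which their heat-by-genotype interaction
#' acts), assigns co-expression module membership, plans every binding peak
#' (one promoter-proximal peak per target, promoter peaks for a set of
#' bound-but-unregulated genes, and decoys kept at least
#' `promoter_window + 1` bp from every TSS), and plants the qPCR panel:
#' trajectory-cluster centres, per-gene log2 trajectories, the stable
#' reference gene and the undetectable genes.
#'
#' All downstream recovery tests compare against this object. Deterministic
#' for a fixed `config$seed`.
#'
#' @param config a [sim_config()].
#' @return an object of class `planted_truth`: a list with elements
#'   `genes` (gene models + module / target annotation), `targets`,
#'   `heat_lfc` (gene x timepoint generic heat effects, log2),
#'   `peaks` (planned peak intervals, 1-based inclusive),
#'   `promoter_bound` (gene ids with >= 1 peak overlapping their strand-aware
#'   upstream window, computed geometrically at planting time), and `ct`
#'   (the planted qPCR panel).
#' @export
plant_truth <- function(config) {
  validate_sim_config(config)
  with_seed(config$seed, plant_truth_impl(config))
}

plant_truth_impl <- function(cfg) {
  n <- cfg$n_genes
  tps <- cfg$timepoints
  ntp <- length(tps)
  ids <- sprintf("g%0*d", max(4L, nchar(n)), seq_len(n))

  ## genome layout: evenly spaced non-overlapping models, random strand
  pitch <- cfg$gene_length + cfg$intergenic
  start <- 1L + (seq_len(n) - 1L) * pitch
  end <- start + cfg$gene_length - 1L
  strand <- sample(c("+", "-"), n, replace = TRUE)
  tss <- ifelse(strand == "+", start, end)

  ## direct targets: split between activated and repressed, each affected at
  ## all timepoints with probability p_all_timepoints, else at a random two
  is_target <- rep(FALSE, n)
  direction <- rep(NA_character_, n)
  tp_sets <- vector("list", n)
  if (cfg$n_direct_targets > 0L) {
    tgt_idx <- sort(sample.int(n, cfg$n_direct_targets))
    is_target[tgt_idx] <- TRUE
    dirs <- rep(c("activated", "repressed"), length.out = cfg$n_direct_targets)
    direction[tgt_idx] <- sample(dirs)
    for (i in tgt_idx) {
      tp_sets[[i]] <- if (ntp <= 2L || runif(1) < cfg$p_all_timepoints) {
        tps
      } else {
        sort_tp(sample(tps, max(2L, ntp - 1L)), tps)
      }
    }
  }

  ## generic (genotype-independent) heat response, decaying over timepoints
  heat_lfc <- matrix(0, n, ntp, dimnames = list(ids, tps))
  responsive <- runif(n) < cfg$prop_heat_responsive
  base_eff <- rnorm(n, 0, cfg$heat_effect_sd) * responsive
  decay <- seq(1, 0.4, length.out = ntp)
  heat_lfc <- outer(base_eff, decay)
  dimnames(heat_lfc) <- list(ids, tps)

  ## co-expression modules
  module <- rep(0L, n)
  if (cfg$n_modules > 0L && sum(cfg$module_sizes) > 0L) {
    pool <- sample.int(n, sum(cfg$module_sizes))
    off <- 0L
    for (m in seq_len(cfg$n_modules)) {
      sz <- cfg$module_sizes[m]
      module[pool[off + seq_len(sz)]] <- m
      off <- off + sz
    }
  }

  genes <- data.frame(
    gene_id = ids, chrom = "chr1", strand = strand,
    start = start, end = end, tss = tss,
    module = module, is_target = is_target, direction = direction,
    affected_timepoints = vapply(
      tp_sets, function(x) paste(x, collapse = ";"), character(1)
    ),
    stringsAsFactors = FALSE
  )
  targets <- genes[genes$is_target,
                   c("gene_id", "direction", "affected_timepoints")]
  rownames(targets) <- NULL

  peaks <- plan_peaks(cfg, genes)
  promoter_bound <- geometric_promoter_flags(genes, peaks, cfg$promoter_window)

  truth <- list(
    seed = cfg$seed,
    genes = genes,
    targets = targets,
    heat_lfc = heat_lfc,
    peaks = peaks,
    promoter_bound = promoter_bound,
    ct = plant_ct_panel(cfg)
  )
  class(truth) <- "planted_truth"
  truth
}

sort_tp <- function(x, levels) levels[sort(match(x, levels))]

## One promoter peak per target and per bound non-target, fully inside the
## strand-aware open window (TSS - w, TSS); decoys in intergenic space with
## every edge > w bp from every TSS, so they can never qualify.
plan_peaks <- function(cfg, genes) {
  w <- cfg$promoter_window
  pw <- cfg$peak_width
  promoter_peak <- function(g, id) {
    off <- sample(seq(50L, w - pw - 50L), 1L)  # gap between peak and TSS
    if (g$strand == "+") {
      s <- g$tss - off - pw + 1L
      e <- g$tss - off
    } else {
      s <- g$tss + off
      e <- g$tss + off + pw - 1L
    }
    data.frame(peak_id = id, chrom = g$chrom, start = s, end = e,
               summit_rel = pw %/% 2L, class = NA_character_,
               gene_id = g$gene_id, stringsAsFactors = FALSE)
  }
  out <- list()
  tgt <- genes[genes$is_target, ]
  if (nrow(tgt) > 0L) {
    rows <- lapply(seq_len(nrow(tgt)), function(i) {
      promoter_peak(tgt[i, ], sprintf("pk_t%04d", i))
    })
    tp <- do.call(rbind, rows); tp$class <- "target"
    out$target <- tp
  }
  nb <- min(cfg$n_bound_nontargets, sum(!genes$is_target))
  if (nb > 0L) {
    bidx <- sort(sample(which(!genes$is_target), nb))
    rows <- lapply(seq_along(bidx), function(i) {
      promoter_peak(genes[bidx[i], ], sprintf("pk_b%04d", i))
    })
    bp <- do.call(rbind, rows); bp$class <- "bound_nontarget"
    out$bound <- bp
  }
  if (cfg$n_decoy_peaks > 0L) {
    ## offsets from the gene-body end into the intergenic gap; the valid band
    ## keeps > w bp from both flanking TSSs regardless of strand
    lo <- w + 2L
    hi <- cfg$intergenic - pw - w - 1L
    gi <- sample.int(nrow(genes), cfg$n_decoy_peaks, replace = TRUE)
    off <- sample(seq(lo, hi), cfg$n_decoy_peaks, replace = TRUE)
    s <- genes$end[gi] + off
    dp <- data.frame(
      peak_id = sprintf("pk_d%04d", seq_len(cfg$n_decoy_peaks)),
      chrom = "chr1", start = s, end = s + pw - 1L,
      summit_rel = ifelse(seq_len(cfg$n_decoy_peaks) %% 3L == 0L,
                          -1L, pw %/% 2L),
      class = "decoy", gene_id = NA_character_,
      stringsAsFactors = FALSE
    )
    out$decoy <- dp
  }
  pk <- do.call(rbind, out)
  rownames(pk) <- NULL
  pk
}

## Brute-force window check used to record the planted qualification flags;
## intentionally written as plain interval arithmetic at planting time.
geometric_promoter_flags <- function(genes, peaks, window) {
  if (is.null(peaks) || nrow(peaks) == 0L) return(character(0))
  hit <- vapply(seq_len(nrow(genes)), function(i) {
    g <- genes[i, ]
    if (g$strand == "+") {
      lo <- g$tss - window + 1L; hi <- g$tss - 1L
    } else {
      lo <- g$tss + 1L; hi <- g$tss + window - 1L
    }
    any(peaks$chrom == g$chrom & peaks$start <= hi & peaks$end >= lo)
  }, logical(1))
  genes$gene_id[hit]
}

## qPCR panel: cluster-centre log2 trajectories from a small shape library,
## per-gene jitter, a flat reference gene, and planted undetectable genes.
plant_ct_panel <- function(cfg) {
  ntp <- length(cfg$timepoints)
  npanel <- cfg$ct_panel_size
  ids <- c(cfg$ct_reference_gene,
           sprintf("P%03d", seq_len(npanel - 1L)))
  undet <- sample(ids[-1L], cfg$ct_n_undetectable)
  assayed <- setdiff(ids[-1L], undet)

  shape_lib <- function(k) {
    s1 <- seq(1, 0.2, length.out = ntp)
    base <- list(s1, -s1, seq(-1, 1, length.out = ntp),
                 rev(s1), rep(0, ntp))
    amp <- 1.6 * (1 + (k - 1) %/% length(base) * 0.8)
    base[[(k - 1L) %% length(base) + 1L]] * amp
  }
  centres <- t(vapply(seq_len(cfg$ct_n_clusters), shape_lib, numeric(ntp)))
  dimnames(centres) <- list(paste0("c", seq_len(cfg$ct_n_clusters)),
                            cfg$timepoints)

  cluster <- sample(rep_len(seq_len(cfg$ct_n_clusters), length(assayed)))
  traj <- centres[cluster, , drop = FALSE] +
    matrix(rnorm(length(assayed) * ntp, 0, 0.15), ncol = ntp)
  dimnames(traj) <- list(assayed, cfg$timepoints)

  list(
    panel = ids,
    reference_gene = cfg$ct_reference_gene,
    undetectable = sort(undet),
    cluster = stats::setNames(cluster, assayed),
    centres = centres,
    trajectories = traj,
    base_expression = stats::setNames(runif(length(assayed), 28, 34), assayed)
  )
}
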