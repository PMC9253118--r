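#' Comparative-Ct expression quantification
#'
#' Implements the comparative-Ct (delta-Ct) rule: technical replicates are
#' averaged (arithmetic mean), each gene's Ct is normalized against the
#' reference gene measured in the same sample (`dCt = Ct_gene - Ct_ref`),
#' and expression is reported on the monotone `40 - dCt` scale (higher =
#' more expressed). A gene is flagged undetectable in a treatment arm when
#' no sample of that arm yields a raw Ct below the detection ceiling, and
#' undetectable overall when that holds in every arm.
#'
#' @param ct long-format Ct table: data.frame with columns `sample_id`,
#'   `arm`, `timepoint`, `gene_id`, `ct` (and optionally `tech_rep`).
#' @param reference_gene id of the reference gene; must be measured in every
#'   sample.
#' @param ceiling detection ceiling in cycles (default 38).
#' @return object of class `ct_expression`: list with `expr` (long
#'   data.frame: sample_id, arm, timepoint, gene_id, ct, expression),
#'   `undetectable` (gene ids undetectable in all arms),
#'   `undetectable_by_arm` (named list), `reference_gene`, `ceiling`.
#' @export
compute_expression <- function(ct, reference_gene, ceiling = 38) {
  need <- c("sample_id", "arm", "timepoint", "gene_id", "ct")
  if (!all(need %in% names(ct))) {
    stop("input error: Ct table must have columns ",
         paste(need, collapse = ", "))
  }
  if (any(ct$ct <= 0)) stop("input error: Ct values must be > 0")

  ## technical-replicate aggregation
  agg <- stats::aggregate(
    ct["ct"],
    ct[c("sample_id", "arm", "timepoint", "gene_id")],
    mean
  )

  ref <- agg[agg$gene_id == reference_gene, c("sample_id", "ct")]
  all_samples <- unique(agg$sample_id)
  if (!all(all_samples %in% ref$sample_id)) {
    stop("input error: reference gene '", reference_gene,
         "' missing in sample(s): ",
         paste(setdiff(all_samples, ref$sample_id), collapse = ", "))
  }
  names(ref)[2] <- "ct_ref"
  out <- merge(agg, ref, by = "sample_id")
  out$expression <- 40 - (out$ct - out$ct_ref)

  ## detectability per arm and overall, judged on raw Ct
  genes <- setdiff(unique(out$gene_id), reference_gene)
  arms <- unique(out$arm)
  undet_by_arm <- lapply(arms, function(a) {
    sub <- out[out$arm == a & out$gene_id %in% genes, ]
    det <- tapply(sub$ct < ceiling, sub$gene_id, any)
    names(det)[!det]
  })
  names(undet_by_arm) <- arms
  undetectable <- sort(Reduce(intersect, undet_by_arm))

  ## genes missing from some samples: those samples are simply absent from
  ## the long table; note them
  n_per_gene <- table(out$sample_id[out$gene_id %in% genes])
  if (length(unique(table(out$gene_id[out$gene_id %in% genes]))) > 1L) {
    warning("some genes are missing from some samples; ",
            "those samples are excluded gene-wise")
  }

  structure(
    list(expr = out[, c("sample_id", "arm", "timepoint", "gene_id",
                        "ct", "expression")],
         undetectable = undetectable,
         undetectable_by_arm = undet_by_arm,
         reference_gene = reference_gene,
         ceiling = ceiling),
    class = "ct_expression"
  )
}

#' Per-timepoint log2 fold-change trajectories between two treatment arms
#'
#' On the `40 - dCt` scale a log2 expression ratio is a plain difference, so
#' the per-timepoint log2 ratio of case over comparator is the difference of
#' arm-mean expression values at the matched timepoint (the delta-delta-Ct
#' identity). Genes undetectable in all arms are dropped into
#' `$undetectable`; genes undetectable in exactly one of the two arms have
#' undefined ratios and are listed in `$excluded` (kept out of clustering).
#'
#' @param expr a [compute_expression()] result.
#' @param case_arm,comparator_arm arm labels present in the table.
#' @return object of class `fc_profiles`: list with `lfc` (gene x timepoint
#'   matrix of log2 ratios), `undetectable`, `excluded`.
#' @export
fold_change_profile <- function(expr, case_arm, comparator_arm) {
  stopifnot(inherits(expr, "ct_expression"))
  e <- expr$expr[expr$expr$gene_id != expr$reference_gene, ]
  tps_case <- unique(e$timepoint[e$arm == case_arm])
  tps_comp <- unique(e$timepoint[e$arm == comparator_arm])
  tps <- intersect(tps_case, tps_comp)
  if (length(tps) == 0L) {
    stop("input error: no shared timepoints between arms '",
         case_arm, "' and '", comparator_arm, "'")
  }

  genes <- sort(setdiff(unique(e$gene_id), expr$undetectable))
  excluded <- sort(intersect(
    genes,
    union(expr$undetectable_by_arm[[case_arm]] %||% character(0),
          expr$undetectable_by_arm[[comparator_arm]] %||% character(0))
  ))

  mean_expr <- function(arm) {
    sub <- e[e$arm == arm & e$gene_id %in% genes & e$timepoint %in% tps, ]
    tapply(sub$expression, list(sub$gene_id, sub$timepoint), mean)
  }
  mc <- mean_expr(case_arm)
  mk <- mean_expr(comparator_arm)
  lfc <- mc[genes, tps, drop = FALSE] - mk[genes, tps, drop = FALSE]
  lfc[excluded, ] <- NA_real_

  structure(list(lfc = lfc, undetectable = expr$undetectable,
                 excluded = excluded,
                 case_arm = case_arm, comparator_arm = comparator_arm),
            class = "fc_profiles")
}

#' Differential-expression calls at a fold-change threshold
#'
#' A gene is differentially expressed when `|log2 ratio| >= log2(threshold)`
#' at one or more timepoints (boundary inclusive); its direction is the sign
#' at the timepoint of maximal absolute ratio. Genes with no defined ratio
#' join the undetectable set, so up/down/unchanged/undetectable partition the
#' assayed panel.
#'
#' @param profiles a [fold_change_profile()] result.
#' @param threshold_fold fold-change threshold (> 1; default 1.5, the
#'   screen's cut-off).
#' @return list of disjoint character vectors `up`, `down`, `unchanged`,
#'   `undetectable`.
#' @export
call_differential <- function(profiles, threshold_fold = 1.5) {
  stopifnot(inherits(profiles, "fc_profiles"))
  if (threshold_fold <= 1) {
    stop("configuration error: threshold_fold must be > 1")
  }
  thr <- log2(threshold_fold)
  lfc <- profiles$lfc
  ok <- rowSums(!is.na(lfc)) > 0L
  undet <- sort(c(profiles$undetectable, rownames(lfc)[!ok]))
  lfc <- lfc[ok, , drop = FALSE]

  up <- character(0); down <- character(0); unchanged <- character(0)
  if (nrow(lfc) > 0L) {
    amax <- apply(abs(lfc), 1L, max, na.rm = TRUE)
    de <- amax >= thr
    peak_sign <- vapply(seq_len(nrow(lfc)), function(i) {
      v <- lfc[i, ]
      sign(v[which.max(abs(v))])
    }, numeric(1))
    up <- sort(rownames(lfc)[de & peak_sign > 0])
    down <- sort(rownames(lfc)[de & peak_sign < 0])
    unchanged <- sort(rownames(lfc)[!de])
  }
  list(up = up, down = down, unchanged = unchanged, undetectable = undet)
}

#' K-means clustering of fold-change trajectories
#'
#' Clusters the per-gene log2-ratio vectors with k-means (Euclidean
#' distance, best of `n_restarts` random starts by within-cluster sum of
#' squares), deterministically for a fixed seed. Genes with no defined ratio
#' are excluded; genes missing single timepoints are imputed with their own
#' row mean for clustering only. Cluster labels are renumbered in decreasing
#' cluster-size order for stability.
#'
#' @param profiles a [fold_change_profile()] result.
#' @param k number of clusters.
#' @param seed RNG seed for initialization.
#' @param n_restarts random restarts (default 25).
#' @return list with `cluster` (named integer vector), `k`, `centers`
#'   (k x timepoints, renumbered), `inertia` (total within-cluster sum of
#'   squares), `seed`.
#' @export
cluster_profiles <- function(profiles, k, seed = 1L, n_restarts = 25L) {
  stopifnot(inherits(profiles, "fc_profiles"))
  x <- profiles$lfc
  x <- x[rowSums(!is.na(x)) > 0L, , drop = FALSE]
  if (anyNA(x)) {
    rm_ <- rowMeans(x, na.rm = TRUE)
    for (j in seq_len(ncol(x))) {
      miss <- is.na(x[, j])
      x[miss, j] <- rm_[miss]
    }
  }
  if (nrow(x) < k) {
    stop("input error: fewer complete profiles (", nrow(x),
         ") than clusters (", k, ")")
  }
  km <- with_seed(seed, stats::kmeans(x, centers = k, nstart = n_restarts,
                                      iter.max = 100L))
  ## relabel by decreasing size, ties by original label
  ord <- order(-km$size, seq_len(k))
  relabel <- integer(k); relabel[ord] <- seq_len(k)
  cl <- stats::setNames(relabel[km$cluster], rownames(x))
  centers <- km$centers[ord, , drop = FALSE]
  rownames(centers) <- seq_len(k)
  list(cluster = cl, k = k, centers = centers,
       inertia = km$tot.withinss, seed = seed)
}
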