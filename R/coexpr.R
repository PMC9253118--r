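#' Weighted co-expression adjacency matrix
#'
#' Unsigned mode raises absolute Pearson correlation to the soft-thresholding
#' power: `a_ij = |cor(g_i, g_j)|^beta`; signed mode uses
#' `((1 + cor) / 2)^beta`. The diagonal is 1. Constant gene rows make the
#' correlation undefined and are an error here (they are dropped with a
#' warning by [soft_power_scan()]).
#'
#' @param expr expression matrix, genes x samples.
#' @param power soft-thresholding power beta >= 1 (default 6).
#' @param type `"unsigned"` (default) or `"signed"`.
#' @return symmetric adjacency matrix in \[0, 1\] with unit diagonal.
#' @export
build_adjacency <- function(expr, power = 6, type = c("unsigned", "signed")) {
  type <- match.arg(type)
  if (power < 1) stop("configuration error: power must be >= 1")
  r <- suppressWarnings(stats::cor(t(expr)))
  if (anyNA(r)) {
    bad <- rownames(expr)[apply(expr, 1L, stats::sd) == 0]
    stop("input error: non-finite correlations (constant genes: ",
         paste(utils::head(bad, 5L), collapse = ", "), ")")
  }
  a <- if (type == "unsigned") abs(r)^power else ((1 + r) / 2)^power
  diag(a) <- 1
  a
}

#' Scale-free topology fit of a connectivity distribution
#'
#' Bins the connectivities into `nbins` equal-width bins, regresses log10
#' bin frequency on log10 mean bin connectivity, and reports the signed fit
#' index `-sign(slope) * R^2` (a positive slope — more frequent high-degree
#' nodes — is penalized). Empty bins are dropped from the regression.
#'
#' @param k connectivity vector (`rowSums(adjacency) - 1`).
#' @param nbins number of equal-width bins (default 10).
#' @return list with `r2` (signed fit index) and `slope`.
#' @export
scale_free_fit <- function(k, nbins = 10L) {
  k <- k[k > 0]
  if (length(unique(k)) < 3L) return(list(r2 = NA_real_, slope = NA_real_))
  cut_ <- cut(k, breaks = nbins)
  freq <- tapply(k, cut_, length)
  centre <- tapply(k, cut_, mean)
  ok <- !is.na(freq) & freq > 0 & is.finite(centre) & centre > 0
  if (sum(ok) < 3L) return(list(r2 = NA_real_, slope = NA_real_))
  fit <- stats::lm(log10(freq[ok]) ~ log10(centre[ok]))
  slope <- stats::coef(fit)[2L]
  r2 <- summary(fit)$r.squared
  list(r2 = unname(-sign(slope) * r2), slope = unname(slope))
}

#' Soft-thresholding power scan
#'
#' For each candidate power, builds the adjacency, computes connectivities
#' and reports the signed scale-free fit index and the mean and median
#' connectivity — the quantities inspected to choose the power (maximum
#' scale-free fit, minimum mean connectivity).
#'
#' @param expr expression matrix, genes x samples (>= 50 genes; constant
#'   rows dropped with a warning).
#' @param powers candidate powers (default 1:10, 12, 14, 16, 18, 20).
#' @param type network type, see [build_adjacency()].
#' @return data.frame: power, fit_r2, mean_k, median_k, max_k.
#' @export
soft_power_scan <- function(expr, powers = c(1:10, seq(12, 20, 2)),
                            type = "unsigned") {
  const <- apply(expr, 1L, stats::sd) == 0
  if (any(const)) {
    warning(sum(const), " constant gene row(s) dropped before correlation")
    expr <- expr[!const, , drop = FALSE]
  }
  if (nrow(expr) < 50L) stop("input error: need >= 50 genes")
  r <- abs(stats::cor(t(expr)))
  rows <- lapply(powers, function(b) {
    a <- if (type == "unsigned") r^b else ((1 + stats::cor(t(expr))) / 2)^b
    diag(a) <- 1
    k <- rowSums(a) - 1
    sf <- scale_free_fit(k)
    data.frame(power = b, fit_r2 = sf$r2, mean_k = mean(k),
               median_k = stats::median(k), max_k = max(k))
  })
  do.call(rbind, rows)
}

#' Topological overlap matrix
#'
#' `TOM_ij = (sum_u a_iu a_uj + a_ij) / (min(k_i, k_j) + 1 - a_ij)` for
#' `i != j` (the shared-neighbour sum runs over `u != i, j`), `TOM_ii = 1`,
#' with connectivity `k_i = sum_{u != i} a_iu`. Values lie in \[0, 1\]; high
#' overlap means two genes share most of their network neighbourhood.
#'
#' @param a symmetric adjacency in \[0, 1\] with unit diagonal.
#' @return symmetric TOM similarity matrix.
#' @export
topological_overlap <- function(a) {
  stopifnot(isSymmetric(unname(a)), all(a >= 0 & a <= 1))
  k <- rowSums(a) - 1
  ## (A^2)_ij counts u = i and u = j (each contributing a_ij); remove them
  num <- a %*% a - 2 * a + a          # = shared-neighbour sum + a_ij
  den <- outer(k, k, pmin) + 1 - a
  stopifnot(all(den[upper.tri(den)] > 0))
  tom <- num / den
  diag(tom) <- 1
  dimnames(tom) <- dimnames(a)
  tom
}

#' Module detection on the topological overlap dissimilarity
#'
#' Average-linkage hierarchical clustering of `1 - TOM`, cut statically at
#' `cut_height`; clusters smaller than `min_size` are relabelled 0
#' (unassigned); surviving modules are renumbered 1..M in decreasing size
#' order. Each module's eigengene is the first principal component of its
#' standardized expression across samples, sign-anchored so the mean gene
#' loading is positive.
#'
#' @param tom TOM similarity matrix from [topological_overlap()].
#' @param expr the expression matrix the network was built from (for
#'   eigengenes); genes must match `tom`.
#' @param cut_height static tree-cut height in (0, 1) (default 0.99).
#' @param min_size minimum module size (>= 3; default 30).
#' @return object of class `module_partition`: list with `labels` (named,
#'   0 = unassigned), `n_modules`, `sizes`, `eigengenes` (samples x
#'   modules), `hclust`.
#' @export
detect_modules <- function(tom, expr, cut_height = 0.99, min_size = 30L) {
  if (cut_height <= 0 || cut_height >= 1) {
    stop("configuration error: cut_height must be in (0, 1)")
  }
  if (min_size < 3L) stop("configuration error: min_size must be >= 3")
  hc <- stats::hclust(stats::as.dist(1 - tom), method = "average")
  raw <- stats::cutree(hc, h = cut_height)
  sizes <- table(raw)
  keep <- as.integer(names(sizes)[sizes >= min_size])
  labels <- integer(length(raw))
  if (length(keep) > 0L) {
    ord <- keep[order(-sizes[as.character(keep)], keep)]
    for (m in seq_along(ord)) labels[raw == ord[m]] <- m
  }
  names(labels) <- rownames(tom)

  nm <- max(labels)
  eig <- NULL
  if (nm > 0L && !is.null(expr)) {
    eig <- vapply(seq_len(nm), function(m) {
      x <- expr[names(labels)[labels == m], , drop = FALSE]
      xs <- t(scale(t(x)))
      sv <- svd(xs, nu = 1L, nv = 1L)
      e <- sv$v[, 1L] * sv$d[1L]
      if (mean(sv$u[, 1L]) < 0) e <- -e
      e
    }, numeric(ncol(expr)))
    dimnames(eig) <- list(colnames(expr), paste0("ME", seq_len(nm)))
  }
  structure(list(labels = labels, n_modules = nm,
                 sizes = tabulate(labels, nbins = max(nm, 1L)),
                 eigengenes = eig, hclust = hc),
            class = "module_partition")
}

#' Hypergeometric enrichment of transcription-factor targets per module
#'
#' For every module and every target set (each transcription factor, plus
#' the intersection of every pair when several sets are given), computes the
#' upper-tail hypergeometric probability of drawing at least the observed
#' number of targets in a module of that size from the universe, and
#' adjusts all module x set tests jointly by Benjamini-Hochberg.
#'
#' @param partition a [detect_modules()] result (or a named label vector).
#' @param target_sets named list of character vectors of target gene ids;
#'   genes outside the universe are dropped with a warning.
#' @param universe gene universe (default: the genes in the partition).
#' @return data.frame: module, set, overlap, module_size, n_targets,
#'   universe, p, adj_p.
#' @export
module_enrichment <- function(partition, target_sets, universe = NULL) {
  labels <- if (inherits(partition, "module_partition")) {
    partition$labels
  } else partition
  universe <- universe %||% names(labels)
  labels <- labels[names(labels) %in% universe]
  N <- length(universe)

  sets <- lapply(target_sets, function(s) {
    drop_ <- setdiff(s, universe)
    if (length(drop_) > 0L) {
      warning(length(drop_), " target gene(s) outside the universe dropped")
    }
    intersect(s, universe)
  })
  if (length(sets) >= 2L) {
    pairs <- utils::combn(names(sets), 2L, simplify = FALSE)
    for (pr in pairs) {
      sets[[paste(pr, collapse = "+")]] <-
        intersect(sets[[pr[1]]], sets[[pr[2]]])
    }
  }

  mods <- sort(unique(labels[labels > 0L]))
  rows <- list()
  for (m in mods) {
    members <- names(labels)[labels == m]
    n <- length(members)
    for (s in names(sets)) {
      K <- length(sets[[s]])
      x <- length(intersect(members, sets[[s]]))
      p <- stats::phyper(x - 1L, K, N - K, n, lower.tail = FALSE)
      rows[[length(rows) + 1L]] <- data.frame(
        module = m, set = s, overlap = x, module_size = n,
        n_targets = K, universe = N, p = p, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  out$adj_p <- stats::p.adjust(out$p, method = "BH")
  rownames(out) <- NULL
  out
}
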