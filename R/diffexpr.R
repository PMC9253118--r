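#' Saturated group-means design matrix for the factorial design
#'
#' Builds a cell-means design (`~ 0 + genotype.condition.timepoint`) over the
#' populated cells of the sample sheet. A single joint model over all cells
#' pools residual degrees of freedom across timepoints, which is what the
#' contrast framework assumes.
#'
#' @param samples sample sheet: data.frame with `sample_id`, `genotype`,
#'   `condition`, `timepoint`.
#' @return design matrix (samples x populated cells) with cell names
#'   `genotype.condition.timepoint`.
#' @export
make_design <- function(samples) {
  grp <- factor(paste(samples$genotype, samples$condition, samples$timepoint,
                      sep = "."))
  x <- stats::model.matrix(~ 0 + grp)
  colnames(x) <- levels(grp)
  rownames(x) <- samples$sample_id
  if (qr(x)$rank < ncol(x)) {
    stop("configuration error: design matrix is rank deficient")
  }
  x
}

#' Precision-weighted log-CPM expression with quantile normalization
#'
#' The transformation that carries counts into the linear-model framework:
#' `log2((count + 0.5) / (libsize + 1) * 1e6)`; an ordinary least-squares fit
#' of each gene on the design provides fitted values and residual standard
#' deviations; the gene-wise mean log-count versus sqrt-residual-sd trend is
#' smoothed by locally weighted regression (span 0.5, 2 robustness
#' iterations) and evaluated at every fitted value; the per-observation
#' precision weight is the predicted standard deviation to the power -4.
#' Afterwards the expression matrix (not the weights) is quantile-normalized
#' onto the column-mean reference distribution.
#'
#' @param counts non-negative integer matrix, genes x samples.
#' @param design design matrix from [make_design()].
#' @param span locally weighted regression span.
#' @return object of class `weighted_expr`: list with `E` (log2 expression,
#'   quantile-normalized), `weights` (matching matrix of positive precision
#'   weights), `design`, `lib_size`, and `all_zero` (flagged all-zero gene
#'   rows, retained).
#' @export
precision_weighted_logcpm <- function(counts, design, span = 0.5) {
  if (ncol(counts) < 2L) stop("input error: need >= 2 samples")
  lib <- colSums(counts)
  if (any(lib == 0)) {
    stop("input error: all-zero sample(s): ",
         paste(colnames(counts)[lib == 0], collapse = ", "))
  }
  if (anyDuplicated(rownames(counts)) || anyDuplicated(colnames(counts))) {
    stop("input error: duplicate gene or sample ids")
  }
  all_zero <- rowSums(counts) == 0

  y <- t(log2(t(counts + 0.5) / (lib + 1) * 1e6))

  ## shared-design OLS pass for the mean-variance trend
  x <- design
  n <- ncol(y); p <- ncol(x)
  if (n <= p) stop("input error: no residual degrees of freedom")
  xtxi <- solve(crossprod(x))
  coef <- y %*% x %*% xtxi              # genes x p
  fitted <- coef %*% t(x)
  res <- y - fitted
  sigma <- sqrt(rowSums(res^2) / (n - p))

  ## trend on the average log2 count scale, as the transformation prescribes
  sx <- rowMeans(y) + mean(log2(lib + 1)) - log2(1e6)
  sy <- sqrt(sigma)
  keep <- sigma > 0
  if (sum(keep) >= 10L) {
    lo <- stats::lowess(sx[keep], sy[keep], f = span, iter = 2L)
    trend <- stats::approxfun(lo$x, lo$y, rule = 2)
    fitted_cnt <- fitted + matrix(log2(lib + 1), nrow(y), n, byrow = TRUE) -
      log2(1e6)
    pred_sd <- pmax(trend(fitted_cnt), 1e-4)
  } else {
    pred_sd <- matrix(1, nrow(y), n)  # too few genes to estimate a trend
  }
  w <- pred_sd^-4
  dim(w) <- dim(y); dimnames(w) <- dimnames(y)

  ## ties = FALSE keeps every column an exact copy of the reference multiset
  E <- limma::normalizeQuantiles(y, ties = FALSE)
  structure(list(E = E, weights = w, design = design, lib_size = lib,
                 all_zero = all_zero),
            class = "weighted_expr")
}

#' Per-gene weighted least-squares fits
#'
#' Fits every gene's quantile-normalized log2 expression on the design by
#' weighted least squares with that gene's observation weights, recording
#' the coefficient vector, the residual variance `s_g^2`, the residual
#' degrees of freedom, and the unscaled coefficient covariance
#' `(X' W X)^-1` needed for contrast standard errors.
#'
#' @param we a [precision_weighted_logcpm()] result (or any list with `E`,
#'   `weights`, `design`).
#' @return object of class `gene_fits`: list with `coefficients`
#'   (genes x p), `sigma2`, `df_resid`, `cov_unscaled` (p x p x genes
#'   array), `design`.
#' @export
fit_gene_models <- function(we) {
  x <- we$design
  y <- we$E
  w <- we$weights
  n <- ncol(y); p <- ncol(x)
  ng <- nrow(y)
  df <- n - p
  coefs <- matrix(NA_real_, ng, p, dimnames = list(rownames(y), colnames(x)))
  sigma2 <- rep(NA_real_, ng)
  covu <- array(NA_real_, c(p, p, ng))
  for (g in seq_len(ng)) {
    sw <- sqrt(w[g, ])
    xw <- x * sw
    yw <- y[g, ] * sw
    ci <- chol2inv(chol(crossprod(xw)))
    b <- drop(ci %*% crossprod(xw, yw))
    r <- yw - drop(xw %*% b)
    coefs[g, ] <- b
    covu[, , g] <- ci
    sigma2[g] <- if (df > 0) sum(r^2) / df else NA_real_
  }
  structure(list(coefficients = coefs, sigma2 = sigma2,
                 df_resid = rep(df, ng), cov_unscaled = covu, design = x),
            class = "gene_fits")
}

#' Invert the trigamma function
#'
#' Newton iteration for `trigamma(x) = y`, used by the empirical-Bayes
#' moment estimator of the prior degrees of freedom.
#'
#' @param y positive value(s).
#' @return x with `trigamma(x) = y`.
#' @keywords internal
trigamma_inverse <- function(y) {
  vapply(y, function(yi) {
    if (!is.finite(yi) || yi <= 0) return(NaN)
    if (yi > 1e7) return(1 / sqrt(yi))
    if (yi < 1e-6) return(1 / yi)
    x <- 0.5 + 1 / yi
    for (i in 1:50) {
      tri <- trigamma(x)
      dif <- tri * (1 - tri / yi) / psigamma(x, deriv = 2L)
      x <- x + dif
      if (abs(dif) / x < 1e-10) break
    }
    x
  }, numeric(1))
}

#' Empirical-Bayes moderation of residual variances
#'
#' Estimates the scaled-F prior of the gene-wise residual variances by
#' moment matching on the log scale: with
#' `e_g = log(s_g^2) - digamma(d_g/2) + log(d_g/2)`, the prior satisfies
#' `E[e] = log(s0^2) + digamma(d0/2) - log(d0/2)` and
#' `Var[e] = trigamma(d_g/2) + trigamma(d0/2)`, so `d0` follows from a
#' trigamma inversion and `s0^2` from the mean equation. The posterior
#' (moderated) variance is the precision-weighted compromise
#' `(d0 s0^2 + d_g s_g^2) / (d0 + d_g)`. When the excess variance is not
#' positive the prior is degenerate: `d0 = Inf` and every posterior variance
#' equals `s0^2`.
#'
#' @param sigma2 gene-wise residual variances.
#' @param df_resid gene-wise residual degrees of freedom.
#' @return list with `d0` (prior df, possibly `Inf`), `s0_2` (prior
#'   variance), `s2_post` (posterior variances), `df_total`
#'   (`df_resid + d0`, capped at the total residual df for the `Inf` case).
#' @export
empirical_bayes_moderate <- function(sigma2, df_resid) {
  ok <- is.finite(sigma2) & df_resid > 0 & sigma2 > 0
  if (sum(ok) < 10L) {
    stop("input error: need >= 10 genes with positive residual df")
  }
  s2 <- sigma2[ok]; df <- df_resid[ok]
  e <- log(s2) - digamma(df / 2) + log(df / 2)
  emean <- mean(e)
  n <- length(e)
  evar <- mean((e - emean)^2) * n / (n - 1L) - mean(trigamma(df / 2))

  if (is.finite(evar) && evar > 0) {
    d0 <- 2 * trigamma_inverse(evar)
    s0_2 <- exp(emean + digamma(d0 / 2) - log(d0 / 2))
  } else {
    d0 <- Inf          # no excess spread beyond sampling: point-mass prior
    s0_2 <- mean(s2)
  }

  s2_post <- rep(s0_2, length(sigma2))
  if (is.finite(d0)) {
    s2_post[ok] <- (d0 * s0_2 + df * s2) / (d0 + df)
    ## genes without residual df shrink fully to the prior
  }
  df_total <- df_resid + d0
  if (!is.finite(d0)) df_total <- rep(sum(df_resid), length(sigma2))
  list(d0 = d0, s0_2 = s0_2, s2_post = s2_post, df_total = df_total)
}

#' Moderated t-test of an arbitrary contrast
#'
#' `logFC = c' beta_g`, standard error `sqrt(c' (X'WX)^-1 c * s2_post_g)`,
#' moderated t on `d0 + d_g` degrees of freedom, two-sided p-value.
#'
#' @param fit a [fit_gene_models()] result.
#' @param mod a [empirical_bayes_moderate()] result (pass `d0 = 0` via
#'   `mod = NULL` to get the ordinary t-test on `s_g^2`).
#' @param contrast numeric contrast vector over the design columns (named or
#'   in design-column order).
#' @param name contrast name carried into the result.
#' @return data.frame: gene, contrast, logFC, t, p.
#' @export
contrast_moderated_t <- function(fit, mod, contrast, name = "contrast") {
  p <- ncol(fit$coefficients)
  cv <- numeric(p)
  if (!is.null(names(contrast))) {
    missing_cells <- setdiff(names(contrast), colnames(fit$coefficients))
    if (length(missing_cells) > 0L) {
      stop("input error: contrast references empty cell(s): ",
           paste(missing_cells, collapse = ", "))
    }
    cv[match(names(contrast), colnames(fit$coefficients))] <- contrast
  } else {
    stopifnot(length(contrast) == p)
    cv <- contrast
  }
  lfc <- drop(fit$coefficients %*% cv)
  vc <- vapply(seq_len(dim(fit$cov_unscaled)[3]), function(g) {
    drop(crossprod(cv, fit$cov_unscaled[, , g] %*% cv))
  }, numeric(1))
  if (is.null(mod)) {
    s2 <- fit$sigma2
    dft <- fit$df_resid
  } else {
    s2 <- mod$s2_post
    dft <- mod$df_total
  }
  tstat <- lfc / sqrt(vc * s2)
  pval <- 2 * stats::pt(-abs(tstat), df = dft)
  data.frame(gene = rownames(fit$coefficients), contrast = name,
             logFC = lfc, t = tstat, p = pval,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Second-order heat-by-genotype interaction contrast
#'
#' The worked contrast of the analysis:
#' `(heat_genoA - control_genoA) - (heat_genoB - control_genoB)` at one
#' timepoint, isolating the genotype-dependent component of the heat
#' response. Swapping `genoA`/`genoB` flips its sign.
#'
#' @param fit a [fit_gene_models()] result with cell-means design columns
#'   named `genotype.condition.timepoint`.
#' @param mod moderation parameters (see [contrast_moderated_t()]).
#' @param genoA,genoB genotype labels (e.g. mutant vs wild type).
#' @param timepoint timepoint label.
#' @param conditions the (control, heat) condition labels.
#' @param name contrast name (default `"int.<genoA>.<timepoint>"`).
#' @return data.frame as [contrast_moderated_t()].
#' @export
interaction_contrast <- function(fit, mod, genoA, genoB, timepoint,
                                 conditions = c("control", "heat"),
                                 name = NULL) {
  cells <- c(
    paste(genoA, conditions[2], timepoint, sep = "."),
    paste(genoA, conditions[1], timepoint, sep = "."),
    paste(genoB, conditions[2], timepoint, sep = "."),
    paste(genoB, conditions[1], timepoint, sep = ".")
  )
  cvec <- stats::setNames(c(1, -1, -1, 1), cells)
  contrast_moderated_t(fit, mod, cvec,
                       name = name %||% paste("int", genoA, timepoint,
                                              sep = "."))
}

#' Within-genotype heat-versus-control contrast at one timepoint
#'
#' @inheritParams interaction_contrast
#' @param genotype genotype label.
#' @return data.frame as [contrast_moderated_t()].
#' @export
heat_contrast <- function(fit, mod, genotype, timepoint,
                          conditions = c("control", "heat"), name = NULL) {
  cells <- c(paste(genotype, conditions[2], timepoint, sep = "."),
             paste(genotype, conditions[1], timepoint, sep = "."))
  cvec <- stats::setNames(c(1, -1), cells)
  contrast_moderated_t(fit, mod, cvec,
                       name = name %||% paste("heat", genotype, timepoint,
                                              sep = "."))
}

#' Global Benjamini-Hochberg decisions across contrasts
#'
#' Pools the p-values of all genes and all contrasts into a single vector,
#' applies the Benjamini-Hochberg step-up adjustment jointly (the "global"
#' multiple-testing method), and calls each (gene, contrast) up (+1), down
#' (-1) or unchanged (0): non-zero iff adjusted p <= alpha and
#' |logFC| >= lfc, signed by the logFC.
#'
#' @param results list of [contrast_moderated_t()] data.frames (one per
#'   contrast, same genes).
#' @param alpha FDR level in (0, 1) (default 0.05).
#' @param lfc absolute log2-fold-change threshold (default 0).
#' @return object of class `decision_set`: list with matrices (genes x
#'   contrasts) `decision`, `logFC`, `p`, `adj_p`, plus `alpha`, `lfc`.
#' @export
decide_global <- function(results, alpha = 0.05, lfc = 0) {
  if (alpha <= 0 || alpha >= 1) {
    stop("configuration error: alpha must be in (0, 1)")
  }
  if (is.data.frame(results)) results <- list(results)
  genes <- results[[1]]$gene
  cn <- vapply(results, function(r) r$contrast[1], character(1))
  mk <- function(field) {
    m <- vapply(results, function(r) {
      stopifnot(identical(r$gene, genes))
      r[[field]]
    }, numeric(length(genes)))
    dim(m) <- c(length(genes), length(results))
    dimnames(m) <- list(genes, cn)
    m
  }
  pm <- mk("p"); fcm <- mk("logFC")
  adj <- stats::p.adjust(as.vector(pm), method = "BH")
  dim(adj) <- dim(pm); dimnames(adj) <- dimnames(pm)
  dec <- sign(fcm) * (adj <= alpha & abs(fcm) >= lfc)
  mode(dec) <- "integer"
  structure(list(decision = dec, logFC = fcm, p = pm, adj_p = adj,
                 alpha = alpha, lfc = lfc),
            class = "decision_set")
}

#' Sample Pearson-correlation matrix with display ordering
#'
#' Pairwise Pearson correlation of the per-sample expression profiles over
#' all genes, plus the leaf order of average-linkage hierarchical clustering
#' on `1 - correlation` for heat-map display. Zero-variance samples yield
#' missing correlations (recorded as NA).
#'
#' @param E expression matrix, genes x samples.
#' @return list with `cor` (symmetric, unit diagonal), `order`, `hclust`.
#' @export
sample_correlation <- function(E) {
  if (ncol(E) < 2L) stop("input error: need >= 2 samples")
  sds <- apply(E, 2L, stats::sd)
  C <- suppressWarnings(stats::cor(E))
  C[sds == 0, ] <- NA_real_
  C[, sds == 0] <- NA_real_
  diag(C) <- 1
  Cc <- C; Cc[is.na(Cc)] <- 0
  hc <- stats::hclust(stats::as.dist(1 - Cc), method = "average")
  list(cor = C, order = hc$order, hclust = hc)
}

#' Classical (Torgerson) multidimensional scaling of samples
#'
#' Euclidean distances between samples over all genes, double-centred and
#' eigendecomposed; the top-`dims` coordinates reproduce the input distances
#' exactly when the configuration is `dims`-dimensional. Warns when the
#' negative eigenvalue mass exceeds `tol` (non-Euclidean input).
#'
#' @param x expression matrix (genes x samples) or a `dist` object over
#'   samples.
#' @param dims embedding dimension (default 2).
#' @param tol tolerated relative negative eigenvalue mass.
#' @return list with `points` (samples x dims), `eig`.
#' @export
classical_mds <- function(x, dims = 2L, tol = 1e-8) {
  d <- if (inherits(x, "dist")) x else stats::dist(t(x))
  n <- attr(d, "Size")
  if (n < 3L) stop("input error: need >= 3 samples")
  mds <- suppressWarnings(stats::cmdscale(d, k = min(dims, n - 1L),
                                          eig = TRUE))
  neg <- sum(pmin(mds$eig, 0)^2)
  pos <- sum(pmax(mds$eig, 0)^2)
  if (pos > 0 && neg / pos > tol) {
    warning("non-Euclidean input: negative eigenvalue mass ",
            signif(neg / pos, 3))
  }
  pts <- mds$points
  if (ncol(pts) < dims) {
    pts <- cbind(pts, matrix(0, n, dims - ncol(pts)))
  }
  list(points = pts, eig = mds$eig)
}
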