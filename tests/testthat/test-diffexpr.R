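test_that("log-CPM uses the 0.5 / +1 offsets and quantile normalization holds", {
  counts <- rbind(g1 = c(100, 100), g2 = c(999900, 999900))
  colnames(counts) <- c("s1", "s2")
  design <- matrix(1, 2, 1, dimnames = list(c("s1", "s2"), "mu"))
  we <- precision_weighted_logcpm(counts, design)
  # identical columns: quantile normalization is the identity
  expect_equal(we$E["g1", "s1"], log2(100.5 * 1e6 / (1e6 + 1)),
               tolerance = 1e-9)
  expect_equal(we$E[, "s1"], we$E[, "s2"])
  expect_true(all(we$weights > 0))
  expect_equal(dim(we$weights), dim(we$E))
})

test_that("quantile-normalized columns share one sorted value multiset", {
  set.seed(4)
  counts <- matrix(rnbinom(300 * 4, mu = 200, size = 10), 300, 4,
                   dimnames = list(sprintf("g%03d", 1:300),
                                   paste0("s", 1:4)))
  counts[, 4] <- counts[sample(300), 3]  # a row permutation of column 3
  design <- matrix(1, 4, 1, dimnames = list(colnames(counts), "mu"))
  we <- precision_weighted_logcpm(counts, design)
  sorted <- apply(we$E, 2L, sort)
  for (j in 2:4) expect_equal(sorted[, 1], sorted[, j], tolerance = 1e-9)
  expect_error(precision_weighted_logcpm(counts[, 1, drop = FALSE], design),
               ">= 2 samples")
  bad <- counts; bad[, 2] <- 0
  expect_error(precision_weighted_logcpm(bad, design), "all-zero sample")
})

test_that("weighted least squares interpolates noise-free cell means", {
  samples <- expand.grid(replicate = 1:2, timepoint = "0h",
                         condition = c("control", "heat"),
                         genotype = c("WT", "OE"), stringsAsFactors = FALSE)
  samples$sample_id <- paste0("s", seq_len(nrow(samples)))
  X <- make_design(samples)
  means <- rbind(gA = c(1, 2, 3, 4), gB = c(0, 0, 5, 5))
  colnames(means) <- colnames(X)
  E <- means %*% t(X)
  we <- list(E = E, weights = matrix(1, 2, nrow(samples),
                                     dimnames = dimnames(E)), design = X)
  fit <- fit_gene_models(we)
  expect_equal(fit$coefficients, means, tolerance = 1e-12)
  expect_equal(unname(fit$sigma2), c(0, 0), tolerance = 1e-12)

  # equal weights reduce to ordinary least squares
  set.seed(9)
  E2 <- E + matrix(rnorm(length(E)), nrow(E))
  we2 <- we; we2$E <- E2
  fit2 <- fit_gene_models(we2)
  ols <- t(apply(E2, 1L, function(y) qr.coef(qr(X), y)))
  expect_equal(unname(fit2$coefficients), unname(ols), tolerance = 1e-10)
})

test_that("empirical-Bayes moment estimator recovers a scaled-F prior", {
  set.seed(31)
  d0 <- 4; s0 <- 2; dg <- 10; n <- 5000
  s2 <- s0 * rf(n, dg, d0)
  mod <- empirical_bayes_moderate(s2, rep(dg, n))
  expect_lt(abs(mod$d0 - d0) / d0, 0.15)
  expect_lt(abs(mod$s0_2 - s0) / s0, 0.15)
  # posterior variances sit strictly between the observed and the prior
  inside <- (mod$s2_post > pmin(s2, mod$s0_2) - 1e-12) &
    (mod$s2_post < pmax(s2, mod$s0_2) + 1e-12)
  expect_true(all(inside))
  # independent cross-check against the reference moderation implementation
  sq <- limma::squeezeVar(s2, df = dg)
  expect_lt(abs(mod$d0 - sq$df.prior) / sq$df.prior, 0.01)
  expect_lt(abs(mod$s0_2 - sq$var.prior) / sq$var.prior, 0.01)
  expect_equal(mod$s2_post, sq$var.post, tolerance = 0.02)
})

test_that("identical residual variances give the degenerate infinite prior", {
  mod <- empirical_bayes_moderate(rep(2, 50), rep(10, 50))
  expect_identical(mod$d0, Inf)
  expect_equal(mod$s2_post, rep(mod$s0_2, 50), tolerance = 1e-12)
  expect_equal(mod$s0_2, 2, tolerance = 1e-9)
})

test_that("without moderation the contrast t equals the ordinary t-test", {
  set.seed(17)
  samples <- data.frame(sample_id = paste0("s", 1:10),
                        genotype = "WT", condition = rep(c("control", "heat"),
                                                         each = 5),
                        timepoint = "0h")
  X <- make_design(samples)
  E <- matrix(rnorm(30 * 10), 30, 10,
              dimnames = list(sprintf("g%02d", 1:30), samples$sample_id))
  we <- list(E = E, weights = matrix(1, 30, 10, dimnames = dimnames(E)),
             design = X)
  fit <- fit_gene_models(we)
  res <- contrast_moderated_t(fit, NULL,
                              setNames(c(1, -1), colnames(X)[c(2, 1)]))
  for (g in c(1, 15, 30)) {
    tt <- t.test(E[g, 6:10], E[g, 1:5], var.equal = TRUE)
    expect_equal(res$t[g], unname(tt$statistic), tolerance = 1e-9)
    expect_equal(res$p[g], tt$p.value, tolerance = 1e-9)
  }
})

test_that("interaction contrasts are antisymmetric and null for additive genes", {
  samples <- expand.grid(replicate = 1:3, timepoint = "0h",
                         condition = c("control", "heat"),
                         genotype = c("WT", "KO"), stringsAsFactors = FALSE)
  samples$sample_id <- paste0("s", seq_len(nrow(samples)))
  X <- make_design(samples)
  # additive gene: heat effect +2 in both genotypes, genotype offset +1
  cellmeans <- setNames(c(5, 7, 6, 8), colnames(X))
  cellmeans[] <- c(`KO.control.0h` = 6, `KO.heat.0h` = 8,
                   `WT.control.0h` = 5, `WT.heat.0h` = 7)[names(cellmeans)]
  E <- matrix(rep(cellmeans[colnames(X)] %*% t(X), 2), 2, byrow = TRUE,
              dimnames = list(c("gA", "gB"), samples$sample_id))
  set.seed(2); E[2, ] <- E[2, ] + rnorm(ncol(E), 0, 0.1)
  we <- list(E = E, weights = matrix(1, 2, ncol(E), dimnames = dimnames(E)),
             design = X)
  fit <- fit_gene_models(we)
  a <- interaction_contrast(fit, NULL, "KO", "WT", "0h")
  b <- interaction_contrast(fit, NULL, "WT", "KO", "0h")
  expect_equal(a$logFC[1], 0, tolerance = 1e-12)  # purely additive
  expect_equal(a$logFC, -b$logFC, tolerance = 1e-12)
  expect_error(interaction_contrast(fit, NULL, "KO", "OE", "0h"),
               "empty cell")
})

test_that("global BH decisions match the step-up hand computation", {
  res <- data.frame(gene = paste0("g", 1:4), contrast = "c1",
                    logFC = c(1, -1, 2, 0.5), t = 1,
                    p = c(0.01, 0.02, 0.03, 0.04))
  dec <- decide_global(list(res), alpha = 0.05)
  expect_equal(unname(dec$adj_p[, 1]), rep(0.04, 4))
  expect_equal(unname(dec$decision[, 1]), c(1L, -1L, 1L, 1L))

  single <- decide_global(list(res[1, ]), alpha = 0.05)
  expect_equal(unname(single$adj_p[1, 1]), 0.01)  # single p: adj == raw

  # alpha = 1, lfc = 0 flags everything with p <= 1 (sanity saturation)
  res2 <- res; res2$p <- runif(4, 0.5, 1)
  sat <- decide_global(list(res2), alpha = 0.999999, lfc = 0)
  expect_true(all(sat$decision != 0L))
  expect_error(decide_global(list(res), alpha = 1.5), "alpha")

  # pooling is global: adding a second contrast changes adjusted values
  res3 <- res; res3$contrast <- "c2"; res3$p <- c(0.2, 0.3, 0.4, 0.5)
  both <- decide_global(list(res, res3))
  expect_equal(unname(both$adj_p[, "c1"]),
               p.adjust(c(res$p, res3$p), "BH")[1:4])
})

test_that("sample correlation matrix is symmetric with unit diagonal", {
  E <- cbind(s1 = c(1, 2, 3), s2 = c(1, 2, 3), s3 = c(3, 2, 1))
  sc <- sample_correlation(E)
  expect_equal(sc$cor["s1", "s2"], 1)        # duplicated sample
  expect_equal(sc$cor["s1", "s3"], -1)       # reversed rank order
  expect_true(isSymmetric(sc$cor))
  expect_equal(unname(diag(sc$cor)), rep(1, 3))
  E0 <- cbind(s1 = c(1, 2, 3), s2 = c(5, 5, 5), s3 = c(3, 1, 2))
  sc0 <- sample_correlation(E0)
  expect_true(is.na(sc0$cor["s1", "s2"]))    # zero-variance sample
})

test_that("classical MDS reproduces low-dimensional configurations exactly", {
  # collinear points at 0, 3, 7: pairwise distances 3, 4, 7
  d <- dist(matrix(c(0, 3, 7), ncol = 1))
  emb <- classical_mds(d, dims = 1)
  expect_equal(sort(as.numeric(dist(emb$points))), c(3, 4, 7),
               tolerance = 1e-9)

  set.seed(6)
  pts <- matrix(rnorm(10 * 2), 10, 2)
  emb2 <- classical_mds(dist(pts), dims = 2)
  expect_equal(as.numeric(dist(emb2$points)), as.numeric(dist(pts)),
               tolerance = 1e-9)

  same <- matrix(5, 4, 3)  # all points identical -> all coordinates 0
  emb3 <- classical_mds(dist(same), dims = 2)
  expect_equal(max(abs(emb3$points)), 0, tolerance = 1e-9)
})
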