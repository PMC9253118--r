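test_that("adjacency applies the soft power to correlations", {
  # construct two genes with correlation exactly 0.5
  n <- 16
  x <- rep(c(1, -1), n / 2)
  z <- rep(c(1, 1, -1, -1), n / 4)
  z <- resid(lm(z ~ x)); z <- z / sqrt(sum(z^2))
  y <- 0.5 * x / sqrt(sum(x^2)) + sqrt(0.75) * z
  expr <- rbind(g1 = x, g2 = y, g3 = -x)
  expect_equal(cor(x, y), 0.5, tolerance = 1e-12)

  a <- build_adjacency(expr, power = 2)
  expect_equal(a["g1", "g2"], 0.25, tolerance = 1e-12)  # 0.5^2
  expect_equal(a["g1", "g3"], 1)                        # |cor| = 1
  expect_equal(unname(diag(a)), rep(1, 3))
  expect_true(isSymmetric(unname(a)))

  s <- build_adjacency(expr, power = 2, type = "signed")
  expect_equal(s["g1", "g3"], 0)   # cor -1 -> ((1-1)/2)^b = 0
  expect_error(build_adjacency(rbind(g1 = rep(1, 5), g2 = 1:5)),
               "constant")
})

test_that("raising the power never increases off-diagonal adjacency", {
  set.seed(8)
  expr <- matrix(rnorm(30 * 20), 30, 20,
                 dimnames = list(sprintf("g%02d", 1:30), NULL))
  a1 <- build_adjacency(expr, power = 1)
  a6 <- build_adjacency(expr, power = 6)
  off <- upper.tri(a1)
  expect_true(all(a6[off] <= a1[off] + 1e-12))
  expect_lt(mean(rowSums(a6) - 1), mean(rowSums(a1) - 1))
})

test_that("scale-free fit index recognizes a power-law degree distribution", {
  set.seed(12)
  # degrees sampled from p(k) ~ k^-2.5: the log-log regression must fit well
  k <- sample(1:2000, 4000, replace = TRUE, prob = (1:2000)^-2.5)
  sf <- scale_free_fit(k + runif(4000))
  expect_gte(sf$r2, 0.8)
  expect_lt(sf$slope, 0)
  # an approximately uniform degree distribution scores poorly
  sf_flat <- scale_free_fit(runif(4000, 1, 100))
  expect_lt(abs(sf_flat$r2), 0.5)
})

test_that("soft power scan reports one row per power", {
  set.seed(3)
  expr <- matrix(rnorm(60 * 18), 60, 18,
                 dimnames = list(sprintf("g%02d", 1:60), NULL))
  sc <- soft_power_scan(expr, powers = c(2, 6))
  expect_equal(sc$power, c(2, 6))
  expect_lt(sc$mean_k[2], sc$mean_k[1])
  sc1 <- soft_power_scan(expr, powers = 6)
  expect_equal(nrow(sc1), 1L)
  expr2 <- rbind(expr, const = rep(1, 18))
  expect_warning(soft_power_scan(expr2, powers = 6), "constant")
})

test_that("topological overlap matches its closed form", {
  # 3-node complete graph with unit adjacency: TOM = (1 + 1)/(2 + 1 - 1) = 1
  a <- matrix(1, 3, 3)
  expect_true(all(topological_overlap(a) == 1))

  # no edges: off-diagonal TOM 0
  a0 <- diag(3)
  t0 <- topological_overlap(a0)
  expect_true(all(t0[upper.tri(t0)] == 0))

  # hand evaluation on an asymmetric-weight triangle
  a2 <- rbind(c(1, 0.5, 0.2), c(0.5, 1, 0.8), c(0.2, 0.8, 1))
  t2 <- topological_overlap(a2)
  k <- rowSums(a2) - 1
  expected_12 <- (0.2 * 0.8 + 0.5) / (min(k[1], k[2]) + 1 - 0.5)
  expect_equal(t2[1, 2], expected_12, tolerance = 1e-12)

  # random symmetric adjacency: TOM in [0, 1], symmetric
  set.seed(15)
  r <- matrix(runif(25), 5, 5); r <- (r + t(r)) / 2; diag(r) <- 1
  tr_ <- topological_overlap(r)
  expect_true(all(tr_ >= 0 & tr_ <= 1 + 1e-12))
  expect_true(isSymmetric(unname(tr_)))
})

test_that("module detection recovers planted modules and rejects noise", {
  cfg <- sim_config(n_genes = 1000, n_direct_targets = 0, n_modules = 2,
                    module_sizes = c(50, 50), module_cor = 0.8,
                    prop_heat_responsive = 0, n_bound_nontargets = 0,
                    n_decoy_peaks = 10, seed = 19)
  tr <- plant_truth(cfg)
  cm <- simulate_counts(cfg, tr)
  E <- precision_weighted_logcpm(cm$counts, make_design(cm$samples))$E
  tom <- topological_overlap(build_adjacency(E, power = 6))
  part <- detect_modules(tom, E, cut_height = 0.99, min_size = 30)

  planted <- tr$genes$module[match(names(part$labels), tr$genes$gene_id)]
  inmod <- planted > 0
  expect_equal(rand_index(part$labels[inmod], planted[inmod]), 1)
  expect_equal(part$n_modules, 2L)
  # labels ordered by decreasing size; sizes consistent
  expect_equal(part$sizes, unname(tabulate(part$labels)))
  expect_true(all(diff(part$sizes) <= 0))
  # eigengenes: one column per module, sign-anchored
  expect_equal(ncol(part$eigengenes), 2L)
  # determinism
  part2 <- detect_modules(tom, E, cut_height = 0.99, min_size = 30)
  expect_identical(part$labels, part2$labels)
  expect_error(detect_modules(tom, E, cut_height = 1.5), "cut_height")
})

test_that("independent noise genes stay unassigned at the default cut", {
  set.seed(23)
  expr <- matrix(rnorm(80 * 30), 80, 30,
                 dimnames = list(sprintf("g%02d", 1:80), NULL))
  tom <- topological_overlap(build_adjacency(expr, power = 6))
  part <- detect_modules(tom, expr, cut_height = 0.99, min_size = 30)
  expect_gte(mean(part$labels == 0), 0.9)
})

test_that("hypergeometric enrichment matches closed-form values", {
  labels <- setNames(c(rep(1L, 4), rep(0L, 6)), paste0("g", 1:10))
  # N = 10, K = 5, n = 4, x = 4: p = C(5,4)/C(10,4) = 5/210
  res <- module_enrichment(labels, list(TF = paste0("g", c(1:4, 10))))
  expect_equal(res$p, 5 / 210, tolerance = 1e-12)

  # x = 0: upper tail is 1
  res0 <- module_enrichment(labels, list(TF = paste0("g", 6:10)))
  expect_equal(res0$overlap, 0L)
  expect_equal(res0$p, 1, tolerance = 1e-12)

  # module = universe: overlap = K, p = 1
  all1 <- setNames(rep(1L, 10), paste0("g", 1:10))
  resU <- module_enrichment(all1, list(TF = paste0("g", 1:5)))
  expect_equal(resU$overlap, 5L)
  expect_equal(resU$p, 1, tolerance = 1e-12)

  # intersection sets appear when two TFs are given; outside genes dropped
  expect_warning(
    res2 <- module_enrichment(labels,
                              list(A = paste0("g", 1:3),
                                   B = c(paste0("g", 2:4), "nope"))),
    "outside the universe"
  )
  expect_setequal(unique(res2$set), c("A", "B", "A+B"))
  expect_equal(res2$n_targets[res2$set == "A+B"], 2L)
})
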