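write_test_gff <- function(path, extra_feature = TRUE) {
  lines <- c(
    "##gff-version 3",
    "chr1\ttest\tgene\t5000\t7000\t.\t+\t.\tID=gPlus",
    "chr1\ttest\tgene\t6000\t8000\t.\t-\t.\tID=gMinus"
  )
  if (extra_feature) {
    lines <- c(lines, "chr1\ttest\tmRNA\t5000\t7000\t.\t+\t.\tID=t1;Parent=gPlus")
  }
  writeLines(lines, path)
  path
}

test_that("gene models parse with strand-aware TSS", {
  f <- withr::local_tempfile(fileext = ".gff3")
  write_test_gff(f)
  expect_message(g <- parse_gene_models(f), "skipped")
  expect_equal(nrow(g), 2L)
  expect_equal(g$tss[g$gene_id == "gPlus"], 5000L)   # + strand: start
  expect_equal(g$tss[g$gene_id == "gMinus"], 8000L)  # - strand: end
})

test_that("narrowPeak parses 0-based half-open and round-trips intervals", {
  f <- withr::local_tempfile(fileext = ".narrowPeak")
  writeLines(c("chr1\t4200\t4300\tpk1\t500\t.\t5.5\t-1\t-1\t50",
               "chr1\t9000\t9400\tpk2\t200\t.\t3.0\t-1\t-1\t-1"), f)
  p <- parse_peaks(f)
  expect_equal(p$start, c(4201L, 9001L))  # 1-based inclusive internally
  expect_equal(p$end, c(4300L, 9400L))
  expect_equal(p$summit, c(50L, -1L))

  out <- withr::local_tempfile(fileext = ".narrowPeak")
  write_peaks(p, out)
  orig3 <- vapply(strsplit(readLines(f), "\t"),
                  function(x) paste(x[1:4], collapse = "\t"), character(1))
  back3 <- vapply(strsplit(readLines(out), "\t"),
                  function(x) paste(x[1:4], collapse = "\t"), character(1))
  expect_identical(back3, orig3)

  empty <- withr::local_tempfile(fileext = ".narrowPeak")
  writeLines(character(0), empty)
  expect_equal(nrow(parse_peaks(empty)), 0L)
})

test_that("nearest TSS distance follows the coordinate conventions", {
  genes <- data.frame(gene_id = c("gA", "gB"), chrom = "chr1",
                      strand = c("+", "+"), start = c(5000L, 20000L),
                      end = c(7000L, 22000L), tss = c(5000L, 20000L))
  # narrowPeak [4200, 4300) is 1-based [4201, 4300]: gap to TSS 5000 is 700
  peaks <- data.frame(peak_id = "pk1", chrom = "chr1",
                      start = 4201L, end = 4300L, score = 0, strand = ".",
                      signal = 0, p = -1, q = -1, summit = -1L)
  nt <- nearest_tss(peaks, genes)
  expect_equal(nt$distance, 700)
  expect_equal(nt$gene_id, "gA")
  expect_true(nt$upstream)

  # TSS inside the peak: distance 0
  peaks$start <- 4900L; peaks$end <- 5100L
  expect_equal(nearest_tss(peaks, genes)$distance, 0)

  # equidistant TSSs: both reported, tie flagged, lower id wins
  peaks$start <- 12400L; peaks$end <- 12600L
  nt2 <- nearest_tss(peaks, genes)
  expect_equal(nrow(nt2), 2L)
  expect_true(all(nt2$tie))
  expect_equal(nt2$gene_id[nt2$nearest], "gA")

  # chromosome without genes
  peaks$chrom <- "chrX"
  nt3 <- nearest_tss(peaks, genes)
  expect_true(is.na(nt3$gene_id) && is.infinite(nt3$distance))
})

test_that("promoter window rule is strand-aware any-overlap", {
  genes <- data.frame(gene_id = c("gP", "gM"), chrom = "chr1",
                      strand = c("+", "-"), start = c(5000L, 3000L),
                      end = c(7000L, 5000L), tss = c(5000L, 5000L))
  pk <- function(s, e, chrom = "chr1") {
    data.frame(peak_id = "p", chrom = chrom, start = s, end = e, score = 0,
               strand = ".", signal = 0, p = -1, q = -1, summit = -1L)
  }
  # + strand TSS 5000: peak 4100-4900 overlaps the (4000, 5000) window
  expect_true("gP" %in% promoter_bound_genes(pk(4100L, 4900L), genes[1, ]))
  # peak ending 1100 bp upstream never overlaps
  expect_false("gP" %in% promoter_bound_genes(pk(3000L, 3900L), genes[1, ]))
  # - strand TSS 5000: downstream-in-genome peak 5200-5400 qualifies
  expect_true("gM" %in% promoter_bound_genes(pk(5200L, 5400L), genes[2, ]))
  expect_error(promoter_bound_genes(pk(1L, 2L), genes, window = 0),
               "window")
  # summit mode: summit outside the window disqualifies an overlapping peak
  p2 <- pk(4900L, 5400L); p2$summit <- 400L  # summit at 5300 (1-based 5301)
  expect_true("gP" %in% promoter_bound_genes(p2, genes[1, ],
                                             mode = "overlap"))
  expect_false("gP" %in% promoter_bound_genes(p2, genes[1, ],
                                              mode = "summit"))
})

test_that("nearest TSS and window rule agree with brute-force oracles", {
  set.seed(101)
  for (rep in 1:50) {
    inst <- random_annotation_instance(sample(5:40, 1), sample(5:60, 1))
    nt <- nearest_tss(inst$peaks, inst$genes)
    for (pid in inst$peaks$peak_id) {
      o <- oracle_nearest(inst$peaks[inst$peaks$peak_id == pid, ],
                          inst$genes)
      got <- nt[nt$peak_id == pid, ]
      expect_equal(unique(got$distance), o$distance)
      if (is.finite(o$distance)) expect_equal(sort(got$gene_id), o$genes)
    }
    w <- sample(c(200L, 1000L), 1)
    bound <- promoter_bound_genes(inst$peaks, inst$genes, window = w)
    oracle <- inst$genes$gene_id[vapply(seq_len(nrow(inst$genes)),
      function(i) oracle_window_qualifies(inst$genes[i, ], inst$peaks, w),
      logical(1))]
    expect_equal(bound, sort(oracle))
  }
})

test_that("promoter filter recovers the planted qualification flags exactly", {
  cfg <- small_config()
  tr <- plant_truth(cfg)
  d <- withr::local_tempdir()
  gff <- file.path(d, "g.gff3"); npk <- file.path(d, "p.npk")
  simulate_annotation_and_peaks(cfg, tr, gff, npk)
  bound <- promoter_bound_genes(parse_peaks(npk), parse_gene_models(gff),
                                window = cfg$promoter_window)
  expect_identical(bound, sort(tr$promoter_bound))
  # decoys are placed clear of every TSS, so they can never qualify
  decoys <- tr$peaks[tr$peaks$class == "decoy", ]
  gap <- vapply(seq_len(nrow(decoys)), function(i) {
    min(pmax(tr$genes$tss - decoys$end[i], decoys$start[i] - tr$genes$tss))
  }, numeric(1))
  expect_true(all(gap > cfg$promoter_window))
})
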