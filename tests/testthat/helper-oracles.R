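# Independent brute-force oracles and tiny fixture builders.
# These deliberately re-derive results from first principles (enumeration,
# all-pairs scans, closed forms) and never call the code paths they check.

# Upper-tail hypergeometric probability by exhaustive enumeration.
oracle_hyper_upper <- function(x, K, N, n) {
  i <- seq(from = x, to = min(n, K))
  if (x > min(n, K)) return(0)
  sum(choose(K, i) * choose(N - K, n - i)) / choose(N, n)
}

# All-pairs nearest-TSS scan: returns min distance and the tied gene ids.
oracle_nearest <- function(peak, genes) {
  g <- genes[genes$chrom == peak$chrom, ]
  if (nrow(g) == 0L) return(list(distance = Inf, genes = NA_character_))
  d <- vapply(seq_len(nrow(g)), function(i) {
    tss <- g$tss[i]
    if (tss >= peak$start && tss <= peak$end) 0L
    else min(abs(tss - peak$start), abs(tss - peak$end))
  }, numeric(1))
  list(distance = min(d), genes = sort(g$gene_id[d == min(d)]))
}

# Position-set promoter-window check: materialize the open upstream window
# as integer positions and intersect with the peak's positions.
oracle_window_qualifies <- function(gene, peaks, window) {
  pos <- if (gene$strand == "+") {
    seq(gene$tss - window + 1L, gene$tss - 1L)
  } else {
    seq(gene$tss + 1L, gene$tss + window - 1L)
  }
  any(vapply(seq_len(nrow(peaks)), function(i) {
    peaks$chrom[i] == gene$chrom &&
      length(intersect(pos, seq(peaks$start[i], peaks$end[i]))) > 0L
  }, logical(1)))
}

# Random annotation instance for property tests.
random_annotation_instance <- function(n_genes, n_peaks, span = 50000L) {
  start <- sort(sample.int(span, n_genes))
  len <- sample(100:2000, n_genes, replace = TRUE)
  strand <- sample(c("+", "-"), n_genes, replace = TRUE)
  genes <- data.frame(
    gene_id = sprintf("g%03d", seq_len(n_genes)),
    chrom = sample(c("chr1", "chr2"), n_genes, replace = TRUE),
    strand = strand, start = start, end = start + len,
    stringsAsFactors = FALSE
  )
  genes$tss <- ifelse(genes$strand == "+", genes$start, genes$end)
  ps <- sample.int(span, n_peaks)
  peaks <- data.frame(
    peak_id = sprintf("p%03d", seq_len(n_peaks)),
    chrom = sample(c("chr1", "chr2"), n_peaks, replace = TRUE),
    start = ps, end = ps + sample(50:500, n_peaks, replace = TRUE),
    score = 0, strand = ".", signal = 0, p = -1, q = -1,
    summit = -1L, stringsAsFactors = FALSE
  )
  list(genes = genes, peaks = peaks)
}

# Small simulation config used across tests.
small_config <- function(...) {
  defaults <- list(n_genes = 300, n_direct_targets = 20, n_modules = 2,
                   module_sizes = c(30, 30), n_bound_nontargets = 30,
                   n_decoy_peaks = 50, seed = 11)
  do.call(sim_config, utils::modifyList(defaults, list(...)))
}

# Hand-built long-format Ct table.
toy_ct_table <- function() {
  grid <- expand.grid(
    arm = c("control", "primed"), timepoint = c("0h", "1h"),
    bio_rep = 1:2, gene_id = c("REF", "gA", "gB"),
    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE
  )
  grid$sample_id <- with(grid, paste(arm, timepoint, bio_rep, sep = "_"))
  grid$ct <- 20
  grid$ct[grid$gene_id == "gA"] <- 25
  grid$ct[grid$gene_id == "gB"] <- 27
  # gA induced 4-fold at 0h in the primed arm
  grid$ct[grid$gene_id == "gA" & grid$arm == "primed" &
            grid$timepoint == "0h"] <- 23
  grid
}

# Decision cube from explicit decision / logFC matrices.
make_cube <- function(decision, logFC = NULL) {
  if (is.null(logFC)) logFC <- decision * 1.0
  ds <- structure(
    list(decision = decision, logFC = logFC,
         p = decision * 0, adj_p = decision * 0, alpha = 0.05, lfc = 0),
    class = "decision_set"
  )
  build_decision_cube(ds)
}
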