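#' Parse gene models from a GFF3 file
#'
#' Reads `gene` features (other feature types are skipped and counted in a
#' message), keeps 1-based inclusive coordinates, and derives the
#' transcription start site strand-aware: `start` on the plus strand, `end`
#' on the minus strand.
#'
#' @param path GFF3 file path.
#' @return data.frame: gene_id, chrom, strand, start, end, tss.
#' @export
parse_gene_models <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  skipped <- sum(gr$type != "gene")
  if (skipped > 0L) {
    message(skipped, " non-gene feature(s) skipped")
  }
  gr <- gr[gr$type == "gene"]
  ids <- gr$ID
  if (is.null(ids) || anyNA(ids)) {
    stop("input error: gene feature without ID attribute")
  }
  strand <- as.character(GenomicRanges::strand(gr))
  if (any(strand == "*")) {
    stop("input error: gene feature without strand")
  }
  start <- GenomicRanges::start(gr)
  end <- GenomicRanges::end(gr)
  data.frame(
    gene_id = as.character(ids),
    chrom = as.character(GenomicRanges::seqnames(gr)),
    strand = strand,
    start = start, end = end,
    tss = ifelse(strand == "+", start, end),
    stringsAsFactors = FALSE
  )
}

#' Parse binding peaks from a narrowPeak file
#'
#' narrowPeak is BED6+4 (0-based half-open); intervals are normalized to the
#' internal 1-based inclusive convention (start + 1). The summit offset is
#' kept as written (-1 = unknown; summit position resolves to the interval
#' midpoint downstream).
#'
#' @param path narrowPeak file path.
#' @return data.frame: peak_id, chrom, start, end (1-based inclusive),
#'   score, strand, signal, p, q, summit (offset from the 0-based start).
#' @export
parse_peaks <- function(path) {
  if (file.size(path) == 0L) {
    return(data.frame(peak_id = character(0), chrom = character(0),
                      start = integer(0), end = integer(0),
                      score = numeric(0), strand = character(0),
                      signal = numeric(0), p = numeric(0), q = numeric(0),
                      summit = integer(0), stringsAsFactors = FALSE))
  }
  gr <- rtracklayer::import(
    path, format = "BED",
    extraCols = c(signalValue = "numeric", pValue = "numeric",
                  qValue = "numeric", peak = "integer")
  )
  data.frame(
    peak_id = gr$name,
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr),
    end = GenomicRanges::end(gr),
    score = gr$score,
    strand = as.character(GenomicRanges::strand(gr)),
    signal = gr$signalValue, p = gr$pValue, q = gr$qValue,
    summit = gr$peak,
    stringsAsFactors = FALSE
  )
}

#' Write peaks back to narrowPeak
#'
#' Converts the internal 1-based inclusive intervals back to 0-based
#' half-open, so a parse/write round trip reproduces the original intervals.
#'
#' @param peaks data.frame as returned by [parse_peaks()].
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_peaks <- function(peaks, path) {
  strand <- ifelse(peaks$strand %in% c("+", "-"), peaks$strand, ".")
  writeLines(sprintf("%s\t%d\t%d\t%s\t%g\t%s\t%g\t%g\t%g\t%d",
                     peaks$chrom, peaks$start - 1L, peaks$end,
                     peaks$peak_id, peaks$score, strand,
                     peaks$signal, peaks$p, peaks$q, peaks$summit),
             path)
  invisible(path)
}

#' Nearest transcription start site for every peak
#'
#' For each peak, finds the gene whose TSS minimizes the distance to the
#' peak interval: 0 when the TSS lies within the peak, otherwise the gap
#' between the TSS and the nearest peak edge (1-based inclusive arithmetic).
#' Ties are reported for all tied genes with `tie = TRUE`; the
#' lexicographically lowest gene id is flagged `nearest = TRUE` as the
#' deterministic winner. Peaks on chromosomes without genes are assigned a
#' missing gene at infinite distance. The `upstream` flag says whether the
#' peak lies 5' of the TSS relative to the gene's strand (TSS-overlapping
#' peaks count as upstream).
#'
#' @param peaks data.frame from [parse_peaks()].
#' @param genes data.frame from [parse_gene_models()].
#' @return data.frame: peak_id, gene_id, distance, upstream, tie, nearest.
#' @export
nearest_tss <- function(peaks, genes) {
  out <- vector("list", nrow(peaks))
  for (i in seq_len(nrow(peaks))) {
    pk <- peaks[i, ]
    g <- genes[genes$chrom == pk$chrom, ]
    if (nrow(g) == 0L) {
      out[[i]] <- data.frame(peak_id = pk$peak_id, gene_id = NA_character_,
                             distance = Inf, upstream = NA, tie = FALSE,
                             nearest = TRUE, stringsAsFactors = FALSE)
      next
    }
    d <- ifelse(g$tss < pk$start, pk$start - g$tss,
                ifelse(g$tss > pk$end, g$tss - pk$end, 0L))
    dmin <- min(d)
    idx <- which(d == dmin)
    idx <- idx[order(g$gene_id[idx])]
    hit <- g[idx, , drop = FALSE]
    upstream <- if (dmin == 0L) {
      rep(TRUE, length(idx))
    } else {
      ifelse(hit$strand == "+", pk$end < hit$tss, pk$start > hit$tss)
    }
    out[[i]] <- data.frame(
      peak_id = pk$peak_id, gene_id = hit$gene_id, distance = dmin,
      upstream = upstream, tie = nrow(hit) > 1L,
      nearest = seq_len(nrow(hit)) == 1L, stringsAsFactors = FALSE
    )
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Genes with a binding peak in the upstream promoter window
#'
#' A gene qualifies as a putative target of the profiled transcription
#' factor when at least one peak overlaps its strand-aware open upstream
#' window: `(TSS - window, TSS)` on the plus strand, `(TSS, TSS + window)`
#' on the minus strand ("within the first `window` bp upstream of the TSS").
#' In `mode = "overlap"` (default) any overlap of the peak interval with the
#' window qualifies; in `mode = "summit"` the peak summit (interval midpoint
#' when the summit offset is -1) must fall inside the window.
#'
#' @param peaks data.frame from [parse_peaks()].
#' @param genes data.frame from [parse_gene_models()].
#' @param window promoter window in bp (> 0; default 1000).
#' @param mode `"overlap"` or `"summit"`.
#' @return sorted character vector of qualifying gene ids.
#' @export
promoter_bound_genes <- function(peaks, genes, window = 1000L,
                                 mode = c("overlap", "summit")) {
  mode <- match.arg(mode)
  if (window <= 0) stop("configuration error: window must be > 0")
  if (nrow(peaks) == 0L) return(character(0))
  if (mode == "summit") {
    summit_pos <- ifelse(peaks$summit >= 0L,
                         peaks$start + peaks$summit,
                         (peaks$start + peaks$end) %/% 2L)
  }
  qual <- vapply(seq_len(nrow(genes)), function(i) {
    g <- genes[i, ]
    if (g$strand == "+") {
      lo <- g$tss - window + 1L; hi <- g$tss - 1L
    } else {
      lo <- g$tss + 1L; hi <- g$tss + window - 1L
    }
    same <- peaks$chrom == g$chrom
    if (mode == "overlap") {
      any(same & peaks$start <= hi & peaks$end >= lo)
    } else {
      any(same & summit_pos >= lo & summit_pos <= hi)
    }
  }, logical(1))
  sort(genes$gene_id[qual])
}
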