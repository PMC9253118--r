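#' Write the synthetic gene models (GFF3) and binding peaks (narrowPeak)
#'
#' Gene models are written as GFF3 `gene` features (1-based inclusive
#' coordinates, `ID=` attribute); peaks as 10-column narrowPeak (BED6+4,
#' 0-based half-open), converting the internally 1-based planted intervals.
#' Writing is pure serialization of the planted truth: no randomness, so the
#' files are byte-identical across calls for the same truth.
#'
#' @param config a [sim_config()].
#' @param truth the matching [plant_truth()] output.
#' @param gff_path,peaks_path output file paths.
#' @return invisibly, a list of the two paths.
#' @export
simulate_annotation_and_peaks <- function(config, truth, gff_path, peaks_path) {
  stopifnot(inherits(truth, "planted_truth"))
  g <- truth$genes
  gff <- c(
    "##gff-version 3",
    sprintf("##sequence-region chr1 1 %d", max(g$end) + config$intergenic),
    sprintf("%s\tthermomem_sim\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
            g$chrom, g$start, g$end, g$strand, g$gene_id)
  )
  writeLines(gff, gff_path)

  p <- truth$peaks
  if (is.null(p) || nrow(p) == 0L) {
    writeLines(character(0), peaks_path)
  } else {
    writeLines(sprintf("%s\t%d\t%d\t%s\t%d\t.\t%.2f\t-1\t-1\t%d",
                       p$chrom, p$start - 1L, p$end, p$peak_id, 500L,
                       5.0, p$summit_rel),
               peaks_path)
  }
  invisible(list(gff = gff_path, peaks = peaks_path))
}

#' Generate and write a complete synthetic data set
#'
#' Runs the whole generator for one configuration and serializes every
#' pipeline input next to a machine-readable record of the planted truth:
#' `counts.tsv` (genes x samples, tab-separated, header of sample ids),
#' `samples.csv`, `ct_table.csv`, `genes.gff3`, `peaks.narrowPeak`,
#' `truth.json` and `config.json`.
#'
#' @param config a [sim_config()].
#' @param outdir output directory (created if missing).
#' @return invisibly, a list with the truth object and all file paths.
#' @export
write_sim_dataset <- function(config, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  truth <- plant_truth(config)
  cm <- simulate_counts(config, truth)
  ctt <- simulate_ct_table(config, truth)

  paths <- list(
    counts = file.path(outdir, "counts.tsv"),
    samples = file.path(outdir, "samples.csv"),
    ct = file.path(outdir, "ct_table.csv"),
    gff = file.path(outdir, "genes.gff3"),
    peaks = file.path(outdir, "peaks.narrowPeak"),
    truth = file.path(outdir, "truth.json"),
    config = file.path(outdir, "config.json")
  )
  utils::write.table(cm$counts, paths$counts, sep = "\t", quote = FALSE,
                     col.names = NA)
  utils::write.csv(cm$samples, paths$samples, row.names = FALSE)
  utils::write.csv(ctt, paths$ct, row.names = FALSE)
  simulate_annotation_and_peaks(config, truth, paths$gff, paths$peaks)

  jsonlite::write_json(
    list(
      seed = config$seed,
      targets = truth$targets,
      module_assignments = truth$genes[truth$genes$module > 0L,
                                       c("gene_id", "module")],
      promoter_bound = truth$promoter_bound,
      ct_undetectable = truth$ct$undetectable,
      ct_cluster = as.list(truth$ct$cluster)
    ),
    paths$truth, auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  jsonlite::write_json(unclass(config), paths$config,
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(c(list(truth = truth, counts = cm$counts, samples = cm$samples,
                   ct_table = ctt), paths))
}
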