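#' Assemble a decision cube from global decisions
#'
#' Reshapes a [decide_global()] result whose contrasts follow the
#' `class.genotype.timepoint` naming of [heat_contrast()] and
#' [interaction_contrast()] into the gene x contrast-class x timepoint cube
#' the target filters consume.
#'
#' @param decisions a [decide_global()] result.
#' @return object of class `decision_cube`: list with `decision`, `logFC`
#'   (genes x contrasts), and `meta` (contrast, class, genotype, timepoint).
#' @export
build_decision_cube <- function(decisions) {
  stopifnot(inherits(decisions, "decision_set"))
  cn <- colnames(decisions$decision)
  parts <- strsplit(cn, ".", fixed = TRUE)
  bad <- lengths(parts) != 3L
  if (any(bad)) {
    stop("input error: contrast name(s) not of the form class.genotype.",
         "timepoint: ", paste(cn[bad], collapse = ", "))
  }
  meta <- data.frame(
    contrast = cn,
    class = vapply(parts, `[`, character(1), 1L),
    genotype = vapply(parts, `[`, character(1), 2L),
    timepoint = vapply(parts, `[`, character(1), 3L),
    stringsAsFactors = FALSE
  )
  structure(list(decision = decisions$decision, logFC = decisions$logFC,
                 meta = meta),
            class = "decision_cube")
}

cube_column <- function(cube, class, genotype, timepoint) {
  m <- cube$meta
  hit <- which(m$class == class & m$genotype == genotype &
                 m$timepoint == timepoint)
  if (length(hit) != 1L) {
    stop("input error: no ", class, " contrast for genotype '", genotype,
         "' at timepoint '", timepoint, "'")
  }
  m$contrast[hit]
}

#' Heat-induced and heat-repressed gene sets per timepoint
#'
#' Reads the heat-versus-control decisions of one genotype: induced =
#' decision +1, repressed = decision -1, per timepoint (the Venn-building
#' sets).
#'
#' @param cube a [build_decision_cube()] result.
#' @param genotype genotype label.
#' @return named list over timepoints, each `list(induced =, repressed =)`.
#' @export
heat_response_sets <- function(cube, genotype) {
  m <- cube$meta
  tps <- unique(m$timepoint[m$class == "heat" & m$genotype == genotype])
  if (length(tps) == 0L) {
    stop("input error: no heat contrasts for genotype '", genotype, "'")
  }
  out <- lapply(tps, function(tp) {
    d <- cube$decision[, cube_column(cube, "heat", genotype, tp)]
    list(induced = sort(names(d)[d == 1L]),
         repressed = sort(names(d)[d == -1L]))
  })
  names(out) <- tps
  out
}

#' Priming-associated sustained response sets
#'
#' Genes induced right after priming whose expression stays up through the
#' memory phase (and the mirrored repressed class). `strict` mode requires a
#' significant call of the same sign at every timepoint; `lenient` mode
#' requires significance at the first timepoint and a same-sign logFC (not
#' necessarily significant) at the later ones.
#'
#' @param cube a [build_decision_cube()] result.
#' @param genotype genotype label.
#' @param timepoints ordered timepoints (default: those in the cube).
#' @param mode `"strict"` or `"lenient"`.
#' @return list with `sustained_induced`, `sustained_repressed`.
#' @export
priming_associated_sets <- function(cube, genotype, timepoints = NULL,
                                    mode = c("strict", "lenient")) {
  mode <- match.arg(mode)
  m <- cube$meta
  tps <- timepoints %||%
    unique(m$timepoint[m$class == "heat" & m$genotype == genotype])
  if (length(tps) < 2L) stop("input error: need >= 2 timepoints")
  cols <- vapply(tps, function(tp) cube_column(cube, "heat", genotype, tp),
                 character(1))
  dec <- cube$decision[, cols, drop = FALSE]
  fc <- cube$logFC[, cols, drop = FALSE]
  later <- seq_along(tps)[-1L]

  pick <- function(s) {
    if (mode == "strict") {
      rowSums(dec == s) == length(tps)
    } else {
      dec[, 1L] == s & rowSums(sign(fc[, later, drop = FALSE]) == s) ==
        length(later)
    }
  }
  list(sustained_induced = sort(rownames(dec)[pick(1L)]),
       sustained_repressed = sort(rownames(dec)[pick(-1L)]))
}

#' Direction-discordant genes between overexpressor and knockout
#'
#' Evaluated on the heat-by-genotype interaction contrasts: a gene is
#' "up in OE, down in KO" at a timepoint iff the OE-versus-WT interaction
#' decision is +1 AND the KO-versus-WT interaction decision is -1 there
#' (both significant calls required); the second class is mirrored. The two
#' sets are disjoint by construction.
#'
#' @param cube a [build_decision_cube()] result.
#' @param timepoint timepoint label.
#' @param oe,ko genotype labels of the overexpressor / knockout interaction
#'   contrasts.
#' @return list with `up_in_oe_down_in_ko`, `down_in_oe_up_in_ko`.
#' @export
discordant_by_genotype <- function(cube, timepoint, oe = "OE", ko = "KO") {
  doe <- cube$decision[, cube_column(cube, "int", oe, timepoint)]
  dko <- cube$decision[, cube_column(cube, "int", ko, timepoint)]
  list(
    up_in_oe_down_in_ko = sort(names(doe)[doe == 1L & dko == -1L]),
    down_in_oe_up_in_ko = sort(names(doe)[doe == -1L & dko == 1L])
  )
}

#' Candidate direct targets: discordance crossed with promoter binding
#'
#' Per timepoint, intersects the discordant sets with the genes carrying a
#' promoter-proximal binding peak of the focal transcription factor.
#' Direction follows the discordance class: up-in-OE/down-in-KO genes are
#' candidate activated targets, the mirrored class candidate repressed
#' targets.
#'
#' @param discordant named list over timepoints of
#'   [discordant_by_genotype()] results.
#' @param tf_bound character vector of promoter-bound gene ids (from
#'   [promoter_bound_genes()]).
#' @return data.frame: gene_id, direction, timepoint (one row per
#'   gene-timepoint support).
#' @export
candidate_direct_targets <- function(discordant, tf_bound) {
  if (length(tf_bound) == 0L) {
    warning("empty binding set: no candidates")
  }
  rows <- list()
  for (tp in names(discordant)) {
    d <- discordant[[tp]]
    act <- intersect(d$up_in_oe_down_in_ko, tf_bound)
    rep_ <- intersect(d$down_in_oe_up_in_ko, tf_bound)
    if (length(act) > 0L) {
      rows[[length(rows) + 1L]] <- data.frame(
        gene_id = act, direction = "activated", timepoint = tp,
        stringsAsFactors = FALSE)
    }
    if (length(rep_) > 0L) {
      rows[[length(rows) + 1L]] <- data.frame(
        gene_id = rep_, direction = "repressed", timepoint = tp,
        stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0L) {
    return(data.frame(gene_id = character(0), direction = character(0),
                      timepoint = character(0), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Commonality filter over supporting timepoints
#'
#' Keeps candidates supported (same gene and direction) at at least
#' `min_timepoints` of the assayed timepoints; the all-timepoint subset is
#' attached as attribute `all_timepoints`.
#'
#' @param candidates data.frame from [candidate_direct_targets()].
#' @param min_timepoints minimum supporting timepoints (1..3, default 2).
#' @param n_timepoints total number of assayed timepoints (default 3).
#' @return data.frame: gene_id, direction, n_timepoints, timepoints
#'   (semicolon-joined), filtered to the commonality rule.
#' @export
commonality_filter <- function(candidates, min_timepoints = 2L,
                               n_timepoints = 3L) {
  if (min_timepoints < 1L || min_timepoints > n_timepoints) {
    stop("configuration error: min_timepoints must be in 1..", n_timepoints)
  }
  if (nrow(candidates) == 0L) {
    out <- data.frame(gene_id = character(0), direction = character(0),
                      n_timepoints = integer(0), timepoints = character(0),
                      stringsAsFactors = FALSE)
    attr(out, "all_timepoints") <- character(0)
    return(out)
  }
  key <- paste(candidates$gene_id, candidates$direction, sep = "\r")
  agg <- lapply(split(candidates, key), function(s) {
    data.frame(gene_id = s$gene_id[1L], direction = s$direction[1L],
               n_timepoints = length(unique(s$timepoint)),
               timepoints = paste(sort(unique(s$timepoint)), collapse = ";"),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, agg)
  out <- out[order(out$gene_id), , drop = FALSE]
  rownames(out) <- NULL
  keep <- out$n_timepoints >= min_timepoints
  res <- out[keep, , drop = FALSE]
  rownames(res) <- NULL
  attr(res, "all_timepoints") <-
    sort(out$gene_id[out$n_timepoints >= n_timepoints])
  res
}
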