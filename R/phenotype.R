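#' Chlorophyll concentrations from DMSO-extract absorbances
#'
#' Applies the published coefficient set verbatim to absorbances at 663 nm
#' (chlorophyll a) and 645 nm (chlorophyll b), after multiplying by the
#' dilution factor:
#' `Chl_a (g/L) = 0.0127 OD663 - 0.00269 OD645`,
#' `Chl_b (g/L) = 0.229 OD645 - 0.00488 OD663`,
#' `Total (g/L) = 0.202 Chl_a + 0.00802 Chl_b`,
#' `Total (mg/g FM) = (20.2 Chl_a + 8.02 Chl_b) / FM`.
#' Note the Chl_b and Total coefficients of this set are mutually
#' inconsistent with the classical Arnon coefficients (0.0229;
#' 0.0202/0.00802 applied to the ODs); `classic_arnon = TRUE` switches to
#' the standard coefficients instead (clearly a different, non-default
#' convention). Negative computed concentrations are kept (the formulas are
#' applied faithfully) but flagged.
#'
#' @param od663,od645 absorbance readings.
#' @param dilution dilution factor in \{1, 10, 100\}.
#' @param fm fresh mass in g (required for the mg/g output; NA otherwise).
#' @param classic_arnon use the classical coefficient set.
#' @return data.frame: chl_a, chl_b, total_gL, total_mg_per_g, negative
#'   (flag).
#' @export
chlorophyll <- function(od663, od645, dilution = 1, fm = NA_real_,
                        classic_arnon = FALSE) {
  if (!all(dilution %in% c(1, 10, 100))) {
    stop("input error: dilution must be 1, 10 or 100")
  }
  if (any(od663 < 0 | od645 < 0)) stop("input error: absorbances must be >= 0")
  a663 <- od663 * dilution
  a645 <- od645 * dilution
  chl_a <- 0.0127 * a663 - 0.00269 * a645
  if (classic_arnon) {
    chl_b <- 0.0229 * a645 - 0.00488 * a663
    total_gL <- 0.0202 * a645 + 0.00802 * a663
    total_mg <- (20.2 * a645 + 8.02 * a663) / fm
  } else {
    chl_b <- 0.229 * a645 - 0.00488 * a663
    total_gL <- 0.202 * chl_a + 0.00802 * chl_b
    total_mg <- (20.2 * chl_a + 8.02 * chl_b) / fm
  }
  neg <- chl_a < 0 | chl_b < 0 | total_gL < 0
  if (any(neg)) warning("negative computed concentration(s) flagged")
  data.frame(chl_a = chl_a, chl_b = chl_b, total_gL = total_gL,
             total_mg_per_g = total_mg, negative = neg)
}

#' Normalize measurements to each genotype's control mean
#'
#' Divides every value by the mean of its genotype's control group, so
#' control groups average 1 by construction.
#'
#' @param values numeric vector.
#' @param genotype,treatment parallel grouping vectors.
#' @param control_label treatment label of the control group.
#' @return numeric vector of normalized values (NA with a warning for
#'   genotypes whose control mean is 0 or missing).
#' @export
normalize_to_control <- function(values, genotype, treatment,
                                 control_label = "control") {
  stopifnot(length(values) == length(genotype),
            length(values) == length(treatment))
  out <- rep(NA_real_, length(values))
  for (g in unique(genotype)) {
    ctl <- values[genotype == g & treatment == control_label]
    if (length(ctl) == 0L) {
      stop("input error: no control group for genotype '", g, "'")
    }
    m <- mean(ctl)
    if (!is.finite(m) || m == 0) {
      warning("control mean is 0 or undefined for genotype '", g, "'")
      next
    }
    out[genotype == g] <- values[genotype == g] / m
  }
  out
}

#' Fresh-mass ratio of stressed to control seedlings per genotype
#'
#' Each replicate mass is a plate average. The ratio is the stressed mean
#' over the control mean; dispersion is the standard deviation of the
#' per-replicate ratios (each stressed replicate over the control mean). A
#' Welch two-sample t comparison is reported descriptively.
#'
#' @param mass data.frame with columns `genotype`, `treatment`, `mass`.
#' @param stressed_label,control_label treatment labels.
#' @return data.frame per genotype: ratio, sd, n_stressed, n_control,
#'   t (statistic), p.
#' @export
fresh_mass_ratio <- function(mass, stressed_label = "stressed",
                             control_label = "control") {
  out <- lapply(unique(mass$genotype), function(g) {
    s <- mass$mass[mass$genotype == g & mass$treatment == stressed_label]
    ctl <- mass$mass[mass$genotype == g & mass$treatment == control_label]
    if (length(s) == 0L || length(ctl) == 0L) {
      stop("input error: missing arm for genotype '", g, "'")
    }
    rr <- s / mean(ctl)
    tt <- if (length(s) > 1L && length(ctl) > 1L &&
              (stats::sd(s) > 0 || stats::sd(ctl) > 0)) {
      stats::t.test(s, ctl)
    } else list(statistic = NA_real_, p.value = NA_real_)
    data.frame(genotype = g, ratio = mean(s) / mean(ctl),
               sd = if (length(rr) > 1L) stats::sd(rr) else NA_real_,
               n_stressed = length(s), n_control = length(ctl),
               t = unname(tt$statistic), p = tt$p.value,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Recovery-class proportions per genotype
#'
#' Converts per-genotype counts over the three thermotolerance recovery
#' classes (full / partial / no recovery — an input labelling, not computed
#' from images) into proportions.
#'
#' @param counts data.frame with columns `genotype`, `class`, `count`.
#' @return data.frame: genotype, class, count, proportion (summing to 1 per
#'   genotype).
#' @export
recovery_class_summary <- function(counts) {
  if (any(counts$count < 0)) stop("input error: counts must be >= 0")
  out <- lapply(unique(counts$genotype), function(g) {
    s <- counts[counts$genotype == g, , drop = FALSE]
    tot <- sum(s$count)
    if (tot == 0) stop("input error: zero total count for genotype '", g, "'")
    s$proportion <- s$count / tot
    s
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
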