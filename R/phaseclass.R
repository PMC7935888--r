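#' Peak time bin of an expression series
#'
#' Folds the series onto a 24 h cycle (averaging across cycles when more
#' than one day of data is present), finds the ZT of maximum cycle-averaged
#' expression (ties toward the earliest ZT) and returns the containing bin
#' of the given width.
#'
#' @param series numeric expression values.
#' @param timepoints hours, same length as \code{series}; must span >= one
#'   full cycle.
#' @param bin_width bin width in hours (default 3, the sampling interval of
#'   the design this mirrors).
#' @return list with \code{peak_zt} (hour of the cycle-averaged maximum),
#'   \code{peak_bin} (label \code{"ZT<start>"}), \code{constant} (flag; a
#'   constant series has no defined peak and is routed to arrhythmic
#'   handling downstream).
#' @export
assign_peak_bin <- function(series, timepoints, bin_width = 3) {
  .assert(length(series) == length(timepoints), "series/timepoints mismatch")
  .assert(max(timepoints) - min(timepoints) >= 24 - bin_width,
          "need at least one full cycle of timepoints")
  if (diff(range(series)) == 0) {
    return(list(peak_zt = NA_real_, peak_bin = NA_character_, constant = TRUE))
  }
  zt <- timepoints %% 24
  prof <- tapply(series, zt, mean)
  hours <- as.numeric(names(prof))
  peak <- hours[which.max(prof)]  # which.max: first maximum = earliest ZT
  start <- floor(peak / bin_width) * bin_width
  list(peak_zt = peak, peak_bin = paste0("ZT", start), constant = FALSE)
}

#' Day/night/arrhythmic class from a rhythm call
#'
#' Rhythmic genes with acrophase (mod 24) inside the lights-on window are
#' DAY, the rest NIGHT; non-rhythmic genes are ARRHYTHMIC. The boundary
#' instant at lights-off (acrophase exactly 12.0 under the default 0-12
#' photoperiod) belongs to NIGHT.
#'
#' @param calls data.frame from \code{\link{rhythm_test}} (columns gene_id,
#'   acrophase, rhythmic at minimum).
#' @param photoperiod lights-on window \code{c(start, end)} in ZT hours,
#'   default \code{c(0, 12)}; DAY means acrophase in [start, end).
#' @param peak_bins optional vector of peak-bin labels (from
#'   \code{\link{assign_peak_bin}}) carried into the output.
#' @return data.frame: gene_id, peak_bin, phase_class.
#' @export
classify_phase <- function(calls, photoperiod = c(0, 12), peak_bins = NULL) {
  .assert(all(c("gene_id", "acrophase", "rhythmic") %in% names(calls)),
          "calls must come from rhythm_test")
  ac <- calls$acrophase %% 24
  cls <- ifelse(!calls$rhythmic, "ARRHYTHMIC",
                ifelse(ac >= photoperiod[1] & ac < photoperiod[2],
                       "DAY", "NIGHT"))
  data.frame(gene_id = calls$gene_id,
             peak_bin = if (is.null(peak_bins)) NA_character_ else peak_bins,
             phase_class = cls, stringsAsFactors = FALSE)
}

#' Peak-time and class distribution of labelled genes
#'
#' @param labels data.frame from \code{\link{classify_phase}}.
#' @return list with \code{class_fractions} (named fractions over all genes,
#'   summing to 1) and \code{bin_fractions} (fractions of rhythmic genes per
#'   peak bin, summing to 1; empty when no gene has a peak bin).
#' @export
phase_distribution <- function(labels) {
  .assert(nrow(labels) >= 1, "need at least one labelled gene")
  cls <- factor(labels$phase_class, levels = c("DAY", "NIGHT", "ARRHYTHMIC"))
  class_fr <- as.numeric(table(cls)) / nrow(labels)
  names(class_fr) <- levels(cls)
  rb <- labels$peak_bin[labels$phase_class != "ARRHYTHMIC" &
                          !is.na(labels$peak_bin)]
  bin_fr <- if (length(rb)) {
    tab <- table(rb)
    setNames(as.numeric(tab) / length(rb), names(tab))
  } else numeric(0)
  list(class_fractions = class_fr, bin_fractions = bin_fr)
}

#' Differential-expression filter at an FDR and fold-ratio threshold
#'
#' A gene is INDUCED when q < \code{fdr_cut} and case/control ratio >
#' \code{up}, REDUCED when q < \code{fdr_cut} and ratio < \code{down}, else
#' UNCHANGED. The defaults (FDR < 0.01, ratio > 2 or < 0.5) are the
#' thresholds used for calling differentially expressed genes in the
#' RNA-seq comparison this mirrors. A pseudocount guards ratios against
#' zero controls.
#'
#' @param expr_case,expr_control non-negative expression vectors, matched by
#'   position.
#' @param q_values precomputed per-gene q-values.
#' @param fdr_cut,up,down thresholds.
#' @param pseudocount added to numerator and denominator of the ratio.
#' @return data.frame: ratio, status in {INDUCED, REDUCED, UNCHANGED}.
#' @export
deg_filter <- function(expr_case, expr_control, q_values, fdr_cut = 0.01,
                       up = 2.0, down = 0.5, pseudocount = 0.01) {
  .assert(length(expr_case) == length(expr_control) &&
            length(expr_case) == length(q_values), "inputs must be matched")
  .assert(all(expr_case >= 0) && all(expr_control >= 0),
          "expression values must be non-negative")
  ratio <- (expr_case + pseudocount) / (expr_control + pseudocount)
  status <- ifelse(q_values < fdr_cut & ratio > up, "INDUCED",
                   ifelse(q_values < fdr_cut & ratio < down, "REDUCED",
                          "UNCHANGED"))
  data.frame(ratio = ratio, status = status, stringsAsFactors = FALSE)
}
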