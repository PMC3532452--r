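# Position-level validation of feature calls against ground-truth
# mis-assembly intervals.

#' Per-position sensitivity and specificity of feature calls
#'
#' Every assembled position is classified against the truth set:
#' true positive if it lies in a truth interval and in at least one feature,
#' false negative if in truth but unflagged, false positive if flagged but
#' not in truth, true negative otherwise. Sensitivity is `TP / (TP + FN)` and
#' specificity `TN / (TN + FP)`; an undefined ratio (empty truth, or features
#' covering everything) is reported as `NA`. The four counts always sum to
#' the total assembled length.
#'
#' `slack` dilates each truth interval by the given number of bp on both
#' sides (clipped to the contig) before counting, crediting feature calls
#' that flank rather than cover an event: breakpoint evidence from read pairs
#' necessarily concentrates within about one fragment length of a junction.
#'
#' @param features Feature-region data frame (columns `contig`, `start`,
#'   `end`; 0-based half-open).
#' @param truth Truth-interval data frame with the same coordinate columns.
#' @param contig_lengths Named vector of assembled contig lengths; defines the
#'   position universe.
#' @param slack Truth dilation in bp (default 0).
#' @return List with `sens`, `spec`, `tp`, `fp`, `tn`, `fn`.
#' @examples
#' lens <- c(ctg = 1000L)
#' truth <- data.frame(contig = "ctg", start = 100L, end = 200L)
#' feat <- data.frame(contig = "ctg", start = 150L, end = 250L)
#' sensitivity_specificity(feat, truth, lens)  # sens 0.5, spec 850/900
#' @export
sensitivity_specificity <- function(features, truth, contig_lengths, slack = 0L) {
  stopifnot(!is.null(names(contig_lengths)), slack >= 0)
  check_bounds <- function(df, what) {
    if (nrow(df) == 0L) return(invisible())
    lens <- contig_lengths[df$contig]
    if (any(is.na(lens)) || any(df$start < 0L) || any(df$end > lens) ||
        any(df$start >= df$end)) {
      stop(sprintf("%s intervals beyond contig bounds", what), call. = FALSE)
    }
  }
  check_bounds(features, "feature")
  check_bounds(truth, "truth")

  tp <- fp <- tn <- fn <- 0
  for (ctg in names(contig_lengths)) {
    len <- as.integer(contig_lengths[[ctg]])
    f <- features[features$contig == ctg, , drop = FALSE]
    t_ <- truth[truth$contig == ctg, , drop = FALSE]
    fmask <- interval_coverage(as.integer(f$start), as.integer(f$end), len) > 0L
    tmask <- interval_coverage(pmax(0L, as.integer(t_$start) - as.integer(slack)),
                               pmin(len, as.integer(t_$end) + as.integer(slack)),
                               len) > 0L
    tp <- tp + sum(fmask & tmask)
    fp <- fp + sum(fmask & !tmask)
    fn <- fn + sum(!fmask & tmask)
    tn <- tn + sum(!fmask & !tmask)
  }
  list(
    sens = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
    spec = if (tn + fp > 0) tn / (tn + fp) else NA_real_,
    tp = tp, fp = fp, tn = tn, fn = fn
  )
}

#' Fraction of flagged bases outside truth and contig edges
#'
#' A false-positive control for clean benchmarks: the fraction of assembled
#' positions flagged by any feature, restricted to positions farther than
#' `edge_exclusion` bp from a contig end (spanning coverage necessarily
#' decays there) and, if a truth set is given, outside the truth intervals
#' dilated by `slack`.
#'
#' @inheritParams sensitivity_specificity
#' @param edge_exclusion Bp excluded at each contig end (typically one insert
#'   mean of the longest-range library).
#' @return List with `flagged_frac`, `flagged`, `total`.
#' @export
flagged_fraction <- function(features, contig_lengths, edge_exclusion = 0L,
                             truth = NULL, slack = 0L) {
  stopifnot(!is.null(names(contig_lengths)))
  flagged <- 0; total <- 0
  for (ctg in names(contig_lengths)) {
    len <- as.integer(contig_lengths[[ctg]])
    f <- features[features$contig == ctg, , drop = FALSE]
    fmask <- interval_coverage(as.integer(f$start), as.integer(f$end), len) > 0L
    keep <- rep(TRUE, len)
    if (edge_exclusion > 0L && len > 0L) {
      drop_n <- min(as.integer(edge_exclusion), len)
      keep[seq_len(drop_n)] <- FALSE
      keep[seq.int(len - drop_n + 1L, len)] <- FALSE
    }
    if (!is.null(truth)) {
      t_ <- truth[truth$contig == ctg, , drop = FALSE]
      tmask <- interval_coverage(pmax(0L, as.integer(t_$start) - as.integer(slack)),
                                 pmin(len, as.integer(t_$end) + as.integer(slack)),
                                 len) > 0L
      keep <- keep & !tmask
    }
    flagged <- flagged + sum(fmask & keep)
    total <- total + sum(keep)
  }
  list(flagged_frac = if (total > 0) flagged / total else NA_real_,
       flagged = flagged, total = total)
}
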