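# Feature Response Curves and assembly summary statistics.

#' Compute a Feature Response Curve
#'
#' Contigs are sorted by length, longest first (length ties broken by contig
#' id for determinism). For each feature threshold `tau`, the longest prefix
#' of contigs whose cumulative feature count is at most `tau` is selected and
#' the approximate genome coverage `min(1, selected length / genome_size)` is
#' one curve point. The comparison is inclusive (`<= tau`), so `tau = 0` reads
#' as "coverage achievable with zero-feature contigs" and the curve reaches
#' its plateau `min(1, total length / genome_size)` at `tau =` total feature
#' count.
#'
#' @param summaries Data frame with columns `contig`, `length` and `features`
#'   (total feature count per contig, possibly restricted to one type).
#' @param genome_size Genome length estimate in bp (> 0).
#' @param tau_values Integer thresholds to sweep; default `0:sum(features)`.
#' @return Data frame with columns `tau` and `coverage` (fraction in [0, 1],
#'   non-decreasing in `tau`).
#' @examples
#' s <- data.frame(contig = c("A", "B", "C"), length = c(100, 80, 50),
#'                 features = c(0, 2, 1))
#' compute_frcurve(s, genome_size = 200)
#' @export
compute_frcurve <- function(summaries, genome_size, tau_values = NULL) {
  if (!is.numeric(genome_size) || genome_size <= 0) {
    stop("genome_size must be > 0", call. = FALSE)
  }
  stopifnot(nrow(summaries) > 0,
            all(c("contig", "length", "features") %in% names(summaries)))
  o <- order(-summaries$length, summaries$contig)
  len <- as.numeric(summaries$length[o])
  feat <- as.numeric(summaries$features[o])
  cum_feat <- cumsum(feat)
  cum_len <- cumsum(len)
  if (is.null(tau_values)) tau_values <- 0:sum(feat)
  tau_values <- as.integer(tau_values)
  # longest prefix with cumulative feature count <= tau
  k <- vapply(tau_values, function(t) sum(cum_feat <= t), integer(1))
  coverage <- ifelse(k > 0L, pmin(1, cum_len[pmax(k, 1L)] / genome_size), 0)
  data.frame(tau = tau_values, coverage = as.numeric(coverage))
}

#' Per-feature-type Feature Response Curves
#'
#' One curve per feature type, counting only that type's merged regions on
#' each contig. Types with no regions anywhere give a curve flat at the
#' assembly's plateau.
#'
#' @param regions Feature-region data frame (all types, all contigs).
#' @param contig_lengths Named integer vector of contig lengths.
#' @param genome_size Genome length estimate in bp.
#' @param types Feature types to report (default all 14).
#' @param tau_values Optional shared threshold sweep.
#' @return Named list of curve data frames, one per type.
#' @export
per_feature_curves <- function(regions, contig_lengths, genome_size,
                               types = FEATURE_TYPES, tau_values = NULL) {
  stopifnot(!is.null(names(contig_lengths)))
  out <- lapply(types, function(tp) {
    sub <- regions[regions$type == tp, , drop = FALSE]
    compute_frcurve(contig_feature_summaries(sub, contig_lengths),
                    genome_size, tau_values)
  })
  names(out) <- types
  out
}

#' Per-contig feature summaries
#'
#' Counts merged feature regions per contig (a "feature" is one merged
#' region, not one base) over all contigs in `contig_lengths`, including
#' contigs with zero features.
#'
#' @inheritParams per_feature_curves
#' @return Data frame with columns `contig`, `length`, `features`.
#' @export
contig_feature_summaries <- function(regions, contig_lengths) {
  stopifnot(!is.null(names(contig_lengths)))
  cnt <- table(factor(regions$contig, levels = names(contig_lengths)))
  data.frame(contig = names(contig_lengths),
             length = as.numeric(contig_lengths),
             features = as.integer(cnt),
             stringsAsFactors = FALSE)
}

#' Assembly summary statistics
#'
#' `NG50` is the length of the contig at which the cumulative sum of
#' descending-sorted contig lengths first reaches half the genome size (0 if
#' never reached). `chaff_pct` is the summed length of contigs shorter than
#' `chaff_cutoff`, as a percentage of the genome size.
#'
#' @param contig_lengths Integer vector of contig lengths in bp.
#' @param genome_size Genome length estimate in bp (> 0).
#' @param chaff_cutoff Chaff length cutoff in bp (default 200).
#' @return List with `n_contigs`, `NG50`, `chaff_pct`.
#' @examples
#' assembly_summary(c(100, 80, 50), genome_size = 200)  # NG50 = 100
#' @export
assembly_summary <- function(contig_lengths, genome_size, chaff_cutoff = 200L) {
  if (!is.numeric(genome_size) || genome_size <= 0) {
    stop("genome_size must be > 0", call. = FALSE)
  }
  if (length(contig_lengths) == 0L) {
    return(list(n_contigs = 0L, NG50 = 0L, chaff_pct = 0))
  }
  len <- sort(as.numeric(contig_lengths), decreasing = TRUE)
  cum <- cumsum(len)
  hit <- which(cum >= genome_size / 2)
  ng50 <- if (length(hit)) as.integer(len[hit[1L]]) else 0L
  chaff <- 100 * sum(len[len < chaff_cutoff]) / genome_size
  list(n_contigs = length(len), NG50 = ng50, chaff_pct = chaff)
}
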