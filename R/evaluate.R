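# Main entry point: evaluate an assembly from read-pair alignments and return
# a classed result with print/summary/plot methods.

# shared pipeline core for file-based and synthetic inputs
evaluate_core <- function(aln_pe, pe_lib, contig_lengths, genome_size,
                          aln_mp = NULL, mp_lib = NULL, th = thresholds(),
                          window = 1000L, step = 200L, tolerance_k = 3) {
  ctgs <- names(contig_lengths)
  keep_mapped <- function(a) {
    if (!is.null(a$mapped)) a <- a[a$mapped, , drop = FALSE]
    a
  }
  split_by_contig <- function(a) {
    split(a, factor(a$contig, levels = ctgs))
  }
  build_all <- function(aln, lib) {
    by_ctg <- split_by_contig(keep_mapped(aln))
    lapply(ctgs, function(cg) {
      build_tracks(by_ctg[[cg]], lib, cg, contig_lengths[[cg]],
                   window = window, step = step, tolerance_k = tolerance_k)
    })
  }

  tracks_pe <- build_all(aln_pe, pe_lib)
  stats_pe <- estimate_global_stats(tracks_pe, pe_lib, genome_size)
  tracks_mp <- stats_mp <- NULL
  if (!is.null(aln_mp)) {
    stopifnot(is_library_profile(mp_lib))
    tracks_mp <- build_all(aln_mp, mp_lib)
    stats_mp <- estimate_global_stats(tracks_mp, mp_lib, genome_size)
  }

  features <- do.call(rbind, lapply(seq_along(ctgs), function(i) {
    annotate_contig(tracks_pe[[i]], stats_pe,
                    if (is.null(tracks_mp)) NULL else tracks_mp[[i]],
                    stats_mp, th)
  }))
  features <- features[order(features$contig, features$start, features$end,
                             features$type), , drop = FALSE]
  rownames(features) <- NULL

  types <- if (is.null(aln_mp)) grep("_PE$", FEATURE_TYPES, value = TRUE) else
    FEATURE_TYPES
  summaries <- contig_feature_summaries(features, contig_lengths)
  structure(list(
    features = features,
    global_curve = compute_frcurve(summaries, genome_size),
    per_feature_curves = per_feature_curves(features, contig_lengths,
                                            genome_size, types = types),
    summary = assembly_summary(contig_lengths, genome_size),
    contig_summaries = summaries,
    stats_pe = stats_pe, stats_mp = stats_mp,
    contig_lengths = contig_lengths,
    genome_size = as.numeric(genome_size),
    thresholds = th
  ), class = "frc_eval")
}

#' Evaluate an assembly from read-pair alignments
#'
#' The full reference-free pipeline: reads the assembly and the
#' coordinate-sorted alignments of one paired-end library (and optionally one
#' mate-pair library), builds per-contig coverage/insert tracks, refines the
#' rough insert estimates from properly aligned pairs, calls the 14 feature
#' types, and computes the global and per-feature Feature Response Curves
#' plus assembly summary statistics.
#'
#' @param assembly_fasta Assembly contigs/scaffolds (FASTA).
#' @param pe_bam PE alignments (BAM, or SAM for small inputs).
#' @param pe_insert_mean,pe_insert_sd Rough PE insert estimate in bp.
#' @param genome_size Genome length estimate in bp.
#' @param mp_bam Optional MP alignments.
#' @param mp_insert_mean,mp_insert_sd Rough MP insert estimate in bp.
#' @param th [thresholds()].
#' @param window,step Sliding-window size and step in bp.
#' @param tolerance_k Proper-pair distance tolerance in standard deviations.
#' @param mapq_min Minimum mapping quality (default 0 keeps multi-mappers).
#' @return An object of class `frc_eval`.
#' @export
frc_evaluate <- function(assembly_fasta, pe_bam, pe_insert_mean, pe_insert_sd,
                         genome_size, mp_bam = NULL, mp_insert_mean = NULL,
                         mp_insert_sd = NULL, th = thresholds(),
                         window = 1000L, step = 200L, tolerance_k = 3,
                         mapq_min = 0L) {
  contigs <- read_fasta(assembly_fasta)
  contig_lengths <- stats::setNames(nchar(contigs), names(contigs))
  pe_lib <- library_profile("PE", pe_insert_mean, pe_insert_sd)
  aln_pe <- read_alignments(pe_bam, mapq_min = mapq_min)
  aln_mp <- mp_lib <- NULL
  if (!is.null(mp_bam)) {
    stopifnot(!is.null(mp_insert_mean), !is.null(mp_insert_sd))
    mp_lib <- library_profile("MP", mp_insert_mean, mp_insert_sd)
    aln_mp <- read_alignments(mp_bam, mapq_min = mapq_min)
  }
  evaluate_core(aln_pe, pe_lib, contig_lengths, genome_size,
                aln_mp = aln_mp, mp_lib = mp_lib, th = th,
                window = window, step = step, tolerance_k = tolerance_k)
}

#' @export
print.frc_eval <- function(x, ...) {
  cat("<frc_eval> reference-free assembly evaluation\n")
  cat(sprintf("  contigs: %d  NG50: %d bp  chaff: %.2f%%  (G = %.0f bp)\n",
              x$summary$n_contigs, x$summary$NG50, x$summary$chaff_pct,
              x$genome_size))
  cat(sprintf("  features: %d regions over %d types\n",
              nrow(x$features), length(unique(x$features$type))))
  invisible(x)
}

#' @export
summary.frc_eval <- function(object, ...) {
  cnt <- table(factor(object$features$type, levels = FEATURE_TYPES))
  print(object)
  cat(sprintf("  PE: mean cov %.1f, insert %.1f +/- %.1f bp\n",
              object$stats_pe$mean_read_cov, object$stats_pe$insert_mean,
              object$stats_pe$insert_sd))
  if (!is.null(object$stats_mp)) {
    cat(sprintf("  MP: mean cov %.1f, insert %.1f +/- %.1f bp\n",
                object$stats_mp$mean_read_cov, object$stats_mp$insert_mean,
                object$stats_mp$insert_sd))
  }
  cat("  feature counts:\n")
  for (tp in names(cnt)[cnt > 0]) cat(sprintf("    %-18s %d\n", tp, cnt[[tp]]))
  invisible(list(feature_counts = cnt, summary = object$summary))
}

#' Plot a Feature Response Curve
#'
#' Approximate genome coverage (percent) against the feature threshold; a
#' steeper curve means more of the genome is covered by low-feature contigs.
#'
#' @param x An `frc_eval` object.
#' @param type Optional feature type for a per-feature curve (default: the
#'   global curve).
#' @param ... Passed to [graphics::plot()].
#' @export
plot.frc_eval <- function(x, type = NULL, ...) {
  curve <- if (is.null(type)) x$global_curve else x$per_feature_curves[[type]]
  lbl <- if (is.null(type)) "all features" else type
  graphics::plot(curve$tau, 100 * curve$coverage, type = "s",
                 xlab = "feature threshold", ylab = "approx. genome coverage (%)",
                 main = sprintf("FRCurve (%s)", lbl), ylim = c(0, 100), ...)
  invisible(x)
}
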