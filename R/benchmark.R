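# End-to-end synthetic benchmark: generate a genome, corrupt it with typed
# events, simulate PE/MP pairs, lift them onto the corrupted assembly, run the
# evaluator and score the calls against the ground truth.

#' Canonical mis-assembly event set
#'
#' The standard corruption used by the benchmark on a 100 kb genome: two
#' inversions (2.5 kb each), a relocation (2 kb segment moved upstream), a
#' fragmentation (contig split), a 500 bp tandem-repeat collapse and a 1 kb
#' chimeric insertion.
#'
#' @return List of [misassembly_event()]s.
#' @export
benchmark_events <- function() {
  list(
    misassembly_event("INVERSION", start = 15000L, end = 17500L),
    misassembly_event("RELOCATION", start = 35000L, end = 37000L,
                      target = 25000L),
    misassembly_event("INVERSION", start = 40000L, end = 42500L),
    misassembly_event("FRAGMENTATION", pos = 50000L),
    misassembly_event("COMPRESSION", start = 60000L, end = 60500L),
    misassembly_event("CHIMERIC_INSERTION", pos = 75000L, length = 1000L)
  )
}

derive_seed <- function(seed, k) {
  as.integer((as.numeric(seed) %% 1000000L) + k * 1000003)
}

#' Run the synthetic benchmark end to end
#'
#' Generates a reference, applies the requested mis-assembly events (planting
#' the tandem duplicate each `COMPRESSION` collapses), simulates PE and MP
#' pairs from the *reference*, lifts them onto the corrupted assembly, runs
#' the full evaluator, and scores the feature calls against the event truth
#' ledger: per-position sensitivity/specificity with breakpoint slack, plus
#' the flagged fraction of non-edge bases (the false-positive control on
#' event-free runs). Deterministic for a fixed seed.
#'
#' @param genome_length Reference length in bp.
#' @param gc GC content.
#' @param events List of [misassembly_event()]s; empty list for a clean run.
#' @param pe,mp Library configurations: lists with `insert_mean`, `insert_sd`,
#'   `coverage`, `read_len`, `err_rate`. `mp = NULL` runs PE-only.
#' @param th [thresholds()].
#' @param window,step,tolerance_k Track parameters (see [build_tracks()]).
#' @param truth_flank Junction truth flank in bp; default: the PE insert mean
#'   (the tighter instrument pins the junction).
#' @param slack Validation slack in bp; default: the longest library insert
#'   mean (pair evidence concentrates within one fragment of a junction).
#' @param breakpoint_tolerance Liftover overhang tolerance in bp.
#' @param seed Master seed; all stage seeds derive from it.
#' @param output_dir If non-`NULL`, write FASTA/GFF3/curve/report files there.
#' @param write_alignments Also write the simulated alignments as SAM.
#' @return An object of class `frc_benchmark`: the `frc_eval` result plus
#'   `truth`, `validation`, `fp_control`, `sim` and library profiles.
#' @export
run_benchmark <- function(genome_length = 100000L, gc = 0.5,
                          events = benchmark_events(),
                          pe = list(insert_mean = 300, insert_sd = 30,
                                    coverage = 80, read_len = 100,
                                    err_rate = 0),
                          mp = list(insert_mean = 3000, insert_sd = 300,
                                    coverage = 20, read_len = 100,
                                    err_rate = 0),
                          th = thresholds(), window = 1000L, step = 200L,
                          tolerance_k = 3, truth_flank = NULL, slack = NULL,
                          breakpoint_tolerance = 20L, seed = 1L,
                          output_dir = NULL, write_alignments = FALSE) {
  events <- lapply(events, function(ev) {
    if (!inherits(ev, "misassembly_event")) do.call(misassembly_event, ev) else ev
  })
  if (is.null(truth_flank)) truth_flank <- pe$insert_mean
  if (is.null(slack)) {
    slack <- max(pe$insert_mean, if (is.null(mp)) 0 else mp$insert_mean)
  }
  edge <- max(pe$insert_mean, if (is.null(mp)) 0 else mp$insert_mean)

  reference <- generate_reference(genome_length, gc, seed = derive_seed(seed, 1L))
  for (ev in events) {
    if (ev$type == "COMPRESSION") {
      reference <- plant_duplicate(reference, ev$start, ev$end, ev$copy_start)
    }
  }
  sim <- apply_misassembly_events(reference, events, truth_flank = truth_flank,
                                  seed = derive_seed(seed, 2L))

  pe_lib <- library_profile("PE", pe$insert_mean, pe$insert_sd)
  pairs_pe <- simulate_pairs(reference, pe_lib, pe$coverage, pe$read_len,
                             err_rate = pe$err_rate,
                             seed = derive_seed(seed, 3L))
  aln_pe <- liftover_alignments(pairs_pe, sim,
                                breakpoint_tolerance = breakpoint_tolerance)
  aln_mp <- mp_lib <- NULL
  if (!is.null(mp)) {
    mp_lib <- library_profile("MP", mp$insert_mean, mp$insert_sd)
    pairs_mp <- simulate_pairs(reference, mp_lib, mp$coverage, mp$read_len,
                               err_rate = mp$err_rate,
                               seed = derive_seed(seed, 4L))
    aln_mp <- liftover_alignments(pairs_mp, sim,
                                  breakpoint_tolerance = breakpoint_tolerance)
  }

  eval <- evaluate_core(aln_pe, pe_lib, sim$contig_lengths, genome_length,
                        aln_mp = aln_mp, mp_lib = mp_lib, th = th,
                        window = window, step = step,
                        tolerance_k = tolerance_k)

  validation <- sensitivity_specificity(eval$features, sim$truth,
                                        sim$contig_lengths, slack = slack)
  fp_control <- flagged_fraction(eval$features, sim$contig_lengths,
                                 edge_exclusion = edge, truth = sim$truth,
                                 slack = slack)

  out <- structure(c(eval, list(
    truth = sim$truth, validation = validation, fp_control = fp_control,
    sim = sim, pe_lib = pe_lib, mp_lib = mp_lib,
    slack = slack, truth_flank = truth_flank, seed = seed
  )), class = c("frc_benchmark", "frc_eval"))

  if (!is.null(output_dir)) {
    dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
    write_fasta(stats::setNames(reference, "reference"),
                file.path(output_dir, "reference.fasta"))
    write_fasta(sim$contigs, file.path(output_dir, "assembly.fasta"))
    write_feature_gff(eval$features, file.path(output_dir, "features.gff"))
    tr <- sim$truth[order(sim$truth$contig, sim$truth$start, sim$truth$end), ,
                    drop = FALSE]
    write_feature_gff(
      data.frame(contig = tr$contig, start = tr$start, end = tr$end,
                 type = tr$type, score = NA_real_, stringsAsFactors = FALSE),
      file.path(output_dir, "truth.gff"), source = "simulator")
    write_curves(eval$global_curve, eval$per_feature_curves,
                 prefix = file.path(output_dir, "frc"))
    if (write_alignments) {
      write_sam(aln_pe, sim$contig_lengths,
                file.path(output_dir, "alignments_pe.sam"))
      if (!is.null(aln_mp)) {
        write_sam(aln_mp, sim$contig_lengths,
                  file.path(output_dir, "alignments_mp.sam"))
      }
    }
    writeLines(benchmark_report_lines(out), file.path(output_dir, "report.txt"))
  }
  out
}

fmt_or_na <- function(x, fmt = "%.6f") {
  if (is.na(x)) "n/a" else sprintf(fmt, x)
}

benchmark_report_lines <- function(x) {
  cnt <- table(factor(x$features$type, levels = FEATURE_TYPES))
  c(
    sprintf("n_contigs: %d", x$summary$n_contigs),
    sprintf("NG50: %d", x$summary$NG50),
    sprintf("chaff_pct: %.2f", x$summary$chaff_pct),
    sprintf("n_features: %d", nrow(x$features)),
    sprintf("sensitivity: %s", fmt_or_na(x$validation$sens, "%.4f")),
    sprintf("specificity: %s", fmt_or_na(x$validation$spec, "%.4f")),
    sprintf("flagged_nonedge_frac: %s", fmt_or_na(x$fp_control$flagged_frac,
                                                  "%.6f")),
    sprintf("feature_count %s: %d", names(cnt), as.integer(cnt))
  )
}

#' @export
print.frc_benchmark <- function(x, ...) {
  cat("<frc_benchmark> synthetic benchmark (seed", x$seed, ")\n")
  cat(sprintf("  events: %d truth intervals; slack %d bp\n",
              nrow(x$truth), as.integer(x$slack)))
  cat(sprintf("  sensitivity: %s  specificity: %s  flagged(non-edge): %s\n",
              fmt_or_na(x$validation$sens, "%.3f"),
              fmt_or_na(x$validation$spec, "%.3f"),
              fmt_or_na(x$fp_control$flagged_frac, "%.4f")))
  NextMethod()
}
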