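# File-format I/O: BAM/SAM reading (Rsamtools), SAM writing for synthetic
# alignments, GFF3 features/truth (rtracklayer), FRCurve text files, FASTA.

#' Read alignments into a read-view data frame
#'
#' Reads a coordinate-sorted BAM (or plain SAM, converted on the fly with
#' [Rsamtools::asBam()]) and returns the package's internal read view:
#' primary, non-duplicate, QC-pass mapped reads with 0-based positions,
#' reference-consumed widths, mate fields and outermost-span fragment lengths
#' taken from TLEN (recomputed from mate positions when TLEN is 0).
#'
#' @param path BAM or SAM file.
#' @param mapq_min Minimum mapping quality to keep (default 0, i.e. keep
#'   multi-mappers).
#' @return Read-view data frame (see [build_tracks()]).
#' @export
read_alignments <- function(path, mapq_min = 0L) {
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    dest <- tempfile(fileext = "")
    path <- Rsamtools::asBam(path, destination = dest, overwrite = TRUE,
                             indexDestination = TRUE)
  }
  flag <- Rsamtools::scanBamFlag(
    isUnmappedQuery = FALSE, isSecondaryAlignment = FALSE,
    isSupplementaryAlignment = FALSE, isDuplicate = FALSE,
    isNotPassingQualityControls = FALSE
  )
  what <- c("qname", "flag", "rname", "strand", "pos", "mapq", "cigar",
            "mrnm", "mpos", "isize")
  res <- Rsamtools::scanBam(path,
                            param = Rsamtools::ScanBamParam(flag = flag,
                                                            what = what))[[1]]
  n <- length(res$pos)
  if (n == 0L) {
    return(data.frame(qname = character(0), contig = character(0),
                      pos = integer(0), width = integer(0),
                      strand = character(0), mapq = integer(0),
                      paired = logical(0), mate_mapped = logical(0),
                      mate_contig = character(0), mate_pos = integer(0),
                      mate_strand = character(0), fragment = integer(0),
                      leftmost = logical(0), stringsAsFactors = FALSE))
  }
  fl <- res$flag
  width <- GenomicAlignments::cigarWidthAlongReferenceSpace(res$cigar)
  paired <- bitwAnd(fl, 0x1L) > 0L
  mate_mapped <- paired & bitwAnd(fl, 0x8L) == 0L
  mate_strand <- ifelse(bitwAnd(fl, 0x20L) > 0L, "-", "+")
  isize <- res$isize
  frag <- abs(isize)
  same <- mate_mapped & !is.na(res$mrnm) &
    as.character(res$mrnm) == as.character(res$rname)
  # TLEN of 0 on a same-contig pair: approximate the span from positions
  fix <- same & (is.na(frag) | frag == 0L)
  if (any(fix)) {
    frag[fix] <- abs(res$mpos[fix] - res$pos[fix]) + width[fix]
  }
  frag[!same] <- NA_integer_

  out <- data.frame(
    qname = res$qname,
    contig = as.character(res$rname),
    pos = res$pos - 1L,
    width = as.integer(width),
    strand = as.character(res$strand),
    mapq = res$mapq,
    paired = paired,
    mate_mapped = mate_mapped,
    mate_contig = ifelse(mate_mapped, as.character(res$mrnm), NA_character_),
    mate_pos = ifelse(mate_mapped, res$mpos - 1L, NA_integer_),
    mate_strand = ifelse(mate_mapped, mate_strand, NA_character_),
    fragment = as.integer(frag),
    leftmost = !is.na(isize) & isize > 0L,
    stringsAsFactors = FALSE
  )
  out <- out[is.na(out$mapq) | out$mapq >= mapq_min, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write a read-view data frame as coordinate-sorted SAM
#'
#' Serialises alignments produced by [liftover_alignments()] as plain SAM
#' with correct FLAG bits, RNAME/POS (1-based), CIGAR, mate fields and signed
#' outermost-span TLEN. Unmapped reads are written with `*` RNAME after all
#' mapped records.
#'
#' @param aln Read-view data frame with `mate`, `cigar` and `seq` columns.
#' @param contig_lengths Named vector of contig lengths for the header.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_sam <- function(aln, contig_lengths, path) {
  hdr <- c("@HD\tVN:1.6\tSO:coordinate",
           sprintf("@SQ\tSN:%s\tLN:%d", names(contig_lengths),
                   as.integer(contig_lengths)))
  flag <- rep(1L, nrow(aln))  # paired
  flag <- flag + ifelse(aln$mapped, 0L, 4L)
  flag <- flag + ifelse(aln$mate_mapped, 0L, 8L)
  flag <- flag + ifelse(aln$mapped & aln$strand == "-", 16L, 0L)
  flag <- flag + ifelse(aln$mate_mapped & aln$mate_strand == "-", 32L, 0L)
  flag <- flag + ifelse(aln$mate == 1L, 64L, 128L)

  same <- aln$mapped & aln$mate_mapped & aln$contig == aln$mate_contig
  tlen <- integer(nrow(aln))
  tlen[same] <- ifelse(aln$leftmost[same], aln$fragment[same],
                       -aln$fragment[same])
  rnext <- ifelse(!aln$mate_mapped, "*",
                  ifelse(same, "=", aln$mate_contig))
  lines <- paste(
    aln$qname, flag,
    ifelse(aln$mapped, aln$contig, "*"),
    ifelse(aln$mapped, aln$pos + 1L, 0L),
    ifelse(aln$mapped, aln$mapq, 0L),
    ifelse(aln$mapped, aln$cigar, "*"),
    rnext,
    ifelse(aln$mate_mapped, aln$mate_pos + 1L, 0L),
    tlen, aln$seq, "*",
    sep = "\t"
  )
  o <- order(!aln$mapped, match(aln$contig, names(contig_lengths)), aln$pos,
             aln$qname, aln$mate, method = "radix")
  writeLines(c(hdr, lines[o]), path)
  invisible(path)
}

features_to_granges <- function(features, source = "frcurve") {
  lib <- sub("^.*_", "", features$type)
  gr <- GenomicRanges::GRanges(
    seqnames = features$contig,
    ranges = IRanges::IRanges(start = features$start + 1L, end = features$end),
    strand = rep("*", nrow(features))
  )
  S4Vectors::mcols(gr)$source <- rep_len(source, nrow(features))
  S4Vectors::mcols(gr)$type <- features$type
  if (!is.null(features$score)) S4Vectors::mcols(gr)$score <- features$score
  S4Vectors::mcols(gr)$lib <- lib
  gr
}

#' Write feature regions as GFF3
#'
#' One line per merged region: `seqid` is the contig, `type` the feature name
#' (e.g. `HIGH_OUTIE_PE`), coordinates 1-based inclusive, `score` the region's
#' mean offending statistic, and a `lib` attribute carrying the library role.
#' Unsorted input is sorted with a warning.
#'
#' @param features Feature-region data frame (0-based half-open internally).
#' @param path Output file.
#' @param source GFF source column value.
#' @return `path`, invisibly.
#' @export
write_feature_gff <- function(features, path, source = "frcurve") {
  if (nrow(features) > 0) {
    o <- order(features$contig, features$start, features$end, features$type)
    if (!identical(o, seq_len(nrow(features)))) {
      warning("features were not sorted by (contig, start); sorting")
      features <- features[o, , drop = FALSE]
    }
  } else {
    # header-only file; rtracklayer cannot export a zero-range GRanges
    writeLines("##gff-version 3", path)
    return(invisible(path))
  }
  if (is.null(features$score)) features$score <- NA_real_
  rtracklayer::export(features_to_granges(features, source), path,
                      format = "gff3")
  invisible(path)
}

#' Read feature or truth regions from GFF3
#'
#' Inverse of [write_feature_gff()]: returns 0-based half-open intervals with
#' the GFF `type` column as the feature/event type.
#'
#' @param path GFF3 file.
#' @return Region data frame (`contig`, `start`, `end`, `type`, `score`).
#' @export
read_feature_gff <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  if (length(gr) == 0L) return(empty_regions())
  score <- S4Vectors::mcols(gr)$score
  if (is.null(score)) score <- rep(NA_real_, length(gr))
  data.frame(
    contig = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    type = as.character(S4Vectors::mcols(gr)$type),
    score = as.numeric(score),
    stringsAsFactors = FALSE
  )
}

#' Write FRCurve text files
#'
#' Writes `<prefix>_FRC.txt` for the global curve and
#' `<prefix>_<TYPE>_FRC.txt` per feature type: two whitespace-separated
#' columns, the feature threshold and the approximate genome coverage as a
#' percentage with two decimals, after a comment header.
#'
#' @param global_curve Curve data frame from [compute_frcurve()].
#' @param per_feature Named list from [per_feature_curves()] (optional).
#' @param prefix Output path prefix.
#' @return Character vector of files written, invisibly.
#' @export
write_curves <- function(global_curve, per_feature = NULL, prefix = "frc") {
  write_one <- function(curve, path, label) {
    writeLines(c(sprintf("# feature threshold vs approximate genome coverage (%%) [%s]",
                         label),
                 sprintf("%d %.2f", curve$tau, 100 * curve$coverage)),
               path)
    path
  }
  files <- write_one(global_curve, paste0(prefix, "_FRC.txt"), "all features")
  for (tp in names(per_feature)) {
    files <- c(files, write_one(per_feature[[tp]],
                                paste0(prefix, "_", tp, "_FRC.txt"), tp))
  }
  invisible(files)
}

#' Write contigs as FASTA
#'
#' @param seqs Named character vector of sequences.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), path)
  invisible(path)
}

#' Read contig sequences from FASTA
#'
#' @param path FASTA file.
#' @return Named character vector of sequences.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  stats::setNames(as.character(x), sub("\\s.*$", "", names(x)))
}
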