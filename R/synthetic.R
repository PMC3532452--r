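# Synthetic benchmark: reference genomes, typed mis-assembled assemblies with
# a ground-truth ledger and a reference->assembly liftover map, simulated
# PE/MP pairs, and liftover alignments. All coordinates 0-based half-open.

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

random_dna <- function(n, gc = 0.5) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

#' Generate a random reference genome
#'
#' I.i.d. bases at the requested GC content, optionally with planted exact
#' repeat families (identical copies at random non-overlapping positions).
#' Deterministic for a fixed seed.
#'
#' @param length Genome length in bp.
#' @param gc GC content in [0, 1].
#' @param repeats `NULL`, or a list with `n_repeats` (families),
#'   `repeat_len` (bp) and `n_copies` (copies per family).
#' @param seed Integer seed.
#' @return A single character string.
#' @export
generate_reference <- function(length, gc = 0.5, repeats = NULL, seed = 1L) {
  stopifnot(length > 0, gc >= 0, gc <= 1)
  set.seed(seed)
  genome <- random_dna(length, gc)
  if (!is.null(repeats)) {
    mass <- repeats$n_repeats * repeats$repeat_len * repeats$n_copies
    if (mass > length) stop("repeat mass exceeds genome length", call. = FALSE)
    occupied <- logical(length)
    for (fam in seq_len(repeats$n_repeats)) {
      unit <- random_dna(repeats$repeat_len, gc)
      placed <- 0L
      tries <- 0L
      while (placed < repeats$n_copies && tries < 10000L) {
        tries <- tries + 1L
        p <- sample.int(length - repeats$repeat_len + 1L, 1L) - 1L
        span <- seq.int(p + 1L, p + repeats$repeat_len)
        if (any(occupied[span])) next
        substr(genome, p + 1L, p + repeats$repeat_len) <- unit
        occupied[span] <- TRUE
        placed <- placed + 1L
      }
      if (placed < repeats$n_copies) {
        stop("could not place all repeat copies without overlap", call. = FALSE)
      }
    }
  }
  genome
}

#' Construct a mis-assembly event request
#'
#' Event types and their coordinates (all on the reference, 0-based
#' half-open):
#' * `INVERSION`, `DELETION`, `EXPANSION`: interval `[start, end)`;
#' * `COMPRESSION`: interval `[start, end)` collapsed onto the copy at
#'   `[copy_start, copy_start + (end - start))` (default: the immediately
#'   preceding tandem copy); reads from the removed copy lift onto the kept
#'   copy, as a real aligner would place them;
#' * `CHIMERIC_INSERTION`: foreign sequence of `length` bp inserted at `pos`;
#' * `FRAGMENTATION`: contig split at `pos`;
#' * `RELOCATION`: interval `[start, end)` excised and reinserted at
#'   reference position `target`.
#'
#' @param type One of the seven event types.
#' @param start,end,pos,length,target,copy_start Coordinates as above.
#' @return An object of class `misassembly_event`.
#' @export
misassembly_event <- function(type = c("INVERSION", "RELOCATION", "COMPRESSION",
                                       "EXPANSION", "CHIMERIC_INSERTION",
                                       "DELETION", "FRAGMENTATION"),
                              start = NULL, end = NULL, pos = NULL,
                              length = NULL, target = NULL, copy_start = NULL) {
  type <- match.arg(type)
  ev <- list(type = type)
  if (type %in% c("INVERSION", "RELOCATION", "COMPRESSION", "EXPANSION",
                  "DELETION")) {
    stopifnot(!is.null(start), !is.null(end), start >= 0, end > start)
    ev$start <- as.integer(start)
    ev$end <- as.integer(end)
  }
  if (type == "COMPRESSION") {
    if (is.null(copy_start)) copy_start <- start - (end - start)
    stopifnot(copy_start >= 0)
    ev$copy_start <- as.integer(copy_start)
  }
  if (type == "RELOCATION") {
    stopifnot(!is.null(target), target >= 0)
    ev$target <- as.integer(target)
  }
  if (type == "CHIMERIC_INSERTION") {
    stopifnot(!is.null(pos), !is.null(length), pos >= 0, length > 0)
    ev$pos <- as.integer(pos)
    ev$length <- as.integer(length)
  }
  if (type == "FRAGMENTATION") {
    stopifnot(!is.null(pos), pos > 0)
    ev$pos <- as.integer(pos)
  }
  structure(ev, class = "misassembly_event")
}

# the reference interval an event occupies (zero width for point events)
event_interval <- function(ev) {
  switch(ev$type,
         CHIMERIC_INSERTION = c(ev$pos, ev$pos),
         FRAGMENTATION = c(ev$pos, ev$pos),
         c(ev$start, ev$end))
}

#' Apply typed mis-assembly events to a reference
#'
#' Produces the corrupted assembly (one or more contigs), a ground-truth
#' ledger in assembly coordinates, and the reference-to-assembly liftover
#' blocks used to place simulated reads. Body-type events (`INVERSION`,
#' `EXPANSION`, `CHIMERIC_INSERTION`) are marked over their assembled body;
#' junction-type events (`DELETION`, `COMPRESSION`, `RELOCATION`,
#' `FRAGMENTATION`) are marked `truth_flank` bp either side of each junction,
#' since read pairs -- the detection instrument -- concentrate their signal
#' within about one fragment length of a junction.
#'
#' Events must be non-overlapping on the reference. A `COMPRESSION` event
#' assumes `[start, end)` duplicates the copy at `copy_start` (see
#' [plant_duplicate()]); reads simulated from the removed copy are lifted
#' onto the kept copy.
#'
#' @param reference Reference genome (single character string).
#' @param events List of [misassembly_event()] requests (possibly empty).
#' @param truth_flank Junction flank in bp (default 300, a typical PE insert
#'   mean).
#' @param foreign_gc GC content of chimeric insert sequence.
#' @param seed Seed for foreign sequence generation.
#' @return An object of class `assembly_sim`: list with `contigs` (named
#'   character vector), `contig_lengths`, `truth` (data frame `contig`,
#'   `start`, `end`, `type`), `blocks` (liftover map) and `reference_length`.
#' @export
apply_misassembly_events <- function(reference, events, truth_flank = 300L,
                                     foreign_gc = 0.5, seed = 1L) {
  L <- nchar(reference)
  set.seed(seed)
  events <- lapply(events, function(ev) {
    if (!inherits(ev, "misassembly_event")) do.call(misassembly_event, ev) else ev
  })

  ivs <- do.call(rbind, lapply(events, event_interval))
  if (!is.null(ivs)) {
    if (any(ivs < 0L) || any(ivs > L)) {
      stop("event coordinates outside the reference", call. = FALSE)
    }
    o <- order(ivs[, 1L], ivs[, 2L])
    si <- ivs[o, , drop = FALSE]
    if (nrow(si) > 1L && any(si[-1L, 1L] < si[-nrow(si), 2L])) {
      stop("events overlap on the reference", call. = FALSE)
    }
    inside_event <- function(p) {
      any(ivs[, 1L] < p & p < ivs[, 2L])
    }
    for (ev in events) {
      if (ev$type == "RELOCATION" && inside_event(ev$target)) {
        stop(sprintf("relocation target %d lies inside another event", ev$target),
             call. = FALSE)
      }
      if (ev$type == "COMPRESSION") {
        cs <- ev$copy_start; ce <- cs + (ev$end - ev$start)
        if (ce > L || any(ivs[, 1L] < ce & cs < ivs[, 2L])) {
          stop("compression copy interval conflicts with an event", call. = FALSE)
        }
      }
    }
    events <- events[o]
  }

  seg <- function(s, e, strand = 1L, truth = NA_character_) {
    list(kind = "seg", s = s, e = e, strand = strand, truth = truth)
  }
  tokens <- list()
  push <- function(tok) tokens[[length(tokens) + 1L]] <<- tok
  relocated <- list()

  cur <- 0L
  for (ev in events) {
    iv <- event_interval(ev)
    if (iv[1L] > cur) push(seg(cur, iv[1L]))
    switch(ev$type,
      INVERSION = push(seg(ev$start, ev$end, strand = -1L, truth = "INVERSION")),
      DELETION = push(list(kind = "junction", truth = "DELETION")),
      COMPRESSION = {
        push(list(kind = "junction", truth = "COMPRESSION"))
      },
      EXPANSION = {
        push(seg(ev$start, ev$end))
        push(list(kind = "dup", s = ev$start, e = ev$end, truth = "EXPANSION"))
      },
      CHIMERIC_INSERTION = push(list(kind = "foreign", len = ev$length,
                                     truth = "CHIMERIC_INSERTION")),
      FRAGMENTATION = push(list(kind = "break")),
      RELOCATION = {
        push(list(kind = "junction", truth = "RELOCATION"))
        relocated[[length(relocated) + 1L]] <-
          list(s = ev$start, e = ev$end, target = ev$target)
      }
    )
    cur <- max(cur, iv[2L])
  }
  if (cur < L) push(seg(cur, L))

  # re-insert relocated segments at their targets (plain segments only)
  for (rl in relocated) {
    hit <- NA_integer_
    for (i in seq_along(tokens)) {
      tk <- tokens[[i]]
      if (tk$kind == "seg" && tk$strand == 1L && is.na(tk$truth) &&
          tk$s <= rl$target && rl$target <= tk$e) {
        hit <- i; break
      }
    }
    if (is.na(hit)) {
      stop(sprintf("relocation target %d not in unaffected sequence", rl$target),
           call. = FALSE)
    }
    tk <- tokens[[hit]]
    replacement <- list()
    if (rl$target > tk$s) replacement <- c(replacement, list(seg(tk$s, rl$target)))
    replacement <- c(replacement,
                     list(list(kind = "junction", truth = "RELOCATION"),
                          seg(rl$s, rl$e),
                          list(kind = "junction", truth = "RELOCATION")))
    if (rl$target < tk$e) replacement <- c(replacement, list(seg(rl$target, tk$e)))
    tokens <- append(tokens[-hit], replacement, after = hit - 1L)
  }

  # realize contigs, liftover blocks and truth intervals
  contigs <- character(0)
  blocks <- list()
  truth <- list()
  ctg_i <- 1L
  parts <- character(0)
  off <- 0L
  junctions <- list()  # deferred until the contig length is known
  bodies <- list()

  flush_contig <- function() {
    if (off == 0L && length(parts) == 0L) return(invisible())
    name <- sprintf("contig_%d", ctg_i)
    contigs[[name]] <<- paste(parts, collapse = "")
    clen <- off
    for (b in bodies) {
      truth[[length(truth) + 1L]] <<-
        data.frame(contig = name, start = b$s, end = b$e, type = b$truth,
                   stringsAsFactors = FALSE)
    }
    for (j in junctions) {
      truth[[length(truth) + 1L]] <<-
        data.frame(contig = name,
                   start = max(0L, j$at - as.integer(truth_flank)),
                   end = min(clen, j$at + as.integer(truth_flank)),
                   type = j$truth, stringsAsFactors = FALSE)
    }
    ctg_i <<- ctg_i + 1L
    parts <<- character(0); off <<- 0L
    junctions <<- list(); bodies <<- list()
  }

  for (tk in tokens) {
    name <- sprintf("contig_%d", ctg_i)
    if (tk$kind == "seg") {
      piece <- substr(reference, tk$s + 1L, tk$e)
      if (tk$strand == -1L) piece <- revcomp(piece)
      parts <- c(parts, piece)
      blocks[[length(blocks) + 1L]] <-
        data.frame(ref_start = tk$s, ref_end = tk$e, strand = tk$strand,
                   contig = name, asm_start = off, stringsAsFactors = FALSE)
      if (!is.na(tk$truth)) {
        bodies[[length(bodies) + 1L]] <-
          list(s = off, e = off + (tk$e - tk$s), truth = tk$truth)
      }
      off <- off + (tk$e - tk$s)
    } else if (tk$kind == "dup") {
      piece <- substr(reference, tk$s + 1L, tk$e)
      parts <- c(parts, piece)
      bodies[[length(bodies) + 1L]] <-
        list(s = off, e = off + (tk$e - tk$s), truth = tk$truth)
      off <- off + (tk$e - tk$s)
    } else if (tk$kind == "foreign") {
      parts <- c(parts, random_dna(tk$len, foreign_gc))
      bodies[[length(bodies) + 1L]] <-
        list(s = off, e = off + tk$len, truth = tk$truth)
      off <- off + tk$len
    } else if (tk$kind == "junction") {
      junctions[[length(junctions) + 1L]] <- list(at = off, truth = tk$truth)
    } else if (tk$kind == "break") {
      # both new contig ends are fragmentation junctions
      junctions[[length(junctions) + 1L]] <- list(at = off, truth = "FRAGMENTATION")
      flush_contig()
      junctions[[length(junctions) + 1L]] <- list(at = 0L, truth = "FRAGMENTATION")
    }
  }
  flush_contig()

  blocks <- if (length(blocks)) do.call(rbind, blocks) else
    data.frame(ref_start = integer(0), ref_end = integer(0), strand = integer(0),
               contig = character(0), asm_start = integer(0))

  # compression aliases: removed copy lifts onto the kept copy
  for (ev in events) {
    if (ev$type != "COMPRESSION") next
    len <- ev$end - ev$start
    cs <- ev$copy_start; ce <- cs + len
    host <- which(blocks$strand == 1L & blocks$ref_start <= cs & ce <= blocks$ref_end)
    if (length(host) == 0L) {
      stop("compression copy interval is not in mapped sequence", call. = FALSE)
    }
    h <- host[1L]
    blocks <- rbind(blocks, data.frame(
      ref_start = ev$start, ref_end = ev$end, strand = 1L,
      contig = blocks$contig[h],
      asm_start = blocks$asm_start[h] + (cs - blocks$ref_start[h]),
      stringsAsFactors = FALSE))
  }

  truth <- if (length(truth)) do.call(rbind, truth) else
    data.frame(contig = character(0), start = integer(0), end = integer(0),
               type = character(0), stringsAsFactors = FALSE)

  structure(list(
    contigs = contigs,
    contig_lengths = stats::setNames(nchar(contigs), names(contigs)),
    truth = truth, blocks = blocks, reference_length = L
  ), class = "assembly_sim")
}

#' Overwrite an interval with a copy of another (tandem duplication)
#'
#' Makes `[start, end)` an exact copy of `[copy_start, copy_start + end -
#' start)`, creating the two-copy repeat that a `COMPRESSION` event then
#' collapses.
#'
#' @param reference Character string genome.
#' @param start,end Interval to overwrite (0-based half-open).
#' @param copy_start Source position (default: immediately preceding copy).
#' @return The modified genome string.
#' @export
plant_duplicate <- function(reference, start, end, copy_start = NULL) {
  len <- end - start
  if (is.null(copy_start)) copy_start <- start - len
  stopifnot(copy_start >= 0, copy_start + len <= nchar(reference))
  substr(reference, start + 1L, end) <-
    substr(reference, copy_start + 1L, copy_start + len)
  reference
}

#' Simulate read pairs from a reference
#'
#' Fragment lengths are Gaussian `N(insert_mean, insert_sd)` truncated below
#' at `2 * read_len`; fragment starts are uniform. Pair orientation on the
#' reference follows the library convention: innie (PE) pairs read inward
#' (leftmost mate forward), outie (MP) pairs read outward. The number of
#' pairs is `floor(coverage * L / (2 * read_len))`. Uniform substitution
#' errors are applied at `err_rate` per base. Deterministic per seed.
#'
#' @param reference Character string genome.
#' @param lib [library_profile()].
#' @param coverage Target vertical read coverage (x).
#' @param read_len Read length in bp (< `insert_mean`).
#' @param err_rate Per-base substitution probability.
#' @param seed Integer seed.
#' @return Data frame with one row per pair: fragment coordinates, per-mate
#'   reference intervals, strands and (reference-forward) sequences.
#' @export
simulate_pairs <- function(reference, lib, coverage, read_len,
                           err_rate = 0, seed = 1L) {
  stopifnot(is_library_profile(lib), coverage > 0, read_len < lib$insert_mean)
  L <- nchar(reference)
  if (lib$insert_mean >= L) {
    stop("insert_mean must be smaller than the reference length", call. = FALSE)
  }
  set.seed(seed)
  n <- floor(coverage * L / (2 * read_len))
  frag <- round(stats::rnorm(n, lib$insert_mean, lib$insert_sd))
  frag <- pmin(pmax(frag, 2L * read_len), L)
  start <- floor(stats::runif(n, 0, L - frag + 1))

  left_s <- as.integer(start)
  left_e <- left_s + as.integer(read_len)
  right_e <- as.integer(start + frag)
  right_s <- right_e - as.integer(read_len)
  if (lib$orientation == "innie") {
    left_strand <- "+"; right_strand <- "-"
  } else {
    left_strand <- "-"; right_strand <- "+"
  }

  left_seq <- substring(reference, left_s + 1L, left_e)
  right_seq <- substring(reference, right_s + 1L, right_e)
  if (err_rate > 0) {
    mutate <- function(seqs) {
      total <- length(seqs) * read_len
      k <- stats::rbinom(1L, total, err_rate)
      if (k == 0L) return(seqs)
      at <- sample.int(total, k)
      ri <- (at - 1L) %/% read_len + 1L
      pi <- (at - 1L) %% read_len + 1L
      for (j in seq_len(k)) {
        old <- substr(seqs[ri[j]], pi[j], pi[j])
        substr(seqs[ri[j]], pi[j], pi[j]) <-
          sample(setdiff(c("A", "C", "G", "T"), old), 1L)
      }
      seqs
    }
    left_seq <- mutate(left_seq)
    right_seq <- mutate(right_seq)
  }

  data.frame(
    pair = seq_len(n), fragment = as.integer(frag),
    left_start = left_s, left_end = left_e, left_strand = left_strand,
    right_start = right_s, right_end = right_e, right_strand = right_strand,
    left_seq = left_seq, right_seq = right_seq,
    stringsAsFactors = FALSE
  )
}

# map read intervals [rs, re) through liftover blocks; reads overhanging the
# best block by more than tol bases are unmapped, smaller overhangs are
# soft-clipped.
lift_read_intervals <- function(blocks, rs, re, tol = 20L) {
  nr <- length(rs)
  nb <- nrow(blocks)
  best_ov <- integer(nr)
  best_b <- rep(NA_integer_, nr)
  for (b in seq_len(nb)) {
    ov <- pmin(re, blocks$ref_end[b]) - pmax(rs, blocks$ref_start[b])
    better <- ov > best_ov
    best_ov[better] <- ov[better]
    best_b[better] <- b
  }
  width <- re - rs
  mapped <- !is.na(best_b) & (width - best_ov) <= tol & best_ov > 0L

  out <- data.frame(
    mapped = mapped, contig = NA_character_, pos = NA_integer_,
    mwidth = NA_integer_, flip = FALSE,
    clip_left = 0L, clip_right = 0L
  )
  i <- which(mapped)
  if (length(i)) {
    b <- best_b[i]
    cs <- pmax(rs[i], blocks$ref_start[b])
    ce <- pmin(re[i], blocks$ref_end[b])
    plus <- blocks$strand[b] == 1L
    pos <- integer(length(i))
    pos[plus] <- blocks$asm_start[b][plus] + (cs[plus] - blocks$ref_start[b][plus])
    pos[!plus] <- blocks$asm_start[b][!plus] +
      (blocks$ref_end[b][!plus] - ce[!plus])
    out$contig[i] <- blocks$contig[b]
    out$pos[i] <- pos
    out$mwidth[i] <- ce - cs
    out$flip[i] <- !plus
    out$clip_left[i] <- ifelse(plus, cs - rs[i], re[i] - ce)
    out$clip_right[i] <- ifelse(plus, re[i] - ce, cs - rs[i])
  }
  out
}

flip_strand <- function(s) ifelse(s == "+", "-", "+")

#' Lift simulated pairs onto the assembly as alignment records
#'
#' Places each read at its true assembly position through the liftover map of
#' [apply_misassembly_events()]: reads inside an inversion have their strand
#' flipped; reads from deleted sequence become unmapped (the mate turns into
#' singleton evidence); reads straddling an event breakpoint by more than
#' `breakpoint_tolerance` bp are unmapped, smaller overhangs are soft-clipped.
#' The result is a read-view data frame ready for [build_tracks()] and
#' [write_sam()], with correct mate fields and outermost-span fragment
#' lengths (TLEN semantics).
#'
#' @param pairs Output of [simulate_pairs()].
#' @param sim Output of [apply_misassembly_events()].
#' @param breakpoint_tolerance Maximum tolerated overhang in bp (default 20).
#' @param mapq Mapping quality assigned to mapped reads.
#' @return Read-view data frame, two rows per pair, coordinate-sorted.
#' @export
liftover_alignments <- function(pairs, sim, breakpoint_tolerance = 20L,
                                mapq = 60L) {
  n <- nrow(pairs)
  qname <- sprintf("pair_%08d", pairs$pair)
  rs <- c(pairs$left_start, pairs$right_start)
  re <- c(pairs$left_end, pairs$right_end)
  ref_strand <- c(pairs$left_strand, pairs$right_strand)
  seqs <- c(pairs$left_seq, pairs$right_seq)

  lifted <- lift_read_intervals(sim$blocks, rs, re, tol = breakpoint_tolerance)
  strand <- ifelse(lifted$flip, flip_strand(ref_strand), ref_strand)
  flipped <- which(lifted$mapped & lifted$flip)
  if (length(flipped)) seqs[flipped] <- revcomp(seqs[flipped])

  cigar <- rep("*", 2L * n)
  i <- which(lifted$mapped)
  cigar[i] <- paste0(
    ifelse(lifted$clip_left[i] > 0L, paste0(lifted$clip_left[i], "S"), ""),
    lifted$mwidth[i], "M",
    ifelse(lifted$clip_right[i] > 0L, paste0(lifted$clip_right[i], "S"), "")
  )

  m1 <- seq_len(n); m2 <- n + m1
  mate_of <- c(m2, m1)
  aln <- data.frame(
    qname = c(qname, qname), mate = rep(1:2, each = n),
    mapped = lifted$mapped, contig = lifted$contig, pos = lifted$pos,
    width = lifted$mwidth, strand = strand, mapq = as.integer(mapq),
    cigar = cigar, seq = seqs, paired = TRUE,
    mate_mapped = lifted$mapped[mate_of],
    mate_contig = lifted$contig[mate_of],
    mate_pos = lifted$pos[mate_of],
    mate_strand = strand[mate_of],
    fragment = NA_integer_, leftmost = FALSE,
    stringsAsFactors = FALSE
  )

  both <- aln$mapped & aln$mate_mapped & !is.na(aln$mate_contig) &
    aln$contig == aln$mate_contig
  ends <- aln$pos + aln$width
  mate_ends <- aln$mate_pos + aln$width[mate_of]
  frag <- pmax(ends, mate_ends) - pmin(aln$pos, aln$mate_pos)
  aln$fragment[both] <- frag[both]
  aln$leftmost <- both & (aln$pos < aln$mate_pos |
                            (aln$pos == aln$mate_pos & aln$mate == 1L))

  o <- order(!aln$mapped, aln$contig, aln$pos, aln$qname, aln$mate,
             method = "radix")
  aln <- aln[o, , drop = FALSE]
  rownames(aln) <- NULL
  aln
}
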