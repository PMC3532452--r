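# Per-contig evidence tracks: vertical coverage, spanning coverage, pair-class
# counters and windowed insert-size accumulators, all on 0-based half-open
# coordinates.

# coverage of [starts, ends) intervals over positions 0..len-1
interval_coverage <- function(starts, ends, len) {
  if (length(starts) == 0L) return(integer(len))
  keep <- ends > starts
  starts <- starts[keep]; ends <- ends[keep]
  if (length(starts) == 0L) return(integer(len))
  d <- tabulate(starts + 1L, nbins = len + 1L) -
    tabulate(pmin(ends, len) + 1L, nbins = len + 1L)
  cumsum(d)[seq_len(len)]
}

# window tiling for a contig: starts/ends/midpoints of sliding windows
contig_windows <- function(len, window, step) {
  stopifnot(window > 0, step > 0)
  if (len <= window) {
    start <- 0L
  } else {
    start <- as.integer(seq.int(0L, len - window, by = step))
  }
  end <- pmin(start + as.integer(window), as.integer(len))
  mid <- (start + end) %/% 2L
  list(start = start, end = end, mid = mid, n = length(start))
}

#' Build per-contig evidence tracks from read alignments
#'
#' Accumulates, for a single contig, the per-position tracks from which all
#' features are computed:
#'
#' * `read_cov` -- vertical coverage of all counted reads;
#' * `proper_cov` -- coverage restricted to reads in `PROPER` pairs;
#' * `span_cov` -- spanning (horizontal) coverage: for each `PROPER` pair,
#'   counted once from its leftmost mate, the whole fragment interval
#'   `[pos, pos + fragment)` is covered;
#' * `singleton_cnt`, `outie_cnt`, `spanning_cnt` -- per-position counts of
#'   reads of the corresponding class (see [classify_pairs()]);
#' * windowed insert accumulators: for every sliding window, the number and
#'   the sum of fragment lengths of `PROPER` pairs whose fragment span covers
#'   the window midpoint (the input of the CE statistic), plus the raw vector
#'   of all `PROPER` fragment lengths for library re-estimation.
#'
#' Reads must already be filtered to primary, non-duplicate, QC-pass
#' alignments; [read_alignments()] does this when reading BAM/SAM.
#'
#' @param reads Read-view data frame as for [classify_pairs()], restricted to
#'   this contig, with the additional columns `width` (reference bases
#'   consumed) and `leftmost` (logical; `TRUE` for the leftmost mate of a
#'   pair) and optionally `paired` (logical; unpaired reads only contribute to
#'   `read_cov`). A zero-row data frame yields all-zero tracks.
#' @param lib A [library_profile()].
#' @param contig_id Contig name.
#' @param contig_length Contig length in bp (> 0).
#' @param window,step Sliding-window size and step in bp (defaults 1000/200).
#' @param tolerance_k Proper-distance tolerance passed to [classify_pairs()].
#' @return An object of class `contig_tracks`.
#' @export
build_tracks <- function(reads, lib, contig_id, contig_length,
                         window = 1000L, step = 200L, tolerance_k = 3) {
  stopifnot(is_library_profile(lib), contig_length > 0)
  len <- as.integer(contig_length)
  win <- contig_windows(len, window, step)

  if (is.null(reads) || nrow(reads) == 0L) {
    z <- integer(len)
    return(structure(list(
      contig_id = contig_id, length = len, lib_role = lib$role,
      window = as.integer(window), step = as.integer(step),
      win_start = win$start, win_end = win$end, win_mid = win$mid,
      read_cov = z, proper_cov = z, span_cov = z,
      singleton_cnt = z, outie_cnt = z, spanning_cnt = z,
      win_n = integer(win$n), win_sum = numeric(win$n),
      proper_fragments = numeric(0), n_reads = 0L
    ), class = "contig_tracks"))
  }

  if (any(reads$pos < 0L) || any(reads$pos + reads$width > len)) {
    stop(sprintf("read coordinates beyond contig '%s' bounds (corrupt input)",
                 contig_id), call. = FALSE)
  }

  paired <- if ("paired" %in% names(reads)) reads$paired else rep(TRUE, nrow(reads))
  cls <- rep(NA_character_, nrow(reads))
  if (any(paired)) {
    cls[paired] <- classify_pairs(reads[paired, , drop = FALSE], lib, tolerance_k)
  }

  s <- as.integer(reads$pos)
  e <- s + as.integer(reads$width)
  read_cov <- interval_coverage(s, e, len)
  sel <- function(klass) which(!is.na(cls) & cls == klass)
  ip <- sel("PROPER")
  proper_cov <- interval_coverage(s[ip], e[ip], len)
  singleton_cnt <- interval_coverage(s[sel("SINGLETON")], e[sel("SINGLETON")], len)
  outie_cnt <- interval_coverage(s[sel("OUTIE")], e[sel("OUTIE")], len)
  spanning_cnt <- interval_coverage(s[sel("SPANNING")], e[sel("SPANNING")], len)

  # fragments counted once, from the leftmost mate of each PROPER pair
  il <- ip[reads$leftmost[ip] & !is.na(reads$fragment[ip])]
  frag <- abs(reads$fragment[il])
  fs <- s[il]
  fe <- pmin(fs + as.integer(frag), len)
  span_cov <- interval_coverage(fs, fe, len)

  win_n <- integer(win$n)
  win_sum <- numeric(win$n)
  if (length(fs)) {
    if (win$n == 1L) {
      hit <- fs <= win$mid[1L] & win$mid[1L] < fe
      win_n[1L] <- sum(hit)
      win_sum[1L] <- sum(frag[hit])
    } else {
      half <- win$mid[1L]  # mid_j = j*step + half for full windows
      stp <- as.integer(step)
      j_lo <- pmax(0L, as.integer(ceiling((fs - half) / stp)))
      j_hi <- pmin(win$n - 1L, as.integer(floor((fe - 1L - half) / stp)))
      k <- j_hi - j_lo + 1L
      keep <- k > 0L
      if (any(keep)) {
        idx <- sequence(k[keep], from = j_lo[keep] + 1L)
        win_n <- tabulate(idx, nbins = win$n)
        agg <- rowsum(rep(frag[keep], k[keep]), idx)
        win_sum[as.integer(rownames(agg))] <- agg[, 1L]
      }
    }
  }

  structure(list(
    contig_id = contig_id, length = len, lib_role = lib$role,
    window = as.integer(window), step = as.integer(step),
    win_start = win$start, win_end = win$end, win_mid = win$mid,
    read_cov = read_cov, proper_cov = proper_cov, span_cov = span_cov,
    singleton_cnt = singleton_cnt, outie_cnt = outie_cnt,
    spanning_cnt = spanning_cnt,
    win_n = win_n, win_sum = win_sum,
    proper_fragments = as.numeric(frag), n_reads = nrow(reads)
  ), class = "contig_tracks")
}

#' @export
print.contig_tracks <- function(x, ...) {
  cat(sprintf("<contig_tracks> %s (%d bp, %s library): %d reads, mean cov %.1f, %d windows\n",
              x$contig_id, x$length, x$lib_role, x$n_reads,
              mean(x$read_cov), length(x$win_n)))
  invisible(x)
}

#' Library-wide coverage and insert-size statistics
#'
#' Pools all contig tracks of one library to estimate the mean vertical and
#' proper-pair coverage over assembled positions, and refines the rough
#' user-supplied insert mean/sd from the observed `PROPER` fragment lengths
#' after discarding fragments outside `insert_mean +/- 5 * insert_sd` of the
#' prior. A degenerate refined sd is floored at `sd_floor` (default 1 bp).
#'
#' @param tracks A list of [build_tracks()] results (one per contig).
#' @param lib The [library_profile()] carrying the rough prior.
#' @param genome_size User-supplied genome length estimate in bp (> 0);
#'   returned unchanged.
#' @param refine Re-estimate insert mean/sd from PROPER fragments
#'   (default `TRUE`; with `FALSE` the prior is kept).
#' @param sd_floor Lower bound for the refined sd in bp.
#' @return An object of class `global_stats` with elements `mean_read_cov`,
#'   `mean_proper_cov`, `genome_size`, `insert_mean`, `insert_sd`,
#'   `n_fragments` and `lib_role`.
#' @export
estimate_global_stats <- function(tracks, lib, genome_size,
                                  refine = TRUE, sd_floor = 1) {
  stopifnot(is_library_profile(lib))
  if (!is.numeric(genome_size) || genome_size <= 0) {
    stop("genome_size must be > 0", call. = FALSE)
  }
  if (inherits(tracks, "contig_tracks")) tracks <- list(tracks)
  total_len <- sum(vapply(tracks, function(t) t$length, numeric(1)))
  total_reads <- sum(vapply(tracks, function(t) t$n_reads, numeric(1)))
  if (total_len == 0 || total_reads == 0) {
    stop("empty alignment", call. = FALSE)
  }
  sum_read <- sum(vapply(tracks, function(t) sum(as.numeric(t$read_cov)), numeric(1)))
  sum_proper <- sum(vapply(tracks, function(t) sum(as.numeric(t$proper_cov)), numeric(1)))
  frags <- unlist(lapply(tracks, function(t) t$proper_fragments), use.names = FALSE)

  mu <- lib$insert_mean
  sd <- lib$insert_sd
  nf <- 0L
  if (refine && length(frags)) {
    keep <- abs(frags - lib$insert_mean) <= 5 * lib$insert_sd
    frags <- frags[keep]
    if (length(frags)) {
      mu <- mean(frags)
      sd <- if (length(frags) > 1L) stats::sd(frags) else 0
      sd <- max(sd, sd_floor)
      nf <- length(frags)
    }
  }

  structure(list(
    mean_read_cov = sum_read / total_len,
    mean_proper_cov = sum_proper / total_len,
    genome_size = as.numeric(genome_size),
    insert_mean = mu, insert_sd = sd,
    n_fragments = nf, lib_role = lib$role
  ), class = "global_stats")
}

#' @export
print.global_stats <- function(x, ...) {
  cat(sprintf(paste0("<global_stats> %s library: mean cov %.2f (proper %.2f), ",
                     "insert %.1f +/- %.1f bp (%d fragments), G = %.0f bp\n"),
              x$lib_role, x$mean_read_cov, x$mean_proper_cov,
              x$insert_mean, x$insert_sd, x$n_fragments, x$genome_size))
  invisible(x)
}
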