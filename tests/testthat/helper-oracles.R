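# Independent brute-force oracles and small read-view builders. The oracles
# deliberately re-derive every quantity with naive per-position loops so that
# the vectorised implementations are checked against a second, independent
# computation.

# one read-view row with sensible defaults
rv <- function(contig = "c", pos = 0L, width = 100L, strand = "+",
               mate_mapped = TRUE, mate_contig = contig,
               mate_pos = NA_integer_, mate_strand = "-",
               fragment = NA_integer_, leftmost = TRUE, paired = TRUE) {
  data.frame(contig = contig, pos = as.integer(pos), width = as.integer(width),
             strand = strand, mate_mapped = mate_mapped,
             mate_contig = mate_contig, mate_pos = as.integer(mate_pos),
             mate_strand = mate_strand, fragment = as.integer(fragment),
             leftmost = leftmost, paired = paired, stringsAsFactors = FALSE)
}

# a consistent innie/outie pair of read views
make_pair <- function(contig = "c", start = 0L, fragment = 300L,
                      read_len = 100L, orientation = "innie") {
  lpos <- as.integer(start)
  rpos <- as.integer(start + fragment - read_len)
  ls <- if (orientation == "innie") "+" else "-"
  rs <- if (orientation == "innie") "-" else "+"
  rbind(
    rv(contig, lpos, read_len, ls, TRUE, contig, rpos, rs, fragment,
       leftmost = TRUE),
    rv(contig, rpos, read_len, rs, TRUE, contig, lpos, ls, fragment,
       leftmost = FALSE)
  )
}

# independent single-read classification
oracle_classify <- function(r, lib, k = 3) {
  if (!r$mate_mapped) return("SINGLETON")
  if (is.na(r$mate_contig) || r$mate_contig != r$contig) return("SPANNING")
  opp <- r$strand != r$mate_strand
  facing <- if (r$pos == r$mate_pos) {
    TRUE
  } else {
    fwd_pos <- if (r$strand == "+") r$pos else r$mate_pos
    fwd_is_left <- fwd_pos == min(r$pos, r$mate_pos)
    if (lib$orientation == "innie") fwd_is_left else !fwd_is_left
  }
  dist_ok <- !is.na(r$fragment) &&
    abs(abs(r$fragment) - lib$insert_mean) <= k * lib$insert_sd
  if (opp && facing && dist_ok) "PROPER" else "OUTIE"
}

# per-base loop over all reads: the track oracle
oracle_tracks <- function(reads, lib, len, window = 1000L, step = 200L, k = 3) {
  rc <- pc <- sc <- si <- ou <- sp <- integer(len)
  cls <- character(nrow(reads))
  for (i in seq_len(nrow(reads))) {
    r <- reads[i, ]
    cls[i] <- if (isTRUE(r$paired)) oracle_classify(r, lib, k) else NA_character_
    for (p in seq.int(r$pos, r$pos + r$width - 1L)) {
      rc[p + 1L] <- rc[p + 1L] + 1L
      if (identical(cls[i], "PROPER")) pc[p + 1L] <- pc[p + 1L] + 1L
      if (identical(cls[i], "SINGLETON")) si[p + 1L] <- si[p + 1L] + 1L
      if (identical(cls[i], "OUTIE")) ou[p + 1L] <- ou[p + 1L] + 1L
      if (identical(cls[i], "SPANNING")) sp[p + 1L] <- sp[p + 1L] + 1L
    }
  }
  spans <- reads[!is.na(cls) & cls == "PROPER" & reads$leftmost &
                   !is.na(reads$fragment), , drop = FALSE]
  if (nrow(spans)) {
    for (i in seq_len(nrow(spans))) {
      hi <- min(spans$pos[i] + abs(spans$fragment[i]), len)
      if (hi > spans$pos[i]) {
        for (p in seq.int(spans$pos[i], hi - 1L)) sc[p + 1L] <- sc[p + 1L] + 1L
      }
    }
  }
  if (len <= window) ws <- 0L else ws <- as.integer(seq.int(0L, len - window, by = step))
  we <- pmin(ws + as.integer(window), len)
  mid <- (ws + we) %/% 2L
  wn <- integer(length(ws)); wsum <- numeric(length(ws))
  if (nrow(spans)) {
    for (j in seq_along(ws)) {
      hit <- spans$pos <= mid[j] &
        mid[j] < pmin(spans$pos + abs(spans$fragment), len)
      wn[j] <- sum(hit)
      wsum[j] <- sum(abs(spans$fragment[hit]))
    }
  }
  list(read_cov = rc, proper_cov = pc, span_cov = sc, singleton_cnt = si,
       outie_cnt = ou, spanning_cnt = sp, win_n = wn, win_sum = wsum)
}

# random valid read set on a contig of length len
random_reads <- function(n, len, lib, read_len = 100L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  out <- list()
  while (length(out) < n) {
    kind <- sample(c("proper", "outie", "singleton", "spanning", "unpaired"),
                   1L, prob = c(0.5, 0.2, 0.1, 0.1, 0.1))
    frag <- max(2L * read_len,
                round(stats::rnorm(1, lib$insert_mean, lib$insert_sd)))
    if (frag >= len) frag <- len
    start <- sample.int(len - frag + 1L, 1L) - 1L
    if (kind == "proper") {
      out <- c(out, split(make_pair("c", start, frag, read_len,
                                    lib$orientation),
                          1:2))
    } else if (kind == "outie") {
      p <- make_pair("c", start, frag, read_len,
                     if (lib$orientation == "innie") "outie" else "innie")
      out <- c(out, split(p, 1:2))
    } else if (kind == "singleton") {
      out <- c(out, list(rv("c", start, read_len,
                            sample(c("+", "-"), 1L), mate_mapped = FALSE,
                            mate_contig = NA, mate_strand = NA,
                            fragment = NA, leftmost = FALSE)))
    } else if (kind == "spanning") {
      out <- c(out, list(rv("c", start, read_len, sample(c("+", "-"), 1L),
                            mate_contig = "other", mate_pos = 0L,
                            fragment = NA, leftmost = FALSE)))
    } else {
      out <- c(out, list(rv("c", start, read_len, sample(c("+", "-"), 1L),
                            paired = FALSE, mate_mapped = FALSE,
                            mate_contig = NA, mate_strand = NA,
                            leftmost = FALSE)))
    }
  }
  df <- do.call(rbind, out[seq_len(n)])
  rownames(df) <- NULL
  df
}

# all-prefix enumeration oracle for the FRCurve
oracle_frcurve <- function(summaries, genome_size, taus) {
  o <- order(-summaries$length, summaries$contig)
  len <- summaries$length[o]
  feat <- summaries$features[o]
  vapply(taus, function(tau) {
    best <- 0
    for (k in 0:length(len)) {
      if (k == 0 || sum(feat[seq_len(k)]) <= tau) {
        if (k > 0) best <- sum(len[seq_len(k)])
      } else {
        break
      }
    }
    min(1, best / genome_size)
  }, numeric(1))
}

# per-position confusion-matrix oracle
oracle_sens_spec <- function(features, truth, lens, slack = 0L) {
  tp <- fp <- tn <- fn <- 0L
  for (ctg in names(lens)) {
    len <- lens[[ctg]]
    inf <- intr <- logical(len)
    f <- features[features$contig == ctg, , drop = FALSE]
    t_ <- truth[truth$contig == ctg, , drop = FALSE]
    for (i in seq_len(nrow(f))) {
      for (p in seq.int(f$start[i], f$end[i] - 1L)) inf[p + 1L] <- TRUE
    }
    for (i in seq_len(nrow(t_))) {
      lo <- max(0L, t_$start[i] - slack)
      hi <- min(len, t_$end[i] + slack)
      for (p in seq.int(lo, hi - 1L)) intr[p + 1L] <- TRUE
    }
    tp <- tp + sum(inf & intr); fp <- fp + sum(inf & !intr)
    fn <- fn + sum(!inf & intr); tn <- tn + sum(!inf & !intr)
  }
  list(sens = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
       spec = if (tn + fp > 0) tn / (tn + fp) else NA_real_,
       tp = tp, fp = fp, tn = tn, fn = fn)
}

# quadratic merge-then-filter oracle for interval merging
oracle_merge <- function(starts, ends, gap, min_len) {
  iv <- cbind(starts, ends)[order(starts), , drop = FALSE]
  repeat {
    merged <- FALSE
    i <- 1L
    while (i < nrow(iv)) {
      if (iv[i + 1L, 1L] - iv[i, 2L] < gap) {
        iv[i, 2L] <- max(iv[i, 2L], iv[i + 1L, 2L])
        iv <- iv[-(i + 1L), , drop = FALSE]
        merged <- TRUE
      } else {
        i <- i + 1L
      }
    }
    if (!merged) break
  }
  iv[iv[, 2L] - iv[, 1L] >= min_len, , drop = FALSE]
}

# minimal contig_tracks stub for detector unit tests
fake_tracks <- function(read_cov, proper_cov = read_cov, len = length(read_cov),
                        lib_role = "PE", window = 1000L, step = 200L,
                        win_n = NULL, win_sum = NULL,
                        singleton_cnt = integer(len), outie_cnt = integer(len),
                        spanning_cnt = integer(len), contig_id = "ctg") {
  w <- frcurve:::contig_windows(len, window, step)
  if (is.null(win_n)) win_n <- integer(w$n)
  if (is.null(win_sum)) win_sum <- numeric(w$n)
  structure(list(
    contig_id = contig_id, length = as.integer(len), lib_role = lib_role,
    window = as.integer(window), step = as.integer(step),
    win_start = w$start, win_end = w$end, win_mid = w$mid,
    read_cov = read_cov, proper_cov = proper_cov,
    span_cov = integer(len), singleton_cnt = singleton_cnt,
    outie_cnt = outie_cnt, spanning_cnt = spanning_cnt,
    win_n = win_n, win_sum = win_sum,
    proper_fragments = numeric(0), n_reads = sum(read_cov > 0)
  ), class = "contig_tracks")
}

flagged_bases <- function(regions) sum(regions$end - regions$start)

# single-type region data frame on one contig
feature_df <- function(starts, ends, type = "LOW_COV_PE", contig = "ctg") {
  n <- length(starts)
  data.frame(contig = rep_len(contig, n), start = as.integer(starts),
             end = as.integer(ends), type = rep_len(type, n),
             score = rep(1, n), stringsAsFactors = FALSE)
}
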