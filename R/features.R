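# Feature detection: turn per-contig tracks into the 14 typed suspicious
# regions. PE libraries yield 9 feature types, MP libraries 5.

#' The 14 feature types
#'
#' Coverage features are PE-only; CE and pair-anomaly features exist for both
#' libraries and carry the library role as a suffix.
#' @export
FEATURE_TYPES <- c(
  "LOW_COV_PE", "HIGH_COV_PE", "LOW_NORM_COV_PE", "HIGH_NORM_COV_PE",
  "COMPR_PE", "STRECH_PE", "HIGH_SINGLE_PE", "HIGH_SPAN_PE", "HIGH_OUTIE_PE",
  "COMPR_MP", "STRECH_MP", "HIGH_SINGLE_MP", "HIGH_SPAN_MP", "HIGH_OUTIE_MP"
)

#' Feature-calling thresholds
#'
#' All values are tool parameters, not biological constants; every one can be
#' tuned. Defaults: a position is low-coverage below 1/3 of the library mean
#' and high-coverage above 3 times the mean; CE windows are flagged outside
#' `[-3, 3]`; a window is anomalous when more than 40% of its reads fall in
#' one anomaly class; merged regions closer than `merge_gap` coalesce and
#' regions shorter than `min_region` are dropped.
#'
#' @param cov_low_frac,cov_high_frac Multiplicative coverage thresholds on the
#'   library's own mean coverage (`cov_low_frac < 1 < cov_high_frac`).
#' @param ce_low,ce_high CE-statistic thresholds (`ce_low < 0 < ce_high`).
#' @param anomaly_frac Minimum fraction of window reads in the offending pair
#'   class, in (0, 1].
#' @param min_region Minimum reported region length in bp.
#' @param merge_gap Same-type regions separated by less than this many bp are
#'   merged (default: the window step).
#' @return An object of class `frc_thresholds`.
#' @export
thresholds <- function(cov_low_frac = 1 / 3, cov_high_frac = 3,
                       ce_low = -3, ce_high = 3, anomaly_frac = 0.4,
                       min_region = 200L, merge_gap = 200L) {
  stopifnot(cov_low_frac < 1, cov_high_frac > 1,
            ce_low < 0, ce_high > 0,
            anomaly_frac > 0, anomaly_frac <= 1,
            min_region >= 0, merge_gap >= 0)
  structure(list(cov_low_frac = cov_low_frac, cov_high_frac = cov_high_frac,
                 ce_low = ce_low, ce_high = ce_high,
                 anomaly_frac = anomaly_frac,
                 min_region = as.integer(min_region),
                 merge_gap = as.integer(merge_gap)),
            class = "frc_thresholds")
}

# empty feature-region data frame
empty_regions <- function() {
  data.frame(contig = character(0), start = integer(0), end = integer(0),
             type = character(0), score = numeric(0),
             stringsAsFactors = FALSE)
}

feature_region_df <- function(contig, start, end, type, score) {
  if (length(start) == 0L) return(empty_regions())
  data.frame(contig = contig, start = as.integer(start), end = as.integer(end),
             type = type, score = as.numeric(score), stringsAsFactors = FALSE)
}

#' Compression/expansion (CE) statistic
#'
#' The z-like score comparing the local mean fragment length of pairs spanning
#' a locus to the library's expected insert length:
#' `Z = (m - insert_mean) / (insert_sd / sqrt(n))`,
#' where `m` is the mean of the `n` spanning fragment lengths. Strongly
#' negative Z signals a compression (the assembly is locally shorter than the
#' sequenced genome), strongly positive Z a stretch/expansion.
#'
#' @param fragments Numeric vector of spanning fragment lengths (bp).
#' @param lib A [library_profile()] (supplies `insert_mean` and `insert_sd`).
#' @return The Z score, or `NA_real_` for an empty window ("no data" is never
#'   encoded as 0, which would mean "perfectly calibrated").
#' @examples
#' lib <- library_profile("PE", 300, 30)
#' ce_statistic(rep(330, 9), lib)  # (330-300)/(30/3) = 3
#' @export
ce_statistic <- function(fragments, lib) {
  stopifnot(is_library_profile(lib))
  if (lib$insert_sd <= 0) stop("insert_sd must be > 0", call. = FALSE)
  n <- length(fragments)
  if (n == 0L) return(NA_real_)
  (mean(fragments) - lib$insert_mean) / (lib$insert_sd / sqrt(n))
}

# flagged sliding windows -> step-resolution tiles -> merged regions.
# Each flagged window contributes its central step-wide tile; overlapping
# windows tile the contig at step resolution, so genuine multi-window signals
# stay contiguous while an isolated noise window marks only `step` bp.
windows_to_regions <- function(tracks, flagged, scores, contig, type, th) {
  idx <- which(flagged)
  if (length(idx) == 0L) return(empty_regions())
  halfstep <- tracks$step %/% 2L
  ts <- pmax(0L, tracks$win_mid[idx] - halfstep)
  te <- pmin(tracks$length, tracks$win_mid[idx] + (tracks$step - halfstep))
  regs <- feature_region_df(contig, ts, te, type, scores[idx])
  merge_regions(regs, merge_gap = th$merge_gap, min_region = th$min_region)
}

#' Merge and filter same-type feature regions
#'
#' Regions of one type on one contig separated by fewer than `merge_gap` bp
#' are merged (scores combine as a length-weighted mean); merged regions
#' shorter than `min_region` bp are dropped. Output is sorted and
#' non-overlapping.
#'
#' @param regions Feature-region data frame (columns `contig`, `start`, `end`,
#'   `type`, `score`) containing a single type on a single contig.
#' @param merge_gap,min_region See [thresholds()].
#' @return The merged, filtered region data frame.
#' @export
merge_regions <- function(regions, merge_gap = 200L, min_region = 200L) {
  if (nrow(regions) == 0L) return(empty_regions())
  if (length(unique(regions$type)) > 1L) {
    stop("merge_regions expects regions of a single type", call. = FALSE)
  }
  if (length(unique(regions$contig)) > 1L) {
    stop("merge_regions expects regions on a single contig", call. = FALSE)
  }
  o <- order(regions$start, regions$end)
  s <- regions$start[o]; e <- regions$end[o]; sc <- regions$score[o]
  ne <- length(s)
  prev_max_end <- c(-Inf, cummax(as.numeric(e))[-ne])
  grp <- cumsum(s - prev_max_end >= merge_gap)
  w <- as.numeric(e - s)
  ms <- tapply(s, grp, min)
  me <- tapply(pmax(e, 0L), grp, max)
  msc <- tapply(sc * w, grp, sum) / tapply(w, grp, sum)
  out <- feature_region_df(regions$contig[1L], as.integer(ms), as.integer(me),
                           regions$type[1L], as.numeric(msc))
  out <- out[out$end - out$start >= min_region, , drop = FALSE]
  out <- out[order(out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Coverage features (PE library only)
#'
#' Per-position thresholding of vertical coverage against the library-wide
#' mean: `LOW_COV_PE`/`HIGH_COV_PE` on all aligned reads, `LOW_NORM_COV_PE`/
#' `HIGH_NORM_COV_PE` on properly paired reads only. Maximal runs of
#' offending positions are merged and length-filtered per [thresholds()].
#'
#' @param tracks PE [build_tracks()] result.
#' @param stats PE [estimate_global_stats()] result (supplies the means).
#' @param th [thresholds()].
#' @return Feature-region data frame.
#' @export
detect_coverage_features <- function(tracks, stats, th = thresholds()) {
  if (tracks$lib_role != "PE") {
    stop("coverage features are defined on the PE library only", call. = FALSE)
  }
  if (stats$mean_read_cov <= 0) stop("empty alignment", call. = FALSE)

  runs_of <- function(track, flag, type) {
    r <- rle(flag)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths
    ki <- which(r$values)
    if (length(ki) == 0L) return(empty_regions())
    sc <- vapply(ki, function(i) mean(track[(starts[i] + 1L):ends[i]]), numeric(1))
    regs <- feature_region_df(tracks$contig_id, starts[ki], ends[ki], type, sc)
    merge_regions(regs, th$merge_gap, th$min_region)
  }

  rc <- tracks$read_cov
  pc <- tracks$proper_cov
  rbind(
    runs_of(rc, rc < th$cov_low_frac * stats$mean_read_cov, "LOW_COV_PE"),
    runs_of(rc, rc > th$cov_high_frac * stats$mean_read_cov, "HIGH_COV_PE"),
    runs_of(pc, pc < th$cov_low_frac * stats$mean_proper_cov, "LOW_NORM_COV_PE"),
    runs_of(pc, pc > th$cov_high_frac * stats$mean_proper_cov, "HIGH_NORM_COV_PE")
  )
}

#' CE (compression/expansion) features
#'
#' Computes the CE statistic per sliding window from the spanning-fragment
#' accumulators in `tracks` and flags windows below `ce_low` (`COMPR_*`) or
#' above `ce_high` (`STRECH_*`); the suffix follows the library role. Windows
#' with no spanning fragments carry no evidence and are skipped.
#'
#' Because fragments are sampled by the condition "span the window midpoint",
#' the sample is length-biased: its null mean is the size-biased mean
#' `insert_mean + insert_sd^2 / insert_mean`, not `insert_mean`. With
#' `size_bias_correction = TRUE` (default) windows are centred at the
#' size-biased mean, which keeps the null calibration of the detector at
#' `2 * pnorm(ce_low)` regardless of the spanning sample size.
#'
#' @param tracks [build_tracks()] result for one library.
#' @param lib [library_profile()] with (possibly refined) insert mean/sd.
#' @param th [thresholds()].
#' @param size_bias_correction Centre windows at the size-biased null mean.
#' @return Feature-region data frame; scores are mean window Z.
#' @export
detect_ce_features <- function(tracks, lib, th = thresholds(),
                               size_bias_correction = TRUE) {
  stopifnot(is_library_profile(lib))
  if (lib$insert_sd <= 0) stop("insert_sd must be > 0", call. = FALSE)
  mu <- lib$insert_mean
  if (size_bias_correction) mu <- mu + lib$insert_sd^2 / lib$insert_mean
  n <- tracks$win_n
  z <- rep(NA_real_, length(n))
  has <- n > 0L
  z[has] <- (tracks$win_sum[has] / n[has] - mu) / (lib$insert_sd / sqrt(n[has]))

  suffix <- tracks$lib_role
  rbind(
    windows_to_regions(tracks, has & z < th$ce_low, z, tracks$contig_id,
                       paste0("COMPR_", suffix), th),
    windows_to_regions(tracks, has & z > th$ce_high, z, tracks$contig_id,
                       paste0("STRECH_", suffix), th)
  )
}

#' Pair-anomaly features (mate-pair happiness)
#'
#' For each sliding window, the per-position ratio of anomalous reads to all
#' reads (positions with zero read coverage are skipped) is averaged; windows
#' whose mean ratio exceeds `anomaly_frac` are flagged as `HIGH_SINGLE_*`
#' (mate unmapped), `HIGH_SPAN_*` (mate on another contig) or `HIGH_OUTIE_*`
#' (mis-oriented or too-distant mate). The suffix follows the library role.
#'
#' @inheritParams detect_ce_features
#' @return Feature-region data frame; scores are mean window anomaly ratio.
#' @export
detect_pair_anomaly_features <- function(tracks, lib, th = thresholds()) {
  stopifnot(is_library_profile(lib))
  cov <- tracks$read_cov
  covered <- cov > 0L
  ci <- c(0, cumsum(as.numeric(covered)))
  ws <- tracks$win_start
  we <- tracks$win_end
  n_covered <- ci[we + 1L] - ci[ws + 1L]

  window_ratio <- function(cnt) {
    r <- numeric(length(cov))
    r[covered] <- cnt[covered] / cov[covered]
    cr <- c(0, cumsum(r))
    val <- rep(NA_real_, length(ws))
    ok <- n_covered > 0
    val[ok] <- (cr[we + 1L] - cr[ws + 1L])[ok] / n_covered[ok]
    val
  }

  suffix <- tracks$lib_role
  one <- function(cnt, type) {
    val <- window_ratio(cnt)
    windows_to_regions(tracks, !is.na(val) & val > th$anomaly_frac, val,
                       tracks$contig_id, paste0(type, suffix), th)
  }
  rbind(one(tracks$singleton_cnt, "HIGH_SINGLE_"),
        one(tracks$spanning_cnt, "HIGH_SPAN_"),
        one(tracks$outie_cnt, "HIGH_OUTIE_"))
}

#' Call all features on one contig
#'
#' Applies the three detectors according to the PE/MP split: coverage features
#' on the PE library only; CE and pair-anomaly features on each available
#' library. With no MP tracks, only the 9 PE-suffixed types can occur.
#'
#' @param tracks_pe PE [build_tracks()] for the contig (required).
#' @param stats_pe PE [estimate_global_stats()] (required).
#' @param tracks_mp,stats_mp MP tracks/stats, or `NULL` when no MP library.
#' @param th [thresholds()].
#' @return Feature-region data frame sorted by start, covering up to 14 types.
#' @export
annotate_contig <- function(tracks_pe, stats_pe, tracks_mp = NULL,
                            stats_mp = NULL, th = thresholds()) {
  refined <- function(stats, orientation) {
    library_profile(stats$lib_role, stats$insert_mean, stats$insert_sd,
                    orientation = orientation)
  }
  pe_lib <- refined(stats_pe, "innie")
  out <- rbind(
    detect_coverage_features(tracks_pe, stats_pe, th),
    detect_ce_features(tracks_pe, pe_lib, th),
    detect_pair_anomaly_features(tracks_pe, pe_lib, th)
  )
  if (!is.null(tracks_mp)) {
    stopifnot(!is.null(stats_mp))
    mp_lib <- refined(stats_mp, "outie")
    out <- rbind(
      out,
      detect_ce_features(tracks_mp, mp_lib, th),
      detect_pair_anomaly_features(tracks_mp, mp_lib, th)
    )
  }
  out[order(out$start, out$end, out$type), , drop = FALSE]
}
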