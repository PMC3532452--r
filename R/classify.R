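#' Classify aligned read pairs
#'
#' Assigns every mapped read that expects a mate to exactly one of four
#' classes, the alphabet on which the pair-anomaly features are built:
#'
#' * `PROPER` -- mate on the same contig, pair in the library's orientation,
#'   and observed fragment length within `tolerance_k` standard deviations of
#'   the library insert mean;
#' * `OUTIE` -- mate on the same contig but mis-oriented, or at an aberrant
#'   distance (`|fragment - insert_mean| > tolerance_k * insert_sd`);
#' * `SINGLETON` -- mate unmapped;
#' * `SPANNING` -- mate mapped to a different contig/scaffold.
#'
#' Orientation is judged from strand and position: an "innie" pair has the
#' leftmost mate on the forward strand and the rightmost on the reverse
#' strand; an "outie" pair is the opposite. Mates starting at the same
#' coordinate are accepted as correctly facing whenever strands are opposite.
#' Negative fragment lengths are normalised to their absolute value.
#'
#' @param reads A data frame of read views, one row per mapped read, with
#'   columns `contig`, `pos` (0-based leftmost position), `strand` (`"+"` or
#'   `"-"`), `mate_mapped` (logical), `mate_contig`, `mate_pos`, `mate_strand`,
#'   and `fragment` (outermost-coordinate span of the pair in bp; may be `NA`
#'   when the mate is unmapped or on another contig).
#' @param lib A [library_profile()].
#' @param tolerance_k Width of the proper-distance window in standard
#'   deviations (default 3, i.e. proper means `insert_mean +/- 3 * insert_sd`).
#' @return A character vector, one class per row of `reads`.
#' @examples
#' pe <- library_profile("PE", 300, 30)
#' r <- data.frame(contig = "c", pos = 0L, strand = "+", mate_mapped = TRUE,
#'                 mate_contig = "c", mate_pos = 200L, mate_strand = "-",
#'                 fragment = 300)
#' classify_pairs(r, pe)  # "PROPER"
#' @export
classify_pairs <- function(reads, lib, tolerance_k = 3) {
  stopifnot(is_library_profile(lib))
  if (!is.numeric(tolerance_k) || tolerance_k <= 0) {
    stop("tolerance_k must be > 0", call. = FALSE)
  }
  n <- nrow(reads)
  if (n == 0L) return(character(0))

  cls <- rep(NA_character_, n)
  mate_mapped <- reads$mate_mapped
  cls[!mate_mapped] <- "SINGLETON"

  same <- mate_mapped & !is.na(reads$mate_contig) &
    reads$mate_contig == reads$contig
  cls[mate_mapped & !same] <- "SPANNING"

  if (any(same)) {
    frag <- abs(reads$fragment[same])
    dist_ok <- !is.na(frag) &
      abs(frag - lib$insert_mean) <= tolerance_k * lib$insert_sd

    strand <- reads$strand[same]
    mstrand <- reads$mate_strand[same]
    pos <- reads$pos[same]
    mpos <- reads$mate_pos[same]
    opposite <- strand != mstrand
    # facing: which mate carries the forward strand
    fwd_is_left <- (pos < mpos & strand == "+") | (pos > mpos & strand == "-")
    fwd_is_right <- (pos < mpos & strand == "-") | (pos > mpos & strand == "+")
    tie <- pos == mpos
    orient_ok <- if (lib$orientation == "innie") {
      opposite & (fwd_is_left | tie)
    } else {
      opposite & (fwd_is_right | tie)
    }
    cls[same] <- ifelse(orient_ok & dist_ok, "PROPER", "OUTIE")
  }
  cls
}
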