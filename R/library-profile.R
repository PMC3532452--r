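#' Sequencing library profile
#'
#' Describes one read-pair library: its role (short-insert paired-end or
#' long-insert mate-pair), the expected fragment (insert) length distribution,
#' and the orientation convention of a correctly assembled pair.
#'
#' Paired-end (PE) libraries face inward ("innie": forward/reverse, leftmost
#' mate on the forward strand) with inserts typically 150-1000 bp. Mate-pair
#' (MP) libraries face outward ("outie": reverse/forward) with inserts
#' typically 3-10 kbp. The insert mean and standard deviation are rough
#' user-supplied estimates; they can be refined from properly aligned pairs
#' with [estimate_global_stats()].
#'
#' @param role `"PE"` or `"MP"`.
#' @param insert_mean Expected fragment length in bp (> 0).
#' @param insert_sd Fragment length standard deviation in bp (> 0).
#' @param orientation `"innie"` or `"outie"`. Defaults to `"innie"` for PE and
#'   `"outie"` for MP.
#' @return An object of class `library_profile`.
#' @examples
#' pe <- library_profile("PE", insert_mean = 300, insert_sd = 30)
#' mp <- library_profile("MP", insert_mean = 3000, insert_sd = 300)
#' @export
library_profile <- function(role = c("PE", "MP"), insert_mean, insert_sd,
                            orientation = NULL) {
  role <- match.arg(role)
  if (is.null(orientation)) {
    orientation <- if (role == "PE") "innie" else "outie"
  }
  orientation <- match.arg(orientation, c("innie", "outie"))
  if (!is.numeric(insert_mean) || length(insert_mean) != 1L || insert_mean <= 0) {
    stop("insert_mean must be a single positive number", call. = FALSE)
  }
  if (!is.numeric(insert_sd) || length(insert_sd) != 1L || insert_sd <= 0) {
    stop("insert_sd must be a single positive number", call. = FALSE)
  }
  structure(
    list(role = role,
         insert_mean = as.numeric(insert_mean),
         insert_sd = as.numeric(insert_sd),
         orientation = orientation),
    class = "library_profile"
  )
}

#' @export
print.library_profile <- function(x, ...) {
  cat(sprintf("<library_profile> %s library, %s orientation, insert %.1f +/- %.1f bp\n",
              x$role, x$orientation, x$insert_mean, x$insert_sd))
  invisible(x)
}

is_library_profile <- function(x) inherits(x, "library_profile")
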