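#' @keywords internal
"_PACKAGE"

## Canonical stage vocabulary, ordered light -> deep; REM sorts last so that
## ties in majority votes resolve toward the lighter stage.
STAGE_LEVELS <- c("W", "N1", "N2", "N3", "R")

#' Stage ordering used for tie-breaks
#'
#' Returns the canonical stage labels ordered from lightest (wake) to REM.
#' @return Character vector of stage codes.
#' @export
stage_levels <- function() STAGE_LEVELS

assert_stages <- function(stages) {
  bad <- setdiff(stages, STAGE_LEVELS)
  if (length(bad) > 0) {
    stop("unknown stage label(s): ", paste(bad, collapse = ", "),
         "; allowed: ", paste(STAGE_LEVELS, collapse = ", "), call. = FALSE)
  }
  invisible(stages)
}

#' Number of fMRI volumes acquired in a session
#'
#' @param duration Session duration in seconds.
#' @param tr Repetition time in seconds (default 2.08).
#' @return Integer volume count, \code{floor(duration / tr)}.
#' @examples
#' volumes_for_duration(52 * 60)  # 1500
#' @export
volumes_for_duration <- function(duration, tr = 2.08) {
  stopifnot(duration > 0, tr > 0)
  ## guard against floating-point shortfall (3120 / 2.08 must be exactly 1500)
  as.integer(floor(duration / tr + 1e-9))
}

#' Session length in minutes implied by a volume count
#'
#' @param n_volumes Number of volumes.
#' @param tr Repetition time in seconds.
#' @return Minutes of scanning.
#' @export
session_minutes <- function(n_volumes, tr = 2.08) {
  n_volumes * tr / 60
}

## Derive a per-subject seed from a master seed, kept inside 32-bit range.
subject_seed <- function(master_seed, index) {
  as.integer((as.numeric(master_seed) + index) %% .Machine$integer.max)
}

## Mode of a histogram with fixed bins on [0, 1]: midpoint of the fullest bin
## (lowest bin wins ties).
#' Peak of an accuracy distribution
#'
#' Summarizes where a distribution of accuracies "peaks": the midpoint of the
#' fullest bin of a fixed-width histogram on \[0, 1\].
#'
#' @param x Numeric vector of values in \[0, 1\].
#' @param bins Number of histogram bins (default 20).
#' @return Midpoint of the modal bin.
#' @export
histogram_mode <- function(x, bins = 20) {
  stopifnot(all(x >= 0 & x <= 1))
  breaks <- seq(0, 1, length.out = bins + 1)
  counts <- tabulate(pmin(pmax(findInterval(x, breaks, rightmost.closed = TRUE), 1L), bins),
                     nbins = bins)
  mid <- (breaks[-1] + breaks[-(bins + 1)]) / 2
  mid[which.max(counts)]
}
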