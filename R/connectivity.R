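## Windowed correlation matrices: the front end of the dynamic connectivity
## pipeline. Volumes are 0-based and windows half-open [start, end).

#' Windowing scheme
#'
#' @param length Window length in volumes (>= 2; default 50).
#' @param step Start-to-start increment in volumes; \code{step = length} gives
#'   non-overlapping windows, \code{step = 1} sliding windows.
#' @return A \code{window_spec}.
#' @export
window_spec <- function(length = 50L, step = length) {
  length <- as.integer(length); step <- as.integer(step)
  if (length < 2) stop("window length must be >= 2", call. = FALSE)
  if (step < 1 || step > length) {
    stop("step must satisfy 1 <= step <= length", call. = FALSE)
  }
  structure(list(length = length, step = step,
                 mode = if (step == length) "non-overlapping" else "sliding"),
            class = "window_spec")
}

#' Window start/end indices for a series of T volumes
#'
#' Windows start at volumes 0, step, 2 step, ...; a trailing partial window is
#' discarded.
#'
#' @param n_volumes Total volume count T.
#' @param spec A \code{window_spec}.
#' @return Data frame with 0-based half-open \code{start}, \code{end}.
#' @export
window_starts <- function(n_volumes, spec) {
  stopifnot(inherits(spec, "window_spec"))
  if (n_volumes < spec$length) {
    stop("series too short: ", n_volumes, " volumes < window length ",
         spec$length, call. = FALSE)
  }
  starts <- seq(0L, n_volumes - spec$length, by = spec$step)
  data.frame(window = seq_along(starts), start = starts,
             end = starts + spec$length)
}

#' Slice a time series into windows
#'
#' @param ts A \code{roi_ts} (or plain T x R matrix).
#' @param spec A \code{window_spec}.
#' @return List of T_w x R matrices, one per window, with the window table as
#'   attribute \code{"windows"}.
#' @export
window_series <- function(ts, spec) {
  X <- if (inherits(ts, "roi_ts")) ts$data else as.matrix(ts)
  w <- window_starts(nrow(X), spec)
  out <- lapply(seq_len(nrow(w)), function(i) {
    X[(w$start[i] + 1L):w$end[i], , drop = FALSE]
  })
  attr(out, "windows") <- w
  out
}

#' Pairwise Pearson correlation matrix of one window
#'
#' Regions with zero variance within the window get correlation 0 with every
#' other region (with a warning) rather than NA, so a single flat region does
#' not invalidate a whole cohort.
#'
#' @param x T_w x R matrix (window slice).
#' @return R x R symmetric correlation matrix with unit diagonal.
#' @export
correlation_matrix <- function(x) {
  x <- as.matrix(x)
  if (nrow(x) < 2) stop("window must contain >= 2 volumes", call. = FALSE)
  sds <- apply(x, 2, stats::sd)
  flat <- sds == 0 | !is.finite(sds)
  C <- suppressWarnings(stats::cor(x))
  if (any(flat)) {
    warning("zero-variance region(s) in window; correlations set to 0")
    C[flat, ] <- 0
    C[, flat] <- 0
  }
  diag(C) <- 1
  C[C > 1] <- 1
  C[C < -1] <- -1
  (C + t(C)) / 2
}

#' Upper-triangle vectorization (row-major above the diagonal)
#'
#' For an R x R matrix the order is (1,2), (1,3), ..., (1,R), (2,3), ...
#'
#' @param m Square matrix.
#' @return Numeric vector of length R(R-1)/2.
#' @export
vectorize_upper <- function(m) {
  m <- as.matrix(m)
  stopifnot(nrow(m) == ncol(m))
  t(m)[lower.tri(m)]
}

#' Inverse of \code{vectorize_upper}
#'
#' @param v Vector of length R(R-1)/2 for some integer R.
#' @param diag_value Diagonal fill (default 1).
#' @return Symmetric R x R matrix.
#' @export
devectorize <- function(v, diag_value = 1) {
  n <- length(v)
  R <- (1 + sqrt(1 + 8 * n)) / 2
  if (abs(R - round(R)) > 1e-9) {
    stop("vector length ", n, " is not a triangular number", call. = FALSE)
  }
  R <- as.integer(round(R))
  m <- matrix(0, R, R)
  m[lower.tri(m)] <- v
  m <- t(m)
  m <- m + t(m)
  diag(m) <- diag_value
  m
}

#' Majority sleep stage of a window
#'
#' Each volume takes the stage of its containing 30-s epoch; the window is
#' labeled with the majority stage, ties resolving to the lighter stage
#' (W < N1 < N2 < N3 < REM).
#'
#' @param hyp A \code{hypnogram}.
#' @param start,end 0-based half-open volume range.
#' @param tr Repetition time in seconds.
#' @return Stage label.
#' @export
stage_label_for_window <- function(hyp, start, end, tr = 2.08) {
  n <- end - start
  vols <- volume_stages(hyp, end, tr)[(start + 1L):end]
  counts <- table(factor(vols, levels = STAGE_LEVELS))
  names(counts)[which.max(counts)]  # which.max takes the first (lightest) tie
}

#' Window-level connectivity and stage labels for one subject
#'
#' @param ts A \code{roi_ts}.
#' @param hyp A \code{hypnogram} or NULL (no ground truth).
#' @param spec A \code{window_spec}.
#' @return List: \code{vectors} (windows x R(R-1)/2 matrix of upper-triangle
#'   correlations), \code{windows} (window table), \code{stage} (per-window
#'   label or NULL), \code{subject}, \code{n_volumes}, \code{tr}.
#' @export
subject_windows <- function(ts, hyp = NULL, spec = window_spec()) {
  slices <- window_series(ts, spec)
  w <- attr(slices, "windows")
  vecs <- t(vapply(slices, function(x) vectorize_upper(correlation_matrix(x)),
                   numeric(ncol(ts$data) * (ncol(ts$data) - 1) / 2)))
  stage <- NULL
  if (!is.null(hyp)) {
    stage <- vapply(seq_len(nrow(w)), function(i) {
      stage_label_for_window(hyp, w$start[i], w$end[i], ts$tr)
    }, character(1))
  }
  list(vectors = vecs, windows = w, stage = stage, subject = ts$subject,
       n_volumes = nrow(ts$data), tr = ts$tr)
}

#' Windowed connectivity for a whole cohort
#'
#' @param cohort List of \code{list(ts, hypnogram)} pairs (as returned by
#'   \code{\link{generate_cohort}}); hypnograms may be NULL.
#' @param spec A \code{window_spec}.
#' @param max_volumes Optional truncation: use only the first
#'   \code{max_volumes} volumes of every subject (short-scan mode).
#' @return List of per-subject window sets (see \code{\link{subject_windows}}).
#' @export
cohort_windows <- function(cohort, spec = window_spec(), max_volumes = NULL) {
  lapply(cohort, function(su) {
    ts <- su$ts
    if (!is.null(max_volumes)) {
      ts$data <- ts$data[seq_len(min(nrow(ts$data), max_volumes)), ,
                         drop = FALSE]
    }
    subject_windows(ts, su$hypnogram, spec)
  })
}
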