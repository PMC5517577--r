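## Accuracy of fMRI-based sleep staging against hypnogram ground truth, the
## chance level, bootstrap accuracy distributions (including the
## label-permutation null), and the window-length / sample-size sweeps.

#' Chance staging accuracy
#'
#' k-means divides the data space into approximately even regions, so the
#' accuracy expected by chance is 1/k regardless of class balance.
#'
#' @param k Number of clusters (>= 1).
#' @return Fraction 1/k.
#' @export
chance_accuracy <- function(k) {
  if (k < 1) stop("k must be >= 1", call. = FALSE)
  1 / k
}

#' Collapse stage labels for a k = 2 analysis
#'
#' Two-cluster staging distinguishes wakefulness from sleep of any depth; all
#' non-W stages collapse to "S".
#'
#' @param labels Character vector of stage labels.
#' @param k Number of clusters in the analysis.
#' @return Possibly collapsed labels.
#' @export
collapse_stages <- function(labels, k) {
  if (k == 2) ifelse(labels == "W", "W", "S") else labels
}

#' Volume-level staging accuracy
#'
#' @param predicted Character vector of predicted per-volume stage labels.
#' @param truth Character vector of reference labels, same length.
#' @return An \code{evaluation_report}: list with \code{accuracy},
#'   \code{n_volumes}, \code{confusion} (truth x predicted counts).
#' @export
staging_accuracy <- function(predicted, truth) {
  if (length(predicted) != length(truth)) {
    stop("predicted and truth labels differ in length", call. = FALSE)
  }
  levels <- union(unique(truth), unique(predicted))
  levels <- c(intersect(STAGE_LEVELS, levels), setdiff(levels, STAGE_LEVELS))
  confusion <- table(truth = factor(truth, levels),
                     predicted = factor(predicted, levels))
  structure(
    list(accuracy = mean(predicted == truth), n_volumes = length(truth),
         confusion = confusion),
    class = "evaluation_report"
  )
}

## Expand per-window labels to per-volume labels by majority vote over the
## windows covering each volume (for non-overlapping windows this is plain
## inheritance); volumes covered by no full window are dropped (index vector
## of retained volumes returned alongside).
expand_window_labels <- function(labels, windows, n_volumes,
                                 levels = STAGE_LEVELS) {
  levels <- union(levels, unique(labels))
  votes <- matrix(0L, n_volumes, length(levels))
  colnames(votes) <- levels
  for (i in seq_along(labels)) {
    rng <- (windows$start[i] + 1L):windows$end[i]
    j <- match(labels[i], levels)
    votes[rng, j] <- votes[rng, j] + 1L
  }
  covered <- rowSums(votes) > 0
  lab <- levels[max.col(votes[covered, , drop = FALSE], ties.method = "first")]
  list(labels = lab, covered = which(covered))
}

## Core staging run on a set of per-subject window objects: pool vectors,
## cluster into k states, match clusters to stages by occurrence profile, and
## score volume-level accuracy. Optionally permutes each subject's
## window-stage labels first (the randomized null).
stage_and_score <- function(wins, k, replicates = 100, seed = 1L,
                            randomize_labels = FALSE,
                            return_model = FALSE) {
  truth_windows <- lapply(wins, function(w) collapse_stages(w$stage, k))
  if (randomize_labels) {
    truth_windows <- lapply(truth_windows, function(lab) {
      lab[sample.int(length(lab))]
    })
  }
  stage_set <- intersect(c("W", "S", STAGE_LEVELS),
                         unique(unlist(truth_windows)))
  if (!randomize_labels &&
      any(vapply(wins, function(w) is.null(w$hypnogram), logical(1)))) {
    stop("volume-level scoring needs hypnograms on the window objects",
         call. = FALSE)
  }
  vectors <- do.call(rbind, lapply(wins, function(w) w$vectors))
  model <- cluster_states(vectors, k, replicates = replicates, seed = seed)
  n_per <- vapply(wins, function(w) nrow(w$vectors), integer(1))
  split_idx <- split(seq_len(sum(n_per)), rep(seq_along(wins), n_per))
  cluster_by_subject <- lapply(split_idx, function(ix) {
    as.character(model$assignments[ix])
  })
  cluster_profiles <- occurrence_profile(cluster_by_subject,
                                         levels = as.character(seq_len(k)))
  ## stage profiles over the same bin grid; absent stages give zero rows so
  ## the similarity matrix stays k x k
  stage_levels_k <- stage_set
  if (length(stage_levels_k) < k) {
    stage_levels_k <- c(stage_levels_k,
                        paste0("unused", seq_len(k - length(stage_levels_k))))
  }
  stage_profiles <- occurrence_profile(truth_windows, levels = stage_levels_k)
  matching <- match_by_profile(cluster_profiles, stage_profiles)

  correct <- 0L; total <- 0L
  for (i in seq_along(wins)) {
    w <- wins[[i]]
    pred_w <- unname(matching$map[paste0("C", cluster_by_subject[[i]])])
    pred <- expand_window_labels(pred_w, w$windows, w$n_volumes,
                                 levels = stage_levels_k)
    if (randomize_labels) {
      tr <- expand_window_labels(truth_windows[[i]], w$windows, w$n_volumes,
                                 levels = stage_levels_k)
      truth_v <- tr$labels
    } else {
      truth_v <- collapse_stages(
        volume_stages(w$hypnogram, w$n_volumes, w$tr), k
      )[pred$covered]
    }
    correct <- correct + sum(pred$labels == truth_v)
    total <- total + length(truth_v)
  }
  out <- list(accuracy = correct / total, n_volumes = total,
              matching = matching)
  if (return_model) out$model <- model
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## stage_and_score needs per-volume truth; carry the hypnogram on the window
## object when preparing a cohort for evaluation.
#' Attach hypnograms to window objects for volume-level scoring
#'
#' @param wins Output of \code{\link{cohort_windows}}.
#' @param cohort The cohort the windows came from.
#' @return \code{wins} with each element carrying its hypnogram.
#' @export
attach_hypnograms <- function(wins, cohort) {
  for (i in seq_along(wins)) wins[[i]]$hypnogram <- cohort[[i]]$hypnogram
  wins
}

#' Bootstrap distribution of staging accuracy
#'
#' Repeatedly samples a subset of subjects without replacement, reclusters
#' their pooled connectivity vectors into k states, matches states to stages
#' by occurrence profile, and scores volume-level accuracy. With
#' \code{randomize_labels = TRUE} each subject's window-stage labels are
#' permuted before matching and scoring, yielding the chance-level null.
#'
#' @param wins Per-subject window objects carrying hypnograms (see
#'   \code{\link{attach_hypnograms}}).
#' @param subset_size Subjects per iteration (default 10).
#' @param iterations Bootstrap iterations (default 100).
#' @param k Number of states.
#' @param randomize_labels Permute window-stage labels (null construction).
#' @param replicates k-means replicates per clustering.
#' @param seed Integer seed.
#' @return A \code{bootstrap_result}: list with \code{accuracies},
#'   \code{mode} (histogram peak), \code{mean}, \code{sd}, \code{subset_size},
#'   \code{iterations}, \code{randomized}, \code{k}.
#' @export
bootstrap_accuracy <- function(wins, subset_size = 10, iterations = 100, k = 2,
                               randomize_labels = FALSE, replicates = 100,
                               seed = 1L) {
  n <- length(wins)
  if (subset_size > n) {
    stop("subset_size exceeds the number of subjects", call. = FALSE)
  }
  acc <- numeric(iterations)
  for (it in seq_len(iterations)) {
    it_seed <- subject_seed(seed, 1000L * it)
    set.seed(it_seed)
    subset <- sample.int(n, subset_size)
    res <- stage_and_score(wins[subset], k, replicates = replicates,
                           seed = subject_seed(it_seed, 1L),
                           randomize_labels = randomize_labels)
    acc[it] <- res$accuracy
  }
  structure(
    list(accuracies = acc, mode = histogram_mode(acc), mean = mean(acc),
         sd = stats::sd(acc), subset_size = subset_size,
         iterations = iterations, randomized = randomize_labels, k = k),
    class = "bootstrap_result"
  )
}

#' Staging accuracy as a function of window length
#'
#' Runs the full pipeline (windowing, clustering, profile matching, scoring)
#' once per window length on the whole cohort.
#'
#' @param cohort List of \code{list(ts, hypnogram)}.
#' @param lengths Integer vector of window lengths (volumes).
#' @param k Number of states.
#' @param step Window step; defaults to the length (non-overlapping).
#' @param replicates k-means replicates.
#' @param seed Integer seed.
#' @return Data frame with \code{length}, \code{accuracy}, \code{n_windows},
#'   \code{sufficient} (FALSE when fewer windows than clusters).
#' @export
window_length_sweep <- function(cohort, lengths, k = 2, step = NULL,
                                replicates = 100, seed = 1L) {
  res <- lapply(lengths, function(L) {
    spec <- window_spec(L, step = if (is.null(step)) L else min(step, L))
    wins <- attach_hypnograms(cohort_windows(cohort, spec), cohort)
    n_windows <- sum(vapply(wins, function(w) nrow(w$vectors), integer(1)))
    if (n_windows < k) {
      return(data.frame(length = L, accuracy = NA_real_,
                        n_windows = n_windows, sufficient = FALSE))
    }
    out <- stage_and_score(wins, k, replicates = replicates,
                           seed = subject_seed(seed, L))
    data.frame(length = L, accuracy = out$accuracy, n_windows = n_windows,
               sufficient = TRUE)
  })
  do.call(rbind, res)
}

#' Staging accuracy as a function of sample size
#'
#' Wraps \code{\link{bootstrap_accuracy}} for each subset size and reports
#' mean and standard deviation over iterations.
#'
#' @param wins Per-subject window objects carrying hypnograms.
#' @param sizes Integer vector of subset sizes.
#' @param iterations Bootstrap iterations per size.
#' @param k Number of states.
#' @param randomize_labels Permute labels (null curve).
#' @param replicates k-means replicates.
#' @param seed Integer seed.
#' @return Data frame with \code{size}, \code{mean_accuracy}, \code{sd},
#'   \code{mode}.
#' @export
sample_size_curve <- function(wins, sizes, iterations = 100, k = 2,
                              randomize_labels = FALSE, replicates = 100,
                              seed = 1L) {
  res <- lapply(sizes, function(sz) {
    b <- bootstrap_accuracy(wins, subset_size = sz, iterations = iterations,
                            k = k, randomize_labels = randomize_labels,
                            replicates = replicates,
                            seed = subject_seed(seed, sz))
    data.frame(size = sz, mean_accuracy = b$mean, sd = b$sd, mode = b$mode)
  })
  do.call(rbind, res)
}
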