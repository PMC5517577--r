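## Mapping dynamic connectivity states to sleep stages. Two fMRI-only
## criteria: similarity of occurrence profiles over the session, and
## similarity of mean correlation matrices. Both solve the assignment exactly
## by enumerating all k! bijections (k <= 5 in practice), maximizing total
## Pearson similarity.

## All permutations of 1..n (n small).
all_permutations <- function(n) {
  if (n == 1) return(list(1L))
  sub <- all_permutations(n - 1L)
  out <- vector("list", n * length(sub))
  i <- 0L
  for (p in sub) {
    for (pos in 0:(n - 1L)) {
      i <- i + 1L
      out[[i]] <- append(p, n, after = pos)
    }
  }
  out
}

## Pearson r with constant-vector correlations defined as 0.
safe_cor <- function(u, v) {
  if (stats::sd(u) == 0 || stats::sd(v) == 0) return(0)
  stats::cor(u, v)
}

#' Occurrence probability of each label over session time
#'
#' For every time bin (window index on the common session clock),
#' \code{P(label, bin)} is the fraction of subjects whose window at that bin
#' carries the label, among subjects contributing a window there.
#'
#' @param labels_by_subject List of per-subject label vectors (one label per
#'   window, windows aligned across subjects).
#' @param levels Label set defining the profile rows; defaults to all labels
#'   observed.
#' @return Matrix (length(levels) x max windows) of probabilities, rownames =
#'   levels; columns where no subject contributes are dropped with a warning.
#' @export
occurrence_profile <- function(labels_by_subject, levels = NULL) {
  if (is.null(levels)) {
    levels <- sort(unique(unlist(labels_by_subject)))
  }
  nb <- max(vapply(labels_by_subject, length, integer(1)))
  counts <- matrix(0, length(levels), nb, dimnames = list(levels, NULL))
  denom <- numeric(nb)
  for (lab in labels_by_subject) {
    nw <- length(lab)
    denom[seq_len(nw)] <- denom[seq_len(nw)] + 1
    for (b in seq_len(nw)) {
      counts[lab[b], b] <- counts[lab[b], b] + 1
    }
  }
  if (any(denom == 0)) {
    warning("bins with no contributing subjects were dropped")
    keep <- denom > 0
    counts <- counts[, keep, drop = FALSE]
    denom <- denom[keep]
  }
  sweep(counts, 2, denom, "/")
}

exact_assignment <- function(sim) {
  k <- nrow(sim)
  perms <- all_permutations(k)
  best <- NULL; best_total <- -Inf
  for (p in perms) {
    total <- sum(sim[cbind(seq_len(k), unlist(p))])
    if (total > best_total + 1e-15) {
      best_total <- total
      best <- unlist(p)
    }
  }
  list(perm = best, total = best_total)
}

#' Match clusters to stages by occurrence-profile correlation
#'
#' Computes the Pearson correlation between every cluster occurrence profile
#' and every stage occurrence profile, then picks the bijection maximizing the
#' total correlation by exhaustive enumeration (exact for k <= 5).
#'
#' @param cluster_profiles k x B matrix (rows = clusters).
#' @param stage_profiles k x B matrix (rows = stages, rownames = stage names).
#' @return A \code{state_matching}: list with \code{map} (named stage per
#'   cluster), \code{similarity} (k x k matrix of r, clusters x stages),
#'   \code{method = "profile"}.
#' @export
match_by_profile <- function(cluster_profiles, stage_profiles) {
  k <- nrow(cluster_profiles)
  if (nrow(stage_profiles) != k) {
    stop("need equally many clusters and stages", call. = FALSE)
  }
  if (ncol(cluster_profiles) != ncol(stage_profiles)) {
    stop("profiles must share the bin grid", call. = FALSE)
  }
  sim <- matrix(0, k, k,
                dimnames = list(paste0("C", seq_len(k)),
                                rownames(stage_profiles)))
  for (i in seq_len(k)) {
    for (j in seq_len(k)) {
      sim[i, j] <- safe_cor(cluster_profiles[i, ], stage_profiles[j, ])
    }
  }
  a <- exact_assignment(sim)
  map <- rownames(stage_profiles)[a$perm]
  names(map) <- rownames(sim)
  structure(list(map = map, similarity = sim, method = "profile"),
            class = "state_matching")
}

#' Match clusters to stages by mean-matrix similarity
#'
#' Similarity is the Pearson correlation of the vectorized upper triangles of
#' the state and stage mean connectivity matrices; the bijection maximizing
#' total similarity is found exactly. The returned k x k similarity matrix is
#' the analog of the pairwise state-stage correlation table used to confirm a
#' one-to-one matching (highest values on the diagonal after matching).
#'
#' @param state_matrices List of k state mean matrices (clusters).
#' @param stage_matrices Named list of k stage mean matrices.
#' @return A \code{state_matching} with \code{method = "matrix"}.
#' @export
match_by_matrix_similarity <- function(state_matrices, stage_matrices) {
  k <- length(state_matrices)
  if (length(stage_matrices) != k) {
    stop("need equally many clusters and stages", call. = FALSE)
  }
  su <- lapply(state_matrices, vectorize_upper)
  tu <- lapply(stage_matrices, vectorize_upper)
  sim <- matrix(0, k, k,
                dimnames = list(paste0("C", seq_len(k)),
                                names(stage_matrices)))
  for (i in seq_len(k)) {
    for (j in seq_len(k)) sim[i, j] <- safe_cor(su[[i]], tu[[j]])
  }
  a <- exact_assignment(sim)
  map <- names(stage_matrices)[a$perm]
  names(map) <- rownames(sim)
  structure(list(map = map, similarity = sim, method = "matrix"),
            class = "state_matching")
}

#' Heuristic identification of the wakefulness state
#'
#' For EEG-free datasets: a state indicates wakefulness if the probability of
#' observing it is higher at the beginning than at the end of the recording.
#' Implemented as the cluster maximizing mean(P, first half of bins) -
#' mean(P, second half of bins); ties resolve to the lowest cluster id.
#'
#' @param cluster_profiles k x B matrix of occurrence probabilities.
#' @return Cluster index (row of \code{cluster_profiles}).
#' @export
identify_wake_heuristic <- function(cluster_profiles) {
  k <- nrow(cluster_profiles)
  if (k < 2) stop("need at least 2 clusters", call. = FALSE)
  B <- ncol(cluster_profiles)
  first <- seq_len(floor(B / 2))
  second <- (floor(B / 2) + 1L):B
  drop <- rowMeans(cluster_profiles[, first, drop = FALSE]) -
    rowMeans(cluster_profiles[, second, drop = FALSE])
  if (sum(drop == max(drop)) > 1) {
    message("wake heuristic tie; returning the lowest cluster id")
  }
  unname(which.max(drop))
}
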