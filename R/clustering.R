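## k-means under correlation distance. Vectors are standardized to zero mean
## and unit norm, under which squared Euclidean distance is an affine function
## of correlation distance (d2 = 2 d_corr); Lloyd iterations with centroids
## re-standardized each pass are therefore exact k-means in correlation
## distance. Initialization is k-means++ per replicate, best of (by default)
## 100 replicates kept by total within-cluster correlation distance.

#' Correlation distance between two vectors
#'
#' \code{1 - cor(u, v)}, in \[0, 2\]; groups connectivity patterns by shape
#' regardless of overall magnitude or offset.
#'
#' @param u,v Numeric vectors of equal length.
#' @return Distance.
#' @export
correlation_distance <- function(u, v) {
  if (length(u) != length(v)) stop("length mismatch", call. = FALSE)
  if (stats::sd(u) == 0 || stats::sd(v) == 0) {
    stop("correlation distance undefined for constant vectors", call. = FALSE)
  }
  1 - stats::cor(u, v)
}

## Rows -> zero mean, unit L2 norm.
standardize_rows <- function(X) {
  X <- X - rowMeans(X)
  nrm <- sqrt(rowSums(X^2))
  if (any(nrm == 0)) {
    stop("constant vector: correlation distance undefined", call. = FALSE)
  }
  X / nrm
}

## Correlation distances (n x k) from standardized rows to standardized
## centroids: for zero-mean unit-norm vectors cor(x, c) = <x, c>, so
## d = 1 - Xs Cs'.
corr_dist_to_centroids <- function(Xs, Cs) {
  1 - Xs %*% t(Cs)
}

kmeanspp_init <- function(Xs, k) {
  n <- nrow(Xs)
  centers <- integer(k)
  centers[1] <- sample.int(n, 1)
  d2 <- corr_dist_to_centroids(Xs, Xs[centers[1], , drop = FALSE])[, 1]
  d2 <- pmax(d2, 0)
  if (k > 1) {
    for (j in 2:k) {
      probs <- d2^2
      if (sum(probs) <= 0) {
        centers[j] <- sample.int(n, 1)
      } else {
        centers[j] <- sample.int(n, 1, prob = probs)
      }
      dj <- pmax(corr_dist_to_centroids(Xs, Xs[centers[j], , drop = FALSE])[, 1], 0)
      d2 <- pmin(d2, dj)
    }
  }
  Xs[centers, , drop = FALSE]
}

lloyd_once <- function(Xs, k, max_iter) {
  n <- nrow(Xs)
  Cs <- kmeanspp_init(Xs, k)
  assign_old <- rep(0L, n)
  for (it in seq_len(max_iter)) {
    D <- corr_dist_to_centroids(Xs, Cs)
    assign_new <- max.col(-D, ties.method = "first")
    ## empty-cluster repair: re-seed from the point farthest from its centroid
    repeat {
      sizes <- tabulate(assign_new, nbins = k)
      empty <- which(sizes == 0)
      if (length(empty) == 0) break
      dmin <- D[cbind(seq_len(n), assign_new)]
      far <- which.max(dmin)
      assign_new[far] <- empty[1]
      Cs[empty[1], ] <- Xs[far, ]
      D[, empty[1]] <- pmax(corr_dist_to_centroids(
        Xs, Xs[far, , drop = FALSE])[, 1], 0)
    }
    if (all(assign_new == assign_old)) break
    assign_old <- assign_new
    for (j in seq_len(k)) {
      mu <- colMeans(Xs[assign_new == j, , drop = FALSE])
      mu <- mu - mean(mu)
      nm <- sqrt(sum(mu^2))
      if (nm > 0) Cs[j, ] <- mu / nm
    }
  }
  D <- corr_dist_to_centroids(Xs, Cs)
  assignments <- max.col(-D, ties.method = "first")
  inertia <- sum(pmax(D[cbind(seq_len(n), assignments)], 0))
  list(centroids = Cs, assignments = assignments, inertia = inertia,
       iterations = it)
}

#' Cluster connectivity vectors into dynamic connectivity states
#'
#' k-means with correlation distance; the replicate with the lowest total
#' within-cluster distance is kept.
#'
#' @param vectors n x p matrix, one connectivity vector per row.
#' @param k Number of states (the study uses 2 to 5).
#' @param replicates Number of independent initializations (default 100).
#' @param seed Integer seed (the whole run is deterministic given it).
#' @param max_iter Lloyd iteration cap per replicate.
#' @return A \code{cluster_model}: list with \code{k}, \code{centroids}
#'   (k x p, standardized), \code{assignments}, \code{inertia},
#'   \code{replicates}, \code{seed}.
#' @export
cluster_states <- function(vectors, k, replicates = 100, seed = 1L,
                           max_iter = 300) {
  vectors <- as.matrix(vectors)
  if (nrow(vectors) < k) {
    stop("need at least k vectors to form k clusters", call. = FALSE)
  }
  Xs <- standardize_rows(vectors)
  set.seed(seed)
  best <- NULL
  for (r in seq_len(replicates)) {
    fit <- lloyd_once(Xs, k, max_iter)
    if (is.null(best) || fit$inertia < best$inertia - 1e-12) best <- fit
  }
  structure(
    list(k = k, centroids = best$centroids, assignments = best$assignments,
         inertia = best$inertia, replicates = replicates, seed = seed),
    class = "cluster_model"
  )
}

#' Mean connectivity matrix of one state
#'
#' Element-wise average of the member windows' correlation matrices
#' (correlations averaged directly, no Fisher transform).
#'
#' @param model A \code{cluster_model}.
#' @param cluster Cluster id in 1..k.
#' @param vectors The n x p matrix of original (unstandardized) connectivity
#'   vectors the model was fit to.
#' @return R x R symmetric matrix with unit diagonal.
#' @export
state_mean_matrix <- function(model, cluster, vectors) {
  stopifnot(inherits(model, "cluster_model"))
  idx <- which(model$assignments == cluster)
  if (length(idx) == 0) stop("cluster ", cluster, " is empty", call. = FALSE)
  devectorize(colMeans(as.matrix(vectors)[idx, , drop = FALSE]))
}
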