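## Stage-wise network characterization: signed weighted modularity Q_W with
## Louvain maximization, node strength, structural aggregation, SC-FC
## coupling, and FDR-corrected edgewise stage contrasts.

#' Signed weighted modularity Q_W
#'
#' Positive and negative weights carry their own null terms:
#' \deqn{Q_W = \frac{1}{v^+}\sum_{ij}(w^+_{ij} - e^+_{ij})\delta_{M_iM_j}
#'   - \frac{1}{v^+ + v^-}\sum_{ij}(w^-_{ij} - e^-_{ij})\delta_{M_iM_j}}
#' with \eqn{w^\pm} the positive/negative parts (magnitudes),
#' \eqn{v^\pm = \sum_{ij} w^\pm_{ij}} and
#' \eqn{e^\pm_{ij} = \sum_i w^\pm_{ij} \sum_j w^\pm_{ij} / v^\pm}.
#' Reduces to classical weighted (Newman) modularity when all weights are
#' non-negative. The diagonal is excluded (set to zero).
#'
#' @param w Symmetric weight matrix (signed reals allowed).
#' @param partition Integer/character module id per node.
#' @return Q_W value.
#' @export
signed_modularity <- function(w, partition) {
  w <- as.matrix(w)
  stopifnot(nrow(w) == ncol(w))
  if (max(abs(w - t(w))) > 1e-10) stop("weight matrix must be symmetric",
                                       call. = FALSE)
  if (length(partition) != nrow(w)) {
    stop("partition must assign every node", call. = FALSE)
  }
  diag(w) <- 0
  if (all(w == 0)) {
    warning("all-zero network; Q_W defined as 0")
    return(0)
  }
  part <- as.integer(factor(partition))
  delta <- outer(part, part, "==")
  term <- function(wp, vtot) {
    vp <- sum(wp)
    if (vp == 0) return(0)
    kp <- rowSums(wp)
    e <- outer(kp, kp) / vp
    sum((wp - e)[delta]) / vtot
  }
  wpos <- pmax(w, 0)
  wneg <- pmax(-w, 0)
  vpos <- sum(wpos)
  vneg <- sum(wneg)
  term(wpos, vpos) - term(wneg, vpos + vneg)
}

## Signed Louvain: local moving with the signed modularity gain, then
## aggregation, repeated until no improvement. Operates on the (possibly
## aggregated) weight matrix with self-loops on the diagonal; self-loop terms
## are invariant under moves, so gains depend only on off-diagonal sums.
louvain_one_pass <- function(w, init = NULL) {
  n <- nrow(w)
  wpos <- pmax(w, 0); wneg <- pmax(-w, 0)
  vpos <- sum(wpos); vneg <- sum(wneg)
  kpos <- rowSums(wpos); kneg <- rowSums(wneg)
  comm <- if (is.null(init)) seq_len(n) else as.integer(init)
  Kpos <- vapply(seq_len(n), function(c) sum(kpos[comm == c]), numeric(1))
  Kneg <- vapply(seq_len(n), function(c) sum(kneg[comm == c]), numeric(1))
  improved_any <- FALSE
  repeat {
    improved <- FALSE
    for (i in sample.int(n)) {
      ci <- comm[i]
      ## links from i to each community (excluding self)
      spos <- tapply(wpos[i, -i], comm[-i], sum)
      sneg <- tapply(wneg[i, -i], comm[-i], sum)
      cand <- as.integer(names(spos))
      gain <- function(cto) {
        s_to_pos <- if (as.character(cto) %in% names(spos)) spos[[as.character(cto)]] else 0
        s_to_neg <- if (as.character(cto) %in% names(sneg)) sneg[[as.character(cto)]] else 0
        s_fr_pos <- if (as.character(ci) %in% names(spos)) spos[[as.character(ci)]] else 0
        s_fr_neg <- if (as.character(ci) %in% names(sneg)) sneg[[as.character(ci)]] else 0
        dpos <- if (vpos > 0) {
          (2 * (s_to_pos - s_fr_pos) -
             2 * kpos[i] * ((Kpos[cto] - (cto == ci) * kpos[i]) -
                            (Kpos[ci] - kpos[i])) / vpos) / vpos
        } else 0
        dneg <- if (vneg > 0) {
          (2 * (s_to_neg - s_fr_neg) -
             2 * kneg[i] * ((Kneg[cto] - (cto == ci) * kneg[i]) -
                            (Kneg[ci] - kneg[i])) / vneg) / (vpos + vneg)
        } else 0
        dpos - dneg
      }
      ## candidate targets: every other occupied community, plus (when i is
      ## not already alone) a fresh singleton community — with negative
      ## weights, isolating a node can raise Q
      cands <- setdiff(unique(cand), ci)
      alone <- sum(comm == ci) == 1L
      fresh <- if (!alone) setdiff(seq_len(n), unique(comm))[1] else integer(0)
      if (length(fresh) == 1 && !is.na(fresh)) {
        Kpos[fresh] <- 0; Kneg[fresh] <- 0
        cands <- c(cands, fresh)
      }
      if (length(cands) == 0) next
      gains <- vapply(cands, gain, numeric(1))
      best <- which.max(gains)
      if (gains[best] > 1e-12) {
        cto <- cands[best]
        Kpos[ci] <- Kpos[ci] - kpos[i]; Kneg[ci] <- Kneg[ci] - kneg[i]
        Kpos[cto] <- Kpos[cto] + kpos[i]; Kneg[cto] <- Kneg[cto] + kneg[i]
        comm[i] <- cto
        improved <- TRUE
        improved_any <- TRUE
      }
    }
    if (!improved) break
  }
  list(comm = as.integer(factor(comm)), improved = improved_any)
}

louvain_run <- function(w) {
  n0 <- nrow(w)
  membership <- seq_len(n0)
  cur <- w
  repeat {
    pass <- louvain_one_pass(cur)
    if (!pass$improved) break
    membership <- pass$comm[membership]
    nc <- max(pass$comm)
    if (nc == nrow(cur)) break
    ## aggregate: ordered-pair sums between communities; diagonal keeps
    ## intra-community totals as self-loops
    agg <- matrix(0, nc, nc)
    for (a in seq_len(nc)) {
      for (b in a:nc) {
        agg[a, b] <- agg[b, a] <- sum(cur[pass$comm == a, pass$comm == b])
      }
    }
    cur <- agg
  }
  as.integer(factor(membership))
}

#' Louvain maximization of signed modularity
#'
#' Runs the (stochastic) Louvain algorithm \code{iterations} times with
#' different node orders and keeps the partition with the largest Q_W; the
#' single-module partition is always a candidate, so the result is never worse
#' than trivial.
#'
#' @param w Symmetric weight matrix.
#' @param iterations Independent Louvain runs (default 100).
#' @param seed Integer seed.
#' @return A \code{modularity_result}: list with \code{partition}, \code{q},
#'   \code{iterations}, \code{seed}.
#' @export
louvain_maximize <- function(w, iterations = 100, seed = 1L) {
  w <- as.matrix(w)
  stopifnot(nrow(w) >= 2)
  diag(w) <- 0
  set.seed(seed)
  best_part <- rep(1L, nrow(w))
  best_q <- suppressWarnings(signed_modularity(w, best_part))
  for (r in seq_len(iterations)) {
    part <- louvain_run(w)
    ## flat refinement: local moves on the original network starting from the
    ## multi-level partition, undoing locked-in aggregation mistakes
    part <- louvain_one_pass(w, init = part)$comm
    q <- suppressWarnings(signed_modularity(w, part))
    if (q > best_q + 1e-12) {
      best_q <- q
      best_part <- part
    }
  }
  structure(list(partition = best_part, q = best_q, iterations = iterations,
                 seed = seed),
            class = "modularity_result")
}

#' Node strength
#'
#' Sum of the weights attached to each node's links.
#'
#' @param w Symmetric weight matrix.
#' @return Numeric vector of strengths.
#' @export
node_strength <- function(w) {
  w <- as.matrix(w)
  diag(w) <- 0
  rowSums(w)
}

#' Aggregate node-level structural connectivity to regions
#'
#' The weight between two regions is the sum of all weights of structural
#' connections starting within one region and ending within the other; the
#' within-region diagonal is set to zero.
#'
#' @param w Node-level symmetric weight matrix.
#' @param membership Region id per node (every node mapped to exactly one
#'   region).
#' @return Region-level symmetric weight matrix with region names.
#' @export
aggregate_structural <- function(w, membership) {
  w <- as.matrix(w)
  if (length(membership) != nrow(w)) {
    stop("every node must be mapped to a region", call. = FALSE)
  }
  if (anyNA(membership)) stop("unmapped node (NA region)", call. = FALSE)
  regions <- sort(unique(membership))
  M <- outer(regions, regions, Vectorize(function(a, b) {
    sum(w[membership == a, membership == b])
  }))
  diag(M) <- 0
  dimnames(M) <- list(regions, regions)
  M
}

#' Structure-function coupling
#'
#' Pearson correlation between the vectorized upper triangles of a functional
#' and a structural connectivity matrix, restricted to a common node subset
#' (the structural network lacks sub-cortical and cerebellar regions, so only
#' the shared cortical subset is compared).
#'
#' @param fc Functional connectivity matrix.
#' @param sc Structural connectivity matrix (same size).
#' @param subset Indices of the common nodes (default: all).
#' @return Pearson r.
#' @export
sc_fc_correlation <- function(fc, sc, subset = NULL) {
  fc <- as.matrix(fc); sc <- as.matrix(sc)
  if (is.null(subset)) subset <- seq_len(nrow(fc))
  if (length(subset) < 3) stop("subset must contain >= 3 nodes", call. = FALSE)
  u <- vectorize_upper(fc[subset, subset])
  v <- vectorize_upper(sc[subset, subset])
  if (stats::sd(u) == 0 || stats::sd(v) == 0) {
    stop("constant connectivity vector", call. = FALSE)
  }
  stats::cor(u, v)
}

#' Per-participant, per-stage mean connectivity matrices
#'
#' Averages each subject's windowed correlation matrices within each sleep
#' stage (windows labeled by the hypnogram), independently per participant.
#'
#' @param wins Per-subject window objects (with \code{stage} labels).
#' @param stages Stage set to summarize (default: all observed).
#' @return Nested list \code{[[subject]][[stage]]} of R x R matrices; stages a
#'   participant never reached are absent.
#' @export
stage_mean_matrices <- function(wins, stages = NULL) {
  if (is.null(stages)) {
    stages <- intersect(STAGE_LEVELS, unique(unlist(lapply(wins, `[[`, "stage"))))
  }
  lapply(wins, function(w) {
    out <- list()
    for (s in stages) {
      idx <- which(w$stage == s)
      if (length(idx) == 0) next
      out[[s]] <- devectorize(colMeans(w$vectors[idx, , drop = FALSE]))
    }
    out
  })
}

#' Edgewise stage contrast with FDR correction
#'
#' Paired t-tests across participants on every edge (upper triangle) between
#' two stages, Benjamini-Hochberg corrected; participants missing either stage
#' are excluded. Optionally aggregates edges into within/between
#' resting-state-network blocks (both the mean difference and the count of
#' significant edges per block are reported).
#'
#' @param stage_mats Output of \code{\link{stage_mean_matrices}}.
#' @param stage_a,stage_b Stage labels to contrast (difference = A - B).
#' @param rsn Optional character vector of network labels, one per region.
#' @param alpha FDR level (default 0.05).
#' @return List with \code{diff} (mean difference matrix), \code{p},
#'   \code{p_adj}, \code{significant} (logical matrix), \code{n_participants},
#'   and, when \code{rsn} is given, \code{blocks} (data frame with per-block
#'   mean difference and significant-edge counts).
#' @export
stage_contrast <- function(stage_mats, stage_a, stage_b, rsn = NULL,
                           alpha = 0.05) {
  have_both <- vapply(stage_mats, function(m) {
    !is.null(m[[stage_a]]) && !is.null(m[[stage_b]])
  }, logical(1))
  if (sum(have_both) < 4) {
    stop("need >= 4 participants with both stages", call. = FALSE)
  }
  if (any(!have_both)) {
    message(sum(!have_both), " participant(s) missing a stage were excluded")
  }
  mats <- stage_mats[have_both]
  da <- t(vapply(mats, function(m) vectorize_upper(m[[stage_a]]),
                 numeric(length(vectorize_upper(mats[[1]][[stage_a]])))))
  db <- t(vapply(mats, function(m) vectorize_upper(m[[stage_b]]),
                 numeric(ncol(da))))
  d <- da - db
  mean_diff <- colMeans(d)
  ## degenerate edges (identical difference in every participant) bypass the
  ## t-test: no difference -> p = 1, constant nonzero difference -> p = 0
  p <- apply(d, 2, function(x) {
    if (stats::sd(x) <= 1e-10 * max(1, abs(mean(x)))) {
      return(if (abs(mean(x)) > 1e-12) 0 else 1)
    }
    stats::t.test(x)$p.value
  })
  p_adj <- stats::p.adjust(p, method = "BH")
  sig <- p_adj < alpha
  R <- nrow(mats[[1]][[stage_a]])
  out <- list(diff = devectorize(mean_diff, diag_value = 0),
              p = devectorize(p, diag_value = 1),
              p_adj = devectorize(p_adj, diag_value = 1),
              significant = devectorize(as.numeric(sig), diag_value = 0) > 0,
              n_participants = sum(have_both))
  if (!is.null(rsn)) {
    stopifnot(length(rsn) == R)
    ## vectorize_upper is row-major above the diagonal; build matching labels
    lab <- t(outer(rsn, rsn, paste, sep = "|"))[lower.tri(diag(R))]
    ## canonical unordered block label
    ab <- do.call(rbind, strsplit(lab, "|", fixed = TRUE))
    block <- ifelse(ab[, 1] <= ab[, 2], paste(ab[, 1], ab[, 2], sep = "-"),
                    paste(ab[, 2], ab[, 1], sep = "-"))
    agg <- data.frame(
      block = sort(unique(block)),
      mean_diff = as.numeric(tapply(mean_diff, block, mean)[sort(unique(block))]),
      n_edges = as.integer(table(block)[sort(unique(block))]),
      n_significant = as.integer(tapply(sig, block, sum)[sort(unique(block))])
    )
    out$blocks <- agg
  }
  out
}
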