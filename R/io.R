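## On-disk formats: ROI time series as TSV (header = region names) with a
## JSON sidecar carrying TR and subject id; hypnograms as two-column TSV
## (epoch_start_seconds, stage). Full-precision text round trips.

sidecar_path <- function(path) sub("\\.tsv$", ".json", path)

#' Write / read an ROI time series
#'
#' The matrix goes to a TSV (one row per volume, header = region names); TR
#' and the subject id go to a JSON sidecar next to it.
#'
#' @param ts A \code{roi_ts}.
#' @param path Output TSV path (sidecar written with extension .json).
#' @return \code{path}, invisibly.
#' @export
write_timeseries <- function(ts, path) {
  stopifnot(inherits(ts, "roi_ts"))
  df <- as.data.frame(ts$data)
  names(df) <- ts$regions
  utils::write.table(format(df, digits = 17, trim = TRUE), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  jsonlite::write_json(list(tr = ts$tr, subject = ts$subject),
                       sidecar_path(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_timeseries
#' @return For the reader, a \code{roi_ts}.
#' @export
read_timeseries <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                          colClasses = "numeric")
  X <- as.matrix(df)
  if (anyNA(X)) {
    bad <- which(is.na(X), arr.ind = TRUE)[1, ]
    stop("non-numeric or missing value at row ", bad[1], ", column ", bad[2],
         " of ", path, call. = FALSE)
  }
  sc <- sidecar_path(path)
  if (!file.exists(sc)) stop("missing TR sidecar: ", sc, call. = FALSE)
  meta <- jsonlite::read_json(sc, simplifyVector = TRUE)
  if (is.null(meta$tr)) stop("sidecar lacks a TR entry: ", sc, call. = FALSE)
  structure(list(data = unname(X), tr = meta$tr,
                 subject = meta$subject %||% basename(path),
                 regions = colnames(df)),
            class = "roi_ts")
}

#' Write / read a hypnogram
#'
#' Two-column TSV with header: \code{epoch_start_seconds} and \code{stage}
#' (W, N1, N2, N3, R).
#'
#' @param hyp A \code{hypnogram}.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_hypnogram <- function(hyp, path) {
  stopifnot(inherits(hyp, "hypnogram"))
  df <- data.frame(
    epoch_start_seconds = (seq_along(hyp$stages) - 1) * hyp$epoch_length,
    stage = hyp$stages
  )
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_hypnogram
#' @param subject Subject id to attach (default: file name).
#' @return For the reader, a \code{hypnogram}.
#' @export
read_hypnogram <- function(path, subject = NULL) {
  df <- utils::read.table(path, sep = "\t", header = TRUE)
  if (!all(c("epoch_start_seconds", "stage") %in% names(df))) {
    stop("hypnogram file needs columns epoch_start_seconds and stage",
         call. = FALSE)
  }
  bad <- setdiff(unique(df$stage), STAGE_LEVELS)
  if (length(bad) > 0) {
    stop("unknown stage code(s): ", paste(bad, collapse = ", "),
         "; allowed: ", paste(STAGE_LEVELS, collapse = ", "), call. = FALSE)
  }
  starts <- df$epoch_start_seconds
  if (any(diff(starts) <= 0)) {
    stop("epoch start times must be strictly increasing", call. = FALSE)
  }
  epoch_length <- if (length(starts) > 1) starts[2] - starts[1] else 30
  if (length(starts) > 2 && any(abs(diff(starts) - epoch_length) > 1e-9)) {
    stop("epochs must be equally spaced", call. = FALSE)
  }
  structure(list(subject = subject %||% basename(path),
                 stages = as.character(df$stage),
                 epoch_length = epoch_length,
                 duration = length(starts) * epoch_length),
            class = "hypnogram")
}

#' Write a cohort to a directory
#'
#' One \code{<subject>_bold.tsv} (+ JSON sidecar) and one
#' \code{<subject>_hypnogram.tsv} per subject.
#'
#' @param cohort List of \code{list(ts, hypnogram)}.
#' @param dir Output directory (created if needed).
#' @return \code{dir}, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (su in cohort) {
    write_timeseries(su$ts, file.path(dir, paste0(su$ts$subject, "_bold.tsv")))
    write_hypnogram(su$hypnogram,
                    file.path(dir, paste0(su$ts$subject, "_hypnogram.tsv")))
  }
  invisible(dir)
}

#' Read a cohort from a directory
#'
#' @param dir Directory written by \code{\link{write_cohort}}.
#' @return List of \code{list(ts, hypnogram)}; hypnograms NULL when absent.
#' @export
read_cohort <- function(dir) {
  bold <- sort(list.files(dir, pattern = "_bold\\.tsv$", full.names = TRUE))
  if (length(bold) == 0) stop("no *_bold.tsv files in ", dir, call. = FALSE)
  lapply(bold, function(f) {
    subject <- sub("_bold\\.tsv$", "", basename(f))
    hf <- file.path(dir, paste0(subject, "_hypnogram.tsv"))
    list(ts = read_timeseries(f),
         hypnogram = if (file.exists(hf)) read_hypnogram(hf, subject) else NULL)
  })
}

#' Write / read windowed connectivity in long format
#'
#' One row per window and region pair: \code{window, i, j, r} with
#' \code{i < j} (upper triangle).
#'
#' @param vectors Windows x R(R-1)/2 matrix of connectivity vectors (one
#'   window per row), as produced by \code{\link{subject_windows}}.
#' @param path Output TSV path.
#' @return \code{path}, invisibly.
#' @export
write_connectivity <- function(vectors, path) {
  vectors <- as.matrix(vectors)
  p <- ncol(vectors)
  R <- as.integer(round((1 + sqrt(1 + 8 * p)) / 2))
  if (R * (R - 1) / 2 != p) stop("not a triangular vector length",
                                 call. = FALSE)
  idx <- which(upper.tri(diag(R)), arr.ind = TRUE)
  idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
  df <- data.frame(
    window = rep(seq_len(nrow(vectors)), each = p),
    i = rep(idx[, 1], nrow(vectors)),
    j = rep(idx[, 2], nrow(vectors)),
    r = as.vector(t(vectors))
  )
  utils::write.table(format(df, digits = 17, trim = TRUE), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_connectivity
#' @return For the reader, the windows x R(R-1)/2 matrix.
#' @export
read_connectivity <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE)
  stopifnot(all(c("window", "i", "j", "r") %in% names(df)))
  df <- df[order(df$window, df$i, df$j), ]
  p <- sum(df$window == df$window[1])
  matrix(df$r, ncol = p, byrow = TRUE)
}

#' Pipeline configuration
#'
#' Validated bag of parameters for \code{\link{run_pipeline}}; unknown
#' arguments are rejected.
#'
#' @param window_length,window_step Windowing (volumes).
#' @param k Number of dynamic connectivity states.
#' @param replicates k-means replicates.
#' @param seed Integer seed governing every stochastic step.
#' @param heuristic_only Skip hypnogram-based matching/accuracy and identify
#'   the wake state by its occurrence-profile trend only.
#' @return A \code{pipeline_config}.
#' @export
pipeline_config <- function(window_length = 50, window_step = window_length,
                            k = 2, replicates = 100, seed = 1L,
                            heuristic_only = FALSE) {
  spec <- window_spec(window_length, window_step)
  stopifnot(k >= 1, replicates >= 1)
  structure(list(spec = spec, k = k, replicates = replicates, seed = seed,
                 heuristic_only = heuristic_only),
            class = "pipeline_config")
}

#' Run the staging pipeline end to end
#'
#' Windows each subject's series, computes windowed correlation vectors,
#' clusters them into k dynamic connectivity states, matches states to stages
#' (occurrence-profile and matrix-similarity criteria) and scores volume-level
#' accuracy against the hypnograms. With \code{heuristic_only = TRUE} (or when
#' hypnograms are absent) only the wakefulness state is identified, via the
#' declining-occurrence heuristic.
#'
#' @param cohort List of \code{list(ts, hypnogram)}.
#' @param config A \code{pipeline_config}.
#' @return List with \code{model}, \code{cluster_profiles},
#'   \code{wake_cluster}, and (when hypnograms are present and
#'   \code{heuristic_only} is FALSE) \code{matching_profile},
#'   \code{matching_matrix}, \code{report} (accuracy), \code{chance}.
#' @export
run_pipeline <- function(cohort, config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  have_hyp <- all(!vapply(cohort, function(s) is.null(s$hypnogram), logical(1)))
  if (!have_hyp && !config$heuristic_only) {
    stop("hypnograms are required unless heuristic_only = TRUE", call. = FALSE)
  }
  wins <- cohort_windows(cohort, config$spec)
  if (have_hyp) wins <- attach_hypnograms(wins, cohort)
  vectors <- do.call(rbind, lapply(wins, function(w) w$vectors))
  model <- cluster_states(vectors, config$k, replicates = config$replicates,
                          seed = config$seed)
  n_per <- vapply(wins, function(w) nrow(w$vectors), integer(1))
  split_idx <- split(seq_len(sum(n_per)), rep(seq_along(wins), n_per))
  cluster_by_subject <- lapply(split_idx,
                               function(ix) as.character(model$assignments[ix]))
  cluster_profiles <- occurrence_profile(
    cluster_by_subject, levels = as.character(seq_len(config$k)))
  out <- list(model = model, cluster_profiles = cluster_profiles,
              wake_cluster = identify_wake_heuristic(cluster_profiles),
              config = config)
  if (have_hyp && !config$heuristic_only) {
    scored <- stage_and_score(wins, config$k, replicates = config$replicates,
                              seed = config$seed, return_model = FALSE)
    ## matrix-similarity criterion on the same clusters
    truth_windows <- lapply(wins, function(w) collapse_stages(w$stage, config$k))
    stage_set <- intersect(c("W", "S", STAGE_LEVELS),
                           unique(unlist(truth_windows)))
    state_mats <- lapply(seq_len(config$k), function(j) {
      state_mean_matrix(model, j, vectors)
    })
    all_truth <- unlist(truth_windows)
    stage_mats <- lapply(stage_set, function(s) {
      devectorize(colMeans(vectors[all_truth == s, , drop = FALSE]))
    })
    names(stage_mats) <- stage_set
    out$matching_profile <- scored$matching
    if (length(stage_mats) == config$k) {
      out$matching_matrix <- match_by_matrix_similarity(state_mats, stage_mats)
      if (!identical(unname(out$matching_matrix$map),
                     unname(out$matching_profile$map))) {
        message("profile and matrix matching disagree; both are reported")
      }
    }
    out$report <- scored
    out$chance <- chance_accuracy(config$k)
  }
  out
}
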