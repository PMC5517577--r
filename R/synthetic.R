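## Synthetic EEG-fMRI sleep cohorts: Markov-chain hypnograms driving
## stage-switched multivariate Gaussian BOLD signals, band-pass filtered as in
## standard resting-state preprocessing.

#' Define a sleep-stage dynamics model
#'
#' A time-inhomogeneous first-order Markov chain over sleep stages at the
#' 30-second epoch scale. The session is split into three equal regimes
#' (thirds); within regime \code{r} the transition matrix is
#' \code{stay * I + (1 - stay) * 1 %o% pi_r}, whose stationary distribution is
#' exactly \code{pi_r}. This is the simplest chain that produces the
#' non-stationarity seen in sleep-scored resting-state sessions: wakefulness
#' decaying over the session, light (N1) sleep peaking early, deeper stages
#' (N2/N3) peaking late.
#'
#' @param stages Character vector of stage labels, subset of
#'   \code{stage_levels()}.
#' @param regime_pi Matrix (3 x length(stages)) of per-regime stationary
#'   distributions; rows sum to 1.
#' @param stay Per-epoch self-transition weight in \[0, 1); controls mean
#'   stage dwell time (\code{0.85} gives a mean dwell of about 3.3 minutes).
#' @param epoch_length Epoch length in seconds (default 30, the AASM scoring
#'   epoch).
#' @param start_probs Distribution of the first epoch's stage; defaults to
#'   wake with probability 1 (subjects enter the scanner awake).
#' @return A \code{stage_model} object.
#' @export
stage_model <- function(stages, regime_pi, stay = 0.85, epoch_length = 30,
                        start_probs = NULL) {
  assert_stages(stages)
  if (epoch_length <= 0) stop("epoch_length must be > 0", call. = FALSE)
  regime_pi <- as.matrix(regime_pi)
  if (ncol(regime_pi) != length(stages) || nrow(regime_pi) != 3) {
    stop("regime_pi must be a 3 x length(stages) matrix", call. = FALSE)
  }
  if (any(abs(rowSums(regime_pi) - 1) > 1e-12)) {
    stop("each regime_pi row must sum to 1", call. = FALSE)
  }
  if (stay < 0 || stay >= 1) stop("stay must be in [0, 1)", call. = FALSE)
  if (is.null(start_probs)) {
    start_probs <- as.numeric(stages == stages[1])
    if (!"W" %in% stages[1] && "W" %in% stages) {
      start_probs <- as.numeric(stages == "W")
    }
  }
  if (abs(sum(start_probs) - 1) > 1e-12) {
    stop("start_probs must sum to 1", call. = FALSE)
  }
  colnames(regime_pi) <- stages
  structure(
    list(stages = stages, regime_pi = regime_pi, stay = stay,
         epoch_length = epoch_length, start_probs = start_probs),
    class = "stage_model"
  )
}

#' Transition matrix of a stage model in one regime
#'
#' @param model A \code{stage_model}.
#' @param regime Regime index (1, 2 or 3 = session third).
#' @return Row-stochastic transition matrix.
#' @export
transition_matrix <- function(model, regime) {
  stopifnot(inherits(model, "stage_model"), regime %in% 1:3)
  k <- length(model$stages)
  P <- model$stay * diag(k) +
    (1 - model$stay) * matrix(model$regime_pi[regime, ], k, k, byrow = TRUE)
  dimnames(P) <- list(model$stages, model$stages)
  P
}

#' Preset stage models for the emulated cohorts
#'
#' \describe{
#'   \item{sleep}{W/N1/N2/N3 model whose long-run prevalences are about
#'     48\% W, 23\% N1, 19\% N2 and 10\% N3 over a 52-minute session, with
#'     wakefulness decreasing over the session, N1 peaking in the middle third
#'     and N2/N3 peaking late.}
#'   \item{wake}{wake-only sessions (no sleep intrusion).}
#'   \item{wake_n1}{two-stage W/N1 model used for short-scan analyses; sleep
#'     pressure is front-loaded so that the first minutes already contain a
#'     substantial N1 fraction.}
#'   \item{narcolepsy}{five-stage model including REM, with REM and N3
#'     concentrated late in the session.}
#'   \item{balanced}{stationary model with equal stage prevalences; used for
#'     stage-wise network characterization so every stage is estimated from
#'     equally many windows (matched estimator precision across stages).}
#' }
#'
#' @param profile One of \code{"sleep"}, \code{"wake"}, \code{"wake_n1"},
#'   \code{"narcolepsy"}, \code{"balanced"}.
#' @return A \code{stage_model}.
#' @export
stage_model_preset <- function(profile = c("sleep", "wake", "wake_n1",
                                           "narcolepsy", "balanced")) {
  profile <- match.arg(profile)
  switch(profile,
    sleep = stage_model(
      stages = c("W", "N1", "N2", "N3"),
      regime_pi = rbind(c(0.66, 0.22, 0.09, 0.03),
                        c(0.40, 0.28, 0.21, 0.11),
                        c(0.25, 0.24, 0.31, 0.20))
    ),
    wake = stage_model(
      stages = "W",
      regime_pi = rbind(1, 1, 1),
      stay = 0
    ),
    wake_n1 = stage_model(
      stages = c("W", "N1"),
      regime_pi = rbind(c(0.45, 0.55),
                        c(0.30, 0.70),
                        c(0.25, 0.75))
    ),
    narcolepsy = stage_model(
      stages = c("W", "N1", "N2", "N3", "R"),
      regime_pi = rbind(c(0.42, 0.28, 0.13, 0.12, 0.05),
                        c(0.22, 0.18, 0.16, 0.26, 0.18),
                        c(0.12, 0.12, 0.13, 0.32, 0.31))
    ),
    balanced = stage_model(
      stages = c("W", "N1", "N2", "N3"),
      regime_pi = rbind(rep(0.25, 4), rep(0.25, 4), rep(0.25, 4)),
      start_probs = rep(0.25, 4)
    )
  )
}

#' Simulate a hypnogram
#'
#' Draws a per-epoch stage sequence from a \code{stage_model}'s Markov chain.
#'
#' @param model A \code{stage_model}.
#' @param duration Session duration in seconds (>= one epoch).
#' @param seed Integer seed.
#' @param subject Subject identifier.
#' @return A \code{hypnogram}: list with \code{stages} (character per epoch),
#'   \code{epoch_length}, \code{duration} and \code{subject}.
#' @export
generate_hypnogram <- function(model, duration, seed = 1L, subject = "s1") {
  stopifnot(inherits(model, "stage_model"))
  if (duration < model$epoch_length) {
    stop("duration must cover at least one epoch", call. = FALSE)
  }
  n_epochs <- as.integer(floor(duration / model$epoch_length + 1e-9))
  k <- length(model$stages)
  P <- lapply(1:3, function(r) transition_matrix(model, r))
  set.seed(seed)
  stages <- character(n_epochs)
  cur <- sample.int(k, 1, prob = model$start_probs)
  stages[1] <- model$stages[cur]
  for (t in seq_len(n_epochs - 1L) + 1L) {
    regime <- min(3L, 1L + ((t - 1L) * 3L) %/% n_epochs)
    cur <- sample.int(k, 1, prob = P[[regime]][cur, ])
    stages[t] <- model$stages[cur]
  }
  structure(
    list(subject = subject, stages = stages,
         epoch_length = model$epoch_length,
         duration = n_epochs * model$epoch_length),
    class = "hypnogram"
  )
}

#' Stage label of each volume implied by a hypnogram
#'
#' Each volume takes the stage of the 30-s epoch containing its acquisition
#' midpoint.
#'
#' @param hyp A \code{hypnogram}.
#' @param n_volumes Number of volumes.
#' @param tr Repetition time (seconds).
#' @return Character vector of length \code{n_volumes}.
#' @export
volume_stages <- function(hyp, n_volumes, tr = 2.08) {
  stopifnot(inherits(hyp, "hypnogram"))
  mid <- (seq_len(n_volumes) - 0.5) * tr
  if (mid[n_volumes] > hyp$duration + hyp$epoch_length) {
    stop("volumes extend beyond the hypnogram", call. = FALSE)
  }
  ep <- pmin(length(hyp$stages), floor(mid / hyp$epoch_length) + 1L)
  hyp$stages[ep]
}

## Symmetric matrix of iid N(0,1) entries, zero diagonal.
sym_noise <- function(R) {
  Z <- matrix(stats::rnorm(R * R), R, R)
  Z <- (Z + t(Z)) / sqrt(2)
  diag(Z) <- 0
  Z
}

## Block pattern: +within on same-module pairs, -between otherwise.
block_pattern <- function(R, modules, within = 0.6, between = -0.2) {
  B <- outer(modules, modules, function(a, b) ifelse(a == b, within, between))
  diag(B) <- 0
  B
}

## Project a symmetric matrix to the nearest PSD correlation matrix:
## eigenvalue clipping at 1e-10, then renormalization to unit diagonal.
nearest_correlation <- function(M) {
  M <- (M + t(M)) / 2
  diag(M) <- 1
  e <- eigen(M, symmetric = TRUE)
  vals <- pmax(e$values, 1e-10)
  M2 <- e$vectors %*% (vals * t(e$vectors))
  M2 <- stats::cov2cor(M2)
  (M2 + t(M2)) / 2
}

#' Rescale a weighted structural matrix to correlation form
#'
#' Off-diagonal weights are scaled to a maximum absolute value of
#' \code{max_abs}, the diagonal set to 1, and the result projected to the
#' nearest positive semi-definite correlation matrix.
#'
#' @param sc Symmetric weight matrix.
#' @param max_abs Maximum absolute off-diagonal value after rescaling.
#' @return Correlation-form matrix.
#' @export
structural_to_correlation <- function(sc, max_abs = 0.6) {
  sc <- as.matrix(sc)
  stopifnot(nrow(sc) == ncol(sc))
  off <- sc
  diag(off) <- 0
  m <- max(abs(off))
  if (m > 0) off <- off * (max_abs / m)
  diag(off) <- 1
  nearest_correlation(off)
}

#' Synthetic structural connectivity template
#'
#' A modular non-negative weight matrix: elevated weights within modules,
#' heavy-tailed (exponential) weight noise throughout, and a weak background
#' between modules. By default the structural modules coincide with the
#' functional block partition (anatomical modules support functional ones);
#' pass \code{modules} to decouple them.
#'
#' @param R Number of regions.
#' @param n_modules Number of structural modules.
#' @param modules Optional explicit module assignment (length R); default
#'   contiguous blocks.
#' @param seed Integer seed.
#' @return Symmetric non-negative R x R weight matrix, zero diagonal.
#' @export
make_structural_template <- function(R, n_modules = 4, modules = NULL,
                                     seed = 1L) {
  stopifnot(R >= 2)
  set.seed(seed)
  if (is.null(modules)) {
    modules <- ((seq_len(R) - 1L) %/% ceiling(R / n_modules)) %% n_modules + 1L
  }
  W <- matrix(0, R, R)
  for (i in 1:(R - 1)) {
    for (j in (i + 1):R) {
      base <- if (modules[i] == modules[j]) 1.0 else 0.05
      w <- base * stats::rexp(1)
      W[i, j] <- W[j, i] <- w
    }
  }
  W
}

#' Build per-stage covariance templates
#'
#' Each stage template is a correlation matrix composed of (i) a block
#' (modular) pattern scaled by the stage's \code{modularity_grade}, (ii) a
#' structural template scaled by the stage's \code{sc_coupling}, and (iii)
#' shared-plus-unique Gaussian perturbations whose mixing weight
#' \code{inter_state_similarity} sets the expected pairwise correlation
#' between the stage-unique parts of the templates. The composition is
#' \deqn{T_s = c_s S + (1 - c_s) (g_s B + \sigma(\sqrt{\rho} Z_0 +
#'   \sqrt{1-\rho} Z_s)),}
#' so \code{sc_coupling = 1} returns the structural template (in correlation
#' form) exactly. Every template is projected to the nearest positive
#' semi-definite correlation matrix and re-verified.
#'
#' @param R Number of regions.
#' @param modularity_grade Named numeric in \[0,1\], one entry per stage.
#' @param sc_coupling Named numeric in \[0,1\], one per stage (default 0).
#' @param structural Structural weight matrix (R x R) or NULL; required if any
#'   \code{sc_coupling > 0}.
#' @param inter_state_similarity Target correlation between the stage-unique
#'   random parts of the templates, in \[0,1\].
#' @param noise_scale Standard deviation of the random perturbation entries.
#' @param n_modules Number of functional modules in the block pattern.
#' @param module_offset Integer; rotates the block-pattern module assignment,
#'   letting different covariance sets use distinguishable partitions.
#' @param seed Integer seed.
#' @return A \code{state_covariances} object: list with \code{templates}
#'   (named list of correlation matrices), \code{modules},
#'   \code{modularity_grade}, \code{sc_coupling}, \code{structural}.
#' @export
make_state_covariances <- function(R, modularity_grade, sc_coupling = NULL,
                                   structural = NULL,
                                   inter_state_similarity = 0.2,
                                   noise_scale = 0.25, n_modules = 4,
                                   module_offset = 0L, seed = 1L) {
  stopifnot(R >= 2)
  stages <- names(modularity_grade)
  if (is.null(stages)) stop("modularity_grade must be named by stage",
                            call. = FALSE)
  assert_stages(stages)
  if (any(modularity_grade < 0 | modularity_grade > 1)) {
    stop("modularity grades must lie in [0, 1]", call. = FALSE)
  }
  if (is.null(sc_coupling)) {
    sc_coupling <- stats::setNames(rep(0, length(stages)), stages)
  }
  sc_coupling <- sc_coupling[stages]
  if (any(sc_coupling < 0 | sc_coupling > 1)) {
    stop("sc couplings must lie in [0, 1]", call. = FALSE)
  }
  if (any(sc_coupling > 0) && is.null(structural)) {
    stop("a structural template is required when sc_coupling > 0",
         call. = FALSE)
  }
  rho <- inter_state_similarity
  stopifnot(rho >= 0, rho <= 1)

  modules <- ((seq_len(R) - 1L + module_offset) %/% ceiling(R / n_modules)) %%
    n_modules + 1L
  B <- block_pattern(R, modules)
  S <- if (!is.null(structural)) structural_to_correlation(structural) else NULL

  set.seed(seed)
  Z0 <- sym_noise(R)
  templates <- vector("list", length(stages))
  names(templates) <- stages
  for (s in stages) {
    Zs <- sym_noise(R)
    func <- modularity_grade[[s]] * B +
      noise_scale * (sqrt(rho) * Z0 + sqrt(1 - rho) * Zs)
    cs <- sc_coupling[[s]]
    M <- if (cs > 0) cs * S + (1 - cs) * func else func
    M[M > 0.95] <- 0.95
    M[M < -0.95] <- -0.95
    diag(M) <- 1
    M <- nearest_correlation(M)
    if (min(eigen(M, symmetric = TRUE, only.values = TRUE)$values) < -1e-8) {
      stop("internal error: template not PSD after projection", call. = FALSE)
    }
    templates[[s]] <- M
  }
  structure(
    list(templates = templates, modules = modules,
         modularity_grade = modularity_grade, sc_coupling = sc_coupling,
         structural = structural),
    class = "state_covariances"
  )
}

#' Preset covariance sets for the emulated cohorts
#'
#' \describe{
#'   \item{two_state}{one wake template and one shared sleep template (N1, N2
#'     and N3 all map to the sleep template), built on different module
#'     partitions so the two states are well separated (vectorized
#'     inter-template correlation well below 0.7). This is the default for
#'     the k = 2 staging and bootstrap analyses.}
#'   \item{graded}{four distinct stage templates with modularity grades
#'     increasing from wakefulness to N3 and structure-function couplings
#'     lowest in N1 and highest in N3, emulating the stage-wise network
#'     findings.}
#'   \item{wake_n1}{two well-separated templates for W and N1 (short-scan
#'     analyses).}
#'   \item{narcolepsy}{five templates (adds REM) with graded modularity.}
#' }
#'
#' @param R Number of regions.
#' @param profile One of \code{"two_state"}, \code{"graded"},
#'   \code{"wake_n1"}, \code{"narcolepsy"}.
#' @param structural Structural weight matrix; synthesized when NULL and
#'   needed.
#' @param seed Integer seed.
#' @return A \code{state_covariances} object.
#' @export
covariance_preset <- function(R = 20,
                              profile = c("two_state", "graded", "wake_n1",
                                          "narcolepsy"),
                              structural = NULL, seed = 1L) {
  profile <- match.arg(profile)
  if (profile %in% c("graded", "narcolepsy") && is.null(structural)) {
    ## interleaved structural modules, deliberately misaligned with the
    ## functional block partition so modularity and structure-function
    ## coupling can be graded independently
    structural <- make_structural_template(
      R, modules = (seq_len(R) - 1L) %% 4L + 1L,
      seed = subject_seed(seed, 7919L))
  }
  switch(profile,
    two_state = {
      w <- make_state_covariances(
        R, modularity_grade = c(W = 0.7), inter_state_similarity = 0,
        module_offset = 0L, seed = subject_seed(seed, 11L))
      s <- make_state_covariances(
        R, modularity_grade = c(N1 = 0.7), inter_state_similarity = 0,
        module_offset = as.integer(ceiling(R / 8)),
        n_modules = 5, seed = subject_seed(seed, 23L))
      templates <- list(W = w$templates$W, N1 = s$templates$N1,
                        N2 = s$templates$N1, N3 = s$templates$N1)
      structure(list(templates = templates, modules = w$modules,
                     modularity_grade = c(W = 0.7, N1 = 0.7, N2 = 0.7,
                                          N3 = 0.7),
                     sc_coupling = NULL, structural = NULL),
                class = "state_covariances")
    },
    graded = make_state_covariances(
      R,
      modularity_grade = c(W = 0.15, N1 = 0.35, N2 = 0.70, N3 = 0.95),
      sc_coupling = c(W = 0.45, N1 = 0.12, N2 = 0.50, N3 = 0.70),
      structural = structural, inter_state_similarity = 0.3,
      seed = subject_seed(seed, 31L)),
    wake_n1 = {
      w <- make_state_covariances(
        R, modularity_grade = c(W = 0.7), inter_state_similarity = 0,
        module_offset = 0L, seed = subject_seed(seed, 11L))
      s <- make_state_covariances(
        R, modularity_grade = c(N1 = 0.7), inter_state_similarity = 0,
        module_offset = as.integer(ceiling(R / 8)),
        n_modules = 5, seed = subject_seed(seed, 23L))
      structure(list(templates = list(W = w$templates$W, N1 = s$templates$N1),
                     modules = w$modules,
                     modularity_grade = c(W = 0.7, N1 = 0.7),
                     sc_coupling = NULL, structural = NULL),
                class = "state_covariances")
    },
    narcolepsy = make_state_covariances(
      R,
      modularity_grade = c(W = 0.15, N1 = 0.35, N2 = 0.70, N3 = 0.95,
                           R = 0.25),
      sc_coupling = c(W = 0.45, N1 = 0.12, N2 = 0.50, N3 = 0.70, R = 0.30),
      structural = structural, inter_state_similarity = 0.3,
      seed = subject_seed(seed, 31L))
  )
}

#' Vectorized correlation between two stage templates
#'
#' Pearson correlation of the upper-triangular parts; the separation measure
#' used to describe how distinct two planted states are.
#'
#' @param covs A \code{state_covariances}.
#' @param a,b Stage names.
#' @return Correlation coefficient.
#' @export
template_similarity <- function(covs, a, b) {
  ua <- covs$templates[[a]][upper.tri(covs$templates[[a]])]
  ub <- covs$templates[[b]][upper.tri(covs$templates[[b]])]
  stats::cor(ua, ub)
}

## 6th-order Butterworth band-pass (0.01-0.1 Hz by default), applied forward
## and backward (zero phase) to each column.
bandpass_filter <- function(x, tr, low = 0.01, high = 0.1) {
  nyq <- 1 / (2 * tr)
  bf <- signal::butter(3, c(low, high) / nyq, type = "pass")
  apply(x, 2, function(col) signal::filtfilt(bf, col))
}

#' Simulate BOLD time series driven by a hypnogram
#'
#' Each volume is drawn from the multivariate normal with the covariance
#' template of the stage active at that volume, plus isotropic measurement
#' noise; the concatenated series is then band-pass filtered (0.01-0.1 Hz,
#' zero-phase 6th-order Butterworth), as in standard resting-state
#' preprocessing. Because the same filter is applied to every region,
#' between-region correlation structure is preserved.
#'
#' @param hyp A \code{hypnogram}.
#' @param covs A \code{state_covariances} with a template for every stage in
#'   the hypnogram.
#' @param tr Repetition time in seconds (default 2.08).
#' @param noise_sd Isotropic noise standard deviation (signal sd is 1).
#' @param seed Integer seed.
#' @param filter Apply the band-pass (TRUE by default).
#' @return A \code{roi_ts}: list with \code{data} (T x R matrix), \code{tr},
#'   \code{subject}, \code{regions}.
#' @export
generate_bold <- function(hyp, covs, tr = 2.08, noise_sd = 0.5, seed = 1L,
                          filter = TRUE) {
  stopifnot(inherits(hyp, "hypnogram"), inherits(covs, "state_covariances"))
  if (tr <= 0) stop("TR must be > 0", call. = FALSE)
  missing_tpl <- setdiff(unique(hyp$stages), names(covs$templates))
  if (length(missing_tpl) > 0) {
    stop("no covariance template for stage(s): ",
         paste(missing_tpl, collapse = ", "), call. = FALSE)
  }
  n_vol <- volumes_for_duration(hyp$duration, tr)
  stages <- volume_stages(hyp, n_vol, tr)
  R <- nrow(covs$templates[[1]])
  chol_by_stage <- lapply(covs$templates, function(S) chol(S))
  set.seed(seed)
  Z <- matrix(stats::rnorm(n_vol * R), n_vol, R)
  X <- matrix(0, n_vol, R)
  for (s in unique(stages)) {
    idx <- which(stages == s)
    X[idx, ] <- Z[idx, , drop = FALSE] %*% chol_by_stage[[s]]
  }
  if (noise_sd > 0) {
    X <- X + noise_sd * matrix(stats::rnorm(n_vol * R), n_vol, R)
  }
  if (filter) X <- bandpass_filter(X, tr)
  regions <- sprintf("roi%03d", seq_len(R))
  structure(
    list(data = X, tr = tr, subject = hyp$subject, regions = regions),
    class = "roi_ts"
  )
}

#' Simulate a cohort of subjects
#'
#' Per-subject seeds are derived deterministically from the master seed
#' (master + subject index), so cohorts are reproducible and individual
#' subjects can be regenerated in isolation.
#'
#' @param n_subjects Number of subjects (>= 1).
#' @param model A \code{stage_model}.
#' @param covs A \code{state_covariances}.
#' @param duration Session duration in seconds (default 52 minutes).
#' @param tr Repetition time in seconds.
#' @param noise_sd Isotropic noise standard deviation.
#' @param seed Master seed.
#' @return List of \code{n_subjects} elements, each
#'   \code{list(ts = roi_ts, hypnogram = hypnogram)}.
#' @export
generate_cohort <- function(n_subjects, model, covs, duration = 52 * 60,
                            tr = 2.08, noise_sd = 0.5, seed = 1L) {
  stopifnot(n_subjects >= 1)
  lapply(seq_len(n_subjects), function(i) {
    sseed <- subject_seed(seed, i)
    hyp <- generate_hypnogram(model, duration, seed = sseed,
                              subject = sprintf("sub%03d", i))
    ts <- generate_bold(hyp, covs, tr = tr, noise_sd = noise_sd,
                        seed = subject_seed(sseed, 500000L))
    list(ts = ts, hypnogram = hyp)
  })
}

#' Default synthetic sleep cohort
#'
#' The study-condition cohort used throughout the validation analyses:
#' 58 subjects scanned for 52 minutes (1500 volumes at TR 2.08 s), 20 regions,
#' a four-stage sleep hypnogram model, and two planted connectivity states
#' (wake vs sleep; N1/N2/N3 share the sleep template).
#'
#' @param n_subjects Number of subjects.
#' @param R Number of regions.
#' @param duration Session duration in seconds.
#' @param noise_sd Isotropic noise standard deviation.
#' @param seed Master seed.
#' @return As \code{\link{generate_cohort}}.
#' @export
default_sleep_cohort <- function(n_subjects = 58, R = 20, duration = 52 * 60,
                                 noise_sd = 0.5, seed = 1L) {
  model <- stage_model_preset("sleep")
  covs <- covariance_preset(R, "two_state", seed = seed)
  generate_cohort(n_subjects, model, covs, duration = duration,
                  noise_sd = noise_sd, seed = seed)
}
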