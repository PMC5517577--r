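## Shared fixtures, built once per test run.

.fixtures <- new.env(parent = emptyenv())

## Small sleep cohort: 10 subjects, 12 regions, 26 minutes, two planted
## connectivity states. Big enough for staging to work, small enough to be
## cheap.
small_cohort <- function() {
  if (is.null(.fixtures$small)) {
    model <- stage_model_preset("sleep")
    covs <- covariance_preset(12, "two_state", seed = 5)
    .fixtures$small <- generate_cohort(10, model, covs, duration = 26 * 60,
                                       seed = 5)
  }
  .fixtures$small
}

small_wins <- function() {
  if (is.null(.fixtures$small_wins)) {
    co <- small_cohort()
    .fixtures$small_wins <- attach_hypnograms(
      cohort_windows(co, window_spec(50)), co)
  }
  .fixtures$small_wins
}

## Full-size study-condition cohort (58 subjects, 1500 volumes, R = 20, two
## planted states) for the acceptance-level checks.
study_cohort <- function() {
  if (is.null(.fixtures$study)) {
    .fixtures$study <- default_sleep_cohort(seed = 1)
  }
  .fixtures$study
}

study_wins <- function() {
  if (is.null(.fixtures$study_wins)) {
    co <- study_cohort()
    .fixtures$study_wins <- attach_hypnograms(
      cohort_windows(co, window_spec(50)), co)
  }
  .fixtures$study_wins
}

## All permutations of 1..n (independent of the package's enumerator).
combinat_perms <- function(n) {
  if (n == 1) return(list(1L))
  do.call(c, lapply(combinat_perms(n - 1L), function(p) {
    lapply(0:(n - 1L), function(pos) append(p, n, after = pos))
  }))
}

## All set partitions of n elements (restricted growth strings).
all_partitions <- function(n) {
  out <- list()
  rgs <- integer(n)
  rec <- function(i, maxv) {
    if (i > n) {
      out[[length(out) + 1]] <<- rgs
      return(invisible())
    }
    for (v in 1:(maxv + 1)) {
      rgs[i] <<- v
      rec(i + 1, max(maxv, v))
    }
  }
  rec(1, 0)
  out
}

## Independent term-by-term oracle for the signed modularity equation,
## written as plain double loops so it shares no code with the implementation.
q_oracle <- function(w, part) {
  diag(w) <- 0
  wp <- pmax(w, 0); wn <- pmax(-w, 0)
  vp <- sum(wp); vn <- sum(wn)
  qp <- 0; qn <- 0
  n <- nrow(w)
  for (i in 1:n) {
    for (j in 1:n) {
      if (part[i] == part[j]) {
        if (vp > 0) qp <- qp + (wp[i, j] - sum(wp[i, ]) * sum(wp[, j]) / vp)
        if (vn > 0) qn <- qn + (wn[i, j] - sum(wn[i, ]) * sum(wn[, j]) / vn)
      }
    }
  }
  (if (vp > 0) qp / vp else 0) - (if (vp + vn > 0) qn / (vp + vn) else 0)
}

## Random symmetric signed weight matrix, zero diagonal.
random_signed_net <- function(n) {
  w <- matrix(0, n, n)
  w[upper.tri(w)] <- stats::rnorm(n * (n - 1) / 2)
  w + t(w)
}

## Signed network with two planted modules of size n/2 each.
modular_signed_net <- function(n) {
  mod <- rep(1:2, length.out = n)[order(rep(1:2, length.out = n))]
  mod <- rep(1:2, each = ceiling(n / 2))[1:n]
  w <- matrix(0, n, n)
  for (i in 1:(n - 1)) {
    for (j in (i + 1):n) {
      mu <- if (mod[i] == mod[j]) 0.6 else -0.2
      w[i, j] <- w[j, i] <- mu + stats::rnorm(1, 0, 0.3)
    }
  }
  w
}
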