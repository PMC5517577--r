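test_that("an absorbing wake state yields an all-W hypnogram", {
  model <- stage_model(c("W", "N1"), rbind(c(1, 0), c(1, 0), c(1, 0)),
                       stay = 0)
  hyp <- generate_hypnogram(model, 52 * 60, seed = 3)
  expect_true(all(hyp$stages == "W"))
  expect_equal(length(hyp$stages), 104)
  expect_equal(hyp$duration, 3120)
})

test_that("hypnogram generation is deterministic given the seed", {
  model <- stage_model_preset("sleep")
  h1 <- generate_hypnogram(model, 52 * 60, seed = 42)
  h2 <- generate_hypnogram(model, 52 * 60, seed = 42)
  expect_identical(h1, h2)
  h3 <- generate_hypnogram(model, 52 * 60, seed = 43)
  expect_false(identical(h1$stages, h3$stages))
})

test_that("sleep-model prevalences and temporal trends", {
  model <- stage_model_preset("sleep")
  stg <- vapply(1:1000, function(i) {
    generate_hypnogram(model, 52 * 60, seed = i)$stages
  }, character(104))
  prev <- as.numeric(table(factor(stg, c("W", "N1", "N2", "N3"))) / length(stg))
  expect_true(all(abs(prev - c(0.48, 0.23, 0.19, 0.10)) < 0.02))

  ## deterministic expected occupancy: wake monotonically non-increasing,
  ## N1 peaks before N2 and N3
  mu <- model$start_probs
  occ <- matrix(0, 104, 4)
  occ[1, ] <- mu
  for (t in 2:104) {
    mu <- mu %*% transition_matrix(model, min(3, 1 + ((t - 1) * 3) %/% 104))
    occ[t, ] <- mu
  }
  expect_true(all(diff(occ[, 1]) <= 1e-12))
  expect_lt(which.max(occ[, 2]), which.max(occ[, 3]))
  expect_lt(which.max(occ[, 2]), which.max(occ[, 4]))

  ## empirical cohort-mean wake curve: non-increasing after 5-minute
  ## smoothing, up to Monte-Carlo error
  pw <- rowMeans(stg == "W")
  sm <- stats::filter(pw, rep(1 / 10, 10))
  expect_true(all(diff(sm[!is.na(sm)]) < 0.01))
})

test_that("state covariance templates are valid correlation matrices", {
  covs <- covariance_preset(20, "graded", seed = 2)
  for (M in covs$templates) {
    expect_equal(M, t(M))
    expect_equal(unname(diag(M)), rep(1, 20))
    expect_true(all(abs(M) <= 1 + 1e-12))
    ev <- eigen(M, symmetric = TRUE, only.values = TRUE)$values
    expect_gt(min(ev), -1e-8)
  }
})

test_that("inter-state similarity target is realized", {
  covs <- make_state_covariances(
    40, modularity_grade = c(W = 0, N1 = 0),
    inter_state_similarity = 0.7, seed = 9)
  expect_equal(template_similarity(covs, "W", "N1"), 0.7, tolerance = 0.08)
})

test_that("the two planted connectivity states are well separated", {
  covs <- covariance_preset(20, "two_state", seed = 1)
  expect_lt(template_similarity(covs, "W", "N1"), 0.7)
  expect_identical(covs$templates$N1, covs$templates$N2)
  expect_identical(covs$templates$N1, covs$templates$N3)
})

test_that("full structural coupling returns the structural template exactly", {
  sc <- make_structural_template(15, seed = 4)
  covs <- make_state_covariances(
    15, modularity_grade = c(W = 0.5), sc_coupling = c(W = 1),
    structural = sc, seed = 4)
  expect_equal(covs$templates$W, structural_to_correlation(sc),
               tolerance = 1e-10)
})

test_that("higher modularity grade yields a more modular template", {
  lo <- make_state_covariances(20, modularity_grade = c(W = 0), seed = 8)
  hi <- make_state_covariances(20, modularity_grade = c(W = 0.8), seed = 8)
  q_lo <- louvain_maximize(lo$templates$W, iterations = 20, seed = 1)$q
  q_hi <- louvain_maximize(hi$templates$W, iterations = 20, seed = 1)$q
  expect_gt(q_hi, q_lo + 0.05)
})

test_that("a 52-minute session at TR 2.08 s yields 1500 volumes", {
  model <- stage_model_preset("wake")
  covs <- covariance_preset(5, "two_state", seed = 1)
  hyp <- generate_hypnogram(model, 52 * 60, seed = 1)
  ts <- generate_bold(hyp, covs, seed = 1)
  expect_equal(nrow(ts$data), 1500)
  expect_equal(ncol(ts$data), 5)
})

test_that("long single-stage series reproduces its covariance template", {
  model <- stage_model_preset("wake")
  covs <- covariance_preset(10, "two_state", seed = 3)
  hyp <- generate_hypnogram(model, 20000 * 2.08, seed = 2)
  ts <- generate_bold(hyp, covs, noise_sd = 0, seed = 2)
  emp <- stats::cor(ts$data)
  frob <- sqrt(sum((emp - covs$templates$W)^2))
  expect_lt(frob, 0.05 * 10)
})

test_that("filtered output concentrates its power in the pass band", {
  model <- stage_model_preset("wake")
  covs <- covariance_preset(4, "two_state", seed = 1)
  hyp <- generate_hypnogram(model, 1500 * 2.08, seed = 6)
  ts <- generate_bold(hyp, covs, seed = 6)
  x <- ts$data[, 1]
  n <- length(x)
  f <- (0:(n - 1)) / (n * 2.08)
  P <- Mod(stats::fft(x))^2
  half <- 2:floor(n / 2)
  inband <- f[half] >= 0.005 & f[half] <= 0.12
  expect_gt(sum(P[half][inband]) / sum(P[half]), 0.95)
})

test_that("invalid generator configurations are rejected", {
  model <- stage_model_preset("sleep")
  covs <- covariance_preset(6, "wake_n1", seed = 1)  # lacks N2/N3 templates
  hyp <- generate_hypnogram(model, 52 * 60, seed = 1)
  expect_error(generate_bold(hyp, covs, seed = 1), "template")
  expect_error(generate_bold(hyp, covariance_preset(6, "two_state"), tr = -1),
               "TR")
  expect_error(stage_model(c("W", "X2"), rbind(c(1, 0), c(1, 0), c(1, 0))),
               "unknown stage")
  expect_error(generate_hypnogram(model, duration = 10), "epoch")
})

test_that("cohorts are reproducible and delegate to single-subject generators", {
  model <- stage_model_preset("sleep")
  covs <- covariance_preset(8, "two_state", seed = 2)
  c1 <- generate_cohort(3, model, covs, duration = 10 * 60, seed = 7)
  c2 <- generate_cohort(3, model, covs, duration = 10 * 60, seed = 7)
  expect_identical(c1, c2)
  ## n = 1 equals the manual composition with the derived per-subject seed
  c3 <- generate_cohort(1, model, covs, duration = 10 * 60, seed = 7)
  sseed <- 7L + 1L
  hyp <- generate_hypnogram(model, 10 * 60, seed = sseed, subject = "sub001")
  ts <- generate_bold(hyp, covs, seed = sseed + 500000L)
  expect_identical(c3[[1]]$hypnogram, hyp)
  expect_equal(c3[[1]]$ts$data, ts$data)
})
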