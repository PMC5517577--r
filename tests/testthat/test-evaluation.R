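test_that("volume-level accuracy and confusion counts", {
  truth <- c("W", "W", "N1", "N2", "N2", "N3")
  expect_equal(staging_accuracy(truth, truth)$accuracy, 1.0)
  pred <- c("N1", "N1", "W", "W", "W", "W")
  rep0 <- staging_accuracy(pred, truth)
  expect_equal(rep0$accuracy, 0.0)
  expect_equal(sum(rep0$confusion), length(truth))
  expect_error(staging_accuracy(pred[-1], truth), "length")
})

test_that("uniform random prediction converges to the 1/k chance level", {
  expect_equal(chance_accuracy(4), 0.25)
  expect_error(chance_accuracy(0), "k must be")
  set.seed(40)
  truth <- sample(c("W", "N1", "N2", "N3"), 40000, replace = TRUE,
                  prob = c(0.5, 0.2, 0.2, 0.1))
  pred <- sample(c("W", "N1", "N2", "N3"), 40000, replace = TRUE)
  expect_equal(staging_accuracy(pred, truth)$accuracy, 0.25, tolerance = 0.03)
})

test_that("stage collapsing for two-state analyses", {
  expect_equal(collapse_stages(c("W", "N1", "N3", "R"), 2),
               c("W", "S", "S", "S"))
  expect_equal(collapse_stages(c("W", "N1"), 4), c("W", "N1"))
})

test_that("bootstrap is reproducible and a single iteration is its own summary", {
  wins <- small_wins()
  b1 <- bootstrap_accuracy(wins, subset_size = 5, iterations = 3, k = 2,
                           replicates = 10, seed = 11)
  b2 <- bootstrap_accuracy(wins, subset_size = 5, iterations = 3, k = 2,
                           replicates = 10, seed = 11)
  expect_identical(b1$accuracies, b2$accuracies)
  one <- bootstrap_accuracy(wins, subset_size = 5, iterations = 1, k = 2,
                            replicates = 10, seed = 12)
  expect_equal(length(one$accuracies), 1)
  expect_equal(one$mean, one$accuracies)
  expect_error(bootstrap_accuracy(wins, subset_size = 99), "exceeds")
})

test_that("label permutation drives accuracy to chance for k = 2", {
  wins <- small_wins()
  b <- bootstrap_accuracy(wins, subset_size = 5, iterations = 20, k = 2,
                          randomize_labels = TRUE, replicates = 10, seed = 13)
  expect_lt(abs(b$mean - 0.5), 0.1)
})

test_that("noiseless planted states with aligned windows give perfect accuracy", {
  ## TR 2 s, 30 s epochs (15 volumes); stages alternate every 2 epochs, so a
  ## 15-volume window always sits inside one stage
  covs <- covariance_preset(8, "wake_n1", seed = 3)
  cohort <- lapply(1:4, function(i) {
    stages <- rep(rep(c("W", "N1"), each = 2), 10)
    hyp <- structure(list(subject = paste0("s", i), stages = stages,
                          epoch_length = 30, duration = length(stages) * 30),
                     class = "hypnogram")
    ts <- generate_bold(hyp, covs, tr = 2, noise_sd = 0, seed = 100 + i,
                        filter = FALSE)
    list(ts = ts, hypnogram = hyp)
  })
  wins <- attach_hypnograms(cohort_windows(cohort, window_spec(15)), cohort)
  out <- sleepstates:::stage_and_score(wins, k = 2, replicates = 10, seed = 1)
  expect_equal(out$accuracy, 1.0)
})

test_that("window-length sweep degrades for noise-dominated short windows", {
  cohort <- small_cohort()
  sw <- window_length_sweep(cohort, c(5, 50), k = 2, replicates = 10, seed = 7)
  expect_true(all(sw$sufficient))
  expect_gt(sw$accuracy[sw$length == 50], sw$accuracy[sw$length == 5])
  ## one subject, window = full series: fewer windows than clusters is flagged
  one <- window_length_sweep(cohort[1], nrow(cohort[[1]]$ts$data), k = 2)
  expect_false(one$sufficient)
  expect_true(is.na(one$accuracy))
})

test_that("a single-size curve equals the direct bootstrap call", {
  wins <- small_wins()
  curve <- sample_size_curve(wins, sizes = 5, iterations = 4, k = 2,
                             replicates = 10, seed = 21)
  direct <- bootstrap_accuracy(wins, subset_size = 5, iterations = 4, k = 2,
                               replicates = 10,
                               seed = sleepstates:::subject_seed(21, 5))
  expect_equal(curve$mean_accuracy, direct$mean)
  expect_equal(curve$sd, direct$sd)
})

test_that("randomized-label curve is flat at chance across sizes", {
  wins <- small_wins()
  curve <- sample_size_curve(wins, sizes = c(4, 8), iterations = 10, k = 2,
                             randomize_labels = TRUE, replicates = 10,
                             seed = 22)
  expect_true(all(abs(curve$mean_accuracy - 0.5) < 0.1))
})

test_that("histogram mode locates the fullest bin", {
  x <- c(rep(0.51, 10), rep(0.9, 3), 0.1)
  expect_equal(histogram_mode(x), 0.525)
  expect_equal(histogram_mode(rep(1, 5)), 0.975)
  expect_equal(histogram_mode(rep(0, 5)), 0.025)
})
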