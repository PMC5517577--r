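test_that("occurrence profiles are normalized per bin", {
  ## all subjects always W
  p <- occurrence_profile(list(rep("W", 10), rep("W", 10)),
                          levels = c("W", "S"))
  expect_true(all(p["W", ] == 1))
  expect_true(all(p["S", ] == 0))
  ## one subject alternating
  p2 <- occurrence_profile(list(rep(c("A", "B"), 5)))
  expect_equal(unname(p2["A", ]), rep(c(1, 0), 5))
  ## synthetic cohort: columns sum to one at every bin
  wins <- small_wins()
  labs <- lapply(wins, `[[`, "stage")
  p3 <- occurrence_profile(labs, levels = c("W", "N1", "N2", "N3"))
  expect_equal(unname(colSums(p3)), rep(1, ncol(p3)), tolerance = 1e-9)
  ## ragged subjects: empty trailing bins dropped with a warning
  expect_warning(occurrence_profile(list(rep("W", 3), rep("W", 5))), NA)
})

test_that("profile matching recovers a known permutation (exhaustive oracle)", {
  set.seed(30)
  for (k in 2:5) {
    stage_profiles <- matrix(runif(k * 40), k, 40,
                             dimnames = list(paste0("S", 1:k), NULL))
    perm <- sample(k)
    cluster_profiles <- stage_profiles[perm, ] +
      matrix(rnorm(k * 40, 0, 0.01), k, 40)
    m <- match_by_profile(cluster_profiles, stage_profiles)
    expect_equal(unname(m$map), paste0("S", perm))
    ## identity case: all diagonal correlations 1
    mi <- match_by_profile(stage_profiles, stage_profiles)
    expect_equal(unname(mi$map), paste0("S", 1:k))
    expect_equal(unname(diag(mi$similarity)), rep(1, k))
  }
})

test_that("the returned bijection attains the exhaustive-enumeration optimum", {
  ## independent enumeration over all k! bijections on random profile sets;
  ## also exhibits a case where greedy row-wise assignment is strictly worse
  set.seed(31)
  greedy_beaten <- FALSE
  for (rep in 1:20) {
    k <- sample(2:5, 1)
    cp <- matrix(runif(k * 30), k, 30)
    sp <- matrix(runif(k * 30), k, 30,
                 dimnames = list(paste0("S", 1:k), NULL))
    m <- match_by_profile(cp, sp)
    totals <- vapply(combinat_perms(k), function(p) {
      sum(m$similarity[cbind(1:k, p)])
    }, numeric(1))
    chosen <- sum(m$similarity[cbind(1:k, match(unname(m$map),
                                                paste0("S", 1:k)))])
    expect_equal(chosen, max(totals), tolerance = 1e-12)
    ## greedy: rows in order take their best remaining column
    taken <- integer(0); g <- 0
    for (i in 1:k) {
      avail <- setdiff(1:k, taken)
      j <- avail[which.max(m$similarity[i, avail])]
      taken <- c(taken, j); g <- g + m$similarity[i, j]
    }
    expect_lte(g, chosen + 1e-12)
    if (g < chosen - 1e-9) greedy_beaten <- TRUE
  }
  expect_true(greedy_beaten)
})

test_that("matrix-similarity matching recovers a permutation and shows a
           dominant diagonal on a planted cohort", {
  set.seed(32)
  mats <- lapply(1:4, function(i) {
    correlation_matrix(matrix(rnorm(60 * 8), 60, 8))
  })
  names(mats) <- c("W", "N1", "N2", "N3")
  perm <- c(3, 1, 4, 2)
  m <- match_by_matrix_similarity(mats[perm], mats)
  expect_equal(unname(m$map), names(mats)[perm])
  mi <- match_by_matrix_similarity(mats, mats)
  expect_equal(unname(diag(mi$similarity)), rep(1, 4))

  ## planted two-state cohort: after matching, state-stage similarity is
  ## highest on the diagonal
  wins <- small_wins()
  X <- do.call(rbind, lapply(wins, function(w) w$vectors))
  truth <- collapse_stages(unlist(lapply(wins, `[[`, "stage")), k = 2)
  model <- cluster_states(X, 2, replicates = 20, seed = 6)
  state_mats <- lapply(1:2, function(j) state_mean_matrix(model, j, X))
  stage_mats <- lapply(c(W = "W", S = "S"), function(s) {
    devectorize(colMeans(X[truth == s, , drop = FALSE]))
  })
  mm <- match_by_matrix_similarity(state_mats, stage_mats)
  sim <- mm$similarity
  ord <- match(unname(mm$map), colnames(sim))
  matched <- sim[, ord, drop = FALSE]
  expect_true(all(diag(matched) > matched[row(matched) != col(matched)]))
})

test_that("matching is invariant to cluster relabeling", {
  set.seed(33)
  sp <- matrix(runif(3 * 25), 3, 25, dimnames = list(c("W", "N1", "N2"), NULL))
  cp <- sp + matrix(rnorm(3 * 25, 0, 0.05), 3, 25)
  m1 <- match_by_profile(cp, sp)
  shuffle <- c(2, 3, 1)
  m2 <- match_by_profile(cp[shuffle, ], sp)
  expect_equal(unname(m2$map), unname(m1$map)[shuffle])
})

test_that("the wake heuristic picks the declining state", {
  B <- 30
  dec <- seq(1, 0, length.out = B)
  inc <- 1 - dec
  expect_equal(identify_wake_heuristic(rbind(inc, dec)), 2)
  ## flat profiles: tie resolves to the lowest cluster id
  expect_message(tie <- identify_wake_heuristic(rbind(rep(0.5, B),
                                                      rep(0.5, B))), "tie")
  expect_equal(tie, 1)
  expect_error(identify_wake_heuristic(rbind(dec)), "2 clusters")
})

test_that("the wake heuristic agrees with profile matching on a sleep cohort", {
  res <- run_pipeline(small_cohort(), pipeline_config(k = 2, replicates = 20,
                                                      seed = 2))
  wake_by_matching <- which(unname(res$matching_profile$map) == "W")
  expect_equal(res$wake_cluster, wake_by_matching)
  expect_equal(unname(res$matching_matrix$map),
               unname(res$matching_profile$map))
})
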