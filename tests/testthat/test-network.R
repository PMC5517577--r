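test_that("signed modularity matches an independent term-by-term oracle", {
  set.seed(50)
  for (trial in 1:10) {
    n <- sample(4:8, 1)
    w <- random_signed_net(n)
    for (rep in 1:8) {
      part <- sample(1:3, n, replace = TRUE)
      expect_equal(signed_modularity(w, part), q_oracle(w, part),
                   tolerance = 1e-12)
    }
  }
})

test_that("canonical modularity values", {
  w <- matrix(0, 8, 8)
  w[1:4, 1:4] <- 1
  w[5:8, 5:8] <- 1
  diag(w) <- 0
  expect_equal(signed_modularity(w, rep(1:2, each = 4)), 0.5)
  expect_equal(signed_modularity(w, rep(1, 8)), 0)
  expect_warning(q0 <- signed_modularity(matrix(0, 4, 4), rep(1, 4)),
                 "all-zero")
  expect_equal(q0, 0)
  expect_error(signed_modularity(matrix(rnorm(16), 4, 4), rep(1, 4)),
               "symmetric")
  expect_error(signed_modularity(w, rep(1, 7)), "every node")
})

test_that("Louvain recovers components and attains the exhaustive optimum", {
  w <- matrix(0, 8, 8)
  w[1:4, 1:4] <- 1
  w[5:8, 5:8] <- 1
  diag(w) <- 0
  res <- louvain_maximize(w, iterations = 20, seed = 1)
  expect_equal(res$q, 0.5)
  expect_equal(length(unique(res$partition)), 2)
  expect_true(all(res$partition[1:4] == res$partition[1]))
  ## complete graph: no partition beats the trivial one
  wc <- matrix(1, 6, 6); diag(wc) <- 0
  expect_lt(abs(louvain_maximize(wc, iterations = 20, seed = 1)$q), 1e-12)
  ## reproducibility
  set.seed(51)
  ws <- modular_signed_net(8)
  r1 <- louvain_maximize(ws, iterations = 30, seed = 2)
  r2 <- louvain_maximize(ws, iterations = 30, seed = 2)
  expect_identical(r1, r2)
  ## best-of-30 matches brute force over all partitions on modular nets
  parts <- all_partitions(7)
  for (trial in 1:5) {
    wm <- modular_signed_net(7)
    qmax <- max(vapply(parts, function(p) signed_modularity(wm, p),
                       numeric(1)))
    expect_equal(louvain_maximize(wm, iterations = 30, seed = trial)$q, qmax,
                 tolerance = 1e-10)
  }
})

test_that("node strength is the row sum of weights", {
  star <- matrix(0, 5, 5)
  star[1, 2:5] <- 1
  star[2:5, 1] <- 1
  expect_equal(node_strength(star), c(4, 1, 1, 1, 1))
  set.seed(52)
  w <- random_signed_net(7)
  expect_equal(node_strength(w), rowSums(w))
  expect_equal(node_strength(matrix(0, 4, 4)), rep(0, 4))
})

test_that("structural aggregation sums weights between regions", {
  ## 4 nodes -> 2 regions with known edges
  w <- matrix(0, 4, 4)
  w[1, 2] <- w[2, 1] <- 1    # within region a
  w[1, 3] <- w[3, 1] <- 2    # a-b
  w[2, 4] <- w[4, 2] <- 3    # a-b
  w[3, 4] <- w[4, 3] <- 4    # within region b
  agg <- aggregate_structural(w, c("a", "a", "b", "b"))
  expect_equal(agg["a", "b"], 5)
  expect_equal(unname(diag(agg)), c(0, 0))
  ## permuting node order leaves the result unchanged
  perm <- c(3, 1, 4, 2)
  agg2 <- aggregate_structural(w[perm, perm], c("a", "a", "b", "b")[perm])
  expect_equal(agg2, agg)
  ## one node per region reproduces the matrix (off-diagonal)
  ident <- aggregate_structural(w, c("n1", "n2", "n3", "n4"))
  expect_equal(unname(ident), w * (1 - diag(4)))
  expect_error(aggregate_structural(w, c("a", "a", NA, "b")), "unmapped")
})

test_that("structure-function coupling on a common subset", {
  set.seed(53)
  sc <- make_structural_template(12, seed = 9)
  S <- structural_to_correlation(sc)
  expect_equal(sc_fc_correlation(S, S), 1)
  expect_equal(sc_fc_correlation(S, S, subset = 3:10), 1)
  ## independent random matrices decorrelate
  a <- correlation_matrix(matrix(rnorm(500 * 90), 500, 90))
  b <- correlation_matrix(matrix(rnorm(500 * 90), 500, 90))
  expect_lt(abs(sc_fc_correlation(a, b)), 0.1)
  expect_error(sc_fc_correlation(S, S, subset = 1:2), "subset")
})

test_that("stage contrasts detect a planted global connectivity drop", {
  set.seed(54)
  R <- 10
  base <- correlation_matrix(matrix(rnorm(400 * R), 400, R))
  sm <- lapply(1:20, function(i) {
    noise_a <- devectorize(rnorm(R * (R - 1) / 2, 0, 0.02), diag_value = 0)
    noise_b <- devectorize(rnorm(R * (R - 1) / 2, 0, 0.02), diag_value = 0)
    list(W = base + noise_a, N3 = base - 0.2 + noise_b)
  })
  con <- stage_contrast(sm, "W", "N3")
  off <- upper.tri(con$diff)
  expect_true(all(con$significant[off]))
  expect_equal(mean(con$diff[off]), 0.2, tolerance = 0.01)
  ## A = B: nothing significant
  sm_eq <- lapply(sm, function(m) list(W = m$W, N3 = m$W))
  con0 <- stage_contrast(sm_eq, "W", "N3")
  expect_true(all(con0$diff[off] == 0))
  expect_false(any(con0$significant[off]))
})

test_that("contrast p-values are Benjamini-Hochberg adjusted", {
  set.seed(55)
  R <- 4
  ## plant a strong effect on one edge only, noise elsewhere
  sm <- lapply(1:12, function(i) {
    a <- devectorize(rnorm(6, 0, 0.05), diag_value = 0)
    b <- a
    b[1, 2] <- b[2, 1] <- a[1, 2] - 0.5 + rnorm(1, 0, 0.03)
    list(W = a, N1 = b)
  })
  con <- stage_contrast(sm, "W", "N1")
  p <- vectorize_upper(con$p)
  ## hand-computed BH: sorted p, compare to i/m * alpha, reject up to the
  ## largest passing index
  m <- length(p)
  o <- order(p)
  passing <- which(p[o] <= (seq_len(m) / m) * 0.05)
  rejected <- logical(m)
  if (length(passing) > 0) rejected[o[seq_len(max(passing))]] <- TRUE
  expect_equal(vectorize_upper(con$significant) > 0, rejected)
  expect_true(con$significant[1, 2])
})

test_that("RSN block aggregation reports means and significant-edge counts", {
  set.seed(56)
  R <- 8
  rsn <- rep(c("DMN", "VIS"), each = 4)
  sm <- lapply(1:10, function(i) {
    a <- devectorize(rnorm(R * (R - 1) / 2, 0.3, 0.02), diag_value = 0)
    b <- devectorize(vectorize_upper(a) + rnorm(R * (R - 1) / 2, 0, 0.02),
                     diag_value = 0)
    ## lower within-DMN connectivity in N2
    b[1:4, 1:4] <- b[1:4, 1:4] - 0.3
    diag(b) <- 0
    list(W = a, N2 = b)
  })
  con <- stage_contrast(sm, "W", "N2", rsn = rsn)
  blk <- con$blocks
  expect_setequal(blk$block, c("DMN-DMN", "DMN-VIS", "VIS-VIS"))
  expect_equal(blk$mean_diff[blk$block == "DMN-DMN"], 0.3, tolerance = 0.02)
  expect_equal(blk$n_significant[blk$block == "DMN-DMN"], 6)
  expect_equal(blk$n_significant[blk$block == "VIS-VIS"], 0)
  expect_equal(sum(blk$n_edges), R * (R - 1) / 2)
  ## participants missing a stage are excluded with a message
  sm2 <- c(sm, list(list(W = sm[[1]]$W)))
  expect_message(stage_contrast(sm2, "W", "N2"), "excluded")
})
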