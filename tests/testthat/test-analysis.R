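test_that("the similarity statistic matches hand-computed cosines", {
  a <- matrix(c(1, 1, 0, 0), 4, 1)
  b <- matrix(c(1, 0, 1, 0), 4, 1)
  expect_equal(raster_similarity(a, b)$q, 0.5)         # cos = 1/(sqrt2*sqrt2)
  # corresponding rows with disjoint support
  a2 <- cbind(c(1, 1, 0, 0), c(1, 0, 0, 0))
  b2 <- cbind(c(0, 0, 1, 1), c(0, 1, 0, 0))
  expect_equal(raster_similarity(a2, b2)$q, 0)
  # one-sided silence counts as 0, mutual silence as 1
  expect_equal(raster_similarity(cbind(c(1, 1)), cbind(c(0, 0)))$q, 0)
  expect_equal(raster_similarity(cbind(c(0, 0)), cbind(c(0, 0)))$q, 1)
  # random pair against the per-row oracle
  set.seed(4)
  A <- matrix(rbinom(16, 1, 0.5), 4); B <- matrix(rbinom(16, 1, 0.5), 4)
  expect_equal(raster_similarity(A, B)$q, q_oracle(A, B))
  expect_equal(raster_similarity(A, B)$per_row_cosines,
               vapply(1:4, function(n) cosine_oracle(A[, n], B[, n]),
                      numeric(1)))
  expect_error(raster_similarity(A, matrix(0, 3, 4)), "shape")
})

test_that("q(a, a) is exactly 1 and q is symmetric and permutation-invariant", {
  set.seed(1)
  r <- matrix(rbinom(200, 1, 0.3), 20, 10)
  r[, 2] <- 0                                          # a silent neuron
  s <- raster_similarity(r, r)
  expect_identical(s$q, 1)
  expect_equal(s$n_zero_pairs, 1)
  set.seed(6)
  for (i in 1:5) {
    A <- matrix(rbinom(60, 1, 0.4), 10)
    B <- matrix(rbinom(60, 1, 0.4), 10)
    expect_equal(raster_similarity(A, B)$q, raster_similarity(B, A)$q)
    p <- sample(6)                                     # common neuron relabel
    expect_equal(raster_similarity(A[, p], B[, p])$q,
                 raster_similarity(A, B)$q)
  }
})

test_that("the shuffle null is seeded and matches the exhaustive oracle", {
  set.seed(8)
  A <- matrix(rbinom(24, 1, 0.5), 8, 3)
  ref <- matrix(rbinom(24, 1, 0.5), 8, 3)
  n1 <- shuffle_null(list(A), ref, n_shuffles = 200, seed = 4)
  n2 <- shuffle_null(list(A), ref, n_shuffles = 200, seed = 4)
  expect_identical(n1$changes, n2$changes)
  expect_identical(n1$threshold_value, n2$threshold_value)
  # exhaustive enumeration vs independent brute-force oracle
  nx <- shuffle_null(list(A), ref, percentile = 85, exhaustive = TRUE)
  ch <- vapply(perms_oracle(3L), function(p)
    q_oracle(A[, p, drop = FALSE], ref) - q_oracle(A, ref), numeric(1))
  expect_equal(sort(nx$changes), sort(ch))
  expect_equal(nx$threshold_value, sort(abs(ch))[ceiling(0.85 * length(ch))])
  expect_equal(q_oracle(A[, 1:3, drop = FALSE], ref) - q_oracle(A, ref),
               0)                                      # identity permutation
  # ECDF is a proper CDF and the threshold is monotone in the percentile
  expect_true(all(diff(nx$ecdf(seq(-1, 1, by = 0.05))) >= 0))
  th <- vapply(c(50, 70, 85, 95), function(p)
    shuffle_null(list(A), ref, 150, p, seed = 2)$threshold_value, numeric(1))
  expect_true(all(diff(th) >= 0))
  expect_error(shuffle_null(list(A), matrix(0, 4, 3), 200), "shape")
  expect_error(shuffle_null(list(A), ref, n_shuffles = 10), "100")
})

test_that("the similarity heatmap has a unit diagonal and per-pair values", {
  set.seed(9)
  mats <- list(a = matrix(rbinom(40, 1, 0.4), 10),
               b = matrix(rbinom(40, 1, 0.4), 10))
  sm <- similarity_heatmap(mats, baseline = mats$a)
  expect_equal(unname(diag(sm$q)), rep(1, 3))
  expect_equal(sm$q["a", "b"], raster_similarity(mats$a, mats$b)$q)
  expect_equal(sm$q["baseline", "a"], 1)
  expect_equal(sm$q, t(sm$q))
  sm2 <- similarity_heatmap(list(x = mats$a, y = mats$a))
  expect_true(all(sm2$q == 1))                         # identical rasters
  # null-based flagging
  nd <- shuffle_null(mats, mats$a, n_shuffles = 150, seed = 3)
  sm3 <- similarity_heatmap(mats, baseline = mats$a, null = nd)
  expect_equal(sm3$flagged, (1 - sm3$q) > nd$threshold_value)
})

test_that("energy trajectories re-derive the recorded energies", {
  M <- matrix(c(0, 0.5, 0.5, 0), 2); W <- c(0.3, 0.1)
  cfg <- network_config(N = 2, plastic_W = FALSE, plastic_M = FALSE)
  pat <- convolve_pattern(make_stimulus("chronic", 10, onset = 0),
                          make_kernel("gaussian", 10, list(mu = 3, sigma = 1)))
  tr <- run_simulation(pat, weight_set(M, W), cfg, init = c(0.2, -0.1),
                       seed = 1)
  et <- energy_trajectory(tr)
  expect_equal(et, tr$energy)
  # hand evaluation at every step (hopfield convention, frozen weights)
  hand <- vapply(1:10, function(t) {
    v <- tr$v_history[t, ]
    -tr$u[t] * sum(W * v) - 0.5 * 2 * M[1, 2] * v[1] * v[2]
  }, numeric(1))
  expect_equal(et, hand)
  # all-zero trace has zero energy; constant state gives constant energy
  trz <- run_simulation(null_pattern(5),
                        weight_set(matrix(0, 2, 2), numeric(2)), cfg,
                        seed = 1)
  expect_equal(energy_trajectory(trz), numeric(5))
  # plastic M without snapshots cannot be re-derived
  cfg2 <- network_config(N = 2)
  tr2 <- run_simulation(pat, weight_set(M, W), cfg2, seed = 1, record_M = 0)
  expect_error(energy_trajectory(tr2), "insufficient")
  # with snapshots, plastic runs re-derive too
  tr3 <- run_simulation(pat, weight_set(M, W), cfg2, seed = 1, record_M = 1)
  expect_equal(energy_trajectory(tr3), tr3$energy)
})
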