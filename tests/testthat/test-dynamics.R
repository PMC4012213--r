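test_that("the three derivative operations match hand evaluation", {
  # rate dynamics
  expect_equal(rate_derivative(numeric(3), matrix(0, 3, 3), numeric(3), 0),
               numeric(3))
  v0 <- c(1.2, -0.4)
  expect_equal(rate_derivative(v0, matrix(0, 2, 2), c(0, 0), 0, tau_v = 2),
               -v0 / 2)
  expect_equal(rate_derivative(c(1, 0), diag(2), c(1, 1), 1, tau_v = 1),
               c(tanh(1), 1))
  expect_error(rate_derivative(c(NaN, 0), diag(2), c(0, 0), 0), "finite")
  # feedforward (Rescorla-Wagner): zero when r = v and when K = 0
  expect_equal(feedforward_derivative(c(0.3, 0.7), diag(2), u = 1, r = 0.5,
                                      v = c(0.5, 0.5), tau_W = 1),
               c(0, 0))
  expect_equal(feedforward_derivative(c(1, 1), matrix(0, 2, 2), u = 1, r = 2,
                                      v = c(0, 0), tau_W = 1),
               c(0, 0))
  expect_equal(feedforward_derivative(c(1, 1), diag(2), u = 1, r = 0.5,
                                      v = c(0, 0), tau_W = 1, epsilon = 1),
               c(0.5, 0.5))
  # recurrent (Goodall): decay to identity; outer-product term
  expect_equal(recurrent_derivative(diag(2), c(1, 0), 0, c(0, 1), tau_M = 1),
               matrix(0, 2, 2))
  M0 <- matrix(c(0.2, 0.1, 0.4, 0.3), 2)
  expect_equal(recurrent_derivative(M0, c(1, 1), 0, c(1, 1), tau_M = 5),
               (diag(2) - M0) / 5)
  expect_equal(recurrent_derivative(diag(2), c(1, 0), 1, c(0, 1), tau_M = 1),
               matrix(c(0, 0, -1, 0), 2))
  expect_error(feedforward_derivative(c(1, 1), diag(3), 1, 1, c(0, 0), 1),
               "shape")
})

test_that("one Euler step composes the derivatives and respects switches", {
  cfg <- network_config(N = 2, tau_v = 1, tau_W = 20, tau_M = 200,
                        epsilon = 0.5, dt = 0.05)
  M0 <- matrix(c(0, 0.3, 0.3, 0), 2)
  W0 <- c(0.2, 0.4)
  v0 <- c(0.5, -0.2)
  u <- 1; r <- 0.7
  out <- step_network(list(v = v0, t = 0), weight_set(M0, W0), u, r, cfg)
  # oracle: plain-arithmetic Euler combination of the three derivatives
  dv <- -v0 + as.vector(M0 %*% tanh(v0)) + W0 * u
  dW <- 0.5 * (as.vector((diag(2) - M0) %*% W0) * u) * (r - v0) / 20
  dM <- (diag(2) - M0 - outer(W0 * u, v0)) / 200
  expect_equal(out$state$v, v0 + 0.05 * dv)
  expect_equal(out$weights$W, W0 + 0.05 * dW)
  expect_equal(out$weights$M, M0 + 0.05 * dM)
  expect_equal(out$weights$K, diag(2) - out$weights$M)
  expect_equal(out$state$t, 0.05)
  # frozen weights are bit-identical
  cfg2 <- network_config(N = 2, plastic_W = FALSE, plastic_M = FALSE,
                         dt = 0.05)
  out2 <- step_network(list(v = v0, t = 0), weight_set(M0, W0), u, r, cfg2)
  expect_identical(out2$weights$W, W0)
  expect_identical(out2$weights$M, M0)
  # the all-zero configuration leaves the state unchanged
  outz <- step_network(list(v = numeric(2), t = 0),
                       weight_set(matrix(0, 2, 2), numeric(2)), 0, 0, cfg)
  expect_equal(outz$state$v, numeric(2))
  # divergence guard names the time
  cfg3 <- network_config(N = 2, v_max = 0.01, dt = 0.05)
  expect_error(step_network(list(v = c(5, 5), t = 0),
                            weight_set(matrix(0, 2, 2), numeric(2)), 0, 0,
                            cfg3),
               "instability")
})

test_that("null simulations give zero rates and fair-coin spikes, reproducibly", {
  cfg <- network_config(N = 6, plastic_W = FALSE, plastic_M = FALSE)
  w <- weight_set(matrix(0, 6, 6), numeric(6))
  tr <- run_simulation(null_pattern(60), w, cfg, seed = 9)
  expect_true(all(tr$v_history == 0))
  expect_true(all(tr$raster %in% 0:1))
  expect_equal(mean(tr$raster), 0.5, tolerance = 0.1)   # P = logistic(0)
  tr2 <- run_simulation(null_pattern(60), w, cfg, seed = 9)
  expect_identical(tr$raster, tr2$raster)
  expect_identical(tr$v_history, tr2$v_history)
  tr3 <- run_simulation(null_pattern(60), w, cfg, seed = 10)
  expect_false(identical(tr$raster, tr3$raster))
})

test_that("a frozen network initialized on an embedded memory retains it", {
  set.seed(21)
  mem <- random_memory_set(1, 8, 0.25)
  rm_ <- embed_memories(mem)
  # oracle: the pattern is a local energy minimum by exhaustive single flips
  p <- mem$patterns[1, ]
  e0 <- energy_oracle(rm_$M, numeric(8), 0, p)
  for (i in 1:8) {
    q <- p; q[i] <- 1 - q[i]
    expect_gte(energy_oracle(rm_$M, numeric(8), 0, q), e0)
  }
  cfg <- network_config(N = 8, plastic_W = FALSE, plastic_M = FALSE)
  tr <- run_simulation(null_pattern(60), weight_set(rm_, numeric(8)), cfg,
                       init = p, seed = 2)
  on <- p == 1
  expect_true(all(tr$v_history[60, on] > 0.5))
  expect_true(all(tr$v_history[60, !on] < 0))
})

test_that("Rescorla-Wagner learning drives the prediction toward the reward", {
  # K = I (M frozen at 0), u = 1, constant r: v converges to r
  T <- 400
  cfg <- network_config(N = 3, tau_W = 5, epsilon = 1, plastic_M = FALSE,
                        w0 = 0.05)
  pat <- convolve_pattern(rep(1, T), c(1, numeric(T - 1)))  # u = 1, r = 1
  tr <- run_simulation(pat, weight_set(matrix(0, 3, 3), rep(0.05, 3)), cfg,
                       seed = 1)
  err <- abs(1 - tr$v_history[, 1])
  expect_lt(min(which(err < 1e-3)), 50 * cfg$tau_W)
  expect_lt(err[T], 1e-3)
})

test_that("with no input the recurrent matrix relaxes to the identity", {
  set.seed(17)
  M0 <- matrix(rnorm(16, 0, 0.5), 4); M0 <- (M0 + t(M0)) / 2
  cfg <- network_config(N = 4, tau_M = 10, plastic_W = FALSE)
  tr <- run_simulation(null_pattern(30), weight_set(M0, numeric(4)), cfg,
                       seed = 1)
  nrm0 <- norm(M0 - diag(4), "F")
  for (tt in c(10, 30)) {                  # t = tau_M and 3 tau_M
    Mt <- tr$M_snapshots[[match(tt, tr$M_times)]]
    expect_equal(norm(Mt - diag(4), "F"), nrm0 * exp(-tt / 10),
                 tolerance = 0.05)
  }
})

test_that("halving the Euler step changes the endpoint at first order", {
  # contractive system (spectral radius < 1): a single smooth trajectory
  set.seed(19)
  M0 <- matrix(rnorm(25, 0, 0.15), 5); M0 <- (M0 + t(M0)) / 2; diag(M0) <- 0
  W0 <- runif(5)
  v0 <- runif(5)
  pat <- make_condition_grid(T = 50)$chronic_resilient
  final_v <- function(dt) {
    cfg <- network_config(N = 5, dt = dt, plastic_W = FALSE,
                          plastic_M = FALSE)
    # measure on the transient: by the end of the run the contraction has
    # collapsed all step sizes onto the same fixed point
    run_simulation(pat, weight_set(M0, W0), cfg, init = v0,
                   seed = 1)$v_history[5, ]
  }
  va <- final_v(0.1)
  vb <- final_v(0.05)
  vc <- final_v(0.025)
  e1 <- sqrt(sum((va - vb)^2))
  e2 <- sqrt(sum((vb - vc)^2))
  expect_gt(e1 / e2, 1.5)                  # first-order: halving dt halves error
  expect_lt(e1 / e2, 3)
})

test_that("configuration invariants are enforced", {
  expect_error(network_config(dt = 0.5), "dt")
  expect_error(network_config(tau_W = -1), "tau_W")
  cfg <- network_config()
  expect_lte(cfg$dt, min(cfg$tau_v, cfg$tau_W, cfg$tau_M) / 10)
})
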