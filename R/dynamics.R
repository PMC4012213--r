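#' Network and plasticity configuration
#'
#' Time constants are in units of the discrete stimulus time step.  The
#' integration step `dt` defaults to `0.1 * min(tau_v, tau_W, tau_M)`,
#' capped at 0.1 so that an integer number of Euler steps tiles each
#' stimulus step.
#'
#' @param N number of units.
#' @param tau_v rate time constant.
#' @param tau_W feedforward (Rescorla-Wagner) plasticity time constant.
#' @param tau_M recurrent (Goodall) plasticity time constant.  The default
#'   equals the protocol length (200 steps) so that structural memory
#'   persists across a 200-step protocol rather than autonomously
#'   dissolving mid-run.
#' @param epsilon associability: learning-rate multiplier on the
#'   reward-prediction-error term.  The default (0.02) makes the total
#'   feedforward weight change over a 200-step protocol order one relative
#'   to the initial weights, so reward learning perturbs the embedded
#'   attractor without overwhelming it (the update is stiff: its linear
#'   growth rate scales with `||I - M|| * |r - v| / tau_W`).
#' @param dt Euler integration step; must satisfy `dt <= min(tau) / 10`.
#' @param w0 initial feedforward weight given to every unit.
#' @param plastic_W,plastic_M switches freezing the corresponding matrix.
#' @param v_max divergence guard: abort when `max(abs(v))` exceeds this.
#' @param flip_fraction fraction of entries flipped when building the
#'   initial condition from an embedded pattern ("within the basin").
#' @param sign_convention energy sign convention used for recorded energies.
#' @return object of class `network_config` (a validated list).
#' @export
network_config <- function(N = 64L, tau_v = 1, tau_W = 20, tau_M = 200,
                           epsilon = 0.02, dt = NULL, w0 = 0.01,
                           plastic_W = TRUE, plastic_M = TRUE,
                           v_max = 1e3, flip_fraction = 0.05,
                           sign_convention = c("hopfield", "as_printed")) {
  if (is.null(dt)) dt <- min(0.1, 0.1 * min(tau_v, tau_W, tau_M))
  cfg <- list(N = as.integer(N), tau_v = tau_v, tau_W = tau_W, tau_M = tau_M,
              epsilon = epsilon, dt = dt, w0 = w0,
              plastic_W = plastic_W, plastic_M = plastic_M,
              v_max = v_max, flip_fraction = flip_fraction,
              sign_convention = match.arg(sign_convention))
  bad <- validate_network_config(cfg)
  if (length(bad)) stop(paste(bad, collapse = "; "), call. = FALSE)
  structure(cfg, class = "network_config")
}

validate_network_config <- function(cfg) {
  f <- character()
  if (cfg$N < 1) f <- c(f, "N must be >= 1")
  for (nm in c("tau_v", "tau_W", "tau_M"))
    if (cfg[[nm]] <= 0) f <- c(f, paste(nm, "must be > 0"))
  if (cfg$dt <= 0) f <- c(f, "dt must be > 0")
  else if (cfg$dt > min(cfg$tau_v, cfg$tau_W, cfg$tau_M) / 10)
    f <- c(f, "dt must satisfy dt <= min(tau)/10")
  if (cfg$epsilon < 0) f <- c(f, "epsilon must be >= 0")
  if (cfg$v_max <= 0) f <- c(f, "v_max must be > 0")
  if (cfg$flip_fraction < 0 || cfg$flip_fraction >= 1)
    f <- c(f, "flip_fraction must lie in [0, 1)")
  f
}

#' Bundle the recurrent, feedforward and gating matrices
#'
#' The gating matrix `K` is defined as `I - M` and is recomputed whenever
#' `M` changes: when the network becomes autonomous (`M = I`) the gate
#' closes (`K = 0`) and reward learning stops.
#'
#' @param M N x N recurrent matrix (or `recurrent_matrix`).
#' @param W length-N feedforward weight vector.
#' @return object of class `weight_set` with fields `M`, `W`, `K`, `N`.
#' @export
weight_set <- function(M, W) {
  M <- as_M(M)
  W <- as.numeric(W)
  N <- nrow(M)
  if (ncol(M) != N || length(W) != N)
    stop("shape error: M must be N x N and W length N", call. = FALSE)
  structure(list(M = M, W = W, K = diag(N) - M, N = N), class = "weight_set")
}

#' Rate dynamics derivative
#'
#' `dv/dt = (-v + M tanh(v) + W u) / tau_v`: leaky rate dynamics with
#' saturating recurrence and feedforward drive by the scalar stimulus.
#'
#' @param v rate vector.
#' @param M recurrent matrix.
#' @param W feedforward weights (length N).
#' @param u scalar stimulus.
#' @param tau_v time constant.
#' @return derivative vector.
#' @export
rate_derivative <- function(v, M, W, u, tau_v = 1) {
  if (any(!is.finite(v)))
    stop("numerical-state error: non-finite rates", call. = FALSE)
  (-v + as.vector(as_M(M) %*% tanh(v)) + as.numeric(W) * u) / tau_v
}

#' Reward-modulated feedforward plasticity derivative
#'
#' Rescorla-Wagner rule gated by `K = I - M`:
#' `dW/dt = epsilon * (K W u) * (r - v) / tau_W`, where `K W u` is an
#' N-vector and the scalar reward `r` is broadcast against the rate vector
#' `v` elementwise.  The update vanishes when the network predicts the
#' reward exactly (`r = v`) or is autonomous (`K = 0`).
#'
#' @param W feedforward weights (length N).
#' @param K gating matrix `I - M`.
#' @param u scalar stimulus.
#' @param r scalar reward.
#' @param v rate vector.
#' @param tau_W time constant.
#' @param epsilon associability (learning-rate multiplier).
#' @return derivative vector (length N).
#' @export
feedforward_derivative <- function(W, K, u, r, v, tau_W = 20, epsilon = 1) {
  W <- as.numeric(W)
  if (nrow(K) != length(W) || length(v) != length(W))
    stop("shape error in feedforward_derivative", call. = FALSE)
  epsilon * (as.vector(K %*% W) * u) * (r - v) / tau_W
}

#' Anti-Hebbian recurrent plasticity derivative (Goodall rule)
#'
#' `dM/dt = ((I - M) - (W u) v') / tau_M`: the recurrent matrix relaxes
#' toward the identity while the outer product of the filtered input and
#' the network activity removes input-driven pairwise correlations.
#'
#' @param M recurrent matrix.
#' @param W feedforward weights.
#' @param u scalar stimulus.
#' @param v rate vector.
#' @param tau_M time constant.
#' @return derivative matrix (N x N).
#' @export
recurrent_derivative <- function(M, W, u, v, tau_M = 200) {
  M <- as_M(M)
  N <- nrow(M)
  if (length(W) != N || length(v) != N)
    stop("shape error in recurrent_derivative", call. = FALSE)
  (diag(N) - M - tcrossprod(as.numeric(W) * u, v)) / tau_M
}

#' One forward-Euler step of the coupled system
#'
#' Advances `v`, `W` and `M` simultaneously (all derivatives evaluated at
#' the current state), recomputes `K = I - M`, and respects the
#' `plastic_W` / `plastic_M` switches.
#'
#' @param state list with `v` (rates) and `t` (time).
#' @param weights a `weight_set`.
#' @param u scalar stimulus at this step.
#' @param r scalar reward at this step.
#' @param config a `network_config`.
#' @return list `(state, weights)` after one step of size `config$dt`.
#' @export
step_network <- function(state, weights, u, r, config) {
  dt <- config$dt
  v <- state$v
  dv <- rate_derivative(v, weights$M, weights$W, u, config$tau_v)
  v2 <- v + dt * dv
  if (max(abs(v2)) > config$v_max)
    stop(sprintf("instability: |v| exceeded %g at time %.3f",
                 config$v_max, state$t + dt), call. = FALSE)
  W2 <- weights$W
  M2 <- weights$M
  if (config$plastic_W)
    W2 <- W2 + dt * feedforward_derivative(weights$W, weights$K, u, r, v,
                                           config$tau_W, config$epsilon)
  if (config$plastic_M)
    M2 <- M2 + dt * recurrent_derivative(weights$M, weights$W, u, v,
                                         config$tau_M)
  w2 <- if (config$plastic_M) weight_set(M2, W2)
        else structure(list(M = M2, W = W2, K = weights$K, N = weights$N),
                       class = "weight_set")
  list(state = list(v = v2, t = state$t + dt), weights = w2)
}

#' Simulate the network over a stimulus-reward pattern
#'
#' Integrates the coupled rate/plasticity system with forward Euler,
#' holding `u(t)` and `r(t)` constant within each stimulus step
#' (zero-order hold, `1/dt` Euler sub-steps per step).  After each stimulus
#' step the rate vector is recorded, a binary spike vector is sampled with
#' per-unit probability [spike_probability()] (the logistic of the rate
#' itself; spikes are a read-out and do not feed back into the dynamics),
#' and the state energy is recorded under the configured sign convention.
#'
#' @param pattern a `stimulus_reward_pattern` (see [convolve_pattern()],
#'   [null_pattern()]).
#' @param weights initial `weight_set`.
#' @param config a `network_config`.
#' @param init initial rate vector (default all zero).
#' @param seed RNG seed for spike sampling.
#' @param record_M record the recurrent matrix every `record_M` stimulus
#'   steps (0 disables snapshots; 1 keeps all).
#' @return object of class `simulation_trace`: `times` (1..T stimulus
#'   steps), `v_history` and `raster` (T x N), `energy` (length T),
#'   `W_history` (T x N), `M_snapshots` + `M_times`, the input `u`, `r`,
#'   labels, `config`, `seed`, and the final `state`/`weights`.
#' @export
run_simulation <- function(pattern, weights, config = network_config(),
                           init = NULL, seed = 1L, record_M = 1L) {
  stim <- pattern$stimulus$values
  rew <- pattern$reward
  T <- length(stim)
  N <- weights$N
  if (is.null(init)) init <- numeric(N)
  if (length(init) != N)
    stop("shape error: init length ", length(init), " != N = ", N,
         call. = FALSE)
  set.seed(seed)
  n_sub <- max(1L, round(1 / config$dt))
  state <- list(v = as.numeric(init), t = 0)
  v_hist <- matrix(NA_real_, T, N)
  raster <- matrix(NA_integer_, T, N)
  W_hist <- matrix(NA_real_, T, N)
  energy <- numeric(T)
  M_snapshots <- list()
  M_times <- integer()
  for (tt in seq_len(T)) {
    u <- stim[tt]
    r <- rew[tt]
    for (k in seq_len(n_sub)) {
      stepped <- step_network(state, weights, u, r, config)
      state <- stepped$state
      weights <- stepped$weights
    }
    v_hist[tt, ] <- state$v
    raster[tt, ] <- as.integer(stats::runif(N) < spike_probability(state$v))
    W_hist[tt, ] <- weights$W
    energy[tt] <- network_energy(
      energy_model(weights$M, weights$W, u,
                   sign_convention = config$sign_convention), state$v)
    if (record_M > 0L && (tt %% record_M == 0L || tt == T)) {
      M_snapshots[[length(M_snapshots) + 1L]] <- weights$M
      M_times <- c(M_times, tt)
    }
  }
  structure(list(times = seq_len(T), v_history = v_hist, raster = raster,
                 energy = energy, W_history = W_hist,
                 M_snapshots = M_snapshots, M_times = M_times,
                 u = stim, r = rew,
                 usage = pattern$usage, susceptibility = pattern$susceptibility,
                 config = config, seed = seed,
                 final = list(state = state, weights = weights)),
            class = "simulation_trace")
}

#' Initial condition within the basin of an embedded pattern
#'
#' The binary pattern with a seeded random fraction of entries flipped,
#' used as the initial rate vector.
#'
#' @param pattern 0/1 vector.
#' @param flip_fraction fraction of entries to flip.
#' @return numeric vector.  Uses the current RNG state.
#' @export
perturbed_pattern <- function(pattern, flip_fraction = 0.05) {
  v <- as.numeric(pattern)
  n_flip <- round(flip_fraction * length(v))
  if (n_flip > 0) {
    idx <- sample.int(length(v), n_flip)
    v[idx] <- 1 - v[idx]
  }
  v
}

#' @export
print.simulation_trace <- function(x, ...) {
  cat("<simulation_trace>", x$usage, "/", x$susceptibility,
      " T:", length(x$times), " N:", ncol(x$raster),
      " spike rate:", format(mean(x$raster), digits = 3),
      " final energy:", format(x$energy[length(x$energy)], digits = 4), "\n")
  invisible(x)
}

#' @export
summary.simulation_trace <- function(object, ...) {
  cat("Simulation trace:", object$usage, "/", object$susceptibility, "\n")
  cat("  steps:", length(object$times), " units:", ncol(object$raster), "\n")
  cat("  mean rate:", format(mean(object$v_history), digits = 4),
      " mean spike prob:", format(mean(object$raster), digits = 4), "\n")
  cat("  energy range: [", format(min(object$energy), digits = 4), ", ",
      format(max(object$energy), digits = 4), "]\n", sep = "")
  invisible(object)
}

#' Raster plot of a simulation trace (raster, stimulus, reward panels)
#' @param x a `simulation_trace`.
#' @param ... passed to [graphics::image()].
#' @export
plot.simulation_trace <- function(x, ...) {
  op <- graphics::par(mfrow = c(3, 1), mar = c(2.5, 4, 1.5, 1))
  on.exit(graphics::par(op))
  graphics::image(x$times, seq_len(ncol(x$raster)), x$raster,
                  col = c("white", "black"), xlab = "", ylab = "neuron",
                  main = paste(x$usage, x$susceptibility, sep = " / "), ...)
  graphics::plot(x$times, x$u, type = "s", ylab = "stimulus", xlab = "")
  graphics::plot(x$times, x$r, type = "l", ylab = "reward", xlab = "time step")
  invisible(x)
}
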