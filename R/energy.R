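#' Glauber spike probability
#'
#' Probability that a unit with instantaneous rate `v` emits a spike in the
#' next step: the logistic `1 / (1 + exp(-v))`.  Strictly increasing, maps
#' 0 to 0.5, and saturates gracefully at +/- infinity.
#'
#' @param v numeric vector of rates.
#' @return probabilities in (0, 1).
#' @export
spike_probability <- function(v) {
  if (any(!is.finite(v) & !is.infinite(v)))
    stop("non-finite rate passed to spike_probability", call. = FALSE)
  stats::plogis(v)
}

#' Boltzmann energy model of the network
#'
#' Bundles the recurrent matrix `M`, the feedforward weights `W` and the
#' scalar stimulus `u` that define the energy of a network state.  Two sign
#' conventions for the quadratic term are supported:
#' \describe{
#'   \item{`as_printed`}{`E(v, u) = -u * sum(W v) + 1/2 v' M v`}
#'   \item{`hopfield`}{`E(v, u) = -u * sum(W v) - 1/2 v' M v` (default):
#'     states with high overlap with the embedded memories have low energy,
#'     which is the convention under which Glauber dynamics with the
#'     logistic acceptance has this Boltzmann distribution as its
#'     stationary law.}
#' }
#'
#' @param M N x N matrix (or `recurrent_matrix`).
#' @param W length-N feedforward weight vector (1-D stimulus).
#' @param u scalar stimulus value.
#' @param sign_convention `"hopfield"` (default) or `"as_printed"`.
#' @return object of class `energy_model`.
#' @export
energy_model <- function(M, W, u = 0,
                         sign_convention = c("hopfield", "as_printed")) {
  sign_convention <- match.arg(sign_convention)
  M <- as_M(M)
  W <- as.numeric(W)
  if (nrow(M) != ncol(M) || length(W) != nrow(M))
    stop("shape error: M must be N x N and W length N", call. = FALSE)
  structure(list(M = M, W = W, u = as.numeric(u)[1L],
                 N = nrow(M), sign_convention = sign_convention),
            class = "energy_model")
}

#' Energy of a network state
#'
#' @param model an `energy_model`.
#' @param v state vector of length N (binary or real-valued rates), or a
#'   matrix of states (one per row).
#' @return scalar energy (or vector, one per row of `v`).
#' @export
network_energy <- function(model, v) {
  sgn <- if (model$sign_convention == "as_printed") 0.5 else -0.5
  if (is.matrix(v)) {
    if (ncol(v) != model$N)
      stop("shape error: states must have N = ", model$N, " columns",
           call. = FALSE)
    quad <- rowSums((v %*% model$M) * v)
    lin <- as.vector(v %*% model$W)
  } else {
    if (length(v) != model$N)
      stop("shape error: state length ", length(v), " != N = ", model$N,
           call. = FALSE)
    quad <- as.numeric(crossprod(v, model$M %*% v))
    lin <- sum(model$W * v)
  }
  -model$u * lin + sgn * quad
}

#' Exact Boltzmann distribution over all binary states
#'
#' Enumerates all `2^N` binary states (integer bit order: state `i` has unit
#' `j` active iff bit `j` of `i - 1` is set), computes their energies and
#' the normalized Boltzmann probabilities `exp(-E) / Z`.
#'
#' @param model an `energy_model` with `N <= 20`.
#' @return object of class `state_distribution`: `energies`,
#'   `probabilities` (sum to 1), `Z`, `N`, `sign_convention`.
#' @export
exact_distribution <- function(model) {
  N <- model$N
  if (N > 20L)
    stop("enumeration too large: N = ", N, " exceeds the bound of 20",
         call. = FALSE)
  S <- all_binary_states(N)
  E <- network_energy(model, S)
  w <- exp(-(E - min(E)))                   # shifted for stability
  probabilities <- w / sum(w)
  structure(list(energies = E, probabilities = probabilities,
                 Z = sum(exp(-E)), N = N,
                 sign_convention = model$sign_convention),
            class = "state_distribution")
}

# all 2^N binary states, one per row, integer bit order
all_binary_states <- function(N) {
  S <- matrix(0L, 2^N, N)
  for (j in seq_len(N))
    S[, j] <- rep(rep(c(0L, 1L), each = 2^(j - 1L)), length.out = 2^N)
  S
}

#' @export
print.state_distribution <- function(x, ...) {
  cat("<state_distribution> N:", x$N, " states:", length(x$energies),
      " Z:", format(x$Z, digits = 6),
      " convention:", x$sign_convention, "\n")
  invisible(x)
}

#' Asynchronous Glauber sampling of binary network states
#'
#' Classical Boltzmann-machine dynamics: at each micro-step one unit `i` is
#' chosen uniformly at random and set to 1 with probability
#' `plogis(u W_i + s (sum_{j != i} M_ij v_j + M_ii / 2))` where `s = +1`
#' under the `hopfield` convention and `-1` under `as_printed`.  This is
#' the heat-bath rule for the model's energy, so for symmetric `M` the
#' chain satisfies detailed balance with respect to
#' [exact_distribution()].  One sweep is `N` micro-steps.
#'
#' @param model an `energy_model`.
#' @param v0 initial 0/1 state of length N.
#' @param sweeps number of sweeps after burn-in.
#' @param seed RNG seed (or `NULL` to use the current state).
#' @param record `"sweep"` records the state after each sweep; `"micro"`
#'   after every micro-step.
#' @param burn_in sweeps to discard before recording.
#' @return matrix of recorded states (one per row), with attributes
#'   `seed`, `sweeps`, `record`.
#' @export
glauber_sample <- function(model, v0, sweeps, seed = NULL,
                           record = c("sweep", "micro"), burn_in = 0L) {
  record <- match.arg(record)
  if (!is.null(seed)) set.seed(seed)
  N <- model$N
  v <- as.numeric(v0)
  if (length(v) != N)
    stop("shape error: v0 length ", length(v), " != N = ", N, call. = FALSE)
  if (sweeps < 1L) stop("sweeps must be >= 1", call. = FALSE)
  s <- if (model$sign_convention == "as_printed") -1 else 1
  bias <- model$u * model$W + s * 0.5 * diag(model$M)
  M0 <- model$M; diag(M0) <- 0              # off-diagonal field
  total <- (sweeps + burn_in) * N
  units <- sample.int(N, total, replace = TRUE)
  unifs <- stats::runif(total)
  n_rec <- if (record == "sweep") sweeps else sweeps * N
  out <- matrix(0L, n_rec, N)
  rec <- 0L
  skip <- burn_in * N
  for (step in seq_len(total)) {
    i <- units[step]
    h <- bias[i] + s * sum(M0[i, ] * v)
    v[i] <- as.numeric(unifs[step] < stats::plogis(h))
    if (step > skip) {
      if (record == "micro") {
        rec <- rec + 1L; out[rec, ] <- v
      } else if ((step - skip) %% N == 0L) {
        rec <- rec + 1L; out[rec, ] <- v
      }
    }
  }
  structure(out, seed = seed, sweeps = sweeps, record = record)
}

#' Empirical state frequencies of a chain of binary states
#'
#' Tabulates visited states in the same integer bit order used by
#' [exact_distribution()], so the two vectors are directly comparable.
#'
#' @param states matrix of 0/1 states, one per row (e.g. from
#'   [glauber_sample()]).
#' @return numeric vector of length `2^N` summing to 1.
#' @export
state_frequencies <- function(states) {
  states <- as.matrix(states)
  N <- ncol(states)
  idx <- as.vector(states %*% 2^(seq_len(N) - 1L)) + 1L
  tabulate(idx, nbins = 2^N) / nrow(states)
}
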