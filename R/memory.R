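#' A set of binary memory patterns
#'
#' @param patterns a P x N 0/1 matrix (one pattern per row), or a list of
#'   equal-length 0/1 vectors.
#' @param alpha sparseness (mean activity) used to centre the covariance
#'   rule; defaults to the empirical mean of `patterns`.  Must lie in (0,1).
#' @return object of class `memory_set` with fields `patterns` (matrix),
#'   `alpha`, `count`, `N`.
#' @export
memory_set <- function(patterns, alpha = NULL) {
  if (is.list(patterns)) patterns <- do.call(rbind, patterns)
  patterns <- as.matrix(patterns)
  if (nrow(patterns) < 1L || ncol(patterns) < 1L)
    stop("empty memory set: at least one pattern is required", call. = FALSE)
  if (!all(patterns %in% c(0, 1)))
    stop("memory patterns must be binary (0/1)", call. = FALSE)
  if (is.null(alpha)) alpha <- mean(patterns)
  if (!is.finite(alpha) || alpha <= 0 || alpha >= 1)
    stop("alpha must lie strictly in (0, 1); got ", alpha, call. = FALSE)
  structure(list(patterns = patterns, alpha = alpha,
                 count = nrow(patterns), N = ncol(patterns)),
            class = "memory_set")
}

#' Random sparse binary memory patterns
#'
#' Each pattern has exactly `round(alpha * N)` active units.  Patterns are
#' rejection-sampled until every pair overlaps in at most `max_overlap`
#' units ("well-separated"); the default bound is chance-level overlap
#' `ceiling(alpha^2 * N)`.
#'
#' Uses the current RNG state; call `set.seed()` first for reproducibility.
#'
#' @param n_patterns number of patterns.
#' @param N number of units.
#' @param alpha sparseness in (0,1).
#' @param max_overlap maximum pairwise overlap (active units in common).
#' @param max_tries resampling budget per pattern.
#' @return a `memory_set`.
#' @export
random_memory_set <- function(n_patterns, N, alpha = 0.25,
                              max_overlap = ceiling(alpha^2 * N),
                              max_tries = 1000L) {
  k <- max(1L, round(alpha * N))
  pats <- matrix(0, n_patterns, N)
  for (p in seq_len(n_patterns)) {
    for (try in seq_len(max_tries)) {
      cand <- integer(N); cand[sample.int(N, k)] <- 1L
      if (p == 1L ||
          all(pats[seq_len(p - 1L), , drop = FALSE] %*% cand <= max_overlap)) {
        pats[p, ] <- cand
        break
      }
      if (try == max_tries)
        stop("could not generate ", n_patterns, " patterns with pairwise ",
             "overlap <= ", max_overlap, call. = FALSE)
    }
  }
  memory_set(pats, alpha = alpha)
}

#' Embed memories into a symmetric recurrent matrix
#'
#' Covariance (sparse Hopfield-type) rule: with patterns `a^O` (rows),
#' sparseness `alpha` and pattern count `P`,
#' `M_ij = 1/((1-alpha) alpha P) * sum_O (a_i - alpha)(a_j - alpha)`
#' minus an inhibitory offset `1/(alpha P)`.  With
#' `uniform_offset = TRUE` the offset is subtracted from every entry; with
#' the default `FALSE` it is subtracted on the diagonal only (where
#' `zero_diagonal` then removes it).  The uniform reading makes every
#' within-pattern coupling negative, so embedded patterns are not energy
#' minima; the diagonal reading is the one consistent with pattern
#' stability and is the default.
#'
#' @param mem a `memory_set` (or P x N 0/1 matrix).
#' @param zero_diagonal zero out self-connections (default `TRUE`).
#' @param uniform_offset subtract the `1/(alpha P)` term from all entries
#'   rather than the diagonal only (default `FALSE`).
#' @return object of class `recurrent_matrix`: fields `M` (N x N symmetric),
#'   `alpha`, `n_patterns`, `zero_diagonal`, `uniform_offset`.
#' @examples
#' embed_memories(memory_set(rbind(c(1, 0)), alpha = 0.5),
#'                zero_diagonal = FALSE, uniform_offset = TRUE)$M
#' @export
embed_memories <- function(mem, zero_diagonal = TRUE, uniform_offset = FALSE) {
  if (!inherits(mem, "memory_set")) mem <- memory_set(mem)
  A <- mem$patterns
  P <- mem$count
  alpha <- mem$alpha
  N <- mem$N
  M <- crossprod(A - alpha) / ((1 - alpha) * alpha * P)
  if (uniform_offset) M <- M - 1 / (alpha * P)
  else diag(M) <- diag(M) - 1 / (alpha * P)
  if (zero_diagonal) diag(M) <- 0
  dimnames(M) <- NULL
  structure(list(M = M, alpha = alpha, n_patterns = P, N = N,
                 zero_diagonal = zero_diagonal,
                 uniform_offset = uniform_offset),
            class = "recurrent_matrix")
}

#' @export
as.matrix.recurrent_matrix <- function(x, ...) x$M

#' @export
print.recurrent_matrix <- function(x, ...) {
  cat("<recurrent_matrix> N:", x$N, " patterns:", x$n_patterns,
      " alpha:", format(x$alpha, digits = 4),
      " zero_diagonal:", x$zero_diagonal,
      " uniform_offset:", x$uniform_offset, "\n")
  invisible(x)
}

# coerce recurrent_matrix | matrix -> plain matrix
as_M <- function(M) {
  if (inherits(M, "recurrent_matrix")) M$M else as.matrix(M)
}

#' Is a binary pattern a fixed point of the embedded network?
#'
#' `mode = "deterministic"`: one synchronous threshold update
#' `v_i' = 1(sum_j M_ij v_j > 0)` (ties keep the current value) must leave
#' the pattern unchanged.  `mode = "energy"`: the pattern's energy
#' `-1/2 v' M v` (Hopfield convention, no input) must not exceed the energy
#' of any single-bit-flip neighbour; ties count as stable.
#'
#' @param M a `recurrent_matrix` or plain N x N matrix.
#' @param pattern 0/1 vector of length N.
#' @param mode `"deterministic"` or `"energy"`.
#' @return list with `stable` (logical) and `diagnostics` (per-mode details:
#'   fields of the threshold update, or neighbour energies and the number
#'   strictly below the pattern's energy).
#' @export
check_fixed_point <- function(M, pattern,
                              mode = c("deterministic", "energy")) {
  mode <- match.arg(mode)
  M <- as_M(M)
  pattern <- as.numeric(pattern)
  if (length(pattern) != nrow(M))
    stop("shape error: pattern length ", length(pattern),
         " does not match N = ", nrow(M), call. = FALSE)
  if (mode == "deterministic") {
    h <- as.vector(M %*% pattern)
    nxt <- ifelse(h > 0, 1, ifelse(h < 0, 0, pattern))
    list(stable = all(nxt == pattern),
         diagnostics = list(field = h, next_state = nxt,
                            n_changed = sum(nxt != pattern)))
  } else {
    e0 <- -0.5 * as.numeric(crossprod(pattern, M %*% pattern))
    n <- length(pattern)
    e_nb <- vapply(seq_len(n), function(i) {
      q <- pattern; q[i] <- 1 - q[i]
      -0.5 * as.numeric(crossprod(q, M %*% q))
    }, numeric(1))
    tol <- 1e-12 * max(1, abs(e0))
    list(stable = all(e_nb >= e0 - tol),
         diagnostics = list(energy = e0, neighbour_energies = e_nb,
                            n_lower = sum(e_nb < e0 - tol)))
  }
}

#' Fraction of random instances whose embedded patterns are energy minima
#'
#' Draws `n_instances` random memory sets (well-separated sparse patterns),
#' embeds each with the covariance rule (zero diagonal), and checks by
#' exhaustive single-flip enumeration that every embedded pattern is a
#' local energy minimum.
#'
#' @param n_instances number of random instances.
#' @param N units per network (kept small; enumeration is over N flips).
#' @param n_patterns patterns per instance (1 or 2 recommended).
#' @param alpha sparseness; also used to centre the rule.
#' @param seed RNG seed.
#' @return fraction of instances in which all embedded patterns are stable,
#'   with attribute `"per_instance"` (logical vector).
#' @export
pattern_stability_rate <- function(n_instances = 100L, N = 16L,
                                   n_patterns = 2L, alpha = 0.25,
                                   seed = 1L) {
  set.seed(seed)
  ok <- vapply(seq_len(n_instances), function(i) {
    mem <- random_memory_set(n_patterns, N, alpha)
    rm_ <- embed_memories(mem, zero_diagonal = TRUE)
    all(vapply(seq_len(mem$count), function(p)
      check_fixed_point(rm_, mem$patterns[p, ], mode = "energy")$stable,
      logical(1)))
  }, logical(1))
  structure(mean(ok), per_instance = ok)
}
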