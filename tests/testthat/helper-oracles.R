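# Independent oracles used by the tests: deliberately naive re-implementations
# (explicit loops, no shared code with the package internals).

# causal discrete convolution by direct double sum
naive_convolve <- function(s, k) {
  T <- length(s)
  r <- numeric(T)
  for (t in seq_len(T))
    for (tau in seq_len(t))
      r[t] <- r[t] + s[tau] * k[t - tau + 1L]
  r
}

# cosine between two rows with the silent-row conventions
cosine_oracle <- function(x, y) {
  sx <- sum(x * x); sy <- sum(y * y)
  if (sx == 0 && sy == 0) return(1)
  if (sx == 0 || sy == 0) return(0)
  sum(x * y) / sqrt(sx * sy)
}

# mean row-wise cosine between two T x N rasters (columns = neurons)
q_oracle <- function(A, B) {
  mean(vapply(seq_len(ncol(A)), function(n) cosine_oracle(A[, n], B[, n]),
              numeric(1)))
}

# all permutations of 1..n by recursive insertion (list of integer vectors)
perms_oracle <- function(n) {
  if (n == 1L) return(list(1L))
  out <- list()
  for (p in perms_oracle(n - 1L))
    for (pos in 0:(n - 1L))
      out[[length(out) + 1L]] <- append(p, n, after = pos)
  out
}

# brute-force state energy by explicit loops (hopfield sign unless flipped)
energy_oracle <- function(M, W, u, v, as_printed = FALSE) {
  e <- -u * sum(W * v)
  sgn <- if (as_printed) 0.5 else -0.5
  for (i in seq_along(v))
    for (j in seq_along(v))
      e <- e + sgn * v[i] * M[i, j] * v[j]
  e
}
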