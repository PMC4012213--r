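#' @keywords internal
raster_of <- function(x) {
  if (inherits(x, "simulation_trace")) x$raster else as.matrix(x)
}

#' Mean row-wise cosine similarity between two rasters
#'
#' Rasters are stored as T x N matrices (rows = time); each neuron
#' contributes the cosine of the angle between its two T-long spike
#' vectors, and `q` is the arithmetic mean over the N neurons:
#' `q_ab = 1/N sum_n (v_na . v_nb) / (||v_na|| ||v_nb||)`.
#' Zero-row convention: if both corresponding rows are silent the cosine is
#' 1 (identical silence); if exactly one is silent, 0.  This preserves
#' `q(a, a) = 1` for any raster.
#'
#' @param a,b T x N binary matrices or `simulation_trace` objects.
#' @param window optional integer vector of time steps to restrict to.
#' @return object of class `similarity_result`: `q` in \[-1, 1\] (in
#'   \[0, 1\] for binary data), `per_row_cosines` (length N),
#'   `n_zero_pairs`.
#' @export
raster_similarity <- function(a, b, window = NULL) {
  A <- raster_of(a); B <- raster_of(b)
  if (!all(dim(A) == dim(B)))
    stop("shape error: rasters have different dimensions", call. = FALSE)
  if (!is.null(window)) {
    A <- A[window, , drop = FALSE]
    B <- B[window, , drop = FALSE]
  }
  na2 <- colSums(A * A)
  nb2 <- colSums(B * B)
  dots <- colSums(A * B)
  both_zero <- na2 == 0 & nb2 == 0
  one_zero <- xor(na2 == 0, nb2 == 0)
  cosines <- numeric(ncol(A))
  ok <- !both_zero & !one_zero
  # sqrt(na2 * nb2) is exact for the self-pair (perfect square), so
  # q(a, a) == 1 holds exactly, silent rows included
  cosines[ok] <- dots[ok] / sqrt(na2[ok] * nb2[ok])
  cosines[both_zero] <- 1
  cosines[one_zero] <- 0
  structure(list(q = mean(cosines), per_row_cosines = cosines,
                 n_zero_pairs = sum(both_zero)),
            class = "similarity_result")
}

#' @export
print.similarity_result <- function(x, ...) {
  cat("<similarity_result> q:", format(x$q, digits = 5),
      " rows:", length(x$per_row_cosines),
      " silent pairs:", x$n_zero_pairs, "\n")
  invisible(x)
}

# all permutations of 1..n (n small), one per row: first element k followed
# by each permutation of the remaining values
all_permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- all_permutations(n - 1L)
  out <- matrix(0L, nrow(sub) * n, n)
  row <- 0L
  for (k in seq_len(n)) {
    rest <- setdiff(seq_len(n), k)
    for (r in seq_len(nrow(sub))) {
      row <- row + 1L
      out[row, ] <- c(k, rest[sub[r, ]])
    }
  }
  out
}

#' Row-shuffle null distribution for raster similarity
#'
#' Pools the neuron rows of all supplied rasters, randomly permutes the
#' assignment of rows to (raster, neuron) slots, recomputes each raster's
#' similarity `q` against the reference, and records the change from the
#' unshuffled value.  The threshold is the requested percentile of the
#' empirical distribution of change magnitudes `|dq|` (ECDF definition
#' `min{x : F(x) >= p}`): a similarity change larger than the threshold is
#' bigger than what row shuffling alone produces at that percentile.
#'
#' @param rasters list of T x N rasters (or traces).
#' @param reference raster against which `q` is computed.
#' @param n_shuffles number of random shuffles (>= 100 unless exhaustive).
#' @param percentile percentile (default 85) defining the threshold.
#' @param seed RNG seed.
#' @param exhaustive enumerate all permutations of the pooled rows instead
#'   of sampling (only feasible for a handful of rows).
#' @return object of class `null_distribution`: `changes` (signed),
#'   `ecdf` (of `|changes|`), `threshold_percentile`, `threshold_value`,
#'   `n_shuffles`, `seed`.
#' @export
shuffle_null <- function(rasters, reference, n_shuffles = 10000L,
                         percentile = 85, seed = NULL, exhaustive = FALSE) {
  if (!is.list(rasters)) rasters <- list(rasters)
  mats <- lapply(rasters, raster_of)
  ref <- raster_of(reference)
  dims <- vapply(mats, dim, integer(2))
  if (any(dims[1, ] != nrow(ref)) || any(dims[2, ] != ncol(ref)))
    stop("shape error: all rasters must share the reference's dimensions",
         call. = FALSE)
  if (!exhaustive && n_shuffles < 100L)
    stop("n_shuffles must be >= 100", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  n_per <- ncol(ref)
  pool <- do.call(cbind, mats)              # T x (R * N) pooled neuron rows
  n_tot <- ncol(pool)
  q0 <- vapply(mats, function(m) raster_similarity(m, ref)$q, numeric(1))
  groups <- rep(seq_along(mats), each = n_per)
  one_shuffle <- function(perm) {
    shuffled <- pool[, perm, drop = FALSE]
    vapply(seq_along(mats), function(r)
      raster_similarity(shuffled[, groups == r, drop = FALSE], ref)$q,
      numeric(1)) - q0
  }
  if (exhaustive) {
    if (n_tot > 8L)
      stop("exhaustive enumeration limited to <= 8 pooled rows", call. = FALSE)
    perms <- all_permutations(n_tot)
    changes <- as.vector(apply(perms, 1L, one_shuffle))
    n_shuffles <- nrow(perms)
  } else {
    changes <- as.vector(vapply(seq_len(n_shuffles), function(i)
      one_shuffle(sample.int(n_tot)), numeric(length(mats))))
  }
  sorted <- sort(abs(changes))
  idx <- min(length(sorted), max(1L, ceiling(percentile / 100 * length(sorted))))
  structure(list(changes = changes, ecdf = stats::ecdf(abs(changes)),
                 threshold_percentile = percentile,
                 threshold_value = sorted[idx],
                 n_shuffles = n_shuffles, seed = seed,
                 exhaustive = exhaustive),
            class = "null_distribution")
}

#' @export
print.null_distribution <- function(x, ...) {
  cat("<null_distribution> shuffles:", x$n_shuffles,
      if (x$exhaustive) "(exhaustive)" else "",
      " p", x$threshold_percentile, " threshold: ",
      format(x$threshold_value, digits = 5), "\n", sep = "")
  invisible(x)
}

#' Pairwise similarity matrix across conditions
#'
#' Computes the mean row-wise cosine `q` between every pair of rasters
#' (conditions plus an optional baseline).  If a `null_distribution` is
#' supplied, cells whose deviation from perfect self-similarity
#' (`1 - q`) exceeds the null threshold are flagged.
#'
#' @param traces named list of rasters or `simulation_trace`s.
#' @param baseline optional baseline raster, added under the name
#'   `"baseline"`.
#' @param null optional `null_distribution` supplying the flag threshold.
#' @return object of class `similarity_matrix`: `q` (labelled matrix),
#'   `flagged` (logical matrix or NULL), `threshold`.
#' @export
similarity_heatmap <- function(traces, baseline = NULL, null = NULL) {
  mats <- lapply(traces, raster_of)
  if (is.null(names(mats)) || any(!nzchar(names(mats))))
    names(mats) <- paste0("condition_", seq_along(mats))
  if (!is.null(baseline)) mats <- c(mats, list(baseline = raster_of(baseline)))
  n <- length(mats)
  Q <- matrix(NA_real_, n, n, dimnames = list(names(mats), names(mats)))
  for (i in seq_len(n)) for (j in i:n) {
    Q[i, j] <- Q[j, i] <- raster_similarity(mats[[i]], mats[[j]])$q
  }
  threshold <- if (!is.null(null)) null$threshold_value else NULL
  flagged <- if (!is.null(threshold)) (1 - Q) > threshold else NULL
  structure(list(q = Q, flagged = flagged, threshold = threshold),
            class = "similarity_matrix")
}

#' @export
print.similarity_matrix <- function(x, ...) {
  cat("<similarity_matrix>\n")
  print(round(x$q, 3))
  if (!is.null(x$flagged))
    cat("cells beyond null threshold (", format(x$threshold, digits = 4),
        "): ", sum(x$flagged[upper.tri(x$flagged, diag = TRUE)]), "\n",
        sep = "")
  invisible(x)
}

#' @export
plot.similarity_matrix <- function(x, ...) {
  n <- nrow(x$q)
  pal <- grDevices::hcl.colors(64, "Blues 3")
  graphics::image(seq_len(n), seq_len(n), t(x$q[n:1, , drop = FALSE]),
                  col = pal, zlim = c(0, 1), axes = FALSE,
                  xlab = "", ylab = "", main = "raster similarity q", ...)
  graphics::axis(1, seq_len(n), colnames(x$q), las = 2, cex.axis = 0.7)
  graphics::axis(2, seq_len(n), rev(rownames(x$q)), las = 2, cex.axis = 0.7)
  invisible(x)
}

#' Recompute the energy trajectory of a simulation trace
#'
#' Evaluates the state energy at every recorded step from the recorded
#' rates, feedforward weights, stimulus, and recurrent-matrix snapshots.
#' Requires either a snapshot at every step (`record_M = 1`) or frozen
#' recurrent weights.
#'
#' @param trace a `simulation_trace`.
#' @param sign_convention override the trace's configured convention.
#' @return numeric vector, one energy per recorded step.
#' @export
energy_trajectory <- function(trace, sign_convention = NULL) {
  if (is.null(sign_convention)) sign_convention <- trace$config$sign_convention
  T <- length(trace$times)
  frozen_M <- !trace$config$plastic_M
  if (!frozen_M && length(trace$M_times) < T)
    stop("insufficient record: recurrent-matrix snapshots missing; rerun ",
         "with record_M = 1 or freeze M", call. = FALSE)
  vapply(seq_len(T), function(tt) {
    M <- if (frozen_M) trace$final$weights$M
         else trace$M_snapshots[[match(tt, trace$M_times)]]
    network_energy(energy_model(M, trace$W_history[tt, ], trace$u[tt],
                                sign_convention = sign_convention),
                   trace$v_history[tt, ])
  }, numeric(1))
}
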