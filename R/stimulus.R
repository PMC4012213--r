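#' Binary stimulus templates
#'
#' Builds one of the three binary drug-usage stimulus templates: `exposure`
#' (a single isolated pulse), `chronic` (tonic ON from onset to the end of
#' the run) and `cessation` (ON from onset until offset, OFF afterwards).
#' Time is discrete, `t = 0, ..., T - 1`; element `t + 1` of `values` is the
#' stimulus at step `t`.
#'
#' @param kind one of `"exposure"`, `"chronic"`, `"cessation"`.
#' @param T number of time steps (default 200).
#' @param onset first ON step (0-based, `0 <= onset < T`).
#' @param pulse_width width of the exposure pulse, in steps.
#' @param offset first OFF step for cessation (`onset < offset <= T`).
#' @return an object of class `stimulus_template` with fields `kind`,
#'   `values` (0/1 vector of length `T`), `onset`, `pulse_width`, `offset`.
#' @examples
#' make_stimulus("exposure", T = 10, onset = 2, pulse_width = 3)$values
#' @export
make_stimulus <- function(kind = c("exposure", "chronic", "cessation"),
                          T = 200L, onset = 10L, pulse_width = 10L,
                          offset = 120L) {
  if (length(kind) == 1L && !kind %in% c("exposure", "chronic", "cessation"))
    stop("unsupported stimulus template kind: '", kind, "'", call. = FALSE)
  kind <- match.arg(kind)
  T <- as.integer(T); onset <- as.integer(onset)
  pulse_width <- as.integer(pulse_width); offset <- as.integer(offset)
  if (T < 1L) stop("T must be a positive integer", call. = FALSE)
  if (onset < 0L || onset >= T)
    stop("onset out of bounds: need 0 <= onset < T", call. = FALSE)
  values <- integer(T)
  t <- seq_len(T) - 1L                      # 0-based time axis
  if (kind == "exposure") {
    if (pulse_width < 1L || onset + pulse_width > T)
      stop("exposure pulse out of bounds: need onset + pulse_width <= T",
           call. = FALSE)
    values[t >= onset & t < onset + pulse_width] <- 1L
  } else if (kind == "chronic") {
    values[t >= onset] <- 1L
  } else {                                  # cessation
    if (offset <= onset || offset > T)
      stop("cessation offset out of bounds: need onset < offset <= T",
           call. = FALSE)
    values[t >= onset & t < offset] <- 1L
  }
  structure(list(kind = kind, values = values, onset = onset,
                 pulse_width = pulse_width, offset = offset, T = T),
            class = "stimulus_template")
}

#' Reward-salience kernels
#'
#' Peak-normalized reward kernels sampled on the integer time grid
#' `t = 0, ..., T - 1`.  The `gaussian` kernel (symmetric about its mode)
#' models resilient reward dynamics; the `loggaussian` kernel (fast rise,
#' long right tail; mode before mean) models susceptible dynamics of
#' positive reinforcement.
#'
#' @param kind `"gaussian"` or `"loggaussian"`.
#' @param T number of samples.
#' @param params named list of shape parameters.  Gaussian: `mu`, `sigma`
#'   (defaults 20, 4).  Log-Gaussian: `mu_log`, `sigma_log`
#'   (defaults `log(10)`, 0.6).  The defaults give the susceptible kernel
#'   about 25\% more integrated salience than the resilient one, delivered
#'   earlier and with a heavy tail.
#' @return object of class `reward_kernel` with fields `kind`, `values`
#'   (nonnegative, max 1), `params`.
#' @export
make_kernel <- function(kind = c("gaussian", "loggaussian"), T = 200L,
                        params = list()) {
  if (length(kind) == 1L && !kind %in% c("gaussian", "loggaussian"))
    stop("unsupported kernel kind: '", kind, "'", call. = FALSE)
  kind <- match.arg(kind)
  T <- as.integer(T)
  t <- seq_len(T) - 1
  if (kind == "gaussian") {
    p <- utils::modifyList(list(mu = 20, sigma = 4), params)
    if (p$sigma <= 0) stop("sigma must be > 0", call. = FALSE)
    values <- exp(-(t - p$mu)^2 / (2 * p$sigma^2))
  } else {
    p <- utils::modifyList(list(mu_log = log(10), sigma_log = 0.6), params)
    if (p$sigma_log <= 0) stop("sigma_log must be > 0", call. = FALSE)
    values <- stats::dlnorm(t, meanlog = p$mu_log, sdlog = p$sigma_log)
  }
  values <- values / max(values)            # peak normalization
  structure(list(kind = kind, values = values, params = p, T = T),
            class = "reward_kernel")
}

#' Convolve a stimulus template with a reward kernel
#'
#' Causal ("full", truncated to `T` samples) discrete convolution
#' `r[t] = sum_{s <= t} stim[s] * kernel[t - s]`: the reward at time `t`
#' depends only on stimulus delivered at or before `t`.
#'
#' @param stim a `stimulus_template` (or 0/1 vector).
#' @param kernel a `reward_kernel` (or nonnegative vector) of equal length.
#' @return object of class `stimulus_reward_pattern` with fields `stimulus`,
#'   `kernel`, `reward`, `usage`, `susceptibility`.
#' @export
convolve_pattern <- function(stim, kernel) {
  s <- if (inherits(stim, "stimulus_template")) stim$values else as.numeric(stim)
  k <- if (inherits(kernel, "reward_kernel")) kernel$values else as.numeric(kernel)
  if (length(s) != length(k))
    stop("shape error: stimulus and kernel lengths differ (",
         length(s), " vs ", length(k), ")", call. = FALSE)
  T <- length(s)
  # direct causal sum; exact (no FFT round-off), O(T^2) is trivial at T ~ 200
  reward <- vapply(seq_len(T), function(t) sum(s[1:t] * k[t:1]), numeric(1))
  usage <- if (inherits(stim, "stimulus_template")) stim$kind else NA_character_
  susc <- if (inherits(kernel, "reward_kernel"))
    c(gaussian = "resilient", loggaussian = "susceptible")[[kernel$kind]]
  else NA_character_
  structure(list(stimulus = if (inherits(stim, "stimulus_template")) stim
                 else make_raw_template(s),
                 kernel = kernel, reward = reward,
                 usage = usage, susceptibility = susc, T = T),
            class = "stimulus_reward_pattern")
}

# wrap a bare 0/1 vector so downstream code can rely on $values
make_raw_template <- function(s) {
  structure(list(kind = "custom", values = as.numeric(s), onset = NA_integer_,
                 pulse_width = NA_integer_, offset = NA_integer_,
                 T = length(s)),
            class = "stimulus_template")
}

#' A silent (all-zero) stimulus-reward pattern
#'
#' Used for the baseline (no-input) condition.
#' @param T number of time steps.
#' @export
null_pattern <- function(T = 200L) {
  T <- as.integer(T)
  structure(list(stimulus = make_raw_template(numeric(T)),
                 kernel = NULL, reward = numeric(T),
                 usage = "baseline", susceptibility = "none", T = T),
            class = "stimulus_reward_pattern")
}

#' The 3 x 2 grid of stimulus-reward conditions
#'
#' All six combinations of usage pattern (exposure, chronic, cessation) and
#' susceptibility (susceptible = log-Gaussian kernel, resilient = Gaussian
#' kernel), each the causal convolution of the template with the kernel.
#'
#' @param T number of time steps (default 200).
#' @param params optional overrides: `onset`, `pulse_width`, `offset`,
#'   `gaussian` (list), `loggaussian` (list).  Timing defaults scale with
#'   `T` (onset and pulse at 5\% of the run, cessation offset at 60\%),
#'   giving onset 10, width 10, offset 120 at the default `T = 200`.
#' @return named list of 6 `stimulus_reward_pattern`s
#'   (`<usage>_<susceptibility>`), class `condition_grid`.
#' @export
make_condition_grid <- function(T = 200L, params = list()) {
  p <- utils::modifyList(list(onset = max(1L, round(0.05 * T)),
                              pulse_width = max(1L, round(0.05 * T)),
                              offset = round(0.6 * T),
                              gaussian = list(), loggaussian = list()),
                         params)
  kernels <- list(
    susceptible = make_kernel("loggaussian", T, p$loggaussian),
    resilient   = make_kernel("gaussian", T, p$gaussian))
  usages <- c("exposure", "chronic", "cessation")
  grid <- list()
  for (u in usages) {
    stim <- make_stimulus(u, T = T, onset = p$onset,
                          pulse_width = p$pulse_width, offset = p$offset)
    for (s in names(kernels))
      grid[[paste(u, s, sep = "_")]] <- convolve_pattern(stim, kernels[[s]])
  }
  structure(grid, class = c("condition_grid", "list"))
}

#' @export
as.data.frame.stimulus_reward_pattern <- function(x, ...) {
  data.frame(time = seq_len(x$T) - 1L, stimulus = x$stimulus$values,
             reward = x$reward)
}

#' Write a stimulus-reward pattern as CSV (columns time, stimulus, reward)
#' @param pattern a `stimulus_reward_pattern`.
#' @param file output path.
#' @export
write_pattern <- function(pattern, file) {
  utils::write.csv(as.data.frame(pattern), file, row.names = FALSE)
  invisible(file)
}

#' @export
print.stimulus_template <- function(x, ...) {
  cat("<stimulus_template> kind:", x$kind, " T:", x$T,
      " ON steps:", sum(x$values), "\n")
  invisible(x)
}

#' @export
print.stimulus_reward_pattern <- function(x, ...) {
  cat("<stimulus_reward_pattern>", x$usage, "/", x$susceptibility,
      " T:", x$T, " peak reward:", format(max(x$reward), digits = 4), "\n")
  invisible(x)
}

#' @export
plot.stimulus_reward_pattern <- function(x, ...) {
  t <- seq_len(x$T) - 1L
  op <- graphics::par(mfrow = c(2, 1), mar = c(2.5, 4, 1, 1))
  on.exit(graphics::par(op))
  graphics::plot(t, x$stimulus$values, type = "s", ylab = "stimulus",
                 xlab = "", main = paste(x$usage, x$susceptibility, sep = " / "))
  graphics::plot(t, x$reward, type = "l", ylab = "reward (a.u.)",
                 xlab = "time step", ...)
  invisible(x)
}
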