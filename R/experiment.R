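#' Full experiment configuration
#'
#' Nested configuration for the end-to-end experiment: `network` (see
#' [network_config()]), `memories` (random-pattern generator spec or
#' explicit patterns), `stimulus` (protocol length and per-kind timing plus
#' kernel parameters) and `analysis` (shuffle-null settings).
#'
#' @param network a `network_config`.
#' @param memories list: `n_patterns`, `alpha`, `zero_diagonal`,
#'   `uniform_offset`, and optionally `patterns` (explicit P x N 0/1
#'   matrix, overriding the generator).
#' @param stimulus list: `T`, `onset`, `pulse_width`, `offset`, `gaussian`,
#'   `loggaussian` kernel parameter lists.
#' @param analysis list: `n_shuffles`, `percentile`.
#' @return object of class `experiment_config`.
#' @export
experiment_config <- function(network = network_config(),
                              memories = list(),
                              stimulus = list(),
                              analysis = list()) {
  memories <- utils::modifyList(
    list(n_patterns = 10L, alpha = 0.25, zero_diagonal = TRUE,
         uniform_offset = FALSE, patterns = NULL), memories)
  stimulus <- utils::modifyList(
    list(T = 200L, onset = 10L, pulse_width = 10L, offset = 120L,
         gaussian = list(mu = 20, sigma = 4),
         loggaussian = list(mu_log = log(10), sigma_log = 0.6)), stimulus)
  analysis <- utils::modifyList(
    list(n_shuffles = 10000L, percentile = 85), analysis)
  structure(list(network = network, memories = memories,
                 stimulus = stimulus, analysis = analysis),
            class = "experiment_config")
}

#' Validate an experiment configuration without running anything
#'
#' @param config an `experiment_config`.
#' @return character vector of findings (empty when the configuration is
#'   valid); findings are reported, never thrown.
#' @export
validate_config <- function(config) {
  f <- character()
  f <- c(f, validate_network_config(config$network))
  m <- config$memories
  if (is.null(m$patterns) && (is.null(m$n_patterns) || m$n_patterns < 1))
    f <- c(f, "memories: need patterns or n_patterns >= 1")
  if (!is.null(m$alpha) && (m$alpha <= 0 || m$alpha >= 1))
    f <- c(f, "memories: alpha must lie strictly in (0, 1)")
  s <- config$stimulus
  if (s$T < 1) f <- c(f, "stimulus: T must be >= 1")
  if (s$onset < 0 || s$onset >= s$T)
    f <- c(f, "stimulus: need 0 <= onset < T")
  if (s$onset + s$pulse_width > s$T)
    f <- c(f, "stimulus: exposure pulse must end by T")
  if (s$offset <= s$onset || s$offset > s$T)
    f <- c(f, "stimulus: need onset < offset <= T")
  a <- config$analysis
  if (a$n_shuffles < 100) f <- c(f, "analysis: n_shuffles must be >= 100")
  if (a$percentile <= 0 || a$percentile >= 100)
    f <- c(f, "analysis: percentile must lie in (0, 100)")
  f
}

stage_error <- function(stage, msg) {
  stop(sprintf("[stage: %s] %s", stage, msg), call. = FALSE)
}

#' Run the full six-condition experiment
#'
#' Embeds the memories, simulates the baseline (no input) plus all six
#' stimulus-reward conditions from the same seeded initial condition
#' (embedded pattern 1 with a small fraction of entries flipped), and
#' analyses the resulting rasters: similarity of each condition to the
#' baseline over the full run and over the post-cessation window
#' (`t >= offset`), the pairwise similarity heatmap, the row-shuffle null
#' distribution, and the per-condition energy trajectories.
#'
#' A single top-level seed deterministically derives per-stage seeds, so
#' one integer reproduces the whole experiment.
#'
#' @param config an `experiment_config`.
#' @param seed top-level integer seed.
#' @param out_dir optional output directory; when given, per-condition
#'   rasters/rates/energies, the analysis tables and a JSON run manifest
#'   (with file checksums) are written there.
#' @param n_shuffles override of `config$analysis$n_shuffles` (e.g. for
#'   quick runs).
#' @return object of class `experiment_result`: `traces` (named list,
#'   baseline first), `similarity` (`similarity_matrix`), `null`,
#'   `q_baseline` (full-run similarity of each condition to baseline),
#'   `q_post` (post-offset window), `memories`, `recurrent`, `manifest`.
#' @export
run_experiment <- function(config = experiment_config(), seed = 1L,
                           out_dir = NULL, n_shuffles = NULL) {
  findings <- validate_config(config)
  if (length(findings))
    stage_error("config", paste(findings, collapse = "; "))
  net <- config$network
  set.seed(seed)
  seeds <- sample.int(.Machine$integer.max - 1L, 12L)

  # --- embed ---------------------------------------------------------------
  memcfg <- config$memories
  mem <- tryCatch({
    if (!is.null(memcfg$patterns)) {
      memory_set(memcfg$patterns, alpha = memcfg$alpha)
    } else {
      set.seed(seeds[1])
      random_memory_set(memcfg$n_patterns, net$N, memcfg$alpha)
    }
  }, error = function(e) stage_error("embed", conditionMessage(e)))
  recurrent <- embed_memories(mem, zero_diagonal = memcfg$zero_diagonal,
                              uniform_offset = memcfg$uniform_offset)

  # --- inputs --------------------------------------------------------------
  grid <- tryCatch(
    make_condition_grid(config$stimulus$T, config$stimulus),
    error = function(e) stage_error("generate-inputs", conditionMessage(e)))

  # --- simulate ------------------------------------------------------------
  set.seed(seeds[2])
  v0 <- perturbed_pattern(mem$patterns[1, ], net$flip_fraction)
  w_init <- weight_set(recurrent, rep(net$w0, net$N))
  patterns <- c(list(baseline = null_pattern(config$stimulus$T)), grid)
  traces <- vector("list", length(patterns))
  names(traces) <- names(patterns)
  for (i in seq_along(patterns)) {
    traces[[i]] <- tryCatch(
      run_simulation(patterns[[i]], w_init, net, init = v0,
                     seed = seeds[2L + i]),
      error = function(e) stage_error(paste0("simulate:", names(patterns)[i]),
                                      conditionMessage(e)))
  }

  # --- analyze -------------------------------------------------------------
  baseline <- traces$baseline
  conds <- traces[names(traces) != "baseline"]
  post_window <- seq(config$stimulus$offset + 1L, config$stimulus$T)
  q_baseline <- vapply(conds, function(tr)
    raster_similarity(tr, baseline)$q, numeric(1))
  q_post <- vapply(conds, function(tr)
    raster_similarity(tr, baseline, window = post_window)$q, numeric(1))
  if (is.null(n_shuffles)) n_shuffles <- config$analysis$n_shuffles
  null <- shuffle_null(traces, baseline, n_shuffles = n_shuffles,
                       percentile = config$analysis$percentile,
                       seed = seeds[10])
  sim <- similarity_heatmap(conds, baseline = baseline, null = null)

  manifest <- list(package_version = as.character(utils::packageVersion("rewardnet")),
                   seed = seed, stage_seeds = seeds,
                   config = unclass_deep(config),
                   conditions = names(conds), files = list())
  result <- structure(list(traces = traces, similarity = sim, null = null,
                           q_baseline = q_baseline, q_post = q_post,
                           memories = mem, recurrent = recurrent,
                           initial_state = v0, manifest = manifest),
                      class = "experiment_result")
  if (!is.null(out_dir)) result <- write_experiment(result, out_dir)
  result
}

unclass_deep <- function(x) {
  if (is.list(x)) lapply(unclass(x), unclass_deep) else x
}

write_experiment <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  files <- character()
  for (nm in names(result$traces)) {
    d <- file.path(out_dir, nm)
    dir.create(d, showWarnings = FALSE)
    tr <- result$traces[[nm]]
    utils::write.csv(tr$raster, file.path(d, "raster.csv"), row.names = FALSE)
    utils::write.csv(tr$v_history, file.path(d, "rates.csv"),
                     row.names = FALSE)
    utils::write.csv(data.frame(time = tr$times, energy = tr$energy),
                     file.path(d, "energy.csv"), row.names = FALSE)
    utils::write.csv(data.frame(time = tr$times, stimulus = tr$u,
                                reward = tr$r),
                     file.path(d, "stimulus_reward.csv"), row.names = FALSE)
    files <- c(files, file.path(d, c("raster.csv", "rates.csv", "energy.csv",
                                     "stimulus_reward.csv")))
  }
  ad <- file.path(out_dir, "analysis")
  dir.create(ad, showWarnings = FALSE)
  utils::write.csv(result$similarity$q, file.path(ad, "similarity_matrix.csv"))
  utils::write.csv(data.frame(change = result$null$changes),
                   file.path(ad, "null_distribution.csv"), row.names = FALSE)
  utils::write.csv(data.frame(condition = names(result$q_baseline),
                              q_full = result$q_baseline,
                              q_post = result$q_post),
                   file.path(ad, "baseline_similarity.csv"),
                   row.names = FALSE)
  files <- c(files, file.path(ad, c("similarity_matrix.csv",
                                    "null_distribution.csv",
                                    "baseline_similarity.csv")))
  result$manifest$files <- lapply(stats::setNames(files, files), function(fp)
    list(md5 = unname(tools::md5sum(fp))))
  jsonlite::write_json(result$manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  result
}

#' @export
print.experiment_result <- function(x, ...) {
  cat("<experiment_result> conditions:",
      paste(names(x$traces), collapse = ", "), "\n")
  cat("similarity to baseline (full run):\n")
  print(round(x$q_baseline, 3))
  cat("similarity to baseline (post-cessation window):\n")
  print(round(x$q_post, 3))
  invisible(x)
}
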