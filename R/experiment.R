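#' Run a synthetic electrode-shift experiment end to end
#'
#' Generates the three-position synthetic benchmark, preprocesses every trial
#' under each requested normalization, trains the requested strategies per
#' subject, and evaluates cross-position differential classification
#' accuracy. Per-position pool models (the BASELINE / single-position models)
#' are always trained: they provide both the vanilla cross-position rows and
#' the same-position baseline every other strategy is differenced against.
#'
#' @param seed Global integer seed; every stochastic step derives its own
#'   sub-seed from it.
#' @param n_subjects Synthetic subjects.
#' @param n_trials_per_position Trials per electrode position per subject.
#' @param trial_duration Trial length in seconds.
#' @param n_channels EMG channels.
#' @param gain_log_sd,crosstalk_alpha Electrode-shift perturbation parameters
#'   (see [shift_model()]).
#' @param normalizations Subset of `c("swn", "none")`.
#' @param strategies Subset of `c("vanilla", "tl", "ada", "mix")`.
#' @param norm_window SWN window in ms.
#' @param feature_window Feature-extraction window in ms.
#' @param epochs Training epochs.
#' @param measurement_noise_sd Additive sensor noise level.
#' @param sequence_length_s Training sequence length in seconds (default: the
#'   trial length).
#' @param batch_size Sequences per optimizer step.
#' @param out_dir Optional run directory: trained models are cached there as
#'   RDS and all result tables are written beside a resolved `config.json`.
#' @param resume If `out_dir` holds a partial prior run, `TRUE` reuses its
#'   cached models; `FALSE` fails loudly.
#' @param verbose Print progress lines.
#' @return A tibble (differential-accuracy table) with one row per
#'   (normalization, strategy, subject, train position, test position):
#'   accuracy `x`, same-position baseline `x_baseline`, difference `y`,
#'   window metadata.
#' @export
run_shift_experiment <- function(seed = 1L, n_subjects = 3L,
                                 n_trials_per_position = 8L,
                                 trial_duration = 10, n_channels = 12L,
                                 gain_log_sd = 0.3, crosstalk_alpha = 0.1,
                                 normalizations = c("swn", "none"),
                                 strategies = "vanilla", norm_window = 200,
                                 feature_window = 200, epochs = 5L,
                                 measurement_noise_sd = 0.05,
                                 sequence_length_s = trial_duration,
                                 batch_size = 128L, out_dir = NULL,
                                 resume = FALSE, verbose = FALSE) {
  strategies <- match.arg(strategies, c("vanilla", "tl", "ada", "mix"),
                          several.ok = TRUE)
  normalizations <- match.arg(normalizations, c("swn", "none"),
                              several.ok = TRUE)
  say <- function(...) if (verbose) message(sprintf(...))
  if (!is.null(out_dir)) {
    if (dir.exists(out_dir) && length(dir(out_dir)) > 0L && !resume)
      stop("`out_dir` holds a prior (possibly partial) run; pass ",
           "`resume = TRUE` to reuse it or choose a fresh directory",
           call. = FALSE)
    dir.create(file.path(out_dir, "models"), recursive = TRUE,
               showWarnings = FALSE)
  }
  scfg <- synth_config(n_channels = n_channels,
                       trial_duration = trial_duration,
                       n_trials_per_position = n_trials_per_position,
                       measurement_noise_sd = measurement_noise_sd,
                       seed = derive_seed(seed, "synth"))
  shifts <- list(
    shift_model("left", gain_log_sd, crosstalk_alpha,
                seed = derive_seed(seed, "shift-left")),
    shift_model("center", 0, 0, seed = derive_seed(seed, "shift-center")),
    shift_model("right", gain_log_sd, crosstalk_alpha,
                seed = derive_seed(seed, "shift-right")))
  say("generating benchmark (%d subjects x 3 x %d trials)...", n_subjects,
      n_trials_per_position)
  bench <- generate_benchmark(scfg, shifts, n_subjects)
  ppcfg <- preproc_config(feature_window = feature_window)
  positions <- c("left", "center", "right")
  rows <- list()
  for (subject in unique(bench$manifest$subject_id)) {
    man_s <- bench$manifest[bench$manifest$subject_id == subject, ]
    plan <- make_splits(man_s, seed = derive_seed(seed, "split", subject))
    # the linear filter + decimation front end is normalization-independent;
    # run it once per trial and branch afterwards
    say("filtering/decimating %s ...", subject)
    decimated <- lapply(bench$trials[man_s$key], function(tr)
      bandpass_decimate(tr$recording, ppcfg))
    for (norm in normalizations) {
      swncfg <- if (norm == "swn")
        swn_config(norm_window, fs = ppcfg$fs_proc) else NULL
      say("preprocessing %s / %s ...", subject, norm)
      frames <- lapply(man_s$key, function(key) {
        x <- decimated[[key]]$signal
        if (!is.null(swncfg)) {
          x <- normalize_stream(x, swncfg)
          attr(x, "swn_state") <- NULL
        }
        assemble_frames(rectify(x), bench$trials[[key]]$labels, ppcfg)
      })
      names(frames) <- man_s$key
      mcfg <- model_config(n_input_channels = n_channels * ppcfg$n_segments,
                           t_seg = ppcfg$seg_samples)
      train_one <- function(strategy, i, j, ada = FALSE) {
        tag <- paste(norm, subject, strategy, i, j, sep = "_")
        cache <- if (!is.null(out_dir))
          file.path(out_dir, "models", paste0(tag, ".rds")) else NULL
        if (!is.null(cache) && file.exists(cache)) return(readRDS(cache))
        cfg_i <- mcfg; cfg_i$ada <- ada
        tcfg <- train_config(epochs = epochs, batch_size = batch_size,
                             sequence_length_s = sequence_length_s,
                             seed = derive_seed(seed, "train", tag))
        say("training %s ...", tag)
        fitted <- train_strategy(strategy, frames, plan, i, j, cfg_i, tcfg)
        if (!is.null(cache)) saveRDS(fitted, cache)
        fitted
      }
      # per-position pool models: vanilla cross rows + baselines
      pool_models <- lapply(stats::setNames(positions, positions),
                            function(p) train_one("baseline", p, p))
      x_base <- vapply(positions, function(j)
        evaluate_strategy(pool_models[[j]], frames)$accuracy, 0)
      add_row <- function(strategy, i, j, x) {
        rows[[length(rows) + 1L]] <<- tibble::tibble(
          normalization = norm, strategy = strategy, subject = subject,
          train_pos = i, test_pos = j, x = x, x_baseline = x_base[[j]],
          y = differential_accuracy(x, x_base[[j]]),
          norm_window = if (norm == "swn") norm_window else NA_real_,
          feature_window = feature_window)
      }
      for (j in positions) add_row("baseline", j, j, x_base[[j]])
      for (i in positions) for (j in setdiff(positions, i)) {
        if ("vanilla" %in% strategies) {
          # a vanilla cross-position model is the position-i pool model
          ev <- local({
            m <- pool_models[[i]]
            m$trials$test <- strategy_trials(plan, "vanilla", i, j)$test
            evaluate_strategy(m, frames)
          })
          add_row("vanilla", i, j, ev$accuracy)
        }
        if ("tl" %in% strategies) {
          ft <- train_one("tl", i, j)
          add_row("tl", i, j, evaluate_strategy(ft, frames)$accuracy)
        }
      }
      for (strategy in intersect(strategies, c("ada", "mix"))) {
        for (j in positions) {
          ft <- train_one(strategy, j, j, ada = strategy == "ada")
          add_row(strategy, j, j, evaluate_strategy(ft, frames)$accuracy)
        }
      }
      rm(frames); gc(FALSE)
    }
    rm(decimated); gc(FALSE)
  }
  out <- dplyr::bind_rows(rows)
  if (!is.null(out_dir)) {
    utils::write.csv(out, file.path(out_dir, "diff_accuracy.csv"),
                     row.names = FALSE)
    utils::write.csv(aggregate_subject_means(out),
                     file.path(out_dir, "subject_means.csv"),
                     row.names = FALSE)
  }
  out
}

#' Mean differential accuracy per normalization
#'
#' Convenience summary of a [run_shift_experiment()] table: the mean of the
#' per-subject mean differential accuracies, per (normalization, strategy).
#'
#' @param table Differential-accuracy tibble.
#' @return Tibble with `normalization`, `strategy`, `mean_diff` (fraction).
#' @export
summarize_shift_experiment <- function(table) {
  aggregate_subject_means(table) |>
    dplyr::group_by(.data$normalization, .data$strategy) |>
    dplyr::summarise(mean_diff = mean(.data$mean_y), .groups = "drop")
}

#' Run a full experiment from a nested configuration
#'
#' Orchestrates simulate, preprocess, train, evaluate and the statistics in
#' one call and writes a self-describing run directory: resolved
#' `config.json`, the differential-accuracy table, per-subject means, and a
#' `stats.json` with Wilcoxon (Bonferroni-corrected) normalization contrasts
#' per strategy and, when the design allows, a Scheirer-Ray-Hare
#' normalization x strategy test on the per-subject means. Re-running with
#' the same configuration reproduces all CSV outputs; an interrupted run can
#' be resumed (cached models are reused, missing ones retrained).
#'
#' @param config Nested list; see [default_experiment_config()] for the
#'   recognized fields and defaults. Unknown fields raise an error.
#' @param out_dir Run directory.
#' @param resume Reuse a partial prior run instead of failing.
#' @return The differential-accuracy tibble, invisibly; side effect: files in
#'   `out_dir`.
#' @export
run_experiment <- function(config = list(), out_dir, resume = FALSE) {
  cfg <- default_experiment_config()
  unknown <- setdiff(names(config), names(cfg))
  if (length(unknown) > 0L)
    stop("unknown config fields: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  cfg[names(config)] <- config
  if (dir.exists(out_dir) && length(dir(out_dir)) > 0L && !resume)
    stop("`out_dir` holds a prior (possibly partial) run; pass ",
         "`resume = TRUE` or choose a fresh directory", call. = FALSE)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  resolved <- c(cfg, list(package_version =
                            as.character(utils::packageVersion("emgswn"))))
  jsonlite::write_json(resolved, file.path(out_dir, "config.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  tab <- run_shift_experiment(
    seed = cfg$seed, n_subjects = cfg$n_subjects,
    n_trials_per_position = cfg$n_trials_per_position,
    trial_duration = cfg$trial_duration, n_channels = cfg$n_channels,
    gain_log_sd = cfg$gain_log_sd, crosstalk_alpha = cfg$crosstalk_alpha,
    normalizations = cfg$normalizations, strategies = cfg$strategies,
    norm_window = cfg$norm_window, feature_window = cfg$feature_window,
    epochs = cfg$epochs, measurement_noise_sd = cfg$measurement_noise_sd,
    sequence_length_s = cfg$sequence_length_s %||% cfg$trial_duration,
    batch_size = cfg$batch_size, out_dir = out_dir, resume = TRUE,
    verbose = cfg$verbose)
  means <- aggregate_subject_means(tab)
  stats_out <- list()
  if (all(c("swn", "none") %in% cfg$normalizations)) {
    per_strategy <- list()
    for (s in unique(means$strategy)) {
      a <- means$mean_y[means$strategy == s & means$normalization == "swn"]
      b <- means$mean_y[means$strategy == s & means$normalization == "none"]
      # the rank-sum p is only meaningful with at least 2 subjects per group
      if (length(a) > 1 && length(b) > 1) {
        w <- wilcoxon_rank_sum(a, b)
        if (is.finite(w$p_value)) per_strategy[[s]] <- w
      }
    }
    if (length(per_strategy) > 0) {
      ps <- vapply(per_strategy, `[[`, 0, "p_value")
      adj <- bonferroni(ps, length(ps))
      stats_out$wilcoxon <- lapply(seq_along(per_strategy), function(k)
        c(strategy = names(per_strategy)[k], per_strategy[[k]],
          p_bonferroni = adj[[k]]))
    }
    cross <- means[means$strategy != "baseline", ]
    if (length(unique(cross$strategy)) >= 2L)
      stats_out$scheirer_ray_hare <-
        scheirer_ray_hare(cross$mean_y, cross$normalization, cross$strategy)
  }
  jsonlite::write_json(stats_out, file.path(out_dir, "stats.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       dataframe = "rows")
  invisible(tab)
}

#' Default experiment configuration
#'
#' The recognized fields of [run_experiment()]'s config and their defaults
#' (desk-scale; raise sizes for real studies).
#'
#' @return Named list of defaults.
#' @export
default_experiment_config <- function() {
  list(seed = 1L, n_subjects = 1L, n_trials_per_position = 4L,
       trial_duration = 10, n_channels = 12L, gain_log_sd = 0.3,
       crosstalk_alpha = 0.1, normalizations = c("swn", "none"),
       strategies = "vanilla", norm_window = 200, feature_window = 200,
       epochs = 2L, measurement_noise_sd = 0.05, sequence_length_s = NULL,
       batch_size = 128L, verbose = FALSE)
}
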