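#' Training hyperparameter configuration
#'
#' Shared optimizer settings of all training regimes: Adam with
#' `lr_train = 1e-3` during (pre-)training and `lr_retrain = 1e-4` during
#' transfer-learning fine-tuning, `beta1 = 0.9`, `beta2 = 0.999`; 40 epochs,
#' batch size 128 sequences, 20 s training sequences, 10 re-training epochs.
#'
#' @param epochs Training epochs (default 40).
#' @param batch_size Sequences per optimizer step (default 128).
#' @param sequence_length_s Length in seconds of the contiguous frame runs a
#'   trial is cut into (default 20; a trial shorter than this contributes one
#'   run spanning the whole trial).
#' @param lr_train,lr_retrain Adam learning rates for training and
#'   fine-tuning.
#' @param beta1,beta2 Adam moment decays.
#' @param tl_retrain_epochs Fine-tuning epochs for transfer learning
#'   (default 10).
#' @param seed Integer seed controlling initialization, shuffling and dropout.
#' @return A list of class `"train_config"`.
#' @export
train_config <- function(epochs = 40L, batch_size = 128L,
                         sequence_length_s = 20, lr_train = 1e-3,
                         lr_retrain = 1e-4, beta1 = 0.9, beta2 = 0.999,
                         tl_retrain_epochs = 10L, seed = 1L) {
  check_scalar_num(epochs, "epochs", min = 1)
  check_scalar_num(batch_size, "batch_size", min = 1)
  check_scalar_num(sequence_length_s, "sequence_length_s", min = 1e-9)
  if (lr_retrain >= lr_train)
    stop("`lr_retrain` must be smaller than `lr_train`", call. = FALSE)
  structure(list(epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 sequence_length_s = sequence_length_s, lr_train = lr_train,
                 lr_retrain = lr_retrain, beta1 = beta1, beta2 = beta2,
                 tl_retrain_epochs = as.integer(tl_retrain_epochs),
                 seed = as.integer(seed)),
            class = "train_config")
}

#' Split trials into training / tuning / testing pools
#'
#' Per electrode position, trials are split at trial granularity into a
#' training pool (70%, floor-rounded) and a common test pool (the remainder).
#' A fixed 30% subset (floor-rounded) of each pool is drawn once and reused
#' wherever a strategy needs "30% of the common training data": it is the
#' transfer-learning tuning set for that position and the per-position
#' contribution to the pooled ADA/MIX training set. The test pool of a
#' position is identical across strategies so comparisons share the same test
#' samples. Deterministic per seed.
#'
#' When the manifest carries a `trial_id` column and `align_trials = TRUE`
#' (the default), the random ordering is shared across positions via the
#' underlying trial id. This matters for benchmarks whose shifted-position
#' trials are derived from the same center trials: an aligned split keeps a
#' trained trial's shifted twin out of every test pool. With independently
#' recorded sessions the alignment is inert (ids are arbitrary).
#'
#' @param manifest Data frame with columns `key` (trial key) and `position`
#'   (one per trial of a single subject), optionally `trial_id`.
#' @param seed Integer seed.
#' @param align_trials Share the split ordering across positions by
#'   `trial_id` when available.
#' @return A list of class `"split_plan"` with per-position `pool`, `test`,
#'   and `sub30` trial-key vectors.
#' @export
make_splits <- function(manifest, seed = 1L, align_trials = TRUE) {
  stopifnot(all(c("key", "position") %in% names(manifest)))
  positions <- unique(manifest$position)
  align <- align_trials && "trial_id" %in% names(manifest)
  if (align) {
    ids <- unique(manifest$trial_id)
    id_order <- with_rng_seed(derive_seed(seed, "split"), sample(ids))
  }
  plan <- list()
  for (pos in positions) {
    sel <- manifest$position == pos
    keys <- manifest$key[sel]
    if (length(keys) < 4L)
      stop("need at least 4 trials per position (", pos, " has ",
           length(keys), ")", call. = FALSE)
    perm <- if (align) {
      keys[order(match(manifest$trial_id[sel], id_order))]
    } else {
      with_rng_seed(derive_seed(seed, "split", pos), sample(keys))
    }
    n_pool <- floor(0.7 * length(keys))
    pool <- sort(perm[seq_len(n_pool)])
    test <- sort(setdiff(keys, pool))
    n_sub <- floor(0.3 * n_pool)   # may be empty; only tl/ada/mix need it
    sub30 <- if (align) sort(perm[seq_len(n_sub)]) else
      sort(with_rng_seed(derive_seed(seed, "sub30", pos),
                         sample(pool, n_sub)))
    plan[[pos]] <- list(pool = pool, test = test, sub30 = sub30)
  }
  structure(list(positions = positions, plan = plan, seed = seed),
            class = "split_plan")
}

#' Realized trial lists for one strategy and position pair
#'
#' @param plan A [make_splits()] plan.
#' @param strategy One of `"vanilla"`, `"tl"`, `"ada"`, `"mix"`, `"baseline"`.
#' @param train_pos Training electrode position (ignored for `ada`/`mix`,
#'   which pool all positions).
#' @param test_pos Testing (and tuning) electrode position.
#' @return List with `train`, `tune` (possibly `NULL`), `test` trial keys, and
#'   `domains` (named position per training trial, for the ADA head).
#' @export
strategy_trials <- function(plan, strategy, train_pos, test_pos) {
  stopifnot(inherits(plan, "split_plan"))
  strategy <- match.arg(strategy, c("vanilla", "tl", "ada", "mix", "baseline"))
  p <- plan$plan
  get_pos <- function(pos) {
    if (is.null(p[[pos]])) stop("no trials for position ", pos, call. = FALSE)
    p[[pos]]
  }
  if (strategy %in% c("vanilla", "tl") && identical(train_pos, test_pos))
    stop("same-position evaluation is the BASELINE strategy; `", strategy,
         "` requires train_pos != test_pos", call. = FALSE)
  if (strategy == "baseline" && !identical(train_pos, test_pos))
    stop("BASELINE requires train_pos == test_pos", call. = FALSE)
  test <- get_pos(test_pos)$test
  if (strategy %in% c("vanilla", "baseline")) {
    train <- get_pos(train_pos)$pool
    doms <- stats::setNames(rep(train_pos, length(train)), train)
    return(list(train = train, tune = NULL, test = test, domains = doms))
  }
  if (strategy == "tl") {
    train <- get_pos(train_pos)$pool
    tune <- get_pos(test_pos)$sub30
    if (length(tune) == 0L)
      stop("tuning subset of position ", test_pos, " is empty; ",
           "need at least 4 pool trials per position for tl", call. = FALSE)
    doms <- stats::setNames(rep(train_pos, length(train)), train)
    return(list(train = train, tune = tune, test = test, domains = doms))
  }
  # ada / mix: pooled 30% subsets of every position's pool
  if (length(plan$positions) < 2L)
    stop("ada/mix need data from all electrode positions", call. = FALSE)
  train <- character(0); doms <- character(0)
  for (pos in plan$positions) {
    sub <- get_pos(pos)$sub30
    if (length(sub) == 0L)
      stop("training subset of position ", pos, " is empty; ",
           "need at least 4 pool trials per position for ada/mix",
           call. = FALSE)
    train <- c(train, sub)
    doms <- c(doms, stats::setNames(rep(pos, length(sub)), sub))
  }
  list(train = train, tune = NULL, test = test, domains = doms)
}

# cut a trial's frames into contiguous non-overlapping runs of
# `seq_len_frames`; remainder frames are dropped; a trial shorter than one
# run contributes a single run spanning the whole trial
cut_sequences <- function(frameset, seq_len_frames, domain_id) {
  Fn <- dim(frameset$frames)[3L]
  if (Fn == 0L) return(list())
  n_runs <- Fn %/% seq_len_frames
  if (n_runs == 0L) {
    return(list(list(x = frameset$frames, y = frameset$labels + 1L,
                     domain = domain_id, len = Fn)))
  }
  lapply(seq_len(n_runs), function(r) {
    idx <- ((r - 1L) * seq_len_frames + 1L):(r * seq_len_frames)
    list(x = frameset$frames[, , idx, drop = FALSE],
         y = frameset$labels[idx] + 1L, domain = domain_id,
         len = seq_len_frames)
  })
}

# one optimization pass over a batch of equal-length sequences
train_batch <- function(model, batch, opt, cfg, tcfg, lr, mask, use_domain) {
  B <- length(batch)
  x <- array(0, c(dim(batch[[1L]]$x)[1:2], sum(vapply(batch, `[[`, 0L, "len"))))
  y <- integer(0); dom <- integer(0)
  at <- 0L
  for (sq in batch) {
    x[, , (at + 1L):(at + sq$len)] <- sq$x
    y <- c(y, sq$y)
    dom <- c(dom, rep(sq$domain, sq$len))
    at <- at + sq$len
  }
  fw <- model_forward(model, x, n_seq = B, training = TRUE,
                      with_domain = use_domain)
  fc <- focal_loss_grad(fw$class_probs, y, cfg$focal_gamma, cfg$alpha_mode)
  loss <- fc$loss
  dd <- NULL
  if (use_domain) {
    fd <- focal_loss_grad(fw$domain_probs, dom, cfg$focal_gamma,
                          cfg$alpha_mode, weight = cfg$domain_loss_weight)
    loss <- loss + fd$loss
    dd <- fd$dlogits
  }
  bw <- model_backward(model, fw$cache, fc$dlogits, dd)
  st <- adam_step(flatten_params(model$params), flatten_params(bw$grads), opt,
                  lr, tcfg$beta1, tcfg$beta2, mask = mask)
  model$params <- unflatten_params(st$theta, model$params)
  acc <- mean(max.col(t(fw$class_probs), ties.method = "first") == y)
  list(model = model, opt = st$state, loss = loss, acc = acc, n = length(y))
}

# core SGD loop shared by all strategies. `mask`: numeric 0/1 vector over the
# flat parameter vector (1 = trainable).
fit_model <- function(model, sequences, tcfg, lr, epochs, use_domain = FALSE,
                      mask = NULL, seed = 1L, log_prefix = "train") {
  lens <- vapply(sequences, `[[`, 0L, "len")
  log <- list()
  with_rng_seed(derive_seed(seed, "fit", log_prefix), {
    opt <- adam_init(length(flatten_params(model$params)))
    for (ep in seq_len(epochs)) {
      ord <- sample(seq_along(sequences))
      ep_loss <- 0; ep_acc <- 0; ep_n <- 0L
      # batch only equal-length runs together
      for (len in unique(lens[ord])) {
        sel <- ord[lens[ord] == len]
        for (chunk in split(sel, ceiling(seq_along(sel) / tcfg$batch_size))) {
          r <- train_batch(model, sequences[chunk], opt, model$config, tcfg,
                           lr, mask, use_domain)
          model <- r$model; opt <- r$opt
          ep_loss <- ep_loss + r$loss; ep_acc <- ep_acc + r$acc * r$n
          ep_n <- ep_n + r$n
        }
      }
      log[[ep]] <- tibble::tibble(phase = log_prefix, epoch = ep,
                                  loss = ep_loss, accuracy = ep_acc / ep_n)
    }
  })
  list(model = model, log = dplyr::bind_rows(log))
}

#' Train a model under one of the benchmark strategies
#'
#' * `vanilla` / `baseline`: single-position training on the position's pool.
#' * `tl` (transfer learning): pretrain on the source position's pool, then
#'   freeze the CNN parameters (bitwise unchanged) and fine-tune the LSTM and
#'   output head on the target position's tuning subset at `lr_retrain` for
#'   `tl_retrain_epochs`.
#' * `mix`: pooled training on the 30% subsets of all positions.
#' * `ada`: like `mix`, additionally minimizing a domain focal loss through
#'   the gradient reversal layer (class loss + `domain_loss_weight` x domain
#'   loss), pushing shared features toward position invariance.
#'
#' Training sequences are contiguous runs of `sequence_length_s` seconds of
#' frames; leftover frames are dropped (a trial shorter than one run is used
#' whole). Reproducible for a fixed seed.
#'
#' @param strategy `"vanilla"`, `"tl"`, `"ada"`, `"mix"`, or `"baseline"`.
#' @param frames Named list of `"dnn_input_sequence"` objects keyed by trial
#'   key (already preprocessed under the chosen normalization).
#' @param plan A [make_splits()] plan.
#' @param train_pos,test_pos Electrode positions (see [strategy_trials()]).
#' @param model_cfg A [model_config()]; its `ada` flag is forced on for the
#'   `ada` strategy.
#' @param tcfg A [train_config()].
#' @return List of class `"trained_strategy"`: `model`, `log` (per-epoch
#'   tibble), `trials` (the realized split), `strategy`.
#' @export
train_strategy <- function(strategy, frames, plan, train_pos, test_pos,
                           model_cfg, tcfg) {
  strategy <- match.arg(strategy, c("vanilla", "tl", "ada", "mix", "baseline"))
  tri <- strategy_trials(plan, strategy, train_pos, test_pos)
  missing <- setdiff(c(tri$train, tri$tune, tri$test), names(frames))
  if (length(missing) > 0L)
    stop("frames missing for trials: ", paste(missing, collapse = ", "),
         call. = FALSE)
  leak <- intersect(c(tri$train, tri$tune), tri$test)
  if (length(leak) > 0L)
    stop("train/tune trials leak into the test pool: ",
         paste(leak, collapse = ", "), call. = FALSE)
  use_domain <- strategy == "ada"
  if (use_domain && !model_cfg$ada) {
    model_cfg$ada <- TRUE
  }
  positions <- plan$positions
  dom_id <- function(keys) match(tri$domains[keys], positions)
  seq_len_frames <- max(1L, as.integer(round(
    tcfg$sequence_length_s * frames[[tri$train[1L]]]$frame_rate)))
  seqs <- list()
  for (key in tri$train)
    seqs <- c(seqs, cut_sequences(frames[[key]], seq_len_frames,
                                  dom_id(key)))
  # seeds are strategy-independent so regimes sharing a data path (ada with a
  # disabled adversarial term vs mix) are exactly comparable under one seed
  model <- build_model(model_cfg, seed = derive_seed(tcfg$seed, "init",
                                                     train_pos, test_pos))
  fit <- fit_model(model, seqs, tcfg, tcfg$lr_train, tcfg$epochs,
                   use_domain = use_domain,
                   seed = derive_seed(tcfg$seed, "fit", train_pos, test_pos),
                   log_prefix = "train")
  model <- fit$model
  log <- fit$log
  if (strategy == "tl") {
    tune_seqs <- list()
    for (key in tri$tune)
      tune_seqs <- c(tune_seqs, cut_sequences(frames[[key]], seq_len_frames,
                                              match(test_pos, positions)))
    mask <- as.numeric(!param_group_mask(model$params, "conv"))
    fit2 <- fit_model(model, tune_seqs, tcfg, tcfg$lr_retrain,
                      tcfg$tl_retrain_epochs, use_domain = FALSE, mask = mask,
                      seed = derive_seed(tcfg$seed, "tl-tune", train_pos,
                                         test_pos),
                      log_prefix = "retrain")
    model <- fit2$model
    log <- dplyr::bind_rows(log, fit2$log)
  }
  structure(list(model = model, log = log, trials = tri, strategy = strategy,
                 train_pos = train_pos, test_pos = test_pos),
            class = "trained_strategy")
}

#' Frame-level accuracy of a trained strategy on its test pool
#'
#' @param fitted A [train_strategy()] result.
#' @param frames Named list of `"dnn_input_sequence"` objects.
#' @return List with `accuracy` (fraction), `n_frames`, and per-trial
#'   accuracies.
#' @export
evaluate_strategy <- function(fitted, frames) {
  stopifnot(inherits(fitted, "trained_strategy"))
  correct <- 0L; total <- 0L
  per_trial <- numeric(0)
  for (key in fitted$trials$test) {
    fr <- frames[[key]]
    pr <- predict_frames(fitted$model, fr)
    ok <- sum(pr$predicted == fr$labels)
    correct <- correct + ok
    total <- total + length(fr$labels)
    per_trial[key] <- ok / length(fr$labels)
  }
  list(accuracy = correct / total, n_frames = total, per_trial = per_trial)
}
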