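make_manifest <- function(n_per_pos) {
  tibble::tibble(
    position = rep(c("left", "center", "right"), each = n_per_pos),
    trial_id = rep(sprintf("trial%02d", seq_len(n_per_pos)), 3),
    key = paste(position, trial_id, sep = "_"))
}

test_that("split sizes follow the 70/30 rule with floor rounding", {
  plan <- make_splits(make_manifest(20), seed = 5)
  for (pos in c("left", "center", "right")) {
    expect_length(plan$plan[[pos]]$pool, 14)   # floor(0.7 * 20)
    expect_length(plan$plan[[pos]]$test, 6)
    expect_length(plan$plan[[pos]]$sub30, 4)   # floor(0.3 * 14)
    # partition: pool and test are disjoint and cover the position
    expect_length(intersect(plan$plan[[pos]]$pool, plan$plan[[pos]]$test), 0)
    expect_setequal(c(plan$plan[[pos]]$pool, plan$plan[[pos]]$test),
                    make_manifest(20)$key[make_manifest(20)$position == pos])
    expect_true(all(plan$plan[[pos]]$sub30 %in% plan$plan[[pos]]$pool))
  }
  tri <- strategy_trials(plan, "mix", "left", "center")
  expect_length(tri$train, 12)                 # 4 + 4 + 4
  tri_tl <- strategy_trials(plan, "tl", "left", "center")
  expect_length(tri_tl$tune, 4)
  # identical plan for an identical seed
  expect_identical(plan, make_splits(make_manifest(20), seed = 5))
  expect_false(identical(plan, make_splits(make_manifest(20), seed = 6)))
})

test_that("strategy trial lists respect the evaluation contracts", {
  plan <- make_splits(make_manifest(10), seed = 1)
  expect_error(strategy_trials(plan, "vanilla", "left", "left"), "BASELINE")
  expect_error(strategy_trials(plan, "baseline", "left", "right"),
               "train_pos == test_pos")
  for (s in c("vanilla", "tl", "ada", "mix")) {
    tri <- strategy_trials(plan, s, "left", "right")
    expect_length(intersect(c(tri$train, tri$tune), tri$test), 0)
  }
  # the common test pool is strategy-independent
  tests <- lapply(c("vanilla", "tl", "ada", "mix"), function(s)
    strategy_trials(plan, s, "left", "center")$test)
  for (tt in tests[-1]) expect_identical(tt, tests[[1]])
})

test_that("aligned splits keep a trial's shifted twins in one pool", {
  plan <- make_splits(make_manifest(8), seed = 3)
  ids <- function(keys) sub("^[a-z]+_", "", keys)
  expect_identical(ids(plan$plan$left$pool), ids(plan$plan$center$pool))
  expect_identical(ids(plan$plan$left$test), ids(plan$plan$right$test))
})

test_that("a linearly separable toy problem is fit almost perfectly", {
  # two classes with disjoint amplitude envelopes on different channels
  set.seed(77)
  C <- 6L; T <- 20L; n_seq <- 120L; Fl <- 10L
  mk_seq <- function(cls) {
    amp <- if (cls == 1) c(5, 5, 5, 0.1, 0.1, 0.1) else c(0.1, 0.1, 0.1, 5, 5, 5)
    list(x = array(abs(rnorm(C * T * Fl)) * amp, c(C, T, Fl)),
         y = rep(cls, Fl), domain = 1L, len = Fl)
  }
  seqs <- lapply(rep(1:2, length.out = n_seq), mk_seq)
  cfg <- model_config(n_input_channels = C, t_seg = T, n_classes = 3)
  model <- build_model(cfg, seed = 4)
  tcfg <- train_config(epochs = 5, batch_size = 2, sequence_length_s = 1,
                       seed = 4)
  fit <- emgswn:::fit_model(model, seqs, tcfg, tcfg$lr_train, 5)
  expect_gte(utils::tail(fit$log$accuracy, 1), 0.95)
})

test_that("transfer learning freezes the CNN bitwise and retrains the rest", {
  frames <- tiny_frames()
  bench <- tiny_bench()
  plan <- make_splits(bench$manifest, seed = 2)
  tcfg <- train_config(epochs = 2, batch_size = 2, sequence_length_s = 2,
                       tl_retrain_epochs = 2, seed = 9)
  ft <- train_strategy("tl", frames, plan, "left", "center",
                       tiny_model_cfg(), tcfg)
  # compare against the pretrain-only model (identical seeds by construction)
  van <- train_strategy("vanilla", frames, plan, "left", "center",
                        tiny_model_cfg(),
                        train_config(epochs = 2, batch_size = 2,
                                     sequence_length_s = 2, seed = 9))
  expect_identical(ft$model$params$conv, van$model$params$conv)
  expect_false(identical(ft$model$params$lstm, van$model$params$lstm))
  expect_false(identical(ft$model$params$head, van$model$params$head))
  expect_setequal(unique(ft$log$phase), c("train", "retrain"))
})

test_that("ADA equals MIX when the adversarial path is disabled", {
  frames <- tiny_frames()
  bench <- tiny_bench()
  plan <- make_splits(bench$manifest, seed = 2)
  tcfg <- train_config(epochs = 2, batch_size = 2, sequence_length_s = 2,
                       seed = 5)
  cfg_off <- tiny_model_cfg(ada = TRUE)
  cfg_off$grl_lambda <- 0
  cfg_off$domain_loss_weight <- 0
  ada <- train_strategy("ada", frames, plan, "center", "center", cfg_off, tcfg)
  mix <- train_strategy("mix", frames, plan, "center", "center",
                        tiny_model_cfg(), tcfg)
  for (grp in c("conv", "lstm_ln", "lstm", "head"))
    expect_equal(ada$model$params[[grp]], mix$model$params[[grp]],
                 tolerance = 1e-12)
  # and an enabled adversarial path changes the shared parameters
  ada_on <- train_strategy("ada", frames, plan, "center", "center",
                           tiny_model_cfg(ada = TRUE), tcfg)
  expect_false(isTRUE(all.equal(ada_on$model$params$conv,
                                mix$model$params$conv, tolerance = 1e-12)))
  # the domain head emits 3-domain probability rows
  pr <- predict_frames(ada_on$model, frames[[ada_on$trials$test[1]]])
  expect_equal(rowSums(pr$domain_probs), rep(1, nrow(pr$domain_probs)),
               tolerance = 1e-6)
})

test_that("training is reproducible for a fixed seed", {
  frames <- tiny_frames()
  bench <- tiny_bench()
  plan <- make_splits(bench$manifest, seed = 2)
  tcfg <- train_config(epochs = 2, batch_size = 2, sequence_length_s = 2,
                       seed = 31)
  a <- train_strategy("baseline", frames, plan, "left", "left",
                      tiny_model_cfg(), tcfg)
  b <- train_strategy("baseline", frames, plan, "left", "left",
                      tiny_model_cfg(), tcfg)
  expect_identical(a$model$params, b$model$params)
  ev <- evaluate_strategy(a, frames)
  expect_true(ev$accuracy >= 0 && ev$accuracy <= 1)
  expect_equal(ev$n_frames, sum(vapply(frames[a$trials$test],
                                       function(f) length(f$labels), 0L)))
})
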