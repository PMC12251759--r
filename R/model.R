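#' CNN-LSTM model configuration
#'
#' Architecture of the sequence classifier. The per-frame path is four
#' convolutional blocks (each: layer normalization, ReLU, channel-preserving
#' 1-D convolution with kernel 3 / stride 1 / padding 2, dropout with rates
#' 0.1/0.2/0.3/0.4), with anti-aliased blur-pooling downsampling (kernel 3,
#' stride 2, padding 1) applied only in the second block, followed by global
#' average pooling over the intra-frame time axis. The sequence path is layer
#' normalization, two stacked LSTM modules (input and hidden sizes equal to
#' the input channel count) with dropout 0.1, and an output head (layer
#' normalization, affine map, softmax over the motion classes). When `ada` is
#' enabled, an adversarial domain-adaptation head branches from the shared
#' LSTM representation through a gradient reversal layer (identity forward,
#' gradient scaled by `-grl_lambda` backward) and predicts the electrode
#' position, driving the shared features toward position invariance.
#'
#' @param n_input_channels Stacked channel count of the input frames
#'   (`n_channels * S` from [assemble_frames()]).
#' @param t_seg Intra-frame temporal length in samples (default 50).
#' @param n_classes Number of motion classes (default 3).
#' @param n_domains Number of electrode positions for the ADA head (default 3).
#' @param dropout_rates Dropout rates of the four conv blocks.
#' @param lstm_dropout Dropout after each LSTM module (default 0.1).
#' @param grl_lambda Gradient-reversal strength (default 1.0).
#' @param focal_gamma Focusing parameter of the focal loss (default 2.0).
#' @param alpha_mode `"as_printed"` weights each class by its batch label rate
#'   `count_l / count` (the loss definition used here); `"inverse"` uses
#'   normalized inverse frequencies instead.
#' @param domain_loss_weight Weight of the domain focal loss in the ADA total
#'   loss (default 1.0; the adversarial gradient is already scaled by
#'   `grl_lambda`).
#' @param ada Logical; build the domain-adaptation head.
#' @return A list of class `"model_config"`.
#' @export
model_config <- function(n_input_channels, t_seg = 50L, n_classes = 3L,
                         n_domains = 3L,
                         dropout_rates = c(0.1, 0.2, 0.3, 0.4),
                         lstm_dropout = 0.1, grl_lambda = 1.0,
                         focal_gamma = 2.0,
                         alpha_mode = c("as_printed", "inverse"),
                         domain_loss_weight = 1.0, ada = FALSE) {
  alpha_mode <- match.arg(alpha_mode)
  check_scalar_num(n_input_channels, "n_input_channels", min = 1)
  check_scalar_num(t_seg, "t_seg", min = 1)
  if (length(dropout_rates) != 4L || any(dropout_rates < 0) ||
      any(dropout_rates >= 1))
    stop("`dropout_rates` must be four values in [0, 1)", call. = FALSE)
  check_scalar_num(grl_lambda, "grl_lambda")
  check_scalar_num(focal_gamma, "focal_gamma", min = 0)
  structure(list(n_input_channels = as.integer(n_input_channels),
                 t_seg = as.integer(t_seg), n_classes = as.integer(n_classes),
                 n_domains = as.integer(n_domains),
                 dropout_rates = dropout_rates, lstm_dropout = lstm_dropout,
                 grl_lambda = grl_lambda, focal_gamma = focal_gamma,
                 alpha_mode = alpha_mode,
                 domain_loss_weight = domain_loss_weight, ada = isTRUE(ada)),
            class = "model_config")
}

unif_init <- function(nr, nc, fan_in) {
  a <- sqrt(6 / fan_in)
  matrix(stats::runif(nr * nc, -a, a), nr, nc)
}

#' Build a CNN-LSTM model
#'
#' Initializes all parameters deterministically from `seed`. The shared
#' parameters (conv blocks, LSTM, class head) are drawn from one RNG stream
#' and the ADA head from a separate derived stream, so models built with and
#' without the ADA head share bit-identical shared parameters for the same
#' seed.
#'
#' @param config A [model_config()].
#' @param seed Integer seed.
#' @return A list of class `"emg_model"` with `config` and `params`.
#' @export
build_model <- function(config, seed = 1L) {
  stopifnot(inherits(config, "model_config"))
  C <- config$n_input_channels
  H <- C
  k <- 3L
  params <- with_rng_seed(derive_seed(seed, "shared"), {
    conv <- lapply(1:4, function(b)
      list(g = rep(1, C), be = rep(0, C),
           W = unif_init(C, C * k, C * k), b = rep(0, C)))
    lstm_u <- 1 / sqrt(H)
    lstm <- lapply(1:2, function(l) {
      b <- stats::runif(4L * H, -lstm_u, lstm_u)
      b[(H + 1L):(2L * H)] <- b[(H + 1L):(2L * H)] + 1  # forget-gate bias +1
      list(Wx = matrix(stats::runif(4L * H * H, -lstm_u, lstm_u), 4L * H, H),
           Wh = matrix(stats::runif(4L * H * H, -lstm_u, lstm_u), 4L * H, H),
           b = b)
    })
    list(conv = conv,
         lstm_ln = list(g = rep(1, C), be = rep(0, C)),
         lstm = lstm,
         head = list(g = rep(1, H), be = rep(0, H),
                     W = unif_init(config$n_classes, H, H),
                     b = rep(0, config$n_classes)))
  })
  if (config$ada) {
    params$ada <- with_rng_seed(derive_seed(seed, "ada"), {
      # small positive hidden bias keeps the head's ReLU units initially
      # active; with a zero bias the whole head can start dead and the
      # adversarial gradient would vanish
      list(g1 = rep(1, H), be1 = rep(0, H),
           W1 = unif_init(H, H, H), b1 = rep(0.1, H),
           g2 = rep(1, H), be2 = rep(0, H),
           W2 = unif_init(config$n_domains, H, H),
           b2 = rep(0, config$n_domains))
    })
  }
  structure(list(config = config, params = params), class = "emg_model")
}

#' @export
print.emg_model <- function(x, ...) {
  cat(sprintf("<emg_model> C_cat=%d, t_seg=%d, classes=%d%s, %d parameters\n",
              x$config$n_input_channels, x$config$t_seg, x$config$n_classes,
              if (x$config$ada) sprintf(", ADA head (%d domains)",
                                        x$config$n_domains) else "",
              length(unlist(x$params, use.names = FALSE))))
  invisible(x)
}

# Forward pass. x: array (C, T, N) with N = F * B frames ordered
# frame-fastest within each sequence. Returns class (and domain) column
# probabilities plus the caches needed by model_backward().
model_forward <- function(model, x, n_seq = 1L, training = FALSE,
                          with_domain = model$config$ada) {
  p <- model$params
  cfg <- model$config
  d <- dim(x)
  stopifnot(d[1L] == cfg$n_input_channels, d[2L] == cfg$t_seg)
  N <- d[3L]
  B <- as.integer(n_seq)
  stopifnot(N %% B == 0L)
  Fn <- N %/% B
  cache <- list(conv = vector("list", 4L))
  for (b in 1:4) {
    db <- dim(x)
    ln <- ln_fwd(matrix(x, db[1L]), p$conv[[b]]$g, p$conv[[b]]$be)
    r <- relu_fwd(ln$out)
    h <- array(r$out, db)
    bp <- NULL
    if (b == 2L) { bp <- blurpool_fwd(h); h <- bp$out }
    cv <- conv1d_fwd(h, p$conv[[b]]$W, p$conv[[b]]$b)
    dr <- dropout_fwd(cv$out, cfg$dropout_rates[b], training)
    cache$conv[[b]] <- list(ln = ln, relu = r$cache, bp = bp$cache,
                            cv = cv$cache, drop = dr$cache, dims_in = db)
    x <- dr$out
  }
  gp <- gap_fwd(x)
  cache$gap <- gp$cache
  ln2 <- ln_fwd(gp$out, p$lstm_ln$g, p$lstm_ln$be)
  cache$lstm_ln <- ln2$cache
  seqs <- array(ln2$out, c(cfg$n_input_channels, Fn, B))
  l1 <- lstm_fwd(seqs, p$lstm[[1]]$Wx, p$lstm[[1]]$Wh, p$lstm[[1]]$b)
  d1 <- dropout_fwd(l1$out, cfg$lstm_dropout, training)
  l2 <- lstm_fwd(d1$out, p$lstm[[2]]$Wx, p$lstm[[2]]$Wh, p$lstm[[2]]$b)
  d2 <- dropout_fwd(l2$out, cfg$lstm_dropout, training)
  cache$seq <- list(x = seqs, l1 = l1, d1 = d1$cache, l2 = l2, d2 = d2$cache,
                    d1out = d1$out, Fn = Fn, B = B)
  feat <- matrix(d2$out, cfg$n_input_channels, N)
  cache$feat <- feat
  hl <- ln_fwd(feat, p$head$g, p$head$be)
  ha <- affine_fwd(hl$out, p$head$W, p$head$b)
  cache$head <- list(ln = hl$cache, aff = ha$cache)
  out <- list(class_logits = ha$out, class_probs = softmax_cols(ha$out))
  if (with_domain) {
    if (is.null(p$ada)) stop("model has no ADA head", call. = FALSE)
    # gradient reversal layer: identity forward
    a1 <- ln_fwd(feat, p$ada$g1, p$ada$be1)
    af1 <- affine_fwd(a1$out, p$ada$W1, p$ada$b1)
    ar <- relu_fwd(af1$out)
    a2 <- ln_fwd(ar$out, p$ada$g2, p$ada$be2)
    af2 <- affine_fwd(a2$out, p$ada$W2, p$ada$b2)
    cache$ada <- list(ln1 = a1$cache, aff1 = af1$cache, relu = ar$cache,
                      ln2 = a2$cache, aff2 = af2$cache)
    out$domain_logits <- af2$out
    out$domain_probs <- softmax_cols(af2$out)
  }
  out$cache <- cache
  out
}

# Backward pass from logit gradients; returns a gradient list with the same
# skeleton as model$params. The domain gradient enters the shared trunk
# through the gradient reversal layer, i.e. scaled by -grl_lambda.
model_backward <- function(model, cache, dclass_logits, ddomain_logits = NULL) {
  p <- model$params
  cfg <- model$config
  g <- list()
  ha <- affine_bwd(dclass_logits, p$head$W, cache$head$aff)
  hl <- ln_bwd(ha$dx, p$head$g, cache$head$ln)
  g$head <- list(g = hl$dgamma, be = hl$dbeta, W = ha$dW, b = ha$db)
  dfeat <- hl$dx
  if (!is.null(ddomain_logits)) {
    aa2 <- affine_bwd(ddomain_logits, p$ada$W2, cache$ada$aff2)
    al2 <- ln_bwd(aa2$dx, p$ada$g2, cache$ada$ln2)
    dar <- relu_bwd(al2$dx, cache$ada$relu)
    aa1 <- affine_bwd(dar, p$ada$W1, cache$ada$aff1)
    al1 <- ln_bwd(aa1$dx, p$ada$g1, cache$ada$ln1)
    g$ada <- list(g1 = al1$dgamma, be1 = al1$dbeta, W1 = aa1$dW, b1 = aa1$db,
                  g2 = al2$dgamma, be2 = al2$dbeta, W2 = aa2$dW, b2 = aa2$db)
    dfeat <- dfeat + (-cfg$grl_lambda) * al1$dx
  } else if (cfg$ada) {
    g$ada <- rapply(p$ada, function(z) z * 0, how = "replace")
  }
  sq <- cache$seq
  dseq <- array(dfeat, c(cfg$n_input_channels, sq$Fn, sq$B))
  dseq <- dropout_bwd(dseq, sq$d2)
  b2 <- lstm_bwd(dseq, sq$d1out, p$lstm[[2]]$Wx, p$lstm[[2]]$Wh, sq$l2$cache)
  dmid <- dropout_bwd(b2$dx, sq$d1)
  b1 <- lstm_bwd(dmid, sq$x, p$lstm[[1]]$Wx, p$lstm[[1]]$Wh, sq$l1$cache)
  g$lstm <- list(list(Wx = b1$dWx, Wh = b1$dWh, b = b1$db),
                 list(Wx = b2$dWx, Wh = b2$dWh, b = b2$db))
  dln2 <- matrix(b1$dx, cfg$n_input_channels, sq$Fn * sq$B)
  l2b <- ln_bwd(dln2, p$lstm_ln$g, cache$lstm_ln)
  g$lstm_ln <- list(g = l2b$dgamma, be = l2b$dbeta)
  dx <- gap_bwd(l2b$dx, cache$gap)
  g$conv <- vector("list", 4L)
  for (b in 4:1) {
    cc <- cache$conv[[b]]
    dx <- dropout_bwd(dx, cc$drop)
    cb <- conv1d_bwd(dx, p$conv[[b]]$W, cc$cv)
    dh <- cb$dx
    if (b == 2L) dh <- blurpool_bwd(dh, cc$bp)
    dr <- relu_bwd(matrix(dh, dim(dh)[1L]), cc$relu)
    lb <- ln_bwd(dr, p$conv[[b]]$g, cc$ln$cache)
    g$conv[[b]] <- list(g = lb$dgamma, be = lb$dbeta, W = cb$dW, b = cb$db)
    dx <- array(lb$dx, cc$dims_in)
  }
  # order grads exactly like params for flattening
  out <- list(conv = g$conv, lstm_ln = g$lstm_ln, lstm = g$lstm, head = g$head)
  if (!is.null(p$ada)) out$ada <- g$ada
  list(grads = out, dx = dx)
}

#' Focal loss
#'
#' `L_F = sum_n alpha_{l(n)} (1 - p_n)^gamma * L_CE(y_n, yhat_n)`, where
#' `L_CE` is the cross-entropy of the true class, `p_n = exp(-L_CE)` is the
#' predicted probability of the true class, and `alpha_l = count(y)_l /
#' count(y)` is the label rate of class `l` in the batch (see
#' [model_config()]'s `alpha_mode` for the inverse-frequency variant). True-
#' class probabilities of zero are clamped at `1e-12` with a warning.
#'
#' @param class_probs Numeric matrix, `N x K`, one probability row per sample
#'   (rows must sum to 1).
#' @param true_labels Integer vector of length `N` with values in `1..K` (or
#'   `0..K-1`, auto-detected when a 0 is present).
#' @param gamma Focusing parameter, `>= 0` (default 2).
#' @param alpha_mode `"as_printed"` or `"inverse"`; see [model_config()].
#' @return The scalar loss (sum over samples, nonnegative; zero iff all true
#'   classes are predicted with probability 1).
#' @examples
#' focal_loss(matrix(c(0.5, 0.25, 0.25), 1), 1, gamma = 2)  # 0.25 * log(2)
#' @export
focal_loss <- function(class_probs, true_labels, gamma = 2,
                       alpha_mode = c("as_printed", "inverse")) {
  alpha_mode <- match.arg(alpha_mode)
  class_probs <- as.matrix(class_probs)
  if (length(true_labels) != nrow(class_probs) || length(true_labels) < 1L)
    stop("need one true label per probability row (and at least one sample)",
         call. = FALSE)
  if (any(class_probs < 0) || any(abs(rowSums(class_probs) - 1) > 1e-6))
    stop("`class_probs` rows must be probability simplices", call. = FALSE)
  y <- as.integer(true_labels)
  if (any(y == 0L)) y <- y + 1L
  if (any(y < 1L | y > ncol(class_probs)))
    stop("labels outside 1..K", call. = FALSE)
  check_scalar_num(gamma, "gamma", min = 0)
  focal_loss_grad(t(class_probs), y, gamma, alpha_mode)$loss
}

#' Gradient reversal layer
#'
#' Identity in the forward pass; during backpropagation the sensitivities
#' flowing through it are multiplied by `-lambda`. This function implements
#' the forward contract and documents the backward one (which the training
#' loop applies when back-propagating the domain loss into the shared trunk);
#' `grl_backward()` exposes the gradient rule for verification.
#'
#' @param x Input features (any numeric array).
#' @param lambda Reversal strength (finite; unused in the forward pass).
#' @return `x`, unchanged.
#' @export
gradient_reversal <- function(x, lambda = 1.0) {
  check_scalar_num(lambda, "lambda")
  x
}

#' @rdname gradient_reversal
#' @param grad Upstream gradient.
#' @export
grl_backward <- function(grad, lambda = 1.0) {
  check_scalar_num(lambda, "lambda")
  -lambda * grad
}

#' Predict class probabilities for a frame sequence
#'
#' Runs the model in evaluation mode (dropout disabled) over a whole trial as
#' one sequence, carrying the LSTM state across frames as a real-time decoder
#' would.
#'
#' @param model An [build_model()] object.
#' @param frames A `"dnn_input_sequence"` from [assemble_frames()], or a bare
#'   `(C, T, N)` array.
#' @return List with `class_probs` (`N x K` rows), `predicted` (0-based class
#'   per frame), and `domain_probs` when the model has an ADA head.
#' @export
predict_frames <- function(model, frames) {
  x <- if (inherits(frames, "dnn_input_sequence")) frames$frames else frames
  if (dim(x)[3L] == 0L)
    return(list(class_probs = matrix(0, 0L, model$config$n_classes),
                predicted = integer(0)))
  fw <- model_forward(model, x, n_seq = 1L, training = FALSE,
                      with_domain = model$config$ada)
  res <- list(class_probs = t(fw$class_probs),
              predicted = max.col(t(fw$class_probs), ties.method = "first") - 1L)
  if (model$config$ada) res$domain_probs <- t(fw$domain_probs)
  res
}

## parameter flattening for the optimizer ----------------------------------
flatten_params <- function(p) unlist(p, use.names = FALSE)
unflatten_params <- function(flat, skel) utils::relist(flat, skel)

# logical mask over the flat parameter vector, TRUE where the parameter
# belongs to one of the named top-level groups
param_group_mask <- function(params, groups) {
  unlist(lapply(names(params), function(nm) {
    rep(nm %in% groups, length(unlist(params[[nm]], use.names = FALSE)))
  }))
}
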