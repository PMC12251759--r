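test_that("compiled layer kernels match the pure-R reference implementations", {
  set.seed(21)
  x <- array(rnorm(5 * 9 * 4), c(5, 9, 4))
  W <- matrix(rnorm(5 * 15), 5, 15); b <- rnorm(5)
  f1 <- emgswn:::conv1d_fwd(x, W, b)
  f2 <- emgswn:::conv1d_fwd_ref(x, W, b)
  expect_equal(f1$out, f2$out, tolerance = 1e-12)
  dy <- array(rnorm(length(f1$out)), dim(f1$out))
  b1 <- emgswn:::conv1d_bwd(dy, W, f1$cache)
  b2 <- emgswn:::conv1d_bwd_ref(dy, W, f2$cache)
  expect_equal(b1$dx, b2$dx, tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(b1$dW, b2$dW, tolerance = 1e-12)
  expect_equal(b1$db, b2$db, tolerance = 1e-12)

  p1 <- emgswn:::blurpool_fwd(x); p2 <- emgswn:::blurpool_fwd_ref(x)
  expect_equal(p1$out, p2$out, tolerance = 1e-12)
  dyp <- array(rnorm(length(p1$out)), dim(p1$out))
  expect_equal(emgswn:::blurpool_bwd(dyp, p1$cache),
               emgswn:::blurpool_bwd_ref(dyp, p2$cache), tolerance = 1e-12,
               ignore_attr = TRUE)

  xm <- matrix(rnorm(6 * 30), 6)
  g <- runif(6, 0.5, 1.5); be <- rnorm(6)
  l1 <- emgswn:::ln_fwd(xm, g, be); l2 <- emgswn:::ln_fwd_ref(xm, g, be)
  expect_equal(l1$out, l2$out, tolerance = 1e-12)
  dyl <- matrix(rnorm(6 * 30), 6)
  r1 <- emgswn:::ln_bwd(dyl, g, l1$cache)
  r2 <- emgswn:::ln_bwd_ref(dyl, g, l2$cache)
  expect_equal(r1$dx, r2$dx, tolerance = 1e-12)
  expect_equal(r1$dgamma, r2$dgamma, tolerance = 1e-12)

  D <- 4L; H <- 4L; Fn <- 7L; B <- 3L
  xs <- array(rnorm(D * Fn * B), c(D, Fn, B))
  Wx <- matrix(rnorm(4 * H * D) * 0.3, 4 * H, D)
  Wh <- matrix(rnorm(4 * H * H) * 0.3, 4 * H, H)
  bb <- rnorm(4 * H) * 0.1
  s1 <- emgswn:::lstm_fwd(xs, Wx, Wh, bb)
  s2 <- emgswn:::lstm_fwd_ref(xs, Wx, Wh, bb)
  expect_equal(s1$out, s2$out, tolerance = 1e-12)
  dys <- array(rnorm(H * Fn * B), c(H, Fn, B))
  t1 <- emgswn:::lstm_bwd(dys, xs, Wx, Wh, s1$cache)
  t2 <- emgswn:::lstm_bwd_ref(dys, xs, Wx, Wh, s2$cache)
  for (nm in c("dx", "dWx", "dWh", "db"))
    expect_equal(t1[[nm]], t2[[nm]], tolerance = 1e-12)
})

test_that("analytic gradients match finite differences, including the GRL sign", {
  set.seed(42)
  cfg <- model_config(n_input_channels = 4, t_seg = 6, ada = TRUE,
                      dropout_rates = rep(0, 4), lstm_dropout = 0)
  N <- 6L; B <- 2L
  x <- array(rnorm(4 * 6 * N) * 2, c(4, 6, N))
  y <- sample(1:3, N, replace = TRUE)
  dom <- sample(1:3, N, replace = TRUE)
  m <- build_model(cfg, seed = 1)   # seed with an active ADA-head ReLU
  fw0 <- emgswn:::model_forward(m, x, n_seq = B, with_domain = TRUE)
  expect_gt(mean(fw0$cache$ada$relu), 0.1)
  flat <- emgswn:::flatten_params(m$params)
  loss_part <- function(fl, part) {
    mm <- m; mm$params <- emgswn:::unflatten_params(fl, m$params)
    f <- emgswn:::model_forward(mm, x, n_seq = B, with_domain = TRUE)
    P <- if (part == "class") f$class_probs else f$domain_probs
    yy <- if (part == "class") y else dom
    emgswn:::focal_loss_grad(P, yy, cfg$focal_gamma)$loss
  }
  fc <- emgswn:::focal_loss_grad(fw0$class_probs, y, cfg$focal_gamma)
  fd <- emgswn:::focal_loss_grad(fw0$domain_probs, dom, cfg$focal_gamma)
  bw <- emgswn:::model_backward(m, fw0$cache, fc$dlogits, fd$dlogits)
  ga <- emgswn:::flatten_params(bw$grads)
  n_ada <- length(unlist(m$params$ada))
  is_ada <- seq_along(flat) > length(flat) - n_ada
  set.seed(7)
  idx <- sort(c(sample(which(!is_ada), 80), sample(which(is_ada), 30)))
  h <- 1e-5
  fd_grad <- function(i, part) {
    f1 <- flat; f2 <- flat
    f1[i] <- f1[i] + h; f2[i] <- f2[i] - h
    (loss_part(f1, part) - loss_part(f2, part)) / (2 * h)
  }
  gC <- vapply(idx, fd_grad, 0, part = "class")
  gD <- vapply(idx, fd_grad, 0, part = "domain")
  expect_gt(mean(abs(gD[!is_ada[idx]])), 0)  # domain loss reaches the trunk
  # through the GRL the trunk sees class - lambda * domain; the ADA head sees
  # the domain gradient unreversed
  expected <- ifelse(is_ada[idx], gD, gC - cfg$grl_lambda * gD)
  expect_lt(max(abs(ga[idx] - expected) / pmax(abs(expected), 1e-4)), 1e-4)
})

test_that("focal loss matches its closed forms and invariants", {
  # perfect predictions -> zero loss
  P <- matrix(c(1, 0, 0, 0, 1, 0), 2, byrow = TRUE)
  expect_equal(focal_loss(P, c(1, 2)), 0)
  # single sample, true-class probability 0.5, gamma = 2:
  # alpha = 1, L_CE = ln 2, L_F = 0.25 * ln 2
  expect_equal(focal_loss(matrix(c(0.5, 0.3, 0.2), 1), 1, gamma = 2),
               0.25 * log(2), tolerance = 1e-12)
  # gamma = 0 and a single-class batch reduce to the plain cross-entropy sum
  set.seed(30)
  p_true <- runif(6, 0.2, 0.9)
  P2 <- cbind(p_true, (1 - p_true) / 2, (1 - p_true) / 2)
  expect_equal(focal_loss(P2, rep(1, 6), gamma = 0), sum(-log(p_true)),
               tolerance = 1e-12)
  # nonnegative; strictly increasing as a true-class probability decreases
  l1 <- focal_loss(matrix(c(0.7, 0.2, 0.1), 1), 1)
  l2 <- focal_loss(matrix(c(0.6, 0.3, 0.1), 1), 1)
  expect_gt(l2, l1)
  expect_gte(l1, 0)
  # batch label-rate weights sum to 1 when every class is present
  al <- emgswn:::focal_loss_grad(t(P2), c(1, 1, 2, 2, 3, 3), 2)$alpha
  expect_equal(sum(al), 1)
  # zero probability for a true class is clamped with a warning
  expect_warning(focal_loss(matrix(c(0, 0.5, 0.5), 1), 1), "clamped")
  expect_error(focal_loss(matrix(c(0.6, 0.6, 0.2), 1), 1), "simplices")
})

test_that("gradient reversal is the identity forward with a sign-flip contract", {
  x <- array(rnorm(12), c(3, 4))
  expect_identical(gradient_reversal(x, 1.0), x)
  g <- matrix(rnorm(12), 3)
  expect_equal(grl_backward(g, 1.0), -g)
  expect_equal(grl_backward(g, 0), 0 * g)
})

test_that("model shapes and eval-mode determinism hold", {
  cfg <- model_config(n_input_channels = 12, t_seg = 50)
  m <- build_model(cfg, seed = 2)
  N <- 7L
  x <- array(abs(rnorm(12 * 50 * N)), c(12, 50, N))
  pr <- predict_frames(m, x)
  expect_equal(dim(pr$class_probs), c(N, 3L))
  expect_equal(rowSums(pr$class_probs), rep(1, N), tolerance = 1e-6)
  expect_true(all(pr$class_probs >= 0 & pr$class_probs <= 1))
  pr2 <- predict_frames(m, x)
  expect_identical(pr$class_probs, pr2$class_probs)
  # intra-frame length halves to 26 at the block-2 anti-aliased downsampling
  fw <- emgswn:::model_forward(m, x, n_seq = 1L)
  expect_equal(dim(fw$cache$conv[[2]]$cv$x)[2], 26L)
  # models with and without the ADA head share identical shared parameters
  m_ada <- build_model(model_config(n_input_channels = 12, t_seg = 50,
                                    ada = TRUE), seed = 2)
  expect_identical(m$params$conv, m_ada$params$conv)
  expect_identical(m$params$lstm, m_ada$params$lstm)
  expect_identical(m$params$head, m_ada$params$head)
  prd <- predict_frames(m_ada, x)
  expect_equal(dim(prd$domain_probs), c(N, 3L))
  expect_equal(rowSums(prd$domain_probs), rep(1, N), tolerance = 1e-6)
})

test_that("frame width follows the feature window but frame length does not", {
  for (fwin in c(200, 600, 1000)) {
    S <- n_segments(fwin)
    cfg <- model_config(n_input_channels = 3 * S, t_seg = 50)
    m <- build_model(cfg, seed = 3)
    x <- array(abs(rnorm(3 * S * 50 * 4)), c(3 * S, 50, 4))
    pr <- predict_frames(m, x)
    expect_equal(dim(pr$class_probs), c(4L, 3L))
  }
})
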