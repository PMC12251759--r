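## Neural-network engine. The layer kernels (layer norm, 1-D convolution,
## blur pooling, global average pooling, LSTM) run in C++ (src/nn_kernels.cpp)
## with BLAS-backed matrix products; pure-R reference implementations with the
## suffix `_ref` are kept below and cross-checked against the kernels in the
## test suite. Layouts:
##   conv stage  : array (channels C, intra-frame time T, frames N)
##   vector stage: matrix (features D, frames N)
##   lstm stage  : array (features D, sequence position F, batch B), N = F * B
##     with frame index fastest within a sequence.
## Every *_fwd returns list(out, cache); every *_bwd takes the upstream grad
## and returns the input gradient plus parameter gradients.

byrow_mat <- function(v, nr) matrix(rep(v, each = nr), nr)

## ---- fast paths ----------------------------------------------------------

ln_fwd <- function(x, gamma, beta, eps = 1e-5) {
  r <- cpp_ln_fwd(x, gamma, beta, eps)
  list(out = r$out, cache = list(xhat = r$xhat, inv = r$inv))
}

ln_bwd <- function(dy, gamma, cache) {
  r <- cpp_ln_bwd(dy, gamma, cache$xhat, cache$inv)
  list(dx = r$dx, dgamma = as.numeric(r$dgamma), dbeta = as.numeric(r$dbeta))
}

conv1d_fwd <- function(x, W, b, k = 3L, pad = 2L) {
  list(out = cpp_conv1d_fwd(x, W, b, k, pad), cache = list(x = x))
}

conv1d_bwd <- function(dy, W, cache, k = 3L, pad = 2L) {
  r <- cpp_conv1d_bwd(dy, W, cache$x, k, pad)
  list(dx = r$dx, dW = r$dW, db = as.numeric(r$db))
}

blurpool_fwd <- function(x) {
  r <- cpp_blurpool_fwd(x)
  list(out = r$out, cache = r$T)
}
blurpool_bwd <- function(dy, cache) cpp_blurpool_bwd(dy, cache)

gap_fwd <- function(x) list(out = cpp_gap_fwd(x), cache = dim(x))
gap_bwd <- function(dy, d) cpp_gap_bwd(dy, d[2L])

lstm_fwd <- function(x, Wx, Wh, b) {
  r <- cpp_lstm_fwd(x, Wx, Wh, b)
  list(out = r$out, cache = list(gates = r$gates, cst = r$cst))
}

lstm_bwd <- function(dy, x, Wx, Wh, cache) {
  r <- cpp_lstm_bwd(dy, x, Wx, Wh, cache$gates, cache$cst)
  list(dx = r$dx, dWx = r$dWx, dWh = r$dWh, db = as.numeric(r$db))
}

## ---- layers without a compiled kernel ------------------------------------

relu_fwd <- function(x) list(out = pmax(x, 0), cache = x > 0)
relu_bwd <- function(dy, cache) dy * cache

dropout_fwd <- function(x, rate, training) {
  if (!training || rate <= 0) return(list(out = x, cache = NULL))
  mask <- array((stats::runif(length(x)) >= rate) / (1 - rate),
                dim(x) %||% length(x))
  list(out = x * mask, cache = mask)
}
dropout_bwd <- function(dy, cache) if (is.null(cache)) dy else dy * cache

affine_fwd <- function(x, W, b) list(out = W %*% x + b, cache = x)
affine_bwd <- function(dy, W, cache)
  list(dx = crossprod(W, dy), dW = dy %*% t(cache), db = rowSums(dy))

sigmoid <- function(x) 1 / (1 + exp(-x))

softmax_cols <- function(z) {
  z <- z - byrow_mat(apply(z, 2L, max), nrow(z))
  e <- exp(z)
  e / byrow_mat(colSums(e), nrow(e))
}

# P: (K, N) column-simplex probabilities; y: integer 1..K. Returns the focal
# loss (sum over samples) and its gradient w.r.t. the logits, treating the
# per-batch label-rate weights alpha as constants.
focal_loss_grad <- function(P, y, gamma, alpha_mode = "as_printed",
                            weight = 1, p_floor = 1e-12) {
  K <- nrow(P); N <- ncol(P)
  counts <- tabulate(y, K)
  alpha <- if (alpha_mode == "inverse") {
    a <- ifelse(counts > 0, 1 / counts, 0); a / sum(a)
  } else counts / N
  an <- alpha[y]
  idx <- cbind(y, seq_len(N))
  p <- P[idx]
  if (any(p < p_floor)) {
    warning("predicted true-class probability clamped at ", p_floor,
            call. = FALSE)
    p <- pmax(p, p_floor)
  }
  ce <- -log(p)
  omp <- 1 - p
  loss <- sum(an * omp^gamma * ce)
  # d/d ce of [(1-p)^gamma * ce] with p = exp(-ce)
  dce <- an * (omp^gamma + if (gamma > 0) {
    term <- gamma * omp^(gamma - 1) * p * ce
    term[ce == 0] <- 0    # removable singularity for gamma < 1
    term
  } else 0)
  onehot <- matrix(0, K, N); onehot[idx] <- 1
  dlogits <- (P - onehot) * byrow_mat(dce, K)
  list(loss = weight * loss, dlogits = weight * dlogits, alpha = alpha)
}

## ---- Adam ----------------------------------------------------------------
adam_init <- function(n) list(m = rep(0, n), v = rep(0, n), t = 0L)

adam_step <- function(theta, grad, st, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8, mask = NULL) {
  st$t <- st$t + 1L
  st$m <- beta1 * st$m + (1 - beta1) * grad
  st$v <- beta2 * st$v + (1 - beta2) * grad^2
  upd <- lr * (st$m / (1 - beta1^st$t)) / (sqrt(st$v / (1 - beta2^st$t)) + eps)
  if (!is.null(mask)) upd <- upd * mask
  list(theta = theta - upd, state = st)
}

## ---- pure-R reference implementations (test oracles) ---------------------

ln_fwd_ref <- function(x, gamma, beta, eps = 1e-5) {
  C <- nrow(x)
  m <- colMeans(x)
  v <- colMeans(x * x) - m * m
  inv <- 1 / sqrt(pmax(v, 0) + eps)
  xhat <- (x - byrow_mat(m, C)) * byrow_mat(inv, C)
  list(out = gamma * xhat + beta, cache = list(xhat = xhat, inv = inv))
}

ln_bwd_ref <- function(dy, gamma, cache) {
  C <- nrow(dy)
  xhat <- cache$xhat
  dxhat <- dy * gamma
  s1 <- colSums(dxhat) / C
  s2 <- colSums(dxhat * xhat) / C
  dx <- byrow_mat(as.numeric(cache$inv), C) *
    (dxhat - byrow_mat(s1, C) - xhat * byrow_mat(s2, C))
  list(dx = dx, dgamma = rowSums(dy * xhat), dbeta = rowSums(dy))
}

conv1d_fwd_ref <- function(x, W, b, k = 3L, pad = 2L) {
  d <- dim(x); C <- d[1L]; T <- d[2L]; N <- d[3L]
  Tp <- T + 2L * pad
  xp <- array(0, c(C, Tp, N))
  xp[, (pad + 1L):(pad + T), ] <- x
  L <- Tp - k + 1L
  xcol <- matrix(0, C * k, L * N)
  for (j in seq_len(k))
    xcol[((j - 1L) * C + 1L):(j * C), ] <-
      matrix(xp[, j:(j + L - 1L), , drop = FALSE], C, L * N)
  y <- W %*% xcol + b
  list(out = array(y, c(nrow(W), L, N)), cache = list(x = x, xcol = xcol))
}

conv1d_bwd_ref <- function(dy, W, cache, k = 3L, pad = 2L) {
  d <- dim(cache$x); C <- d[1L]; T <- d[2L]; N <- d[3L]
  L <- dim(dy)[2L]
  dym <- matrix(dy, dim(dy)[1L], L * N)
  dW <- dym %*% t(cache$xcol)
  db <- rowSums(dym)
  dxcol <- crossprod(W, dym)
  Tp <- T + 2L * pad
  dxp <- array(0, c(C, Tp, N))
  for (j in seq_len(k))
    dxp[, j:(j + L - 1L), ] <- dxp[, j:(j + L - 1L), , drop = FALSE] +
      array(dxcol[((j - 1L) * C + 1L):(j * C), ], c(C, L, N))
  list(dx = dxp[, (pad + 1L):(pad + T), , drop = FALSE], dW = dW, db = db)
}

blurpool_fwd_ref <- function(x) {
  d <- dim(x); C <- d[1L]; T <- d[2L]; N <- d[3L]
  xp <- array(0, c(C, T + 2L, N))
  xp[, 2L:(T + 1L), ] <- x
  L <- (T + 2L - 3L) %/% 2L + 1L
  st <- seq.int(1L, by = 2L, length.out = L)
  y <- (xp[, st, , drop = FALSE] + 2 * xp[, st + 1L, , drop = FALSE] +
          xp[, st + 2L, , drop = FALSE]) / 4
  list(out = y, cache = list(dims = d, st = st))
}

blurpool_bwd_ref <- function(dy, cache) {
  d <- cache$dims; st <- cache$st
  dxp <- array(0, c(d[1L], d[2L] + 2L, d[3L]))
  dxp[, st, ] <- dxp[, st, , drop = FALSE] + dy / 4
  dxp[, st + 1L, ] <- dxp[, st + 1L, , drop = FALSE] + dy / 2
  dxp[, st + 2L, ] <- dxp[, st + 2L, , drop = FALSE] + dy / 4
  dxp[, 2L:(d[2L] + 1L), , drop = FALSE]
}

lstm_fwd_ref <- function(x, Wx, Wh, b) {
  d <- dim(x); D <- d[1L]; Fn <- d[2L]; B <- d[3L]
  H <- nrow(Wh) %/% 4L
  h <- matrix(0, H, B); cst <- matrix(0, H, B)
  out <- array(0, c(H, Fn, B))
  cache <- vector("list", Fn)
  ri <- 1:H; rf <- (H + 1L):(2L * H); rg <- (2L * H + 1L):(3L * H)
  ro <- (3L * H + 1L):(4L * H)
  for (t in seq_len(Fn)) {
    xt <- matrix(x[, t, ], D, B)
    z <- Wx %*% xt + Wh %*% h + b
    i <- sigmoid(z[ri, , drop = FALSE]); f <- sigmoid(z[rf, , drop = FALSE])
    g <- tanh(z[rg, , drop = FALSE]); o <- sigmoid(z[ro, , drop = FALSE])
    c_prev <- cst
    cst <- f * c_prev + i * g
    tc <- tanh(cst)
    h_prev <- h
    h <- o * tc
    out[, t, ] <- h
    cache[[t]] <- list(xt = xt, i = i, f = f, g = g, o = o, c = cst,
                       c_prev = c_prev, tc = tc, h_prev = h_prev)
  }
  list(out = out, cache = cache)
}

lstm_bwd_ref <- function(dy, x, Wx, Wh, cache) {
  d <- dim(x); D <- d[1L]; Fn <- d[2L]; B <- d[3L]
  H <- nrow(Wh) %/% 4L
  dWx <- matrix(0, 4L * H, D); dWh <- matrix(0, 4L * H, H); db <- rep(0, 4L * H)
  dx <- array(0, c(D, Fn, B))
  dh_next <- matrix(0, H, B); dc_next <- matrix(0, H, B)
  for (t in rev(seq_len(Fn))) {
    cc <- cache[[t]]
    dh <- matrix(dy[, t, ], H, B) + dh_next
    do_ <- dh * cc$tc
    dc <- dh * cc$o * (1 - cc$tc^2) + dc_next
    di <- dc * cc$g; df <- dc * cc$c_prev; dg <- dc * cc$i
    dc_next <- dc * cc$f
    dz <- rbind(di * cc$i * (1 - cc$i),
                df * cc$f * (1 - cc$f),
                dg * (1 - cc$g^2),
                do_ * cc$o * (1 - cc$o))
    dWx <- dWx + dz %*% t(cc$xt)
    dWh <- dWh + dz %*% t(cc$h_prev)
    db <- db + rowSums(dz)
    dx[, t, ] <- crossprod(Wx, dz)
    dh_next <- crossprod(Wh, dz)
  }
  list(dx = dx, dWx = dWx, dWh = dWh, db = db)
}
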