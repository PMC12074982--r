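# Selective state-space (Mamba-style) layer: reference sequential scan plus
# a single-direction block (pre-norm, causal depthwise conv, SiLU, scan,
# multiplicative gate, output projection). Every forward returns a cache and
# has a matching hand-written backward; gradients are exercised by
# finite-difference tests.
#
# Discretization: zero-order hold for the transition (Abar = exp(delta * A))
# and the simplified Euler form for the input matrix (Bbar = delta * B).
# A is parameterized as -exp(A_log) so the discretized transition magnitude
# never exceeds 1 and the recurrence is stable for any positive delta.

.sigmoid <- function(x) 1 / (1 + exp(-x))
.silu <- function(x) x * .sigmoid(x)
.dsilu <- function(x) { s <- .sigmoid(x); s * (1 + x * (1 - s)) }
.softplus <- function(x) ifelse(x > 30, x, log1p(exp(pmin(x, 30))))

#' Configuration of one selective state-space block
#'
#' @param model_dim embedding width D of the residual stream
#' @param state_dim per-channel hidden state size N of the scan
#' @param expand expansion factor of the inner width (inner = expand * D)
#' @param conv_width kernel width of the causal depthwise convolution
#' @param dt_rank low-rank width of the step-size projection
#'   (default `ceiling(model_dim / 16)`)
#' @return a list of class `mamba_config`
#' @export
mamba_block_config <- function(model_dim, state_dim = 16L, expand = 2L,
                               conv_width = 4L, dt_rank = NULL) {
  if (is.null(dt_rank)) dt_rank <- max(1L, ceiling(model_dim / 16))
  cfg <- list(model_dim = as.integer(model_dim),
              state_dim = as.integer(state_dim),
              expand = as.integer(expand),
              conv_width = as.integer(conv_width),
              dt_rank = as.integer(dt_rank),
              inner_dim = as.integer(expand * model_dim))
  if (any(unlist(cfg) <= 0L)) stop("all mamba_block_config fields must be positive")
  class(cfg) <- "mamba_config"
  cfg
}

# torch-Linear-style uniform init on [-1/sqrt(fan_in), 1/sqrt(fan_in)]
.init_mat <- function(nr, nc, fan_in = nr) {
  b <- 1 / sqrt(fan_in)
  matrix(stats::runif(nr * nc, -b, b), nr, nc)
}

# Parameters of one single-direction block. The step size delta is produced
# by softplus(dt_in %*% W_dt + b_dt) with b_dt initialized so that delta
# starts in [1e-3, 0.1] (log-uniform), the standard choice for this family.
.init_block <- function(cfg) {
  E <- cfg$inner_dim; D <- cfg$model_dim; N <- cfg$state_dim
  k <- cfg$conv_width; R <- cfg$dt_rank
  dt0 <- exp(stats::runif(E, log(1e-3), log(0.1)))
  list(
    w_norm = rep(1, D),
    W_in   = .init_mat(D, 2L * E),
    W_conv = .init_mat(E, k, fan_in = k),
    b_conv = rep(0, E),
    W_x    = .init_mat(E, R + 2L * N),
    W_dt   = .init_mat(R, E),
    b_dt   = log(expm1(dt0)),           # softplus inverse
    A_log  = matrix(log(seq_len(N)), E, N, byrow = TRUE),
    D_skip = rep(1, E),
    W_out  = .init_mat(E, D)
  )
}

#' Sequential selective scan (reference recurrence)
#'
#' Runs the per-channel linear recurrence
#' `h_t = exp(delta_t * A) h_{t-1} + (delta_t * B_t) x_t`,
#' `y_t = C_t . h_t + D_skip * x_t`
#' over the sequence, one position at a time. This is the reference
#' implementation every optimized variant must match; it is also the exact
#' path used inside the block forward.
#'
#' @param delta positive step sizes, `[length, inner]`
#' @param A state transition parameters, `[inner, state]`, elementwise <= 0
#' @param B input projections per position, `[length, state]`
#' @param C readout projections per position, `[length, state]`
#' @param D_skip per-channel skip coefficients, length `inner`
#' @param x input, `[length, inner]`
#' @param h0 optional initial state `[inner, state]` (default zero)
#' @return list with `y` (`[length, inner]`) and `h` (final state)
#' @export
selective_scan <- function(delta, A, B, C, D_skip, x, h0 = NULL) {
  if (!all(is.finite(x)) || !all(is.finite(delta)))
    stop("non-finite input to selective_scan")
  sc <- .scan_forward(delta, A, B, C, D_skip, x, h0)
  list(y = sc$y, h = matrix(sc$H[, , dim(sc$H)[3L]], ncol(x), ncol(A)))
}

.scan_forward <- function(delta, A, B, C, D_skip, x, h0 = NULL) {
  L <- nrow(x); E <- ncol(x); N <- ncol(A)
  if (is.null(h0)) h0 <- matrix(0, E, N)
  H <- array(0, c(E, N, L))
  y <- matrix(0, L, E)
  h <- h0
  for (t in seq_len(L)) {
    Ab <- exp(A * delta[t, ])                     # [E,N], delta recycled by row
    h <- Ab * h + outer(delta[t, ] * x[t, ], B[t, ])
    H[, , t] <- h
    y[t, ] <- h %*% C[t, ] + D_skip * x[t, ]
  }
  list(y = y, H = H, h0 = h0, delta = delta, A = A, B = B, C = C,
       D_skip = D_skip, x = x)
}

.scan_backward <- function(cache, dy) {
  delta <- cache$delta; A <- cache$A; B <- cache$B; C <- cache$C
  x <- cache$x; H <- cache$H; h0 <- cache$h0; D_skip <- cache$D_skip
  L <- nrow(x); E <- ncol(x); N <- ncol(A)
  dx <- matrix(0, L, E); ddelta <- matrix(0, L, E)
  dB <- matrix(0, L, N); dC <- matrix(0, L, N)
  dA <- matrix(0, E, N); dD <- rep(0, E)
  dh <- matrix(0, E, N)
  for (t in rev(seq_len(L))) {
    ht <- matrix(H[, , t], E, N)
    dC[t, ] <- drop(crossprod(ht, dy[t, ]))
    dD <- dD + dy[t, ] * x[t, ]
    dx[t, ] <- D_skip * dy[t, ]
    dh <- dh + outer(dy[t, ], C[t, ])
    hprev <- if (t > 1L) matrix(H[, , t - 1L], E, N) else h0
    Ab <- exp(A * delta[t, ])
    dAb <- dh * hprev
    dA <- dA + dAb * Ab * delta[t, ]
    du_row <- dh %*% B[t, ]                       # [E,1]: sum_n dh * B
    dB[t, ] <- drop(crossprod(dh, delta[t, ] * x[t, ]))
    ddelta[t, ] <- drop(du_row) * x[t, ] + rowSums(dAb * Ab * A)
    dx[t, ] <- dx[t, ] + drop(du_row) * delta[t, ]
    dh <- dh * Ab
  }
  list(dx = dx, ddelta = ddelta, dB = dB, dC = dC, dA = dA, dD_skip = dD,
       dh0 = dh)
}

# --- RMSNorm ----------------------------------------------------------------

.rmsnorm_forward <- function(X, w, eps = 1e-5) {
  s <- 1 / sqrt(rowMeans(X^2) + eps)
  list(y = X * s * rep(w, each = nrow(X)), cache = list(X = X, w = w, s = s))
}

.rmsnorm_backward <- function(cache, dY) {
  X <- cache$X; w <- cache$w; s <- cache$s
  D <- ncol(X)
  Wd <- rep(w, each = nrow(X))
  dot <- rowSums(dY * X * Wd)                     # sum_j dy_ij x_ij w_j
  dX <- dY * Wd * s - X * (s^3 * dot / D)
  dw <- colSums(dY * X * s)
  list(dX = dX, dw = dw)
}

# --- causal depthwise conv1d ------------------------------------------------

.conv_forward <- function(X, W, b) {
  L <- nrow(X); E <- ncol(X); k <- ncol(W)
  Y <- matrix(rep(b, each = L), L, E)
  for (j in seq_len(k)) {
    lag <- j - 1L
    if (lag >= L) break
    idx <- seq_len(L - lag)
    Y[idx + lag, ] <- Y[idx + lag, ] + X[idx, ] * rep(W[, j], each = L - lag)
  }
  Y
}

.conv_backward <- function(X, W, dY) {
  L <- nrow(X); E <- ncol(X); k <- ncol(W)
  dX <- matrix(0, L, E); dW <- matrix(0, E, k)
  for (j in seq_len(k)) {
    lag <- j - 1L
    if (lag >= L) break
    idx <- seq_len(L - lag)
    dX[idx, ] <- dX[idx, ] + dY[idx + lag, ] * rep(W[, j], each = L - lag)
    dW[, j] <- colSums(X[idx, , drop = FALSE] * dY[idx + lag, , drop = FALSE])
  }
  list(dX = dX, dW = dW, db = colSums(dY))
}

# --- mixer (inner part of the block, after pre-norm) ------------------------

.mixer_forward <- function(p, cfg, X) {
  E <- cfg$inner_dim; N <- cfg$state_dim; R <- cfg$dt_rank
  xz <- X %*% p$W_in
  x1 <- xz[, seq_len(E), drop = FALSE]
  z  <- xz[, E + seq_len(E), drop = FALSE]
  xc <- .conv_forward(x1, p$W_conv, p$b_conv)
  xa <- .silu(xc)
  dbc <- xa %*% p$W_x
  dt_in <- dbc[, seq_len(R), drop = FALSE]
  Bt <- dbc[, R + seq_len(N), drop = FALSE]
  Ct <- dbc[, R + N + seq_len(N), drop = FALSE]
  dt_pre <- dt_in %*% p$W_dt + rep(p$b_dt, each = nrow(X))
  delta <- .softplus(dt_pre)
  A <- -exp(p$A_log)
  sc <- .scan_forward(delta, A, Bt, Ct, p$D_skip, xa)
  y <- sc$y
  yg <- y * .silu(z)
  out <- yg %*% p$W_out
  list(out = out,
       cache = list(X = X, x1 = x1, z = z, xc = xc, xa = xa, dt_in = dt_in,
                    dt_pre = dt_pre, sc = sc, y = y, yg = yg))
}

.mixer_backward <- function(p, cfg, cache, dOut) {
  E <- cfg$inner_dim; N <- cfg$state_dim; R <- cfg$dt_rank
  y <- cache$y; z <- cache$z; xa <- cache$xa; xc <- cache$xc
  dW_out <- crossprod(cache$yg, dOut)
  dyg <- tcrossprod(dOut, p$W_out)
  dy <- dyg * .silu(z)
  dz <- dyg * y * .dsilu(z)
  sb <- .scan_backward(cache$sc, dy)
  dA_log <- sb$dA * cache$sc$A                    # dA/dA_log = -exp(A_log) = A
  dpre <- sb$ddelta * .sigmoid(cache$dt_pre)
  dW_dt <- crossprod(cache$dt_in, dpre)
  db_dt <- colSums(dpre)
  ddt_in <- tcrossprod(dpre, p$W_dt)
  ddbc <- cbind(ddt_in, sb$dB, sb$dC)
  dW_x <- crossprod(xa, ddbc)
  dxa <- sb$dx + tcrossprod(ddbc, p$W_x)
  dxc <- dxa * .dsilu(xc)
  cb <- .conv_backward(cache$x1, p$W_conv, dxc)
  dxz <- cbind(cb$dX, dz)
  dW_in <- crossprod(cache$X, dxz)
  dX <- tcrossprod(dxz, p$W_in)
  list(dX = dX,
       grads = list(W_in = dW_in, W_conv = cb$dW, b_conv = cb$db,
                    W_x = dW_x, W_dt = dW_dt, b_dt = db_dt,
                    A_log = dA_log, D_skip = sb$dD_skip, W_out = dW_out))
}

# --- full single-direction block (pre-norm + residual contract) -------------

# residual_new = hidden + residual (or hidden when residual is NULL);
# hidden_new = mixer(rmsnorm(residual_new)). Returns both streams, matching
# the (hidden_states, residual) signature the bidirectional wrapper zips.
.block_forward <- function(p, cfg, hidden, residual = NULL) {
  res <- if (is.null(residual)) hidden else hidden + residual
  nf <- .rmsnorm_forward(res, p$w_norm)
  mx <- .mixer_forward(p, cfg, nf$y)
  list(hidden = mx$out, residual = res,
       cache = list(norm = nf$cache, mixer = mx$cache))
}

.block_backward <- function(p, cfg, cache, dhidden, dresidual) {
  mb <- .mixer_backward(p, cfg, cache$mixer, dhidden)
  nb <- .rmsnorm_backward(cache$norm, mb$dX)
  dres <- nb$dX + dresidual
  grads <- c(list(w_norm = nb$dw), mb$grads)   # field order mirrors .init_block
  # d(hidden_in) = dres; d(residual_in) = dres (residual_new = hidden + residual)
  list(dhidden = dres, dresidual = dres, grads = grads)
}

.map_batch <- function(h, f) {
  # accept [L,D] matrix or [B,L,D] array; apply f per sequence matrix
  if (is.matrix(h)) return(f(h))
  out <- h
  for (b in seq_len(dim(h)[1L])) out[b, , ] <- f(h[b, , ])
  out
}

#' Forward pass of one single-direction selective state-space layer
#'
#' Applies pre-normalization with residual update, input projection with
#' expansion, causal depthwise 1-D convolution, SiLU, the selective scan,
#' a multiplicative SiLU gate branch and the output projection back to
#' `model_dim`. Shape-preserving. The layer is causal: position `t` of the
#' output depends only on positions `<= t` of the input — bidirectional
#' context requires the wrapper in [bidirectional_layer_forward()].
#'
#' @param params block parameters (see [init_lm_weights()] internals)
#' @param cfg a [mamba_block_config()]
#' @param hidden `[length, model_dim]` matrix or `[batch, length, model_dim]`
#'   array
#' @param residual same shape as `hidden`, or `NULL` on the first layer
#' @return list with updated `hidden` and `residual`
#' @export
mamba_layer_forward <- function(params, cfg, hidden, residual = NULL) {
  dims <- if (is.matrix(hidden)) dim(hidden) else dim(hidden)[-1L]
  if (dims[1L] < 1L) stop("empty sequence")
  if (is.matrix(hidden)) {
    fw <- .block_forward(params, cfg, hidden, residual)
    return(list(hidden = fw$hidden, residual = fw$residual))
  }
  Bn <- dim(hidden)[1L]
  outh <- hidden; outr <- hidden
  for (b in seq_len(Bn)) {
    rb <- if (is.null(residual)) NULL else residual[b, , ]
    fw <- .block_forward(params, cfg, hidden[b, , ], rb)
    outh[b, , ] <- fw$hidden; outr[b, , ] <- fw$residual
  }
  list(hidden = outh, residual = outr)
}
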