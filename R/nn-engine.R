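#' @include features.R
NULL

# ---------------------------------------------------------------------------
# Minimal neural-network engine on base-R matrix ops (BLAS-backed).
#
# A model is an ordered list of layer objects; each layer is a list with a
# $type, trainable $params (named numeric arrays), and optional $state
# (non-trainable, e.g. batch-norm running moments). Forward passes return
# caches consumed by the matching backward pass; gradients mirror the
# $params structure. Optimisation is Adam. Everything is deterministic
# given the RNG state, which the training loop seeds.
#
# Data layouts:
#   conv/pool path: array (L, B, C)        -- length x batch x channels;
#                                             chosen so im2col, batch norm
#                                             and pooling are pure reshapes
#   recurrent path: array (T, D, B)        -- timesteps x features x batch
#   token path:     matrix (Tn*B, d)       -- rows grouped by batch, token
#                                             index fastest
#   dense head:     matrix (B, D)
# ---------------------------------------------------------------------------

.glorot <- function(fan_in, fan_out, dims = c(fan_in, fan_out)) {
  lim <- sqrt(6 / (fan_in + fan_out))
  array(stats::runif(prod(dims), -lim, lim), dim = dims)
}

# column-broadcast helpers (avoid sweep(), which aperm-copies)
.col_add <- function(M, v) M + rep(v, each = nrow(M))
.col_mul <- function(M, v) M * rep(v, each = nrow(M))

.sigmoid <- function(x) 1 / (1 + exp(-x))

# -- conv1d ("same" padding, stride 1) --------------------------------------

layer_conv1d <- function(c_in, c_out, k) {
  list(type = "conv1d", k = k, c_in = c_in, c_out = c_out,
       params = list(W = .glorot(k * c_in, c_out),
                     b = numeric(c_out)))
}

.im2col <- function(xp, L, C, B, k) {
  M <- matrix(0, nrow = L * B, ncol = k * C)
  for (j in seq_len(k)) {
    # (L, B, C) slice flattens with l fastest then b: exactly the row order
    M[, ((j - 1L) * C + 1L):(j * C)] <- xp[j:(j + L - 1L), , , drop = FALSE]
  }
  M
}

fw_conv1d <- function(layer, x, training) {
  d <- dim(x); L <- d[1]; B <- d[2]; C <- d[3]; k <- layer$k
  pl <- (k - 1L) %/% 2L
  xp <- array(0, dim = c(L + k - 1L, B, C))
  xp[(pl + 1L):(pl + L), , ] <- x
  M <- .im2col(xp, L, C, B, k)
  Y <- .col_add(M %*% layer$params$W, layer$params$b)
  dim(Y) <- c(L, B, layer$c_out)
  list(out = Y, cache = list(M = M, L = L, C = C, B = B, pl = pl))
}

bw_conv1d <- function(layer, cache, dy) {
  L <- cache$L; C <- cache$C; B <- cache$B; k <- layer$k
  dYm <- matrix(dy, nrow = L * B)                     # (L*B, c_out)
  dW <- crossprod(cache$M, dYm)
  db <- colSums(dYm)
  dM <- dYm %*% t(layer$params$W)                     # (L*B, k*C)
  dxp <- array(0, dim = c(L + k - 1L, B, C))
  for (j in seq_len(k)) {
    dxp[j:(j + L - 1L), , ] <- dxp[j:(j + L - 1L), , , drop = FALSE] +
      c(dM[, ((j - 1L) * C + 1L):(j * C)])
  }
  dx <- dxp[(cache$pl + 1L):(cache$pl + L), , , drop = FALSE]
  list(dx = dx, grads = list(W = dW, b = db))
}

# -- batch normalisation over (length, batch) per channel -------------------

layer_batchnorm <- function(c_ch, eps = 1e-5, momentum = 0.1) {
  list(type = "batchnorm", eps = eps, momentum = momentum,
       params = list(gamma = rep(1, c_ch), beta = numeric(c_ch)),
       state = list(mean = numeric(c_ch), var = rep(1, c_ch)))
}

fw_batchnorm <- function(layer, x, training) {
  d <- dim(x); L <- d[1]; B <- d[2]; C <- d[3]
  xm <- matrix(x, ncol = C)                           # (L*B, C)
  if (training) {
    mu <- colMeans(xm)
    v <- colMeans(xm^2) - mu^2
    layer$state$mean <- (1 - layer$momentum) * layer$state$mean + layer$momentum * mu
    layer$state$var <- (1 - layer$momentum) * layer$state$var + layer$momentum * v
  } else {
    mu <- layer$state$mean
    v <- layer$state$var
  }
  inv <- 1 / sqrt(v + layer$eps)
  xhat <- .col_mul(.col_add(xm, -mu), inv)
  y <- .col_add(.col_mul(xhat, layer$params$gamma), layer$params$beta)
  dim(y) <- c(L, B, C)
  list(out = y, cache = list(xhat = xhat, inv = inv, L = L, C = C, B = B,
                             training = training),
       layer = layer)
}

bw_batchnorm <- function(layer, cache, dy) {
  L <- cache$L; C <- cache$C; B <- cache$B
  dym <- matrix(dy, ncol = C)
  dgamma <- colSums(dym * cache$xhat)
  dbeta <- colSums(dym)
  g_inv <- layer$params$gamma * cache$inv
  if (cache$training) {
    t1 <- .col_add(dym, -colMeans(dym))
    t2 <- .col_mul(cache$xhat, colMeans(dym * cache$xhat))
    dxm <- .col_mul(t1 - t2, g_inv)
  } else {
    dxm <- .col_mul(dym, g_inv)
  }
  dim(dxm) <- c(L, B, C)
  list(dx = dxm, grads = list(gamma = dgamma, beta = dbeta))
}

# -- elementwise ReLU -------------------------------------------------------

layer_relu <- function() list(type = "relu", params = list())

fw_relu <- function(layer, x, training) {
  mask <- x > 0
  list(out = x * mask, cache = list(mask = mask))
}

bw_relu <- function(layer, cache, dy) {
  list(dx = dy * cache$mask, grads = list())
}

# -- max pooling (window = stride = p) over the length axis -----------------

layer_maxpool <- function(p) list(type = "maxpool", p = p, params = list())

fw_maxpool <- function(layer, x, training) {
  d <- dim(x); L <- d[1]; B <- d[2]; C <- d[3]; p <- layer$p
  stopifnot(L %% p == 0L)
  L2 <- L %/% p
  xm <- matrix(x, nrow = p)                           # (p, L2*B*C)
  best <- xm[1, ]; idx <- rep(1L, ncol(xm))
  if (p > 1L) {
    for (j in 2:p) {
      upd <- xm[j, ] > best
      best[upd] <- xm[j, upd]
      idx[upd] <- j
    }
  }
  out <- array(best, dim = c(L2, B, C))
  list(out = out, cache = list(idx = idx, L = L, p = p, dims = c(L2, B, C)))
}

bw_maxpool <- function(layer, cache, dy) {
  p <- cache$p
  m <- length(cache$idx)
  dxm <- matrix(0, nrow = p, ncol = m)
  dxm[cbind(cache$idx, seq_len(m))] <- as.numeric(dy)
  dx <- array(dxm, dim = c(cache$L, cache$dims[2], cache$dims[3]))
  list(dx = dx, grads = list())
}

# -- average pool (window = stride = p) over the length axis ----------------

layer_avgpool <- function(p) list(type = "avgpool", p = p, params = list())

fw_avgpool <- function(layer, x, training) {
  d <- dim(x); L <- d[1]; B <- d[2]; C <- d[3]; p <- layer$p
  stopifnot(L %% p == 0L)
  out <- array(colMeans(matrix(x, nrow = p)), dim = c(L %/% p, B, C))
  list(out = out, cache = list(L = L, p = p, dims = dim(out)))
}

bw_avgpool <- function(layer, cache, dy) {
  dx <- array(rep(as.numeric(dy) / cache$p, each = cache$p),
              dim = c(cache$L, cache$dims[2], cache$dims[3]))
  list(dx = dx, grads = list())
}

# -- flatten (L,B,C) -> (B, L*C) --------------------------------------------

layer_flatten <- function() list(type = "flatten", params = list())

fw_flatten <- function(layer, x, training) {
  d <- dim(x)
  xt <- aperm(x, c(2, 1, 3))
  dim(xt) <- c(d[2], d[1] * d[3])
  list(out = xt, cache = list(dims = d))
}

bw_flatten <- function(layer, cache, dy) {
  d <- cache$dims
  dim(dy) <- c(d[2], d[1], d[3])
  list(dx = aperm(dy, c(2, 1, 3)), grads = list())
}

# -- global average pool over the length axis: (L,B,C) -> (B,C) -------------

layer_gap <- function() list(type = "gap", params = list())

fw_gap <- function(layer, x, training) {
  d <- dim(x); L <- d[1]; B <- d[2]; C <- d[3]
  cm <- colMeans(matrix(x, nrow = L))                 # length B*C, b fastest
  list(out = matrix(cm, nrow = B), cache = list(L = L, C = C, B = B))
}

bw_gap <- function(layer, cache, dy) {
  L <- cache$L; C <- cache$C; B <- cache$B
  dx <- array(rep(as.numeric(dy) / L, each = L), dim = c(L, B, C))
  list(dx = dx, grads = list())
}

# -- inverted dropout -------------------------------------------------------

layer_dropout <- function(rate) list(type = "dropout", rate = rate, params = list())

fw_dropout <- function(layer, x, training) {
  if (!training || layer$rate <= 0) {
    return(list(out = x, cache = list(mask = NULL)))
  }
  keep <- 1 - layer$rate
  mask <- (stats::runif(length(x)) < keep) / keep
  dim(mask) <- dim(x)
  list(out = x * mask, cache = list(mask = mask))
}

bw_dropout <- function(layer, cache, dy) {
  if (is.null(cache$mask)) list(dx = dy, grads = list())
  else list(dx = dy * cache$mask, grads = list())
}

# -- fully connected --------------------------------------------------------

layer_dense <- function(d_in, d_out) {
  list(type = "dense", params = list(W = .glorot(d_in, d_out),
                                     b = numeric(d_out)))
}

fw_dense <- function(layer, x, training) {
  y <- x %*% layer$params$W
  y <- sweep(y, 2, layer$params$b, `+`)
  list(out = y, cache = list(x = x))
}

bw_dense <- function(layer, cache, dy) {
  list(dx = dy %*% t(layer$params$W),
       grads = list(W = crossprod(cache$x, dy), b = colSums(dy)))
}

# -- LSTM (returns the final hidden state) ----------------------------------

layer_lstm <- function(d_in, h) {
  W <- .glorot(d_in + h, 4 * h)
  b <- numeric(4 * h)
  b[(h + 1):(2 * h)] <- 1 # forget-gate bias init
  list(type = "lstm", d_in = d_in, h = h, params = list(W = W, b = b))
}

fw_lstm <- function(layer, x, training) {
  d <- dim(x); Tn <- d[1]; D <- d[2]; B <- d[3]; H <- layer$h
  h <- matrix(0, B, H); cc <- matrix(0, B, H)
  steps <- vector("list", Tn)
  for (t in seq_len(Tn)) {
    xt <- t(matrix(x[t, , ], nrow = D))               # (B, D)
    z <- cbind(xt, h) %*% layer$params$W
    z <- sweep(z, 2, layer$params$b, `+`)
    i <- .sigmoid(z[, 1:H, drop = FALSE])
    f <- .sigmoid(z[, (H + 1):(2 * H), drop = FALSE])
    g <- tanh(z[, (2 * H + 1):(3 * H), drop = FALSE])
    o <- .sigmoid(z[, (3 * H + 1):(4 * H), drop = FALSE])
    c_prev <- cc
    cc <- f * c_prev + i * g
    tc <- tanh(cc)
    steps[[t]] <- list(xt = xt, h_prev = h, c_prev = c_prev, i = i, f = f,
                       g = g, o = o, tc = tc)
    h <- o * tc
  }
  list(out = h, cache = list(steps = steps, Tn = Tn, D = D, B = B))
}

bw_lstm <- function(layer, cache, dy, need_dx = FALSE) {
  H <- layer$h; D <- cache$D; Tn <- cache$Tn; B <- cache$B
  W <- layer$params$W
  dW <- matrix(0, nrow = D + H, ncol = 4 * H)
  db <- numeric(4 * H)
  dh <- dy
  dc <- matrix(0, B, H)
  dx <- if (need_dx) array(0, dim = c(Tn, D, B)) else NULL
  for (t in rev(seq_len(Tn))) {
    s <- cache$steps[[t]]
    do <- dh * s$tc
    dc <- dc + dh * s$o * (1 - s$tc^2)
    di <- dc * s$g
    dg <- dc * s$i
    df <- dc * s$c_prev
    dz <- cbind(di * s$i * (1 - s$i), df * s$f * (1 - s$f),
                dg * (1 - s$g^2), do * s$o * (1 - s$o))
    dW <- dW + crossprod(cbind(s$xt, s$h_prev), dz)
    db <- db + colSums(dz)
    dinp <- dz %*% t(W)
    dh <- dinp[, (D + 1):(D + H), drop = FALSE]
    dc <- dc * s$f
    if (need_dx) dx[t, , ] <- t(dinp[, 1:D, drop = FALSE])
  }
  list(dx = dx, grads = list(W = dW, b = db))
}

# -- patch embedding + learnable positional encoding ------------------------
# input array (Tn, Tp, B) -> token matrix (Tn*B, d), token index fastest.

layer_patch_embed <- function(t_patch, d_model, n_tokens) {
  list(type = "patch_embed", Tn = n_tokens,
       params = list(W = .glorot(t_patch, d_model),
                     b = numeric(d_model),
                     pe = array(stats::rnorm(n_tokens * d_model, sd = 0.02),
                                dim = c(n_tokens, d_model))))
}

fw_patch_embed <- function(layer, x, training) {
  d <- dim(x); Tn <- d[1]; Tp <- d[2]; B <- d[3]
  stopifnot(Tn == layer$Tn)
  xm <- matrix(aperm(x, c(1, 3, 2)), nrow = Tn * B)   # (Tn*B, Tp)
  E <- xm %*% layer$params$W
  E <- sweep(E, 2, layer$params$b, `+`)
  E <- E + layer$params$pe[rep(seq_len(Tn), B), , drop = FALSE]
  list(out = E, cache = list(xm = xm, Tn = Tn, B = B))
}

bw_patch_embed <- function(layer, cache, dy) {
  dpe <- rowsum(dy, group = rep(seq_len(cache$Tn), cache$B))
  list(dx = NULL,
       grads = list(W = crossprod(cache$xm, dy), b = colSums(dy),
                    pe = array(dpe, dim = dim(layer$params$pe))))
}

# rowwise layer normalisation helpers
.ln_fw <- function(x, g, b, eps = 1e-5) {
  mu <- rowMeans(x)
  v <- rowMeans(x^2) - mu^2
  inv <- 1 / sqrt(v + eps)
  xhat <- (x - mu) * inv
  list(y = sweep(sweep(xhat, 2, g, `*`), 2, b, `+`), xhat = xhat, inv = inv)
}

.ln_bw <- function(dy, xhat, inv, g) {
  dxhat <- sweep(dy, 2, g, `*`)
  dx <- inv * (dxhat - rowMeans(dxhat) - xhat * rowMeans(dxhat * xhat))
  list(dx = dx, dg = colSums(dy * xhat), db = colSums(dy))
}

# -- transformer encoder layer (post-norm MHSA + FFN) -----------------------

layer_encoder <- function(d_model, n_heads, ffn_dim, dropout_rate) {
  list(type = "encoder", d = d_model, n_heads = n_heads,
       dh = d_model %/% n_heads, rate = dropout_rate,
       params = list(
         Wq = .glorot(d_model, d_model), bq = numeric(d_model),
         Wk = .glorot(d_model, d_model), bk = numeric(d_model),
         Wv = .glorot(d_model, d_model), bv = numeric(d_model),
         Wo = .glorot(d_model, d_model), bo = numeric(d_model),
         ln1_g = rep(1, d_model), ln1_b = numeric(d_model),
         W1 = .glorot(d_model, ffn_dim), b1 = numeric(ffn_dim),
         W2 = .glorot(ffn_dim, d_model), b2 = numeric(d_model),
         ln2_g = rep(1, d_model), ln2_b = numeric(d_model)))
}

.enc_proj <- function(x, W, b) sweep(x %*% W, 2, b, `+`)

fw_encoder <- function(layer, x, training, Tn, B) {
  p <- layer$params; dh <- layer$dh; H <- layer$n_heads
  Q <- .enc_proj(x, p$Wq, p$bq)
  K <- .enc_proj(x, p$Wk, p$bk)
  V <- .enc_proj(x, p$Wv, p$bv)
  O <- matrix(0, nrow(x), layer$d)
  attn <- vector("list", B * H)
  for (b in seq_len(B)) {
    rows <- ((b - 1L) * Tn + 1L):(b * Tn)
    for (h in seq_len(H)) {
      cols <- ((h - 1L) * dh + 1L):(h * dh)
      S <- tcrossprod(Q[rows, cols, drop = FALSE],
                      K[rows, cols, drop = FALSE]) / sqrt(dh)
      S <- S - apply(S, 1, max)
      A <- exp(S); A <- A / rowSums(A)
      O[rows, cols] <- A %*% V[rows, cols, drop = FALSE]
      attn[[(b - 1L) * H + h]] <- A
    }
  }
  AO <- .enc_proj(O, p$Wo, p$bo)
  drop1 <- NULL
  if (training && layer$rate > 0) {
    keep <- 1 - layer$rate
    drop1 <- (stats::runif(length(AO)) < keep) / keep
    dim(drop1) <- dim(AO)
    AO <- AO * drop1
  }
  ln1 <- .ln_fw(x + AO, p$ln1_g, p$ln1_b)
  X1 <- ln1$y
  Z1 <- .enc_proj(X1, p$W1, p$b1)
  F1 <- pmax(Z1, 0)
  F2 <- .enc_proj(F1, p$W2, p$b2)
  drop2 <- NULL
  if (training && layer$rate > 0) {
    keep <- 1 - layer$rate
    drop2 <- (stats::runif(length(F2)) < keep) / keep
    dim(drop2) <- dim(F2)
    F2 <- F2 * drop2
  }
  ln2 <- .ln_fw(X1 + F2, p$ln2_g, p$ln2_b)
  list(out = ln2$y,
       cache = list(x = x, Q = Q, K = K, V = V, O = O, attn = attn,
                    drop1 = drop1, ln1 = ln1, X1 = X1, relu_mask = Z1 > 0,
                    F1 = F1, drop2 = drop2, ln2 = ln2, Tn = Tn, B = B))
}

bw_encoder <- function(layer, cache, dy) {
  p <- layer$params; dh <- layer$dh; H <- layer$n_heads
  Tn <- cache$Tn; B <- cache$B
  l2 <- .ln_bw(dy, cache$ln2$xhat, cache$ln2$inv, p$ln2_g)
  dR2 <- l2$dx
  dF2 <- dR2
  if (!is.null(cache$drop2)) dF2 <- dF2 * cache$drop2
  dW2 <- crossprod(cache$F1, dF2); db2 <- colSums(dF2)
  dF1 <- (dF2 %*% t(p$W2)) * cache$relu_mask
  dW1 <- crossprod(cache$X1, dF1); db1 <- colSums(dF1)
  dX1 <- dR2 + dF1 %*% t(p$W1)
  l1 <- .ln_bw(dX1, cache$ln1$xhat, cache$ln1$inv, p$ln1_g)
  dR1 <- l1$dx
  dAO <- dR1
  if (!is.null(cache$drop1)) dAO <- dAO * cache$drop1
  dWo <- crossprod(cache$O, dAO); dbo <- colSums(dAO)
  dO <- dAO %*% t(p$Wo)
  dQ <- matrix(0, nrow(dO), layer$d)
  dK <- matrix(0, nrow(dO), layer$d)
  dV <- matrix(0, nrow(dO), layer$d)
  for (b in seq_len(B)) {
    rows <- ((b - 1L) * Tn + 1L):(b * Tn)
    for (h in seq_len(H)) {
      cols <- ((h - 1L) * dh + 1L):(h * dh)
      A <- cache$attn[[(b - 1L) * H + h]]
      dOb <- dO[rows, cols, drop = FALSE]
      Vb <- cache$V[rows, cols, drop = FALSE]
      dA <- tcrossprod(dOb, Vb)
      dV[rows, cols] <- crossprod(A, dOb)
      dS <- A * (dA - rowSums(dA * A))
      dQ[rows, cols] <- dS %*% cache$K[rows, cols, drop = FALSE] / sqrt(dh)
      dK[rows, cols] <- crossprod(dS, cache$Q[rows, cols, drop = FALSE]) / sqrt(dh)
    }
  }
  dWq <- crossprod(cache$x, dQ); dbq <- colSums(dQ)
  dWk <- crossprod(cache$x, dK); dbk <- colSums(dK)
  dWv <- crossprod(cache$x, dV); dbv <- colSums(dV)
  dx <- dR1 + dQ %*% t(p$Wq) + dK %*% t(p$Wk) + dV %*% t(p$Wv)
  list(dx = dx,
       grads = list(Wq = dWq, bq = dbq, Wk = dWk, bk = dbk, Wv = dWv,
                    bv = dbv, Wo = dWo, bo = dbo, ln1_g = l1$dg,
                    ln1_b = l1$db, W1 = dW1, b1 = db1, W2 = dW2, b2 = db2,
                    ln2_g = l2$dg, ln2_b = l2$db))
}

# -- token global average pool: (Tn*B, d) -> (B, d) -------------------------

layer_token_gap <- function(n_tokens) {
  list(type = "token_gap", Tn = n_tokens, params = list())
}

fw_token_gap <- function(layer, x, training) {
  Tn <- layer$Tn
  B <- nrow(x) %/% Tn
  out <- rowsum(x, group = rep(seq_len(B), each = Tn)) / Tn
  list(out = out, cache = list(Tn = Tn, B = B))
}

bw_token_gap <- function(layer, cache, dy) {
  list(dx = dy[rep(seq_len(cache$B), each = cache$Tn), , drop = FALSE] / cache$Tn,
       grads = list())
}

# ---------------------------------------------------------------------------
# network-level forward / backward
# ---------------------------------------------------------------------------

nn_forward <- function(layers, x, training = FALSE, token_geom = NULL) {
  caches <- vector("list", length(layers))
  for (i in seq_along(layers)) {
    ly <- layers[[i]]
    r <- switch(ly$type,
      conv1d = fw_conv1d(ly, x, training),
      batchnorm = fw_batchnorm(ly, x, training),
      relu = fw_relu(ly, x, training),
      maxpool = fw_maxpool(ly, x, training),
      avgpool = fw_avgpool(ly, x, training),
      flatten = fw_flatten(ly, x, training),
      gap = fw_gap(ly, x, training),
      dropout = fw_dropout(ly, x, training),
      dense = fw_dense(ly, x, training),
      lstm = fw_lstm(ly, x, training),
      patch_embed = fw_patch_embed(ly, x, training),
      encoder = fw_encoder(ly, x, training, token_geom$Tn, token_geom$B),
      token_gap = fw_token_gap(ly, x, training),
      stop("unknown layer type: ", ly$type))
    x <- r$out
    caches[[i]] <- r$cache
    if (!is.null(r$layer)) layers[[i]] <- r$layer # updated running stats
  }
  list(out = x, caches = caches, layers = layers)
}

nn_backward <- function(layers, caches, dy) {
  grads <- vector("list", length(layers))
  for (i in rev(seq_along(layers))) {
    ly <- layers[[i]]
    r <- switch(ly$type,
      conv1d = bw_conv1d(ly, caches[[i]], dy),
      batchnorm = bw_batchnorm(ly, caches[[i]], dy),
      relu = bw_relu(ly, caches[[i]], dy),
      maxpool = bw_maxpool(ly, caches[[i]], dy),
      avgpool = bw_avgpool(ly, caches[[i]], dy),
      flatten = bw_flatten(ly, caches[[i]], dy),
      gap = bw_gap(ly, caches[[i]], dy),
      dropout = bw_dropout(ly, caches[[i]], dy),
      dense = bw_dense(ly, caches[[i]], dy),
      lstm = bw_lstm(ly, caches[[i]], dy, need_dx = FALSE),
      patch_embed = bw_patch_embed(ly, caches[[i]], dy),
      encoder = bw_encoder(ly, caches[[i]], dy),
      token_gap = bw_token_gap(ly, caches[[i]], dy))
    grads[[i]] <- r$grads
    dy <- r$dx
    if (is.null(dy) && i > 1L) break # input layer reached
  }
  grads
}

# softmax + cross-entropy; y is a 1-based integer class vector
softmax_probs <- function(logits) {
  z <- logits - apply(logits, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

ce_loss <- function(logits, y) {
  p <- softmax_probs(logits)
  B <- nrow(p)
  eps <- 1e-12
  loss <- -mean(log(p[cbind(seq_len(B), y)] + eps))
  grad <- p
  grad[cbind(seq_len(B), y)] <- grad[cbind(seq_len(B), y)] - 1
  list(loss = loss, grad = grad / B, probs = p)
}

# -- Adam -------------------------------------------------------------------

adam_init <- function(layers) {
  lapply(layers, function(ly) {
    lapply(ly$params, function(p) list(m = array(0, dim = dim(p) %||% length(p)),
                                       v = array(0, dim = dim(p) %||% length(p))))
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

adam_step <- function(layers, grads, state, lr, t, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  bc1 <- 1 - beta1^t
  bc2 <- 1 - beta2^t
  for (i in seq_along(layers)) {
    for (nm in names(layers[[i]]$params)) {
      g <- grads[[i]][[nm]]
      if (is.null(g)) next
      st <- state[[i]][[nm]]
      st$m <- beta1 * st$m + (1 - beta1) * as.numeric(g)
      st$v <- beta2 * st$v + (1 - beta2) * as.numeric(g)^2
      upd <- lr * (st$m / bc1) / (sqrt(st$v / bc2) + eps)
      layers[[i]]$params[[nm]] <- layers[[i]]$params[[nm]] - array(upd,
        dim = dim(layers[[i]]$params[[nm]]) %||% length(upd))
      state[[i]][[nm]] <- st
    }
  }
  list(layers = layers, state = state)
}
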