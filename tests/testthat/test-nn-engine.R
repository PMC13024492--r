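# Analytic gradients of every layer type are checked against central
# finite differences on small tensors.

ng <- function(f, x, eps = 1e-5) {
  g <- array(0, dim = dim(x) %||% length(x))
  for (i in seq_along(x)) {
    xp <- x; xp[i] <- xp[i] + eps
    xm <- x; xm[i] <- xm[i] - eps
    g[i] <- (f(xp) - f(xm)) / (2 * eps)
  }
  g
}

`%||%` <- function(a, b) if (is.null(a)) b else a

relerr <- function(a, b) max(abs(a - b)) / max(max(abs(b)), 1e-8)

check_grads <- function(layer, x, fwd, bwd, check_dx = TRUE, tol = 1e-6) {
  set.seed(99)
  r <- fwd(layer, x, TRUE)
  dy <- array(rnorm(length(r$out)), dim = dim(r$out) %||% length(r$out))
  bk <- bwd(layer, r$cache, dy)
  if (check_dx && !is.null(bk$dx)) {
    expect_lt(relerr(bk$dx, ng(function(z) sum(fwd(layer, z, TRUE)$out * dy),
                               x)), tol)
  }
  for (nm in names(layer$params)) {
    f <- function(p) {
      l2 <- layer; l2$params[[nm]] <- p
      sum(fwd(l2, x, TRUE)$out * dy)
    }
    numg <- ng(f, layer$params[[nm]])
    if (max(abs(numg)) < 1e-7) next # direction with no effect (e.g. key bias)
    expect_lt(relerr(bk$grads[[nm]], numg), tol)
  }
  invisible(NULL)
}

test_that("conv, batchnorm, pooling and head layers backpropagate exactly", {
  set.seed(5)
  x <- array(rnorm(12 * 2 * 3), dim = c(12, 2, 3)) # (L, B, C)
  check_grads(ptfm:::layer_conv1d(3, 4, 5), x, ptfm:::fw_conv1d,
              ptfm:::bw_conv1d)
  check_grads(ptfm:::layer_batchnorm(3), x, ptfm:::fw_batchnorm,
              ptfm:::bw_batchnorm)
  check_grads(ptfm:::layer_relu(), x, ptfm:::fw_relu, ptfm:::bw_relu)
  check_grads(ptfm:::layer_maxpool(2), x, ptfm:::fw_maxpool,
              ptfm:::bw_maxpool)
  check_grads(ptfm:::layer_avgpool(3), x, ptfm:::fw_avgpool,
              ptfm:::bw_avgpool)
  check_grads(ptfm:::layer_flatten(), x, ptfm:::fw_flatten,
              ptfm:::bw_flatten)
  check_grads(ptfm:::layer_gap(), x, ptfm:::fw_gap, ptfm:::bw_gap)
  xm <- matrix(rnorm(4 * 6), 4, 6)
  check_grads(ptfm:::layer_dense(6, 3), xm, ptfm:::fw_dense, ptfm:::bw_dense)
})

test_that("LSTM backpropagation through time matches finite differences", {
  set.seed(6)
  x <- array(rnorm(5 * 4 * 3), dim = c(5, 4, 3)) # (T, D, B)
  lstm <- ptfm:::layer_lstm(4, 6)
  r <- ptfm:::fw_lstm(lstm, x, TRUE)
  dy <- matrix(rnorm(3 * 6), 3, 6)
  bk <- ptfm:::bw_lstm(lstm, r$cache, dy)
  for (nm in names(lstm$params)) {
    f <- function(p) {
      l2 <- lstm; l2$params[[nm]] <- p
      sum(ptfm:::fw_lstm(l2, x, TRUE)$out * dy)
    }
    expect_lt(relerr(bk$grads[[nm]], ng(f, lstm$params[[nm]])), 1e-6)
  }
})

test_that("transformer encoder layers backpropagate exactly", {
  set.seed(7)
  Tn <- 4L; Tp <- 6L; B <- 3L; d <- 8L
  xa <- array(rnorm(Tn * Tp * B), dim = c(Tn, Tp, B))
  pe <- ptfm:::layer_patch_embed(Tp, d, Tn)
  r1 <- ptfm:::fw_patch_embed(pe, xa, TRUE)
  enc <- ptfm:::layer_encoder(d, 2L, 12L, 0) # dropout off for the check
  r2 <- ptfm:::fw_encoder(enc, r1$out, FALSE, Tn, B)
  dy <- matrix(rnorm(length(r2$out)), nrow(r2$out))
  bk2 <- ptfm:::bw_encoder(enc, r2$cache, dy)
  for (nm in names(enc$params)) {
    f <- function(p) {
      l2 <- enc; l2$params[[nm]] <- p
      sum(ptfm:::fw_encoder(l2, r1$out, FALSE, Tn, B)$out * dy)
    }
    numg <- ng(f, enc$params[[nm]])
    if (max(abs(numg)) < 1e-7) next # softmax is invariant to key bias
    expect_lt(relerr(bk2$grads[[nm]], numg), 1e-5)
  }
  expect_lt(relerr(bk2$dx,
                   ng(function(z) sum(ptfm:::fw_encoder(enc, z, FALSE, Tn,
                                                        B)$out * dy),
                      r1$out)), 1e-5)
  bk1 <- ptfm:::bw_patch_embed(pe, r1$cache, bk2$dx)
  for (nm in names(pe$params)) {
    f <- function(p) {
      l2 <- pe; l2$params[[nm]] <- p
      e <- ptfm:::fw_patch_embed(l2, xa, TRUE)$out
      sum(ptfm:::fw_encoder(enc, e, FALSE, Tn, B)$out * dy)
    }
    expect_lt(relerr(bk1$grads[[nm]], ng(f, pe$params[[nm]])), 1e-5)
  }
})

test_that("softmax cross-entropy loss and gradient are consistent", {
  set.seed(8)
  logits <- matrix(rnorm(4 * 3), 4, 3)
  y <- c(1L, 3L, 2L, 1L)
  l <- ptfm:::ce_loss(logits, y)
  expect_equal(rowSums(l$probs), rep(1, 4), tolerance = 1e-12)
  numg <- ng(function(z) ptfm:::ce_loss(z, y)$loss, logits)
  expect_lt(relerr(l$grad, numg), 1e-6)
})

test_that("Adam drives a small least-squares problem to convergence", {
  set.seed(9)
  layers <- list(ptfm:::layer_dense(3, 1))
  state <- ptfm:::adam_init(layers)
  xb <- matrix(rnorm(60), 20, 3)
  w_true <- c(1, -2, 0.5)
  yb <- xb %*% w_true
  for (t in 1:300) {
    fw <- ptfm:::nn_forward(layers, xb)
    dy <- 2 * (fw$out - yb) / 20
    gr <- ptfm:::nn_backward(layers, fw$caches, dy)
    upd <- ptfm:::adam_step(layers, gr, state, 0.05, t)
    layers <- upd$layers; state <- upd$state
  }
  expect_equal(as.numeric(layers[[1]]$params$W), w_true, tolerance = 0.02)
})

test_that("batchnorm keeps running statistics for evaluation mode", {
  set.seed(10)
  bn <- ptfm:::layer_batchnorm(2)
  x <- array(rnorm(20 * 3 * 2, mean = 4, sd = 3), dim = c(20, 3, 2))
  for (i in 1:60) bn <- ptfm:::fw_batchnorm(bn, x, TRUE)$layer
  expect_equal(bn$state$mean, colMeans(matrix(x, ncol = 2)), tolerance = 0.1)
  out_eval <- ptfm:::fw_batchnorm(bn, x, FALSE)$out
  expect_equal(mean(out_eval), 0, tolerance = 0.15)
})

test_that("dropout rescales and disappears in evaluation mode", {
  set.seed(11)
  dl <- ptfm:::layer_dropout(0.4)
  x <- matrix(1, 100, 50)
  tr <- ptfm:::fw_dropout(dl, x, TRUE)$out
  expect_equal(mean(tr), 1, tolerance = 0.05) # inverted scaling
  expect_true(any(tr == 0))
  expect_identical(ptfm:::fw_dropout(dl, x, FALSE)$out, x)
})
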