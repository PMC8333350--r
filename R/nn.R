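#' @useDynLib aaenorm, .registration = TRUE
#' @importFrom Rcpp evalCpp
NULL

# Internal dense-network machinery for the adversarial autoencoder.
# Networks are lists of layers; layer l holds W (in x out) and b (out).
# Hidden activations are leaky ReLU; the output layer is linear (the caller
# applies a sigmoid where a probability is needed). These R functions serve
# initialisation, inference-time forward passes and small probe fits; the
# training inner loop lives in src/aae_train.cpp with identical semantics.

mlpInit <- function(sizes) {
  L <- length(sizes) - 1L
  lapply(seq_len(L), function(l) {
    fan_in <- sizes[l]
    lim <- sqrt(6 / fan_in)              # fan-in-scaled uniform
    list(W = matrix(runif(fan_in * sizes[l + 1L], -lim, lim),
                    fan_in, sizes[l + 1L]),
         b = numeric(sizes[l + 1L]))
  })
}

leakyRelu <- function(a, slope) {
  neg <- a < 0
  a[neg] <- a[neg] * slope
  a
}

# forward pass; returns output plus the per-layer caches backprop needs
mlpForward <- function(net, X, slope) {
  L <- length(net)
  act <- vector("list", L + 1L)
  pre <- vector("list", L)
  act[[1L]] <- X
  for (l in seq_len(L)) {
    A <- act[[l]] %*% net[[l]]$W
    A <- A + rep(net[[l]]$b, each = nrow(A))
    pre[[l]] <- A
    act[[l + 1L]] <- if (l < L) leakyRelu(A, slope) else A
  }
  list(out = act[[L + 1L]], act = act, pre = pre)
}

# backward pass from the gradient w.r.t. the (linear) output layer
# preactivation; returns per-layer gradients and the input gradient
mlpBackward <- function(net, cache, dOut, slope, needInputGrad = TRUE,
                        needParamGrad = TRUE) {
  L <- length(net)
  gW <- if (needParamGrad) vector("list", L) else NULL
  gb <- if (needParamGrad) vector("list", L) else NULL
  dA <- dOut
  for (l in rev(seq_len(L))) {
    if (needParamGrad) {
      gW[[l]] <- crossprod(cache$act[[l]], dA)
      gb[[l]] <- colSums(dA)
    }
    if (l > 1L || needInputGrad) {
      dZ <- tcrossprod(dA, net[[l]]$W)
      if (l > 1L) {
        dA <- dZ
        neg <- cache$pre[[l - 1L]] < 0
        dA[neg] <- dA[neg] * slope
      }
    }
  }
  list(gW = gW, gb = gb, dX = if (needInputGrad) dZ else NULL)
}

adamInit <- function(net) {
  list(m = lapply(net, function(l) list(W = l$W * 0, b = l$b * 0)),
       v = lapply(net, function(l) list(W = l$W * 0, b = l$b * 0)),
       t = 0L)
}

# one Adam step on every layer of `net`; standard moments (0.9, 0.999, 1e-8)
adamStep <- function(net, grads, state, lr,
                     beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  c1 <- 1 - beta1^state$t
  c2 <- 1 - beta2^state$t
  for (l in seq_along(net)) {
    for (p in c("W", "b")) {
      g <- if (p == "W") grads$gW[[l]] else grads$gb[[l]]
      state$m[[l]][[p]] <- beta1 * state$m[[l]][[p]] + (1 - beta1) * g
      state$v[[l]][[p]] <- beta2 * state$v[[l]][[p]] + (1 - beta2) * g * g
      net[[l]][[p]] <- net[[l]][[p]] -
        lr * (state$m[[l]][[p]] / c1) / (sqrt(state$v[[l]][[p]] / c2) + eps)
    }
  }
  list(net = net, state = state)
}

sigmoid <- function(a) plogis(a)

# numerically safe log(sigmoid(a)) = -log1p(exp(-a))
logSigmoid <- function(a) ifelse(a > -30, -log1p(exp(-a)), a)

mlpParamCount <- function(net)
  sum(vapply(net, function(l) length(l$W) + length(l$b), numeric(1)))
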