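## Minimal convolutional-network engine used by the survival models.
## Batches are arrays: 1D signals (length, channels, batch) and 2D images
## (height, width, channels, batch). Convolutions are im2col + BLAS
## matrix products; gradients are hand-derived per layer. Everything is
## seeded and deterministic.

## ---- conv1d -------------------------------------------------------------

.conv1dPad <- function(L, k, stride) {
  Lout <- as.integer(ceiling(L / stride))
  padTot <- max(0L, (Lout - 1L) * stride + k - L)
  list(Lout = Lout, pl = padTot %/% 2L, padTot = padTot)
}

.im2col1d <- function(Xp, k, stride, Lout) {
  d <- dim(Xp); C <- d[2]; N <- d[3]
  M <- matrix(0, Lout * N, k * C)
  for (j in seq_len(k)) {
    idx <- (seq_len(Lout) - 1L) * stride + j
    A <- Xp[idx, , , drop = FALSE]
    M[, ((j - 1L) * C + 1L):(j * C)] <- matrix(aperm(A, c(1, 3, 2)), Lout * N, C)
  }
  M
}

.conv1dForward <- function(layer, X) {
  d <- dim(X); L <- d[1]; C <- d[2]; N <- d[3]
  pp <- .conv1dPad(L, layer$k, layer$stride)
  Xp <- array(0, c(L + pp$padTot, C, N))
  Xp[pp$pl + seq_len(L), , ] <- X
  M <- .im2col1d(Xp, layer$k, layer$stride, pp$Lout)
  Y <- sweep(M %*% layer$W, 2L, layer$b, "+")
  out <- aperm(array(Y, c(pp$Lout, N, ncol(layer$W))), c(1, 3, 2))
  list(out = out, cache = list(M = M, dimXp = dim(Xp), pp = pp, L = L, N = N))
}

.conv1dBackward <- function(layer, cache, dOut) {
  pp <- cache$pp
  Cout <- ncol(layer$W)
  dYmat <- matrix(aperm(dOut, c(1, 3, 2)), pp$Lout * cache$N, Cout)
  dW <- crossprod(cache$M, dYmat)
  db <- colSums(dYmat)
  dM <- tcrossprod(dYmat, layer$W)
  dXp <- array(0, cache$dimXp)
  C <- cache$dimXp[2]
  for (j in seq_len(layer$k)) {
    idx <- (seq_len(pp$Lout) - 1L) * layer$stride + j
    dA <- aperm(array(dM[, ((j - 1L) * C + 1L):(j * C)],
                      c(pp$Lout, cache$N, C)), c(1, 3, 2))
    dXp[idx, , ] <- dXp[idx, , , drop = FALSE] + dA
  }
  dX <- dXp[pp$pl + seq_len(cache$L), , , drop = FALSE]
  list(dX = dX, grads = list(W = dW, b = db))
}

## ---- conv2d -------------------------------------------------------------

.conv2dForward <- function(layer, X) {
  d <- dim(X); H <- d[1]; W2 <- d[2]; C <- d[3]; N <- d[4]
  k <- layer$k; s <- layer$stride
  ppH <- .conv1dPad(H, k, s); ppW <- .conv1dPad(W2, k, s)
  Xp <- array(0, c(H + ppH$padTot, W2 + ppW$padTot, C, N))
  Xp[ppH$pl + seq_len(H), ppW$pl + seq_len(W2), , ] <- X
  Hout <- ppH$Lout; Wout <- ppW$Lout
  M <- matrix(0, Hout * Wout * N, k * k * C)
  col <- 0L
  for (jw in seq_len(k)) for (jh in seq_len(k)) {
    idxH <- (seq_len(Hout) - 1L) * s + jh
    idxW <- (seq_len(Wout) - 1L) * s + jw
    A <- Xp[idxH, idxW, , , drop = FALSE]       # Hout x Wout x C x N
    M[, col + seq_len(C)] <- matrix(aperm(A, c(1, 2, 4, 3)), Hout * Wout * N, C)
    col <- col + C
  }
  Y <- sweep(M %*% layer$W, 2L, layer$b, "+")
  out <- aperm(array(Y, c(Hout, Wout, N, ncol(layer$W))), c(1, 2, 4, 3))
  list(out = out,
       cache = list(M = M, dimXp = dim(Xp), ppH = ppH, ppW = ppW,
                    H = H, W2 = W2, N = N))
}

.conv2dBackward <- function(layer, cache, dOut) {
  Hout <- cache$ppH$Lout; Wout <- cache$ppW$Lout
  Cout <- ncol(layer$W)
  k <- layer$k; s <- layer$stride
  dYmat <- matrix(aperm(dOut, c(1, 2, 4, 3)), Hout * Wout * cache$N, Cout)
  dW <- crossprod(cache$M, dYmat)
  db <- colSums(dYmat)
  dM <- tcrossprod(dYmat, layer$W)
  dXp <- array(0, cache$dimXp)
  C <- cache$dimXp[3]
  col <- 0L
  for (jw in seq_len(k)) for (jh in seq_len(k)) {
    idxH <- (seq_len(Hout) - 1L) * s + jh
    idxW <- (seq_len(Wout) - 1L) * s + jw
    dA <- aperm(array(dM[, col + seq_len(C)], c(Hout, Wout, cache$N, C)),
                c(1, 2, 4, 3))
    dXp[idxH, idxW, , ] <- dXp[idxH, idxW, , , drop = FALSE] + dA
    col <- col + C
  }
  dX <- dXp[cache$ppH$pl + seq_len(cache$H),
            cache$ppW$pl + seq_len(cache$W2), , , drop = FALSE]
  list(dX = dX, grads = list(W = dW, b = db))
}

## ---- simple layers ------------------------------------------------------

.reluForward <- function(X) list(out = pmax(X, 0), cache = X > 0)
.reluBackward <- function(cache, dOut) dOut * cache

## global average pool over all spatial dims -> N x C matrix
.gapForward <- function(X) {
  d <- dim(X)
  nd <- length(d)
  spatial <- prod(d[-c(nd - 1L, nd)])
  Xm <- matrix(X, spatial, d[nd - 1L] * d[nd])
  out <- matrix(colMeans(Xm), d[nd - 1L], d[nd])   # C x N
  list(out = t(out), cache = d)
}
.gapBackward <- function(cache, dOut) {
  d <- cache
  nd <- length(d)
  spatial <- prod(d[-c(nd - 1L, nd)])
  dXm <- matrix(rep(as.vector(t(dOut)) / spatial, each = spatial),
                spatial, d[nd - 1L] * d[nd])
  array(dXm, d)
}

.denseForward <- function(layer, X)
  list(out = sweep(X %*% layer$W, 2L, layer$b, "+"), cache = X)
.denseBackward <- function(layer, cache, dOut)
  list(dX = tcrossprod(dOut, layer$W),
       grads = list(W = crossprod(cache, dOut), b = colSums(dOut)))

## ---- residual blocks ----------------------------------------------------

.resForward <- function(layer, X, convF) {
  c1 <- convF(layer$conv1, X)
  r1 <- .reluForward(c1$out)
  c2 <- convF(layer$conv2, r1$out)
  sk <- if (!is.null(layer$skip)) convF(layer$skip, X) else list(out = X, cache = NULL)
  s <- c2$out + sk$out
  r2 <- .reluForward(s)
  list(out = r2$out, cache = list(c1 = c1$cache, r1 = r1$cache,
                                  c2 = c2$cache, sk = sk$cache, r2 = r2$cache))
}

.resBackward <- function(layer, cache, dOut, convB) {
  dS <- .reluBackward(cache$r2, dOut)
  b2 <- convB(layer$conv2, cache$c2, dS)
  dR1 <- .reluBackward(cache$r1, b2$dX)
  b1 <- convB(layer$conv1, cache$c1, dR1)
  if (!is.null(layer$skip)) {
    bs <- convB(layer$skip, cache$sk, dS)
    dX <- b1$dX + bs$dX
    grads <- list(conv1 = b1$grads, conv2 = b2$grads, skip = bs$grads)
  } else {
    dX <- b1$dX + dS
    grads <- list(conv1 = b1$grads, conv2 = b2$grads)
  }
  list(dX = dX, grads = grads)
}

## ---- network-level forward / backward ----------------------------------

.netForward <- function(layers, X) {
  acts <- vector("list", length(layers))
  for (i in seq_along(layers)) {
    l <- layers[[i]]
    r <- switch(l$type,
      conv1d = .conv1dForward(l, X),
      conv2d = .conv2dForward(l, X),
      res1d = .resForward(l, X, .conv1dForward),
      res2d = .resForward(l, X, .conv2dForward),
      relu = .reluForward(X),
      gap = .gapForward(X),
      dense = .denseForward(l, X),
      sigmoid = list(out = stats::plogis(X), cache = NULL),
      stop("unknown layer type: ", l$type))
    acts[[i]] <- r
    X <- r$out
  }
  acts
}

## dZ is the gradient at the pre-sigmoid head (the sigmoid layer is fused
## with the loss); returns per-layer gradient lists and the input gradient
.netBackward <- function(layers, acts, dZ) {
  grads <- vector("list", length(layers))
  d <- dZ
  for (i in rev(seq_along(layers))) {
    l <- layers[[i]]
    cache <- acts[[i]]$cache
    r <- switch(l$type,
      conv1d = .conv1dBackward(l, cache, d),
      conv2d = .conv2dBackward(l, cache, d),
      res1d = .resBackward(l, cache, d, .conv1dBackward),
      res2d = .resBackward(l, cache, d, .conv2dBackward),
      relu = list(dX = .reluBackward(cache, d), grads = NULL),
      gap = list(dX = .gapBackward(cache, d), grads = NULL),
      dense = .denseBackward(l, cache, d),
      sigmoid = list(dX = d, grads = NULL),   # fused: d is already dZ
      stop("unknown layer type: ", l$type))
    grads[i] <- list(r$grads)   # keep NULL placeholders for param-free layers
    d <- r$dX
  }
  list(grads = grads, dX = d)
}

## ---- parameter plumbing (flatten / He init / Adam) ----------------------

.heConv <- function(fanIn, nOut) {
  matrix(rnorm(fanIn * nOut, sd = sqrt(2 / fanIn)), fanIn, nOut)
}

.newConv1d <- function(k, cIn, cOut, stride)
  list(type = "conv1d", k = as.integer(k), stride = as.integer(stride),
       W = .heConv(k * cIn, cOut), b = numeric(cOut))

.newConv2d <- function(k, cIn, cOut, stride)
  list(type = "conv2d", k = as.integer(k), stride = as.integer(stride),
       W = .heConv(k * k * cIn, cOut), b = numeric(cOut))

.newRes <- function(dim1d, k, cIn, cOut, stride) {
  newc <- if (dim1d) .newConv1d else .newConv2d
  l <- list(type = if (dim1d) "res1d" else "res2d",
            conv1 = newc(k, cIn, cOut, stride),
            conv2 = newc(k, cOut, cOut, 1L))
  if (cIn != cOut || stride != 1L) l$skip <- newc(1L, cIn, cOut, stride)
  l
}

## walk layer lists applying f(param, grad-or-state) to every W/b pair
.mapParams <- function(layers, grads, f) {
  for (i in seq_along(layers)) {
    l <- layers[[i]]
    g <- grads[[i]]
    if (is.null(g)) next
    if (l$type %in% c("res1d", "res2d")) {
      for (part in names(g)) {
        layers[[i]][[part]]$W <- f(l[[part]]$W, g[[part]]$W, sprintf("%d.%s.W", i, part))
        layers[[i]][[part]]$b <- f(l[[part]]$b, g[[part]]$b, sprintf("%d.%s.b", i, part))
      }
    } else {
      layers[[i]]$W <- f(l$W, g$W, sprintf("%d.W", i))
      layers[[i]]$b <- f(l$b, g$b, sprintf("%d.b", i))
    }
  }
  layers
}

.adamStep <- function(layers, grads, state, lr, weightDecay = 0,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  tt <- state$t
  upd <- function(p, g, key) {
    m <- state$m[[key]]; v <- state$v[[key]]
    if (is.null(m)) { m <- p * 0; v <- p * 0 }
    m <- beta1 * m + (1 - beta1) * g
    v <- beta2 * v + (1 - beta2) * g^2
    state$m[[key]] <<- m
    state$v[[key]] <<- v
    mh <- m / (1 - beta1^tt)
    vh <- v / (1 - beta2^tt)
    ## decoupled weight decay; biases (vectors) are exempt
    wd <- if (is.matrix(p)) weightDecay else 0
    p - lr * (mh / (sqrt(vh) + eps) + wd * p)
  }
  layers <- .mapParams(layers, grads, upd)
  list(layers = layers, state = state)
}
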