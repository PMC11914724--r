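## Discrete-time survival deep learning: the interval grid, target
## encoding, the censoring-aware likelihood loss, small 1D residual and
## 2D convolutional architectures with a K-unit sigmoid hazard head,
## patient-level cohort filtering/splitting, Adam training with early
## stopping, and vanilla-gradient saliency.

#' Construct a discrete-time interval grid
#'
#' The default covers 5 years in 10 half-year intervals (182.625 days
#' each), matching the 5-year life-status framing used for cohort
#' stratification.
#'
#' @param boundaries numeric boundaries in days starting at 0; or NULL
#'   for the default grid.
#' @param years,K convenience: horizon in years split into K intervals.
#' @return an [IntervalGrid-class].
#' @export
intervalGrid <- function(boundaries = NULL, years = 5, K = 10L) {
  if (is.null(boundaries))
    boundaries <- seq(0, years * 365.25, length.out = K + 1L)
  new("IntervalGrid", boundaries = as.numeric(boundaries))
}

#' Encode survival records as per-interval targets
#'
#' For each record, `y[j] = 1` iff death occurred in interval j, and the
#' observation mask `m` is 1 for every interval contributing to the
#' likelihood: an event in interval k sets `m[1..k] = 1`; censoring in
#' interval k credits only fully survived intervals, `m[1..k-1] = 1`.
#' A time beyond the final boundary contributes all K intervals as
#' survived (an event past the horizon is treated as censored there).
#'
#' @param time numeric vector of observed times, days.
#' @param event binary vector (1 = death, 0 = censored).
#' @param grid an [IntervalGrid-class].
#' @return list of matrices `y` and `m`, each n x K.
#' @examples
#' g <- intervalGrid(0:5 * 365.25)
#' encodeTargets(2.5 * 365.25, 1, g)
#' @export
encodeTargets <- function(time, event, grid) {
  stopifnot(is(grid, "IntervalGrid"))
  .assert(all(time >= 0), "times must be >= 0")
  .assert(all(event %in% c(0, 1)), "event must be binary")
  b <- intervalBoundaries(grid)
  K <- length(b) - 1L
  n <- length(time)
  k <- findInterval(time, b, left.open = TRUE)   # interval of (t_{j-1}, t_j]
  k[time == 0] <- 0L
  beyond <- k > K
  y <- matrix(0, n, K)
  m <- matrix(0, n, K)
  for (i in seq_len(n)) {
    if (beyond[i]) { m[i, ] <- 1; next }         # survived the whole grid
    ki <- k[i]
    if (event[i] == 1) {
      if (ki == 0L) ki <- 1L                     # death at t = 0
      y[i, ki] <- 1
      m[i, seq_len(ki)] <- 1
    } else if (ki > 1L) {
      m[i, seq_len(ki - 1L)] <- 1
    } else if (ki == 1L && time[i] >= b[2]) {
      m[i, 1L] <- 1                              # censored exactly at t_1
    }
  }
  list(y = y, m = m)
}

#' Discrete-time survival likelihood loss
#'
#' Mean over records of the masked negative log likelihood
#' `-sum_j m_j [ y_j log h_j + (1 - y_j) log(1 - h_j) ]`. With a single
#' interval and full observation this is binary cross-entropy on the
#' event indicator. Hazards at 0 or 1 are clipped at 1e-7.
#'
#' @param hazards n x K matrix of conditional hazards in (0, 1).
#' @param targets list with `y` and `m` as from [encodeTargets()].
#' @return scalar loss (>= 0).
#' @examples
#' g <- intervalGrid(c(0, 1, 2))
#' discreteSurvivalLoss(matrix(c(0.2, 0.3), 1), encodeTargets(1.5, 1, g))
#' @export
discreteSurvivalLoss <- function(hazards, targets) {
  h <- as.matrix(hazards)
  y <- targets$y; m <- targets$m
  .assert(all(dim(h) == dim(y)), "hazard and target shapes differ")
  eps <- 1e-7
  h <- pmin(pmax(h, eps), 1 - eps)
  ll <- m * (y * log(h) + (1 - y) * log(1 - h))
  -sum(ll) / nrow(h)
}

#' Survival curve and risk score from hazards
#'
#' `S_k = prod_{j<=k} (1 - h_j)` and the risk score is the cumulative
#' hazard `-sum_j log(1 - h_j)`, which orders records identically to
#' `1 - S_K`.
#'
#' @param hazards vector of K hazards, or an n x K matrix.
#' @return list with `survival` (same shape) and `risk` (per record).
#' @examples
#' hazardsToSurvival(c(0.2, 0.3))
#' @export
hazardsToSurvival <- function(hazards) {
  h <- if (is.matrix(hazards)) hazards else matrix(hazards, 1)
  .assert(all(h >= 0 & h < 1), "hazards must lie in [0, 1)")
  S <- t(apply(1 - h, 1L, cumprod))
  if (ncol(h) == 1L) S <- matrix(S, ncol = 1L)
  risk <- -rowSums(log(1 - h))
  if (!is.matrix(hazards)) list(survival = drop(S), risk = risk)
  else list(survival = S, risk = risk)
}

#' Network configuration
#'
#' Desk-scale defaults: the 1D residual network has a strided stem
#' convolution and 3 residual blocks over the 4096-sample axis; the 2D
#' network stacks strided residual stages over the image. Full-size
#' variants are a matter of widening `channels` and `kernel`.
#'
#' @param architecture "residual1d" or "conv2d".
#' @param inputShape c(4096, 8) for signals; c(height, width) for images.
#' @param K number of hazard intervals (head size).
#' @param channels per-stage channel counts (first = stem).
#' @param kernel stem/block kernel size (1D default 16/8; 2D default 3).
#' @param strides per-stage downsampling factors.
#' @param seed initialization seed.
#' @param lr,batchSize,epochs,patience,weightDecay optimizer settings
#'   (decoupled L2 decay on weight matrices only).
#' @return list of class `netConfig`.
#' @export
netConfig <- function(architecture = c("residual1d", "conv2d"),
                      inputShape = c(4096L, 8L), K = 10L,
                      channels = NULL, kernel = NULL, strides = NULL,
                      seed = 1L, lr = 5e-4, batchSize = 32L, epochs = 60L,
                      patience = 20L, weightDecay = 1e-3) {
  architecture <- match.arg(architecture)
  if (architecture == "residual1d") {
    channels <- channels %||% c(16L, 24L, 32L, 48L)
    kernel <- kernel %||% c(16L, 8L)
    strides <- strides %||% c(4L, 4L, 4L, 4L)
  } else {
    channels <- channels %||% c(8L, 16L, 24L, 32L)
    kernel <- kernel %||% c(3L, 3L)
    strides <- strides %||% c(1L, 2L, 2L, 2L)
  }
  .assert(length(channels) == length(strides), "channels/strides length mismatch")
  structure(list(architecture = architecture, inputShape = as.integer(inputShape),
                 K = as.integer(K), channels = as.integer(channels),
                 kernel = as.integer(kernel), strides = as.integer(strides),
                 seed = as.integer(seed), lr = lr,
                 batchSize = as.integer(batchSize), epochs = as.integer(epochs),
                 patience = as.integer(patience), weightDecay = weightDecay),
            class = "netConfig")
}

#' Build an untrained discrete-time survival network
#'
#' 1D: strided stem convolution + residual blocks downsampling the
#' 4096-sample axis, global average pooling, K-unit sigmoid head.
#' 2D: stem convolution + strided residual stages over the image, global
#' average pooling, K-unit sigmoid head. Parameters are He-initialized,
#' deterministic given `config$seed`.
#'
#' @param config a [netConfig()].
#' @param grid the [IntervalGrid-class] the head predicts over
#'   (K must equal `config$K`).
#' @return an untrained [SurvivalModel-class].
#' @export
buildModel <- function(config, grid = intervalGrid()) {
  stopifnot(inherits(config, "netConfig"), is(grid, "IntervalGrid"))
  .assert(config$K == nIntervals(grid), "config$K must match the grid")
  set.seed(config$seed)
  ch <- config$channels
  dim1d <- config$architecture == "residual1d"
  cIn <- if (dim1d) config$inputShape[2] else 1L
  layers <- list()
  if (dim1d) {
    layers[[1]] <- .newConv1d(config$kernel[1], cIn, ch[1], config$strides[1])
  } else {
    layers[[1]] <- .newConv2d(config$kernel[1], cIn, ch[1], config$strides[1])
  }
  layers[[2]] <- list(type = "relu")
  kBlock <- config$kernel[min(2L, length(config$kernel))]
  for (i in seq_along(ch)[-1]) {
    layers[[length(layers) + 1L]] <-
      .newRes(dim1d, kBlock, ch[i - 1L], ch[i], config$strides[i])
  }
  layers[[length(layers) + 1L]] <- list(type = "gap")
  ## head bias starts near a plausible per-interval hazard (~0.1) so early
  ## epochs refine discrimination rather than the output scale
  layers[[length(layers) + 1L]] <-
    list(type = "dense", W = .heConv(ch[length(ch)], config$K) / sqrt(2),
         b = rep(stats::qlogis(0.1), config$K))
  layers[[length(layers) + 1L]] <- list(type = "sigmoid")
  new("SurvivalModel", layers = layers, config = unclass(config),
      grid = grid, history = list())
}

## stack model inputs into the batch array the engine expects
.stackInputs <- function(inputs, architecture) {
  n <- length(inputs)
  if (architecture == "residual1d") {
    d <- dim(inputs[[1]])
    X <- array(0, c(d[1], d[2], n))
    for (i in seq_len(n)) X[, , i] <- inputs[[i]]
  } else {
    d <- dim(inputs[[1]])
    X <- array(0, c(d[1], d[2], 1L, n))
    for (i in seq_len(n)) X[, , 1L, i] <- inputs[[i]]
  }
  X
}

.batchSlice <- function(X, idx) {
  if (length(dim(X)) == 3L) X[, , idx, drop = FALSE]
  else X[, , , idx, drop = FALSE]
}

#' Predict per-interval hazards
#'
#' @param model a [SurvivalModel-class].
#' @param X batch array: (length, channels, n) for 1D models or
#'   (height, width, 1, n) for 2D models; a single unbatched input is
#'   also accepted.
#' @param batchSize records per forward pass.
#' @return n x K hazard matrix.
#' @export
predictHazards <- function(model, X, batchSize = 64L) {
  X <- .coerceBatch(model, X)
  n <- tail(dim(X), 1L)
  out <- NULL
  for (lo in seq(1L, n, by = batchSize)) {
    idx <- lo:min(n, lo + batchSize - 1L)
    acts <- .netForward(model@layers, .batchSlice(X, idx))
    out <- rbind(out, acts[[length(acts)]]$out)
  }
  out
}

.coerceBatch <- function(model, X) {
  dim1d <- model@config$architecture == "residual1d"
  want <- if (dim1d) 3L else 4L
  if (length(dim(X)) == want) return(X)
  if (dim1d && length(dim(X)) == 2L) return(array(X, c(dim(X), 1L)))
  if (!dim1d && length(dim(X)) == 2L) return(array(X, c(dim(X), 1L, 1L)))
  .stopf("input shape does not match the %s architecture", model@config$architecture)
}

#' Filter and split a cohort for training
#'
#' Drops ECGs without 30-day life status (censored before day 30), then
#' splits subjects 50/10/40 into train/validation/test, stratified by
#' availability of 5-year life status (an event at any time, or follow-up
#' reaching the grid horizon). All of a subject's records land in one
#' split. Deterministic given `seed`.
#'
#' @param records data.frame with subjectId, time (days), event.
#' @param grid an [IntervalGrid-class]; its horizon defines "5-year"
#'   status availability.
#' @param ratios train/validation/test proportions.
#' @param seed integer seed.
#' @return list: integer record-row indices `train`, `val`, `test`, plus
#'   `kept` (rows surviving the 30-day filter).
#' @export
prepareCohort <- function(records, grid = intervalGrid(),
                          ratios = c(0.5, 0.1, 0.4), seed = 1L) {
  .assert(abs(sum(ratios) - 1) < 1e-9, "ratios must sum to 1")
  keep <- which(records$time >= 30 | records$event == 1)
  kept <- records[keep, , drop = FALSE]
  subj <- unique(kept$subjectId)
  .assert(length(subj) >= 3L, "cohort must have at least 3 subjects")
  horizon <- max(intervalBoundaries(grid))
  has5y <- vapply(subj, function(s) {
    r <- kept[kept$subjectId == s, ]
    any(r$event == 1) || any(r$time >= horizon)
  }, logical(1))
  set.seed(as.integer(seed))
  assign <- setNames(character(length(subj)), subj)
  for (stratum in unique(has5y)) {
    ss <- sample(subj[has5y == stratum])
    nTr <- round(ratios[1] * length(ss))
    nVa <- round(ratios[2] * length(ss))
    lab <- rep("test", length(ss))
    lab[seq_len(nTr)] <- "train"
    if (nVa > 0) lab[nTr + seq_len(min(nVa, length(ss) - nTr))] <- "val"
    assign[ss] <- lab
  }
  split(keep, assign[kept$subjectId])[c("train", "val", "test")] |>
    lapply(function(x) if (is.null(x)) integer(0) else x) |>
    c(list(kept = keep))
}

#' Train a survival network
#'
#' Minimizes the discrete-time survival loss by mini-batch Adam with
#' early stopping on validation loss (best weights restored).
#' Deterministic given `config$seed` up to floating-point reduction
#' order.
#'
#' @param model an untrained (or warm) [SurvivalModel-class].
#' @param X full batch array of inputs (see [predictHazards()]).
#' @param targets list (`y`, `m`) from [encodeTargets()] for all records.
#' @param splits list with `train` and `val` index vectors into X.
#' @param epochs,batchSize,lr,patience override the model config.
#' @param verbose print per-epoch losses.
#' @return the trained [SurvivalModel-class] with `history`.
#' @export
trainModel <- function(model, X, targets, splits, epochs = NULL,
                       batchSize = NULL, lr = NULL, patience = NULL,
                       verbose = FALSE) {
  stopifnot(is(model, "SurvivalModel"))
  cf <- model@config
  epochs <- epochs %||% cf$epochs
  batchSize <- batchSize %||% cf$batchSize
  lr <- lr %||% cf$lr
  patience <- patience %||% cf$patience
  tr <- splits$train; va <- splits$val
  .assert(length(tr) > 0 && length(va) > 0, "need non-empty train and val splits")
  X <- .coerceBatch(model, X)
  layers <- model@layers
  state <- list(t = 0L, m = list(), v = list())
  ## model selection: validation C-index on the interval-rank implied by
  ## the targets (falls back to loss-only when no pairs are comparable)
  valY <- targets$y[va, , drop = FALSE]
  valM <- targets$m[va, , drop = FALSE]
  valEvent <- as.integer(rowSums(valY) > 0)
  valRank <- rowSums(valM)
  valStats <- function(layers) {
    h <- .predictWith(layers, X, va, batchSize)
    loss <- discreteSurvivalLoss(h, list(y = valY, m = valM))
    cidx <- tryCatch(.harrellC(hazardsToSurvival(h)$risk, valRank, valEvent),
                     error = function(e) NA_real_)
    list(loss = loss, c = cidx)
  }
  score <- function(st) if (is.finite(st$c)) st$c else -st$loss
  bestLayers <- layers
  init <- valStats(layers)
  bestScore <- score(init)
  bestVal <- init$loss
  initVal <- init$loss
  bad <- 0L
  trainLoss <- valLoss <- valC <- numeric(0)
  set.seed(cf$seed + 1L)
  for (ep in seq_len(epochs)) {
    ord <- sample(tr)
    epLoss <- 0; nb <- 0L
    for (lo in seq(1L, length(ord), by = batchSize)) {
      idx <- ord[lo:min(length(ord), lo + batchSize - 1L)]
      acts <- .netForward(layers, .batchSlice(X, idx))
      h <- acts[[length(acts)]]$out
      yB <- targets$y[idx, , drop = FALSE]
      mB <- targets$m[idx, , drop = FALSE]
      loss <- discreteSurvivalLoss(h, list(y = yB, m = mB))
      .assert(is.finite(loss), "training diverged (non-finite loss) at epoch %d", ep)
      dZ <- (h - yB) * mB / length(idx)      # fused sigmoid + likelihood
      bk <- .netBackward(layers, acts, dZ)
      stepRes <- .adamStep(layers, bk$grads, state, lr, cf$weightDecay %||% 0)
      layers <- stepRes$layers
      state <- stepRes$state
      epLoss <- epLoss + loss; nb <- nb + 1L
    }
    st <- valStats(layers)
    trainLoss <- c(trainLoss, epLoss / nb)
    valLoss <- c(valLoss, st$loss)
    valC <- c(valC, st$c)
    if (verbose)
      message(sprintf("epoch %02d train %.4f val %.4f valC %.3f",
                      ep, epLoss / nb, st$loss, st$c))
    if (score(st) > bestScore + 1e-6 && st$loss <= initVal) {
      bestScore <- score(st); bestVal <- st$loss
      bestLayers <- layers; bad <- 0L
    } else {
      bad <- bad + 1L
      if (bad >= patience) break
    }
  }
  model@layers <- bestLayers
  model@history <- list(trainLoss = trainLoss, valLoss = valLoss, valC = valC,
                        bestVal = bestVal, initVal = initVal)
  model
}

.predictWith <- function(layers, X, idx, batchSize) {
  out <- NULL
  for (lo in seq(1L, length(idx), by = batchSize)) {
    ii <- idx[lo:min(length(idx), lo + batchSize - 1L)]
    acts <- .netForward(layers, .batchSlice(X, ii))
    out <- rbind(out, acts[[length(acts)]]$out)
  }
  out
}

#' Vanilla-gradient saliency map
#'
#' The absolute gradient of the risk score (cumulative hazard) with
#' respect to the input, max-reduced over channels; same spatial shape
#' as the input.
#'
#' @param model a trained [SurvivalModel-class].
#' @param x a single model input (matrix: length x channels, or
#'   height x width image).
#' @return non-negative numeric vector (1D) or matrix (2D).
#' @export
saliencyMap <- function(model, x) {
  X <- .coerceBatch(model, x)
  acts <- .netForward(model@layers, X)
  h <- acts[[length(acts)]]$out
  ## risk = -sum log(1 - sigmoid(z)); d risk / d z_j = h_j
  bk <- .netBackward(model@layers, acts, h)
  g <- abs(bk$dX)
  d <- dim(g)
  if (model@config$architecture == "residual1d") {
    apply(g[, , 1, drop = FALSE], 1L, max)     # max over channels
  } else {
    g[, , 1, 1]
  }
}
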