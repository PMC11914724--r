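yearGrid <- intervalGrid(0:5 * 365.25)

test_that("target encoding follows the event/censoring rules", {
  # death at 2.5 y with yearly intervals
  tg <- encodeTargets(2.5 * 365.25, 1, yearGrid)
  expect_equal(drop(tg$y), c(0, 0, 1, 0, 0))
  expect_equal(drop(tg$m), c(1, 1, 1, 0, 0))
  # censoring within the first interval contributes nothing
  tg2 <- encodeTargets(0.2 * 365.25, 0, yearGrid)
  expect_true(all(tg2$y == 0) && all(tg2$m == 0))
  # K = 1: any death is interval 1 with full mask
  g1 <- intervalGrid(c(0, 1000))
  tg3 <- encodeTargets(c(1, 500, 999), c(1, 1, 1), g1)
  expect_true(all(tg3$y == 1) && all(tg3$m == 1))
  # beyond-horizon time counts all intervals as survived
  tg4 <- encodeTargets(10 * 365.25, 1, yearGrid)
  expect_true(all(tg4$y == 0) && all(tg4$m == 1))
  # invariants: at most one event; mask is a prefix covering the event
  set.seed(2)
  tg5 <- encodeTargets(runif(50, 0, 2200), rbinom(50, 1, 0.5), yearGrid)
  expect_true(all(rowSums(tg5$y) <= 1))
  expect_true(all(tg5$y <= tg5$m))
  expect_true(all(apply(tg5$m, 1, function(m) all(diff(m) <= 0))))
})

test_that("the survival loss matches hand-computed values", {
  g2 <- intervalGrid(c(0, 100, 200))
  # h = (0.2, 0.3), death in interval 2: -ln(0.8) - ln(0.3)
  loss <- discreteSurvivalLoss(matrix(c(0.2, 0.3), 1),
                               encodeTargets(150, 1, g2))
  expect_equal(loss, -log(0.8) - log(0.3), tolerance = 1e-10)
  expect_equal(round(loss, 4), 1.4271)
  # K = 1 with full observation reduces to binary cross-entropy
  g1 <- intervalGrid(c(0, 100))
  h <- matrix(c(0.9, 0.2), 2, 1)
  y <- c(1, 0)
  tg <- encodeTargets(c(50, 150), y, g1)
  bce <- -mean(y * log(h) + (1 - y) * log(1 - h))
  expect_equal(discreteSurvivalLoss(h, tg), bce, tolerance = 1e-10)
  # perfect prediction drives the loss to zero
  hPerf <- matrix(c(1 - 1e-9, 1e-9), 1)
  expect_lt(discreteSurvivalLoss(hPerf, encodeTargets(50, 1, g2)), 1e-5)
})

test_that("the loss decomposes into per-record terms", {
  set.seed(3)
  n <- 40
  h <- matrix(runif(n * 5, 0.01, 0.6), n, 5)
  tg <- encodeTargets(runif(n, 0, 2200), rbinom(n, 1, 0.5), yearGrid)
  total <- discreteSurvivalLoss(h, tg)
  perRecord <- sapply(seq_len(n), function(i)
    discreteSurvivalLoss(h[i, , drop = FALSE],
                         list(y = tg$y[i, , drop = FALSE],
                              m = tg$m[i, , drop = FALSE])))
  expect_equal(total, mean(perRecord), tolerance = 1e-12)
  # exp(-loss) of one record equals its likelihood under the model
  i <- which(rowSums(tg$m) > 0)[1]
  hi <- h[i, ]; yi <- tg$y[i, ]; mi <- tg$m[i, ]
  lik <- prod(ifelse(mi == 1, ifelse(yi == 1, hi, 1 - hi), 1))
  expect_equal(exp(-perRecord[i]), lik, tolerance = 1e-10)
})

test_that("survival curves are monotone and risk ranks match 1 - S_K", {
  hs <- hazardsToSurvival(c(0.2, 0.3))
  expect_equal(hs$survival, c(0.8, 0.56))
  expect_equal(hs$risk, -log(0.56), tolerance = 1e-12)
  z <- hazardsToSurvival(rep(0, 4))
  expect_true(all(z$survival == 1) && z$risk == 0)
  set.seed(4)
  H <- matrix(runif(200, 0, 0.9), 20, 10)
  out <- hazardsToSurvival(H)
  expect_true(all(apply(out$survival, 1, function(s) all(diff(s) <= 0))))
  expect_identical(order(out$risk), order(1 - out$survival[, 10]))
})

test_that("model construction is deterministic with a K-unit sigmoid head", {
  g <- intervalGrid(years = 2.5, K = 5L)
  cfg <- netConfig("residual1d", inputShape = c(256L, 8L), K = 5L,
                   channels = c(8L, 12L), strides = c(4L, 4L), seed = 7L)
  m1 <- buildModel(cfg, g)
  m2 <- buildModel(cfg, g)
  expect_identical(m1@layers, m2@layers)
  X <- array(rnorm(256 * 8 * 3), c(256, 8, 3))
  h <- predictHazards(m1, X)
  expect_identical(dim(h), c(3L, 5L))
  expect_true(all(h > 0 & h < 1))
  # with a neutral (zero-bias) head, hazards sit near 0.5 and the loss on
  # fully observed records is close to K * ln 2
  m1@layers[[length(m1@layers) - 1L]]$b <- rep(0, 5L)
  h0 <- predictHazards(m1, X)
  tg <- list(y = matrix(0, 3, 5), m = matrix(1, 3, 5))
  expect_equal(discreteSurvivalLoss(h0, tg), 5 * log(2), tolerance = 0.1 * 5 * log(2))
  expect_error(buildModel(netConfig("residual1d", K = 4L), g), "match the grid")
})

test_that("cohort preparation filters, stratifies and partitions by subject", {
  set.seed(11)
  n <- 100
  rec <- data.frame(subjectId = sprintf("P%03d", 1:n),
                    time = runif(n, 0, 2200),
                    event = rbinom(n, 1, 0.3))
  rec$time[1:3] <- c(10, 29, 15); rec$event[1:3] <- c(0, 0, 1)
  sp <- prepareCohort(rec, intervalGrid(), seed = 3)
  expect_false(1 %in% sp$kept)   # censored day 10: no 30-day status
  expect_false(2 %in% sp$kept)
  expect_true(3 %in% sp$kept)    # early death still informative
  all_idx <- c(sp$train, sp$val, sp$test)
  expect_setequal(all_idx, sp$kept)
  expect_identical(anyDuplicated(all_idx), 0L)
  # 50/10/40 at subject level (up to stratum rounding)
  expect_lt(abs(length(sp$train) / length(sp$kept) - 0.5), 0.03)
  expect_lt(abs(length(sp$val) / length(sp$kept) - 0.1), 0.03)
  # multiple ECGs of one subject never straddle splits
  rec2 <- rbind(rec, transform(rec, time = time + 1))
  sp2 <- prepareCohort(rec2, intervalGrid(), seed = 3)
  splitOf <- integer(nrow(rec2))
  splitOf[sp2$train] <- 1L; splitOf[sp2$val] <- 2L; splitOf[sp2$test] <- 3L
  bySubj <- tapply(splitOf[sp2$kept], rec2$subjectId[sp2$kept],
                   function(z) length(unique(z)))
  expect_true(all(bySubj == 1))
  expect_identical(sp, prepareCohort(rec, intervalGrid(), seed = 3))
  expect_error(prepareCohort(rec[1:2, ], intervalGrid()), "3 subjects")
})

test_that("training reduces validation loss on a small learnable problem", {
  # risk is a simple function of input amplitude
  set.seed(21)
  n <- 80
  amp <- runif(n, 0.2, 1)
  X <- array(0, c(64, 2, n))
  for (i in 1:n) X[, , i] <- rnorm(128, sd = 0.05) + amp[i]
  g1 <- intervalGrid(c(0, 100))
  h <- 0.15 + 0.7 * (amp > 0.6)
  ev <- rbinom(n, 1, h)
  tg <- encodeTargets(ifelse(ev == 1, 50, 150), ev, g1)
  cfg <- netConfig("residual1d", inputShape = c(64L, 2L), K = 1L,
                   channels = c(6L, 8L), strides = c(4L, 4L), seed = 5L,
                   epochs = 15L, patience = 15L, batchSize = 16L)
  m <- trainModel(buildModel(cfg, g1), X, tg,
                  list(train = 1:60, val = 61:80))
  expect_lte(m@history$bestVal, m@history$initVal)
  hPred <- predictHazards(m, X[, , 61:80])
  expect_gt(cor(drop(hPred), amp[61:80]), 0.5)
})

test_that("saliency maps are non-negative with the input's spatial shape", {
  g <- intervalGrid(c(0, 100, 200))
  cfg <- netConfig("conv2d", inputShape = c(20L, 30L), K = 2L,
                   channels = c(4L, 6L), strides = c(1L, 2L), seed = 2L)
  m <- buildModel(cfg, g)
  x <- matrix(runif(20 * 30), 20, 30)
  s <- saliencyMap(m, x)
  expect_identical(dim(s), c(20L, 30L))
  expect_true(all(s >= 0))
  cfg1 <- netConfig("residual1d", inputShape = c(128L, 2L), K = 2L,
                    channels = c(4L, 6L), strides = c(4L, 4L), seed = 2L)
  m1 <- buildModel(cfg1, g)
  s1 <- saliencyMap(m1, matrix(rnorm(256), 128, 2))
  expect_length(s1, 128L)
  expect_true(all(s1 >= 0))
})

test_that("a trained 2D model attends to the panel carrying the risk signal", {
  # only the top-left quadrant's intensity drives the hazard
  set.seed(31)
  n <- 90
  z <- runif(n)
  X <- array(0, c(16, 32, 1, n))
  for (i in 1:n) {
    X[, , 1, i] <- matrix(runif(16 * 32, 0, 0.3), 16, 32)
    X[1:8, 1:16, 1, i] <- X[1:8, 1:16, 1, i] + z[i]
  }
  g1 <- intervalGrid(c(0, 100))
  ev <- rbinom(n, 1, 0.1 + 0.8 * z)
  tg <- encodeTargets(ifelse(ev == 1, 50, 150), ev, g1)
  cfg <- netConfig("conv2d", inputShape = c(16L, 32L), K = 1L,
                   channels = c(4L, 8L), strides = c(1L, 2L), seed = 6L,
                   epochs = 25L, patience = 25L, batchSize = 16L, lr = 2e-3)
  m <- trainModel(buildModel(cfg, g1), X, tg, list(train = 1:70, val = 71:90))
  sal <- Reduce(`+`, lapply(71:90, function(i) saliencyMap(m, X[, , 1, i])))
  inPanel <- mean(sal[1:8, 1:16])
  outPanel <- mean(sal[-(1:8), -(1:16)])
  expect_gt(inPanel, outPanel)
})
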