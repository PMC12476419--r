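# Independent literal evaluators used as oracles -------------------------




test_that("dice and cross-entropy match literal oracle evaluations", {
  set.seed(101)
  for (rep in 1:100) {
    n <- sample(4:40, 1)
    r <- random_pred(n, 3)
    yh <- matrix(0, n, 3); yh[cbind(1:n, r$y + 1)] <- 1
    eps <- 1e-5
    expect_equal(diceLoss(r$p, yh, eps), dice_ref(r$p, yh, eps),
                 tolerance = 1e-6)
    w <- runif(3, 0.5, 2)
    expect_equal(weightedCrossEntropy(r$logits, r$y, w),
                 wce_ref(r$logits, r$y, w), tolerance = 1e-6)
  }
})

test_that("worked Dice example: half-overlap uniform prediction", {
  # 8 voxels, 4 of class 0 and 4 of class 1, prediction 0.5/0.5/0
  p <- matrix(rep(c(0.5, 0.5, 0), each = 8), 8, 3)
  y <- matrix(0, 8, 3)
  y[1:4, 1] <- 1; y[5:8, 2] <- 1
  expect_equal(diceLoss(p, y, 1e-5), 1 / 3, tolerance = 1e-5)
})

test_that("dice loss boundary behaviour", {
  y <- matrix(0, 10, 3); y[cbind(1:10, sample(1:3, 10, TRUE))] <- 1
  expect_lt(diceLoss(y, y, 1e-5), 1e-3)          # perfect overlap
  bg <- matrix(0, 6, 3); bg[, 1] <- 1
  expect_lt(diceLoss(bg, bg, 1e-5), 1e-6)        # empty classes smoothed
  expect_error(diceLoss(matrix(0.4, 4, 3), y[1:4, ]), "sum to 1")
  expect_error(diceLoss(y[1:4, ], y), "differ")
})

test_that("cross-entropy closed forms and invariances", {
  z <- matrix(0, 5, 3)
  expect_equal(weightedCrossEntropy(z, rep(1L, 5)), log(3),
               tolerance = 1e-9)
  strong <- matrix(0, 5, 3); strong[, 2] <- 20
  expect_lt(weightedCrossEntropy(strong, rep(1L, 5)), 1e-6)
  set.seed(7)
  r <- random_pred(20, 3)
  w <- runif(3, 0.5, 2)
  expect_equal(weightedCrossEntropy(r$logits, r$y, w),
               weightedCrossEntropy(r$logits, r$y, 2 * w),
               tolerance = 1e-12)
  expect_error(weightedCrossEntropy(r$logits, rep(3L, 20)), "0..C-1")
})

test_that("dice loss never increases when a foreground voxel is fixed", {
  set.seed(33)
  for (rep in 1:40) {
    n <- 30
    tgt <- sample(0:2, n, replace = TRUE, prob = c(0.5, 0.25, 0.25))
    pred <- sample(0:2, n, replace = TRUE)
    wrong_fg <- which(tgt > 0 & pred != tgt)
    if (!length(wrong_fg)) next
    yh <- matrix(0, n, 3); yh[cbind(1:n, tgt + 1)] <- 1
    ph <- matrix(0, n, 3); ph[cbind(1:n, pred + 1)] <- 1
    before <- dice_ref(ph, yh, 1e-5)
    i <- wrong_fg[1]
    ph[i, ] <- 0; ph[i, tgt[i] + 1] <- 1
    after <- diceLoss(ph, yh, 1e-5)
    expect_lte(after, before + 1e-12)
  }
})

test_that("deep supervision composes per-level losses", {
  cfg <- lossConfig()
  set.seed(5)
  tgt <- array(sample(0:2, 64, TRUE), c(4, 4, 4))
  lg1 <- array(rnorm(64 * 3), c(4, 4, 4, 3))
  # single level, weight 1: equals dice + cross-entropy directly
  one <- deepSupervisionSegLoss(list(lg1), tgt,
                                lossConfig(deepSupervisionWeights = 1))
  lm <- matrix(lg1, 64, 3)
  p <- exp(lm - apply(lm, 1, max)); p <- p / rowSums(p)
  yh <- matrix(0, 64, 3); yh[cbind(1:64, as.integer(tgt) + 1)] <- 1
  expect_equal(one, dice_ref(p, yh, cfg$epsilon) +
                 wce_ref(lm, as.integer(tgt), rep(1, 3)),
               tolerance = 1e-9)

  # three levels with halving weights (4/7, 2/7, 1/7)
  lg2 <- array(rnorm(8 * 3), c(2, 2, 2, 3))
  lg3 <- array(rnorm(3), c(1, 1, 1, 3))
  nn_down <- function(arr, od) {
    idx <- lapply(1:3, function(a) {
      i <- round((seq_len(od[a]) - 0.5) * dim(arr)[a] / od[a] + 0.5 -
                   1e-9)
      pmin(pmax(i, 1), dim(arr)[a])
    })
    arr[idx[[1]], idx[[2]], idx[[3]], drop = FALSE]
  }
  lvl <- function(lg, t_) {
    lm <- matrix(lg, prod(dim(lg)[1:3]), 3)
    p <- exp(lm - apply(lm, 1, max)); p <- p / rowSums(p)
    n <- nrow(p)
    yh <- matrix(0, n, 3); yh[cbind(1:n, as.integer(t_) + 1)] <- 1
    dice_ref(p, yh, cfg$epsilon) +
      wce_ref(lm, as.integer(t_), rep(1, 3))
  }
  manual <- 4 / 7 * lvl(lg1, tgt) +
    2 / 7 * lvl(lg2, nn_down(tgt, c(2, 2, 2))) +
    1 / 7 * lvl(lg3, nn_down(tgt, c(1, 1, 1)))
  expect_equal(deepSupervisionSegLoss(list(lg1, lg2, lg3), tgt, cfg),
               manual, tolerance = 1e-9)
  expect_error(
    deepSupervisionSegLoss(list(lg1, lg2), tgt,
                           lossConfig(deepSupervisionWeights = 1)),
    "does not match")

  # perfect prediction at all levels
  hot <- function(t_, mag = 30) {
    n <- prod(dim(t_))
    lm <- matrix(0, n, 3); lm[cbind(1:n, as.integer(t_) + 1)] <- mag
    array(lm, c(dim(t_), 3))
  }
  expect_lt(deepSupervisionSegLoss(
    list(hot(tgt), hot(nn_down(tgt, c(2, 2, 2))),
         hot(nn_down(tgt, c(1, 1, 1)))), tgt, cfg), 1e-3)
})

test_that("total loss applies the configured weighting", {
  cfg <- lossConfig()
  expect_equal(totalLoss(0.5, 1.0, cfg), 0.7)
  expect_equal(totalLoss(0.3, 0, cfg), 0.3)
  expect_equal(totalLoss(0.3, 5, lossConfig(lambdaSeg = 0)), 0.3)
  set.seed(2)
  for (i in 1:20) {
    a <- runif(1, 0, 3); b <- runif(1, 0, 3)
    expect_equal(totalLoss(a, b, cfg), 1 * a + 0.2 * b)
  }
  # linearity in each argument
  expect_equal(totalLoss(2, 3, cfg) - totalLoss(1, 3, cfg),
               totalLoss(1, 0, cfg))
  expect_error(totalLoss(-1, 0, cfg), "non-negative")
  expect_error(totalLoss(Inf, 0, cfg), "finite")
})
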