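test_that("deep-supervision outputs and taps follow the shape algebra", {
  for (L in 3:5) {
    cfg <- networkConfig(nLevels = L, baseChannels = 4, channelCap = 32,
                         dropoutP = 0)
    net <- buildNetwork(cfg, seed = 1)
    dims <- c(16, 32, 32)
    x <- array(runif(prod(dims)), dims)
    fw <- forwardSingle(net, x)
    expect_length(fw$segLogits, L)
    # repeated stride-2 halving with ceiling; a size-1 axis stays 1
    half_k <- function(d, k) {
      for (j in seq_len(k)) d <- pmax(1, ceiling(d / 2))
      as.integer(d)
    }
    for (k in seq_len(L)) {
      d <- dim(fw$segLogits[[k]])
      expect_equal(d[1:3], half_k(dims, k - 1))  # full resolution first
      expect_equal(d[4], 3L)                     # three classes per level
    }
    expect_named(fw$taps, c("cmid", "bottleneck", "dmid"))
    mid <- ceiling(L / 2)
    expect_equal(dim(fw$taps$cmid)[1:3], half_k(dims, mid))
    expect_equal(dim(fw$taps$bottleneck)[1:3], half_k(dims, L))
    expect_equal(dim(fw$taps$dmid)[1:3], dims)
    expect_true(all(vapply(fw$taps, function(t) dim(t)[4], numeric(1)) >
                      0))
    # softmax over the class channel is a distribution at every level
    p <- SiameseCT:::softmax_rows(SiameseCT:::fm_mat(fw$segLogits[[2]]))
    expect_lt(max(abs(rowSums(p) - 1)), 1e-5)
  }
})

test_that("network construction is deterministic and size-checked", {
  cfg <- tiny_net_config()
  n1 <- buildNetwork(cfg, seed = 42)
  n2 <- buildNetwork(cfg, seed = 42)
  expect_identical(n1$params, n2$params)
  expect_identical(parameterCount(n1), parameterCount(n2))
  # input below the structural minimum is rejected at forward time
  small <- array(0, c(2, 8, 8))
  expect_error(forwardSingle(n1, small), "too small")
  # evaluation-mode forward is deterministic
  x <- array(runif(8 * 16 * 16), c(8, 16, 16))
  expect_identical(forwardSingle(n1, x)$segLogits,
                   forwardSingle(n1, x)$segLogits)
})

test_that("Siamese weight sharing gives identical streams and neutral
           zero-difference response", {
  net <- buildNetwork(tiny_net_config(dropoutP = 0), seed = 3)
  sp <- c(5, 2, 2)
  vol <- ctVolume(array(runif(8 * 16 * 16), c(8, 16, 16)), sp,
                  normalised = TRUE)
  pair <- longitudinalPair(vol, vol)
  out <- forwardPair(net, pair)
  # both streams share one parameter set: identical inputs give exactly
  # identical segmentations
  expect_identical(out$segLogitsBaseline, out$segLogitsFollowup)
  # zero difference maps: the response logit collapses to the bias
  expect_equal(out$responseLogit, net$params[["head.linear.b"]],
               tolerance = 1e-12)

  # swapping pre and post negates every difference: the bias-free head
  # is antisymmetric about the linear-layer bias
  vol2 <- ctVolume(array(runif(8 * 16 * 16), c(8, 16, 16)), sp,
                   normalised = TRUE)
  f1 <- forwardSingle(net, vol)
  f2 <- forwardSingle(net, vol2)
  l12 <- responseHead(net, f1$taps, f2$taps)
  l21 <- responseHead(net, f2$taps, f1$taps)
  b <- net$params[["head.linear.b"]]
  expect_equal(l12 - b, -(l21 - b), tolerance = 1e-9)

  # mismatched tap shapes are a contract error
  bad <- f2$taps
  bad$bottleneck <- bad$bottleneck[, , , 1:2, drop = FALSE]
  expect_error(responseHead(net, f1$taps, bad), "shapes differ")
})

test_that("response head reproduces the closed-form trace on hand-built
           taps", {
  # one-channel 2x2x2 taps, identity depth-wise filters, unit point-wise
  # projection: logit = sum_s w_s * mean(diff_s) + bias
  cfg <- networkConfig(nLevels = 3, baseChannels = 4, headChannels = 1)
  net <- buildNetwork(cfg, seed = 1)
  p <- list()
  delta <- array(0, c(3, 3, 3, 1, 1)); delta[2, 2, 2, 1, 1] <- 1
  for (s in c("cmid", "bottleneck", "dmid")) {
    p[[sprintf("head.%s.dw", s)]] <- delta
    p[[sprintf("head.%s.pw", s)]] <- matrix(1, 1, 1)
  }
  w <- c(2, -1, 0.5); b <- 0.25
  p[["head.linear.W"]] <- w
  p[["head.linear.b"]] <- b
  net$params[names(p)] <- p
  set.seed(8)
  tp <- lapply(1:3, function(i) array(rnorm(8), c(2, 2, 2, 1)))
  tq <- lapply(1:3, function(i) array(rnorm(8), c(2, 2, 2, 1)))
  names(tp) <- names(tq) <- c("cmid", "bottleneck", "dmid")
  expected <- b + sum(w * vapply(1:3, function(i)
    mean(tp[[i]] - tq[[i]]), numeric(1)))
  expect_equal(responseHead(net, tp, tq), expected, tolerance = 1e-9)
})

test_that("response-loss gradients reach the shared encoder", {
  ns <- asNamespace("SiameseCT")
  net <- buildNetwork(tiny_net_config(dropoutP = 0), seed = 5)
  x1 <- array(runif(8 * 16 * 16), c(8, 16, 16))
  x2 <- array(runif(8 * 16 * 16), c(8, 16, 16))
  f1 <- ns$net_forward(net, x1)
  f2 <- ns$net_forward(net, x2)
  hd <- ns$head_forward(net, f1$taps, f2$taps)
  bce <- ns$bce_with_logit(hd$logit, 1)
  hb <- ns$head_backward(net, hd$cache, bce$dlogit)
  # the perturbed weights act in both Siamese streams: accumulate the
  # gradients of the pre and the post pass
  g1 <- ns$net_backward(net, f1$cache, NULL, hb$dTapsPre)
  g2 <- ns$net_backward(net, f2$cache, NULL, hb$dTapsPost)
  g <- g1
  for (nm in names(g2)) g[[nm]] <- g[[nm]] + g2[[nm]]
  expect_gt(max(abs(g[["enc1.down.W"]])), 0)
  expect_gt(max(abs(g[["enc3.c2.W"]])), 0)

  # finite-difference check of that path on one encoder weight
  loss_at <- function(params) {
    n2 <- net; n2$params <- params
    a <- ns$net_forward(n2, x1); b <- ns$net_forward(n2, x2)
    ns$bce_with_logit(ns$head_forward(n2, a$taps, b$taps)$logit, 1)$loss
  }
  idx <- which.max(abs(g[["enc1.down.W"]]))
  h <- 1e-3
  p1 <- net$params; p1[["enc1.down.W"]][idx] <- p1[["enc1.down.W"]][idx] + h
  p2 <- net$params; p2[["enc1.down.W"]][idx] <- p2[["enc1.down.W"]][idx] - h
  fd <- (loss_at(p1) - loss_at(p2)) / (2 * h)
  expect_equal(fd, g[["enc1.down.W"]][idx], tolerance = 5e-2)
})

test_that("checkpoints round-trip through disk", {
  net <- buildNetwork(tiny_net_config(), seed = 9)
  path <- tempfile(fileext = ".rds")
  saveCheckpoint(net, path)
  back <- loadCheckpoint(path)
  expect_identical(back$params, net$params)
  expect_equal(unclass(back$config), unclass(net$config))
  x <- array(runif(8 * 16 * 16), c(8, 16, 16))
  expect_identical(forwardSingle(back, x)$segLogits,
                   forwardSingle(net, x)$segLogits)
})

test_that("unnormalised input volumes trigger the contract warning", {
  net <- buildNetwork(tiny_net_config(dropoutP = 0), seed = 2)
  raw <- ctVolume(array(rnorm(8 * 16 * 16, 40, 100), c(8, 16, 16)),
                  c(5, 2, 2), normalised = FALSE)
  expect_warning(forwardSingle(net, raw), "normalised")
})
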