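zero_config <- function(...) {
  zero <- list(pShift = 0, pScale = 0, pNoise = 0, pSmooth = 0,
               pContrast = 0, pFlip = 0, pSpatialScale = 0, pShear = 0,
               pRotation = 0)
  do.call(augmentConfig, utils::modifyList(zero, list(...)))
}

test_that("all-zero probabilities give the identity augmentation", {
  cfg <- zero_config()
  set.seed(1)
  expect_equal(sampleAffine(cfg), diag(4))
  v <- ctVolume(array(runif(4 * 6 * 6), c(4, 6, 6)), c(5, 2, 2),
                normalised = TRUE)
  expect_equal(volData(greyTransform(v, cfg)), volData(v))
  pair <- longitudinalPair(v, v)
  out <- augmentPair(pair, cfg)
  expect_equal(volData(baseline(out)), volData(v), tolerance = 1e-9)
})

test_that("grey transforms follow the documented arithmetic and order", {
  v <- ctVolume(array(0.5, c(4, 6, 6)), c(5, 2, 2), normalised = TRUE)
  shift_only <- zero_config(pShift = 1, shiftRange = c(0.1, 0.1))
  set.seed(2)
  expect_equal(range(volData(greyTransform(v, shift_only))), c(0.6, 0.6),
               tolerance = 1e-12)
  scale_only <- zero_config(pScale = 1, scaleRange = c(1.1, 1.1))
  set.seed(2)
  expect_equal(range(volData(greyTransform(v, scale_only))),
               c(0.55, 0.55), tolerance = 1e-12)
  # contrast about the mean leaves a constant volume unchanged
  contrast_only <- zero_config(pContrast = 1)
  set.seed(2)
  expect_equal(range(volData(greyTransform(v, contrast_only))),
               c(0.5, 0.5), tolerance = 1e-12)
})

test_that("augmented intensities stay in [0,1] and labels are never
           invented over random draws", {
  cfg <- augmentConfig()   # default probabilities
  case <- generateCase(micro_config(seed = 4), 1, rngSeed = 6)
  pair <- as_training_pair(case)
  set.seed(123)
  for (i in 1:100) {
    out <- augmentPair(pair, cfg)
    expect_gte(min(volData(baseline(out))), 0)
    expect_lte(max(volData(baseline(out))), 1)
    expect_true(all(volData(baselineMask(out)) %in% 0:2))
    expect_true(all(volData(followupMask(out)) %in% 0:2))
    expect_identical(responseLabel(out), responseLabel(pair))
    expect_identical(recistCategory(out), recistCategory(pair))
  }
})

test_that("the affine transform is shared within a pair", {
  # pass the same structure as baseline and follow-up: after any spatial
  # draw the two transformed masks must still coincide exactly
  spatial <- zero_config(pFlip = 0.5, pSpatialScale = 1, pShear = 1,
                         pRotation = 1)
  m <- ellipsoid_mask(c(12, 16, 16), c(5, 2.5, 2.5), c(0, 0, 5),
                      c(9, 9, 9), 2L)
  v <- ctVolume(array(0.5 * (volData(m) > 0), dim(volData(m))),
                c(5, 2.5, 2.5), normalised = TRUE)
  pair <- longitudinalPair(v, v, baselineMask = m, followupMask = m)
  set.seed(7)
  for (i in 1:20) {
    out <- augmentPair(pair, spatial)
    expect_identical(volData(baselineMask(out)),
                     volData(followupMask(out)))
  }
})

test_that("grey transforms never touch masks and are drawn independently
           per time point", {
  grey <- augmentConfig(pShift = 1, pScale = 1, pNoise = 1, pSmooth = 1,
                        pContrast = 1, pFlip = 0, pSpatialScale = 0,
                        pShear = 0, pRotation = 0)
  case <- generateCase(micro_config(seed = 9), 0, rngSeed = 2)
  pair <- as_training_pair(case)
  set.seed(11)
  out <- augmentPair(pair, grey)
  expect_identical(volData(baselineMask(out)),
                   volData(baselineMask(pair)))
  expect_identical(volData(followupMask(out)),
                   volData(followupMask(pair)))

  # identical input volumes produce different noise fields per stream
  v <- baseline(pair)
  twin <- longitudinalPair(v, v)
  set.seed(13)
  noisy <- augmentPair(twin, zero_config(pNoise = 1))
  expect_gt(max(abs(volData(baseline(noisy)) -
                      volData(followup(noisy)))), 0)
})

test_that("augmentation is deterministic under a fixed seed", {
  cfg <- augmentConfig()
  pair <- as_training_pair(generateCase(micro_config(seed = 5), 1, 3))
  set.seed(99); a <- augmentPair(pair, cfg)
  set.seed(99); b <- augmentPair(pair, cfg)
  expect_identical(volData(baseline(a)), volData(baseline(b)))
  expect_identical(volData(followupMask(a)), volData(followupMask(b)))
  set.seed(100); c_ <- augmentPair(pair, cfg)
  expect_false(identical(volData(baseline(a)), volData(baseline(c_))))
})

test_that("sampled affines are well-formed", {
  set.seed(3)
  rot <- zero_config(pRotation = 1)
  M <- sampleAffine(rot)
  R <- M[1:3, 1:3]
  expect_equal(crossprod(R), diag(3), tolerance = 1e-9)   # orthonormal
  expect_equal(det(R), 1, tolerance = 1e-9)
  expect_equal(M[1:3, 4], c(0, 0, 0))
  flip <- zero_config(pFlip = 1)
  Mf <- sampleAffine(flip)
  expect_true(all(abs(abs(diag(Mf[1:3, 1:3])) - 1) < 1e-12))
})
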