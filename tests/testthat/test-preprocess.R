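test_that("NIfTI round trip preserves data and anisotropic spacing", {
  set.seed(1)
  arr <- array(rnorm(16^3, 40, 120), c(16, 16, 16))
  v <- ctVolume(arr, c(5, 0.8, 0.75))
  path <- tempfile(fileext = ".nii.gz")
  writeVolume(v, path)
  back <- readVolume(path)
  expect_equal(volData(back), arr, tolerance = 1e-6)
  expect_equal(voxelSpacing(back), c(5, 0.8, 0.75), tolerance = 1e-6)

  m <- labelMask(array(sample(0:2, 4^3, TRUE), c(4, 4, 4)), c(5, 2, 2))
  mp <- tempfile(fileext = ".nii.gz")
  writeVolume(m, mp)
  expect_identical(volData(readVolume(mp, mask = TRUE)), volData(m))

  expect_error(readVolume(tempfile(fileext = ".nii")), "not found")
  # 4D series are rejected as non-scalar volumes
  p4 <- tempfile(fileext = ".nii.gz")
  RNifti::writeNifti(RNifti::asNifti(array(0, c(4, 4, 4, 2))), p4)
  expect_error(readVolume(p4), "3D")
})

test_that("HU clipping and normalisation follow the linear window map", {
  v <- ctVolume(array(c(-1000, -150, 50, 250, 3000, 0), c(6, 1, 1)),
                c(5, 0.8, 0.8))
  nv <- clipAndNormalize(v)
  expect_true(isNormalised(nv))
  expect_equal(as.numeric(volData(nv)),
               c(0, 0, 0.5, 1, 1, 0.375), tolerance = 1e-12)
  expect_error(clipAndNormalize(nv), "twice")
})

test_that("resampling honours the target spacing and interpolation
           contracts", {
  set.seed(2)
  v <- ctVolume(array(runif(8 * 20 * 20), c(8, 20, 20)), c(5, 1.6, 1.6),
                normalised = TRUE)
  # resampling to the native spacing is the identity
  same <- resampleVolume(v, c(5, 1.6, 1.6))
  expect_equal(volData(same), volData(v), tolerance = 1e-9)
  fine <- resampleVolume(v, c(5, 0.8, 0.8))
  expect_equal(voxelSpacing(fine), c(5, 0.8, 0.8))
  expect_equal(dim(volData(fine)), c(8L, 40L, 40L))

  # constant volumes stay constant
  const <- resampleVolume(ctVolume(array(0.3, c(6, 10, 10)),
                                   c(5, 1.6, 1.6), normalised = TRUE),
                          c(5, 0.8, 0.8))
  expect_equal(range(volData(const)), c(0.3, 0.3), tolerance = 1e-12)

  # nearest-neighbour mask resampling never invents labels
  m <- array(0L, c(8, 20, 20)); m[3:5, 8:12, 8:12] <- 2L
  mr <- resampleVolume(labelMask(m, c(5, 1.6, 1.6)), c(5, 0.8, 0.8))
  expect_true(all(volData(mr) %in% c(0L, 2L)))

  expect_error(resampleVolume(v, c(0, 1, 1)), "positive")

  # band-limited volume survives down/up resampling within 2% of range
  cc <- lapply(1:3, function(a) seq(-1, 1, length.out = c(16, 32, 32)[a]))
  smooth <- 0.5 + 0.45 * outer(outer(cos(pi * cc[[1]] / 2),
                                     cos(pi * cc[[2]] / 2)),
                               cos(pi * cc[[3]] / 2))
  sv <- ctVolume(array(smooth, c(16, 32, 32)), c(5, 0.8, 0.8),
                 normalised = TRUE)
  down <- resampleVolume(sv, c(5, 1.6, 1.6))
  back <- resampleVolume(down, c(5, 0.8, 0.8))
  expect_lt(max(abs(volData(back) - volData(sv))) / 0.9, 0.02)
})

test_that("rigid registration recovers known transforms", {
  # moving scans carry the same anatomy under a known rigid transform
  # but an independent noise realisation, as two acquisitions would
  cfgN <- phantomConfig(seed = 31, noiseSd = 15)
  cfg0 <- phantomConfig(seed = 31, noiseSd = 0)
  caseN <- generateCase(cfgN, 0, 4)
  case0 <- generateCase(cfg0, 0, 4)
  fixed <- clipAndNormalize(baseline(caseN))
  sp <- voxelSpacing(fixed)
  mknoise <- function(mv) {
    a <- volData(mv) +
      array(pmin(pmax(rnorm(length(volData(mv)), 0, 15), -60), 60),
            dim(volData(mv)))
    clipAndNormalize(ctVolume(a, voxelSpacing(mv)))
  }

  # pre-aligned identical grids: the transform stays at the identity
  reg0 <- rigidRegister(fixed,
                        clipAndNormalize(
                          ctVolume(volData(baseline(caseN)), sp)))
  expect_lt(max(abs(reg0$transform[4:6])), 1)       # mm
  expect_lt(max(abs(reg0$transform[1:3])), 0.5)     # degrees

  set.seed(5)
  # known translation (0, 8, -8) mm: the registration recovers the
  # inverse displacement within one voxel per axis
  par_t <- c(0, 0, 0, 0, 8, -8)
  moving <- mknoise(applyRigidTransform(baseline(case0), par_t,
                                        fill = -1000))
  reg <- rigidRegister(fixed, moving)
  expect_lt(abs(reg$transform[4] + par_t[4]), sp[1])
  expect_lt(abs(reg$transform[5] + par_t[5]), sp[2])
  expect_lt(abs(reg$transform[6] + par_t[6]), sp[3])

  # known 5-degree rotation about the slice axis within 0.5 degrees
  par_r <- c(5, 0, 0, 0, 0, 0)
  movr <- mknoise(applyRigidTransform(baseline(case0), par_r,
                                      fill = -1000))
  regr <- rigidRegister(fixed, movr)
  expect_lt(abs(regr$transform[1] + 5), 0.5)
})

test_that("preprocessPair runs the full chain on phantom files", {
  cfg <- tiny_config(seed = 8)
  dir <- file.path(tempdir(), "ppair")
  manifest <- generateCohort(cfg, 1, dir)
  pair <- preprocessPair(manifest$baseline_path,
                         manifest$followup_path,
                         baselineMaskPath = manifest$baseline_mask_path,
                         followupMaskPath = manifest$followup_mask_path,
                         targetSpacing = c(5, 2, 2), register = FALSE)
  expect_identical(dim(volData(baseline(pair))),
                   dim(volData(followup(pair))))
  expect_equal(voxelSpacing(pair), c(5, 2, 2))
  expect_gte(min(volData(baseline(pair))), 0)
  expect_lte(max(volData(followup(pair))), 1)
  expect_s4_class(baselineMask(pair), "LabelMask")

  # missing masks yield absent mask slots, not an error
  nomask <- preprocessPair(manifest$baseline_path,
                           manifest$followup_path,
                           targetSpacing = c(5, 2, 2), register = FALSE)
  expect_null(baselineMask(nomask))
  expect_null(followupMask(nomask))

  # with registration enabled on an aligned pair the recovered
  # transform is close to the identity
  reg <- preprocessPair(manifest$baseline_path, manifest$followup_path,
                        targetSpacing = c(5, 2, 2), register = TRUE)
  expect_lt(max(abs(reg@transform[4:6])), 2.5)
  unlink(dir, recursive = TRUE)
})
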