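# brute-force oracles -----------------------------------------------------



test_that("dice score formula, symmetry and relation to the Dice loss", {
  a <- array(0L, c(4, 4, 4)); b <- a
  a[1:2, 1, 1] <- 1L
  expect_equal(diceScore(a, a, 1L), 1)
  b[3:4, 2, 1] <- 1L
  expect_equal(diceScore(a, b, 1L), 0)       # disjoint
  a2 <- array(0L, c(4, 4, 4)); b2 <- array(0L, c(4, 4, 4))
  a2[1:8] <- 2L; b2[5:12] <- 2L              # 8 vs 8 voxels, overlap 4
  expect_equal(diceScore(a2, b2, 2L), 0.5)
  expect_equal(diceScore(b2, a2, 2L), diceScore(a2, b2, 2L))
  expect_equal(diceScore(a, b, 2L), 1)       # both empty -> defined as 1
  expect_error(diceScore(a, array(0L, c(2, 2, 2)), 1L), "aligned")

  # diceLoss on hard one-hot encodings equals 1 - mean per-class DSC
  set.seed(4)
  tgt <- array(sample(0:2, 64, TRUE), c(4, 4, 4))
  prd <- array(sample(0:2, 64, TRUE), c(4, 4, 4))
  oh <- function(x) {
    m <- matrix(0, 64, 3); m[cbind(1:64, as.integer(x) + 1)] <- 1; m
  }
  meanDsc <- mean(vapply(0:2, function(cl) diceScore(prd, tgt, cl),
                         numeric(1)))
  expect_equal(diceLoss(oh(prd), oh(tgt), 1e-12), 1 - meanDsc,
               tolerance = 1e-9)
})

test_that("AUC equals Mann-Whitney pair counting", {
  expect_equal(rocAuc(c(0.2, 0.6, 0.4, 0.9), c(0, 0, 1, 1)), 0.75)
  expect_equal(rocAuc(c(1, 2, 3, 4), c(0, 0, 1, 1)), 1)
  expect_equal(rocAuc(rep(0.5, 6), c(0, 1, 0, 1, 0, 1)), 0.5)
  expect_error(rocAuc(1:4, rep(1, 4)), "both classes")
  set.seed(17)
  for (i in 1:100) {
    n <- sample(5:30, 1)
    lab <- c(0, 1, sample(0:1, n - 2, TRUE))
    sc <- round(runif(n), 2)               # ties likely
    expect_equal(rocAuc(sc, lab), auc_ref(sc, lab), tolerance = 1e-12)
  }
})

test_that("AUC is invariant under monotone score transforms and matches
           the trapezoidal ROC integral", {
  set.seed(23)
  sc <- runif(40); lab <- rbinom(40, 1, 0.5); lab[1:2] <- c(0, 1)
  a <- rocAuc(sc, lab)
  expect_equal(rocAuc(qlogis(sc * 0.98 + 0.01), lab), a)
  expect_equal(rocAuc(sc^3, lab), a)
  # trapezoidal integral over the empirical ROC curve
  th <- c(Inf, sort(unique(sc), decreasing = TRUE))
  sens <- vapply(th, function(t) mean(sc[lab == 1] >= t), numeric(1))
  fpr <- vapply(th, function(t) mean(sc[lab == 0] >= t), numeric(1))
  trap <- sum(diff(fpr) * (head(sens, -1) + tail(sens, -1)) / 2)
  expect_equal(a, trap, tolerance = 1e-10)
})

test_that("AUC agrees with an established ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(31)
  sc <- runif(50); lab <- c(0, 1, rbinom(48, 1, 0.4))
  expect_equal(rocAuc(sc, lab),
               as.numeric(pROC::auc(lab, sc, direction = "<",
                                    quiet = TRUE)),
               tolerance = 1e-12)
})

test_that("Youden cut-off matches exhaustive search with documented
           tie-breaks", {
  y <- youdenCutoff(c(0.1, 0.4, 0.35, 0.8), c(0, 1, 0, 1))
  expect_equal(y$threshold, 0.4)
  expect_equal(y$sensitivity, 1)
  expect_equal(y$specificity, 1)
  set.seed(47)
  for (i in 1:100) {
    n <- sample(6:200, 1)
    lab <- c(0, 1, rbinom(n - 2, 1, runif(1, 0.2, 0.8)))
    sc <- round(runif(n), sample(1:3, 1))
    got <- youdenCutoff(sc, lab)
    ref <- youden_ref(sc, lab)
    expect_equal(got$threshold, ref$t)
    expect_equal(got$sensitivity + got$specificity - 1, ref$j,
                 tolerance = 1e-12)
  }
  expect_error(youdenCutoff(1:3, c(1, 1, 1)), "both classes")
})

test_that("classification report arithmetic at a fixed threshold", {
  # construct scores reproducing TP=7 FN=1 TN=5 FP=3 at threshold 0.5
  scores <- c(rep(0.9, 7), 0.2, rep(0.1, 5), rep(0.8, 3))
  labels <- c(rep(1, 8), rep(0, 8))
  r <- classificationReport(scores, labels, 0.5)
  expect_equal(r$tp, 7); expect_equal(r$fn, 1)
  expect_equal(r$tn, 5); expect_equal(r$fp, 3)
  expect_equal(r$sensitivity, 0.875)
  expect_equal(r$specificity, 0.625)
  expect_equal(r$ppv, 0.7)
  expect_equal(r$npv, 5 / 6)

  perfect <- classificationReport(c(0.9, 0.9, 0.1), c(1, 1, 0), 0.5)
  expect_equal(perfect$f1, 1)
  expect_equal(perfect$precision, 1)
  allpos <- classificationReport(c(0.9, 0.8, 0.7), c(1, 0, 1), 0)
  expect_equal(allpos$sensitivity, 1)
  expect_equal(allpos$specificity, 0)
})

test_that("bootstrap CI is deterministic under seed and covers the true
           AUC", {
  set.seed(3)
  sc <- c(rnorm(25, 1.2), rnorm(25)); lab <- rep(c(1, 0), each = 25)
  ci1 <- bootstrapCi(sc, lab, nBoot = 300, seed = 9)
  ci2 <- bootstrapCi(sc, lab, nBoot = 300, seed = 9)
  expect_identical(ci1, ci2)
  expect_lte(ci1[1], rocAuc(sc, lab))
  expect_gte(ci1[2], rocAuc(sc, lab))
  expect_error(bootstrapCi(sc, lab, nBoot = 10), "nBoot")
  expect_error(bootstrapCi(1:4, rep(1, 4), nBoot = 200), "both classes")

  # perfectly separated large sample: tight interval at 1
  ps <- bootstrapCi(c(rep(1, 30), rep(0, 30)), rep(c(1, 0), each = 30),
                    nBoot = 200, seed = 1)
  expect_equal(unname(ps), c(1, 1))

  # coverage study: N(mu,1) vs N(0,1) with true AUC = pnorm(mu/sqrt(2))
  mu <- sqrt(2) * qnorm(0.8)
  hits <- 0
  set.seed(99)
  for (i in 1:200) {
    s <- c(rnorm(25, mu), rnorm(25))
    l <- rep(c(1, 0), each = 25)
    ci <- bootstrapCi(s, l, nBoot = 300, seed = i)
    if (ci[1] <= 0.8 && ci[2] >= 0.8) hits <- hits + 1
  }
  expect_gte(hits / 200, 0.9)
})

test_that("evaluation report serialises and restores through JSON", {
  rep_ <- new("EvalReport", auc = 0.9, aucCI = c(0.8, 0.97),
              threshold = 0.4, sensitivity = 0.9, specificity = 0.8,
              ppv = 0.85, npv = 0.75, weightedF1 = 0.82,
              dscPerClass = rbind(omental = c(mean = 0.5, sd = 0.1),
                                  pelvic_ovarian = c(mean = 0.6,
                                                     sd = 0.2)),
              perCase = data.frame(case = 1:2, score = c(0.2, 0.9),
                                   label = c(0L, 1L),
                                   prediction = c(0L, 1L),
                                   dsc_omental = c(0.4, 0.6),
                                   dsc_pelvic_ovarian = c(0.5, 0.7)))
  path <- tempfile(fileext = ".json")
  reportToJson(rep_, path)
  back <- reportFromJson(path)
  expect_equal(back@auc, rep_@auc)
  expect_equal(back@dscPerClass, rep_@dscPerClass)
  expect_equal(back@perCase, rep_@perCase)
})
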