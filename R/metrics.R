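#' Dice similarity coefficient for one class
#'
#' \eqn{2|A \cap B| / (|A| + |B|)} over the voxel sets carrying
#' \code{classId}.  When the class is empty in both masks the score is
#' defined as 1 (perfect agreement on absence, as for complete
#' responders).
#'
#' @param predMask,gtMask aligned \code{\linkS4class{LabelMask}} objects
#'   or integer arrays.
#' @param classId the label value to score (1 = omental,
#'   2 = pelvic/ovarian).
#' @return DSC in \eqn{[0, 1]}.
#' @export
diceScore <- function(predMask, gtMask, classId) {
  a <- if (is(predMask, "LabelMask")) volData(predMask) else predMask
  b <- if (is(gtMask, "LabelMask")) volData(gtMask) else gtMask
  if (!identical(dim(a), dim(b)))
    stop("masks are not aligned: grid shapes differ")
  na <- sum(a == classId); nb <- sum(b == classId)
  if (na + nb == 0) return(1)
  2 * sum(a == classId & b == classId) / (na + nb)
}

#' Area under the ROC curve
#'
#' Mann-Whitney form: the probability that a randomly chosen responder
#' outscores a randomly chosen non-responder, ties counting one half.
#'
#' @param scores numeric prediction scores.
#' @param labels binary labels (1 = positive/responder).
#' @return AUC in \eqn{[0, 1]}.
#' @export
rocAuc <- function(scores, labels) {
  labels <- as.integer(labels)
  n1 <- sum(labels == 1L); n0 <- sum(labels == 0L)
  if (n1 == 0L || n0 == 0L)
    stop("AUC undefined: both classes must be present")
  r <- rank(scores)
  (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Operating point maximising Youden's index
#'
#' Scans all distinct score values as candidate thresholds (classify
#' positive when \code{score >= threshold}) and returns the one
#' maximising \eqn{J = sensitivity + specificity - 1}.  Ties are broken
#' toward higher sensitivity, then toward the lower threshold.
#'
#' @param scores numeric prediction scores.
#' @param labels binary labels (1 = positive).
#' @return A list with \code{threshold}, \code{sensitivity},
#'   \code{specificity}.
#' @export
youdenCutoff <- function(scores, labels) {
  labels <- as.integer(labels)
  n1 <- sum(labels == 1L); n0 <- sum(labels == 0L)
  if (n1 == 0L || n0 == 0L)
    stop("operating point undefined: both classes must be present")
  th <- sort(unique(scores))
  sens <- vapply(th, function(t) sum(scores >= t & labels == 1L) / n1,
                 numeric(1))
  spec <- vapply(th, function(t) sum(scores < t & labels == 0L) / n0,
                 numeric(1))
  J <- sens + spec - 1
  cand <- which(J >= max(J) - 1e-12)
  cand <- cand[order(-sens[cand], th[cand])]
  i <- cand[1]
  list(threshold = th[i], sensitivity = sens[i], specificity = spec[i])
}

#' Classification report at a fixed threshold
#'
#' Confusion counts at \code{score >= threshold}, per-class precision,
#' recall and F1 with support-weighted averages, plus PPV and NPV.
#' Degenerate denominators yield 0.
#'
#' @param scores numeric prediction scores.
#' @param labels binary labels (1 = positive).
#' @param threshold classification cut-off.
#' @return A list with the confusion counts (\code{tp}, \code{fp},
#'   \code{tn}, \code{fn}), \code{sensitivity}, \code{specificity},
#'   \code{ppv}, \code{npv}, and sample-weighted \code{precision},
#'   \code{recall}, \code{f1}.
#' @export
classificationReport <- function(scores, labels, threshold) {
  labels <- as.integer(labels)
  pred <- as.integer(scores >= threshold)
  tp <- sum(pred == 1L & labels == 1L)
  fp <- sum(pred == 1L & labels == 0L)
  tn <- sum(pred == 0L & labels == 0L)
  fn <- sum(pred == 0L & labels == 1L)
  div <- function(a, b) if (b > 0) a / b else 0
  prec1 <- div(tp, tp + fp); rec1 <- div(tp, tp + fn)
  prec0 <- div(tn, tn + fn); rec0 <- div(tn, tn + fp)
  f1 <- function(p, r) if (p + r > 0) 2 * p * r / (p + r) else 0
  n1 <- tp + fn; n0 <- tn + fp; n <- n1 + n0
  list(tp = tp, fp = fp, tn = tn, fn = fn,
       sensitivity = rec1, specificity = rec0,
       ppv = prec1, npv = div(tn, tn + fn),
       precision = (n1 * prec1 + n0 * prec0) / n,
       recall = (n1 * rec1 + n0 * rec0) / n,
       f1 = (n1 * f1(prec1, rec1) + n0 * f1(prec0, rec0)) / n)
}

#' Percentile bootstrap confidence interval for the AUC
#'
#' Case-level resampling with replacement; resamples containing a
#' single class are redrawn.
#'
#' @param scores numeric prediction scores.
#' @param labels binary labels (1 = positive).
#' @param nBoot number of bootstrap resamples (>= 100).
#' @param seed RNG seed.
#' @param conf confidence level.
#' @return numeric(2): lower and upper bounds.
#' @export
bootstrapCi <- function(scores, labels, nBoot = 2000, seed = 1L,
                        conf = 0.95) {
  stopifnot(nBoot >= 100)
  labels <- as.integer(labels)
  if (length(unique(labels)) < 2)
    stop("both classes must be present to bootstrap the AUC")
  n <- length(scores)
  with_seed(seed, {
    aucs <- numeric(nBoot)
    for (b in seq_len(nBoot)) {
      repeat {
        idx <- sample.int(n, n, replace = TRUE)
        if (length(unique(labels[idx])) == 2) break
      }
      aucs[b] <- rocAuc(scores[idx], labels[idx])
    }
    unname(quantile(aucs, c((1 - conf) / 2, 1 - (1 - conf) / 2)))
  })
}

#' 3D Grad-CAM relevance map
#'
#' For the response target, channel weights are the global-average
#' gradients of the response logit with respect to the chosen tap's
#' difference features; the map is the rectified channel-weighted sum,
#' upsampled trilinearly to the input grid and scaled to \eqn{[0, 1]}
#' when non-zero.  For a segmentation class target the final decoder
#' features of the baseline stream are used with the gradient of that
#' class's summed logit.
#'
#' @param network a \code{SiameseNet}.
#' @param pair a preprocessed \code{\linkS4class{LongitudinalPair}}.
#' @param target \code{"response"}, \code{"omental"} or
#'   \code{"pelvic_ovarian"}.
#' @param tap tap stream for the response target
#'   (\code{"bottleneck"}, \code{"cmid"} or \code{"dmid"}).
#' @return A \code{\linkS4class{CTVolume}} relevance map on the input
#'   grid with values in \eqn{[0, 1]}.
#' @export
gradCam <- function(network, pair,
                    target = c("response", "omental", "pelvic_ovarian"),
                    tap = c("bottleneck", "cmid", "dmid")) {
  target <- match.arg(target)
  tap <- match.arg(tap)
  fb <- net_forward(network, volData(baseline(pair)))
  sdims <- dim(volData(baseline(pair)))
  if (target == "response") {
    ff <- net_forward(network, volData(followup(pair)))
    hd <- head_forward(network, fb$taps, ff$taps)
    hb <- head_backward(network, hd$cache, 1)
    feat <- hd$cache$streams[[tap]]$diff
    grad <- hb$dTapsPre[[tap]]
  } else {
    cls <- if (target == "omental") 2L else 3L   # logit channel
    feat <- fb$cache$dec[[1L]]$m3
    w <- network$params[["dec0.seg.W"]][, cls]
    grad <- array(rep(w, each = prod(dim(feat)[1:3])), dim(feat))
  }
  n <- fm_nvox(feat)
  cw <- .colMeans(fm_mat(grad), n, dim(feat)[4])
  if (all(cw == 0)) {
    warning("target has zero gradient on the selected features; ",
            "returning an all-zero map")
    return(ctVolume(array(0, sdims), voxelSpacing(pair),
                    normalised = TRUE))
  }
  m <- fm_mat(feat) %*% cw
  m <- pmax(m, 0)
  m <- array(cpp_resize3d(as.double(m), dim(feat)[1:3], 1L,
                          as.integer(sdims)), sdims)
  m <- pmax(m, 0)
  if (max(m) > 0) m <- m / max(m)
  ctVolume(m, voxelSpacing(pair), normalised = TRUE)
}

#' Predict segmentation masks for one volume
#'
#' Argmax of the full-resolution softmax of the segmentation head.
#'
#' @param network a \code{SiameseNet}.
#' @param vol a normalised \code{\linkS4class{CTVolume}}.
#' @return A \code{\linkS4class{LabelMask}}.
#' @export
predictMask <- function(network, vol) {
  fw <- net_forward(network, as_input_array(vol))
  lg <- fm_mat(fw$segLogits[[1L]])
  lab <- max.col(lg, ties.method = "first") - 1L
  labelMask(array(as.integer(lab), dim(volData(vol))),
            voxelSpacing(vol))
}

#' Evaluate a trained network on a labelled cohort
#'
#' Runs inference on every pair, computes the response ROC (AUC with
#' percentile-bootstrap 95\% CI), the Youden operating point with
#' sensitivity/specificity/PPV/NPV and weighted F1, and per-class Dice
#' scores of the predicted segmentations at both time points.
#'
#' @param network a trained \code{SiameseNet}.
#' @param pairs a list of labelled preprocessed
#'   \code{\linkS4class{LongitudinalPair}} objects, or a manifest
#'   (data frame or CSV path).
#' @param nBoot bootstrap resamples for the AUC CI.
#' @param seed bootstrap seed.
#' @param register,targetSpacing passed to \code{\link{preprocessPair}}
#'   when loading from a manifest.
#' @return An \code{\linkS4class{EvalReport}}.
#' @export
evaluateModel <- function(network, pairs, nBoot = 2000, seed = 1L,
                          register = FALSE,
                          targetSpacing = c(5, 0.8, 0.8)) {
  if (is.character(pairs)) pairs <- read.csv(pairs,
                                             stringsAsFactors = FALSE)
  if (is.data.frame(pairs)) pairs <- load_manifest_pairs(pairs, register,
                                                         targetSpacing)
  labels <- vapply(pairs, responseLabel, integer(1))
  if (any(is.na(labels)))
    stop("evaluation requires labelled pairs")
  scores <- numeric(length(pairs))
  dscO <- c(); dscP <- c()
  caseDscO <- numeric(length(pairs)); caseDscP <- numeric(length(pairs))
  for (i in seq_along(pairs)) {
    p <- pairs[[i]]
    fb <- net_forward(network, volData(baseline(p)))
    ff <- net_forward(network, volData(followup(p)))
    scores[i] <- sigmoid(head_forward(network, fb$taps, ff$taps)$logit)
    dO <- NA_real_; dP <- NA_real_
    if (!is.null(baselineMask(p)) && !is.null(followupMask(p))) {
      predB <- max.col(fm_mat(fb$segLogits[[1L]]),
                       ties.method = "first") - 1L
      predF <- max.col(fm_mat(ff$segLogits[[1L]]),
                       ties.method = "first") - 1L
      dims <- dim(volData(baseline(p)))
      predB <- array(predB, dims); predF <- array(predF, dims)
      dsO <- c(diceScore(predB, volData(baselineMask(p)), 1L),
               diceScore(predF, volData(followupMask(p)), 1L))
      dsP <- c(diceScore(predB, volData(baselineMask(p)), 2L),
               diceScore(predF, volData(followupMask(p)), 2L))
      dscO <- c(dscO, dsO); dscP <- c(dscP, dsP)
      dO <- mean(dsO); dP <- mean(dsP)
    }
    caseDscO[i] <- dO; caseDscP[i] <- dP
  }
  if (length(dscO) == 0) { dscO <- NA_real_; dscP <- NA_real_ }
  auc <- rocAuc(scores, labels)
  ci <- bootstrapCi(scores, labels, nBoot = nBoot, seed = seed)
  yj <- youdenCutoff(scores, labels)
  rep_ <- classificationReport(scores, labels, yj$threshold)
  dsc <- rbind(omental = c(mean = mean(dscO), sd = sd(dscO)),
               pelvic_ovarian = c(mean = mean(dscP), sd = sd(dscP)))
  perCase <- data.frame(case = seq_along(pairs), score = scores,
                        label = labels,
                        prediction = as.integer(scores >= yj$threshold),
                        dsc_omental = caseDscO,
                        dsc_pelvic_ovarian = caseDscP)
  new("EvalReport", auc = auc, aucCI = ci, threshold = yj$threshold,
      sensitivity = yj$sensitivity, specificity = yj$specificity,
      ppv = rep_$ppv, npv = rep_$npv, weightedF1 = rep_$f1,
      dscPerClass = dsc, perCase = perCase)
}

#' Serialise / restore an EvalReport as JSON
#'
#' @param report an \code{\linkS4class{EvalReport}}.
#' @param path optional file path; when \code{NULL} the JSON string is
#'   returned.
#' @return \code{reportToJson}: the JSON string or the path;
#'   \code{reportFromJson}: the restored \code{EvalReport}.
#' @export
reportToJson <- function(report, path = NULL) {
  x <- list(auc = report@auc, auc_ci = report@aucCI,
            threshold = report@threshold,
            sensitivity = report@sensitivity,
            specificity = report@specificity, ppv = report@ppv,
            npv = report@npv, weighted_f1 = report@weightedF1,
            dsc = list(omental =
                         as.list(report@dscPerClass["omental", ]),
                       pelvic_ovarian =
                         as.list(report@dscPerClass["pelvic_ovarian", ])),
            per_case = report@perCase)
  if (is.null(path))
    jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA)
  else {
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
    invisible(path)
  }
}

#' @rdname reportToJson
#' @param json a JSON string or file path produced by
#'   \code{reportToJson}.
#' @export
reportFromJson <- function(json) {
  x <- jsonlite::fromJSON(json)
  new("EvalReport", auc = x$auc, aucCI = as.numeric(x$auc_ci),
      threshold = x$threshold, sensitivity = x$sensitivity,
      specificity = x$specificity, ppv = x$ppv, npv = x$npv,
      weightedF1 = x$weighted_f1,
      dscPerClass = rbind(omental = unlist(x$dsc$omental),
                          pelvic_ovarian = unlist(x$dsc$pelvic_ovarian)),
      perCase = as.data.frame(x$per_case))
}
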