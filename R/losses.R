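#' Loss configuration for joint response + segmentation training
#'
#' The total training loss is \eqn{\lambda_1 L_{class} + \lambda_2
#' L_{seg}}, with \eqn{\lambda_1 = 1} and \eqn{\lambda_2 = 0.2} by
#' default so a unit improvement in response classification moves the
#' total five times more than a unit improvement in segmentation.  The
#' segmentation term is a deep-supervision sum of (Dice +
#' cross-entropy) over decoder levels, with level weights halving per
#' coarser level and normalised to sum to one.
#'
#' @param lambdaClass weight of the response-classification loss.
#' @param lambdaSeg weight of the segmentation loss.
#' @param epsilon Dice smoothing constant.
#' @param classWeights positive per-class cross-entropy weights.
#' @param nClasses number of segmentation classes.
#' @param deepSupervisionWeights optional per-level weights (full
#'   resolution first); must sum to 1.  \code{NULL} derives halving
#'   weights from the level count at evaluation time.
#' @return A \code{LossConfig} list.
#' @export
lossConfig <- function(lambdaClass = 1, lambdaSeg = 0.2, epsilon = 1e-5,
                       classWeights = c(1, 1, 1), nClasses = 3,
                       deepSupervisionWeights = NULL) {
  stopifnot(lambdaClass >= 0, lambdaSeg >= 0, epsilon > 0,
            all(classWeights > 0), length(classWeights) == nClasses)
  if (!is.null(deepSupervisionWeights) &&
      abs(sum(deepSupervisionWeights) - 1) > 1e-8)
    stop("deep-supervision weights must sum to 1")
  structure(list(lambdaClass = lambdaClass, lambdaSeg = lambdaSeg,
                 epsilon = epsilon, classWeights = classWeights,
                 nClasses = as.integer(nClasses),
                 deepSupervisionWeights = deepSupervisionWeights),
            class = "LossConfig")
}

ds_weights <- function(config, nLevels) {
  w <- config$deepSupervisionWeights
  if (is.null(w)) w <- 0.5^(seq_len(nLevels) - 1)
  if (length(w) != nLevels)
    stop("deep-supervision weight count (", length(w),
         ") does not match the number of decoder levels (", nLevels, ")")
  w / sum(w)
}

as_prob_matrix <- function(x, nClasses) {
  if (is.array(x) && length(dim(x)) == 4L) x <- fm_mat(x)
  if (!is.matrix(x) || ncol(x) != nClasses)
    stop("expected per-voxel class probabilities with ", nClasses,
         " columns")
  x
}

#' Soft multi-class Dice loss
#'
#' \deqn{L = 1 - \frac{1}{C}\sum_{c=1}^{C}
#'   \frac{2\sum_i \hat y_{i,c}\, y_{i,c} + \epsilon}
#'        {\sum_i (\hat y_{i,c} + y_{i,c}) + \epsilon}}
#' where \eqn{\hat y} are per-voxel softmax probabilities and \eqn{y}
#' the one-hot ground truth.  The value lies in \eqn{[0, 1]}; classes
#' empty in both prediction and truth contribute
#' \eqn{\epsilon/\epsilon = 1} to the sum, i.e. zero loss.
#'
#' @param predSoftmax per-voxel class probabilities: an N x C matrix or
#'   a (D, H, W, C) array whose rows sum to 1.
#' @param targetOnehot one-hot ground truth of the same shape.
#' @param epsilon smoothing constant.
#' @return Scalar loss in \eqn{[0, 1]}.
#' @export
diceLoss <- function(predSoftmax, targetOnehot, epsilon = 1e-5) {
  C <- if (is.matrix(predSoftmax)) ncol(predSoftmax) else
    dim(predSoftmax)[length(dim(predSoftmax))]
  p <- as_prob_matrix(predSoftmax, C)
  y <- as_prob_matrix(targetOnehot, C)
  if (!identical(dim(p), dim(y)))
    stop("prediction and target shapes differ")
  if (max(abs(rowSums(p) - 1)) > 1e-4)
    stop("prediction rows must sum to 1 (softmax output expected)")
  num <- 2 * colSums(p * y) + epsilon
  den <- colSums(p) + colSums(y) + epsilon
  1 - mean(num / den)
}

# gradient of diceLoss w.r.t. the softmax probabilities (N x C)
dice_loss_grad <- function(p, y, epsilon = 1e-5) {
  C <- ncol(p)
  num <- 2 * colSums(p * y) + epsilon
  den <- colSums(p) + colSums(y) + epsilon
  n <- nrow(p)
  -(2 * y * rep(den, each = n) - rep(num, each = n)) /
    rep(den^2, each = n) / C
}

#' Weighted multi-class cross-entropy
#'
#' Mean over voxels of \eqn{w_{y_n}(-\log \mathrm{softmax}(z_n)_{y_n})},
#' normalised by the sum of applied weights (the standard weighted-mean
#' form; with unit weights this is the plain mean negative
#' log-likelihood, and doubling all class weights leaves the value
#' unchanged).
#'
#' @param logits N x C matrix or (D, H, W, C) array of unnormalised
#'   class scores.
#' @param targetIndices integer class indices in \code{0:(C-1)} (the
#'   label coding of \code{\linkS4class{LabelMask}}).
#' @param classWeights positive per-class weights (default: unit).
#' @return Scalar loss.
#' @export
weightedCrossEntropy <- function(logits, targetIndices,
                                 classWeights = NULL) {
  if (is.array(logits) && length(dim(logits)) == 4L)
    logits <- fm_mat(logits)
  C <- ncol(logits)
  targetIndices <- as.integer(targetIndices)
  if (any(targetIndices < 0L) || any(targetIndices >= C))
    stop("target indices must lie in 0..C-1")
  if (is.null(classWeights)) classWeights <- rep(1, C)
  p <- softmax_rows(logits)
  n <- length(targetIndices)
  w <- classWeights[targetIndices + 1L]
  nll <- -log(pmax(p[cbind(seq_len(n), targetIndices + 1L)], 1e-12))
  sum(w * nll) / sum(w)
}

# gradient of weightedCrossEntropy w.r.t. the logits (N x C)
wce_grad <- function(logits, targetIndices, classWeights = NULL) {
  C <- ncol(logits)
  if (is.null(classWeights)) classWeights <- rep(1, C)
  p <- softmax_rows(logits)
  n <- length(targetIndices)
  y <- onehot_rows(targetIndices, C)
  w <- classWeights[targetIndices + 1L]
  (p - y) * (w / sum(w))
}

#' Deep-supervision segmentation loss
#'
#' Weighted sum over decoder levels of (Dice + weighted cross-entropy),
#' the ground-truth mask being downsampled to each level by nearest
#' neighbour.
#'
#' @param logitList list of logit arrays (full resolution first), one
#'   per decoder level.
#' @param targetMask a \code{\linkS4class{LabelMask}} or integer 3D
#'   array at full resolution.
#' @param config a \code{\link{lossConfig}}.
#' @return Scalar loss.
#' @export
deepSupervisionSegLoss <- function(logitList, targetMask,
                                   config = lossConfig()) {
  w <- ds_weights(config, length(logitList))
  tgt <- if (is(targetMask, "LabelMask")) volData(targetMask) else
    targetMask
  total <- 0
  for (i in seq_along(logitList)) {
    lg <- logitList[[i]]
    t_i <- nn_resize_labels(tgt, dim(lg)[1:3])
    lm <- fm_mat(lg)
    p <- softmax_rows(lm)
    y <- onehot_rows(as.integer(t_i), config$nClasses)
    total <- total + w[i] *
      (diceLoss(p, y, config$epsilon) +
         weightedCrossEntropy(lm, as.integer(t_i), config$classWeights))
  }
  total
}

# per-level logit gradients of deepSupervisionSegLoss
seg_loss_grads <- function(logitList, targetMask, config) {
  w <- ds_weights(config, length(logitList))
  tgt <- if (is(targetMask, "LabelMask")) volData(targetMask) else
    targetMask
  lapply(seq_along(logitList), function(i) {
    lg <- logitList[[i]]
    t_i <- as.integer(nn_resize_labels(tgt, dim(lg)[1:3]))
    lm <- fm_mat(lg)
    p <- softmax_rows(lm)
    y <- onehot_rows(t_i, config$nClasses)
    dDice <- dice_loss_grad(p, y, config$epsilon)
    # chain through softmax: dz = p * (g - rowSums(g * p))
    dz_dice <- p * (dDice - rowSums(dDice * p))
    dz <- w[i] * (dz_dice + wce_grad(lm, t_i, config$classWeights))
    mat_fm(dz, dim(lg)[1:3])
  })
}

#' Total multi-task loss
#'
#' \eqn{\lambda_1 L_{class} + \lambda_2 L_{seg}}.
#'
#' @param classLoss response-classification loss (finite, >= 0).
#' @param segLoss segmentation loss (finite, >= 0).
#' @param config a \code{\link{lossConfig}}.
#' @return Scalar total loss.
#' @examples
#' totalLoss(0.5, 1.0, lossConfig())  # 1 * 0.5 + 0.2 * 1.0 = 0.7
#' @export
totalLoss <- function(classLoss, segLoss, config = lossConfig()) {
  if (!is.finite(classLoss) || !is.finite(segLoss) || classLoss < 0 ||
      segLoss < 0)
    stop("loss components must be finite and non-negative")
  config$lambdaClass * classLoss + config$lambdaSeg * segLoss
}

# binary cross-entropy with logit input; returns loss and dlogit
bce_with_logit <- function(logit, label) {
  p <- sigmoid(logit)
  loss <- -(label * log(pmax(p, 1e-12)) +
              (1 - label) * log(pmax(1 - p, 1e-12)))
  list(loss = loss, dlogit = p - label)
}
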