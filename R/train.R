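#' Training configuration
#'
#' Defaults follow the reference schedule: batch size 2, linear warm-up
#' over the first 4\% of steps to a maximum learning rate of
#' \eqn{5\times 10^{-5}}, cosine decay to zero afterwards, and early
#' stopping on validation response AUC.  The optimiser is Adam.
#'
#' @param totalSteps planned optimisation steps.
#' @param warmupFraction fraction of steps used for linear warm-up.
#' @param maxLr peak learning rate.
#' @param batchSize pairs per step.
#' @param valInterval steps between validation evaluations.
#' @param patience consecutive non-improving evaluations before stopping.
#' @param seed master seed for initialisation, data order, augmentation
#'   and dropout.
#' @param valFraction held-out fraction when no validation split is
#'   given (split by case, never by scan).
#' @param loss a \code{\link{lossConfig}}.
#' @param augment an \code{\link{augmentConfig}}.
#' @param network a \code{\link{networkConfig}}.
#' @return A \code{TrainConfig} list.
#' @export
trainConfig <- function(totalSteps = 1500, warmupFraction = 0.04,
                        maxLr = 5e-5, batchSize = 2, valInterval = 250,
                        patience = 10, seed = 1L, valFraction = 0.2,
                        loss = lossConfig(), augment = augmentConfig(),
                        network = networkConfig()) {
  stopifnot(totalSteps >= 1, warmupFraction > 0, warmupFraction < 1,
            maxLr > 0, batchSize >= 1, valInterval >= 1, patience >= 1,
            valFraction > 0, valFraction < 1)
  structure(list(totalSteps = as.integer(totalSteps),
                 warmupFraction = warmupFraction, maxLr = maxLr,
                 batchSize = as.integer(batchSize),
                 valInterval = as.integer(valInterval),
                 patience = as.integer(patience), seed = as.integer(seed),
                 valFraction = valFraction, loss = loss,
                 augment = augment, network = network),
            class = "TrainConfig")
}

#' Learning rate at a given step
#'
#' Linear warm-up over the first \code{round(warmupFraction *
#' totalSteps)} steps to \code{maxLr}, then cosine decay:
#' \eqn{lr = maxLr \cdot \tfrac12 (1 + \cos(\pi (s - W)/(T - W)))}.
#' Continuous at the warm-up boundary and zero at \code{totalSteps}.
#'
#' @param step step number(s) in \code{0:totalSteps}.
#' @param config a \code{\link{trainConfig}}.
#' @return Learning rate(s).
#' @export
lrAtStep <- function(step, config) {
  total <- config$totalSteps
  if (any(step < 0) || any(step > total))
    stop("step must lie in [0, totalSteps]")
  W <- max(1, round(config$warmupFraction * total))
  ifelse(step <= W, config$maxLr * step / W,
         config$maxLr * 0.5 * (1 + cos(pi * (step - W) / (total - W))))
}

adam_init <- function(params)
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0), t = 0L)

adam_update <- function(params, grads, state, lr, beta1 = 0.9,
                        beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (n in names(params)) {
    gr <- grads[[n]]
    if (is.null(gr)) gr <- params[[n]] * 0
    state$m[[n]] <- beta1 * state$m[[n]] + (1 - beta1) * gr
    state$v[[n]] <- beta2 * state$v[[n]] + (1 - beta2) * gr * gr
    params[[n]] <- params[[n]] -
      lr * (state$m[[n]] / bc1) / (sqrt(state$v[[n]] / bc2) + eps)
  }
  list(params = params, state = state)
}

# combined seg loss + per-level logit gradients (fused C pass)
seg_loss_with_grads <- function(logitList, tgt, config) {
  w <- ds_weights(config, length(logitList))
  loss <- 0
  grads <- vector("list", length(logitList))
  for (i in seq_along(logitList)) {
    lg <- logitList[[i]]
    t_i <- as.integer(nn_resize_labels(tgt, dim(lg)[1:3]))
    r <- cpp_seg_loss(lg, t_i, config$nClasses, config$classWeights,
                      config$epsilon)
    loss <- loss + w[i] * (r$dice + r$ce)
    grads[[i]] <- array(w[i] * r$dlogits, dim(lg))
  }
  list(loss = loss, grads = grads)
}

# one optimisation step over a batch of pairs; returns losses + grads
train_step_grads <- function(network, batchPairs, lossCfg, augCfg) {
  B <- length(batchPairs)
  acc <- new.env(parent = emptyenv())
  add_all <- function(gl) {
    for (n in names(gl)) {
      cur <- acc[[n]]
      acc[[n]] <- if (is.null(cur)) gl[[n]] else cur + gl[[n]]
    }
  }
  classLoss <- 0; segLoss <- 0
  for (pair in batchPairs) {
    ap <- augmentPair(pair, augCfg)
    fb <- net_forward(network, volData(baseline(ap)), training = TRUE)
    ff <- net_forward(network, volData(followup(ap)), training = TRUE)
    hd <- head_forward(network, fb$taps, ff$taps)
    bce <- bce_with_logit(hd$logit, responseLabel(ap))
    sb <- seg_loss_with_grads(fb$segLogits, volData(baselineMask(ap)),
                              lossCfg)
    sf <- seg_loss_with_grads(ff$segLogits, volData(followupMask(ap)),
                              lossCfg)
    classLoss <- classLoss + bce$loss / B
    segLoss <- segLoss + 0.5 * (sb$loss + sf$loss) / B
    hb <- head_backward(network, hd$cache,
                        lossCfg$lambdaClass * bce$dlogit / B)
    add_all(hb$grads)
    sc <- lossCfg$lambdaSeg * 0.5 / B
    add_all(net_backward(network, fb$cache,
                         lapply(sb$grads, function(gx) gx * sc),
                         hb$dTapsPre))
    add_all(net_backward(network, ff$cache,
                         lapply(sf$grads, function(gx) gx * sc),
                         hb$dTapsPost))
  }
  list(classLoss = classLoss, segLoss = segLoss,
       total = lossCfg$lambdaClass * classLoss +
         lossCfg$lambdaSeg * segLoss,
       grads = as.list(acc))
}

validation_scores <- function(network, pairs) {
  vapply(pairs, function(p) {
    fb <- net_forward(network, volData(baseline(p)))
    ff <- net_forward(network, volData(followup(p)))
    sigmoid(head_forward(network, fb$taps, ff$taps)$logit)
  }, numeric(1))
}

#' Train the Siamese multi-task network
#'
#' Runs the full schedule: every step draws \code{batchSize} labelled
#' pairs, augments them, evaluates the joint loss
#' (\eqn{\lambda_1 L_{class} + \lambda_2 L_{seg}} with deep-supervision
#' segmentation terms for both time points) and applies one Adam update
#' at \code{\link{lrAtStep}}.  Every \code{valInterval} steps the
#' validation response AUC is evaluated; training stops early when
#' \code{patience} consecutive evaluations fail to improve the best AUC,
#' and the best-AUC parameter snapshot is retained.  Fully deterministic
#' under the config seed.
#'
#' @param pairs a list of preprocessed labelled
#'   \code{\linkS4class{LongitudinalPair}} objects (normalised volumes
#'   and masks present), or a cohort manifest (data frame or CSV path as
#'   written by \code{\link{generateCohort}}), which is then loaded with
#'   \code{\link{preprocessPair}}.
#' @param config a \code{\link{trainConfig}}.
#' @param valIndices optional indices of validation cases; by default a
#'   seeded \code{valFraction} split by case.
#' @param outDir optional directory for the best checkpoint
#'   (\code{checkpoint.rds}) and a JSON history log.
#' @param register,targetSpacing passed to \code{\link{preprocessPair}}
#'   when loading from a manifest.
#' @param verbose print progress lines.
#' @return A \code{TrainState} list: \code{network} (final),
#'   \code{bestNetwork}, \code{bestValAuc}, \code{history} (per-step
#'   losses and learning rate), \code{valHistory}, \code{stoppedEarly}
#'   and \code{stepsRun}.
#' @export
trainModel <- function(pairs, config = trainConfig(), valIndices = NULL,
                       outDir = NULL, register = FALSE,
                       targetSpacing = c(5, 0.8, 0.8),
                       verbose = FALSE) {
  if (is.character(pairs)) pairs <- read.csv(pairs,
                                             stringsAsFactors = FALSE)
  if (is.data.frame(pairs)) pairs <- load_manifest_pairs(pairs, register,
                                                         targetSpacing)
  stopifnot(length(pairs) >= 2)
  labels <- vapply(pairs, responseLabel, integer(1))
  if (any(is.na(labels)))
    stop("all training pairs must carry a binary response label")
  with_seed(config$seed, {
    network <- buildNetwork(config$network,
                            seed = config$seed + 1L)
    n <- length(pairs)
    if (is.null(valIndices)) {
      # stratified by response so the validation AUC is defined
      nval <- max(2L, round(config$valFraction * n))
      pos <- which(labels == 1L); neg <- which(labels == 0L)
      nv1 <- max(1L, min(length(pos), round(nval * length(pos) / n)))
      nv0 <- max(1L, min(length(neg), nval - nv1))
      valIndices <- c(sample(pos, nv1), sample(neg, nv0))
    }
    trainIdx <- setdiff(seq_len(n), valIndices)
    stopifnot(length(trainIdx) >= 1)
    if (length(unique(labels[valIndices])) < 2)
      stop("validation split contains a single class; AUC undefined")
    opt <- adam_init(network$params)
    hist_step <- integer(0); hist_lr <- numeric(0)
    hist_total <- numeric(0); hist_class <- numeric(0)
    hist_seg <- numeric(0)
    val_step <- integer(0); val_auc <- numeric(0)
    best <- -Inf; bestParams <- network$params; sinceBest <- 0L
    stoppedEarly <- FALSE
    step <- 0L
    while (step < config$totalSteps) {
      step <- step + 1L
      bi <- sample(trainIdx, config$batchSize,
                   replace = length(trainIdx) < config$batchSize)
      sg <- train_step_grads(network, pairs[bi], config$loss,
                             config$augment)
      if (!is.finite(sg$total))
        stop("non-finite loss at step ", step,
             " (class ", sg$classLoss, ", seg ", sg$segLoss, ")")
      lr <- lrAtStep(step, config)
      up <- adam_update(network$params, sg$grads, opt, lr)
      network$params <- up$params
      opt <- up$state
      hist_step <- c(hist_step, step); hist_lr <- c(hist_lr, lr)
      hist_total <- c(hist_total, sg$total)
      hist_class <- c(hist_class, sg$classLoss)
      hist_seg <- c(hist_seg, sg$segLoss)
      if (step %% config$valInterval == 0L) {
        scores <- validation_scores(network, pairs[valIndices])
        auc <- rocAuc(scores, labels[valIndices])
        val_step <- c(val_step, step); val_auc <- c(val_auc, auc)
        if (verbose)
          message(sprintf("step %d: loss %.4f, val AUC %.3f", step,
                          sg$total, auc))
        if (auc >= best - 1e-12) {
          # among AUC ties keep the most recent parameters: the
          # segmentation branch keeps improving after the response
          # branch saturates
          bestParams <- network$params
        }
        if (auc > best + 1e-9) {
          best <- auc; sinceBest <- 0L
        } else {
          sinceBest <- sinceBest + 1L
          if (sinceBest >= config$patience) {
            stoppedEarly <- step < config$totalSteps
            break
          }
        }
      }
    }
    if (!is.finite(best)) {            # no validation pass happened
      best <- NA_real_; bestParams <- network$params
    }
    bestNetwork <- network
    bestNetwork$params <- bestParams
    state <- list(network = network, bestNetwork = bestNetwork,
                  bestValAuc = best,
                  history = data.frame(step = hist_step, lr = hist_lr,
                                       total = hist_total,
                                       class = hist_class,
                                       seg = hist_seg),
                  valHistory = data.frame(step = val_step,
                                          auc = val_auc),
                  valIndices = valIndices,
                  stoppedEarly = stoppedEarly, stepsRun = step)
    class(state) <- "TrainState"
    if (!is.null(outDir)) {
      if (!dir.exists(outDir))
        dir.create(outDir, recursive = TRUE)
      saveCheckpoint(bestNetwork, file.path(outDir, "checkpoint.rds"))
      jsonlite::write_json(
        list(history = state$history, valHistory = state$valHistory,
             bestValAuc = best, stoppedEarly = stoppedEarly),
        file.path(outDir, "history.json"), auto_unbox = TRUE,
        digits = NA)
    }
    state
  })
}

load_manifest_pairs <- function(manifest, register = FALSE,
                                targetSpacing = c(5, 0.8, 0.8)) {
  lapply(seq_len(nrow(manifest)), function(i) {
    row <- manifest[i, ]
    preprocessPair(row$baseline_path, row$followup_path,
                   baselineMaskPath = row$baseline_mask_path,
                   followupMaskPath = row$followup_mask_path,
                   targetSpacing = targetSpacing,
                   register = register, response = row$response,
                   recist = row$recist)
  })
}

#' @export
print.TrainState <- function(x, ...) {
  cat(sprintf(paste0("TrainState: %d steps run%s, best validation ",
                     "AUC %.3f\n"), x$stepsRun,
              if (x$stoppedEarly) " (stopped early)" else "",
              x$bestValAuc))
  invisible(x)
}
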