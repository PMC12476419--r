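# Independent brute-force oracles shared by the unit and acceptance
# tests.  These deliberately use naive loops, not the package's code
# paths.

dice_ref <- function(p, y, eps) {
  C <- ncol(p)
  acc <- 0
  for (cl in seq_len(C)) {
    num <- 0; den <- 0
    for (i in seq_len(nrow(p))) {
      num <- num + 2 * p[i, cl] * y[i, cl]
      den <- den + p[i, cl] + y[i, cl]
    }
    acc <- acc + (num + eps) / (den + eps)
  }
  1 - acc / C
}

wce_ref <- function(logits, targets, w) {
  num <- 0; den <- 0
  for (i in seq_len(nrow(logits))) {
    z <- logits[i, ]
    p <- exp(z - max(z)) / sum(exp(z - max(z)))
    num <- num + w[targets[i] + 1] * (-log(p[targets[i] + 1]))
    den <- den + w[targets[i] + 1]
  }
  num / den
}

auc_ref <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) for (q in neg)
    tot <- tot + if (p > q) 1 else if (p == q) 0.5 else 0
  tot / (length(pos) * length(neg))
}

youden_ref <- function(scores, labels) {
  best <- NULL
  for (t in sort(unique(scores))) {
    sens <- mean(scores[labels == 1] >= t)
    spec <- mean(scores[labels == 0] < t)
    j <- sens + spec - 1
    if (is.null(best) || j > best$j + 1e-12 ||
        (abs(j - best$j) <= 1e-12 &&
           (sens > best$sens + 1e-12 ||
              (abs(sens - best$sens) <= 1e-12 && t < best$t))))
      best <- list(t = t, j = j, sens = sens, spec = spec)
  }
  best
}

random_pred <- function(n, C) {
  z <- matrix(rnorm(n * C), n, C)
  p <- exp(z) / rowSums(exp(z))
  list(logits = z, p = p, y = sample(0:(C - 1), n, replace = TRUE))
}
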