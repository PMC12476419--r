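#' Network configuration for the Siamese 3D U-Net
#'
#' The segmentation backbone is an encoder/decoder 3D U-Net: each encoder
#' level applies a stride-2 3x3x3 convolution that doubles the channel
#' count (capped at \code{channelCap}) followed by a pre-activation
#' residual context block (instance norm, leaky-ReLU, 3x3x3 convolution,
#' dropout, instance norm, leaky-ReLU, 3x3x3 convolution, residual add).
#' Each decoder level begins with a localisation module -- a 3x3x3
#' convolution that carries the features to the next finer resolution
#' (trilinear upsampling) -- then concatenates the matching encoder skip
#' (the raw input volume at full resolution) and merges with another
#' 3x3x3 convolution; every decoder level emits a deep-supervision
#' segmentation head (1x1x1 convolution to \code{nClasses} logits).
#'
#' Three feature taps feed the response head: the context-block output of
#' the middle encoder level (\code{ceiling(nLevels/2)}), the bottleneck
#' (deepest context-block output), and the penultimate decoder feature
#' map before the final 1x1x1 classifier.
#'
#' @param nLevels number of resolution levels (>= 3).
#' @param baseChannels channels after the first stride-2 convolution.
#' @param channelCap maximum channel count.
#' @param dropoutP dropout probability inside context blocks.
#' @param nClasses segmentation classes (3: background, omental,
#'   pelvic/ovarian).
#' @param headChannels channels of the depth-wise response head per tap
#'   stream (32).
#' @param negSlope leaky-ReLU negative slope.
#' @return A \code{NetworkConfig} list.
#' @export
networkConfig <- function(nLevels = 5, baseChannels = 32,
                          channelCap = 320, dropoutP = 0.3, nClasses = 3,
                          headChannels = 32, negSlope = 0.01) {
  stopifnot(nLevels >= 3, baseChannels >= 2, channelCap >= baseChannels,
            dropoutP >= 0, dropoutP < 1, nClasses == 3,
            headChannels >= 1)
  structure(list(nLevels = as.integer(nLevels),
                 baseChannels = as.integer(baseChannels),
                 channelCap = as.integer(channelCap),
                 dropoutP = dropoutP, nClasses = as.integer(nClasses),
                 headChannels = as.integer(headChannels),
                 negSlope = negSlope,
                 tapContracting = as.integer(ceiling(nLevels / 2))),
            class = "NetworkConfig")
}

enc_channels <- function(config)
  pmin(config$baseChannels * 2^(seq_len(config$nLevels) - 1),
       config$channelCap)

dec0_channels <- function(config) max(4L, config$baseChannels %/% 2L)

tap_channels <- function(config) {
  chs <- enc_channels(config)
  c(cmid = chs[config$tapContracting], bottleneck = chs[config$nLevels],
    dmid = dec0_channels(config))
}

init_conv <- function(cin, cout)
  array(rnorm(27 * cin * cout, 0, sqrt(2 / (27 * cin))),
        c(3, 3, 3, cin, cout))

#' Build a Siamese 3D U-Net
#'
#' Initialises all parameters (He initialisation for convolutions, unit
#' gain / zero shift for instance norm, bias-free response-head
#' convolutions).  The same parameter set serves both Siamese streams:
#' weight sharing is structural, not copied.
#'
#' @param config a \code{\link{networkConfig}}.
#' @param seed integer seed; the same seed gives bit-identical initial
#'   weights.
#' @return A \code{SiameseNet} list with elements \code{config} and
#'   \code{params} (flat named list of arrays).
#' @export
buildNetwork <- function(config, seed = 1L) {
  stopifnot(inherits(config, "NetworkConfig"))
  with_seed(seed, {
    chs <- enc_channels(config)
    L <- config$nLevels
    p <- list()
    inC <- 1L
    for (l in seq_len(L)) {
      pre <- sprintf("enc%d.", l)
      p[[paste0(pre, "down.W")]] <- init_conv(inC, chs[l])
      p[[paste0(pre, "down.b")]] <- numeric(chs[l])
      p[[paste0(pre, "in1.g")]] <- rep(1, chs[l])
      p[[paste0(pre, "in1.b")]] <- numeric(chs[l])
      p[[paste0(pre, "c1.W")]] <- init_conv(chs[l], chs[l])
      p[[paste0(pre, "c1.b")]] <- numeric(chs[l])
      p[[paste0(pre, "in2.g")]] <- rep(1, chs[l])
      p[[paste0(pre, "in2.b")]] <- numeric(chs[l])
      p[[paste0(pre, "c2.W")]] <- init_conv(chs[l], chs[l])
      p[[paste0(pre, "c2.b")]] <- numeric(chs[l])
      inC <- chs[l]
    }
    prevC <- chs[L]
    for (d in rev(seq_len(L) - 1L)) {      # L-1, ..., 1, 0
      pre <- sprintf("dec%d.", d)
      oc <- if (d >= 1) chs[d] else dec0_channels(config)
      skipC <- if (d >= 1) chs[d] else 1L
      p[[paste0(pre, "up.W")]] <- init_conv(prevC, oc)
      p[[paste0(pre, "up.b")]] <- numeric(oc)
      p[[paste0(pre, "up.g")]] <- rep(1, oc)
      p[[paste0(pre, "up.beta")]] <- numeric(oc)
      p[[paste0(pre, "merge.W")]] <- init_conv(oc + skipC, oc)
      p[[paste0(pre, "merge.b")]] <- numeric(oc)
      p[[paste0(pre, "merge.g")]] <- rep(1, oc)
      p[[paste0(pre, "merge.beta")]] <- numeric(oc)
      p[[paste0(pre, "seg.W")]] <-
        matrix(rnorm(oc * config$nClasses, 0, sqrt(2 / oc)), oc,
               config$nClasses)
      # class-prior bias: lesions are rare foreground, so the heads
      # start near the background prior instead of uniform -- this
      # removes the long all-uniform phase under extreme imbalance
      p[[paste0(pre, "seg.b")]] <- c(0, rep(-4, config$nClasses - 1L))
      prevC <- oc
    }
    tc <- tap_channels(config)
    hc <- config$headChannels
    for (s in names(tc)) {
      p[[sprintf("head.%s.dw", s)]] <-
        array(rnorm(27 * tc[s], 0, sqrt(2 / 27)), c(3, 3, 3, 1, tc[s]))
      p[[sprintf("head.%s.pw", s)]] <-
        matrix(rnorm(tc[s] * hc, 0, sqrt(2 / tc[s])), tc[s], hc)
    }
    p[["head.linear.W"]] <- rnorm(3 * hc, 0, sqrt(1 / (3 * hc)))
    p[["head.linear.b"]] <- 0
    structure(list(config = config, params = p), class = "SiameseNet")
  })
}

#' Number of trainable parameters of a network
#' @param network a \code{SiameseNet}.
#' @return Integer parameter count (a pure function of the config).
#' @export
parameterCount <- function(network)
  sum(vapply(network$params, length, integer(1)))

#' @export
print.SiameseNet <- function(x, ...) {
  cat(sprintf(paste0("SiameseNet: %d levels, base %d channels, ",
                     "%d classes, %s parameters\n"),
              x$config$nLevels, x$config$baseChannels,
              x$config$nClasses,
              format(parameterCount(x), big.mark = ",")))
  invisible(x)
}

# ---- forward / backward --------------------------------------------------

check_input_size <- function(config, sdims) {
  if (any(sdims < 2^(config$nLevels - 1)))
    stop("input grid ", paste(sdims, collapse = "x"),
         " is too small for ", config$nLevels,
         " resolution levels (every spatial dimension must be >= ",
         2^(config$nLevels - 1), ")")
}

net_forward <- function(network, x, training = FALSE) {
  cfg <- network$config
  p <- network$params
  sdims <- dim(x)[1:3]
  check_input_size(cfg, sdims)
  L <- cfg$nLevels
  xin <- array(x, c(sdims, 1L))
  enc <- vector("list", L)
  cur <- xin
  for (l in seq_len(L)) {
    pre <- sprintf("enc%d.", l)
    a <- conv3d_fwd(cur, p[[paste0(pre, "down.W")]],
                    p[[paste0(pre, "down.b")]], 2L)
    i1 <- inl_fwd(a, p[[paste0(pre, "in1.g")]],
                  p[[paste0(pre, "in1.b")]], cfg$negSlope)
    c1 <- conv3d_fwd(i1$y, p[[paste0(pre, "c1.W")]],
                     p[[paste0(pre, "c1.b")]], 1L)
    dr <- dropout_fwd(c1, cfg$dropoutP, training)
    i2 <- inl_fwd(dr$y, p[[paste0(pre, "in2.g")]],
                  p[[paste0(pre, "in2.b")]], cfg$negSlope)
    c2 <- conv3d_fwd(i2$y, p[[paste0(pre, "c2.W")]],
                     p[[paste0(pre, "c2.b")]], 1L)
    out <- a + c2
    enc[[l]] <- list(xin = cur, i1 = i1$cache, r1 = i1$y,
                     dmask = dr$cache, i2 = i2$cache, r2 = i2$y,
                     out = out)
    cur <- out
  }
  dec <- vector("list", L)            # indexed d+1 for stage d
  segLogits <- vector("list", L)      # segLogits[[d+1]] at /2^d
  for (d in rev(seq_len(L) - 1L)) {
    pre <- sprintf("dec%d.", d)
    tdims <- if (d >= 1) dim(enc[[d]]$out)[1:3] else sdims
    skip <- if (d >= 1) enc[[d]]$out else xin
    # localisation module: 3x3x3 convolution at the coarser grid, then
    # trilinear upsampling to the skip resolution
    u1 <- conv3d_fwd(cur, p[[paste0(pre, "up.W")]],
                     p[[paste0(pre, "up.b")]], 1L)
    iu <- inl_fwd(u1, p[[paste0(pre, "up.g")]],
                  p[[paste0(pre, "up.beta")]], cfg$negSlope)
    u0 <- resize_fm(iu$y, tdims)
    cc <- concat_fm(u0, skip)
    m1 <- conv3d_fwd(cc, p[[paste0(pre, "merge.W")]],
                     p[[paste0(pre, "merge.b")]], 1L)
    im <- inl_fwd(m1, p[[paste0(pre, "merge.g")]],
                  p[[paste0(pre, "merge.beta")]], cfg$negSlope)
    segLogits[[d + 1L]] <- pwconv_fwd(im$y, p[[paste0(pre, "seg.W")]],
                                      p[[paste0(pre, "seg.b")]])
    dec[[d + 1L]] <- list(curdims = dim(cur)[1:3], xup = cur,
                          iu = iu$cache, cc = cc, im = im$cache,
                          m3 = im$y, skipC = dim(skip)[4])
    cur <- im$y
  }
  taps <- list(cmid = enc[[cfg$tapContracting]]$out,
               bottleneck = enc[[L]]$out, dmid = dec[[1L]]$m3)
  list(segLogits = segLogits, taps = taps,
       cache = list(enc = enc, dec = dec, sdims = sdims))
}

# dSegLogits: list indexed like segLogits (NULL entries allowed);
# dTaps: named list (cmid, bottleneck, dmid), NULL entries allowed.
net_backward <- function(network, cache, dSegLogits = NULL,
                         dTaps = NULL) {
  cfg <- network$config
  p <- network$params
  L <- cfg$nLevels
  enc <- cache$enc
  dec <- cache$dec
  g <- new.env(parent = emptyenv())
  add_g <- function(name, val) {
    cur <- g[[name]]
    g[[name]] <- if (is.null(cur)) val else cur + val
  }
  denc <- vector("list", L)
  add_enc <- function(l, val)
    denc[[l]] <<- if (is.null(denc[[l]])) val else denc[[l]] + val
  dprev <- NULL
  for (d in seq_len(L) - 1L) {        # 0, 1, ..., L-1
    pre <- sprintf("dec%d.", d)
    st <- dec[[d + 1L]]
    dm3 <- NULL
    if (!is.null(dSegLogits) && !is.null(dSegLogits[[d + 1L]])) {
      pb <- pwconv_bwd(st$m3, p[[paste0(pre, "seg.W")]],
                       dSegLogits[[d + 1L]])
      add_g(paste0(pre, "seg.W"), pb$dw)
      add_g(paste0(pre, "seg.b"), pb$db)
      dm3 <- pb$dx
    }
    if (d == 0L && !is.null(dTaps) && !is.null(dTaps$dmid))
      dm3 <- if (is.null(dm3)) dTaps$dmid else dm3 + dTaps$dmid
    if (!is.null(dprev))
      dm3 <- if (is.null(dm3)) dprev else dm3 + dprev
    if (is.null(dm3))
      dm3 <- array(0, dim(st$m3))
    ib <- inl_bwd(dm3, st$im)
    add_g(paste0(pre, "merge.g"), ib$dgamma)
    add_g(paste0(pre, "merge.beta"), ib$dbeta)
    cb <- conv3d_bwd(st$cc, p[[paste0(pre, "merge.W")]], 1L, ib$dx)
    add_g(paste0(pre, "merge.W"), cb$dw)
    add_g(paste0(pre, "merge.b"), cb$db)
    ocU <- dim(st$cc)[4] - st$skipC
    sp <- split_fm(cb$dx, ocU)
    if (d >= 1L) add_enc(d, sp$b)      # skip gradient (input skip at
                                       # d = 0 needs no gradient)
    du3 <- resize_fm_adj(sp$a, st$curdims)
    iu <- inl_bwd(du3, st$iu)
    add_g(paste0(pre, "up.g"), iu$dgamma)
    add_g(paste0(pre, "up.beta"), iu$dbeta)
    ub <- conv3d_bwd(st$xup, p[[paste0(pre, "up.W")]], 1L, iu$dx)
    add_g(paste0(pre, "up.W"), ub$dw)
    add_g(paste0(pre, "up.b"), ub$db)
    dprev <- ub$dx
  }
  add_enc(L, dprev)                    # stage L-1 consumed enc[[L]]
  if (!is.null(dTaps)) {
    if (!is.null(dTaps$cmid)) add_enc(cfg$tapContracting, dTaps$cmid)
    if (!is.null(dTaps$bottleneck)) add_enc(L, dTaps$bottleneck)
  }
  for (l in rev(seq_len(L))) {
    pre <- sprintf("enc%d.", l)
    lv <- enc[[l]]
    dout <- denc[[l]]
    if (is.null(dout)) dout <- array(0, dim(lv$out))
    da <- dout                          # residual branch
    cb2 <- conv3d_bwd(lv$r2, p[[paste0(pre, "c2.W")]], 1L, dout)
    add_g(paste0(pre, "c2.W"), cb2$dw)
    add_g(paste0(pre, "c2.b"), cb2$db)
    ib2 <- inl_bwd(cb2$dx, lv$i2)
    add_g(paste0(pre, "in2.g"), ib2$dgamma)
    add_g(paste0(pre, "in2.b"), ib2$dbeta)
    ddr <- dropout_bwd(ib2$dx, lv$dmask)
    cb1 <- conv3d_bwd(lv$r1, p[[paste0(pre, "c1.W")]], 1L, ddr)
    add_g(paste0(pre, "c1.W"), cb1$dw)
    add_g(paste0(pre, "c1.b"), cb1$db)
    ib1 <- inl_bwd(cb1$dx, lv$i1)
    add_g(paste0(pre, "in1.g"), ib1$dgamma)
    add_g(paste0(pre, "in1.b"), ib1$dbeta)
    da <- da + ib1$dx
    db_ <- conv3d_bwd(lv$xin, p[[paste0(pre, "down.W")]], 2L, da)
    add_g(paste0(pre, "down.W"), db_$dw)
    add_g(paste0(pre, "down.b"), db_$db)
    if (l > 1L) add_enc(l - 1L, db_$dx)
  }
  as.list(g)
}

head_forward <- function(network, tapsPre, tapsPost) {
  p <- network$params
  hc <- network$config$headChannels
  gall <- numeric(0)
  cache <- list()
  for (s in c("cmid", "bottleneck", "dmid")) {
    if (!identical(dim(tapsPre[[s]]), dim(tapsPost[[s]])))
      stop("pre/post tap shapes differ for stream '", s, "'")
    diff <- tapsPre[[s]] - tapsPost[[s]]
    dwv <- dwconv3d_fwd(diff, p[[sprintf("head.%s.dw", s)]])
    # global average commutes with the point-wise projection:
    # mean_n(dwv_n W) = (mean_n dwv_n) W
    m <- .colMeans(fm_mat(dwv), fm_nvox(dwv), dim(dwv)[4])
    gvec <- as.numeric(m %*% p[[sprintf("head.%s.pw", s)]])
    cache[[s]] <- list(diff = diff, dwv = dwv, m = m)
    gall <- c(gall, gvec)
  }
  logit <- sum(p[["head.linear.W"]] * gall) + p[["head.linear.b"]]
  list(logit = logit, cache = list(streams = cache, gall = gall))
}

head_backward <- function(network, cache, dlogit) {
  p <- network$params
  hc <- network$config$headChannels
  g <- list()
  g[["head.linear.W"]] <- dlogit * cache$gall
  g[["head.linear.b"]] <- dlogit
  dPre <- list(); dPost <- list()
  streams <- c("cmid", "bottleneck", "dmid")
  for (i in seq_along(streams)) {
    s <- streams[i]
    st <- cache$streams[[s]]
    n <- fm_nvox(st$dwv)
    dg <- dlogit * p[["head.linear.W"]][(i - 1) * hc + seq_len(hc)]
    g[[sprintf("head.%s.pw", s)]] <- outer(st$m, dg)
    # every voxel of d(dwv) carries the same channel vector
    v <- as.numeric(p[[sprintf("head.%s.pw", s)]] %*% dg) / n
    ddwv <- mat_fm(tcrossprod(rep(1, n), v), dim(st$dwv)[1:3])
    dwb <- dwconv3d_bwd(st$diff, p[[sprintf("head.%s.dw", s)]], ddwv)
    g[[sprintf("head.%s.dw", s)]] <- dwb$dw
    dPre[[s]] <- dwb$dx
    dPost[[s]] <- -dwb$dx
  }
  list(dTapsPre = dPre, dTapsPost = dPost, grads = g)
}

as_input_array <- function(vol) {
  if (is(vol, "CTVolume")) {
    if (!isNormalised(vol))
      warning("input volume is not flagged as normalised; the network ",
              "expects intensities in [0, 1]")
    volData(vol)
  } else if (is.array(vol) && length(dim(vol)) == 3L) {
    vol
  } else stop("expected a CTVolume or a 3D array")
}

#' Run one stream of the Siamese network
#'
#' @param network a \code{SiameseNet} from \code{\link{buildNetwork}}.
#' @param vol a normalised \code{\linkS4class{CTVolume}} or 3D array.
#' @param training logical; enables dropout (training mode).  In
#'   evaluation mode the forward pass is deterministic.
#' @return A list with \code{segLogits} (deep-supervision logit arrays,
#'   full resolution first), \code{taps} (named feature-tap list:
#'   \code{cmid}, \code{bottleneck}, \code{dmid}) and an internal
#'   \code{cache} for backpropagation.
#' @export
forwardSingle <- function(network, vol, training = FALSE) {
  x <- as_input_array(vol)
  net_forward(network, x, training = training)
}

#' Response head: classify change from paired feature taps
#'
#' Computes voxel-wise differences (pre minus post) of the three tapped
#' feature maps; each difference map passes through a bias-free
#' depth-wise 3x3x3 convolution and a point-wise projection to 32
#' channels, is globally averaged per channel, and the three 32-vectors
#' are concatenated and mapped by a single linear layer to one response
#' logit.  With identical taps the logit equals the linear layer's bias.
#'
#' @param network a \code{SiameseNet}.
#' @param tapsPre,tapsPost named tap lists from
#'   \code{\link{forwardSingle}} (pre- and post-treatment streams).
#' @return The scalar response logit.
#' @export
responseHead <- function(network, tapsPre, tapsPost)
  head_forward(network, tapsPre, tapsPost)$logit

#' Forward pass of the full Siamese pair model
#'
#' Both volumes run through the same parameter set (structural weight
#' sharing); the response head consumes the tap differences.
#'
#' @param network a \code{SiameseNet}.
#' @param pair a preprocessed \code{\linkS4class{LongitudinalPair}}.
#' @param training logical; enables dropout.
#' @return A \code{PairOutput} list: \code{segLogitsBaseline},
#'   \code{segLogitsFollowup} (deep-supervision lists, full resolution
#'   first), \code{responseLogit}, \code{responseProb}, plus the tap
#'   lists and internal caches.
#' @export
forwardPair <- function(network, pair, training = FALSE) {
  fb <- forwardSingle(network, baseline(pair), training = training)
  ff <- forwardSingle(network, followup(pair), training = training)
  hd <- head_forward(network, fb$taps, ff$taps)
  structure(list(segLogitsBaseline = fb$segLogits,
                 segLogitsFollowup = ff$segLogits,
                 responseLogit = hd$logit,
                 responseProb = sigmoid(hd$logit),
                 tapsBaseline = fb$taps, tapsFollowup = ff$taps,
                 cacheBaseline = fb$cache, cacheFollowup = ff$cache,
                 headCache = hd$cache),
            class = "PairOutput")
}

#' Save / load a network checkpoint
#'
#' @param network a \code{SiameseNet}.
#' @param path checkpoint file path (RDS).
#' @return \code{saveCheckpoint}: the path, invisibly;
#'   \code{loadCheckpoint}: the restored \code{SiameseNet}.
#' @export
saveCheckpoint <- function(network, path) {
  saveRDS(list(config = unclass(network$config),
               params = network$params), path)
  invisible(path)
}

#' @rdname saveCheckpoint
#' @export
loadCheckpoint <- function(path) {
  x <- readRDS(path)
  structure(list(config = structure(x$config, class = "NetworkConfig"),
                 params = x$params), class = "SiameseNet")
}
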