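## SWAU-Net: dual-path regularized U-Net encoder, weight-shared sliding-window
## axial attention temporal core, DynNet latent-state evolution, and a shared
## decoder for next-frame prediction plus anchor-frame reconstruction.
##
## Parameters live in model@env$par (named list). Forward passes are built on
## the autodiff tape in tape.R; feature maps are (H*W) x C matrices.

.variantFlags <- function(variant) {
  list(
    spatialAttention = variant != "no_spatial_attention",
    cfb = variant != "no_cfb",
    core = switch(variant,
                  swa1_standard_attention = "swa_unshared",
                  swa2_conv_aggregator = "conv",
                  swa3_convlstm = "convlstm",
                  "swa"),
    dynnet = variant != "no_dynnet")
}

## ---- parameter allocation --------------------------------------------------

.addPar <- function(m, name, v, shape) {
  m$par[[name]] <- v
  m$shape[[name]] <- shape
  invisible(m)
}

## Residual side branches (zero = TRUE) start at exactly zero so that every
## block is an identity map at initialization: activations stay at unit scale
## through the deep unnormalized network, and gradients still reach the
## zeroed weights through their inputs.
.addConv3 <- function(m, name, Cin, Cout, zero = FALSE) {
  sd <- if (zero) 0 else sqrt(2 / (Cin * 9))
  .addPar(m, paste0(name, ".W"), matrix(rnorm(Cin * 9 * Cout, 0, sd), Cin * 9, Cout),
          c(Cin * 9L, Cout))
  .addPar(m, paste0(name, ".b"), numeric(Cout), Cout)
}

.addConv1 <- function(m, name, Cin, Cout, zero = FALSE) {
  sd <- if (zero) 0 else sqrt(2 / Cin)
  .addPar(m, paste0(name, ".W"), matrix(rnorm(Cin * Cout, 0, sd), Cin, Cout),
          c(Cin, Cout))
  .addPar(m, paste0(name, ".b"), numeric(Cout), Cout)
}

.addMHA <- function(m, name, C) {
  sd <- sqrt(1 / C)
  for (p in c("Wq", "Wk", "Wv"))
    .addPar(m, paste0(name, ".", p), matrix(rnorm(C * C, 0, sd), C, C), c(C, C))
  .addPar(m, paste0(name, ".Wo"), matrix(0, C, C), c(C, C))
  for (p in c("bq", "bk", "bv", "bo"))
    .addPar(m, paste0(name, ".", p), numeric(C), C)
}

.addPos <- function(m, name, N, C) {
  .addPar(m, name, matrix(rnorm(N * C, 0, 0.02), N, C), c(N, C))
}

.addScalar <- function(m, name, v) .addPar(m, name, v, 1L)

.allocCore <- function(m, prefix, config) {
  fl <- m$flags
  sch <- levelSchedule(config)
  ch <- sch$channels; sz <- sch$sizes
  if (fl$core %in% c("swa", "swa_unshared")) {
    for (l in 4:5) {
      c <- ch[l]
      .addMHA(m, sprintf("%sL%d.p1", prefix, l), c)
      .addPos(m, sprintf("%sL%d.pos1", prefix, l), 3L * sz[l], c)
      .addMHA(m, sprintf("%sL%d.p2", prefix, l), c)
      .addPos(m, sprintf("%sL%d.pos2", prefix, l), 3L * sz[l], c)
      .addConv1(m, sprintf("%sL%d.gc1", prefix, l), 3L * c, 2L * c)
      .addConv3(m, sprintf("%sL%d.gc3", prefix, l), c, c)
      .addScalar(m, sprintf("%sL%d.gamma", prefix, l), config@gateInit)
    }
    for (l in 1:3) .addConv3(m, sprintf("%smix%d", prefix, l), 3L * ch[l], ch[l])
  } else if (fl$core == "conv") {
    for (l in 1:5) .addConv3(m, sprintf("%smix%d", prefix, l), 3L * ch[l], ch[l])
  } else if (fl$core == "convlstm") {
    for (l in 4:5) {
      c <- ch[l]
      .addConv3(m, sprintf("%sL%d.lstm1", prefix, l), 2L * c, 4L * c)
      .addConv3(m, sprintf("%sL%d.lstm2", prefix, l), 2L * c, 4L * c)
    }
    for (l in 1:3) .addConv3(m, sprintf("%smix%d", prefix, l), 3L * ch[l], ch[l])
  }
}

.allocModel <- function(config, seed) {
  m <- new.env(parent = emptyenv())
  m$par <- list()
  m$shape <- list()
  m$cache <- list()
  m$flags <- .variantFlags(config@variant)
  m$config <- config
  set.seed(seed)
  fl <- m$flags
  sch <- levelSchedule(config)
  ch <- sch$channels
  Ch <- config@baseChannels %/% 2L
  .addConv3(m, "stem.faf.c1", 1L, Ch);  .addConv3(m, "stem.faf.c2", Ch, Ch)
  .addConv3(m, "stem.mask.c1", 2L, Ch); .addConv3(m, "stem.mask.c2", Ch, Ch)
  for (l in 1:5) {
    c <- ch[l]
    if (l > 1L) .addConv3(m, sprintf("enc.down%d", l), ch[l - 1], c)
    .addConv3(m, sprintf("enc.grb%d.r1", l), c, c)
    .addConv3(m, sprintf("enc.grb%d.r2", l), c, c, zero = TRUE)
    .addConv3(m, sprintf("enc.grb%d.hf", l), c, c, zero = TRUE)
    .addConv1(m, sprintf("enc.grb%d.gate", l), c, c)
    if (fl$cfb) {
      .addConv1(m, sprintf("enc.cfb%d.i", l), c, c %/% 2L)
      .addConv3(m, sprintf("enc.cfb%d.m", l), c %/% 2L, c %/% 2L)
      .addConv1(m, sprintf("enc.cfb%d.o", l), c %/% 2L, c, zero = TRUE)
    }
    if (fl$spatialAttention && l >= 4L) .addMHA(m, sprintf("enc.att%d", l), c)
  }
  if (fl$core == "swa_unshared") {
    for (w in 1:3) .allocCore(m, sprintf("swa.w%d.", w), config)
  } else {
    .allocCore(m, "swa.", config)
  }
  for (l in 1:5) {
    .addScalar(m, sprintf("fuse.alpha%d", l), 1)
    .addScalar(m, sprintf("fuse.beta%d", l), 1)
  }
  if (fl$dynnet) {
    D <- config@dynnetBaseChannels
    for (l in 1:5) .addConv1(m, sprintf("dyn.in%d", l), ch[l], D)
    .addConv1(m, "dyn.fuse", 5L * D, D)
    .addConv3(m, "dyn.enc1a", D, D);          .addConv3(m, "dyn.enc1b", D, D)
    .addConv3(m, "dyn.down2", D, 2L * D)
    .addConv3(m, "dyn.enc2a", 2L * D, 2L * D); .addConv3(m, "dyn.enc2b", 2L * D, 2L * D)
    .addConv3(m, "dyn.down3", 2L * D, 4L * D)
    .addConv3(m, "dyn.enc3a", 4L * D, 4L * D); .addConv3(m, "dyn.enc3b", 4L * D, 4L * D)
    if (fl$spatialAttention) .addMHA(m, "dyn.att", 4L * D)
    .addConv1(m, "dyn.up2", 4L * D, 2L * D);  .addConv3(m, "dyn.dec2", 4L * D, 2L * D)
    .addConv1(m, "dyn.up1", 2L * D, D);       .addConv3(m, "dyn.dec1", 2L * D, D)
    .addConv3(m, "dyn.out", D, D)
    for (l in 1:5) .addConv1(m, sprintf("dyn.red%d", l), D, ch[l], zero = TRUE)
  }
  for (l in 1:5) {
    c <- ch[l]
    if (fl$cfb) {
      .addConv1(m, sprintf("dec.cfb%d.i", l), c, c %/% 2L)
      .addConv3(m, sprintf("dec.cfb%d.m", l), c %/% 2L, c %/% 2L)
      .addConv1(m, sprintf("dec.cfb%d.o", l), c %/% 2L, c, zero = TRUE)
    }
  }
  .addConv3(m, "dec.fuse5", 2L * ch[5], ch[5])
  for (l in 4:1) {
    .addConv1(m, sprintf("dec.up%d", l), ch[l + 1], ch[l])
    .addConv3(m, sprintf("dec.fuse%d", l), 3L * ch[l], ch[l])
  }
  .addConv1(m, "dec.head", ch[1], 3L)
  m
}

## ---- forward building blocks ----------------------------------------------

.fConv3 <- function(tp, m, x, name, stride = 1L, relu = FALSE) {
  y <- tConv3(tp, x, tParam(tp, m, paste0(name, ".W")),
              tParam(tp, m, paste0(name, ".b")), stride)
  if (relu) tRelu(tp, y) else y
}

.fConv1 <- function(tp, m, x, name, relu = FALSE) {
  y <- tConv1(tp, x, tParam(tp, m, paste0(name, ".W")),
              tParam(tp, m, paste0(name, ".b")))
  if (relu) tRelu(tp, y) else y
}

## Gated residual block: y = R(x) + sigmoid(G(x)) * Conv(x - blur(x)) where
## R(x) = x + conv(relu(conv(x))). The high-frequency side path preserves
## sharp lesion boundaries against over-smoothing.
.fGRB <- function(tp, m, x, name) {
  r <- tAdd(tp, x, .fConv3(tp, m, tRelu(tp, .fConv3(tp, m, x, paste0(name, ".r1"))),
                           paste0(name, ".r2")))
  hf <- .fConv3(tp, m, tSub(tp, x, tBlur3(tp, x)), paste0(name, ".hf"))
  gate <- tSigmoid(tp, .fConv1(tp, m, x, paste0(name, ".gate")))
  tAdd(tp, r, tMul(tp, gate, hf))
}

## Channel-fusion bottleneck: residual 1x1 -> 3x3 -> 1x1 stack with 2x inner
## channel compression. Identity when the no_cfb ablation removes it.
.fCFB <- function(tp, m, x, name) {
  if (!m$flags$cfb) return(x)
  y <- .fConv1(tp, m, x, paste0(name, ".i"), relu = TRUE)
  y <- .fConv3(tp, m, y, paste0(name, ".m"), relu = TRUE)
  y <- .fConv1(tp, m, y, paste0(name, ".o"))
  tAdd(tp, x, y)
}

.fMHAName <- function(tp, m, x, name, B, N, mask = NULL) {
  p <- function(s) tParam(tp, m, paste0(name, ".", s))
  tMHA(tp, x, p("Wq"), p("Wk"), p("Wv"), p("Wo"),
       p("bq"), p("bk"), p("bv"), p("bo"),
       m$config@nHeads, B, N, mask)
}

## Spatial self-attention with residual connection over all H*W tokens.
.fSpatialAtt <- function(tp, m, x, name) {
  a <- .fMHAName(tp, m, x, name, 1L, nrow(x$v))
  tAdd(tp, x, tDropout(tp, a, m$config@dropout))
}

.fEncode <- function(tp, m, x) {
  fl <- m$flags
  faf <- tCols(tp, x, 1L)
  msk <- tCols(tp, x, 2:3)
  faf <- .fConv3(tp, m, faf, "stem.faf.c1", relu = TRUE)
  faf <- .fConv3(tp, m, faf, "stem.faf.c2", relu = TRUE)
  msk <- .fConv3(tp, m, msk, "stem.mask.c1", relu = TRUE)
  msk <- .fConv3(tp, m, msk, "stem.mask.c2", relu = TRUE)
  h <- tConcat(tp, list(faf, msk))
  pyr <- vector("list", 5L)
  for (l in 1:5) {
    if (l > 1L) h <- .fConv3(tp, m, h, sprintf("enc.down%d", l), stride = 2L,
                             relu = TRUE)
    h <- .fGRB(tp, m, h, sprintf("enc.grb%d", l))
    h <- .fCFB(tp, m, h, sprintf("enc.cfb%d", l))
    if (fl$spatialAttention && l >= 4L)
      h <- .fSpatialAtt(tp, m, h, sprintf("enc.att%d", l))
    pyr[[l]] <- h
  }
  pyr
}

.zeroPyramid <- function(tp, m) {
  sch <- levelSchedule(m$config)
  lapply(1:5, function(l)
    tConst(tp, matrix(0, sch$sizes[l]^2, sch$channels[l]),
           sch$sizes[l], sch$sizes[l]))
}

## Token permutation tables for the axial passes, cached per spatial size.
## Global token layout: frame t occupies rows (t-1)*H*W + (1:HW), pixel index
## r + (c-1)*H. Pass 1 batches over rows (tokens ordered t major, then w);
## pass 2 batches over columns (tokens ordered t major, then h).
.axialIndex <- function(m, H, W) {
  key <- sprintf("ax.%d.%d", H, W)
  if (!is.null(m$cache[[key]])) return(m$cache[[key]])
  HW <- H * W
  g <- function(t, h, w) (t - 1L) * HW + h + (w - 1L) * H
  idx1 <- integer(3L * HW); k <- 0L
  for (h in seq_len(H)) for (t in 1:3) for (w in seq_len(W)) {
    k <- k + 1L; idx1[k] <- g(t, h, w)
  }
  idx2 <- integer(3L * HW); k <- 0L
  for (w in seq_len(W)) for (t in 1:3) for (h in seq_len(H)) {
    k <- k + 1L; idx2[k] <- g(t, h, w)
  }
  inv1 <- integer(length(idx1)); inv1[idx1] <- seq_along(idx1)
  inv2 <- integer(length(idx2)); inv2[idx2] <- seq_along(idx2)
  res <- list(idx1 = idx1, inv1 = inv1, idx2 = idx2, inv2 = inv2)
  m$cache[[key]] <- res
  res
}

## Additive causal mask over an axial token block (time-major order): key
## tokens from later time slices are hidden from earlier queries.
.causalMask <- function(m, axlen) {
  key <- sprintf("mask.%d", axlen)
  if (!is.null(m$cache[[key]])) return(m$cache[[key]])
  tt <- rep(1:3, each = axlen)
  M <- matrix(0, 3L * axlen, 3L * axlen)
  M[outer(tt, tt, function(a, b) b > a)] <- -Inf
  m$cache[[key]] <- M
  M
}

## Axially factorized attention over a 3-frame window at one deep level:
## sequential time-width then time-height passes with learned positional
## embeddings, followed by a gated convolutional (width,height,time) fusion
## block scaled by a trainable scalar. Returns the last-time-slice output.
.fAxialCore <- function(tp, m, frames, prefix, l, causal) {
  H <- frames[[3]]$H; W <- frames[[3]]$W
  c <- ncol(frames[[3]]$v)
  HW <- H * W
  ax <- .axialIndex(m, H, W)
  p <- m$config@dropout
  stack <- tRbind(tp, frames)
  x1 <- tPermRows(tp, stack, ax$idx1)
  x1 <- tAddPos(tp, x1, tParam(tp, m, sprintf("%sL%d.pos1", prefix, l)), H, 3L * W)
  a1 <- .fMHAName(tp, m, x1, sprintf("%sL%d.p1", prefix, l), H, 3L * W,
                  mask = if (causal) .causalMask(m, W))
  r1 <- tAdd(tp, x1, tDropout(tp, a1, p))
  back <- tPermRows(tp, r1, ax$inv1)
  x2 <- tPermRows(tp, back, ax$idx2)
  x2 <- tAddPos(tp, x2, tParam(tp, m, sprintf("%sL%d.pos2", prefix, l)), W, 3L * H)
  a2 <- .fMHAName(tp, m, x2, sprintf("%sL%d.p2", prefix, l), W, 3L * H,
                  mask = if (causal) .causalMask(m, H))
  r2 <- tAdd(tp, x2, tDropout(tp, a2, p))
  g2 <- tPermRows(tp, r2, ax$inv2)
  attnOut <- tRows(tp, g2, (2L * HW + 1L):(3L * HW), H, W)
  z <- tConcat(tp, frames)
  u <- .fConv1(tp, m, z, sprintf("%sL%d.gc1", prefix, l))
  glu <- tMul(tp, tCols(tp, u, seq_len(c)),
              tSigmoid(tp, tCols(tp, u, (c + 1L):(2L * c))))
  v <- .fConv3(tp, m, glu, sprintf("%sL%d.gc3", prefix, l))
  tAdd(tp, attnOut, tScale(tp, tParam(tp, m, sprintf("%sL%d.gamma", prefix, l)), v))
}

## Two stacked ConvLSTM cells run over the 3-frame window (swa3 variant).
.fConvLstmCore <- function(tp, m, frames, prefix, l) {
  H <- frames[[3]]$H; W <- frames[[3]]$W
  c <- ncol(frames[[3]]$v)
  zero <- function() tConst(tp, matrix(0, H * W, c), H, W)
  h1 <- zero(); c1 <- zero(); h2 <- zero(); c2 <- zero()
  cell <- function(x, h, cc, name) {
    g <- .fConv3(tp, m, tConcat(tp, list(x, h)), name)
    i <- tSigmoid(tp, tCols(tp, g, seq_len(c)))
    f <- tSigmoid(tp, tCols(tp, g, (c + 1L):(2L * c)))
    o <- tSigmoid(tp, tCols(tp, g, (2L * c + 1L):(3L * c)))
    gg <- tTanh(tp, tCols(tp, g, (3L * c + 1L):(4L * c)))
    cc <- tAdd(tp, tMul(tp, f, cc), tMul(tp, i, gg))
    list(h = tMul(tp, o, tTanh(tp, cc)), c = cc)
  }
  for (t in 1:3) {
    s1 <- cell(frames[[t]], h1, c1, sprintf("%sL%d.lstm1", prefix, l))
    h1 <- s1$h; c1 <- s1$c
    s2 <- cell(h1, h2, c2, sprintf("%sL%d.lstm2", prefix, l))
    h2 <- s2$h; c2 <- s2$c
  }
  h2
}

## Weight-shared 3-frame temporal convolution mixer (shallow levels).
.fMixer <- function(tp, m, frames, prefix, l) {
  tRelu(tp, .fConv3(tp, m, tConcat(tp, frames), sprintf("%smix%d", prefix, l)))
}

## One window through the temporal core: returns the integrated latent state
## M (per-level pyramid) for the window's last visit, fused with the current
## visit's encoder features via macro-residuals with learnable scalars.
.fCoreWindow <- function(tp, m, window, prefix) {
  fl <- m$flags
  M <- vector("list", 5L)
  for (l in 1:5) {
    frames <- list(window[[1]][[l]], window[[2]][[l]], window[[3]][[l]])
    out <-
      if (l >= 4L && fl$core %in% c("swa", "swa_unshared")) {
        .fAxialCore(tp, m, frames, prefix, l, causal = fl$core == "swa_unshared")
      } else if (l >= 4L && fl$core == "convlstm") {
        .fConvLstmCore(tp, m, frames, prefix, l)
      } else {
        .fMixer(tp, m, frames, prefix, l)
      }
    M[[l]] <- tAdd(tp,
                   tScale(tp, tParam(tp, m, sprintf("fuse.alpha%d", l)), window[[3]][[l]]),
                   tScale(tp, tParam(tp, m, sprintf("fuse.beta%d", l)), out))
  }
  M
}

## DynNet: 3-level U-Net over the latent state, operating at the L3 grid.
## All levels are resampled into L3, fused, evolved, and redistributed; the
## evolved state is a residual update E = M + delta.
.fDynNet <- function(tp, m, M) {
  fl <- m$flags
  down <- function(x, k) { for (i in seq_len(k)) x <- tAvgpool2(tp, x); x }
  up <- function(x, k) { for (i in seq_len(k)) x <- tUpsample2(tp, x); x }
  g <- list(.fConv1(tp, m, down(M[[1]], 2L), "dyn.in1"),
            .fConv1(tp, m, down(M[[2]], 1L), "dyn.in2"),
            .fConv1(tp, m, M[[3]], "dyn.in3"),
            .fConv1(tp, m, up(M[[4]], 1L), "dyn.in4"),
            .fConv1(tp, m, up(M[[5]], 2L), "dyn.in5"))
  u0 <- .fConv1(tp, m, tConcat(tp, g), "dyn.fuse", relu = TRUE)
  d1 <- .fConv3(tp, m, .fConv3(tp, m, u0, "dyn.enc1a", relu = TRUE), "dyn.enc1b",
                relu = TRUE)
  d2 <- .fConv3(tp, m, d1, "dyn.down2", stride = 2L, relu = TRUE)
  d2 <- .fConv3(tp, m, .fConv3(tp, m, d2, "dyn.enc2a", relu = TRUE), "dyn.enc2b",
                relu = TRUE)
  d3 <- .fConv3(tp, m, d2, "dyn.down3", stride = 2L, relu = TRUE)
  d3 <- .fConv3(tp, m, .fConv3(tp, m, d3, "dyn.enc3a", relu = TRUE), "dyn.enc3b",
                relu = TRUE)
  if (fl$spatialAttention) d3 <- .fSpatialAtt(tp, m, d3, "dyn.att")
  u2 <- .fConv1(tp, m, tUpsample2(tp, d3), "dyn.up2")
  u2 <- .fConv3(tp, m, tConcat(tp, list(u2, d2)), "dyn.dec2", relu = TRUE)
  u1 <- .fConv1(tp, m, tUpsample2(tp, u2), "dyn.up1")
  u1 <- .fConv3(tp, m, tConcat(tp, list(u1, d1)), "dyn.dec1", relu = TRUE)
  out <- .fConv3(tp, m, u1, "dyn.out")
  E <- vector("list", 5L)
  red <- list(up(.fConv1(tp, m, out, "dyn.red1"), 2L),
              up(.fConv1(tp, m, out, "dyn.red2"), 1L),
              .fConv1(tp, m, out, "dyn.red3"),
              down(.fConv1(tp, m, out, "dyn.red4"), 1L),
              down(.fConv1(tp, m, out, "dyn.red5"), 2L))
  for (l in 1:5) E[[l]] <- tAdd(tp, M[[l]], red[[l]])
  E
}

## Decoder: per-level channel fusion then a U-Net decoder with encoder skip
## connections; one 3x3 fusion convolution per level; 3-channel head
## (FAF, lesion logits, growth logits).
.fDecode <- function(tp, m, E, skips) {
  Ec <- lapply(1:5, function(l) .fCFB(tp, m, E[[l]], sprintf("dec.cfb%d", l)))
  x <- .fConv3(tp, m, tConcat(tp, list(Ec[[5]], skips[[5]])), "dec.fuse5",
               relu = TRUE)
  for (l in 4:1) {
    x <- .fConv1(tp, m, tUpsample2(tp, x), sprintf("dec.up%d", l))
    x <- .fConv3(tp, m, tConcat(tp, list(x, Ec[[l]], skips[[l]])),
                 sprintf("dec.fuse%d", l), relu = TRUE)
  }
  .fConv1(tp, m, x, "dec.head")
}

## Full forward graph over visits 0..2: windows with zero padding, one core
## application per window (weight-shared unless swa1), DynNet evolution,
## decode with the window anchor's skips. Returns node-level outputs.
.fForward <- function(tp, m, frameNodes) {
  fl <- m$flags
  pyr <- lapply(frameNodes, function(x) .fEncode(tp, m, x))
  z <- .zeroPyramid(tp, m)
  windows <- list(list(z, z, pyr[[1]]),
                  list(z, pyr[[1]], pyr[[2]]),
                  list(pyr[[1]], pyr[[2]], pyr[[3]]))
  pred <- vector("list", 3L)
  recon <- vector("list", 3L)
  Ms <- vector("list", 3L)
  for (w in 1:3) {
    prefix <- if (fl$core == "swa_unshared") sprintf("swa.w%d.", w) else "swa."
    M <- .fCoreWindow(tp, m, windows[[w]], prefix)
    Ms[[w]] <- M
    if (fl$dynnet) {
      E <- .fDynNet(tp, m, M)
      pred[[w]] <- .fDecode(tp, m, E, pyr[[w]])
      recon[[w]] <- .fDecode(tp, m, M, pyr[[w]])
    } else {
      pred[[w]] <- .fDecode(tp, m, M, pyr[[w]])
    }
  }
  list(pred = pred, recon = recon, pyramids = pyr, M = Ms)
}

## ---- array <-> node conversion --------------------------------------------

.visitToMatrix <- function(visit) {
  d <- dim(visit)
  if (length(d) != 3L || d[3] != 3L)
    stop("input-validation error: a visit must be an H x W x 3 array ",
         "(FAF, lesion mask, growth mask)")
  if (!all(visit[, , 2:3] %in% c(0, 1)))
    stop("input-validation error: mask channels must be binary")
  matrix(visit, d[1] * d[2], 3L)
}

.nodeToPlanes <- function(nd) {
  array(nd$v, dim = c(nd$H, nd$W, ncol(nd$v)))
}

.tripletFromNode <- function(nd) {
  a <- .nodeToPlanes(nd)
  list(faf = 1 / (1 + exp(-a[, , 1])),
       lesionLogits = a[, , 2],
       growthLogits = a[, , 3])
}

.framesFromInput <- function(frames) {
  if (is(frames, "LesionSequence")) {
    if (length(frames) < 3L)
      stop("forwardSequence needs 3 input visits")
    frames <- lapply(1:3, function(i)
      array(c(frames@faf[[i]], frames@lesionMasks[[i]], frames@growthMasks[[i]]),
            dim = c(dim(frames@faf[[i]]), 3L)))
  }
  if (length(frames) != 3L) stop("exactly 3 input visits are required")
  frames
}

## ---- public API ------------------------------------------------------------

#' Build a SWAU-Net model
#'
#' Allocates and initializes all trainable parameters of the requested
#' variant. With the default reference configuration the network has four
#' down-sampling stages (16 x 16 x 256 bottleneck from a 256 x 256 input)
#' and about 8.3 million trainable parameters.
#'
#' @param config a \code{\link{modelConfig}}.
#' @param seed RNG seed for weight initialization.
#' @return A \code{\linkS4class{SWAUNet}} model object.
#' @examples
#' model <- buildModel(modelConfig(inputSize = 64, baseChannels = 8))
#' countParameters(model)
#' @export
buildModel <- function(config, seed = 1L) {
  v <- validObject(config, test = TRUE)
  if (!isTRUE(v)) stop("configuration error: ", paste(v, collapse = "; "))
  m <- .allocModel(config, seed)
  new("SWAUNet", config = config, variant = config@variant, env = m)
}

#' Count trainable parameters
#'
#' @param model a \code{SWAUNet}.
#' @return Integer-valued count of trainable scalar parameters.
#' @export
countParameters <- function(model) {
  sum(vapply(model@env$par, length, 0L))
}

#' Count temporal-core parameters
#'
#' Parameters of the sliding-window temporal core (attention passes,
#' positional embeddings, gated conv fusion, shallow mixers). The
#' non-weight-shared swa1 variant carries three unshared copies.
#'
#' @param model a \code{SWAUNet}.
#' @return Parameter count of the temporal core.
#' @export
countTemporalCoreParameters <- function(model) {
  nm <- names(model@env$par)
  sum(vapply(model@env$par[startsWith(nm, "swa.")], length, 0L))
}

#' Encode one visit into the feature pyramid
#'
#' Runs the dual-path stems (FAF and masks through separate convolutional
#' stems), the per-level down-sample / gated-residual / channel-fusion
#' pipeline, and spatial self-attention at L4/L5.
#'
#' @param model a \code{SWAUNet}.
#' @param visit an \code{inputSize} x \code{inputSize} x 3 array (FAF in
#'   [0,1], binary lesion and growth masks).
#' @return List of five H x W x C feature arrays (L1..L5).
#' @export
encodeVisit <- function(model, visit) {
  tp <- newTape(grad = FALSE)
  x <- tConst(tp, .visitToMatrix(visit), dim(visit)[1], dim(visit)[2])
  lapply(.fEncode(tp, model@env, x), .nodeToPlanes)
}

#' Build the three zero-padded temporal windows
#'
#' Given encoder pyramids for visits 0..2, returns the three context windows
#' \code{(0,0,F0)}, \code{(0,F0,F1)}, \code{(F0,F1,F2)} where 0 denotes
#' all-zero pyramids of matching shape. Window w produces the latent state
#' used to predict visit w+1; causality is enforced by this windowing alone.
#'
#' @param pyramids list of exactly 3 feature pyramids (as from
#'   \code{\link{encodeVisit}}).
#' @return List of 3 windows, each a list of 3 pyramids.
#' @export
makeWindows <- function(pyramids) {
  if (length(pyramids) != 3L)
    stop("exactly 3 visit pyramids are required (months 0, 6, 12)")
  ref <- lapply(pyramids[[1]], dim)
  for (p in pyramids)
    if (!identical(lapply(p, dim), ref))
      stop("dimension error: pyramids must share shapes across visits")
  z <- lapply(pyramids[[1]], function(a) array(0, dim(a)))
  list(list(z, z, pyramids[[1]]),
       list(z, pyramids[[1]], pyramids[[2]]),
       list(pyramids[[1]], pyramids[[2]], pyramids[[3]]))
}

.pyramidToNodes <- function(tp, pyr) {
  lapply(pyr, function(a) {
    d <- dim(a)
    tConst(tp, matrix(a, d[1] * d[2], d[3]), d[1], d[2])
  })
}

#' Aggregate one temporal window into the latent state M
#'
#' Applies the (weight-shared) temporal core to one 3-frame window: axial
#' time-width / time-height attention with the gated convolutional fusion
#' block at L4/L5, the 3-frame convolution mixer at L1-L3, and macro-residual
#' fusion with the current visit's encoder features.
#'
#' @param model a \code{SWAUNet}.
#' @param window one window from \code{\link{makeWindows}}.
#' @param windowIndex 1..3; selects the unshared core copy in the swa1
#'   variant (ignored by weight-shared cores).
#' @return The integrated latent state: list of 5 feature arrays.
#' @export
swaAggregate <- function(model, window, windowIndex = 3L) {
  m <- model@env
  tp <- newTape(grad = FALSE)
  wn <- lapply(window, function(p) .pyramidToNodes(tp, p))
  prefix <- if (m$flags$core == "swa_unshared")
    sprintf("swa.w%d.", windowIndex) else "swa."
  lapply(.fCoreWindow(tp, m, wn, prefix), .nodeToPlanes)
}

#' Evolve the latent state one visit forward
#'
#' Runs the dynamics U-Net (DynNet) on the integrated latent state; the
#' evolved state is a residual update of M with parameters disjoint from the
#' encoder and temporal core.
#'
#' @param model a \code{SWAUNet} (must not be the no_dynnet variant).
#' @param M latent state pyramid (list of 5 feature arrays).
#' @return Evolved state \code{E}, same shapes as \code{M}.
#' @export
dynnetEvolve <- function(model, M) {
  if (!model@env$flags$dynnet)
    stop("configuration error: the no_dynnet variant has no dynamics network")
  tp <- newTape(grad = FALSE)
  lapply(.fDynNet(tp, model@env, .pyramidToNodes(tp, M)), .nodeToPlanes)
}

#' Decode a latent state into a prediction triplet
#'
#' Channel fusion per level, then a U-Net decoder with the anchor visit's
#' encoder skip connections, up to a 3-channel full-resolution head.
#'
#' @param model a \code{SWAUNet}.
#' @param E latent pyramid to decode (evolved state for prediction, the
#'   integrated state M for reconstruction).
#' @param skips the anchor visit's encoder pyramid.
#' @return List with \code{faf} (in [0,1]), \code{lesionLogits},
#'   \code{growthLogits}, each \code{inputSize} square.
#' @export
decodeFrame <- function(model, E, skips) {
  tp <- newTape(grad = FALSE)
  nd <- .fDecode(tp, model@env, .pyramidToNodes(tp, E), .pyramidToNodes(tp, skips))
  .tripletFromNode(nd)
}

#' Forward pass over a 3-visit input window
#'
#' Produces predictions for visits 1..3 (months 6, 12, 18) and
#' reconstructions of each window's anchor frame. Prediction w is computed
#' from window w only (zero-padded for early visits), so months 6 and 12 are
#' bit-invariant to any perturbation of later inputs.
#'
#' @param model a \code{SWAUNet}.
#' @param frames list of 3 H x W x 3 visit arrays, or a
#'   \code{LesionSequence} (its first three visits are used).
#' @return List with \code{predictions} (3 triplets, see
#'   \code{\link{decodeFrame}}) and \code{reconstructions} (3 triplets; NULL
#'   for the no_dynnet variant, which has no reconstruction path).
#' @export
forwardSequence <- function(model, frames) {
  frames <- .framesFromInput(frames)
  tp <- newTape(grad = FALSE)
  nodes <- lapply(frames, function(f) {
    d <- dim(f)
    if (d[1] != model@config@inputSize)
      stop("dimension error: visit size does not match the model input size")
    tConst(tp, .visitToMatrix(f), d[1], d[2])
  })
  out <- .fForward(tp, model@env, nodes)
  list(predictions = lapply(out$pred, .tripletFromNode),
       reconstructions = if (model@env$flags$dynnet)
         lapply(out$recon, .tripletFromNode))
}

#' Binarize predicted mask logits
#' @param logits matrix of logits.
#' @param threshold probability threshold (default 0.5).
#' @return Binary matrix.
#' @export
binarizeLogits <- function(logits, threshold = 0.5) {
  (1 / (1 + exp(-logits)) >= threshold) * 1
}

## ---- persistence / reporting ----------------------------------------------

#' Save / load model checkpoints
#'
#' Single-file serialized weights with the configuration snapshot and a
#' format version string.
#'
#' @param model a \code{SWAUNet}.
#' @param path file path.
#' @return \code{loadCheckpoint} returns the restored \code{SWAUNet}.
#' @export
saveCheckpoint <- function(model, path) {
  saveRDS(list(format = "swaunet-checkpoint-1", config = model@config,
               variant = model@variant, par = model@env$par), path)
  invisible(path)
}

#' @rdname saveCheckpoint
#' @export
loadCheckpoint <- function(path) {
  ck <- readRDS(path)
  if (!identical(ck$format, "swaunet-checkpoint-1"))
    stop("not a swaunet checkpoint: ", path)
  model <- buildModel(ck$config)
  model@env$par <- ck$par
  model
}

#' Write a per-layer parameter summary as TSV
#'
#' @param model a \code{SWAUNet}.
#' @param path output TSV path.
#' @return Invisibly, the summary data.frame (name, shape, count).
#' @export
writeModelSummary <- function(model, path) {
  nm <- names(model@env$par)
  df <- data.frame(
    name = nm,
    shape = vapply(model@env$shape[nm], function(s) paste(s, collapse = "x"), ""),
    parameters = vapply(model@env$par[nm], length, 0L))
  write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(df)
}
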