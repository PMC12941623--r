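## Architecture contracts: shapes, parameter audit, block semantics, window
## causality, weight sharing, determinism.

## Independent closed-form parameter enumeration from the config arithmetic;
## kept deliberately separate from the allocation code.
enumerateParams <- function(cfg) {
  C <- cfg@baseChannels
  ch <- C * 2^(0:4)
  sz <- cfg@inputSize / 2^(0:4)
  D <- cfg@dynnetBaseChannels
  h <- C / 2
  conv3 <- function(ci, co) 9 * ci * co + co
  conv1 <- function(ci, co) ci * co + co
  mha <- function(c) 4 * c^2 + 4 * c
  cfb <- function(c) conv1(c, c / 2) + conv3(c / 2, c / 2) + conv1(c / 2, c)
  total <- conv3(1, h) + conv3(h, h) + conv3(2, h) + conv3(h, h)
  for (l in 1:5) {
    c <- ch[l]
    if (l > 1) total <- total + conv3(ch[l - 1], c)
    total <- total + 3 * conv3(c, c) + conv1(c, c)      # GRB
    total <- total + cfb(c)
    if (l >= 4) total <- total + mha(c)
  }
  for (l in 4:5) {                                       # SWA deep levels
    c <- ch[l]
    total <- total + 2 * mha(c) + 2 * (3 * sz[l] * c) +
      conv1(3 * c, 2 * c) + conv3(c, c) + 1
  }
  for (l in 1:3) total <- total + conv3(3 * ch[l], ch[l])  # shallow mixers
  total <- total + 10                                      # macro-residual scalars
  total <- total + sum(conv1(ch, D)) + conv1(5 * D, D) +   # DynNet
    2 * conv3(D, D) + conv3(D, 2 * D) + 2 * conv3(2 * D, 2 * D) +
    conv3(2 * D, 4 * D) + 2 * conv3(4 * D, 4 * D) + mha(4 * D) +
    conv1(4 * D, 2 * D) + conv3(4 * D, 2 * D) + conv1(2 * D, D) +
    conv3(2 * D, D) + conv3(D, D) + sum(conv1(D, ch))
  total <- total + sum(vapply(ch, cfb, 0)) +               # decoder
    conv3(2 * ch[5], ch[5]) +
    sum(vapply(4:1, function(l) conv1(ch[l + 1], ch[l]) +
                 conv3(3 * ch[l], ch[l]), 0)) +
    conv1(ch[1], 3)
  total
}

test_that("reference configuration matches the printed architecture constants", {
  model <- buildModel(modelConfig())
  sch <- levelSchedule(model@config)
  expect_equal(sch$channels, c(16L, 32L, 64L, 128L, 256L))
  expect_equal(sch$sizes, c(256L, 128L, 64L, 32L, 16L))
  expect_equal(round(countParameters(model) / 1e6, 1), 8.3)
  expect_equal(countParameters(model), enumerateParams(model@config))
})

test_that("parameter count matches the closed-form enumeration on a tiny config", {
  cfg <- modelConfig(inputSize = 64, baseChannels = 8)
  model <- buildModel(cfg)
  expect_equal(countParameters(model), enumerateParams(cfg))
  ## count is an architecture property, independent of data or seed
  expect_equal(countParameters(buildModel(cfg, seed = 99)),
               countParameters(model))
})

test_that("encoder produces the full pyramid with the documented schedule", {
  model <- tinyModel(inputSize = 64, baseChannels = 8)
  sq <- tinySeq(seed = 5, imageSize = 64)
  pyr <- encodeVisit(model, visitArray(sq, 1))
  expect_equal(lapply(pyr, dim),
               list(c(64L, 64L, 8L), c(32L, 32L, 16L), c(16L, 16L, 32L),
                    c(8L, 8L, 64L), c(4L, 4L, 128L)))
  expect_true(all(vapply(pyr, function(a) all(is.finite(a)), TRUE)))
  ## all-zero input stays finite (bias response only)
  z <- array(0, c(64, 64, 3))
  pz <- encodeVisit(model, z)
  expect_true(all(vapply(pz, function(a) all(is.finite(a)), TRUE)))
  ## the two mask channels feed an asymmetric path: swapping them changes output
  v <- visitArray(sq, 2)
  vswap <- v[, , c(1, 3, 2)]
  expect_gt(max(abs(encodeVisit(model, v)[[1]] - encodeVisit(model, vswap)[[1]])), 0)
  expect_error(encodeVisit(model, array(0.5, c(64, 64, 3))), "binary")
})

test_that("gated residual block semantics: constant input and closed gate", {
  m <- tinyModel()@env
  set.seed(31)
  ## give the (zero-initialized) side branches non-trivial weights so the
  ## semantics are actually exercised
  m$par[["enc.grb1.r2.W"]][] <- rnorm(length(m$par[["enc.grb1.r2.W"]]), 0, 0.2)
  m$par[["enc.grb1.hf.W"]][] <- rnorm(length(m$par[["enc.grb1.hf.W"]]), 0, 0.2)
  tp <- swaunet:::newTape(grad = FALSE)
  H <- 8L; c <- 4L
  ## constant input: x - blur(x) vanishes away from borders, so the output
  ## equals the residual branch R(x) there
  xconst <- matrix(1.7, H * H, c)
  xn <- swaunet:::tConst(tp, xconst, H, H)
  y <- swaunet:::.fGRB(tp, m, xn, "enc.grb1")
  W1 <- m$par[["enc.grb1.r1.W"]]; b1 <- m$par[["enc.grb1.r1.b"]]
  W2 <- m$par[["enc.grb1.r2.W"]]; b2 <- m$par[["enc.grb1.r2.b"]]
  a1 <- swaunet:::.c_im2col3(xconst, H, H, 1L) %*% W1
  a1 <- pmax(sweep(a1, 2, b1, "+"), 0)
  r <- xconst + sweep(swaunet:::.c_im2col3(a1, H, H, 1L) %*% W2, 2, b2, "+")
  inner <- as.vector(matrix(seq_len(H * H), H, H)[3:6, 3:6])
  expect_equal(y$v[inner, ], r[inner, ], tolerance = 1e-10)
  ## forcing the gate far negative closes the high-frequency path entirely
  m2 <- tinyModel(seed = 4)@env
  m2$par[["enc.grb1.hf.W"]][] <- rnorm(length(m2$par[["enc.grb1.hf.W"]]), 0, 0.2)
  m2$par[["enc.grb1.r2.W"]][] <- rnorm(length(m2$par[["enc.grb1.r2.W"]]), 0, 0.2)
  x0 <- matrix(rnorm(H * H * c), H * H, c)
  openGate <- swaunet:::.fGRB(swaunet:::newTape(grad = FALSE), m2,
                              swaunet:::tConst(tp, x0, H, H), "enc.grb1")$v
  m2$par[["enc.grb1.gate.b"]][] <- -1e4
  m2$par[["enc.grb1.gate.W"]][] <- 0
  closed <- swaunet:::.fGRB(swaunet:::newTape(grad = FALSE), m2,
                            swaunet:::tConst(tp, x0, H, H), "enc.grb1")$v
  W1 <- m2$par[["enc.grb1.r1.W"]]; b1 <- m2$par[["enc.grb1.r1.b"]]
  W2 <- m2$par[["enc.grb1.r2.W"]]; b2 <- m2$par[["enc.grb1.r2.b"]]
  a1 <- pmax(sweep(swaunet:::.c_im2col3(x0, H, H, 1L) %*% W1, 2, b1, "+"), 0)
  r <- x0 + sweep(swaunet:::.c_im2col3(a1, H, H, 1L) %*% W2, 2, b2, "+")
  expect_equal(closed, r, tolerance = 1e-4)
  expect_false(isTRUE(all.equal(openGate, closed, tolerance = 1e-6)))
})

test_that("channel-fusion bottleneck is a shape-preserving residual stack", {
  m <- tinyModel()@env
  tp <- swaunet:::newTape(grad = FALSE)
  x0 <- matrix(rnorm(16 * 16 * 8), 256, 8)
  xn <- swaunet:::tConst(tp, x0, 16L, 16L)
  ## zeroed inner output projection (the initialization state) -> identity
  y <- swaunet:::.fCFB(tp, m, xn, "enc.cfb2")
  expect_identical(dim(y$v), dim(x0))
  expect_equal(y$v, x0)
  ## non-zero projection departs from identity but preserves shape
  m$par[["enc.cfb2.o.W"]][] <- rnorm(length(m$par[["enc.cfb2.o.W"]]), 0, 0.3)
  y2 <- swaunet:::.fCFB(swaunet:::newTape(grad = FALSE), m, xn, "enc.cfb2")
  expect_identical(dim(y2$v), dim(x0))
  expect_gt(max(abs(y2$v - x0)), 0)
})

test_that("windows are zero-padded with fixed shapes", {
  model <- tinyModel()
  sq <- tinySeq(seed = 6)
  pyr <- lapply(seqFrames(sq), function(f) encodeVisit(model, f))
  w <- makeWindows(pyr)
  expect_length(w, 3L)
  ## window 0: two zero frames then F0
  expect_true(all(w[[1]][[1]][[4]] == 0))
  expect_true(all(w[[1]][[2]][[5]] == 0))
  expect_identical(w[[1]][[3]], pyr[[1]])
  ## window 2 has no padding
  expect_identical(w[[3]], list(pyr[[1]], pyr[[2]], pyr[[3]]))
  ## identical tensor shapes across windows
  shp <- function(win) lapply(win, function(p) lapply(p, dim))
  expect_identical(shp(w[[1]]), shp(w[[3]]))
  expect_error(makeWindows(pyr[1:2]), "3 visit")
})

test_that("one shared SWA parameter set drives all three windows", {
  model <- tinyModel(seed = 3)
  sq <- tinySeq(seed = 8)
  pyr <- lapply(seqFrames(sq), function(f) encodeVisit(model, f))
  w <- makeWindows(pyr)
  M <- lapply(1:3, function(i) swaAggregate(model, w[[i]], i))
  ## perturbing one shared weight changes every window's state (the output
  ## projection: the one attention matrix that is live at initialization)
  model@env$par[["swa.L5.p1.Wo"]][1, 1] <-
    model@env$par[["swa.L5.p1.Wo"]][1, 1] + 0.5
  M2 <- lapply(1:3, function(i) swaAggregate(model, w[[i]], i))
  for (i in 1:3)
    expect_gt(max(abs(M[[i]][[5]] - M2[[i]][[5]])), 0)
  ## identical window contents give identical states (no index dependence)
  expect_identical(swaAggregate(model, w[[2]], 2),
                   swaAggregate(model, w[[2]], 3))
})

test_that("the gated conv fusion is exactly inert at gate_init = 0", {
  model <- tinyModel(seed = 5)
  sq <- tinySeq(seed = 9)
  pyr <- lapply(seqFrames(sq), function(f) encodeVisit(model, f))
  w <- makeWindows(pyr)
  M <- swaAggregate(model, w[[3]])
  ## scrambling the gated-conv weights cannot change anything while the
  ## trainable scalar is exactly zero
  expect_equal(model@env$par[["swa.L4.gamma"]], 0)
  model@env$par[["swa.L4.gc3.W"]][] <- 17
  model@env$par[["swa.L5.gc3.W"]][] <- -3
  expect_identical(swaAggregate(model, w[[3]]), M)
  ## opening the gate activates the branch
  model@env$par[["swa.L4.gamma"]] <- 0.1
  expect_gt(max(abs(swaAggregate(model, w[[3]])[[4]] - M[[4]])), 0)
})

test_that("DynNet is a shape-preserving endomorphism with its own parameters", {
  model <- tinyModel(seed = 2)
  sq <- tinySeq(seed = 10)
  pyr <- lapply(seqFrames(sq), function(f) encodeVisit(model, f))
  M <- swaAggregate(model, makeWindows(pyr)[[3]])
  E <- dynnetEvolve(model, M)
  expect_identical(lapply(E, dim), lapply(M, dim))
  expect_true(all(vapply(E, function(a) all(is.finite(a)), TRUE)))
  ## zero latent input -> finite bias response
  Z <- lapply(M, function(a) array(0, dim(a)))
  expect_true(all(vapply(dynnetEvolve(model, Z),
                         function(a) all(is.finite(a)), TRUE)))
  ## parameter disjointness: dyn.* names never overlap other modules
  nm <- names(model@env$par)
  expect_gt(sum(startsWith(nm, "dyn.")), 0)
  expect_equal(intersect(nm[startsWith(nm, "dyn.")],
                         nm[!startsWith(nm, "dyn.")]), character(0))
})

test_that("decoder emits a full-resolution 3-channel triplet", {
  model <- tinyModel(seed = 6)
  sq <- tinySeq(seed = 11)
  pyr <- lapply(seqFrames(sq), function(f) encodeVisit(model, f))
  M <- swaAggregate(model, makeWindows(pyr)[[3]])
  tri <- decodeFrame(model, dynnetEvolve(model, M), pyr[[3]])
  expect_identical(dim(tri$faf), c(32L, 32L))
  expect_identical(dim(tri$lesionLogits), c(32L, 32L))
  expect_true(all(tri$faf >= 0 & tri$faf <= 1))
  bm <- binarizeLogits(tri$lesionLogits)
  expect_true(all(bm %in% c(0, 1)))
  d <- diceCoefficient(bm, lesionMasks(sq)[[4]])
  expect_true(d >= 0 && d <= 1)
})

test_that("predictions are causal: later visits cannot affect earlier forecasts", {
  for (variant in c("reference", "swa1_standard_attention",
                    "swa2_conv_aggregator", "swa3_convlstm")) {
    model <- tinyModel(variant, seed = 4)
    sq <- tinySeq(seed = 12)
    frames <- seqFrames(sq)
    base <- forwardSequence(model, frames)
    ## noise into visit 3 (index 3): months 6 and 12 must be bit-identical
    f3 <- frames
    set.seed(1)
    f3[[3]][, , 1] <- matrix(runif(32 * 32), 32, 32)
    pert <- forwardSequence(model, f3)
    expect_identical(base$predictions[[1]], pert$predictions[[1]],
                     label = paste(variant, "month 6"))
    expect_identical(base$predictions[[2]], pert$predictions[[2]],
                     label = paste(variant, "month 12"))
    expect_false(identical(base$predictions[[3]], pert$predictions[[3]]))
    ## noise into visit 2: month 6 must be untouched
    f2 <- frames
    f2[[2]][, , 1] <- matrix(runif(32 * 32), 32, 32)
    pert2 <- forwardSequence(model, f2)
    expect_identical(base$predictions[[1]], pert2$predictions[[1]])
  }
})

test_that("forward passes are deterministic in evaluation mode", {
  model <- tinyModel(seed = 8)
  sq <- tinySeq(seed = 13)
  expect_identical(forwardSequence(model, sq), forwardSequence(model, sq))
})

test_that("checkpoints round-trip and the summary accounts for every parameter", {
  model <- tinyModel(seed = 9)
  path <- tempfile(fileext = ".rds")
  saveCheckpoint(model, path)
  back <- loadCheckpoint(path)
  expect_identical(back@env$par, model@env$par)
  sq <- tinySeq(seed = 14)
  expect_identical(forwardSequence(back, sq), forwardSequence(model, sq))
  tsv <- tempfile(fileext = ".tsv")
  df <- writeModelSummary(model, tsv)
  expect_equal(sum(df$parameters), countParameters(model))
  expect_true(file.exists(tsv))
  unlink(c(path, tsv))
})

test_that("model configs are validated", {
  expect_error(modelConfig(inputSize = 100), "divisible")
  expect_error(modelConfig(windowLength = 4), "windowLength")
  expect_error(buildVariant("bogus"), "unknown variant")
})
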