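test_that("single-bump field is maximal at its center and symmetric", {
  cfg <- simulatorConfig(imageSize = 64, seed = 1)
  f <- sampleGaussianField(cfg, nPeaks = 1,
                           centers = matrix(c(32.5, 32.5), 1),
                           sigmas = 8)
  expect_equal(which(f == max(f)), c(32 + 31 * 64, 33 + 31 * 64, 32 + 32 * 64,
                                     33 + 32 * 64))
  ## radial symmetry: the four pixels at distance 10 along the axes agree
  expect_equal(f[22, 32], f[43, 33], tolerance = 1e-12)
  expect_equal(f[32, 22], f[33, 43], tolerance = 1e-12)
})

test_that("two well-separated peaks give exactly two strong local maxima", {
  cfg <- simulatorConfig(imageSize = 64, seed = 1)
  f <- sampleGaussianField(cfg, nPeaks = 2,
                           centers = matrix(c(20, 20, 45, 45), 2, byrow = TRUE),
                           sigmas = c(5, 5))
  ## exhaustive 8-neighbourhood scan
  n <- nrow(f)
  nmax <- 0L
  for (r in 2:(n - 1)) for (c in 2:(n - 1)) {
    v <- f[r, c]
    if (v > 0.5 * max(f) &&
        v == max(f[(r - 1):(r + 1), (c - 1):(c + 1)]))
      nmax <- nmax + 1L
  }
  expect_equal(nmax, 2L)
})

test_that("field generation is deterministic under a fixed seed", {
  cfg <- tinySimulatorConfig(seed = 9)
  set.seed(5); f1 <- sampleGaussianField(cfg)
  set.seed(5); f2 <- sampleGaussianField(cfg)
  expect_identical(f1, f2)
})

test_that("lesion initialization thresholds relative to the field maximum", {
  toy <- matrix(c(0, 1, 0, 1, 4, 1, 0, 1, 0), 3, 3)
  m <- initializeLesion(toy, 0.5)
  expect_equal(sum(m), 1)
  expect_equal(m[2, 2], 1)
  ## monotone: a lower threshold gives a superset
  set.seed(11)
  f <- sampleGaussianField(simulatorConfig(imageSize = 64))
  expect_true(all(initializeLesion(f, 0.6) <= initializeLesion(f, 0.3)))
  ## threshold -> 1 shrinks toward the argmax set
  hi <- initializeLesion(f, 0.999)
  expect_true(sum(hi) >= 1 && sum(hi) <= 8)
  expect_true(hi[which.max(f)] == 1)
  expect_error(initializeLesion(matrix(0, 4, 4), 0.5), "degenerate")
})

test_that("grow step is a monotone superset with deterministic replay", {
  cfg <- tinySimulatorConfig(imageSize = 64)
  for (s in 1:8) {
    set.seed(s)
    f <- sampleGaussianField(cfg)
    m0 <- initializeLesion(f, 0.5)
    set.seed(100 + s); m1 <- growStep(m0, cfg)
    expect_true(all(m1 >= m0), label = paste("superset seed", s))
    set.seed(100 + s); m2 <- growStep(m0, cfg)
    expect_identical(m1, m2)
  }
  expect_error(growStep(matrix(0, 8, 8), cfg), "empty mask")
})

test_that("directional dilation from a point extends one-sided along +x", {
  cfg <- simulatorConfig(imageSize = 64,
                         directionalDilationRadiusRange = c(3, 3),
                         nStochasticCycles = 0,
                         anisotropyDirection = c(1, 0))
  m <- matrix(0, 64, 64); m[32, 32] <- 1
  set.seed(1)
  g <- growStep(m, cfg)
  cols <- which(g == 1, arr.ind = TRUE)[, 2]
  expect_equal(max(cols) - 32, 3)   # reaches exactly the element radius in +x
  expect_equal(min(cols), 32)       # no growth against the direction
  ## independent oracle: dilation of a point is the (mirrored) element itself,
  ## i.e. every grown pixel lies in the +x half-ellipse around the seed
  px <- which(g == 1, arr.ind = TRUE)
  u <- px[, 2] - 32; v <- px[, 1] - 32
  expect_true(all(u >= 0 & (u / 3)^2 + (v / 2)^2 <= 1 + 1e-9))
})

test_that("growth mask is the one-sided set difference", {
  a <- matrix(0, 5, 5); a[3, 3] <- 1
  expect_equal(sum(computeGrowthMask(a, a)), 0)
  b <- a; b[3, 4] <- 1; b[2, 3] <- 1
  g <- computeGrowthMask(a, b)
  expect_equal(sum(g), 2)
  expect_equal(sum(g * a), 0)
  expect_error(computeGrowthMask(a, matrix(0, 4, 4)), "dimension")
  shrunk <- a * 0
  expect_warning(computeGrowthMask(a, shrunk), "ignored")
  ## disjointness property over random mask pairs
  set.seed(3)
  for (i in 1:10) {
    p <- matrix(rbinom(64, 1, 0.3), 8, 8)
    q <- matrix(rbinom(64, 1, 0.5), 8, 8)
    expect_equal(sum(suppressWarnings(computeGrowthMask(p, q)) * p), 0)
  }
})

test_that("rendered FAF is dark inside the lesion and recoverable when clean", {
  cfg <- tinySimulatorConfig(imageSize = 64)
  set.seed(21)
  mask <- initializeLesion(sampleGaussianField(cfg), 0.5)
  for (s in 1:5) {
    set.seed(s)
    img <- renderFAF(mask, cfg)
    expect_true(all(img >= 0 & img <= 1))
    expect_lt(mean(img[mask == 1]), mean(img[mask == 0]))
  }
  ## noiseless, vessel-free, rim-free render is two-level + texture:
  ## mid-level thresholding recovers the mask exactly
  clean <- simulatorConfig(imageSize = 64, noiseSigma = 0,
                           nVesselsRange = c(0L, 0L), rimGain = 1)
  img <- renderFAF(mask, clean)
  rec <- (img < (clean@backgroundLevel + clean@lesionLevel) / 2) * 1
  expect_identical(rec, mask)
})

test_that("peripheral noise variance exceeds central variance", {
  clean <- simulatorConfig(imageSize = 64, noiseSigma = 0,
                           nVesselsRange = c(0L, 0L), rimGain = 1)
  noisy <- simulatorConfig(imageSize = 64, noiseSigma = 0.03,
                           peripheralNoiseGain = 2, nVesselsRange = c(0L, 0L),
                           rimGain = 1)
  mask <- matrix(0, 64, 64); mask[30:34, 30:34] <- 1
  set.seed(2)
  tex <- matrix(0, 64, 64)   # fixed zero texture isolates the noise field
  base <- renderFAF(mask, clean, vessels = mask * 0, texture = tex)
  resid <- replicate(100, renderFAF(mask, noisy, vessels = mask * 0,
                                    texture = tex) - base)
  vmap <- apply(resid, 1:2, var)
  rr <- matrix(1:64, 64, 64); cc <- t(rr)
  d <- sqrt((rr - 32.5)^2 + (cc - 32.5)^2)
  ## stay away from the clipping zone right at the lesion
  central <- vmap[d < 20 & mask == 0]
  periph <- vmap[d > 28]
  expect_gt(mean(periph), 2 * mean(central))
})

test_that("generated sequences satisfy nestedness and the growth identity", {
  cfg <- tinySimulatorConfig()
  for (s in 1:6) {
    sq <- generateSequence(cfg, seed = s)
    expect_s4_class(sq, "LesionSequence")
    expect_length(fafImages(sq), 4L)
    expect_length(lesionMasks(sq), 4L)
    expect_length(growthMasks(sq), 4L)
    areas <- vapply(lesionMasks(sq), sum, 0)
    expect_true(all(diff(areas) >= 0))
    expect_equal(sum(growthMasks(sq)[[1]]), 0)
    for (i in 2:4) {
      prev <- lesionMasks(sq)[[i - 1]]; cur <- lesionMasks(sq)[[i]]
      expect_true(all(prev <= cur))
      expect_identical(growthMasks(sq)[[i]], pmax(cur - prev, 0))
    }
  }
  ## determinism: regeneration is identical
  expect_identical(generateSequence(cfg, seed = 42),
                   generateSequence(cfg, seed = 42))
})

test_that("a stationary configuration produces empty growth masks", {
  cfg <- tinySimulatorConfig(directionalDilationRadiusRange = c(0, 0),
                             nStochasticCycles = 0L)
  sq <- generateSequence(cfg, seed = 4)
  for (i in 2:4) expect_equal(sum(growthMasks(sq)[[i]]), 0)
})

test_that("growth is anisotropic along the configured direction", {
  ## with stochastic cycles disabled the centroid must move with the
  ## direction in at least 90% of seeds
  dirs <- list(c(1, 0), c(0, 1), c(-0.6, 0.8))
  hits <- 0L; total <- 0L
  for (d in dirs) {
    cfg <- simulatorConfig(imageSize = 64, peakSigmaRange = c(4, 8),
                           directionalDilationRadiusRange = c(2, 4),
                           nStochasticCycles = 0L, anisotropyDirection = d)
    for (s in 1:17) {
      set.seed(s)
      m0 <- initializeLesion(sampleGaussianField(cfg), 0.5)
      m1 <- growStep(m0, cfg)
      c0 <- which(m0 == 1, arr.ind = TRUE)
      c1 <- which(m1 == 1, arr.ind = TRUE)
      disp <- c(mean(c1[, 2]) - mean(c0[, 2]),   # x = column
                mean(c1[, 1]) - mean(c0[, 1]))   # y = row
      hits <- hits + (sum(disp * d) > 0)
      total <- total + 1L
    }
  }
  expect_gte(total, 50L)
  expect_gte(hits / total, 0.9)
})

test_that("stochastic growth fronts are more jagged than a disc", {
  cfg <- simulatorConfig(imageSize = 96, peakSigmaRange = c(6, 10),
                         directionalDilationRadiusRange = c(2, 5),
                         nStochasticCycles = 3L)
  worse <- 0L
  for (s in 1:6) {
    sq <- generateSequence(cfg, seed = 300 + s)
    m <- lesionMasks(sq)[[4]]
    ratio <- boundaryPixels(m) / sum(m)
    disc <- rasterDisc(sum(m), 96)
    discRatio <- boundaryPixels(disc) / sum(disc)
    worse <- worse + (ratio > discRatio)
  }
  expect_gte(worse, 5L)
})

test_that("dataset generation writes a manifest and round-trips losslessly", {
  cfg <- tinySimulatorConfig(nSequences = 2L, seed = 7)
  out <- file.path(tempdir(), "swaunet-ds-test")
  unlink(out, recursive = TRUE)
  man <- generateDataset(cfg, out)
  expect_equal(man$nImages, 8L)
  expect_length(man$sequences, 2L)
  expect_true(file.exists(file.path(out, "manifest.json")))
  expect_true(file.exists(file.path(out, "seq0001", "frame0_faf.png")))
  back <- readDataset(file.path(out, "manifest.json"))
  ref <- generateSequence(cfg, seed = cfg@seed + 1, eyeId = "seq0001")
  expect_identical(lesionMasks(back[[1]]), lesionMasks(ref))
  expect_identical(growthMasks(back[[1]]), growthMasks(ref))
  ## FAF is 8-bit quantized on disk
  expect_equal(fafImages(back[[1]])[[1]],
               round(255 * fafImages(ref)[[1]]) / 255, tolerance = 1e-12)
  ## regeneration is byte-identical
  out2 <- file.path(tempdir(), "swaunet-ds-test2")
  unlink(out2, recursive = TRUE)
  generateDataset(cfg, out2)
  f1 <- readBin(file.path(out, "seq0002", "frame2_mask.png"), "raw", 1e6)
  f2 <- readBin(file.path(out2, "seq0002", "frame2_mask.png"), "raw", 1e6)
  expect_identical(f1, f2)
  ## vacuous case
  cfg0 <- tinySimulatorConfig(nSequences = 0L)
  man0 <- generateDataset(cfg0, file.path(tempdir(), "swaunet-ds-empty"))
  expect_length(man0$sequences, 0L)
  unlink(c(out, out2), recursive = TRUE)
})

test_that("simulator configs are validated with named errors", {
  expect_error(simulatorConfig(imageSize = 20), "imageSize")
  expect_error(simulatorConfig(fieldThreshold = 1.2), "fieldThreshold")
  expect_error(simulatorConfig(lesionLevel = 0.7, backgroundLevel = 0.6),
               "lesionLevel")
  expect_error(simulatorConfig(framesPerSequence = 1), "framesPerSequence")
})
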