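test_that("soft Dice loss matches hand-worked values", {
  expect_equal(softDiceLoss(c(1, 0), c(0, 1), eps = 1), 2 / 3)
  ## empty-vs-empty is a perfect match under the smoothing convention
  expect_equal(softDiceLoss(rep(0, 10), rep(0, 10), eps = 1), 0)
  ## perfect binary overlap: eps-limited, exactly 0 as eps -> 0
  t <- c(1, 1, 0, 1)
  expect_lt(softDiceLoss(t, t, eps = 1), 0.15)
  expect_equal(softDiceLoss(t, t, eps = 1e-12), 0, tolerance = 1e-9)
  expect_error(softDiceLoss(c(1, 0), c(0, 1, 1)), "dimension")
})

test_that("prediction loss composes Dice, BCE and L1 with frame averaging", {
  sq <- tinySeq(seed = 2)
  targets <- lapply(2:4, function(i) visitArray(sq, i))
  ## perfect predictions: saturated correct logits, exact FAF
  perfect <- lapply(targets, function(t)
    list(faf = t[, , 1], lesionLogits = (t[, , 2] * 2 - 1) * 50,
         growthLogits = (t[, , 3] * 2 - 1) * 50))
  lp <- predictionLoss(perfect, targets, lossConfig())
  expect_lt(lp, 0.05)
  ## the growth Dice component scales linearly in growthWeight
  model <- tinyModel(seed = 3)
  preds <- forwardSequence(model, sq)$predictions
  l0 <- predictionLoss(preds, targets, lossConfig(growthWeight = 0))
  l1 <- predictionLoss(preds, targets, lossConfig(growthWeight = 1))
  l2 <- predictionLoss(preds, targets, lossConfig(growthWeight = 2))
  expect_equal(l2 - l1, l1 - l0, tolerance = 1e-10)
})

test_that("total loss applies the bounded reconstruction weight", {
  expect_equal(totalLoss(1.0, 0.4, lossConfig(lambdaRecon = 0.25)), 1.1)
  expect_equal(totalLoss(2.0, 5.0, lossConfig(lambdaRecon = 0)), 2.0)
  expect_error(lossConfig(lambdaRecon = 0.5), "lambdaRecon")
  expect_error(lossConfig(lambdaRecon = 0.7), "lambdaRecon")
})

test_that("augmentation preserves all sequence invariants", {
  sq <- tinySeq(seed = 5, imageSize = 64)
  ## all switches off -> identity
  expect_identical(augmentSample(sq, FALSE, FALSE), sq)
  set.seed(8)
  for (i in 1:5) {
    aug <- augmentSample(sq, geometric = TRUE, intensity = TRUE)
    expect_true(validObject(aug))    # nestedness + growth identity + binarity
    for (k in 1:4) {
      expect_true(all(lesionMasks(aug)[[k]] %in% c(0, 1)))
      expect_true(all(fafImages(aug)[[k]] >= 0 & fafImages(aug)[[k]] <= 1))
    }
    for (k in 2:4)
      expect_identical(growthMasks(aug)[[k]],
                       pmax(lesionMasks(aug)[[k]] - lesionMasks(aug)[[k - 1]], 0))
  }
})

test_that("training decreases the loss and is reproducible under a seed", {
  corpus <- lapply(1:8, function(s) tinySeq(seed = 40 + s))
  run <- function() {
    model <- tinyModel(seed = 1)
    runTraining(model, corpus,
                trainConfig(pretrainEpochs = 2, finetuneEpochs = 1,
                            batchSize = 2, accumulationSteps = 2, seed = 5,
                            augmentGeometric = FALSE, augmentIntensity = FALSE,
                            valFraction = 0.2),
                lossConfig())
  }
  r1 <- run()
  expect_equal(nrow(r1$log), 3L)
  expect_equal(r1$log$stage, c("pretrain", "pretrain", "finetune"))
  expect_lt(r1$log$loss[2], r1$log$loss[1])
  r2 <- run()
  expect_identical(r1$log, r2$log)
})

test_that("gradient accumulation reproduces the equivalent large batch", {
  corpus <- lapply(1:4, function(s) tinySeq(seed = 60 + s))
  run <- function(bs, acc) {
    model <- tinyModel(seed = 2)
    runTraining(model, corpus,
                trainConfig(pretrainEpochs = 1, finetuneEpochs = 0,
                            batchSize = bs, accumulationSteps = acc, seed = 3,
                            augmentGeometric = FALSE, augmentIntensity = FALSE,
                            valFraction = 0.25),
                lossConfig())$model@env$par
  }
  pA <- run(1L, 2L)
  pB <- run(2L, 1L)
  for (nm in names(pA))
    expect_equal(pA[[nm]], pB[[nm]], tolerance = 1e-12, label = nm)
})

test_that("a zero learning rate leaves parameters untouched", {
  corpus <- lapply(1:5, function(s) tinySeq(seed = 70 + s))
  model <- tinyModel(seed = 4)
  before <- model@env$par
  runTraining(model, corpus,
              trainConfig(pretrainEpochs = 1, finetuneEpochs = 0,
                          lrPretrain = 0, seed = 1,
                          augmentGeometric = FALSE, augmentIntensity = FALSE,
                          valFraction = 0.2),
              lossConfig())
  expect_identical(model@env$par, before)
})

test_that("non-finite losses abort with a diagnostic", {
  corpus <- lapply(1:5, function(s) tinySeq(seed = 80 + s))
  model <- tinyModel(seed = 5)
  model@env$par[["dec.head.W"]][1] <- NaN
  expect_error(
    runTraining(model, corpus,
                trainConfig(pretrainEpochs = 1, finetuneEpochs = 0, seed = 1,
                            valFraction = 0.2),
                lossConfig()),
    "non-finite")
  expect_error(runTraining(tinyModel(), list(), trainConfig(), lossConfig()),
               "empty dataset")
})
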