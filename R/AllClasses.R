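#' @import methods
#' @importFrom stats rnorm runif median sd pt quantile setNames
#' @importFrom utils write.csv read.csv
#' @useDynLib swaunet, .registration = TRUE
#' @importFrom Rcpp evalCpp
NULL

## ---------------------------------------------------------------------------
## SimulatorConfig
## ---------------------------------------------------------------------------

#' Configuration of the synthetic lesion-growth simulator
#'
#' Holds every tunable of the anisotropic geographic-atrophy growth simulator:
#' lesion seeding (multi-peak Gaussian fields thresholded at a fraction of
#' their maximum), growth (one-sided directional dilation plus stochastic
#' erosion/dilation cycles), and FAF rendering (dark lesion on a textured
#' bright background, junctional rim, vessel-like dark tracks, peripheral
#' noise).
#'
#' @slot imageSize pixels per side; >= 32 and a multiple of 16.
#' @slot nSequences number of sequences in a generated dataset.
#' @slot framesPerSequence visits per eye (>= 2).
#' @slot nPeaksRange integer range of Gaussian peaks seeding a lesion.
#' @slot peakSigmaRange range of peak standard deviations (pixels).
#' @slot fieldThreshold threshold as a fraction of the field maximum, in (0,1).
#' @slot anisotropyDirection unit 2-vector of preferred growth; NA values mean
#'   "draw a random direction per sequence".
#' @slot directionalDilationRadiusRange radius range (pixels) of the one-sided
#'   directional structuring element applied at each growth step.
#' @slot nStochasticCycles number of random erosion/dilation cycles per step.
#' @slot stochasticElementRadiusRange radius range of the stochastic elements.
#' @slot nVesselsRange number of vessel-like dark tracks per eye.
#' @slot vesselWidthRange vessel width range (pixels).
#' @slot backgroundLevel FAF background intensity in [0,1].
#' @slot lesionLevel FAF intensity inside the lesion (dark), < backgroundLevel.
#' @slot rimGain brightening factor of the junctional rim (1 disables).
#' @slot noiseSigma additive Gaussian noise sigma.
#' @slot peripheralNoiseGain noise multiplier outside the central disc
#'   (radius 40% of the frame).
#' @slot seed integer RNG seed.
#' @export
setClass("SimulatorConfig", representation(
  imageSize = "integer", nSequences = "integer", framesPerSequence = "integer",
  nPeaksRange = "integer", peakSigmaRange = "numeric", fieldThreshold = "numeric",
  anisotropyDirection = "numeric", directionalDilationRadiusRange = "numeric",
  nStochasticCycles = "integer", stochasticElementRadiusRange = "numeric",
  nVesselsRange = "integer", vesselWidthRange = "numeric",
  backgroundLevel = "numeric", lesionLevel = "numeric", rimGain = "numeric",
  noiseSigma = "numeric", peripheralNoiseGain = "numeric", seed = "integer"))

setValidity("SimulatorConfig", function(object) {
  msg <- character()
  if (object@imageSize < 32L || object@imageSize %% 16L != 0L)
    msg <- c(msg, "imageSize must be >= 32 and a multiple of 16")
  if (object@framesPerSequence < 2L)
    msg <- c(msg, "framesPerSequence must be >= 2")
  if (!(object@fieldThreshold > 0 && object@fieldThreshold < 1))
    msg <- c(msg, "fieldThreshold must lie strictly in (0, 1)")
  for (f in c("backgroundLevel", "lesionLevel")) {
    v <- slot(object, f)
    if (v < 0 || v > 1) msg <- c(msg, paste(f, "must lie in [0, 1]"))
  }
  if (object@lesionLevel >= object@backgroundLevel)
    msg <- c(msg, "lesionLevel must be smaller than backgroundLevel")
  if (object@nSequences < 0L) msg <- c(msg, "nSequences must be >= 0")
  if (any(diff(object@nPeaksRange) < 0) || object@nPeaksRange[1] < 1L)
    msg <- c(msg, "nPeaksRange must be an increasing range with minimum >= 1")
  if (object@noiseSigma < 0) msg <- c(msg, "noiseSigma must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Create a simulator configuration
#'
#' Defaults emit 256 x 256 sequences of 4 visits and, at dataset scale,
#' 2000 sequences (8000 frames). All lengths are in pixels at
#' \code{imageSize} resolution; when building scaled-down corpora, scale the
#' length-type parameters with the frame (see \code{\link{tinySimulatorConfig}}).
#'
#' @param imageSize,nSequences,framesPerSequence,nPeaksRange,peakSigmaRange,fieldThreshold,anisotropyDirection,directionalDilationRadiusRange,nStochasticCycles,stochasticElementRadiusRange,nVesselsRange,vesselWidthRange,backgroundLevel,lesionLevel,rimGain,noiseSigma,peripheralNoiseGain,seed
#'   see the slot documentation of \code{\linkS4class{SimulatorConfig}}.
#' @return A validated \code{SimulatorConfig}.
#' @examples
#' cfg <- simulatorConfig(imageSize = 64, nSequences = 2)
#' @export
simulatorConfig <- function(imageSize = 256L, nSequences = 2000L,
                            framesPerSequence = 4L, nPeaksRange = c(1L, 4L),
                            peakSigmaRange = c(10, 40), fieldThreshold = 0.5,
                            anisotropyDirection = c(NA_real_, NA_real_),
                            directionalDilationRadiusRange = c(2, 8),
                            nStochasticCycles = 3L,
                            stochasticElementRadiusRange = c(1, 3),
                            nVesselsRange = c(3L, 8L), vesselWidthRange = c(2, 5),
                            backgroundLevel = 0.6, lesionLevel = 0.12,
                            rimGain = 1.15, noiseSigma = 0.03,
                            peripheralNoiseGain = 2.0, seed = 1L) {
  new("SimulatorConfig", imageSize = as.integer(imageSize),
      nSequences = as.integer(nSequences),
      framesPerSequence = as.integer(framesPerSequence),
      nPeaksRange = as.integer(nPeaksRange), peakSigmaRange = peakSigmaRange,
      fieldThreshold = fieldThreshold, anisotropyDirection = anisotropyDirection,
      directionalDilationRadiusRange = directionalDilationRadiusRange,
      nStochasticCycles = as.integer(nStochasticCycles),
      stochasticElementRadiusRange = stochasticElementRadiusRange,
      nVesselsRange = as.integer(nVesselsRange),
      vesselWidthRange = vesselWidthRange, backgroundLevel = backgroundLevel,
      lesionLevel = lesionLevel, rimGain = rimGain, noiseSigma = noiseSigma,
      peripheralNoiseGain = peripheralNoiseGain, seed = as.integer(seed))
}

#' Scaled-down simulator configuration for small frames
#'
#' Rescales the length-type parameters (peak sigma, dilation radii, vessel
#' width) proportionally to \code{imageSize / 256} so that lesions and growth
#' fronts occupy the same fraction of the frame as at full resolution.
#' Intensity and noise parameters are resolution-free and kept unchanged.
#'
#' @param imageSize frame side in pixels (default 64).
#' @param ... overrides passed to \code{\link{simulatorConfig}}.
#' @return A \code{SimulatorConfig}.
#' @export
tinySimulatorConfig <- function(imageSize = 64L, ...) {
  s <- imageSize / 256
  args <- list(...)
  scaled <- list(peakSigmaRange = pmax(2, c(10, 40) * s),
                 directionalDilationRadiusRange = pmax(1, round(c(2, 8) * s)),
                 stochasticElementRadiusRange = pmax(1, round(c(1, 3) * s)),
                 vesselWidthRange = pmax(1, round(c(2, 5) * s)))
  scaled <- scaled[setdiff(names(scaled), names(args))]
  do.call(simulatorConfig, c(list(imageSize = imageSize), scaled, args))
}

setMethod("show", "SimulatorConfig", function(object) {
  cat(sprintf("SimulatorConfig: %d sequences x %d frames at %dx%d px\n",
              object@nSequences, object@framesPerSequence,
              object@imageSize, object@imageSize))
  cat(sprintf("  peaks %d-%d (sigma %.1f-%.1f), threshold %.2f of max\n",
              object@nPeaksRange[1], object@nPeaksRange[2],
              object@peakSigmaRange[1], object@peakSigmaRange[2],
              object@fieldThreshold))
  cat(sprintf("  growth: directional radius %.0f-%.0f px, %d stochastic cycles\n",
              object@directionalDilationRadiusRange[1],
              object@directionalDilationRadiusRange[2],
              object@nStochasticCycles))
})

## ---------------------------------------------------------------------------
## LesionSequence
## ---------------------------------------------------------------------------

#' One eye's longitudinal record
#'
#' Ordered per-visit triplets of FAF image, lesion mask and growth mask, with
#' nominal visit months. Validity enforces the core invariants: equal frame
#' shapes, monotone (nested) lesion growth, and the growth-mask identity
#' growth[i] = lesion[i] AND NOT lesion[i-1] with growth[1] all-zero.
#'
#' @slot faf list of grayscale matrices in [0,1].
#' @slot lesionMasks list of binary (0/1) matrices.
#' @slot growthMasks list of binary (0/1) matrices.
#' @slot visitMonths numeric vector of nominal months (0, 6, 12, 18).
#' @slot eyeId character identifier.
#' @slot laterality "left" or "right".
#' @export
setClass("LesionSequence", representation(
  faf = "list", lesionMasks = "list", growthMasks = "list",
  visitMonths = "numeric", eyeId = "character", laterality = "character"))

setValidity("LesionSequence", function(object) {
  msg <- character()
  n <- length(object@faf)
  if (length(object@lesionMasks) != n || length(object@growthMasks) != n ||
      length(object@visitMonths) != n)
    return("faf, lesionMasks, growthMasks and visitMonths must have equal length")
  if (n < 2L) msg <- c(msg, "a sequence needs at least 2 visits")
  d <- dim(object@faf[[1]])
  for (i in seq_len(n)) {
    if (!identical(dim(object@faf[[i]]), d) ||
        !identical(dim(object@lesionMasks[[i]]), d) ||
        !identical(dim(object@growthMasks[[i]]), d))
      return("all frames must share one spatial shape")
    if (!all(object@lesionMasks[[i]] %in% c(0, 1)))
      return("lesion masks must be binary")
    if (!all(object@growthMasks[[i]] %in% c(0, 1)))
      return("growth masks must be binary")
  }
  if (any(object@growthMasks[[1]] != 0))
    msg <- c(msg, "growth mask of the first visit must be all-zero")
  for (i in 2:n) {
    prev <- object@lesionMasks[[i - 1L]]; cur <- object@lesionMasks[[i]]
    if (any(prev > cur))
      msg <- c(msg, sprintf("lesion masks not nested at visit %d", i))
    if (any(object@growthMasks[[i]] != pmax(cur - prev, 0)))
      msg <- c(msg, sprintf("growth mask at visit %d is not lesion[i] AND NOT lesion[i-1]", i))
  }
  if (!object@laterality %in% c("left", "right"))
    msg <- c(msg, "laterality must be 'left' or 'right'")
  if (is.unsorted(object@visitMonths, strictly = TRUE))
    msg <- c(msg, "visitMonths must be strictly increasing")
  if (length(msg)) msg else TRUE
})

#' @rdname LesionSequence-class
#' @param faf,lesionMasks,growthMasks,visitMonths,eyeId,laterality see slots.
#' @export
lesionSequence <- function(faf, lesionMasks, growthMasks = NULL,
                           visitMonths = seq(0, by = 6, length.out = length(faf)),
                           eyeId = "eye", laterality = "left") {
  if (is.null(growthMasks)) {
    growthMasks <- vector("list", length(lesionMasks))
    growthMasks[[1]] <- lesionMasks[[1]] * 0
    for (i in seq_along(lesionMasks)[-1])
      growthMasks[[i]] <- computeGrowthMask(lesionMasks[[i - 1]], lesionMasks[[i]])
  }
  new("LesionSequence", faf = faf, lesionMasks = lesionMasks,
      growthMasks = growthMasks, visitMonths = visitMonths,
      eyeId = eyeId, laterality = laterality)
}

#' @export
setGeneric("fafImages", function(x) standardGeneric("fafImages"))
#' @export
setGeneric("lesionMasks", function(x) standardGeneric("lesionMasks"))
#' @export
setGeneric("growthMasks", function(x) standardGeneric("growthMasks"))
#' @export
setGeneric("visitMonths", function(x) standardGeneric("visitMonths"))
#' @export
setGeneric("eyeId", function(x) standardGeneric("eyeId"))
#' @export
setGeneric("laterality", function(x) standardGeneric("laterality"))

#' Accessors for LesionSequence
#' @param x a \code{LesionSequence}.
#' @name LesionSequence-accessors
#' @aliases fafImages lesionMasks growthMasks visitMonths eyeId laterality
NULL

#' @rdname LesionSequence-accessors
#' @export
setMethod("fafImages", "LesionSequence", function(x) x@faf)
#' @rdname LesionSequence-accessors
#' @export
setMethod("lesionMasks", "LesionSequence", function(x) x@lesionMasks)
#' @rdname LesionSequence-accessors
#' @export
setMethod("growthMasks", "LesionSequence", function(x) x@growthMasks)
#' @rdname LesionSequence-accessors
#' @export
setMethod("visitMonths", "LesionSequence", function(x) x@visitMonths)
#' @rdname LesionSequence-accessors
#' @export
setMethod("eyeId", "LesionSequence", function(x) x@eyeId)
#' @rdname LesionSequence-accessors
#' @export
setMethod("laterality", "LesionSequence", function(x) x@laterality)

setMethod("show", "LesionSequence", function(object) {
  d <- dim(object@faf[[1]])
  areas <- vapply(object@lesionMasks, sum, 0)
  cat(sprintf("LesionSequence '%s' (%s eye): %d visits at months %s, %dx%d px\n",
              object@eyeId, object@laterality, length(object@faf),
              paste(object@visitMonths, collapse = "/"), d[1], d[2]))
  cat(sprintf("  lesion area (px): %s\n", paste(areas, collapse = " -> ")))
})

setMethod("length", "LesionSequence", function(x) length(x@faf))

## ---------------------------------------------------------------------------
## ModelConfig
## ---------------------------------------------------------------------------

#' Architectural hyperparameters of SWAU-Net
#'
#' Pins the reference architecture and every ablation variant: a 5-level
#' U-Net encoder (four down-sampling stages) with channel schedule
#' C, 2C, 4C, 8C, 16C, spatial self-attention and sliding-window temporal
#' attention at L4/L5, a weight-shared 3-frame temporal convolution mixer at
#' L1-L3, a 3-level dynamics U-Net (DynNet), and a shared decoder.
#'
#' @slot inputSize input side in pixels (divisible by 16).
#' @slot inChannels 3: FAF, lesion mask, growth mask.
#' @slot baseChannels channel width C at the first level.
#' @slot nLevels number of feature resolutions (5).
#' @slot windowLength temporal context window (fixed at 3 visits).
#' @slot nHeads attention heads.
#' @slot dropout dropout probability on attention branches.
#' @slot gateInit initial value of the gated-conv fusion scalar.
#' @slot dynnetBaseChannels base width of the dynamics U-Net (default 2C;
#'   the reference value 32 calibrates the total parameter count).
#' @slot variant "reference" or an ablation name (see \code{\link{listVariants}}).
#' @export
setClass("ModelConfig", representation(
  inputSize = "integer", inChannels = "integer", baseChannels = "integer",
  nLevels = "integer", windowLength = "integer", nHeads = "integer",
  dropout = "numeric", gateInit = "numeric", dynnetBaseChannels = "integer",
  variant = "character"))

setValidity("ModelConfig", function(object) {
  msg <- character()
  if (object@nLevels != 5L) msg <- c(msg, "nLevels is fixed at 5 (L1-L5)")
  if (object@windowLength != 3L) msg <- c(msg, "windowLength is fixed at 3 visits")
  if (object@inputSize %% 2L^(object@nLevels - 1L) != 0L)
    msg <- c(msg, "inputSize must be divisible by 16 (four down-sampling stages)")
  if (object@inChannels != 3L) msg <- c(msg, "inChannels is fixed at 3")
  if (object@baseChannels %% 2L != 0L)
    msg <- c(msg, "baseChannels must be even (dual-path stems use C/2 each)")
  ch <- object@baseChannels * 2L^(0:4)
  if (any(ch[4:5] %% object@nHeads != 0L))
    msg <- c(msg, "deep channel widths must be divisible by nHeads")
  if (object@dropout < 0 || object@dropout >= 1)
    msg <- c(msg, "dropout must lie in [0, 1)")
  ok <- c("reference", .variantNames())
  if (!object@variant %in% ok)
    msg <- c(msg, paste("variant must be one of:", paste(ok, collapse = ", ")))
  if (length(msg)) msg else TRUE
})

#' Create a model configuration
#'
#' @param inputSize,inChannels,baseChannels,nLevels,windowLength,nHeads,dropout,gateInit,dynnetBaseChannels,variant
#'   see \code{\linkS4class{ModelConfig}}. \code{dynnetBaseChannels = NA}
#'   defaults to \code{2 * baseChannels}.
#' @return A validated \code{ModelConfig}. The default arguments give the
#'   reference configuration: 256 x 256 input, C = 16 doubling to 256 at the
#'   16 x 16 bottleneck, about 8.3 million trainable parameters.
#' @examples
#' cfg <- modelConfig(inputSize = 64, baseChannels = 8)  # tiny test config
#' @export
modelConfig <- function(inputSize = 256L, inChannels = 3L, baseChannels = 16L,
                        nLevels = 5L, windowLength = 3L, nHeads = 4L,
                        dropout = 0.2, gateInit = 0.0,
                        dynnetBaseChannels = NA_integer_,
                        variant = "reference") {
  if (is.na(dynnetBaseChannels)) dynnetBaseChannels <- 2L * as.integer(baseChannels)
  new("ModelConfig", inputSize = as.integer(inputSize),
      inChannels = as.integer(inChannels),
      baseChannels = as.integer(baseChannels), nLevels = as.integer(nLevels),
      windowLength = as.integer(windowLength), nHeads = as.integer(nHeads),
      dropout = dropout, gateInit = gateInit,
      dynnetBaseChannels = as.integer(dynnetBaseChannels), variant = variant)
}

#' Channel and spatial-size schedule of a configuration
#' @param config a \code{ModelConfig}.
#' @return list with integer vectors \code{channels} and \code{sizes} (L1..L5).
#' @export
levelSchedule <- function(config) {
  list(channels = config@baseChannels * 2L^(0:4),
       sizes = config@inputSize %/% 2L^(0:4))
}

setMethod("show", "ModelConfig", function(object) {
  sch <- levelSchedule(object)
  cat(sprintf("ModelConfig ('%s'): %dx%d input, C=%d\n", object@variant,
              object@inputSize, object@inputSize, object@baseChannels))
  cat(sprintf("  levels L1-L5: %s\n",
              paste(sprintf("%d^2x%d", sch$sizes, sch$channels), collapse = ", ")))
  cat(sprintf("  %d-head attention at L4/L5, window %d, DynNet width %d\n",
              object@nHeads, object@windowLength, object@dynnetBaseChannels))
})

## ---------------------------------------------------------------------------
## SWAUNet model object
## ---------------------------------------------------------------------------

#' A built SWAU-Net model
#'
#' Wraps the parameter store (an environment, so that optimizer updates are
#' by reference) together with its configuration. Use
#' \code{\link{buildModel}} to construct, \code{\link{countParameters}},
#' \code{\link{forwardSequence}}, \code{\link{runTraining}} to operate.
#'
#' @slot config the \code{ModelConfig} used to build the model.
#' @slot variant the variant actually built.
#' @slot env environment holding \code{par} (named list of numeric arrays)
#'   and cached index tables.
#' @export
setClass("SWAUNet", representation(config = "ModelConfig", variant = "character",
                                   env = "environment"))

setMethod("show", "SWAUNet", function(object) {
  cat(sprintf("SWAU-Net model (variant '%s'), %s trainable parameters\n",
              object@variant, format(countParameters(object), big.mark = ",")))
  show(object@config)
})

## ---------------------------------------------------------------------------
## Loss / training configs
## ---------------------------------------------------------------------------

#' Weights of the hybrid training objective
#'
#' Total loss = LPred + lambdaRecon * LRecon with lambdaRecon < 0.5. Each
#' component combines a Soft Dice loss on the lesion mask, a Soft Dice loss
#' on the (sparse) growth mask weighted by \code{growthWeight}, a small BCE
#' stabilizer on both mask logit channels, and an L1 term on the FAF channel.
#'
#' @slot lambdaRecon reconstruction weight in [0, 0.5).
#' @slot growthWeight multiplier on the growth-mask Dice term.
#' @slot bceWeight weight of the BCE stabilizer.
#' @slot diceSmooth additive Dice smoothing epsilon.
#' @slot fafL1Weight weight of the FAF L1 term.
#' @export
setClass("LossConfig", representation(
  lambdaRecon = "numeric", growthWeight = "numeric", bceWeight = "numeric",
  diceSmooth = "numeric", fafL1Weight = "numeric"))

setValidity("LossConfig", function(object) {
  msg <- character()
  if (object@lambdaRecon < 0 || object@lambdaRecon >= 0.5)
    msg <- c(msg, "lambdaRecon must lie in [0, 0.5)")
  for (f in c("growthWeight", "bceWeight", "fafL1Weight"))
    if (slot(object, f) < 0) msg <- c(msg, paste(f, "must be >= 0"))
  if (object@diceSmooth <= 0) msg <- c(msg, "diceSmooth must be > 0")
  if (length(msg)) msg else TRUE
})

#' @rdname LossConfig-class
#' @param lambdaRecon,growthWeight,bceWeight,diceSmooth,fafL1Weight see slots.
#' @export
lossConfig <- function(lambdaRecon = 0.25, growthWeight = 4.0, bceWeight = 0.1,
                       diceSmooth = 1.0, fafL1Weight = 1.0) {
  new("LossConfig", lambdaRecon = lambdaRecon, growthWeight = growthWeight,
      bceWeight = bceWeight, diceSmooth = diceSmooth, fafL1Weight = fafL1Weight)
}

#' Two-stage optimization protocol
#'
#' Stage 1 pretrains on synthetic sequences (50 epochs at lr 1e-3), stage 2
#' fine-tunes (60 epochs at lr 1e-4) on the target dataset; Adam optimizer,
#' gradient accumulation to emulate larger batches, online augmentation.
#'
#' @slot pretrainEpochs,finetuneEpochs epoch counts of the two stages.
#' @slot lrPretrain,lrFinetune Adam learning rates.
#' @slot batchSize mini-batch size.
#' @slot accumulationSteps mini-batches accumulated per parameter update.
#' @slot seed RNG seed for shuffling, dropout and augmentation.
#' @slot augmentGeometric,augmentIntensity online-augmentation switches.
#' @slot evalEpochWindow trailing epochs used by the fold aggregation.
#' @slot valFraction fraction of sequences held out for validation.
#' @export
setClass("TrainConfig", representation(
  pretrainEpochs = "integer", finetuneEpochs = "integer",
  lrPretrain = "numeric", lrFinetune = "numeric", batchSize = "integer",
  accumulationSteps = "integer", seed = "integer",
  augmentGeometric = "logical", augmentIntensity = "logical",
  evalEpochWindow = "integer", valFraction = "numeric"))

setValidity("TrainConfig", function(object) {
  msg <- character()
  if (object@pretrainEpochs < 0L || object@finetuneEpochs < 0L)
    msg <- c(msg, "epoch counts must be >= 0")
  if (object@lrPretrain < 0 || object@lrFinetune < 0)
    msg <- c(msg, "learning rates must be >= 0")
  if (object@batchSize < 1L || object@accumulationSteps < 1L)
    msg <- c(msg, "batchSize and accumulationSteps must be >= 1")
  if (length(msg)) msg else TRUE
})

#' @rdname TrainConfig-class
#' @param pretrainEpochs,finetuneEpochs,lrPretrain,lrFinetune,batchSize,accumulationSteps,seed,augmentGeometric,augmentIntensity,evalEpochWindow,valFraction
#'   see slots.
#' @export
trainConfig <- function(pretrainEpochs = 50L, finetuneEpochs = 60L,
                        lrPretrain = 1e-3, lrFinetune = 1e-4, batchSize = 2L,
                        accumulationSteps = 4L, seed = 1L,
                        augmentGeometric = TRUE, augmentIntensity = TRUE,
                        evalEpochWindow = 10L, valFraction = 0.1) {
  new("TrainConfig", pretrainEpochs = as.integer(pretrainEpochs),
      finetuneEpochs = as.integer(finetuneEpochs), lrPretrain = lrPretrain,
      lrFinetune = lrFinetune, batchSize = as.integer(batchSize),
      accumulationSteps = as.integer(accumulationSteps), seed = as.integer(seed),
      augmentGeometric = augmentGeometric, augmentIntensity = augmentIntensity,
      evalEpochWindow = as.integer(evalEpochWindow), valFraction = valFraction)
}
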