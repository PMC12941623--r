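## Hybrid loss (Soft Dice on lesion + growth masks, BCE stabilizer, FAF L1),
## online augmentation, Adam with gradient accumulation, and the two-stage
## (synthetic pretraining -> fine-tuning) protocol.

#' Soft Dice loss
#'
#' \code{1 - (2 * sum(pred * target) + eps) / (sum(pred) + sum(target) + eps)}.
#' The smoothing epsilon makes empty-vs-empty a perfect (zero-loss) match.
#'
#' @param pred probability map in [0,1].
#' @param target binary map of the same shape.
#' @param eps smoothing term (> 0).
#' @return Scalar loss in [0, 1].
#' @examples
#' softDiceLoss(c(1, 0), c(0, 1), eps = 1)  # 2/3
#' @export
softDiceLoss <- function(pred, target, eps = 1) {
  if (!identical(dim(pred), dim(target)) || length(pred) != length(target))
    stop("dimension error: pred and target must share one shape")
  1 - (2 * sum(pred * target) + eps) / (sum(pred) + sum(target) + eps)
}

.bceLogits <- function(z, t) {
  mean(pmax(z, 0) - t * z + log1p(exp(-abs(z))))
}

#' Prediction loss over the three forecast frames
#'
#' Per frame: Soft Dice on the lesion mask + \code{growthWeight} times Soft
#' Dice on the (sparse) growth mask + \code{bceWeight} times BCE on both
#' logit channels + \code{fafL1Weight} times mean absolute FAF error;
#' averaged over the three frames.
#'
#' @param predictions list of 3 prediction triplets (\code{faf},
#'   \code{lesionLogits}, \code{growthLogits}), as returned by
#'   \code{\link{forwardSequence}}.
#' @param targets list of 3 target visits, each an H x W x 3 array
#'   (FAF, lesion mask, growth mask).
#' @param cfg a \code{\link{lossConfig}}.
#' @return Scalar loss.
#' @export
predictionLoss <- function(predictions, targets, cfg = lossConfig()) {
  stopifnot(length(predictions) == length(targets))
  per <- vapply(seq_along(predictions), function(w) {
    p <- predictions[[w]]; t <- targets[[w]]
    if (!identical(dim(p$faf), dim(t[, , 1])))
      stop("dimension error: prediction and target shapes differ")
    pm <- 1 / (1 + exp(-p$lesionLogits))
    pg <- 1 / (1 + exp(-p$growthLogits))
    softDiceLoss(pm, t[, , 2], cfg@diceSmooth) +
      cfg@growthWeight * softDiceLoss(pg, t[, , 3], cfg@diceSmooth) +
      cfg@bceWeight * (.bceLogits(p$lesionLogits, t[, , 2]) +
                       .bceLogits(p$growthLogits, t[, , 3])) +
      cfg@fafL1Weight * mean(abs(p$faf - t[, , 1]))
  }, 0)
  mean(per)
}

#' Total hybrid loss
#'
#' \code{LTotal = LPred + lambdaRecon * LRecon}, with the bound
#' \code{lambdaRecon < 0.5} enforced.
#'
#' @param predLoss,reconLoss finite scalars.
#' @param cfg a \code{\link{lossConfig}}.
#' @return Scalar total loss.
#' @export
totalLoss <- function(predLoss, reconLoss, cfg = lossConfig()) {
  if (cfg@lambdaRecon >= 0.5)
    stop("configuration error: lambdaRecon must be < 0.5")
  stopifnot(is.finite(predLoss), is.finite(reconLoss))
  predLoss + cfg@lambdaRecon * reconLoss
}

## ---- online augmentation ---------------------------------------------------

.geomApply <- function(img, par, nearest) {
  n <- nrow(img)
  filt <- if (nearest) "none" else "bilinear"
  out <- img
  if (par$flip) out <- out[, rev(seq_len(ncol(out))), drop = FALSE]
  if (abs(par$angle) > 1e-8)
    out <- EBImage::rotate(out, par$angle, filter = filt,
                           output.dim = c(n, n), bg.col = 0)
  if (abs(par$zoom - 1) > 1e-8) {
    nz <- max(4L, round(n * par$zoom))
    z <- EBImage::resize(out, w = nz, h = nz, filter = filt)
    out <- matrix(0, n, n)
    if (nz >= n) {
      o <- (nz - n) %/% 2L
      out <- z[(o + 1L):(o + n), (o + 1L):(o + n)]
    } else {
      o <- (n - nz) %/% 2L
      out[(o + 1L):(o + nz), (o + 1L):(o + nz)] <- z
    }
  }
  out <- as.matrix(out)
  if (nearest) (out > 0.5) * 1 else pmin(pmax(out, 0), 1)
}

.corruptFaf <- function(img) {
  n <- nrow(img)
  out <- pmin(pmax(img, 0), 1)^runif(1, 0.8, 1.25)
  out <- out + rnorm(length(out), 0, 0.02)
  for (b in seq_len(sample(0:2, 1))) {
    r <- runif(1, n / 20, n / 8)
    cy <- runif(1, 1, n); cx <- runif(1, 1, n)
    rr <- matrix(seq_len(n), n, n); cc <- matrix(seq_len(n), n, n, byrow = TRUE)
    blot <- (rr - cy)^2 + (cc - cx)^2 <= r^2
    out[blot] <- out[blot] * runif(1, 0.5, 0.9)
  }
  pmin(pmax(out, 0), 1)
}

#' Online augmentation of one sequence
#'
#' Samples one geometric transform (rotation within +/-15 degrees,
#' horizontal flip with probability 0.5, zoom 0.9-1.1) and applies it
#' identically to every frame and channel (temporal and channel
#' consistency); masks are resampled nearest-neighbour and re-binarized,
#' and growth masks are recomputed from the transformed lesion masks so the
#' growth identity holds exactly. FAF-only intensity corruption (gamma
#' jitter, additive noise, dark blotches) is applied per frame.
#'
#' @param seq a \code{\linkS4class{LesionSequence}}.
#' @param geometric,intensity switches; with both FALSE the input is
#'   returned unchanged.
#' @return An augmented \code{LesionSequence}.
#' @export
augmentSample <- function(seq, geometric = TRUE, intensity = TRUE) {
  if (!geometric && !intensity) return(seq)
  faf <- seq@faf; les <- seq@lesionMasks
  if (geometric) {
    par <- list(angle = runif(1, -15, 15), flip = runif(1) < 0.5,
                zoom = runif(1, 0.9, 1.1))
    faf <- lapply(faf, .geomApply, par = par, nearest = FALSE)
    les <- lapply(les, .geomApply, par = par, nearest = TRUE)
  }
  if (intensity) faf <- lapply(faf, .corruptFaf)
  growth <- vector("list", length(les))
  growth[[1]] <- les[[1]] * 0
  for (i in seq_along(les)[-1])
    growth[[i]] <- pmax(les[[i]] - les[[i - 1]], 0)
  new("LesionSequence", faf = faf, lesionMasks = les, growthMasks = growth,
      visitMonths = seq@visitMonths, eyeId = seq@eyeId,
      laterality = seq@laterality)
}

## ---- loss graph + optimizer ------------------------------------------------

.visitArray <- function(sq, i) {
  array(c(sq@faf[[i]], sq@lesionMasks[[i]], sq@growthMasks[[i]]),
        dim = c(dim(sq@faf[[i]]), 3L))
}

.frameLossNodes <- function(tp, outNode, target, cfg) {
  fafT <- target[, , 1]; lesT <- target[, , 2]; groT <- target[, , 3]
  zl <- tCols(tp, outNode, 2L)
  zg <- tCols(tp, outNode, 3L)
  faf <- tSigmoid(tp, tCols(tp, outNode, 1L))
  list(nodes = list(tDiceLoss(tp, tSigmoid(tp, zl), lesT, cfg@diceSmooth),
                    tDiceLoss(tp, tSigmoid(tp, zg), groT, cfg@diceSmooth),
                    tBceLoss(tp, zl, lesT),
                    tBceLoss(tp, zg, groT),
                    tL1Loss(tp, faf, fafT)),
       w = c(1, cfg@growthWeight, cfg@bceWeight, cfg@bceWeight, cfg@fafL1Weight))
}

## Forward + hybrid loss for one sequence; returns loss node and tape.
.sampleLoss <- function(model, sq, cfg, training) {
  m <- model@env
  tp <- newTape(training = training, grad = TRUE)
  frames <- lapply(1:3, function(i) {
    a <- .visitArray(sq, i)
    tConst(tp, matrix(a, dim(a)[1] * dim(a)[2], 3L), dim(a)[1], dim(a)[2])
  })
  out <- .fForward(tp, m, frames)
  nodes <- list(); w <- numeric()
  for (k in 1:3) {
    fl <- .frameLossNodes(tp, out$pred[[k]], .visitArray(sq, k + 1L), cfg)
    nodes <- c(nodes, fl$nodes); w <- c(w, fl$w / 3)
  }
  lp <- tAffine(tp, nodes, w)
  if (m$flags$dynnet && cfg@lambdaRecon > 0) {
    rn <- list(); rw <- numeric()
    for (k in 1:3) {
      fl <- .frameLossNodes(tp, out$recon[[k]], .visitArray(sq, k), cfg)
      rn <- c(rn, fl$nodes); rw <- c(rw, fl$w / 3)
    }
    lr <- tAffine(tp, rn, rw)
    lt <- tAffine(tp, list(lp, lr), c(1, cfg@lambdaRecon))
  } else {
    lr <- NULL
    lt <- lp
  }
  list(tape = tp, total = lt, pred = lp, recon = lr)
}

.adamInit <- function(par) {
  list(m = lapply(par, function(p) { p[] <- 0; p }),
       v = lapply(par, function(p) { p[] <- 0; p }),
       t = 0L)
}

.adamStep <- function(menv, st, grads, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  st$t <- st$t + 1L
  c1 <- 1 - beta1^st$t
  c2 <- 1 - beta2^st$t
  for (nm in names(grads)) {
    g <- grads[[nm]]
    st$m[[nm]] <- beta1 * st$m[[nm]] + (1 - beta1) * g
    st$v[[nm]] <- beta2 * st$v[[nm]] + (1 - beta2) * g * g
    menv$par[[nm]] <- menv$par[[nm]] -
      lr * (st$m[[nm]] / c1) / (sqrt(st$v[[nm]] / c2) + eps)
  }
  st
}

## Mean mask/growth DSC of thresholded predictions over the 3 forecast frames.
.evalSequences <- function(model, seqs) {
  md <- numeric(); gd <- numeric()
  for (sq in seqs) {
    out <- forwardSequence(model, sq)
    for (w in 1:3) {
      p <- out$predictions[[w]]
      md <- c(md, diceCoefficient(binarizeLogits(p$lesionLogits),
                                  sq@lesionMasks[[w + 1L]]))
      gd <- c(gd, diceCoefficient(binarizeLogits(p$growthLogits),
                                  sq@growthMasks[[w + 1L]]))
    }
  }
  c(mask = mean(md), growth = mean(gd))
}

.trainEpoch <- function(model, seqs, st, lr, trainCfg, lossCfg) {
  m <- model@env
  ord <- sample(length(seqs))
  eb <- trainCfg@batchSize * trainCfg@accumulationSteps
  acc <- NULL; nacc <- 0L
  losses <- numeric(length(seqs))
  for (i in seq_along(ord)) {
    sq <- seqs[[ord[i]]]
    if (trainCfg@augmentGeometric || trainCfg@augmentIntensity)
      sq <- augmentSample(sq, trainCfg@augmentGeometric, trainCfg@augmentIntensity)
    sl <- .sampleLoss(model, sq, lossCfg, training = TRUE)
    lv <- as.numeric(sl$total$v)
    if (!is.finite(lv))
      stop("training aborted: non-finite loss at sample ", i)
    losses[i] <- lv
    tBackward(sl$tape, sl$total)
    g <- tGradients(sl$tape)
    if (is.null(acc)) acc <- g else
      for (nm in names(g)) acc[[nm]] <- acc[[nm]] + g[[nm]]
    nacc <- nacc + 1L
    if (nacc == eb || i == length(ord)) {
      if (lr > 0) {
        for (nm in names(acc)) acc[[nm]] <- acc[[nm]] / nacc
        ## parameters never touched this round keep zero gradients
        full <- lapply(m$par, function(p) { p[] <- 0; p })
        full[names(acc)] <- acc
        st <- .adamStep(m, st, full, lr)
      }
      acc <- NULL; nacc <- 0L
    }
  }
  list(state = st, loss = mean(losses))
}

#' Two-stage training of a SWAU-Net model
#'
#' Stage 1 pretrains on the synthetic corpus, stage 2 fine-tunes at a lower
#' learning rate on a disjoint split (or on \code{finetuneData}, e.g. a
#' clinical-style dataset). A fixed fraction of sequences is held out for
#' validation throughout; per-epoch training loss and held-out mask/growth
#' DSC are logged. Optimization is Adam with gradient accumulation
#' (\code{batchSize * accumulationSteps} samples per parameter update).
#'
#' @param model a \code{SWAUNet} (updated by reference and also returned).
#' @param data list of \code{LesionSequence} (the synthetic corpus).
#' @param trainCfg a \code{\link{trainConfig}}.
#' @param lossCfg a \code{\link{lossConfig}}. For the no_dynnet variant
#'   \code{lambdaRecon} must be 0 (it has no reconstruction path).
#' @param finetuneData optional fine-tuning dataset; when NULL a disjoint
#'   synthetic split (twice the validation fraction) is used.
#' @param verbose print per-epoch progress.
#' @return List with \code{model}, \code{log} (data.frame: stage, epoch,
#'   loss, maskDsc, growthDsc) and the split indices.
#' @export
runTraining <- function(model, data, trainCfg = trainConfig(),
                        lossCfg = lossConfig(), finetuneData = NULL,
                        verbose = FALSE) {
  if (length(data) == 0L) stop("configuration error: empty dataset")
  if (!model@env$flags$dynnet && lossCfg@lambdaRecon > 0)
    stop("configuration error: the no_dynnet variant has no reconstruction ",
         "path; set lambdaRecon = 0")
  set.seed(trainCfg@seed)
  n <- length(data)
  nVal <- max(1L, round(trainCfg@valFraction * n))
  nFt <- if (is.null(finetuneData)) max(1L, round(2 * trainCfg@valFraction * n)) else 0L
  ord <- sample(n)
  valIdx <- ord[seq_len(nVal)]
  ftIdx <- if (nFt > 0L) ord[nVal + seq_len(min(nFt, n - nVal))] else integer()
  trIdx <- setdiff(ord, c(valIdx, ftIdx))
  if (length(trIdx) == 0L) stop("configuration error: no training sequences left")
  val <- data[valIdx]
  if (is.null(finetuneData)) finetuneData <- data[ftIdx]
  st <- .adamInit(model@env$par)
  log <- list()
  stageSpec <- list(list(name = "pretrain", epochs = trainCfg@pretrainEpochs,
                         lr = trainCfg@lrPretrain, data = data[trIdx]),
                    list(name = "finetune", epochs = trainCfg@finetuneEpochs,
                         lr = trainCfg@lrFinetune, data = finetuneData))
  for (stg in stageSpec) {
    if (stg$epochs == 0L || length(stg$data) == 0L) next
    for (ep in seq_len(stg$epochs)) {
      res <- .trainEpoch(model, stg$data, st, stg$lr, trainCfg, lossCfg)
      st <- res$state
      dsc <- .evalSequences(model, val)
      log[[length(log) + 1L]] <- data.frame(
        stage = stg$name, epoch = ep, loss = res$loss,
        maskDsc = dsc["mask"], growthDsc = dsc["growth"])
      if (verbose)
        message(sprintf("[%s %d/%d] loss %.4f  mask DSC %.3f  growth DSC %.3f",
                        stg$name, ep, stg$epochs, res$loss, dsc["mask"],
                        dsc["growth"]))
    }
  }
  log <- do.call(rbind, log)
  rownames(log) <- NULL
  list(model = model, log = log, valIdx = valIdx, finetuneIdx = ftIdx,
       trainIdx = trIdx)
}
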