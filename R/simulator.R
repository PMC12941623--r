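## Synthetic longitudinal GA sequence simulator: multi-peak Gaussian seeding,
## anisotropic one-sided directional dilation with stochastic erosion/dilation
## cycles, and FAF rendering with vessel-like dark tracks and peripheral noise.

.checkSimulatorConfig <- function(config) {
  if (!is(config, "SimulatorConfig"))
    stop("config must be a SimulatorConfig")
  v <- validObject(config, test = TRUE)
  if (!isTRUE(v)) stop("invalid SimulatorConfig: ", paste(v, collapse = "; "))
  invisible(config)
}

#' Sample a multi-peak Gaussian field
#'
#' Sums 1-4 isotropic Gaussian bumps with centers drawn uniformly inside the
#' central 60\% of the frame and standard deviations drawn from
#' \code{peakSigmaRange}. Thresholding such a field seeds a lesion.
#'
#' @param config a \code{\linkS4class{SimulatorConfig}}.
#' @param nPeaks,centers,sigmas optional overrides (centers: n x 2 matrix of
#'   (row, col) coordinates); drawn from the config ranges when NULL.
#' @return A non-negative \code{imageSize} x \code{imageSize} matrix with
#'   positive maximum.
#' @examples
#' f <- sampleGaussianField(simulatorConfig(imageSize = 64, seed = 1))
#' @export
sampleGaussianField <- function(config, nPeaks = NULL, centers = NULL,
                                sigmas = NULL) {
  .checkSimulatorConfig(config)
  n <- config@imageSize
  if (is.null(nPeaks))
    nPeaks <- sample(config@nPeaksRange[1]:config@nPeaksRange[2], 1L)
  if (nPeaks < 1L) stop("configuration error: nPeaksRange must allow >= 1 peak")
  if (is.null(centers)) {
    lo <- 0.2 * n; hi <- 0.8 * n
    centers <- cbind(runif(nPeaks, lo, hi), runif(nPeaks, lo, hi))
  }
  if (is.null(sigmas))
    sigmas <- runif(nPeaks, config@peakSigmaRange[1], config@peakSigmaRange[2])
  rr <- matrix(seq_len(n), n, n)        # row coordinate
  cc <- matrix(seq_len(n), n, n, byrow = TRUE)
  field <- matrix(0, n, n)
  for (i in seq_len(nPeaks)) {
    d2 <- (rr - centers[i, 1])^2 + (cc - centers[i, 2])^2
    field <- field + exp(-d2 / (2 * sigmas[i]^2))
  }
  field
}

#' Initialize a lesion mask by relative thresholding
#'
#' @param field non-negative scalar field with positive maximum.
#' @param thresholdFraction fraction of the field maximum in (0,1); pixels at
#'   or above \code{thresholdFraction * max(field)} become lesion.
#' @return Binary (0/1) matrix with at least one foreground pixel.
#' @examples
#' initializeLesion(matrix(c(0,1,0, 1,4,1, 0,1,0), 3, 3), 0.5)
#' @export
initializeLesion <- function(field, thresholdFraction) {
  if (!(thresholdFraction > 0 && thresholdFraction < 1))
    stop("configuration error: thresholdFraction must lie strictly in (0, 1)")
  if (any(field < 0)) stop("field must be non-negative")
  m <- max(field)
  if (m <= 0) stop("degenerate input: all-zero field cannot seed a lesion")
  (field >= thresholdFraction * m) * 1
}

## Half-ellipse structuring element growing the mask along `direction`
## (x, y with y = image row, increasing downward). EBImage::dilate extends the
## foreground toward the REFLECTION of the kernel offsets, so the kernel is
## built on the mirrored side.
.directionalKernel <- function(radius, direction) {
  r <- max(1L, round(radius))
  s <- 2L * r + 1L
  d <- direction / sqrt(sum(direction^2))
  off <- expand.grid(dy = -r:r, dx = -r:r)
  u <- -(off$dx * d[1] + off$dy * d[2])        # mirrored along-direction comp.
  v <- -(-off$dx * d[2] + off$dy * d[1])
  b <- r / 2 + 0.5
  keep <- u >= -1e-9 & (u / r)^2 + (v / b)^2 <= 1 + 1e-9
  keep[off$dy == 0 & off$dx == 0] <- TRUE
  matrix(as.numeric(keep), s, s)
}

## EBImage's morphology crashes on a single-pixel (identity) kernel; such a
## kernel is a no-op anyway.
.safeDilate <- function(mask, kern) {
  if (sum(kern) <= 1) return(mask)
  EBImage::dilate(mask, kern)
}

.safeErode <- function(mask, kern) {
  if (sum(kern) <= 1) return(mask)
  EBImage::erode(mask, kern)
}

.discKernel <- function(radius) {
  r <- max(1L, round(radius))
  EBImage::makeBrush(2L * r + 1L, shape = "disc")
}

#' Grow a lesion mask by one visit interval
#'
#' Applies (1) one-sided directional dilation with a half-elliptical element
#' elongated along \code{direction} and radius drawn from
#' \code{directionalDilationRadiusRange}, (2) \code{nStochasticCycles}
#' alternating random erosion/dilation cycles with small disc elements, and
#' (3) a final union with the input so that growth is monotone (clinical GA
#' does not regress).
#'
#' @param mask binary matrix with at least one foreground pixel.
#' @param config a \code{SimulatorConfig}.
#' @param direction unit 2-vector (x, y); defaults to the config direction or,
#'   if that is NA, a random direction.
#' @return Binary matrix, superset of \code{mask}, with an irregular boundary.
#' @export
growStep <- function(mask, config, direction = NULL) {
  .checkSimulatorConfig(config)
  if (sum(mask) < 1) stop("degenerate input: empty mask cannot grow")
  if (is.null(direction)) {
    direction <- config@anisotropyDirection
    if (anyNA(direction)) {
      a <- runif(1, 0, 2 * pi)
      direction <- c(cos(a), sin(a))
    }
  }
  rr <- config@directionalDilationRadiusRange
  radius <- runif(1, rr[1], rr[2])
  out <- if (radius < 0.5) mask else
    .safeDilate(mask, .directionalKernel(radius, direction))
  er <- config@stochasticElementRadiusRange
  for (i in seq_len(config@nStochasticCycles)) {
    ke <- .discKernel(runif(1, er[1], er[2]))
    kd <- .discKernel(runif(1, er[1], er[2]))
    out <- .safeErode(out, ke)
    out <- .safeDilate(out, kd)
  }
  pmax(out, mask)
}

#' Pixel-wise growth mask between adjacent visits
#'
#' The growth mask is the one-sided set difference \code{curr AND NOT prev}:
#' the newly atrophic area since the previous visit. Pixels present in
#' \code{prev} but absent from \code{curr} (which a monotone disease cannot
#' produce, but noisy gradings can) are ignored with a warning.
#'
#' @param prevMask,currMask binary matrices of equal shape.
#' @return Binary matrix, disjoint from \code{prevMask}.
#' @examples
#' computeGrowthMask(matrix(0, 2, 2), matrix(c(1, 0, 0, 0), 2, 2))
#' @export
computeGrowthMask <- function(prevMask, currMask) {
  if (!identical(dim(prevMask), dim(currMask)))
    stop("dimension error: masks must share one shape")
  if (any(prevMask > currMask))
    warning("current mask does not contain the previous mask; ",
            "lost pixels are ignored (one-sided difference)")
  pmax(currMask - prevMask, 0)
}

## Smooth random-walk polyline vessel tracks, fixed per sequence (vessels are
## anatomy, not noise, and must persist across frames).
.vesselMask <- function(config) {
  n <- config@imageSize
  nV <- sample(config@nVesselsRange[1]:config@nVesselsRange[2], 1L)
  vm <- matrix(0, n, n)
  if (nV < 1L) return(vm)
  for (v in seq_len(nV)) {
    side <- sample(4L, 1L)
    pos <- switch(side,
                  c(1, runif(1, 1, n)), c(n, runif(1, 1, n)),
                  c(runif(1, 1, n), 1), c(runif(1, 1, n), n))
    ang <- atan2(n / 2 - pos[1], n / 2 - pos[2]) + runif(1, -0.5, 0.5)
    path <- matrix(0, n, n)
    for (s in seq_len(3L * n)) {
      r <- round(pos[1]); c <- round(pos[2])
      if (r < 1 || r > n || c < 1 || c > n) break
      path[r, c] <- 1
      ang <- ang + rnorm(1, 0, 0.08)
      pos <- pos + c(sin(ang), cos(ang))
    }
    w <- runif(1, config@vesselWidthRange[1], config@vesselWidthRange[2])
    if (w > 1.5) path <- .safeDilate(path, .discKernel((w - 1) / 2))
    vm <- pmax(vm, path)
  }
  vm
}

.lowFreqTexture <- function(n) {
  tx <- matrix(rnorm(n * n), n, n)
  tx <- EBImage::gblur(tx, sigma = max(2, n / 16))
  a <- max(abs(tx))
  if (a > 0) tx <- tx / a * 0.05
  tx
}

#' Render a synthetic FAF frame from a lesion mask
#'
#' The lesion interior is dark (hypoautofluorescent), the background bright
#' with low-frequency texture, a thin junctional rim outside the lesion
#' boundary is brightened by \code{rimGain}, vessel-like dark curvilinear
#' tracks cross the frame, and additive Gaussian noise is amplified by
#' \code{peripheralNoiseGain} outside the central disc (radius 40\% of the
#' frame). Values are clipped to [0, 1].
#'
#' @param lesionMask binary matrix.
#' @param config a \code{SimulatorConfig}.
#' @param vessels optional precomputed vessel mask (shared across a
#'   sequence); drawn fresh when NULL.
#' @param texture optional precomputed background texture matrix.
#' @return Matrix in [0, 1] of the same shape as \code{lesionMask}.
#' @export
renderFAF <- function(lesionMask, config, vessels = NULL, texture = NULL) {
  .checkSimulatorConfig(config)
  n <- config@imageSize
  stopifnot(identical(dim(lesionMask), c(n, n)))
  if (is.null(texture)) texture <- .lowFreqTexture(n)
  if (is.null(vessels)) vessels <- .vesselMask(config)
  img <- config@backgroundLevel + texture
  les <- lesionMask > 0
  img[les] <- config@lesionLevel + 0.3 * texture[les]
  if (config@rimGain != 1 && any(les)) {
    rim <- EBImage::dilate(lesionMask, .discKernel(3)) > 0 & !les
    img[rim] <- img[rim] * config@rimGain
  }
  ves <- vessels > 0 & !les
  img[ves] <- config@lesionLevel * 1.5
  if (config@noiseSigma > 0) {
    rr <- matrix(seq_len(n), n, n)
    cc <- matrix(seq_len(n), n, n, byrow = TRUE)
    periph <- sqrt((rr - (n + 1) / 2)^2 + (cc - (n + 1) / 2)^2) > 0.4 * n
    sdmap <- matrix(config@noiseSigma, n, n)
    sdmap[periph] <- config@noiseSigma * config@peripheralNoiseGain
    img <- img + rnorm(n * n) * sdmap
  }
  pmin(pmax(img, 0), 1)
}

#' Generate one synthetic longitudinal sequence
#'
#' Seeds a lesion by thresholding a multi-peak Gaussian field, grows it with
#' \code{\link{growStep}} for each subsequent visit, derives growth masks by
#' \code{\link{computeGrowthMask}} (all-zero at the first visit), and renders
#' per-visit FAF frames with a vessel layout and anisotropy direction held
#' fixed within the sequence.
#'
#' @param config a \code{SimulatorConfig}.
#' @param seed RNG seed; together with \code{config} it fully determines the
#'   output. Defaults to \code{config@seed}.
#' @param eyeId identifier stored in the sequence.
#' @return A \code{\linkS4class{LesionSequence}}.
#' @examples
#' seq1 <- generateSequence(tinySimulatorConfig(), seed = 7)
#' @export
generateSequence <- function(config, seed = config@seed, eyeId = "synthetic") {
  .checkSimulatorConfig(config)
  set.seed(seed)
  nF <- config@framesPerSequence
  direction <- config@anisotropyDirection
  if (anyNA(direction)) {
    a <- runif(1, 0, 2 * pi)
    direction <- c(cos(a), sin(a))
  }
  field <- sampleGaussianField(config)
  masks <- vector("list", nF)
  masks[[1]] <- initializeLesion(field, config@fieldThreshold)
  for (i in 2:nF) masks[[i]] <- growStep(masks[[i - 1]], config, direction)
  growth <- vector("list", nF)
  growth[[1]] <- masks[[1]] * 0
  for (i in 2:nF) growth[[i]] <- computeGrowthMask(masks[[i - 1]], masks[[i]])
  vessels <- .vesselMask(config)
  texture <- .lowFreqTexture(config@imageSize)
  faf <- lapply(masks, renderFAF, config = config, vessels = vessels,
                texture = texture)
  new("LesionSequence", faf = faf, lesionMasks = masks, growthMasks = growth,
      visitMonths = seq(0, by = 6, length.out = nF), eyeId = eyeId,
      laterality = "left")
}

.s4ToList <- function(x) {
  sn <- slotNames(class(x))
  setNames(lapply(sn, function(s) slot(x, s)), sn)
}

#' Generate and write a synthetic dataset
#'
#' Writes \code{nSequences} sequences under
#' \code{<outDir>/<seqId>/frame<k>_{faf|mask|growth}.png} (FAF as 8-bit
#' grayscale, masks as 0/255) plus a JSON manifest listing every sequence,
#' its per-frame paths, the per-sequence seed and a config snapshot.
#' Sequence k uses seed \code{config@seed + k}, so regeneration with the same
#' master seed is byte-identical.
#'
#' @param config a \code{SimulatorConfig}.
#' @param outDir writable output directory (created if missing).
#' @return Invisibly, the manifest as a list (with \code{$path} pointing at
#'   the written JSON file).
#' @export
generateDataset <- function(config, outDir) {
  .checkSimulatorConfig(config)
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(outDir)) stop("I/O error: cannot create ", outDir)
  records <- vector("list", config@nSequences)
  for (k in seq_len(config@nSequences)) {
    seqId <- sprintf("seq%04d", k)
    sq <- generateSequence(config, seed = config@seed + k, eyeId = seqId)
    sdir <- file.path(outDir, seqId)
    dir.create(sdir, showWarnings = FALSE)
    frames <- vector("list", length(sq))
    for (f in seq_len(length(sq))) {
      pf <- file.path(sdir, sprintf("frame%d_faf.png", f - 1L))
      pm <- file.path(sdir, sprintf("frame%d_mask.png", f - 1L))
      pg <- file.path(sdir, sprintf("frame%d_growth.png", f - 1L))
      png::writePNG(round(255 * sq@faf[[f]]) / 255, pf)
      png::writePNG(sq@lesionMasks[[f]], pm)
      png::writePNG(sq@growthMasks[[f]], pg)
      frames[[f]] <- list(month = sq@visitMonths[f],
                          faf = file.path(seqId, basename(pf)),
                          mask = file.path(seqId, basename(pm)),
                          growth = file.path(seqId, basename(pg)))
    }
    records[[k]] <- list(seqId = seqId, laterality = sq@laterality,
                         seed = config@seed + k, frames = frames)
  }
  manifest <- list(generator = "swaunet-simulator",
                   version = as.character(utils::packageVersion("swaunet")),
                   seed = config@seed,
                   nImages = config@nSequences * config@framesPerSequence,
                   config = .s4ToList(config),
                   sequences = records)
  path <- file.path(outDir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  manifest$path <- path
  invisible(manifest)
}

#' Generate an in-memory corpus of sequences
#'
#' Convenience wrapper used by training and tests: the same per-sequence
#' seeding as \code{\link{generateDataset}} without touching the filesystem.
#'
#' @param config a \code{SimulatorConfig}.
#' @param n number of sequences (default \code{config@nSequences}).
#' @return List of \code{LesionSequence}.
#' @export
generateCorpus <- function(config, n = config@nSequences) {
  lapply(seq_len(n), function(k)
    generateSequence(config, seed = config@seed + k, eyeId = sprintf("seq%04d", k)))
}
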