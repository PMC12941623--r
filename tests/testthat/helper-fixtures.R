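## Shared tiny fixtures, generated in code. The 32-pixel configuration is the
## smallest legal frame (one 2x2 map at L5) and keeps every structural test
## fast; study-scale behaviour is covered by the acceptance suite.

tinyCfg <- function(variant = "reference", inputSize = 32L, baseChannels = 4L,
                    dropout = 0) {
  modelConfig(inputSize = inputSize, baseChannels = baseChannels,
              dropout = dropout, variant = variant)
}

tinyModel <- function(variant = "reference", seed = 1L, ...) {
  buildModel(tinyCfg(variant = variant, ...), seed = seed)
}

tinySeq <- function(seed = 3L, imageSize = 32L, ...) {
  generateSequence(tinySimulatorConfig(imageSize = imageSize, ...), seed = seed)
}

visitArray <- function(sq, i) {
  array(c(fafImages(sq)[[i]], lesionMasks(sq)[[i]], growthMasks(sq)[[i]]),
        dim = c(dim(fafImages(sq)[[i]]), 3L))
}

seqFrames <- function(sq) lapply(1:3, function(i) visitArray(sq, i))

## Brute-force centered 3x3 convolution oracle (zero padding 1), independent
## of the package's im2col path.
bruteConv3 <- function(x, H, W, Wt, b, stride) {
  C <- ncol(x)
  Ho <- (H - 1) %/% stride + 1
  Wo <- (W - 1) %/% stride + 1
  out <- matrix(0, Ho * Wo, ncol(Wt))
  for (wo in 0:(Wo - 1)) for (ho in 0:(Ho - 1)) {
    acc <- b
    for (dx in -1:1) for (dy in -1:1) {
      hi <- ho * stride + dy; wi <- wo * stride + dx
      if (hi < 0 || hi >= H || wi < 0 || wi >= W) next
      k <- (dy + 1) + 3 * (dx + 1)
      for (ch in seq_len(C))
        acc <- acc + x[hi + wi * H + 1, ch] * Wt[(ch - 1) * 9 + k + 1, ]
    }
    out[ho + wo * Ho + 1, ] <- acc
  }
  out
}

## Count of 4-connected boundary pixels of a binary mask.
boundaryPixels <- function(mask) {
  n <- nrow(mask); m <- ncol(mask)
  pad <- matrix(0, n + 2, m + 2)
  pad[2:(n + 1), 2:(m + 1)] <- mask
  inner <- pad[2:(n + 1), 2:(m + 1)]
  nb <- pad[1:n, 2:(m + 1)] + pad[3:(n + 2), 2:(m + 1)] +
    pad[2:(n + 1), 1:m] + pad[2:(n + 1), 3:(m + 2)]
  sum(inner == 1 & nb < 4)
}

rasterDisc <- function(area, size) {
  r <- sqrt(area / pi)
  cc <- (size + 1) / 2
  xs <- matrix(seq_len(size), size, size)
  ys <- t(xs)
  ((xs - cc)^2 + (ys - cc)^2 <= r^2) * 1
}
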