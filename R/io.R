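## Dataset readers and clinical-style preprocessing.

#' Preprocess a clinical-style FAF frame and mask
#'
#' Right-eye frames are mirrored horizontally (so all eyes share one
#' anatomical orientation); the frame is zero-padded symmetrically to a
#' square (preserving aspect ratio), the FAF resized with bilinear
#' interpolation and the mask with nearest-neighbour resampling followed by
#' re-binarization; intensities are rescaled to [0, 1].
#'
#' @param faf grayscale matrix (e.g. 768 x 868 clinical frame).
#' @param mask binary matrix of the same shape.
#' @param laterality "left" or "right".
#' @param targetSize output side in pixels (default 256).
#' @return List with \code{faf} and \code{mask}, both targetSize square.
#' @export
preprocessClinicalFrame <- function(faf, mask, laterality, targetSize = 256L) {
  if (!identical(dim(faf), dim(mask)))
    stop("validation error: FAF and mask shapes differ")
  if (!laterality %in% c("left", "right"))
    stop("validation error: laterality must be 'left' or 'right'")
  if (max(faf) > 1) faf <- faf / 255
  mask <- (mask > 0.5) * 1
  if (laterality == "right") {
    faf <- faf[, rev(seq_len(ncol(faf))), drop = FALSE]
    mask <- mask[, rev(seq_len(ncol(mask))), drop = FALSE]
  }
  d <- dim(faf)
  s <- max(d)
  padTo <- function(x) {
    out <- matrix(0, s, s)
    ro <- (s - nrow(x)) %/% 2L
    co <- (s - ncol(x)) %/% 2L
    out[ro + seq_len(nrow(x)), co + seq_len(ncol(x))] <- x
    out
  }
  faf <- as.matrix(EBImage::resize(padTo(faf), w = targetSize, h = targetSize,
                                   filter = "bilinear"))
  mask <- as.matrix(EBImage::resize(padTo(mask), w = targetSize, h = targetSize,
                                    filter = "none"))
  list(faf = pmin(pmax(faf, 0), 1), mask = (mask > 0.5) * 1)
}

#' Read a generated dataset back from its manifest
#'
#' Loads every sequence listed in a \code{\link{generateDataset}} manifest,
#' re-validates all sequence invariants, and recomputes growth masks from
#' the stored lesion masks (a mismatch with the stored growth files raises a
#' warning; the recomputed masks win).
#'
#' @param manifestPath path to \code{manifest.json}.
#' @return List of \code{\linkS4class{LesionSequence}}.
#' @export
readDataset <- function(manifestPath) {
  if (!file.exists(manifestPath))
    stop("I/O error: manifest not found: ", manifestPath)
  man <- jsonlite::read_json(manifestPath)
  root <- dirname(manifestPath)
  lapply(man$sequences, function(rec) {
    nF <- length(rec$frames)
    faf <- vector("list", nF); les <- vector("list", nF)
    gro <- vector("list", nF); months <- numeric(nF)
    for (f in seq_len(nF)) {
      fr <- rec$frames[[f]]
      for (p in c(fr$faf, fr$mask, fr$growth))
        if (!file.exists(file.path(root, p)))
          stop("I/O error: missing file: ", file.path(root, p))
      faf[[f]] <- png::readPNG(file.path(root, fr$faf))
      les[[f]] <- (png::readPNG(file.path(root, fr$mask)) > 0.5) * 1
      gro[[f]] <- (png::readPNG(file.path(root, fr$growth)) > 0.5) * 1
      months[f] <- fr$month
    }
    rg <- vector("list", nF)
    rg[[1]] <- les[[1]] * 0
    for (f in 2:nF) rg[[f]] <- pmax(les[[f]] - les[[f - 1]], 0)
    for (f in seq_len(nF))
      if (any(rg[[f]] != gro[[f]])) {
        warning("stored growth mask of ", rec$seqId, " frame ", f - 1,
                " disagrees with the recomputed mask; using the recomputed one")
        break
      }
    new("LesionSequence", faf = faf, lesionMasks = les, growthMasks = rg,
        visitMonths = months, eyeId = rec$seqId,
        laterality = rec$laterality)
  })
}
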