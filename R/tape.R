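## Reverse-mode automatic differentiation on a dynamic tape.
##
## Values are dense numeric matrices: feature maps are (H*W) x C with
## column-major pixel index (row-major image row r, column c -> r + (c-1)*H),
## scalars are length-1 numerics. Nodes are environments; the tape records
## creation order so that reversing it is a valid topological order.

newTape <- function(training = FALSE, grad = TRUE) {
  tp <- new.env(parent = emptyenv())
  tp$nodes <- vector("list", 256L)
  tp$n <- 0L
  tp$training <- training
  tp$grad <- grad
  tp$leaf <- list()
  tp
}

.nd <- function(tp, v, H = NULL, W = NULL, pa = list(), bk = NULL) {
  nd <- new.env(parent = emptyenv())
  nd$v <- v
  nd$g <- NULL
  nd$H <- H
  nd$W <- W
  if (tp$grad) {
    nd$pa <- pa
    nd$bk <- bk
    tp$n <- tp$n + 1L
    if (tp$n > length(tp$nodes)) tp$nodes <- c(tp$nodes, vector("list", length(tp$nodes)))
    tp$nodes[[tp$n]] <- nd
  }
  nd
}

.acc <- function(n, g) {
  if (is.null(n$g)) n$g <- g else n$g <- n$g + g
}

## Constant (no gradient requested) leaf.
tConst <- function(tp, v, H = NULL, W = NULL) {
  nd <- new.env(parent = emptyenv())
  nd$v <- v; nd$g <- NULL; nd$H <- H; nd$W <- W
  nd$pa <- list(); nd$bk <- NULL; nd$const <- TRUE
  nd
}

## Parameter leaf; cached per tape so shared weights accumulate gradients.
tParam <- function(tp, model, name) {
  nd <- tp$leaf[[name]]
  if (!is.null(nd)) return(nd)
  v <- model$par[[name]]
  if (is.null(v)) stop("unknown parameter: ", name)
  nd <- .nd(tp, v)
  nd$pname <- name
  tp$leaf[[name]] <- nd
  nd
}

tBackward <- function(tp, loss) {
  stopifnot(tp$grad, length(loss$v) == 1L)
  loss$g <- 1
  for (i in seq_len(tp$n)) {
    nd <- tp$nodes[[tp$n - i + 1L]]
    if (!is.null(nd$bk) && !is.null(nd$g)) {
      nd$bk(nd)
      ## caches and gradients of interior nodes are dead past this point;
      ## release them so the allocator can recycle the arena mid-sweep
      nd$cols <- NULL; nd$Q <- NULL; nd$K <- NULL; nd$V <- NULL
      nd$O <- NULL; nd$A <- NULL; nd$m <- NULL
      if (is.null(nd$pname)) { nd$g <- NULL; nd$v <- NULL }
    }
    tp$nodes[tp$n - i + 1L] <- list(NULL)
  }
  invisible(NULL)
}

tGradients <- function(tp) {
  lapply(tp$leaf, function(nd) if (is.null(nd$g)) {
    z <- nd$v; z[] <- 0; z
  } else nd$g)
}

## ---- elementwise ----------------------------------------------------------

tAdd <- function(tp, a, b) {
  .nd(tp, a$v + b$v, a$H, a$W, list(a, b), function(nd) {
    .acc(nd$pa[[1L]], nd$g); .acc(nd$pa[[2L]], nd$g)
  })
}

tSub <- function(tp, a, b) {
  .nd(tp, a$v - b$v, a$H, a$W, list(a, b), function(nd) {
    .acc(nd$pa[[1L]], nd$g); .acc(nd$pa[[2L]], -nd$g)
  })
}

tMul <- function(tp, a, b) {
  .nd(tp, a$v * b$v, a$H, a$W, list(a, b), function(nd) {
    .acc(nd$pa[[1L]], nd$g * nd$pa[[2L]]$v)
    .acc(nd$pa[[2L]], nd$g * nd$pa[[1L]]$v)
  })
}

## scalar node s times tensor node x
tScale <- function(tp, s, x) {
  .nd(tp, as.numeric(s$v) * x$v, x$H, x$W, list(s, x), function(nd) {
    .acc(nd$pa[[1L]], sum(nd$g * nd$pa[[2L]]$v))
    .acc(nd$pa[[2L]], as.numeric(nd$pa[[1L]]$v) * nd$g)
  })
}

tRelu <- function(tp, x) {
  v <- x$v; v[v < 0] <- 0
  .nd(tp, v, x$H, x$W, list(x), function(nd) {
    g <- nd$g; g[nd$v <= 0] <- 0
    .acc(nd$pa[[1L]], g)
  })
}

tSigmoid <- function(tp, x) {
  v <- 1 / (1 + exp(-x$v))
  .nd(tp, v, x$H, x$W, list(x), function(nd) {
    .acc(nd$pa[[1L]], nd$g * nd$v * (1 - nd$v))
  })
}

tTanh <- function(tp, x) {
  v <- tanh(x$v)
  .nd(tp, v, x$H, x$W, list(x), function(nd) {
    .acc(nd$pa[[1L]], nd$g * (1 - nd$v * nd$v))
  })
}

## Inverted dropout; identity unless the tape is in training mode.
tDropout <- function(tp, x, p) {
  if (!tp$training || p <= 0) return(x)
  keep <- 1 - p
  m <- (matrix(stats::runif(length(x$v)), nrow(x$v)) < keep) / keep
  nd <- .nd(tp, x$v * m, x$H, x$W, list(x), function(nd) {
    .acc(nd$pa[[1L]], nd$g * nd$m)
  })
  nd$m <- m
  nd
}

## ---- structural -----------------------------------------------------------

tConcat <- function(tp, xs) {
  vs <- lapply(xs, function(x) x$v)
  cc <- vapply(vs, ncol, 1L)
  nd <- .nd(tp, do.call(cbind, vs), xs[[1L]]$H, xs[[1L]]$W, xs, function(nd) {
    off <- 0L
    for (i in seq_along(nd$pa)) {
      .acc(nd$pa[[i]], nd$g[, (off + 1L):(off + nd$cc[i]), drop = FALSE])
      off <- off + nd$cc[i]
    }
  })
  nd$cc <- cc
  nd
}

tCols <- function(tp, x, idx) {
  nd <- .nd(tp, x$v[, idx, drop = FALSE], x$H, x$W, list(x), function(nd) {
    g <- nd$pa[[1L]]$v; g[] <- 0
    g[, nd$idx] <- nd$g
    .acc(nd$pa[[1L]], g)
  })
  nd$idx <- idx
  nd
}

tRbind <- function(tp, xs) {
  vs <- lapply(xs, function(x) x$v)
  rr <- vapply(vs, nrow, 1L)
  nd <- .nd(tp, do.call(rbind, vs), NULL, NULL, xs, function(nd) {
    off <- 0L
    for (i in seq_along(nd$pa)) {
      .acc(nd$pa[[i]], nd$g[(off + 1L):(off + nd$rr[i]), , drop = FALSE])
      off <- off + nd$rr[i]
    }
  })
  nd$rr <- rr
  nd
}

## Row permutation (idx must be a permutation of the rows).
tPermRows <- function(tp, x, idx, H = NULL, W = NULL) {
  nd <- .nd(tp, x$v[idx, , drop = FALSE], H, W, list(x), function(nd) {
    g <- nd$g
    g[nd$idx, ] <- nd$g
    .acc(nd$pa[[1L]], g)
  })
  nd$idx <- idx
  nd
}

tRows <- function(tp, x, idx, H = NULL, W = NULL) {
  nd <- .nd(tp, x$v[idx, , drop = FALSE], H, W, list(x), function(nd) {
    g <- matrix(0, nrow(nd$pa[[1L]]$v), ncol(nd$pa[[1L]]$v))
    g[nd$idx, ] <- nd$g
    .acc(nd$pa[[1L]], g)
  })
  nd$idx <- idx
  nd
}

## ---- convolution / resampling ---------------------------------------------

## 3x3 convolution, zero padding 1, stride 1 or 2. W: (Cin*9) x Cout, b: Cout.
tConv3 <- function(tp, x, Wn, bn, stride = 1L) {
  cols <- .c_im2col3(x$v, x$H, x$W, stride)
  v <- cols %*% Wn$v
  v <- sweep(v, 2L, bn$v, "+")
  Ho <- (x$H - 1L) %/% stride + 1L
  Wo <- (x$W - 1L) %/% stride + 1L
  nd <- .nd(tp, v, Ho, Wo, list(x, Wn, bn), function(nd) {
    x <- nd$pa[[1L]]; Wn <- nd$pa[[2L]]; bn <- nd$pa[[3L]]
    .acc(Wn, crossprod(nd$cols, nd$g))
    .acc(bn, colSums(nd$g))
    if (is.null(x$const))
      .acc(x, .c_col2im3(nd$g %*% t(Wn$v), x$H, x$W, nd$stride, ncol(x$v)))
  })
  nd$cols <- cols
  nd$stride <- as.integer(stride)
  nd
}

## 1x1 convolution (pure channel mixing). W: Cin x Cout.
tConv1 <- function(tp, x, Wn, bn) {
  v <- sweep(x$v %*% Wn$v, 2L, bn$v, "+")
  .nd(tp, v, x$H, x$W, list(x, Wn, bn), function(nd) {
    x <- nd$pa[[1L]]; Wn <- nd$pa[[2L]]; bn <- nd$pa[[3L]]
    .acc(Wn, crossprod(x$v, nd$g))
    .acc(bn, colSums(nd$g))
    if (is.null(x$const)) .acc(x, nd$g %*% t(Wn$v))
  })
}

tBlur3 <- function(tp, x) {
  .nd(tp, .c_blur3(x$v, x$H, x$W), x$H, x$W, list(x), function(nd) {
    x <- nd$pa[[1L]]
    .acc(x, .c_blur3(nd$g, x$H, x$W))
  })
}

tUpsample2 <- function(tp, x) {
  .nd(tp, .c_upsample2(x$v, x$H, x$W), 2L * x$H, 2L * x$W, list(x), function(nd) {
    .acc(nd$pa[[1L]], .c_downsum2(nd$g, nd$H, nd$W))
  })
}

tAvgpool2 <- function(tp, x) {
  .nd(tp, .c_downsum2(x$v, x$H, x$W) / 4, x$H %/% 2L, x$W %/% 2L, list(x),
      function(nd) {
        .acc(nd$pa[[1L]], .c_upsample2(nd$g, nd$H, nd$W) / 4)
      })
}

## ---- multi-head attention --------------------------------------------------
## Tokens: (B*N) x C, batch b occupying rows ((b-1)N+1):(bN). Optional additive
## mask (N x N, 0 or -Inf) applied to attention logits of every batch and head.

tMHA <- function(tp, x, Wq, Wk, Wv, Wo, bq, bk, bv, bo, nheads, B, N, mask = NULL) {
  C <- ncol(x$v)
  dh <- C %/% nheads
  sc <- 1 / sqrt(dh)
  Q <- sweep(x$v %*% Wq$v, 2L, bq$v, "+")
  K <- sweep(x$v %*% Wk$v, 2L, bk$v, "+")
  V <- sweep(x$v %*% Wv$v, 2L, bv$v, "+")
  O <- matrix(0, nrow(x$v), C)
  A <- vector("list", B * nheads)
  for (b in seq_len(B)) {
    rows <- ((b - 1L) * N + 1L):(b * N)
    for (h in seq_len(nheads)) {
      cols <- ((h - 1L) * dh + 1L):(h * dh)
      S <- tcrossprod(Q[rows, cols, drop = FALSE], K[rows, cols, drop = FALSE]) * sc
      if (!is.null(mask)) S <- S + mask
      S <- S - apply(S, 1L, max)
      P <- exp(S)
      P <- P / rowSums(P)
      A[[(b - 1L) * nheads + h]] <- P
      O[rows, cols] <- P %*% V[rows, cols, drop = FALSE]
    }
  }
  v <- sweep(O %*% Wo$v, 2L, bo$v, "+")
  nd <- .nd(tp, v, x$H, x$W, list(x, Wq, Wk, Wv, Wo, bq, bk, bv, bo), function(nd) {
    x <- nd$pa[[1L]]
    Wq <- nd$pa[[2L]]; Wk <- nd$pa[[3L]]; Wv <- nd$pa[[4L]]; Wo <- nd$pa[[5L]]
    bq <- nd$pa[[6L]]; bkn <- nd$pa[[7L]]; bv <- nd$pa[[8L]]; bo <- nd$pa[[9L]]
    g <- nd$g
    .acc(Wo, crossprod(nd$O, g))
    .acc(bo, colSums(g))
    dO <- g %*% t(Wo$v)
    dQ <- matrix(0, nrow(dO), ncol(dO))
    dK <- dQ; dV <- dQ
    for (b in seq_len(nd$B)) {
      rows <- ((b - 1L) * nd$N + 1L):(b * nd$N)
      for (h in seq_len(nd$nheads)) {
        cols <- ((h - 1L) * nd$dh + 1L):(h * nd$dh)
        P <- nd$A[[(b - 1L) * nd$nheads + h]]
        dOb <- dO[rows, cols, drop = FALSE]
        Vb <- nd$V[rows, cols, drop = FALSE]
        dV[rows, cols] <- crossprod(P, dOb)
        dP <- tcrossprod(dOb, Vb)
        dS <- P * (dP - rowSums(dP * P))
        dQ[rows, cols] <- (dS %*% nd$K[rows, cols, drop = FALSE]) * nd$sc
        dK[rows, cols] <- (crossprod(dS, nd$Q[rows, cols, drop = FALSE])) * nd$sc
      }
    }
    .acc(Wq, crossprod(x$v, dQ)); .acc(bq, colSums(dQ))
    .acc(Wk, crossprod(x$v, dK)); .acc(bkn, colSums(dK))
    .acc(Wv, crossprod(x$v, dV)); .acc(bv, colSums(dV))
    if (is.null(x$const))
      .acc(x, dQ %*% t(Wq$v) + dK %*% t(Wk$v) + dV %*% t(Wv$v))
  })
  nd$Q <- Q; nd$K <- K; nd$V <- V; nd$O <- O; nd$A <- A
  nd$B <- B; nd$N <- N; nd$nheads <- nheads; nd$dh <- dh; nd$sc <- sc
  nd
}

## Add a learned positional embedding (N x C) to every batch block.
tAddPos <- function(tp, x, pos, B, N) {
  rep_pos <- pos$v[rep.int(seq_len(N), B), , drop = FALSE]
  nd <- .nd(tp, x$v + rep_pos, x$H, x$W, list(x, pos), function(nd) {
    .acc(nd$pa[[1L]], nd$g)
    gi <- rep.int(seq_len(nd$N), nd$B)
    .acc(nd$pa[[2L]], rowsum(nd$g, gi, reorder = TRUE))
  })
  nd$B <- B; nd$N <- N
  nd
}

## ---- losses (scalar outputs) -----------------------------------------------

## Soft Dice loss on a probability map node vs a fixed binary target.
tDiceLoss <- function(tp, p, target, eps) {
  t <- as.numeric(target)
  Sp <- sum(p$v); St <- sum(t); Spt <- sum(p$v * t)
  num <- 2 * Spt + eps
  den <- Sp + St + eps
  nd <- .nd(tp, 1 - num / den, NULL, NULL, list(p), function(nd) {
    dp <- -(2 * nd$t * nd$den - nd$num) / (nd$den^2)
    .acc(nd$pa[[1L]], as.numeric(nd$g) * matrix(dp, nrow(nd$pa[[1L]]$v)))
  })
  nd$t <- t; nd$num <- num; nd$den <- den
  nd
}

## Mean binary cross-entropy with logits (numerically stable).
tBceLoss <- function(tp, z, target) {
  t <- as.numeric(target)
  zv <- as.numeric(z$v)
  l <- mean(pmax(zv, 0) - t * zv + log1p(exp(-abs(zv))))
  nd <- .nd(tp, l, NULL, NULL, list(z), function(nd) {
    zv <- as.numeric(nd$pa[[1L]]$v)
    s <- 1 / (1 + exp(-zv))
    .acc(nd$pa[[1L]],
         as.numeric(nd$g) * matrix((s - nd$t) / length(zv), nrow(nd$pa[[1L]]$v)))
  })
  nd$t <- t
  nd
}

## Mean absolute error vs a fixed target.
tL1Loss <- function(tp, x, target) {
  t <- as.numeric(target)
  d <- as.numeric(x$v) - t
  nd <- .nd(tp, mean(abs(d)), NULL, NULL, list(x), function(nd) {
    .acc(nd$pa[[1L]],
         as.numeric(nd$g) * matrix(sign(nd$d) / length(nd$d), nrow(nd$pa[[1L]]$v)))
  })
  nd$d <- d
  nd
}

## Weighted sum of scalar nodes: sum(w_i * s_i).
tAffine <- function(tp, xs, w) {
  v <- sum(vapply(seq_along(xs), function(i) w[i] * as.numeric(xs[[i]]$v), 0))
  nd <- .nd(tp, v, NULL, NULL, xs, function(nd) {
    for (i in seq_along(nd$pa)) .acc(nd$pa[[i]], as.numeric(nd$g) * nd$w[i])
  })
  nd$w <- w
  nd
}
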