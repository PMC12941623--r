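## DSC metrics, k-fold protocol, fold-median/last-epoch-window aggregation,
## Nadeau-Bengio corrected paired t-test, Bonferroni thresholding.

#' Dice similarity coefficient
#'
#' \code{2|P intersect T| / (|P| + |T|)} between two binary masks. Two empty
#' masks score 1 (perfect agreement on absence: growth masks can
#' legitimately be empty).
#'
#' @param pred,truth binary matrices of one shape.
#' @return Score in [0, 1].
#' @examples
#' diceCoefficient(matrix(c(1,1,0,0),2), matrix(c(1,0,0,0),2))  # 2/3
#' @export
diceCoefficient <- function(pred, truth) {
  if (!identical(dim(pred), dim(truth)))
    stop("dimension error: masks must share one shape")
  if (!all(pred %in% c(0, 1)) || !all(truth %in% c(0, 1)))
    stop("validation error: masks must be binary")
  s <- sum(pred) + sum(truth)
  if (s == 0) return(1)
  2 * sum(pred * truth) / s
}

#' Randomized k-fold split by sample id
#'
#' Partitions n samples into k test folds whose sizes differ by at most one;
#' every sample appears in exactly one test fold. With n = 66 and k = 5 the
#' sorted fold sizes are 13/13/13/13/14.
#'
#' @param n sample count.
#' @param k fold count (2 <= k <= n).
#' @param seed RNG seed.
#' @return Integer vector of length n giving each sample's test fold.
#' @export
kfoldSplit <- function(n, k, seed = 1L) {
  if (k < 2L || n < k) stop("configuration error: need n >= k >= 2")
  set.seed(seed)
  sizes <- rep(n %/% k, k) + c(rep(1L, n %% k), rep(0L, k - n %% k))
  sample(rep(seq_len(k), times = sizes))
}

#' Aggregate per-eye per-epoch DSC into fold and cohort scores
#'
#' For each fold and each epoch of the trailing window, takes the median DSC
#' over the fold's test eyes, then averages those medians over the window;
#' cohort statistics are the mean and SD of the k per-fold scores.
#'
#' @param scores data.frame with columns \code{fold}, \code{eye},
#'   \code{epoch}, \code{dsc}.
#' @param window epochs to use: either a vector of epoch numbers or a single
#'   count meaning "the last that-many epochs present".
#' @return List with \code{perFold} (data.frame fold, score), \code{mean},
#'   \code{sd}.
#' @export
foldScoreSummary <- function(scores, window = 10L) {
  need <- c("fold", "eye", "epoch", "dsc")
  if (!all(need %in% names(scores)))
    stop("validation error: scores must have columns ",
         paste(need, collapse = ", "))
  epochs <- sort(unique(scores$epoch))
  if (length(window) == 1L && window <= length(epochs))
    window <- utils::tail(epochs, window)
  folds <- sort(unique(scores$fold))
  perFold <- vapply(folds, function(f) {
    sf <- scores[scores$fold == f, ]
    med <- vapply(window, function(e) {
      se <- sf[sf$epoch == e, ]
      if (nrow(se) == 0L)
        stop("validation error: fold ", f, " is missing epoch ", e)
      median(se$dsc)
    }, 0)
    mean(med)
  }, 0)
  list(perFold = data.frame(fold = folds, score = perFold),
       mean = mean(perFold), sd = sd(perFold))
}

#' Nadeau-Bengio corrected paired t-test
#'
#' Corrected resampled t-test for k-fold cross-validation: the variance of
#' the per-fold paired differences is inflated by \code{(1/k + r)} with
#' \code{r = n_test / n_train} to account for the overlap of training folds.
#' \code{t = mean(d) / sqrt((1/k + r) * var(d))}, two-sided p from the t
#' distribution with k - 1 degrees of freedom. At r = 0 this reduces exactly
#' to the classical paired t-test.
#'
#' @param d per-fold paired score differences (length k >= 2).
#' @param r test/train size ratio (1/4 for 5-fold CV).
#' @return An object of class \code{htest} with \code{statistic},
#'   \code{p.value}, \code{parameter} (df) and \code{estimate} (mean
#'   difference). Zero variance gives t = 0 / p = 1 when the mean is zero,
#'   and p = 0 with a degeneracy note otherwise.
#' @examples
#' nbCorrectedTTest(c(0.02, 0.03, 0.01, 0.04, 0.02), r = 0.25)
#' @export
nbCorrectedTTest <- function(d, r = 0.25) {
  k <- length(d)
  if (k < 2L) stop("configuration error: need at least 2 folds")
  if (r < 0) stop("configuration error: r must be >= 0")
  dbar <- mean(d)
  s2 <- var(d)
  degenerate <- FALSE
  if (s2 == 0) {
    if (dbar == 0) { tstat <- 0; p <- 1 } else { tstat <- Inf * sign(dbar); p <- 0 }
    degenerate <- TRUE
  } else {
    tstat <- dbar / sqrt((1 / k + r) * s2)
    p <- 2 * pt(-abs(tstat), df = k - 1)
  }
  structure(list(
    statistic = c(t = tstat), parameter = c(df = k - 1),
    p.value = p, estimate = c(`mean difference` = dbar),
    alternative = "two.sided",
    method = paste0("Nadeau-Bengio corrected paired t-test (r = ", r, ")",
                    if (degenerate) "; zero-variance degenerate case"),
    data.name = deparse(substitute(d))), class = "htest")
}

#' Bonferroni-corrected significance threshold
#'
#' @param alpha family-wise level in (0, 1).
#' @param m number of comparisons (>= 1).
#' @return \code{alpha / m}; 0.05 over 9 comparisons gives 0.0056 (4 dp).
#' @export
bonferroniThreshold <- function(alpha, m) {
  if (!(alpha > 0 && alpha < 1)) stop("configuration error: alpha must be in (0,1)")
  if (m < 1) stop("configuration error: m must be >= 1")
  alpha / m
}
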