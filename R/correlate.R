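# Correlation with permutation inference and bootstrap confidence
# intervals.

allPermutations <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- allPermutations(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(k) {
    cbind(k, sub + (sub >= k))
  }))
}

#' Correlation with permutation p-value and percentile bootstrap CI
#'
#' Pearson's r or Kendall's tau with a two-sided permutation p-value
#' obtained by shuffling \code{y}: when the full permutation space fits in
#' the requested budget (\code{factorial(n) <= nPerm}), the space is
#' enumerated and the p-value is exact; otherwise \code{nPerm} random
#' shuffles with the add-one estimator
#' \code{(1 + #(|r*| >= |r|)) / (1 + nPerm)} are used. The confidence
#' interval is the percentile bootstrap over \code{bBoot} pair resamples
#' (degenerate resamples are redrawn); it is widened, if ever needed, to
#' contain the point estimate.
#'
#' @param x,y numeric vectors of equal length >= 3, finite, non-constant.
#' @param method \code{"pearson"} or \code{"kendall"}.
#' @param nPerm permutation budget.
#' @param bBoot bootstrap resamples (default 1000).
#' @param confLevel confidence level (default 0.95).
#' @param seed integer seed.
#' @return A \linkS4class{CorrelationResult}.
#' @export
correlateWithInference <- function(x, y, method = c("pearson", "kendall"),
                                   nPerm = 999, bBoot = 1000,
                                   confLevel = 0.95, seed = 1L) {
  method <- match.arg(method)
  stopifnot(length(x) == length(y))
  n <- length(x)
  if (n < 3) stop("need at least 3 observations")
  if (!all(is.finite(x)) || !all(is.finite(y)))
    stop("inputs must be finite")
  if (sd(x) == 0 || sd(y) == 0) stop("zero-variance input")
  r <- cor(x, y, method = method)
  eps <- 1e-12
  exhaustive <- factorial(n) <= nPerm
  if (exhaustive) {
    perms <- allPermutations(n)
    rstar <- apply(perms, 1, function(p) cor(x, y[p], method = method))
    permP <- mean(abs(rstar) >= abs(r) - eps)
    nPermUsed <- nrow(perms)
  } else {
    rstar <- withSeed(deriveSeed(seed, "correlate-perm"),
                      vapply(seq_len(nPerm), function(i)
                        cor(x, sample(y), method = method), 0))
    permP <- (1 + sum(abs(rstar) >= abs(r) - eps)) / (1 + nPerm)
    nPermUsed <- nPerm
  }
  rb <- withSeed(deriveSeed(seed, "correlate-boot"), {
    vapply(seq_len(bBoot), function(i) {
      repeat {
        idx <- sample.int(n, n, replace = TRUE)
        if (sd(x[idx]) > 0 && sd(y[idx]) > 0)
          return(cor(x[idx], y[idx], method = method))
      }
    }, 0)
  })
  a <- (1 - confLevel) / 2
  ci <- pctl(rb, c(a, 1 - a))
  ci <- c(min(ci[1], r), max(ci[2], r))
  new("CorrelationResult", method = method, estimate = r, permP = permP,
      ci = ci, confLevel = confLevel, nPerm = as.integer(nPermUsed),
      bBoot = as.integer(bBoot), n = as.integer(n),
      seed = as.integer(seed), exhaustive = exhaustive)
}
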