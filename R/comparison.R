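# Cross-resolution comparison machinery: symmetric percent difference,
# mean +/- sample-SD summaries, and the exact Wilcoxon signed-rank test.

#' Symmetric percent difference
#'
#' \eqn{|a - b| / ((a + b)/2) \times 100}: the absolute difference relative
#' to the pair mean. Symmetric in its arguments and scale-invariant; zero
#' iff the two values are equal.
#'
#' @param a,b non-negative quantities (vectorized) with \code{a + b > 0}.
#' @return Percent difference(s) on the 0-200 scale.
#' @examples
#' pct_diff(1.018, 0.9988)   # 1.904
#' @export
pct_diff <- function(a, b) {
  if (any(a + b <= 0)) stop("`a + b` must be positive")
  abs(a - b) / ((a + b) / 2) * 100
}

#' Mean and sample standard deviation
#'
#' Arithmetic mean and the n-1 (sample) standard deviation.
#'
#' @param values numeric vector of length >= 2.
#' @return Named numeric vector \code{c(mean = , sd = )}.
#' @examples
#' mean_sd(c(2.658, 2.555, 2.491, 2.474))  # 2.5445, 0.0833
#' @export
mean_sd <- function(values) {
  if (length(values) < 2L) stop("need at least 2 values")
  c(mean = mean(values), sd = stats::sd(values))
}

#' Exact Wilcoxon signed-rank test
#'
#' Paired two-sided Wilcoxon signed-rank test with the classical exact
#' conventions: zero differences are dropped, tied absolute differences are
#' mid-ranked, and for \code{n_eff <= 25} the two-sided p-value is computed
#' from the exact null distribution over all \eqn{2^n} sign assignments
#' (counted by a generating-function convolution over the doubled, integer
#' ranks): \eqn{p = P(|W^* - \mu| \ge |W - \mu|)}. Above 25 pairs a normal
#' approximation with tie correction and continuity correction is used.
#'
#' @param a,b equal-length (>= 2) paired numeric vectors.
#' @return An object of class \code{wilcoxon_result}: \code{statistic} (W,
#'   the sum of positive-difference ranks), \code{n_effective},
#'   \code{p_value}, and \code{method} ("exact" or "normal approximation").
#' @examples
#' wilcoxon_signed_rank(2:9, 1:8)$p_value  # 0.0078125
#' @export
wilcoxon_signed_rank <- function(a, b) {
  if (length(a) != length(b) || length(a) < 2L)
    stop("`a` and `b` must be paired vectors of equal length >= 2")
  d <- a - b
  d <- d[d != 0]
  n <- length(d)
  if (n == 0L) {
    message("wilcoxon_signed_rank: all differences are zero; degenerate result")
    return(structure(list(statistic = 0, n_effective = 0L, p_value = 1,
                          method = "degenerate"), class = "wilcoxon_result"))
  }
  r <- rank(abs(d))               # mid-ranks for ties
  W <- sum(r[d > 0])
  mu <- n * (n + 1) / 4
  if (n <= 25L) {
    w2 <- as.integer(round(2 * r))          # doubled ranks are integers
    total <- sum(w2)
    # counts over achievable doubled rank-sums 0..total
    cnt <- numeric(total + 1)
    cnt[1] <- 1
    for (w in w2) {
      shifted <- c(numeric(w), cnt[seq_len(total + 1 - w)])
      cnt <- cnt + shifted
    }
    dev <- abs(2 * W - total / 2)
    s <- 0:total
    p <- sum(cnt[abs(s - total / 2) >= dev - 1e-9]) / 2^n
    method <- "exact"
  } else {
    sigma <- sqrt(sum(r^2) / 4)
    z <- (abs(W - mu) - 0.5) / sigma
    p <- min(1, 2 * stats::pnorm(-z))
    method <- "normal approximation"
  }
  structure(list(statistic = W, n_effective = n, p_value = p, method = method),
            class = "wilcoxon_result")
}

#' @export
print.wilcoxon_result <- function(x, ...) {
  cat(sprintf("Wilcoxon signed-rank: W = %g, n = %d, p = %g (%s)\n",
              x$statistic, x$n_effective, x$p_value, x$method))
  invisible(x)
}
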