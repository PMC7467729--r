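# Spectrum and subtype-rate statistics: bootstrap proportion CI with a
# pseudo-count, error-propagated foldback inversion rates, Fisher's exact
# test and the Mann-Whitney U test.

#' Bootstrap confidence interval for a proportion
#'
#' `B` resamples of size `n` are drawn with replacement from the `n` observed
#' 0/1 GCR-type observations (1 = foldback inversion); the proportion per
#' resample is its mean, and the 95% interval is the empirical 0.025/0.975
#' quantile of the resampled proportions. When the foldback or non-foldback
#' count is zero, a pseudo-count of one observation of the missing class is
#' added before resampling (n increases by one), avoiding degenerate 0-0 or
#' 1-1 intervals. Resampled success counts are drawn as Binomial(n, k/n),
#' which is the exact distribution of a with-replacement resample of iid 0/1
#' observations.
#'
#' @param k foldback inversion count (successes).
#' @param n total GCR count.
#' @param B number of bootstrap resamples (default 100000).
#' @param seed integer seed.
#' @return a list of class `proportion_ci`: `k`, `n`, `pseudo_applied`, `p`,
#'   `p_lo`, `p_hi`, `B`.
#' @export
bootstrap_proportion_ci <- function(k, n, B = 100000L, seed = 1L) {
  stopifnot(n >= 1L, k >= 0L)
  if (k > n) stop("k must not exceed n")
  pseudo <- (k == 0L || k == n)
  k2 <- if (k == 0L) 1L else k
  n2 <- if (pseudo) n + 1L else n
  set.seed(as.integer(seed))
  p_hat <- k2 / n2
  draws <- stats::rbinom(B, n2, p_hat) / n2
  qs <- stats::quantile(draws, c(0.025, 0.975), names = FALSE, type = 1)
  out <- list(k = k, n = n, pseudo_applied = pseudo,
              p = p_hat, p_lo = qs[1], p_hi = qs[2], B = as.integer(B))
  class(out) <- "proportion_ci"
  out
}

#' Propagate rate and proportion uncertainty into a subtype rate
#'
#' Combines a total GCR rate `r` (95% CI `r_lo..r_hi`) with a foldback
#' inversion proportion `p` (95% CI `p_lo..p_hi`) into the foldback inversion
#' rate `q` with propagated bounds:
#' \deqn{q = r p}
#' \deqn{q_{lo} = q - q \sqrt{((r - r_{lo})/r)^2 + ((p - p_{lo})/p)^2}}
#' \deqn{q_{hi} = q + q \sqrt{((r - r_{hi})/r)^2 + ((p - p_{hi})/p)^2}}
#' With a degenerate proportion (p = p_lo = p_hi = 1) the bounds collapse to
#' the rate CI. A negative `q_lo` is floored at zero and flagged.
#'
#' @param rate a `rate_estimate` or list with `r`, `r_lo`, `r_hi`.
#' @param prop a `proportion_ci` or list with `p`, `p_lo`, `p_hi`.
#' @return a list of class `subtype_rate`: `q`, `q_lo`, `q_hi`, `floored`.
#' @export
propagate_subtype_rate <- function(rate, prop) {
  r <- rate$r; r_lo <- rate$r_lo; r_hi <- rate$r_hi
  p <- prop$p; p_lo <- prop$p_lo; p_hi <- prop$p_hi
  if (is.null(r) || r <= 0) {
    stop("r must be positive; for all-zero fluctuation data use the boundary",
         " rate handling in estimate_rate")
  }
  if (is.null(p) || p <= 0) {
    stop("p must be positive; apply the pseudo-count path in ",
         "bootstrap_proportion_ci for zero counts")
  }
  q <- r * p
  q_lo <- q - q * sqrt(((r - r_lo) / r)^2 + ((p - p_lo) / p)^2)
  q_hi <- q + q * sqrt(((r - r_hi) / r)^2 + ((p - p_hi) / p)^2)
  floored <- q_lo < 0
  if (floored) q_lo <- 0
  out <- list(q = q, q_lo = q_lo, q_hi = q_hi, floored = floored)
  class(out) <- "subtype_rate"
  out
}

#' Two-sided Fisher's exact test for a 2x2 table
#'
#' Exact two-sided p-value by point-probability summation: with margins
#' fixed, sums the hypergeometric probabilities of all tables whose point
#' probability does not exceed that of the observed table (relative tolerance
#' 1 + 1e-7 on the comparison, the dominant software convention).
#'
#' @param table a 2x2 matrix (or something coercible) of non-negative counts.
#' @return the two-sided p-value in (0, 1].
#' @export
fisher_exact_2x2 <- function(table) {
  tb <- matrix(as.numeric(unlist(table)), nrow = 2)
  if (any(tb < 0)) stop("table entries must be non-negative")
  if (sum(tb) == 0) stop("at least one margin must be positive")
  a <- tb[1, 1]
  m <- sum(tb[1, ])       # row 1 total
  n2 <- sum(tb[2, ])      # row 2 total
  kk <- sum(tb[, 1])      # column 1 total
  lo <- max(0, kk - n2)
  hi <- min(kk, m)
  x <- lo:hi
  d <- stats::dhyper(x, m, n2, kk)
  p_obs <- stats::dhyper(a, m, n2, kk)
  p <- sum(d[d <= p_obs * (1 + 1e-7)])
  min(1, p)
}

#' Two-sided Mann-Whitney U test
#'
#' Exact when `min(n1, n2) <= 8` and there are no ties (using the exact
#' rank-sum distribution); otherwise a normal approximation with the tie
#' correction of the rank variance. Two-sided in both cases.
#'
#' @param x,y numeric samples (both non-empty).
#' @return the two-sided p-value.
#' @export
mann_whitney_u <- function(x, y) {
  if (length(x) == 0L || length(y) == 0L) stop("both samples must be ",
                                               "non-empty")
  n1 <- length(x); n2 <- length(y)
  rk <- rank(c(x, y))
  u <- sum(rk[seq_len(n1)]) - n1 * (n1 + 1) / 2
  ties <- any(duplicated(c(x, y)))
  if (min(n1, n2) <= 8L && !ties) {
    p <- 2 * min(stats::pwilcox(u, n1, n2),
                 1 - stats::pwilcox(u - 1, n1, n2))
    return(min(1, p))
  }
  nn <- n1 + n2
  tie_tab <- table(c(x, y))
  sigma2 <- (n1 * n2 / 12) *
    ((nn + 1) - sum(tie_tab^3 - tie_tab) / (nn * (nn - 1)))
  mu <- n1 * n2 / 2
  if (sigma2 <= 0) return(1)
  z <- (u - mu) / sqrt(sigma2)
  2 * stats::pnorm(-abs(z))
}
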