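# Luria-Delbruck fluctuation analysis: the distribution of mutant counts
# across parallel cultures under random (pre-plating) mutation, its pmf
# recursion, sampling, and Ma-Sandri-Sarkar maximum-likelihood estimation of
# m (expected mutations per culture).

#' Luria-Delbruck probability mass function
#'
#' Computes `P(R = r)` for `r = 0..r_max` by the standard recursion
#' `p_0 = exp(-m)`, `p_r = (m/r) * sum_{i=0}^{r-1} p_i / (r - i + 1)`.
#' The distribution is heavy-tailed (`P(R > r) ~ m/r`), so the recursion is
#' truncated at `r_max`; the missing tail mass is approximately `m / r_max`
#' and is handled analytically where needed (see
#' [simulate_fluctuation_experiment()]).
#'
#' @param m expected mutations per culture (> 0).
#' @param r_max truncation point of the recursion.
#' @return numeric vector of length `r_max + 1` with `P(R = 0..r_max)`.
#' @export
ld_pmf <- function(m, r_max = 10000L) {
  stopifnot(m > 0, r_max >= 0L)
  p <- numeric(r_max + 1L)
  p[1] <- exp(-m)
  if (r_max >= 1L) {
    for (r in seq_len(r_max)) {
      i <- 0:(r - 1L)
      p[r + 1L] <- (m / r) * sum(p[i + 1L] / (r - i + 1L))
    }
  }
  p
}

#' Simulate a fluctuation experiment
#'
#' Draws mutant counts for parallel cultures from the Luria-Delbruck
#' distribution with parameter `m` by inverse-CDF sampling on the pmf
#' recursion. Draws falling beyond the recursion truncation use the
#' asymptotic tail `P(R > r) ~ m/r`, i.e. `r = ceiling(m / (1 - u))`.
#'
#' @param m expected mutations per culture (> 0).
#' @param n_cultures number of parallel cultures (>= 1).
#' @param seed integer seed.
#' @param r_max pmf truncation point.
#' @return integer vector of mutant counts, one per culture.
#' @export
simulate_fluctuation_experiment <- function(m, n_cultures, seed = 1L,
                                            r_max = 10000L) {
  stopifnot(m > 0, n_cultures >= 1L)
  set.seed(as.integer(seed))
  cdf <- cumsum(ld_pmf(m, r_max))
  u <- stats::runif(n_cultures)
  counts <- findInterval(u, cdf)  # = r when cdf[r] < u <= cdf[r+1]
  over <- which(u > cdf[r_max + 1L])
  if (length(over) > 0L) {
    counts[over] <- as.integer(ceiling(m / (1 - u[over])))
  }
  as.integer(counts)
}

#' Estimate a mutation rate by fluctuation analysis
#'
#' Maximum-likelihood estimation of `m` (expected mutations per culture) over
#' the Luria-Delbruck pmf (Ma-Sandri-Sarkar), by golden-section search on
#' `log m`. The 95% confidence interval uses the standard log-scale
#' approximation `sigma_lnm = 1.225 * m^-0.315 / sqrt(C)` (C = number of
#' cultures), `exp(ln m +/- 1.96 sigma)`. The rate per cell division is
#' `r = m / N` for `N` cells per culture. Counts are winsorized at
#' `count_cap` before likelihood evaluation ("jackpot" cultures carry little
#' additional information about m and would make the recursion unbounded).
#'
#' The zero-fraction (p0) estimator `m = -ln(P(R = 0))` is reported alongside
#' when any culture has zero mutants. If all cultures are zero the MLE is at
#' the boundary: `m = 0`, with `m_hi` from the exact p0 bound
#' `P(all C zero) = exp(-m C) = 0.025`.
#'
#' @param counts integer mutant counts, one per culture (>= 5 cultures).
#' @param n_cells cells per culture, `N` (scales m into the rate r).
#' @param count_cap winsorization bound for the likelihood.
#' @return a list of class `rate_estimate`: `m`, `m_lo`, `m_hi`, `m_p0`,
#'   `r`, `r_lo`, `r_hi`, `n_cultures`, `all_zero`.
#' @export
estimate_rate <- function(counts, n_cells = 1, count_cap = 1000L) {
  if (length(counts) < 5L) stop("need at least 5 cultures")
  stopifnot(all(counts >= 0), n_cells > 0)
  cc <- as.integer(pmin(counts, count_cap))
  n_c <- length(cc)
  frac_zero <- mean(cc == 0L)
  m_p0 <- if (frac_zero > 0 && frac_zero < 1) -log(frac_zero) else NA_real_

  if (all(cc == 0L)) {
    m_hi <- -log(0.025) / n_c
    out <- list(m = 0, m_lo = 0, m_hi = m_hi, m_p0 = NA_real_,
                r = 0, r_lo = 0, r_hi = m_hi / n_cells,
                n_cultures = n_c, all_zero = TRUE)
    class(out) <- "rate_estimate"
    return(out)
  }

  r_need <- max(cc)
  tab <- table(cc)
  vals <- as.integer(names(tab))
  wts <- as.numeric(tab)
  negll <- function(logm) {
    p <- ld_pmf(exp(logm), r_need)
    -sum(wts * log(pmax(p[vals + 1L], 1e-300)))
  }
  opt <- golden_minimize(negll, log(1e-4), log(50), tol = 1e-6)
  m <- exp(opt$x)
  sigma <- 1.225 * m^(-0.315) / sqrt(n_c)
  m_lo <- exp(log(m) - 1.96 * sigma)
  m_hi <- exp(log(m) + 1.96 * sigma)
  out <- list(m = m, m_lo = m_lo, m_hi = m_hi, m_p0 = m_p0,
              r = m / n_cells, r_lo = m_lo / n_cells, r_hi = m_hi / n_cells,
              n_cultures = n_c, all_zero = FALSE)
  class(out) <- "rate_estimate"
  out
}

# Derivative-free golden-section minimization on [a, b]
golden_minimize <- function(f, a, b, tol = 1e-6) {
  gr <- (sqrt(5) - 1) / 2
  x1 <- b - gr * (b - a)
  x2 <- a + gr * (b - a)
  f1 <- f(x1)
  f2 <- f(x2)
  while (b - a > tol) {
    if (f1 < f2) {
      b <- x2; x2 <- x1; f2 <- f1
      x1 <- b - gr * (b - a); f1 <- f(x1)
    } else {
      a <- x1; x1 <- x2; f1 <- f2
      x2 <- a + gr * (b - a); f2 <- f(x2)
    }
  }
  x <- (a + b) / 2
  list(x = x, value = f(x))
}
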