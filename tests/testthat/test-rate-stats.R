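test_that("fluctuation rate estimation matches its analytic anchors", {
  # exactly half the cultures empty: p0 estimator gives m = ln 2
  counts <- c(rep(0L, 12L), rep(4L, 12L))
  est <- estimate_rate(counts)
  expect_equal(est$m_p0, log(2), tolerance = 1e-9)
  expect_true(est$m > 0)

  # all-zero boundary: zero rate with a finite upper bound from p0
  az <- estimate_rate(rep(0L, 20L), n_cells = 1e8)
  expect_true(az$all_zero)
  expect_equal(az$r, 0)
  expect_equal(az$r_hi, -log(0.025) / 20 / 1e8)
  expect_gt(az$r_hi, 0)

  expect_error(estimate_rate(c(0L, 1L)), "at least 5")

  # rate scales with cells per culture
  c2 <- simulate_fluctuation_experiment(1, 200L, seed = 9L)
  e1 <- estimate_rate(c2, n_cells = 1)
  e2 <- estimate_rate(c2, n_cells = 1e7)
  expect_equal(e1$m, e2$m)
  expect_equal(e2$r, e1$r / 1e7)
  expect_true(e2$r_lo <= e2$r && e2$r <= e2$r_hi)
})

test_that("bootstrap proportion CI matches the exact binomial resample law", {
  ci <- bootstrap_proportion_ci(15L, 20L, B = 100000L, seed = 2L)
  expect_false(ci$pseudo_applied)
  expect_equal(ci$p, 0.75)
  expect_lte(abs(ci$p_lo - qbinom(0.025, 20, 0.75) / 20), 1 / 20)
  expect_lte(abs(ci$p_hi - qbinom(0.975, 20, 0.75) / 20), 1 / 20)

  # degenerate counts trigger the pseudo-count of one added observation
  top <- bootstrap_proportion_ci(10L, 10L, B = 50000L, seed = 3L)
  expect_true(top$pseudo_applied)
  expect_equal(top$p, 10 / 11)
  expect_equal(top$p_hi, 1)              # (10/11)^11 ~ 0.35 > 0.025
  expect_lt(top$p_lo, 1)
  bot <- bootstrap_proportion_ci(0L, 12L, B = 50000L, seed = 3L)
  expect_true(bot$pseudo_applied)
  expect_equal(bot$p, 1 / 13)
  expect_equal(bot$p_lo, 0)
  expect_gt(bot$p_hi, 0)

  expect_error(bootstrap_proportion_ci(5L, 3L), "exceed")
  ci2 <- bootstrap_proportion_ci(3L, 7L, B = 20000L, seed = 5L)
  expect_true(ci2$p_lo >= 0 && ci2$p_lo <= ci2$p && ci2$p <= ci2$p_hi &&
                ci2$p_hi <= 1)
})

test_that("subtype-rate propagation follows the printed equations", {
  # degenerate proportion: q inherits the rate CI exactly
  rate <- list(r = 3.2e-10, r_lo = 1.9e-10, r_hi = 5.4e-10)
  prop1 <- list(p = 1, p_lo = 1, p_hi = 1)
  q1 <- propagate_subtype_rate(rate, prop1)
  expect_equal(q1$q, rate$r)
  expect_equal(q1$q_lo, rate$r_lo)
  expect_equal(q1$q_hi, rate$r_hi)

  # worked example evaluated independently
  q2 <- propagate_subtype_rate(list(r = 100, r_lo = 80, r_hi = 130),
                               list(p = 0.5, p_lo = 0.3, p_hi = 0.7))
  expect_equal(q2$q, 50)
  expect_equal(q2$q_lo, 50 - 50 * sqrt(0.2^2 + 0.4^2), tolerance = 1e-12)
  expect_equal(q2$q_hi, 75)

  # zero-width CIs propagate to a zero-width interval
  q3 <- propagate_subtype_rate(list(r = 10, r_lo = 10, r_hi = 10),
                               list(p = 0.5, p_lo = 0.5, p_hi = 0.5))
  expect_equal(c(q3$q_lo, q3$q, q3$q_hi), c(5, 5, 5))

  # scale equivariance in the rate
  base <- propagate_subtype_rate(list(r = 2, r_lo = 1, r_hi = 4),
                                 list(p = 0.4, p_lo = 0.2, p_hi = 0.6))
  for (c_mult in c(0.5, 3, 1e-9)) {
    sc <- propagate_subtype_rate(
      list(r = 2 * c_mult, r_lo = 1 * c_mult, r_hi = 4 * c_mult),
      list(p = 0.4, p_lo = 0.2, p_hi = 0.6)
    )
    expect_equal(sc$q, base$q * c_mult)
    expect_equal(sc$q_lo, base$q_lo * c_mult)
    expect_equal(sc$q_hi, base$q_hi * c_mult)
  }

  expect_error(propagate_subtype_rate(list(r = 0, r_lo = 0, r_hi = 0),
                                      list(p = 0.5, p_lo = 0.2, p_hi = 0.9)),
               "boundary")
  expect_error(propagate_subtype_rate(rate, list(p = 0, p_lo = 0, p_hi = 0)),
               "pseudo-count")
})

test_that("fisher exact matches the base-R oracle across random small tables", {
  expect_equal(fisher_exact_2x2(matrix(c(1, 1, 1, 1), 2)), 1)
  expect_error(fisher_exact_2x2(matrix(c(-1, 1, 1, 1), 2)), "non-negative")
  set.seed(33)
  for (i in seq_len(200)) {
    tab <- matrix(rpois(4, sample(1:8, 1)), 2)
    if (sum(tab) == 0) next
    expect_equal(fisher_exact_2x2(tab), stats::fisher.test(tab)$p.value,
                 tolerance = 1e-10)
  }
})

test_that("mann-whitney is exact for small untied samples and approximate otherwise", {
  expect_equal(mann_whitney_u(c(1, 2, 3), c(4, 5, 6)), 0.1)
  expect_equal(mann_whitney_u(c(7, 8, 9), c(7, 8, 9)), 1)
  set.seed(44)
  x <- rnorm(50)
  y <- rnorm(50, mean = 2)
  expect_lt(mann_whitney_u(x, y), 1e-3)
  expect_error(mann_whitney_u(numeric(0), 1:3), "non-empty")
  # cross-check the exact branch against the base-R oracle
  for (i in seq_len(50)) {
    a <- sample(1:1000, sample(3:8, 1))
    b <- sample(seq(0.5, 999.5, by = 1), sample(3:8, 1))  # never ties with a
    expect_equal(mann_whitney_u(a, b),
                 stats::wilcox.test(a, b, exact = TRUE)$p.value,
                 tolerance = 1e-10)
  }
})
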