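test_that("correlation Bayes factors reproduce default-prior reference values", {
  # Jeffreys closed-form approximation as an independent sanity bound
  jeffreys <- function(r, n) 1 / (sqrt((2 * n - 3) / pi) *
                                    (1 - r^2)^((n - 4) / 2))
  for (r in c(0, 0.2, 0.4, -0.5)) {
    for (n in c(20, 29, 60)) {
      bf <- bf10_correlation(r, n)
      expect_lt(abs(bf - jeffreys(r, n)) / jeffreys(r, n), 0.15)
    }
  }
})

test_that("the Bayes factor is symmetric in the sign of r", {
  for (r in c(0.1, 0.43, 0.8)) {
    expect_equal(bf10_correlation(r, 29), bf10_correlation(-r, 29),
                 tolerance = 1e-8)
  }
})

test_that("the Bayes factor is monotone in |r| and in n as expected", {
  rs <- seq(0, 0.9, by = 0.1)
  bfs <- vapply(rs, bf10_correlation, 0, n = 29)
  expect_true(all(diff(bfs) > 0))
  ns <- c(10, 20, 40, 80)
  bf_n <- vapply(ns, function(n) bf10_correlation(0.4, n), 0)
  expect_true(all(diff(bf_n) > 0))           # evidence accumulates at r != 0
  bf_null <- vapply(ns, function(n) bf10_correlation(0, n), 0)
  expect_true(all(diff(bf_null) < 0))        # the null gains at r = 0
})

test_that("perfect correlations return the infinite-evidence sentinel", {
  expect_identical(bf10_correlation(1, 29), Inf)
  expect_identical(bf10_correlation(-1, 29), Inf)
  expect_error(bf10_correlation(0.5, 3), "at least 4")
  expect_error(bf10_correlation(1.2, 29), "exceed")
})

test_that("quadrature agrees with an importance-sampled marginal likelihood", {
  set.seed(1234)
  M <- 1e6
  rho <- runif(M, -1, 1)                     # draws from the uniform prior
  for (r in c(-0.6, -0.3, 0, 0.3, 0.6)) {
    for (n in c(10, 25, 40, 60, 100)) {
      w <- exp(gradcptr:::.log_lik_rho(rho, r, n) -
                 gradcptr:::.log_lik_rho(0, r, n))
      mc <- mean(w)
      se <- sd(w) / sqrt(M)
      expect_lt(abs(bf10_correlation(r, n) - mc), 3 * se)
    }
  }
})

test_that("credible intervals are symmetric at r = 0 and widen with level", {
  ci <- rho_credible_interval(0, 29)
  expect_equal(ci[1], -ci[2], tolerance = 1e-3)
  w95 <- diff(rho_credible_interval(0, 29))
  w99 <- diff(rho_credible_interval(0, 29, level = 0.99))
  expect_gt(w99, w95)
  # with a weak likelihood the interval approaches the full support
  wide <- rho_credible_interval(0, 4, level = 0.999999)
  expect_lt(wide[1], -0.99)
  expect_gt(wide[2], 0.99)
  expect_error(rho_credible_interval(0.5, 29, level = 1), "level")
})

test_that("a 95% CI excluding zero implies BF10 above 1, and conversely at r=0", {
  for (r in c(0.3, 0.45, 0.6)) {
    for (n in c(20, 29, 50)) {
      ci <- rho_credible_interval(r, n)
      if (ci[1] > 0) expect_gt(bf10_correlation(r, n), 1)
    }
  }
  ci0 <- rho_credible_interval(0, 29)
  expect_lt(ci0[1], 0)
  expect_gt(ci0[2], 0)
})

test_that("the JZS paired-t Bayes factor behaves as a default two-sided test", {
  expect_lt(bf10_paired_t(0, 29), 1)
  ts <- c(0.5, 1, 2, 3, 5)
  bfs <- vapply(ts, bf10_paired_t, 0, n = 29)
  expect_true(all(diff(bfs) > 0))
  expect_gt(bf10_paired_t(5, 29), 100)
  expect_equal(bf10_paired_t(2, 29), bf10_paired_t(-2, 29), tolerance = 1e-8)
  expect_error(bf10_paired_t(1, 1), "at least 2")
})

test_that("evidence labels follow the conventional cut points", {
  expect_equal(evidence_label(12), "strong-H1")
  expect_equal(evidence_label(10), "strong-H1")
  expect_equal(evidence_label(5), "moderate-H1")
  expect_equal(evidence_label(3), "moderate-H1")
  expect_equal(evidence_label(1), "absent")
  expect_equal(evidence_label(1 / 3), "moderate-H0")
  expect_equal(evidence_label(0.2), "moderate-H0")
  expect_equal(evidence_label(1 / 10), "strong-H0")
  expect_equal(evidence_label(0.05), "strong-H0")
  expect_equal(evidence_label(Inf), "strong-H1")
  expect_error(evidence_label(0), "positive")
})

test_that("cor_bf matches cor.test on data and the printed-r pathway", {
  set.seed(99)
  x <- rnorm(25)
  y <- x + rnorm(25)
  ct <- cor.test(x, y)
  cb <- cor_bf(x, y)
  expect_equal(cb$r, unname(ct$estimate))
  expect_equal(cb$p_two_tailed, ct$p.value)
  expect_equal(cb$bf10, bf10_correlation(cb$r, 25))
  # identity and anti-identity
  expect_equal(cor_bf(x, x)$r, 1)
  expect_identical(cor_bf(x, x)$bf10, Inf)
  expect_equal(cor_bf(x, -x)$r, -1)
  # the printed-r pathway reproduces a published p-value
  cb2 <- cor_bf(r = 0.50, n = 25)
  expect_equal(cb2$p_two_tailed, 0.011, tolerance = 0.02)
  expect_error(cor_bf(x, rep(1, 25)), "degenerate")
  expect_error(cor_bf(r = 0.5), "supply")
})
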