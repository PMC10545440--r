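# double-gamma evaluated directly, the reference for regressor tests
ref_hrf <- function(t, dt = 0.1) {
  g <- function(t) dgamma(t, shape = 6, scale = 1) -
    dgamma(t, shape = 16, scale = 1) / 6
  peak <- max(g(seq(0, 32, by = dt)))
  ifelse(t >= 0 & t <= 32, g(pmax(t, 0)) / peak, 0)
}

test_that("the canonical HRF peaks near 5 s, starts at zero, undershoots late", {
  dt <- 0.1
  h <- canonical_hrf(dt)
  t <- seq(0, 32, by = dt)
  expect_equal(h[1], 0)
  expect_equal(max(h), 1)
  expect_lt(abs(t[which.max(h)] - 5), dt + 1e-9)
  expect_lt(min(h), 0)
  expect_gt(t[which.min(h)], t[which.max(h)])
  expect_error(canonical_hrf(0), "dt")
})

test_that("a single stick equals the HRF delayed by its onset on the scan grid", {
  tb <- raw_trials(c("Go"), 0.6, soa = 0.8)
  tb$onset <- 10
  regs <- stick_regressors(tb, dt = 0.1, tr = 2, n_scans = 30, t0 = 10)
  scan_t <- 10 + (0:29) * 2
  expect_equal(regs$hit$values, ref_hrf(scan_t - 10), tolerance = 1e-9)
  # classes with no trials are identically zero
  expect_true(all(regs$FA$values == 0))
  expect_true(all(regs$CR$values == 0))
  expect_true(all(regs$miss$values == 0))
})

test_that("stick regressors are linear: two impulses superpose", {
  tb <- raw_trials(c("Go", "Go"), c(0.6, 0.6), soa = 0.8)
  tb$onset <- c(4, 12)
  both <- stick_regressors(tb, n_scans = 25, t0 = 10)$hit
  one <- function(on) {
    t1 <- tb[1, , drop = FALSE]
    t1$onset <- on
    attr(t1, "soa") <- 0.8
    class(t1) <- c("gradcpt_trials", "data.frame")
    stick_regressors(t1, n_scans = 25, t0 = 10)$hit$values
  }
  expect_equal(both$values, one(4) + one(12), tolerance = 1e-10)
})

test_that("convolve-then-downsample agrees with the analytic superposition", {
  sch <- make_schedule(60, 0.8, seed = 8)
  set.seed(9)
  w <- runif(nrow(sch), 0, 2)
  reg <- vtc_regressor(w, sch, dt = 0.1, tr = 2, n_scans = 25, t0 = 10)
  scan_t <- 10 + (0:24) * 2
  direct <- vapply(scan_t, function(tt) sum(w * ref_hrf(tt - sch$onset)), 0)
  expect_equal(reg$values, direct, tolerance = 1e-8)
})

test_that("the VTC regressor is linear in its amplitudes", {
  sch <- make_schedule(40, 0.8, seed = 2)
  set.seed(3)
  a <- runif(nrow(sch)); b <- runif(nrow(sch))
  ra <- vtc_regressor(a, sch, n_scans = 20, t0 = 10)$values
  rb <- vtc_regressor(b, sch, n_scans = 20, t0 = 10)$values
  rab <- vtc_regressor(2 * a + 3 * b, sch, n_scans = 20, t0 = 10)$values
  expect_equal(rab, 2 * ra + 3 * rb, tolerance = 1e-10)
  expect_true(all(vtc_regressor(numeric(nrow(sch)), sch, n_scans = 20,
                                t0 = 10)$values == 0))
})

test_that("a constant VTC is proportional to the all-trials stick regressor", {
  sch <- make_schedule(40, 0.8, seed = 6)
  const <- vtc_regressor(rep(0.7, nrow(sch)), sch, n_scans = 20, t0 = 10)
  unit <- vtc_regressor(rep(1, nrow(sch)), sch, n_scans = 20, t0 = 10)
  expect_equal(const$values, 0.7 * unit$values, tolerance = 1e-10)
})

test_that("a 400-s run at TR 2 s yields a 200-sample regressor", {
  sch <- make_schedule(400, 0.8, seed = 1)
  reg <- vtc_regressor(rep(1, 500), sch, tr = 2, n_scans = 200, t0 = 10)
  expect_length(reg$values, 200)
  expect_error(vtc_regressor(rep(1, 10), sch, n_scans = 200, t0 = 10),
               "match")
})

test_that("the 128-s discrete-cosine basis has floor(2*N*tr/cutoff) columns", {
  expect_equal(ncol(highpass_basis(200, 2)), 6)
  expect_equal(ncol(highpass_basis(100, 2, cutoff = 100)), 4)
  expect_error(highpass_basis(100, 2, cutoff = 3), "cutoff")
})

test_that("residualizing against the basis removes slow trends, keeps noise", {
  n <- 200
  X <- cbind(1, highpass_basis(n, 2))
  # a pure linear trend is almost entirely explained by the basis
  trend <- seq(0, 1, length.out = n)
  res <- lm.fit(X, trend)$residuals
  expect_lt(sum(res^2) / sum((trend - mean(trend))^2), 0.01)
  # white noise loses only K+1 of N degrees of freedom
  set.seed(12)
  eps <- rnorm(n)
  res_e <- lm.fit(X, eps)$residuals
  expect_gt(sum(res_e^2) / sum(eps^2), 0.9)
})

test_that("design matrices round-trip through the TSV writer", {
  sch <- make_schedule(40, 0.8, seed = 3)
  reg <- vtc_regressor(rep(1, nrow(sch)), sch, n_scans = 15, t0 = 10)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_design_matrix(list(vtc = reg,
                           drift1 = highpass_basis(15, 2, cutoff = 20)[, 1]),
                      f)
  back <- read.table(f, header = TRUE, sep = "\t")
  expect_equal(back$vtc, reg$values, tolerance = 1e-12)
  expect_equal(nrow(back), 15)
})
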