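#' Fill in RTs for response-absent trials by linear interpolation
#'
#' Miss and correct-rejection trials carry no RT; for the variance time
#' course every trial needs one, so absent RTs are linearly interpolated in
#' trial time between the nearest preceding and following observed RTs.
#' Leading and trailing gaps take the nearest observed value. `rt_source`
#' is set to `"interpolated"` for filled trials.
#'
#' @param table A `gradcpt_trials` table with at least 2 observed RTs.
#' @return The table with a complete `rt` column.
#' @export
interpolate_rts <- function(table) {
  stopifnot(inherits(table, "gradcpt_trials"))
  obs <- which(table$rt_source == "observed")
  if (length(obs) < 2) stop("need at least 2 observed RTs to interpolate")
  filled <- stats::approx(table$onset[obs], table$rt[obs],
                          xout = table$onset, rule = 2)$y
  miss <- is.na(table$rt)
  table$rt[miss] <- filled[miss]
  table$rt_source[miss] <- "interpolated"
  table
}

#' Variance time course: absolute z-scored RTs
#'
#' z-scores the full per-run RT series (mean 0, sample SD 1, denominator
#' n - 1) and returns absolute values. Both unusually quick and unusually
#' slow responses map to large values, so the series indexes moment-to-
#' moment attentional fluctuation. Invariant under affine RT
#' transformations `rt -> a*rt + b`, `a > 0`.
#'
#' @param rts Complete numeric RT series for one run (length >= 3,
#'   non-constant).
#' @return Non-negative numeric vector, same length.
#' @examples
#' compute_vtc(c(1, 2, 3))  # 1 0 1
#' @export
compute_vtc <- function(rts) {
  rts <- as.numeric(rts)
  if (length(rts) < 3) stop("need at least 3 RTs")
  if (anyNA(rts)) stop("RT series must be complete; see interpolate_rts()")
  s <- stats::sd(rts)
  if (s == 0) stop("degenerate RT series: zero spread")
  abs((rts - mean(rts)) / s)
}

#' Smooth a VTC with a Gaussian kernel
#'
#' Convolves the trialwise series with a discrete Gaussian of
#' \eqn{\sigma = \mathrm{FWHM} / (2\sqrt{2\ln 2})} seconds, i.e.
#' \eqn{\sigma/\mathrm{SOA}} trials, truncated at \eqn{\pm 4\sigma} and
#' renormalized where the support is cut by the series edges. Output
#' length equals input length; a constant series is returned unchanged.
#'
#' @param raw_vtc Numeric series on the uniform trial grid.
#' @param soa Trial spacing, seconds.
#' @param fwhm Kernel full width at half maximum, seconds (default 7).
#' @return Smoothed series, same length.
#' @export
smooth_vtc <- function(raw_vtc, soa, fwhm = 7) {
  if (fwhm <= 0) stop("'fwhm' must be positive")
  if (soa <= 0) stop("'soa' must be positive")
  sigma <- fwhm / (2 * sqrt(2 * log(2))) / soa   # in trials
  h <- ceiling(4 * sigma)
  k <- stats::dnorm(-h:h, 0, sigma)
  n <- length(raw_vtc)
  out <- numeric(n)
  for (i in seq_len(n)) {
    j <- max(1, i - h):min(n, i + h)
    w <- k[j - i + h + 1]
    out[i] <- sum(w * raw_vtc[j]) / sum(w)
  }
  out
}

#' Estimate the dominant fluctuation frequency of a session's VTCs
#'
#' For each run the smoothed VTC is mean-centred and its discrete-Fourier
#' amplitude spectrum evaluated at frequencies \eqn{k/(N\,\mathrm{soa})};
#' spectra are averaged across runs (interpolated onto the grid of the
#' longest run when trial counts differ) and the frequency of the maximum
#' amplitude within `band` is returned.
#'
#' @param vtcs A numeric vector (one run) or list of vectors (smoothed VTC
#'   per run).
#' @param soa Trial spacing, seconds.
#' @param band Search band in Hz (default `c(0.005, 0.10)`); must lie
#'   within the resolvable range `[1/(N*soa), 1/(2*soa)]`.
#' @return The peak frequency (Hz), with the averaged spectrum attached as
#'   attributes `freq` and `amplitude`.
#' @export
fluctuation_frequency <- function(vtcs, soa, band = c(0.005, 0.10)) {
  if (is.numeric(vtcs)) vtcs <- list(vtcs)
  stopifnot(length(vtcs) >= 1, soa > 0)
  n_max <- max(lengths(vtcs))
  f_grid <- seq_len(floor(n_max / 2)) / (n_max * soa)
  if (band[1] < 1 / (n_max * soa) - 1e-12 || band[2] > 1 / (2 * soa) + 1e-12)
    stop(sprintf("band outside resolvable range [%.4g, %.4g] Hz",
                 1 / (n_max * soa), 1 / (2 * soa)))
  spec <- rowMeans(vapply(vtcs, function(v) {
    n <- length(v)
    amp <- Mod(stats::fft(v - mean(v)))[1 + seq_len(floor(n / 2))] / n
    f <- seq_len(floor(n / 2)) / (n * soa)
    if (n == n_max) amp
    else stats::approx(f, amp, xout = f_grid, rule = 2)$y
  }, numeric(length(f_grid))))
  in_band <- f_grid >= band[1] & f_grid <= band[2]
  if (!any(in_band)) stop("no Fourier frequency falls inside 'band'")
  peak <- f_grid[in_band][which.max(spec[in_band])]
  structure(peak, freq = f_grid, amplitude = spec)
}
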