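#' Canonical double-gamma hemodynamic response function
#'
#' \eqn{h(t) = g(t; 6, 1) - g(t; 16, 1)/6} with \eqn{g} the gamma density
#' parameterized by delay (shape) and dispersion (scale): response peak
#' near 5 s, undershoot peak near 15 s, ratio 1/6, sampled on
#' `[0, duration]` at step `dt` and normalized to unit peak.
#'
#' @param dt Sampling step, seconds (0 < dt <= 1).
#' @param duration Kernel support, seconds (default 32).
#' @return Numeric kernel vector of length `duration/dt + 1`.
#' @export
canonical_hrf <- function(dt, duration = 32) {
  if (dt <= 0 || dt > 1) stop("'dt' must be in (0, 1]")
  t <- seq(0, duration, by = dt)
  h <- stats::dgamma(t, shape = 6, scale = 1) -
    stats::dgamma(t, shape = 16, scale = 1) / 6
  h / max(h)
}

new_regressor <- function(values, dt, t0) {
  structure(list(values = as.numeric(values), dt = dt, t0 = t0),
            class = "gradcpt_regressor")
}

#' @export
print.gradcpt_regressor <- function(x, ...) {
  cat(sprintf("regressor: %d samples, step %.3g s, first sample at %.3g s\n",
              length(x$values), x$dt, x$t0))
  invisible(x)
}

# impulse train at `onsets` with weights, on a fine dt grid; convolved with
# the canonical HRF and read off at the scan times t0 + k*tr
.convolve_sample <- function(onsets, weights, span, dt, tr, n_scans, t0) {
  keep <- onsets >= 0 & onsets <= span
  if (any(!keep)) {
    warning(sprintf("%d onset(s) beyond the run span dropped", sum(!keep)))
    onsets <- onsets[keep]; weights <- weights[keep]
  }
  n_fine <- ceiling((max(span, t0 + (n_scans - 1) * tr) + 32) / dt) + 1
  u <- numeric(n_fine)
  if (length(onsets)) {
    i <- round(onsets / dt) + 1
    for (k in seq_along(i)) u[i[k]] <- u[i[k]] + weights[k]
  }
  h <- canonical_hrf(dt)
  conv <- stats::filter(c(numeric(length(h) - 1), u), h,
                        method = "convolution", sides = 1)
  conv <- as.numeric(conv)[length(h) - 1 + seq_len(n_fine)]
  scan_idx <- round((t0 + (seq_len(n_scans) - 1) * tr) / dt) + 1
  new_regressor(conv[scan_idx], tr, t0)
}

#' Stick-function regressors per trial outcome, convolved with the HRF
#'
#' Builds one regressor per outcome class (hit, miss, FA, CR): unit
#' impulses at the class's trial onsets on a fine `dt` grid, convolved with
#' [canonical_hrf()], then sampled at the scan times `t0 + k*tr`. A class
#' with no trials yields an all-zero regressor.
#'
#' @param table A classified `gradcpt_trials` table.
#' @param dt Fine grid step, seconds (default 0.1).
#' @param tr Scan repetition time, seconds (default 2).
#' @param n_scans Number of retained scans.
#' @param t0 Time of the first retained scan relative to run start,
#'   seconds; default 10 s = 5 discarded volumes at TR 2 s.
#' @return Named list of 4 `gradcpt_regressor` objects.
#' @export
stick_regressors <- function(table, dt = 0.1, tr = 2, n_scans, t0 = 10) {
  stopifnot(inherits(table, "gradcpt_trials"), n_scans > 0)
  span <- max(table$onset)
  out <- lapply(c(hit = "hit", miss = "miss", FA = "FA", CR = "CR"),
                function(cls) {
    on <- table$onset[table$outcome == cls]
    .convolve_sample(on, rep(1, length(on)), span, dt, tr, n_scans, t0)
  })
  out
}

#' Amplitude-modulated VTC regressor on the scan grid
#'
#' The non-smoothed variance time course weights an impulse at each trial
#' onset; the train is convolved with [canonical_hrf()] and downsampled to
#' the scan grid (TR = 2 s by default, i.e. 0.5 Hz). This is the regressor
#' used to locate BOLD signal changes tracking trial-by-trial RT
#' variability.
#'
#' @param raw_vtc Non-smoothed VTC, one value per trial of `schedule`.
#' @param schedule The run's `gradcpt_schedule`.
#' @inheritParams stick_regressors
#' @return A `gradcpt_regressor`.
#' @export
vtc_regressor <- function(raw_vtc, schedule, dt = 0.1, tr = 2, n_scans,
                          t0 = 10) {
  stopifnot(inherits(schedule, "gradcpt_schedule"))
  if (length(raw_vtc) != nrow(schedule))
    stop("length of 'raw_vtc' must match the number of trials")
  .convolve_sample(schedule$onset, raw_vtc, max(schedule$onset),
                   dt, tr, n_scans, t0)
}

#' Discrete-cosine high-pass drift basis
#'
#' Basis functions \eqn{c_k(t) = \cos(\pi k (2t+1) / (2N))},
#' \eqn{k = 1..K} with \eqn{K = \lfloor 2 N\,\mathrm{tr} / \mathrm{cutoff}
#' \rfloor}: residualizing a series against this basis plus a constant
#' removes fluctuations with period longer than `cutoff`.
#'
#' @param n_scans Number of scans N (> 2).
#' @param tr Repetition time, seconds.
#' @param cutoff High-pass cutoff period, seconds (default 128; must be
#'   >= 2*tr).
#' @return N x K matrix of drift regressors.
#' @examples
#' ncol(highpass_basis(200, 2))  # 6
#' @export
highpass_basis <- function(n_scans, tr, cutoff = 128) {
  stopifnot(n_scans > 2)
  if (cutoff < 2 * tr) stop("'cutoff' must be at least 2*tr")
  K <- floor(2 * n_scans * tr / cutoff)
  t <- 0:(n_scans - 1)
  vapply(seq_len(K), function(k) cos(pi * k * (2 * t + 1) / (2 * n_scans)),
         numeric(n_scans))
}

#' Write a design matrix as tab-separated text
#'
#' One column per regressor, one row per scan.
#'
#' @param regressors Named list of `gradcpt_regressor` objects and/or
#'   numeric columns of equal length.
#' @param path File path.
#' @export
write_design_matrix <- function(regressors, path) {
  cols <- lapply(regressors, function(r)
    if (inherits(r, "gradcpt_regressor")) r$values else as.numeric(r))
  utils::write.table(as.data.frame(cols), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
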