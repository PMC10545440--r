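#' Analyze a gradCPT session
#'
#' The main fitting-style entry point: takes the stimulus schedules and
#' keypress logs of one participant's session (one or more runs at a
#' common SOA) and runs the full behavioral analysis — keypress-to-trial
#' assignment, outcome classification, pooled performance metrics,
#' per-run variance time courses (raw and smoothed) and the cross-run
#' fluctuation-frequency estimate.
#'
#' @param schedules A `gradcpt_schedule` or list of them (one per run).
#' @param logs A keypress vector or list of them, parallel to `schedules`.
#' @param fwhm Gaussian smoothing kernel FWHM for the VTC, seconds
#'   (default 7).
#' @param band Spectral search band for the fluctuation frequency, Hz
#'   (default `c(0.005, 0.10)`).
#' @return An object of class `"gradcpt_session"`: list with `trials`
#'   (list of `gradcpt_trials`), `metrics` (a `gradcpt_metrics`, with
#'   `fluct_freq` filled), `vtc` (per run: list with `trial_times`, `raw`,
#'   `smoothed`), `spectrum` (averaged amplitude spectrum), `soa`, `fwhm`,
#'   `band`.
#' @examples
#' sch <- lapply(1:2, function(i) make_schedule(400, 0.8, seed = i))
#' logs <- lapply(1:2, function(i)
#'   simulate_observer(sch[[i]], observer_params(seed = 100 + i)))
#' fit <- gradcpt_session(sch, logs)
#' fit
#' coef(fit)
#' @export
gradcpt_session <- function(schedules, logs, fwhm = 7,
                            band = c(0.005, 0.10)) {
  if (inherits(schedules, "gradcpt_schedule")) schedules <- list(schedules)
  if (!is.list(logs)) logs <- list(logs)
  if (length(schedules) != length(logs))
    stop("'schedules' and 'logs' must have the same length")
  soa <- attr(schedules[[1]], "soa")

  trials <- mapply(assign_presses, schedules, logs, SIMPLIFY = FALSE)
  metrics <- session_metrics(trials)

  vtc <- lapply(trials, function(tb) {
    full <- interpolate_rts(tb)
    raw <- compute_vtc(full$rt)
    list(trial_times = tb$onset, raw = raw,
         smoothed = smooth_vtc(raw, soa, fwhm))
  })
  freq <- fluctuation_frequency(lapply(vtc, `[[`, "smoothed"), soa, band)
  metrics$fluct_freq <- as.numeric(freq)

  structure(list(trials = trials, metrics = metrics, vtc = vtc,
                 spectrum = data.frame(freq = attr(freq, "freq"),
                                       amplitude = attr(freq, "amplitude")),
                 soa = soa, fwhm = fwhm, band = band),
            class = "gradcpt_session")
}

#' @export
print.gradcpt_session <- function(x, ...) {
  cat(sprintf("gradCPT session: %d run(s), SOA %.3g s, %d trials\n",
              length(x$trials), x$soa, sum(vapply(x$trials, nrow, 0L))))
  print(x$metrics)
  invisible(x)
}

#' @export
summary.gradcpt_session <- function(object, ...) {
  m <- object$metrics
  per_run <- do.call(rbind, lapply(seq_along(object$trials), function(i) {
    tb <- object$trials[[i]]
    data.frame(run = i,
               n_trials = nrow(tb),
               hit = sum(tb$outcome == "hit"),
               miss = sum(tb$outcome == "miss"),
               FA = sum(tb$outcome == "FA"),
               CR = sum(tb$outcome == "CR"),
               discarded = attr(tb, "n_discarded"),
               ignored = attr(tb, "n_ignored"))
  }))
  out <- list(per_run = per_run, metrics = m)
  class(out) <- "summary.gradcpt_session"
  out
}

#' @export
print.summary.gradcpt_session <- function(x, ...) {
  print(x$metrics)
  cat("per-run outcome counts:\n")
  print(x$per_run, row.names = FALSE)
  invisible(x)
}

#' @export
coef.gradcpt_session <- function(object, ...) {
  m <- object$metrics
  c(hit_rate = m$hit_rate, fa_rate = m$fa_rate, d_prime = m$d_prime,
    median_rt = m$median_rt, fluct_freq = m$fluct_freq)
}

#' Plot a session's variance time courses
#'
#' One panel per run: raw |z|-RT values (points) and the 7-s-FWHM smoothed
#' VTC (line), with false-alarm trials marked.
#'
#' @param x A `gradcpt_session`.
#' @param runs Which runs to draw (default all).
#' @param ... Passed to [graphics::plot()].
#' @export
plot.gradcpt_session <- function(x, runs = seq_along(x$vtc), ...) {
  op <- graphics::par(mfrow = c(length(runs), 1),
                      mar = c(4, 4, 1.5, 1))
  on.exit(graphics::par(op))
  for (i in runs) {
    v <- x$vtc[[i]]
    graphics::plot(v$trial_times, v$raw, pch = 16, cex = 0.3,
                   col = "grey60", xlab = "time (s)", ylab = "|z(RT)|",
                   main = sprintf("run %d", i), ...)
    graphics::lines(v$trial_times, v$smoothed, lwd = 2)
    fa <- x$trials[[i]]$outcome == "FA"
    graphics::points(v$trial_times[fa], v$raw[fa], pch = 4, col = 2)
  }
  invisible(x)
}
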