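#' Signal-detection sensitivity d'
#'
#' \eqn{d' = \Phi^{-1}(h) - \Phi^{-1}(f)} where the hit rate \eqn{h} and
#' false-alarm rate \eqn{f} are first clipped to
#' \eqn{[1/(2N),\, 1 - 1/(2N)]} with the respective trial counts, the
#' standard correction that keeps d' finite at ceiling or floor
#' performance.
#'
#' @param hit_rate,fa_rate Proportions in \[0, 1\].
#' @param n_go,n_nogo Numbers of Go and No-go trials (> 0).
#' @return d' (dimensionless). Antisymmetric: `d_prime(h, f, a, b) ==
#'   -d_prime(f, h, b, a)`.
#' @examples
#' d_prime(0.741, 0.238, 1e6, 1e6)  # 1.36
#' @export
d_prime <- function(hit_rate, fa_rate, n_go, n_nogo) {
  if (any(n_go <= 0) || any(n_nogo <= 0)) stop("trial counts must be positive")
  if (any(hit_rate < 0 | hit_rate > 1 | fa_rate < 0 | fa_rate > 1))
    stop("rates must be in [0, 1]")
  clip <- function(p, n) pmin(1 - 1 / (2 * n), pmax(1 / (2 * n), p))
  stats::qnorm(clip(hit_rate, n_go)) - stats::qnorm(clip(fa_rate, n_nogo))
}

#' Session-level gradCPT performance metrics
#'
#' Pools outcome counts over the runs of a session, then computes hit rate,
#' false-alarm rate, d' (from the pooled rates) and the median of observed
#' (non-interpolated) RTs. The fluctuation-frequency slot is filled by
#' [gradcpt_session()], which also builds the variance time courses.
#'
#' @param tables A `gradcpt_trials` table or a list of them (one per run).
#' @return A list of class `"gradcpt_metrics"`: `hit_rate`, `fa_rate`,
#'   `d_prime`, `median_rt` (s), `fluct_freq` (Hz, `NA` here), `n_go`,
#'   `n_nogo`.
#' @export
session_metrics <- function(tables) {
  if (inherits(tables, "gradcpt_trials")) tables <- list(tables)
  stopifnot(all(vapply(tables, inherits, TRUE, "gradcpt_trials")))
  out <- do.call(rbind, lapply(tables, as.data.frame))
  n_go <- sum(out$category == "Go")
  n_nogo <- sum(out$category == "NoGo")
  if (n_go == 0) stop("no Go trials in session")
  hit_rate <- sum(out$outcome == "hit") / n_go
  fa_rate <- if (n_nogo > 0) sum(out$outcome == "FA") / n_nogo else 0
  rts <- out$rt[out$rt_source == "observed"]
  structure(list(
    hit_rate = hit_rate, fa_rate = fa_rate,
    d_prime = d_prime(hit_rate, fa_rate, n_go, max(n_nogo, 1L)),
    median_rt = stats::median(rts),
    fluct_freq = NA_real_, n_go = n_go, n_nogo = n_nogo),
    class = "gradcpt_metrics")
}

#' @export
print.gradcpt_metrics <- function(x, ...) {
  cat(sprintf(paste0("gradCPT session metrics: hit %.1f%%, FA %.1f%%, ",
                     "d' %.2f, median RT %.0f ms, freq %s Hz\n"),
              100 * x$hit_rate, 100 * x$fa_rate, x$d_prime,
              1000 * x$median_rt,
              ifelse(is.na(x$fluct_freq), "NA",
                     sprintf("%.4f", x$fluct_freq))))
  invisible(x)
}
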