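#' Parameters of the latent fluctuating-attention observer
#'
#' The synthetic observer responds to a gradCPT schedule with a reaction
#' time (RT) whose noise magnitude is modulated by a slow sinusoidal
#' attentional state \eqn{s(t) = \sin(2\pi f_0 t + \phi)}. On trial \eqn{n}
#' at onset \eqn{t_n} the RT noise SD is
#' \eqn{\sigma_n = \sigma_0 (1 + m\, s(t_n))}, so the magnitude envelope of
#' the absolute z-scored RT series (the variance time course) fluctuates at
#' \eqn{f_0}. Lapses couple to the same state: the miss probability on Go
#' trials is \eqn{\mathrm{clamp}(p_\mathrm{miss} + k_\mathrm{miss}\, m\,
#' s(t_n))} and the commission (false-alarm) probability on No-go trials is
#' \eqn{\mathrm{clamp}(p_\mathrm{fa} + k_\mathrm{fa}\, m\, s(t_n))}.
#'
#' Defaults emulate the visual-task regime: mean Go RT 625 ms, baseline RT
#' noise SD 60 ms, attentional fluctuation at 0.032 Hz with modulation
#' depth 0.6. After response assignment these yield session hit rates near
#' 92% and false-alarm rates near 23% (commissions plus ambiguous-press
#' reassignments), with median RT near 625 ms.
#'
#' @param mu_rt Mean Go reaction time, seconds.
#' @param sigma0 Baseline RT noise SD, seconds (> 0).
#' @param mod_depth Modulation depth \eqn{m \in [0, 1)}.
#' @param f0 Attentional fluctuation frequency, Hz.
#' @param phase Phase of the latent sinusoid, radians.
#' @param p_fa_base Baseline commission probability on No-go trials.
#' @param fa_slope Coupling of the latent state to commission probability.
#' @param p_miss_base Baseline miss probability on Go trials.
#' @param miss_slope Coupling of the latent state to miss probability.
#' @param seed Integer seed; identical seeds give identical logs.
#' @return A list of class `"observer_params"`.
#' @export
observer_params <- function(mu_rt = 0.625, sigma0 = 0.06, mod_depth = 0.6,
                            f0 = 0.032, phase = 0,
                            p_fa_base = 0.12, fa_slope = 0.3,
                            p_miss_base = 0.03, miss_slope = 0.3,
                            seed = NULL) {
  if (sigma0 <= 0) stop("'sigma0' must be positive")
  if (mod_depth < 0 || mod_depth >= 1) stop("'mod_depth' must be in [0, 1)")
  if (f0 <= 0) stop("'f0' must be positive")
  for (p in c(p_fa_base, p_miss_base))
    if (p < 0 || p > 1) stop("probabilities must be in [0, 1]")
  structure(list(mu_rt = mu_rt, sigma0 = sigma0, mod_depth = mod_depth,
                 f0 = f0, phase = phase, p_fa_base = p_fa_base,
                 fa_slope = fa_slope, p_miss_base = p_miss_base,
                 miss_slope = miss_slope, seed = seed),
            class = "observer_params")
}

# RT floor: physiological lower bound, keeps simulated RTs positive
.RT_FLOOR <- 0.05

#' Simulate an observer's keypress log for a schedule
#'
#' Draws one keypress log from the latent fluctuating-attention model (see
#' [observer_params()]). Misses emit no press at all; commissions on No-go
#' trials follow the same RT law as Go responses. RTs are floored at 50 ms.
#'
#' @param schedule A [make_schedule()] object.
#' @param params An [observer_params()] object.
#' @return Numeric vector of press times (seconds, sorted increasing),
#'   class `"keypress_log"`.
#' @examples
#' sch <- make_schedule(400, 0.8, seed = 1)
#' log <- simulate_observer(sch, observer_params(seed = 1))
#' @export
simulate_observer <- function(schedule, params) {
  stopifnot(inherits(schedule, "gradcpt_schedule"),
            inherits(params, "observer_params"))
  if (!is.null(params$seed)) set.seed(params$seed)
  t_n <- schedule$onset
  s <- sin(2 * pi * params$f0 * t_n + params$phase)
  sigma_n <- params$sigma0 * (1 + params$mod_depth * s)
  clamp <- function(p) pmin(1, pmax(0, p))
  p_press <- ifelse(schedule$category == "Go",
                    1 - clamp(params$p_miss_base +
                              params$miss_slope * params$mod_depth * s),
                    clamp(params$p_fa_base +
                          params$fa_slope * params$mod_depth * s))
  pressed <- stats::runif(length(t_n)) < p_press
  rt <- pmax(.RT_FLOOR,
             params$mu_rt + stats::rnorm(length(t_n), 0, sigma_n))
  presses <- sort((t_n + rt)[pressed])
  structure(presses, class = "keypress_log")
}

#' Write or read a keypress log
#'
#' Single-column tab-separated file of press times in run-relative seconds.
#'
#' @param presses A `keypress_log` (numeric vector of press times).
#' @param path File path.
#' @export
write_keypresses <- function(presses, path) {
  utils::write.table(
    data.frame(press_time = sprintf("%.6f", as.numeric(presses))),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_keypresses
#' @export
read_keypresses <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t")
  if (!"press_time" %in% names(df))
    stop(sprintf("malformed keypress file '%s': need column press_time", path))
  structure(sort(df$press_time), class = "keypress_log")
}

#' Simulate a BOLD series coupled to a regressor
#'
#' Returns `coupling * regressor + Normal(0, noise_sd)` on the same scan
#' grid — a minimal generative surface for testing that ordinary least
#' squares on the amplitude-modulated regressor recovers the coupling.
#'
#' @param regressor A [vtc_regressor()] / [stick_regressors()] output
#'   (class `"gradcpt_regressor"`).
#' @param coupling Dimensionless coupling coefficient.
#' @param noise_sd SD of additive white noise (>= 0).
#' @param seed Integer seed.
#' @return A `gradcpt_regressor` holding the simulated series.
#' @export
simulate_bold <- function(regressor, coupling, noise_sd, seed = NULL) {
  stopifnot(inherits(regressor, "gradcpt_regressor"))
  if (length(regressor$values) == 0) stop("empty regressor")
  if (noise_sd < 0) stop("'noise_sd' must be non-negative")
  if (!is.null(seed)) set.seed(seed)
  vals <- coupling * regressor$values +
    stats::rnorm(length(regressor$values), 0, noise_sd)
  new_regressor(vals, regressor$dt, regressor$t0)
}
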