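#' Generate a gradCPT stimulus schedule
#'
#' Builds the trial sequence for one run of a gradual-onset continuous
#' performance task (gradCPT). Stimuli cross-fade continuously: each
#' stimulus fades in over one stimulus onset asynchrony (SOA) and fades out
#' over the next, so trial onsets are uniformly spaced at `soa` starting at
#' time 0 and a 400-s run yields `floor(run_duration / soa)` trials (250 at
#' SOA 1.6 s, 500 at SOA 0.8 s). Most trials are frequent Go stimuli that
#' require a button press; a minority are rare No-go stimuli for which the
#' response must be withheld.
#'
#' Exemplars (e.g. 10 city and 10 mountain scenes, or 10 male and 10 female
#' voices) are drawn uniformly within their category with the constraint
#' that the same exemplar never appears on two consecutive trials.
#'
#' @param run_duration Run length in seconds (default 400).
#' @param soa Stimulus onset asynchrony in seconds (1.6 for the auditory
#'   task, 0.8 for the visual task).
#' @param nogo_rate Probability that a trial is No-go (default 0.1).
#' @param n_go_exemplars,n_nogo_exemplars Number of distinct exemplars per
#'   category (>= 2 so the no-immediate-repeat rule is satisfiable).
#' @param seed Optional integer seed; identical seeds give identical
#'   schedules.
#' @param exact_counts If `TRUE`, the number of No-go trials is fixed at
#'   `round(nogo_rate * n_trials)` and their positions are a random
#'   permutation; if `FALSE` (default) each trial is independently No-go
#'   with probability `nogo_rate`.
#'
#' @return An object of class `"gradcpt_schedule"`: a data.frame with
#'   columns `onset` (s), `category` (`"Go"`/`"NoGo"`) and `exemplar`
#'   (integer id, 0-based within category), and attributes `run_duration`,
#'   `soa` and `nogo_rate`.
#' @examples
#' sch <- make_schedule(400, 0.8, seed = 1)
#' nrow(sch)          # 500 trials
#' table(sch$category)
#' @export
make_schedule <- function(run_duration = 400, soa = 0.8, nogo_rate = 0.1,
                          n_go_exemplars = 10, n_nogo_exemplars = 10,
                          seed = NULL, exact_counts = FALSE) {
  if (!is.numeric(run_duration) || run_duration <= 0)
    stop("'run_duration' must be positive")
  if (!is.numeric(soa) || soa <= 0 || soa > run_duration)
    stop("'soa' must be positive and no longer than the run")
  if (nogo_rate < 0 || nogo_rate > 1)
    stop("'nogo_rate' must be in [0, 1]")
  if (n_go_exemplars < 2 || n_nogo_exemplars < 2)
    stop("need at least 2 exemplars per category")
  if (!is.null(seed)) set.seed(seed)

  n <- floor(run_duration / soa)
  onsets <- (seq_len(n) - 1) * soa
  if (exact_counts) {
    k <- round(nogo_rate * n)
    is_nogo <- logical(n)
    is_nogo[sample.int(n, k)] <- TRUE
  } else {
    is_nogo <- stats::runif(n) < nogo_rate
  }
  category <- ifelse(is_nogo, "NoGo", "Go")

  # exemplar draw: uniform within category, excluding the immediately
  # preceding exemplar (of either category) when it shares the pool index
  n_ex <- ifelse(is_nogo, n_nogo_exemplars, n_go_exemplars)
  exemplar <- integer(n)
  prev_cat <- ""
  prev_ex <- -1L
  for (i in seq_len(n)) {
    pool <- 0:(n_ex[i] - 1L)
    if (identical(prev_cat, category[i])) pool <- setdiff(pool, prev_ex)
    exemplar[i] <- if (length(pool) == 1L) pool else sample(pool, 1L)
    prev_cat <- category[i]
    prev_ex <- exemplar[i]
  }

  out <- data.frame(onset = onsets, category = category, exemplar = exemplar,
                    stringsAsFactors = FALSE)
  attr(out, "run_duration") <- run_duration
  attr(out, "soa") <- soa
  attr(out, "nogo_rate") <- nogo_rate
  class(out) <- c("gradcpt_schedule", "data.frame")
  out
}

#' @export
print.gradcpt_schedule <- function(x, ...) {
  cat(sprintf("gradCPT schedule: %d trials, SOA %.3g s, run %.4g s, %d NoGo (%.1f%%)\n",
              nrow(x), attr(x, "soa"), attr(x, "run_duration"),
              sum(x$category == "NoGo"),
              100 * mean(x$category == "NoGo")))
  invisible(x)
}

#' Write or read a schedule as a BIDS-style events table
#'
#' The on-disk format is a tab-separated file with columns `onset`,
#' `duration`, `trial_type` and `stim_id`; `duration` is the full
#' cross-fade span (2 SOA: one SOA fade-in, one fade-out). Times are
#' run-relative seconds.
#'
#' @param schedule A `gradcpt_schedule`.
#' @param path File path.
#' @return `read_events` returns a `gradcpt_schedule`.
#' @export
write_events <- function(schedule, path) {
  stopifnot(inherits(schedule, "gradcpt_schedule"))
  soa <- attr(schedule, "soa")
  df <- data.frame(onset = sprintf("%.6f", schedule$onset),
                   duration = sprintf("%.6f", rep(2 * soa, nrow(schedule))),
                   trial_type = schedule$category,
                   stim_id = schedule$exemplar)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_events
#' @param run_duration,nogo_rate Metadata not stored in the events file;
#'   `run_duration` defaults to last onset + one SOA.
#' @export
read_events <- function(path, run_duration = NULL, nogo_rate = NA_real_) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  need <- c("onset", "duration", "trial_type", "stim_id")
  if (!all(need %in% names(df)))
    stop(sprintf("malformed events file '%s': need columns %s", path,
                 paste(need, collapse = ", ")))
  soa <- if (nrow(df) > 1) df$onset[2] - df$onset[1] else df$duration[1] / 2
  out <- data.frame(onset = df$onset, category = df$trial_type,
                    exemplar = df$stim_id, stringsAsFactors = FALSE)
  attr(out, "run_duration") <- if (is.null(run_duration))
    df$onset[nrow(df)] + soa else run_duration
  attr(out, "soa") <- soa
  attr(out, "nogo_rate") <- nogo_rate
  class(out) <- c("gradcpt_schedule", "data.frame")
  out
}
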