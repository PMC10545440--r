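#' Assign key presses to gradCPT trials
#'
#' Implements the response-assignment rule for gradual-onset stimuli, where
#' each stimulus fades in over one SOA (appearance phase) and fades out
#' over the next (disappearance phase). The response window of the trial
#' with onset \eqn{t_n} runs from 70% of the appearance phase to 40% of the
#' disappearance phase, i.e. \eqn{[t_n + 0.7\,\mathrm{SOA},\; t_n +
#' 1.4\,\mathrm{SOA})}. Every press inside a window is attributed to that
#' trial; if a trial collects several presses the shortest RT is kept and
#' the surplus discarded. Presses falling in the gap between consecutive
#' windows, \eqn{[t_n + 1.4\,\mathrm{SOA},\; t_n + 1.7\,\mathrm{SOA})},
#' are ambiguous and treated as responses to an adjacent trial: they go to
#' trial \eqn{n} if it has no response yet, otherwise to trial \eqn{n+1} if
#' that one has none, otherwise they are discarded. All intervals are
#' half-open so a press at a boundary belongs to exactly one region.
#'
#' Presses before the first window or beyond the run end plus two SOAs are
#' ignored with a warning.
#'
#' @param schedule A [make_schedule()] schedule.
#' @param presses A sorted numeric vector of press times (seconds), e.g. a
#'   `keypress_log`.
#' @return A `gradcpt_trials` data.frame with one row per trial: columns
#'   `trial`, `onset`, `category`, `rt` (seconds, `NA` when no response),
#'   `outcome` (`hit`/`miss`/`FA`/`CR`) and `rt_source`
#'   (`observed`/`absent`). Attributes `soa`, `n_discarded` (surplus +
#'   unassignable gap presses) and `n_ignored` (out-of-range presses)
#'   record the fate of every input press.
#' @examples
#' sch <- make_schedule(2.4, 0.8, nogo_rate = 0, seed = 1)
#' assign_presses(sch, c(0.9, 1.20))  # gap press goes to trial 1
#' @export
assign_presses <- function(schedule, presses) {
  stopifnot(inherits(schedule, "gradcpt_schedule"))
  presses <- as.numeric(presses)
  if (is.unsorted(presses)) stop("'presses' must be sorted")
  soa <- attr(schedule, "soa")
  onsets <- schedule$onset
  n <- length(onsets)

  run_end <- attr(schedule, "run_duration")
  late <- presses >= run_end + 2 * soa
  early <- presses < onsets[1] + 0.7 * soa
  if (any(late))
    warning(sprintf("%d press(es) beyond run end + 2 SOA ignored", sum(late)))
  if (any(early))
    warning(sprintf("%d press(es) before the first response window ignored",
                    sum(early)))
  n_ignored <- sum(late | early)
  presses <- presses[!late & !early]

  # region of each press: windows and gaps tile [0.7, 1.7) SOA after each
  # onset; phase within an SOA cycle decides window vs gap
  rel <- (presses - onsets[1]) / soa          # in units of SOA from t_0
  idx <- floor(rel - 0.7)                     # candidate trial index (0-based)
  phase <- rel - idx                          # in [0.7, 1.7)
  in_window <- phase < 1.4

  rt <- rep(NA_real_, n)
  n_discarded <- sum(idx >= n)                # past the last trial's regions
  # pass 1: primary windows, shortest RT wins
  for (k in which(in_window & idx < n)) {
    i <- idx[k] + 1L
    cand <- presses[k] - onsets[i]
    if (is.na(rt[i])) rt[i] <- cand
    else { rt[i] <- min(rt[i], cand); n_discarded <- n_discarded + 1L }
  }
  # pass 2: gap presses, in time order, to the earlier response-less trial
  for (k in which(!in_window & idx < n)) {
    i <- idx[k] + 1L                          # gap follows trial i's window
    if (is.na(rt[i])) rt[i] <- presses[k] - onsets[i]
    else if (i < n && is.na(rt[i + 1L])) rt[i + 1L] <- presses[k] - onsets[i + 1L]
    else n_discarded <- n_discarded + 1L
  }

  out <- data.frame(trial = seq_len(n) - 1L, onset = onsets,
                    category = schedule$category, rt = rt,
                    outcome = NA_character_,
                    rt_source = ifelse(is.na(rt), "absent", "observed"),
                    stringsAsFactors = FALSE)
  attr(out, "soa") <- soa
  attr(out, "n_discarded") <- n_discarded
  attr(out, "n_ignored") <- n_ignored
  class(out) <- c("gradcpt_trials", "data.frame")
  classify_trials(out)
}

#' Classify trials as hit, miss, false alarm or correct rejection
#'
#' Go trials with an observed response are hits and without one misses;
#' No-go trials with a response are false alarms (commission errors) and
#' without one correct rejections.
#'
#' @param table A `gradcpt_trials` table from [assign_presses()].
#' @return The table with the `outcome` column filled in.
#' @export
classify_trials <- function(table) {
  stopifnot(inherits(table, "gradcpt_trials"))
  go <- table$category == "Go"
  resp <- table$rt_source == "observed"
  table$outcome <- ifelse(go, ifelse(resp, "hit", "miss"),
                          ifelse(resp, "FA", "CR"))
  table
}

#' @export
print.gradcpt_trials <- function(x, ...) {
  tb <- table(factor(x$outcome, levels = c("hit", "miss", "FA", "CR")))
  cat(sprintf("gradCPT trial table: %d trials (SOA %.3g s) — %s\n",
              nrow(x), attr(x, "soa"),
              paste(names(tb), tb, sep = ":", collapse = " ")))
  NextMethod()
}

#' Write a trial table as tab-separated text
#'
#' Columns `trial_index`, `onset`, `trial_type`, `response_time`,
#' `outcome`, `rt_source`; times in seconds.
#'
#' @param table A `gradcpt_trials` table.
#' @param path File path.
#' @export
write_trials <- function(table, path) {
  stopifnot(inherits(table, "gradcpt_trials"))
  df <- data.frame(trial_index = table$trial,
                   onset = sprintf("%.6f", table$onset),
                   trial_type = table$category,
                   response_time = ifelse(is.na(table$rt), "n/a",
                                          sprintf("%.6f", table$rt)),
                   outcome = table$outcome, rt_source = table$rt_source)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
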