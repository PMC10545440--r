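# shared helpers: hand-built schedules/trial tables and a naive
# reference implementation of the press-assignment rules

# schedule object from raw onsets (bypasses make_schedule's generator)
raw_schedule <- function(onsets, soa, categories = NULL,
                         run_duration = max(onsets) + soa) {
  n <- length(onsets)
  if (is.null(categories)) categories <- rep("Go", n)
  out <- data.frame(onset = onsets, category = categories,
                    exemplar = rep(0L, n), stringsAsFactors = FALSE)
  attr(out, "run_duration") <- run_duration
  attr(out, "soa") <- soa
  attr(out, "nogo_rate") <- mean(categories == "NoGo")
  class(out) <- c("gradcpt_schedule", "data.frame")
  out
}

# trial table from categories + RTs (NA = no response)
raw_trials <- function(categories, rt, soa = 0.8) {
  n <- length(categories)
  out <- data.frame(trial = seq_len(n) - 1L, onset = (seq_len(n) - 1) * soa,
                    category = categories, rt = rt,
                    outcome = NA_character_,
                    rt_source = ifelse(is.na(rt), "absent", "observed"),
                    stringsAsFactors = FALSE)
  attr(out, "soa") <- soa
  attr(out, "n_discarded") <- 0L
  attr(out, "n_ignored") <- 0L
  class(out) <- c("gradcpt_trials", "data.frame")
  gradcptr::classify_trials(out)
}

# Reference assignment: plain nested loops, each press located by
# exhaustive scan over every trial's window and gap region, rules applied
# case by case. Deliberately naive; kept independent of the package's
# vectorized region arithmetic.
oracle_assign <- function(onsets, soa, presses, run_duration = NULL) {
  n <- length(onsets)
  if (is.null(run_duration)) run_duration <- onsets[n] + soa
  rt <- rep(NA_real_, n)
  discarded <- 0L
  ignored <- 0L

  kind <- character(length(presses))   # "window", "gap", "ignored", "dead"
  owner <- integer(length(presses))
  for (k in seq_along(presses)) {
    p <- presses[k]
    kind[k] <- "dead"
    if (p < onsets[1] + 0.7 * soa || p >= run_duration + 2 * soa) {
      kind[k] <- "ignored"
      next
    }
    for (i in seq_len(n)) {
      w_lo <- onsets[i] + 0.7 * soa
      w_hi <- onsets[i] + 1.4 * soa
      g_hi <- onsets[i] + 1.7 * soa
      if (p >= w_lo && p < w_hi) { kind[k] <- "window"; owner[k] <- i; break }
      if (p >= w_hi && p < g_hi) { kind[k] <- "gap"; owner[k] <- i; break }
    }
  }
  ignored <- sum(kind == "ignored")
  discarded <- discarded + sum(kind == "dead")
  # windows first: shortest RT kept, surplus discarded
  for (i in seq_len(n)) {
    hits <- presses[kind == "window" & owner == i]
    if (length(hits) > 0) {
      rt[i] <- min(hits) - onsets[i]
      discarded <- discarded + length(hits) - 1L
    }
  }
  # gap presses in time order: earlier response-less neighbor, else later
  for (k in seq_along(presses)[kind == "gap"]) {
    i <- owner[k]
    if (is.na(rt[i])) rt[i] <- presses[k] - onsets[i]
    else if (i < n && is.na(rt[i + 1]))
      rt[i + 1] <- presses[k] - onsets[i + 1]
    else discarded <- discarded + 1L
  }
  list(rt = rt, n_discarded = discarded, n_ignored = ignored)
}

# one simulated session (list of schedules + keypress logs), fixed seeds
sim_session <- function(master_seed, n_runs = 4, run_duration = 400,
                        soa = 0.8, ...) {
  set.seed(master_seed)
  phase <- runif(1, 0, 2 * pi)
  schedules <- lapply(seq_len(n_runs), function(i)
    make_schedule(run_duration, soa, seed = master_seed * 1000 + i))
  logs <- lapply(seq_len(n_runs), function(i)
    simulate_observer(schedules[[i]],
                      observer_params(phase = phase,
                                      seed = master_seed * 1000 + 500 + i,
                                      ...)))
  list(schedules = schedules, logs = logs)
}
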