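#' Simulate a multi-participant gradCPT fixture directory
#'
#' Generates, for each participant and modality, `n_runs` schedule/keypress
#' file pairs plus a ground-truth parameter sidecar (JSON), and a global
#' manifest. Observer parameters vary across participants around the
#' modality's typical regime so that group-level analyses have real
#' between-subject variance. Deterministic under `seed`.
#'
#' @param out_dir Output directory (created if needed).
#' @param n_participants Number of participants.
#' @param n_runs Runs per participant and modality (default 4).
#' @param modalities Character subset of `c("auditory", "visual")`; the
#'   auditory task uses SOA 1.6 s, the visual task 0.8 s.
#' @param run_duration Run length, seconds (default 400).
#' @param seed Integer seed.
#' @return Invisibly, the manifest data.frame (one row per run bundle:
#'   participant, modality, run, soa, events/keypress file paths).
#' @export
run_simulate <- function(out_dir, n_participants = 1, n_runs = 4,
                         modalities = c("auditory", "visual"),
                         run_duration = 400, seed = 1) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  modalities <- match.arg(modalities, several.ok = TRUE)
  soa_of <- c(auditory = 1.6, visual = 0.8)
  mu_of <- c(auditory = 1.558, visual = 0.625)
  sigma_of <- c(auditory = 0.14, visual = 0.06)
  set.seed(seed)
  rows <- list()
  for (p in seq_len(n_participants)) {
    for (mod in modalities) {
      # per-participant trait draws (kept in plausible Table-1-like ranges)
      par <- observer_params(
        mu_rt = mu_of[[mod]] * stats::runif(1, 0.92, 1.08),
        sigma0 = sigma_of[[mod]] * stats::runif(1, 0.7, 1.3),
        mod_depth = 0.6,
        f0 = stats::runif(1, 0.025, 0.04),
        phase = stats::runif(1, 0, 2 * pi),
        p_fa_base = if (mod == "auditory") stats::runif(1, 0.1, 0.3)
                    else stats::runif(1, 0.05, 0.2),
        p_miss_base = if (mod == "auditory") stats::runif(1, 0.1, 0.35)
                      else stats::runif(1, 0.01, 0.06))
      truth <- par[setdiff(names(par), "seed")]
      for (run in seq_len(n_runs)) {
        sch <- make_schedule(run_duration, soa_of[[mod]],
                             seed = sample.int(2^31 - 1, 1))
        par$seed <- sample.int(2^31 - 1, 1)
        log <- simulate_observer(sch, par)
        stem <- sprintf("sub-%02d_%s_run-%d", p, mod, run)
        ev <- file.path(out_dir, paste0(stem, "_events.tsv"))
        kp <- file.path(out_dir, paste0(stem, "_keypresses.tsv"))
        write_events(sch, ev)
        write_keypresses(log, kp)
        rows[[length(rows) + 1]] <- data.frame(
          participant = p, modality = mod, run = run,
          soa = soa_of[[mod]], events = ev, keypresses = kp)
      }
      jsonlite::write_json(truth,
                           file.path(out_dir,
                                     sprintf("sub-%02d_%s_truth.json", p, mod)),
                           auto_unbox = TRUE, digits = NA)
    }
  }
  manifest <- do.call(rbind, rows)
  utils::write.table(manifest, file.path(out_dir, "manifest.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(manifest)
}

#' Analyze a fixture directory into a participant metrics table
#'
#' Reads every run bundle listed in the directory's manifest, fits a
#' [gradcpt_session()] per participant and modality, and returns (and
#' optionally writes) one metrics row each, with per-run VTC tables
#' alongside when `out_dir` is given.
#'
#' @param in_dir Directory produced by [run_simulate()] (or hand-built,
#'   with a compatible `manifest.tsv`).
#' @param out_dir Optional output directory for `metrics.csv` and per-run
#'   VTC TSV files.
#' @param fwhm,band Passed to [gradcpt_session()].
#' @return Data.frame with columns `participant`, `modality`, `n_runs`,
#'   `hit_rate`, `fa_rate`, `d_prime`, `median_rt`, `fluct_freq`.
#' @export
run_analyze <- function(in_dir, out_dir = NULL, fwhm = 7,
                        band = c(0.005, 0.10)) {
  mf <- file.path(in_dir, "manifest.tsv")
  if (!file.exists(mf)) stop(sprintf("no manifest.tsv in '%s'", in_dir))
  manifest <- utils::read.table(mf, header = TRUE, sep = "\t",
                                stringsAsFactors = FALSE)
  if (!is.null(out_dir))
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  groups <- split(manifest, manifest[c("participant", "modality")],
                  drop = TRUE)
  rows <- lapply(groups, function(g) {
    g <- g[order(g$run), ]
    for (f in c(g$events, g$keypresses))
      if (!file.exists(f)) stop(sprintf("missing file '%s'", f))
    schedules <- lapply(g$events, read_events)
    logs <- lapply(g$keypresses, read_keypresses)
    fit <- gradcpt_session(schedules, logs, fwhm = fwhm, band = band)
    if (!is.null(out_dir)) {
      for (i in seq_along(fit$vtc)) {
        v <- fit$vtc[[i]]
        utils::write.table(
          data.frame(trial_index = seq_along(v$raw) - 1L,
                     time = sprintf("%.6f", v$trial_times),
                     raw_vtc = sprintf("%.6f", v$raw),
                     smoothed_vtc = sprintf("%.6f", v$smoothed)),
          file.path(out_dir, sprintf("sub-%02d_%s_run-%d_vtc.tsv",
                                     g$participant[1], g$modality[1],
                                     g$run[i])),
          sep = "\t", quote = FALSE, row.names = FALSE)
      }
    }
    m <- coef(fit)
    data.frame(participant = g$participant[1], modality = g$modality[1],
               n_runs = nrow(g), hit_rate = m[["hit_rate"]],
               fa_rate = m[["fa_rate"]], d_prime = m[["d_prime"]],
               median_rt = m[["median_rt"]],
               fluct_freq = m[["fluct_freq"]])
  })
  res <- do.call(rbind, rows)
  res <- res[order(res$participant, res$modality), ]
  rownames(res) <- NULL
  if (!is.null(out_dir))
    utils::write.csv(res, file.path(out_dir, "metrics.csv"),
                     row.names = FALSE)
  res
}

#' Group-level correlation report
#'
#' For each requested variable pair, computes the Pearson correlation with
#' default Bayes factor, credible interval and evidence label over
#' pairwise-complete participant rows ([cor_bf()]). Pairs with fewer than
#' 4 complete cases are flagged, not computed.
#'
#' @param metrics Data.frame of per-participant metrics (e.g. from
#'   [run_analyze()], possibly reshaped one row per participant).
#' @param covariates Optional data.frame of per-participant covariates
#'   (e.g. neurometabolite levels) merged on a `participant` column.
#' @param pairs Character matrix or list of length-2 vectors naming the
#'   column pairs to correlate.
#' @param kappa Prior width for the Bayes factors.
#' @return Data.frame: `var_x`, `var_y`, `n`, `r`, `p`, `bf10`,
#'   `ci_lower`, `ci_upper`, `evidence`, `note`.
#' @export
run_group <- function(metrics, covariates = NULL, pairs, kappa = 1) {
  df <- metrics
  if (!is.null(covariates)) df <- merge(df, covariates, by = "participant")
  if (is.matrix(pairs)) pairs <- asplit(pairs, 1)
  rows <- lapply(pairs, function(pr) {
    x <- df[[pr[1]]]; y <- df[[pr[2]]]
    if (is.null(x) || is.null(y))
      stop(sprintf("unknown column in pair (%s, %s)", pr[1], pr[2]))
    ok <- stats::complete.cases(x, y)
    base <- data.frame(var_x = pr[1], var_y = pr[2], n = sum(ok),
                       r = NA_real_, p = NA_real_, bf10 = NA_real_,
                       ci_lower = NA_real_, ci_upper = NA_real_,
                       evidence = NA_character_, note = "")
    if (sum(ok) < 4) { base$note <- "insufficient n"; return(base) }
    if (stats::sd(x[ok]) == 0 || stats::sd(y[ok]) == 0) {
      base$note <- "degenerate (constant column)"; return(base)
    }
    cb <- cor_bf(x[ok], y[ok], kappa = kappa)
    base$r <- cb$r; base$p <- cb$p_two_tailed; base$bf10 <- cb$bf10
    base$ci_lower <- cb$ci95[1]; base$ci_upper <- cb$ci95[2]
    base$evidence <- cb$evidence
    base
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
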