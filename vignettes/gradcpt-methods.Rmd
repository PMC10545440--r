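---
title: "Models and methods behind gradcptr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind gradcptr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gradcptr)
```

# The task and what the package computes

In a gradual-onset continuous performance task (gradCPT) stimuli cross-fade
continuously: each stimulus ramps up over one stimulus onset asynchrony
(SOA) and ramps down over the next, so there is no abrupt onset to capture
attention exogenously. Participants press a button for frequent Go stimuli
(90%) and withhold the press for rare No-go stimuli (10%). Typical
configurations are 400-s runs at SOA 1.6 s (auditory version, 250 trials)
or 0.8 s (visual version, 500 trials).

`gradcptr` implements the full behavioral analysis chain for such data:

1. keypress-to-trial **response assignment** and hit/miss/FA/CR
   classification,
2. session **metrics** — hit rate, false-alarm rate, signal-detection
   sensitivity d′, median RT,
3. the **variance time course** (VTC) — the trial-by-trial absolute
   z-scored RT series — with Gaussian smoothing and a spectral estimate of
   its dominant fluctuation frequency,
4. **fMRI regressor construction** — canonical double-gamma HRF, stick
   regressors per trial type, the amplitude-modulated VTC regressor on a
   TR = 2 s scan grid, and a 128-s discrete-cosine high-pass basis,
5. **default Bayesian correlation statistics** — BF10 and credible
   intervals for Pearson correlations, and the JZS paired-t Bayes factor,
6. a **synthetic observer** whose sessions have the statistical structure
   the analysis assumes, so every stage is testable end to end.

# Response assignment

With onset $t_n$ and appearance/disappearance phases of one SOA each, the
response window of trial $n$ is
$[t_n + 0.7\,\mathrm{SOA},\, t_n + 1.4\,\mathrm{SOA})$ — from 70% of the
fade-in to 40% of the fade-out. Every press in a window belongs to that
trial; when several land there the shortest RT is kept and the surplus
discarded. Presses in the inter-window gap
$[t_n + 1.4\,\mathrm{SOA},\, t_n + 1.7\,\mathrm{SOA})$ are ambiguous and
are treated as responses to an adjacent trial: trial $n$ if it is still
response-less, otherwise trial $n{+}1$ if that one is, otherwise the press
is discarded.

Three details here were genuinely open and are package decisions:

* **Half-open intervals.** A press at an exact boundary belongs to exactly
  one region; no double assignment is possible.
* **Ambiguity order.** The earlier response-less trial is served first;
  when both neighbors already have responses the gap press is discarded.
  The per-run counts of discarded and ignored presses are kept as
  attributes of the trial table, so this bookkeeping is auditable.
* **Surplus presses are discarded, not cascaded** to later trials; the
  shortest-RT rule already picks the best candidate and cascading would
  let a single noisy burst claim several trials.

A consequence worth knowing: a gap press reassigned *forward* to trial
$n{+}1$ has an RT in $[0.4, 0.7)\,\mathrm{SOA}$, and one kept *backward*
by trial $n$ has an RT in $[1.4, 1.7)\,\mathrm{SOA}$ — assigned RTs
therefore live in $[0.4, 1.7)\,\mathrm{SOA}$, not only inside the primary
window. The test suite pins the whole rule set against a deliberately
naive reference implementation on small random instances.

# Metrics

d′ is $\Phi^{-1}(h) - \Phi^{-1}(f)$ after clipping each rate to
$[1/(2N),\, 1 - 1/(2N)]$ with its own trial count — the standard
correction that keeps d′ finite for participants at ceiling (a 500-trial
visual run with no false alarms would otherwise be $-\infty$ away). Rates
are pooled over a session's runs before the transform, and median RT uses
observed responses only (interpolated values exist for the VTC, not for RT
summaries).

# Variance time course and its frequency

RTs of response-absent trials (misses, correct rejections) are linearly
interpolated between the neighboring observed RTs in trial time; leading
and trailing gaps take the nearest observed value. Each run's complete RT
series is z-scored within the run (sample SD, $n-1$) and the absolute
value taken: both unusually fast and unusually slow responses signal
attentional lapses. Smoothing uses a discrete Gaussian of
$\sigma = \mathrm{FWHM}/(2\sqrt{2\ln 2})$ seconds (FWHM 7 s by default,
i.e. $\sigma = 3.72$ trials at SOA 0.8 s), truncated at $\pm 4\sigma$ and
renormalized at the series edges, so a constant series is a fixed point
and the mean of interior-dominated series is conserved to $10^{-10}$.

The fluctuation frequency is estimated by a deliberately simple
construction (the statistic's *value* is standard; the estimator behind it
had to be designed here): per run the smoothed VTC is mean-centred and its
discrete-Fourier amplitude spectrum taken on the natural grid
$k/(N\,\mathrm{soa})$; spectra are averaged across runs and the band-limited
argmax over 0.005–0.10 Hz returned. For a 400-s run the frequency
resolution is 0.0025 Hz. The 7-s smoother attenuates by
$e^{-2\pi^2\sigma^2 f^2}$ — gain 0.84 at 0.032 Hz but 0.001 at 0.2 Hz —
so estimating on the smoothed series costs nothing in the band of
interest while suppressing trial-to-trial noise. Alternatives (multitaper,
unsmoothed VTC, run concatenation) would be drop-in replacements; the
estimator is a single function with the band as an argument.

# fMRI regressors

The canonical HRF is the double-gamma
$h(t) = g(t;6,1) - g(t;16,1)/6$ (gamma densities parameterized by
delay/dispersion), sampled on a 32-s support and normalized to unit peak;
it peaks near 5 s with a late negative undershoot. Regressors are built on
a fine grid (dt = 0.1 s, which keeps the peak error of the sampled kernel
below about 0.3%), convolved, and read off at scan times
$t_0 + k\,\mathrm{TR}$ with TR = 2 s and $t_0 = 10$ s by default — five
discarded equilibration volumes at TR 2 s, so a 400-s run keeps 200
scans. The amplitude-modulated VTC regressor weights each trial's impulse
by the *non-smoothed* VTC value (smoothing would double-dip with the HRF's
own low-pass). "Time-delayed" here means the delay induced by HRF
convolution; no extra fixed lag is inserted. The high-pass basis is the
discrete-cosine set with periods above the 128-s cutoff,
$K = \lfloor 2N\,\mathrm{TR}/\mathrm{cutoff}\rfloor$ functions (6 for 200
scans). GLM estimation, prewhitening and motion covariates are outside
this package's scope; the design-matrix writer emits plain TSV for
external tools.

# Default Bayes factors

For a Pearson correlation the package evaluates the exact sampling density
of $r$ given $\rho$ and $n$,

$$f(r \mid \rho, n) \propto
  (1-\rho^2)^{(n-1)/2}\,(1-\rho r)^{-(n-3/2)}\,
  {}_2F_1\!\left(\tfrac12, \tfrac12; n-\tfrac12; \tfrac{1+\rho r}{2}\right),$$

integrates it against a stretched-beta prior on $(-1,1)$ of width
$\kappa$ (the default $\kappa = 1$ is the uniform prior used by common
Bayesian software defaults), and divides by the density at $\rho = 0$.
The hypergeometric series is evaluated directly (its third parameter is
large, so a few dozen terms converge); the likelihood ratio is formed in
log space for stability at large $n$ or $|r|$ near 1. Credible intervals
invert the trapezoid-rule posterior CDF on an 8001-point grid, accurate to
well under the ±0.02 the published two-decimal intervals can support.
$|r| = 1$ returns an infinite-evidence sentinel. The paired-t Bayes factor
is the two-sided JZS integral with Cauchy prior scale $\sqrt{2}/2$ on the
standardized effect.

Three cross-checks guard the quadrature: the Jeffreys closed-form
approximation (within 15% for $|r| \le 0.5$, $n \ge 20$), an
importance-sampled Monte-Carlo estimate of the same marginal likelihood
(within 3 Monte-Carlo SEs on a 5×5 grid of $r$ and $n$), and published
BF/CI values recomputed from their printed $(r, n)$. Published analyses
do not always share one $n$ (degrees of freedom printed alongside some
correlations imply smaller samples), so $n$ is always an explicit
argument, never a package-wide constant. Evidence labels use the
conventional 1/10, 1/3, 3, 10 cut points.

# The synthetic observer

The generator is a latent-state observer, not a cognitive model: the
attentional state is the deterministic sinusoid
$s(t) = \sin(2\pi f_0 t + \phi)$ and on the trial at $t_n$

* RT $= \max(0.05, \mu + \varepsilon_n)$,
  $\varepsilon_n \sim N(0, \sigma_0^2 (1 + m\,s(t_n))^2)$,
* miss probability $\mathrm{clamp}(p_\mathrm{miss} + k\,m\,s(t_n))$ on Go
  trials (misses emit no press, matching their treatment as
  response-absent trials),
* commission probability $\mathrm{clamp}(p_\mathrm{fa} + k\,m\,s(t_n))$
  on No-go trials, with the same RT law.

A deterministic sinusoid (rather than, say, an Ornstein–Uhlenbeck state)
makes frequency recovery a sharp test: the VTC's magnitude envelope must
peak at $f_0$ within one Fourier bin. Defaults emulate the visual-task
regime — $\mu = 0.625$ s, $\sigma_0 = 0.06$ s, $m = 0.6$,
$f_0 = 0.032$ Hz, $p_\mathrm{fa} = 0.12$, $p_\mathrm{miss} = 0.03$. Two
of these deserve explanation. $\sigma_0$ and the baseline error rates
were chosen so that the *measured* session statistics land in the
plausible published envelope (hit rates roughly 74–96%, false-alarm rates
roughly 19–24%, median RTs near 625/1558 ms): with a Gaussian RT
distribution a non-trivial fraction of responses falls before the 70%
window onset, and the adjacent-trial reassignment then converts a share
of them into false alarms on preceding No-go trials, so the measured FA
rate sits well above the generative commission probability. The
multi-participant simulator (`run_simulate()`) draws each participant's
traits from modest ranges around these values (auditory:
$\mu = 1.558$ s, $\sigma_0 = 0.14$ s, higher miss rates).

What the generator does **not** emulate: right-skewed RT distributions,
post-error slowing, drift or fatigue trends, speed–accuracy trade-off
strategies, or any coupling between consecutive trials beyond the slow
state. Passing tests therefore demonstrate that the analysis chain
recovers the structure it assumes, not that real observers have a
sinusoidal attentional state.

# Problem sizes and numerical choices

The test-suite and acceptance computations use the task's native
geometry: 400-s runs, four runs per session, 10 simulated observers for
the frequency-recovery checks — enough for the one-bin criterion to be
meaningful while keeping the suite quick. Quadrature tolerances are
1e-8 (relative) for Bayes factors; the CI grid step is 2.5e-4 in $\rho$;
degenerate inputs (zero RT spread, constant covariate columns, |r| = 1,
empty outcome classes, sub-resolution spectral bands) raise errors or
sentinels rather than propagating NaNs.

# Known limitations

* The assignment rule set matches the gradual-onset convention described
  above; coherence-based variants used by other gradCPT implementations
  are not provided.
* The fluctuation-frequency estimator returns the argmax bin; no peak
  interpolation or confidence band is attempted.
* The paired-t Bayes factor is two-sided only; published one-sided values
  can differ (a known source of discrepancy when comparing against tables
  computed with directional priors).
* `run_group()` computes pairwise-complete Pearson correlations; no
  partial correlations, outlier rejection, or multiplicity control.
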