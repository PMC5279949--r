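---
title: "Models and methods: planted-parameter recovery of implicit-memory decay"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: planted-parameter recovery of implicit-memory decay}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(memdecay)
```

## The scientific problem

In two-tone frequency discrimination, listeners do not judge each trial in
isolation: the remembered first tone is contracted toward an implicit prior
formed from preceding trials (the *contraction bias*). Depending on the
geometry of a trial, that contraction can enlarge the perceived within-trial
difference (*Bias+* trials, discrimination helped) or shrink it (*Bias-*,
discrimination hurt). The difference in sensitivity between the two trial
classes, `delta d' = d'(Bias+) - d'(Bias-)`, measures the behavioral weight
of the prior. The prior is a memory trace: spacing trials further apart
weakens it, and the decay of `delta d'` with the inter-trial interval (ITI)
estimates the trace's time constant. Auditory-cortex adaptation — the
recovery of the N1 and P2 event-related potentials with time since the
previous tone — provides a neural counterpart with the same exponential
form, and repetition priming of oral reading (faster second readings of a
non-word, fading with re-reading lag) a reading-level counterpart.

The interest in these time constants comes from dyslexia research: the
hypothesis is that dyslexics' implicit memory decays faster, so their
priors integrate a shorter stimulus history and are noisier. None of the
underlying raw data are public. This package therefore takes the
*planted-parameter recovery* approach: generators synthesize behavior, EEG,
and reading sessions whose ground-truth dynamics are set to published
group-level estimates, and the analysis pipeline must recover those planted
parameters from the raw synthetic data. Everything downstream of the
generators — filtering, artifact rejection, epoching, d' computation, GLM
fitting, bounded decay fitting, group statistics — is the same code a real
dataset would pass through.

## The decay model

Every dynamic quantity is fit with the three-parameter exponential

\[ y(t) = \alpha + \beta e^{-t/\tau} \]

where `alpha` is the asymptote after full recovery (`t -> Inf`), `beta` the
magnitude of adaptation (value at `t = 0` minus `alpha`), and `tau` the time
constant in seconds. Fits minimize squared error inside fixed boxes: for the
`d'` difference both `alpha` and `beta` lie in `[0, 100]`; for the P2 area
`alpha` in `[0, 15000]`, `beta` in `[-15000, 0]` µV·ms; N1, a negative
component recovering toward a negative asymptote, uses the mirrored boxes.
`tau` is limited to `[0, 100]` s everywhere.

### Numerical strategy

With four design points and three parameters the SSE surface is nearly flat
in `tau` whenever the data wiggle, so a single local optimizer is
unreliable. `fit_decay()` therefore runs a multi-start search: 25
log-spaced `tau` values in `[0.1, 100]` s, with the conditionally linear
pair `(alpha, beta)` solved exactly at each `tau` by box-constrained least
squares (the 2-parameter QP optimum is either interior or on an active
bound, so candidate enumeration is exact), followed by a local refinement of
`tau` between the best grid point's neighbours.

### When `tau` is not identifiable

Four noisy points often cannot pin down a time constant: the SSE profile can
be flat all the way to the `tau = 100` s bound, and the bounded global
optimum then lands anywhere in a long right tail. Averaging such fits
inflates group means badly (Monte-Carlo at the behavioral signal-to-noise
ratio puts the naive group mean at +20% to +120% of the planted value).
`fit_decay()` flags a fit's `tau` as non-identifiable when either

* the fitted `|beta|` is below twice the residual SD (no measurable
  adaptation), or
* refitting with `tau` pinned at the upper bound costs less than 30%
  extra SSE (the profile cannot distinguish the optimum from the bound),

and `summarize_decay_fits()` excludes flagged subjects from group parameter
summaries, reporting how many were dropped. With this screen the group mean
is approximately unbiased (planted 6 s recovers as ~6.1, planted 2.9 as
~3.1 in 400-replicate Monte-Carlo runs).

## The contraction-bias observer

`simulate_observer()` implements a trial-by-trial decision model. The prior
estimate before trial *t* mixes the most recent first tone with the running
mean of all previous first tones,

\[ \mathrm{prior}(t) = \gamma f_1(t-1) + (1-\gamma)\,\overline{f_1}(1..t-1), \]

with `gamma = 0.6` by default: recency dominates, but a global component
remains — the minimal form that produces both a Recent and a Global context
effect in the choice GLM. The effective contraction weight decays with the
time since the previous trial,

\[ w(t) = w_{\mathrm{floor}} + (w_0 - w_{\mathrm{floor}})\,e^{-\mathrm{ITI}/\tau_{\mathrm{mem}}}, \]

the percept of the first tone is `f1* = (1 - w) f1 + w prior`, and the
response is `first higher` when `f1* + e > f2` with `e ~ N(0, sigma * f1)`
(Weber-like noise). Decay acts on the *weight*, not on the prior's value,
matching the observation that it is the magnitude of the bias that fades
with ITI. Trial 1 has no prior (`w = 0`): nothing precedes it.

### Calibrating the observer to a planted delta-d' curve

The planted quantity is the measured `delta d'(ITI)` curve, but the
observer's knob is `w`. The mapping from `w` to measured `delta d'` is
nonlinear: the signal-detection transform saturates, extreme rates are
clamped at `1/(2N)`, and labeling trials with the analysis prior (the
previous trial's f1) rather than the generative mixture dilutes the effect.
Instead of assuming linearity, `calibrate_ddprime_map()` *measures* the
channel: it simulates blocks at fixed `w` over a grid (120 blocks of 100
trials per grid point, fixed internal seed), applies the exact
`context_effect()` computation, and smooths the mean response with isotonic
regression. `observer_from_decay()` then finds `(w_0, w_{floor},
\tau_{mem})` minimizing the squared distance — in `delta d'` units — between
the mapped weight trajectory and the planted curve at the four block ITIs.
Two consequences are worth noting:

* the calibrated `tau_mem` is generally *not* equal to the planted `tau`
  (it absorbs the channel's curvature so that the measured curve, not the
  weight curve, is exponential);
* curve values outside the achievable range do not matter: the printed
  dyslexic curve extrapolates to `delta d' = 4.5` at `t = 0`, more than any
  contraction weight can produce, but the curve only needs to hold at the
  observable ITIs (1.4–8.9 s), where it does.

`sigma = 0.02` keeps the needed weights inside the channel's monotone,
less-saturated range for both groups' curves. This makes overall accuracy
higher than a real psychophysical session; the package deliberately
prioritizes reproducing the `delta d'(ITI)` curve, which is the quantity
under study, over matching overall percent correct.

### Two stimulus-statistics subtleties

Only the *base* tone of each trial is constrained to the 800–1250 Hz band;
the comparison sits at a ±1–30% relative difference and may leave the band.
Forcing both tones into the band couples trial difficulty to the base
tone's position in the band and manufactures a spurious negative context
effect (about −0.8 d') even in a prior-blind observer.

Even with faithful stimuli, a broad 1–30% difficulty range leaves a smaller
composition artifact: the most extreme comparison-derived first tones are
simultaneously the easiest trials and the ones most likely to be labeled
Bias− (any prior lies toward the band center, i.e. toward f2). A
prior-blind observer therefore shows a small negative `delta d'` (about
−0.3) of purely stimulus-composition origin. The unit tests verify the true
null on a narrow difficulty band, where the artifact vanishes; the
calibration map absorbs it for cohort work (it shifts the channel's zero
point, not its usable range).

## The choice GLM

On specially designed sequences in which the sign of the global context
`G(t) = sign(f1 - mean(f1))` and of the recent context
`R(t) = sign(f1 - f1(t-1))` are decorrelated (|phi| < 0.05, achieved by
greedy pairwise order swaps with a bounded budget), the two context
contributions become separately estimable. `fit_choice_glm()` regresses
trial correctness on three predictors with a binomial/logit GLM: the
within-trial difference as percent of the lower tone, and
congruence-coded global and recent context terms (+1 when contraction
toward that prior helps the trial, −1 when it hurts). Correctness (not the
raw choice) is the outcome because the stimuli are specified in relative
terms and the context coding is congruence-signed; a small ridge-penalized
IRLS refit, flagged in the output, guards against separation.

## The ERP pipeline and its generator

The analysis chain follows standard ERP practice on a single virtual vertex
channel sampled at 256 Hz: zero-phase 1–30 Hz Butterworth band-pass;
artifact rejection on the continuous signal (±100 µV absolute, 100 µV
max-min within 50 ms, 50 µV adjacent-sample steps, with ±300/±200/±300 ms
rejection spans); 2000 ms epochs from −500 ms before first-tone onset,
dropped wholesale if they touch a rejected sample; baseline correction by
the −500..−150 ms mean (stopping short of 0 to exclude anticipatory
activity); and component areas as trapezoidal integrals of the block-average
waveform over 70–130 ms (N1) and 150–250 ms (P2), in µV·ms.

The generator plants, per event, component areas on the recovery curve
`alpha + beta * exp(-dt / tau)` with `dt` the time since the previous event
and `dt = Inf` (fully recovered, `area = alpha`) for a block's first event —
blocks were separated in the underlying design. Components are raised-cosine
deflections whose supports coincide exactly with their analysis windows
(N1: 100 ± 30 ms; 70–130 ms window; P2: 200 ± 50 ms; 150–250 ms window), so
the clean kernels do not cross-contaminate windows. Kernel shape itself is
a free choice — the analysis only uses windowed areas — and any fixed
unimodal kernel would do.

### Area calibration: what "planting an area" means

A zero-phase 1 Hz high-pass necessarily removes each kernel's DC content,
spreading an opposite-signed shallow wave over roughly ±1 s. Numerically,
only ~90% (N1) and ~79% (P2) of a kernel's area survives inside its own
window after filtering, a few µV·ms leak into the *other* component's
window, and at 2–3.5 s onset asynchronies the neighbouring events and the
trial's second tone leak into both windows and the baseline. The generator
therefore supports two conventions:

* `area_calibration = "pipeline"` (default): amplitudes solve a linear
  system built from unit-kernel *steady-state train* responses measured
  through the full pipeline at the block's SOA (plus the second-tone
  leakage term in active blocks). Noise-free recordings then reproduce the
  generative curve through the whole pipeline to well under 1% of the
  component's adaptation magnitude, once the block average is compared to
  its true expectation `(area(Inf) + (n-1) area(dt)) / n`.
* `area_calibration = "raw"`: amplitudes scale the clean kernel so its
  plain trapezoidal window area equals the curve, useful when inspecting
  unfiltered signals.

Artifacts are injected as 240 ms, 150–200 µV blink-like pulses at Poisson
times — large enough to trip the ±100 µV rule even after filtering — and
cost roughly the same small fraction of epochs (~1–3%) that real recordings
lose.

### Noise scale

The published group SEMs of fitted ERP parameters bundle between-subject
variability with per-subject estimation error. Injecting measurement noise
at that scale makes the 4-point `tau` fit's sampling skew dominate group
means (up to +25% on the passive P2 time constant). The generator's default
`noise_sd = 2` µV — the residual noise level of a clean 100-epoch average —
keeps per-subject `tau` estimates precise, so that cohort spread comes from
the *between-subject parameter draws* (truncated normal, CV 0.15 by
default) and group-mean recovery is unbiased to within ~4%. This is a
deliberate division of variance for planted-parameter recovery, not a claim
about raw-EEG noise floors.

## Reading sessions

Sessions are self-paced: each non-word appears 500 ms after the previous
voice offset; RT is visual onset to voice onset. Non-words are CV+CVC or
CVC+CV conjunctions over a transliterated consonant/vowel inventory —
pronounceable template strings, with no claim to Hebrew orthographic
realism. The second reading of a token is faster by

\[ \mathrm{benefit}(\Delta t) = b_{\mathrm{floor}} + (b_0 - b_{\mathrm{floor}})\,e^{-\Delta t/\tau_{\mathrm{read}}} \ (\%), \]

applied to the *realized* first RT, with `delta t` running from the first
reading's voice offset to the second presentation's visual onset. The lag
plan mixes closest-possible repetitions (one intervening word — repetitions
are never consecutive) with long-range pairs (5 + geometric intervening
words, capped at 100), giving a long-bin mean lag of ~40 s at realistic
word rates. Group presets pin `(b_0, b_{floor}, tau_read)` so the generated
sessions reproduce the published bin means (controls: ~25% below 2 s, ~12%
above; dyslexics: ~23% and ~6%) with `tau_read` tied to each group's
behavioral time constant; the percentage benefit is invariant to a uniform
slowdown, which is what makes the measure comparable across groups with
different baseline speeds.

## Cohorts, experiments, group statistics

`simulate_cohort()` draws per-subject generative parameters from the group
presets and derives every seed hierarchically from one master seed, so a
cohort and all downstream experiments are byte-reproducible. Behavioral
decay parameters are shared within a group — per-subject estimation noise
alone already reproduces a realistic between-subject `tau` SD of ~4–5 s —
while ERP and reading parameters are drawn per subject (CV 0.15 and 0.10).
`run_experiment()` wires the four designs: decorrelated-sequence GLM
(`exp1`, 4 × 150 trials), active two-tone blocks with simultaneous EEG
(`exp2_active`, ITIs 1.4/2.9/5.9/8.9 s; EEG SOAs 2/3.5/6.5/9.5 s, block
order counterbalanced by rotation across subjects), passive single-tone
EEG (`exp2_passive`, ISIs 2/3.5/6.5/9.5 s), and reading (`exp3`, 6 × 120
words). Decay fits use the nominal block ITIs/ISIs as `t`.

Group comparisons are conservative and nonparametric throughout:
Mann-Whitney between groups (the reported statistic is the first group's U;
normal approximation with tie correction), Wilcoxon signed-rank within
subjects, Friedman across repeated conditions.

## Problem sizes and what the tests show

The test suite and the acceptance script run the full study scale — 23
controls / 25 dyslexics for behavior and EEG (4 blocks × 100 trials or
events each), 29/23 reading sessions of 720 words — in a few minutes. The
calibration map and channel diagnostics use 60–120 blocks per operating
point. Passing recoveries demonstrate that the pipeline is unbiased and
correctly wired *under the generators' assumptions*: exponential dynamics,
stationary per-block weights, independent Gaussian sensory noise, a single
noiseless virtual channel with fixed-shape components, and error-free
self-paced timing. Real data violate all of these gracefully (drifting
attention, component-latency jitter, correlated EEG noise, voice-key
errors), so passing tests certify the analysis code, not the biology.

## Known limitations

* The exponential-weight observer cannot exactly produce an exponential
  measured `delta d'` curve through the saturating d' channel; calibration
  minimizes the residual at the observable ITIs (it is small there), but
  extrapolating the fitted curve to `t = 0` inherits the printed curves'
  ambiguity.
* `tau` from four points is intrinsically fragile; the identifiability
  screen is essential, and per-subject behavioral `tau` estimates should
  never be interpreted individually.
* The ERP generator plants areas, not waveform shapes: latency, peak
  amplitude, and morphology carry no information here.
* A single channel means no topography, no re-referencing, and no
  ocular-component decomposition; the amplitude rules stand in for the
  full artifact battery.
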