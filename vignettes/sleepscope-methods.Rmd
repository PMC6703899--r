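---
title: "sleepscope: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{sleepscope: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sleepscope)
```

## What the package computes

`sleepscope` analyzes single-cell calcium activity recorded by a head-mounted
miniscope (10 frames/s) alongside EEG/EMG sleep scoring (4 s epochs) in
narcoleptic and control mice, with a predator-odor exposure late in the
session. The analysis chain is:

1. **Normalization** — raw fluorescence to dF/F against a per-cell
   background, then per-cell Z-scores.
2. **State scoring** — epochs into active wake (AW), quiet wake (QW), NREMS,
   REMS, with rule-based cataplexy validation.
3. **Derived bout labels** — post-odor AW bouts tested for hyperactivity
   (HAW vs AWO); cataplexy bouts subtyped spontaneous (SC) vs
   emotion-induced (EC).
4. **ON-cell classification** — per-state mean Z against the quiet-wake
   baseline, with an ANOVA confirmation and composition summaries.
5. **Peaks** — prominent transient detection (80% of per-cell max, 2 s
   refractory) and per-state amplitude/frequency statistics with a KS
   comparison.
6. **Synchrony** — bout-wise pairwise Pearson R, Fisher-Z transform,
   per-cell mean positive Z_R, and spatial connectivity maps
   (edges at R >= 0.6).
7. **Transitions** — time-normalized (0–100% of bout duration) activity
   profiles across the HAW-to-EC transition for cell groups.

A synthetic-session generator with full ground truth drives validation:
every stage is tested against data whose true labels, tunings and event
times are known.

## Normalization

For cell $i$ with raw trace $F$, the background $F_0$ is the mean of the
cell's trace over the whole recording, and

$$\left(\Delta F/F\right)_t = \frac{F_t - F_0}{F_0}, \qquad
  z_t = \frac{(\Delta F/F)_t - \mathrm{mean}}{\mathrm{SD}},$$

with the population (divisor $N$) standard deviation over the full
recording. Two choices deserve note:

* **Trace-level $F_0$.** In movie-based processing the background is an
  average-projection frame; with movie processing out of scope, the
  per-cell trace mean is the exact analogue (and makes the per-cell mean of
  dF/F identically zero).
* **Full-recording standardization, including the odor window.** The
  alternative (undisturbed period only) is defensible; the full recording
  is used and the consequence is quantified below ("Known limitations"):
  cells with very strong odor responses have an inflated SD, which makes
  the ON criterion *conservative* in odor-dominated sessions.

Flat cells (zero SD) are an error rather than silent `NaN`s, because a NaN
row would silently poison every downstream mean.

## Epoch scoring and cataplexy rules

Scoring uses four per-epoch features: delta power, theta power, EMG RMS
and a behavioral movement flag. The decision rules, with all thresholds in
one `score_thresholds()` object: high EMG means wake (AW when the animal
moves or EMG is very high, else QW); low EMG with delta > theta means
NREMS; atonic EMG with theta/delta above the ratio threshold marks a
REMS/cataplexy *candidate*. A candidate run qualifies as cataplexy iff

1. it lasts at least 8 s (2 epochs) with atonia throughout,
2. the movement flag is false throughout,
3. theta exceeds delta throughout, and
4. the 40 s immediately preceding are all wake — or the run starts within
   40 s of the end of a qualifying cataplexy bout with only wake in the
   gap (sequential cataplexy).

Non-qualifying candidates become REMS when preceded by NREMS, otherwise
QW. A subtle point fixed during development: the prior-wake context must
be judged on the labels *as scored*, never on labels already relabeled by
the validator — otherwise a rejected candidate run (relabeled QW) can
manufacture a fake wake context for the next candidate.

**HAW.** The hyperactivity test takes, for each post-odor AW bout, the
per-cell mean Z within the bout, and compares these (one-sided, one-sample
t test, closed form) to the grand mean Z over all pre-odor AW frames
pooled across cells. Per-cell bout means are the test unit, not frames:
frames are strongly autocorrelated (the transient decay constant alone is
1.5 s), whereas cells are the nearest-to-independent replication unit. The
test is one-sided because hyperactivity is directional.

**SC vs EC.** Each cataplexy bout is typed by the nearest preceding
AW-family bout (AW, AWO, HAW), skipping QW: HAW means EC; an undisturbed
AW — or an AWO that failed the hyperactivity test — means SC. Chained
bouts inherit the type of the chain's first bout. A post-odor bout whose
nearest AW-family bout started before odor onset is typed by that bout and
flagged for review, since no rule in the source conventions covers it.

## ON-cell classification

A cell is ON in a state when its mean Z over all frames of that state is
at least its own QW mean + 1 (boundary inclusive). Reported categories are
mutually exclusive with precedence: REMS and AW together form REMS_AW_ON;
then REMS, AW, SC, NREMS; cells ON nowhere pre-odor are "unscored". SC
takes precedence over NREMS because spontaneous-cataplexy-ON populations
are reported as SC-ON even when also NREMS-active; the SC/NREMS overlap is
additionally reported explicitly by `summarize_fractions()`, so neither
reading is lost. EC-ON and HAW-ON are non-exclusive flags crossed against
the pre-odor categories by `composition_table()`. Percentages are rounded
half-up to two decimals, matching printed-summary conventions.

## Peaks

Candidates are local maxima (plateaus contribute their leftmost frame;
boundary frames are eligible) at or above 80% of the cell's maximum Z over
the whole recording. The 2 s minimum interval is enforced by
amplitude-priority greedy selection — candidates accepted in decreasing
amplitude order, ties to the earlier frame — so when two prominences
conflict, the more prominent survives. Frequencies are reported per minute
of scored state time; states with zero scored time are absent, not zero.

## Synchrony

Within each sufficiently long bout (>= 10 s, i.e. >= 100 frames, bounding
the correlation estimator's variance), Pearson R is computed for every
unordered pair, Fisher-transformed
($Z_R = \tfrac12[\ln(1+R) - \ln(1-R)]$, with $|R| > 1 - 10^{-6}$ clipped
so perfect pairs stay finite and in the averages), and summarized per cell
as the mean $Z_R$ over *positively* correlated partners only. Bouts are
correlated separately and averaged unweighted within a state; frames are
not concatenated across bouts, so between-bout mean differences cannot
masquerade as within-bout correlation. Pearson's shift invariance gives
the intensity/synchrony dissociation: uniformly shifting all cells' Z
within a bout moves state means but leaves R, $Z_R$ and edge counts
untouched — which is why hyperactive wake can show the highest Z-scores
and simultaneously the sparsest connectivity map.

## Transition profiles

Each selected cataplexy bout is resampled per cell to 101 points (0–100%
of bout duration, inclusive) by linear interpolation at fractional frame
positions, averaged across cells, then across bouts — equal bout weight
regardless of duration. A native-time pre-onset window (default 60 s,
truncated at recording start) is emitted alongside so either rendering of
the transition is possible.

## The synthetic-session generator

The generator is first-class, tested code; its defaults encode the study
conditions the analysis assumes.

* **Protocol.** 10 frames/s, 4 s epochs, a 4 h session with a 1 h odor
  window starting 3 h in (`session_config()` defaults).
* **Hypnogram.** Semi-Markov over AW/QW/NREMS/REMS; bout durations
  exponential (memoryless — the simplest defensible choice, exposed in
  `state_model()` since per-state duration distributions are not published)
  truncated at one epoch; REMS reachable only from NREMS (standard rodent
  sleep architecture). Mean durations: AW 80 s, QW 40 s, NREMS 160 s,
  REMS 60 s, cataplexy 40 s — typical mouse polysomnography scales.
* **Cataplexy.** Inserted after wake runs >= 40 s with per-bout hazard
  0.25 (x3 during the odor window), zero for controls; minimum 2 epochs;
  chains with probability 0.25 across a short all-wake gap. Narcoleptic AW
  bouts inside the odor window are hyperactive in ground truth, and
  cataplexy entered from them is EC; the analysis must rediscover both
  from the traces and features alone.
* **Features.** State-conditioned lognormals (shared log-SD 0.2) chosen so
  the default thresholds recover labels exactly at zero noise; cataplexy
  shares the REMS atonia/theta parameters and differs only in waking
  context, which is precisely what makes the 40 s rule necessary.
* **Traces.** Per-cell inhomogeneous Poisson events at state-dependent
  rates (ON states 0.5 events/s against a 0.01 events/s floor), each event
  a double-exponential transient $e^{-t/\tau_d} - e^{-t/\tau_r}$ with
  $\tau_r = 0.2$ s, $\tau_d = 1.5$ s (GCaMP6s-like at 10 fps; the slow
  sensor used in the recordings), lognormal amplitudes, Gaussian noise on
  a positive baseline. During EC, events mix a private process with a
  shared latent Poisson train sampled per cell with probability `coupling`
  — one latent train is the simplest mechanism that produces the observed
  EC hyper-synchrony jump while leaving rates roughly intact.
* **Determinism.** All randomness flows from one master seed;
  per-cell substreams derive from a stable hash of the cell id, so adding
  a cell never reshuffles the others.

What the generator does **not** emulate: photobleaching and slow drift,
movement artifacts, cell-extraction crosstalk between neighboring ROIs,
non-Poisson burstiness, and EEG waveforms (only epoch-level features).
Passing tests therefore demonstrate correctness of the *analysis rules*
under the stated statistical structure, not robustness to every artifact
of real recordings.

## Numerical choices

* Population (divisor $N$) SD for Z-scores, fixed for reproducibility.
* Correlations clipped at $1 - 10^{-6}$ before the Fisher transform rather
  than excluded, preserving the pair in per-cell means.
* Half-up rounding to 2 decimals for percentages (printed convention;
  base R rounds half-even).
* Half-open, 0-based frame and epoch intervals everywhere in bout tables
  and output files.
* The closed-form tests (one-sample t, one-/two-way ANOVA, KS with
  asymptotic p) are implemented from their textbook definitions as module
  operations and cross-checked in the test suite against `t.test`, `aov`
  and `ks.test` on random data to 1e-9 or better. The two-way ANOVA uses
  classical balanced-layout sums of squares and warns on unbalanced
  layouts.
* Degenerate inputs are explicit: zero within-group variance reports a
  degenerate ANOVA rather than an infinite F; flat cells error in
  normalization and are excluded pairwise in correlations; bouts shorter
  than the synchrony minimum are skipped with a warning.

## Problem sizes used in the shipped experiments

The test suite and the acceptance script run: one narcoleptic session of
60 cells over 3 h (1 h odor window), one control session of 40 cells over
1.5 h, a 10^5-epoch hypnogram against a 10-replicate occupancy oracle,
500 null replicates (30 cells, 260 epochs each) for the hyperactivity
type-I rate, and 25-replicate Monte-Carlo oracles for the synchrony null.
These sizes give stable statistics for every check while keeping a full
run in tens of seconds.

## Known limitations

* **Full-recording Z-scoring interacts with session composition.** In
  sessions where the odor window dominates total variance (many HAW/EC
  bouts), the per-cell SD inflates and the AW-vs-QW mean separation of
  genuinely tuned cells compresses toward the +1 threshold; category
  recovery on synthetic sessions is typically 95–100% but can dip to
  ~90% in strongly odor-dominated draws. This is a property of the
  normalization convention, not of the classifier; restricting the
  standardization window to the undisturbed period would remove it at the
  cost of departing from the stated convention.
* **The hyperactivity test's nominal alpha is approximate.** The baseline
  mean is itself estimated from pooled pre-odor frames, which couples the
  per-cell deviations; the inflation scales with the tested-bout /
  baseline length ratio and is negligible at protocol-realistic ratios
  (measured 0.054 against a nominal 0.05 at a 250:5 epoch ratio over
  5000 null replicates).
* **Single-session scope.** Multi-animal aggregation is plain
  concatenation of per-session profiles; no mixed-effects pooling is
  implemented.
* The composition conventions reported by `composition_table()` combine
  REMS with REMS/AW origins and NREMS with SC origins, mirroring the
  summary-table layout they reproduce; finer crossings are available from
  the `cell_profiles` data frame directly.

## A worked miniature session

```{r demo, eval = FALSE}
cfg <- session_config("narcoleptic", n_cells = 24, duration_s = 3600,
                      odor_onset_s = 2400, odor_duration_s = 1200, seed = 8)
s <- run_session(cfg)
print(s)
summary(s)                      # full Markdown report
plot(activity_heatmap(s$zmat, s$profiles, s$bouts))
```
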