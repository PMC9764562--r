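---
title: "Methods: place-cell and LFP analysis of repeated novel-environment sessions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: place-cell and LFP analysis of repeated novel-environment sessions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette documents the models, conventions and numerical choices
behind `placecells`. The package analyses hippocampal CA1 tetrode
recordings from a repeated-exposure design: three 10-minute foraging
sessions per day, over two consecutive days, in an initially novel
62-cm cylindrical arena. The core scientific question the toolchain
supports is whether single-cell firing and spatial-coding properties
change with experience across days, and whether such changes are genuine
or secondary to changes in mean firing rate.

## Data model

Each session is a `session_dataset` bundling a `trajectory` (timestamped
x/y positions in arena-centred cm, nominally 50 Hz), a set of
`spike_train`s (sorted spike times plus per-spike waveform feature
vectors and a mean waveform width), and optionally one `lfp_recording`
(single-channel voltage, nominally 4.8 kHz). All components must share a
single session clock; misalignment is rejected at construction rather
than silently repaired, because clock repair belongs to acquisition, not
analysis. File exchange uses plain UTF-8 CSV with mandatory headers —
times in seconds, coordinates in cm — because no archival binary format
is assumed.

## Behavioural measures and the locomotion mask

Speed is computed per 500-ms epoch as path length within the epoch
divided by the epoch duration. This epoch-based definition (rather than
an instantaneous derivative) matches the grid used for LFP power binning
and is robust to tracking jitter. Locomotion is *speed > 3 cm/s*, a
strict inequality; immobility is its complement. All spike-based
statistics (mean rate, bursts, maps, phase locking) use only locomotion
epochs, so that immobility-associated activity (e.g. ripple-related
firing) does not contaminate place coding estimates.

Band-power estimation is restricted to *post-immobility activity
epochs*: the first 4 s of every locomotion run that lasts at least 4 s
and is immediately preceded by at least one sub-threshold epoch. The
minimum immobility duration before a qualifying run is one epoch
(0.5 s); no stricter value is assumed because the selection is already
conditioned on a genuine transition.

Coverage counts arena bins occupied for at least 100 ms — the same
criterion that admits a bin into the rate map — over bins whose centre
lies inside the arena disc.

## Cluster quality and cell classification

Clusters arrive pre-sorted; the package computes quality metrics, it
does not sort. For a cluster $C$ with $n_c$ spikes and feature matrix
rows $x_i$:

* **Isolation distance**: the squared Mahalanobis distance — with
  respect to $\mu_C$ and $\Sigma_C$ — of the $n_c$-th closest non-$C$
  spike. Undefined (reported missing, never auto-rejected) when fewer
  than $n_c$ non-cluster spikes exist.
* **L-ratio**: $L = \sum_{i \notin C} \left[1 -
  \mathrm{CDF}_{\chi^2_d}(D^2_{i,C})\right]$ divided by $n_c$. The
  degrees of freedom default to the feature dimensionality; 8 is the
  conventional value for four-channel, two-feature reductions.

A singular cluster covariance raises an explicit error; an optional
ridge term is available but never applied silently, since silent
regularisation would bias the metrics in exactly the low-spike-count
regime where they matter most.

A cluster is classified as a pyramidal neuron when Iso-D > 15, L-ratio
< 0.2, mean waveform width > 250 µs and locomotion-masked mean rate
< 5 Hz (all strict). A pyramidal cell is *active* in a session when its
masked rate lies strictly between 0.1 and 5 Hz. Classification uses the
masked rate for consistency with the global spike filter; per-session
classification is used throughout (both per-session and pooled rates are
reportable).

Bursts are maximal groups of ≥ 2 spikes whose consecutive ISIs are all
below 10 ms; burst probability is $N_B/(N_B+N_S)$. Grouping is greedy
and maximal — a spike belongs to at most one burst; ties are impossible
with a strict threshold. The alternative statistic (spikes in bursts
over total spikes) is reported alongside. Thresholds of 6, 9 and 12 ms
give rank-consistent results on synthetic populations, which the test
suite asserts (Spearman ρ > 0.9).

## Rate maps and spatial tuning

Maps use 2.5-cm square bins anchored at the arena centre; bins occupied
under 100 ms count as unvisited. The smoothed rate at a bin centre $x$
is a ratio of Gaussian kernel sums,

$$\lambda(x) = \frac{\sum_i g(\|S_i - x\|/h)}{\int_0^T g(\|y(t) - x\|/h)\,dt},
\qquad g(u) = e^{-u^2/2},\; h = 2.5\ \text{cm},$$

with the occupancy integral approximated by a Riemann sum over the
position samples at their native 20-ms interval — the data's own
discretisation, so no resampling artefacts are introduced. The
denominator depends only on the trajectory, so it is computed once and
cached across all cells sharing a session. Spike positions come from
linear interpolation of the trajectory at spike times.

Spatial information is the Skaggs measure
$\sum_i P_i (R_i/R)\log_2(R_i/R)$ (bits/spike) and sparsity is
$(\sum_i P_i R_i)^2 / \sum_i P_i R_i^2$, both over valid bins with
$P_i$ the occupancy probability and $R_i$ the smoothed rate; zero-rate
bins contribute zero by the $x \log x$ limit. The percentage of active
bins deliberately uses *raw* spike-containing bins over visited bins, so
that it is independent of the smoothing kernel.

Place fields are connected components of at least 9 bins above 20% of
the map maximum. Contiguity is 4-connectivity by default (8-connectivity
is a documented option); the *main* field is the component containing
the global peak bin, with a largest-area alternative exposed. Field area
is bin count × 6.25 cm².

Map stability is the Pearson correlation between two sessions' maps over
jointly valid bins, Fisher-z transformed ($z = \operatorname{atanh} r$,
$|r|$ clipped at $1 - 10^{-7}$ since atanh diverges at ±1). Cells enter
only with SI > 0.5 bits/spike in *both* sessions — low correlations from
weak spatial coding are an exclusion, not a zero. Successive-session
pairs S1–S2 … S5–S6 are assembled by `run_experiment()`, with S3–S4 the
between-day comparison.

## Spectral analysis and phase locking

The LFP is z-scored per session. Session band power is estimated over
concatenated post-immobility activity epochs with a long-window
spectrogram (20-s windows, 10-s step). Within each window a Welch PSD
(Hamming windows, 50% overlap) is integrated over the analysis bands —
theta 6–12 Hz, slow gamma 30–45 Hz, medium gamma 55–100 Hz — and
averaged across windows. A Welch estimator is used for all PSDs (the
multitaper alternative offers little at these long windows and adds a
parameter surface); the per-epoch variant integrates a Welch PSD within
each 500-ms epoch, and velocity stratification averages those epoch
powers within 3 cm/s speed bins on the shared epoch grid.

Phase extraction uses wider filter bands (theta 4–14, slow gamma 28–47,
medium gamma 58–102 Hz) with stop bands 2 Hz outside the pass band. The
filter is a linear-phase Hamming-design FIR applied with zero net phase
by multiplying the signal spectrum with the kernel's real frequency
response; Hamming design gives ≈ 53 dB stop-band attenuation and
pass-band ripple far below 1 dB, and phase fidelity is exact by
symmetry — essential when downstream statistics are phase histograms.
Instantaneous phase and amplitude come from the analytic signal
(frequency-domain Hilbert transform). The **trough = 0°** convention is
obtained by adding π to the analytic-signal argument; generator and
analyser share this convention by construction, because the simulated
phase-locked spikes are rejection-sampled against the *filtered* phase.

Spike phases are collected only within 500-ms epochs of strong
oscillation (per-epoch band power > mean + 2 SD; power rather than
amplitude, with amplitude exposed as an option). The mean resultant
vector $r = \sum_j e^{i\theta_j}/N$ gives the MVL $|r|$ and the
preferred phase $\arg r$; non-uniformity is tested with the Rayleigh
test, and results from fewer than 30 spikes are flagged insufficient.
Realistic concentrations put single-cell MVLs mostly in 0–0.2, which
the synthetic populations reproduce.

## Circular and proportion statistics

The Rayleigh p-value uses the standard small-sample-corrected
exponential approximation ($Z = n|r|^2$). Watson–Williams (common mean
direction across groups) includes the $1 + 3/(8\hat\kappa)$ correction
and checks concentration homogeneity, warning rather than refusing when
$\hat\kappa < 1$. The Harrison–Kanji two-factor test implements the
high-concentration two-way decomposition with the
$1/(1 - 1/(5k) - 1/(10k^2))$ correction; below $\hat\kappa \approx 2$
the approximation degrades and the function warns. All three are
calibrated by null simulation in the test suite (type-I error within
[0.035, 0.065] at α = 0.05). Proportions of phase-locked cells are
compared with a pooled-variance two-proportion z-test under
Benjamini–Hochberg FDR control (the adjusted p-values come from
`stats::p.adjust`). Mixed-model inference (LME/GLMM, Tukey post hocs) is
deliberately out of scope: the pipeline exports tidy per-cell tables
(`metrics_long()`, `write_metrics_table()`) for lme4-style software,
with the intended model being metric ~ genotype × day × session-in-day
with animal and cell as random effects.

## The rate-constrained down-sampling control

To ask whether a metric difference is secondary to a rate difference,
`constrained_subsample()` draws 1000 subsamples of 30 cells (the
approximate per-animal cell count) with replacement, accepting only
subsamples whose mean rate is within ±5% of a target (e.g. the
reference population's day-2 mean). Each accepted subsample's metric
values are tested against the full population — Welch two-sample t-test,
or Watson–Williams for circular metrics — and the fraction of
significant subsamples at α = 0.05 is the *modulation probability*:
≈ 0.05 when the metric is rate-independent (the test's type-I level),
approaching 1 when the metric is rate-driven. The sampler is plain
rejection sampling with a 10⁶-per-subsample attempt budget; an
unattainable constraint raises a feasibility error reporting the
achieved acceptance rate. The full population is used as-is in each
comparison (subsample duplicates are not removed from it).
`rate_change_matched_subsample()` applies the same logic to the
between-day stability comparison, constraining the S3–S4 mean rate
*decrease* either to a reference value or to zero.

## The synthetic-session generator

The generator exists so that every stage has a ground-truth test bed;
no public recordings accompany the design it emulates. It produces:

* **Trajectories**: Ornstein–Uhlenbeck speed (target mean 10 cm/s,
  s.d. 4 cm/s, 2-s time constant) with a diffusing heading steered away
  from the wall and reflected at it. These defaults give > 93% arena
  coverage in a 600-s session and a plausible speed-bin occupancy
  profile.
* **Place cells**: inhomogeneous Poisson spiking from a Gaussian tuning
  curve. The rate is piecewise constant over the 20-ms position-sample
  intervals, which makes the sampling exact (per-interval Poisson
  counts, uniform placement) — position is only known at 50 Hz, so a
  finer rate grid would be interpolation, not information. Burstiness is
  injected as doublets at 4–8 ms ISI with a per-spike probability,
  directly controlling the burst statistic under test. Per-spike
  features are Gaussian around a cluster-specific centre, giving
  well-separated clusters for the quality metrics.
* **LFP**: 8/38/75-Hz carriers with slow frequency jitter plus 1/f-like
  noise; amplitudes optionally speed-coupled. Carriers avoid 48–52 Hz so
  mains-notch questions never arise in synthetic data.
* **Experiments**: six sessions × animals per group, with day-2 effect
  multipliers (`effect_spec`): rate multiplier, tuning-width multiplier
  (σ down ⇒ SI up), preferred-theta-phase shift, and an optional field
  displacement producing between-day partial remapping. Identity
  multipliers give the no-change pattern. The rate multiplier scales the
  cell's *session-mean* rate: when σ also changes, the tuning amplitude
  is renormalised by the ratio of in-disc field masses (computed
  numerically, so wall-truncated fields are handled exactly), which
  keeps the two effect axes orthogonal — a 0.7 rate multiplier yields a
  day-2/day-1 mean-rate ratio of 0.7 regardless of the tuning change,
  and the pipeline recovers it within sampling error.

What the generator does *not* emulate — and what passing tests therefore
do not establish about real data: theta-phase precession, ripples and
immobility firing, interneurons, electrode drift, cluster overlap from
real waveform variability, head-direction or boundary coding, and any
biophysics of the rate changes. Tests built on it validate the
*estimators* (bias, calibration, effect recovery), not the biology.

## Problem sizes and numerical choices

Simulation-based tests use 600-s sessions at 50 Hz for behaviour and
maps (the native session length of the design), LFP checks at 1.2 kHz —
comfortably above twice the highest analysed frequency (102 Hz) — and
populations of 100–200 cells for effect-recovery and down-sampling
calibration, which keep sampling error well inside the asserted bands.
Determinism is enforced end to end: identical seeds give identical
datasets, and the analysis side is seed-free.

Degenerate inputs fail loudly and specifically: constant LFP cannot be
z-scored; zero overall rate makes SI/sparsity undefined; zero masked
time makes rates undefined; maps with under 10 jointly valid bins are
excluded from stability with a reason. Fisher z clipping, the strict
inequalities at every published threshold (3 cm/s, 0.1/5 Hz, 15, 0.2,
250 µs, 9 bins, 20%, 0.5 bits/spike) and the 4-connectivity default are
all asserted by tests so they cannot drift.
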