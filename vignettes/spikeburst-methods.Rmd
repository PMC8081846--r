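---
title: "Burst detection, spike-train metrics and stimulation-train synthesis: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Burst detection, spike-train metrics and stimulation-train synthesis: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spikeburst)
```

## Scope and data model

`spikeburst` analyses trial-structured single-unit spike trains of the kind
recorded from visual cortex in awake head-fixed mice (typically 200 trials
of 1 s each), detects bursts with a two-stage mean-ISI threshold, summarises
each train with a suite of burst and rate metrics, selects exemplar cells
for replay experiments, synthesises rate-matched Poisson stimulation trains,
and provides the group-comparison statistics used for such experiments,
including mEPSC amplitude and frequency comparisons. Synthetic generators
for bursty trains and mEPSC samples make every stage testable with known
ground truth.

A `spike_train` stores trial-relative spike times (seconds) with 0-based
trial indices. Inter-spike intervals (ISIs) are computed strictly within
trials: the time between the last spike of one trial and the first spike of
the next is dead time, not an interval. Whether a concatenated ISI array
should include inter-trial gaps is genuinely open for trial-structured
acquisition; we exclude them because the inter-trial interval is not part
of the neuron's spontaneous stream. Times are serialised with six decimal
places (1 µs), comfortably finer than 25-kHz acquisition (40 µs).

One boundary convention deserves mention: a continuous ("plain") recording
whose duration is not stated is taken to extend exactly to its last spike,
so validation accepts spikes on the closed interval `[0, duration]`. This
keeps the firing-rate denominator equal to the observed span rather than an
arbitrary padded value.

## The two-stage mean-ISI burst threshold

All ISIs of a train are pooled (one threshold per train) and averaged
(stage 1). Every ISI **greater than or equal to** that mean is removed, and
the mean of the retained sub-mean ISIs is the burst threshold (stage 2).
The procedure runs exactly twice — there is no iteration to convergence. A
burst is a maximal run of **two or more consecutive** ISIs each **strictly
below** the threshold, and runs never cross trial boundaries.

Tie-breaks are deliberate: stage-1 removal uses `>=`, burst membership uses
`<`, so an ISI exactly at threshold is interburst. On a train whose ISIs
are all equal, stage 1 removes everything, the threshold is undefined, and
the train has zero bursts — reported as such rather than as an error, so
batch runs over heterogeneous cells never abort. The same applies to trains
with fewer than two ISIs.

For exponential ISIs with mean $\mu$ (a homogeneous Poisson train) the
threshold converges to the conditional mean

$$E[X \mid X < \mu] \;=\; \mu\,\frac{1 - 2e^{-1}}{1 - e^{-1}} \;\approx\; 0.41802\,\mu,$$

and the fraction of ISIs below threshold to $1 - e^{-0.41802} \approx
0.342$. The test suite checks both against simulation, and checks the
segmentation itself against an independent brute-force run scan on a
thousand random arrays.

## Train metrics

Per train, with total recorded duration $T$ (the sum of trial durations —
silent trials still count as recording time):

* average firing rate $= n_\text{spikes}/T$; frequency of bursts
  $= n_\text{bursts}/T$;
* mean burst length in ISIs and in spikes (a burst of $k$ ISIs spans $k+1$
  spikes), and mean burst duration (sum of member ISIs; no half-ISI margins
  are added);
* mean burst frequency $= 1/\overline{\text{ISI}}_\text{intra}$ and mean
  non-burst frequency $= 1/\overline{\text{ISI}}_\text{inter}$, each over
  the pooled labelled ISIs;
* fraction of ISIs in bursts — the conventional "fraction of spikes in
  bursts" is defined operationally as a ratio of ISI counts, and we
  implement that formula exactly despite its name;
* interior-gap statistics (number of interburst ISIs per gap, gap
  duration), counted only over maximal interburst runs lying between two
  bursts of the same trial. Leading/trailing non-burst stretches are not
  gaps "between bursts", though their ISIs still enter the non-burst
  frequency.

Metrics that depend on bursts are `NA` — never a number — when no burst
exists; gap metrics are `NA` unless some trial contains two bursts. Group
summaries report mean ± SEM (sample SD over $\sqrt{n}$), skipping undefined
cells with per-metric $n$. The exemplar of a group is the cell whose
average firing rate is closest to the group mean (ties: lexicographically
smallest cell id), the standard choice for picking a replay template.

## Poisson synthesis and stimulation protocols

`generate_poisson_train()` draws i.i.d. exponential ISIs at the requested
mean and accumulates them from the first draw (no spike at $t = 0$); no
refractory period is imposed. Draws are floored at 1 µs so that times stay
strictly increasing after 6-decimal rounding on export. The canonical
rate-matched train uses the reciprocal of the gray-screen group mean rate
(5.52 Hz → mean ISI 181.16 ms) over the full 7200-s (2-h) protocol.

Protocols are plain text: a version line, `duration_s` and `source`
metadata, then ascending pulse times at fixed 6 decimals with LF endings —
bit-exact across platforms, so identical seeds give byte-identical files.
Import validates the header, monotonicity and bounds, and round-trips
exactly. A 200-s recording cannot span 2 h; exemplar-based protocols
optionally replay the train end-to-end until the duration is filled, with
the repetition recorded in the source descriptor. This extension rule is
this package's own convention.

## The bursty generator and its calibration

The synthetic bursty process is an alternating renewal model: exponential
inter-event gaps (mean `nonburst_isi_mean_s`); each event is, with
probability `burst_prob`, a burst of $N = 3 + \text{Geom}$ spikes with
i.i.d. exponential internal ISIs (mean `intraburst_isi_mean_s`), else a
lone spike. It is the simplest process with independently controllable
rate, burst size and the two ISI scales, and it carries its generating
parameters as ground truth.

The condition presets (`DE`, `GRAY`, `PATTERN`) aim the **detected**
metrics of generated trains at the in vivo group means (rates
2.74/5.52/5.82 Hz; within-burst frequencies 33.17/54.28/51.30 Hz; non-burst
frequencies 1.39/2.34/2.56 Hz). The detector is nonlinear in the ISI
mixture: the threshold truncates the intraburst distribution, inflating the
detected within-burst frequency above the generating $1/\text{mean}$, and
ISIs from split bursts contaminate the non-burst pool. Indeed, once the
rate target is fixed, the mixture weight of intraburst ISIs is fully
determined by the two ISI scales, so generator constants cannot simply be
reciprocals of the targets, and no parameter choice matches all table
metrics at once. The preset constants were therefore fitted by a damped
fixed-point simulation sweep followed by a small grid refinement (moment
matching on rate and the two ISI-scale frequencies, burst probability held
fixed), and are stored in the package. With these constants, 10-seed means
at 1200 s recover the rate target within ±15% and both ISI-scale targets
within ±25%, with margin, across disjoint seed sets. Detected burst *rate*
and burst *length* are not matched (long generated bursts are split by the
threshold); they are reported but should not be read as emulating the
table.

What the generator does not emulate: slow non-stationarity across a 2-h
session, refractoriness, trial-locked stimulus responses, and any
correlation between burst size and gap length. Passing recovery tests
therefore show the pipeline is consistent on a stationary renewal world,
not that real cortical trains satisfy the model.

Synthetic mEPSC samples draw amplitudes from a log-normal law (CV 0.35)
truncated below at a 5-pA detection floor, with the scale solved
numerically so the truncated mean hits the target (e.g. 13.46 pA for the
dark-exposed group), and exponential inter-event intervals. The log-normal
choice reflects the right-skewed shape of empirical mEPSC amplitude
distributions; per-event distributions for the real groups are not
published, so these are stand-ins with the published means, 200 events per
cell by convention.

## Statistical battery

Routing is automated from the D'Agostino–Pearson omnibus test (implemented
from the published skewness and kurtosis transformations; the kurtosis
approximation needs $n \ge 8$, below which a sample is "untestable" and
routed non-parametrically). Both samples normal → pooled-variance unpaired
*t*; otherwise Mann–Whitney (exact when tie-free and small, tie-corrected
normal approximation otherwise; the reported statistic is the centred
standardised $U$). Three or more groups: one-way ANOVA with Bartlett's
variance-homogeneity test reported alongside and a Student–Newman–Keuls
post-hoc on the studentized-range distribution with stepwise range gating
(a Tukey HSD option is provided for comparison), or Kruskal–Wallis with
Bonferroni-adjusted Dunn comparisons. Either post-hoc runs only when the
omnibus is significant, so a pair can never be flagged under a
non-significant omnibus. An override flag forces a route when the
experimenter's choice is known. Cumulative distributions are compared with
the two-sample Kolmogorov–Smirnov $D$ and its asymptotic $p$, with a
stringent default cutoff of $p < 0.001$ as is conventional for large
per-event mEPSC samples.

Because the per-figure statistics of any particular study depend on raw
per-cell data, the battery is validated by calibration instead: under null
simulations (1000 replicates) each test's type-I error at $\alpha = 0.05$
must fall in [0.03, 0.07], and power simulations require SNK to flag
exactly the pairs involving a shifted group.

## Problem sizes and reproducibility

The test suite uses: the 10-ISI worked train (hand-derivable exactly),
1000 random arrays of ≤ 50 ISIs against the brute-force oracle, $10^5$-ISI
Poisson trains for the exponential-limit constants, 1200-s preset trains
over 10 fixed seeds for recovery, and 1000-replicate null calibrations.
`scripts/acceptance.R` regenerates the rate-matched 7200-s Poisson train
from a supplied seed and reports its measured rate. All randomness is
seeded; per-cell streams can be derived from a master seed by stable label
hashing so adding a cell never perturbs the others.

## Known limitations

* A published exemplar table lists a Poisson train with mean burst length
  2.38 spikes and burst fraction 0.06; under a ≥ 2-consecutive-ISI burst
  definition a burst has ≥ 3 spikes, and an exponential train puts ≈ 0.19
  of its ISIs in such runs, so those two entries cannot arise under this
  detector as specified. We reproduce the detector's wording, not that
  table row.
* The "fraction of spikes in bursts" is an ISI-count ratio (see above);
  its name suggests a spike-count ratio, which would differ.
* Detected burst rate/length for the bursty presets do not match the in
  vivo tables (splitting; see calibration section).
* The SNK and Dunn procedures are classical; no multiplicity adjustment
  across *metrics* is applied — that is the analyst's decision.
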