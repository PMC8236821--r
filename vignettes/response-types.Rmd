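---
title: "Identifying recurring response types in intracellular recordings"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Identifying recurring response types in intracellular recordings}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vmtypes)
```

## The problem

A neocortical neuron recorded intracellularly integrates synaptic input
from thousands of partner neurons, so its membrane potential is a read-out
of the momentary state of the subnetworks it is embedded in. When the same
spatiotemporal tactile stimulation pattern is delivered many times, the
evoked 350-ms voltage trajectory varies widely across repetitions — yet the
variations are not arbitrary: responses tend to recur in a small number of
stereotyped shapes, the *response types*. This package implements the
complete chain needed to identify such types and to test that they are
statistically real: shape normalisation, an unsupervised threshold-based
clustering, per-timepoint nonparametric specificity tests with a shuffle
null, PCA + kNN decoding, ECoG brain-state association, and single-pulse
EPSP quantification. Because real whole-cell data are large and scarce, a
seeded synthetic-session generator with planted ground truth accompanies
every stage.

## The clustering model

Windows are compared on their *shape*: each 350-ms window is low-pass
filtered (1-ms boxcar), resampled to 1 kHz, freed of its offset by
subtracting a centred 100-ms moving average, and min-max scaled to
[0, 1]. Two normalised windows $a$ and $b$ belong to the same type when
the mean overshoot above a per-sample threshold stays small:

$$ \frac{1}{350}\sum_t \max\!\big(0, |a_t - b_t| - \theta\big) \; < \; \omega $$

with the threshold difference $\theta = 0.13$ and the overshoot bound
$\omega = 0.08$ (normalized units). The hinge construction de-emphasises
brief large transients and stresses persistent low-amplitude differences.
Types are extracted greedily: every remaining window is a candidate leader
whose group is itself plus its direct matches; the largest candidate group
becomes the next type (ties resolved towards the lowest repetition index);
extraction repeats until no windows remain, and groups with fewer than
five members dissolve into an *ungrouped* class. A leader's group contains
only direct matches — no transitive closure — which is the most literal
reading of the pairwise decision rule; the alternative (closing the
relation transitively) would chain dissimilar windows together through
intermediates. The complete pairwise sweep is evaluated first and
extraction happens afterwards, so the result does not depend on the order
in which comparisons were made.

Degenerate (flat) windows cannot carry shape information; they are filled
with 0.5, flagged, and forced into the ungrouped class so record counts
stay aligned.

### Parameters that matter

| parameter | default | units | role |
|---|---|---|---|
| threshold difference $\theta$ | 0.13 | normalized | per-sample tolerance |
| overshoot bound $\omega$ | 0.08 | normalized | mean-overshoot decision bound |
| minimum members | 5 | windows | smallest valid type |
| explained variance | 0.95 | – | PC count for decoding |
| kNN $k$ | 4 / 9 | neighbours | within-pattern / cross-scope |
| KW alpha | 0.05 | – | per-timepoint significance |

The sensitivity grid (`sensitivity_grid`) re-runs the clustering across a
$\theta \times \omega$ grid and reports the number of types, the ungrouped
proportion and a neighbour-cell *cluster agreement*: for every cluster of a
grid cell, the proportion of its members contained in the best-matching
cluster of each of the up to eight neighbouring cells, averaged first over
clusters and then over neighbours. Around the default cell the landscape
is smooth, i.e. the clustering is not brittle in its parameters.

## Statistical validation

**Per-timepoint specificity.** At every 1-ms sample of the (up to 1200-ms)
windows, each type is tested against all other responses of the same
(neuron, pattern) cell with a two-group Kruskal-Wallis test
(tie-corrected; equivalent to a rank-sum chi-square). The curve of the
fraction of types significant at $\alpha = 0.05$ summarises the dataset.
No correction across samples is applied; instead, the same analysis after
shuffling the type labels within each cell serves as the control — under
the null the time-averaged fraction sits at $\alpha$. The implementation
ranks each sample once and reuses the ranks across types and shuffles,
which makes the 50-shuffle null cheap; it is verified against
`stats::kruskal.test` in the unit tests.

A structural property of this test is worth recording: a type whose
amplitudes lie at the pooled rest-mass midpoint at some sample produces no
rank shift and is undetectable there *regardless of how well separated the
types are*. With $k$ types per cell this caps the expected per-sample
fraction near $1 - 1.5/k$; the observed curves (synthetic and, by its
published band, real) sit in the 0.6–0.85 range during stimulation.

**Decoding.** The PC basis is fitted on the type mean curves only (centred
on their mean), with the component count chosen to explain 95% of the
mean-curve variance; this keeps the basis independent of the
trial-to-trial noise. All responses are projected and classified by the
relative majority among their $k$ nearest training responses over 40
random half splits; class ties fall back to the single nearest neighbour
(a decision needed because $k = 4$ admits 2–2 ties). F1 scores are
computed per class from the summed confusion counts. Splits that leave a
class empty on either side are redrawn. Cross-scope tasks exclude the
ungrouped class, whose heterogeneity would otherwise dominate; the
cross-scope PCA is centred on the mean of the type mean curves, consistent
with the within-pattern construction.

**Brain state.** The ECoG is cut into 1000-ms segments hopping by 875 ms;
each segment is mean-detrended and its periodogram power summed over
(0, 12] Hz (no additional tapering — the quantity of interest is a
relative comparison against the median, not an unbiased spectrum). A
segment is desynchronized only when strictly below the median power for at
least two consecutive segments; ties and isolated dips count as
synchronized. A stimulus onset inside the 125-ms overlap of two segments
takes the later segment's state. Each type's desynchronized fraction is
paired with its own cell's fraction (paired t-test), once for all types
and once restricted to types with more than nine members, whose fractions
move in finer steps.

**Single-pulse EPSPs.** The manual cursor measurements of the original
workflow are replaced by an automated detector: the onset is the first
post-pulse time at which the 1-ms-smoothed derivative exceeds the
pre-pulse mean plus three SDs for at least 0.5 ms (searching 1–25 ms after
the pulse, clear of the blanked artifact span); the peak is the maximum
within 30 ms of onset. Detection templates are built from at least 100
aligned events as 5–20 equally spaced time-voltage checkpoints with
tolerances of twice the across-event SD (floored at 0.2 mV), and matching
requires every checkpoint of the offset-corrected trace to fall within
tolerance. A pulse's response fraction is gated against the spontaneous
baseline measured in twelve 14-ms bins before every pattern onset: the
response is significant only above the baseline mean plus two SDs and with
at least five matched events; non-significant entries are excluded from
the relative-amplitude and relative-latency summaries (which are expressed
as multiples of the same channel's isolated single-pulse means).

## The synthetic-data generator

The generator is the package's test bed: it produces sessions whose
ground truth (planted type labels, EPSP events, ECoG state intervals,
spike times) is known exactly.

**Membrane potential.** An Up/Down telegraph (gamma-distributed dwells,
means 1.2 s Down / 0.8 s Up, levels −72/−60 mV) carries correlated noise
(OU-like, 10-ms correlation, 0.4 mV), spontaneous EPSP shot noise,
stimulus artifacts (1-ms biphasic, blanked by the pipeline) and occasional
stereotyped spikes. Slow state flips are deferred until just after each
evoked window — the stimulus-locked reset of the slow oscillation — so a
planted response shape is not confounded by a mid-window state flip.

**Evoked responses.** Each (neuron, pattern) cell owns $k$ latent
templates (default 3–5) built from four components: a slow network-drive
envelope taking type-specific levels in eight ~44-ms blocks (in every
block the types split into a depolarised and a quiescent cluster with
distinct sub-levels, re-shuffled per block), a spindle-band oscillation
with a type-specific phase, pulse-locked EPSP kernels whose gains co-vary
with the envelope, and a smooth type-specific perturbation. Construction
is rejection-sampled until the templates are mutually separated (pairwise
mean absolute difference at least 0.24 on the [0, 1] template scale, and
pairwise mean overshoot at least 0.12 — one and a half times the
clustering decision bound — after window normalisation). Two further
design points matter:

* *The diffuse (ungrouped) process is repulsive.* Every ungrouped draw
  must stay at least 0.10 mean overshoot away from each planted template
  and from recent previous draws. The first constraint keeps the ground
  truth coherent (a draw that matches a type *is* that type) and removes
  the pathological case where a draw lying between two types matches both
  and bridges them into one greedily extracted group; the second prevents
  diffuse draws from condensing into spurious small types.
* *Per-window normalisation constants must not encode type identity.*
  Long statistics windows are min-max scaled over their full extent, so
  whatever sets their extrema leaks into every sample. The extended
  drives therefore share a fast, stereotyped biphasic off-response whose
  post-filter extrema dominate the window, the drives are rescaled so
  their filtered ranges agree to 2%, all drives join a common end anchor
  before the off-response, and the window tail carries the spontaneous
  slow-wave regime. Together these make the post-stimulation samples
  carry no type information, so the significant fraction collapses to
  chance within ~150 ms of stimulation offset, as it should.

Why a mean-absolute-difference of 0.24 and not more: for smooth curves
min-max scaled to [0, 1] the geometric ceiling of the pairwise mean
absolute difference is ≈ 0.4 (reached only by anti-phase binary
switching), and multi-component realistic curves land below ≈ 0.37. The
operative margin for the clustering is the pairwise mean overshoot, which
the generator enforces directly.

**Pulse times.** Inter-pulse intervals are drawn log-uniform on
[1, 123] ms and compressed proportionally when a draw overruns the 340-ms
pattern bound; pulse counts are 5–33 per pattern, summing near 152 over
the default eight patterns. The published patterns' exact pulse times are
not public, so pulse-count-dependent results (such as the exact number of
analysis-eligible pulses) are statistical stand-ins.

**Single-pulse statistics.** Amplitude, onset latency and time-to-peak
are hierarchical: within-neuron values are gamma-distributed with CVs
0.43, 0.28 and 0.29, and the neuron means vary so that the pooled
population statistics are 7.7 ± 4.8 mV, 11.1 ± 3.1 ms and 9.8 ± 5.6 ms.
(The latency needs no between-neuron spread: its within-neuron SD already
equals the pooled SD.) In-pattern pulses carry a neuron-specific
relative-gain mosaic (log-normal, mean ≈ 0.22 of the isolated amplitude)
with modest trial jitter and faster decay, reflecting the driven
high-conductance regime during patterned stimulation.

**ECoG.** Synchronized epochs carry a large 1.5–3.5 Hz oscillation whose
amplitude waxes and wanes with a ~1.8-s period over broadband noise;
desynchronized epochs (gamma dwells, mean 4 s, ~20% of session time) are
attenuated broadband noise. The periodic waxing keeps neighbouring
segment powers anti-correlated, so isolated below-median synchronized
segments rarely form runs of two — without it, the median split marks
roughly a third of synchronized segments as desynchronized and no
generator could reach high segmentation agreement at a 20% true fraction.

**What the generator does not emulate.** Type templates are stylised
(block envelopes, phase-tagged spindles); real types differ in slower,
less structured ways. Electrode drift, seal degradation, line noise and
slow anesthesia-depth trends are absent. The Up/Down process is
uncoupled from the ECoG state by default (the two are correlated but not
equivalent in vivo; the coupling is deliberately off so state-association
nulls are exact). Passing tests therefore demonstrate that the analysis
recovers truth under controlled, favourable-but-plausible conditions —
not that it is robust to every artifact of real recordings.

## Numerical choices and degenerate inputs

* Both moving averages use shrinking windows at the edges, so outputs
  keep the input length; resampling to 1 kHz is plain decimation after
  the 1-ms average (which supplies the anti-aliasing).
* Windows are half-open `[onset, onset + duration)` with 0-based sample
  indexing; windows truncated by the end of the recording are dropped
  and counted (recordings lost mid-protocol are thereby handled).
* A window whose range is below 1e-9 is degenerate: filled with 0.5,
  flagged, excluded from clustering.
* Statistics windows are normalised over their full 1200-ms extent (the
  350-ms alternative would tie the constants even more tightly to the
  type-specific stimulation epoch).
* Greedy ties (equal candidate-group sizes) resolve to the lowest
  repetition index; re-numbering after dissolving small types preserves
  extraction order.
* All-tied samples give p = 1 in the rank tests; classes with fewer than
  two members are skipped.
* The kNN tie-break is the nearest neighbour's class; splits are simple
  random halves, not stratified; degenerate splits are redrawn.
* Every simulation consumes one master seed, with per-component
  sub-streams derived from it, so partial re-configuration leaves
  unrelated components unchanged and reruns are bit-identical.

## Problem sizes used in the tests

The bundled tests run the clustering-recovery property at 80 repetitions
per cell over 20 seeds, the shuffle-null calibration on 4 cells × 4 types
× 80 repetitions with 50 shuffles, the stimulation-window separability
bound on 24 cells × 5 types × 100 repetitions, and the measurement
calibration on 400 single-pulse trials. The acceptance script evaluates
the same quantities at 48 cells × 100 repetitions. The per-sample
significant fraction concentrates as the number of cells grows: with only
a handful of cells its minimum over 341 samples fluctuates by ±0.07,
which is why the bound is evaluated at the study-like scale of dozens of
cells.

## Known limitations

* The clustering relation is non-transitive; the greedy extraction is a
  deterministic, well-tested resolution of it, but alternative orderings
  (e.g. extracting tightest rather than largest groups) would produce
  different partitions on borderline data.
* The adaptive-filter artifact suppression of the original workflow is
  unpublished; blanking with linear interpolation stands in for it.
* Between-neuron decoding requires several simulated neurons and is
  correspondingly slow; the pipeline exposes it but the default test
  scale exercises the within-pattern and cross-pattern scopes.
* Session containers use TSV + RDS rather than a hierarchical array
  format, keeping the package dependency-free.
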