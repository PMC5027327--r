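---
title: "Discovering lobe-level EEG patterns with decision trees: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Discovering lobe-level EEG patterns with decision trees: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(neurotree)
```

## The question and the method

When a person handles an object they cannot see, which cortical regions
carry the information that distinguishes one object from another?
`neurotree` operationalizes this question as an interpretable machine
learning problem: record multi-channel EEG while a subject handles a
sequence of objects (ball, cube, parallelogram, separated by rest
"interval" periods), reduce the recording to a small labeled feature
table, induce a decision tree that classifies the handled object from the
per-electrode band power, and then read off **which electrodes the tree
chose to split on**. An electrode chosen as a split attribute is evidence
that its cortical region carried class-discriminative activity; a lobe
none of whose electrodes appears is, under this operationalization, not
informative for the task. Contrasting the lobes selected for different
subject groups (e.g. congenitally blind vs sighted) turns an opaque
classifier into a neuroscientific statement: if occipital electrodes
appear only in sighted subjects' trees, visual cortex was informative
only for them.

The pipeline is deliberately simple and fully seeded, so that every
artifact — recording, feature table, tree, rule list, attribution
report — is reproducible from a subject identifier and an integer seed.

## Synthetic recordings

No public EEG corpus matches this protocol, so the package ships a
simulator that generates sessions with the statistical structure the
analysis assumes. Its defaults are the package's study conditions:

* **Montage**: the standard 32-electrode active-cap 10-20 layout
  (`build_default_montage()`), each electrode annotated with lobe and
  hemisphere. Lobe assignment follows the electrode prefix: `Fp/F/FC/FT`
  frontal, `T/TP` temporal, `C` central, `CP/P` parietal, `O` occipital.
  Centro-parietal (`CP*`) electrodes sit over parietal cortex and are
  mapped to the parietal lobe; `C3/Cz/C4` form their own "central" row.
* **Signal envelope**: scalp EEG amplitudes lie within 0–200 µV with
  spectral content in roughly 0.3–100 Hz. Baseline activity is Gaussian
  white noise shaped by a second-order Butterworth band-pass to that
  band, scaled to a 20 µV standard deviation. If any sample would exceed
  the 200 µV cap the **whole recording** is rescaled by one common
  factor; clipping is avoided because it would distort the relative band
  power that the downstream contrast depends on.
* **Sampling rate**: 512 Hz by default. Only the post-averaging instance
  rate matters downstream, so the raw rate is configurable.
* **Epoch schedule**: `interval 1 s, ball 2.5 s, interval 1 s, cube
  2.5 s, interval 1 s, parallelogram 2.5 s, interval 1 s`. At 512 Hz
  with the 32-sample preprocessing buffer this yields 40 instances per
  object class and 64 interval instances, so balancing lands exactly on
  40 per class — the bookkeeping the rest of the pipeline expects.
  "interval" is a first-class label: rest periods participate in
  balancing, grouping and tree induction like any object class.
* **Discriminative activity**: during an epoch of class *c*, channels
  whose lobe is in `active_lobes_per_class[[c]]` additionally carry
  band-limited 8–13 Hz (alpha-band) noise at `burst_gain` times the
  baseline amplitude scale. The default `burst_gain = 3` produces a
  strong, clearly separable contrast after squaring and averaging — an
  idealization chosen so that the grouped tables are class-separable,
  matching the regime in which the tree analysis is meaningful.

**Subject profiles.** `subject_profile()` encodes the two simulated
groups. Both groups engage frontal and parietal cortex (executive and
tactile processing); only the sighted group engages occipital cortex
(visual imagery of the handled object):

* sighted: ball → parietal, cube → **occipital**, parallelogram → frontal;
* blind: ball → parietal, cube → frontal, parallelogram → frontal + parietal.

The per-class assignment within each group's lobe set is a modeling
choice the data cannot dictate. Occipital activity is attached to the
*middle* object (cube) deliberately: the first and last object epochs
are contiguous blocks at the edges of the session, so the instance index
(`Time`, itself a tree attribute) can often separate them on its own,
whereas the middle object stays temporally interleaved with interval
groups and can only be isolated by a channel. Attaching the
group-defining lobe to that class makes the group contrast depend on
channel information, not on epoch timing — which is the mechanism the
pipeline is meant to detect.

What the simulator does **not** emulate: volume conduction and realistic
cross-channel covariance, 1/f ("pink") spectral shape, eye-blink and
muscle artifacts, electrode drift, or inter-subject variability beyond
the seed. Passing tests therefore show that the pipeline's inference
mechanism works when lobe-specific band power is present; they do not
show that real recordings satisfy those assumptions.

## Preprocessing chain

Each channel passes through three stages
(`to_feature_table()`):

1. **Band-pass**: an order-4 Butterworth band-pass, 3.5–30 Hz, keeping
   the theta/alpha/beta rhythms. Filtering is causal (forward-only) by
   default, matching the real-time semantics of an online BCI chain;
   zero-phase forward-backward filtering is available via `zero_phase =
   TRUE`. Cutoffs at or above Nyquist are rejected with the offending
   cutoff named. The analytic magnitude response of the design is
   exposed as `bandpass_response()` (direct polynomial evaluation of
   H(z) at z = e^{i2πf/rate}) and the suite checks the measured
   sinusoid attenuation against it to within 1 dB at ten probe
   frequencies.
2. **Squaring** (`square_signal()`): x·x removes the sign so that
   averaging measures power instead of cancelling oscillations.
3. **Buffered averaging** (`buffered_average()`): non-overlapping
   buffers of 32 samples reduced to their mean; a trailing partial
   buffer is dropped rather than padded, because padding would inject
   synthetic amplitudes. At 512 Hz this yields 16 instances per second,
   each a mean band power in µV².

Each buffer becomes one instance; its class is the majority epoch label
within the buffer, with ties resolved toward "interval" so an ambiguous
buffer is never credited to an object. `Time` is the 1-based instance
index.

## Feature-table preparation

* **Balancing** (`balance_classes()`): every class is downsampled,
  uniformly at random without replacement under a seed, to the
  minority-class count (40 under the default schedule). Within-class
  time order is preserved.
* **Normalization** (`normalize_minmax()`): each channel column is
  independently mapped to [0, 1] by (x − min)/(max − min); a constant
  column maps to 0. Normalization precedes grouping; grouping first
  would change every threshold the tree later prints.
* **Peak grouping** (`group_peaks()`): within each class, instances in
  time order are partitioned into windows of 10 (≈1 s of instances) and
  each window emits one instance holding the per-channel **maximum**,
  with the window's latest `Time`. Windows never mix classes, so the
  balanced 4 × 40 table becomes exactly 4 × 4 = 16 instances. Grouping
  is applied per class rather than per contiguous run: the interval
  class occupies four separate runs whose post-balancing lengths vary,
  and run-wise windows would lose groups to truncation, breaking the
  4-per-class bookkeeping that defines the analysis table. Trailing
  partial windows are dropped.
* **Channel subsetting** (`select_channels()`): optionally restricts the
  table to a named electrode list. `default_channel_subset()` provides a
  12-electrode reduced montage spanning all five lobe groups (Fp1, F3,
  F7, Fz, FT9, FT10, CP1, CP2, P4, P7, Pz, O1); the particular list is a
  configurable stand-in, not a canonical fact.

## The tree inducer

`induce_tree()` is a from-scratch C4.5-style binary inducer on numeric
attributes. All non-`Class` columns — including `Time` — are candidate
attributes.

* **Split criterion**: at each node every attribute's candidate
  thresholds (midpoints between consecutive distinct sorted values) are
  scored by **gain ratio** — information gain divided by the split
  information of the two-way partition — and the maximum is taken among
  splits with strictly positive gain and at least the minimum leaf count
  on both sides. Gain ratio is bounded by 1, attained exactly when every
  class falls wholly on one side of the cut.
* **Minimum leaf size**: expressed as a fraction of the training set
  (`min_leaf_fraction`, default 0.01) and converted to a count by
  ceiling, so 1% of 16 instances still means at least 1 instance.
* **Stopping**: purity, no admissible split, or fewer than twice the
  minimum leaf count remaining.
* **Tie-breaking**: equal gain ratios (within 1e-9) resolve to the
  earlier attribute column, then the lower threshold — induction is
  deterministic given the table.
* **Pruning**: pessimistic subtree replacement. A leaf's error is
  estimated as n times the Wilson-score upper confidence bound on its
  observed error rate at `confidence_factor` (default 0.25); bottom-up,
  a subtree collapses to a leaf when the leaf estimate does not exceed
  the sum of its descendant leaves' estimates. Subtree *raising* and the
  MDL correction on numeric-split gain found in later C4.5 releases are
  intentionally omitted for clarity; trees may therefore differ from
  J48's output in borderline cases, though not in the regimes exercised
  here. Missing values are unsupported — the pipeline never produces
  them.

`predict()` follows thresholds (≤ left, > right) to a leaf and returns
its majority class, erroring on any missing tested attribute.
`extract_rules()` emits one rule per leaf in root-to-leaf order; the
rules are mutually exclusive and jointly exhaustive. `render_indented()`
and `render_dot()` print the same tree as indented text and as a
Graphviz digraph, thresholds to 3 decimals.

## Lobe attribution

`attribute_tree()` resolves every split attribute through the lobe map:
a lobe is **present** exactly when at least one of its electrodes
appears as a split attribute anywhere in the tree — depth is recorded
but deliberately ignored for the presence decision, since a shallow and
a deep split both certify that the inducer found the electrode
informative. `Time` and other non-electrode attributes are tallied
separately and belong to no lobe. `compare_reports()` reduces two
reports to shared / one-sided lobe sets, the group-contrast statement of
the analysis.

## Why mechanism recovery uses the reduced montage

The cohort-level check of the pipeline (20 simulated sighted vs 20 blind
subjects; occipital presence rate difference) runs on the 12-electrode
reduced montage. The reason is a degeneracy of clean synthetic data: in
a perfectly separable 16-instance table every class-respecting cut —
genuine or lucky — ties at the maximal gain ratio of 1, and the
deterministic tie-break then favors earlier montage columns. With 31
competitor columns the probability that some irrelevant channel happens
to order a small node perfectly is substantial, and the occipital
electrodes, last in the montage, lose every such tie. Reducing to 12
channels lowers that collision probability enough for the genuinely
informative occipital electrode to be selected in nearly every sighted
run while never appearing in blind runs. This mirrors standard practice
of pruning uninformative electrodes before interpreting a tree, and the
choice was fixed as part of the experiment design, on its own
simulations, before the cohort check was written.

## Problem sizes and runtime choices

Tests run each simulated session at 512 Hz × 11.5 s × 32 channels
(~189k samples), grouped tables at 16 instances × 33 attributes, the
split-selection oracle on 100 random tables of ≤ 12 instances × 3
attributes, and the cohort comparison on 20 + 20 subjects; the whole
suite completes in well under a minute on one CPU. Filter-response
agreement is asserted to 1 dB; split-oracle agreement to 1e-10 on the
gain ratio; all other checks are exact.

## Known limitations

* The simulator's idealizations (above) mean the pipeline's behavior on
  real, artifact-laden EEG is untested here.
* Resubstitution accuracy is reported because the analysis goal is
  pattern discovery on the training subjects themselves, not
  generalization; it must not be read as a classifier benchmark.
* The 16-instance analysis table makes tree structure sensitive to
  single instances; the minimum-leaf sweep (1%, 5%, 10%) is the provided
  control for that fragility.
* Binary numeric splits only; no categorical attributes, no missing
  data, no cross-validation machinery.
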