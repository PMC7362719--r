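---
title: "Blinded classification of dreamful and dreamless sleep: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Blinded classification of dreamful and dreamless sleep: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(dreamcatcher)
```

## The problem

Can the presence versus absence of dream experience be read out of a sleep
polysomnogram alone, without access to the sleeper's report?  The protocol
this package implements phrases that question as a fully blinded,
step-wise classification exercise.  A cohort of 54 one-minute NREM
(Stages 2--3) pre-awakening polysomnogram segments -- 27 followed by a
dream report, 27 by a report of dreamless sleep, three of each from each
of nine participants -- is stripped of all identifying information and
handed to an analysis side that must sort the recordings into the two
conditions.  Blindness is then lifted in five steps: first nothing is
known beyond the 54 case ids, then the 27 dreamful/dreamless pairs from
the same participant, then the nine participant groups, then the 18
participant-condition groups, and finally the two 27-case condition
groups (whose dreamfulness identity is still withheld).  After each step
the scoring side returns only an accuracy, evaluated by an exact
two-tailed binomial test at that step's decision granularity (54 cases,
27 pairs, 27 pairs, 9 participants, 1 decision).

The package implements both sides of this protocol -- the data/scoring
side as an information-gated oracle, the analysis side as a five-step
pipeline -- together with a synthetic cohort generator that emulates the
study design, so the whole procedure can be exercised end to end and its
operating characteristics studied under known ground truth.

## The analysis machinery

### Combination clustering

All unsupervised stages use an evidence-accumulation ensemble referred to
as *combination clustering*.  Many weak *sub-clusterings* are run, each a
2-means on a small random subset of features (never more than nine at a
time, to sidestep the curse of dimensionality; in the case-level
configuration every single feature is also clustered on its own).  Each
sub-clustering contributes its co-membership pattern to a co-association
matrix, weighted by its mean silhouette (clipped at zero, since the
tallies are frequencies).  The accumulated matrix is clustered
hierarchically on the dissimilarity `1 - coassociation` (average linkage
at Steps 1--2; Ward at Steps 3--4, which resists the uneven cluster sizes
average linkage tends to produce on this kind of matrix).  Because the
design guarantees two near-equal classes, the dendrogram is cut at the
threshold whose best single cluster is closest to half the cases; ties go
to the highest threshold (fewest clusters), and everything outside the
chosen cluster forms the other class.

With the canonical case-level configuration (subset sizes 2--9, 10 000
random combinations per size, plus one run per single feature) the
fine-resolution power set of 2475 features yields 82 475 sub-clusterings.
Simulation studies in this package use reduced ensembles (typically 30--60
combinations per size, 5 k-means restarts) and a 100 Hz sampling rate;
these sizes are stated where used and were chosen so that a full
five-step run completes in about two minutes on one core while leaving
the qualitative behavior of the ensemble unchanged.

### Features

Power spectra are estimated by Welch's method with 2-s Hann windows and
80% overlap (0.5-Hz native resolution), mean-detrended per segment and
scaled so the integral of the density recovers the signal variance.  All
log transforms are natural logs of uV^2/Hz.  The candidate sets for the
Step-1 screen are: per-channel log PSD at 99 fine bins (0.5--49.5 Hz);
log band powers in the six classical bands; autocorrelation summaries
(1/e decay time, first zero crossing, lag-1 value); permutation entropy
(order 3, delay 1) and approximate entropy (m = 2, r = 0.2 SD, computed
on a 4x-decimated trace); EOG and EMG RMS per 15-s quarter; and an
11-feature emulation of the posterior "hot zone" findings.  The Step-2
set condenses this to 50 features: 19 geometrically spaced scalp-average
log-PSD bins over 0.5--49.5 Hz (computed at 0.125-Hz resolution so no
bin is empty), the 11 hot-zone features, and per modality (EMG, EOG) the
0/25/50/75/100th percentiles of 1-s-window RMS in each 30-s half.

The hot-zone emulation operates on scalp electrode groups of a fixed
10-20/10-10 montage (the source montage is not public, so a concrete
25-channel subset is defined in `standardMontage()`), with low = 1--12 Hz
and high = 18--50 Hz, whole-scalp and regional band-averaged log power
over trailing 20/40/60-s windows.  The exact electrode lists, windows and
entropy parameters are documented defaults and configurable; they stand
in for unpublished supplementary definitions.

### Temporal-consistency screening

Step 1 selects its feature set by clustering each 15-s quarter of every
case independently and measuring the agreement of adjacent-segment
clusterings: `C = 2|pi1 - 1/2|`, where `pi1` is the fraction of cases
keeping co-membership under one of the two possible label mappings
(`pi1 + pi2 = 1`, so `C` is relabeling-invariant).  Significance is
assessed against a Monte-Carlo null of independent random balanced
labelings (Bonferroni-corrected quantile; the original null's cluster
size model is unpublished, so balanced labelings are the documented
default) and by an exact binomial test on the agreement count under the
better mapping (N = cases; the per-case reading of the count is a
documented choice where the original is ambiguous).  A one-tailed
permutation test probes rising trends toward awakening.  The screen only
ranks; choosing the winning set remains an analyst decision, as in the
original protocol.

### Paired geometry (Steps 2--4)

Once pairs are known, each pair becomes a *difference vector*: the
Studentized feature vectors of its two members are subtracted, the
arbitrary polarity canonicalized (first non-zero coordinate positive) and
the vector normalized to unit length.  The *mean orientation* of a set of
such sign-ambiguous vectors is the unit vector maximizing the mean
absolute cosine similarity.  The maximizer is found by alternating
sign-assignment/averaging ascent, initialized from the leading
eigenvector of the outer-product sum plus ten seeded random restarts,
with a 1-opt/2-opt local search over sign flips interleaved for small
sets (n <= 20) -- the objective is non-convex and the bare alternating
scheme stalls in shallow sign-pattern fixed points.  For up to 15
vectors an exhaustive sign-enumeration reference,
`meanOrientationExact()`, certifies the ascent in the test suite to
1e-9; on random stress instances the polished ascent still misses the
global optimum about once per thousand sets, which is the practical
price of avoiding the exponential enumeration at production sizes.  A hyperplane through the origin
normal to the mean orientation splits every pair -- members always land
on opposite sides, exact ties go to the positive side -- and side
co-membership is tallied into the co-association matrix.  Pairwise
sub-clusterings are weighted by their mean absolute cosine similarity
divided by its Monte-Carlo expectation under random orientations of
matched number and dimension, making goodness comparable across subset
sizes (these expectations are memoized per size).

Step 3 averages four co-association matrices: pairwise splits against
the global mean orientation; pairwise splits against each participant's
own orientation; case-level 2-means sub-clustering; and within-participant
2-means tallied globally.  Each component matrix is normalized to [0, 1]
by its own accumulated weights before the equal-weight average, so the
two weight families (normalized cosine goodness, silhouette) never need
cross-calibration -- this is the package's resolution of an
underspecified averaging step.  Step 4 replaces the 27 pair vectors by 9
per-participant condition-group mean difference vectors and proceeds the
same way, with each group's three cases inheriting their group's side.

### ICA cleanup (Steps 3--4)

Participant-specific, condition-irrelevant structure is removed by a
per-participant ICA over the concatenated EEG+EOG channels (EMG is never
touched): whitening followed by a symmetric fixed-point iteration with a
tanh contrast.  Near-Gaussian sources make the contrast surface flat, so
the iteration is capped (default 100 iterations on a subsampled design
matrix) rather than required to converge; the decomposition remains
deterministic under its seed, and with full retention it reconstructs
the input to numerical precision -- the property the pipeline actually
relies on.  Component relevance is scored from the paired design: per
component, the within-pair difference of log component power under the
polarity that maximizes its absolute mean (equivalently the mean
absolute difference -- pair member order is blinded, so a fixed-order
signed mean would be ill-defined), scaled by its standard error; Step 4
scores the participant's condition-group mean contrast instead.  The top
half of components by score is retained by default; the original
selection criterion is unpublished, and the fraction is exposed as a
parameter.

### Labeling and evaluation

Clusters are mapped to conditions by the literature-derived rule: the
cluster with higher low-frequency (1--12 Hz) and lower high-frequency
(18--50 Hz) log power is called dreamless, quantified as the mean
per-bin Cohen's d between clusters.  When the two bands disagree in
sign, the band with the larger |mean d| decides and the conflict is
recorded on the call -- the original adjudication was qualitative, so
this quantitative precedence rule is the package's own documented
choice.  Step 4 additionally consults the frontal high-frequency
hot-zone contrast (lower power indicating absent dreaming) as the
tiebreaker.  Step 5 compares the two condition groups on three summary
features (parieto-occipital 1--4 Hz power, parieto-occipital +
lateral-frontal + temporal 20--50 Hz power, left fronto-temporal
0.50--4.75 Hz power) after subtracting each participant's mean, by
majority vote; a tied vote is an error rather than a guess.

Cohen's d uses the standard pooled SD for raw samples and
`sqrt((s1^2 + s2^2)/2)` for summary inputs -- the convention that
reproduces the protocol's printed effect sizes from its printed summary
statistics.  Scoring uses the exact point-probability two-tailed
binomial test (equal to the doubled tail, capped at one, under a fair
null), and the design's sensitivity is characterized by Monte-Carlo
power of a one-tailed paired t-test on Gaussian unit-SD differences --
the minimal model consistent with the stated assumption.

## The synthetic cohort

`synthCohort()` generates the full blinded design: 9 participants x 3
sessions x 2 conditions.  Each EEG channel is 1/f^a colored noise
(spectral shaping of white noise by inverse FFT) plus amplitude-modulated
delta bursts and 12--15 Hz spindles, with additive white sensor noise;
EOG carries slow conjugate eye-movement events plus frontal crosstalk;
EMG is high-pass-shaped noise.  Two participant random effects (overall
log-power offset, SD 0.4 on the natural-log scale; spectral exponent,
mean 1.5, SD 0.2) reproduce the dominant between-participant structure
that defeated the original Step-1 clustering -- note that "participant
variance off" in simulation studies means zeroing *both*.  The condition
effect is purely spectral: dreamful cases have 0.5--4 Hz power divided
by `condition_delta_ratio` and 18--50 Hz power multiplied by
`condition_high_ratio`, applied as a band filter to the assembled signal
(so the injected in-band log-power contrast is exact before sensor
noise), weighted per electrode position (low-frequency effect
concentrated parieto-occipitally, high-frequency frontally, 0.25--0.5
elsewhere).  The defaults (ratios 2.2 and 1.8) give a per-case band-power
Cohen's d of roughly 1.5 with participant effects off -- deliberately
large for parameter-recovery testing, and explicitly synthetic: the
original study's central result is that no such recoverable effect was
found in real data, so the generator treats effect size as a free
parameter, not a claim.  EOG/EMG activity is condition-independent by
default; `eog_coupled`/`emg_coupled` optionally couple it to condition
to reproduce the observation that ocular and muscular features dominated
the mid-step clusterings.

What the generator does *not* emulate: sleep microstructure
(K-complexes, stage transitions), non-stationarity across the minute,
volume-conduction-realistic topographies, or source-level "hot zones"
(regional effects are injected at scalp electrode groups).  Passing
parameter-recovery tests therefore shows the pipeline is correct and
sensitive under its own assumptions -- not that the assumptions hold for
real sleep EEG.

## Numerical choices and degenerate inputs

Blinded labels are random bijections drawn from a single master seed;
every stochastic stage (k-means restarts, subset sampling, Monte-Carlo
nulls, ICA initialization) derives an independent stream from its
configuration seed, so whole runs are bit-reproducible.  Zero-variance
features Studentize to all-zeros with a warning; identical pair members
are excluded from difference sets with a warning; an all-identical
sub-clustering input yields one cluster with weight zero; a uniform
co-association matrix is a hard error (nothing to separate); exact
hyperplane ties go to the positive side; a zero-variance series has
approximate entropy 0 by convention.  EDF storage quantizes to 16 bits
(the round-trip tolerance is the per-channel quantization step); the
float64-plus-JSON-header `raw` format is lossless and is what the test
suite uses when exactness matters.

## Known limitations

The Step-1 screen and entropy features are computationally heavy at full
rate; defaults decimate entropy inputs and the simulation studies run at
100 Hz.  The hot-zone emulation is a scalp-level proxy for source-level
findings.  Several supplementary-level details of the original protocol
(exact hot-zone lists, ICA component selection, Step-3 averaging
weights, the null model's cluster sizes) are unpublished; each is
implemented as a documented, configurable default and flagged above.
The mean-orientation ascent is certified against the exhaustive
reference only for small sets; for 27 vectors the restarts make failure
unlikely but unproven.
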