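# dreamcatcher

Blinded, unsupervised classification of dreamful vs. dreamless NREM
sleep from 1-minute polysomnograms — the full two-team protocol
(blinding, step-wise disclosure, analysis, scoring) plus a synthetic
cohort generator to exercise it under known ground truth.

## Who this is for

Sleep/consciousness researchers who want to study the operating
characteristics of blinded EEG classification protocols, and method
developers who need a reference implementation of co-association
ensemble clustering ("combination clustering") with paired-design
geometry (difference vectors, mean orientations, hyperplane
sub-clustering) on polysomnographic features.

## The core machinery

* **Design**: 54 blinded cases (9 participants × 3 sessions × 2
  conditions), disclosure in five steps (nothing → pairs → participants
  → participant-condition groups → condition groups), scored per step
  by an exact two-tailed binomial test on 54 / 27 / 27 / 9 / 1
  decisions.
* **Combination clustering**: thousands of 2-means sub-clusterings on
  random feature subsets (size ≤ 9), silhouette-weighted into a
  co-association matrix *M*; hierarchical clustering on 1 − *M*
  (average or Ward linkage) cut at the threshold whose best cluster is
  closest to *n*/2.
* **Temporal consistency** (Step-1 screen):
  *C*(*m*, *n*) = 2·|π₁(*m*, *n*) − ½| with π₁ + π₂ = 1 over the two
  possible cluster-label mappings between independently clustered 15-s
  segments, against a Monte-Carlo null.
* **Paired geometry** (Steps 2–4): per pair a polarity-canonical unit
  difference vector of Studentized features; the mean orientation **v**
  maximizes mean |cos(**v**, **uᵢ**)| (alternating ascent, certified
  against exhaustive sign enumeration for small sets); a hyperplane
  normal to **v** sub-clusters cases so pair members never co-associate,
  weighted by Monte-Carlo-normalized goodness.
* **Labeling**: the cluster with higher low-frequency (1–12 Hz) and
  lower high-frequency (18–50 Hz) log power is called dreamless
  (per-bin Cohen's *d*, *d* = (μ₁ − μ₂)/σ); Step 4 adds a frontal
  high-frequency tiebreak, Step 5 a three-feature majority vote after
  per-participant centering.
* **Synthetic cohorts**: 1/f^α EEG background with participant random
  effects, delta bursts, spindles, EOG/EMG activity, and an exact
  multiplicative condition effect on 0.5–4 Hz and 18–50 Hz band power
  with regional weights.

## Worked example

```r
library(dreamcatcher)

# a synthetic blinded cohort with a strong injected condition effect
cfg <- cohortConfig(seed = 101, rate = 100,
                    participant_effect_sd = 0, spectral_exponent_sd = 0,
                    condition_delta_ratio = 4, condition_high_ratio = 2)
coh    <- synthCohort(cfg)
oracle <- DataTeamOracle(coh$truth, coh$key)

rc <- runConfig(seed = 9,
  ensemble        = ensembleConfig(sizes = 2:9, combinations = 30, seed = 9),
  paired_ensemble = ensembleConfig(sizes = 2:9, combinations = 25,
                                   singletons = FALSE, seed = 9))
ex <- runExperiment(coh$cases, oracle, rc)
ex$table
```

```
  Step Information revealed Number of decisions Number correct Accuracy (%)
1    1                 Case                  54             54          100
2    2                 Pair                  27             27          100
3    3              Subject                  27             27          100
4    4    Subject-condition                   9              9          100
5    5            Condition                   1              1          100
             p
1 1.110223e-16
2 1.490116e-08
3 1.490116e-08
4 3.906250e-03
5 1.000000e+00
```

With participant random effects off and a large spectral effect, every
step recovers the truth; the first row says all 54 case-level decisions
were correct, with the exact two-tailed binomial p against chance.
Replacing the condition effect by strong participant variance
(`participant_effect_sd = 1, condition_delta_ratio = 1`) reproduces the
protocol's characteristic failure mode instead: clustering groups by
participant, so most pairs wrongly co-cluster and accuracy drops to
chance.  `truthTable(oracle)` is an error — the analysis side can only
ever see `reveal(oracle, step)` and the returned accuracies.

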