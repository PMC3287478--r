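---
title: "Target-aware drug-drug relationship scoring: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Target-aware drug-drug relationship scoring: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pairdrs)
```

## The problem and the model

Structural similarity (a Tanimoto coefficient over substructure
fingerprints) is the workhorse measure of drug relatedness, but it misses a
well-documented phenomenon: many structurally unrelated drugs bind the same
protein target. `pairdrs` instead *learns* a drug-drug relationship score
(DRS) from known drug-target interactions, under the assumption that pairs
sharing a target carry a common, learnable signature in chemical descriptor
space even when their global structures differ.

The estimation is cast as a large-scale binary classification over unordered
drug pairs:

* **positive** pairs share at least one annotated target;
* **negative** pairs are annotated on both sides with disjoint target sets;
* pairs with an unannotated member are **unknown** — excluded from training
  but still scoreable.

Each drug is first represented by the principal components of its cleaned
molecular descriptors. A pair $(a, b)$ with projections
$x^{(a)}, x^{(b)} \in \mathbb{R}^k$ becomes the concatenation of two
$k$-vectors,

$$ M_i = \tfrac{1}{2}\left(x^{(a)}_i + x^{(b)}_i\right), \qquad
   E_i = \left(x^{(a)}_i - x^{(b)}_i\right)^2 , $$

the *basal chemistry* of the pair and its per-component *divergence*. Both
are symmetric in $a$ and $b$, so the score cannot depend on pair order; $E$
is kept as a vector rather than collapsed to a distance so the classifier
can weight divergence differently per component.

An ensemble of $L = 10$ probability Random Forests is trained, every forest
on the same positives but a different under-sampled negative set. With
$p_\ell$ the positive-class vote fraction of forest $\ell$,

$$ \mathrm{DRS}(a,b) \;=\; \frac{2}{L}\sum_{\ell=1}^{L} p_\ell(a,b) \;-\; 1
   \;\in\; [-1, 1], $$

so 0 is the majority-vote boundary and $(\mathrm{DRS}+1)/2$ puts the score
on the same unit scale as a Tanimoto similarity.

## Descriptor cleaning and the component space

`clean_descriptors()` removes descriptors that (a) failed to compute for any
drug (carried as a missing-cell mask, never silently zeroed or imputed) or
(b) take their modal value in strictly more than 90% of drugs. The
strictly-greater-than comparison means a descriptor constant in exactly 90%
of drugs survives. The rule is idempotent.

`fit_pc_space()` z-scores the surviving columns by default before the SVD.
Descriptor pools mix counts, logP-type quantities and fingerprint bits whose
ranges differ by orders of magnitude; without standardization the
widest-ranged columns dominate every component. A flag disables it for
pre-scaled input. The component count $k$ is the smallest whose cumulative
explained variance reaches the target (default 90%); $k$ is therefore a
property of the data, not a tuning knob. Loadings follow a fixed sign
convention (largest-magnitude element positive) so fits are identical across
runs and platforms.

## Inverse-density under-sampling

Negative pairs outnumber positives by an order of magnitude here and by far
more in real interaction databases. Uniform under-sampling would
over-represent the bulk of mutually dissimilar pairs and teach the forests
little about the hard region. Instead, each negative pair is weighted by the
reciprocal of the *density* of its fingerprint Tanimoto similarity across
all negative pairs, and each of the ten sets (sized to the positive count)
is drawn without replacement under those weights. Rare-similarity pairs —
including the structurally similar ones — are therefore over-included, and
the sets stay structurally diverse.

The density estimator is a 50-bin histogram on $[0,1]$ by default (a
Gaussian KDE with Silverman bandwidth is selectable). A floor of
$\varepsilon = 1/(10n)$ is added to every bin before normalization so empty
bins cannot yield infinite weights. Sets are drawn independently — two sets
may overlap, which keeps every classifier's training distribution identical;
within a set pairs are unique. All draws derive from one integer seed.

## Training and validation

Forests use Breiman defaults: 500 trees (200 in the package's own
experiments, see below), `mtry` $= \lfloor\sqrt{2k}\rfloor$, minimum node
size 1. Forest $\ell$ is seeded with `seed` $+\ \ell$, making the ensemble
reproducible while decorrelating forests even if two negative sets happened
to coincide.

Two validation routes mirror standard practice:

* **Internal**: the out-of-bag votes of a *single* classifier
  (`oob_validation_scores()`). Each pair is scored only by the trees whose
  bootstrap excluded it, so the estimate is honest; using one classifier
  avoids averaging away the OOB property across forests that share the
  positives.
* **External**: `holdout_split()` removes 50 whole drugs before training;
  every pair touching a held-out drug is unseen and scored by the full
  ensemble. This mimics scanning a library with a novel query compound.

Performance is reported as sensitivity/specificity sweeps
(`sensitivity_specificity_curve()`), compared against Tanimoto baselines
from any supplied fingerprint set at matched specificity.

## Target transfer

`predict_targets()` turns pair scores into target candidates: a target's
score is the **maximum** DRS between the query and any database drug
annotated with it, and ties are broken by the number of such drugs scoring
above 0.5 (the configurable `tie_threshold`), then lexicographically for
determinism. Evidence drugs are optionally split into those sharing a known
target with the query and those sharing none; rankings from the second
table are genuinely new predictions.

`known_target_recovery()` evaluates the scheme leave-one-drug-out: each
query is removed from the database so it cannot vouch for its own targets,
and the curve reports the fraction of drugs recovering a true target within
each rank. The query's own annotation is used only to define success and the
evidence split, never as evidence.

## The synthetic benchmark

`generate_synthetic()` builds a fully self-contained dataset in which every
downstream claim is checkable against planted ground truth:

* targets are partitioned into **domain families** (default: 2 targets per
  family); family centroids are drawn iid $\mathcal{N}(0,\sigma_b^2 I)$ with
  background spread $\sigma_b$ (`noise_sd`, default 1.0), and each target
  sits a small offset (sd `domain_sd`, default 0.25) from its family
  centroid. Same-family targets are therefore chemically adjacent, which is
  what makes domain matching among high-scoring negative pairs a meaningful,
  non-trivial signal;
* each drug binds $1 + \mathrm{Poisson}(\mu - 1)$ targets
  ($\mu$ = `mean_targets_per_drug`, default 1.5 — a modest mean degree with
  a heavy single-target majority, as in curated interaction databases) and
  its descriptors are drawn around the mean of those targets' centroids with
  within-cluster spread `cluster_sd` (default 0.3);
* a `promiscuity` fraction (default 10%) of drugs additionally binds one
  target from a *foreign* family **without moving in descriptor space** —
  these create the structurally dissimilar common-target pairs that plain
  structural similarity cannot rank highly, the regime the DRS exists for;
* fingerprint bits threshold noisy random projections of the descriptors
  (projection noise sd 1.0), so Tanimoto similarity correlates with, but
  does not equal, descriptor proximity — an informative yet beatable
  baseline;
* ATC codes are derived from the planted clusters: the level-2 prefix
  identifies the domain family, the level-3 character the target. Drugs
  inherit one code per primary target.

Defaults (200 drugs, 20 targets, 60 descriptors, 128 bits, seed 7) are the
package's standard study conditions and are used unchanged by the test suite
and the acceptance script. What the generator does **not** emulate: real
chemistry (no SMILES, no correlated descriptor blocks), heavy-tailed target
degree distributions, annotation noise, or assay bias. Passing on synthetic
data therefore demonstrates that the machinery implements its contracts and
recovers planted structure — not that the learned scores transfer to any
particular interaction database.

## Numerical choices and degenerate inputs

* Two all-zero fingerprints have Tanimoto $0/0$; the package defines the
  similarity as 0.
* A constant similarity sample breaks Silverman's bandwidth rule; the KDE
  falls back to a fixed bandwidth of 0.05.
* Pairs are always canonicalized (`drug_a < drug_b` lexicographically) so
  written artifacts are deterministic.
* DRS threshold 0 equals majority vote 0.5 exactly; no calibration beyond
  the linear rescale is applied.
* Fitted spaces and models are persisted with `saveRDS()` (the R idiom); a
  `schema_version` field is stored for forward compatibility.
* Pairs never out-of-bag (possible at very small tree counts) are omitted
  from OOB tables with a logged count.

## Problem sizes

The package's own experiments run at the generator defaults: 19,900 pairs,
roughly 2,100–2,500 positives, ten forests of 200 trees each over
$2k \approx 26$ features ($k \approx 13$ at the 90% variance target), and a
50-drug hold-out. A full train-and-evaluate cycle takes on the order of a
minute on one CPU; the 500-tree default in `train_drs_ensemble()` is the
recommended setting for real descriptor tables, where feature counts are in
the thousands.

## Known limitations

* The negative class is defined by *absence of annotation*; some training
  negatives are unrecorded positives. The domain-matching analysis turns
  this from a flaw into a prediction channel, but it biases measured
  specificity downward.
* The evidence universe for ATC-matching curves is the supplied test set's
  partner ranking; with a different ranking universe the absolute curves
  change (the DRS-vs-baseline comparison is run on identical universes).
* Inverse-density weights depend on the chosen density estimator; the
  histogram default is robust but coarse near 0 and 1.
* The optional SMILES fingerprint path (atom-pair, 1024-bit folding) is a
  convenience, not a reimplementation of any published fingerprint standard;
  results depend only on bit algebra, so any binary fingerprint table can be
  supplied instead.
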