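---
title: "Ligand- and structure-based classification of hERG liability: models and methods"
author: "hergml authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ligand- and structure-based classification of hERG liability}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE, collapse = TRUE, comment = "#>")
```

## The problem

Off-target blockade of the hERG potassium channel is the most frequent cause
of drug-induced QT prolongation and, ultimately, fatal arrhythmia, which is
why hERG liability is screened as early as possible in discovery campaigns.
Two computational families dominate that screening. *Ligand-based* (LB)
classifiers learn from the structures of known binders — physicochemical
descriptors and hashed circular fingerprints — and are accurate for
chemistry similar to their training set but degrade on novel chemotypes.
*Structure-based* (SB) classifiers instead featurize each compound by the
scores that docking programs and rescoring functions assign to its predicted
binding poses in the channel pore; they need no structural similarity to the
training set, but docking scores are a noisy readout of affinity.

`hergml` implements the comparative workflow end to end: activity-data
curation to binary binder labels, both feature families, two pose-score
aggregation strategies, correlation-based feature selection, random-forest
modelling with cross-validation and consensus voting, and a four-method
applicability-domain (AD) consensus. Because the original training data mix
a commercial database with public sources, and the docking engines are
proprietary, the package ships a synthetic-data generator that emulates both
the activity tables and the engine output, with enough controlled structure
that every claim the workflow makes can be tested.

## Curation model

Raw activity records carry a compound id, a SMILES string, an endpoint type
(IC50, EC50, Ki or Kd), a relation qualifier, a value and a concentration
unit. Curation applies, in order:

1. endpoint vocabulary filtering, and optional exact-match filtering on
   `target`/`organism` columns when present (source selection);
2. exclusion of censored records (relation `>` or `<`) — these carry only a
   bound, not a measurement;
3. conversion to pK, the negative decadic logarithm of the molar
   concentration, so 10 µM ↦ pK 5;
4. structure standardization: largest covalent fragment (salt stripping),
   neutralization, canonical SMILES (OpenBabel);
5. collapse of duplicate structures to the **median** pK, pooled across
   endpoint types — the median is taken in pK space, not concentration
   space (the two differ for even-sized groups; log-space medians are the
   robust convention for mixed-endpoint potency data);
6. labelling: *binder* iff pK ≥ 5 (boundary inclusive), the 10 µM
   hit-calling convention.

Tautomer canonicalization is deliberately not applied; the cleaning
sequence covers salts, charges and functional-group normal forms only.

## Ligand-based features

Eleven physicochemical descriptors (logP, TPSA, molecular weight, rotatable
bonds, H-bond donors and acceptors, heteroatoms, atoms, heavy atoms,
declared stereocentres, fraction of sp³ carbons) plus two 1024-bit hashed
circular fingerprint blocks of diameter 6: an element-invariant block
(ECFP6, computed by OpenBabel and folded from 4096 to 1024 bits by OR) and a
functional-class block (FCFP6-like, a Morgan iteration over atom roles —
donor, acceptor, basic, acidic, aromatic, halogen — implemented in the
package because no installed toolkit provides it). Total: 2059 features.

Tanimoto similarity on the ECFP6 block drives the AD similarity method and
diversity splitting. Two all-zero fingerprints have similarity defined as 1
(two featureless structures are indistinguishable); this convention only
matters for near-empty structures.

Chemical-space summaries use a 26-descriptor panel (the 11 above plus 15
standard 2-D counts such as rings, aromatic atoms, basic nitrogens, acidic
groups, amide bonds and molar refractivity — a documented stand-in for an
unspecified commercial panel), standardized and decomposed by PCA with a
fixed sign convention (each component's largest-magnitude loading positive).
Murcko frameworks are obtained by iteratively pruning terminal atoms until
only ring systems and inter-ring linkers remain; acyclic molecules fall
into an explicit "no-scaffold" group.

## Structure-based features

A pose-score table holds, per engine, one row per (compound, stereoisomer,
pose rank) with the engine's primary score (lower is better; it defines the
stored ranking) and 25 rescoring functions; the LiGen engine adds a
29-column pharmacophore-distance block for 55 columns in total. Direction
conventions are carried as metadata and never used to flip values.

Two aggregations produce one row per compound:

* **best pose (BP)** — the rank-1 row of each stereoisomer, averaged
  column-wise across isomers;
* **average (AV)** — the pooled column-wise mean over *all* poses of all
  isomers (the "binding space" view). With equal pose counts per isomer
  this equals the mean of the isomer means, so no weighting question
  arises.

"Top ranked" always means the engine's stored `pose_rank`; rescoring
columns never re-rank poses. Multi-engine consensus blocks concatenate
engine-prefixed columns over the intersection of compounds docked by every
engine (compounds undocked by any engine are excluded and logged).

## Feature selection

Correlation-based feature selection (CFS) scores a subset `S` by

$$\mathrm{merit}(S) \;=\; \frac{k\,\bar r_{cf}}{\sqrt{k + k(k-1)\,\bar r_{ff}}}$$

with `k = |S|`, `r̄_cf` the mean absolute feature–class correlation and
`r̄_ff` the mean absolute pairwise feature–feature correlation. The package
uses plain Pearson correlation against the 0/1 class (point-biserial); the
toolkit this mirrors discretizes features and uses symmetric uncertainty
instead, but the continuous form is deterministic, fast and has the same
qualitative behaviour (relevance rewarded, redundancy penalized). One
algebraic consequence worth knowing: an exact duplicate of a selected
feature leaves the merit *unchanged* at `k = 2` (it does not lower it), so
duplicate removal relies on the search preferring the smaller subset, which
the name-order tie-break guarantees.

The search is forward best-first: an open list of subsets ordered by merit,
expanded from the best unexpanded state by single-feature additions,
stopping after 5 consecutive expansions that fail to improve the best merit
found (the conventional patience). Ties are broken by feature-name order,
making the selection fully deterministic. On data sets with at most ten
features the result is verified against exhaustive enumeration in the test
suite. Selection is always fitted on the full training partition, never
inside cross-validation folds — with selection outside the folds the CV
estimate is mildly optimistic, but it matches the printed workflow this
package mirrors (a single selected descriptor list reused everywhere), and
the external validation set provides the unbiased check.

## Modelling and evaluation

The classifier is a 100-tree random forest (unlimited depth, probability
forest, impurity importance), delegated to `ranger` with a fixed seed and
one thread, so training is bit-reproducible. Prediction refuses any input
whose columns do not exactly match the training schema. The binder label is
assigned at probability ≥ 0.5; the boundary goes to binder, preferring
sensitivity under the binder-heavy class balance these data sets have.

Ten-fold cross-validation is stratified by class and seeded; fold
assignment is keyed on compound identifiers, so metrics are invariant to
row order. Out-of-fold predictions are pooled and scored once. Metrics are
MCC, accuracy, precision, sensitivity, specificity (with binder as the
positive class) and a rank-statistic AUC (probability that a random binder
outscores a random non-binder, ties at ½ — identical to trapezoidal ROC
integration but trivially testable against pair enumeration). Zero
denominators return 0 and are flagged; they never occur in realistic runs.

The diversity split mirrors a MaxMin picker on Tanimoto distance: a seeded
random first pick, then repeatedly the compound farthest (by minimum
distance) from the picked set, until the test fraction (default 30%) is
reached. Consensus prediction over several models is a minimum-vote rule:
binder iff at least `minVotes` (default 3) models vote binder; votes are
unweighted.

## Applicability domain

Four methods, each fitted on the training descriptors/fingerprints:

1. **similarity** — nearest-neighbour ECFP6 Tanimoto strictly above 0.7
   ("higher than" is a strict inequality, so Tc = 0.7 is outside);
2. **range** — inside the training min/max box of the first two
   standardized PCA components (closed interval, with a 10⁻⁸-scale
   numerical guard so training extremes re-project onto their own
   boundary). The range is taken in PCA space rather than on raw
   descriptors, matching how the verdict is reported alongside the other
   methods;
3. **Euclidean** — standardized-space distance to the training centroid at
   most the 95th percentile of training distances;
4. **density** — Gaussian product-kernel density on the first five PCA
   components (KDE in the full descriptor space would be degenerate),
   bandwidth by the multivariate rule of thumb
   $h_d = \sigma_d\,(4/(d+2))^{1/(d+4)} n^{-1/(d+4)}$, at least the cutoff
   covering 95% of training points.

The 95/95 thresholds are package choices (the upstream AD software's
internal defaults are not published); both are calibrated by construction,
which the tests verify on seeded Gaussian clouds. The consensus verdict is
inside-domain iff at least 3 of the 4 methods agree; it is monotone in
every flag. The similarity-accuracy trend report bins nearest-neighbour
Tanimoto into 0.1-wide intervals and tabulates per-bin accuracy — the
diagnostic separating similarity-dependent (LB) from similarity-independent
(SB) reliability.

## The synthetic-data generator

The generator stands in for two proprietary inputs: the activity databases
and the docking engines. It is a first-class, tested module, not a fixture.

**Structures.** Compounds are assembled from a closed three-slot fragment
grammar — 12 aryl heads, 12 alkyl/ether/amide linkers, 14 amine or polar
tails — echoing the aryl-plus-basic-amine chemotypes that dominate hERG
binder collections. All 2016 combinations are valid SMILES, so descriptor
and fingerprint computation is real chemistry. A disjoint novel sub-grammar
(6 heads, 5 linkers, 6 tails) supports external sets whose nearest-neighbour
similarity to a reference cohort decreases as the requested dissimilarity
(`low`/`medium`/`high` ↦ 20%/60%/100% novel-slot probability) rises.

**Latent affinity.** Each compound's affinity combines three ingredients:

* a lipophilicity term: `lipophilicityShift` (default 1.0) times the
  standardized residual of computed logP on TPSA;
* a polarity penalty: `polarityShift` (default 0.7) times the standardized
  residual of TPSA on logP (sign-reversed);
* a chemotype term: `scaffoldEffectSd` (default 0.8) times a fixed
  standard-normal offset attached to every (head, tail) fragment pair,
  drawn once from an internal constant seed so the SAR landscape is a
  property of the grammar itself, identical across cohorts and seeds;
* Gaussian noise `pkNoiseSd` (default 0.5; at 0 the pK is an exact
  function of structure, which the curation tests exploit).

The residualization makes the two shift parameters orthogonal by
construction: setting `lipophilicityShift = 0` removes the class contrast
in logP exactly, even though logP and TPSA correlate across the grammar.
The chemotype term is what gives fingerprints similarity-dependent signal:
a model can learn the offsets of chemotypes it has seen but not of novel
fragments, which is the mechanism behind the accuracy-versus-similarity
trend. Affinity maps to pK by standardization: pK = 5 + `pkSpread`·(z −
z\*), where z\* places the binder fraction at its target (default
7303/12789 ≈ 0.571, the class balance of the emulated training
collection), so pK mass concentrates near the 5.0 labelling threshold and
labels follow binomially. Emitted activity records spread each compound
over 1–3 exact measurements across endpoint types and µM/nM units, plus a
5% admixture of censored records for the curation filter to discard.

**Pose scores.** For each engine, every scoring function receives a loading
drawn once per engine from uniform(0.3, 1) — negative for the
lower-is-better primary score, weakly negative (0–0.2) for the LiGen
pharmacophore distances. A pose's score is

```
score = loading × (affinity + compound noise + pose noise) + engine bias + jitter
```

i.e. the noise perturbs the *binding quality the pose presents*, and every
scoring function sees that common perturbation through its own loading,
with only a small per-column jitter (¼ of the pose noise) independent.
This loading-mediated form matters: if the shared noise entered additively
outside the loadings, the 26-column system would be near-invertible and a
forest could recover the latent affinity essentially noise-free, making
structure-based models implausibly strong. Compound-level noise
(`compoundNoiseSd` 1.2) is split 70% shared across engines / 30%
engine-specific — docking's systematic errors look similar to every
program — so a multi-engine consensus helps without washing compound noise
out. Pose-level noise (`poseNoiseSd` 2.5) strictly exceeds compound-level
noise, which is exactly why averaging over the five poses denoises and AV
models beat BP models; at `poseNoiseSd = 0` all poses of an isomer are
identical and BP ≡ AV, a degenerate case the tests assert. Poses are
ranked by the noisy primary score (rank 1 = best), 2.4% of compounds per
engine fail to dock (seeded binomial), and 10% of compounds appear as
2-isomer groups sharing affinity but drawing independent pose noise.

These defaults were fixed once, by calibrating the generator to the
qualitative structure the workflow is known to produce on real data —
ligand-based models strongest in cross-validation, structure-based MCC in
the 0.3–0.5 range, average-score models above best-pose models, combined
models best on external sets — and have not been revisited since.

**What the generator does not emulate.** Real pose geometry (no 3-D
conformers and no physically meaningful score magnitudes), assay
heterogeneity beyond unit/endpoint mixing, correlated measurement error,
activity cliffs sharper than the per-chemotype offsets, tautomers, and the
scale (10⁴ compounds, 6732 scaffolds) of the real collections. Passing
tests therefore demonstrate that the *pipeline machinery* is correct and
that the qualitative orderings follow from the stated noise structure —
not that any particular accuracy will be achieved on real hERG data.

## Problem sizes used by the tests and the acceptance script

The test suite works at cohort sizes of 400 for unit-level properties and
2000 (ten seeds) for the model-ordering properties; AD calibration uses
10 000 seeded Gaussian points; the selection oracle enumerates all subsets
of up to 10 features over 100 random draws. The acceptance script runs one
full experiment at 2000 training compounds, a 320-compound external set and
three 150-compound trend sets. These sizes were chosen as the smallest at
which the measured quantities are stable against seed variation.

## Known limitations

* The CFS correlation measure deviates from the discretized
  symmetric-uncertainty original; selected subsets will differ in detail.
* Forward-only best-first search cannot drop a feature once added.
* Murcko pruning removes exocyclic double-bonded atoms (e.g. ring
  carbonyl oxygens), a simplification of some framework definitions.
* The stereocentre count covers declared centres only (wedge/@-annotated),
  not potential ones.
* Fingerprint folding (4096→1024) slightly inflates bit collisions
  relative to direct 1024-bit hashing.
* The AD density method operates on five principal components; domains in
  the full descriptor space would be tighter.
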