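# hergml

Ligand- and structure-based random-forest classification of hERG channel
liability, in one tested R workflow.

Blockade of the hERG potassium channel is the leading cause of drug-induced
QT prolongation, so candidate compounds are screened for hERG liability as
early as possible. Two model families compete for that job: *ligand-based*
(LB) classifiers trained on molecular descriptors and fingerprints, and
*structure-based* (SB) classifiers trained on the scores that docking
engines and rescoring functions assign to a compound's predicted binding
poses. `hergml` implements the full comparative pipeline for
medicinal-chemistry and predictive-toxicology groups who want to build,
compare and audit such models:

* **curation** — raw activity tables (IC50/EC50/Ki/Kd with relation
  qualifiers and units) to one labelled record per unique standardized
  structure: censored values excluded, values converted to
  pK = −log₁₀(molar), salts stripped and charges neutralized, duplicate
  measurements collapsed to their median, *binder* iff pK ≥ 5 (10 µM);
* **LB features** — 11 physicochemical descriptors + ECFP6 and FCFP6
  1024-bit hashed circular fingerprints (2059 features), Tanimoto
  similarity, Murcko scaffold summaries, chemical-space PCA;
* **SB features** — multi-engine, multi-pose score tables aggregated per
  compound by *best pose* (rank-1 scores, averaged over stereoisomers) or
  by the *binding-space average* (pooled mean over all poses), plus
  multi-engine consensus blocks;
* **feature selection** — correlation-based subset merit
  k·r̄꜀f / √(k + k(k−1)·r̄ff) searched by deterministic forward best-first;
* **modelling** — seeded 100-tree random forests, stratified ten-fold
  cross-validation, MaxMin diversity splits, ≥3-vote consensus prediction;
* **evaluation** — MCC, accuracy, precision, sensitivity, specificity and
  rank-based AUC, with binder as the positive class;
* **applicability domain** — 3-of-4 consensus of fingerprint similarity
  (Tc > 0.7, strict), PCA range, centroid distance and kernel-density
  criteria, plus the accuracy-versus-similarity trend report;
* **synthetic data** — a fragment-grammar generator that emulates curated
  activity databases and docking/rescoring output (5 poses × 3 engines,
  25 rescoring functions, 55-descriptor LiGen mode, 2.4% docking
  failures, stereoisomer groups) with controlled statistical structure,
  so the whole pipeline runs and is tested without proprietary data or
  docking software.

## Worked example

Simulate a 400-compound cohort, curate it, build both feature families and
compare cross-validated models:

```r
library(hergml)

cfg <- generatorConfig(nCompounds = 400, seed = 42)
cohort <- generateCohort(cfg)
cohort
#> SyntheticCohort: 400 compounds ( 238 binders ), 598 activity records, 3 pose table(s)

curated <- curateActivities(cohort@activities)
head(curated, 3)
#>                   canonical_smiles       pK  label n_measurements
#> 1 C(Cc1ccc(cc1)c1ccccc1)CCN1CCOCC1 7.006230 binder              2
#> 2  C(Cc1ccc(cc1)c1ccccc1)CN1CCCCC1 6.620932 binder              1
#> 3 C(CN1CCCCC1)COc1ccc(cc1)c1ccccc1 6.086849 binder              2

lb <- computeLBFeatures(cohort@compounds$smiles, ids = cohort@compounds$compound_id)
lb
#> FeatureMatrix: 400 compounds x 2059 features ( lb_fp:2048, lb_physchem:11 )

selected <- bestFirstSelect(lb, cohort@compounds$label)
head(selected, 6); length(selected)
#> [1] "logP"           "TPSA"           "ECFP6_0498"     "FCFP6_0401"
#> [5] "HBondAcceptors" "FCFP6_0227"
#> [1] 60

labels <- cohort@compounds$label
cvLB <- crossValidate(subsetFeatures(lb, features = selected), labels, modelSpec(seed = 1))
cvLB
#> EvaluationReport (n = 400 ): TP 204 TN 121 FP 41 FN 34
#>   MCC=0.609  ACC=0.812  AUC=0.882  precision=0.833  SE=0.857  SP=0.747

av <- assembleConsensusFeatures(lapply(cohort@poseTables, averagePoseFeatures))
bp <- assembleConsensusFeatures(lapply(cohort@poseTables, bestPoseFeatures))
lf <- function(f) labels[match(compoundIds(f), cohort@compounds$compound_id)]
compareModels(list(LB = cvLB,
                   `SB best-pose` = crossValidate(bp, lf(bp), modelSpec(seed = 1)),
                   `SB average`  = crossValidate(av, lf(av), modelSpec(seed = 1))))
#>      metric        LB SB best-pose SB average
#> 1       MCC 0.6086598    0.5408116  0.5600255
#> 2       ACC 0.8125000    0.7801609  0.7882038
#> 3       AUC 0.8820158    0.8167882  0.8660677
#> 4 precision 0.8326531    0.7795918  0.8070175
#> 5        SE 0.8571429    0.8721461  0.8401826
#> 6        SP 0.7469136    0.6493506  0.7142857
```

The selection starts with logP and TPSA — lipophilicity and polarity are
the dominant axes separating hERG binders from non-binders — then adds
fingerprint bits marking specific chemotypes. The ligand-based model is
strongest in cross-validation, and the binding-space average beats the
best-pose aggregation: averaging over poses cancels pose-level scoring
noise. Both orderings are asserted as multi-seed properties in the test
suite. `runExperiment()` (or `inst/scripts/run_experiment.R` with a YAML
config) packages these stages, external validation and the applicability
domain into a single reproducible run directory.

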