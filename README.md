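# rxrec

Medication recommendation from small longitudinal electronic medical
records (EMR), for methodologists and clinical-informatics researchers who
need the full pipeline — data model, pre-training, adversarial fine-tuning,
evaluation and ablations — runnable on a laptop CPU and on synthetic data.

## The problem and the model

Given a patient's admission sequence, where visit *t* carries a set of
ICD-10-style diagnosis codes *d<sub>t</sub>*, NDC-style drug codes
*m<sub>t</sub>* and symptom terms *s<sub>t</sub>*, the task is multi-label
prediction of the drug set of the current visit (*t* ≥ 2) from the history
plus the current diagnoses and symptoms. Longitudinal (multi-visit)
records are scarce; single-visit records are plentiful. The model combines
three ingredients:

1. **Ontology-aware code embeddings.** Codes are leaves of classification
   trees (e.g. `J98.4` under `J98`; 14-digit drug codes segmented
   country/category/enterprise/product/final). A leaf embedding is a
   multi-head graph attention over the leaf and its ancestors,
   *o<sub>c</sub>* = ∥<sub>k</sub> σ(Σ<sub>j∈N<sub>c</sub></sub>
   a<sup>k</sup><sub>c,j</sub> W<sup>k</sup> h<sub>j</sub>),
   so sibling codes share statistical strength.
2. **Pre-trained visit encoder.** Each visit field is encoded by a small
   transformer (no positional encodings — fields are sets); the `[CLS]`
   state is the field's visit embedding. Pre-training on single-visit
   records combines a masked-EMR-field objective (recover the field's code
   set from a partially masked sequence) with cross-field correlation
   objectives (predict each field's codes from another field's embedding),
   all as multi-label binary cross entropy.
3. **Adversarial fine-tuning.** The recommender is one logistic layer over
   the concatenation of history means and the current diagnosis/symptom
   embeddings, *y<sub>t</sub>* = sigmoid(W x<sub>t</sub> + b). Each training
   step adds a fast-gradient-method (FGM) disturbance
   r = ε g / ‖g‖₂ to the diagnosis and drug ontology embeddings and
   accumulates the disturbed gradient, which regularises fine-tuning on
   scarce labels. Pre-training and fine-tuning can alternate in cycles so
   the pre-trained representation is not forgotten.

Because the clinical data this family of methods is built on is private,
the package ships a first-class synthetic-EMR generator: ontologies,
per-diagnosis disease profiles with ontology-correlated drug
distributions, a large single-visit pool and a small multi-visit pool with
realistic per-visit code counts (≈2.2 diagnoses / 16.8 drugs per single
visit; ≈1.4 / 3.9 and 2.27 visits per multi-visit patient), and chronic
diagnoses that persist across visits so that history carries signal.

## Worked example

```r
library(rxrec)

# a synthetic study cohort: 50 diagnosis leaves, 100 drug leaves,
# 2000 single-visit + 300 multi-visit patients
data <- simulate_corpus(synthetic_config(seed = 1))
corpus_summary(data$single)

splits <- split_patients(data$multi, seed = 1)     # patient-level 4:1:1

cfg <- config_from_yaml(system.file("configs", "tiny.yaml", package = "rxrec"))
run <- alternating_train(data$single, splits, data$ontologies, cfg$experiment)

# calibrate the decision threshold on the validation split, then test
theta <- calibrate_threshold(run$model, run$pred, splits$validation)
evaluate_model(run$model, run$pred, splits$test, theta)
```

On this cohort `corpus_summary()` prints per-visit means matching the
configured shape (`avg_diagnoses 2.20`, `avg_drugs 16.67`,
`avg_symptoms 1.03`), calibration selects `theta = 0.10`, and the final
report reads

```
Jaccard 0.1428 | F1 0.2260 | PR-AUC 0.1778  (50 patients, 66 visits)
```

(at the fixed conventional 30% cut the same model reads
`Jaccard 0.0743 | F1 0.1100 | PR-AUC 0.1778`). The recommended drug sets
overlap the prescribed sets far above the chance floor: a uniform-random
recommender scores Jaccard ≈ 0.042 here, and the label-frequency
recommender recommends nothing at these cuts. `lr_baseline()`,
`frequency_baseline()` and `random_baseline()` reproduce the comparison
baselines; `ablation_suite()` re-runs the model with knowledge
enhancement (K), pre-training (P) or adversarial training (A) removed in
any combination on identical data, splits and seeds.

A command-line wrapper covers the same pipeline:

```sh
rxrec=$(Rscript -e 'cat(system.file("exec", "rxrec", package = "rxrec"))')
Rscript "$rxrec" simulate --config inst/configs/tiny.yaml --out data/ --seed 1
Rscript "$rxrec" train    --data data/ --config inst/configs/tiny.yaml --out model.rds --seed 1
Rscript "$rxrec" evaluate --model model.rds --data data/
```

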