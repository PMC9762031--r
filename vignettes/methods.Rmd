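---
title: "Knowledge-enhanced pre-training and adversarial fine-tuning for medication recommendation: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Given a patient's admission history — per visit, a set of ICD-10-style
diagnosis codes $d_t$, a set of NDC-style drug codes $m_t$ and a set of
symptom terms $s_t$ — the task is to recommend the drug set of the current
visit $t \ge 2$ from the history $P_1, \dots, P_{t-1}$ plus the current
diagnoses and symptoms. This is multi-label classification over the drug
vocabulary (size $M_L$). The regime of interest is *small longitudinal
data*: multi-visit patients are scarce (a few hundred), while single-visit
records are plentiful (thousands). The package therefore pre-trains a visit
representation on the single-visit pool and fine-tunes a recommender on the
multi-visit pool, with three ingredients: ontology-aware code embeddings,
masked-field/cross-field pre-training, and adversarial (FGM) fine-tuning.

## Ontology embedding

Medical codes sit at the leaves of classification trees: a diagnosis leaf
`J98.4` under category `J98` under chapter `J`; a 14-digit drug code
segmented country(2)/category(1)/enterprise(5)/product(5)/final(1), with an
internal node at every boundary. Every tree node $j$ owns a learned vector
$h_j$ (rows of a node table $H$). A leaf $c$ attends over
$N_c = \{c\} \cup \mathrm{ancestors}(c)$ and its embedding is the K-head
concatenation

$$o_c = \Vert_{k=1}^{K}\ \sigma\!\Big(\sum_{j \in N_c} a^k_{c,j} W^k h_j\Big),$$

with $a^k_{c,j}$ a softmax over leaky-rectified pairwise scores of the
transformed centre and neighbour vectors — the standard graph-attention
scorer, adopted because the formulation names the mechanism but not the
scorer. Choices made where the formulation is silent:

* **$N_c$ is the full root path**, not only the direct parent: the
  knowledge-enhanced EMR lineage (GRAM, G-BERT) attends over all ancestors,
  and "parents … and itself" reads as plural.
* **One attention layer**, since the embedding is written as a single
  aggregation.
* **Per-head width $d = l/K$** so that concatenation matches the encoder
  width $l$; $K = 4$ heads (stated), $l = 64$ by default ($l$ is unstated;
  32 is used in the desk-scale experiments below).
* **$\sigma$ = ELU** (configurable: tanh, ReLU, identity).
* The node table is trained end-to-end; it is initialised from
  $\mathcal N(0, 0.1^2)$ and all weight transforms use Glorot scaling
  ($\mathrm{sd} = \sqrt{2/(n_{in}+n_{out})}$). With uniformly tiny
  initial transforms the leaf embeddings start almost collinear across
  codes and every training loss pins to its marginal-frequency floor;
  Glorot scaling removes that failure mode and is the field default.

Sibling leaves share most of their attention set, which is exactly how
classification knowledge enters: after pre-training, siblings embed closer
than random leaf pairs (a property test asserts this).

## Visit encoder

Each field of a visit is tokenised as `[CLS], c_1, ..., c_k, [PAD], ...`
(codes ordered by vocabulary index — fields are sets, so an arbitrary but
fixed order is imposed; unseen codes map to `[UNK]`) and encoded by a
2-layer, 4-head transformer; the `[CLS]` output is the visit embedding
($v_d, v_m, v_s$). Three encoders share hyper-parameters but not weights,
so field semantics can diverge; weight sharing was the alternative and the
formulation does not choose, so separateness is configurable in code.
**No positional encodings are used**: sets have no order, and together with
key-side padding masks this makes the embedding provably invariant to token
permutation and extra padding (asserted numerically to $10^{-6}$).
Diagnosis and drug token embeddings are the ontology embeddings $o_c$;
symptom tokens use a plain dictionary lookup; special tokens are learned
vectors.

The default per-field caps (32 diagnosis, 72 drug, 8 symptom positions,
`[CLS]` included) cover the maxima a small regional EMR extract exhibits;
the desk-scale experiments use 12/32/6, covering their corpus maxima.

## Pre-training

Two self-supervised tasks train the encoder on single-visit records:

* **Masked EMR field**: each code token is replaced by `[MASK]`
  independently with rate 0.15 (rate and strategy are the package's
  choice; `[MASK]`-only, no random/keep variants). If a non-empty field
  draws no mask, one token is masked anyway, so every non-empty field
  always contributes. The loss scores the *full* code multi-hot of the
  field from the masked `[CLS]` embedding with a linear head and
  multi-label binary cross entropy
  $L_s(v, C) = -\sum_{c \in C}\log P(c\mid v) - \sum_{c \notin C}\log(1 - P(c\mid v)).$
  The printed form of this objective carries a $+\log P$ over absent codes,
  which is unbounded below; the stated intent (binary cross entropy) is
  implemented.
* **Correlation prediction**: cross-field mutual prediction,
  $L_{dm} = \mathrm{BCE}(C_d \mid v_m) + \mathrm{BCE}(C_m \mid v_d)$ and
  analogously $L_{ds}$, $L_{ms}$. Six heads in total: three self heads and
  three cross heads, the cross head for target field $f$ being shared by
  both source fields (the head count is stated as six, which pins this
  sharing down).

The combined objective is the unweighted sum
$L_{pr} = L_s(v_d) + L_s(v_m) + L_s(v_s) + L_{dm} + L_{ds} + L_{ms}$. The
source prints $L_s$ where $L_{ds}$ must be meant ($L_{ds}$ is defined and
otherwise unused); the reading is recorded in the configuration metadata
(`loss_combination`), not silently.

Optimisation is Adam. The published learning rate (5e-4) is stated for the
prediction model only; pre-training uses 1e-3 by default (2e-3 in the
desk-scale experiments), chosen by validation loss. A held-out tenth of
the single-visit pool, masked once with a fixed seed, provides a
comparable validation loss per epoch; the best-validation parameters are
returned.

## Prediction and adversarial fine-tuning

For visit $t \ge 2$ the recommender concatenates five width-$l$ blocks —
the means over $\tau < t$ of $v_d^\tau$, $v_s^\tau$, $v_m^\tau$, plus the
*current* $v_d^t$ and $v_s^t$ — and applies one logistic layer
$y_t = \mathrm{sigmoid}(W x_t + b)$, $W \in \mathbb R^{M_L \times 5l}$.
The printed dimension $3l$ contradicts the five-way concatenation it
accompanies; the dimension is derived from the concatenation. The trailing
current-visit blocks are read as diagnosis and symptom embeddings of visit
$t$: current drugs are the target and must not leak. The loss is the mean
over $t = 2..T$ of the multi-label BCE against the true drug multi-hot
(the printed loss swaps the roles of prediction and truth in its own
notation; standard BCE is implemented). Patients contribute one example
per visit $t \in 2..T$; visit 1 is context only.

**FGM.** Each step runs a normal forward/backward pass, builds
$r_{adv} = \epsilon\, g / \lVert g \rVert_2$ from the gradient $g$ of the
loss with respect to the diagnosis and drug ontology-embedding tables (the
two inputs the method disturbs; symptoms are left alone), re-runs the pass
on the disturbed tables, and updates once on the *mean* of the two passes'
gradients; the perturbation is then discarded, leaving the tables
bit-identical. Choices and their reasons:

* **Sign**: the printed disturbance is $-\epsilon g/\lVert g\rVert$, which
  *decreases* the loss — the opposite of the stated aim of making the
  model err. The default is therefore the ascent direction ($+$), with
  `fgm_sign = -1` reproducing the printed variant.
* **Magnitude**: $\epsilon$ is only described as "a constant".
  $\epsilon = 0.5$ is the default, selected by validation loss among
  $\{0, 0.2, 0.5, 1\}$ on the synthetic study conditions (1.0 also
  regularises but converges visibly more slowly).
* **Combination**: summing the two passes (the literal "accumulated"
  reading) merely rescales the Adam step except for its $\hat\epsilon$
  stabiliser; the mean is used so that $\epsilon = 0$ reduces *exactly* to
  a plain step (a tested contract).

**Alternation.** Pre-training and fine-tuning run in alternating cycles —
the ontology tables, encoders and pre-training heads persist across phases
and the prediction head is created at the first fine-tuning cycle — which
is what lets the two objectives keep correcting each other and limits
forgetting of the pre-trained representation. The cadence is free; the
default is 3 cycles of 5 + 10 epochs, and the desk-scale experiments use a
single cycle of 45 + 55 epochs (at their corpus sizes one long cycle
reached the same validation loss as several short ones at lower cost).
Alternation is epoch-level, the simplest reading of "alternate cycles".

**Threshold.** Recommendations are the drugs with $y_t > \theta$. The
default is $\theta = 0.3$, the one thresholding convention the domain
literature states (a 30% rule for thresholded recommenders). A degenerate
threshold analysis of the synthetic generator supports it: with the
multi-visit regimen averaging 3.9 drugs over a 100-drug vocabulary, even
the *true* generative mixture rarely assigns any drug more than 0.5
probability, so a 0.5 threshold recommends almost nothing and collapses
the set metrics; 0.3 separates informative recommenders from chance
cleanly. Because the useful cut depends on where a trained model's
probability mass sits, `calibrate_threshold()` additionally tunes
$\theta$ per trained model on validation Jaccard over the grid
$\{0.10, 0.15, \dots, 0.50\}$ (floor 0.1 so recommendation sets stay
plausible); the ablation harness applies this calibration to every
variant identically, which compares models by the best decision rule each
can support rather than by where a fixed cut happens to fall.

## The synthetic generator

The private clinical extract the method targets cannot be shipped, so the
package generates corpora with the same statistical shape:

* Single visits average 2.233 diagnosis codes, 16.77 drug codes, 1.0
  symptom terms; multi-visit records average 1.400 / 3.943 / 0.774 and
  2.27 visits (maximum 8). Counts per visit are zero-truncated Poisson
  (diagnoses and drugs; at least one each) or Poisson (symptoms; may be
  empty) with rates solved to hit those means — the simplest family
  matching mean and maximum constraints, flagged as a stand-in since the
  source reports only means and maxima.
* Every diagnosis leaf owns a **disease profile**: a sparse drug
  distribution (expected support = `profile_sparsity` x vocabulary,
  default 0.1) drawn preferentially (`branch_affinity` = 0.7) from one
  branch of the drug ontology, so ontology siblings get correlated
  weights and the code hierarchy is genuinely informative; plus a sparse
  symptom distribution. Visit drugs/symptoms are drawn without
  replacement from the active profiles' mixture, blended with a 10%
  uniform background (co-medication noise).
* Multi-visit patients re-draw their fields each visit; each diagnosis
  recurs at the next visit with probability `chronic_persistence`
  (default 0.7) — chronic conditions are what make history informative.
  Single- and multi-visit patients are disjoint pools, mirroring the
  separate pre-training and fine-tuning sources.
* Symptoms are emitted pre-tokenised; free-text synthesis is out of scope.

What the generator does *not* emulate: real code co-occurrence structure,
dosing, temporal gaps between admissions, site effects, or any privacy
properties. Passing tests therefore show that the implementation learns a
planted compositional diagnosis-to-drug signal under realistic sparsity —
not that it reaches any particular accuracy on real EMR data.

## Numerical choices

* All BCE losses are computed in the logit domain with the stable
  $\max(z,0) - zt + \log(1 + e^{-|z|})$ form; probabilities returned to
  users are exact sigmoids.
* Softmaxes subtract the row maximum; masked attention keys receive
  $-10^{30}$ before the softmax, making their weights exactly zero.
* Layer normalisation uses $\varepsilon = 10^{-5}$.
* Ties and orderings: visit fields are ordered by vocabulary index;
  vocabularies sort codes lexicographically; splits shuffle with a seeded
  permutation. Every stochastic component takes an explicit seed, and the
  whole pipeline is bit-reproducible in single-threaded mode (tested).
* Degenerate inputs: empty symptom fields contribute only absent-code
  terms; zero gradients map to zero FGM perturbations; patients with one
  visit are skipped (with a warning) at evaluation and never produce
  training examples.
* Gradients are analytic throughout (transformer in C++, attention
  embedding and heads in R) and are verified against central finite
  differences in the test suite.

## Problem sizes used by the packaged experiments

The committed experiment configuration (`inst/configs/tiny.yaml`) uses 50
diagnosis leaves, 100 drug leaves, 30 symptoms, 2,000 single-visit and 300
multi-visit patients, width $l = 32$, one cycle of 45 pre-training epochs
(batch 64 visits is the default; the tiny config uses 32) and 55
fine-tuning epochs (batches of 8 patients). The ablation harness trains
the full model and its component-removed variants on identical data and
seeds — the split fingerprint is asserted — and compares median test
Jaccard over three seeds against frequency, logistic-regression and
uniform-random baselines.

## Known limitations

* The transformer and attention embedding are compact re-implementations
  aimed at CPU-scale corpora; there is no GPU path and no mini-batch
  parallelism.
* The *sum* reading of gradient accumulation, per-field $\epsilon$, and
  annealing schedules are exposed or documented but not defaulted.
* The logistic-regression baseline uses ridge-penalised `glmnet` fits with
  a small fixed penalty rather than per-drug cross-validation; with tens
  of positives per drug, cross-validated penalties were unstable.
* Chinese-language segmentation of chief complaints is replaced by
  delimiter-based segmentation; symptom text realism is out of scope.
* Reported synthetic-data metrics are not comparable to published
  real-data numbers; only the qualitative component orderings are.
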