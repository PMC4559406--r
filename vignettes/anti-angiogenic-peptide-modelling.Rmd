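---
title: "Modelling anti-angiogenic peptides: datasets, features, motifs and classifiers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling anti-angiogenic peptides}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(angiopept)
```

## The problem

Angiogenesis — the growth of new capillaries — is a prerequisite for solid
tumour growth, and peptides that inhibit it are candidate cancer
therapeutics. Experimentally validated anti-angiogenic peptides are short
(roughly 5–50 residues) and scarce, so sequence-based classifiers are used
to triage candidate peptides before assays. `angiopept` implements the full
modelling chain for this problem: dataset curation, composition and
propensity analytics, discriminative gapped motif discovery, cross-validated
machine-learning classifiers over terminus views of the peptide, and an
end-user predictor with single-mutant scanning.

## Datasets and curation

A literature-curated positive collection is redundant: the same parent
protein fragment is reported repeatedly with small edits. `reduce_redundancy()`
removes this bias by greedy identity clustering in the CD-HIT style:
records are scanned longest-first and each joins the first cluster whose
representative exceeds the identity threshold (default 70%), otherwise it
founds a new cluster. Identity between two peptides is defined as the number
of identical aligned residues divided by the number of alignment columns
(end gaps included) of a Needleman–Wunsch global alignment under BLOSUM62
with gap open 10 and gap extension 1. The alignment engine is
`Biostrings::pairwiseAlignment()`; the identity definition and the greedy
protocol are this package's own, since clustering tools differ in both and
neither is fully standardised.

No experimentally validated *non*-anti-angiogenic peptides exist, so the
negative class is built by `sample_negative_regions()`: contiguous regions
cut from background proteins at uniform positions, with the sampled length
multiset constrained to equal the positive set's length multiset exactly.
This removes length as a confounder; it cannot remove the deeper limitation
that a random region is only *probably* inactive.

`split_train_independent()` holds out a stratified random fraction per class
(default 20%) before any model development; the held-out set is only touched
by `evaluate()`.

## Feature encodings

Three fixed-schema encodings are provided, all over the fixed residue order
`ACDEFGHIKLMNPQRSTVWY`:

* **AAC** — 20 percentages, `100 * count / length`. Order-free.
* **DPC** — 400 percentages of overlapping residue pairs,
  `100 * count / (length - 1)`. The denominator is the number of overlapping
  windows, which preserves the 100-sum property.
* **Binary profile** — one-hot blocks of 20 per position. Requires a fixed
  width, so it is only defined on terminus views; peptides shorter than the
  window are refused rather than padded, because padding would invent a
  21st symbol the model has never seen.

Terminus views (`extract_terminus()`) take the first k residues (`NTk`),
the last k (`CTk`) or their concatenation (`NTCTk`), k ∈ {5, 10, 15}.
Peptides shorter than k contribute their whole sequence (composition
features remain well-defined); `NTCTk` is a literal concatenation, so
residues of a short peptide can appear in both halves.

## Propensities

Residue preference is measured by the ratio

P(i) = AACp(i) / (AACp(i) + AACs(i)),

where AACp is the mean composition of the peptide class and AACs a reference
composition (bundled: the average Swiss-Prot composition). P = 0.5 means no
preference; the ratio is antisymmetric in its two arguments. Mean
composition averages per-peptide AAC vectors (each peptide carries equal
weight); pooling residues instead would over-weight long peptides.
`positional_propensity()` applies the same ratio position-wise, with
position frequencies among the peptides long enough to have that position;
by package convention C1 is the *last* residue and Ck the k-th from the end
(a `flip_c` switch reverses the labelling, since both conventions occur in
practice). `two_sample_enrichment()` computes the numeric content of a
two-sample logo — per-position frequencies in both classes, their
difference, and a two-proportion z-test at α = 0.05 without
multiple-testing correction, matching the convention of the standard
two-sample-logo tool.

## Gapped motif mining

Motifs are written as residue strings with `-` for a gap (`"CG-G"`), where a
gap matches zero or one arbitrary residue. The grammar forbids leading or
trailing gaps and two consecutive gaps, and allows at most 5 gaps and 8
elements (the informative motifs in this problem are 2–5 elements, so 8
leaves headroom while bounding the search). `enumerate_motifs()` grows
motifs level-wise from single residues, extending on the right by a residue
or a gap-plus-residue; peptide-level support (a peptide counts once no
matter how many matches it contains) is anti-monotone under extension, so
infrequent motifs prune their whole subtree. Matching compiles a motif to a
regular expression (`-` → `.?`); the exhaustive-expansion semantics is kept
as an independent oracle in the test suite. Motif propensity reuses the
P(i) ratio on peptide-level occurrence fractions against the negative set —
the negative set rather than a background composition, because the miner is
discriminative; a different reference can be passed by scoring motifs
manually with `motif_propensity()`.

## Classifiers and evaluation

`peptide_model()` fits one of seven classifiers (RBF-kernel SVM, 1-nearest
neighbour, decision tree, random forest, naive Bayes, logistic regression,
single-hidden-layer perceptron) on any terminus × feature combination. SVM,
k-NN, logistic and MLP inputs are standardised with training-fold means and
variances; trees and naive Bayes take raw percentages. The SVM tunes
cost ∈ 2^−5..2^5 and γ ∈ 2^−7..2^3 (powers of two) by an internal 3-fold
grid search selecting on inner MCC — all inside the training data, so
cross-validation remains leakage-free. Classifier engines are the standard
R implementations (`e1071`, `class`, `rpart`, `randomForest`, `nnet`,
`glm`); the encodings, the protocol and the evaluation layer are this
package's.

Evaluation reports sensitivity, specificity and accuracy as percentages and
the Matthews correlation coefficient, with MCC defined as 0 when its
denominator vanishes. `cross_validate()` uses stratified folds and
aggregates by pooling fold confusion counts (well-defined for MCC, unlike
averaging per-fold MCCs over folds that may be single-class); a
`fold_mean` option reproduces the per-fold-average alternative.
`compare_classifiers()` reuses one fold assignment across classifiers, and
`stability_experiment()` re-samples the negative set to check that
performance does not hinge on one particular random negative draw.

All randomness — fold assignment, tuning folds, sampling, classifier
internals — flows through explicit integer seeds.

## Deployment: routing and mutant scanning

The deployed predictor (`model_registry()`, `predict_batch()`) routes each
query by length: peptides of ≥ 15 residues go to the NT15/AAC model (the
configuration that carries the most discriminative signal, concentrated in
the N-terminal region), shorter ones to the whole-peptide AAC model. The
15-mer boundary itself routes to the NT15 model; the boundary is a
`min_length` argument for users who prefer the other reading.
`mutant_scan()` enumerates all 19 × L single-residue analogs of a parent,
predicts each with the same routing rule, and reports the substitutions
that flip the predicted class — the minimal single mutations toward or away
from predicted activity. Positions are 1-based.

## The synthetic data generator

The curated peptide collections behind this problem are not
redistributable, so the package ships a generator instead of data.
`generate_fixture_data()` draws positives i.i.d. from a background residue
distribution re-weighted by per-residue multipliers, and negatives plus a
background proteome from the unweighted distribution.
`synthetic_study_data()` assembles a full synthetic analogue of a curation
study: 257 "literature" records organised as 135 founder peptides plus
near-duplicate variants (a fixed ≤ 8% of positions per founder substituted,
so variants stay > 70% identical within a cluster while founders are
rejection-sampled to ≤ 60% mutual identity), a length-matched random
negative set, and a 107 + 107 / 28 + 28 train/independent split.

The default study conditions were fixed once, before any model was
evaluated, to emulate the documented biology of this peptide class:

* enrichment multipliers C×4, W×2, P×1.5, S×1.4, R×1.3, T×1.3, G×1.2 and
  depletion A×0.65, D×0.7, I×0.65, L×0.6, V×0.65, F×0.7 over the
  Swiss-Prot-like reference — Cys strongly preferred (many actives are
  fragments of disulfide-rich antiangiogenic domains), the rest mild;
* the enrichment confined to the first 15 residues, with a mild C/G/R boost
  over the last 5 — emulating the observation that the N-terminal region
  carries most of the discriminative signal while the C-terminus carries a
  weaker Cys/Gly/Arg preference;
* lengths uniform on 5–50 residues.

What the generator does **not** emulate: real positional motif structure
(actives share literal subsequences inherited from common parent proteins;
i.i.d. draws have no such shared motifs), phylogenetic and curation
correlations between peptides, and the exact class-contrast magnitude of the
curated data. Consequently, tests passing on synthetic data demonstrate that
the machinery is correct and that effect sizes of the assumed magnitude are
recoverable — they do not certify performance numbers on the real curated
sets. In particular, motif counts and motif propensities on synthetic data
are structurally lower than on curated data, and cross-validated accuracies
track the assumed (deliberately moderate) contrast.

## Numerical choices and degenerate inputs

* Composition percentages are ×100 (a "percentage" scale); all composition
  and frequency tables sum to 100 (or 1) within 1e-9.
* Propensity with a zero denominator (residue absent from both
  compositions) is reported `NA`, not 0, to keep "no information" distinct
  from "never preferred".
* MCC with a zero denominator is 0.
* Non-standard residues (B, J, O, U, X, Z) are rejected with the offending
  position and record id; silently remapping them would corrupt
  composition features.
* Redundancy-reduction ties (equal length) keep input order, making the
  greedy scan deterministic.
* Problem sizes in the test suite are scaled-down replicas (30-cluster
  studies, 5-fold CV) except for the end-to-end evaluation tests, which run
  the full 135-cluster, 10-fold protocol with 5 replicate studies.

## Known limitations

* The negative class is random background sequence; a model trained this
  way separates "anti-angiogenic-like" from "average protein fragment",
  which overstates performance against hard negatives (e.g. bioactive but
  non-anti-angiogenic peptides).
* Small datasets (~100 per class) make single-split metrics noisy; medians
  over replicate studies are reported where stability matters.
* The binary-profile encoder refuses peptides shorter than its window, so
  binary models cannot score very short queries; routing falls back to
  composition models, which is why the deployed registry uses AAC.
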