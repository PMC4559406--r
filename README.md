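# angiopept

Sequence-based prediction and analysis of **anti-angiogenic peptides** —
short (≈5–50 residue) peptides that inhibit the growth of new blood vessels
and are of interest as cancer therapeutics. The package is aimed at
computational biologists who need to (a) curate labelled peptide datasets,
(b) quantify what distinguishes active peptides from background sequence,
and (c) train, validate and deploy classifiers of anti-angiogenic activity.

## What it implements

**Dataset curation.** Greedy identity clustering (CD-HIT style) for
redundancy reduction, where identity = matches / alignment columns of a
global BLOSUM62 alignment (gap open 10 / extend 1); length-matched random
negative sampling from a background proteome; stratified train/independent
splits; a synthetic study generator standing in for the non-redistributable
curated collections.

**Features.** Amino acid composition `AAC(i) = 100·count(i)/L` (20-dim),
dipeptide composition `DPC(d) = 100·count(d)/(L−1)` (400-dim), and one-hot
binary profiles (20·L) — over the whole peptide or terminus views NTk / CTk
/ NTCTk (k ∈ {5, 10, 15}).

**Analytics.** Residue propensity

```
P(i) = AACp(i) / (AACp(i) + AACs(i))
```

against a bundled Swiss-Prot-like reference composition (0.5 = no
preference), its position-wise variant at both termini, and two-sample
per-position enrichment matrices (frequencies, differences, two-proportion
z-tests) — the numeric content of a two-sample logo.

**Gapped motif mining.** Level-wise enumeration of motifs such as `CG-G`
(`-` matches zero or one arbitrary residue), with peptide-level support,
anti-monotone pruning, and discriminative propensity scoring against the
negative set.

**Models.** Seven classifiers (RBF SVM with nested grid tuning, k-NN,
decision tree, random forest, naive Bayes, logistic, MLP) over any
terminus × feature combination; stratified 10-fold cross-validation with
pooled confusion counts; Sn/Sp/Acc/MCC metrics; independent-set evaluation;
negative-set-resampling stability experiments.

**Deployment.** A two-model registry routing queries by length (≥15
residues → NT15/AAC model, shorter → whole-peptide model), batch
prediction, and single-mutant scans reporting the 19·L analogs and the
substitutions that flip the predicted class.

## Worked example

```r
library(angiopept)

## synthetic labelled data with the compositional signature of the class
fx <- generate_fixture_data(n_pos = 60, n_neg = 60,
                            length_range = c(8, 30), seed = 7)
peps <- bind_peptides(fx$positive, fx$negative, name = "demo")

## which residues are preferred?
pt <- as.data.frame(residue_propensity(mean_composition(fx$positive)))
print(head(pt[order(-pt$propensity), ], 5), row.names = FALSE)
#>  residue comp_positive comp_reference propensity
#>        W      2.732714       1.081189  0.7165137
#>        C      3.330841       1.371509  0.7083354
#>        P      8.126666       4.705176  0.6333203
#>        S      8.953997       6.567224  0.5768874
#>        R      6.944733       5.536090  0.5564323

## cross-validated SVM on whole-peptide composition
cross_validate(peps, "svm", "aac", "WHOLE", k = 5, seed = 7, tune = FALSE)
#> 5-fold cross-validation: svm on WHOLE/aac
#> Sn 83.3%  Sp 76.7%  Acc 80.0%  MCC 0.60

## deploy: length-routed prediction and mutant scanning
reg <- model_registry(
  peptide_model(peps, "svm", "aac", "WHOLE", seed = 7, tune = FALSE),
  peptide_model(peps, "svm", "aac", "NT15",  seed = 7, tune = FALSE))

predict_batch(c("CSCSSWPCRRGTCC", "ALLIVFADLLKEAF"), reg)
#>   id       sequence model      score               class error
#> 1 q1 CSCSSWPCRRGTCC whole  0.2750633     anti-angiogenic  <NA>
#> 2 q2 ALLIVFADLLKEAF whole -1.4818478 non-anti-angiogenic  <NA>

mutant_scan("ASCWWGAL", reg)
#> Mutant scan of ASCWWGAL (anti-angiogenic, score 0.167)
#> 152 analogs, 8 flip the predicted class
#>  position from to       score               class
#>         4    W  A -0.06439664 non-anti-angiogenic
#>         4    W  F -0.07266433 non-anti-angiogenic
#>         ...
```

Propensities above 0.5 mark residues over-represented in the positive class
(here Trp, Cys, Pro, Ser, Arg — the expected signature). The SVM scores are
margins: positive margin → predicted anti-angiogenic. The scan shows that
this borderline peptide's predicted activity hinges on its tryptophans:
replacing either Trp with an aliphatic/aromatic non-preferred residue flips
the call.

A command-line wrapper over the same functions ships in
`inst/scripts/aap.R` (subcommands `reduce`, `split`, `sample-negatives`,
`fixtures`, `composition`, `propensity`, `motifs`, `cv`, `predict`, `scan`).

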