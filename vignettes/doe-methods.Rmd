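---
title: "Predicting the direction of effect for drug targets: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting the direction of effect for drug targets: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Choosing a drug target is only half of a therapeutic hypothesis; the other
half is the **direction of effect (DOE)** — whether benefit requires
*activating* or *inhibiting* the target. Getting the direction wrong wastes
a program as surely as picking the wrong gene. `doepred` implements a
framework for predicting DOE at two levels:

1. **Gene level** (disease-agnostic): from a design matrix of tabular gene
   annotations plus gene- and protein-language-model embeddings, one-vs-rest
   gradient-boosted models score each gene's suitability as an activator,
   inhibitor, or other-mechanism target. Labels are *multi-label*: a gene
   targeted by both agonists and antagonists is a positive example for both
   classes, which is why three binary models are trained rather than one
   multiclass model.
2. **Gene-disease level**: from signed genetic-association evidence, a
   31-feature vector per gene-disease pair encodes an allelic series — the
   idea that variants of graded severity in a gene trace out a dose-response
   curve for the disease. A gain-of-function variant that increases disease
   risk argues for an inhibitor; a gain-of-function variant that protects
   argues for an activator; loss-of-function and expression-lowering
   evidence mirror this.

Because the framework is designed for inputs at biobank scale (drug
mechanism catalogs, GWAS and rare-variant summary statistics, eQTL maps), a
first-class synthetic-data generator reproduces their statistical structure
at desk scale, with a planted, tunable signal. Everything the package
claims about recovery, calibration and enrichment is demonstrated on that
generator by the test suite and `scripts/acceptance.R`.

## Drug catalog unification

Multi-source drug catalogs disagree on identity and on mechanism.
`unify_drugs()` resolves identity with a disjoint-set structure over shared
(namespace, value) identifier pairs: two records are one drug exactly when
they are connected, directly or transitively. The unified id is the
smallest member record id, a convention chosen purely for reproducibility.

Raw mechanism terms are mapped to the three DOE classes by
`classify_mechanism()`. The shipped term map covers the
agonist/antagonist/activator/inhibitor/blocker/allosteric-modulator
families, with binding agents, mixed agonists/antagonists and replacement
therapies in *other*; it is a reconstruction (the original curation table
is not public in full) and deliberately ships as an editable TSV.
Discrepant annotations for one drug-gene pair are resolved
lexicographically by `resolve_discrepancies()`: tier-1 sources (ChEMBL,
DrugBank) beat the rest, then directional classes beat *other*. On real
curated inputs this resolves everything; on arbitrary inputs a residual
activator-versus-inhibitor tie at equal tier is possible, and we exclude
and log such pairs rather than guess.

## Gene-level design matrix

The gene-level matrix has three blocks, always in this order: 41 tabular
features (schema-defined, user-replaceable), the leading 256 dimensions of
a gene embedding, and 128 principal components of a raw protein embedding
— 425 columns at full width.

* **Truncation, not projection, for gene embeddings.** The gene embeddings
  emulated here come from Matryoshka-style representation learning, whose
  defining property is that earlier coordinates carry more information, so
  dimensionality reduction is simply `truncate_gene_embedding()`. The
  synthetic generator reproduces this property by decaying class-centroid
  separation geometrically across dimensions.
* **PCA for protein embeddings** (`fit_protein_projection()`), fit once on
  all genes. This is deliberate rather than per-fold: the projection never
  sees labels, so it cannot leak outcome information into
  cross-validation, and a single shared basis keeps holdout predictions
  comparable across folds. Component signs are fixed (largest-magnitude
  loading positive) so results are platform-independent.
* **Missingness is honest.** Tabular missing values stay `NA` all the way
  into the tree learner, which handles them natively; imputation and
  normalization are not applied. Genes lacking an embedding are dropped
  with a logged count, never zero-imputed — an all-zero embedding is a
  point far outside the embedding distribution and would silently
  mislead the model.

## Gene-disease genetic evidence: 31 features

Every feature is a **signed, tri-state** quantity:

* *missing* — the pair was never tested in the corresponding dataset;
* *0* — tested, but no association at `p < 0.05` (strict; the boundary is
  excluded);
* *signed value* — `sign(beta) * -log10(p)` of the qualifying association.

The distinction between missing and zero is load-bearing: "no evidence
because nobody looked" and "looked and found nothing" are different facts,
and the tree learner can use both. File I/O (`write_doe_tsv()` /
`read_doe_tsv()`) preserves the distinction with empty-field-versus-"0"
encoding.

The 31-feature composition is 4 common + 14 rare + 9 burden + 4
complementary. The exact identities in the original analysis are in a
non-public supplement, so this package reconstructs them from the described
structure and ships the schema as a TSV (`pair_feature_schema()`) that
real-data users can rebind:

* **Common (4):** eQTL sign-concordance features for each mechanism
  (a variant whose risk-increasing allele also raises expression argues
  the gene's product drives risk, hence inhibition; sign-discordance
  argues activation; multi-gene eQTLs go to the closest gene, ties to the
  lexicographically smaller id), and two Locus2gene features holding a
  normalized harmonic sum $H = \sum_i s_{(i)}/i^2 \big/ \sum_i 1/i^2$ of
  scores grouped by predicted mechanism, larger sum retained. The
  normalization divisor is our explicit choice ("normalized" being
  otherwise undefined): it makes a single score encode to itself and a
  run of perfect scores to 1.
* **Rare (14):** 7 functional categories — GOF, high- and low-confidence
  LOF, damaging missense (deleteriousness score > 0.5), benign missense,
  other, unknown — crossed with 2 rare-variant datasets; each feature is
  the encoding of the most significant variant in its category (ties:
  variant order). The deleteriousness score is the proportion of
  prediction algorithms calling a variant deleterious, reported only when
  at least 8 return a prediction; quantitative tools count as deleterious
  strictly above rank score 0.9. Missense variants without a score fall
  into *unknown*.
* **Burden (9):** 3 burden datasets crossed with 3 variant masks, one
  signed encoding each. Burden tests aggregate rare putatively deleterious
  variants, so all masks carry LOF-like direction semantics.
* **Complementary (4):** clinical GOF and LOF variant evidence, mouse
  knockout direction, expression direction — encoded the same signed way.
  Whether these are signed or categorical upstream is not documented; we
  chose signed for uniformity.

`bin_support_counts()` reduces a feature vector to the number of allele
frequency bins (common / rare / ultrarare) supporting each mechanism.
The feature-to-bin mapping (common features → common, per-variant rare
categories → rare, burden → ultrarare) is our reconstruction of the bin
structure. A key invariant, tested by property tests: flipping every beta
sign negates all signed features, swaps the concordance-paired features
between mechanisms, and swaps the two mechanisms' support counts.

## The nested cross-validation estimator

`doe_nested_cv()` is the package's central fitting function. For each class
it trains binary gradient-boosted trees in a nested 8×8 scheme: items are
split into 8 outer folds; within each outer training set, 8 inner folds;
each of the 8 inner models early-stops on its inner validation fold
(validation log-loss — the early-stopping metric is not specified upstream,
and log-loss matches the training objective) and predicts the outer
holdout; the holdout probability is the arithmetic mean of the 8 inner
probabilities (probabilities, not margins — another open choice, made
because probabilities are what the downstream calibration analysis
consumes). Every item thus gets exactly one holdout prediction per class
from models that never saw it, in training *or* early stopping — the fit
object retains per-model row bookkeeping and the test suite audits this
leakage-freedom mechanically.

Hyperparameters are library defaults except `min_child_weight = 10`
(guards against overly specific splits at these sample sizes) and
early stopping after 10 stagnant rounds; the full configuration is frozen
in a JSON lockfile shipped with the package (`doe_model_config()`).
Splitting is purely random; a `strata` option exists but is off by
default, and the trainer fails loudly if a class vanishes from an inner
training fold. Folds are shared across the three class models so that
per-class predictions are comparable item by item.

Feature attributions (`feature_attribution()`) are additive per-row
contributions computed from the same inner models that produced each
item's holdout prediction; the contract — bias plus contributions equals
the averaged model margin to at most 1e-6 — is what the tests enforce,
not a specific attribution algorithm.

`novelty_split_cv()` is the generalization variant: rank genes by a
publication-novelty score, train and validate on the bottom 7/8 with
8-fold CV, and predict the top 1/8 (a 1/2 split is supported for scarce
positives).

## Evaluation

* `auroc()`: midrank formula; ties count one half. Verified against an
  O(n²) pair-enumeration oracle to 1e-12.
* `bootstrap_ci()`: reverse-percentile interval
  $[2\hat\theta - q_{0.975},\, 2\hat\theta - q_{0.025}]$ over row
  resamples. Degenerate resamples (e.g. single-class for AUROC) are
  redrawn, up to 100 attempts, keeping the iteration count fixed — the
  alternative of skipping them would silently change the nominal level.
  Reverse-percentile intervals can fail to bracket the point estimate and
  slightly undercover; the acceptance run measures empirical coverage
  ≈ 0.93 at n = 500 with 200 resamples for a known AUROC of 0.76.
* `macro_micro()`: macro is the unweighted per-class mean; micro pools the
  one-vs-rest (score, label) rows, each item contributing once per class.
* `calibration()`: 10 equal-width bins on [0, 1], count-weighted least
  squares of observed rate on mean prediction. Equal-width bins and the
  weighted fit are our choices; a degenerate single-bin curve is flagged
  rather than fitted.
* `optimal_cutoff()`: scans all distinct prediction values as thresholds
  (classify positive at `>=`), maximizing
  $F_\beta = (1+\beta^2)PR/(\beta^2 P + R)$; ties break to the smallest
  threshold, which maximizes recall at equal F. Gene-level models use
  $\beta = 1$; gene-disease models use $\beta = 0.2$, which heavily
  favors precision — appropriate when the model is a shortlist filter.

## Downstream validation

`phase_outcomes()` labels clinical phase transitions: success if any drug
of the unit reached the destination phase; failure if some drug reached
the origin phase, none reached the destination, and none of those drugs
remains in active development; otherwise excluded. Without timestamps, a
drug's activity is judged from its highest-phase records. `enrichment_or()`
dichotomizes a score at a nearest-rank percentile of the analyzed
population and reports the 2×2 odds ratio with a Wald CI (identical to a
one-covariate logistic regression; zero cells get the Haldane 0.5
correction). `intersect_predictions()` combines gene-level and
gene-disease thresholds and computes the enrichment of each flag and of
their conjunction.

## The synthetic-data generator

`sim_config()` fixes the study conditions. Defaults encode the observed
structure of the real catalogs: multi-label DOE fractions 0.232 / 0.759 /
0.429 (activator / inhibitor / other among druggable genes), five
annotation sources with most drugs in few sources, ~2% discrepant
drug-gene annotations, tabular missingness around 7%, and sparse genetic
testedness (60% common-variant, 40% rare and burden availability per
dataset — chosen as plausible biobank phenotype coverage; the real rates
are not published).

Tabular features are Gaussian with class-shifted means (binary: Bernoulli
with class-shifted log-odds); embeddings are isotropic Gaussian around
once-per-run class centroids whose separation decays geometrically with
dimension. One knob, `signal_strength`, scales every shift; 0 is an exact
null. Per-feature effect sizes are not published, so the scale is a
package choice made once: weight standard deviation 0.3 per feature per
class, which makes any single feature weak and the full matrix strongly
informative — a regime a tree ensemble should, and does, recover
(macro-AUROC ≈ 0.95 at n = 4000 with 136 columns in the acceptance run).

Genetic-evidence signal is planted per mechanism-labelled pair, per tested
channel, with probability $1 - e^{-0.8 s}$ at signal strength $s$, always
obeying the direction framework (GOF risk / LOF protective /
sign-concordant eQTL for inhibitor pairs; mirrored for activator pairs);
noise associations with uniform p values are emitted regardless of label.
"Other"-mechanism pairs receive no directional genetic signal — the
framework defines none for them — so their gene-disease AUROC is expected
to sit at chance even when activator and inhibitor AUROCs are high.

All randomness flows from one root seed through fixed per-stream offsets,
so regenerating one table never perturbs another and identical
configurations are byte-identical.

**What the generator does not emulate** (so what passing tests do *not*
show): linkage disequilibrium and realistic genome structure, informative
missingness, correlated tabular features, realistic source schemas, class
imbalance varying across diseases, and any relationship between embedding
geometry and true protein biology. Recovery on this generator demonstrates
that the pipeline is correct and leak-free, not that real-data AUROCs of
any particular magnitude are attainable.

## Numerical and degenerate-input choices

* Tie-breaks are deterministic everywhere: smallest record id names a
  drug; smaller gene id wins equidistant eQTLs; variant order breaks
  equal minimum p; smallest threshold breaks equal F; alphabetical
  mechanism breaks equal harmonic sums.
* `n_genes = 0` and empty evidence tables produce empty, well-formed
  outputs rather than errors; a single-bin calibration curve and a
  degenerate flag set in prediction intersection are flagged, not fitted.
* Problem sizes in tests and the acceptance script (4000 genes at
  40 + 64 + 32 columns; 20,000 gene-disease pairs; 500 coverage
  simulations with 200 bootstrap resamples) were chosen as the smallest
  sizes at which the measured quantities are stable; they are the
  package's documented reference conditions.

## Known limitations

The mechanism term map and the 31-feature schema are reconstructions; the
complementary features' signedness is assumed; burden masks are all
treated as LOF-like; the generator's missingness is completely at random.
Reproducibility of trained models is deterministic given the library
version (single-threaded training with fixed seeds), not across library
versions.
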