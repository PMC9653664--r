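---
title: "The hybrid carcinogenicity model: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The hybrid carcinogenicity model: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette is the package's own account of what it computes and why
its defaults are what they are. It states no empirical result that the
test suite does not itself compute.

## The prediction problem

Carcinogenicity is assessed here in three forms: a binary class
(carcinogen = 1 vs non-carcinogen = 0), a ternary severity class
(2 = carcinogens and probable carcinogens, 1 = possible carcinogens and
not-classifiable chemicals, 0 = non-carcinogens), and a quantitative
potency, pTD50 = log10(1/TD50). TD50 is a dose rate in mg/kg body
weight/day (or mmol/kg/day; the transform is unit-agnostic but models
must not mix units), so larger pTD50 means a smaller tumorigenic dose,
i.e. a more potent carcinogen. Base 10 is used for the logarithm,
following the pIC50/pKi convention in QSAR.

## SMILES as a character sequence

The model treats a SMILES string as raw text. The vocabulary is fixed
once and for all: the 94 printable, non-space ASCII characters (codes
33–126), each mapped to `code − 32`, so `'!' -> 1`, `'C' -> 67−32 = 35`,
`'~' -> 94`. Index 0 is reserved for padding, which is why the embedding
has input cardinality 95. Because the vocabulary is the whole printable
ASCII range, no character a SMILES writer can legally emit is ever
unseen — the failure mode of the legacy scheme (shipped as
`legacy_onehot_encode()` for comparison) in which the dictionary is
built from training-set characters only and unseen test-set characters
are silently skipped.

Encoding is character-wise, not token-wise: `"Cl"` is two characters,
two indices. This matches the dictionary's worked behavior
(`"C=CC#N"` → 35, 29, 35, 35, 3, 46) and keeps the encoder trivially
total; learning multi-character chemistry is delegated to the
convolution, whose window (default 5 characters) spans such digraphs.

Three choices here were genuinely open and are fixed as follows:

* **Truncation side.** Strings longer than L = 325 keep their *first*
  325 characters. Canonical SMILES writers start at a terminal atom of
  the core scaffold, so the head of the string is the more informative
  end.
* **Whitespace.** Surrounding whitespace is stripped as formatting;
  *interior* whitespace (code 32, outside the 33–126 vocabulary) is an
  error rather than being skipped. Silently dropping characters is
  exactly the legacy defect the fixed dictionary exists to remove, so
  the encoder refuses rather than guesses. Both behaviors are the
  encoder's contract, not options, to keep encodings comparable across
  studies.
* **Padding index.** 0 is exclusively padding; its embedding row is
  pinned to the zero vector and excluded from gradient updates, so a
  string's prediction cannot depend on how much padding follows it.

## Network architecture

Inputs are a K×325 integer matrix (SMILES branch) and a K×D numeric
matrix (descriptor branch).

* SMILES branch: embedding to K×325×100 → 1D convolution (64 filters,
  kernel 5, ReLU) → global max pooling over the 321 window positions →
  K×64.
* Descriptor branch: dense ReLU layers of widths 256 and 128 with
  dropout 0.2.
* Merge: concatenation (K×192) → dense ReLU layer of width 64 with
  dropout → final fully connected layer: sigmoid (binary), 3-way
  softmax (ternary), linear (regression).

Of these, the embedding size (100), the ReLU activation, the presence
of pooling, and the merge-then-final-layer topology are the method's
fixed commitments. Everything else — filter count, kernel width, layer
widths, dropout, optimizer, epochs, batch size — is unstated by the
method and therefore exposed in `hnn_config()` with the defaults above,
chosen as ordinary magnitudes for networks of this size rather than
tuned values. Losses are binary cross-entropy, categorical
cross-entropy and mean squared error; the optimizer is Adam
(learning rate 1e-3, β₁ = 0.9, β₂ = 0.999) with batch size 32 and 30
epochs by default.

The implementation is deliberately plain R: the convolution is an
im2col matrix product, pooling is a reshape-and-argmax, and
backpropagation is hand-derived. A gradient test in the suite checks
every parameter block against central finite differences on a small
configuration (tolerance 1e-4, biases nudged off the ReLU kink at 0,
where the loss is genuinely non-differentiable). All randomness —
initialization (He-scaled Gaussians; uniform(−0.05, 0.05) embedding),
epoch shuffling, dropout masks — flows from `cfg$seed`, so a fit is a
pure function of (data, config).

Numerical details worth knowing: softmax is computed with the row-max
subtracted; cross-entropy clips probabilities at 1e-12; ties in global
max pooling and in argmax class decisions resolve to the first (lowest)
index; the binary decision threshold is 0.5.

## Descriptors

Descriptor *computation* is out of scope by design: any external 2D
calculator can be used, behind the contract "identifier + SMILES in,
named numeric columns out". What the package owns is the completeness
filter — keep exactly the columns with no missing value across the
entire dataset — and standardization. Filtering before modeling (rather
than imputing) mirrors the upstream practice this package reimplements.
Standardization (train-statistics only, sample sd, constant columns to
zero) is applied for the neural branches, which need comparable input
scales; tree and kernel baselines receive raw filtered features, which
is both customary and scale-equivariant for trees. Whether the original
pipeline standardized is unstated; this split is the package's choice.

## Label harmonization

Source agencies grade carcinogenicity on incompatible scales; the maps
in `map_binary_label()` / `map_multiclass_label()` collapse them onto
the two tasks. Points that needed a decision:

* The ternary IARC rule's published wording garbles one group list; it
  is read as "Groups 2B and 3 → class 1", the only reading consistent
  with the surrounding scheme (2B = possibly carcinogenic,
  3 = not classifiable — the definition of class 1).
* IARC Group 4 ("probably not carcinogenic") is *excluded* from the
  ternary task rather than forced into class 0: the source scheme never
  assigns it a class, and a single probably-negative category is too
  weak evidence of non-carcinogenicity to label on its own.
* Duplicate identifiers: identical labels collapse; conflicting labels
  drop the chemical *from that task only* (the default, mirroring
  curation by removal of conflicting chemicals). A source-priority mode
  is available, resolving by the fixed source order MEG, TG230, NTP,
  IARC, JSOH, NIOSH, CPDB, CCRIS, DrugBank.
* Identity is the supplied identifier column (e.g. CAS); there is no
  structure-based deduplication, which would require canonicalization
  machinery the method itself never uses.

## Evaluation protocol

Percent metrics follow the printed-formula convention:
accuracy = (TP+TN)/(TP+TN+FN+FP)×100, sensitivity = TP/(TP+FN)×100,
specificity = TN/(TN+FP)×100, with class 1 positive. A metric with a
zero denominator is `NA`, never 0. Multiclass metrics are
micro-averaged: each class in turn is binarized one-vs-rest, the four
counts are pooled by summation, and the binary formulas are applied to
the pools — including the accuracy variant that keeps pooled TN in both
numerator and denominator. AUC is the Mann–Whitney statistic (ties
1/2); micro AUC flattens the one-vs-rest indicators with their class
scores into one long binary problem before ranking.

For regression, the default R² is 1 − RSS/TSS. The alternative ESS/TSS
form is provided behind `r_squared(..., method = "ess")` because it
equals the default only for fitted least-squares predictions and can
exceed 1 for arbitrary predictions; reported numbers use the default.
R is the sample Pearson correlation.

The split protocol shuffles with a per-repeat seed, holds out 20% (no
stratification — splits are plain random; a stratified mode exists but
is off by default), trains via a user-supplied factory, and averages
per-repeat metrics: 10 repeats for binary and regression, 30 for
ternary. A classification repeat whose training part lacks a class is
re-drawn with the next seed and the replacement is recorded in the
report. Reports serialize to CSV (per-repeat rows plus a mean row) and
JSON, and identical seeds reproduce byte-identical files.

## The synthetic generator

`generate_smiles()` / `generate_dataset()` emulate the *shape* of a
curated carcinogenicity dataset, not its chemistry: strings of 5–120
characters over a small SMILES-like alphabet (including the
two-character token "Cl", so the character-level codec is exercised),
with a planted structural alert — by default the nitro group written as
`N(=O)=O`, a classic carcinogenicity alert — inserted into an exact
fraction (default 0.5) of the strings. Descriptor `D001` is the motif
count plus Gaussian reporter noise (sd 0.25, small enough that a stump
on `D001` alone recovers the noiseless rule, mimicking how real
descriptor sets contain near-sufficient summaries of an alert);
remaining descriptors are standard-normal distractors. Binary labels
are the motif indicator XOR'd with Bernoulli(ε) noise (default
ε = 0.1); ternary labels cut the score β·count + D001 + N(0,1) at its
empirical tertiles; regression targets are β·count + 0.5·D001 +
N(0, σ), σ = 0.5 by default.

Two consequences to keep in mind. First, the label-noise ceiling: with
flip noise ε, no model can exceed an expected AUC of
(1−ε)² + ε(1−ε) = 0.90 at ε = 0.1 against the observed labels, which is
why the suite's learnability bar is 0.85 (ceiling minus a margin) and
why a logistic oracle on the true motif indicator is tested to sit at
that ceiling. Second, what passing on fixtures does *not* show: the
generator has no ring systems, no stereochemistry, no correlated
descriptor blocks, no class imbalance beyond the configured prevalence,
and its alert is a literal substring — so fixture results demonstrate
that the machinery learns a planted structure–activity rule through
both branches, not that any particular accuracy transfers to real
chemical collections. A small table of 20 real, hand-checked SMILES is
bundled separately for codec and descriptor-provider smoke tests.

## Baselines and consensus

Classification baselines are random forest, bagged trees (a forest
whose trees consider every feature at each split, i.e. `mtry = p`), and
AdaBoost (SAMME over depth-limited trees). Regression baselines are
random forest, RBF-kernel support vector regression, gradient-boosted
trees, RBF kernel ridge (closed form, (K + λI)α = y), AdaBoost.R2 over
regression trees (linear loss, weighted-median combination), and
k-nearest neighbours with equally weighted neighbours. Hyperparameters
default to the underlying implementations' defaults with a fixed seed
and are recorded in run-directory config snapshots; none are tuned by
the package. The seven-way consensus is the element-wise mean of the
HNN and the six regression baselines. By convexity of squared error,
the consensus MSE never exceeds the mean of the members' MSEs — the
suite asserts exactly this guaranteed form, not the stronger (and
false in general) claim that the consensus beats the worst member.

## Problem sizes in the shipped tests

The suite trains the full-size default network (embedding 100, 64
filters, hidden 256/128) on 2000 synthetic chemicals for the
learnability check (three seeds, 8 training epochs — the planted rule
converges within a few epochs, so the default 30-epoch schedule is not
needed there) and on 500 chemicals for the consensus check; unit tests
use a reduced configuration (embedding 8, max length 60) where only
mechanics, not capacity, are under test. These sizes are chosen so the
whole suite runs in a few minutes on one CPU while still exercising the
default architecture at realistic width.

## Known limitations

* Descriptor calculation is not included; users must supply a
  descriptor table (any calculator works, provided columns are numeric
  and keyed by identifier).
* The network supports exactly two descriptor-branch hidden layers;
  width is configurable, depth is not.
* No hyperparameter search, uncertainty quantification, applicability
  domain, or transfer learning.
* SMILES are not validated or canonicalized; the codec is faithful to
  its input, including syntactically invalid strings.
* Training is single-threaded CPU code; it is sized for datasets of
  10³–10⁴ chemicals, not 10⁶.
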