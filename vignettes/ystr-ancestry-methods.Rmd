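---
title: "Y-STR ancestry classification: models, design choices and limitations"
author: "ystrancestry"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Y-STR ancestry classification: models, design choices and limitations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ystrancestry)
```

## The problem

Y-chromosomal short tandem repeats (Y-STRs) are paternally inherited loci
whose alleles — integer repeat counts, occasionally with partial-repeat
microvariants such as `13.2` — show strongly population-specific
frequency spectra. A standard forensic screening profile over ~20 such
loci can be typed in hours, which makes it attractive for *initial*
ancestry assessment of an unknown male donor, before slower multi-marker
analyses complete. The statistical difficulty is that the populations of
interest (in the motivating setting, Northeast-Asian groups) overlap
heavily, so the output must be probabilistic guidance, never an
identification.

This package implements a complete classification stack for that problem
and — because reference haplotype databases are access-restricted — a
synthetic population simulator rich enough to exercise every stage.

## Data model

A `marker_panel` fixes the locus list and copy counts; multi-copy markers
(DYS385ab) are split into locus-copies `DYS385a`/`DYS385b`, with calls
stored in nondecreasing numeric order, the standard reporting convention.
The built-in panel follows the printed 20-marker screening set, which
enumerates 18 locus names and hence 19 locus-copies; any other panel can
be supplied as JSON.

Alleles are **categories, not numbers**: `"13.2"` is a distinct level,
not 13.2. Internally every call is a canonical string (no leading zeros,
no trailing fractional zeros), and numeric values are used only for
ordering. The `MISSING` state is represented by `NA` and is distinct from
allele `"0"`. DYS389II is stored as reported, with no subtraction of the
DYS389I fragment, since reporting conventions differ and recoding is not
this package's business.

## The simulator

Each synthetic population is a set of independent categorical allele
distributions, one per locus-copy, drawn from a symmetric Dirichlet over
a realistic repeat range (8–20, with an optional microvariant
probability). The `concentration` parameter controls how spiky the
spectra are: values well below 1 give the sparse, population-specific
spectra typical of real Y-STR data; large values approach uniform.
Admixture is modeled by `mix_populations()`, the per-locus convex
combination of two populations' frequencies, and missingness is applied
MCAR at a configurable per-call rate (the pipeline excludes incomplete
profiles outright, so the missingness mechanism is irrelevant
downstream).

What the simulator deliberately does **not** model: linkage between loci
(the classifiers never exploit inter-locus dependence, and independence
keeps the sampling distributions analytic), haplogroup structure,
mutation processes, and genotyping artifacts. Passing tests on simulated
data therefore demonstrate that the machinery is correct and that the
architecture responds to distributional structure as intended — not that
any particular real-data accuracy will be achieved.

## Preprocessing

`filter_complete()` drops any profile with a missing call ("any marker"
rule). `stratified_split()` uses the largest-remainder rule: the global
training size is `round(f·n)`, each class receives `floor(f·n_c)`, and
the remainder goes to the classes with the largest fractional parts (ties
by name), keeping every class within one sample of exact
proportionality. `downsample_to_min()` equalizes classes at the smallest
class size by uniform subsampling.

Ordering is a genuine design choice the source procedure leaves open: we
split first and downsample **only the training partition**, so that
training sees balanced classes while held-out evaluation keeps natural
class proportions (support-weighted metrics then reflect the population
mix). Class order in the integer label encoding is lexicographic — purely
cosmetic, but fixed for determinism.

## Features

One-hot encoding over the vocabulary of observed (locus-copy, allele)
pairs, fit on training data only. For complete profiles each locus-copy
contributes exactly one 1, so row sums equal the panel's locus-copy
count — a cheap invariant the tests lean on. Unseen test-time alleles are
a hard error by default, because silently zero-filling a locus block
changes row sums; the permissive `unseen = "zero"` mode exists for
screening use and warns per sample.

The `select_one_per_marker()` transformer retains, per locus-copy, the
single allele indicator with maximal plug-in mutual information against
the labels (natural log, `0·log 0 = 0`, no bias correction; ties go to
the lowest numeric allele). It is a sensitivity-analysis option: the
default pipeline uses the full one-hot matrix, since one allele per
marker demonstrably discards within-locus information that closely
related populations need.

## One-vs-rest experts and calibration

One binary expert per population (that population versus the rest
pooled). Three families are supported — ridge logistic regression
(glmnet), random forests (ranger), gradient-boosted trees (xgboost) —
with a per-expert automatic family choice (`specs = "auto"`) by
cross-validated balanced accuracy, recorded in the run manifest.
Hyperparameters can be tuned by `tune_hyperparameters()`, a sequential
model-based optimizer: maximin Latin-hypercube initialization, a
Gaussian-process surrogate (RBF kernel on the unit cube, fixed
lengthscale `0.3·sqrt(d)`, standardized responses, nugget `1e-6`) and
expected-improvement acquisition over a random candidate set. Balanced
accuracy is the objective because the one-vs-rest decomposition makes
every binary problem imbalanced by construction.

Raw scores are calibrated by Platt scaling, `P(y=1|s) = 1/(1+exp(A·s+B))`
— note the sign convention: a well-oriented map has `A < 0`. Parameters
are fit by BFGS on the negative log-likelihood of **out-of-fold** scores
from a stratified k-fold refit (default 5 folds), with Platt's smoothed
targets `(N₊+1)/(N₊+2)` and `1/(N₋+2)`, which keep `(A, B)` finite even
on separable data and damp the overconfidence typical of raw outputs. A
cross-validated likelihood comparison of calibrated versus raw scores is
attached as a diagnostic, and `calibration_diagnostics()` computes binned
expected calibration error.

## Attention fusion and the meta-network

The ingredients named for the fusion weights are expert reliability and
mutual information; the concrete formula is this package's choice:

> weights = softmax((out-of-fold balanced accuracy + normalized mean
> feature MI) / temperature), temperature 1 by default.

This is monotone in both ingredients, nonnegative and normalized by
construction; all components are logged on the model object. The fused
representation passed to the meta-network keeps the k weighted terms
`w_i·p_i` **and** their sum — the scalar weighted prediction alone would
discard which expert contributed, while the raw (k × 2) probability
tensor's negative-class columns are redundant complements; keeping terms
plus sum preserves the information content of both readings.

The meta-network is a small fully connected network: ReLU hidden layers
(default 64, 32), softmax output, mean cross-entropy, full-batch Adam
(default 300 epochs, learning rate 1e-3), He-initialized with a fixed
seed — training is exactly reproducible. `hidden_sizes = integer(0)`
gives a single softmax-regression layer; with uniform attention and that
linear head trained to convergence, predictions coincide with the argmax
of the mean calibrated probabilities on separable data (a sanity
equivalence the tests check). The meta-network is trained on the
**out-of-fold** calibrated probabilities, so it never sees the experts'
resubstitution optimism. Argmax ties break toward the lowest class index.

## The one-vs-one comparator

`train_ovo_stacking()` trains one Platt-calibrated classifier per
unordered class pair — k(k−1)/2 of them, each on its own two classes
only, lower-indexed class positive — and stacks the calibrated pairwise
probabilities (probabilities, not votes: voting discards confidence)
through a combiner with the same meta-network design. The
`pairwise_accuracy()` matrix is symmetric with an undefined diagonal;
pairs absent from a test partition yield `NA` (serialized as null). Both
architectures are always evaluated by the same evaluation module on the
identical test partition, so comparisons are apples to apples.

## Evaluation surfaces

Confusion matrices (rows true, columns predicted), per-class
precision/recall/F1 with zero-denominator cells reported as 0 with a
warning, support-weighted headline averages (weighted recall equals
overall accuracy — an identity the tests verify to 1e-12) plus macro
averages, ranked misclassification summaries, and per-population
discriminative-allele rankings: native importances (impurity/gain for
tree families, |standardized coefficient| for the linear family),
normalized to a maximum of 1 per population, named `LOCUS_ALLELE`. The
normalization is an interpretive choice — importance scales are not
comparable across families — so rankings, not absolute scores, are the
meaningful output.

## Validation designs and their sizes

The test suite and `scripts/acceptance.R` rerun the whole pipeline on
constructed designs chosen for statistical power:

- **Separability ceiling**: seven populations with disjoint allele
  supports, 220 samples each (the smallest class size of the motivating
  screening database). Any correct implementation must reach ~1.0
  accuracy with both architectures.
- **Null floor**: seven copies of one distribution; with exchangeable
  labels the expected accuracy is exactly 1/7 regardless of the fitted
  model, so the observed accuracy must sit within three binomial standard
  errors of 1/7.
- **Admixture echo**: three populations where one (PopC) takes 60% of its
  gene pool from PopA and the rest from a support-matched frequency
  redraw (`resample_frequencies()`), so exactly one pair shares ancestry
  and the blend differs from PopA in allele *frequencies* only. The
  blended pair must be the minimum of the pairwise-accuracy matrix and
  the largest misclassification cell in ≥90% of 20 seeded replicates.
  Two design points matter for power and were chosen on that basis: the
  admixture partner must not introduce novel alleles (those act as
  giveaway markers and can make even the blended pair perfectly
  separable), and 500 samples per class are used so each pair's
  ~200-sample test partition resolves the accuracy ordering off the
  ceiling. An earlier design that blended PopC from PopA *and PopB*
  additionally let B↔C confusion compete with the intended A↔C signal.
- **Planted signal**: a private allele at frequency 0.8 in one of four
  otherwise weakly differentiated populations (Dirichlet concentration
  20) must top that population's importance ranking in ≥95% of 20
  replicates at 220 samples per class.

Ridge logistic regression is the default expert family in these studies:
with a few hundred samples and a few hundred binary features it is fast,
deterministic, and as accurate as the tree families on categorical
one-hot data, which keeps the full validation suite within minutes on one
CPU.

## Numerical conventions and degenerate inputs

- Plug-in MI with natural logs; `0·log 0 = 0`; verified against
  brute-force contingency summation to 1e-12.
- Platt map evaluated via `plogis` for overflow safety; strictly monotone
  in `s` with direction `sign(-A)`.
- Softmax computations subtract the row maximum before exponentiation.
- Largest-remainder split counts; uniform-without-replacement
  downsampling; all randomness routed through explicit integer seeds
  (`withr::with_seed`), so identical configurations yield byte-identical
  reports and written tables.
- Degenerate cases: an empty simulation yields a valid zero-row table;
  `k = 2` one-vs-one has a single pair classifier; a one-point search
  space is returned without optimization; single-allele loci keep their
  only feature.

## Known limitations

Simulated populations have independent loci and no haplogroup structure,
so results here bound correctness, not field performance. The one-vs-one
stacking combiner's form is not dictated by the underlying procedure; the
symmetric choice (same meta-network design) is an assumption recorded in
the manifest. Importance scores are family-specific and only
rank-interpretable. Tree-family experts serialize to native `.rds` rather
than JSON inside saved model directories. The framework infers paternal
ancestry only, and its output is probabilistic screening guidance, not
evidence.
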