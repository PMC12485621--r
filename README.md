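# ystrancestry

Population-of-origin inference for male DNA samples from Y-chromosomal
short tandem repeat (Y-STR) haplotypes.

Y-STR loci are paternally inherited and carry strongly population-specific
allele spectra, which makes a 20-locus forensic screening profile a fast,
cheap signal for *initial* ancestry assessment — useful in the first hours
of an investigation when comprehensive marker panels are not yet available,
and especially for closely related Northeast-Asian populations that
commercial ancestry panels tend to merge into a single group. This package
implements that screening method end to end, for forensic geneticists and
population-genetics researchers, together with a synthetic haplotype
simulator so every stage can be exercised and validated without access to
restricted reference databases.

## The method

Given a haplotype table (one row per sample, one allele call per
locus-copy; multi-copy markers such as DYS385ab contribute two calls),
the pipeline is:

1. **Quality control** — profiles with an empty call at any marker are
   excluded; population labels are integer-encoded; the data are split
   80:20 with stratification and the training partition is downsampled to
   the smallest class.
2. **Encoding** — every observed (locus, allele) pair, microvariants such
   as `13.2` included, becomes a binary presence/absence feature
   (`DYS439_10` style names). An optional mutual-information selector
   retains one allele per marker for sensitivity analyses.
3. **One-vs-rest experts** — one binary classifier per population
   (ridge logistic regression, random forest, or gradient-boosted trees;
   hyperparameters tunable by a sequential model-based optimizer over
   stratified CV). Each expert's raw score *s* is calibrated by Platt
   scaling,

   P(y = 1 | s) = 1 / (1 + exp(A·s + B)),

   with (A, B) fit by maximum likelihood on out-of-fold scores using
   Platt's smoothed targets.
4. **Attention fusion** — experts receive nonnegative weights summing
   to 1, a softmax over each expert's out-of-fold balanced accuracy plus a
   normalized mutual-information ingredient. The fused representation
   keeps the k weighted terms w_i·p_i and their sum Σ w_i·p_i.
5. **Meta-network** — a small fully connected network (ReLU hidden layers,
   softmax output, cross-entropy) maps the fused vector to final k-class
   probabilities, reported as probabilistic guidance (e.g. "P(Korean) =
   0.75, P(Han) = 0.15").

A one-vs-one stacking comparator (k(k−1)/2 calibrated pairwise
classifiers, same meta-network design) is provided for architecture
comparisons, along with its pairwise-accuracy matrix, which exposes which
population pairs are hardest to distinguish.

## Worked example

```r
library(ystrancestry)

panel <- default_panel()                    # the 20-marker screening panel
pops <- lapply(1:4, function(i)
  sample_population_model(panel, alleles_per_locus = 6, concentration = 0.4,
                          seed = 100 + i, name = paste0("Pop", LETTERS[i])))
tab  <- generate_table(simulation_config(panel, pops, n_per_population = 120,
                                         missing_rate = 0.02, seed = 7))
tab  <- filter_complete(tab)                # 336 complete profiles survive
sp   <- stratified_split(tab, 0.8, seed = 3)
train <- downsample_to_min(sp$train, seed = 4)   # 65 per population

model <- train_ovr_attention(train, seed = 5)
model
#> <ovr_attention_model> 4 population experts (PopA, PopB, PopC, PopD)
#>   attention weights: 0.259, 0.247, 0.238, 0.256

pred <- predict_population(model, sp$test, unseen = "zero")
print(report(confusion(sp$test$data$Population, pred$predicted,
                       model$encoding)))
#> accuracy: 1.0000
#>  class precision recall     f1 support
#>   PopA    1.0000 1.0000 1.0000      17
#>   PopB    1.0000 1.0000 1.0000      18
#>   PopC    1.0000 1.0000 1.0000      16
#>   PopD    1.0000 1.0000 1.0000      16
#> weighted: precision 1.0000, recall 1.0000, F1 1.0000
```

Four synthetic populations drawn from sparse Dirichlet allele spectra are
fully separable over 19 locus-copies, so the held-out report is perfect
(`unseen = "zero"` zero-fills the occasional test allele never observed in
training, with a warning naming the samples — the strict default would
refuse to encode them);
the attention weights are near-uniform because all four experts are
equally reliable. `run_experiment()` / `compare_architectures()` wrap the
same steps (plus the one-vs-one comparator, confusion matrices,
misclassification summaries, pairwise accuracies and discriminative-allele
rankings) behind a single seeded `run_config()`, and the
`exec/ystr-ancestry` script exposes
`simulate | preprocess | train | predict | evaluate | compare`
subcommands over the same functions.

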