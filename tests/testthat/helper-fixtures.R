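# Shared fixture builders. Everything is generated in code; no data files.

# Small single-copy panel for fast unit tests.
toy_panel <- function(n_loci = 5L) marker_panel(paste0("L", seq_len(n_loci)))

# Panel with one multi-copy marker (the DYS385ab convention).
multicopy_panel <- function() {
  marker_panel(c("DYS19", "DYS385ab", "DYS390"), multicopy = c(DYS385ab = 2))
}

# Population models with fully disjoint allele supports: population i carries
# alleles 100*i + {1..alleles} at every locus, so a single feature separates
# any pair perfectly.
disjoint_models <- function(panel, n_pops, alleles = 3L, seed = 1L) {
  lapply(seq_len(n_pops), function(i) {
    freqs <- lapply(stats::setNames(panel$locus_copies, panel$locus_copies),
      function(lc) {
        labels <- as.character(100 * i + seq_len(alleles))
        stats::setNames(rep(1 / alleles, alleles), labels)
      })
    population_model(sprintf("Pop%02d", i), panel, freqs)
  })
}

# n_pops references to one shared model: class labels carry no information.
identical_models <- function(panel, n_pops, seed = 1L) {
  base <- sample_population_model(panel, alleles_per_locus = 6,
                                  concentration = 1, seed = seed, name = "base")
  lapply(seq_len(n_pops), function(i) {
    population_model(sprintf("Pop%02d", i), panel, base$freqs)
  })
}

# Complete labeled table from explicit models.
simulate_table <- function(panel, models, n, missing_rate = 0, seed = 1L) {
  generate_table(simulation_config(panel, models, n, missing_rate, seed = seed))
}

# A small labeled table with hand-set calls (3-locus single-copy panel).
hand_table <- function() {
  panel <- toy_panel(3L)
  haplotype_table(panel, data.frame(
    SampleID = c("s1", "s2", "s3", "s4"),
    Population = c("A", "A", "B", "B"),
    L1 = c("14", "15", "14", "15"),
    L2 = c("9", "9", "9", "9"),
    L3 = c("10", "10", "13.2", "13.2"),
    stringsAsFactors = FALSE
  ))
}

# Brute-force plug-in MI over the full contingency table (independent oracle).
brute_force_mi <- function(x, y) {
  xs <- unique(x); ys <- unique(y)
  n <- length(x)
  total <- 0
  for (a in xs) for (b in ys) {
    pxy <- sum(x == a & y == b) / n
    if (pxy > 0) {
      total <- total + pxy * log(pxy / ((sum(x == a) / n) * (sum(y == b) / n)))
    }
  }
  total
}
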