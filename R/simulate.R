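#' Construct a population allele-frequency model
#'
#' A population model assigns each locus-copy of a panel a categorical
#' distribution over canonical allele strings. It is the generative ground
#' truth behind [generate_table()]: loci are independent given the
#' population, which matches what the downstream classifiers consume (they
#' never use inter-locus dependence) and keeps the simulator's sampling
#' distributions analytic.
#'
#' @param name population name.
#' @param panel a [marker_panel()].
#' @param freqs named list (one element per locus-copy, in panel order) of
#'   named numeric vectors: allele string -> frequency. Each vector must be
#'   nonnegative and sum to 1 within 1e-9.
#' @return an object of class `population_model`.
#' @export
population_model <- function(name, panel, freqs) {
  stopifnot(inherits(panel, "marker_panel"))
  if (!setequal(names(freqs), panel$locus_copies)) {
    stop("freqs must name every locus-copy of the panel exactly once")
  }
  freqs <- freqs[panel$locus_copies]
  for (lc in panel$locus_copies) {
    f <- freqs[[lc]]
    if (is.null(names(f)) || any(is.na(names(f)))) stop("frequencies must be named by allele at ", lc)
    if (any(f < 0)) stop("negative frequency at ", lc)
    if (abs(sum(f) - 1) > 1e-9) stop("frequencies at ", lc, " sum to ", sum(f), ", not 1")
    canon <- canonical_allele(names(f))
    if (anyNA(canon)) stop("non-canonical allele label at ", lc)
    names(f) <- canon
    freqs[[lc]] <- f[order_alleles(names(f))]
  }
  structure(list(name = name, panel = panel, freqs = freqs),
            class = "population_model")
}

#' @export
print.population_model <- function(x, ...) {
  cat("<population_model> '", x$name, "' over ",
      length(x$freqs), " locus-copies\n", sep = "")
  invisible(x)
}

#' Draw a random population model from a Dirichlet prior
#'
#' Allele labels are drawn from a realistic repeat range (default 8--20
#' repeats) per locus-copy, with an optional probability of each label being
#' a microvariant (a `.2` partial repeat), and frequencies drawn from a
#' symmetric Dirichlet. A small `concentration` yields the spiky,
#' population-specific allele spectra typical of Y-STR loci; a large one
#' yields near-uniform spectra.
#'
#' @param panel a [marker_panel()].
#' @param alleles_per_locus number of distinct alleles per locus-copy.
#' @param concentration symmetric Dirichlet concentration (> 0).
#' @param seed integer seed; the draw is deterministic given the seed.
#' @param name population name (default `"pop"`).
#' @param repeat_range integer range alleles are drawn from.
#' @param microvariant_prob probability that a drawn allele label is a
#'   microvariant such as `"13.2"`.
#' @return a [population_model()].
#' @export
sample_population_model <- function(panel, alleles_per_locus, concentration,
                                    seed, name = "pop",
                                    repeat_range = c(8L, 20L),
                                    microvariant_prob = 0.1) {
  if (alleles_per_locus < 1) stop("alleles_per_locus must be >= 1")
  if (!is.numeric(concentration) || concentration <= 0) {
    stop("concentration must be a positive real")
  }
  freqs <- withr::with_seed(seed, {
    lapply(stats::setNames(panel$locus_copies, panel$locus_copies), function(lc) {
      reps <- seq.int(repeat_range[1L], repeat_range[2L])
      base <- reps[sample.int(length(reps), min(alleles_per_locus, length(reps)))]
      # top up with microvariants if the integer range is exhausted
      while (length(base) < alleles_per_locus) {
        base <- c(base, repeat_range[2L] + length(base))
      }
      micro <- stats::runif(length(base)) < microvariant_prob
      labels <- ifelse(micro, paste0(base, ".2"), as.character(base))
      labels <- unique(labels)
      while (length(labels) < alleles_per_locus) {
        extra <- max(allele_numeric(labels)) + 1
        labels <- c(labels, as.character(extra))
      }
      g <- stats::rgamma(length(labels), shape = concentration, rate = 1)
      if (sum(g) == 0) g <- rep(1, length(labels))
      stats::setNames(g / sum(g), labels)
    })
  })
  population_model(name, panel, freqs)
}

#' Mix two population models (admixture)
#'
#' Emulates admixture or shared ancestry between populations: per-locus
#' frequencies of the mixture are `alpha * a + (1 - alpha) * b` over the
#' union of the two allele supports. Used to create population pairs with
#' controlled overlap, the synthetic analogue of historically interconnected
#' groups.
#'
#' @param a,b [population_model()]s on the same panel.
#' @param alpha mixing weight of `a`, in `[0, 1]`.
#' @param name name of the mixed population.
#' @return a [population_model()].
#' @export
mix_populations <- function(a, b, alpha, name = paste0(a$name, "x", b$name)) {
  if (!identical(a$panel$locus_copies, b$panel$locus_copies)) {
    stop("population models use different panels")
  }
  if (alpha < 0 || alpha > 1) stop("alpha must lie in [0, 1]")
  freqs <- lapply(stats::setNames(a$panel$locus_copies, a$panel$locus_copies),
    function(lc) {
      fa <- a$freqs[[lc]]; fb <- b$freqs[[lc]]
      alleles <- union(names(fa), names(fb))
      va <- stats::setNames(rep(0, length(alleles)), alleles)
      vb <- va
      va[names(fa)] <- fa
      vb[names(fb)] <- fb
      f <- alpha * va + (1 - alpha) * vb
      f[f > 0]
    })
  population_model(name, a$panel, freqs)
}

#' Redraw allele frequencies over an existing support
#'
#' Produces a new population with exactly the same allele support as
#' `model` at every locus-copy but freshly drawn symmetric-Dirichlet
#' frequencies. Useful as an admixture partner: blending a population with
#' a support-matched redraw yields overlap in frequencies only, with no
#' novel alleles that would give the mixture away — the hard case for
#' classification, as with historically interconnected populations typed
#' on a shared repeat range.
#'
#' @param model a [population_model()].
#' @param concentration symmetric Dirichlet concentration (> 0).
#' @param seed integer seed.
#' @param name name of the new population.
#' @return a [population_model()] with identical supports.
#' @export
resample_frequencies <- function(model, concentration, seed,
                                 name = paste0(model$name, "_redraw")) {
  if (concentration <= 0) stop("concentration must be a positive real")
  freqs <- withr::with_seed(as.integer(seed), {
    lapply(model$freqs, function(f) {
      g <- stats::rgamma(length(f), shape = concentration, rate = 1)
      if (sum(g) == 0) g <- rep(1, length(f))
      stats::setNames(g / sum(g), names(f))
    })
  })
  population_model(name, model$panel, freqs)
}

#' Plant a population-private allele
#'
#' Inserts allele `allele` at `locus_copy` with frequency `freq`, rescaling
#' the existing alleles to `1 - freq`. With the allele absent from every
#' other population this creates a perfectly private marker — the synthetic
#' analogue of a population-diagnostic allele — used to test discriminative-
#' allele recovery.
#'
#' @param model a [population_model()].
#' @param locus_copy locus-copy identifier.
#' @param allele canonical allele string.
#' @param freq target frequency of the private allele in `(0, 1)`.
#' @return the modified [population_model()].
#' @export
plant_private_allele <- function(model, locus_copy, allele, freq) {
  stopifnot(freq > 0, freq < 1)
  if (!locus_copy %in% names(model$freqs)) stop("unknown locus-copy: ", locus_copy)
  allele <- canonical_allele(allele)
  f <- model$freqs[[locus_copy]]
  f <- f[setdiff(names(f), allele)]
  f <- f / sum(f) * (1 - freq)
  f[allele] <- freq
  model$freqs[[locus_copy]] <- f
  population_model(model$name, model$panel, model$freqs)
}

#' Simulation configuration
#'
#' @param panel a [marker_panel()].
#' @param populations list of [population_model()]s on that panel.
#' @param n_per_population integer vector of per-population sample counts
#'   (recycled if length 1).
#' @param missing_rate probability, in `[0, 1]`, that any individual call is
#'   replaced by a missing value (missing completely at random).
#' @param seed integer seed.
#' @return an object of class `simulation_config`.
#' @export
simulation_config <- function(panel, populations, n_per_population,
                              missing_rate = 0, seed = 1L) {
  stopifnot(inherits(panel, "marker_panel"))
  if (!length(populations)) stop("at least one population model required")
  for (p in populations) {
    if (!identical(p$panel$locus_copies, panel$locus_copies)) {
      stop("population model '", p$name, "' uses a different panel")
    }
  }
  n_per_population <- as.integer(rep(n_per_population,
                                     length.out = length(populations)))
  if (any(n_per_population < 0)) stop("counts must be >= 0")
  if (missing_rate < 0 || missing_rate > 1) stop("missing_rate must lie in [0, 1]")
  structure(
    list(panel = panel, populations = populations,
         n_per_population = n_per_population,
         missing_rate = missing_rate, seed = as.integer(seed)),
    class = "simulation_config"
  )
}

#' Generate a synthetic haplotype table
#'
#' For each population, draws `n` independent profiles with every locus-copy
#' sampled from that population's categorical allele distribution, then
#' replaces each call independently by a missing value with probability
#' `missing_rate`. Sample identifiers are `<population>_<i>`; population
#' labels are attached. Deterministic given `config$seed`.
#'
#' @param config a [simulation_config()].
#' @return a [haplotype_table()].
#' @export
generate_table <- function(config) {
  panel <- config$panel
  rows <- withr::with_seed(config$seed, {
    blocks <- mapply(function(pop, n) {
      if (n == 0L) return(NULL)
      df <- data.frame(
        SampleID = sprintf("%s_%04d", pop$name, seq_len(n)),
        Population = pop$name,
        stringsAsFactors = FALSE
      )
      for (lc in panel$locus_copies) {
        f <- pop$freqs[[lc]]
        df[[lc]] <- sample(names(f), n, replace = TRUE, prob = f)
      }
      df
    }, config$populations, config$n_per_population, SIMPLIFY = FALSE)
    df <- do.call(rbind, blocks)
    if (!is.null(df) && config$missing_rate > 0) {
      for (lc in panel$locus_copies) {
        drop <- stats::runif(nrow(df)) < config$missing_rate
        df[[lc]][drop] <- NA_character_
      }
    }
    df
  })
  if (is.null(rows)) {
    rows <- data.frame(SampleID = character(), Population = character(),
                       stringsAsFactors = FALSE)
    for (lc in panel$locus_copies) rows[[lc]] <- character()
  }
  haplotype_table(panel, rows, canonicalize = TRUE)
}

# Serialize the true models alongside a simulated table (JSON sidecar).
write_population_models <- function(populations, path) {
  payload <- lapply(populations, function(p) {
    list(name = p$name, freqs = lapply(p$freqs, as.list))
  })
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
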