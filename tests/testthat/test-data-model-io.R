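test_that("allele strings are canonicalized and ordered numerically", {
  expect_equal(canonical_allele(c("14", "013", "13.20", "14.0", "0")),
               c("14", "13", "13.2", "14", "0"))
  expect_true(is.na(canonical_allele("x13")))
  # microvariants sit between integer alleles in numeric order
  alleles <- c("14", "13.2", "13")
  expect_equal(alleles[ystrancestry:::order_alleles(alleles)],
               c("13", "13.2", "14"))
  expect_lt(allele_numeric("13"), allele_numeric("13.2"))
  expect_lt(allele_numeric("13.2"), allele_numeric("14"))
})

test_that("marker panels enforce their invariants", {
  p <- multicopy_panel()
  expect_equal(p$locus_copies, c("DYS19", "DYS385a", "DYS385b", "DYS390"))
  expect_equal(sum(p$copies), 4)
  expect_error(marker_panel(c("A", "A")), "unique")
  expect_error(marker_panel("A", multicopy = c(B = 2)), "not in panel")
  d <- default_panel()
  expect_equal(length(d$loci), 18L)          # printed screening list
  expect_equal(length(d$locus_copies), 19L)  # DYS385ab split into a/b
})

test_that("reading accepts both multi-copy dialects and normalizes order", {
  panel <- multicopy_panel()
  split_csv <- tempfile(fileext = ".csv")
  writeLines(c(
    "SampleID,Population,DYS19,DYS385a,DYS385b,DYS390",
    "s1,A,14,14,11,22",
    "s2,A,15,12,12,23",
    "s3,B,13,16,10,24"
  ), split_csv)
  joined_csv <- tempfile(fileext = ".csv")
  writeLines(c(
    "SampleID,Population,DYS19,DYS385ab,DYS390",
    "s1,A,14,\"14,11\",22",
    "s2,A,15,\"12,12\",23",
    "s3,B,13,\"16,10\",24"
  ), joined_csv)
  t1 <- read_haplotype_table(split_csv, panel)
  t2 <- read_haplotype_table(joined_csv, panel)
  expect_equal(t1$data, t2$data)
  # "14,11" stored as ("11","14"): nondecreasing numeric order
  expect_equal(t1$data$DYS385a, c("11", "12", "10"))
  expect_equal(t1$data$DYS385b, c("14", "12", "16"))
})

test_that("header-only input yields an empty table and errors name the problem", {
  panel <- toy_panel(3L)
  f <- tempfile(fileext = ".csv")
  writeLines("SampleID,Population,L1,L2,L3", f)
  expect_equal(n_profiles(read_haplotype_table(f, panel)), 0L)

  writeLines(c("SampleID,L1,L2", "s1,1,2"), f)
  expect_error(read_haplotype_table(f, panel), "L3")

  writeLines(c("SampleID,L1,L2,L3", "s1,14,abc,10"), f)
  expect_error(read_haplotype_table(f, panel), "abc")
})

test_that("microvariants and missing calls survive a write/read round trip", {
  panel <- toy_panel(3L)
  tab <- haplotype_table(panel, data.frame(
    SampleID = paste0("s", 1:5),
    Population = c("A", "A", "B", "B", "B"),
    L1 = c("13.2", "14", NA, "13", "15"),
    L2 = c("9", "9.3", "10", NA, "11"),
    L3 = c("20", "21", "22", "23", "24"),
    stringsAsFactors = FALSE
  ))
  f <- tempfile(fileext = ".csv")
  write_haplotype_table(tab, f)
  back <- read_haplotype_table(f, panel)
  expect_equal(back$data, tab$data)
  expect_equal(back$data$L1[1], "13.2")  # fractional part intact
  # write-read-write idempotence, byte for byte
  f2 <- tempfile(fileext = ".csv")
  write_haplotype_table(back, f2)
  expect_identical(readLines(f), readLines(f2))
  # TSV dialect auto-detection
  ftsv <- tempfile(fileext = ".tsv")
  write_haplotype_table(tab, ftsv, delim = "\t")
  expect_equal(read_haplotype_table(ftsv, panel)$data, tab$data)
})

test_that("validate_table reports missing calls and duplicate ids without mutating", {
  panel <- toy_panel(2L)
  clean <- haplotype_table(panel, data.frame(
    SampleID = c("a", "b"), Population = "X",
    L1 = c("10", "11"), L2 = c("12", "13"), stringsAsFactors = FALSE
  ))
  expect_equal(nrow(validate_table(clean)), 0L)

  dirty <- haplotype_table(panel, data.frame(
    SampleID = c("a", "b"), Population = "X",
    L1 = c("10", NA), L2 = c("12", "13"), stringsAsFactors = FALSE
  ))
  before <- dirty$data
  f <- validate_table(dirty)
  expect_equal(nrow(f), 1L)
  expect_equal(f$type, "missing_call")
  expect_equal(f$sample_id, "b")
  expect_equal(f$locus, "L1")
  expect_identical(dirty$data, before)

  dup <- suppressWarnings(haplotype_table(panel, data.frame(
    SampleID = c("a", "a"), Population = "X",
    L1 = c("10", "11"), L2 = c("12", "13"), stringsAsFactors = FALSE
  )))
  f2 <- validate_table(dup)
  expect_equal(sum(f2$type == "duplicate_id"), 1L)
})

test_that("panel JSON round-trips and drives table reading", {
  p <- multicopy_panel()
  f <- tempfile(fileext = ".json")
  write_panel(p, f)
  p2 <- read_panel(f)
  expect_equal(p2$loci, p$loci)
  expect_equal(p2$copies, p$copies)
  expect_equal(p2$locus_copies, p$locus_copies)
})

test_that("multi-copy ordering holds on simulator output", {
  panel <- multicopy_panel()
  models <- lapply(1:2, function(i) {
    sample_population_model(panel, 5, 0.8, seed = i, name = paste0("P", i))
  })
  tab <- simulate_table(panel, models, 50, seed = 3)
  a <- allele_numeric(tab$data$DYS385a)
  b <- allele_numeric(tab$data$DYS385b)
  expect_true(all(a <= b))
  expect_equal(nrow(validate_table(tab)), 0L)
})
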