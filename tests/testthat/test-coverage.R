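make_planted_records <- function(n, fwd, rev, lineages, seed = 1) {
  set.seed(seed)
  seqs <- vapply(seq_len(n), function(i) {
    paste0(
      random_acgt_string(15),
      sample(oracle_expand_set(fwd), 1),
      random_acgt_string(150),
      oracle_reverse_complement(sample(oracle_expand_set(rev), 1)),
      random_acgt_string(15)
    )
  }, character(1))
  reference_set(sprintf("r%03d", seq_len(n)), seqs, lineages)
}

test_that("all-perfect records give 100% coverage with full counts", {
  fwd <- "GTGYCAGCMGCCGCGGTAA"; rev <- "GGACTACNVGGGTWTCTAAT"
  recs <- make_planted_records(
    10, fwd, rev,
    rep(list(c("Bacteria", "Phylum_A", "Class_A")), 10)
  )
  tab <- compute_coverage(recs, fwd, rev, rank = "phylum")
  expect_equal(nrow(tab), 1L)
  expect_equal(tab$taxon, "Phylum_A")
  expect_equal(tab$n_total, 10L)
  expect_equal(tab$n_evaluated, 10L)
  expect_equal(tab$n_match_0mm, 10L)
  expect_equal(tab$pct_0mm, 100.0)
})

test_that("records without a reverse site are counted as no_span everywhere", {
  fwd <- "GTGYCAGCMGCCGCGGTAA"
  set.seed(31)
  seqs <- vapply(1:6, function(i) {
    paste0(random_acgt_string(10), sample(oracle_expand_set(fwd), 1),
           random_acgt_string(20))
  }, character(1))
  recs <- reference_set(sprintf("r%d", 1:6), seqs,
                        rep(list(c("Bacteria", "P1")), 6))
  tab <- compute_coverage(recs, fwd, "GGACTACNVGGGTWTCTAAT", rank = "phylum")
  expect_equal(tab$n_evaluated, 0L)
  expect_equal(tab$pct_0mm, 0.0)
  expect_equal(tab$n_match_le1mm, 0L)
})

test_that("coverage equals fixture ground truth and aggregates across ranks", {
  plan <- data.frame(
    taxon = c("Class_1_1", "Class_2_2"),
    site = c("fwd", "fwd"),
    positions = c("2", "2,5"),
    fraction = c(0.5, 1.0),
    stringsAsFactors = FALSE
  )
  spec <- fixture_spec(seed = 33, n_phyla = 3, classes_per_phylum = 2,
                       genera_per_class = 2, records_per_genus = 3,
                       variant_plan = plan)
  fx <- generate_reference(spec)
  for (rank in c("phylum", "class", "genus")) {
    truth <- fixture_truth_coverage(fx, rank = rank)
    got <- compute_coverage(fx$records, spec$fwd, spec$rev, rank = rank)
    expect_equal(got, truth, ignore_attr = TRUE, info = rank)
  }
  # the single-substitution class: half its records carry 1 planted mismatch
  cls <- compute_coverage(fx$records, spec$fwd, spec$rev, rank = "class")
  r <- cls[cls$taxon == "Class_1_1", ]
  expect_equal(r$n_match_0mm, 3L)       # 6 records, half mutated
  expect_equal(r$n_match_le1mm, 6L)
  # the two-substitution class exceeds the <=1 budget entirely
  r2 <- cls[cls$taxon == "Class_2_2", ]
  expect_equal(r2$n_match_0mm, 0L)
  expect_equal(r2$n_match_le1mm, 0L)

  # hierarchical consistency: genus counts sum to phylum counts
  gen <- compute_coverage(fx$records, spec$fwd, spec$rev, rank = "genus")
  phy <- compute_coverage(fx$records, spec$fwd, spec$rev, rank = "phylum")
  expect_equal(sum(gen$n_match_0mm), sum(phy$n_match_0mm))
  expect_equal(sum(gen$n_total), sum(phy$n_total))

  # budget monotonicity
  expect_true(all(cls$n_match_le1mm >= cls$n_match_0mm))
  expect_true(all(cls$pct_le1mm >= cls$pct_0mm))
})

test_that("coverage is monotone under primer generalization", {
  plan <- data.frame(taxon = "Phylum_1", site = "fwd",
                     positions = "11", bases = "G", fraction = 0.5,
                     stringsAsFactors = FALSE)
  spec <- fixture_spec(seed = 34, n_phyla = 2, classes_per_phylum = 2,
                       genera_per_class = 1, records_per_genus = 4,
                       variant_plan = plan)
  fx <- generate_reference(spec)
  # widened primer: position 11 C -> B absorbs the planted G variant
  wide <- primer("GTGYCAGCMGBCGCGGTAA", "515F_wide")
  base <- compute_coverage(fx$records, spec$fwd, spec$rev, rank = "phylum")
  gen <- compute_coverage(fx$records, wide, spec$rev, rank = "phylum")
  expect_true(all(gen$n_match_0mm >= base$n_match_0mm))
  expect_true(all(gen$n_match_le1mm >= base$n_match_le1mm))
  expect_equal(gen[gen$taxon == "Phylum_1", "n_match_0mm"],
               base[base$taxon == "Phylum_1", "n_match_0mm"] + 4L)
})

test_that("records lacking the rank are bucketed as Unclassified", {
  fwd <- "ACGTACGTACGT"; rev <- "TTGGTTGGTTGG"
  set.seed(35)
  seqs <- vapply(1:4, function(i) {
    paste0(random_acgt_string(5), fwd, random_acgt_string(60),
           oracle_reverse_complement(rev), random_acgt_string(5))
  }, character(1))
  recs <- reference_set(
    sprintf("r%d", 1:4), seqs,
    list(c("Bacteria", "P1"), c("Bacteria", "P1"), c("Bacteria"), character(0))
  )
  tab <- compute_coverage(recs, fwd, rev, rank = "phylum")
  expect_setequal(tab$taxon, c("P1", "Unclassified"))
  expect_equal(tab$n_total[tab$taxon == "Unclassified"], 2L)
  expect_warning(compute_coverage(recs, fwd, rev, rank = "species"),
                 "no record is classified")
})

test_that("compare_primer_pairs joins pair blocks and computes deltas", {
  spec <- fixture_spec(seed = 36, n_phyla = 2, classes_per_phylum = 1,
                       genera_per_class = 1, records_per_genus = 5)
  fx <- generate_reference(spec)
  p <- list(spec$fwd, spec$rev)
  cmpt <- compare_primer_pairs(fx$records, list(a = p, b = p))
  expect_true(all(cmpt$delta_pct_0mm_b_vs_a == 0))
  expect_error(
    compare_primer_pairs(fx$records, setNames(list(p, p), c("a", "a"))),
    "duplicate pair labels"
  )
  expect_error(compare_primer_pairs(fx$records, list(a = p)), "at least two")
})
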