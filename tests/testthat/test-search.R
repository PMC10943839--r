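cfg <- function(...) search_config(...)

test_that("locate finds exact and near-exact sites with leftmost tie-break", {
  s <- locate("ACGT", "TTACGTTT")
  expect_equal(s$start, 3L)
  expect_equal(s$mismatches, 0L)
  expect_equal(s$window, "ACGT")

  s <- locate("ACGT", "TTACGATT", cfg(max_mismatches_locate = 1))
  expect_equal(s$start, 3L)
  expect_equal(s$mismatches, 1L)

  # N matches everything; ties resolve to the leftmost window
  s <- locate("NNNN", "ACGTACGT")
  expect_equal(s$start, 1L)
  expect_equal(s$mismatches, 0L)

  # window invariant: reported window is the reference substring
  ref <- "GGGACGTGGG"
  s <- locate("ACGT", ref)
  expect_equal(substr(ref, s$start, s$end), s$window)

  expect_null(locate("ACGTACGT", "ACG"))  # shorter reference: no span
  expect_error(locate("ACGT", ""), "nonempty")
})

test_that("locate matches the expand-and-scan oracle on random cases", {
  set.seed(21)
  for (i in 1:30) {
    p <- random_iupac_string(sample(4:12, 1))
    ref <- random_acgt_string(sample(20:60, 1))
    got <- locate(p, ref, cfg(max_mismatches_locate = nchar(p)))
    want <- oracle_locate(p, ref)
    expect_equal(got$start, want$start, info = paste(p, ref))
    expect_equal(got$mismatches, want$mismatches, info = paste(p, ref))
  }
})

test_that("a 3' clamp disqualifies windows with terminal mismatches", {
  # mismatch sits in the last 2 primer positions of the best window
  ref <- paste0("TT", "ACGA", "TT")         # primer ACGT vs window ACGA
  expect_equal(locate("ACGT", ref, cfg(max_mismatches_locate = 1))$mismatches, 1L)
  expect_null(locate("ACGT", ref,
                     cfg(max_mismatches_locate = 1, three_prime_clamp = 2)))
  # a clean window elsewhere is still found under the clamp
  ref2 <- paste0("TT", "ACGA", "ACGT")
  s <- locate("ACGT", ref2, cfg(max_mismatches_locate = 1, three_prime_clamp = 2))
  expect_equal(s$start, 7L)
  expect_equal(s$mismatches, 0L)
})

test_that("evaluate_pair recovers planted amplicons and classifies status", {
  fwd <- primer("GTGYCAGCMGCCGCGGTAA", "515F")
  rev <- primer("GGACTACNVGGGTWTCTAAT", "806R", "reverse")
  set.seed(22)
  fe <- sample(oracle_expand_set(fwd$sequence), 1)
  re <- sample(oracle_expand_set(rev$sequence), 1)
  ref <- paste0(fe, strrep("A", 100), oracle_reverse_complement(re))

  pm <- evaluate_pair(fwd, rev, ref)
  expect_equal(pm$status, "perfect")
  expect_equal(pm$total_mismatches, 0L)
  expect_equal(pm$insert_length, 100L)
  expect_equal(pm$amplicon_start, 1L)
  expect_equal(pm$amplicon_end, nchar(ref))

  # forward site only: no geometrically valid pair
  expect_equal(evaluate_pair(fwd, rev, paste0(fe, strrep("A", 10)))$status,
               "no_span")

  # planted single substitution inside the forward site
  fe_mut <- fe
  substr(fe_mut, 3, 3) <- setdiff(c("A", "C", "G", "T"), substr(fe, 3, 3))[1]
  ref_mut <- paste0(fe_mut, strrep("A", 100), oracle_reverse_complement(re))
  pm1 <- evaluate_pair(fwd, rev, ref_mut, cfg(pair_budget = 1))
  expect_equal(pm1$status, "single_mismatch")
  expect_equal(pm1$total_mismatches, 1L)
  expect_true(pm1$within_budget)
  # oracle recount of the planted forward window
  expect_equal(oracle_locate(fwd$sequence,
                             substr(ref_mut, 1, nchar(fe)))$mismatches, 1)

  # budget monotonicity: raising pair_budget never revokes within_budget
  pm0 <- evaluate_pair(fwd, rev, ref_mut, cfg(pair_budget = 0))
  expect_false(pm0$within_budget)
  expect_equal(pm0$status, pm1$status)
})

test_that("extract_binding_regions returns planted windows and reports skips", {
  fwd <- primer("GTGYCAGCMGCCGCGGTAA", "515F")
  rev <- primer("GGACTACNVGGGTWTCTAAT", "806R", "reverse")
  set.seed(23)
  n <- 20
  fe <- sample(oracle_expand_set(fwd$sequence), n, replace = TRUE)
  re <- sample(oracle_expand_set(rev$sequence), n, replace = TRUE)
  # plant up to 2 substitutions per forward site
  nsub <- sample(0:2, n, replace = TRUE)
  for (i in seq_len(n)) {
    for (j in seq_len(nsub[i])) {
      pos <- 1 + j
      substr(fe[i], pos, pos) <-
        setdiff(c("A", "C", "G", "T"),
                IUPAC_SETS[[substr(fwd$sequence, pos, pos)]])[1]
    }
  }
  seqs <- vapply(seq_len(n), function(i) {
    paste0(random_acgt_string(10), fe[i], random_acgt_string(120),
           oracle_reverse_complement(re[i]), random_acgt_string(10))
  }, character(1))
  recs <- reference_set(
    c(sprintf("r%02d", seq_len(n)), "short"),
    c(seqs, "ACGTACGT"),
    rep(list(character(0)), n + 1)
  )
  res <- extract_binding_regions(fwd, rev, recs)
  expect_equal(nrow(res$regions), n)
  expect_equal(res$regions$fwd_region, fe)
  expect_equal(res$regions$rev_region, re)
  expect_equal(res$regions$fwd_mismatches, nsub)
  expect_equal(res$skipped$record_id, "short")
  expect_equal(res$skipped$reason, "no_span")

  # rescoring invariant: per-position recount reproduces reported mismatches
  rescore <- vapply(seq_len(n), function(i) {
    chars <- strsplit(res$regions$fwd_region[i], "")[[1]]
    codes <- strsplit(fwd$sequence, "")[[1]]
    sum(!vapply(seq_along(chars),
                function(j) chars[j] %in% IUPAC_SETS[[codes[j]]], logical(1)))
  }, numeric(1))
  expect_equal(res$regions$fwd_mismatches, rescore)

  expect_error(extract_binding_regions(fwd, rev, recs[0, ]), "no records")
})
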