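make_counts <- function(values, asvs, samples) {
  matrix(values, nrow = length(asvs), ncol = length(samples),
         dimnames = list(asvs, samples))
}

test_that("filter_table removes organelles, unclassified ASVs and shallow samples", {
  counts <- make_counts(rep(3000, 8), paste0("asv", 1:4), paste0("s", 1:2))
  tax <- data.frame(
    asv_id = paste0("asv", 1:4),
    phylum = c("Proteobacteria", "Patescibacteria", "", "Cyanobacteria"),
    organelle = c("", "", "", "chloroplast"),
    stringsAsFactors = FALSE
  )
  res <- filter_table(counts, tax, min_reads = 5000)
  expect_equal(rownames(res$counts), c("asv1", "asv2"))
  expect_setequal(res$removed_asvs$asv_id, c("asv3", "asv4"))
  expect_equal(sort(res$removed_asvs$reason),
               c("chloroplast" = "organelle",
                 "unclassified" = "unclassified_phylum"),
               ignore_attr = TRUE)
  expect_equal(res$removed_samples, character(0))

  # identity transform on a clean, deep table
  clean_tax <- data.frame(asv_id = paste0("asv", 1:4),
                          phylum = rep("P", 4), organelle = "",
                          stringsAsFactors = FALSE)
  res2 <- filter_table(counts, clean_tax, min_reads = 5000)
  expect_equal(res2$counts, counts)
  expect_equal(nrow(res2$removed_asvs), 0L)
  expect_equal(res2$report$pct_reads, c(0, 0))

  # threshold edge: a sample retaining 4999 reads is dropped, others kept
  counts3 <- make_counts(c(4999, 6000), "asv1", c("shallow", "deep"))
  res3 <- filter_table(counts3, clean_tax[1, ], min_reads = 5000)
  expect_equal(colnames(res3$counts), "deep")
  expect_equal(res3$removed_samples, "shallow")

  expect_error(filter_table(make_counts(10, "asv1", "s1"), clean_tax[1, ]),
               "all samples")
})

test_that("removal report states planted organelle read percentages", {
  set.seed(51)
  counts <- make_counts(rpois(40, 2000), paste0("asv", 1:8), paste0("s", 1:5))
  # plant organelle ASVs carrying 10% of all reads
  total <- sum(counts[1:6, ])
  counts[7, ] <- 0; counts[8, ] <- 0
  counts[7, 1] <- round(total / 9)  # organelle/total' = 10%
  tax <- data.frame(
    asv_id = paste0("asv", 1:8), phylum = "P",
    organelle = c(rep("", 6), "mitochondria", ""),
    stringsAsFactors = FALSE
  )
  res <- filter_table(counts, tax, min_reads = 100)
  expect_equal(res$report$pct_reads[res$report$category == "organelle"],
               100 * counts[7, 1] / sum(counts), tolerance = 1e-10)
  expect_equal(round(res$report$pct_reads[1]), 10)
})

test_that("core classification applies prevalence rules at the boundary", {
  v <- make_counts(0, paste0("g", 1:3), paste0("s", 1:10))
  tab <- abundance_table(v)
  cc <- classify_core(tab)
  expect_true(all(cc$overall$label == "none"))

  # 0.2% in exactly 2 of 10 samples: prevalence 0.20 -> loose (>= rule)
  v2 <- v
  v2["g1", 1:2] <- 0.2
  cc2 <- classify_core(abundance_table(v2))
  expect_equal(cc2$overall$label[cc2$overall$taxon == "g1"], "loose_core")

  # exactly at the abundance threshold does not count as present (> rule)
  v3 <- v
  v3["g1", 1:9] <- 0.1
  cc3 <- classify_core(abundance_table(v3))
  expect_equal(cc3$overall$prevalence[cc3$overall$taxon == "g1"], 0)
})

test_that("core and CRAT labels match a brute-force reimplementation", {
  for (seed in c(61, 62, 63, 64, 65)) {
    set.seed(seed)
    v <- matrix(
      rexp(50 * 40, rate = 2), nrow = 40,
      dimnames = list(paste0("g", 1:40), paste0("s", 1:50))
    )
    v <- counts_to_percent(v)
    tab <- abundance_table(v)
    cc <- classify_core(tab)
    want <- oracle_core_labels(v)
    got <- setNames(cc$overall$label, cc$overall$taxon)
    expect_equal(got[names(want)], want, info = seed)

    cr <- identify_crat(tab, cc)
    expect_setequal(cr$taxon, oracle_crat_taxa(v, want))
    # CRAT and core sets are disjoint; union covers all taxa above 1%
    core_taxa <- names(want)[want != "none"]
    expect_length(intersect(cr$taxon, core_taxa), 0L)
    above <- rownames(v)[apply(v, 1, max) > 1.0]
    expect_setequal(union(cr$taxon, core_taxa),
                    union(above, core_taxa))
  }
})

test_that("core label is monotone when thresholds are relaxed", {
  set.seed(66)
  v <- counts_to_percent(matrix(
    rexp(30 * 20, 2), nrow = 20,
    dimnames = list(paste0("g", 1:20), paste0("s", 1:30))
  ))
  tab <- abundance_table(v)
  rank_of <- function(l) match(l, c("none", "loose_core", "general_core",
                                    "strict_core"))
  strictv <- classify_core(tab, abundance_threshold = 0.2)$overall
  relaxed <- classify_core(tab, abundance_threshold = 0.05)$overall
  expect_true(all(rank_of(relaxed$label) >= rank_of(strictv$label)))
  low_cut <- classify_core(tab, prevalence_cutoffs =
                             c(loose = 0.1, general = 0.3, strict = 0.6))$overall
  expect_true(all(rank_of(low_cut$label) >= rank_of(strictv$label)))
})

test_that("group-specific core taxa are those core in exactly one group", {
  v <- make_counts(0, paste0("g", 1:3), paste0("s", 1:8))
  v["g1", 1:4] <- 0.5          # core only in group A (samples 1-4)
  v["g2", ] <- 0.5             # core in both groups
  md <- data.frame(sample_id = paste0("s", 1:8),
                   group = rep(c("A", "B"), each = 4),
                   stringsAsFactors = FALSE)
  cc <- classify_core(abundance_table(v, md), groups = "group")
  expect_equal(cc$group_specific$taxon, "g1")
  expect_equal(cc$group_specific$group, "A")
  expect_error(classify_core(abundance_table(v, md), groups = "nope"),
               "grouping field")
})

test_that("CRAT requires non-core status and one sample above threshold", {
  v <- make_counts(0, c("burst", "core3pc", "quiet"), paste0("s", 1:10))
  v["burst", 1] <- 5                  # 5% once, absent elsewhere
  v["core3pc", 1:9] <- 3              # loose/strict core at 3%
  tab <- abundance_table(v)
  cc <- classify_core(tab)
  cr <- identify_crat(tab, cc)
  expect_equal(cr$taxon, "burst")
  expect_equal(cr$n_above_threshold, 1)
  expect_true(cr$single_sample)
  expect_false("core3pc" %in% cr$taxon)
})

test_that("novelty fractions follow the strict-below-threshold rule", {
  all_mapped <- data.frame(sample = "s1", asv = paste0("a", 1:5),
                           pident = rep(100, 5))
  nv <- novelty_fractions(all_mapped)
  expect_true(all(nv$per_sample$fraction == 0))
  expect_true(all(nv$cumulative$fraction == 0))

  toy <- data.frame(sample = "s1", asv = c("a", "b", "c"),
                    pident = c(98.5, 99.5, 94.0))
  nv2 <- novelty_fractions(toy)
  expect_equal(nv2$summary$mean[nv2$summary$threshold_name == "high_identity"],
               2 / 3)
  expect_equal(nv2$summary$mean[nv2$summary$threshold_name == "genus"], 1 / 3)

  # exactly at the threshold counts as mapped; inclusive flips that
  edge <- data.frame(sample = "s1", asv = "a", pident = 99.0)
  expect_equal(novelty_fractions(edge)$per_sample$fraction[1], 0)
  expect_equal(novelty_fractions(edge, inclusive = TRUE)$per_sample$fraction[1], 1)

  # no-hit marker is always novel; anti-monotone in threshold
  set.seed(67)
  hits <- data.frame(
    sample = rep(paste0("s", 1:5), each = 20),
    asv = paste0("a", 1:100),
    pident = ifelse(runif(100) < 0.1, NA, runif(100, 85, 100))
  )
  nv3 <- novelty_fractions(hits)
  hi <- nv3$per_sample$fraction[nv3$per_sample$threshold_name == "high_identity"]
  lo <- nv3$per_sample$fraction[nv3$per_sample$threshold_name == "genus"]
  expect_true(all(lo <= hi))

  # subsetting restricts scope
  nv4 <- novelty_fractions(toy, asv_subset = c("a", "b"))
  expect_equal(nv4$per_sample$n_total[1], 2)
  expect_error(novelty_fractions(toy, asv_subset = "zzz"), "no hits")
  expect_error(novelty_fractions(data.frame(sample = "s", asv = "a",
                                            pident = 101)), "\\[0, 100\\]")
})
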