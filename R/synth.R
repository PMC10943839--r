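# Seeded synthetic fixtures: reference databases with planted primer sites
# and controlled variants, abundance tables with planted core/CRAT taxa, and
# best-hit identity tables with planted novelty proportions. Every generator
# records its ground truth so downstream modules can be verified end to end
# without external database downloads. Randomness comes from R's default
# Mersenne-Twister generator under the mandatory seed, so outputs are
# byte-identical across runs and platforms.

#' Specification for synthetic fixtures
#'
#' Defaults emulate a small but structured 16S reference database (5 phyla x
#' 4 classes x 2 genera x 10 records) carrying planted V4 primer sites with
#' a V4-like insert of 230-270 nt, a 2% fraction of long (300-1000 nt)
#' inserts emulating intron-bearing records, and a 60-sample abundance
#' survey across the four main activated-sludge process types.
#'
#' @param seed integer seed (mandatory).
#' @param n_phyla,classes_per_phylum,genera_per_class,records_per_genus
#'   taxonomy shape.
#' @param fwd,rev the primer pair whose expansions are planted as binding
#'   sites.
#' @param variant_plan data.frame with columns `taxon` (a phylum/class/genus
#'   label), `site` (`"fwd"`/`"rev"`), `positions` (comma-separated 1-based
#'   primer positions), optional `bases` (comma-separated replacement bases;
#'   when absent, the first base outside the planted primer's base set is
#'   used), `fraction` (fraction of that taxon's records affected,
#'   deterministically the first `round(fraction * n)` records).
#' @param insert_range,long_insert_range integer length-2 vectors of insert
#'   lengths (nt).
#' @param long_insert_frac fraction of records receiving a long insert.
#' @param pad_range random pad lengths flanking the amplicon.
#' @param n_samples,groups abundance plan: number of samples and group
#'   labels cycled across them.
#' @param abundance_plan data.frame with columns `taxon`, `label` (planted
#'   membership: `strict_core`/`general_core`/`loose_core`/`crat`/`none`),
#'   `prevalence` (target fraction of samples above the presence threshold;
#'   used for core taxa), `n_above` (number of samples above 1% for CRAT
#'   taxa).
#' @param n_background number of background taxa kept below the presence
#'   threshold everywhere.
#' @param novelty_samples,asvs_per_sample,novel_prop,novel_sd novelty plan:
#'   per-sample novel-ASV proportion is drawn around `novel_prop`.
#' @return a list of class `fixture_spec`.
#' @export
fixture_spec <- function(seed,
                         n_phyla = 5L, classes_per_phylum = 4L,
                         genera_per_class = 2L, records_per_genus = 10L,
                         fwd = primer_registry()[["515F"]],
                         rev = primer_registry()[["806R"]],
                         variant_plan = NULL,
                         insert_range = c(230L, 270L),
                         long_insert_frac = 0.02,
                         long_insert_range = c(300L, 1000L),
                         pad_range = c(15L, 40L),
                         n_samples = 60L,
                         groups = c("C", "C,N", "C,N,DN", "C,N,DN,P"),
                         abundance_plan = NULL,
                         n_background = 10L,
                         novelty_samples = 20L, asvs_per_sample = 40L,
                         novel_prop = 0.25, novel_sd = 0.05) {
  if (missing(seed)) stop("a seed is mandatory for fixtures", call. = FALSE)
  stopifnot(
    n_phyla >= 1L, classes_per_phylum >= 1L, genera_per_class >= 1L,
    records_per_genus >= 1L,
    long_insert_frac >= 0, long_insert_frac <= 1,
    novel_prop >= 0, novel_prop <= 1
  )
  if (!is.null(variant_plan)) {
    stopifnot(all(c("taxon", "site", "positions", "fraction") %in%
                    names(variant_plan)))
    stopifnot(all(variant_plan$fraction >= 0 & variant_plan$fraction <= 1))
  }
  structure(
    list(
      seed = as.integer(seed),
      n_phyla = as.integer(n_phyla),
      classes_per_phylum = as.integer(classes_per_phylum),
      genera_per_class = as.integer(genera_per_class),
      records_per_genus = as.integer(records_per_genus),
      fwd = .as_primer(fwd), rev = .as_primer(rev, "reverse"),
      variant_plan = variant_plan,
      insert_range = as.integer(insert_range),
      long_insert_frac = long_insert_frac,
      long_insert_range = as.integer(long_insert_range),
      pad_range = as.integer(pad_range),
      n_samples = as.integer(n_samples),
      groups = groups,
      abundance_plan = abundance_plan,
      n_background = as.integer(n_background),
      novelty_samples = as.integer(novelty_samples),
      asvs_per_sample = as.integer(asvs_per_sample),
      novel_prop = novel_prop, novel_sd = novel_sd
    ),
    class = "fixture_spec"
  )
}

.random_bases <- function(n) {
  paste(sample(.BASES, n, replace = TRUE), collapse = "")
}

# One fully-resolved realization of a degenerate primer.
.realize_primer <- function(bits) {
  vapply(bits, function(b) {
    opts <- .BASES[bitwAnd(b, c(1L, 2L, 4L, 8L)) > 0L]
    if (length(opts) == 1L) opts else sample(opts, 1L)
  }, character(1L))
}

# Replacement base for a planted substitution: the stated base, or the first
# base outside the planted primer's base set at that position.
.sub_base <- function(bits_at_pos, stated = NA_character_) {
  if (!is.na(stated) && nzchar(stated)) return(toupper(stated))
  outside <- .BASES[bitwAnd(bits_at_pos, c(1L, 2L, 4L, 8L)) == 0L]
  if (!length(outside)) {
    stop("cannot plant a mismatch at a position whose code is N",
         call. = FALSE)
  }
  outside[1L]
}

.parse_int_list <- function(x) as.integer(strsplit(as.character(x), ",")[[1L]])
.parse_chr_list <- function(x) trimws(strsplit(as.character(x), ",")[[1L]])

#' Generate a synthetic reference database with planted primer sites
#'
#' Each record is built as random pad + a fully-resolved realization of the
#' forward primer + insert + the reverse complement of a realization of the
#' reverse primer + pad. Planted substitutions follow the spec's variant
#' plan; the realized binding windows are recorded verbatim, so ground-truth
#' mismatch counts for any primer pair can be recomputed by direct
#' position-wise recounting, independent of the window-scanning search.
#'
#' @param spec a [fixture_spec()].
#' @return list of class `reference_fixture`: `records` (a
#'   [reference_set()]), `sites` (data.frame `record_id`, `fwd_region`,
#'   `rev_region` in primer orientation, `insert_length`), and `truth`
#'   (ground-truth [compute_coverage()]-shaped table at phylum rank for the
#'   planted pair; see [fixture_truth_coverage()] for other ranks/pairs).
#' @export
generate_reference <- function(spec) {
  stopifnot(inherits(spec, "fixture_spec"))
  n_rec <- with(spec, n_phyla * classes_per_phylum * genera_per_class *
                  records_per_genus)
  if (n_rec == 0L) stop("degenerate spec: no records", call. = FALSE)
  set.seed(spec$seed)

  ids <- character(n_rec)
  lineages <- vector("list", n_rec)
  fwd_regions <- rev_regions <- character(n_rec)
  inserts <- integer(n_rec)
  i <- 0L
  genus_counter <- 0L
  for (p in seq_len(spec$n_phyla)) {
    for (cl in seq_len(spec$classes_per_phylum)) {
      for (g in seq_len(spec$genera_per_class)) {
        genus_counter <- genus_counter + 1L
        for (r in seq_len(spec$records_per_genus)) {
          i <- i + 1L
          ids[i] <- sprintf("rec_%04d", i)
          lineages[[i]] <- c(
            "Bacteria",
            sprintf("Phylum_%d", p),
            sprintf("Class_%d_%d", p, cl),
            sprintf("Order_%d_%d", p, cl),
            sprintf("Family_%d_%d_%d", p, cl, g),
            sprintf("midas_g_%d", genus_counter)
          )
          fwd_regions[i] <- paste(.realize_primer(spec$fwd$bits), collapse = "")
          rev_regions[i] <- paste(.realize_primer(spec$rev$bits), collapse = "")
          long <- stats::runif(1L) < spec$long_insert_frac
          rng <- if (long) spec$long_insert_range else spec$insert_range
          inserts[i] <- sample(rng[1L]:rng[2L], 1L)
        }
      }
    }
  }

  # apply the variant plan: deterministic prefix of each taxon's records
  if (!is.null(spec$variant_plan)) {
    for (v in seq_len(nrow(spec$variant_plan))) {
      row <- spec$variant_plan[v, ]
      hit <- vapply(lineages, function(l) row$taxon %in% l, logical(1L))
      idx <- which(hit)
      if (!length(idx)) {
        stop(sprintf("variant plan names unknown taxon '%s'", row$taxon),
             call. = FALSE)
      }
      n_aff <- round(row$fraction * length(idx))
      aff <- idx[seq_len(n_aff)]
      positions <- .parse_int_list(row$positions)
      stated <- if ("bases" %in% names(row) && !is.na(row$bases)) {
        .parse_chr_list(row$bases)
      } else rep(NA_character_, length(positions))
      pr <- if (row$site == "fwd") spec$fwd else spec$rev
      for (j in aff) {
        region <- if (row$site == "fwd") fwd_regions[j] else rev_regions[j]
        for (q in seq_along(positions)) {
          pos <- positions[q]
          substr(region, pos, pos) <- .sub_base(pr$bits[pos], stated[q])
        }
        if (row$site == "fwd") fwd_regions[j] <- region else rev_regions[j] <- region
      }
    }
  }

  sequences <- vapply(seq_len(n_rec), function(j) {
    paste0(
      .random_bases(sample(spec$pad_range[1L]:spec$pad_range[2L], 1L)),
      fwd_regions[j],
      .random_bases(inserts[j]),
      reverse_complement(rev_regions[j]),
      .random_bases(sample(spec$pad_range[1L]:spec$pad_range[2L], 1L))
    )
  }, character(1L))

  fixture <- list(
    records = reference_set(ids, sequences, lineages),
    sites = data.frame(
      record_id = ids, fwd_region = fwd_regions, rev_region = rev_regions,
      insert_length = inserts, stringsAsFactors = FALSE
    ),
    spec = spec
  )
  class(fixture) <- "reference_fixture"
  fixture$truth <- fixture_truth_coverage(fixture, spec$fwd, spec$rev, "phylum")
  fixture
}

#' Ground-truth coverage of a fixture for an arbitrary primer pair
#'
#' Recounts mismatches of the planted binding windows directly against the
#' primer codes (subset matching, position by position) — the generator's
#' bookkeeping, independent of the window-scanning search it is used to
#' verify.
#'
#' @param fixture a [generate_reference()] result.
#' @param fwd,rev primers to score (default: the planted pair).
#' @param rank rank at which to aggregate.
#' @return a `coverage_table`-shaped data.frame.
#' @export
fixture_truth_coverage <- function(fixture, fwd = NULL, rev = NULL,
                                   rank = "phylum") {
  stopifnot(inherits(fixture, "reference_fixture"))
  f <- .as_primer(if (is.null(fwd)) fixture$spec$fwd else fwd)
  r <- .as_primer(if (is.null(rev)) fixture$spec$rev else rev, "reverse")
  count_mm <- function(region, bits) {
    rb <- .seq_bits(region, "region")
    sum(bitwAnd(rb, bitwAnd(bitwNot(bits), 15L)) != 0L)
  }
  total_mm <- vapply(seq_len(nrow(fixture$sites)), function(j) {
    count_mm(fixture$sites$fwd_region[j], f$bits) +
      count_mm(fixture$sites$rev_region[j], r$bits)
  }, numeric(1L))
  rank_i <- .rank_index(rank)
  taxa <- .taxon_at_rank(fixture$records$lineage, rank_i)
  .aggregate_coverage(taxa, spans = rep(TRUE, length(taxa)),
                      total_mm = as.integer(total_mm),
                      rank = rank, denominator = "total")
}

#' Generate a synthetic abundance table with planted membership labels
#'
#' Planted core taxa are placed above the presence threshold (at 0.5%
#' relative abundance) in exactly `round(prevalence * n_samples)` randomly
#' chosen samples, so their target prevalence is achieved exactly; CRAT taxa
#' are placed at 2.5% in exactly `n_above` samples. Background taxa stay
#' below the presence threshold everywhere, and a `background_filler` taxon
#' absorbs the remaining mass so every sample sums to 100% (it is therefore
#' always a strict-core member, and is labelled as such in the truth table).
#'
#' @param spec a [fixture_spec()]; its `abundance_plan` defaults to one
#'   taxon per membership class.
#' @return list of class `abundance_fixture`: `table` (an
#'   [abundance_table()] with process-type/country metadata) and `truth`
#'   (data.frame `taxon`, `label`, `n_present`, achieved `prevalence`).
#' @export
generate_abundance <- function(spec) {
  stopifnot(inherits(spec, "fixture_spec"))
  set.seed(spec$seed + 1L)
  n <- spec$n_samples
  plan <- spec$abundance_plan
  if (is.null(plan)) {
    plan <- data.frame(
      taxon = c("midas_g_2215", "midas_g_67", "midas_g_4375",
                "crat_g_1", "rare_g_1"),
      label = c("strict_core", "general_core", "loose_core", "crat", "none"),
      prevalence = c(0.90, 0.60, 0.25, NA, NA),
      n_above = c(NA, NA, NA, 3L, NA),
      stringsAsFactors = FALSE
    )
  }
  cutoffs <- c(loose = 0.20, general = 0.50, strict = 0.80)
  samples <- sprintf("WWTP_%03d", seq_len(n))
  taxa <- c(plan$taxon,
            sprintf("bg_g_%d", seq_len(spec$n_background)),
            "background_filler")
  v <- matrix(0, nrow = length(taxa), ncol = n,
              dimnames = list(taxa, samples))
  truth <- data.frame(taxon = character(0L), label = character(0L),
                      n_present = integer(0L), prevalence = numeric(0L),
                      stringsAsFactors = FALSE)
  for (j in seq_len(nrow(plan))) {
    row <- plan[j, ]
    if (row$label %in% c("strict_core", "general_core", "loose_core")) {
      k <- round(row$prevalence * n)
      if (k > n) stop("infeasible plan: prevalence demands more samples than exist",
                      call. = FALSE)
      achieved <- k / n
      expect <- .core_label(achieved, cutoffs)
      if (expect != row$label) {
        stop(sprintf(
          "infeasible plan: target prevalence %.2f for '%s' yields label %s",
          row$prevalence, row$taxon, expect
        ), call. = FALSE)
      }
      v[row$taxon, sample(n, k)] <- 0.5
      truth <- rbind(truth, data.frame(
        taxon = row$taxon, label = row$label, n_present = k,
        prevalence = achieved, stringsAsFactors = FALSE
      ))
    } else if (row$label == "crat") {
      k <- as.integer(row$n_above)
      if (k < 1L || k > n) stop("infeasible plan: CRAT n_above out of range",
                                call. = FALSE)
      if (k / n >= cutoffs[["loose"]]) {
        stop(sprintf(
          "infeasible plan: CRAT taxon '%s' present in %d/%d samples would be core",
          row$taxon, k, n
        ), call. = FALSE)
      }
      v[row$taxon, sample(n, k)] <- 2.5
      truth <- rbind(truth, data.frame(
        taxon = row$taxon, label = "crat", n_present = k,
        prevalence = k / n, stringsAsFactors = FALSE
      ))
    } else {
      v[row$taxon, ] <- 0.05
      truth <- rbind(truth, data.frame(
        taxon = row$taxon, label = "none", n_present = 0L,
        prevalence = 0, stringsAsFactors = FALSE
      ))
    }
  }
  for (b in seq_len(spec$n_background)) {
    v[sprintf("bg_g_%d", b), ] <- stats::runif(n, 0, 0.08)
  }
  v["background_filler", ] <- 100 - colSums(v)
  truth <- rbind(truth, data.frame(
    taxon = "background_filler", label = "strict_core", n_present = n,
    prevalence = 1, stringsAsFactors = FALSE
  ))
  metadata <- data.frame(
    sample_id = samples,
    group = rep_len(spec$groups, n),
    country = rep_len(c("Denmark", "Austria", "China", "USA", "Brazil"), n),
    stringsAsFactors = FALSE
  )
  structure(
    list(table = abundance_table(v, metadata), truth = truth, spec = spec),
    class = "abundance_fixture"
  )
}

#' Generate a synthetic best-hit identity table with planted novelty
#'
#' Per sample, a novel-ASV proportion is drawn around `novel_prop`; novel
#' ASVs receive best-hit identities uniform on \[90, 98.9\] (or no hit at
#' all, for one in ten), mapped ASVs uniform on \[99, 100\]. The achieved
#' per-sample fractions are recorded as truth.
#'
#' @param spec a [fixture_spec()].
#' @return list of class `novelty_fixture`: `hits` (data.frame `sample`,
#'   `asv`, `pident`) and `truth` (data.frame `sample`, `fraction_novel`
#'   at the high-identity threshold).
#' @export
generate_novelty <- function(spec) {
  stopifnot(inherits(spec, "fixture_spec"))
  set.seed(spec$seed + 2L)
  m <- spec$asvs_per_sample
  out <- vector("list", spec$novelty_samples)
  truth <- numeric(spec$novelty_samples)
  for (s in seq_len(spec$novelty_samples)) {
    prop <- min(max(stats::rnorm(1L, spec$novel_prop, spec$novel_sd), 0), 1)
    n_novel <- round(prop * m)
    truth[s] <- n_novel / m
    pid <- c(
      stats::runif(n_novel, 90, 98.9),
      stats::runif(m - n_novel, 99, 100)
    )
    # one in ten novel ASVs has no reportable hit at all
    if (n_novel > 0L) {
      nohit <- seq_len(n_novel)[seq_len(n_novel) %% 10L == 0L]
      pid[nohit] <- NA_real_
    }
    out[[s]] <- data.frame(
      sample = sprintf("WWTP_%03d", s),
      asv = sprintf("s%d_asv%03d", s, seq_len(m)),
      pident = pid,
      stringsAsFactors = FALSE
    )
  }
  structure(
    list(
      hits = do.call(rbind, out),
      truth = data.frame(
        sample = sprintf("WWTP_%03d", seq_len(spec$novelty_samples)),
        fraction_novel = truth, stringsAsFactors = FALSE
      ),
      spec = spec
    ),
    class = "novelty_fixture"
  )
}
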