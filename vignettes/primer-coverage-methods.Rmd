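---
title: "Methods: in silico primer coverage, degeneracy redesign, and community membership"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: in silico primer coverage, degeneracy redesign, and community membership}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(primercov)
```

## The problem

Universal 16S rRNA gene primers are degenerate oligonucleotides: IUPAC
ambiguity codes let one synthesized pool cover sequence variation across
taxa. But "universal" is only as good as the reference sequences the primers
were designed against, and divergent clades — the Candidate Phyla Radiation
phylum *Patescibacteria* being the canonical example in wastewater treatment
plant (WWTP) microbiology — can be almost invisible to a primer pair that
covers most other bacteria well. `primercov` provides the machinery to
quantify that blind spot (per-taxon in silico coverage of a primer pair
against a reference database), to repair it (profile the primer binding
regions of a target clade and propose minimal degeneracy expansions), and to
interpret the resulting community profiles (core/CRAT membership rules and
sequence-novelty fractions).

## Matching model

Every IUPAC code is a nonempty subset of {A,C,G,T}; internally codes are
4-bit masks so set operations are single bitwise instructions.

Two code-level match modes exist because reference databases themselves
contain ambiguity codes:

* **subset** (default): a database code matches a primer code only if every
  base it could be is covered by the primer code. A database `N` therefore
  only matches a primer `N`. This is deliberately conservative — `N`-rich
  database records can never inflate coverage.
* **intersect**: one shared base suffices. Available as a flag for users who
  prefer the permissive reading.

Site search is an exhaustive Hamming-distance window scan: every window of
primer length is scored position-wise; indels are not modelled (the binding
site of a short oligo is a fixed-length window; indel-tolerant matching is a
non-goal). The best window is the one with fewest mismatches, ties going to
the smallest start coordinate so results are platform-independent. An
optional 3' clamp (`three_prime_clamp`) disqualifies windows with mismatches
in the terminal positions for users who want PCR-realistic stringency; it
defaults to 0 and is off in all shipped analyses.

Reverse primers are stored 5'->3' as synthesized and matched as their
reverse complement on the forward strand, downstream of the forward site.
References are assumed sense-strand (as in SILVA/MiDAS exports) and are
never reverse-complemented.

## Pair evaluation and mismatch budgets

`evaluate_pair()` considers every geometrically valid combination of
forward and reverse windows — reverse window after the forward window,
insert at least `min_insert` (default 30 nt), amplicon at most
`max_amplicon` (default 5000 nt, generous enough for intron-bearing 16S
genes) — and selects the combination minimizing total mismatches, then
amplicon length, then forward start. The per-primer location cap
(`max_mismatches_locate`, default 5) is deliberately loose so that divergent
target-clade sequences are still located for binding-region extraction.

Status is a function of the selected combination's total mismatch count
alone: `perfect` (0), `single_mismatch` (1), `no_match` (2+), or `no_span`
when no valid geometry exists; a separate `within_budget` flag compares the
total against `pair_budget`. Keeping the label and the budget orthogonal
makes the label stable under budget changes (raising the budget can never
demote a match) and keeps the accounting of non-spanning records — e.g.
trimmed database sequences that simply do not contain both binding sites —
explicit rather than silently folded into "no match".

The shipped coverage tables count matches at total budgets 0 and <=1. The
<=1 budget is interpreted pair-wise: one primer may carry one mismatch while
the other is perfect — the stricter of the possible readings of "a single
mismatch with one of the two primers".

## Coverage tables

`compute_coverage()` aggregates per-record outcomes at any taxonomic rank.
Records lacking the rank are bucketed as `Unclassified` and reported.
Percentages default to `n_total` (all records of the taxon) as denominator;
`denominator = "evaluated"` switches to spanning records only, which is the
honest choice for databases of trimmed sequences where a primer pair cannot
be evaluated on every record. Both counts are always retained, percentages
are rounded half-up to one decimal to mirror the usual table style, and raw
counts are never rounded. Coverage is monotone by construction: enlarging a
primer's base sets position-wise can only convert mismatches to matches, a
property the test suite asserts on fixtures.

## Degeneracy redesign

`build_profile()` tallies per-position base counts over binding regions
oriented in primer coordinates (reverse-site regions are
reverse-complemented by the extractor, so position 1 is always the primer's
5' base). `propose_degeneracy()` then runs a deterministic greedy rule:

1. per position, the candidate code is the union of the current base set
   with every base at frequency >= `min_base_freq` (default 0.10 over
   unambiguous calls; below that a base is treated as a rare variant or
   sequencing noise);
2. candidate positions are accepted one at a time by marginal gain in the
   fraction of target regions matched with zero mismatches, ties broken by
   smaller degeneracy increase, then by the 5'-most position;
3. acceptance stops when `max_changed_positions` or `max_degeneracy` would
   be exceeded or no positive gain remains.

Only expansions are ever proposed. Narrowings (such as trading an `M` for an
`A` to sharpen specificity at the cost of an off-target clade) require an
off-target objective that a single frequency profile cannot supply; they
remain explicit user edits, and off-target regions, when supplied, are
scored before/after for reporting only. The published modified V4 pair
(`515F_Mod`/`806R_Mod`) is shipped in the primer registry as a named
built-in; it is the product of expert judgment and is not guaranteed to be
re-derivable by the greedy rule.

`diff_primers()` classifies per-position differences between two
equal-length primers as expansion / narrowing / substitution, reported
1-based from the 5' end. Sequences of unequal length are rejected rather
than auto-aligned.

## Community membership rules

All rules operate on relative abundances in percent of the per-sample
total.

* **Presence** in a sample means abundance strictly greater than
  `abundance_threshold` (default 0.1%) — the strict `>` reading of the
  usual "with > 0.1% relative abundance" phrasing.
* **Prevalence** is compared against the cutoffs with `>=` (loose 20%,
  general 50%, strict 80% of samples by default). The published definitions
  mix "more than 80%" and "at least 20%" at the boundary; `>=` is chosen
  and documented, and both the threshold and the cutoffs are arguments.
* **CRAT** (conditionally rare or abundant taxa) are non-core taxa
  exceeding 1% in at least one sample, with the secondary stratification
  (exactly one sample vs more than ten samples above threshold) reported.
* **Novelty**: an ASV is novel at identity threshold `t` if it has no
  database hit or its best-hit identity is strictly below `t` (an ASV at
  exactly 99.0% counts as mapped; `inclusive = TRUE` flips this). Defaults
  are the high-identity (99%) and genus-level (94.5%) conventions.
  Per-sample fractions are summarized as mean ± sd; the cumulative fraction
  uses each distinct ASV's best identity across samples.

Read filtering (`filter_table()`) removes ASVs unclassified at phylum level
or flagged as mitochondria/chloroplasts, then drops samples not retaining
more than 5000 reads, and reports the read percentage removed per category.

## Synthetic fixtures and what they do (not) show

`generate_reference()` builds records as random pad + a fully-resolved
realization of the forward primer + insert + reverse-complemented
realization of the reverse primer + pad, with a variant plan planting
substitutions (always bases outside the planted primer's code at that
position, unless stated) in a deterministic fraction of a taxon's records.
Inserts default to 230–270 nt (a V4-like insert) with a 2% fraction of
300–1000 nt inserts emulating intron-bearing records. Ground truth is the
recorded planted windows themselves: truth coverage for any primer pair is
a direct per-position recount, independent of the window-scanning search it
validates. `generate_abundance()` places planted core taxa above the
presence threshold in exactly `round(prevalence * n)` samples and CRAT taxa
in exactly `n_above` samples (plans that would make a CRAT taxon core are
rejected as infeasible); a filler taxon absorbs the remaining mass so
samples sum to 100% and is honestly labelled strict-core in the truth
table. `generate_novelty()` draws per-sample novel proportions around 0.25.

All generators use R's default Mersenne-Twister generator under a mandatory
seed; outputs are byte-identical across runs and platforms. Test and
validation runs use databases of a few hundred records (e.g. 5 phyla × 4
classes × 20 records) and surveys of 40–60 samples — large enough to give
every rule non-trivial work, small enough that the whole suite runs in well
under a minute.

What the fixtures deliberately do **not** emulate: real 16S evolution
(positions vary independently, with no phylogenetic correlation or
covariation between primer positions), chimeras, read-level errors, or the
compositional structure of real abundance tables. Passing fixture tests
therefore demonstrates that the rules and the search are implemented
exactly as specified — not that any particular primer pair performs well on
a real database. Database-scale conclusions require running the same
pipeline (`read_reference_set()` → `compute_coverage()` /
`compare_primer_pairs()`) on a SILVA or MiDAS download, which is supported
but intentionally not bundled.

## Numerical and degenerate-input conventions

* Coordinates are 1-based inclusive throughout the R API
  (`substr(reference, start, end) == window`); reports match the 1-based
  primer-position convention of the primer literature.
* References shorter than the required geometry yield a `no_span` result,
  not an error; an empty reference or an empty record set is an error.
* Primers with invalid characters are rejected hard, with the offending
  character and position named; database sequences are repaired (gaps
  stripped, non-IUPAC characters to `N`) with a warning count.
* Percentage rounding is half-up to one decimal, applied only to the
  `pct_*` display columns.
* All-zero abundance tables classify every taxon as `none`; empty novelty
  scopes are an error rather than a silent zero.

## Known limitations

* No indel-aware matching; a single indel in a binding region scores as
  multiple mismatches.
* No thermodynamic modelling (melting temperature, duplex stability,
  primer-dimer): mismatch counts are position-blind unless the 3' clamp is
  enabled.
* The greedy designer optimizes exact-match coverage only; it will not find
  coordinated multi-position changes whose individual gains are zero, and
  it never proposes narrowings.
* `compare_primer_pairs()` compares pairs on identical record sets; it does
  not model primer-specific amplicon length effects on downstream
  sequencing.
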