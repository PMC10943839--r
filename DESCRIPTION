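Package: primercov
Title: In Silico Coverage, Degeneracy Redesign, and Community Membership
    Analysis for 16S rRNA Gene Primers
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Toolkit for evaluating degenerate PCR primer pairs against 16S
    rRNA gene reference databases by exhaustive in silico matching with IUPAC
    ambiguity-code semantics, aggregating per-taxon coverage tables at
    configurable mismatch budgets, extracting primer binding regions, and
    proposing minimal degeneracy expansions from per-position base profiles.
    Also implements prevalence-based core-community classification
    (strict/general/loose), detection of conditionally rare or abundant taxa
    (CRAT), and sequence-novelty fractions from best-hit identity tables, plus
    seeded synthetic reference databases and abundance tables with recorded
    ground truth for end-to-end validation without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    Biostrings,
    optparse,
    jsonlite
Config/testthat/edition: 3
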