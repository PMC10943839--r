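# Independent brute-force oracles. These deliberately avoid the package's
# bit-mask machinery: codes are handled as explicit base-set vectors and
# matching as string enumeration, so agreement is a real cross-check.

IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

IUPAC_COMPLEMENT <- c(
  A = "T", C = "G", G = "C", T = "A", R = "Y", Y = "R", S = "S", W = "W",
  K = "M", M = "K", B = "V", V = "B", D = "H", H = "D", N = "N"
)

# every fully-resolved ACGT string a degenerate sequence encodes
oracle_expand_set <- function(seq) {
  sets <- IUPAC_SETS[strsplit(seq, "")[[1]]]
  apply(do.call(expand.grid, c(rev(sets), stringsAsFactors = FALSE)), 1,
        function(row) paste(rev(row), collapse = ""))
}

oracle_reverse_complement <- function(seq) {
  chars <- strsplit(seq, "")[[1]]
  paste(rev(unname(IUPAC_COMPLEMENT[chars])), collapse = "")
}

# min-over-expansions Hamming distance of a primer to every window of an
# ACGT-only reference; returns leftmost window achieving the minimum
oracle_locate <- function(primer_seq, reference) {
  expansions <- oracle_expand_set(primer_seq)
  k <- nchar(primer_seq)
  n <- nchar(reference) - k + 1
  if (n < 1) return(NULL)
  hamming <- function(a, b) {
    sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
  }
  mm <- vapply(seq_len(n), function(s) {
    w <- substr(reference, s, s + k - 1)
    min(vapply(expansions, hamming, numeric(1), b = w))
  }, numeric(1))
  list(start = which.min(mm), mismatches = min(mm))
}

random_iupac_string <- function(len) {
  paste(sample(names(IUPAC_SETS), len, replace = TRUE), collapse = "")
}

random_acgt_string <- function(len) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}

# independent reimplementation of the core/CRAT rules with plain loops
oracle_core_labels <- function(values, abundance_threshold = 0.1,
                               cutoffs = c(loose = 0.20, general = 0.50,
                                           strict = 0.80)) {
  labels <- character(nrow(values))
  names(labels) <- rownames(values)
  for (tx in rownames(values)) {
    n_present <- 0
    for (s in colnames(values)) {
      if (values[tx, s] > abundance_threshold) n_present <- n_present + 1
    }
    prev <- n_present / ncol(values)
    labels[tx] <-
      if (prev >= cutoffs[["strict"]]) "strict_core"
      else if (prev >= cutoffs[["general"]]) "general_core"
      else if (prev >= cutoffs[["loose"]]) "loose_core"
      else "none"
  }
  labels
}

oracle_crat_taxa <- function(values, core_labels, crat_threshold = 1.0) {
  out <- character(0)
  for (tx in rownames(values)) {
    if (core_labels[[tx]] != "none") next
    if (any(values[tx, ] > crat_threshold)) out <- c(out, tx)
  }
  out
}

# exact-match fraction of regions against a degenerate primer, by set lookup
oracle_exact_fraction <- function(regions, primer_seq) {
  sets <- IUPAC_SETS[strsplit(primer_seq, "")[[1]]]
  hit <- vapply(regions, function(r) {
    chars <- strsplit(r, "")[[1]]
    all(vapply(seq_along(chars), function(j) chars[j] %in% sets[[j]],
               logical(1)))
  }, logical(1))
  mean(hit)
}
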