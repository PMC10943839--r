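# Position profiles of primer binding regions and degeneracy-expansion
# proposals. The published modified V4 primers were designed by expert
# inspection of such profiles; propose_degeneracy() replaces that judgment
# with a deterministic greedy rule under explicit caps.

#' Build a per-position base profile from binding regions
#'
#' Tallies A/C/G/T counts at every primer position over a set of binding
#' regions already oriented in primer coordinates (reverse-site regions are
#' reverse-complemented by [extract_binding_regions()]). Non-ACGT characters
#' are tallied as `other` and excluded from frequency denominators.
#'
#' @param regions character vector of binding-region strings, each exactly
#'   primer length.
#' @param primer a `primer_sequence` or IUPAC string (supplies the expected
#'   length and the profile's name).
#' @return a data.frame of class `position_profile` with columns `position`,
#'   `primer_code`, `A`, `C`, `G`, `T`, `other`; attribute `n_regions`.
#' @export
build_profile <- function(regions, primer) {
  p <- .as_primer(primer)
  k <- length(p$bits)
  if (!length(regions)) stop("no regions supplied", call. = FALSE)
  lens <- nchar(regions)
  bad <- which(lens != k)
  if (length(bad)) {
    stop(sprintf(
      "region %d ('%s') has length %d, expected primer length %d",
      bad[1L], regions[bad[1L]], lens[bad[1L]], k
    ), call. = FALSE)
  }
  mat <- do.call(rbind, strsplit(toupper(regions), "", fixed = TRUE))
  counts <- vapply(seq_len(k), function(j) {
    col <- mat[, j]
    c(A = sum(col == "A"), C = sum(col == "C"),
      G = sum(col == "G"), T = sum(col == "T"),
      other = sum(!col %in% .BASES))
  }, numeric(5L))
  out <- data.frame(
    position = seq_len(k),
    primer_code = strsplit(p$sequence, "", fixed = TRUE)[[1L]],
    A = counts["A", ], C = counts["C", ], G = counts["G", ],
    T = counts["T", ], other = counts["other", ],
    stringsAsFactors = FALSE
  )
  attr(out, "primer_name") <- p$name
  attr(out, "n_regions") <- length(regions)
  class(out) <- c("position_profile", "data.frame")
  out
}

# Fraction of regions matched with zero mismatches by a primer bit vector.
.exact_match_fraction <- function(region_bits, pbits) {
  if (!length(region_bits)) return(0)
  notp <- bitwAnd(bitwNot(pbits), 15L)
  hits <- vapply(region_bits, function(rb) {
    all(bitwAnd(rb, notp) == 0L)
  }, logical(1L))
  mean(hits)
}

.regions_to_bits <- function(regions) {
  lapply(toupper(regions), .seq_bits, what = "region")
}

#' Propose minimal degeneracy expansions for a primer
#'
#' Greedy algorithm: for every position the candidate new code is the IUPAC
#' symbol for the union of the current base set with all bases whose profile
#' frequency is at least `min_base_freq`; candidate positions are then
#' accepted one at a time in order of marginal gain in the fraction of
#' target regions matched with zero mismatches, while the number of changed
#' positions stays within `max_changed_positions`, total degeneracy stays
#' within `max_degeneracy`, and the gain is positive. Ties in gain are
#' broken by the smaller degeneracy increase, then by the 5'-most position.
#' Only expansions are ever generated; narrowings (which trade off-target
#' coverage and require judgment the frequency profile cannot supply) must
#' be made by explicit user edits.
#'
#' @param primer a `primer_sequence` or IUPAC string.
#' @param profile a [build_profile()] result for the same primer, or `NULL`
#'   to build one from `regions`.
#' @param regions the target binding regions (primer-oriented); required for
#'   coverage scoring.
#' @param min_base_freq minimum per-position base frequency (over ACGT
#'   calls) for a base to be absorbed into the code; default 0.10, below
#'   which a base is treated as a rare variant or noise.
#' @param max_changed_positions cap on the number of modified positions.
#' @param max_degeneracy cap on the proposed primer's degeneracy.
#' @param offtarget_regions optional off-target regions scored before/after
#'   for comparison (never part of the objective).
#' @return a list of class `design_proposal`: `original`, `proposed`
#'   (`primer_sequence`s), `changes` (data.frame `position`, `old`, `new`,
#'   `class`), coverage before/after on target (and off-target when given),
#'   and degeneracy before/after.
#' @export
propose_degeneracy <- function(primer, profile = NULL, regions,
                               min_base_freq = 0.10,
                               max_changed_positions = Inf,
                               max_degeneracy = Inf,
                               offtarget_regions = NULL) {
  p <- .as_primer(primer)
  k <- length(p$bits)
  if (is.null(profile)) profile <- build_profile(regions, p)
  stopifnot(nrow(profile) == k)
  if (max_degeneracy < degeneracy(p)) {
    stop(structure(
      class = c("primercov_constraint_error", "error", "condition"),
      list(message = sprintf(
        "max_degeneracy (%s) is below the primer's existing degeneracy (%s)",
        format(max_degeneracy), format(degeneracy(p))
      ), call = NULL)
    ))
  }
  region_bits <- .regions_to_bits(regions)
  off_bits <- if (!is.null(offtarget_regions)) .regions_to_bits(offtarget_regions)

  base_bit <- c(A = 1L, C = 2L, G = 4L, T = 8L)
  acgt <- as.matrix(profile[, c("A", "C", "G", "T")])
  denom <- rowSums(acgt)
  # candidate code per position: old set union frequent bases
  cand_bits <- p$bits
  for (j in seq_len(k)) {
    if (denom[j] > 0L) {
      freq <- acgt[j, ] / denom[j]
      add <- base_bit[freq >= min_base_freq]
      cand_bits[j] <- Reduce(bitwOr, add, p$bits[j])
    }
  }

  cur_bits <- p$bits
  cur_cov <- .exact_match_fraction(region_bits, cur_bits)
  before_cov <- cur_cov
  changed <- integer(0L)
  repeat {
    open <- setdiff(which(cand_bits != cur_bits), changed)
    if (!length(open) || length(changed) >= max_changed_positions) break
    gains <- vapply(open, function(j) {
      trial <- cur_bits
      trial[j] <- cand_bits[j]
      .exact_match_fraction(region_bits, trial) - cur_cov
    }, numeric(1L))
    deg_inc <- vapply(open, function(j) {
      trial <- cur_bits
      trial[j] <- cand_bits[j]
      degeneracy(.bits_to_string(trial)) / degeneracy(.bits_to_string(cur_bits))
    }, numeric(1L))
    feasible <- vapply(open, function(j) {
      trial <- cur_bits
      trial[j] <- cand_bits[j]
      degeneracy(.bits_to_string(trial)) <= max_degeneracy
    }, logical(1L))
    ok <- which(gains > 0 & feasible)
    if (!length(ok)) break
    pick <- ok[order(-gains[ok], deg_inc[ok], open[ok])][1L]
    j <- open[pick]
    cur_bits[j] <- cand_bits[j]
    cur_cov <- cur_cov + gains[pick]
    changed <- c(changed, j)
  }

  proposed <- primer(.bits_to_string(cur_bits),
                     name = paste0(p$name, "_proposed"),
                     orientation = p$orientation)
  changes <- diff_primers(p, proposed)
  out <- list(
    original = p,
    proposed = proposed,
    changes = changes,
    target_coverage_before = before_cov,
    target_coverage_after = .exact_match_fraction(region_bits, cur_bits),
    degeneracy_before = degeneracy(p),
    degeneracy_after = degeneracy(proposed)
  )
  if (!is.null(off_bits)) {
    out$offtarget_coverage_before <- .exact_match_fraction(off_bits, p$bits)
    out$offtarget_coverage_after <- .exact_match_fraction(off_bits, cur_bits)
  }
  class(out) <- "design_proposal"
  out
}

#' @export
print.design_proposal <- function(x, ...) {
  cat(sprintf("<design_proposal> %s -> %s\n",
              x$original$sequence, x$proposed$sequence))
  cat(sprintf("  changes: %d; degeneracy %d -> %d\n",
              nrow(x$changes), x$degeneracy_before, x$degeneracy_after))
  cat(sprintf("  target exact-match coverage: %.3f -> %.3f\n",
              x$target_coverage_before, x$target_coverage_after))
  if (!is.null(x$offtarget_coverage_before)) {
    cat(sprintf("  off-target exact-match coverage: %.3f -> %.3f\n",
                x$offtarget_coverage_before, x$offtarget_coverage_after))
  }
  if (nrow(x$changes)) print(x$changes, row.names = FALSE)
  invisible(x)
}

#' Classify the differences between two equal-length primers
#'
#' Per differing position reports the old and new code and a change class:
#' `expansion` when the old base set is a strict subset of the new,
#' `narrowing` when the new is a strict subset of the old, and
#' `substitution` otherwise. Positions are 1-based from the primer's 5' end,
#' the convention used in primer literature.
#'
#' @param original,modified `primer_sequence` objects or IUPAC strings of
#'   equal length (unequal lengths raise an error; align manually first).
#' @return data.frame with columns `position`, `old`, `new`, `class`.
#' @examples
#' diff_primers("GTGYCAGCMGCCGCGGTAA", "GTGYCAGMAGBNKCGGTVA")
#' @export
diff_primers <- function(original, modified) {
  a <- .as_primer(original)
  b <- .as_primer(modified)
  if (length(a$bits) != length(b$bits)) {
    stop(sprintf(
      "primers differ in length (%d vs %d); align them manually before diffing",
      length(a$bits), length(b$bits)
    ), call. = FALSE)
  }
  pos <- which(a$bits != b$bits)
  cls <- vapply(pos, function(j) {
    old <- a$bits[j]; new <- b$bits[j]
    if (bitwAnd(old, new) == old) "expansion"       # old strictly inside new
    else if (bitwAnd(old, new) == new) "narrowing"  # new strictly inside old
    else "substitution"
  }, character(1L))
  data.frame(
    position = pos,
    old = .BITS_TO_SYM[a$bits[pos]],
    new = .BITS_TO_SYM[b$bits[pos]],
    class = cls,
    stringsAsFactors = FALSE
  )
}
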