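# Exhaustive Hamming-distance window scanning for primer binding sites.
#
# No indels: each candidate site is a fixed-length window of the reference,
# compared position-wise under the configured ambiguity-matching mode.
# Coordinates are 1-based inclusive (R string convention); every reported
# window satisfies substr(reference, start, end) == window.

#' Search configuration
#'
#' @param max_mismatches_locate maximum mismatches for a site to be located
#'   at all. The generous default (5) lets divergent target-clade sequences
#'   still be found for binding-region extraction.
#' @param pair_budget total mismatch budget over both primers used to flag a
#'   pair match as within budget (0 = perfect match only; 1 allows a single
#'   mismatch with one of the two primers).
#' @param min_insert minimum number of bases strictly between the two primer
#'   windows.
#' @param max_amplicon maximum amplicon length (outer primer end to end).
#'   The default 5000 admits intron-containing 16S genes.
#' @param match_mode `"subset"` (default, conservative) or `"intersect"`;
#'   see [code_match()].
#' @param three_prime_clamp number of 3'-terminal primer positions in which
#'   any mismatch disqualifies a window (0 = off, the default).
#' @return an object of class `search_config`.
#' @export
search_config <- function(max_mismatches_locate = 5L, pair_budget = 1L,
                          min_insert = 30L, max_amplicon = 5000L,
                          match_mode = c("subset", "intersect"),
                          three_prime_clamp = 0L) {
  match_mode <- match.arg(match_mode)
  stopifnot(
    max_mismatches_locate >= 0L, pair_budget >= 0L,
    min_insert >= 0L, three_prime_clamp >= 0L,
    min_insert < max_amplicon
  )
  structure(
    list(
      max_mismatches_locate = as.integer(max_mismatches_locate),
      pair_budget = as.integer(pair_budget),
      min_insert = as.integer(min_insert),
      max_amplicon = as.integer(max_amplicon),
      match_mode = match_mode,
      three_prime_clamp = as.integer(three_prime_clamp)
    ),
    class = "search_config"
  )
}

# Per-window mismatch counts of a primer pattern against a reference, both
# given as bit vectors. Returns integer vector of length n_windows; windows
# disqualified by the 3' clamp are set to NA.
# three_prime = "right" when the pattern's 3' end is its last position (a
# forward primer), "left" when the pattern is a reverse primer already
# reverse-complemented onto the forward strand.
.window_mismatches <- function(pbits, rbits, mode, clamp = 0L,
                               three_prime = "right") {
  k <- length(pbits)
  n <- length(rbits) - k + 1L
  if (n < 1L) return(integer(0L))
  notp <- bitwAnd(bitwNot(pbits), 15L)
  mm <- integer(n)
  clamped <- logical(n)
  clamp_pos <- if (clamp > 0L) {
    if (three_prime == "right") (k - clamp + 1L):k else 1L:min(clamp, k)
  } else integer(0L)
  for (j in seq_len(k)) {
    rb <- rbits[j:(j + n - 1L)]
    miss <- if (mode == "subset") {
      bitwAnd(rb, notp[j]) != 0L
    } else {
      bitwAnd(rb, pbits[j]) == 0L
    }
    mm <- mm + miss
    if (j %in% clamp_pos) clamped <- clamped | miss
  }
  mm[clamped] <- NA_integer_
  mm
}

#' Locate the best binding site of a primer in a reference sequence
#'
#' Scans every window of primer length (Hamming distance only, no indels)
#' and returns the window with the minimum mismatch count, provided it does
#' not exceed `config$max_mismatches_locate`. Ties are broken by the
#' smallest start coordinate. The primer must already be oriented for
#' forward-strand comparison; [evaluate_pair()] handles reverse primers.
#'
#' @param primer a `primer_sequence` or IUPAC string.
#' @param reference nucleotide string (gaps are stripped, non-IUPAC
#'   characters become `N`).
#' @param config a [search_config()].
#' @param three_prime `"right"` (forward-oriented primer) or `"left"` (a
#'   reverse primer pattern already reverse-complemented); only relevant
#'   when `three_prime_clamp > 0`.
#' @return a list with elements `primer_name`, `start`, `end` (1-based
#'   inclusive), `strand`, `mismatches`, `window`, or `NULL` when no window
#'   qualifies. References shorter than the primer yield `NULL` (a no-span
#'   condition, not an error); an empty reference is an error.
#' @export
locate <- function(primer, reference, config = search_config(),
                   three_prime = c("right", "left")) {
  three_prime <- match.arg(three_prime)
  p <- .as_primer(primer)
  if (!is.character(reference) || length(reference) != 1L || !nzchar(reference)) {
    stop("reference must be a nonempty nucleotide string", call. = FALSE)
  }
  ref <- clean_reference_sequence(reference, warn = FALSE)
  rbits <- .seq_bits(ref, "reference")
  mm <- .window_mismatches(p$bits, rbits, config$match_mode,
                           config$three_prime_clamp, three_prime)
  .best_site(p, ref, mm, config$max_mismatches_locate)
}

.best_site <- function(p, ref, mm, max_mm, strand = "+") {
  if (!length(mm) || all(is.na(mm))) return(NULL)
  best <- min(mm, na.rm = TRUE)
  if (best > max_mm) return(NULL)
  start <- which(mm == best)[1L]
  k <- length(p$bits)
  list(
    primer_name = p$name,
    start = start,
    end = start + k - 1L,
    strand = strand,
    mismatches = as.integer(best),
    window = substr(ref, start, start + k - 1L)
  )
}

#' Evaluate a primer pair against a reference sequence
#'
#' The reverse primer is given 5'->3' as synthesized; its reverse complement
#' is matched on the forward strand downstream of the forward site. All
#' (forward window, reverse window) combinations satisfying the geometry
#' (reverse window after the forward window, insert >= `min_insert`,
#' amplicon <= `max_amplicon`) are considered; the combination minimizing
#' total mismatches, then amplicon length, then forward start is selected.
#'
#' @param fwd,rev `primer_sequence` objects or IUPAC strings.
#' @param reference nucleotide string (sense strand assumed, as in
#'   SILVA/MiDAS exports).
#' @param config a [search_config()].
#' @return a list of class `pair_match` with the forward and reverse sites
#'   (both reported in forward-strand coordinates), `amplicon_start`,
#'   `amplicon_end`, `insert_length`, `total_mismatches`, `within_budget`
#'   and `status` in `perfect` / `single_mismatch` / `no_match` / `no_span`.
#' @export
evaluate_pair <- function(fwd, rev, reference, config = search_config()) {
  f <- .as_primer(fwd)
  r <- .as_primer(rev, orientation = "reverse")
  if (!is.character(reference) || length(reference) != 1L || !nzchar(reference)) {
    stop("reference must be a nonempty nucleotide string", call. = FALSE)
  }
  ref <- clean_reference_sequence(reference, warn = FALSE)
  rbits <- .seq_bits(ref, "reference")
  kf <- length(f$bits)
  rc_bits <- rev(.COMP_BITS[r$bits])
  kr <- length(rc_bits)

  no_span <- structure(
    list(
      forward_site = NULL, reverse_site = NULL,
      amplicon_start = NA_integer_, amplicon_end = NA_integer_,
      insert_length = NA_integer_, total_mismatches = NA_integer_,
      within_budget = FALSE, status = "no_span"
    ),
    class = "pair_match"
  )
  if (length(rbits) < kf + config$min_insert + kr) return(no_span)

  mmf <- .window_mismatches(f$bits, rbits, config$match_mode,
                            config$three_prime_clamp, "right")
  mmr <- .window_mismatches(rc_bits, rbits, config$match_mode,
                            config$three_prime_clamp, "left")
  fc <- which(!is.na(mmf) & mmf <= config$max_mismatches_locate)
  rc <- which(!is.na(mmr) & mmr <= config$max_mismatches_locate)
  if (!length(fc) || !length(rc)) return(no_span)

  best <- NULL
  for (fs in fc) {
    fe <- fs + kf - 1L
    rs_min <- fe + 1L + config$min_insert
    rs_max <- fs + config$max_amplicon - kr
    ok <- rc[rc >= rs_min & rc <= rs_max]
    if (!length(ok)) next
    tot <- mmf[fs] + mmr[ok]
    amp <- ok + kr - 1L - fs + 1L
    ord <- order(tot, amp, ok)
    cand <- list(fs = fs, rs = ok[ord[1L]],
                 tot = tot[ord[1L]], amp = amp[ord[1L]])
    if (is.null(best) ||
        cand$tot < best$tot ||
        (cand$tot == best$tot && cand$amp < best$amp)) {
      # forward starts are visited left to right, so equal (tot, amp)
      # keeps the leftmost forward start
      best <- cand
    }
  }
  if (is.null(best)) return(no_span)

  fs <- best$fs; rs <- best$rs
  fsite <- list(
    primer_name = f$name, start = fs, end = fs + kf - 1L,
    strand = "+", mismatches = as.integer(mmf[fs]),
    window = substr(ref, fs, fs + kf - 1L)
  )
  rsite <- list(
    primer_name = r$name, start = rs, end = rs + kr - 1L,
    strand = "-", mismatches = as.integer(mmr[rs]),
    window = substr(ref, rs, rs + kr - 1L)
  )
  tot <- as.integer(best$tot)
  status <- if (tot == 0L) "perfect" else if (tot == 1L) "single_mismatch" else "no_match"
  structure(
    list(
      forward_site = fsite, reverse_site = rsite,
      amplicon_start = fs, amplicon_end = rs + kr - 1L,
      insert_length = rs - (fs + kf - 1L) - 1L,
      total_mismatches = tot,
      within_budget = tot <= config$pair_budget,
      status = status
    ),
    class = "pair_match"
  )
}

#' @export
print.pair_match <- function(x, ...) {
  if (x$status == "no_span") {
    cat("<pair_match> no_span\n")
  } else {
    cat(sprintf(
      "<pair_match> %s: amplicon %d-%d (insert %d nt), %d total mismatch(es)\n",
      x$status, x$amplicon_start, x$amplicon_end, x$insert_length,
      x$total_mismatches
    ))
  }
  invisible(x)
}

#' Extract primer binding regions from a reference set
#'
#' For each record with a geometrically valid primer pair at no more than
#' `config$max_mismatches_locate` mismatches per primer, returns the forward
#' binding window (forward-strand orientation) and the reverse binding
#' window re-oriented into primer coordinates (reverse-complemented, so
#' position 1 corresponds to the reverse primer's 5' base). Records without
#' a locatable pair are reported with a reason instead of being dropped
#' silently.
#'
#' @param fwd,rev `primer_sequence` objects or IUPAC strings.
#' @param records a `reference_set` (see [reference_set()]).
#' @param config a [search_config()].
#' @return a list with `regions` (data.frame: `record_id`, `fwd_region`,
#'   `rev_region`, `fwd_mismatches`, `rev_mismatches`, `insert_length`) and
#'   `skipped` (data.frame: `record_id`, `reason`).
#' @export
extract_binding_regions <- function(fwd, rev, records,
                                    config = search_config()) {
  records <- .as_reference_set(records)
  if (nrow(records) == 0L) {
    stop("no records supplied for binding-region extraction", call. = FALSE)
  }
  n <- nrow(records)
  keep <- logical(n)
  fwd_region <- rev_region <- character(n)
  fmm <- rmm <- ins <- integer(n)
  reason <- character(n)
  for (i in seq_len(n)) {
    pm <- evaluate_pair(fwd, rev, records$sequence[i], config)
    if (pm$status == "no_span") {
      reason[i] <- "no_span"
      next
    }
    keep[i] <- TRUE
    fwd_region[i] <- pm$forward_site$window
    rev_region[i] <- reverse_complement(pm$reverse_site$window)
    fmm[i] <- pm$forward_site$mismatches
    rmm[i] <- pm$reverse_site$mismatches
    ins[i] <- pm$insert_length
  }
  list(
    regions = data.frame(
      record_id = records$record_id[keep],
      fwd_region = fwd_region[keep],
      rev_region = rev_region[keep],
      fwd_mismatches = fmm[keep],
      rev_mismatches = rmm[keep],
      insert_length = ins[keep],
      stringsAsFactors = FALSE
    ),
    skipped = data.frame(
      record_id = records$record_id[!keep],
      reason = reason[!keep],
      stringsAsFactors = FALSE
    )
  )
}
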