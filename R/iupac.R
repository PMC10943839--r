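# IUPAC nucleotide ambiguity-code semantics.
#
# Codes are represented internally as 4-bit masks over {A,C,G,T}
# (A=1, C=2, G=4, T=8), so set operations reduce to bitwise arithmetic.

.IUPAC_BITS <- c(
  A = 1L, C = 2L, G = 4L, T = 8L,
  M = 3L,  # A/C
  R = 5L,  # A/G
  W = 9L,  # A/T
  S = 6L,  # C/G
  Y = 10L, # C/T
  K = 12L, # G/T
  V = 7L,  # A/C/G
  H = 11L, # A/C/T
  D = 13L, # A/G/T
  B = 14L, # C/G/T
  N = 15L
)

.BITS_TO_SYM <- local({
  x <- character(15L)
  x[.IUPAC_BITS] <- names(.IUPAC_BITS)
  x
})

# Watson-Crick complement on the bit level: A<->T, C<->G.
.COMP_BITS <- local({
  b <- 1:15
  bitwOr(
    bitwOr(bitwAnd(b, 1L) * 8L, bitwAnd(b, 2L) * 2L),
    bitwOr(bitwAnd(b, 4L) %/% 2L, bitwAnd(b, 8L) %/% 8L)
  )
})

.BASES <- c("A", "C", "G", "T")

#' Convert an IUPAC string to its bit-mask representation
#'
#' @param x a single character string of IUPAC symbols.
#' @param what label used in error messages (e.g. a primer name).
#' @return integer vector of 4-bit masks, one per position.
#' @keywords internal
#' @noRd
.seq_bits <- function(x, what = "sequence") {
  chars <- strsplit(x, "", fixed = TRUE)[[1L]]
  bits <- unname(.IUPAC_BITS[chars])
  bad <- which(is.na(bits))
  if (length(bad)) {
    stop(sprintf(
      "invalid IUPAC character '%s' at position %d of %s",
      chars[bad[1L]], bad[1L], what
    ), call. = FALSE)
  }
  bits
}

.bits_to_string <- function(bits) {
  paste(.BITS_TO_SYM[bits], collapse = "")
}

#' Expand an IUPAC ambiguity code into its base set
#'
#' Each of the 15 IUPAC one-letter nucleotide codes denotes a nonempty subset
#' of \{A,C,G,T\} (e.g. `M` = \{A,C\}, `B` = \{C,G,T\}, `N` = all four).
#'
#' @param symbol a single IUPAC character.
#' @return character vector of the bases the code stands for, in ACGT order.
#' @examples
#' expand_code("N")
#' expand_code("M")
#' @export
expand_code <- function(symbol) {
  if (!is.character(symbol) || length(symbol) != 1L || nchar(symbol) != 1L) {
    stop("'symbol' must be a single character", call. = FALSE)
  }
  bits <- .IUPAC_BITS[toupper(symbol)]
  if (is.na(bits)) {
    stop(sprintf("invalid IUPAC character '%s'", symbol), call. = FALSE)
  }
  .BASES[bitwAnd(bits, c(1L, 2L, 4L, 8L)) > 0L]
}

#' Match a database code against a primer code
#'
#' Two modes are supported. In `subset` mode (the conservative default used
#' throughout coverage analysis) the database code matches only if every base
#' it could stand for is covered by the primer code, so e.g. a database `N`
#' is only matched by a primer `N`. In `intersect` mode a single shared base
#' suffices.
#'
#' @param primer_code,db_code single IUPAC characters.
#' @param mode `"subset"` or `"intersect"`.
#' @return logical scalar.
#' @examples
#' code_match("M", "A", "subset")    # TRUE: {A} is inside {A,C}
#' code_match("A", "N", "subset")    # FALSE
#' code_match("A", "N", "intersect") # TRUE
#' @export
code_match <- function(primer_code, db_code, mode = c("subset", "intersect")) {
  mode <- match.arg(mode)
  p <- .seq_bits(toupper(primer_code), "primer code")
  d <- .seq_bits(toupper(db_code), "database code")
  if (length(p) != 1L || length(d) != 1L) {
    stop("codes must be single characters", call. = FALSE)
  }
  if (mode == "subset") {
    bitwAnd(d, bitwAnd(bitwNot(p), 15L)) == 0L
  } else {
    bitwAnd(d, p) > 0L
  }
}

#' Construct a primer sequence
#'
#' Normalizes the sequence (uppercase, U to T) and validates every character
#' against the IUPAC alphabet. Primers containing any other character are
#' rejected. The sequence is stored 5'->3' as synthesized.
#'
#' @param sequence IUPAC string, 5'->3'.
#' @param name primer label, e.g. `"515F"`.
#' @param orientation `"forward"` or `"reverse"` (relative to the sense
#'   strand of the target).
#' @return an object of class `primer_sequence`.
#' @examples
#' p <- primer("GTGYCAGCMGCCGCGGTAA", "515F", "forward")
#' degeneracy(p)
#' @export
primer <- function(sequence, name = "primer",
                   orientation = c("forward", "reverse")) {
  orientation <- match.arg(orientation)
  if (!is.character(sequence) || length(sequence) != 1L || !nzchar(sequence)) {
    stop("primer sequence must be a nonempty character string", call. = FALSE)
  }
  seq <- chartr("u", "t", sequence)
  seq <- toupper(chartr("U", "T", seq))
  bits <- .seq_bits(seq, sprintf("primer '%s'", name))
  structure(
    list(name = name, sequence = seq, orientation = orientation, bits = bits),
    class = "primer_sequence"
  )
}

#' @export
print.primer_sequence <- function(x, ...) {
  cat(sprintf(
    "<primer> %s (%s): 5'-%s-3'  length %d, degeneracy %d\n",
    x$name, x$orientation, x$sequence, length(x$bits), degeneracy(x)
  ))
  invisible(x)
}

.as_primer <- function(x, orientation = "forward") {
  if (inherits(x, "primer_sequence")) x else primer(x, orientation = orientation)
}

#' Degeneracy of a primer
#'
#' The number of distinct fully-resolved (ACGT-only) sequences a degenerate
#' primer encodes: the product over positions of the base-set sizes.
#'
#' @param seq a `primer_sequence` or an IUPAC string.
#' @return positive integer (as double to avoid overflow on long primers).
#' @examples
#' degeneracy("ACGT") # 1
#' degeneracy("NN")   # 16
#' @export
degeneracy <- function(seq) {
  p <- .as_primer(seq)
  counts <- vapply(p$bits, function(b) {
    sum(bitwAnd(b, c(1L, 2L, 4L, 8L)) > 0L)
  }, integer(1L))
  prod(counts)
}

#' Reverse complement of an IUPAC string
#'
#' Complements each code through the IUPAC complement involution (A<->T,
#' C<->G, R<->Y, K<->M, B<->V, D<->H; S, W and N are self-complementary),
#' then reverses. Applying the operation twice returns the input.
#'
#' @param seq a `primer_sequence` or an IUPAC string.
#' @return a character string (the input class is not preserved).
#' @examples
#' reverse_complement("ACGT") # "ACGT"
#' reverse_complement("GGACTACNVGGGTWTCTAAT")
#' @export
reverse_complement <- function(seq) {
  bits <- if (inherits(seq, "primer_sequence")) seq$bits else .seq_bits(toupper(chartr("Uu", "Tt", seq)))
  .bits_to_string(rev(.COMP_BITS[bits]))
}

#' Normalize a database (reference) sequence
#'
#' Applies the lenient normalization used for reference databases: uppercase,
#' U to T, alignment gap characters (`-`, `.`) stripped, and any remaining
#' non-IUPAC character replaced by `N`. Replacement counts are reported via a
#' warning so corrupt inputs are visible but do not abort a database scan.
#'
#' @param x character vector of sequences.
#' @param warn warn when non-IUPAC characters were replaced.
#' @return character vector of cleaned sequences.
#' @export
clean_reference_sequence <- function(x, warn = TRUE) {
  y <- toupper(chartr("Uu", "Tt", x))
  y <- gsub("[.-]", "", y)
  n_bad <- 0L
  ok <- paste(names(.IUPAC_BITS), collapse = "")
  bad_rx <- sprintf("[^%s]", ok)
  has_bad <- grepl(bad_rx, y)
  if (any(has_bad)) {
    n_bad <- sum(vapply(
      gregexpr(bad_rx, y[has_bad]),
      function(m) sum(m > 0L), integer(1L)
    ))
    y[has_bad] <- gsub(bad_rx, "N", y[has_bad])
    if (warn) {
      warning(sprintf(
        "replaced %d non-IUPAC character(s) with 'N' in %d sequence(s)",
        n_bad, sum(has_bad)
      ), call. = FALSE)
    }
  }
  y
}
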