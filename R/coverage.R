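# Per-taxon coverage tables for primer pairs over a reference database.

.RANKS <- c("domain", "phylum", "class", "order", "family", "genus", "species")

#' Construct a reference sequence set
#'
#' Bundles sequences with ranked taxonomy lineages. Lineages may be ragged
#' (trailing ranks absent) but must not have gaps in the middle; rank values
#' are opaque labels, so placeholder names such as `midas_g_2215` are kept
#' verbatim.
#'
#' @param record_id character vector of unique record identifiers.
#' @param sequence character vector of nucleotide sequences (cleaned via
#'   [clean_reference_sequence()] on construction).
#' @param lineage list of character vectors, ordered domain, phylum, class,
#'   order, family, genus and optionally species.
#' @return a data.frame of class `reference_set` with a `lineage`
#'   list-column.
#' @export
reference_set <- function(record_id, sequence, lineage) {
  stopifnot(length(record_id) == length(sequence),
            length(record_id) == length(lineage))
  if (anyDuplicated(record_id)) {
    stop("duplicate record ids: ",
         paste(unique(record_id[duplicated(record_id)]), collapse = ", "),
         call. = FALSE)
  }
  sequence <- clean_reference_sequence(as.character(sequence))
  if (any(!nzchar(sequence))) {
    stop("empty sequence after gap stripping for record(s): ",
         paste(record_id[!nzchar(sequence)], collapse = ", "), call. = FALSE)
  }
  lineage <- lapply(lineage, function(l) {
    l <- as.character(l)
    l[is.na(l)] <- ""
    nz <- nzchar(l)
    if (any(nz) && any(!nz[seq_len(max(which(nz)))])) {
      stop("lineage has an empty middle rank", call. = FALSE)
    }
    l[nz]
  })
  out <- data.frame(record_id = as.character(record_id),
                    sequence = sequence, stringsAsFactors = FALSE)
  out$lineage <- lineage
  class(out) <- c("reference_set", "data.frame")
  out
}

.as_reference_set <- function(x) {
  if (inherits(x, "reference_set")) return(x)
  if (is.data.frame(x) && all(c("record_id", "sequence") %in% names(x))) {
    lin <- if ("lineage" %in% names(x)) x$lineage else rep(list(character(0L)), nrow(x))
    return(reference_set(x$record_id, x$sequence, lin))
  }
  stop("expected a reference_set (see ?reference_set)", call. = FALSE)
}

.rank_index <- function(rank) {
  i <- match(tolower(rank), .RANKS)
  if (is.na(i)) {
    stop(sprintf("unknown rank '%s'; expected one of %s",
                 rank, paste(.RANKS, collapse = ", ")), call. = FALSE)
  }
  i
}

.taxon_at_rank <- function(lineage, rank_i) {
  vapply(lineage, function(l) {
    if (length(l) >= rank_i) l[[rank_i]] else "Unclassified"
  }, character(1L))
}

# Half-up rounding to one decimal, mirroring printed table style.
.pct1 <- function(x) floor(x * 10 + 0.5) / 10

#' Per-taxon primer-pair coverage at mismatch budgets 0 and <=1
#'
#' Evaluates the primer pair against every record and aggregates matches per
#' taxon at the requested rank. `n_total` counts all records of the taxon,
#' `n_evaluated` those with a geometrically valid pair (status not
#' `no_span`); matches are counted at total pair budgets 0 and <= 1.
#' Percentages use `n_total` as denominator by default; `denominator =
#' "evaluated"` restricts to spanning records (useful for databases of
#' trimmed sequences where some primers cannot be evaluated at all).
#'
#' @param records a [reference_set()].
#' @param fwd,rev `primer_sequence` objects or IUPAC strings.
#' @param config a [search_config()].
#' @param rank taxonomic rank to aggregate at (default `"phylum"`).
#' @param denominator `"total"` or `"evaluated"`.
#' @return a data.frame of class `coverage_table` with columns `rank`,
#'   `taxon`, `n_total`, `n_evaluated`, `n_match_0mm`, `n_match_le1mm`,
#'   `pct_0mm`, `pct_le1mm`, sorted by taxon.
#' @export
compute_coverage <- function(records, fwd, rev, config = search_config(),
                             rank = "phylum",
                             denominator = c("total", "evaluated")) {
  denominator <- match.arg(denominator)
  records <- .as_reference_set(records)
  if (nrow(records) == 0L) stop("empty record set", call. = FALSE)
  rank_i <- .rank_index(rank)
  taxa <- .taxon_at_rank(records$lineage, rank_i)
  if (all(taxa == "Unclassified")) {
    warning(sprintf("no record is classified at rank '%s'", rank),
            call. = FALSE)
  }
  n <- nrow(records)
  spans <- logical(n)
  total_mm <- rep(NA_integer_, n)
  for (i in seq_len(n)) {
    pm <- evaluate_pair(fwd, rev, records$sequence[i], config)
    if (pm$status != "no_span") {
      spans[i] <- TRUE
      total_mm[i] <- pm$total_mismatches
    }
  }
  .aggregate_coverage(taxa, spans, total_mm, rank, denominator,
                      fwd = .as_primer(fwd), rev = .as_primer(rev, "reverse"))
}

.aggregate_coverage <- function(taxa, spans, total_mm, rank, denominator,
                                fwd = NULL, rev = NULL) {
  ord_taxa <- sort(unique(taxa))
  rows <- lapply(ord_taxa, function(tx) {
    sel <- taxa == tx
    n_total <- sum(sel)
    n_eval <- sum(spans[sel])
    m0 <- sum(spans[sel] & total_mm[sel] == 0L, na.rm = TRUE)
    m1 <- sum(spans[sel] & total_mm[sel] <= 1L, na.rm = TRUE)
    denom <- if (denominator == "evaluated") n_eval else n_total
    data.frame(
      rank = rank, taxon = tx, n_total = n_total, n_evaluated = n_eval,
      n_match_0mm = m0, n_match_le1mm = m1,
      pct_0mm = if (denom > 0L) .pct1(100 * m0 / denom) else 0,
      pct_le1mm = if (denom > 0L) .pct1(100 * m1 / denom) else 0,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  attr(out, "denominator") <- denominator
  if (!is.null(fwd)) {
    attr(out, "primers") <- c(fwd = fwd$sequence, rev = rev$sequence)
  }
  class(out) <- c("coverage_table", "data.frame")
  out
}

#' Compare several primer pairs on the same reference set
#'
#' Computes coverage for each labelled pair over identical records and joins
#' the results into one wide table, with a delta column (`pct_0mm`
#' difference against a designated baseline pair) so coverage gains of a
#' modified pair are immediately visible per taxon.
#'
#' @param records a [reference_set()].
#' @param pairs named list; each element is a list/pair of (fwd, rev)
#'   primers. Names are the pair labels and must be unique.
#' @param config a [search_config()].
#' @param rank taxonomic rank.
#' @param baseline label of the baseline pair (default: first).
#' @param denominator passed to [compute_coverage()].
#' @return a data.frame of class `coverage_comparison`: `rank`, `taxon`,
#'   `n_total`, then per pair `<label>.n_match_0mm`, `<label>.pct_0mm`,
#'   `<label>.pct_le1mm`, and `delta_pct_0mm_vs_<baseline>` per non-baseline
#'   pair.
#' @export
compare_primer_pairs <- function(records, pairs, config = search_config(),
                                 rank = "phylum", baseline = NULL,
                                 denominator = c("total", "evaluated")) {
  denominator <- match.arg(denominator)
  if (length(pairs) < 2L) stop("need at least two primer pairs", call. = FALSE)
  labels <- names(pairs)
  if (is.null(labels) || any(!nzchar(labels))) {
    stop("primer pairs must be named", call. = FALSE)
  }
  if (anyDuplicated(labels)) {
    stop("duplicate pair labels: ",
         paste(unique(labels[duplicated(labels)]), collapse = ", "),
         call. = FALSE)
  }
  if (is.null(baseline)) baseline <- labels[1L]
  if (!baseline %in% labels) stop("unknown baseline label", call. = FALSE)

  tabs <- lapply(pairs, function(pr) {
    compute_coverage(records, pr[[1L]], pr[[2L]], config, rank, denominator)
  })
  base_cols <- tabs[[1L]][, c("rank", "taxon", "n_total")]
  out <- base_cols
  for (lab in labels) {
    tb <- tabs[[lab]]
    stopifnot(identical(tb$taxon, base_cols$taxon))
    block <- tb[, c("n_match_0mm", "n_match_le1mm", "pct_0mm", "pct_le1mm")]
    names(block) <- paste(lab, names(block), sep = ".")
    out <- cbind(out, block)
  }
  base_pct <- tabs[[baseline]]$pct_0mm
  for (lab in setdiff(labels, baseline)) {
    out[[paste0("delta_pct_0mm_", lab, "_vs_", baseline)]] <-
      .pct1(tabs[[lab]]$pct_0mm - base_pct)
  }
  attr(out, "baseline") <- baseline
  class(out) <- c("coverage_comparison", "data.frame")
  out
}
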