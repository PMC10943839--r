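# Community-membership rules for genus-level amplicon tables:
# read filtering, strict/general/loose core classification, conditionally
# rare or abundant taxa (CRAT), and sequence-novelty fractions.

#' Construct a relative-abundance table
#'
#' @param values numeric matrix, taxa in rows, samples in columns, values as
#'   percent of the sample total (each column sums to at most 100, within a
#'   small tolerance).
#' @param metadata optional data.frame with one row per sample; must contain
#'   a `sample_id` column matching the matrix column names. Additional
#'   columns (process type, country, ...) are free-form.
#' @return an object of class `abundance_table`.
#' @export
abundance_table <- function(values, metadata = NULL) {
  values <- as.matrix(values)
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop("abundance matrix needs taxon rownames and sample colnames",
         call. = FALSE)
  }
  if (anyDuplicated(rownames(values))) stop("duplicate taxon ids", call. = FALSE)
  if (anyDuplicated(colnames(values))) stop("duplicate sample ids", call. = FALSE)
  if (any(values < 0)) stop("negative abundances", call. = FALSE)
  sums <- colSums(values)
  if (any(sums > 100 + 1e-6)) {
    stop("per-sample abundances exceed 100%: ",
         paste(colnames(values)[sums > 100 + 1e-6], collapse = ", "),
         call. = FALSE)
  }
  if (!is.null(metadata)) {
    if (!"sample_id" %in% names(metadata)) {
      stop("metadata must contain a 'sample_id' column", call. = FALSE)
    }
    missing <- setdiff(colnames(values), metadata$sample_id)
    if (length(missing)) {
      stop("metadata missing for sample(s): ",
           paste(missing, collapse = ", "), call. = FALSE)
    }
    metadata <- metadata[match(colnames(values), metadata$sample_id), ,
                         drop = FALSE]
    rownames(metadata) <- NULL
  }
  structure(list(values = values, metadata = metadata),
            class = "abundance_table")
}

#' Convert a count matrix to per-sample relative abundance (percent)
#'
#' @param counts numeric matrix, taxa in rows, samples in columns.
#' @return matrix of the same shape with columns summing to 100 (all-zero
#'   samples stay zero).
#' @export
counts_to_percent <- function(counts) {
  counts <- as.matrix(counts)
  sums <- colSums(counts)
  sweep(counts, 2L, ifelse(sums > 0, sums, 1), "/") * 100
}

#' Filter an ASV count table by classification and sequencing depth
#'
#' Removes ASVs with no phylum-level classification or classified as
#' mitochondria/chloroplasts, then removes samples whose retained read sum
#' does not exceed `min_reads`. The removal report gives the percentage of
#' all reads removed per category, so the cost of filtering is explicit.
#'
#' @param counts numeric matrix of reads, ASVs in rows, samples in columns.
#' @param taxonomy data.frame with columns `asv_id`, `phylum` (empty or NA
#'   when unclassified) and optionally `organelle` (`"mitochondria"`,
#'   `"chloroplast"`, or empty/NA).
#' @param min_reads retained-read threshold; samples are kept only when
#'   their retained sum is strictly greater (default 5000).
#' @return list with `counts` (filtered matrix), `removed_asvs` (data.frame
#'   `asv_id`, `reason`), `removed_samples` (character), and `report`
#'   (data.frame `category`, `n_asvs`, `pct_reads` of the original total).
#' @export
filter_table <- function(counts, taxonomy, min_reads = 5000) {
  counts <- as.matrix(counts)
  stopifnot(all(c("asv_id", "phylum") %in% names(taxonomy)))
  tax <- taxonomy[match(rownames(counts), taxonomy$asv_id), , drop = FALSE]
  if (anyNA(tax$asv_id)) {
    stop("taxonomy missing for ASV(s): ",
         paste(setdiff(rownames(counts), taxonomy$asv_id), collapse = ", "),
         call. = FALSE)
  }
  phylum <- as.character(tax$phylum)
  unclassified <- is.na(phylum) | !nzchar(phylum)
  organelle <- if ("organelle" %in% names(tax)) {
    o <- tolower(as.character(tax$organelle))
    !is.na(o) & o %in% c("mitochondria", "mitochondrion", "chloroplast")
  } else rep(FALSE, nrow(counts))

  total_reads <- sum(counts)
  pct <- function(x) if (total_reads > 0) 100 * x / total_reads else 0
  report <- data.frame(
    category = c("organelle", "unclassified_phylum"),
    n_asvs = c(sum(organelle), sum(unclassified & !organelle)),
    pct_reads = c(pct(sum(counts[organelle, , drop = FALSE])),
                  pct(sum(counts[unclassified & !organelle, , drop = FALSE]))),
    stringsAsFactors = FALSE
  )
  drop_asv <- unclassified | organelle
  kept <- counts[!drop_asv, , drop = FALSE]
  depth <- colSums(kept)
  drop_sample <- depth <= min_reads
  out <- kept[, !drop_sample, drop = FALSE]
  if (ncol(out) == 0L) {
    stop(sprintf("all samples fall at or below %d retained reads", min_reads),
         call. = FALSE)
  }
  list(
    counts = out,
    removed_asvs = data.frame(
      asv_id = rownames(counts)[drop_asv],
      reason = ifelse(organelle[drop_asv], "organelle", "unclassified_phylum"),
      stringsAsFactors = FALSE
    ),
    removed_samples = colnames(counts)[drop_sample],
    report = report
  )
}

.CORE_LEVELS <- c("none", "loose_core", "general_core", "strict_core")

.core_label <- function(prevalence, cutoffs) {
  # highest cutoff met; prevalence comparison is >= cutoff
  if (prevalence >= cutoffs[["strict"]]) "strict_core"
  else if (prevalence >= cutoffs[["general"]]) "general_core"
  else if (prevalence >= cutoffs[["loose"]]) "loose_core"
  else "none"
}

#' Classify core community members by prevalence
#'
#' A taxon's prevalence is the fraction of samples in scope in which its
#' relative abundance strictly exceeds `abundance_threshold`. The label is
#' the highest prevalence cutoff met (prevalence >= cutoff): strict core at
#' 80%, general core at 50%, loose core at 20% by default. Classification
#' is computed over all samples and, when a grouping metadata field is
#' given, within each group; group-specific core taxa (core in exactly one
#' group) are reported for overlap-style summaries.
#'
#' @param table an [abundance_table()].
#' @param abundance_threshold percent threshold a taxon must exceed in a
#'   sample to count as present there (default 0.1).
#' @param prevalence_cutoffs named numeric vector with elements `loose`,
#'   `general`, `strict` (fractions).
#' @param groups name of a metadata column to classify within, or `NULL`.
#' @return a list of class `core_classification`: `overall` (data.frame
#'   `taxon`, `scope`, `n_samples`, `prevalence`, `mean_abundance`,
#'   `max_abundance`, `label`), `by_group` (same layout, one scope per
#'   group, or `NULL`), and `group_specific` (data.frame `taxon`, `group`
#'   for taxa core in exactly one group).
#' @export
classify_core <- function(table, abundance_threshold = 0.1,
                          prevalence_cutoffs = c(loose = 0.20,
                                                 general = 0.50,
                                                 strict = 0.80),
                          groups = NULL) {
  stopifnot(inherits(table, "abundance_table"))
  stopifnot(all(c("loose", "general", "strict") %in% names(prevalence_cutoffs)))
  v <- table$values

  classify_scope <- function(mat, scope) {
    present <- mat > abundance_threshold
    prev <- rowMeans(present)
    data.frame(
      taxon = rownames(mat),
      scope = scope,
      n_samples = ncol(mat),
      prevalence = prev,
      mean_abundance = rowMeans(mat),
      max_abundance = apply(mat, 1L, max),
      label = vapply(prev, .core_label, character(1L),
                     cutoffs = prevalence_cutoffs),
      stringsAsFactors = FALSE,
      row.names = NULL
    )
  }

  overall <- classify_scope(v, "overall")
  by_group <- NULL
  group_specific <- NULL
  if (!is.null(groups)) {
    md <- table$metadata
    if (is.null(md) || !groups %in% names(md)) {
      stop(sprintf("grouping field '%s' not found in metadata", groups),
           call. = FALSE)
    }
    g <- as.character(md[[groups]])
    by_group <- do.call(rbind, lapply(sort(unique(g)), function(lev) {
      classify_scope(v[, g == lev, drop = FALSE], lev)
    }))
    is_core <- by_group$label != "none"
    core_counts <- table(by_group$taxon[is_core])
    uniq <- names(core_counts)[core_counts == 1L]
    group_specific <- by_group[is_core & by_group$taxon %in% uniq,
                               c("taxon", "scope")]
    names(group_specific) <- c("taxon", "group")
    rownames(group_specific) <- NULL
  }
  structure(
    list(overall = overall, by_group = by_group,
         group_specific = group_specific,
         abundance_threshold = abundance_threshold,
         prevalence_cutoffs = prevalence_cutoffs),
    class = "core_classification"
  )
}

#' Identify conditionally rare or abundant taxa (CRAT)
#'
#' CRAT are taxa that are not core members (overall scope) but exceed
#' `crat_threshold` percent relative abundance in at least one sample. The
#' result also carries the secondary stratification used to describe such
#' taxa: those exceeding the threshold in exactly one sample versus in more
#' than ten samples.
#'
#' @param table the [abundance_table()] the core classification was
#'   computed on.
#' @param core a [classify_core()] result on the same table.
#' @param crat_threshold percent threshold (default 1.0).
#' @return data.frame of class `crat_table`: `taxon`, `n_above_threshold`,
#'   `max_abundance`, `single_sample` (logical), `gt10_samples` (logical).
#' @export
identify_crat <- function(table, core, crat_threshold = 1.0) {
  stopifnot(inherits(table, "abundance_table"),
            inherits(core, "core_classification"))
  v <- table$values
  core_taxa <- core$overall$taxon[core$overall$label != "none"]
  n_above <- rowSums(v > crat_threshold)
  cand <- rownames(v)[n_above >= 1L & !rownames(v) %in% core_taxa]
  out <- data.frame(
    taxon = cand,
    n_above_threshold = unname(n_above[cand]),
    max_abundance = unname(apply(v[cand, , drop = FALSE], 1L, max)),
    stringsAsFactors = FALSE,
    row.names = NULL
  )
  out$single_sample <- out$n_above_threshold == 1L
  out$gt10_samples <- out$n_above_threshold > 10L
  class(out) <- c("crat_table", "data.frame")
  out
}

#' Sequence-novelty fractions at identity thresholds
#'
#' An ASV is novel at threshold `t` when it has no database hit or its best
#' percent identity is below `t` (strict `<`: an ASV at exactly the
#' threshold counts as mapped; set `inclusive = TRUE` to flip). Per-sample
#' fractions are summarized as mean and standard deviation across samples;
#' the cumulative fraction is computed over the union of distinct ASVs,
#' using each ASV's best identity across all samples.
#'
#' @param hits data.frame with columns `sample`, `asv`, `pident` (best-hit
#'   percent identity in \[0, 100\], `NA` for an explicit no-hit).
#' @param thresholds named numeric vector of identity thresholds; defaults
#'   to the high-identity (99) and genus-level (94.5) conventions.
#' @param asv_subset optional character vector restricting the analysis to
#'   a subset of ASV ids (e.g. ASVs of one phylum).
#' @param inclusive when `TRUE`, an ASV exactly at a threshold counts as
#'   novel (`<=` instead of `<`).
#' @return list of class `novelty_summary`: `per_sample` (data.frame
#'   `sample`, `threshold_name`, `threshold`, `n_total`, `n_novel`,
#'   `fraction`), `summary` (per threshold: mean, sd, n_samples), and
#'   `cumulative` (per threshold: n_asvs, n_novel, fraction). Samples with
#'   no ASV in scope are omitted from the mean/sd.
#' @export
novelty_fractions <- function(hits,
                              thresholds = c(high_identity = 99.0,
                                             genus = 94.5),
                              asv_subset = NULL, inclusive = FALSE) {
  stopifnot(all(c("sample", "asv", "pident") %in% names(hits)))
  if (any(!is.na(hits$pident) & (hits$pident < 0 | hits$pident > 100))) {
    stop("percent identities must lie in [0, 100]", call. = FALSE)
  }
  if (!is.null(asv_subset)) hits <- hits[hits$asv %in% asv_subset, , drop = FALSE]
  if (nrow(hits) == 0L) stop("no hits in scope", call. = FALSE)
  is_novel <- function(pident, t) {
    is.na(pident) | (if (inclusive) pident <= t else pident < t)
  }
  per_sample <- do.call(rbind, lapply(seq_along(thresholds), function(i) {
    t <- thresholds[[i]]
    agg <- lapply(split(hits$pident, hits$sample), function(pid) {
      c(n_total = length(pid), n_novel = sum(is_novel(pid, t)))
    })
    data.frame(
      sample = names(agg),
      threshold_name = names(thresholds)[i],
      threshold = t,
      n_total = vapply(agg, `[[`, numeric(1L), "n_total"),
      n_novel = vapply(agg, `[[`, numeric(1L), "n_novel"),
      stringsAsFactors = FALSE,
      row.names = NULL
    )
  }))
  per_sample$fraction <- per_sample$n_novel / per_sample$n_total
  summary <- do.call(rbind, lapply(names(thresholds), function(nm) {
    fr <- per_sample$fraction[per_sample$threshold_name == nm]
    data.frame(threshold_name = nm, threshold = thresholds[[nm]],
               mean = mean(fr), sd = stats::sd(fr), n_samples = length(fr),
               stringsAsFactors = FALSE)
  }))
  # best identity per distinct ASV; an all-NA ASV stays NA (never mapped)
  best <- tapply(hits$pident, hits$asv, function(x) {
    if (all(is.na(x))) NA_real_ else max(x, na.rm = TRUE)
  })
  cumulative <- do.call(rbind, lapply(names(thresholds), function(nm) {
    nv <- sum(is_novel(as.numeric(best), thresholds[[nm]]))
    data.frame(threshold_name = nm, threshold = thresholds[[nm]],
               n_asvs = length(best), n_novel = nv,
               fraction = nv / length(best),
               stringsAsFactors = FALSE)
  }))
  structure(list(per_sample = per_sample, summary = summary,
                 cumulative = cumulative),
            class = "novelty_summary")
}
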