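# Readers and writers for the interchange formats: FASTA, taxonomy TSV
# (SILVA/MiDAS export styles), abundance matrices, BLAST tabular output,
# and commented TSV reports. Plus the built-in primer registry.

#' Built-in primer registry
#'
#' Commonly used 16S rRNA gene primer pairs, addressable by name: the V1-V3
#' pair 27F/534R, the V3-V4 pair 341F/805R, the V4 pair 515F/806R, and the
#' degeneracy-expanded V4 pair 515F_Mod/806R_Mod designed to capture
#' Patescibacteria.
#'
#' @return named list of `primer_sequence` objects.
#' @examples
#' names(primer_registry())
#' primer_registry()[["515F_Mod"]]
#' @export
primer_registry <- function() {
  list(
    `27F`      = primer("AGAGTTTGATCMTGGCTCAG", "27F", "forward"),
    `534R`     = primer("ATTACCGCGGCTGCTGG", "534R", "reverse"),
    `341F`     = primer("CCTACGGGNGGCWGCAG", "341F", "forward"),
    `805R`     = primer("GACTACHVGGGTATCTAATCC", "805R", "reverse"),
    `515F`     = primer("GTGYCAGCMGCCGCGGTAA", "515F", "forward"),
    `806R`     = primer("GGACTACNVGGGTWTCTAAT", "806R", "reverse"),
    `515F_Mod` = primer("GTGYCAGMAGBNKCGGTVA", "515F_Mod", "forward"),
    `806R_Mod` = primer("RGACTAMNVRGGTHTCTAAT", "806R_Mod", "reverse")
  )
}

#' Resolve a primer by registry name or literal sequence
#'
#' @param x a registry name (e.g. `"515F_Mod"`), a literal IUPAC string, or
#'   a `primer_sequence`.
#' @param orientation used when `x` is a literal string.
#' @return a `primer_sequence`.
#' @export
resolve_primer <- function(x, orientation = "forward") {
  if (inherits(x, "primer_sequence")) return(x)
  reg <- primer_registry()
  if (is.character(x) && length(x) == 1L && x %in% names(reg)) {
    return(reg[[x]])
  }
  tryCatch(
    primer(x, orientation = orientation),
    error = function(e) {
      stop(sprintf(
        "'%s' is neither a registered primer name (%s) nor a valid IUPAC sequence",
        x, paste(names(reg), collapse = ", ")
      ), call. = FALSE)
    }
  )
}

#' Read a FASTA file
#'
#' Multi-line records are supported; the description after the first
#' whitespace of a header is retained separately. Sequences are normalized
#' for database use: uppercase, U to T, alignment gaps stripped, non-IUPAC
#' characters replaced by `N` (with a warning count).
#'
#' @param path file path.
#' @return data.frame with columns `record_id`, `description`, `sequence`.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  if (!length(lines)) stop("empty FASTA file: ", path, call. = FALSE)
  headers <- grep("^>", lines)
  if (!length(headers) || headers[1L] != 1L) {
    first_bad <- if (length(headers)) 1L else 1L
    stop(sprintf("malformed FASTA (line %d does not start a record): %s",
                 first_bad, path), call. = FALSE)
  }
  starts <- headers + 1L
  ends <- c(headers[-1L] - 1L, length(lines))
  ids <- sub("^>\\s*", "", lines[headers])
  record_id <- sub("\\s.*$", "", ids)
  description <- ifelse(grepl("\\s", ids), sub("^\\S+\\s+", "", ids), "")
  sequence <- vapply(seq_along(headers), function(i) {
    if (starts[i] > ends[i]) return("")
    paste(lines[starts[i]:ends[i]], collapse = "")
  }, character(1L))
  sequence <- clean_reference_sequence(sequence)
  empty <- !nzchar(sequence)
  if (any(empty)) {
    stop("empty sequence for record(s): ",
         paste(record_id[empty], collapse = ", "), call. = FALSE)
  }
  data.frame(record_id = record_id, description = description,
             sequence = sequence, stringsAsFactors = FALSE)
}

#' Write sequences as FASTA
#'
#' @param ids,sequences character vectors of equal length.
#' @param path output path.
#' @param width line-wrap width (default 70).
#' @export
write_fasta <- function(ids, sequences, path, width = 70L) {
  stopifnot(length(ids) == length(sequences))
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(ids)) {
    writeLines(paste0(">", ids[i]), con)
    s <- sequences[i]
    n <- nchar(s)
    starts <- seq(1L, n, by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, n)), con)
  }
  invisible(path)
}

#' Read a taxonomy table
#'
#' Two dialects are supported. `semicolon`: two tab-separated columns,
#' record id and a semicolon-delimited lineage string (`Bacteria;...` or
#' `d__Bacteria;p__...`; rank prefixes are stripped, trailing empty ranks
#' tolerated). `columns`: record id followed by one rank per column.
#'
#' @param path file path.
#' @param dialect `"semicolon"` or `"columns"`.
#' @param header whether the file has a header line (default `FALSE` for
#'   `semicolon`, `TRUE` for `columns`).
#' @return named list: record id -> character vector lineage.
#' @export
read_taxonomy <- function(path, dialect = c("semicolon", "columns"),
                          header = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (is.null(header)) header <- dialect == "columns"
  df <- utils::read.delim(path, header = header, sep = "\t",
                          stringsAsFactors = FALSE, comment.char = "#",
                          check.names = FALSE)
  ids <- as.character(df[[1L]])
  if (anyDuplicated(ids)) {
    stop("duplicate record ids in taxonomy: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  }
  strip_prefix <- function(x) sub("^[a-z]__", "", x)
  lineages <- if (dialect == "semicolon") {
    lapply(strsplit(as.character(df[[2L]]), ";", fixed = TRUE), function(l) {
      l <- strip_prefix(trimws(l))
      l[seq_len(max(c(0L, which(nzchar(l)))))]
    })
  } else {
    lapply(seq_along(ids), function(i) {
      l <- strip_prefix(trimws(as.character(df[i, -1L])))
      l[is.na(l)] <- ""
      l[seq_len(max(c(0L, which(nzchar(l)))))]
    })
  }
  names(lineages) <- ids
  lineages
}

#' Assemble a reference set from FASTA and taxonomy files
#'
#' @param fasta_path FASTA file of reference sequences.
#' @param taxonomy_path taxonomy TSV (see [read_taxonomy()]).
#' @param dialect taxonomy dialect.
#' @return a [reference_set()]; records without taxonomy get empty lineages.
#' @export
read_reference_set <- function(fasta_path, taxonomy_path,
                               dialect = c("semicolon", "columns")) {
  fa <- read_fasta(fasta_path)
  tax <- read_taxonomy(taxonomy_path, dialect)
  lineage <- lapply(fa$record_id, function(id) {
    if (id %in% names(tax)) tax[[id]] else character(0L)
  })
  reference_set(fa$record_id, fa$sequence, lineage)
}

#' Read an abundance matrix with optional metadata
#'
#' The matrix may have taxa in rows (first header cell `taxon`, `genus`,
#' `otu` or `asv`) or samples in rows (first header cell `sample` or
#' `sample_id`); orientation is auto-detected from that cell and can be
#' forced.
#'
#' @param path TSV/CSV matrix path (delimiter sniffed from the header).
#' @param metadata_path optional metadata TSV with a `sample_id` column.
#' @param orientation `"auto"`, `"taxa_rows"` or `"samples_rows"`.
#' @return an [abundance_table()].
#' @export
read_abundance <- function(path, metadata_path = NULL,
                           orientation = c("auto", "taxa_rows",
                                           "samples_rows")) {
  orientation <- match.arg(orientation)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  first <- readLines(path, n = 1L)
  sep <- if (grepl("\t", first)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, comment.char = "#",
                          check.names = FALSE)
  corner <- tolower(names(df)[1L])
  if (orientation == "auto") {
    orientation <- if (corner %in% c("sample", "sample_id", "samples")) {
      "samples_rows"
    } else "taxa_rows"
  }
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- as.character(df[[1L]])
  if (orientation == "samples_rows") m <- t(m)
  storage.mode(m) <- "double"
  metadata <- if (!is.null(metadata_path)) {
    utils::read.delim(metadata_path, header = TRUE, sep = "\t",
                      stringsAsFactors = FALSE, comment.char = "#")
  }
  abundance_table(m, metadata)
}

#' Read best-hit identities from BLAST tabular output (outfmt 6)
#'
#' Standard 12-column layout (`qseqid sseqid pident length mismatch gapopen
#' qstart qend sstart send evalue bitscore`). When a query has several rows
#' the one with the highest bit score (then highest identity) is kept.
#' Queries listed in `all_queries` but absent from the file are returned
#' with `pident = NA`, the explicit no-hit marker consumed by
#' [novelty_fractions()].
#'
#' @param path BLAST tabular file.
#' @param all_queries optional character vector of every query id searched.
#' @return data.frame `asv`, `pident`.
#' @export
read_blast_outfmt6 <- function(path, all_queries = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  cols <- c("qseqid", "sseqid", "pident", "length", "mismatch", "gapopen",
            "qstart", "qend", "sstart", "send", "evalue", "bitscore")
  df <- tryCatch(
    utils::read.delim(path, header = FALSE, sep = "\t",
                      stringsAsFactors = FALSE, comment.char = "#"),
    error = function(e) data.frame()
  )
  if (nrow(df) > 0L) {
    if (ncol(df) < 12L) {
      stop("expected 12 tab-separated BLAST outfmt 6 columns, found ",
           ncol(df), call. = FALSE)
    }
    names(df)[1:12] <- cols
    df <- df[order(df$qseqid, -df$bitscore, -df$pident), , drop = FALSE]
    df <- df[!duplicated(df$qseqid), c("qseqid", "pident")]
  } else {
    df <- data.frame(qseqid = character(0L), pident = numeric(0L))
  }
  out <- data.frame(asv = df$qseqid, pident = df$pident,
                    stringsAsFactors = FALSE)
  if (!is.null(all_queries)) {
    missing <- setdiff(all_queries, out$asv)
    if (length(missing)) {
      out <- rbind(out, data.frame(asv = missing, pident = NA_real_,
                                   stringsAsFactors = FALSE))
    }
    out <- out[match(all_queries, out$asv), , drop = FALSE]
    rownames(out) <- NULL
  }
  out
}

#' Write a data.frame as TSV with a provenance header comment
#'
#' The header block consists of `#`-prefixed key-value lines (tool version
#' plus any caller-supplied entries), so the file stays a valid TSV for any
#' reader that skips comments.
#'
#' @param df data.frame to write.
#' @param path output path.
#' @param provenance named character vector of extra header entries.
#' @export
write_tsv_report <- function(df, path, provenance = character(0L)) {
  header <- c(
    sprintf("# primercov %s", as.character(utils::packageVersion("primercov"))),
    sprintf("# date: %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S %Z")),
    if (length(provenance)) sprintf("# %s: %s", names(provenance), provenance)
  )
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(header, con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a TSV written by [write_tsv_report()]
#'
#' @param path file path.
#' @return data.frame (header comments skipped).
#' @export
read_tsv_report <- function(path) {
  utils::read.delim(path, header = TRUE, sep = "\t", comment.char = "#",
                    stringsAsFactors = FALSE, check.names = FALSE)
}
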