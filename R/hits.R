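# The alignment-hit table shared by the internal aligner and external
# hit-table ingestion. One row per local alignment; the conserved-protein
# filter reads percent_identity, evalue and the query-side coverage derived
# from query_start/query_end/query_len. Multiple rows per (query, subject)
# pair (multiple HSPs) are allowed; conservation needs only one passing row.

HIT_COLUMNS <- c("query_id", "subject_id", "percent_identity",
                 "align_columns", "query_start", "query_end", "evalue",
                 "score", "query_len")

#' Construct an alignment-hit table
#'
#' Validating constructor for the hit table used throughout the package.
#' Identity follows the BLAST `pident` convention (identical residues over
#' all alignment columns, including gap columns); coordinates are 1-based
#' inclusive on the query.
#'
#' @param query_id,subject_id Character vectors of sequence ids.
#' @param percent_identity Percent identity in \[0, 100\].
#' @param align_columns Number of alignment columns (>= 1).
#' @param query_start,query_end 1-based inclusive query coordinates.
#' @param evalue Non-negative e-values.
#' @param score Raw score or bitscore; carried through, not used by filters.
#' @param query_len Query sequence lengths (>= 1).
#' @return A `data.frame` with one row per hit.
#' @export
alignment_hits <- function(query_id, subject_id, percent_identity,
                           align_columns, query_start, query_end, evalue,
                           score, query_len) {
  h <- data.frame(query_id = as.character(query_id),
                  subject_id = as.character(subject_id),
                  percent_identity = as.numeric(percent_identity),
                  align_columns = as.integer(align_columns),
                  query_start = as.integer(query_start),
                  query_end = as.integer(query_end),
                  evalue = as.numeric(evalue),
                  score = as.numeric(score),
                  query_len = as.integer(query_len),
                  stringsAsFactors = FALSE)
  bad <- which(h$query_start < 1L | h$query_start > h$query_end |
                 h$query_end > h$query_len)
  if (length(bad) > 0L)
    stop("hit ", bad[1L], " (query '", h$query_id[bad[1L]],
         "'): query coordinates violate 1 <= start <= end <= length",
         call. = FALSE)
  if (any(h$percent_identity < 0 | h$percent_identity > 100))
    stop("percent_identity must lie in [0, 100]", call. = FALSE)
  if (any(h$evalue < 0)) stop("e-values must be non-negative", call. = FALSE)
  h
}

empty_hits <- function() {
  alignment_hits(character(), character(), numeric(), integer(), integer(),
                 integer(), numeric(), numeric(), integer())
}

#' Query coverage of alignment hits
#'
#' The "alignable region" of the conservation filter: the percentage of the
#' query protein spanned by the aligned region,
#' `100 * (query_end - query_start + 1) / query_len`. The span, not the
#' column count, is used, so gaps in the query do not inflate coverage.
#'
#' @param hits An alignment-hit table.
#' @return Numeric vector of per-hit query coverage percentages.
#' @export
hit_query_coverage <- function(hits) {
  100 * (hits$query_end - hits$query_start + 1) / hits$query_len
}

#' Parse a BLAST/DIAMOND tabular hit file
#'
#' Reads the standard 12-column tab-separated alignment report
#' (`qseqid sseqid pident length mismatch gapopen qstart qend sstart send
#' evalue bitscore`, BLAST+ `-outfmt 6` / DIAMOND `--outfmt 6`), optionally
#' with a 13th `qlen` column. When `qlen` is absent, query lengths are
#' looked up by `qseqid` in `query_proteome`. Lines starting with `#` are
#' skipped; an empty file is a valid "no hits" outcome.
#'
#' @param path Path to the tabular hit file.
#' @param query_proteome The query-side `proteome`; required unless every
#'   row carries the 13th `qlen` column.
#' @return An alignment-hit table in file order (see [alignment_hits()]).
#' @export
parse_tabular_hits <- function(path, query_proteome = NULL) {
  if (!file.exists(path)) stop("hit table not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*#", lines) & nzchar(trimws(lines))
  lineno <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0L) return(empty_hits())

  fields <- strsplit(lines, "\t", fixed = TRUE)
  ncols <- lengths(fields)
  bad <- which(ncols != 12L & ncols != 13L)
  if (length(bad) > 0L)
    stop(basename(path), " line ", lineno[bad[1L]], ": expected 12 or 13 ",
         "tab-separated columns, found ", ncols[bad[1L]], call. = FALSE)

  col <- function(i) vapply(fields, function(f)
    if (length(f) >= i) f[i] else NA_character_, character(1L))
  num <- function(i, name) {
    v <- suppressWarnings(as.numeric(col(i)))
    bad <- which(is.na(v))
    if (length(bad) > 0L)
      stop(basename(path), " line ", lineno[bad[1L]], ", column ", i,
           " (", name, "): not a number: '", col(i)[bad[1L]], "'",
           call. = FALSE)
    v
  }

  qseqid <- col(1L)
  qlen <- rep(NA_real_, length(lines))
  has13 <- ncols == 13L
  if (any(has13)) {
    v <- suppressWarnings(as.numeric(vapply(fields[has13], `[`,
                                            character(1L), 13L)))
    if (anyNA(v))
      stop(basename(path), ": non-numeric qlen column", call. = FALSE)
    qlen[has13] <- v
  }
  if (anyNA(qlen)) {
    if (is.null(query_proteome))
      stop(basename(path), ": no qlen column and no query proteome given ",
           "to resolve query lengths", call. = FALSE)
    stopifnot(inherits(query_proteome, "proteome"))
    miss <- which(is.na(qlen))
    found <- query_proteome$lengths[qseqid[miss]]
    lost <- which(is.na(found))
    if (length(lost) > 0L)
      stop(basename(path), " line ", lineno[miss[lost[1L]]], ": query id '",
           qseqid[miss[lost[1L]]], "' not found in proteome '",
           query_proteome$label, "'", call. = FALSE)
    qlen[miss] <- found
  }

  alignment_hits(query_id = qseqid,
                 subject_id = col(2L),
                 percent_identity = num(3L, "pident"),
                 align_columns = num(4L, "length"),
                 query_start = num(7L, "qstart"),
                 query_end = num(8L, "qend"),
                 evalue = num(11L, "evalue"),
                 score = num(12L, "bitscore"),
                 query_len = qlen)
}

#' Convert a local alignment to a one-row hit table
#'
#' Percent identity is `100 * n_identical / n_columns` (the BLAST `pident`
#' convention: the denominator includes gap columns).
#'
#' @param aln A non-empty `local_alignment` from [smith_waterman()].
#' @param query_len Length of the query sequence in residues.
#' @return A one-row alignment-hit table.
#' @export
from_local_alignment <- function(aln, query_len) {
  stopifnot(inherits(aln, "local_alignment"))
  alignment_hits(query_id = aln$query_id,
                 subject_id = aln$subject_id,
                 percent_identity = 100 * aln$n_identical / aln$n_columns,
                 align_columns = aln$n_columns,
                 query_start = aln$query_start,
                 query_end = aln$query_end,
                 evalue = aln$evalue,
                 score = aln$score,
                 query_len = query_len)
}
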