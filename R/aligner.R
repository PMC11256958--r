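# Built-in pairwise local protein alignment.
#
# Smith-Waterman with a substitution matrix and affine gaps, plus a
# Karlin-Altschul e-value estimate, so POCP can be computed without an
# external aligner. Defaults mirror BLASTP's protein defaults
# (BLOSUM62, gap open 11, gap extend 1) because the conserved-protein
# thresholds were calibrated against BLASTP-style alignments.

#' Scoring scheme for local protein alignment
#'
#' Bundles a substitution matrix (taken from the matrices shipped with
#' Biostrings, e.g. `"BLOSUM62"`, `"BLOSUM45"`, `"PAM250"`) with affine gap
#' penalties. A gap of length g costs `gap_open + g * gap_extend`.
#'
#' @param matrix_name Name of a substitution matrix available in Biostrings.
#' @param gap_open Gap opening penalty (non-negative integer).
#' @param gap_extend Gap extension penalty per residue; must not exceed
#'   `gap_open`.
#' @return A `scoring_scheme` object.
#' @examples
#' s <- scoring_scheme()
#' s$matrix["M", "M"]
#' @export
scoring_scheme <- function(matrix_name = "BLOSUM62", gap_open = 11L,
                           gap_extend = 1L) {
  gap_open <- as.integer(gap_open)
  gap_extend <- as.integer(gap_extend)
  if (is.na(gap_open) || gap_open < 0L || is.na(gap_extend) || gap_extend < 0L)
    stop("gap penalties must be non-negative integers", call. = FALSE)
  if (gap_extend > gap_open)
    stop("gap_extend must not exceed gap_open", call. = FALSE)
  env <- new.env(parent = emptyenv())
  ok <- tryCatch({
    utils::data(list = matrix_name, package = "Biostrings", envir = env)
    TRUE
  }, warning = function(w) FALSE)
  if (!ok || !matrix_name %in% ls(env))
    stop("unknown substitution matrix: ", matrix_name, call. = FALSE)
  mat <- env[[matrix_name]]
  if (!all(POCP_ALPHABET %in% rownames(mat)))
    stop("matrix '", matrix_name, "' does not cover the protein alphabet",
         call. = FALSE)
  structure(
    list(matrix_name = matrix_name,
         matrix = mat,
         alphabet = rownames(mat),
         gap_open = gap_open,
         gap_extend = gap_extend),
    class = "scoring_scheme")
}

#' Karlin-Altschul parameters for e-value estimation
#'
#' Parameters of the extreme-value statistic E = K * m * n * exp(-lambda * S)
#' for a raw local-alignment score S in a search space of m * n residues.
#' Defaults are the published gapped values for BLOSUM62 with gap open 11 /
#' extend 1 (lambda = 0.267, K = 0.041).
#'
#' @param lambda Scale parameter, strictly positive.
#' @param k Prefactor K, strictly positive.
#' @return A `ka_params` object.
#' @export
ka_params <- function(lambda = 0.267, k = 0.041) {
  if (!is.numeric(lambda) || lambda <= 0 || !is.numeric(k) || k <= 0)
    stop("lambda and k must be strictly positive", call. = FALSE)
  structure(list(lambda = lambda, k = k), class = "ka_params")
}

#' Karlin-Altschul e-value for a raw alignment score
#'
#' Computes E = K * m * n * exp(-lambda * S) with m the query length and n
#' the subject length of the single compared pair. No edge-effect or
#' database-size correction is applied: the search space is the one
#' protein-vs-protein comparison, which makes these e-values systematically
#' smaller than database-wide BLAST/DIAMOND e-values. They are accurate
#' enough for the 1e-5 conservation cutoff, where the identity and coverage
#' filters dominate anyway.
#'
#' @param score Raw alignment score(s), non-negative.
#' @param query_len,subject_len Sequence lengths in residues (>= 1).
#' @param params A [ka_params()] object.
#' @return Numeric vector of e-values.
#' @examples
#' estimate_evalue(50, 100, 100)  # ~6.54e-4
#' @export
estimate_evalue <- function(score, query_len, subject_len,
                            params = ka_params()) {
  stopifnot(inherits(params, "ka_params"))
  if (any(score < 0)) stop("score must be non-negative", call. = FALSE)
  if (any(query_len < 1L) || any(subject_len < 1L))
    stop("sequence lengths must be >= 1", call. = FALSE)
  params$k * as.numeric(query_len) * as.numeric(subject_len) *
    exp(-params$lambda * score)
}

# Run the compiled aligner over two sets of sequences; returns the raw
# hit list (1-based indices into each set) without e-values.
sw_align_sets <- function(qseqs, sseqs, scoring) {
  res <- sw_align_sets_cpp(qseqs, sseqs,
                           scoring$matrix, scoring$alphabet,
                           scoring$gap_open, scoring$gap_extend)
  as.data.frame(res)
}

#' Optimal local alignment of two protein sequences
#'
#' Smith-Waterman alignment under affine-gap scoring. Returns one optimal
#' local alignment, or `NULL` when no cell of the dynamic-programming matrix
#' is positive (no local similarity). On tied scores the traceback prefers a
#' substitution column, then a gap in the subject, then a gap in the query;
#' co-optimal alignments share the score but may differ in identity and
#' span.
#'
#' @param query,subject Protein sequences as character strings (or named
#'   length-1 character vectors; names become the ids).
#' @param scoring A [scoring_scheme()].
#' @param params A [ka_params()] used to attach an e-value to the result.
#' @return A `local_alignment` (list with `score`, `query_id`, `subject_id`,
#'   `query_start`, `query_end`, `subject_start`, `subject_end`,
#'   `n_identical`, `n_columns`, `evalue`) or `NULL` for the empty result.
#' @examples
#' smith_waterman("MKV", "MKV")$score  # 14
#' @export
smith_waterman <- function(query, subject, scoring = scoring_scheme(),
                           params = ka_params()) {
  stopifnot(inherits(scoring, "scoring_scheme"))
  qid <- if (!is.null(names(query))) names(query)[1L] else "query"
  sid <- if (!is.null(names(subject))) names(subject)[1L] else "subject"
  query <- unname(query[1L]); subject <- unname(subject[1L])
  if (!nzchar(query) || !nzchar(subject))
    stop("sequences must be non-empty", call. = FALSE)
  hits <- sw_align_sets(query, subject, scoring)
  if (nrow(hits) == 0L) return(NULL)
  structure(
    list(score = hits$score, query_id = qid, subject_id = sid,
         query_start = hits$query_start, query_end = hits$query_end,
         subject_start = hits$subject_start, subject_end = hits$subject_end,
         n_identical = hits$n_identical, n_columns = hits$n_columns,
         evalue = estimate_evalue(hits$score, nchar(query), nchar(subject),
                                  params)),
    class = "local_alignment")
}

#' All-vs-all alignment of two proteomes
#'
#' Aligns every protein of the query proteome against every protein of the
#' subject proteome and returns one hit per (query, subject) pair with a
#' non-empty optimal local alignment, as an alignment-hit table (see
#' [alignment_hits()]). Output order is query file order, then subject file
#' order; results are deterministic for fixed inputs.
#'
#' @param query,subject `proteome` objects.
#' @param scoring A [scoring_scheme()].
#' @param params A [ka_params()] for per-hit e-values (search space is the
#'   individual query length times subject length).
#' @return Alignment-hit `data.frame` with columns `query_id`, `subject_id`,
#'   `percent_identity`, `align_columns`, `query_start`, `query_end`,
#'   `evalue`, `score`, `query_len`.
#' @export
align_proteomes <- function(query, subject, scoring = scoring_scheme(),
                            params = ka_params()) {
  stopifnot(inherits(query, "proteome"), inherits(subject, "proteome"),
            inherits(scoring, "scoring_scheme"), inherits(params, "ka_params"))
  raw <- sw_align_sets(unname(query$sequences), unname(subject$sequences),
                       scoring)
  if (nrow(raw) == 0L) return(empty_hits())
  qlen <- unname(query$lengths)[raw$query_idx]
  slen <- unname(subject$lengths)[raw$subject_idx]
  alignment_hits(
    query_id = query$ids[raw$query_idx],
    subject_id = subject$ids[raw$subject_idx],
    percent_identity = 100 * raw$n_identical / raw$n_columns,
    align_columns = raw$n_columns,
    query_start = raw$query_start,
    query_end = raw$query_end,
    evalue = estimate_evalue(raw$score, qlen, slen, params),
    score = raw$score,
    query_len = qlen)
}
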