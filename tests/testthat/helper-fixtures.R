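# Shared fixtures and independent oracles, built in code at test time.

AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L", "M", "N", "P",
          "Q", "R", "S", "T", "V", "W", "Y")

random_seq <- function(len) paste(sample(AA20, len, TRUE), collapse = "")

write_fasta_lines <- function(lines) {
  path <- tempfile(fileext = ".faa")
  writeLines(lines, path)
  path
}

make_proteome <- function(seqs, label = "test", ids = NULL) {
  if (is.null(ids)) ids <- paste0(label, "_p", seq_along(seqs))
  path <- write_fasta_lines(as.vector(rbind(paste0(">", ids), seqs)))
  read_protein_fasta(path, label = label)
}

# Random hit table in the package's column layout; thresholds are drawn
# around the filter boundaries so both outcomes occur.
random_hit_table <- function(n_rows, n_queries = 8L) {
  if (n_rows == 0L) {
    return(alignment_hits(character(), character(), numeric(), integer(),
                          integer(), integer(), numeric(), numeric(),
                          integer()))
  }
  qlen <- sample(60:400, n_rows, replace = TRUE)
  qstart <- sample(1:30, n_rows, replace = TRUE)
  qend <- pmin(qlen, qstart + floor(runif(n_rows) * qlen))
  alignment_hits(
    query_id = paste0("q", sample(n_queries, n_rows, replace = TRUE)),
    subject_id = paste0("s", sample(50L, n_rows, replace = TRUE)),
    percent_identity = runif(n_rows, 20, 100),
    align_columns = pmax(1L, qend - qstart + 1L),
    query_start = qstart,
    query_end = qend,
    evalue = 10^runif(n_rows, -30, 0),
    score = runif(n_rows, 20, 500),
    query_len = qlen)
}

# Independent brute-force oracle for count_conserved: scan rows one by one
# and collect distinct passing query ids.
brute_force_count <- function(hits, criteria) {
  seen <- character()
  for (i in seq_len(nrow(hits))) {
    cov <- 100 * (hits$query_end[i] - hits$query_start[i] + 1) /
      hits$query_len[i]
    if (hits$evalue[i] < criteria$max_evalue &&
        hits$percent_identity[i] > criteria$min_identity_pct &&
        cov > criteria$min_coverage_pct) {
      seen <- union(seen, hits$query_id[i])
    }
  }
  length(seen)
}

# Independent reference for local alignment scores.
biostrings_sw_score <- function(s1, s2, gap_open = 11, gap_extend = 1) {
  env <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = env)
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(s1), Biostrings::AAString(s2), type = "local",
    substitutionMatrix = env$BLOSUM62,
    gapOpening = gap_open, gapExtension = gap_extend)
  max(0, Biostrings::score(pa))
}
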