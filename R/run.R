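# End-to-end pipeline: FASTA inputs -> (internal alignment | precomputed
# hit tables) -> conservation filter -> POCP matrix -> TSV outputs + run
# log. The run log records version, criteria, scoring and the input
# manifest so a reported result can always be traced to its configuration.

#' Run the POCP pipeline
#'
#' Reads one protein FASTA per genome/strain, compares the proteomes
#' (all-vs-all, or one-vs-all when `target` is given), and writes four files
#' into `output_dir`: `pocp_matrix.tsv` (square matrix, 2 decimals, `NA` for
#' uncomputed cells), `pocp_pairs.tsv` (one row per computed pair with
#' conserved counts and totals), `pocp_summary.tsv` (summary statistics,
#' version and criteria) and `run_log.txt` (the full configuration).
#' Exactly one alignment source is active: the built-in aligner (default)
#' or, when `hits_dir` is given, precomputed BLAST/DIAMOND tabular files
#' named `<queryLabel>__vs__<subjectLabel>.tsv`, one per directed pair.
#'
#' @param inputs Character vector of protein FASTA paths (globs are
#'   expanded), or a list of `proteome` objects.
#' @param output_dir Directory for the output files (created if needed).
#' @param hits_dir Optional directory of precomputed directed hit tables;
#'   switches the backend from the internal aligner to file ingestion.
#' @param target Optional proteome label switching to one-vs-all mode.
#' @param criteria A [filter_criteria()]; non-default values trigger the
#'   nonstandard-parameter warning (also recorded in the log).
#' @param scoring A [scoring_scheme()] for the internal aligner.
#' @param params A [ka_params()] for the internal aligner's e-values.
#' @param genus_threshold_pct Genus-boundary threshold for the summary.
#' @param threads Worker processes for pairwise comparisons.
#' @return The `pocp_matrix`, invisibly.
#' @export
run_pocp <- function(inputs, output_dir, hits_dir = NULL, target = NULL,
                     criteria = filter_criteria(),
                     scoring = scoring_scheme(), params = ka_params(),
                     genus_threshold_pct = 50, threads = 1L) {
  if (is.character(inputs)) {
    paths <- unlist(lapply(inputs, function(p)
      if (grepl("[*?[]", p)) Sys.glob(p) else p))
    if (length(paths) < 2L)
      stop("need at least 2 input FASTA files, got ", length(paths),
           call. = FALSE)
    proteomes <- lapply(paths, read_protein_fasta)
  } else {
    paths <- rep(NA_character_, length(inputs))
    proteomes <- inputs
  }
  mode <- if (is.null(target)) "all" else "one-vs-all"
  proteomes <- validate_run_inputs(proteomes, mode)
  labels <- vapply(proteomes, `[[`, character(1L), "label")

  backend <- if (is.null(hits_dir)) {
    internal_backend(scoring, params)
  } else {
    bk <- hits_backend(hits_dir)
    resolve_hit_tables(hits_dir, labels, target)  # fail early, name the gap
    bk
  }

  res <- compute_matrix(proteomes, mode = mode, target = target,
                        backend = backend, criteria = criteria,
                        genus_threshold_pct = genus_threshold_pct,
                        threads = threads)

  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  write_pocp_matrix(res, file.path(output_dir, "pocp_matrix.tsv"))
  write_pocp_pairs(res, file.path(output_dir, "pocp_pairs.tsv"))
  write_pocp_summary(res, file.path(output_dir, "pocp_summary.tsv"))
  write_run_log(file.path(output_dir, "run_log.txt"), proteomes, paths,
                mode, target, criteria, scoring,
                backend_name = if (is.null(hits_dir)) "internal" else hits_dir,
                genus_threshold_pct, threads)
  invisible(res)
}

#' Resolve the directed hit tables required for a comparison
#'
#' The hit-table backend expects one file per directed proteome pair, named
#' `<queryLabel>__vs__<subjectLabel>.tsv`. Both directions of every
#' compared pair are required (conservation is counted bidirectionally).
#' Returns the complete mapping for the requested mode, or fails naming the
#' first missing file.
#'
#' @param hits_dir Directory holding the hit tables.
#' @param labels Proteome labels in input order.
#' @param target Optional target label (one-vs-all mode).
#' @return Named character vector: `"<q>__vs__<s>"` -> file path.
#' @export
resolve_hit_tables <- function(hits_dir, labels, target = NULL) {
  if (!dir.exists(hits_dir))
    stop("hit-table directory not found: ", hits_dir, call. = FALSE)
  pairs <- list()
  n <- length(labels)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      if (!is.null(target) &&
          labels[i] != target && labels[j] != target) next
      pairs[[length(pairs) + 1L]] <- c(labels[i], labels[j])
    }
  }
  files <- vapply(pairs, function(p)
    paste0(p[1L], "__vs__", p[2L], ".tsv"), character(1L))
  paths <- file.path(hits_dir, files)
  miss <- which(!file.exists(paths))
  if (length(miss) > 0L)
    stop("missing directed hit table(s): ",
         paste(files[miss], collapse = ", "), " in ", hits_dir,
         call. = FALSE)
  stats::setNames(paths, sub("\\.tsv$", "", files))
}

write_run_log <- function(path, proteomes, paths, mode, target, criteria,
                          scoring, backend_name, genus_threshold_pct,
                          threads) {
  kv <- c(tool = "pocpr",
          version = pocpr_version(),
          date = format(Sys.time(), "%Y-%m-%d %H:%M:%S %Z"),
          mode = mode,
          target = if (is.null(target)) "NA" else target,
          backend = backend_name,
          max_evalue = format(criteria$max_evalue),
          min_identity_pct = format(criteria$min_identity_pct),
          min_coverage_pct = format(criteria$min_coverage_pct),
          nonstandard_criteria = tolower(!is_default_criteria(criteria)),
          matrix_name = scoring$matrix_name,
          gap_open = scoring$gap_open,
          gap_extend = scoring$gap_extend,
          genus_threshold_pct = format(genus_threshold_pct),
          threads = threads)
  manifest <- vapply(seq_along(proteomes), function(i)
    paste("input", proteomes[[i]]$label,
          if (is.na(paths[i])) "<in-memory>" else paths[i],
          proteomes[[i]]$total_proteins, sep = "\t"),
    character(1L))
  writeLines(c(paste(names(kv), kv, sep = "\t"), manifest), path)
  invisible(path)
}

#' Parse a pipeline run log
#'
#' Reads `run_log.txt` back into a list: every `key<TAB>value` line becomes
#' an entry, and `input` lines are collected into an `inputs` data.frame
#' (label, path, n_proteins). Together with the input files this suffices
#' to reconstruct the full run configuration.
#'
#' @param path Path to a `run_log.txt` written by [run_pocp()].
#' @return Named list of configuration values.
#' @export
read_run_log <- function(path) {
  lines <- readLines(path)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  is_input <- vapply(parts, function(p) p[1L] == "input", logical(1L))
  out <- stats::setNames(
    lapply(parts[!is_input], function(p) paste(p[-1L], collapse = "\t")),
    vapply(parts[!is_input], `[`, character(1L), 1L))
  for (f in c("max_evalue", "min_identity_pct", "min_coverage_pct",
              "gap_open", "gap_extend", "genus_threshold_pct", "threads"))
    if (!is.null(out[[f]])) out[[f]] <- as.numeric(out[[f]])
  if (any(is_input)) {
    m <- do.call(rbind, parts[is_input])
    out$inputs <- data.frame(label = m[, 2L], path = m[, 3L],
                             n_proteins = as.integer(m[, 4L]),
                             stringsAsFactors = FALSE)
  }
  out
}
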