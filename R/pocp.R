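# The core POCP computation: conserved-protein filtering, bidirectional
# counting, the POCP formula, matrix assembly and summary statistics.
#
# POCP between proteomes A and B is 100 * (C1 + C2) / (T1 + T2): C1 is the
# number of proteins of A with at least one qualifying hit in B, C2 the
# converse, T1/T2 the proteome sizes. A hit qualifies when its e-value is
# strictly below 1e-5, identity strictly above 40% and query coverage
# strictly above 50% (the original criteria; all three boundaries excluded).

#' Conserved-protein filter criteria
#'
#' The three thresholds that decide whether an alignment hit marks its query
#' protein as conserved. All comparisons are strict: e-value < `max_evalue`,
#' identity > `min_identity_pct`, query coverage > `min_coverage_pct`, so
#' hits exactly at a boundary are rejected. The defaults are the original
#' POCP criteria; deviating from them triggers a prominent warning at run
#' time (see [compute_matrix()]) so that shared results always disclose
#' nonstandard parameters.
#'
#' @param max_evalue Maximum e-value (exclusive). Default 1e-5.
#' @param min_identity_pct Minimum percent identity (exclusive). Default 40.
#' @param min_coverage_pct Minimum query coverage percent (exclusive).
#'   Default 50.
#' @return A `filter_criteria` object.
#' @export
filter_criteria <- function(max_evalue = 1e-5, min_identity_pct = 40,
                            min_coverage_pct = 50) {
  if (!is.numeric(max_evalue) || max_evalue <= 0)
    stop("max_evalue must be positive", call. = FALSE)
  if (min_identity_pct < 0 || min_identity_pct > 100 ||
      min_coverage_pct < 0 || min_coverage_pct > 100)
    stop("identity and coverage thresholds must lie in [0, 100]",
         call. = FALSE)
  structure(list(max_evalue = max_evalue,
                 min_identity_pct = min_identity_pct,
                 min_coverage_pct = min_coverage_pct),
            class = "filter_criteria")
}

is_default_criteria <- function(criteria) {
  d <- filter_criteria()
  isTRUE(all.equal(unclass(criteria), unclass(d)))
}

warn_nonstandard_criteria <- function(criteria) {
  if (is_default_criteria(criteria)) return(invisible(FALSE))
  d <- filter_criteria()
  changed <- character()
  for (f in names(d)) {
    if (!isTRUE(all.equal(criteria[[f]], d[[f]])))
      changed <- c(changed, paste0(f, "=", format(criteria[[f]])))
  }
  warning("NONSTANDARD conservation criteria in use (",
          paste(changed, collapse = ", "), "); report these values and ",
          "pocpr version ", pocpr_version(), " alongside any shared POCP ",
          "results", call. = FALSE)
  invisible(TRUE)
}

#' Does a hit mark its query protein as conserved?
#'
#' Vectorized over the rows of an alignment-hit table. A hit passes when
#' `evalue < max_evalue` AND `percent_identity > min_identity_pct` AND query
#' coverage `> min_coverage_pct`, all strict.
#'
#' @param hits An alignment-hit table (see [alignment_hits()]).
#' @param criteria A [filter_criteria()] object.
#' @return Logical vector, one element per hit row.
#' @export
is_conserved <- function(hits, criteria = filter_criteria()) {
  stopifnot(inherits(criteria, "filter_criteria"))
  hits$evalue < criteria$max_evalue &
    hits$percent_identity > criteria$min_identity_pct &
    hit_query_coverage(hits) > criteria$min_coverage_pct
}

#' Count conserved query proteins in one directed comparison
#'
#' Conservation is a per-protein property, not per-hit: the count is the
#' number of distinct query ids with at least one passing hit, so a protein
#' with many passing HSPs counts once.
#'
#' @param hits Alignment-hit table from one directed comparison (one query
#'   proteome against one subject proteome).
#' @param criteria A [filter_criteria()] object.
#' @return Integer count of conserved query proteins.
#' @export
count_conserved <- function(hits, criteria = filter_criteria()) {
  length(unique(hits$query_id[is_conserved(hits, criteria)]))
}

#' POCP from conserved counts and proteome sizes
#'
#' `100 * (c1 + c2) / (t1 + t2)`: the summed conserved proteins of the two
#' genomes over their summed proteome sizes, as a percentage. Stored at full
#' precision; rounding happens only when writing output files.
#'
#' @param c1,c2 Conserved-protein counts of each proteome against the other.
#' @param t1,t2 Total protein counts of the two proteomes.
#' @return POCP percentage in \[0, 100\].
#' @examples
#' pocp_from_counts(300, 320, 500, 600)  # 56.3636...
#' @export
pocp_from_counts <- function(c1, c2, t1, t2) {
  if (any(t1 < 1L) || any(t2 < 1L))
    stop("proteome sizes must be >= 1", call. = FALSE)
  if (any(c1 < 0L) || any(c2 < 0L) || any(c1 > t1) || any(c2 > t2))
    stop("conserved counts must satisfy 0 <= c <= t ",
         "(a violation indicates an upstream counting bug)", call. = FALSE)
  100 * (c1 + c2) / (t1 + t2)
}

# --- alignment backends ----------------------------------------------------

#' Alignment backends for pairwise comparison
#'
#' A backend supplies, for an ordered proteome pair (query, subject), the
#' directed alignment-hit table the conservation filter reads.
#' `internal_backend()` runs the built-in Smith-Waterman aligner;
#' `hits_backend()` loads precomputed BLAST/DIAMOND tabular files from a
#' directory, one file per directed pair, named
#' `<queryLabel>__vs__<subjectLabel>.tsv`.
#'
#' @param scoring A [scoring_scheme()] (internal backend).
#' @param params A [ka_params()] (internal backend).
#' @param dir Directory holding directed hit tables (hits backend).
#' @return A `pocp_backend` object.
#' @name pocp_backend
NULL

#' @rdname pocp_backend
#' @export
internal_backend <- function(scoring = scoring_scheme(),
                             params = ka_params()) {
  structure(list(scoring = scoring, params = params),
            class = c("internal_backend", "pocp_backend"))
}

#' @rdname pocp_backend
#' @export
hits_backend <- function(dir) {
  if (!dir.exists(dir))
    stop("hit-table directory not found: ", dir, call. = FALSE)
  structure(list(dir = dir), class = c("hits_backend", "pocp_backend"))
}

directed_hits <- function(backend, query, subject) {
  UseMethod("directed_hits")
}

#' @export
directed_hits.internal_backend <- function(backend, query, subject) {
  align_proteomes(query, subject, backend$scoring, backend$params)
}

#' @export
directed_hits.hits_backend <- function(backend, query, subject) {
  fname <- paste0(query$label, "__vs__", subject$label, ".tsv")
  path <- file.path(backend$dir, fname)
  if (!file.exists(path))
    stop("missing hit table for direction ", query$label, " -> ",
         subject$label, ": expected file '", fname, "' in ", backend$dir,
         call. = FALSE)
  parse_tabular_hits(path, query_proteome = query)
}

# --- pairwise and matrix computation ---------------------------------------

#' Compare one proteome pair bidirectionally
#'
#' Runs (or loads) both directed searches — A as query against B, and B as
#' query against A — counts conserved proteins in each direction, and
#' computes POCP. The result is direction-independent: both directed
#' searches are performed either way, so `compare_pair(a, b)` and
#' `compare_pair(b, a)` agree exactly on the POCP value.
#'
#' @param a,b `proteome` objects with distinct labels.
#' @param backend An alignment backend (see [internal_backend()]).
#' @param criteria A [filter_criteria()] object.
#' @return A `pairwise_result`: list with `label_a`, `label_b`, `c1`, `c2`,
#'   `t1`, `t2` and `pocp_pct` (unrounded).
#' @export
compare_pair <- function(a, b, backend = internal_backend(),
                         criteria = filter_criteria()) {
  stopifnot(inherits(a, "proteome"), inherits(b, "proteome"),
            inherits(backend, "pocp_backend"),
            inherits(criteria, "filter_criteria"))
  if (identical(a$label, b$label))
    stop("proteome labels must differ for a pairwise comparison",
         call. = FALSE)
  c1 <- count_conserved(directed_hits(backend, a, b), criteria)
  c2 <- count_conserved(directed_hits(backend, b, a), criteria)
  structure(
    list(label_a = a$label, label_b = b$label,
         c1 = c1, c2 = c2,
         t1 = a$total_proteins, t2 = b$total_proteins,
         pocp_pct = pocp_from_counts(c1, c2, a$total_proteins,
                                     b$total_proteins)),
    class = "pairwise_result")
}

#' @export
print.pairwise_result <- function(x, ...) {
  cat(sprintf("POCP %s vs %s: %.2f%%  (C1=%d/%d, C2=%d/%d)\n",
              x$label_a, x$label_b, x$pocp_pct, x$c1, x$t1, x$c2, x$t2))
  invisible(x)
}

#' POCP matrix over a set of proteomes
#'
#' All-vs-all mode computes every unordered proteome pair (n(n-1)/2 pairs);
#' one-vs-all mode computes only the n-1 pairs involving the `target`
#' proteome, leaving the remaining cells `NA` (missing, never zero-filled).
#' The diagonal is set to 100 by convention without computation:
#' self-comparison is uninformative, and for very short proteins the
#' internal e-value estimate could otherwise fail a self-hit. Nonstandard
#' filter criteria trigger a warning carrying the changed values and the
#' package version.
#'
#' @param proteomes List of `proteome` objects (>= 2, unique labels).
#' @param mode `"all"` or `"one-vs-all"`.
#' @param target Label of the target proteome (one-vs-all mode only).
#' @param backend An alignment backend.
#' @param criteria A [filter_criteria()] object.
#' @param genus_threshold_pct Threshold for the summary's genus-boundary
#'   count; 50 is the originally proposed genus limit.
#' @param threads Number of worker processes for pairwise comparisons
#'   (forked via the parallel package; results are assembled in
#'   deterministic label order regardless of completion order).
#' @return A `pocp_matrix`: list with `labels`, `values` (symmetric numeric
#'   matrix, diagonal 100), `pairs` (one `data.frame` row per computed
#'   pair), `summary` (see [summarize_pairs()]), `criteria`, `mode` and
#'   `target`.
#' @export
compute_matrix <- function(proteomes, mode = c("all", "one-vs-all"),
                           target = NULL, backend = internal_backend(),
                           criteria = filter_criteria(),
                           genus_threshold_pct = 50, threads = 1L) {
  mode <- match.arg(mode)
  proteomes <- validate_run_inputs(proteomes, mode)
  labels <- vapply(proteomes, `[[`, character(1L), "label")
  warn_nonstandard_criteria(criteria)

  if (mode == "one-vs-all") {
    if (is.null(target) || !target %in% labels)
      stop("one-vs-all mode needs a target among the input labels: ",
           paste(labels, collapse = ", "), call. = FALSE)
    ti <- match(target, labels)
    idx <- lapply(setdiff(seq_along(labels), ti), function(j)
      c(min(ti, j), max(ti, j)))
  } else {
    n <- length(labels)
    idx <- list()
    for (i in seq_len(n - 1L))
      for (j in seq(i + 1L, n)) idx[[length(idx) + 1L]] <- c(i, j)
  }

  worker <- function(ij) {
    compare_pair(proteomes[[ij[1L]]], proteomes[[ij[2L]]], backend, criteria)
  }
  results <- if (threads > 1L) {
    parallel::mclapply(idx, worker, mc.cores = threads)
  } else {
    lapply(idx, worker)
  }
  err <- vapply(results, inherits, logical(1L), what = "try-error")
  if (any(err)) stop(results[[which(err)[1L]]], call. = FALSE)

  pairs <- do.call(rbind, lapply(results, function(r)
    data.frame(label_a = r$label_a, label_b = r$label_b,
               c1 = r$c1, c2 = r$c2, t1 = r$t1, t2 = r$t2,
               pocp_pct = r$pocp_pct, stringsAsFactors = FALSE)))

  values <- matrix(NA_real_, length(labels), length(labels),
                   dimnames = list(labels, labels))
  diag(values) <- 100
  for (r in results) {
    values[r$label_a, r$label_b] <- r$pocp_pct
    values[r$label_b, r$label_a] <- r$pocp_pct
  }

  structure(
    list(labels = labels, values = values, pairs = pairs,
         summary = summarize_pairs(pairs, genus_threshold_pct),
         criteria = criteria, mode = mode, target = target),
    class = "pocp_matrix")
}

#' Summary statistics over computed POCP pairs
#'
#' Minimum, maximum and arithmetic mean POCP over the computed pairs, plus
#' the number of pairs strictly above the genus threshold (strict, mirroring
#' the filter convention; a pair at exactly the threshold is not counted).
#' An empty pair set yields `n_pairs = 0` with `NA` statistics.
#'
#' @param pairs `data.frame` of pairwise results (column `pocp_pct`).
#' @param genus_threshold_pct Genus-boundary threshold; default 50.
#' @return A `pocp_summary` list.
#' @export
summarize_pairs <- function(pairs, genus_threshold_pct = 50) {
  v <- if (is.null(pairs)) numeric() else pairs$pocp_pct
  structure(
    list(n_pairs = length(v),
         min_pocp = if (length(v)) min(v) else NA_real_,
         max_pocp = if (length(v)) max(v) else NA_real_,
         mean_pocp = if (length(v)) mean(v) else NA_real_,
         genus_threshold_pct = genus_threshold_pct,
         n_pairs_above_genus_threshold = sum(v > genus_threshold_pct)),
    class = "pocp_summary")
}

#' @export
print.pocp_summary <- function(x, ...) {
  cat(sprintf("%d pair(s); POCP min %.2f / mean %.2f / max %.2f; %d above the %g%% genus threshold\n",
              x$n_pairs, x$min_pocp, x$mean_pocp, x$max_pocp,
              x$n_pairs_above_genus_threshold, x$genus_threshold_pct))
  invisible(x)
}

#' @export
print.pocp_matrix <- function(x, ...) {
  cat("POCP matrix (", x$mode,
      if (!is.null(x$target)) paste0(", target ", x$target), "): ",
      length(x$labels), " proteomes\n", sep = "")
  print(round(x$values, 2))
  print(x$summary)
  invisible(x)
}

# --- tab-separated outputs -------------------------------------------------

#' Write POCP results as tab-separated files
#'
#' `write_pocp_matrix()` writes the square matrix (labels in the first row
#' and column, cells with 2 decimals, uncomputed cells as `NA`);
#' `write_pocp_pairs()` the long table with one row per computed pair
#' (`label_a label_b c1 c2 t1 t2 pocp_pct`); `write_pocp_summary()`
#' key/value lines for the summary statistics plus the tool version and the
#' criteria used.
#'
#' @param x A `pocp_matrix`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @name pocp_output
NULL

#' @rdname pocp_output
#' @export
write_pocp_matrix <- function(x, path) {
  stopifnot(inherits(x, "pocp_matrix"))
  cells <- ifelse(is.na(x$values), "NA", sprintf("%.2f", x$values))
  out <- cbind(label = x$labels, cells)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = c("label", x$labels))
  invisible(path)
}

#' @rdname pocp_output
#' @export
write_pocp_pairs <- function(x, path) {
  stopifnot(inherits(x, "pocp_matrix"))
  pairs <- x$pairs
  pairs$pocp_pct <- sprintf("%.2f", pairs$pocp_pct)
  utils::write.table(pairs, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname pocp_output
#' @export
write_pocp_summary <- function(x, path) {
  stopifnot(inherits(x, "pocp_matrix"))
  s <- x$summary
  kv <- c(tool = "pocpr",
          version = pocpr_version(),
          mode = x$mode,
          target = if (is.null(x$target)) "NA" else x$target,
          max_evalue = format(x$criteria$max_evalue),
          min_identity_pct = format(x$criteria$min_identity_pct),
          min_coverage_pct = format(x$criteria$min_coverage_pct),
          n_pairs = s$n_pairs,
          min_pocp = if (is.na(s$min_pocp)) "NA" else sprintf("%.2f", s$min_pocp),
          max_pocp = if (is.na(s$max_pocp)) "NA" else sprintf("%.2f", s$max_pocp),
          mean_pocp = if (is.na(s$mean_pocp)) "NA" else sprintf("%.2f", s$mean_pocp),
          genus_threshold_pct = format(s$genus_threshold_pct),
          n_pairs_above_genus_threshold = s$n_pairs_above_genus_threshold)
  writeLines(paste(names(kv), kv, sep = "\t"), path)
  invisible(path)
}
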