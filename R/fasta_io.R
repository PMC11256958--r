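# Protein FASTA input and the proteome container.
#
# A proteome is a labelled, ordered set of amino-acid sequences for one
# genome or strain: one multi-FASTA file per species is the expected input
# convention. Record ids are the first whitespace-delimited token of each
# header, because that token is what BLAST/DIAMOND tabular output reports
# and hit-table joining depends on it.

# Residues accepted after sanitization: the 20 canonical amino acids plus
# the ambiguity codes B, Z and X. U (selenocysteine), O (pyrrolysine) and
# J are mapped to X; '*' is only tolerated as a trailing stop and stripped.
POCP_ALPHABET <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L", "M",
                   "N", "P", "Q", "R", "S", "T", "V", "W", "Y", "X", "B", "Z")

new_proteome <- function(label, ids, sequences) {
  structure(
    list(label = label,
         ids = ids,
         sequences = stats::setNames(sequences, ids),
         lengths = stats::setNames(nchar(sequences), ids),
         total_proteins = length(sequences)),
    class = "proteome")
}

#' Read a protein multi-FASTA file as a proteome
#'
#' Parses one protein FASTA file (one genome/strain per file), sanitizes the
#' sequences and returns a `proteome` object. Record ids are the first
#' whitespace-delimited token of each header. Lowercase residues are
#' uppercased, a trailing stop character `*` is stripped, and the
#' nonstandard residues `U`, `O` and `J` are mapped to `X`. Any residue that
#' cannot be mapped to the accepted alphabet (20 canonical amino acids plus
#' `B`, `Z`, `X`), or a `*` that is not terminal, is an error naming the
#' record and position.
#'
#' @param path Path to a protein multi-FASTA file.
#' @param label Proteome label used in matrix headers and outputs. Defaults
#'   to the file's basename with one `.faa`/`.fasta`/`.fa`/`.pep` extension
#'   stripped.
#' @return A `proteome`: list with `label`, `ids`, `sequences` (named
#'   character vector, file order preserved), `lengths` and
#'   `total_proteins`.
#' @examples
#' fa <- tempfile(fileext = ".faa")
#' writeLines(c(">p1 hypothetical", "MKV", ">p2", "ACDE"), fa)
#' p <- read_protein_fasta(fa)
#' p$total_proteins
#' @seealso [validate_run_inputs()], [write_proteome_fasta()]
#' @export
read_protein_fasta <- function(path, label = NULL) {
  if (!file.exists(path)) stop("input FASTA not found: ", path, call. = FALSE)
  set <- tryCatch(
    Biostrings::readAAStringSet(path),
    error = function(e) stop("failed to parse FASTA '", path, "': ",
                             conditionMessage(e), call. = FALSE))
  if (length(set) == 0L)
    stop("FASTA file '", path, "' contains no sequences", call. = FALSE)

  ids <- sub("\\s.*$", "", names(set))
  dup <- ids[duplicated(ids)]
  if (length(dup) > 0L)
    stop("duplicate record id(s) in '", path, "': ",
         paste(unique(dup), collapse = ", "), call. = FALSE)

  seqs <- toupper(as.character(set))
  seqs <- sub("\\*+$", "", seqs)  # trailing stop codons from gene callers
  empty <- which(!nzchar(seqs))
  if (length(empty) > 0L)
    stop("record '", ids[empty[1L]], "' in '", path,
         "' is empty after sanitization", call. = FALSE)
  seqs <- chartr("UOJ", "XXX", seqs)

  bad <- regexpr(paste0("[^", paste(POCP_ALPHABET, collapse = ""), "]"), seqs)
  hit <- which(bad > 0L)
  if (length(hit) > 0L) {
    i <- hit[1L]
    ch <- substr(seqs[i], bad[i], bad[i])
    stop("record '", ids[i], "' in '", path, "': unmappable residue '", ch,
         "' at position ", bad[i],
         if (ch == "*") " (internal stop codon)" else "", call. = FALSE)
  }

  if (is.null(label)) {
    label <- sub("\\.(faa|fasta|fa|pep)$", "", basename(path),
                 ignore.case = TRUE)
  }
  new_proteome(label, ids, unname(seqs))
}

#' Write a proteome back to FASTA
#'
#' @param proteome A `proteome` object.
#' @param path Output file path.
#' @param width Line width for wrapping sequence bodies.
#' @return `path`, invisibly.
#' @export
write_proteome_fasta <- function(proteome, path, width = 60L) {
  stopifnot(inherits(proteome, "proteome"))
  set <- Biostrings::AAStringSet(proteome$sequences)
  names(set) <- proteome$ids
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}

#' Validate proteomes before a comparison run
#'
#' Single entry gate before any pairwise comparison: checks that labels are
#' unique across proteomes and that enough proteomes are present for the
#' requested mode (all-vs-all needs at least two).
#'
#' @param proteomes List of `proteome` objects.
#' @param mode `"all"` (all-vs-all) or `"one-vs-all"`.
#' @return The input list, unchanged, if valid.
#' @export
validate_run_inputs <- function(proteomes, mode = c("all", "one-vs-all")) {
  mode <- match.arg(mode)
  if (!is.list(proteomes) || length(proteomes) == 0L)
    stop("no proteomes supplied", call. = FALSE)
  ok <- vapply(proteomes, inherits, logical(1L), what = "proteome")
  if (!all(ok)) stop("all inputs must be proteome objects", call. = FALSE)
  labels <- vapply(proteomes, `[[`, character(1L), "label")
  dup <- unique(labels[duplicated(labels)])
  if (length(dup) > 0L)
    stop("duplicate proteome label(s): ", paste(dup, collapse = ", "),
         call. = FALSE)
  if (length(proteomes) < 2L)
    stop("at least 2 proteomes are required for pairwise comparison",
         call. = FALSE)
  proteomes
}

#' @export
print.proteome <- function(x, ...) {
  cat("proteome '", x$label, "': ", x$total_proteins, " proteins, ",
      "lengths ", min(x$lengths), "-", max(x$lengths), " aa\n", sep = "")
  invisible(x)
}
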