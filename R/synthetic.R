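# Synthetic proteome pairs with a controlled shared-protein fraction.
#
# The generator makes the whole pipeline testable without downloads: a pair
# built to share a fraction f of identical proteins has an expected POCP of
# 100 * f, because every shared protein has a full-length identical partner
# (identity 100 > 40, coverage 100 > 50, e-value far below 1e-5 at the
# default lengths) while unshared random proteins only rarely reach 40%
# identity over more than half their length.

# Background amino-acid frequencies (Robinson & Robinson), the composition
# underlying the BLOSUM62 statistics. Realistic composition keeps chance
# identity between unrelated proteins low and stable.
AA_BACKGROUND_FREQS <- c(
  A = 0.07805, R = 0.05129, N = 0.04487, D = 0.05364, C = 0.01925,
  Q = 0.04264, E = 0.06295, G = 0.07377, H = 0.02199, I = 0.05142,
  L = 0.09019, K = 0.05744, M = 0.02243, F = 0.03856, P = 0.05203,
  S = 0.07120, T = 0.05841, W = 0.01330, Y = 0.03216, V = 0.06441)

# sample() treats a length-1 vector as 1:x, so draw from the range width
random_lengths <- function(n, length_range) {
  length_range[1L] + sample.int(length_range[2L] - length_range[1L] + 1L,
                                n, replace = TRUE) - 1L
}

random_protein <- function(len) {
  paste(sample(names(AA_BACKGROUND_FREQS), len, replace = TRUE,
               prob = AA_BACKGROUND_FREQS), collapse = "")
}

#' Generate a random proteome
#'
#' Draws `n` protein sequences with i.i.d. residues from the background
#' amino-acid frequency table and lengths uniform over `length_range`.
#' Deterministic under `seed`; the caller's RNG state is restored.
#'
#' @param n Number of proteins (>= 1).
#' @param length_range Integer pair, minimum and maximum residue count;
#'   lengths must be >= 30.
#' @param seed Integer seed; `NULL` uses (and advances) the current RNG
#'   state.
#' @param label Proteome label.
#' @return A `proteome` object with ids `<label>_p0001`, ...
#' @export
generate_proteome <- function(n, length_range = c(100L, 400L), seed = NULL,
                              label = "synthetic") {
  n <- as.integer(n)
  length_range <- as.integer(length_range)
  if (is.na(n) || n < 1L) stop("n must be >= 1", call. = FALSE)
  if (length(length_range) != 2L || any(is.na(length_range)) ||
      length_range[1L] < 30L || length_range[1L] > length_range[2L])
    stop("length_range must be an increasing pair with minimum >= 30",
         call. = FALSE)
  with_seed(seed, {
    lens <- random_lengths(n, length_range)
    seqs <- vapply(lens, random_protein, character(1L))
    new_proteome(label, sprintf("%s_p%04d", label, seq_len(n)), seqs)
  })
}

# Point substitutions to a uniformly random *different* residue; no indels.
mutate_sequence <- function(seq, rate) {
  if (rate <= 0) return(seq)
  chars <- strsplit(seq, "", fixed = TRUE)[[1L]]
  hit <- which(stats::runif(length(chars)) < rate)
  aas <- names(AA_BACKGROUND_FREQS)
  for (i in hit) {
    chars[i] <- sample(setdiff(aas, chars[i]), 1L)
  }
  paste(chars, collapse = "")
}

#' Generate a proteome pair with a controlled shared-protein fraction
#'
#' Builds two proteomes of `n_proteins` each that share exactly
#' `k = round(n_proteins * shared_fraction)` proteins: the shared proteins
#' are copied from the first proteome into the second (after optional point
#' mutation), the rest are generated independently. Shared proteins carry
#' distinct ids in each proteome, so conservation must be detected by
#' alignment, not id matching. The construction's expected POCP,
#' `100 * 2k / (2 * n_proteins)`, is returned for test assertions.
#'
#' @param n_proteins Proteins per proteome (>= 2).
#' @param shared_fraction Fraction of shared proteins in \[0, 1\].
#' @param length_range Protein length range in residues.
#' @param point_mutation_rate Per-site substitution probability applied to
#'   the second proteome's copy of each shared protein, in \[0, 1).
#' @param seed Integer seed; the same seed reproduces the pair exactly.
#' @param labels Character pair of proteome labels.
#' @return List with `a`, `b` (proteomes), `n_shared` and
#'   `expected_pocp_pct`.
#' @examples
#' p <- generate_pair(20, 0.5, seed = 1)
#' p$expected_pocp_pct
#' @export
generate_pair <- function(n_proteins, shared_fraction,
                          length_range = c(100L, 400L),
                          point_mutation_rate = 0, seed = 1L,
                          labels = c("synthA", "synthB")) {
  n <- as.integer(n_proteins)
  if (is.na(n) || n < 2L) stop("n_proteins must be >= 2", call. = FALSE)
  if (shared_fraction < 0 || shared_fraction > 1)
    stop("shared_fraction must lie in [0, 1]", call. = FALSE)
  if (point_mutation_rate < 0 || point_mutation_rate >= 1)
    stop("point_mutation_rate must lie in [0, 1)", call. = FALSE)
  k <- as.integer(round(n * shared_fraction))
  with_seed(seed, {
    a <- generate_proteome(n, length_range, seed = NULL, label = labels[1L])
    b_seqs <- character(n)
    if (k > 0L) {
      b_seqs[seq_len(k)] <- vapply(unname(a$sequences[seq_len(k)]),
                                   mutate_sequence, character(1L),
                                   rate = point_mutation_rate)
    }
    if (k < n) {
      lens <- random_lengths(n - k, length_range)
      b_seqs[seq(k + 1L, n)] <- vapply(lens, random_protein, character(1L))
    }
    b <- new_proteome(labels[2L], sprintf("%s_p%04d", labels[2L], seq_len(n)),
                      b_seqs)
    list(a = a, b = b, n_shared = k,
         expected_pocp_pct = 100 * (2 * k) / (2 * n))
  })
}

#' Write a synthetic pair to FASTA files
#'
#' Convenience wrapper around [generate_pair()] that writes the two
#' proteomes as `<label>.faa` files into `dir`, ready for [run_pocp()].
#' Same seed, same files, byte for byte.
#'
#' @inheritParams generate_pair
#' @param dir Output directory (created if needed).
#' @return Character vector of the two file paths.
#' @export
write_synthetic_pair <- function(dir, n_proteins, shared_fraction,
                                 length_range = c(100L, 400L),
                                 point_mutation_rate = 0, seed = 1L,
                                 labels = c("synthA", "synthB")) {
  pair <- generate_pair(n_proteins, shared_fraction, length_range,
                        point_mutation_rate, seed, labels)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(dir, paste0(labels, ".faa"))
  write_proteome_fasta(pair$a, paths[1L])
  write_proteome_fasta(pair$b, paths[2L])
  paths
}
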