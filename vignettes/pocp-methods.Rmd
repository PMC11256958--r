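---
title: "Computing the Percentage of Conserved Proteins: model, parameters and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Computing the Percentage of Conserved Proteins}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The metric

The Percentage of Conserved Proteins (POCP) is a proteome-level similarity
index used to assess genus boundaries in prokaryotic taxonomy. For two
proteomes A and B with T1 and T2 proteins,

$$\mathrm{POCP} = 100 \cdot \frac{C_1 + C_2}{T_1 + T_2}$$

where $C_1$ is the number of proteins of A that have at least one
qualifying alignment hit against B, and $C_2$ the converse. A hit
qualifies — and marks its query protein as *conserved* — when

* its e-value is strictly below `1e-5`,
* its percent identity is strictly above 40, and
* its alignable query region (coverage) is strictly above 50%.

A POCP above 50% has been proposed as evidence that two strains may belong
to the same genus; it is one genomic metric among several and is sensitive
to proteome-size differences between the two strains, which this package
documents but does not correct.

Conservation is existential, not best-hit: a protein with *any* passing hit
counts, and it counts once no matter how many of its HSPs pass. This makes
the count independent of hit-table sort order. Whether a best-hit rule would
differ in practice is negligible for the counting (a best hit passes iff
some hit passes under monotone criteria applied per hit).

### Boundary semantics

All three thresholds are strict, matching the "< 1e-5", "> 40%", "> 50%"
formulation of the original criteria. A hit at exactly e-value `1e-5`,
identity 40, or coverage 50 is therefore rejected, and the summary's
genus count uses the same convention (`pocp_pct > 50`, a pair at exactly 50
is not counted). Both choices are configurable but warned about: any
deviation from the default criteria emits a warning carrying the changed
values and the package version, so shared results disclose nonstandard
parameters.

## Quantities read by the filter

* **Percent identity** follows the BLAST `pident` convention: identical
  aligned residues divided by *all* alignment columns, gap columns
  included.
* **Coverage** is measured on the query: `100 * (qend - qstart + 1) /
  qlen`. The span, not the column count, is used, so gaps inserted into the
  query cannot inflate coverage; with 12-column tabular input the span is
  also the only query-side measure available. Subject-side coverage is not
  computed — the original definition measures the query's aligned region.
* **E-values** come either from the external aligner (hit-table input) or
  from the built-in estimate described next.

## The built-in aligner

`align_proteomes()` runs an exact Smith–Waterman local alignment with
affine gaps for every query/subject protein pair. Defaults are the BLASTP
protein defaults — BLOSUM62 with gap open 11 and gap extend 1 (a gap of
length $g$ costs $11 + g$) — because the conservation thresholds were
calibrated against BLASTP-style alignments. Substitution matrices are taken
from the published tables shipped with Biostrings.

One optimal alignment is reported per pair; sub-optimal HSPs are not
enumerated. On tied dynamic-programming scores the traceback prefers a
substitution column, then a gap in the subject, then a gap in the query;
only the *score* of co-optimal alignments is unique, so the test suite's
oracle comparisons (against an independent reference implementation)
compare scores, not spans. No low-complexity masking or composition-based
statistics are applied; DIAMOND masks by default, so borderline hits can
differ between backends.

### E-value estimate

Raw scores are converted with the Karlin–Altschul form

$$E = K \, m \, n \, e^{-\lambda S}$$

with the published gapped BLOSUM62/11/1 parameters $\lambda = 0.267$,
$K = 0.041$, $m$ the query length and $n$ the subject length of the single
compared pair. Two deliberate simplifications:

* **No edge-effect (effective length) correction.** For desk-scale
  proteins the correction moves e-values by far less than the nine orders
  of magnitude that separate a typical conserved hit from the `1e-5`
  cutoff.
* **Pairwise, not database-wide search space.** Scaling $n$ by the subject
  proteome size would make POCP depend on proteome size in a way the metric
  does not define. The consequence is that internal e-values are
  systematically *smaller* than BLAST/DIAMOND database-wide e-values;
  expect small deviations on borderline hits. The identity and coverage
  filters dominate the decision in practice.

For a self-hit of a protein of length $L$, the score is at least $4L$
(the smallest BLOSUM62 diagonal entry) so the e-value bound
$0.041 L^2 e^{-0.267 \cdot 4L} < 10^{-5}$ holds for every $L \ge 30$;
identical proteins of the generator's default lengths always pass all
three filters, which is what makes the self-identity check exact.

### The diagonal convention

The matrix diagonal is set to 100 without computation. Self-comparison
carries no taxonomic information, and pinning it avoids ever confusing a
user should an extremely short protein fail its own e-value under the
pairwise approximation.

## External hit tables

Precomputed searches (BLAST+ or DIAMOND, tabular `outfmt 6`) can replace
the internal aligner. One file per *directed* pair is required, named
`<queryLabel>__vs__<subjectLabel>.tsv`, because conservation is counted in
both directions. The reader accepts the standard 12 columns or 13 with a
trailing `qlen`; without `qlen` the query FASTA supplies lengths, joined on
the first whitespace-delimited header token (the token BLAST reports).
Rows are validated individually, with line and column numbers in every
parse error.

## The synthetic generator

`generate_pair()` builds two proteomes of `n` proteins that share exactly
`round(n * f)` proteins; shared proteins are copied (optionally with
point substitutions at a per-site rate) under fresh ids, the rest are drawn
independently. Residues are i.i.d. from the Robinson–Robinson background
frequencies — the composition underlying BLOSUM62 statistics — which keeps
chance identity between unrelated proteins low and stable. Defaults: 100 to
400 residues per protein, no mutation. By construction the expected POCP is
$100 f$: every shared protein has an identical full-length partner, and two
unrelated random proteins essentially never align at >40% identity over
more than half their length (measured chance-level POCP is 0 at these
conditions).

What the generator does *not* emulate: paralogy, domain shuffling, indels,
length and composition biases of real proteomes, and annotation differences
between gene callers. Passing the recovery tests therefore demonstrates the
correctness of the counting machinery under controlled conditions, not
concordance with any particular aligner on real data.

A note on the mutation dial: at 0.3 substitutions per site (~70% expected
identity) every shared protein stays conserved; at 0.75 (~25% identity)
POCP collapses to the unrelated baseline. At 0.6 the expected identity sits
exactly on the 40% threshold, and because a local aligner preferentially
reports the highest-identity subregion that still clears coverage, the
collapse there is only partial. The property tests encode exactly this
bracketing.

## Problem sizes used in validation

The test-suite and acceptance-script workloads were chosen as the smallest
sizes at which each property is meaningful rather than vacuous: 100
proteins (lengths 100–400) for the self-identity check, 20 random pairs of
15 proteins for symmetry and bounds, 200 proteins per proteome for
shared-fraction recovery at $f \in \{0, 0.25, 0.5, 0.75, 1\}$ (within 2
percentage points), 1000 randomized hit tables against a brute-force
row-scan oracle, and 200 random sequence pairs (length ≤ 50) against an
independent alignment reference with exact integer score agreement.

## Known limitations

* Internal e-values approximate, as described; do not compare them to
  database-wide BLAST e-values directly.
* No HSP enumeration: a protein whose similarity is split across several
  short HSPs by a heuristic aligner may be counted differently here.
* No correction for proteome-size asymmetry; report T1 and T2 (the long
  output table includes them) alongside POCP values.
* Nucleotide input and gene prediction are out of scope: inputs are
  protein FASTA files, one per genome/strain.
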