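test_that("a standard 12-column row maps onto the hit fields", {
  tsv <- tempfile(fileext = ".tsv")
  writeLines("q1\ts9\t52.5\t200\t90\t3\t5\t204\t1\t198\t3e-40\t150", tsv)
  prot <- make_proteome(random_seq(210), label = "q", ids = "q1")
  h <- parse_tabular_hits(tsv, prot)
  expect_equal(nrow(h), 1L)
  expect_equal(h$percent_identity, 52.5)
  expect_equal(h$align_columns, 200L)
  expect_equal(c(h$query_start, h$query_end), c(5L, 204L))
  expect_equal(h$evalue, 3e-40)
  expect_equal(h$query_len, 210L)
  expect_equal(hit_query_coverage(h), 100 * 200 / 210)
})

test_that("a 13th qlen column takes precedence over the proteome lookup", {
  tsv <- tempfile(fileext = ".tsv")
  writeLines("q1\ts9\t52.5\t200\t90\t3\t5\t204\t1\t198\t3e-40\t150\t210",
             tsv)
  h <- parse_tabular_hits(tsv)  # no proteome needed
  expect_equal(h$query_len, 210L)
})

test_that("empty files and comment lines are tolerated", {
  tsv <- tempfile(fileext = ".tsv")
  writeLines(character(), tsv)
  expect_equal(nrow(parse_tabular_hits(tsv)), 0L)
  writeLines(c("# produced by some aligner",
               "q1\ts1\t60\t100\t40\t0\t1\t100\t1\t100\t1e-20\t99\t120"),
             tsv)
  expect_equal(nrow(parse_tabular_hits(tsv)), 1L)
})

test_that("malformed hit tables fail with line and column diagnostics", {
  tsv <- tempfile(fileext = ".tsv")
  writeLines(c("q1\ts1\t60\t100\t40\t0\t1\t100\t1\t100\t1e-20\t99\t120",
               "q1\ts1\t60\t100"), tsv)
  expect_error(parse_tabular_hits(tsv), "line 2.*12 or 13")
  writeLines("q1\ts1\tabc\t100\t40\t0\t1\t100\t1\t100\t1e-20\t99\t120", tsv)
  expect_error(parse_tabular_hits(tsv), "line 1, column 3")
  writeLines("qX\ts1\t60\t100\t40\t0\t1\t100\t1\t100\t1e-20\t99", tsv)
  prot <- make_proteome("MKVL", label = "q", ids = "q1")
  expect_error(parse_tabular_hits(tsv, prot), "qX.*not found")
  expect_error(parse_tabular_hits(tsv), "no qlen column")
})

test_that("parse then re-serialize reproduces the numeric fields", {
  tsv <- tempfile(fileext = ".tsv")
  rows <- c("q1\ts1\t52.5\t200\t90\t3\t5\t204\t1\t198\t3e-40\t150\t210",
            "q2\ts7\t98.0\t64\t1\t0\t2\t65\t3\t66\t1.2e-08\t88\t80")
  writeLines(rows, tsv)
  h <- parse_tabular_hits(tsv)
  expect_equal(h$percent_identity, c(52.5, 98.0))
  expect_equal(h$evalue, c(3e-40, 1.2e-08))
  expect_equal(h$score, c(150, 88))
  expect_equal(h$query_len, c(210L, 80L))
})

test_that("local alignments convert with the pident convention", {
  aln <- structure(list(score = 30L, query_id = "q", subject_id = "s",
                        query_start = 1L, query_end = 11L,
                        subject_start = 4L, subject_end = 15L,
                        n_identical = 6L, n_columns = 12L, evalue = 1e-9),
                   class = "local_alignment")
  h <- from_local_alignment(aln, query_len = 20L)
  expect_equal(h$percent_identity, 50)  # 6 of 12 columns incl. gaps
  expect_equal(h$align_columns, 12L)
  expect_equal(hit_query_coverage(h), 55)

  s <- random_seq(100)
  a <- smith_waterman(s, s)
  h2 <- from_local_alignment(a, 100L)
  expect_equal(h2$percent_identity, 100)
  expect_equal(hit_query_coverage(h2), 100)
})

test_that("hit construction guards the coordinate invariants", {
  expect_error(alignment_hits("q", "s", 50, 10L, 5L, 4L, 1e-9, 10, 100L),
               "coordinates")
  expect_error(alignment_hits("q", "s", 50, 10L, 1L, 120L, 1e-9, 10, 100L),
               "coordinates")
  expect_error(alignment_hits("q", "s", 101, 10L, 1L, 10L, 1e-9, 10, 100L),
               "identity")
})
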