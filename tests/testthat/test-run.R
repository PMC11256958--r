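# End-to-end pipeline behaviour: file inputs to TSV outputs, hit-table
# backend resolution, and the reproducibility contract of the run log.

run_fixture_dir <- function(n = 6, seeds = c(101, 102, 103)) {
  d <- tempfile("fastas")
  dir.create(d)
  for (i in seq_along(seeds)) {
    p <- generate_proteome(n, c(60, 120), seed = seeds[i],
                           label = paste0("g", i))
    write_proteome_fasta(p, file.path(d, paste0("g", i, ".faa")))
  }
  d
}

test_that("a default run writes the four outputs with a coherent matrix", {
  d <- run_fixture_dir()
  out <- tempfile("out")
  res <- run_pocp(file.path(d, "*.faa"), out)
  expect_true(all(file.exists(file.path(
    out, c("pocp_matrix.tsv", "pocp_pairs.tsv", "pocp_summary.tsv",
           "run_log.txt")))))
  mat <- read.delim(file.path(out, "pocp_matrix.tsv"), check.names = FALSE)
  expect_equal(dim(mat), c(3L, 4L))
  expect_equal(mat$label, c("g1", "g2", "g3"))
  expect_equal(diag(as.matrix(mat[, -1])), rep(100, 3),
               ignore_attr = TRUE)
  m <- as.matrix(mat[, -1])
  expect_equal(m, t(m), ignore_attr = TRUE)
})

test_that("re-running an identical configuration is byte-reproducible", {
  d <- run_fixture_dir()
  out1 <- tempfile(); out2 <- tempfile()
  run_pocp(file.path(d, "*.faa"), out1)
  run_pocp(file.path(d, "*.faa"), out2)
  for (f in c("pocp_matrix.tsv", "pocp_pairs.tsv")) {
    expect_identical(readLines(file.path(out1, f)),
                     readLines(file.path(out2, f)))
  }
})

test_that("the run log round-trips the configuration", {
  d <- run_fixture_dir()
  out <- tempfile()
  expect_warning(
    run_pocp(file.path(d, "*.faa"), out,
             criteria = filter_criteria(min_identity_pct = 30)),
    "NONSTANDARD")
  log <- read_run_log(file.path(out, "run_log.txt"))
  expect_equal(log$min_identity_pct, 30)
  expect_equal(log$max_evalue, 1e-5)
  expect_equal(log$nonstandard_criteria, "true")
  expect_equal(log$matrix_name, "BLOSUM62")
  expect_equal(log$gap_open, 11)
  expect_equal(log$inputs$label, c("g1", "g2", "g3"))
  expect_equal(log$inputs$n_proteins, rep(6L, 3))
  # the logged values rebuild equivalent criteria and scoring objects
  rebuilt <- filter_criteria(log$max_evalue, log$min_identity_pct,
                             log$min_coverage_pct)
  expect_equal(rebuilt$min_identity_pct, 30)
})

test_that("an unknown one-vs-all target fails listing the valid labels", {
  d <- run_fixture_dir()
  expect_error(run_pocp(file.path(d, "*.faa"), tempfile(), target = "nope"),
               "g1, g2, g3")
})

test_that("the hit-table backend reproduces the internal aligner's POCP", {
  pair <- generate_pair(8, 0.5, length_range = c(60, 120), seed = 51)
  internal <- compare_pair(pair$a, pair$b)

  # export the internal aligner's directed hit tables, then re-ingest them
  hd <- tempfile(); dir.create(hd)
  export <- function(q, s) {
    h <- align_proteomes(q, s)
    rows <- sprintf("%s\t%s\t%.3f\t%d\t%d\t%d\t%d\t%d\t%d\t%d\t%g\t%g\t%d",
                    h$query_id, h$subject_id, h$percent_identity,
                    h$align_columns, 0L, 0L, h$query_start, h$query_end,
                    1L, 1L, h$evalue, h$score, h$query_len)
    writeLines(rows, file.path(hd, paste0(q$label, "__vs__", s$label,
                                          ".tsv")))
  }
  export(pair$a, pair$b)
  export(pair$b, pair$a)

  via_files <- compare_pair(pair$a, pair$b, backend = hits_backend(hd))
  expect_equal(via_files$c1, internal$c1)
  expect_equal(via_files$c2, internal$c2)
  expect_equal(via_files$pocp_pct, internal$pocp_pct)
})

test_that("missing directed hit tables are named in the error", {
  hd <- tempfile(); dir.create(hd)
  writeLines(character(), file.path(hd, "a__vs__b.tsv"))
  expect_error(resolve_hit_tables(hd, c("a", "b")), "b__vs__a\\.tsv")
  # one-vs-all with 3 labels needs exactly 2 directions x 2 pairs
  for (f in c("a__vs__b", "b__vs__a", "a__vs__c", "c__vs__a"))
    writeLines(character(), file.path(hd, paste0(f, ".tsv")))
  mapping <- resolve_hit_tables(hd, c("a", "b", "c"), target = "a")
  expect_length(mapping, 4L)
})
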