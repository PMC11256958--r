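hit_row <- function(evalue, identity, coverage, query_id = "q1") {
  qlen <- 200L
  span <- as.integer(round(qlen * coverage / 100))
  alignment_hits(query_id, "s1", identity, span, 1L, span, evalue, 50, qlen)
}

test_that("all three conservation thresholds are strict", {
  crit <- filter_criteria()
  expect_true(is_conserved(hit_row(1e-6, 41, 51), crit))
  expect_false(is_conserved(hit_row(1e-5, 90, 90), crit))  # e-value at bound
  expect_false(is_conserved(hit_row(1e-10, 40, 80), crit)) # identity at bound
  expect_false(is_conserved(hit_row(1e-10, 80, 50), crit)) # coverage at bound
  expect_true(is_conserved(hit_row(9.99e-6, 40.01, 50.5), crit))
})

test_that("conservation is counted per distinct query protein", {
  crit <- filter_criteria()
  hits <- rbind(hit_row(1e-9, 80, 90, "q1"),
                hit_row(1e-8, 70, 80, "q1"),   # second passing HSP, same query
                hit_row(1e-2, 90, 90, "q2"),   # fails the e-value filter
                hit_row(1e-9, 60, 70, "q3"))
  expect_equal(count_conserved(hits, crit), 2L)
  expect_equal(count_conserved(empty_hits <- hits[0, ], crit), 0L)
})

test_that("counting agrees with a brute-force row scan on random tables", {
  set.seed(19)
  crit <- filter_criteria()
  for (i in 1:50) {
    hits <- random_hit_table(sample(1:60, 1))
    expect_identical(count_conserved(hits, crit),
                     brute_force_count(hits, crit))
  }
})

test_that("the POCP formula and its guards are exact", {
  expect_equal(pocp_from_counts(500, 600, 500, 600), 100)
  expect_equal(pocp_from_counts(0, 0, 500, 600), 0)
  expect_equal(pocp_from_counts(300, 320, 500, 600), 100 * 620 / 1100)
  expect_error(pocp_from_counts(501, 0, 500, 600), "counting bug")
  expect_error(pocp_from_counts(1, 1, 0, 5), "sizes")
})

test_that("pair comparison is bidirectional and direction-independent", {
  pair <- generate_pair(12, 0.5, length_range = c(60, 120), seed = 3)
  ab <- compare_pair(pair$a, pair$b)
  ba <- compare_pair(pair$b, pair$a)
  expect_identical(ab$pocp_pct, ba$pocp_pct)
  expect_identical(ab$c1, ba$c2)
  expect_identical(ab$t1, ba$t2)
  expect_true(ab$pocp_pct >= 0 && ab$pocp_pct <= 100)
  expect_error(compare_pair(pair$a, pair$a), "labels must differ")
})

test_that("a relabelled copy of a proteome gives POCP 100", {
  p <- generate_proteome(8, c(80, 150), seed = 9, label = "orig")
  q <- p; q$label <- "copy"
  expect_equal(compare_pair(p, q)$pocp_pct, 100)
})

test_that("proteomes with no qualifying hits give POCP 0", {
  pair <- generate_pair(8, 0, length_range = c(60, 120), seed = 21)
  r <- compare_pair(pair$a, pair$b)
  expect_equal(r$pocp_pct, 0)
  expect_equal(c(r$c1, r$c2), c(0L, 0L))
})

test_that("tightening any one criterion never increases the count", {
  set.seed(29)
  hits <- random_hit_table(300, n_queries = 30L)
  base <- count_conserved(hits, filter_criteria())
  tighter <- list(filter_criteria(max_evalue = 1e-8),
                  filter_criteria(min_identity_pct = 60),
                  filter_criteria(min_coverage_pct = 75))
  for (crit in tighter) {
    expect_warning(n <- count_conserved(hits, crit), NA)
    expect_lte(n, base)
  }
})

test_that("matrix assembly covers both modes with a conventional diagonal", {
  set.seed(33)
  prots <- lapply(c("a", "b", "c"), function(lb)
    generate_proteome(6, c(60, 100), seed = utf8ToInt(lb), label = lb))
  m <- compute_matrix(prots)
  expect_equal(nrow(m$pairs), 3L)  # 3*2/2
  expect_true(isSymmetric(m$values))
  expect_equal(unname(diag(m$values)), rep(100, 3))
  expect_true(all(m$values >= 0 & m$values <= 100))

  one <- compute_matrix(prots, mode = "one-vs-all", target = "b")
  expect_equal(nrow(one$pairs), 2L)  # n - 1
  expect_true(is.na(one$values["a", "c"]))  # uncomputed, never zero-filled
  expect_false(anyNA(one$values["b", ]))
  expect_error(compute_matrix(prots, mode = "one-vs-all", target = "zz"),
               "a, b, c")
})

test_that("summary statistics use a strict genus threshold", {
  pairs <- data.frame(pocp_pct = c(40, 60))
  s <- summarize_pairs(pairs)
  expect_equal(c(s$min_pocp, s$mean_pocp, s$max_pocp), c(40, 50, 60))
  expect_equal(s$n_pairs_above_genus_threshold, 1L)
  expect_equal(summarize_pairs(data.frame(pocp_pct = 50))$
                 n_pairs_above_genus_threshold, 0L)  # strict at the limit
  empty <- summarize_pairs(data.frame(pocp_pct = numeric()))
  expect_equal(empty$n_pairs, 0L)
  expect_true(is.na(empty$mean_pocp))
})

test_that("nonstandard criteria trigger a version-carrying warning", {
  pair <- generate_pair(4, 1, length_range = c(60, 80), seed = 41)
  expect_warning(
    compute_matrix(list(pair$a, pair$b),
                   criteria = filter_criteria(min_identity_pct = 30)),
    "NONSTANDARD.*min_identity_pct=30.*version")
  expect_silent(m <- compute_matrix(list(pair$a, pair$b)))
})

test_that("TSV outputs round-trip the matrix and pair values", {
  pair <- generate_pair(6, 0.5, length_range = c(60, 120), seed = 43)
  m <- compute_matrix(list(pair$a, pair$b))
  d <- tempfile(); dir.create(d)
  write_pocp_matrix(m, file.path(d, "m.tsv"))
  write_pocp_pairs(m, file.path(d, "p.tsv"))
  write_pocp_summary(m, file.path(d, "s.tsv"))

  mat <- read.delim(file.path(d, "m.tsv"), check.names = FALSE)
  expect_equal(mat$label, m$labels)
  expect_equal(mat[1, 2], 100)
  expect_equal(mat[1, 3], round(m$pairs$pocp_pct, 2))

  pr <- read.delim(file.path(d, "p.tsv"))
  expect_equal(pr$c1 + pr$c2, m$pairs$c1 + m$pairs$c2)
  expect_equal(pr$pocp_pct, round(m$pairs$pocp_pct, 2))

  sm <- read.delim(file.path(d, "s.tsv"), header = FALSE)
  expect_true("version" %in% sm$V1)
  expect_equal(sm$V2[sm$V1 == "n_pairs"], "1")
})
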