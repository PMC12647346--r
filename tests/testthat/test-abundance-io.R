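test_that("missing tokens are masked and values parsed at the right cells", {
  path <- write_lines_tmp(c(
    "protein_id\tS1\tS2\tS3\tS4",
    "P1\t1\tNA\t3\t4",
    "P2\t5\t6\t\t8",
    "P3\t9\t10\t11\t12"))
  m <- read_abundance_table(path)
  expect_equal(dim(m), c(3L, 4L))
  expect_true(m$mask["P1", "S2"])
  expect_true(m$mask["P2", "S3"])
  expect_equal(sum(m$mask), 2L)
  expect_equal(m$values["P3", "S2"], 10)
  expect_true(all(is.na(m$values[m$mask])))
})

test_that("read/write round trip is the identity for both dialects and gzip", {
  set.seed(11)
  m <- random_ties_abundance(6, 9)
  for (dialect in c("tsv", "csv")) {
    for (gz in c("", ".gz")) {
      path <- tempfile(fileext = paste0(".", dialect, gz))
      write_abundance_table(m, path, dialect = dialect)
      back <- read_abundance_table(path, dialect = dialect)
      expect_identical(back$values, m$values)
      expect_identical(back$mask, m$mask)
      expect_identical(back$protein_ids, m$protein_ids)
      expect_identical(back$sample_ids, m$sample_ids)
    }
  }
})

test_that("malformed abundance tables are rejected with informative errors", {
  dup <- write_lines_tmp(c("protein_id\tS1\tS2", "P1\t1\t2", "P1\t3\t4"))
  expect_error(read_abundance_table(dup), "duplicate protein ids.*P1")
  ragged <- write_lines_tmp(c("protein_id\tS1\tS2", "P1\t1\t2", "P2\t3"))
  expect_error(read_abundance_table(ragged), "line 3")
  neg <- write_lines_tmp(c("protein_id\tS1", "P1\t-4"))
  expect_error(read_abundance_table(neg), "negative")
  junk <- write_lines_tmp(c("protein_id\tS1", "P1\tabc"))
  expect_error(read_abundance_table(junk), "cannot parse cell")
  expect_error(read_abundance_table(write_lines_tmp(character())), "empty file")
})

test_that("custom missing tokens and transpose are honoured", {
  path <- write_lines_tmp(c("sample\tP1\tP2", "S1\t1\t-999", "S2\t2\t4"))
  m <- read_abundance_table(path, missing_tokens = c("", "-999"),
                            transpose = TRUE)
  expect_identical(m$protein_ids, c("P1", "P2"))
  expect_true(m$mask["P2", "S1"])
  expect_false(any(m$mask[!(m$protein_ids == "P2"), ]))
})

test_that("term maps aggregate rows with set semantics", {
  path <- write_lines_tmp(c("T1\tA", "T1\tB", "T2\tC", "T1\tA"))
  tm <- read_term_map(path)
  expect_identical(tm$T1, c("A", "B"))
  expect_identical(tm$T2, "C")
  expect_error(read_term_map(write_lines_tmp("term\tprotein"), header = TRUE),
               "no data rows")
  expect_error(read_term_map(write_lines_tmp(c("T1\tA", "T2"))), "line 2")
})

test_that("pair lists filter by evidence, canonicalise and deduplicate", {
  path <- write_lines_tmp(c(
    "gene_a,gene_b,evidence_source",
    "B,A,CRISPR", "C,D,CRISPR", "E,F,low-throughput", "G,H,text-mining",
    "A,B,low-throughput"), ext = ".csv")
  ps <- read_pair_list(path, allowed_sources = c("CRISPR", "low-throughput"))
  expect_equal(nrow(ps), 3L)           # text-mining dropped, (A,B) deduped
  expect_true(all(ps$gene_a < ps$gene_b))
  expect_identical(ps$gene_a[1L], "A") # (B,A) canonicalised

  expect_warning(sp <- pair_set(c("A", "A"), c("A", "B")), "self-pair")
  expect_equal(nrow(sp), 1L)

  bad <- write_lines_tmp(c("gene_a,gene_b", "A,B"), ext = ".csv")
  expect_error(read_pair_list(bad), "missing required column.*evidence_source")
})

test_that("pair-list size is monotone in the allowed evidence sources", {
  lines <- c("gene_a,gene_b,evidence_source",
             sprintf("G%d,H%d,%s", 1:12, 1:12,
                     rep(c("CRISPR", "low-throughput", "text-mining"), 4)))
  path <- write_lines_tmp(lines, ext = ".csv")
  sets <- list(c("CRISPR"), c("CRISPR", "low-throughput"),
               c("CRISPR", "low-throughput", "text-mining"))
  sizes <- vapply(sets, function(s) nrow(read_pair_list(path, s)), integer(1))
  expect_true(all(diff(sizes) >= 0))
  expect_equal(sizes, c(4L, 8L, 12L))
})

test_that("replicate experiments parse condition:replicate headers", {
  path <- write_lines_tmp(c(
    "protein_id\toff:1\toff:2\twt:1\twt:2",
    "P1\t1\t2\t3\t4", "P2\t5\t6\t7\t8"))
  e <- read_replicate_experiment(path)
  expect_identical(levels(e$condition), c("off", "wt"))
  expect_equal(unname(table(e$condition)[["off"]]), 2L)
  expect_error(replicate_experiment(
    matrix(1:4, 2, dimnames = list(c("P1", "P2"), NULL)), c("a", "b")),
    "at least 2 replicates")
  expect_error(replicate_experiment(
    matrix(1:8, 2, dimnames = list(c("P1", "P2"), NULL)),
    c("a", "a", "b", "c")), "exactly two conditions")
})

test_that("panel files ignore comments and blanks and preserve order", {
  path <- write_lines_tmp(c("# CCAN-like panel", "CENPC", "", "NDC80 # outer",
                            "CENPA"))
  expect_identical(read_panel_file(path), c("CENPC", "NDC80", "CENPA"))
})
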