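test_that("a well-formed count table parses with recomputed totals and preserved order", {
  pair <- read_count_table(count_fixture())
  expect_s3_class(pair, "library_pair")
  expect_equal(pair$genes$gene_id, c("g1", "g2", "g3"))
  expect_equal(pair$total_a, 17)
  expect_equal(pair$total_b, 23)
  expect_equal(pair$genes$length_bp, c(1000L, 500L, 2000L))
})

test_that("count table validation reports the offending line or id", {
  expect_error(read_count_table(tempfile()), "does not exist")
  bad_header <- write_lines_tmp(c("gene\tlen\ta\tb", "g1\t10\t1\t1"))
  expect_error(read_count_table(bad_header), "malformed header")
  neg <- write_lines_tmp(c("gene_id\tlength_bp\tcount_a\tcount_b",
                           "g1\t100\t1\t1", "g2\t100\t2\t2",
                           "g3\t100\t-3\t1"))
  expect_error(read_count_table(neg), "line 4.*count_a must be >= 0")
  dup <- write_lines_tmp(c("gene_id\tlength_bp\tcount_a\tcount_b",
                           "g1\t100\t1\t1", "g1\t100\t2\t2"))
  expect_error(read_count_table(dup), "duplicate gene_id 'g1'")
  shortlen <- write_lines_tmp(c("gene_id\tlength_bp\tcount_a\tcount_b",
                                "g1\t0\t1\t1"))
  expect_error(read_count_table(shortlen), "length_bp must be >= 1")
  frac <- write_lines_tmp(c("gene_id\tlength_bp\tcount_a\tcount_b",
                            "g1\t100\t1.5\t1"))
  expect_error(read_count_table(frac), "not an integer")
})

test_that("term table parses, deduplicates with a warning, and rejects bad namespaces", {
  asg <- read_term_table(term_fixture())
  expect_equal(nrow(asg), 2L)
  expect_equal(asg$namespace, c("GO", "KEGG"))

  dup <- write_lines_tmp(c("gene_id\tterm_id\tnamespace\tterm_name",
                           "g1\tGO:1\tGO\tx", "g1\tGO:1\tGO\tx"))
  expect_warning(asg2 <- read_term_table(dup), "1 duplicate")
  expect_equal(nrow(asg2), 1L)

  pfam <- write_lines_tmp(c("gene_id\tterm_id\tnamespace\tterm_name",
                            "g1\tPF1\tPFAM\tx"))
  expect_error(read_term_table(pfam), "unknown namespace 'PFAM'")
  noterm <- write_lines_tmp(c("gene_id\tterm_id\tnamespace\tterm_name",
                              "g1\t\tGO\tx"))
  expect_error(read_term_table(noterm), "empty term_id")
})

test_that("term-table genes absent from the count table are dropped unless whitelisted", {
  path <- term_fixture()
  expect_message(asg <- read_term_table(path, count_genes = "g1"),
                 "dropped 1")
  expect_equal(asg$gene_id, "g1")
  asg2 <- suppressMessages(read_term_table(path, count_genes = "g1",
                                           keep_unmatched = TRUE))
  expect_equal(nrow(asg2), 2L)
})

test_that("result tables round-trip through write_results/read_results", {
  sim <- simulate_pair(sim_config(n_genes = 10, total_a = 1e4, total_b = 1e4,
                                  de_fraction = 0, seed = 5))
  deg <- call_degs(sim$pair)
  tf <- tempfile(fileext = ".tsv")
  write_results(deg, tf)
  back <- read_results(tf, numeric_cols = c("rpkm_a", "rpkm_b", "log2_ratio",
                                            "p_value", "fdr"))
  expect_equal(back$gene_id, deg$gene_id)
  expect_equal(back$p_value, signif(deg$p_value, 6))
  expect_equal(back$rpkm_a, signif(deg$rpkm_a, 6))

  empty <- deg[0, ]
  write_results(empty, tf)
  expect_equal(readLines(tf), paste(names(deg), collapse = "\t"))

  expect_error(write_results(deg, file.path(tempfile(), "x.tsv")),
               "does not exist")
})

test_that("count tables round-trip byte-identically and ignore stale totals", {
  src <- count_fixture()
  pair <- read_count_table(src)
  out <- tempfile(fileext = ".tsv")
  write_count_table(pair, out)
  expect_identical(readLines(out), readLines(src))
  # totals always recomputed from columns, whatever a caller claims
  pair2 <- library_pair(pair$genes)
  expect_equal(pair2$total_a, sum(pair$genes$count_a))
})
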