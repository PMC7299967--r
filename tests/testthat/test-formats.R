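test_that("read_fasta preserves order, unwraps and upper-cases", {
  f <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">a first gene", "AC", "gt", ">b", "TT"), f)
  rec <- read_fasta(f)
  expect_equal(rec$id, c("a", "b"))
  expect_equal(rec$seq, c("ACGT", "TT"))
  expect_equal(rec$desc, c("first gene", ""))
})

test_that("read_fasta rejects duplicate ids and warns on empty files", {
  f <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">a", "AC", ">a", "GG"), f)
  expect_error(read_fasta(f), "duplicate id a")
  f2 <- withr::local_tempfile(fileext = ".fasta")
  file.create(f2)
  expect_warning(rec <- read_fasta(f2), "empty")
  expect_equal(nrow(rec), 0L)
})

test_that("FASTA writing round-trips ids, descriptions and residues", {
  set.seed(11)
  recs <- data.frame(
    id = sprintf("seq%02d", 1:20),
    desc = ifelse(1:20 %% 2 == 0, "some annotation", ""),
    seq = vapply(1:20, function(i) {
      paste(sample(c("A", "C", "G", "T"), sample(5:200, 1),
                   replace = TRUE), collapse = "")
    }, character(1)),
    stringsAsFactors = FALSE
  )
  f <- withr::local_tempfile(fileext = ".fasta")
  write_fasta(recs, f, width = 17L)
  expect_equal(read_fasta(f), recs)
})

test_that("complete-ORF extraction keeps only start..stop frames", {
  recs <- data.frame(
    id = c("ok", "nostop", "internal", "frame", "nostart"),
    desc = "",
    seq = c("ATGAAATAA", "ATGAAA", "ATGTAGAAATAA", "ATGAAATA",
            "AAAATGTAA"),
    stringsAsFactors = FALSE
  )
  out <- extract_complete_orfs(recs)
  expect_equal(out$kept$id, "ok")
  expect_equal(out$translated$seq, "MK")
  expect_equal(
    out$report,
    c(kept = 1L, not_multiple_of_3 = 1L, no_start = 1L, no_stop = 1L,
      internal_stop = 1L)
  )
  # "MKVEF" cannot be nucleotide: E and F are outside the IUPAC codes
  expect_error(
    extract_complete_orfs(data.frame(id = "x", desc = "", seq = "MKVEF")),
    "non-nucleotide"
  )
})

test_that("complete-ORF extraction is idempotent on its kept set", {
  set.seed(7)
  sense <- codon_table("1")
  sense <- sense$codon[!sense$stop]
  seqs <- vapply(1:30, function(i) {
    body <- paste(sample(sense, sample(5:40, 1), replace = TRUE),
                  collapse = "")
    core <- paste0("ATG", body, sample(c("TAA", "TAG", "TGA"), 1))
    # randomly break some: truncate, or drop the stop
    switch(sample(3, 1), core, substr(core, 1, nchar(core) - 1),
           substr(core, 1, nchar(core) - 3))
  }, character(1))
  recs <- data.frame(id = sprintf("g%02d", 1:30), desc = "", seq = seqs,
                     stringsAsFactors = FALSE)
  once <- extract_complete_orfs(recs)
  twice <- extract_complete_orfs(once$kept)
  expect_equal(twice$kept, once$kept)
  expect_equal(sum(twice$report[-1]), 0L)
})

test_that("tabular hits parse with explicit or mapped lengths", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(paste(c("q1", "s1", "90.0", "50", "5", "0", "1", "50", "1",
                     "50", "1e-20", "100", "100", "200"), collapse = "\t"),
             f)
  h <- read_blast_tab(f)
  expect_equal(h$qcov, 0.5)
  expect_equal(h$scov, 0.25)
  expect_equal(h$evalue, 1e-20)

  f12 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(paste(c("q1", "s1", "90.0", "50", "5", "0", "1", "50", "1",
                     "50", "1e-20", "100"), collapse = "\t"), f12)
  h2 <- read_blast_tab(f12, query_lengths = c(q1 = 100),
                       subject_lengths = c(s1 = 200))
  expect_equal(h2$qcov, 0.5)
  expect_error(read_blast_tab(f12, query_lengths = c(other = 1),
                              subject_lengths = c(s1 = 200)),
               "unknown query length q1")
})

test_that("tabular lines with wrong column counts are rejected by line", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(paste(rep("x", 11), collapse = "\t"), f)
  expect_error(read_blast_tab(f), "line 1: expected 12 or 14 columns")
})

test_that("GO annotations parse, de-duplicate and validate ids", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("p1\tGO:0019253;GO:0006006", "p2\tGO:0019253;GO:0019253"),
             f)
  ann <- read_go_annotations(f)
  expect_setequal(ann$terms$p1, c("GO:0019253", "GO:0006006"))
  expect_equal(ann$terms$p2, "GO:0019253")

  f2 <- withr::local_tempfile(fileext = ".tsv")
  writeLines("p1\tGO:19253", f2)
  expect_error(read_go_annotations(f2), "GO:19253")
})

test_that("GO term edges must be acyclic", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines("p1\tGO:0000001", f)
  fe <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("GO:0000001\tGO:0000002", "GO:0000002\tGO:0000003"), fe)
  ann <- read_go_annotations(f, edges_path = fe)
  expect_equal(nrow(ann$edges), 2L)
  fc <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("GO:0000001\tGO:0000002", "GO:0000002\tGO:0000001"), fc)
  expect_error(read_go_annotations(f, edges_path = fc), "cycle")
})

test_that("Newick trees parse with verbatim tips; errors carry position", {
  f <- withr::local_tempfile(fileext = ".nwk")
  writeLines("((a:1,b:2):0.5,c:3);", f)
  tr <- read_newick(f)
  expect_setequal(tr$tip.label, c("a", "b", "c"))
  term <- setNames(tr$edge.length[match(match(c("a", "b", "c"),
                                              tr$tip.label),
                                        tr$edge[, 2])], c("a", "b", "c"))
  expect_equal(term, c(a = 1, b = 2, c = 3))

  f2 <- withr::local_tempfile(fileext = ".nwk")
  writeLines("(a,b);", f2)
  expect_null(read_newick(f2)$edge.length)

  f3 <- withr::local_tempfile(fileext = ".nwk")
  writeLines("((a,b);", f3)
  expect_error(read_newick(f3), "unbalanced parentheses")
})
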