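test_that("local alignment reproduces hand-scored examples", {
  sw <- smith_waterman("ACDE", "ACDE")
  expect_equal(sw$score, 24)   # BLOSUM62 diagonal 4 + 9 + 6 + 5
  expect_equal(sw$aln_len, 4L)
  expect_equal(sw$identities, 4L)

  none <- smith_waterman("AAAA", "CCCC")
  expect_equal(none$score, 0)
  expect_equal(none$aln_len, 0L)

  expect_equal(smith_waterman("MKV", "MKV")$identities, 3L)
  expect_error(smith_waterman("", "MKV"), "empty sequence")
})

test_that("alignment scores match the plain-R affine DP oracle", {
  data(BLOSUM62, package = "Biostrings", envir = environment())
  aas <- c("A", "C", "D", "E", "K", "M", "V", "W")
  set.seed(17)
  for (i in 1:40) {
    a <- paste(sample(aas, sample(2:6, 1), replace = TRUE), collapse = "")
    b <- paste(sample(aas, sample(2:6, 1), replace = TRUE), collapse = "")
    expect_equal(smith_waterman(a, b)$score,
                 oracle_sw_score(a, b, BLOSUM62),
                 info = paste(a, b))
  }
})

test_that("alignment score is symmetric for symmetric matrices", {
  set.seed(18)
  aas <- rownames(Biostrings::AMINO_ACID_CODE)
  aas <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L", "K")
  for (i in 1:10) {
    a <- paste(sample(aas, 30, replace = TRUE), collapse = "")
    b <- paste(sample(aas, 25, replace = TRUE), collapse = "")
    expect_equal(smith_waterman(a, b)$score, smith_waterman(b, a)$score)
  }
})

test_that("hit filtering applies the e-value and mutual-coverage rules", {
  hits <- data.frame(
    query = "q", subject = "s",
    evalue = c(1e-2, 1e-5, 1e-5, 1e-5),
    score = 500,
    qcov = c(0.5, 0.30, 0.25, 0.5),
    scov = c(0.5, 0.15, 0.25, 0.5),
    stringsAsFactors = FALSE
  )
  kept <- filter_hits(hits)
  expect_equal(nrow(kept), 2L)          # rows 3 (boundary) and 4
  expect_equal(kept$qcov, c(0.25, 0.5)) # >= is inclusive
  # one-sided coverage mode admits the subject-coverage failure
  kept2 <- filter_hits(hits, require_subject_cov = FALSE)
  expect_equal(nrow(kept2), 3L)
  # raw-score path: e-value absent
  raw <- data.frame(query = "q", subject = "s", evalue = NA_real_,
                    score = c(120, 80), qcov = 0.9, scov = 0.9)
  expect_error(filter_hits(raw), "score_min")
  expect_equal(nrow(filter_hits(raw, score_min = 100)), 1L)
  raw$score <- NA_real_
  expect_error(filter_hits(raw, score_min = 100), "neither")
})

test_that("relaxing any filter threshold never removes a surviving hit", {
  set.seed(19)
  n <- 2000
  hits <- data.frame(
    query = sprintf("q%d", sample(20, n, TRUE)),
    subject = sprintf("s%d", sample(50, n, TRUE)),
    evalue = 10^runif(n, -30, 1),
    score = runif(n, 0, 500),
    qcov = runif(n), scov = runif(n),
    stringsAsFactors = FALSE
  )
  base <- filter_hits(hits, evalue_max = 1e-3, mutual_cov_min = 0.25)
  key <- function(h) paste(rownames(h), h$evalue, h$qcov, h$scov)
  for (args in list(list(evalue_max = 1e-1, mutual_cov_min = 0.25),
                    list(evalue_max = 1e-3, mutual_cov_min = 0.10),
                    list(evalue_max = 1, mutual_cov_min = 0))) {
    relaxed <- do.call(filter_hits, c(list(hits), args))
    expect_true(all(paste(base$evalue, base$qcov, base$scov) %in%
                      paste(relaxed$evalue, relaxed$qcov, relaxed$scov)))
  }
})

test_that("presence matrix reflects surviving hits and keeps support", {
  catalog <- data.frame(
    symbol = c("MER3", "HOP1"),
    query_ids = c("MER3_q1;MER3_q2", "HOP1_q1"),
    group = c("ZMM proteins", "synaptonemal complex"),
    meiosis_specific = TRUE, stringsAsFactors = FALSE
  )
  iso_map <- data.frame(prefix = c("X|", "Y|"), isolate = c("X", "Y"),
                        stringsAsFactors = FALSE)
  hits <- data.frame(
    query = c("MER3_q1", "MER3_q2"), subject = c("X|p1", "X|p1"),
    evalue = 1e-9, score = 300, qcov = 0.9, scov = 0.9,
    stringsAsFactors = FALSE
  )
  pm <- build_presence_matrix(hits, catalog, iso_map)
  m <- plain_presence(pm)
  expect_equal(m["MER3", "X"], 1L)
  expect_equal(m["MER3", "Y"], 0L)
  expect_true(all(m["HOP1", ] == 0L))   # no hits anywhere -> all absent
  sup <- attr(pm, "support")
  expect_equal(sum(sup$symbol == "MER3" & sup$isolate == "X"), 2L)

  bad <- hits; bad$subject <- "Z|p9"
  expect_error(build_presence_matrix(bad, catalog, iso_map),
               "unmapped subject id Z\\|p9")
  bad2 <- hits; bad2$query <- "NOVEL_q"
  expect_error(build_presence_matrix(bad2, catalog, iso_map),
               "not in catalog")
})

test_that("completeness counts complete plus fragmented orthologs", {
  expect_equal(completeness_score(c(rep("complete", 50),
                                    rep("fragmented", 10),
                                    rep("missing", 40))), 60)
  expect_equal(completeness_score(rep("missing", 7)), 0)
  expect_equal(completeness_score(rep("complete", 171)), 100)
  expect_error(completeness_score(character()), "empty")
  expect_error(completeness_score("partial"), "unknown")
})

test_that("the shipped seed catalog is a valid 42-gene table", {
  path <- system.file("extdata", "sex_gene_catalog.tsv",
                      package = "dinocodon")
  cat42 <- utils::read.delim(path, stringsAsFactors = FALSE)
  expect_equal(nrow(cat42), 42L)
  expect_equal(anyDuplicated(cat42$symbol), 0L)
  expect_true(all(c("symbol", "query_ids", "group",
                    "meiosis_specific") %in% names(cat42)))
  # it plugs straight into the presence-matrix builder
  iso <- data.frame(prefix = "X|", isolate = "X", stringsAsFactors = FALSE)
  hits <- data.frame(query = "MER3_q", subject = "X|p1", evalue = 1e-9,
                     score = 500, qcov = 0.9, scov = 0.9,
                     stringsAsFactors = FALSE)
  pm <- build_presence_matrix(hits, cat42, iso)
  expect_equal(plain_presence(pm)["MER3", "X"], 1L)
  expect_true(all(plain_presence(pm)[setdiff(cat42$symbol, "MER3"), ] == 0L))
})
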