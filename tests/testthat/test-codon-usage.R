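test_that("codon counting drops the terminal stop and skips ambiguity", {
  ct <- count_codons("ATGGCTGCTTAA")
  expect_equal(ct$total, 3L)
  expect_equal(unname(ct$counts[c("ATG", "GCT")]), c(1L, 2L))
  ct2 <- count_codons("ATGGNTGCT")
  expect_equal(ct2$skipped, 1L)
  expect_equal(ct2$total, 2L)
  expect_error(count_codons("ATGGC"), "length not multiple of 3")
  expect_true(count_codons("ATGTAGAAATAA")$internal_stop)
})

test_that("positional GC-content matches direct position counts", {
  cnt <- setNames(integer(61), sense_codons_for_tests())
  cnt[c("ATG", "GCT")] <- c(1L, 2L)
  gm <- gc_metrics(cnt)
  expect_equal(unname(gm["gc1"]), 200 / 3)
  expect_equal(unname(gm["gc2"]), 200 / 3)
  expect_equal(unname(gm["gc3"]), 100 / 3)
  expect_equal(unname(gm["gc_overall"]), 500 / 9)
  expect_equal(unname(gm["gc12"]), (gm[["gc1"]] + gm[["gc2"]]) / 2)

  all_gc <- cnt; all_gc[] <- 0L; all_gc["GGG"] <- 5L
  expect_true(all(gc_metrics(all_gc) == 100))
  no_gc <- cnt; no_gc[] <- 0L; no_gc["ATA"] <- 4L
  expect_true(all(gc_metrics(no_gc) == 0))
  expect_error(gc_metrics(no_gc * 0L), "empty")
})

test_that("GC3s covers synonymous families only", {
  cnt <- setNames(integer(61), sense_codons_for_tests())
  cnt[c("GCG", "GCT")] <- c(3L, 1L)
  expect_equal(gc3s(cnt), 75)
  met_trp <- cnt; met_trp[] <- 0L; met_trp[c("ATG", "TGG")] <- c(5L, 2L)
  expect_true(is.na(gc3s(met_trp)))
  lys <- cnt; lys[] <- 0L; lys[c("AAA", "AAG")] <- c(2L, 2L)
  expect_equal(gc3s(lys), 50)
})

test_that("family homozygosity follows Wright's estimator", {
  expect_equal(family_homozygosity(c(3, 1)), 0.5)
  expect_equal(family_homozygosity(c(2, 2)), 1 / 3)
  expect_equal(family_homozygosity(5), 1)
  expect_true(is.na(family_homozygosity(c(1, 0))))
})

test_that("Nc reproduces hand-worked values and the one-codon floor", {
  # one codon per family, count 2 each: every F = 1, Nc = 2+9+1+5+3
  tab <- codon_table("1")
  tab <- tab[!tab$stop, ]
  one_per_fam <- vapply(split(tab$codon, tab$aa), `[`, character(1), 1L)
  cnt <- setNames(integer(61), sense_codons_for_tests())
  cnt[one_per_fam] <- 2L
  expect_equal(effective_number_of_codons(cnt)$nc, 20)

  # Lys(3,1) Asp(2,2) Ile(2,1,1) Ala(2,0,0,2) Leu(2,0,2,0,0,0)
  cnt2 <- setNames(integer(61), sense_codons_for_tests())
  cnt2[c("AAA", "AAG")] <- c(3L, 1L)
  cnt2[c("GAT", "GAC")] <- c(2L, 2L)
  cnt2[c("ATT", "ATC", "ATA")] <- c(2L, 1L, 1L)
  cnt2[c("GCT", "GCG")] <- c(2L, 2L)
  cnt2[c("CTT", "CTG")] <- c(2L, 2L)
  enc <- effective_number_of_codons(cnt2)
  expect_equal(enc$nc, 53.6)
  expect_true("short" %in% enc$flags)

  # uniform synonymous usage on a long gene approaches (and is capped at) 61
  cnt3 <- setNames(integer(61), sense_codons_for_tests())
  for (fam in split(tab$codon, tab$aa)) {
    cnt3[fam] <- 600L %/% length(fam)
  }
  enc3 <- effective_number_of_codons(cnt3)
  expect_equal(enc3$nc, 61)
  expect_true("capped" %in% enc3$flags)
})

test_that("Nc handles missing families per Wright's conventions", {
  cnt <- setNames(integer(61), sense_codons_for_tests())
  cnt[c("AAA", "AAG")] <- c(4L, 4L)              # 2-fold
  cnt[c("GCT", "GCC", "GCA", "GCG")] <- 2L       # 4-fold
  cnt[c("CTT", "CTC")] <- 2L                     # 6-fold
  # no Ile observed: the 3-fold class is imputed as (F2bar + F4bar)/2
  enc <- effective_number_of_codons(cnt)
  F2 <- family_homozygosity(c(4, 4))
  F4 <- family_homozygosity(c(2, 2, 2, 2))
  F6 <- family_homozygosity(c(2, 2, 0, 0, 0, 0))
  raw <- 2 + 9 / F2 + 1 / ((F2 + F4) / 2) + 5 / F4 + 3 / F6
  expect_equal(enc$nc, min(raw, 61))
  # with the 6-fold class also unobserved, Nc is undefined and flagged
  cnt[c("CTT", "CTC")] <- 0L
  enc6 <- effective_number_of_codons(cnt)
  expect_true(is.na(enc6$nc))
  expect_true("missing_family" %in% enc6$flags)
})

test_that("expected Nc curve has the closed-form values and maximum", {
  expect_equal(expected_enc(0), 31)
  expect_equal(expected_enc(1), 32)
  expect_equal(expected_enc(0.5), 60.5)
  expect_error(expected_enc(1.2), "\\[0, 1\\]")
  # the linear +s term tilts the peak slightly above s = 0.5: on a fine
  # grid the maximum sits within a few thousandths of 0.5, just above 60.5
  s <- seq(0, 1, by = 0.001)
  v <- expected_enc(s)
  expect_lt(abs(s[which.max(v)] - 0.5), 0.005)
  expect_gte(max(v), 60.5)
  expect_lt(max(v), 60.51)
})

test_that("RSCU matches uniform/skewed family examples", {
  cnt <- setNames(integer(61), sense_codons_for_tests())
  cnt[c("GCT", "GCC", "GCA", "GCG")] <- 3L       # 4-fold uniform
  cnt[c("AAA", "AAG")] <- c(2L, 0L)              # 2-fold skewed
  cnt[c("CTT", "CTC", "CTA", "CTG", "TTA", "TTG")] <- c(6L, 0L, 0L, 0L,
                                                        0L, 0L)
  r <- rscu(cnt)
  expect_equal(unname(r[c("GCT", "GCC", "GCA", "GCG")]), rep(1, 4))
  expect_equal(unname(r[c("AAA", "AAG")]), c(2, 0))
  expect_equal(unname(r["CTT"]), 6)
  expect_equal(length(r), 59L)
})

test_that("mean RSCU within every observed family is exactly 1", {
  set.seed(5)
  for (i in 1:20) {
    ct <- count_codons(random_gene(sample(20:200, 1)))
    r <- rscu(ct)
    fams <- split(names(r), codon_table("1")$aa[match(names(r),
                                                      codon_table("1")$codon)])
    for (fam in fams) {
      if (sum(ct$counts[fam]) > 0) {
        expect_equal(mean(r[fam]), 1)
      }
    }
  }
})

test_that("preference classification applies strict thresholds", {
  prof <- data.frame(
    nc = c(30, 35.5, 61, NA),
    gc3s = c(50, 50, 50, 50),
    gc12 = c(20, 20, 48, 48),
    gc3 = c(80, 80, 50, 50)
  )
  cls <- classify_preference(prof)
  # row 2: distance exactly 25 is not strong (strict >); row 4: undefined
  # Nc forces "other" even on the diagonal
  expect_equal(cls, c("strong_preference", "other", "neutral", "other"))
})

test_that("raising the curve threshold never adds strong calls", {
  set.seed(9)
  prof <- data.frame(
    nc = runif(300, 20, 61), gc3s = runif(300, 0, 100),
    gc12 = runif(300, 0, 100), gc3 = runif(300, 0, 100)
  )
  strong_at <- function(th) {
    which(classify_preference(prof, curve_threshold = th) ==
            "strong_preference")
  }
  prev <- strong_at(0)
  for (th in c(5, 15, 25, 35)) {
    cur <- strong_at(th)
    expect_true(all(cur %in% prev))
    prev <- cur
  }
})

test_that("Nc stays within [20, 61] and gc12 is the mean of gc1, gc2", {
  set.seed(31)
  for (i in 1:50) {
    ct <- count_codons(random_gene(sample(10:400, 1)))
    enc <- effective_number_of_codons(ct)
    if (!is.na(enc$nc)) {
      expect_gte(enc$nc, 20)
      expect_lte(enc$nc, 61)
    }
    gm <- gc_metrics(ct)
    expect_equal(unname(gm["gc12"]), (gm[["gc1"]] + gm[["gc2"]]) / 2)
    expect_true(all(gm >= 0 & gm <= 100))
  }
})

test_that("codon_usage assembles profiles and excludes internal stops", {
  set.seed(13)
  recs <- generate_cds_set(6, 120, alpha = 1, seed = 4)$records
  broken <- data.frame(id = "bad", desc = "",
                       seq = "ATGTAGAAAAAAAAAAAAAAATAA",
                       stringsAsFactors = FALSE)
  expect_warning(cu <- codon_usage(rbind(recs, broken), min_codons = 50),
                 "internal stop")
  expect_equal(cu$dropped, "bad")
  expect_equal(nrow(cu$profiles), 6L)
  expect_true(all(c("nc", "gc3s", "curve_distance", "neutrality_distance",
                    "preference_class") %in% names(cu$profiles)))
  expect_equal(cu$profiles$neutrality_distance,
               abs(cu$profiles$gc12 - cu$profiles$gc3))
})
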