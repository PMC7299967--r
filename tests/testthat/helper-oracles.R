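# Independent oracles used by the test suite. These deliberately avoid the
# package's own code paths: codon-to-amino-acid mapping comes from seqinr,
# the alignment oracle is a plain-R affine-gap DP, and the Fisher oracle
# enumerates draws explicitly.

# --- ENC oracle -----------------------------------------------------------
# Wright's estimator evaluated directly from a codon string, with the same
# published conventions (class means over families with n >= 2; 3-fold
# class imputed as (F2bar + F4bar)/2; undefined if any other class is
# missing or a class mean is zero; capped at 61).
.oracle_all_cod <- apply(expand.grid(c("T", "C", "A", "G"),
                                     c("T", "C", "A", "G"),
                                     c("T", "C", "A", "G"),
                                     stringsAsFactors = FALSE),
                         1, paste, collapse = "")
.oracle_codon_aa <- setNames(
  vapply(.oracle_all_cod, function(cd) {
    seqinr::translate(strsplit(cd, "")[[1]])
  }, character(1)),
  .oracle_all_cod
)

oracle_enc <- function(codon_string) {
  cods <- substring(codon_string, seq(1, nchar(codon_string), 3),
                    seq(3, nchar(codon_string), 3))
  aa <- unname(.oracle_codon_aa[cods])
  keep <- aa != "*"
  cods <- cods[keep]; aa <- aa[keep]
  fam_size <- table(.oracle_codon_aa[.oracle_codon_aa != "*"])
  Fhat <- list()
  for (a in unique(aa)) {
    n <- sum(aa == a)
    if (n < 2) next
    p <- table(cods[aa == a]) / n
    Fhat[[a]] <- (n * sum(p^2) - 1) / (n - 1)
  }
  ks <- c(`1` = NA, `2` = NA, `3` = NA, `4` = NA, `6` = NA)
  Nk <- table(fam_size)
  Fbar <- sapply(names(Nk), function(k) {
    fams <- names(fam_size)[fam_size == as.integer(k)]
    vals <- unlist(Fhat[intersect(fams, names(Fhat))])
    if (length(vals)) mean(vals) else NA_real_
  })
  if (is.na(Fbar[["3"]]) && !is.na(Fbar[["2"]]) && !is.na(Fbar[["4"]])) {
    Fbar[["3"]] <- (Fbar[["2"]] + Fbar[["4"]]) / 2
  }
  contrib <- Fbar[names(Fbar) != "1"]
  if (anyNA(contrib) || any(contrib <= 0)) return(NA_real_)
  nc <- unname(Nk[["1"]]) +
    sum(as.numeric(Nk[names(contrib)]) / contrib)
  min(nc, 61)
}

# random sense-codon gene (no stops, pure ACGT), length in codons
random_gene <- function(n_codons) {
  sense <- dinocodon::codon_table("1")
  sense <- sense$codon[!sense$stop]
  paste(sample(sense, n_codons, replace = TRUE), collapse = "")
}

# --- Smith-Waterman oracle ------------------------------------------------
# Plain-R affine-gap local alignment DP (Gotoh). A gap of length L costs
# gap_open + L * gap_extend, matching the package contract.
oracle_sw_score <- function(a, b, mat, gap_open = 11, gap_extend = 1) {
  A <- strsplit(a, "")[[1]]
  B <- strsplit(b, "")[[1]]
  n <- length(A); m <- length(B)
  H <- matrix(0, n + 1, m + 1)
  E <- matrix(-Inf, n + 1, m + 1)  # gap in A (move along B)
  Fm <- matrix(-Inf, n + 1, m + 1) # gap in B
  best <- 0
  for (i in 2:(n + 1)) {
    for (j in 2:(m + 1)) {
      E[i, j] <- max(H[i, j - 1] - (gap_open + gap_extend),
                     E[i, j - 1] - gap_extend)
      Fm[i, j] <- max(H[i - 1, j] - (gap_open + gap_extend),
                      Fm[i - 1, j] - gap_extend)
      H[i, j] <- max(0,
                     H[i - 1, j - 1] + mat[A[i - 1], B[j - 1]],
                     E[i, j], Fm[i, j])
      best <- max(best, H[i, j])
    }
  }
  best
}

# --- Fisher oracle --------------------------------------------------------
# Upper-tail probability by explicit enumeration of all C(N, n) draws.
oracle_fisher_upper <- function(k, n, K, N) {
  draws <- utils::combn(N, n)
  hits <- colSums(draws <= K)  # items 1..K carry the term
  mean(hits >= k)
}
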