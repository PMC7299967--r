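# Per-CDS codon statistics: positional GC, GC3s, Wright's effective number
# of codons (Nc), RSCU, the neutral Nc-GC3s expectation and the two
# bias classifiers (curve distance and neutrality-plot distance).

#' Count codons of one coding sequence
#'
#' Codons are read in frame 0. A terminal stop codon is excluded; codons
#' containing non-ACGT characters are skipped and tallied; internal stop
#' codons set a flag (stop codons are never counted).
#'
#' @param record A nucleotide sequence string, or a one-row record
#'   data.frame as produced by [read_fasta()].
#' @param code Genetic code id.
#' @param id Optional sequence id when `record` is a bare string.
#' @return An object of class `codon_counts`: list with `id`, `counts`
#'   (named integer vector over the sense codons), `total`, `skipped`,
#'   `internal_stop`, `code`.
#' @export
count_codons <- function(record, code = "1", id = NULL) {
  if (is.data.frame(record)) {
    stopifnot(nrow(record) == 1L)
    id <- record$id
    s <- record$seq
  } else {
    s <- as.character(record)
    if (is.null(id)) id <- NA_character_
  }
  s <- toupper(s)
  n <- nchar(s)
  if (n %% 3L != 0L) {
    stop("length not multiple of 3", if (!is.na(id)) paste0(" for ", id))
  }
  cod <- substring(s, seq(1L, n, 3L), seq(3L, n, 3L))
  stops <- stop_codons(code)
  if (length(cod) && cod[length(cod)] %in% stops) cod <- cod[-length(cod)]
  valid <- grepl("^[ACGT]{3}$", cod)
  skipped <- sum(!valid)
  cod <- cod[valid]
  internal_stop <- any(cod %in% stops)
  cod <- cod[!(cod %in% stops)]
  counts <- table(factor(cod, levels = sense_codons(code)))
  counts <- setNames(as.integer(counts), names(counts))
  structure(
    list(id = id, counts = counts, total = sum(counts),
         skipped = skipped, internal_stop = internal_stop,
         code = as.character(code)),
    class = "codon_counts"
  )
}

.as_counts_vector <- function(counts) {
  if (inherits(counts, "codon_counts")) counts$counts else counts
}

#' Positional GC-content of a codon count vector
#'
#' @param counts A `codon_counts` object (or named codon count vector).
#' @param code Genetic code id (taken from `counts` when available).
#' @return Named numeric vector with `gc_overall`, `gc1`, `gc2`, `gc3`,
#'   `gc12`, all percentages in \[0, 100\].
#' @export
gc_metrics <- function(counts, code = if (inherits(counts, "codon_counts"))
                         counts$code else "1") {
  cnt <- .as_counts_vector(counts)
  total <- sum(cnt)
  if (total < 1) stop("empty codon counts")
  tab <- codon_table(code)
  tab <- tab[match(names(cnt), tab$codon), ]
  gc_at <- function(p) 100 * sum(cnt[tab[[p]] %in% c("G", "C")]) / total
  gc1 <- gc_at("p1"); gc2 <- gc_at("p2"); gc3 <- gc_at("p3")
  c(gc_overall = (gc1 + gc2 + gc3) / 3, gc1 = gc1, gc2 = gc2, gc3 = gc3,
    gc12 = (gc1 + gc2) / 2)
}

#' GC-content at synonymous third codon positions (GC3s)
#'
#' Computed over codons of amino acids with at least two synonymous codons
#' (Met, Trp and stops excluded), as a percentage. Undefined (`NA`) when no
#' synonymous codon was observed.
#'
#' @inheritParams gc_metrics
#' @return Percentage in \[0, 100\], or `NA_real_`.
#' @export
gc3s <- function(counts, code = if (inherits(counts, "codon_counts"))
                   counts$code else "1") {
  cnt <- .as_counts_vector(counts)
  syn <- intersect(names(cnt), synonymous_codons(code))
  m <- sum(cnt[syn])
  if (m == 0) return(NA_real_)
  tab <- codon_table(code)
  p3 <- tab$p3[match(syn, tab$codon)]
  100 * sum(cnt[syn][p3 %in% c("G", "C")]) / m
}

#' Codon homozygosity of one synonymous family
#'
#' Wright's unbiased estimator of the probability that two randomly drawn
#' codons of the family are identical:
#' \eqn{F = (n \sum p_i^2 - 1) / (n - 1)} with \eqn{p_i} the observed codon
#' proportions and \eqn{n} the family total.
#'
#' @param family_counts Non-negative integer counts of the family's codons.
#' @return `F` in \[0, 1\], or `NA_real_` when `n < 2`.
#' @export
family_homozygosity <- function(family_counts) {
  n <- sum(family_counts)
  if (n < 2) return(NA_real_)
  p <- family_counts / n
  (n * sum(p^2) - 1) / (n - 1)
}

#' Wright's effective number of codons (Nc)
#'
#' Families are grouped by degeneracy k; the class mean homozygosity
#' \eqn{\bar F_k} averages families with n >= 2 observations. Under the
#' standard code \eqn{N_c = 2 + 9/\bar F_2 + 1/\bar F_3 + 5/\bar F_4 +
#' 3/\bar F_6}. If the 3-fold class is missing it is imputed as
#' \eqn{(\bar F_2 + \bar F_4)/2}; any other missing class leaves Nc
#' undefined (flag `missing_family`). Nc is capped at 61. Genes with fewer
#' than `min_codons` counted codons are flagged `short` but not excluded.
#'
#' @inheritParams gc_metrics
#' @param min_codons Flag threshold for short genes (default 100).
#' @return List with `nc` (numeric or `NA`) and `flags` (character vector).
#' @export
effective_number_of_codons <- function(counts,
                                       code = if (inherits(counts, "codon_counts"))
                                         counts$code else "1",
                                       min_codons = 100L) {
  cnt <- .as_counts_vector(counts)
  flags <- character()
  if (sum(cnt) < min_codons) flags <- c(flags, "short")
  if (inherits(counts, "codon_counts") && counts$internal_stop) {
    flags <- c(flags, "internal_stop")
  }
  tab <- codon_table(code)
  tab <- tab[!tab$stop, ]
  fams <- split(tab$codon, tab$aa)
  deg <- lengths(fams)
  n_single <- sum(deg == 1L)
  ks <- sort(unique(deg[deg >= 2L]))
  Fbar <- setNames(rep(NA_real_, length(ks)), ks)
  Nk <- setNames(integer(length(ks)), ks)
  for (k in ks) {
    members <- fams[deg == k]
    Nk[[as.character(k)]] <- length(members)
    Fs <- vapply(members, function(cd) family_homozygosity(cnt[cd]),
                 numeric(1))
    Fs <- Fs[!is.na(Fs)]
    if (length(Fs)) Fbar[[as.character(k)]] <- mean(Fs)
  }
  # Wright's imputation for the 3-fold (Ile) class
  if ("3" %in% names(Fbar) && is.na(Fbar[["3"]]) &&
      all(c("2", "4") %in% names(Fbar)) &&
      !is.na(Fbar[["2"]]) && !is.na(Fbar[["4"]])) {
    Fbar[["3"]] <- (Fbar[["2"]] + Fbar[["4"]]) / 2
  }
  if (anyNA(Fbar)) {
    return(list(nc = NA_real_, flags = c(flags, "missing_family")))
  }
  if (any(Fbar <= 0)) {
    return(list(nc = NA_real_, flags = c(flags, "zero_homozygosity")))
  }
  nc <- n_single + sum(Nk / Fbar)
  if (nc > 61) {
    nc <- 61
    flags <- c(flags, "capped")
  }
  list(nc = nc, flags = flags)
}

#' Expected Nc under neutral evolution
#'
#' The neutral expectation of the effective number of codons as a function
#' of GC3s: \eqn{N_c = 2 + s + 29/(s^2 + (1-s)^2)}.
#'
#' @param s GC3s as a fraction in \[0, 1\] (vectorised).
#' @return Expected Nc.
#' @export
expected_enc <- function(s) {
  s <- as.numeric(s)
  if (anyNA(s) || any(s < 0 | s > 1)) stop("s must lie in [0, 1]")
  2 + s + 29 / (s^2 + (1 - s)^2)
}

#' Relative synonymous codon usage (RSCU)
#'
#' For codon j of a k-fold family with family total m > 0,
#' RSCU = count_j / (m / k). Families with m = 0 yield RSCU 0 for all their
#' codons (reported in the `zero_families` attribute). Met, Trp and stop
#' codons are excluded.
#'
#' @inheritParams gc_metrics
#' @return Named numeric vector over the 59 synonymous sense codons, with
#'   attribute `zero_families` naming unobserved families.
#' @export
rscu <- function(counts, code = if (inherits(counts, "codon_counts"))
                   counts$code else "1") {
  cnt <- .as_counts_vector(counts)
  fams <- synonymous_families(code)
  out <- setNames(numeric(0), character(0))
  zero <- character()
  for (aa in names(fams)) {
    cd <- fams[[aa]]
    x <- cnt[cd]
    x[is.na(x)] <- 0
    m <- sum(x)
    if (m == 0) {
      zero <- c(zero, aa)
      vals <- setNames(rep(0, length(cd)), cd)
    } else {
      vals <- setNames(x * length(cd) / m, cd)
    }
    out <- c(out, vals)
  }
  out <- out[synonymous_codons(code)]
  attr(out, "zero_families") <- zero
  out
}

#' Classify codon-usage preference of gene profiles
#'
#' A gene shows strong codon-usage preference when its Nc lies strictly more
#' than `curve_threshold` units below the neutral expectation at its GC3s;
#' otherwise it is neutral when strictly closer than `neutral_threshold`
#' percentage points to the GC12 = GC3 diagonal; otherwise `other`. Genes
#' with undefined Nc or GC3s are classified `other`.
#'
#' @param profile Data.frame with columns `nc`, `gc3s`, `gc12`, `gc3`
#'   (e.g. the `profiles` table of a [codon_usage()] object).
#' @param curve_threshold Nc units below the expected curve (default 25).
#' @param neutral_threshold GC percentage points from the diagonal
#'   (default 5).
#' @return Character vector over `{strong_preference, neutral, other}`.
#' @export
classify_preference <- function(profile, curve_threshold = 25,
                                neutral_threshold = 5) {
  stopifnot(all(c("nc", "gc3s", "gc12", "gc3") %in% names(profile)))
  n <- nrow(profile)
  out <- rep("other", n)
  defined <- !is.na(profile$nc) & !is.na(profile$gc3s)
  curve_dist <- rep(NA_real_, n)
  curve_dist[defined] <- expected_enc(profile$gc3s[defined] / 100) -
    profile$nc[defined]
  strong <- defined & curve_dist > curve_threshold
  neut <- defined & !strong & !is.na(profile$gc12) & !is.na(profile$gc3) &
    abs(profile$gc12 - profile$gc3) < neutral_threshold
  out[strong] <- "strong_preference"
  out[neut] <- "neutral"
  out
}

#' Codon usage profiles for a set of coding sequences
#'
#' The main per-CDS analysis: codon counts, positional GC, GC3s, Nc, the
#' neutral-curve expectation and distance, the neutrality-plot distance
#' |GC12 - GC3|, and the preference class of every gene.
#'
#' @param x A FASTA path or a record data.frame as from [read_fasta()].
#' @param code Genetic code id.
#' @param min_codons Short-gene flag threshold (codons).
#' @param curve_threshold,neutral_threshold Classification thresholds; see
#'   [classify_preference()].
#' @param exclude_internal_stop Drop genes with internal stop codons from
#'   the statistics (default TRUE); they are reported in `dropped`.
#' @return Object of class `codon_usage`: list with `profiles` (one row per
#'   CDS), `counts` (list of `codon_counts`), `dropped`, `params`.
#' @export
codon_usage <- function(x, code = "1", min_codons = 100L,
                        curve_threshold = 25, neutral_threshold = 5,
                        exclude_internal_stop = TRUE) {
  records <- if (is.character(x) && length(x) == 1L) read_fasta(x) else x
  stopifnot(is.data.frame(records), nrow(records) >= 1L)
  counts <- lapply(seq_len(nrow(records)), function(i) {
    count_codons(records$seq[i], code = code, id = records$id[i])
  })
  names(counts) <- records$id
  dropped <- character()
  if (exclude_internal_stop) {
    bad <- vapply(counts, `[[`, logical(1), "internal_stop")
    dropped <- names(counts)[bad]
    if (length(dropped)) {
      warning(length(dropped), " gene(s) with internal stop codons excluded")
      counts <- counts[!bad]
    }
  }
  if (length(counts) == 0L) stop("no usable coding sequences")
  prof <- do.call(rbind, lapply(counts, function(ct) {
    gm <- gc_metrics(ct)
    g3s <- gc3s(ct)
    enc <- effective_number_of_codons(ct, min_codons = min_codons)
    nc_exp <- if (!is.na(g3s)) expected_enc(g3s / 100) else NA_real_
    data.frame(
      id = ct$id,
      gc_overall = gm[["gc_overall"]], gc1 = gm[["gc1"]], gc2 = gm[["gc2"]],
      gc3 = gm[["gc3"]], gc12 = gm[["gc12"]], gc3s = g3s,
      nc = enc$nc, nc_expected = nc_exp,
      curve_distance = if (!is.na(enc$nc) && !is.na(nc_exp))
        nc_exp - enc$nc else NA_real_,
      neutrality_distance = abs(gm[["gc12"]] - gm[["gc3"]]),
      n_codons = ct$total, skipped = ct$skipped,
      flags = paste(enc$flags, collapse = ","),
      stringsAsFactors = FALSE
    )
  }))
  rownames(prof) <- NULL
  prof$preference_class <- classify_preference(
    prof, curve_threshold = curve_threshold,
    neutral_threshold = neutral_threshold
  )
  structure(
    list(profiles = prof, counts = counts, dropped = dropped,
         params = list(code = as.character(code), min_codons = min_codons,
                       curve_threshold = curve_threshold,
                       neutral_threshold = neutral_threshold)),
    class = "codon_usage"
  )
}

#' @export
print.codon_usage <- function(x, ...) {
  p <- x$profiles
  cat("Codon usage profiles:", nrow(p), "CDS\n")
  cat(sprintf("  mean GC %% %.1f | mean GC3s %% %.1f | mean Nc %.1f\n",
              mean(p$gc_overall), mean(p$gc3s, na.rm = TRUE),
              mean(p$nc, na.rm = TRUE)))
  cls <- table(p$preference_class)
  cat("  classes:", paste(sprintf("%s=%d", names(cls), cls), collapse = ", "),
      "\n")
  if (length(x$dropped)) {
    cat("  dropped (internal stop):", length(x$dropped), "\n")
  }
  invisible(x)
}

#' @export
summary.codon_usage <- function(object, ...) {
  p <- object$profiles
  out <- list(
    n = nrow(p),
    class_counts = table(p$preference_class),
    gc = summary(p$gc_overall), gc3s = summary(p$gc3s),
    nc = summary(p$nc),
    n_short = sum(grepl("short", p$flags)),
    n_undefined_nc = sum(is.na(p$nc)),
    params = object$params
  )
  class(out) <- "summary.codon_usage"
  out
}

#' @export
print.summary.codon_usage <- function(x, ...) {
  cat("Codon usage over", x$n, "CDS\n")
  cat("Preference classes:\n"); print(x$class_counts)
  cat("Nc:\n"); print(x$nc)
  cat("GC3s (%):\n"); print(x$gc3s)
  cat("short genes:", x$n_short, "| undefined Nc:", x$n_undefined_nc, "\n")
  invisible(x)
}

#' Plot Nc against GC3s or the neutrality plane
#'
#' `which = 1` draws Nc versus GC3s with the neutral expectation curve;
#' `which = 2` draws GC12 versus GC3 with the y = x diagonal and the OLS
#' trend line.
#'
#' @param x A `codon_usage` object.
#' @param which Panel selection, 1 and/or 2.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.codon_usage <- function(x, which = 1L, ...) {
  p <- x$profiles
  if (1L %in% which) {
    graphics::plot(p$gc3s, p$nc, xlab = "GC3s (%)", ylab = "Nc",
                   xlim = c(0, 100), ylim = c(20, 61),
                   col = ifelse(p$preference_class == "strong_preference",
                                "firebrick", "grey40"), ...)
    s <- seq(0, 1, by = 0.005)
    graphics::lines(100 * s, expected_enc(s), lwd = 2)
  }
  if (2L %in% which) {
    graphics::plot(p$gc3, p$gc12, xlab = "GC3 (%)", ylab = "GC12 (%)",
                   xlim = c(0, 100), ylim = c(0, 100), col = "grey40", ...)
    graphics::abline(0, 1, lty = 2)
    fit <- stats::lm(gc12 ~ gc3, data = p)
    graphics::abline(fit, col = "red", lwd = 2)
  }
  invisible(x)
}
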