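# Correspondence analysis of the gene x codon RSCU matrix.

#' Assemble the gene x codon RSCU matrix
#'
#' One row per gene, columns the 59 synonymous sense codons in fixed order.
#' Genes with zero counted codons are dropped with a warning.
#'
#' @param counts_list List of `codon_counts` objects (e.g. the `counts`
#'   element of a [codon_usage()] object, or the object itself).
#' @param code Genetic code id.
#' @return Numeric matrix with gene ids as rownames.
#' @export
build_rscu_matrix <- function(counts_list, code = "1") {
  if (inherits(counts_list, "codon_usage")) {
    code <- counts_list$params$code
    counts_list <- counts_list$counts
  }
  stopifnot(length(counts_list) >= 2L)
  usable <- vapply(counts_list, function(ct) sum(.as_counts_vector(ct)) > 0,
                   logical(1))
  if (any(!usable)) {
    warning(sum(!usable), " gene(s) with zero counted codons dropped")
    counts_list <- counts_list[usable]
  }
  if (length(counts_list) < 2L) stop("fewer than 2 usable genes")
  m <- t(vapply(counts_list, function(ct) as.numeric(rscu(ct, code = code)),
                numeric(length(synonymous_codons(code)))))
  colnames(m) <- synonymous_codons(code)
  ids <- vapply(counts_list, function(ct) {
    if (inherits(ct, "codon_counts")) ct$id else NA_character_
  }, character(1))
  if (anyNA(ids)) ids <- names(counts_list)
  rownames(m) <- ids
  m
}

#' Correspondence analysis of a non-negative matrix
#'
#' Standard (chi-square metric) correspondence analysis: the matrix is
#' normalised to proportions P with row masses r and column masses c; the
#' standardised residual matrix
#' \eqn{S = D_r^{-1/2} (P - r c^T) D_c^{-1/2}} is decomposed by SVD. The
#' inertia of each axis is its squared singular value; relative inertia is
#' the fraction of total inertia; principal coordinates are the mass-scaled
#' singular vectors times the singular values.
#'
#' @param m Non-negative numeric matrix (genes x codons) with at least two
#'   rows and a positive grand total. Zero-mass rows/columns are dropped.
#' @return Object of class `rscu_ca`: `singular_values`, `inertia`,
#'   `relative_inertia`, `row_coords`, `col_coords`, `row_mass`, `col_mass`,
#'   `n_axes`, `degenerate`.
#' @export
correspondence_analysis <- function(m) {
  m <- as.matrix(m)
  stopifnot(nrow(m) >= 2L, all(m >= 0))
  total <- sum(m)
  if (total <= 0) stop("matrix grand total must be positive")
  rs <- rowSums(m); cs <- colSums(m)
  if (any(rs == 0)) m <- m[rs > 0, , drop = FALSE]
  if (any(cs == 0)) m <- m[, colSums(m) > 0, drop = FALSE]
  if (nrow(m) < 2L) stop("fewer than 2 non-empty rows")
  P <- m / sum(m)
  r <- rowSums(P); cc <- colSums(P)
  E <- outer(r, cc)
  S <- (P - E) / sqrt(E)
  sv <- svd(S)
  d <- sv$d
  tol <- max(dim(S)) * .Machine$double.eps * max(d, 0)
  keep <- which(d > max(tol, max(d) * 1e-8))
  if (length(keep) == 0L) {
    return(structure(
      list(singular_values = numeric(0), inertia = numeric(0),
           relative_inertia = numeric(0),
           row_coords = matrix(numeric(0), nrow(m), 0,
                               dimnames = list(rownames(m), NULL)),
           col_coords = matrix(numeric(0), ncol(m), 0,
                               dimnames = list(colnames(m), NULL)),
           row_mass = r, col_mass = cc, n_axes = 0L, degenerate = TRUE),
      class = "rscu_ca"
    ))
  }
  d <- d[keep]
  inertia <- d^2
  row_coords <- sweep(sv$u[, keep, drop = FALSE] / sqrt(r), 2L, d, `*`)
  col_coords <- sweep(sv$v[, keep, drop = FALSE] / sqrt(cc), 2L, d, `*`)
  dimnames(row_coords) <- list(rownames(m),
                               paste0("axis", seq_along(keep)))
  dimnames(col_coords) <- list(colnames(m),
                               paste0("axis", seq_along(keep)))
  structure(
    list(singular_values = d, inertia = inertia,
         relative_inertia = inertia / sum(inertia),
         row_coords = row_coords, col_coords = col_coords,
         row_mass = r, col_mass = cc,
         n_axes = length(keep), degenerate = FALSE),
    class = "rscu_ca"
  )
}

#' @export
print.rscu_ca <- function(x, ...) {
  if (x$degenerate) {
    cat("Correspondence analysis: degenerate (total inertia 0)\n")
    return(invisible(x))
  }
  cat("Correspondence analysis:", nrow(x$row_coords), "genes,",
      nrow(x$col_coords), "codons,", x$n_axes, "axes\n")
  k <- min(5L, x$n_axes)
  for (i in seq_len(k)) {
    cat(sprintf("  axis %d: inertia %.5f (%.1f%%)\n", i, x$inertia[i],
                100 * x$relative_inertia[i]))
  }
  invisible(x)
}

#' @export
plot.rscu_ca <- function(x, ...) {
  if (x$degenerate || x$n_axes < 2L) stop("need at least 2 axes to plot")
  graphics::plot(x$row_coords[, 1L], x$row_coords[, 2L],
                 xlab = sprintf("Axis 1 (%.1f%%)",
                                100 * x$relative_inertia[1L]),
                 ylab = sprintf("Axis 2 (%.1f%%)",
                                100 * x$relative_inertia[2L]),
                 col = "grey40", ...)
  graphics::abline(h = 0, v = 0, lty = 3)
  invisible(x)
}
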