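# Neutrality-plot analysis: OLS of GC12 on GC3, quadrant occupancy and
# per-gene distance from the y = x diagonal.

#' Neutrality-plot fit (GC12 on GC3)
#'
#' Ordinary least squares of GC12 on GC3 over all genes with both values
#' defined, plus the proportion of genes in each quadrant of the GC plane
#' (split at 50% on each axis; values of exactly 50% count as low). A slope
#' near 1 indicates mutation-driven (neutral) evolution of GC-content; a
#' shallow slope indicates selection on third codon positions.
#'
#' @param x A `codon_usage` object or a data.frame with columns `gc3`,
#'   `gc12`.
#' @return Object of class `neutrality_fit`: `slope`, `intercept`,
#'   `quadrants` (named proportions summing to 1), `n`, `distances`
#'   (|GC12 - GC3| per gene), `model` (the underlying [stats::lm] fit).
#' @export
neutrality_analysis <- function(x) {
  p <- if (inherits(x, "codon_usage")) x$profiles else x
  stopifnot(is.data.frame(p), all(c("gc3", "gc12") %in% names(p)))
  ok <- !is.na(p$gc3) & !is.na(p$gc12)
  p <- p[ok, , drop = FALSE]
  if (nrow(p) < 2L) stop("need at least 2 genes with defined GC3 and GC12")
  if (length(unique(p$gc3)) < 2L) {
    stop("slope undefined: all GC3 values identical")
  }
  fit <- stats::lm(gc12 ~ gc3, data = p)
  hi3 <- p$gc3 > 50
  hi12 <- p$gc12 > 50
  quad <- c(
    high_gc3_high_gc12 = mean(hi3 & hi12),
    high_gc3_low_gc12 = mean(hi3 & !hi12),
    low_gc3_high_gc12 = mean(!hi3 & hi12),
    low_gc3_low_gc12 = mean(!hi3 & !hi12)
  )
  structure(
    list(slope = unname(stats::coef(fit)[2L]),
         intercept = unname(stats::coef(fit)[1L]),
         quadrants = quad, n = nrow(p),
         distances = setNames(abs(p$gc12 - p$gc3),
                              if ("id" %in% names(p)) p$id else NULL),
         model = fit),
    class = "neutrality_fit"
  )
}

#' @export
print.neutrality_fit <- function(x, ...) {
  cat(sprintf("Neutrality plot fit over %d genes\n", x$n))
  cat(sprintf("  GC12 = %.3f + %.3f * GC3\n", x$intercept, x$slope))
  cat("  quadrant proportions (split at 50%):\n")
  for (q in names(x$quadrants)) {
    cat(sprintf("    %-20s %.3f\n", q, x$quadrants[[q]]))
  }
  invisible(x)
}

#' @export
coef.neutrality_fit <- function(object, ...) {
  c(intercept = object$intercept, slope = object$slope)
}
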