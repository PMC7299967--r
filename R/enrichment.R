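# GO-term over-representation: one-sided (upper tail) Fisher exact test of
# a test protein set against an annotated background.

#' Upper-tail Fisher exact (hypergeometric) p-value
#'
#' Exact probability of drawing at least `k` term-annotated proteins in a
#' sample of `n` from a background of `N` proteins of which `K` carry the
#' term: \eqn{p = P(X \ge k)} for \eqn{X \sim} Hypergeometric(N, K, n),
#' summed over the upper tail.
#'
#' @param k Annotated proteins in the test set.
#' @param n Test-set size.
#' @param K Annotated proteins in the background.
#' @param N Background size.
#' @return p-value in (0, 1\].
#' @export
fisher_exact_upper <- function(k, n, K, N) {
  stopifnot(length(k) == 1L, length(n) == 1L, length(K) == 1L,
            length(N) == 1L)
  if (!(K <= N && n <= N && k >= 0 && k <= min(n, K) &&
        (n - k) <= (N - K))) {
    stop("invalid contingency cell: k=", k, " n=", n, " K=", K, " N=", N)
  }
  p <- sum(stats::dhyper(seq.int(k, min(n, K)), K, N - K, n))
  min(p, 1)
}

# transitive closure of term -> ancestor edges
.propagate_terms <- function(term_sets, edges) {
  parents <- split(edges$parent, edges$child)
  ancestors_of <- function(t) {
    seen <- character()
    frontier <- t
    while (length(frontier)) {
      nxt <- unique(unlist(parents[frontier], use.names = FALSE))
      nxt <- setdiff(nxt, seen)
      seen <- c(seen, nxt)
      frontier <- nxt
    }
    seen
  }
  all_terms <- unique(unlist(term_sets, use.names = FALSE))
  closure <- setNames(lapply(all_terms, ancestors_of), all_terms)
  lapply(term_sets, function(ts) {
    unique(c(ts, unlist(closure[ts], use.names = FALSE)))
  })
}

#' GO-term enrichment of a test set against a background
#'
#' One row per GO term annotated to at least one test protein, with the
#' contingency counts and the one-sided Fisher exact p-value. Following the
#' usual over-representation convention, the background is the set of
#' annotated background proteins and the test-set size counts annotated
#' test proteins. Raw p-values rank the output (ties broken by descending
#' `k`, then term id); a Benjamini-Hochberg column is emitted additionally
#' but not used for ranking.
#'
#' @param test_ids Test protein ids (must be a subset of `background_ids`).
#' @param annotations A named list protein id -> GO ids, or the object
#'   returned by [read_go_annotations()].
#' @param background_ids Background protein ids.
#' @param propagate Propagate annotations to ancestor terms via `edges`.
#' @param edges Child-parent edge data.frame (e.g. from
#'   [read_go_annotations()]); required when `propagate = TRUE`.
#' @param term_names Optional named character vector of term descriptions.
#' @return Object of class `go_enrichment`: data.frame with columns `term`,
#'   `name`, `k`, `n`, `K`, `N`, `p`, `padj`, sorted by ascending p.
#' @export
enrich_terms <- function(test_ids, annotations, background_ids,
                         propagate = FALSE, edges = NULL,
                         term_names = NULL) {
  if (is.list(annotations) && !is.null(annotations$terms) &&
      is.list(annotations$terms)) {
    if (is.null(edges)) edges <- annotations$edges
    annotations <- annotations$terms
  }
  stopifnot(is.list(annotations))
  if (!all(test_ids %in% background_ids)) {
    stop("test set is not a subset of the background")
  }
  if (propagate) {
    if (is.null(edges)) stop("propagate = TRUE requires term edges")
    annotations <- .propagate_terms(annotations, edges)
  }
  ann <- annotations[intersect(names(annotations), background_ids)]
  ann <- ann[lengths(ann) > 0L]
  N <- length(ann)
  if (N == 0L) stop("no annotated background proteins")
  test_ann <- ann[intersect(names(ann), test_ids)]
  n <- length(test_ann)
  k_tab <- table(unlist(test_ann, use.names = FALSE))
  if (length(k_tab) == 0L) {
    stop("annotations cover no test protein")
  }
  K_tab <- table(unlist(ann, use.names = FALSE))
  terms <- names(k_tab)
  k <- as.integer(k_tab)
  K <- as.integer(K_tab[terms])
  p <- vapply(seq_along(terms), function(i) {
    fisher_exact_upper(k[i], n, K[i], N)
  }, numeric(1))
  nm <- if (!is.null(term_names)) unname(term_names[terms])
        else NA_character_
  out <- data.frame(term = terms, name = nm, k = k, n = n, K = K, N = N,
                    p = p, padj = stats::p.adjust(p, method = "BH"),
                    stringsAsFactors = FALSE)
  out <- out[order(out$p, -out$k, out$term), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("go_enrichment", class(out))
  out
}

#' @export
print.go_enrichment <- function(x, max_rows = 10L, ...) {
  cat("GO enrichment:", nrow(x), "terms; test n =", x$n[1L],
      "of background N =", x$N[1L], "\n")
  df <- as.data.frame(x)[seq_len(min(max_rows, nrow(x))), ]
  df$p <- signif(df$p, 3)
  df$padj <- signif(df$padj, 3)
  print(df)
  if (nrow(x) > max_rows) cat("...", nrow(x) - max_rows, "more terms\n")
  invisible(x)
}
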