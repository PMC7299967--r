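# Tree-based validation of candidate homologs: does the candidate branch
# with the ingroup (dinoflagellates/alveolates or the queries themselves),
# and is its terminal branch length comparable to the queries'?

.taxon_groups <- function(tree, taxon_map) {
  if (is.data.frame(taxon_map)) {
    stopifnot(all(c("tip", "group") %in% names(taxon_map)))
    groups <- setNames(taxon_map$group, taxon_map$tip)
  } else {
    groups <- taxon_map
  }
  missing <- setdiff(tree$tip.label, names(groups))
  if (length(missing)) stop("tip not in taxon map: ", missing[1L])
  bad <- setdiff(unique(groups[tree$tip.label]),
                 c("ingroup", "query", "outgroup"))
  if (length(bad)) stop("unknown taxon group '", bad[1L], "'")
  groups[tree$tip.label]
}

.terminal_length <- function(tree, tip) {
  idx <- match(tip, tree$tip.label)
  tree$edge.length[tree$edge[, 2L] == idx]
}

#' Clade-membership check for a candidate tip
#'
#' The candidate passes when the nearest non-candidate tip by patristic
#' (path-length) distance belongs to the ingroup or to the queries. Ties are
#' broken by fewest intervening edges, then lexicographic label. Trees
#' without branch lengths fall back to edge-count distances with a warning.
#' `mode = "monophyly"` instead requires the candidate plus all ingroup and
#' query tips to be monophyletic under the tree's rooting.
#'
#' @param tree An [ape::phylo] tree.
#' @param candidate Candidate tip label.
#' @param taxon_map Data.frame (`tip`, `group`) or named vector mapping
#'   every tip to one of `ingroup`, `query`, `outgroup`.
#' @param mode `"nearest"` (default) or `"monophyly"`.
#' @return List with `clade_ok`, `nearest` (tip label), `nearest_group`.
#' @export
clade_membership_check <- function(tree, candidate, taxon_map,
                                   mode = c("nearest", "monophyly")) {
  mode <- match.arg(mode)
  if (!(candidate %in% tree$tip.label)) {
    stop("candidate tip not in tree: ", candidate)
  }
  groups <- .taxon_groups(tree, taxon_map)
  if (!any(groups == "query")) stop("taxon map has no query tips")
  if (is.null(tree$edge.length)) {
    warning("tree has no branch lengths; using edge-count distances")
    tree$edge.length <- rep(1, nrow(tree$edge))
  }
  topo <- tree
  topo$edge.length <- rep(1, nrow(topo$edge))
  D <- stats::cophenetic(tree)
  Dt <- stats::cophenetic(topo)
  others <- setdiff(tree$tip.label, candidate)
  ord <- order(D[candidate, others], Dt[candidate, others], others)
  nearest <- others[ord[1L]]
  if (mode == "nearest") {
    clade_ok <- groups[[nearest]] %in% c("ingroup", "query")
  } else {
    inq <- names(groups)[groups %in% c("ingroup", "query")]
    clade_ok <- ape::is.monophyletic(tree, c(candidate, setdiff(inq,
                                                                candidate)))
  }
  list(clade_ok = clade_ok, nearest = nearest,
       nearest_group = unname(groups[[nearest]]))
}

#' Terminal-branch-length check for a candidate tip
#'
#' The candidate's terminal branch length is compared to the median terminal
#' branch length of the query tips; it passes when the ratio is at most
#' `ratio_max` (inclusive).
#'
#' @inheritParams clade_membership_check
#' @param ratio_max Maximum allowed ratio (default 2).
#' @return List with `length_ok`, `ratio`, `candidate_length`,
#'   `median_query_length`.
#' @export
branch_length_check <- function(tree, candidate, taxon_map, ratio_max = 2) {
  if (!(candidate %in% tree$tip.label)) {
    stop("candidate tip not in tree: ", candidate)
  }
  if (is.null(tree$edge.length)) {
    stop("branch lengths required for the length check")
  }
  groups <- .taxon_groups(tree, taxon_map)
  qtips <- setdiff(names(groups)[groups == "query"], candidate)
  if (!length(qtips)) stop("taxon map has no query tips")
  med <- stats::median(vapply(qtips, function(t) .terminal_length(tree, t),
                              numeric(1)))
  if (med == 0) stop("degenerate reference branch lengths")
  cl <- .terminal_length(tree, candidate)
  ratio <- cl / med
  list(length_ok = ratio <= ratio_max, ratio = ratio,
       candidate_length = cl, median_query_length = med)
}

#' Validate a candidate homolog on its gene tree
#'
#' Combines the clade-membership and terminal-branch-length checks; the
#' candidate is verified only when both pass.
#'
#' @inheritParams branch_length_check
#' @param mode Clade check mode, see [clade_membership_check()].
#' @return Object of class `homolog_validation` with `candidate`,
#'   `clade_ok`, `nearest`, `nearest_group`, `length_ok`, `ratio`,
#'   `candidate_length`, `median_query_length`, `verdict`.
#' @export
validate_candidate <- function(tree, candidate, taxon_map, ratio_max = 2,
                               mode = c("nearest", "monophyly")) {
  clade <- clade_membership_check(tree, candidate, taxon_map, mode = mode)
  len <- branch_length_check(tree, candidate, taxon_map,
                             ratio_max = ratio_max)
  structure(
    c(list(candidate = candidate), clade, len,
      list(verdict = clade$clade_ok && len$length_ok)),
    class = "homolog_validation"
  )
}

#' @export
print.homolog_validation <- function(x, ...) {
  cat("Candidate", x$candidate, "->",
      if (x$verdict) "VERIFIED" else "not verified", "\n")
  cat(sprintf("  clade: %s (nearest %s, %s)\n",
              if (x$clade_ok) "ok" else "fail", x$nearest, x$nearest_group))
  cat(sprintf("  length: %s (ratio %.3f = %.4g / median %.4g)\n",
              if (x$length_ok) "ok" else "fail", x$ratio,
              x$candidate_length, x$median_query_length))
  invisible(x)
}
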