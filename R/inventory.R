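# Sex-gene inventory stage: desk-scale local protein search, hit filtering
# (e-value / mutual coverage), presence/absence matrices and ortholog-set
# completeness.

#' Smith-Waterman local alignment of two proteins
#'
#' Optimal local alignment under affine gap penalties (a gap of length L
#' costs `gap_open + L * gap_extend`). A best score of zero or less is
#' reported as no hit. The built-in aligner reports raw scores, not
#' e-values; e-value filtering applies only to imported tabular hits.
#'
#' @param query,subject Amino-acid sequence strings.
#' @param substitution_matrix Matrix name (default `"BLOSUM62"`) or a
#'   numeric substitution matrix.
#' @param gap_open,gap_extend Positive affine gap penalties (defaults 11, 1).
#' @return List with `score`, `aln_len` (aligned columns incl. gaps),
#'   `identities`, `qstart`, `qend`, `sstart`, `send`. Score 0 marks no hit.
#' @export
smith_waterman <- function(query, subject, substitution_matrix = "BLOSUM62",
                           gap_open = 11, gap_extend = 1) {
  if (!nzchar(query) || !nzchar(subject)) stop("empty sequence")
  stopifnot(gap_open > 0, gap_extend > 0)
  mat <- substitution_matrix
  if (is.character(mat)) {
    mat <- get(utils::data(list = mat, package = "Biostrings",
                    envir = environment()))
  }
  al <- Biostrings::pairwiseAlignment(
    pattern = Biostrings::AAString(query),
    subject = Biostrings::AAString(subject),
    type = "local", substitutionMatrix = mat,
    gapOpening = gap_open, gapExtension = gap_extend
  )
  sc <- Biostrings::score(al)
  if (sc <= 0) {
    return(list(score = 0, aln_len = 0L, identities = 0L,
                qstart = NA_integer_, qend = NA_integer_,
                sstart = NA_integer_, send = NA_integer_))
  }
  list(score = sc,
       aln_len = Biostrings::nchar(al),
       identities = Biostrings::nmatch(al),
       qstart = Biostrings::start(Biostrings::pattern(al)),
       qend = Biostrings::end(Biostrings::pattern(al)),
       sstart = Biostrings::start(Biostrings::subject(al)),
       send = Biostrings::end(Biostrings::subject(al)))
}

#' All-against-all local search of queries versus subject proteins
#'
#' Runs [smith_waterman()] for every query/subject pair and returns hits
#' with positive score, with coverages resolved against the full sequence
#' lengths. E-values are `NA` (raw-score filtering applies downstream).
#'
#' @param queries,subjects Record data.frames (`id`, `seq`).
#' @inheritParams smith_waterman
#' @return Data.frame of hits: `query`, `subject`, `score`, `aln_len`,
#'   `identities`, `evalue` (NA), `qlen`, `slen`, `qcov`, `scov`.
#' @export
search_homologs <- function(queries, subjects,
                            substitution_matrix = "BLOSUM62",
                            gap_open = 11, gap_extend = 1) {
  stopifnot(is.data.frame(queries), is.data.frame(subjects))
  mat <- substitution_matrix
  if (is.character(mat)) {
    mat <- get(utils::data(list = mat, package = "Biostrings",
                    envir = environment()))
  }
  qset <- Biostrings::AAStringSet(setNames(queries$seq, queries$id))
  rows <- vector("list", nrow(subjects))
  for (j in seq_len(nrow(subjects))) {
    al <- Biostrings::pairwiseAlignment(
      pattern = qset, subject = Biostrings::AAString(subjects$seq[j]),
      type = "local", substitutionMatrix = mat,
      gapOpening = gap_open, gapExtension = gap_extend
    )
    sc <- Biostrings::score(al)
    pos <- which(sc > 0)
    if (!length(pos)) next
    rows[[j]] <- data.frame(
      query = queries$id[pos], subject = subjects$id[j],
      score = sc[pos],
      aln_len = Biostrings::nchar(al)[pos],
      identities = Biostrings::nmatch(al)[pos],
      evalue = NA_real_,
      qlen = nchar(queries$seq)[pos], slen = nchar(subjects$seq[j]),
      stringsAsFactors = FALSE
    )
  }
  hits <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(hits)) {
    hits <- data.frame(query = character(), subject = character(),
                       score = numeric(), aln_len = integer(),
                       identities = integer(), evalue = numeric(),
                       qlen = numeric(), slen = numeric(),
                       stringsAsFactors = FALSE)
  }
  hits$qcov <- hits$aln_len / hits$qlen
  hits$scov <- hits$aln_len / hits$slen
  rownames(hits) <- NULL
  hits
}

#' Filter homology hits by significance and mutual coverage
#'
#' A hit survives when it is significant (e-value strictly below
#' `evalue_max` when an e-value is present, otherwise raw score at least
#' `score_min`) and its query coverage — and, unless disabled, its subject
#' coverage — is at least `mutual_cov_min` (inclusive).
#'
#' @param hits Hit data.frame with `evalue`, `score`, `qcov`, `scov`.
#' @param evalue_max E-value ceiling (default 1e-3, strict `<`).
#' @param mutual_cov_min Coverage floor (default 0.25, inclusive `>=`).
#' @param score_min Raw-score floor for hits without e-values.
#' @param require_subject_cov Require the coverage floor on the subject side
#'   too (default TRUE; both-sided reading of "mutual coverage").
#' @return The surviving rows of `hits`.
#' @export
filter_hits <- function(hits, evalue_max = 1e-3, mutual_cov_min = 0.25,
                        score_min = NULL, require_subject_cov = TRUE) {
  stopifnot(all(c("evalue", "qcov", "scov") %in% names(hits)))
  if (nrow(hits) == 0L) return(hits)
  has_e <- !is.na(hits$evalue)
  if (any(!has_e)) {
    if (!("score" %in% names(hits)) || anyNA(hits$score[!has_e])) {
      stop("hit with neither e-value nor score")
    }
    if (is.null(score_min)) {
      stop("score_min required for hits without e-values")
    }
  }
  sig <- logical(nrow(hits))
  sig[has_e] <- hits$evalue[has_e] < evalue_max
  if (any(!has_e)) sig[!has_e] <- hits$score[!has_e] >= score_min
  cov <- hits$qcov >= mutual_cov_min
  if (require_subject_cov) cov <- cov & hits$scov >= mutual_cov_min
  out <- hits[sig & cov, , drop = FALSE]
  rownames(out) <- NULL
  out
}

.map_isolate <- function(subject_ids, isolate_map) {
  stopifnot(all(c("prefix", "isolate") %in% names(isolate_map)))
  ord <- order(-nchar(isolate_map$prefix))  # longest prefix wins
  out <- rep(NA_character_, length(subject_ids))
  for (i in ord) {
    hit <- is.na(out) & startsWith(subject_ids, isolate_map$prefix[i])
    out[hit] <- isolate_map$isolate[i]
  }
  if (anyNA(out)) stop("unmapped subject id ", subject_ids[is.na(out)][1L])
  out
}

.catalog_query_map <- function(catalog) {
  stopifnot(all(c("symbol", "query_ids") %in% names(catalog)))
  qids <- strsplit(catalog$query_ids, ";", fixed = TRUE)
  map <- setNames(rep(catalog$symbol, lengths(qids)),
                  trimws(unlist(qids)))
  if (anyDuplicated(names(map))) {
    stop("query id mapped to more than one symbol: ",
         names(map)[duplicated(names(map))][1L])
  }
  map
}

#' Presence/absence matrix of catalog genes across isolates
#'
#' A gene is present in an isolate when at least one surviving hit links one
#' of its query proteins to a protein of that isolate. Supporting hits are
#' retained per cell.
#'
#' @param hits Surviving hits (see [filter_hits()]).
#' @param catalog Gene catalog data.frame: `symbol`, `query_ids`
#'   (semicolon-separated), optionally `group` and `meiosis_specific`.
#' @param isolate_map Data.frame `prefix`, `isolate` mapping subject-id
#'   prefixes to isolates; all isolates appear as columns.
#' @return Object of class `presence_matrix`: 0/1 integer matrix gene x
#'   isolate with attributes `support` (hit table with `symbol`, `isolate`)
#'   and `catalog`.
#' @export
build_presence_matrix <- function(hits, catalog, isolate_map) {
  qmap <- .catalog_query_map(catalog)
  isolates <- unique(isolate_map$isolate)
  m <- matrix(0L, nrow = nrow(catalog), ncol = length(isolates),
              dimnames = list(catalog$symbol, isolates))
  support <- NULL
  if (nrow(hits) > 0L) {
    unknown <- setdiff(unique(hits$query), names(qmap))
    if (length(unknown)) stop("query id not in catalog: ", unknown[1L])
    sym <- unname(qmap[hits$query])
    iso <- .map_isolate(hits$subject, isolate_map)
    for (i in seq_along(sym)) m[sym[i], iso[i]] <- 1L
    support <- cbind(hits, symbol = sym, isolate = iso,
                     stringsAsFactors = FALSE)
  }
  structure(m, class = c("presence_matrix", class(m)),
            support = support, catalog = catalog)
}

#' @export
print.presence_matrix <- function(x, ...) {
  m <- unclass(x)
  attr(m, "support") <- NULL
  attr(m, "catalog") <- NULL
  cat("Presence/absence matrix:", nrow(m), "genes x", ncol(m), "isolates\n")
  cat("  present cells:", sum(m), "of", length(m), "\n")
  print(m)
  invisible(x)
}

#' Completeness of a reference ortholog set
#'
#' Fraction of orthologs recovered, counting both complete and fragmented
#' ones, as a percentage (the convention used for BUSCO-style completeness
#' reporting).
#'
#' @param status Character/factor vector over
#'   `{complete, fragmented, missing}`, one entry per reference ortholog.
#' @return Percentage in \[0, 100\].
#' @export
completeness_score <- function(status) {
  status <- as.character(status)
  if (length(status) == 0L) stop("empty ortholog status set")
  bad <- setdiff(unique(status), c("complete", "fragmented", "missing"))
  if (length(bad)) stop("unknown ortholog status '", bad[1L], "'")
  100 * mean(status %in% c("complete", "fragmented"))
}
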