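# Readers and writers for the external formats the pipeline touches:
# FASTA, BLAST-style tabular hits, GO annotation TSVs and Newick trees,
# plus the complete-ORF preprocessing applied to transcriptome input.

.empty_records <- function() {
  data.frame(id = character(), desc = character(), seq = character(),
             stringsAsFactors = FALSE)
}

#' Read a FASTA file into a record table
#'
#' Records are returned in file order with sequences upper-cased and line
#' wrapping removed. The first whitespace-delimited token of each header is
#' the record id; the remainder is kept as the description.
#'
#' @param path Path to a FASTA file.
#' @return A data.frame with columns `id`, `desc`, `seq`.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (file.size(path) == 0L) {
    warning("empty FASTA file: ", path)
    return(.empty_records())
  }
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) {
    warning("empty FASTA file: ", path)
    return(.empty_records())
  }
  hdr <- names(set)
  id <- sub("\\s.*$", "", hdr)
  desc <- ifelse(grepl("\\s", hdr), sub("^\\S+\\s+", "", hdr), "")
  if (any(!nzchar(id))) stop("record with empty id in ", path)
  dup <- unique(id[duplicated(id)])
  if (length(dup)) stop("duplicate id ", dup[1L])
  seqs <- toupper(as.character(set))
  if (any(!nzchar(seqs))) {
    stop("empty sequence for id ", id[which(!nzchar(seqs))[1L]])
  }
  data.frame(id = id, desc = desc, seq = unname(seqs),
             stringsAsFactors = FALSE)
}

#' Write a record table to FASTA
#'
#' @param records Data.frame with columns `id`, `seq` and optionally `desc`.
#' @param path Output path.
#' @param width Line width for sequence wrapping.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path, width = 60L) {
  stopifnot(is.data.frame(records), all(c("id", "seq") %in% names(records)))
  desc <- if ("desc" %in% names(records)) records$desc else ""
  nm <- ifelse(nzchar(desc), paste(records$id, desc), records$id)
  set <- Biostrings::BStringSet(records$seq)
  names(set) <- nm
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}

#' Keep complete ORFs and translate them
#'
#' Transcript-derived coding sequences are retained only when they look like
#' complete ORFs: length a multiple of three, a start codon at position one,
#' a terminal stop codon and no internal stop. Kept sequences are translated
#' (terminal stop removed); removals are tallied by reason.
#'
#' @param records Nucleotide record table as from [read_fasta()].
#' @param code Genetic code id (default standard code).
#' @param start_codons Accepted start codons; `"ATG"` only by default.
#' @return A list with `kept` (nucleotide records), `translated` (amino-acid
#'   records) and `report` (named integer vector of counts by fate).
#' @export
extract_complete_orfs <- function(records, code = "1", start_codons = "ATG") {
  stopifnot(is.data.frame(records))
  if (nrow(records) == 0L) {
    return(list(kept = records, translated = records,
                report = c(kept = 0L, not_multiple_of_3 = 0L, no_start = 0L,
                           no_stop = 0L, internal_stop = 0L)))
  }
  seqs <- toupper(records$seq)
  bad <- grepl("[^ACGTRYSWKMBDHVN]", seqs)
  if (any(bad)) {
    stop("non-nucleotide alphabet in record ", records$id[which(bad)[1L]])
  }
  stops <- stop_codons(code)
  fate <- vapply(seqs, function(s) {
    n <- nchar(s)
    if (n %% 3L != 0L) return("not_multiple_of_3")
    cod <- substring(s, seq(1L, n, 3L), seq(3L, n, 3L))
    if (!(cod[1L] %in% start_codons)) return("no_start")
    if (!(cod[length(cod)] %in% stops)) return("no_stop")
    if (any(cod[-length(cod)] %in% stops)) return("internal_stop")
    "kept"
  }, character(1), USE.NAMES = FALSE)
  kept <- records[fate == "kept", , drop = FALSE]
  rownames(kept) <- NULL
  translated <- .empty_records()
  if (nrow(kept) > 0L) {
    body <- substr(toupper(kept$seq), 1L, nchar(kept$seq) - 3L)
    aa <- Biostrings::translate(
      Biostrings::DNAStringSet(body),
      genetic.code = Biostrings::getGeneticCode(as.character(code)),
      if.fuzzy.codon = "solve"
    )
    translated <- data.frame(id = kept$id, desc = kept$desc,
                             seq = as.character(aa), stringsAsFactors = FALSE)
  }
  report <- c(
    kept = sum(fate == "kept"),
    not_multiple_of_3 = sum(fate == "not_multiple_of_3"),
    no_start = sum(fate == "no_start"),
    no_stop = sum(fate == "no_stop"),
    internal_stop = sum(fate == "internal_stop")
  )
  list(kept = kept, translated = translated, report = report)
}

#' Read BLAST-style tabular hits
#'
#' Accepts the 12-column tabular dialect (qseqid sseqid pident length
#' mismatch gapopen qstart qend sstart send evalue bitscore) or a 14-column
#' variant with query and subject full lengths appended. When length columns
#' are absent, lengths are resolved from the supplied maps; query and subject
#' coverage are computed as alignment length over each full length.
#'
#' @param path Path to the tabular file. Lines starting with `#` are skipped.
#' @param query_lengths,subject_lengths Named numeric vectors mapping
#'   sequence id to full length; required for 12-column input.
#' @return A data.frame of hits with coverage columns `qcov`, `scov`; the
#'   bitscore is carried as `score`.
#' @export
read_blast_tab <- function(path, query_lengths = NULL, subject_lengths = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  keep <- nzchar(lines) & !startsWith(lines, "#")
  lineno <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0L) {
    return(data.frame(query = character(), subject = character(),
                      pident = numeric(), aln_len = integer(),
                      evalue = numeric(), score = numeric(),
                      qlen = numeric(), slen = numeric(),
                      qcov = numeric(), scov = numeric(),
                      stringsAsFactors = FALSE))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  bad <- which(!(nf %in% c(12L, 14L)))
  if (length(bad)) {
    stop(sprintf("line %d: expected 12 or 14 columns, got %d",
                 lineno[bad[1L]], nf[bad[1L]]))
  }
  get <- function(i) vapply(fields, `[[`, character(1), i)
  hits <- data.frame(
    query = get(1L), subject = get(2L),
    pident = as.numeric(get(3L)), aln_len = as.integer(get(4L)),
    evalue = as.numeric(get(11L)), score = as.numeric(get(12L)),
    stringsAsFactors = FALSE
  )
  qlen <- rep(NA_real_, nrow(hits))
  slen <- rep(NA_real_, nrow(hits))
  has14 <- nf == 14L
  if (any(has14)) {
    qlen[has14] <- as.numeric(vapply(fields[has14], `[[`, character(1), 13L))
    slen[has14] <- as.numeric(vapply(fields[has14], `[[`, character(1), 14L))
  }
  need <- which(!has14)
  if (length(need)) {
    if (is.null(query_lengths)) stop("unknown query length ",
                                     hits$query[need][1L])
    mq <- unname(query_lengths[hits$query[need]])
    if (anyNA(mq)) stop("unknown query length ",
                        hits$query[need][is.na(mq)][1L])
    if (is.null(subject_lengths)) stop("unknown subject length ",
                                       hits$subject[need][1L])
    ms <- unname(subject_lengths[hits$subject[need]])
    if (anyNA(ms)) stop("unknown subject length ",
                        hits$subject[need][is.na(ms)][1L])
    qlen[need] <- mq
    slen[need] <- ms
  }
  hits$qlen <- qlen
  hits$slen <- slen
  hits$qcov <- hits$aln_len / hits$qlen
  hits$scov <- hits$aln_len / hits$slen
  hits
}

.go_pattern <- "^GO:[0-9]{7}$"

#' Read a protein-to-GO annotation table
#'
#' Flat TSV with two columns: protein id and a semicolon-separated list of GO
#' term ids. Term sets are de-duplicated. A header row is skipped when its
#' second field contains no valid GO id. Optional child-to-parent term edges
#' (two-column TSV) may be supplied for ancestor propagation; the edge
#' relation must be acyclic.
#'
#' @param path Path to the annotation TSV.
#' @param edges_path Optional path to a child-parent edge TSV.
#' @return A list with `terms` (named list protein id -> character vector of
#'   GO ids) and `edges` (data.frame with columns `child`, `parent`, or NULL).
#' @export
read_go_annotations <- function(path, edges_path = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  if (length(fields) && length(fields[[1L]]) >= 2L &&
      !grepl("^GO:", strsplit(fields[[1L]][2L], ";",
                              fixed = TRUE)[[1L]][1L])) {
    fields <- fields[-1L]  # header row
  }
  terms <- list()
  for (f in fields) {
    if (length(f) < 2L) stop("annotation line with fewer than 2 columns")
    ids <- unique(trimws(strsplit(f[2L], ";", fixed = TRUE)[[1L]]))
    ids <- ids[nzchar(ids)]
    ok <- grepl(.go_pattern, ids)
    if (any(!ok)) stop("malformed GO id '", ids[which(!ok)[1L]], "'")
    terms[[f[1L]]] <- unique(c(terms[[f[1L]]], ids))
  }
  edges <- NULL
  if (!is.null(edges_path)) {
    ed <- utils::read.table(edges_path, sep = "\t", header = FALSE,
                            col.names = c("child", "parent"),
                            stringsAsFactors = FALSE)
    ok <- grepl(.go_pattern, ed$child) & grepl(.go_pattern, ed$parent)
    if (any(!ok)) {
      bad <- c(ed$child, ed$parent)[!grepl(.go_pattern, c(ed$child, ed$parent))]
      stop("malformed GO id '", bad[1L], "'")
    }
    .check_acyclic(ed)
    edges <- ed
  }
  list(terms = terms, edges = edges)
}

# topological check: error if the child->parent relation has a cycle
.check_acyclic <- function(edges) {
  nodes <- unique(c(edges$child, edges$parent))
  adj <- split(edges$parent, factor(edges$child, levels = nodes))
  state <- setNames(integer(length(nodes)), nodes)  # 0 new, 1 open, 2 done
  visit <- function(v) {
    if (state[[v]] == 1L) stop("cycle in GO term edges at ", v)
    if (state[[v]] == 2L) return(invisible())
    state[[v]] <<- 1L
    for (w in adj[[v]]) visit(w)
    state[[v]] <<- 2L
  }
  for (v in nodes) visit(v)
  invisible(TRUE)
}

#' Read a single Newick tree
#'
#' Tip labels are preserved verbatim. Missing branch lengths are reported as
#' absent (`NULL` `edge.length`), not silently set to zero; negative branch
#' lengths are rejected.
#'
#' @param path Path to a Newick file (a single tree).
#' @return An [ape::phylo] object.
#' @export
read_newick <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  txt <- paste(readLines(path), collapse = "")
  depth <- cumsum((strsplit(txt, "")[[1L]] == "(") -
                  (strsplit(txt, "")[[1L]] == ")"))
  if (length(depth) && (any(depth < 0L) || utils::tail(depth, 1L) != 0L)) {
    pos <- if (any(depth < 0L)) which(depth < 0L)[1L] else nchar(txt)
    stop("Newick parse error: unbalanced parentheses at position ", pos)
  }
  tree <- tryCatch(ape::read.tree(text = txt),
                   error = function(e) stop("Newick parse error: ",
                                            conditionMessage(e)))
  if (is.null(tree) || inherits(tree, "multiPhylo")) {
    stop("Newick parse error: expected a single tree in ", path)
  }
  if (!is.null(tree$edge.length) && any(tree$edge.length < 0)) {
    stop("negative branch length in ", path)
  }
  tree
}
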