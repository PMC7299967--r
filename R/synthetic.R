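# Synthetic fixtures with planted ground truth for every pipeline stage:
# CDS sets with controlled synonymous-codon concentration and GC3 tilt,
# protein families with planted presence/absence and divergence, annotation
# sets with a planted enriched term, and gene trees with planted placement.
#
# All generators are deterministic under an integer seed. A master seed can
# be shared across stages: each generator draws from its own stream started
# at seed + a fixed offset so stages can be regenerated independently.

.AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L", "M", "N",
           "P", "Q", "R", "S", "T", "V", "W", "Y")

.rdirichlet1 <- function(k, alpha) {
  g <- stats::rgamma(k, shape = alpha)
  while (sum(g) == 0) g <- stats::rgamma(k, shape = alpha)  # alpha tiny
  g / sum(g)
}

#' Generate a synthetic CDS set with controlled codon bias
#'
#' Genes are built by sampling amino acids, then synonymous codons from a
#' per-gene, per-family Dirichlet-multinomial: the symmetric Dirichlet
#' concentration `alpha` controls bias (`alpha` near 0 plants one dominant
#' codon per family, i.e. strong codon-usage preference; large `alpha`
#' approaches uniform usage, i.e. neutrality). `gc3_bias` multiplies the
#' probability of G/C-ending codons within each family (with family-wise
#' renormalisation) to tilt GC3. Each gene gets an ATG start and a random
#' stop codon.
#'
#' @param n_genes Number of genes.
#' @param len_codons Gene body length in codons: a single value, a range
#'   `c(min, max)` sampled uniformly, or one value per gene. Must be >= 30.
#' @param alpha Symmetric Dirichlet concentration, > 0.
#' @param gc3_bias Multiplicative odds for G/C-ending codons (1 = no tilt).
#' @param aa_freq Amino-acid sampling weights over the 20 residues
#'   (default uniform); named, or given in alphabetical one-letter order.
#' @param seed Integer seed.
#' @param prefix Gene id prefix.
#' @return List with `records` (FASTA-ready data.frame) and `truth`
#'   (per-gene data.frame: id, n_codons, alpha, gc3_bias).
#' @export
generate_cds_set <- function(n_genes, len_codons = 300L, alpha = 1,
                             gc3_bias = 1, aa_freq = NULL, seed = 1L,
                             prefix = "gene") {
  stopifnot(n_genes >= 1L, alpha > 0, gc3_bias > 0)
  set.seed(as.integer(seed))
  if (length(len_codons) == 2L && n_genes != 2L) {
    lens <- sample(len_codons[1L]:len_codons[2L], n_genes, replace = TRUE)
  } else if (length(len_codons) == 1L) {
    lens <- rep(as.integer(len_codons), n_genes)
  } else {
    stopifnot(length(len_codons) == n_genes)
    lens <- as.integer(len_codons)
  }
  if (any(lens < 30L)) stop("gene lengths must be >= 30 codons")
  if (is.null(aa_freq)) aa_freq <- setNames(rep(1, 20L), .AA20)
  if (is.null(names(aa_freq))) names(aa_freq) <- .AA20
  stopifnot(all(.AA20 %in% names(aa_freq)))
  aa_freq <- aa_freq[.AA20] / sum(aa_freq[.AA20])

  tab <- codon_table("1")
  tab <- tab[!tab$stop, ]
  fams <- split(tab$codon, tab$aa)
  ends_gc <- lapply(fams, function(cd) substr(cd, 3L, 3L) %in% c("G", "C"))
  stops <- stop_codons("1")

  seqs <- character(n_genes)
  for (g in seq_len(n_genes)) {
    probs <- lapply(names(fams), function(aa) {
      k <- length(fams[[aa]])
      p <- .rdirichlet1(k, alpha)
      w <- ifelse(ends_gc[[aa]], gc3_bias, 1)
      p <- p * w
      p / sum(p)
    })
    names(probs) <- names(fams)
    aa_seq <- sample(.AA20, lens[g], replace = TRUE, prob = aa_freq)
    codons <- character(lens[g])
    for (aa in unique(aa_seq)) {
      at <- which(aa_seq == aa)
      cd <- fams[[aa]]
      codons[at] <- if (length(cd) == 1L) cd else
        sample(cd, length(at), replace = TRUE, prob = probs[[aa]])
    }
    seqs[g] <- paste0("ATG", paste(codons, collapse = ""),
                      sample(stops, 1L))
  }
  ids <- sprintf("%s%04d", prefix, seq_len(n_genes))
  list(
    records = data.frame(id = ids, desc = "", seq = seqs,
                         stringsAsFactors = FALSE),
    truth = data.frame(id = ids, n_codons = lens, alpha = alpha,
                       gc3_bias = gc3_bias, stringsAsFactors = FALSE)
  )
}

.random_protein <- function(len) {
  paste(sample(.AA20, len, replace = TRUE), collapse = "")
}

.mutate_protein <- function(seq, divergence) {
  ch <- strsplit(seq, "")[[1L]]
  n_mut <- round(divergence * length(ch))
  if (n_mut > 0L) {
    at <- sample(length(ch), n_mut)
    ch[at] <- vapply(ch[at], function(a) sample(setdiff(.AA20, a), 1L),
                     character(1))
  }
  paste(ch, collapse = "")
}

#' Generate a homology-search fixture with planted presence/absence
#'
#' Random query proteins stand in for the catalog genes. For each
#' (gene, isolate) cell planted present, the isolate carries a subject
#' protein derived from the query by point substitutions at rate
#' `divergence`; absent cells get no homolog. Each isolate additionally
#' carries composition-matched shuffled decoy proteins (never true
#' homologs), so specificity can be measured.
#'
#' @param n_genes,n_isolates Catalog and isolate panel sizes.
#' @param presence_prob Probability a cell is planted present.
#' @param divergence Substitution rate in \[0, 0.6\].
#' @param n_decoys Decoy proteins per isolate.
#' @param query_len Query protein length (residues).
#' @param seed Integer seed.
#' @return List with `queries`, `subjects` (record data.frames; subject ids
#'   are `<isolate>|...`), `catalog`, `isolate_map`, `truth` (0/1 matrix
#'   gene x isolate), `decoy_ids`.
#' @export
generate_homology_fixture <- function(n_genes = 10L, n_isolates = 5L,
                                      presence_prob = 0.8,
                                      divergence = 0.2, n_decoys = 5L,
                                      query_len = 300L, seed = 1L) {
  stopifnot(divergence >= 0, divergence <= 0.6,
            presence_prob >= 0, presence_prob <= 1)
  set.seed(as.integer(seed))
  genes <- sprintf("GENE%02d", seq_len(n_genes))
  isolates <- sprintf("iso%02d", seq_len(n_isolates))
  queries <- data.frame(
    id = paste0(genes, "_q"), desc = "",
    seq = vapply(seq_len(n_genes), function(i) .random_protein(query_len),
                 character(1)),
    stringsAsFactors = FALSE
  )
  truth <- matrix(as.integer(stats::runif(n_genes * n_isolates) <
                               presence_prob),
                  nrow = n_genes, dimnames = list(genes, isolates))
  rows <- list()
  for (iso in isolates) {
    for (g in seq_len(n_genes)) {
      if (truth[g, iso] == 1L) {
        rows[[length(rows) + 1L]] <- data.frame(
          id = paste0(iso, "|", genes[g], "_h"), desc = "",
          seq = .mutate_protein(queries$seq[g], divergence),
          stringsAsFactors = FALSE
        )
      }
    }
    for (j in seq_len(n_decoys)) {
      src <- sample(n_genes, 1L)
      ch <- strsplit(queries$seq[src], "")[[1L]]
      rows[[length(rows) + 1L]] <- data.frame(
        id = paste0(iso, "|decoy", j), desc = "",
        seq = paste(sample(ch), collapse = ""),
        stringsAsFactors = FALSE
      )
    }
  }
  subjects <- do.call(rbind, rows)
  rownames(subjects) <- NULL
  list(
    queries = queries, subjects = subjects,
    catalog = data.frame(symbol = genes, query_ids = paste0(genes, "_q"),
                         group = "synthetic", meiosis_specific = FALSE,
                         stringsAsFactors = FALSE),
    isolate_map = data.frame(prefix = paste0(isolates, "|"),
                             isolate = isolates, stringsAsFactors = FALSE),
    truth = truth,
    decoy_ids = subjects$id[grepl("\\|decoy", subjects$id)]
  )
}

#' Generate an annotation fixture with one planted enriched term
#'
#' Background term frequencies are drawn uniformly; inside the test set the
#' planted term's annotation probability is multiplied by
#' `enrichment_factor` (capped at 1).
#'
#' @param n_prot Background size.
#' @param n_terms Number of GO terms.
#' @param planted_term Term id to enrich (default the first term).
#' @param test_size Test-set size.
#' @param enrichment_factor Multiplier >= 1; 1 plants nothing (null).
#' @param freq_range Range of background annotation frequencies.
#' @param seed Integer seed.
#' @return List with `annotations` (named list id -> GO ids), `test_ids`,
#'   `background_ids`, `truth` (planted term, factor, base frequencies).
#' @export
generate_annotation_fixture <- function(n_prot = 1000L, n_terms = 40L,
                                        planted_term = NULL,
                                        test_size = 50L,
                                        enrichment_factor = 10,
                                        freq_range = c(0.01, 0.2),
                                        seed = 1L) {
  stopifnot(enrichment_factor >= 1, test_size <= n_prot)
  set.seed(as.integer(seed))
  prot <- sprintf("prot%05d", seq_len(n_prot))
  terms <- sprintf("GO:%07d", seq_len(n_terms))
  if (is.null(planted_term)) planted_term <- terms[1L]
  stopifnot(planted_term %in% terms)
  freq <- stats::runif(n_terms, freq_range[1L], freq_range[2L])
  names(freq) <- terms
  has <- matrix(stats::runif(n_prot * n_terms) < rep(freq, each = n_prot),
                nrow = n_prot, dimnames = list(prot, terms))
  test_ids <- sample(prot, test_size)
  p_test <- min(1, freq[[planted_term]] * enrichment_factor)
  has[test_ids, planted_term] <- stats::runif(test_size) < p_test
  annotations <- apply(has, 1L, function(row) terms[row], simplify = FALSE)
  annotations <- annotations[lengths(annotations) > 0L]
  list(annotations = annotations, test_ids = test_ids,
       background_ids = prot,
       truth = list(planted_term = planted_term,
                    enrichment_factor = enrichment_factor,
                    base_freq = freq))
}

#' Generate a gene-tree fixture with planted candidate placement
#'
#' Query and ingroup tips form one random coalescent clade, outgroup tips a
#' second; the candidate is grafted onto the terminal edge of a random tip
#' of the requested group, with terminal branch length equal to
#' `terminal_length_ratio` times the median query terminal branch length.
#'
#' @param n_ingroup,n_outgroup,n_query Tip counts per group (queries sit
#'   inside the ingroup clade).
#' @param candidate_placement `"ingroup"` or `"outgroup"`.
#' @param terminal_length_ratio Candidate terminal length as a multiple of
#'   the median query terminal length.
#' @param seed Integer seed.
#' @return List with `tree` (phylo, candidate tip `"cand"`), `taxon_map`
#'   (data.frame `tip`, `group`), `truth` (expected check outcomes).
#' @export
generate_tree_fixture <- function(n_ingroup = 6L, n_outgroup = 4L,
                                  n_query = 4L,
                                  candidate_placement = c("ingroup",
                                                          "outgroup"),
                                  terminal_length_ratio = 1,
                                  seed = 1L) {
  candidate_placement <- match.arg(candidate_placement)
  stopifnot(n_ingroup >= 2L, n_outgroup >= 2L, n_query >= 1L,
            terminal_length_ratio >= 0)
  set.seed(as.integer(seed))
  qtips <- sprintf("query%02d", seq_len(n_query))
  dtips <- sprintf("dino%02d", seq_len(n_ingroup))
  otips <- sprintf("out%02d", seq_len(n_outgroup))
  t_in <- ape::rcoal(n_ingroup + n_query,
                     tip.label = sample(c(qtips, dtips)))
  t_out <- ape::rcoal(n_outgroup, tip.label = otips)
  s_in <- sub(";\\s*$", "", ape::write.tree(t_in))
  s_out <- sub(";\\s*$", "", ape::write.tree(t_out))
  tree <- ape::read.tree(text = paste0("(", s_in, ":0.5,", s_out,
                                       ":0.5);"))
  med <- stats::median(vapply(qtips, function(t) .terminal_length(tree, t),
                              numeric(1)))
  cand_len <- terminal_length_ratio * med
  host_pool <- if (candidate_placement == "ingroup") dtips else otips
  host <- sample(host_pool, 1L)
  w <- match(host, tree$tip.label)
  el <- tree$edge.length[tree$edge[, 2L] == w]
  tree <- phytools::bind.tip(tree, "cand", edge.length = cand_len,
                             where = w, position = el / 2)
  taxon_map <- data.frame(
    tip = c(qtips, dtips, otips, "cand"),
    group = c(rep("query", n_query), rep("ingroup", n_ingroup),
              rep("outgroup", n_outgroup), "ingroup"),
    stringsAsFactors = FALSE
  )
  list(
    tree = tree, taxon_map = taxon_map,
    truth = list(placement = candidate_placement, host = host,
                 ratio = terminal_length_ratio,
                 expected_clade_ok = candidate_placement == "ingroup",
                 expected_length_ok = terminal_length_ratio <= 2)
  )
}
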