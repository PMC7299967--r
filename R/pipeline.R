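# End-to-end runs: codon-usage analysis (profiles + neutrality fit + CA +
# class lists) and the homology inventory (search/import, filter, presence
# matrix, optional tree validation), with TSV outputs that carry a header
# comment recording tool version, configuration hash and seed.

.config_hash <- function(cfg) {
  s <- paste(names(cfg), vapply(cfg, function(v) paste(format(v),
                                                       collapse = ","),
                                character(1)),
             sep = "=", collapse = ";")
  h <- 0
  for (ch in utf8ToInt(s)) h <- (h * 31 + ch) %% 2147483647
  sprintf("%08x", h)
}

.output_header <- function(cfg, seed = NULL) {
  v <- tryCatch(as.character(utils::packageVersion("dinocodon")),
                error = function(e) "dev")
  sprintf("# dinocodon %s config=%s seed=%s", v, .config_hash(cfg),
          if (is.null(seed)) "NA" else seed)
}

.write_tsv <- function(df, path, cfg, seed = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(.output_header(cfg, seed), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Run the full codon-usage analysis on a CDS set
#'
#' Computes per-CDS usage profiles, the neutrality-plot fit, correspondence
#' analysis of the RSCU matrix and the preference-class gene lists; when
#' `out_dir` is given, writes the plot-ready tables
#' (`codon_usage_profiles.tsv`, `neutrality_fit.tsv`, `ca_axes.tsv`,
#' `ca_gene_coords.tsv`, `class_*.txt`).
#'
#' @param cds FASTA path or record data.frame of coding sequences.
#' @param out_dir Optional output directory (created if needed).
#' @param code Genetic code id.
#' @param curve_threshold,neutral_threshold,min_codons Classification and
#'   flag thresholds, see [codon_usage()].
#' @param seed Recorded in output headers (the analysis itself is
#'   deterministic).
#' @return Object of class `codon_pipeline`: list with `usage`,
#'   `neutrality`, `ca`, `classes` (list of id vectors), `config`.
#' @export
run_codon_pipeline <- function(cds, out_dir = NULL, code = "1",
                               curve_threshold = 25, neutral_threshold = 5,
                               min_codons = 100L, seed = NULL) {
  cfg <- list(code = code, curve_threshold = curve_threshold,
              neutral_threshold = neutral_threshold,
              min_codons = min_codons)
  cu <- codon_usage(cds, code = code, min_codons = min_codons,
                    curve_threshold = curve_threshold,
                    neutral_threshold = neutral_threshold)
  nf <- tryCatch(neutrality_analysis(cu), error = function(e) {
    warning("neutrality fit skipped: ", conditionMessage(e))
    NULL
  })
  ca <- tryCatch(correspondence_analysis(build_rscu_matrix(cu)),
                 error = function(e) {
                   warning("correspondence analysis skipped: ",
                           conditionMessage(e))
                   NULL
                 })
  p <- cu$profiles
  classes <- split(p$id, p$preference_class)
  for (cl in c("strong_preference", "neutral", "other")) {
    if (is.null(classes[[cl]])) classes[[cl]] <- character()
  }
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    .write_tsv(p, file.path(out_dir, "codon_usage_profiles.tsv"), cfg, seed)
    if (!is.null(nf)) {
      nf_df <- data.frame(slope = nf$slope, intercept = nf$intercept,
                          n = nf$n, t(nf$quadrants))
      .write_tsv(nf_df, file.path(out_dir, "neutrality_fit.tsv"), cfg, seed)
    }
    if (!is.null(ca) && !ca$degenerate) {
      axes <- data.frame(axis = seq_len(ca$n_axes),
                         singular_value = ca$singular_values,
                         inertia = ca$inertia,
                         relative_inertia = ca$relative_inertia)
      .write_tsv(axes, file.path(out_dir, "ca_axes.tsv"), cfg, seed)
      k <- min(2L, ca$n_axes)
      coords <- data.frame(id = rownames(ca$row_coords),
                           ca$row_coords[, seq_len(k), drop = FALSE],
                           gc3s = p$gc3s[match(rownames(ca$row_coords),
                                               p$id)])
      .write_tsv(coords, file.path(out_dir, "ca_gene_coords.tsv"), cfg,
                 seed)
    }
    for (cl in names(classes)) {
      writeLines(classes[[cl]],
                 file.path(out_dir, paste0("class_", cl, ".txt")))
    }
  }
  structure(list(usage = cu, neutrality = nf, ca = ca, classes = classes,
                 config = cfg),
            class = "codon_pipeline")
}

#' @export
print.codon_pipeline <- function(x, ...) {
  print(x$usage)
  if (!is.null(x$neutrality)) {
    cat(sprintf("Neutrality slope %.3f (n = %d)\n", x$neutrality$slope,
                x$neutrality$n))
  }
  if (!is.null(x$ca) && !x$ca$degenerate) {
    cat(sprintf("CA axis 1 relative inertia %.1f%%\n",
                100 * x$ca$relative_inertia[1L]))
  }
  invisible(x)
}

#' Run the homology inventory on subject proteomes or imported hits
#'
#' Either aligns the catalog queries against subject proteins with the
#' built-in local aligner, or takes pre-computed tabular hits; applies the
#' e-value / raw-score and mutual-coverage filters; builds the gene x
#' isolate presence matrix; and, when gene trees are supplied, validates
#' each named candidate tip.
#'
#' @param queries Query record data.frame (needed unless `hits` given).
#' @param subjects Subject record data.frame (ids carrying isolate
#'   prefixes), or NULL when `hits` are imported.
#' @param hits Optional pre-computed hit table (e.g. [read_blast_tab()]).
#' @param catalog,isolate_map See [build_presence_matrix()].
#' @param evalue_max,mutual_cov_min,score_min,require_subject_cov Filter
#'   thresholds, see [filter_hits()].
#' @param trees Optional named list of [ape::phylo] trees; names are
#'   candidate tip labels to validate on each tree.
#' @param taxon_maps Taxon map (shared data.frame) or named list parallel
#'   to `trees`.
#' @param ratio_max Branch-length ratio threshold for validation.
#' @param out_dir Optional output directory (`presence_matrix.tsv`,
#'   `validation.tsv`).
#' @param seed Recorded in output headers.
#' @return Object of class `inventory_pipeline`: list with `hits`,
#'   `surviving`, `presence`, `validation` (data.frame or NULL), `config`.
#' @export
run_inventory_pipeline <- function(queries = NULL, subjects = NULL,
                                   hits = NULL, catalog, isolate_map,
                                   evalue_max = 1e-3,
                                   mutual_cov_min = 0.25, score_min = 100,
                                   require_subject_cov = TRUE,
                                   trees = NULL, taxon_maps = NULL,
                                   ratio_max = 2, out_dir = NULL,
                                   seed = NULL) {
  if (missing(catalog) || is.null(catalog)) stop("catalog is required")
  cfg <- list(evalue_max = evalue_max, mutual_cov_min = mutual_cov_min,
              score_min = score_min,
              require_subject_cov = require_subject_cov,
              ratio_max = ratio_max)
  if (is.null(hits)) {
    if (is.null(queries) || is.null(subjects)) {
      stop("either hits or both queries and subjects must be supplied")
    }
    hits <- if (nrow(subjects) == 0L) {
      data.frame(query = character(), subject = character(),
                 score = numeric(), aln_len = integer(),
                 identities = integer(), evalue = numeric(),
                 qlen = numeric(), slen = numeric(), qcov = numeric(),
                 scov = numeric(), stringsAsFactors = FALSE)
    } else {
      search_homologs(queries, subjects)
    }
  }
  surviving <- filter_hits(hits, evalue_max = evalue_max,
                           mutual_cov_min = mutual_cov_min,
                           score_min = score_min,
                           require_subject_cov = require_subject_cov)
  presence <- build_presence_matrix(surviving, catalog, isolate_map)
  validation <- NULL
  if (!is.null(trees)) {
    stopifnot(!is.null(names(trees)))
    validation <- do.call(rbind, lapply(names(trees), function(cand) {
      tm <- if (is.data.frame(taxon_maps)) taxon_maps
            else taxon_maps[[cand]]
      v <- validate_candidate(trees[[cand]], cand, tm,
                              ratio_max = ratio_max)
      data.frame(candidate = v$candidate, clade_ok = v$clade_ok,
                 nearest = v$nearest, nearest_group = v$nearest_group,
                 length_ok = v$length_ok, ratio = v$ratio,
                 verdict = v$verdict, stringsAsFactors = FALSE)
    }))
  }
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    pm <- as.data.frame(unclass(presence)[, , drop = FALSE])
    pm <- cbind(symbol = rownames(pm), pm)
    .write_tsv(pm, file.path(out_dir, "presence_matrix.tsv"), cfg, seed)
    if (!is.null(validation)) {
      .write_tsv(validation, file.path(out_dir, "validation.tsv"), cfg,
                 seed)
    }
  }
  structure(list(hits = hits, surviving = surviving, presence = presence,
                 validation = validation, config = cfg),
            class = "inventory_pipeline")
}

#' @export
print.inventory_pipeline <- function(x, ...) {
  cat("Inventory:", nrow(x$hits), "raw hits ->", nrow(x$surviving),
      "surviving\n")
  m <- unclass(x$presence)
  attr(m, "support") <- NULL; attr(m, "catalog") <- NULL
  cat("  presence:", sum(m), "of", length(m), "gene x isolate cells\n")
  if (!is.null(x$validation)) {
    cat("  validated:", sum(x$validation$verdict), "of",
        nrow(x$validation), "candidates\n")
  }
  invisible(x)
}
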