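# Genetic-code bookkeeping shared by the codon statistics.
# Tables are derived from Biostrings::getGeneticCode() and cached per code id.

.codon_cache <- new.env(parent = emptyenv())

#' Codon table for a genetic code
#'
#' Returns one row per codon with its encoded amino acid, the three codon
#' positions, a stop flag and the synonymous-family size (degeneracy) of the
#' encoded amino acid under that code.
#'
#' @param code Genetic code id as understood by
#'   [Biostrings::getGeneticCode()]; `"1"` is the standard code, the default
#'   used throughout (dinoflagellate nuclear genes use the standard code).
#' @return A data.frame with columns `codon`, `aa`, `p1`, `p2`, `p3`,
#'   `stop`, `degeneracy`.
#' @export
codon_table <- function(code = "1") {
  key <- as.character(code)
  cached <- .codon_cache[[key]]
  if (!is.null(cached)) return(cached)
  gc <- Biostrings::getGeneticCode(key)
  tab <- data.frame(
    codon = names(gc),
    aa = unname(gc),
    p1 = substr(names(gc), 1L, 1L),
    p2 = substr(names(gc), 2L, 2L),
    p3 = substr(names(gc), 3L, 3L),
    stringsAsFactors = FALSE
  )
  tab$stop <- tab$aa == "*"
  fam_size <- table(tab$aa[!tab$stop])
  tab$degeneracy <- ifelse(tab$stop, NA_integer_,
                           as.integer(fam_size[tab$aa]))
  .codon_cache[[key]] <- tab
  tab
}

# 61 sense codons (standard code) in fixed table order
sense_codons <- function(code = "1") {
  tab <- codon_table(code)
  tab$codon[!tab$stop]
}

# the 59 codons of amino acids with >= 2 synonymous codons
synonymous_codons <- function(code = "1") {
  tab <- codon_table(code)
  tab$codon[!tab$stop & tab$degeneracy >= 2L]
}

stop_codons <- function(code = "1") {
  tab <- codon_table(code)
  tab$codon[tab$stop]
}

# synonymous families: list amino acid -> codons, only degeneracy >= 2
synonymous_families <- function(code = "1") {
  tab <- codon_table(code)
  keep <- !tab$stop & tab$degeneracy >= 2L
  split(tab$codon[keep], tab$aa[keep])
}
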