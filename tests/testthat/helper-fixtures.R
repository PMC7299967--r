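# Shared small helpers for building fixtures in code.

sense_codons_for_tests <- function() {
  tab <- dinocodon::codon_table("1")
  tab$codon[!tab$stop]
}

# strip the class/attribute decoration off a presence matrix
plain_presence <- function(pm) {
  m <- unclass(pm)
  attr(m, "support") <- NULL
  attr(m, "catalog") <- NULL
  m
}
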