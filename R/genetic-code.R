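# Small helpers around the standard genetic code. The codon table itself is
# Biostrings::GENETIC_CODE; only the lookup conventions live here.

stop_codons <- function() c("TAA", "TAG", "TGA")

sense_codons <- function() {
  gc <- Biostrings::GENETIC_CODE
  names(gc)[gc != "*"]
}

# Alternative initiator codons recognized when classifying first-codon SNPs:
# a change of ATG into one of these is a start-codon substitution rather than
# a start loss.
alt_start_codons <- function() c("CTG", "TTG", "GTG")

translate_codon <- function(codon) {
  unname(Biostrings::GENETIC_CODE[codon])
}

comp_base <- function(b) chartr("ACGT", "TGCA", b)

revcomp <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}

random_bases <- function(n) {
  sample(c("A", "C", "G", "T"), n, replace = TRUE)
}
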