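# Small genetic-code helpers shared by the tuning and molecular-evolution
# modules. The standard code is taken from Biostrings; nothing is hand-rolled.

genetic_code <- function() Biostrings::GENETIC_CODE

split_codons <- function(cds) {
  n <- nchar(cds)
  if (n == 0L || n %% 3L != 0L)
    stop_input("coding sequence length must be a positive multiple of 3")
  substring(cds, seq(1L, n, 3L), seq(3L, n, 3L))
}

# Translate an unambiguous in-frame CDS to one-letter amino acids.
translate_cds <- function(cds) {
  codons <- split_codons(toupper(cds))
  aa <- unname(genetic_code()[codons])
  if (anyNA(aa))
    stop_input("CDS contains characters outside ACGT; expand ambiguity ",
               "codes first (see enumerate_haplotype_genotypes)")
  paste(aa, collapse = "")
}

has_internal_stop <- function(protein) {
  body <- substr(protein, 1L, nchar(protein) - 1L)
  grepl("*", body, fixed = TRUE)
}

ambiguous_positions <- function(cds) {
  chars <- strsplit(toupper(cds), "")[[1L]]
  which(!chars %in% c("A", "C", "G", "T"))
}
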