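# Helpers for annotated editing oligos: lowercase letters mark edited
# codons in an otherwise uppercase homology-arm sequence.

#' Count lowercase-edited codons encoding a given amino acid
#'
#' Editing donors are conventionally written with the edited codons in
#' lowercase inside uppercase homology arms. This extracts every maximal
#' lowercase run, reads it in-frame as codons, and counts those that encode
#' the requested residue.
#'
#' @param sequence donor sequence (single string; whitespace ignored).
#' @param codons codon set to count (default the lysine codons AAA/AAG).
#' @return integer count of lowercase codons in the set.
#' @export
count_edited_codons <- function(sequence, codons = c("AAA", "AAG")) {
  s <- gsub("\\s", "", sequence)
  runs <- regmatches(s, gregexpr("[acgtu]+", s))[[1]]
  n <- 0L
  for (r in runs) {
    k <- nchar(r) %/% 3L
    if (k == 0L) next
    trip <- toupper(substring(r, 3L * seq_len(k) - 2L, 3L * seq_len(k)))
    n <- n + sum(trip %in% toupper(codons))
  }
  n
}

#' Path to the bundled MIWI-RK donor oligonucleotide
#'
#' 200-nt single-stranded donor with the edited lysine codons in lowercase,
#' flanked by 84-nt and 83-nt homology arms.
#'
#' @return file path of the bundled plain-text sequence.
#' @export
miwi_rk_donor_path <- function() {
  system.file("extdata", "miwi_rk_donor_oligo.txt", package = "pirnakit",
              mustWork = TRUE)
}
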