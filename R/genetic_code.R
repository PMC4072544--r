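#' The standard nuclear genetic code
#'
#' Returns the standard genetic code as the lookup used throughout the
#' package: all 64 codons over \{A,C,G,T\}, the one-letter amino acid (or
#' `"*"` for a stop) each encodes, and the 61 sense codons in lexicographic
#' order. The sense-codon ordering fixes the state space of the codon rate
#' matrix and of codon pair-count matrices.
#'
#' @return An object of class `genetic_code`: a list with elements
#'   `codon_to_aa` (named character vector of length 64), `sense_codons`
#'   (character vector of length 61) and `stop_codons` (length 3).
#' @examples
#' code <- standard_genetic_code()
#' code$codon_to_aa[["ATG"]]
#' length(code$sense_codons)
#' @export
standard_genetic_code <- function() {
  codon_to_aa <- Biostrings::GENETIC_CODE
  # drop the alt_init_codons attribute; keep a plain named vector
  codon_to_aa <- setNames(as.character(codon_to_aa), names(codon_to_aa))
  # Biostrings uses T-containing names already (DNA alphabet)
  stopifnot(length(codon_to_aa) == 64L)
  sense <- sort(names(codon_to_aa)[codon_to_aa != "*"])
  structure(
    list(
      codon_to_aa = codon_to_aa[sort(names(codon_to_aa))],
      sense_codons = sense,
      stop_codons = sort(names(codon_to_aa)[codon_to_aa == "*"])
    ),
    class = "genetic_code"
  )
}

#' @export
print.genetic_code <- function(x, ...) {
  cat("<genetic_code> standard nuclear code:",
      length(x$sense_codons), "sense codons, stops",
      paste(x$stop_codons, collapse = ", "), "\n")
  invisible(x)
}

DNA_BASES <- c("A", "C", "G", "T")
PURINES <- c("A", "G")

#' Translate codons to one-letter amino acids
#'
#' Vectorised codon translation. Gap codons (`"---"`) translate to `"-"`,
#' codons containing non-ACGT characters to `"X"`.
#'
#' @param codons character vector of 3-letter codons.
#' @param code a [standard_genetic_code()] object.
#' @return character vector of one-letter residues (`"*"` for stops).
#' @export
translate_codons <- function(codons, code = standard_genetic_code()) {
  out <- unname(code$codon_to_aa[codons])
  out[codons == "---"] <- "-"
  out[is.na(out)] <- "X"
  out
}

# All 9 single-nucleotide mutants of a codon (3 positions x 3 alternative bases)
single_nt_mutants <- function(codon) {
  out <- character(9L)
  k <- 1L
  for (pos in 1:3) {
    ref <- substr(codon, pos, pos)
    for (b in DNA_BASES[DNA_BASES != ref]) {
      mut <- codon
      substr(mut, pos, pos) <- b
      out[k] <- mut
      k <- k + 1L
    }
  }
  out
}

# TRUE if the single differing base between two codons is a transition
# (purine<->purine or pyrimidine<->pyrimidine)
is_transition <- function(base_a, base_b) {
  (base_a %in% PURINES) == (base_b %in% PURINES)
}

# canonical unordered pair key, e.g. "AV" for {A, V}
pair_key <- function(a, b) {
  paste0(pmin(a, b), pmax(a, b))
}

#' Amino-acid pairs that are single-nucleotide neighbors in the genetic code
#'
#' Enumerates every unordered pair of distinct amino acids \{a, b\} such that
#' some sense codon of a differs from some sense codon of b at exactly one
#' nucleotide position. Only these pairs can interconvert through a single
#' point mutation, and only these pairs are in the domain of the
#' conservative/non-conservative classification.
#'
#' @param code a [standard_genetic_code()] object.
#' @return A tibble with columns `aa1`, `aa2` (lexicographically ordered
#'   within each row), one row per unordered pair; 75 rows for the standard
#'   code.
#' @examples
#' nrow(single_nt_neighbor_pairs())
#' @export
single_nt_neighbor_pairs <- function(code = standard_genetic_code()) {
  keys <- character(0)
  for (codon in code$sense_codons) {
    aa <- code$codon_to_aa[[codon]]
    muts <- single_nt_mutants(codon)
    aas <- code$codon_to_aa[muts]
    ok <- aas != "*" & aas != aa
    if (any(ok)) keys <- c(keys, pair_key(aa, aas[ok]))
  }
  keys <- sort(unique(keys))
  tibble(aa1 = substr(keys, 1, 1), aa2 = substr(keys, 2, 2))
}
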