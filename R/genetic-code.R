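#' The standard genetic code as a tidy table
#'
#' Tabulates the standard (nuclear) genetic code: one row per codon with the
#' encoded amino acid and the degeneracy of its synonymous-codon family.
#' Leucine, serine and arginine are treated as single six-codon families.
#' Stop codons carry the `"*"` symbol and `NA` degeneracy.
#'
#' @return A tibble with columns `codon` (DNA alphabet, e.g. `"TTT"`),
#'   `amino_acid` (one-letter symbol, `"*"` for stop) and `degeneracy`
#'   (1, 2, 3, 4 or 6; `NA` for stop codons).
#' @examples
#' genetic_code()
#' dplyr::count(genetic_code(), degeneracy)
#' @export
genetic_code <- function() {
  gc <- Biostrings::GENETIC_CODE
  tbl <- tibble::tibble(codon = names(gc), amino_acid = unname(gc))
  deg <- table(tbl$amino_acid[tbl$amino_acid != "*"])
  tbl$degeneracy <- ifelse(tbl$amino_acid == "*", NA_integer_,
                           as.integer(deg[tbl$amino_acid]))
  tbl
}

# codon -> amino acid lookup (named character, 64 entries)
codon_to_aa <- function() Biostrings::GENETIC_CODE

# list: amino acid -> its sense codons
codon_families <- function() {
  gc <- Biostrings::GENETIC_CODE
  fams <- split(names(gc), unname(gc))
  fams[setdiff(names(fams), "*")]
}

sense_codons <- function() {
  gc <- Biostrings::GENETIC_CODE
  names(gc)[gc != "*"]
}

stop_codons <- function() {
  gc <- Biostrings::GENETIC_CODE
  names(gc)[gc == "*"]
}

#' Normalize nucleotide residues to the DNA alphabet
#'
#' Uppercases and replaces U with T. Any character outside `{A, C, G, T}`
#' after normalization (including IUPAC ambiguity codes such as N) raises an
#' error listing the offending symbols.
#'
#' @param x Character vector of nucleotide sequences.
#' @return Character vector of the same length over `{A, C, G, T}`.
#' @examples
#' normalize_residues("augGCu")
#' @export
normalize_residues <- function(x) {
  out <- chartr("U", "T", toupper(x))
  bad <- stringr::str_remove_all(out, "[ACGT]")
  bad_chr <- unique(unlist(strsplit(bad[nzchar(bad)], "")))
  if (length(bad_chr) > 0) {
    rlang::abort(sprintf(
      "non-ACGT/U characters in sequence: %s",
      paste(sort(bad_chr), collapse = ", ")
    ), class = "codonuse_alphabet_error")
  }
  out
}

# split a CDS string into codons; errors if length not divisible by 3
split_codons <- function(sequence) {
  n <- nchar(sequence)
  if (n %% 3 != 0) {
    rlang::abort("sequence length not divisible by 3",
                 class = "codonuse_frame_error")
  }
  substring(sequence, seq(1, n, 3), seq(3, n, 3))
}

# validate a coding sequence: ATG start, single terminal stop, no internal stop
validate_cds <- function(sequence, what = "cds") {
  sequence <- normalize_residues(sequence)
  codons <- split_codons(sequence)
  if (codons[1] != "ATG") {
    rlang::abort(sprintf("%s does not start with ATG", what),
                 class = "codonuse_cds_error")
  }
  is_stop <- codons %in% stop_codons()
  if (!is_stop[length(codons)]) {
    rlang::abort(sprintf("%s does not end with a stop codon", what),
                 class = "codonuse_cds_error")
  }
  if (any(is_stop[-length(codons)])) {
    rlang::abort(sprintf("%s contains an internal stop codon", what),
                 class = "codonuse_cds_error")
  }
  sequence
}
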