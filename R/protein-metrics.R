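#' Kyte-Doolittle hydropathy indices
#'
#' Hydropathy index of each of the 20 standard amino acids on the
#' Kyte-Doolittle scale (isoleucine 4.5 down to arginine -4.5), the scale
#' behind the ProtParam GRAVY statistic.
#'
#' @format Named numeric vector of length 20 (one-letter amino-acid symbols).
#' @examples
#' kyte_doolittle[c("I", "G", "R")]
#' @export
kyte_doolittle <- c(
  A =  1.8, R = -4.5, N = -3.5, D = -3.5, C =  2.5,
  Q = -3.5, E = -3.5, G = -0.4, H = -3.2, I =  4.5,
  L =  3.8, K = -3.9, M =  1.9, F =  2.8, P = -1.6,
  S = -0.8, T = -0.7, W = -0.9, Y = -1.3, V =  4.2
)

gravy_one <- function(protein, scale) {
  if (!nzchar(protein)) {
    rlang::abort("empty protein sequence", class = "codonuse_domain_error")
  }
  aa <- strsplit(toupper(protein), "")[[1]]
  unknown <- setdiff(unique(aa), names(scale))
  if (length(unknown) > 0) {
    rlang::abort(sprintf("unknown residue symbol(s): %s",
                         paste(unknown, collapse = ", ")),
                 class = "codonuse_alphabet_error")
  }
  mean(scale[aa])
}

#' Grand average of hydropathy (GRAVY)
#'
#' The GRAVY score of a protein is the arithmetic mean of the hydropathy
#' indices of its residues. Negative scores mark hydrophilic (water-soluble)
#' proteins, positive scores hydrophobic ones.
#'
#' @param proteins A data frame with columns `id` and `protein` (e.g. from
#'   [translate_cds()]), or a character vector of protein sequences.
#' @param scale Named numeric hydropathy scale; defaults to
#'   [kyte_doolittle].
#' @return For a data frame, the input with `gravy` and `n_residues`
#'   appended; for a character vector, a numeric vector of scores.
#' @examples
#' gravy("GGGG")                     # -0.4
#' gravy(tibble::tibble(id = "x", protein = "IV"))
#' @export
gravy <- function(proteins, scale = kyte_doolittle) {
  stopifnot(is.numeric(scale), all(names(kyte_doolittle) %in% names(scale)))
  if (is.character(proteins)) {
    return(vapply(proteins, gravy_one, numeric(1), scale = scale,
                  USE.NAMES = FALSE))
  }
  stopifnot(is.data.frame(proteins),
            all(c("id", "protein") %in% names(proteins)))
  dplyr::mutate(tibble::as_tibble(proteins),
                gravy = gravy(.data$protein, scale = scale),
                n_residues = nchar(.data$protein))
}
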