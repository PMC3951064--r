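#' Preferred codon of each synonymous family
#'
#' Identifies, per sequence and family row, the codon(s) with maximal RSCU.
#' Two row schemes are supported: `"amino_acid_families"` treats the 18
#' multi-codon amino acids as one row each (Leu, Ser, Arg as six-codon
#' rows), while `"display_rows"` splits serine into its TCN and AGY codon
#' blocks and arginine into CGN and AGR, giving the 20 rows codon-usage
#' tables are conventionally printed in. RSCU values themselves always come
#' from joint six-fold normalization; the scheme only changes the rows
#' within which the maximum is taken.
#'
#' @param rscu_tbl An RSCU tibble from [rscu()].
#' @param scheme `"display_rows"` (default) or `"amino_acid_families"`.
#' @return A tibble with columns `id`, `row`, `amino_acid`, `codons`
#'   (list-column of the argmax set), `ending` (`"AU"`, `"GC"` or
#'   `"mixed"`, from the third bases of the argmax set), `max_rscu` and
#'   `n_tied`. Rows whose family is absent from the sequence are dropped.
#' @examples
#' preferred_codons(rscu(albumin_codon_counts("ALB")))
#' @export
preferred_codons <- function(rscu_tbl,
                             scheme = c("display_rows",
                                        "amino_acid_families")) {
  scheme <- match.arg(scheme)
  stopifnot(is.data.frame(rscu_tbl),
            all(c("id", "codon", "amino_acid", "rscu") %in% names(rscu_tbl)))
  rscu_tbl |>
    dplyr::mutate(row = family_row(.data$codon, .data$amino_acid, scheme)) |>
    dplyr::filter(!is.na(.data$rscu)) |>
    dplyr::group_by(.data$id, .data$row, .data$amino_acid) |>
    dplyr::summarise(
      codons = list(sort(.data$codon[.data$rscu == max(.data$rscu)])),
      max_rscu = max(.data$rscu),
      n_tied = sum(.data$rscu == max(.data$rscu)),
      .groups = "drop"
    ) |>
    dplyr::mutate(ending = vapply(.data$codons, function(x) {
      third <- substr(x, 3, 3)
      if (all(third %in% c("A", "T"))) "AU"
      else if (all(third %in% c("G", "C"))) "GC"
      else "mixed"
    }, character(1))) |>
    dplyr::arrange(.data$id, .data$row)
}

# row label under the chosen scheme
family_row <- function(codon, amino_acid, scheme) {
  if (scheme == "amino_acid_families") return(amino_acid)
  dplyr::case_when(
    amino_acid == "S" & substr(codon, 1, 1) == "T" ~ "S(TCN)",
    amino_acid == "S" ~ "S(AGY)",
    amino_acid == "R" & substr(codon, 1, 1) == "C" ~ "R(CGN)",
    amino_acid == "R" ~ "R(AGR)",
    .default = amino_acid
  )
}

#' Tally A/U-ending versus G/C-ending preferred codons
#'
#' Counts, per sequence, how many family rows prefer an A- or U-ending
#' codon versus a G- or C-ending codon. By default any row whose maximal
#' RSCU is shared by several codons is excluded from both tallies and
#' reported under `tie_rows`; with `ties = "count_if_consistent"` a tied
#' row still counts when all tied codons share an A/U or G/C ending, and
#' only mixed-ending ties are excluded.
#'
#' @param rscu_tbl An RSCU tibble from [rscu()], or the output of
#'   [preferred_codons()].
#' @inheritParams preferred_codons
#' @param ties `"exclude"` (default) or `"count_if_consistent"`.
#' @return A tibble with one row per `id`: `scheme`, `n_rows` (family rows
#'   present), `au_count`, `gc_count` and `tie_rows` (rows excluded).
#' @examples
#' au_gc_tally(rscu(albumin_codon_counts("ALB")))
#' @export
au_gc_tally <- function(rscu_tbl,
                        scheme = c("display_rows", "amino_acid_families"),
                        ties = c("exclude", "count_if_consistent")) {
  scheme <- match.arg(scheme)
  ties <- match.arg(ties)
  pref <- if ("codons" %in% names(rscu_tbl) && "n_tied" %in% names(rscu_tbl)) {
    rscu_tbl
  } else {
    preferred_codons(rscu_tbl, scheme = scheme)
  }
  pref |>
    dplyr::mutate(.counted = if (ties == "exclude") .data$n_tied == 1
                  else .data$ending != "mixed") |>
    dplyr::group_by(.data$id) |>
    dplyr::summarise(
      scheme = scheme,
      n_rows = dplyr::n(),
      au_count = sum(.data$.counted & .data$ending == "AU"),
      gc_count = sum(.data$.counted & .data$ending == "GC"),
      tie_rows = sum(!.data$.counted),
      .groups = "drop"
    )
}
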