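#' Count codon usage in coding sequences
#'
#' Tallies sense codons of each coding sequence; the terminal stop codon is
#' excluded, so totals equal `length_bp / 3 - 1`. The output covers all 61
#' sense codons per sequence, with explicit zeros for unused ones.
#'
#' @param cds_tbl A data frame with columns `id` and `cds`, e.g. from
#'   [extract_orf()].
#' @return A tibble with columns `id`, `codon`, `amino_acid`, `degeneracy`
#'   and `count`, one row per sense codon per sequence.
#' @examples
#' counts <- count_codons(tibble::tibble(id = "x", cds = "ATGTTTTTTTAA"))
#' dplyr::filter(counts, count > 0)
#' @export
count_codons <- function(cds_tbl) {
  stopifnot(is.data.frame(cds_tbl), all(c("id", "cds") %in% names(cds_tbl)))
  code <- dplyr::filter(genetic_code(), .data$amino_acid != "*")
  purrr::map2_dfr(cds_tbl$id, cds_tbl$cds, function(id, cds) {
    cds <- validate_cds(cds, what = id)
    codons <- split_codons(cds)
    codons <- codons[-length(codons)] # drop terminal stop
    tab <- table(factor(codons, levels = code$codon))
    dplyr::mutate(code, count = as.integer(tab[code$codon]), id = id,
                  .before = 1) |>
      dplyr::relocate("count", .after = "degeneracy")
  })
}

#' Read a per-codon count table
#'
#' Reads a TSV with columns `codon` and `count` (DNA or RNA codons, any
#' case), the interchange format for analysing published count tables
#' without the underlying sequences. Codons absent from the file get count
#' zero; stop codons are rejected.
#'
#' @param path Path to a tab-separated file with columns `codon`, `count`.
#' @param id Identifier attached to the table (default: file base name).
#' @return A tibble in the schema of [count_codons()].
#' @export
read_codon_counts <- function(path, id = NULL) {
  if (is.null(id)) {
    id <- sub("\\.[^.]*$", "", basename(path))
  }
  raw <- readr::read_tsv(path, col_types = readr::cols(
    codon = readr::col_character(), count = readr::col_integer()
  ))
  raw$codon <- normalize_residues(raw$codon)
  if (any(nchar(raw$codon) != 3) || anyDuplicated(raw$codon)) {
    rlang::abort("codon column must hold unique 3-letter codons",
                 class = "codonuse_parse_error")
  }
  if (any(raw$codon %in% stop_codons())) {
    rlang::abort("stop codons are not part of a codon-usage count table",
                 class = "codonuse_parse_error")
  }
  if (any(raw$count < 0)) {
    rlang::abort("negative codon counts", class = "codonuse_parse_error")
  }
  code <- dplyr::filter(genetic_code(), .data$amino_acid != "*")
  counts <- setNames(raw$count, raw$codon)[code$codon]
  counts[is.na(counts)] <- 0L
  dplyr::mutate(code, count = as.integer(counts), id = id, .before = 1) |>
    dplyr::relocate("count", .after = "degeneracy")
}

#' Nucleotide composition of coding sequences
#'
#' Counts A, T, G and C over the full coding sequence (stop codon included)
#' and derives the percentage of each base and the combined A+T and G+C
#' content. Percentages are exact count ratios; rounding is left to report
#' formatting.
#'
#' @param cds_tbl A data frame with columns `id` and `cds` (or `sequence`).
#' @return A tibble with one row per sequence: `id`, `length_bp`, `n_A`,
#'   `n_T`, `n_G`, `n_C`, `pct_A` .. `pct_C`, `pct_AT`, `pct_GC`.
#' @examples
#' nucleotide_composition(tibble::tibble(id = "x", cds = "ATGGGCTAA"))
#' @export
nucleotide_composition <- function(cds_tbl) {
  col <- if ("cds" %in% names(cds_tbl)) "cds" else "sequence"
  stopifnot(is.data.frame(cds_tbl), all(c("id", col) %in% names(cds_tbl)))
  seqs <- normalize_residues(cds_tbl[[col]])
  n <- vapply(c("A", "T", "G", "C"), function(b) {
    stringr::str_count(seqs, stringr::fixed(b))
  }, numeric(length(seqs)))
  n <- matrix(n, nrow = length(seqs),
              dimnames = list(NULL, c("A", "T", "G", "C")))
  composition_from_counts(tibble::tibble(
    id = cds_tbl$id, A = n[, "A"], T = n[, "T"], G = n[, "G"], C = n[, "C"]
  ))
}

#' Composition summary from per-base counts
#'
#' Same derivation as [nucleotide_composition()] but starting from already
#' tabulated A/T/G/C counts, so published per-gene nucleotide tallies can be
#' summarized without the sequences.
#'
#' @param counts A data frame with columns `id`, `A`, `T`, `G`, `C`.
#' @return A tibble in the schema of [nucleotide_composition()].
#' @export
composition_from_counts <- function(counts) {
  stopifnot(is.data.frame(counts),
            all(c("id", "A", "T", "G", "C") %in% names(counts)))
  a <- as.numeric(unname(counts$A)); t <- as.numeric(unname(counts$T))
  g <- as.numeric(unname(counts$G)); c <- as.numeric(unname(counts$C))
  len <- a + t + g + c
  tibble::tibble(
    id = counts$id,
    length_bp = as.integer(len),
    n_A = as.integer(a), n_T = as.integer(t),
    n_G = as.integer(g), n_C = as.integer(c),
    pct_A = 100 * a / len, pct_T = 100 * t / len,
    pct_G = 100 * g / len, pct_C = 100 * c / len,
    pct_AT = 100 * (a + t) / len,
    pct_GC = 100 * (g + c) / len
  )
}

#' GC content at synonymous third codon positions (GC3s)
#'
#' Fraction of G- or C-ending codons among codons of amino acids with more
#' than one synonymous codon. Methionine, tryptophan and stop codons enter
#' neither numerator nor denominator.
#'
#' @param counts A codon-count tibble from [count_codons()],
#'   [read_codon_counts()] or [albumin_codon_counts()].
#' @return A tibble with one row per `id`: `n_synonymous` (codons counted),
#'   `n_gc_ending` and `gc3s_pct` (= 100 * n_gc_ending / n_synonymous).
#' @examples
#' gc3s(albumin_codon_counts("ALB"))
#' @export
gc3s <- function(counts) {
  check_counts(counts)
  out <- counts |>
    dplyr::filter(.data$degeneracy > 1) |>
    dplyr::group_by(.data$id) |>
    dplyr::summarise(
      n_synonymous = sum(.data$count),
      n_gc_ending = sum(.data$count[substr(.data$codon, 3, 3) %in% c("G", "C")]),
      .groups = "drop"
    )
  if (any(out$n_synonymous == 0)) {
    rlang::abort("GC3s undefined: no synonymous codons",
                 class = "codonuse_undefined_error")
  }
  dplyr::mutate(out, gc3s_pct = 100 * .data$n_gc_ending / .data$n_synonymous)
}

#' Relative synonymous codon usage (RSCU)
#'
#' For each amino acid with `n` synonymous codons, the RSCU of codon `j` is
#' its observed count divided by the count expected were all `n` codons used
#' equally: `RSCU_j = count_j * n / family_total`. Values above 1 mark
#' codons used more often than expected. The six-codon families (Leu, Ser,
#' Arg) are normalized jointly over all six codons. Methionine and
#' tryptophan (single-codon families) are excluded; families with zero
#' occurrences yield `NA`.
#'
#' @inheritParams gc3s
#' @return The count tibble restricted to multi-codon families, with
#'   `family_total` and `rscu` columns appended.
#' @examples
#' rscu(albumin_codon_counts("ALB")) |>
#'   dplyr::filter(amino_acid == "F")
#' @export
rscu <- function(counts) {
  check_counts(counts)
  counts |>
    dplyr::filter(.data$degeneracy > 1) |>
    dplyr::group_by(.data$id, .data$amino_acid) |>
    dplyr::mutate(family_total = sum(.data$count)) |>
    dplyr::ungroup() |>
    dplyr::mutate(rscu = dplyr::if_else(
      .data$family_total > 0,
      .data$count * .data$degeneracy / .data$family_total,
      NA_real_
    ))
}

# per-family Wright homozygosity: F = (n * sum(p^2) - 1) / (n - 1)
family_homozygosity <- function(counts) {
  counts |>
    dplyr::filter(.data$degeneracy > 1) |>
    dplyr::group_by(.data$id, .data$amino_acid, .data$degeneracy) |>
    dplyr::summarise(n = sum(.data$count),
                     sum_p2 = ifelse(sum(.data$count) > 0,
                                     sum((.data$count / sum(.data$count))^2),
                                     NA_real_),
                     .groups = "drop") |>
    dplyr::mutate(f = dplyr::if_else(.data$n >= 2,
                                     (.data$n * .data$sum_p2 - 1) / (.data$n - 1),
                                     NA_real_))
}

#' Wright's effective number of codons (Nc)
#'
#' The observed effective number of codons summarizes codon-usage bias on a
#' scale from 20 (one codon per amino acid) to 61 (uniform synonymous
#' usage). Each multi-codon family contributes a bias-corrected
#' homozygosity `F = (n * sum(p_j^2) - 1) / (n - 1)` computed from its codon
#' proportions `p_j`; `F` is averaged within degeneracy classes and
#' `Nc = 2 + 9 / F2 + 1 / F3 + 5 / F4 + 3 / F6`.
#'
#' Families with fewer than two occurrences, or with non-positive `F`, are
#' excluded from their class mean. If the three-fold class (isoleucine
#' alone) is empty its mean is imputed as the average of the two- and
#' four-fold class means; an empty two-, four- or six-fold class is an
#' error. Nc is capped at 61.
#'
#' @inheritParams gc3s
#' @return A tibble with one row per `id`: class mean homozygosities
#'   `f2`, `f3`, `f4`, `f6`, the number of families behind each mean
#'   (`n_fam2` .. `n_fam6`), and `nc`.
#' @examples
#' enc_observed(albumin_codon_counts("ALB"))
#' @export
enc_observed <- function(counts) {
  check_counts(counts)
  fams <- family_homozygosity(counts) |>
    dplyr::filter(!is.na(.data$f), .data$f > 0)
  cls <- fams |>
    dplyr::group_by(.data$id, .data$degeneracy) |>
    dplyr::summarise(fbar = mean(.data$f), n_fam = dplyr::n(),
                     .groups = "drop") |>
    tidyr::complete(id = unique(counts$id),
                    degeneracy = c(2L, 3L, 4L, 6L),
                    fill = list(n_fam = 0L)) |>
    tidyr::pivot_wider(names_from = "degeneracy",
                       values_from = c("fbar", "n_fam"))
  out <- cls |>
    dplyr::mutate(
      fbar_3 = dplyr::if_else(is.na(.data$fbar_3),
                              (.data$fbar_2 + .data$fbar_4) / 2,
                              .data$fbar_3)
    )
  bad <- is.na(out$fbar_2) | is.na(out$fbar_4) | is.na(out$fbar_6) |
    is.na(out$fbar_3)
  if (any(bad)) {
    rlang::abort(sprintf(
      "Nc undefined (empty degeneracy class with no fallback) for: %s",
      paste(out$id[bad], collapse = ", ")
    ), class = "codonuse_undefined_error")
  }
  out |>
    dplyr::transmute(
      id = .data$id,
      f2 = .data$fbar_2, f3 = .data$fbar_3, f4 = .data$fbar_4,
      f6 = .data$fbar_6,
      n_fam2 = .data$n_fam_2, n_fam3 = .data$n_fam_3,
      n_fam4 = .data$n_fam_4, n_fam6 = .data$n_fam_6,
      nc = pmin(61, 2 + 9 / .data$f2 + 1 / .data$f3 + 5 / .data$f4 +
                  3 / .data$f6)
    )
}

#' Expected effective number of codons under GC3 alone
#'
#' Under mutation pressure and drift only, the effective number of codons
#' expected for a gene with synonymous third-position G+C fraction `s` is
#' `2 + s + 29 / (s^2 + (1 - s)^2)`. Genes whose observed Nc falls well
#' below this curve are candidates for selection on codon usage.
#'
#' @param s Numeric vector of GC3s fractions in `[0, 1]`.
#' @return Numeric vector of expected Nc values (not capped).
#' @examples
#' enc_expected(0.5) # 60.5
#' enc_expected(0)   # 31
#' @export
enc_expected <- function(s) {
  if (!is.numeric(s) || any(is.na(s)) || any(s < 0 | s > 1)) {
    rlang::abort("s must be a GC3 fraction in [0, 1]",
                 class = "codonuse_domain_error")
  }
  2 + s + 29 / (s^2 + (1 - s)^2)
}

# schema check shared by the count-consuming statistics
check_counts <- function(counts) {
  need <- c("id", "codon", "amino_acid", "degeneracy", "count")
  if (!is.data.frame(counts) || !all(need %in% names(counts))) {
    rlang::abort(sprintf(
      "expected a codon-count table with columns %s (see count_codons())",
      paste(need, collapse = ", ")
    ), class = "codonuse_schema_error")
  }
  invisible(counts)
}
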