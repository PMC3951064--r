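#' Bundled human codon-usage reference
#'
#' The packaged human codon-usage frequency table (occurrences per thousand
#' codons over a large set of human coding sequences, the table commonly
#' shipped with codon-analysis tools), covering all 61 sense codons.
#'
#' @return A tibble with columns `codon`, `amino_acid`, `degeneracy` and
#'   `per_thousand`.
#' @examples
#' human_codon_usage()
#' @export
human_codon_usage <- function() {
  read_usage_table(system.file("extdata", "human_codon_usage.tsv",
                               package = "codonuse"))
}

#' Read a codon-usage reference table
#'
#' @param path TSV with columns `codon` and `per_thousand` (or any single
#'   numeric usage column named `per_thousand`); units only need to be
#'   consistent within the table.
#' @return A tibble with columns `codon`, `amino_acid`, `degeneracy`,
#'   `per_thousand`, covering all 61 sense codons.
#' @export
read_usage_table <- function(path) {
  raw <- readr::read_tsv(path, col_types = readr::cols(
    codon = readr::col_character(), per_thousand = readr::col_double()
  ))
  raw$codon <- normalize_residues(raw$codon)
  code <- dplyr::filter(genetic_code(), .data$amino_acid != "*")
  missing <- setdiff(code$codon, raw$codon)
  if (length(missing) > 0) {
    rlang::abort(sprintf("usage table lacks sense codons: %s",
                         paste(missing, collapse = ", ")),
                 class = "codonuse_schema_error")
  }
  dplyr::inner_join(code, raw[c("codon", "per_thousand")], by = "codon")
}

#' Scale codon usage relative to each family's most-used codon
#'
#' Rescales a codon-usage reference so the most-used codon of every
#' synonymous family scores 100; single-codon amino acids (Met, Trp) score
#' 100 by construction. Codons scoring below a threshold (30 by convention)
#' are called rare.
#'
#' @param usage A usage tibble from [human_codon_usage()] or
#'   [read_usage_table()].
#' @return The input with a `relative_score` column in `(0, 100]` appended.
#' @examples
#' relative_adaptiveness(human_codon_usage()) |>
#'   dplyr::filter(relative_score < 30)
#' @export
relative_adaptiveness <- function(usage) {
  stopifnot(is.data.frame(usage),
            all(c("codon", "amino_acid", "per_thousand") %in% names(usage)))
  if (any(usage$per_thousand <= 0)) {
    rlang::abort("usage frequencies must be positive",
                 class = "codonuse_domain_error")
  }
  usage |>
    dplyr::group_by(.data$amino_acid) |>
    dplyr::mutate(relative_score =
                    100 * .data$per_thousand / max(.data$per_thousand)) |>
    dplyr::ungroup()
}

#' Rare-codon content of coding sequences
#'
#' Scores every sense codon of each sequence against a host codon-usage
#' reference scaled per family to a 0-100 range ([relative_adaptiveness()])
#' and reports the percentage of codons falling below the rare-codon
#' threshold. Such codons are depleted in the host's highly expressed genes
#' and can limit translational efficiency.
#'
#' @param x A coding-sequence tibble (`id`, `cds`) or a codon-count tibble
#'   from [count_codons()] / [albumin_codon_counts()].
#' @param reference A usage table; scored with [relative_adaptiveness()] if
#'   it has no `relative_score` column. Defaults to the bundled human table.
#' @param threshold Relative-score cutoff below which a codon is rare
#'   (default 30).
#' @return A tibble with one row per `id`: `n_codons`, `n_rare`, `pct_low`
#'   (exact percentage), `pct_low_rounded` (nearest integer, half away from
#'   zero, as such figures are conventionally reported) and `threshold`.
#' @examples
#' rare_codon_fraction(albumin_codon_counts("ALB"))
#' @export
rare_codon_fraction <- function(x, reference = human_codon_usage(),
                                threshold = 30) {
  stopifnot(is.numeric(threshold), length(threshold) == 1)
  if (!"relative_score" %in% names(reference)) {
    reference <- relative_adaptiveness(reference)
  }
  counts <- if ("count" %in% names(x)) check_counts(x) else count_codons(x)
  counts |>
    dplyr::inner_join(reference[c("codon", "relative_score")], by = "codon") |>
    dplyr::group_by(.data$id) |>
    dplyr::summarise(
      n_codons = sum(.data$count, na.rm = TRUE),
      n_rare = sum(.data$count[.data$relative_score < threshold],
                   na.rm = TRUE),
      .groups = "drop"
    ) |>
    dplyr::mutate(pct_low = 100 * .data$n_rare / .data$n_codons,
                  pct_low_rounded = round_half_up(.data$pct_low, 0),
                  threshold = threshold)
}

#' Per-position relative codon scores
#'
#' The codon-by-codon score track behind a rare-codon frequency plot: each
#' sense codon position of a coding sequence annotated with its relative
#' usage score in the host.
#'
#' @inheritParams rare_codon_fraction
#' @param cds_tbl A data frame with columns `id` and `cds`.
#' @return A tibble with columns `id`, `position` (codon index, start codon
#'   = 1), `codon`, `amino_acid` and `relative_score`.
#' @export
codon_score_track <- function(cds_tbl, reference = human_codon_usage()) {
  stopifnot(is.data.frame(cds_tbl), all(c("id", "cds") %in% names(cds_tbl)))
  if (!"relative_score" %in% names(reference)) {
    reference <- relative_adaptiveness(reference)
  }
  purrr::map2_dfr(cds_tbl$id, cds_tbl$cds, function(id, cds) {
    codons <- split_codons(validate_cds(cds, what = id))
    codons <- codons[-length(codons)]
    tibble::tibble(id = id, position = seq_along(codons), codon = codons)
  }) |>
    dplyr::left_join(
      reference[c("codon", "amino_acid", "relative_score")], by = "codon"
    )
}
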