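#' Run the full codon-usage analysis
#'
#' One-call pipeline: reads sequences and/or packaged count tables, and for
#' each gene computes nucleotide composition, GRAVY, GC3s, observed and
#' expected effective number of codons, RSCU, the rare-codon fraction and
#' the A/U-vs-G/C preferred-codon tally. Sequence-level statistics
#' (composition over the full ORF, GRAVY) are `NA` for inputs supplied as
#' bare count tables.
#'
#' @param fasta Optional path to a FASTA file of mRNA or CDS sequences; the
#'   ORF of each record is selected with [extract_orf()].
#' @param fixtures Optional character vector of packaged albumin-superfamily
#'   gene names (see [albumin_codon_counts()]).
#' @param counts Optional codon-count tibble (schema of [count_codons()])
#'   analysed as-is.
#' @param reference Codon-usage reference for the rare-codon analysis;
#'   default [human_codon_usage()].
#' @param rare_threshold Rare-codon relative-score cutoff (default 30).
#' @param scheme Row scheme for the preference tally (see [au_gc_tally()]).
#' @return An object of class `codon_usage_report`: a list with tibbles
#'   `summary` (one row per gene), `rscu`, `preference` and `rare`.
#'   Use [glance()][generics::glance], [tidy()][generics::tidy],
#'   [autoplot()][ggplot2::autoplot] and [write_report()] on it.
#' @examples
#' report <- analyze(fixtures = c("ALB", "VDBP"))
#' glance(report)
#' @export
analyze <- function(fasta = NULL, fixtures = NULL, counts = NULL,
                    reference = human_codon_usage(), rare_threshold = 30,
                    scheme = "display_rows") {
  if (is.null(fasta) && is.null(fixtures) && is.null(counts)) {
    rlang::abort("supply at least one of fasta, fixtures or counts",
                 class = "codonuse_input_error")
  }
  all_counts <- list()
  seq_summary <- NULL
  if (!is.null(fasta)) {
    cds <- read_fasta(fasta) |>
      extract_orf() |>
      translate_cds() |>
      gravy()
    comp <- nucleotide_composition(cds)
    seq_summary <- dplyr::left_join(
      dplyr::select(cds, "id", orf_length_bp = "length_bp", "gravy",
                    "n_residues"),
      dplyr::select(comp, -"length_bp"), by = "id"
    )
    all_counts <- c(all_counts, list(count_codons(cds)))
  }
  if (!is.null(fixtures)) {
    all_counts <- c(all_counts, list(albumin_codon_counts(fixtures)))
  }
  if (!is.null(counts)) {
    all_counts <- c(all_counts, list(check_counts(counts)))
  }
  counts_tbl <- dplyr::bind_rows(all_counts)
  ids <- unique(counts_tbl$id)

  gc3 <- gc3s(counts_tbl)
  enc <- enc_observed(counts_tbl)
  rscu_tbl <- rscu(counts_tbl)
  rare <- rare_codon_fraction(counts_tbl, reference = reference,
                              threshold = rare_threshold)
  pref <- au_gc_tally(rscu_tbl, scheme = scheme)

  summary <- tibble::tibble(id = ids)
  if (!is.null(seq_summary)) {
    summary <- dplyr::left_join(summary, seq_summary, by = "id")
  }
  summary <- summary |>
    dplyr::left_join(
      dplyr::select(gc3, "id", "gc3s_pct", "n_synonymous"), by = "id") |>
    dplyr::left_join(dplyr::select(enc, "id", enc_observed = "nc"),
                     by = "id") |>
    dplyr::mutate(enc_expected = enc_expected(.data$gc3s_pct / 100)) |>
    dplyr::left_join(
      dplyr::select(rare, "id", rare_pct = "pct_low",
                    rare_threshold = "threshold"), by = "id") |>
    dplyr::left_join(
      dplyr::select(pref, "id", "au_count", "gc_count", "tie_rows"),
      by = "id")
  if (!"gravy" %in% names(summary)) {
    summary <- dplyr::mutate(summary, orf_length_bp = NA_integer_,
                             gravy = NA_real_, pct_GC = NA_real_,
                             pct_AT = NA_real_, .after = "id")
  }
  structure(
    list(summary = summary, rscu = rscu_tbl, preference = pref, rare = rare,
         scheme = scheme, rare_threshold = rare_threshold),
    class = "codon_usage_report"
  )
}

#' @export
print.codon_usage_report <- function(x, ...) {
  cat("<codon_usage_report>", nrow(x$summary), "gene(s);",
      "scheme:", x$scheme, "| rare-codon threshold:", x$rare_threshold, "\n")
  print(glance(x), ...)
  invisible(x)
}

#' Glance at a codon-usage report
#'
#' @param x A `codon_usage_report` from [analyze()].
#' @param ... Unused.
#' @return One row per gene with the headline statistics: ORF length, GC
#'   and GC3s percentages, GRAVY, observed and expected effective number of
#'   codons, rare-codon percentage and the A/U vs G/C preference tally.
#' @method glance codon_usage_report
#' @export
glance.codon_usage_report <- function(x, ...) {
  dplyr::select(x$summary, "id", dplyr::any_of(c(
    "orf_length_bp", "pct_GC", "pct_AT", "gravy", "gc3s_pct",
    "enc_observed", "enc_expected", "rare_pct", "au_count", "gc_count",
    "tie_rows"
  )))
}

#' Tidy a codon-usage report into a long per-codon table
#'
#' @param x A `codon_usage_report` from [analyze()].
#' @param ... Unused.
#' @return The long RSCU tibble: one row per gene x sense codon of the
#'   multi-codon families, with counts and RSCU values.
#' @method tidy codon_usage_report
#' @export
tidy.codon_usage_report <- function(x, ...) {
  x$rscu
}

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom generics tidy
#' @export
generics::tidy

#' Write a codon-usage report to disk
#'
#' `format = "tsv"` writes `summary.tsv` (one row per gene, numbers at the
#' precision codon-usage tables are conventionally printed at: composition
#' 3 dp, GRAVY 3 dp, ENC/GC3s 2 dp) and `rscu.tsv` (long table, RSCU 2 dp);
#' re-running on identical input yields byte-identical files.
#' `format = "json"` writes a single loss-less full-precision `report.json`.
#'
#' @param report A `codon_usage_report` from [analyze()].
#' @param dir Output directory (created if needed).
#' @param format `"tsv"` or `"json"`.
#' @return Character vector of the files written, invisibly.
#' @export
write_report <- function(report, dir, format = c("tsv", "json")) {
  stopifnot(inherits(report, "codon_usage_report"))
  format <- match.arg(format)
  if (nrow(report$summary) == 0) {
    rlang::abort("empty report", class = "codonuse_input_error")
  }
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (format == "json") {
    path <- file.path(dir, "report.json")
    jsonlite::write_json(
      list(summary = report$summary, rscu = report$rscu,
           preference = report$preference, rare = report$rare),
      path, digits = NA, na = "null", pretty = TRUE
    )
    return(invisible(path))
  }
  summary <- report$summary |>
    dplyr::mutate(
      dplyr::across(dplyr::any_of(c("pct_A", "pct_T", "pct_G", "pct_C")),
                    ~ format_fixed(.x, 1)),
      dplyr::across(dplyr::any_of(c("pct_AT", "pct_GC", "gravy")),
                    ~ format_fixed(.x, 3)),
      dplyr::across(dplyr::any_of(c("gc3s_pct", "enc_observed",
                                    "enc_expected", "rare_pct")),
                    ~ format_fixed(.x, 2))
    )
  spath <- file.path(dir, "summary.tsv")
  rpath <- file.path(dir, "rscu.tsv")
  rscu_out <- dplyr::mutate(report$rscu, rscu = format_fixed(.data$rscu, 2))
  utils::write.table(summary, spath, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  utils::write.table(rscu_out, rpath, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(c(spath, rpath))
}
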