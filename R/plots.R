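#' Effective-number-of-codons plot
#'
#' The classic codon-bias diagnostic: observed Nc for each gene against its
#' synonymous GC3, over the null curve of Nc expected when composition
#' alone (mutation pressure and drift) shapes codon usage. Points on or
#' near the curve indicate little selection on synonymous sites; points
#' well below it indicate biased usage beyond composition.
#'
#' @param object A `codon_usage_report` from [analyze()].
#' @param ... Unused.
#' @return A ggplot object.
#' @examples
#' autoplot(analyze(fixtures = "ALB"))
#' @method autoplot codon_usage_report
#' @export
autoplot.codon_usage_report <- function(object, ...) {
  curve <- tibble::tibble(gc3 = seq(0, 1, by = 0.005),
                          nc = enc_expected(seq(0, 1, by = 0.005)))
  ggplot2::ggplot(object$summary,
                  ggplot2::aes(x = .data$gc3s_pct / 100,
                               y = .data$enc_observed)) +
    ggplot2::geom_line(data = curve,
                       ggplot2::aes(x = .data$gc3, y = .data$nc),
                       linetype = "dashed", colour = "grey40") +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_text(ggplot2::aes(label = .data$id),
                       vjust = -0.8, size = 3) +
    ggplot2::coord_cartesian(ylim = c(20, 62)) +
    ggplot2::labs(x = "GC3s (fraction)", y = "Effective number of codons",
                  title = "Observed Nc against the composition-only expectation") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' RSCU profile plot
#'
#' Bar panel of RSCU values per amino-acid family and gene; the horizontal
#' line at 1 marks unbiased synonymous usage.
#'
#' @param report A `codon_usage_report` from [analyze()].
#' @param amino_acids Optional subset of one-letter amino-acid symbols.
#' @return A ggplot object.
#' @export
plot_rscu <- function(report, amino_acids = NULL) {
  stopifnot(inherits(report, "codon_usage_report"))
  dat <- report$rscu
  if (!is.null(amino_acids)) {
    dat <- dplyr::filter(dat, .data$amino_acid %in% amino_acids)
  }
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$codon, y = .data$rscu,
                                    fill = .data$id)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::geom_hline(yintercept = 1, linetype = "dotted") +
    ggplot2::facet_wrap(~amino_acid, scales = "free_x") +
    ggplot2::labs(x = NULL, y = "RSCU", fill = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}

#' Rare-codon score track plot
#'
#' Per-position relative codon-usage scores along a coding sequence, with
#' the rare-codon threshold drawn as a horizontal line.
#'
#' @param cds_tbl A data frame with columns `id` and `cds`.
#' @param reference Codon-usage reference (default [human_codon_usage()]).
#' @param threshold Rare-codon cutoff drawn on the plot.
#' @return A ggplot object.
#' @export
plot_codon_track <- function(cds_tbl, reference = human_codon_usage(),
                             threshold = 30) {
  track <- codon_score_track(cds_tbl, reference = reference)
  ggplot2::ggplot(track, ggplot2::aes(x = .data$position,
                                      y = .data$relative_score)) +
    ggplot2::geom_col(width = 1,
                      ggplot2::aes(fill = .data$relative_score < threshold)) +
    ggplot2::scale_fill_manual(values = c(`FALSE` = "grey60",
                                          `TRUE` = "firebrick"),
                               labels = c("common", "rare"), name = NULL) +
    ggplot2::geom_hline(yintercept = threshold, linetype = "dashed") +
    ggplot2::facet_wrap(~id, ncol = 1) +
    ggplot2::labs(x = "Codon position", y = "Relative usage score") +
    ggplot2::theme_minimal()
}
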