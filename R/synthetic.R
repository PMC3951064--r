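#' Specify a codon-usage model for sequence simulation
#'
#' Describes an i.i.d. codon model: interior codons are drawn by first
#' sampling an amino acid from `aa_probs`, then a codon from that amino
#' acid's `family_probs`. Defaults are uniform over the 20 standard amino
#' acids and uniform within every family, i.e. unbiased synonymous usage.
#'
#' @param n_codons Number of interior codons to simulate (start and stop
#'   codons are added on top).
#' @param aa_probs Named probability vector over (a subset of) the 20
#'   amino-acid symbols; normalized to sum to 1.
#' @param family_probs Named list, amino-acid symbol -> probability vector
#'   over that family's codons (named by codon, or unnamed in the codon
#'   order of [genetic_code()]). Families not listed stay uniform.
#' @param seed Integer seed making generation reproducible.
#' @return An object of class `usage_spec`.
#' @examples
#' usage_spec(100, family_probs = list(F = c(TTT = 0.714, TTC = 0.286)))
#' @export
usage_spec <- function(n_codons, aa_probs = NULL, family_probs = NULL,
                       seed = 1L) {
  stopifnot(is.numeric(n_codons), length(n_codons) == 1, n_codons >= 1)
  fams <- codon_families()
  fams <- fams[setdiff(names(fams), character(0))]
  if (is.null(aa_probs)) {
    aa_probs <- setNames(rep(1 / length(fams), length(fams)), names(fams))
  }
  aa_probs <- check_probs(aa_probs, names(fams), "aa_probs")
  fp <- lapply(names(fams), function(aa) {
    p <- family_probs[[aa]]
    if (is.null(p)) {
      p <- setNames(rep(1 / length(fams[[aa]]), length(fams[[aa]])),
                    fams[[aa]])
    }
    if (is.null(names(p))) names(p) <- fams[[aa]]
    check_probs(p, fams[[aa]], paste0("family_probs$", aa))
  })
  names(fp) <- names(fams)
  structure(list(n_codons = as.integer(n_codons), aa_probs = aa_probs,
                 family_probs = fp, seed = as.integer(seed)),
            class = "usage_spec")
}

check_probs <- function(p, allowed, what) {
  if (!is.numeric(p) || is.null(names(p)) ||
      !all(names(p) %in% allowed) || any(p < 0)) {
    rlang::abort(sprintf("%s must be non-negative and named among: %s",
                         what, paste(allowed, collapse = ", ")),
                 class = "codonuse_spec_error")
  }
  if (sum(p) <= 0) {
    rlang::abort(sprintf("%s has zero total probability", what),
                 class = "codonuse_spec_error")
  }
  full <- setNames(rep(0, length(allowed)), allowed)
  full[names(p)] <- p
  full / sum(full)
}

#' Simulate coding sequences with controlled codon usage
#'
#' Draws interior codons i.i.d. from a [usage_spec()] model, prepends ATG
#' and appends a TAA stop, yielding valid coding sequences whose empirical
#' codon frequencies converge to the specified probabilities. The same seed
#' always reproduces the same sequences.
#'
#' @param spec A [usage_spec()].
#' @param n_sequences Number of independent sequences to generate.
#' @param id_prefix Identifier prefix; sequences are named
#'   `<prefix>1 .. <prefix>n`.
#' @return A tibble with columns `id`, `cds`, `length_bp`, `n_codons` and
#'   `seed`, directly consumable by [count_codons()] and friends.
#' @examples
#' generate_cds(usage_spec(10, seed = 42))
#' @export
generate_cds <- function(spec, n_sequences = 1, id_prefix = "sim") {
  stopifnot(inherits(spec, "usage_spec"))
  # flatten the hierarchical model to one categorical draw per codon
  codon_p <- unlist(lapply(names(spec$aa_probs), function(aa) {
    spec$aa_probs[[aa]] * spec$family_probs[[aa]]
  }))
  names(codon_p) <- unlist(lapply(names(spec$aa_probs),
                                  function(aa) names(spec$family_probs[[aa]])))
  if (sum(codon_p) <= 0) {
    rlang::abort("degenerate usage spec: zero probability everywhere",
                 class = "codonuse_spec_error")
  }
  seqs <- withr::with_seed(spec$seed, {
    vapply(seq_len(n_sequences), function(i) {
      codons <- sample(names(codon_p), spec$n_codons, replace = TRUE,
                       prob = codon_p)
      paste0("ATG", paste(codons, collapse = ""), "TAA")
    }, character(1))
  })
  tibble::tibble(
    id = paste0(id_prefix, seq_len(n_sequences)),
    cds = seqs,
    length_bp = nchar(seqs),
    n_codons = spec$n_codons + 1L, # sense codons incl. ATG, excl. stop
    seed = spec$seed
  )
}

#' Packaged codon counts of the human albumin superfamily
#'
#' Per-codon usage counts for the coding sequences of the four human
#' albumin superfamily genes — serum albumin (ALB, NM_000477.5),
#' alpha-fetoprotein (AFP, NM_001134.1), afamin (AFM, NM_001133.2) and
#' vitamin D-binding protein (VDBP, NM_000583.3) — over the 59 sense codons
#' of the 18 multi-codon amino acids, as tabulated in the published
#' codon-usage survey of this family. ATG and TGG (single-codon families)
#' are not part of the tabulation and carry `NA` counts.
#'
#' @param genes Character vector among `"ALB"`, `"AFP"`, `"AFM"`,
#'   `"VDBP"`.
#' @return A codon-count tibble in the schema of [count_codons()], stacked
#'   over the requested genes.
#' @examples
#' albumin_codon_counts("ALB") |> dplyr::filter(amino_acid == "K")
#' @export
albumin_codon_counts <- function(genes = c("ALB", "AFP", "AFM", "VDBP")) {
  genes <- match.arg(genes, several.ok = TRUE)
  purrr::map_dfr(genes, function(g) {
    path <- system.file("extdata",
                        sprintf("codon_counts_%s.tsv", g),
                        package = "codonuse")
    tbl <- read_codon_counts(path, id = g)
    # ATG/TGG are outside the published tabulation, not zero
    tbl$count[tbl$degeneracy == 1] <- NA_integer_
    tbl
  })
}

#' Packaged nucleotide counts of the human albumin superfamily
#'
#' Published per-base counts (A, T, G, C) of the four albumin-superfamily
#' coding sequences, summing to each gene's ORF length.
#'
#' @return A tibble with columns `id`, `A`, `T`, `G`, `C`.
#' @examples
#' composition_from_counts(albumin_nucleotide_counts())
#' @export
albumin_nucleotide_counts <- function() {
  raw <- readr::read_tsv(
    system.file("extdata", "nucleotide_counts.tsv", package = "codonuse"),
    col_types = "ciiii"
  )
  dplyr::rename(raw, id = "gene")
}
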