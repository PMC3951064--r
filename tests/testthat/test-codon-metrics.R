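alb <- albumin_codon_counts("ALB")
all_counts <- albumin_codon_counts()

test_that("count_codons tallies sense codons and excludes the stop", {
  got <- count_codons(tibble::tibble(id = "x", cds = "ATGTTTTTTTAA"))
  expect_equal(nrow(got), 61)
  expect_equal(got$count[got$codon == "ATG"], 1L)
  expect_equal(got$count[got$codon == "TTT"], 2L)
  expect_equal(sum(got$count), 3L)

  minimal <- count_codons(tibble::tibble(id = "x", cds = "ATGTAA"))
  expect_equal(sum(minimal$count), 1L)
})

test_that("nucleotide composition reproduces the published per-gene cells", {
  comp <- composition_from_counts(albumin_nucleotide_counts())
  # printed values: per-base rows at 1 dp, AT/GC rows at 3 dp (half-up)
  printed <- list(
    ALB  = c(A = 30.4, T = 26.7, G = 23.0, C = 19.9, AT = 57.049, GC = 42.951),
    AFP  = c(A = 32.6, T = 25.4, G = 21.7, C = 20.3, AT = 57.978, GC = 42.022),
    AFM  = c(A = 32.8, T = 27.9, G = 20.1, C = 19.2, AT = 60.722, GC = 39.278),
    VDBP = c(A = 29.9, T = 25.5, G = 21.4, C = 23.2, AT = 55.368, GC = 44.632)
  )
  for (g in names(printed)) {
    row <- comp[comp$id == g, ]
    expect_equal(round_half_up(row$pct_A, 1), printed[[g]][["A"]])
    expect_equal(round_half_up(row$pct_T, 1), printed[[g]][["T"]])
    expect_equal(round_half_up(row$pct_G, 1), printed[[g]][["G"]])
    expect_equal(round_half_up(row$pct_C, 1), printed[[g]][["C"]])
    expect_equal(round_half_up(row$pct_AT, 3), printed[[g]][["AT"]])
    expect_equal(round_half_up(row$pct_GC, 3), printed[[g]][["GC"]])
    expect_equal(row$pct_AT + row$pct_GC, 100, tolerance = 1e-12)
  }
  # ORF lengths recovered from the counts
  expect_equal(comp$length_bp[match(c("ALB", "AFP", "AFM", "VDBP"), comp$id)],
               c(1830L, 1830L, 1800L, 1425L))
})

test_that("sequence-based composition equals direct base counting", {
  comp <- nucleotide_composition(
    tibble::tibble(id = "g", cds = paste0("ATG", strrep("GGG", 8), "TAA")))
  expect_equal(comp$n_G, 1L + 24L)
  expect_equal(comp$pct_GC, 100 * 25 / 30)
  expect_equal(comp$pct_A, 100 * 3 / 30)
})

test_that("GC3s counts G/C-ending synonymous codons only", {
  expect_equal(gc3s(alb)$n_synonymous, 600L)
  expect_equal(gc3s(alb)$n_gc_ending, 228L)
  expect_equal(gc3s(alb)$gc3s_pct, 38)

  au_only <- count_codons(tibble::tibble(id = "x", cds = "ATGAAAGAAGAATAA"))
  expect_equal(gc3s(au_only)$gc3s_pct, 0)
  gc_only <- count_codons(tibble::tibble(id = "x", cds = "ATGAAGGAGTAA"))
  expect_equal(gc3s(gc_only)$gc3s_pct, 100)

  # Met/Trp contribute nothing: a Trp codon leaves GC3s unchanged
  with_trp <- count_codons(tibble::tibble(id = "x", cds = "ATGAAATGGTAA"))
  expect_equal(gc3s(with_trp)$gc3s_pct, 0)
  expect_equal(gc3s(with_trp)$n_synonymous, 1L)
})

test_that("RSCU reproduces the published spot values from the counts", {
  r <- rscu(alb)
  val <- function(tbl, codon) tbl$rscu[tbl$codon == codon]
  expect_equal(round_half_up(val(r, "TTT"), 2), 1.43)
  # six-fold families normalized jointly over all six codons
  expect_equal(round_half_up(val(r, "TCC"), 2), 1.50)
  expect_equal(round_half_up(val(r, "AGT"), 2), 1.29)
  expect_equal(val(r, "CTT"), 19 * 6 / 64)

  uniform <- rscu(count_codons(
    tibble::tibble(id = "u", cds = "ATGAAAAAGTTTTTCTAA")))
  expect_equal(uniform$rscu[uniform$count > 0], rep(1, 4))
})

test_that("RSCU family sums equal degeneracy; absent families are NA", {
  for (g in unique(all_counts$id)) {
    sums <- rscu(all_counts[all_counts$id == g, ]) |>
      dplyr::filter(!is.na(rscu)) |>
      dplyr::group_by(amino_acid) |>
      dplyr::summarise(s = sum(rscu), d = degeneracy[1])
    expect_equal(sums$s, as.numeric(sums$d), tolerance = 1e-9)
  }
  no_phe <- rscu(count_codons(tibble::tibble(id = "x", cds = "ATGAAATAA")))
  expect_true(all(is.na(no_phe$rscu[no_phe$amino_acid == "F"])))
})

test_that("RSCU agrees with seqinr's independent implementation", {
  skip_if_not_installed("seqinr")
  set.seed(5)
  sim <- generate_cds(usage_spec(2000, seed = 17))
  ours <- rscu(count_codons(sim))
  theirs <- seqinr::uco(seqinr::s2c(tolower(sim$cds)), index = "rscu")
  names(theirs) <- toupper(names(theirs))
  # seqinr computes over the full CDS incl. stop and Met/Trp; compare the
  # shared multi-codon families, stop codon removed from its input effects
  theirs_cmp <- theirs[ours$codon]
  ours_val <- ours$rscu
  keep <- !is.na(theirs_cmp) & !is.na(ours_val)
  expect_gt(sum(keep), 50)
  expect_equal(ours_val[keep], unname(theirs_cmp[keep]), tolerance = 1e-6)
})

test_that("Wright Nc reproduces the published ALB value and hand computation", {
  enc <- enc_observed(alb)
  expect_equal(round_half_up(enc$nc, 2), 53.91)
  expect_equal(enc$nc, 53.908, tolerance = 5e-4)
  # frozen class-mean homozygosities from the hand computation
  expect_equal(enc$f2, 0.5316, tolerance = 5e-4)
  expect_equal(enc$f3, 0.3333, tolerance = 5e-4)
  expect_equal(enc$f4, 0.2882, tolerance = 5e-4)
  expect_equal(enc$f6, 0.2051, tolerance = 5e-4)
  # and the loop-style oracle agrees on every bundled gene
  for (g in unique(all_counts$id)) {
    expect_equal(enc_observed(all_counts[all_counts$id == g, ])$nc,
                 nc_by_hand(counts_as_vector(all_counts, g)),
                 tolerance = 1e-12)
  }
})

test_that("Nc hits its analytic limits", {
  one_per_family <- generate_cds(usage_spec(
    3000,
    family_probs = lapply(codonuse::genetic_code() |>
                            dplyr::filter(amino_acid != "*") |>
                            (\(d) split(d$codon, d$amino_acid))(),
                          function(f) stats::setNames(c(1, rep(0, length(f) - 1)), f)),
    seed = 9
  ))
  expect_equal(enc_observed(count_codons(one_per_family))$nc, 20)

  near_uniform <- generate_cds(usage_spec(50000, seed = 13))
  nc <- enc_observed(count_codons(near_uniform))$nc
  expect_gte(nc, 60)
  expect_lte(nc, 61)
})

test_that("Nc is permutation-invariant within families and decreases with skew", {
  base <- alb
  # swap the counts of the two Phe codons
  swapped <- base
  i <- match(c("TTT", "TTC"), swapped$codon)
  swapped$count[i] <- swapped$count[rev(i)]
  expect_equal(enc_observed(swapped)$nc, enc_observed(base)$nc)

  # moving Lys usage into one codon (totals fixed) cannot raise Nc
  skewed <- base
  j <- match(c("AAA", "AAG"), skewed$codon)
  skewed$count[j] <- c(60L, 0L)
  expect_lt(enc_observed(skewed)$nc, enc_observed(base)$nc)
})

test_that("isoleucine-free input falls back to the imputed 3-fold class", {
  no_ile <- alb
  no_ile$count[no_ile$amino_acid == "I"] <- 0L
  enc <- enc_observed(no_ile)
  expect_equal(enc$n_fam3, 0L)
  expect_equal(enc$f3, (enc$f2 + enc$f4) / 2)
  # an empty two-fold class has no fallback
  no_two <- alb
  no_two$count[no_two$degeneracy == 2] <- 0L
  expect_error(enc_observed(no_two), class = "codonuse_undefined_error")
})

test_that("the composition-only ENC expectation is evaluated exactly", {
  expect_equal(enc_expected(0.5), 60.5)
  expect_equal(enc_expected(0), 31)
  expect_equal(enc_expected(0.38), 2 + 0.38 + 29 / (0.38^2 + 0.62^2))
  expect_equal(round_half_up(enc_expected(0.38), 2), 57.22)
  expect_error(enc_expected(1.2), class = "codonuse_domain_error")
  expect_error(enc_expected(-0.1), class = "codonuse_domain_error")
})
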