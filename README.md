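# codonuse

Tidy analysis of synonymous codon usage bias in protein-coding sequences.

Most amino acids are encoded by several synonymous codons, and genes do not
use them equally. The strength and direction of that bias carries signal
about mutation pressure, base composition and translational selection, and
is routinely summarized by a small set of statistics that this package
computes from either raw coding sequences or published per-codon count
tables:

- **RSCU** (relative synonymous codon usage): for an amino acid with
  *n<sub>i</sub>* synonymous codons,
  `RSCU_ij = X_ij / ((1/n_i) * sum_j X_ij)` — the observed count of codon
  *j* over the count expected under uniform usage. 1 means no bias; the
  six-codon families (Leu, Ser, Arg) are normalized jointly.
- **Wright's effective number of codons** `Nc`, from per-family
  homozygosities `F = (n * sum(p_j^2) - 1) / (n - 1)` averaged within
  degeneracy classes: `Nc = 2 + 9/F2 + 1/F3 + 5/F4 + 3/F6`, ranging from 20
  (one codon per amino acid) to 61 (uniform usage).
- The **composition-only expectation** `Nc = 2 + s + 29 / (s^2 + (1-s)^2)`,
  where `s` is **GC3s** — the G+C fraction at third positions of synonymous
  codons (Met, Trp and stops excluded).
- Full-ORF **nucleotide composition** (A/T/G/C, AT%, GC%).
- **GRAVY**, the mean Kyte–Doolittle hydropathy of the translated product
  (negative = hydrophilic).
- **Rare-codon content**: each codon scored against a host codon-usage
  reference rescaled so every family's most-used codon scores 100; codons
  under 30 are called rare.
- The **A+U vs G+C preference tally** of each family's highest-RSCU codon.

The package ships the per-codon count tables, nucleotide counts and a human
codon-usage reference for the four human albumin superfamily genes — serum
albumin (ALB), alpha-fetoprotein (AFP), afamin (AFM) and vitamin D-binding
protein (VDBP) — plus a seeded generator of coding sequences with
controlled codon-usage structure, so every estimator is testable without
network access.

## Worked example

```r
library(codonuse)

report <- analyze(fixtures = c("ALB", "AFP", "AFM", "VDBP"))
glance(report)
#> # A tibble: 4 × 12
#>   id    orf_length_bp pct_GC pct_AT gravy gc3s_pct enc_observed enc_expected
#>   <chr>         <int>  <dbl>  <dbl> <dbl>    <dbl>        <dbl>        <dbl>
#> 1 ALB              NA     NA     NA    NA     38           53.9         57.2
#> 2 AFP              NA     NA     NA    NA     37.0         53.8         56.7
#> 3 AFM              NA     NA     NA    NA     37.4         52.7         56.9
#> 4 VDBP             NA     NA     NA    NA     42.8         56.6         59.2
```

Reading the ALB row: of its 600 synonymous codons, 38.0% end in G or C
(`gc3s_pct`), the observed effective number of codons is 53.91 — high on
the 20–61 scale, so synonymous codons are used fairly evenly — and a gene
of that composition would be expected at Nc ≈ 57.2 were composition alone
at work. Sequence-level columns (`gravy`, `pct_GC`, `orf_length_bp`) are
`NA` here because the packaged inputs are count tables, not sequences; they
are filled in when you pass a FASTA file via `analyze(fasta = ...)`.

Per-codon detail and plots:

```r
library(dplyr)
rscu(albumin_codon_counts("ALB")) |> filter(amino_acid == "F")
#>   id    codon amino_acid degeneracy count family_total  rscu
#> 1 ALB   TTT   F                   2    25           35 1.43
#> 2 ALB   TTC   F                   2    10           35 0.571

autoplot(report)          # observed Nc against the composition-only curve
plot_rscu(report, "L")    # leucine RSCU profile across the four genes
```

Phenylalanine in ALB is used 25:10 in favour of TTT, i.e. RSCU 1.43 —
43% more often than expected under even usage.

The full pipeline works from any FASTA of mRNA/CDS records
(`read_fasta() |> extract_orf() |> translate_cds() |> ...`), and a thin
command-line wrapper is installed at
`system.file("cli", "codonuse.R", package = "codonuse")` with `analyze`
and `simulate` subcommands.

## Notes on scope

Sequence retrieval from GenBank, alignment-based similarity and any
expressivity interpretation are out of scope; analyses run on local FASTA
files, packaged count tables, or simulated sequences. See the methods
vignette (`vignettes/codon-usage-bias.Rmd`) for the statistical details,
rounding conventions and known inconsistencies in the published tables.
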