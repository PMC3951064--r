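---
title: "Measuring synonymous codon usage bias"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring synonymous codon usage bias}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(codonuse)
library(dplyr)
```

# The problem

Synonymous codons encode the same amino acid but are not used
interchangeably: within a genome, and between genes of one genome, some
codons are systematically preferred. The bias reflects a mix of mutation
pressure (base composition, especially at the free-to-vary third codon
position), drift, and translational selection mediated by tRNA abundance.
`codonuse` implements the standard descriptive statistics of that bias for
single genes, in a tidy data-frame-first interface, and bundles as worked
material the published per-codon count tables of the four human albumin
superfamily genes (ALB, AFP, AFM, VDBP) — paralogous serum transport
proteins on chromosome 4.

# From transcript to codon counts

`read_fasta()` accepts DNA or RNA, any case, and normalizes to uppercase
DNA; IUPAC ambiguity codes are rejected outright rather than silently
skipped, since a single undetermined base shifts a codon count. The coding
region is selected by `extract_orf()` as the **longest forward-strand
ATG-initiated frame that ends in a stop with no internal stop**, breaking
ties in favour of the 5'-most start. Annotation-based CDS selection or
six-frame search are deliberately not implemented: for the reference
transcripts this package targets, the longest forward ORF and the annotated
CDS coincide, and the rule is fully reproducible from the FASTA alone. The
choice is validated in the test suite against an exhaustive scan over all
ATG-initiated frames.

All codon statistics (`count_codons()` onward) are computed over **sense
codons only, terminal stop excluded**; nucleotide composition
(`nucleotide_composition()`) is computed over the **full ORF including the
stop codon**, because that is the convention under which the bundled
published per-base counts sum exactly to each gene's ORF length (e.g. ALB:
556 + 488 + 421 + 365 = 1830 bp). The genetic code is fixed to the standard
nuclear code; no alternative-code plumbing exists.

# The statistics

## RSCU

For amino acid *i* with $n_i$ synonymous codons and codon counts $X_{ij}$,

$$\mathrm{RSCU}_{ij} = \frac{X_{ij}}{\tfrac{1}{n_i}\sum_{j=1}^{n_i} X_{ij}},$$

the observed count relative to the uniform-usage expectation. Values sum to
$n_i$ within each family — a quantified test invariant. **Six-codon
families (Leu, Ser, Arg) are treated as single families** normalized over
all six codons jointly, not as 2+4 splits: the bundled ALB serine values
(e.g. RSCU(TCC) = 1.50 with the TCN and AGY counts pooled to 28) are
consistent only with joint normalization. Families absent from a gene give
`NA`, not an error; single-codon families (Met, Trp) are excluded.

## Wright's effective number of codons

Each multi-codon family contributes a bias-corrected homozygosity
$F = (n\sum_j p_j^2 - 1)/(n-1)$ from its codon proportions; class means
$\bar F_k$ over families of degeneracy $k$ give

$$N_c = 2 + \frac{9}{\bar F_2} + \frac{1}{\bar F_3} + \frac{5}{\bar F_4} + \frac{3}{\bar F_6}.$$

Numerical choices, all exercised by tests:

- families with $n < 2$ or $F \le 0$ (possible for small, near-uniform
  families) are excluded from their class mean, matching common practice in
  codon-usage tools;
- if the three-fold class (isoleucine alone) ends up empty, $\bar F_3$ is
  imputed as $(\bar F_2 + \bar F_4)/2$; an empty two-, four- or six-fold
  class is an error, since no defensible fallback exists;
- $N_c$ is capped at 61 (small near-uniform samples can exceed it
  numerically).

From the bundled ALB counts this yields $\bar F_2 = 0.5316$,
$\bar F_3 = 0.3333$, $\bar F_4 = 0.2882$, $\bar F_6 = 0.2051$ and
$N_c = 53.91$, reproducing the published value exactly. The published ENC
values for AFP and AFM (54.78, 51.65) are *not* reproducible from their own
published count tables (which give 53.76 and 52.67); those published values
were evidently computed from the full sequences with counts tabulated
separately, and the discrepancy is documented rather than patched.

## Expected ENC from composition

`enc_expected()` evaluates $N_c = 2 + s + 29/(s^2 + (1-s)^2)$ for a
synonymous-GC3 fraction $s \in [0,1]$, the effective number of codons
expected when composition alone (mutation pressure and drift) shapes
usage. It is reported separately from, and deliberately not conflated
with, the observed Wright $N_c$: at ALB's $s = 0.38$ the expectation is
57.22 while the observed value is 53.91. `autoplot()` draws the familiar
Nc-vs-GC3s diagnostic with this curve.

## GC3s

`gc3s()` implements *synonymous* GC3: G/C-ending codons of multi-codon
amino acids over all codons of multi-codon amino acids, excluding Met, Trp
and stops from numerator and denominator. For ALB this is 228/600 = 38.00%,
matching the published table; all-codon GC3 would not.

## GRAVY

`gravy()` is the arithmetic mean of per-residue hydropathy indices, fixed
to the Kyte–Doolittle scale (the ProtParam default) but injectable for
other scales. It is permutation-invariant and mixes as a length-weighted
mean under concatenation — both tested properties.

## Rare codons

`relative_adaptiveness()` rescales a host codon-usage table so each
family's most-used codon scores 100; `rare_codon_fraction()` reports the
percentage of a gene's codons scoring below a threshold, default 30, the
conventional cutoff for codons likely to slow translation. The bundled
reference is the standard human codon-usage frequency table (occurrences
per thousand codons, as distributed with common codon-analysis tools).
Because published rare-codon percentages for the albumin superfamily come
from a web service whose reference-table version is unstated, the 3–4%
figures are validated as approximate (±2 percentage points), not exact;
with the bundled table the four genes come out at 4.5%, 5.1%, 4.5% and
5.2%.

## A+U vs G+C preference tally

`preferred_codons()` returns each family's argmax-RSCU codon set;
`au_gc_tally()` counts rows preferring A/U-ending vs G/C-ending codons.
Two row schemes are provided: 18 amino-acid families, or the 20 "display
rows" of conventional codon-usage tables (serine split into TCN/AGY,
arginine into CGN/AGR). Tied rows are excluded from both tallies by
default; `ties = "count_if_consistent"` keeps ties whose codons share an
ending. No tie rule we examined reproduces every cell of the published
per-gene A+U/G+C totals for this family (ALB recomputes to 15/3 under the
literal argmax rule against published 17/3, while AFP 17/1 and VDBP 11/4
match exactly), so the tally is validated against an exhaustive brute-force
tally of the count tables rather than against those printed totals.

# The simulator

`generate_cds(usage_spec(...))` draws interior codons i.i.d. — an amino
acid from `aa_probs`, then a codon from that family's `family_probs` —
and wraps them in ATG…TAA. Defaults are uniform over amino acids and
uniform within families, i.e. unbiased usage; biases are opt-in per
family. The model reproduces exactly the quantities the estimators measure
(marginal codon frequencies, and through them RSCU, homozygosity, GC3s),
which is what makes it a sound test bed: one-codon-per-family
specifications drive $N_c$ to its analytic floor of 20, uniform usage at
50,000 codons lands in [60, 61], and an ALB-like phenylalanine bias of
0.714/0.286 at 10,000 codons recovers RSCU(TTT) within ±0.05 of 1.43 in at
least 19 of 20 seeds. It does **not** emulate dinucleotide or
codon-context correlations, amino-acid composition of real proteins,
isochore structure, or mutation–selection dynamics — so passing tests
certify the estimators, not any biological realism of the sequences.
Validation problem sizes (10,000-codon draws, 20 seeds; one 50,000-codon
draw) were chosen so sampling error sits an order of magnitude below the
tolerances being checked.

# Rounding and report conventions

Published codon-usage tables round half away from zero (1.125 prints as
1.13); base R rounds half to even. `round_half_up()` is therefore used
wherever output is compared with, or formatted like, printed tables: RSCU
at 2 decimals, ENC and GC3s at 2, AT/GC composition at 3, per-base
composition at 1. TSV reports from `write_report()` use these fixed
formats and are byte-identical across reruns; JSON reports keep full
precision.

With half-up rounding the computed RSCU values reproduce all 59 printed
cells for ALB and for VDBP. Seven AFP cells (the serine family and GGG)
and the five AFM serine cells are internally inconsistent with their own
printed counts — the printed values imply family totals different from
what the printed counts sum to — and are documented here rather than
excluded from the fixtures: the fixtures carry the counts as printed, and
97.8% of the remaining cells reproduce exactly.

# Known limitations

- Single-gene descriptive statistics only: no codon adaptation index, tRNA
  adaptation index, or correspondence analysis across genes.
- The ORF rule is a documented assumption, not annotation-aware; spliced
  or reverse-strand coding regions are out of scope.
- The rare-codon reference is one published snapshot of human codon usage;
  results shift by a point or two under other tables, which is why the
  bundled analyses treat rare-codon percentages as approximate.
- Count-table inputs cannot yield sequence-level statistics (composition,
  GRAVY); `analyze()` reports them as `NA` rather than guessing.
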