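# Independent reference implementations used as oracles. Deliberately
# written in a plain, loop-heavy style, sharing no code with the package.

# exhaustive scan over every ATG-initiated forward frame; returns the ORF
# substring (longest, 5'-most on ties) or NA
orf_exhaustive <- function(seq) {
  seq <- toupper(gsub("u", "T", seq, ignore.case = TRUE))
  stops <- c("TAA", "TAG", "TGA")
  best <- NA_character_
  best_len <- -1L
  best_start <- Inf
  n <- nchar(seq)
  for (i in seq_len(max(n - 5, 0))) {
    if (substr(seq, i, i + 2) != "ATG") next
    j <- i
    while (j + 5 <= n) {
      cod <- substr(seq, j + 3, j + 5)
      if (cod %in% stops) {
        len <- j + 5 - i + 1
        if (len > best_len || (len == best_len && i < best_start)) {
          best <- substr(seq, i, j + 5)
          best_len <- len
          best_start <- i
        }
        break
      }
      j <- j + 3
    }
  }
  best
}

# Wright Nc straight from a named codon-count vector, written as the hand
# computation: per-family F, arithmetic class means, 2 + 9/F2 + 1/F3 + 5/F4 + 3/F6
nc_by_hand <- function(counts) {
  gc <- Biostrings::GENETIC_CODE
  fams <- split(names(gc), unname(gc))
  fams <- fams[names(fams) != "*"]
  fs <- list()
  for (aa in names(fams)) {
    k <- length(fams[[aa]])
    if (k == 1) next
    x <- counts[fams[[aa]]]
    x[is.na(x)] <- 0
    n <- sum(x)
    if (n < 2) next
    f <- (n * sum((x / n)^2) - 1) / (n - 1)
    if (f <= 0) next
    fs[[length(fs) + 1]] <- c(k = k, f = f)
  }
  m <- do.call(rbind, fs)
  fbar <- tapply(m[, "f"], m[, "k"], mean)
  f3 <- if ("3" %in% names(fbar)) fbar[["3"]] else (fbar[["2"]] + fbar[["4"]]) / 2
  min(61, 2 + 9 / fbar[["2"]] + 1 / f3 + 5 / fbar[["4"]] + 3 / fbar[["6"]])
}

# counts tibble -> named vector over the 61 sense codons
counts_as_vector <- function(counts_tbl, gene = NULL) {
  if (!is.null(gene)) counts_tbl <- counts_tbl[counts_tbl$id == gene, ]
  stats::setNames(counts_tbl$count, counts_tbl$codon)
}

# exhaustive A/U-vs-G/C preference tally straight off a named count vector,
# independent of the package's grouped-tibble path
tally_by_hand <- function(counts, scheme) {
  gc <- Biostrings::GENETIC_CODE
  fams <- split(names(gc), unname(gc))
  fams <- fams[!names(fams) %in% c("*", "M", "W")]
  rows <- list()
  for (aa in names(fams)) {
    if (scheme == "display_rows" && aa == "S") {
      rows[["S1"]] <- intersect(fams$S, c("TCT", "TCC", "TCA", "TCG"))
      rows[["S2"]] <- intersect(fams$S, c("AGT", "AGC"))
    } else if (scheme == "display_rows" && aa == "R") {
      rows[["R1"]] <- intersect(fams$R, c("CGT", "CGC", "CGA", "CGG"))
      rows[["R2"]] <- intersect(fams$R, c("AGA", "AGG"))
    } else {
      rows[[aa]] <- fams[[aa]]
    }
  }
  au <- 0; gcn <- 0; ties <- 0
  for (row in rows) {
    aa <- unname(gc[row[1]])
    fam <- fams[[aa]]
    tot <- sum(counts[fam], na.rm = TRUE)
    if (tot == 0) next
    vals <- counts[row] * length(fam) / tot
    best <- row[vals == max(vals)]
    if (length(best) > 1) {
      ties <- ties + 1
    } else if (substr(best, 3, 3) %in% c("A", "T")) {
      au <- au + 1
    } else {
      gcn <- gcn + 1
    }
  }
  c(au = au, gc = gcn, ties = ties)
}

# random valid CDS string for property tests (may also contain none)
random_nt <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}
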