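#' Read nucleotide sequences from a FASTA file
#'
#' Accepts multi-record FASTA with wrapped or unwrapped lines and either DNA
#' or RNA alphabet in any case; residues are normalized to uppercase DNA
#' (U becomes T). IUPAC ambiguity codes are rejected with an error naming the
#' offending symbols.
#'
#' @param path Path to a FASTA file.
#' @return A tibble with one row per record: `id` (header up to the first
#'   whitespace), `sequence` (normalized residues) and `length` in bp,
#'   preserving file order.
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">x", "ATGAAATGA"), fa)
#' read_fasta(fa)
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) {
    rlang::abort(sprintf("file not found: %s", path), class = "codonuse_io_error")
  }
  lines <- readLines(path, warn = FALSE)
  nonblank <- which(nzchar(trimws(lines)))
  if (length(nonblank) == 0) {
    rlang::abort("empty FASTA file", class = "codonuse_parse_error")
  }
  first <- nonblank[1]
  if (!startsWith(trimws(lines[first]), ">")) {
    rlang::abort(sprintf("malformed FASTA: line %d does not start a record", first),
                 class = "codonuse_parse_error")
  }
  set <- Biostrings::readBStringSet(path)
  ids <- stringr::str_extract(names(set), "^\\S+")
  seqs <- normalize_residues(as.character(set))
  seqs <- unname(seqs)
  tibble::tibble(id = ids, sequence = seqs, length = nchar(seqs))
}

# all ATG-initiated forward-frame ORFs terminating in a stop with no internal
# stop; returns a data.frame of (start, end) in 1-based bp coordinates
orf_candidates <- function(sequence) {
  n <- nchar(sequence)
  codons_at <- function(from) {
    substring(sequence, seq(from, n - 2, 3), seq(from + 2, n, 3))
  }
  out <- list()
  for (frame in 0:2) {
    if (n - frame < 6) next
    codons <- codons_at(frame + 1)
    is_start <- codons == "ATG"
    is_stop <- codons %in% stop_codons()
    if (!any(is_start) || !any(is_stop)) next
    stops <- which(is_stop)
    for (s in which(is_start)) {
      nxt <- stops[stops > s]
      if (length(nxt) == 0) next
      out[[length(out) + 1]] <- c(start = frame + (s - 1) * 3 + 1,
                                  end = frame + nxt[1] * 3)
    }
  }
  if (length(out) == 0) {
    return(data.frame(start = integer(), end = integer()))
  }
  as.data.frame(do.call(rbind, out))
}

# longest ATG..stop forward-strand ORF, 5'-most on ties; NA if none
find_orf_one <- function(sequence) {
  cand <- orf_candidates(sequence)
  if (nrow(cand) == 0) return(c(start = NA_integer_, end = NA_integer_))
  len <- cand$end - cand$start + 1
  best <- cand[order(-len, cand$start)[1], ]
  c(start = best$start, end = best$end)
}

#' Extract the open reading frame of each sequence
#'
#' Selects, on the forward strand, the longest reading frame that starts with
#' ATG, ends in a stop codon and contains no internal stop; ties are broken in
#' favour of the 5'-most start. This is the ORF rule the annotated CDSs of the
#' human albumin superfamily transcripts satisfy.
#'
#' @param seqs A data frame with columns `id` and `sequence`, e.g. from
#'   [read_fasta()].
#' @return A tibble with columns `id`, `cds` (the ORF, start and stop codons
#'   included), `orf_start` (1-based bp position in the input), `length_bp`
#'   and `n_codons` (sense codons, terminal stop excluded).
#' @examples
#' extract_orf(tibble::tibble(id = "x", sequence = "GGATGAAATGATT"))
#' @export
extract_orf <- function(seqs) {
  stopifnot(is.data.frame(seqs), all(c("id", "sequence") %in% names(seqs)))
  seqs <- dplyr::mutate(seqs, sequence = normalize_residues(.data$sequence))
  hits <- t(vapply(seqs$sequence, find_orf_one,
                   c(start = NA_real_, end = NA_real_)))
  missing <- is.na(hits[, "start"])
  if (any(missing)) {
    rlang::abort(sprintf("no ATG..stop open reading frame found for: %s",
                         paste(seqs$id[missing], collapse = ", ")),
                 class = "codonuse_orf_error")
  }
  tibble::tibble(
    id = seqs$id,
    cds = substr(seqs$sequence, hits[, "start"], hits[, "end"]),
    orf_start = as.integer(hits[, "start"]),
    length_bp = as.integer(hits[, "end"] - hits[, "start"] + 1),
    n_codons = as.integer((hits[, "end"] - hits[, "start"] + 1) / 3 - 1)
  )
}

translate_one <- function(cds) {
  cds <- validate_cds(cds)
  codons <- split_codons(cds)
  aa <- codon_to_aa()[codons]
  paste(aa[-length(aa)], collapse = "")
}

#' Translate coding sequences under the standard genetic code
#'
#' @param cds_tbl A data frame with columns `id` and `cds`, e.g. from
#'   [extract_orf()]. Each `cds` must satisfy the coding-sequence invariants
#'   (ATG start, single terminal stop, length divisible by 3).
#' @return The input with columns `protein` (one symbol per sense codon, stop
#'   omitted) and `n_residues` appended.
#' @examples
#' translate_cds(tibble::tibble(id = "x", cds = "ATGTTTTAA"))
#' @export
translate_cds <- function(cds_tbl) {
  stopifnot(is.data.frame(cds_tbl), all(c("id", "cds") %in% names(cds_tbl)))
  dplyr::mutate(tibble::as_tibble(cds_tbl),
                protein = vapply(.data$cds, translate_one, character(1),
                                 USE.NAMES = FALSE),
                n_residues = nchar(.data$protein))
}

#' Write sequences to FASTA
#'
#' @param seqs A data frame with `id` and a sequence column.
#' @param path Output file path.
#' @param sequence_col Name of the column holding the sequence
#'   (default `"sequence"`, falling back to `"cds"` if absent).
#' @param width Line-wrap width in characters.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, sequence_col = NULL, width = 70) {
  if (is.null(sequence_col)) {
    sequence_col <- if ("sequence" %in% names(seqs)) "sequence" else "cds"
  }
  stopifnot(sequence_col %in% names(seqs))
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(seqs))) {
    writeLines(paste0(">", seqs$id[i]), con)
    s <- seqs[[sequence_col]][i]
    starts <- seq(1, nchar(s), width)
    writeLines(substring(s, starts, pmin(starts + width - 1, nchar(s))), con)
  }
  invisible(path)
}
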