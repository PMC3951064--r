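write_fa <- function(...) {
  path <- withr::local_tempfile(fileext = ".fa",
                                .local_envir = parent.frame())
  writeLines(c(...), path)
  path
}

test_that("read_fasta parses records, normalizes U/case, keeps order", {
  one <- read_fasta(write_fa(">x", "ATGTAA"))
  expect_equal(one$id, "x")
  expect_equal(one$sequence, "ATGTAA")
  expect_equal(one$length, 6L)

  rna <- read_fasta(write_fa(">r desc here", "AUGaaa", "uaa"))
  expect_equal(rna$id, "r")
  expect_equal(rna$sequence, "ATGAAATAA")

  two <- read_fasta(write_fa(">b", "ATGTAA", ">a", "ATGGGGTAA"))
  expect_equal(two$id, c("b", "a"))
  expect_equal(two$length, c(6L, 9L))
})

test_that("read_fasta error contract: missing, empty, malformed, bad alphabet", {
  expect_error(read_fasta(file.path(tempdir(), "no-such.fa")),
               class = "codonuse_io_error")
  expect_error(read_fasta(write_fa("")), class = "codonuse_parse_error")
  err <- expect_error(read_fasta(write_fa("ATG", ">x", "ATG")),
                      class = "codonuse_parse_error")
  expect_match(conditionMessage(err), "line 1")
  expect_error(read_fasta(write_fa(">x", "ATGNNN")),
               class = "codonuse_alphabet_error")
})

test_that("extract_orf picks the longest 5'-most ATG..stop frame", {
  got <- extract_orf(tibble::tibble(id = "x", sequence = "GGATGAAATGATT"))
  expect_equal(got$cds, "ATGAAATGA")
  expect_equal(got$orf_start, 3L)
  expect_equal(got$length_bp, 9L)
  expect_equal(got$n_codons, 2L)

  minimal <- extract_orf(tibble::tibble(id = "m", sequence = "ATGTAA"))
  expect_equal(minimal$n_codons, 1L)

  expect_error(extract_orf(tibble::tibble(id = "none", sequence = "ATGAAATTT")),
               class = "codonuse_orf_error")
})

test_that("extract_orf agrees with an exhaustive frame scan on random input", {
  set.seed(101)
  n_with_orf <- 0
  for (i in 1:200) {
    s <- random_nt(sample(20:200, 1))
    expected <- orf_exhaustive(s)
    if (is.na(expected)) {
      expect_error(extract_orf(tibble::tibble(id = "s", sequence = s)),
                   class = "codonuse_orf_error")
    } else {
      n_with_orf <- n_with_orf + 1
      got <- extract_orf(tibble::tibble(id = "s", sequence = s))
      expect_equal(got$cds, expected)
      expect_lte(got$length_bp, nchar(s))
      expect_equal(got$length_bp %% 3, 0)
    }
  }
  expect_gt(n_with_orf, 50) # the property actually got exercised
})

test_that("translation drops the terminal stop and flags internal stops", {
  expect_equal(
    translate_cds(tibble::tibble(id = "x", cds = "ATGTTTTAA"))$protein, "MF")
  expect_equal(
    translate_cds(tibble::tibble(id = "x", cds = "ATGTAA"))$protein, "M")
  expect_error(
    translate_cds(tibble::tibble(id = "x", cds = "ATGTAGTTTTAA")),
    class = "codonuse_cds_error")

  # translate . extract_orf never emits a stop symbol
  set.seed(42)
  for (i in 1:50) {
    s <- paste0("ATG", random_nt(3 * sample(5:60, 1)), "TAA")
    orf <- try(extract_orf(tibble::tibble(id = "s", sequence = s)),
               silent = TRUE)
    if (inherits(orf, "try-error")) next
    expect_false(grepl("\\*", translate_cds(orf)$protein))
  }
})

test_that("write_fasta round-trips through read_fasta", {
  tbl <- tibble::tibble(id = c("a", "b"),
                        sequence = c("ATGTAA", strrep("ATGGCA", 40)))
  path <- withr::local_tempfile(fileext = ".fa")
  write_fasta(tbl, path, width = 60)
  back <- read_fasta(path)
  expect_equal(back$id, tbl$id)
  expect_equal(back$sequence, tbl$sequence)
})
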