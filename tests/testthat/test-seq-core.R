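test_that("FASTA round-trip preserves ids, order and sequences", {
  seqs <- c(p1 = "MKTAYIAK", p2 = "MVLSPADKTN", p3 = "MA")
  path <- withr::local_tempfile(fileext = ".fasta")
  write_fasta(seqs, path)
  back <- read_fasta(path, "protein")
  expect_identical(back, seqs)

  # wrapped lines are re-joined
  long <- c(wide = paste(rep("MKTAYIAKQRQISFVK", 8), collapse = ""))
  write_fasta(long, path)
  expect_identical(read_fasta(path, "protein"), long)
})

test_that("read_fasta validates alphabet, uniqueness and degenerate input", {
  path <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">a", "MKJ"), path)
  expect_error(read_fasta(path, "protein"), "'a'.*'J'.*position 3")

  writeLines(c(">a", "MKT", ">a", "MKV"), path)
  expect_error(read_fasta(path, "protein"), "duplicate")

  writeLines(character(0), path)
  expect_warning(out <- read_fasta(path, "protein"), "empty")
  expect_length(out, 0)

  writeLines(c(">d", "ACGU"), path)
  expect_error(read_fasta(path, "dna"), "'U'")
})

test_that("coding_sequence validates DNA and handles partial codons", {
  expect_error(coding_sequence("x", "ATGN"), "'N' at position 4")
  expect_warning(cs <- coding_sequence("x", "ATGAA"), "partial codon")
  expect_identical(cs$dna, "ATG")
  cs <- coding_sequence("y", "atgaaa")
  expect_identical(codons(cs), c("ATG", "AAA"))
  expect_identical(paste(codons(cs), collapse = ""), cs$dna)
})

test_that("translate follows standard-code stop-at-first-stop semantics", {
  expect_identical(translate("ATGAAATAA")$residues, "MK")
  expect_identical(translate("ATGGCC")$residues, "MA")
  expect_identical(translate("ATGAAATAAGGG")$residues, "MK")
  expect_warning(expect_error(translate("AT"), "shorter"), "partial")
  expect_error(translate("ATGAXA"), "'X' at position 5")
})

test_that("translate agrees with Biostrings over all 64 codons", {
  codons64 <- names(enztriage:::GENETIC_CODE_TABLE)
  for (cd in codons64) {
    dna <- paste0("ATG", cd, "GGG")
    mine <- tryCatch(translate(dna)$residues, error = function(e) NA)
    bios <- as.character(Biostrings::translate(
      Biostrings::DNAString(dna), if.fuzzy.codon = "error"))
    bios <- sub("\\*.*$", "", bios)  # same stop-truncation convention
    if (!is.na(mine)) expect_identical(mine, bios, info = cd)
  }
})

test_that("codon_optimize is deterministic max-usage and round-trips", {
  usage <- default_codon_usage()
  # Met has a single codon; highest-frequency stop is TAA
  expect_identical(codon_optimize("M", usage)$dna, "ATGTAA")
  # explicit max-usage rule on a two-codon amino acid
  toy <- codon_usage_table(c(AAA = 0.7, AAG = 0.3, ATG = 1, TAA = 1,
    GCG = 1, TGC = 1, GAT = 1, GAA = 1, TTT = 1, GGC = 1, CAT = 1,
    ATT = 1, CTG = 1, AAT = 1, CCG = 1, CAG = 1, CGC = 1, AGC = 1,
    ACC = 1, GTG = 1, TGG = 1, TAT = 1))
  expect_identical(codon_optimize("KK", toy)$dna, "AAAAAATAA")

  set.seed(99)
  for (i in 1:25) {
    p <- random_protein(sample(5:40, 1))
    expect_identical(translate(codon_optimize(p, usage))$residues, p)
  }
})

test_that("codon_usage_table rejects missing amino acids", {
  expect_error(codon_usage_table(c(ATG = 1)), "no codon with positive")
})

test_that("protein_sequence flags X and rejects other letters", {
  expect_true(protein_sequence("p", "MKX")$has_x)
  expect_false(protein_sequence("p", "MK")$has_x)
  expect_error(protein_sequence("p", "MKB"), "'B' at position 3")
  expect_error(protein_sequence("p", ""), "empty")
})
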