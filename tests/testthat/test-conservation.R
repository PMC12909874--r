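toy_aln <- function() {
  msa(c(s1 = "MKTA-Y",
        s2 = "MKTA-Y",
        s3 = "MRT--Y",
        s4 = "M-TAC-"))
}

test_that("msa validates shape and characters", {
  expect_error(msa(c(a = "MKT", b = "MK")), "unequal")
  expect_error(msa(c(a = "M+T")), "invalid")
  expect_error(msa(c(a = "---")), "all gaps")
  a <- toy_aln()
  expect_equal(ncol(a$matrix), 6)
})

test_that("trimming removes exactly the high-gap columns", {
  a <- toy_aln()  # per-column gap counts: 0,1,0,1,3,1 (of 4)
  t50 <- trim_high_gap_columns(a, 0.5)
  expect_identical(attr(t50, "removed"), 5L)
  expect_equal(ncol(t50$matrix), 5)
  # no-gap alignment unchanged at any threshold
  clean <- msa(c(x = "MKT", y = "MRT"))
  expect_equal(ncol(trim_high_gap_columns(clean, 0)$matrix), 3)
  # threshold 0 removes every column with any gap
  t0 <- trim_high_gap_columns(a, 0)
  expect_identical(attr(t0, "removed"), c(2L, 4L, 5L, 6L))
  # idempotence at a fixed threshold
  expect_identical(trim_high_gap_columns(t50, 0.5)$rows, t50$rows)
  # a 4-row alignment with gap counts {0,1,2,3}/4 keeps 2 columns at 0.5
  mixed <- msa(c(a = "MKTA", b = "MK-A", c = "MKT-", d = "M--A",
                 e = "M-T-", f = "MK--", g = "M---", h = "MKTA"))
  # columns gaps: 0/8, 3/8, 4/8, 4/8 -> at 0.5 all survive; at 0.4 cols 3,4 go
  expect_equal(ncol(trim_high_gap_columns(mixed, 0.5)$matrix), 4)
  expect_equal(ncol(trim_high_gap_columns(mixed, 0.4)$matrix), 2)
  expect_error(trim_high_gap_columns(msa(c(a = "M-", b = "-K")), -1))
})

test_that("column entropy reproduces closed forms", {
  # conserved column: 0 bits; 50/50 column: 1 bit
  a <- msa(c(s1 = "AA", s2 = "AK"))
  prof <- column_entropy(a)
  expect_equal(prof$entropy, c(0, 1))
  # uniform over the 20 amino acids: log2(20) bits
  unif <- msa(setNames(enztriage:::AA_ALPHABET,
                       paste0("u", 1:20)))
  expect_equal(column_entropy(unif)$entropy, log2(20))
  # gaps are excluded from the distribution
  g <- msa(c(s1 = "AM", s2 = "AM", s3 = "-M"))
  expect_equal(column_entropy(g)$entropy, c(0, 0))
  expect_equal(column_entropy(g)$gap_fraction, c(1 / 3, 0))
})

test_that("entropy is bounded and gap-aware on random alignments", {
  set.seed(13)
  for (i in 1:15) {
    n <- sample(3:10, 1)
    width <- sample(5:25, 1)
    rows <- vapply(seq_len(n), function(.)
      paste(sample(c(enztriage:::AA_ALPHABET, "-"), width, replace = TRUE,
                   prob = c(rep(1, 20), 4)), collapse = ""), character(1))
    ok <- vapply(strsplit(rows, ""), function(ch) any(ch != "-"), logical(1))
    rows <- rows[ok]
    if (length(rows) < 2) next
    a <- msa(setNames(rows, paste0("r", seq_along(rows))))
    prof <- column_entropy(a)
    defined <- !is.na(prof$entropy)
    expect_true(all(prof$entropy[defined] >= 0))
    expect_true(all(prof$entropy[defined] <= log2(20) + 1e-12))
    expect_true(all(is.na(prof$entropy) == (prof$gap_fraction == 1)))
    # IC + H = log2(20) wherever both are defined
    lm <- logo_matrix(a)
    expect_equal(lm$information[defined] + prof$entropy[defined],
                 rep(log2(20), sum(defined)))
  }
})

test_that("logo matrix holds per-column frequencies summing to one", {
  single <- msa(c(only = "MKT"))
  lm <- logo_matrix(single)
  expect_equal(rowSums(lm$freq), c(1, 1, 1))
  expect_equal(unname(lm$freq[1, "M"]), 1)
  # hand-counted 3-row alignment
  a <- msa(c(r1 = "MK", r2 = "MR", r3 = "-R"))
  lm <- logo_matrix(a)
  expect_equal(unname(lm$freq[1, "M"]), 1)           # gaps out of the denominator
  expect_equal(unname(lm$freq[2, c("K", "R")]), c(1 / 3, 2 / 3))
  # all-gap column flagged with zero row
  b <- msa(c(r1 = "M-", r2 = "K-"))
  lm <- logo_matrix(b)
  expect_true(lm$all_gap[2])
  expect_equal(sum(lm$freq[2, ]), 0)
})

test_that("center-star MSA reduces to pairwise and preserves sequences", {
  # identical sequences: gap-free alignment
  same <- build_small_msa(c(a = "MKTAY", b = "MKTAY", c = "MKTAY"))
  expect_false(any(same$matrix == "-"))
  # two sequences: equals the pairwise global alignment
  two <- build_small_msa(c(a = "MKTAYI", b = "MKAYI"))
  pw <- global_align("MKTAYI", "MKAYI")
  expect_identical(unname(two$rows["a"]), pw$aligned_a)
  expect_identical(unname(two$rows["b"]), pw$aligned_b)
  # degapped rows always reproduce the inputs
  set.seed(3)
  seqs <- setNames(vapply(1:6, function(.)
    random_peptide(sample(6:14, 1)), character(1)), paste0("s", 1:6))
  aln <- build_small_msa(seqs)
  for (id in names(seqs)) {
    expect_identical(gsub("-", "", aln$rows[[id]], fixed = TRUE),
                     seqs[[id]])
  }
})

test_that("center-star columns project back onto the center alignments", {
  seqs <- c(a = "MKTAYIAK", b = "MKTYIAK", c = "MKTAWIAK")
  aln <- build_small_msa(seqs)
  # pairwise projection of each non-center row against the center row
  # reproduces the pairwise global alignment it was built from
  sc <- scoring_scheme()
  total <- vapply(names(seqs), function(i) sum(vapply(
    setdiff(names(seqs), i), function(j)
      global_align(seqs[[i]], seqs[[j]], sc)$score, numeric(1))),
    numeric(1))
  center <- names(seqs)[order(-total, names(seqs))][1]
  for (other in setdiff(names(seqs), center)) {
    rows <- strsplit(c(aln$rows[[other]], aln$rows[[center]]), "")
    keep <- !(rows[[1]] == "-" & rows[[2]] == "-")
    proj_other <- paste(rows[[1]][keep], collapse = "")
    proj_center <- paste(rows[[2]][keep], collapse = "")
    pw <- global_align(seqs[[other]], seqs[[center]], sc)
    expect_identical(proj_other, pw$aligned_a, info = other)
    expect_identical(proj_center, pw$aligned_b, info = other)
  }
})

test_that("aligned FASTA and profile tables round-trip", {
  a <- toy_aln()
  path <- withr::local_tempfile(fileext = ".fasta")
  write_msa(a, path)
  expect_identical(read_msa(path)$rows, a$rows)
  prof_path <- withr::local_tempfile(fileext = ".tsv")
  write_profile(column_entropy(a), prof_path)
  back <- read.delim(prof_path)
  expect_equal(back$entropy, column_entropy(a)$entropy)
  write_profile(logo_matrix(a), prof_path)
  expect_equal(nrow(read.delim(prof_path, check.names = FALSE)), 6)
})
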