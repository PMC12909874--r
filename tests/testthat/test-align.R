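test_that("global alignment handles trivial and hand-checked cases", {
  r <- global_align("MKT", "MKT")
  expect_equal(r$score, 3)
  expect_equal(r$identity, 1)
  expect_identical(r$aligned_a, "MKT")

  # one mismatch vs gapping it out: tie at 2.0, diagonal preferred
  r <- global_align("MKVL", "MKVI")
  expect_equal(r$score, 2)
  expect_identical(r$aligned_a, "MKVL")
  expect_identical(r$aligned_b, "MKVI")
  expect_equal(r$identity, 0.75)

  # "MK" vs "A": brute-force optimum
  expect_equal(global_align("MK", "A")$score, oracle_global_score("MK", "A"))
  expect_equal(global_align("MKV", "MQV")$score, 1)

  expect_error(global_align("", "MK"), "non-empty")
})

test_that("degapping aligned strings recovers the inputs", {
  set.seed(5)
  for (i in 1:20) {
    a <- random_peptide(sample(1:12, 1))
    b <- random_peptide(sample(1:12, 1))
    r <- global_align(a, b)
    expect_identical(gsub("-", "", r$aligned_a, fixed = TRUE), a)
    expect_identical(gsub("-", "", r$aligned_b, fixed = TRUE), b)
    expect_equal(nchar(r$aligned_a), nchar(r$aligned_b))
    expect_equal(r$columns, nchar(r$aligned_a))
  }
})

test_that("local alignment handles trivial and hand-checked cases", {
  expect_equal(local_align("MMM", "KKK")$score, 0)
  r <- local_align("AMKTA", "GMKTG")
  expect_equal(r$score, 3)
  expect_identical(r$aligned_a, "MKT")
  a <- "MKTAYIAK"
  expect_equal(local_align(a, a)$score, nchar(a))
})

test_that("aligner scores are symmetric and local >= global", {
  set.seed(11)
  for (i in 1:30) {
    a <- random_peptide(sample(1:10, 1))
    b <- random_peptide(sample(1:10, 1))
    expect_equal(global_align(a, b)$score, global_align(b, a)$score)
    expect_equal(local_align(a, b)$score, local_align(b, a)$score)
    expect_gte(local_align(a, b)$score, global_align(a, b)$score)
    expect_equal(global_align(a, a)$score, nchar(a))
    expect_equal(global_align(a, a)$identity, 1)
  }
})

test_that("DP scores equal exhaustive enumeration on short random pairs", {
  set.seed(23)
  for (i in 1:60) {
    a <- random_peptide(sample(1:6, 1))
    b <- random_peptide(sample(1:6, 1))
    expect_equal(global_align(a, b)$score, oracle_global_score(a, b),
                 info = paste(a, b))
    expect_equal(local_align(a, b)$score, oracle_local_score(a, b),
                 info = paste(a, b))
  }
})

test_that("DP scores match Biostrings pairwiseAlignment on longer pairs", {
  set.seed(31)
  for (i in 1:15) {
    a <- random_peptide(sample(10:35, 1), alphabet = enztriage:::AA_ALPHABET)
    b <- random_peptide(sample(10:35, 1), alphabet = enztriage:::AA_ALPHABET)
    expect_equal(global_align(a, b)$score, biostrings_score(a, b),
                 tolerance = 1e-5, info = paste("global", a, b))
    expect_equal(local_align(a, b)$score,
                 biostrings_score(a, b, local = TRUE),
                 tolerance = 1e-5, info = paste("local", a, b))
  }
})

test_that("identity is invariant under alphabet renaming", {
  set.seed(41)
  for (i in 1:10) {
    a <- random_peptide(sample(4:10, 1))
    b <- random_peptide(sample(4:10, 1))
    map <- c(A = "L", K = "R", M = "S", T = "V")
    ren <- function(x) paste(map[strsplit(x, "")[[1]]], collapse = "")
    expect_equal(global_align(a, b)$identity,
                 global_align(ren(a), ren(b))$identity)
  }
})

test_that("composite_score is the weighted mean of global and local", {
  # identical single reference of length 4: 3*4 + 8*4
  expect_equal(composite_score("MKTA", c(r1 = "MKTA")), 44)
  # duplicated reference leaves the mean unchanged
  refs1 <- c(r1 = "MKTAYI")
  refs2 <- c(r1 = "MKTAYI", r2 = "MKTAYI")
  expect_equal(composite_score("MKTWYI", refs1),
               composite_score("MKTWYI", refs2))
  # three-reference toy set against the brute-force oracle
  cand <- "MKTA"
  refs <- c(x = "MKA", y = "MKTT", z = "AKTA")
  sc <- scoring_scheme()
  expected <- sc$w_global * mean(vapply(refs, oracle_global_score,
                                        numeric(1), a = cand)) +
    sc$w_local * mean(vapply(refs, oracle_local_score, numeric(1),
                             a = cand))
  expect_equal(composite_score(cand, refs), expected)
})

test_that("max_identity finds the best reference with id tie-breaks", {
  refs <- tiny_refs()
  # exact member -> 100%
  r <- max_identity("MKTAYIAKQR", refs)
  expect_equal(r$identity, 100)
  expect_identical(r$best_ref_id, "rA")
  # single-substitution pair under the all-columns denominator
  r <- max_identity("MKVL", c(s = "MKVI"))
  expect_equal(r$identity, 75)
  expect_equal(r$matches, 3L)
  expect_equal(r$columns, 4L)
  # tie between rA and rB on a candidate equidistant from both
  r <- max_identity("MKTAYIAKQW", refs)
  expect_identical(r$best_ref_id, "rA")
})

test_that("identity denominator counts all alignment columns", {
  # full-length denominator: a 2-residue overhang costs identity even
  # though every aligned column matches
  r <- global_align("MKTAYI", "MKTA")
  expect_equal(r$matches, 4L)
  expect_equal(r$columns, 6L)
  expect_equal(r$identity, 4 / 6)
})

test_that("score_candidates returns one row per candidate in order", {
  refs <- tiny_refs()
  out <- score_candidates(c(c2 = "MKTAYIAKQR", c1 = "MKTPYIAKQK"), refs)
  expect_identical(out$id, c("c2", "c1"))
  expect_equal(out$maxid[1], 100)
  expect_true(all(out$score > 0))
})

test_that("scoring_scheme validates its invariants", {
  expect_error(scoring_scheme(match = -1, mismatch = 1))
  expect_error(scoring_scheme(gap_open = 0.5))
  expect_error(scoring_scheme(gap_open = -0.1, gap_extend = -0.5))
})
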