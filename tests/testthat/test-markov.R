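test_that("fit_codon_markov tallies exact n-gram counts", {
  # single path: P(AAA | ATG) = 1
  m <- fit_codon_markov(list(coding_sequence("s", "ATGAAATAA")), order = 1)
  expect_equal(unname(transition_probs(m, "ATG")["AAA"]), 1)
  expect_equal(unname(transition_probs(m, "TAA")["<END>"]), 1)

  # proportionality: k copies give the same model up to count scaling
  one <- fit_codon_markov(c("ATGAAACCCTAA"), order = 1)
  three <- fit_codon_markov(rep("ATGAAACCCTAA", 3), order = 1)
  expect_identical(lapply(one$counts, names), lapply(three$counts, names))
  for (k in seq_along(one$counts)) {
    for (ctx in names(one$counts[[k]])) {
      expect_equal(three$counts[[k]][[ctx]], 3 * one$counts[[k]][[ctx]])
    }
  }

  # two sequences sharing a context: probabilities = empirical fractions
  # hand tally: after ATG -> AAA (seq1), AAG (seq2); after AAA -> TAA etc.
  m2 <- fit_codon_markov(c("ATGAAATAA", "ATGAAGTAA"), order = 1)
  p <- transition_probs(m2, "ATG")
  expect_equal(unname(p[c("AAA", "AAG")]), c(0.5, 0.5))
  expect_equal(sum(p), 1)

  # codons after an in-frame stop are ignored
  m3 <- fit_codon_markov(c("ATGTAAGGG"), order = 1)
  expect_null(transition_probs(m3, "GGG"))

  expect_error(fit_codon_markov(list(), 1), "empty")
  expect_error(fit_codon_markov(c("ATGAAA"), -1), "non-negative")
  expect_error(fit_codon_markov(c("ATG"), 1), "fewer than")
})

test_that("sampling_distribution applies temperature, top-k, top-p in order", {
  probs <- c(AAA = 0.5, AAG = 0.3, AAC = 0.2)
  # no truncation: unchanged
  expect_equal(sampling_distribution(probs, 1, 50, 1), sort(probs, TRUE))
  # top-k = 2 drops the smallest then renormalizes
  d <- sampling_distribution(probs, 1, 2, 1)
  expect_equal(unname(d), c(0.5, 0.3) / 0.8)
  # nucleus 0.75 keeps the smallest prefix reaching 0.75: {0.5, 0.3}
  d <- sampling_distribution(probs, 1, 50, 0.75)
  expect_identical(names(d), c("AAA", "AAG"))
  # temperature flattens before truncation
  d <- sampling_distribution(probs, 1e6, 50, 1)
  expect_true(max(d) - min(d) < 1e-4)
  # always at least one token and sums to 1
  d <- sampling_distribution(probs, 1, 50, 1e-9)
  expect_length(d, 1)
  expect_equal(sum(d), 1)
  # support never exceeds top_k (property over random distributions)
  set.seed(7)
  for (i in 1:20) {
    p <- runif(10)
    names(p) <- paste0("T", 1:10)
    k <- sample(1:10, 1)
    d <- sampling_distribution(p, runif(1, 0.5, 2), k, runif(1, 0.1, 1))
    expect_lte(length(d), k)
    expect_equal(sum(d), 1)
  }
})

test_that("sampling is seed-deterministic and greedy when top_k = 1", {
  m <- fit_codon_markov(c("ATGAAACCCTAA", "ATGAAAGGGTAA", "ATGCCCTAA"),
                        order = 1)
  cfg <- sampling_config(seed = 42, max_codons = 30)
  s1 <- sample_sequence(m, cfg)
  s2 <- sample_sequence(m, cfg)
  expect_identical(s1$dna, s2$dna)

  # a deterministic chain reproduces its training sequence for any seed
  det <- fit_codon_markov(c("ATGAAACCCTAA"), order = 1)
  for (seed in c(1, 2, 3)) {
    expect_identical(
      sample_sequence(det, sampling_config(seed = seed))$dna,
      "ATGAAACCCTAA")
  }

  # top_k = 1 is argmax generation: seed-independent
  g1 <- sample_sequence(m, sampling_config(top_k = 1, seed = 1))
  g2 <- sample_sequence(m, sampling_config(top_k = 1, seed = 999))
  expect_identical(g1$dna, g2$dna)
})

test_that("samples start with the prompt and respect max_codons", {
  m <- fit_codon_markov(c("ATGAAACCCAAACCCTAA"), order = 1)
  cfg <- sampling_config(seed = 3, max_codons = 4, top_p = 1)
  for (i in 1:5) {
    s <- sample_sequence(m, sampling_config(seed = i, max_codons = 4,
                                            top_p = 1))
    expect_identical(substr(s$dna, 1, 3), "ATG")
    expect_lte(nchar(s$dna) / 3, 4)
  }
})

test_that("unseen contexts back off to shorter contexts", {
  m <- fit_codon_markov(c("ATGAAATAA"), order = 1)
  # prompt with a context never observed at order 1: GGG backs off to the
  # unconditional distribution instead of erroring
  cfg <- sampling_config(prompt = "ATGGGG", seed = 2, max_codons = 6)
  expect_no_error(sample_sequence(m, cfg))
})

test_that("model serialization round-trips through the tabular format", {
  m <- fit_codon_markov(c("ATGAAACCCTAA", "ATGCCCAAATAA"), order = 2)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_markov_model(m, path)
  m2 <- read_markov_model(path)
  expect_equal(m2$order, m$order)
  expect_identical(lapply(m2$counts, names), lapply(m$counts, names))
  for (k in seq_along(m$counts)) {
    for (ctx in names(m$counts[[k]])) {
      expect_equal(sort(m2$counts[[k]][[ctx]]), sort(m$counts[[k]][[ctx]]),
                   info = ctx)
    }
  }
})

test_that("refitting from samples recovers transition probabilities", {
  # known order-1 model whose per-context nuclei keep all tokens at
  # top_p = 0.9 (cumulative mass hits 0.9 only with the full support)
  truth <- codon_markov_model(list(
    "ATG" = c(AAA = 0.5, CCC = 0.3, GGG = 0.2),
    "AAA" = c(CCC = 0.6, TAA = 0.4),
    "CCC" = c(AAA = 0.5, GGG = 0.3, TAA = 0.2),
    "GGG" = c(CCC = 0.7, TAA = 0.3)), order = 1)
  set.seed(77)
  seqs <- sample_sequences(truth, sampling_config(top_p = 1, top_k = 64),
                           n = 1500)
  refit <- fit_codon_markov(seqs, order = 1)
  for (ctx in c("ATG", "AAA", "CCC", "GGG")) {
    p_true <- transition_probs(truth, ctx)
    p_hat <- transition_probs(refit, ctx)
    n_ctx <- sum(refit$counts[[2]][[ctx]])
    for (tok in names(p_true)) {
      se <- sqrt(p_true[[tok]] * (1 - p_true[[tok]]) / n_ctx)
      expect_lt(abs(p_hat[[tok]] - p_true[[tok]]), 3 * se + 1e-9,
                label = paste(ctx, tok))
    }
  }
})

test_that("sampling_config validates parameter ranges", {
  expect_error(sampling_config(temperature = 0))
  expect_error(sampling_config(top_k = 0))
  expect_error(sampling_config(top_k = 66))
  expect_error(sampling_config(top_p = 0))
  expect_error(sampling_config(top_p = 1.2))
})
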