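# Independent brute-force oracles for the aligners: exhaustive enumeration
# over the alignment space (no dynamic programming), feasible for short
# sequences only.

# Optimal global alignment score by enumerating every gapped alignment.
# prev: 0 = aligned pair, 1 = gap in b (consuming a), 2 = gap in a.
oracle_global_score <- function(a, b, sc = scoring_scheme()) {
  A <- strsplit(a, "", fixed = TRUE)[[1]]
  B <- strsplit(b, "", fixed = TRUE)[[1]]
  na <- length(A)
  nb <- length(B)
  best <- -Inf
  rec <- function(i, j, prev, acc) {
    if (i > na && j > nb) {
      if (acc > best) best <<- acc
      return(invisible(NULL))
    }
    if (i <= na && j <= nb)
      rec(i + 1L, j + 1L, 0L,
          acc + if (A[i] == B[j]) sc$match else sc$mismatch)
    if (i <= na)
      rec(i + 1L, j, 1L,
          acc + if (prev == 1L) sc$gap_extend else sc$gap_open)
    if (j <= nb)
      rec(i, j + 1L, 2L,
          acc + if (prev == 2L) sc$gap_extend else sc$gap_open)
  }
  rec(1L, 1L, 0L, 0)
  best
}

# Optimal local alignment score: enumerate every alignment that starts and
# ends with an aligned residue pair (end gaps only lower the score under
# non-positive gap penalties), plus the empty alignment (score 0).
oracle_local_score <- function(a, b, sc = scoring_scheme()) {
  A <- strsplit(a, "", fixed = TRUE)[[1]]
  B <- strsplit(b, "", fixed = TRUE)[[1]]
  na <- length(A)
  nb <- length(B)
  best <- 0
  rec <- function(i, j, prev, acc) {
    if (i <= na && j <= nb) {
      s <- acc + if (A[i] == B[j]) sc$match else sc$mismatch
      if (s > best) best <<- s  # the alignment may end on this pair
      rec(i + 1L, j + 1L, 0L, s)
    }
    if (prev != -1L) {  # gap moves only once the alignment has started
      if (i <= na)
        rec(i + 1L, j, 1L,
            acc + if (prev == 1L) sc$gap_extend else sc$gap_open)
      if (j <= nb)
        rec(i, j + 1L, 2L,
            acc + if (prev == 2L) sc$gap_extend else sc$gap_open)
    }
  }
  for (i in seq_len(na)) {
    for (j in seq_len(nb)) rec(i, j, -1L, 0)
  }
  best
}

# random short peptide over a reduced alphabet (frequent ties and matches)
random_peptide <- function(len, alphabet = c("A", "K", "M", "T")) {
  paste(sample(alphabet, len, replace = TRUE), collapse = "")
}

# Biostrings cross-check: same scoring model, independent implementation.
# Biostrings charges gapOpening + g * gapExtension for a length-g gap, so
# our gap_open/gap_extend map to opening |open| - |ext| and extension |ext|.
biostrings_score <- function(a, b, sc = scoring_scheme(), local = FALSE) {
  letters_used <- sort(unique(strsplit(paste0(a, b), "")[[1]]))
  mat <- matrix(sc$mismatch, length(letters_used), length(letters_used),
                dimnames = list(letters_used, letters_used))
  diag(mat) <- sc$match
  Biostrings::pairwiseAlignment(
    a, b, type = if (local) "local" else "global",
    substitutionMatrix = mat,
    gapOpening = abs(sc$gap_open) - abs(sc$gap_extend),
    gapExtension = abs(sc$gap_extend),
    scoreOnly = TRUE)
}
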