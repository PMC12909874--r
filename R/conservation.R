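# MSA-based conservation analysis: gap trimming, per-column Shannon
# entropy, sequence-logo matrices, and a small center-star MSA builder so
# fixtures need no external aligner.

#' Multiple sequence alignment container
#'
#' Equal-length gapped amino-acid rows. Degapped rows must be valid
#' proteins.
#'
#' @param rows Named character vector of gapped sequences (gap `-`).
#' @return Object of class `msa`: list with `rows` (named character) and
#'   `matrix` (rows x columns character matrix).
#' @export
msa <- function(rows) {
  stopifnot(is.character(rows), length(rows) >= 1L, !is.null(names(rows)))
  widths <- nchar(rows)
  if (length(unique(widths)) != 1L)
    stop("alignment rows have unequal lengths")
  rows <- toupper(rows)
  mat <- do.call(rbind, strsplit(rows, "", fixed = TRUE))
  rownames(mat) <- names(rows)
  bad <- !(mat %in% c(AA_ALPHABET, "X", "-"))
  if (any(bad))
    stop("invalid alignment character(s): ",
         paste(unique(mat[bad]), collapse = ", "))
  for (id in names(rows)) {
    degap <- gsub("-", "", rows[[id]], fixed = TRUE)
    if (!nzchar(degap)) stop("row '", id, "' is all gaps")
  }
  structure(list(rows = rows, matrix = mat), class = "msa")
}

#' @export
print.msa <- function(x, ...) {
  cat(sprintf("<msa> %d sequences x %d columns\n", nrow(x$matrix),
              ncol(x$matrix)))
  invisible(x)
}

#' Read / write an aligned FASTA
#'
#' @param path Aligned FASTA file (all records equal length, `-` gaps).
#' @return An [msa()].
#' @export
read_msa <- function(path) {
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) stop("empty alignment file: ", path)
  ids <- vapply(strsplit(names(set), "\\s+"), `[`, character(1), 1L)
  msa(setNames(toupper(as.character(set)), ids))
}

#' @rdname read_msa
#' @param aln An [msa()].
#' @export
write_msa <- function(aln, path) {
  write_fasta(aln$rows, path)
}

#' Trim high-gap columns
#'
#' Removes every column whose gap fraction exceeds `max_gap_fraction`
#' (strictly greater; a threshold of 1 removes only all-gap columns). Row
#' order is preserved; the removed column indices are attached as the
#' `removed` attribute. Trimming is idempotent at a fixed threshold.
#'
#' @param aln An [msa()].
#' @param max_gap_fraction Maximum tolerated per-column gap fraction
#'   (default 0.5).
#' @return Trimmed [msa()] with attribute `removed` (integer column
#'   indices); an error if no column survives.
#' @export
trim_high_gap_columns <- function(aln, max_gap_fraction = 0.5) {
  stopifnot(inherits(aln, "msa"),
            max_gap_fraction >= 0, max_gap_fraction <= 1)
  gap_frac <- colMeans(aln$matrix == "-")
  drop <- which(gap_frac > max_gap_fraction)
  if (length(drop) == ncol(aln$matrix))
    stop("trimming removed every column")
  kept <- aln$matrix[, setdiff(seq_len(ncol(aln$matrix)), drop),
                     drop = FALSE]
  out <- msa(setNames(apply(kept, 1L, paste, collapse = ""),
                      rownames(kept)))
  attr(out, "removed") <- drop
  out
}

#' Per-column Shannon entropy profile
#'
#' Positional variability in bits: per column,
#' `H = -sum_a f_a log2 f_a` over the 20 amino acids, with gaps (and `X`)
#' excluded from the counts. An all-gap column has undefined entropy and is
#' reported as `NA`.
#'
#' @param aln An [msa()].
#' @return `data.frame` with `column`, `entropy` (bits, in
#'   \[0, log2(20)\]) and `gap_fraction`.
#' @export
column_entropy <- function(aln) {
  stopifnot(inherits(aln, "msa"))
  mat <- aln$matrix
  ent <- vapply(seq_len(ncol(mat)), function(j) {
    col <- mat[, j]
    col <- col[col %in% AA_ALPHABET]
    if (length(col) == 0L) return(NA_real_)
    f <- table(col) / length(col)
    -sum(f * log2(f))
  }, numeric(1))
  data.frame(column = seq_len(ncol(mat)), entropy = ent,
             gap_fraction = colMeans(mat == "-"))
}

#' Sequence-logo frequency matrix
#'
#' Per-column residue frequencies over the 20 amino acids with gaps
#' excluded from the denominator; all-gap columns get all-zero rows and
#' are flagged. Information content per column is
#' `IC = log2(20) - H` wherever entropy is defined, the conventional logo
#' scaling.
#'
#' @param aln An [msa()].
#' @return Object of class `logo_matrix`: list with `freq` (columns x 20
#'   matrix, rows sum to 1 or 0), `information` (per-column IC in bits,
#'   `NA` for all-gap columns) and `all_gap` (logical).
#' @export
logo_matrix <- function(aln) {
  stopifnot(inherits(aln, "msa"))
  mat <- aln$matrix
  freq <- t(vapply(seq_len(ncol(mat)), function(j) {
    col <- mat[, j]
    col <- col[col %in% AA_ALPHABET]
    if (length(col) == 0L) return(setNames(rep(0, 20), AA_ALPHABET))
    f <- table(factor(col, levels = AA_ALPHABET)) / length(col)
    setNames(as.numeric(f), AA_ALPHABET)
  }, setNames(numeric(20), AA_ALPHABET)))
  ent <- column_entropy(aln)$entropy
  structure(list(freq = freq,
                 information = ifelse(is.na(ent), NA_real_, log2(20) - ent),
                 all_gap = rowSums(freq) == 0),
            class = "logo_matrix")
}

#' Center-star multiple alignment for small sequence sets
#'
#' A deterministic progressive aligner for fixture-scale inputs (tens to a
#' couple hundred sequences): the center is the sequence maximizing the
#' total pairwise global-alignment score to all others (ties by id); every
#' other sequence is aligned to the center and the pairwise alignments are
#' merged on center coordinates ("once a gap, always a gap"). This is a
#' testing convenience, not a substitute for a production MSA tool;
#' externally computed alignments are accepted via [read_msa()].
#'
#' @param seqs Named character vector of protein sequences (>= 1).
#' @param scheme A [scoring_scheme()].
#' @return An [msa()] whose degapped rows equal the inputs.
#' @export
build_small_msa <- function(seqs, scheme = scoring_scheme()) {
  stopifnot(is.character(seqs), !is.null(names(seqs)), length(seqs) >= 1L)
  seqs <- toupper(seqs)
  if (length(seqs) == 1L) return(msa(seqs))
  ids <- names(seqs)
  total <- vapply(ids, function(i) {
    sum(vapply(setdiff(ids, i), function(j)
      global_align(seqs[[i]], seqs[[j]], scheme)$score, numeric(1)))
  }, numeric(1))
  center <- ids[order(-total, ids)][1]
  others <- setdiff(ids, center)
  alns <- lapply(others, function(i)
    global_align(seqs[[i]], seqs[[center]], scheme))
  names(alns) <- others

  # per-pairwise-alignment insertion lengths before each center position
  # (slot k = insertions before center residue k; slot L+1 = after last)
  L <- nchar(seqs[[center]])
  ins <- matrix(0L, nrow = length(others), ncol = L + 1L,
                dimnames = list(others, NULL))
  for (i in others) {
    cen <- strsplit(alns[[i]]$aligned_b, "", fixed = TRUE)[[1]]
    pos <- 1L
    run <- 0L
    for (ch in cen) {
      if (ch == "-") run <- run + 1L
      else {
        ins[i, pos] <- run
        run <- 0L
        pos <- pos + 1L
      }
    }
    ins[i, L + 1L] <- run
  }
  master_ins <- apply(ins, 2L, max)

  expand_row <- function(row_chars, cen_chars) {
    # re-emit one pairwise row on the master coordinate system
    out <- character(0)
    pos <- 1L
    k <- 1L
    pending <- character(0)
    flush <- function(slot, pending) {
      c(pending, rep("-", master_ins[slot] - length(pending)))
    }
    for (idx in seq_along(cen_chars)) {
      if (cen_chars[idx] == "-") {
        pending <- c(pending, row_chars[idx])
      } else {
        out <- c(out, flush(pos, pending), row_chars[idx])
        pending <- character(0)
        pos <- pos + 1L
      }
    }
    c(out, flush(L + 1L, pending))
  }

  center_row <- expand_row(strsplit(seqs[[center]], "", fixed = TRUE)[[1]],
                           strsplit(seqs[[center]], "", fixed = TRUE)[[1]])
  rows <- list()
  rows[[center]] <- paste(center_row, collapse = "")
  for (i in others) {
    rc <- strsplit(alns[[i]]$aligned_a, "", fixed = TRUE)[[1]]
    cc <- strsplit(alns[[i]]$aligned_b, "", fixed = TRUE)[[1]]
    rows[[i]] <- paste(expand_row(rc, cc), collapse = "")
  }
  msa(unlist(rows[ids]))
}

#' Write an entropy profile or logo matrix as TSV
#'
#' @param x A `data.frame` from [column_entropy()] or a `logo_matrix`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_profile <- function(x, path) {
  if (inherits(x, "logo_matrix")) {
    df <- data.frame(column = seq_len(nrow(x$freq)),
                     information = x$information, x$freq,
                     check.names = FALSE)
  } else df <- x
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
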