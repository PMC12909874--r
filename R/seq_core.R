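# Sequence domain types, codon handling, translation, codon optimization and
# FASTA / tabular I/O shared by every pipeline stage.

AA_ALPHABET <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L", "M", "N",
                 "P", "Q", "R", "S", "T", "V", "W", "Y")
DNA_ALPHABET <- c("A", "C", "G", "T")
STOP_CODONS <- c("TAA", "TAG", "TGA")

# standard genetic code keyed by codon; single source of truth for translate()
GENETIC_CODE_TABLE <- local({
  bases <- c("T", "C", "A", "G")
  codons <- as.vector(outer(outer(bases, bases, paste0), bases, paste0))
  codons <- sort(codons)
  aas <- vapply(codons, function(cd) {
    as.character(Biostrings::GENETIC_CODE[[cd]])
  }, character(1))
  setNames(aas, codons)
})

#' Coding DNA sequence
#'
#' A codon-resolved protein-coding DNA record. The DNA must consist of
#' `A`/`C`/`G`/`T` only; a trailing partial codon is dropped with a warning.
#' The codon view and the translation are derived on demand with [codons()]
#' and [translate()].
#'
#' @param id Single character identifier.
#' @param dna Nucleotide string over `{A,C,G,T}` (case-insensitive; stored
#'   upper-case).
#' @return An object of class `coding_sequence` with elements `id` and `dna`.
#' @examples
#' cs <- coding_sequence("c1", "ATGAAATAA")
#' codons(cs)
#' translate(cs)
#' @export
coding_sequence <- function(id, dna) {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  dna <- toupper(as.character(dna))
  chars <- strsplit(dna, "", fixed = TRUE)[[1]]
  bad <- which(!chars %in% DNA_ALPHABET)
  if (length(bad) > 0L) {
    stop(sprintf("invalid DNA character '%s' at position %d in '%s'",
                 chars[bad[1]], bad[1], id))
  }
  if (nchar(dna) %% 3L != 0L) {
    warning(sprintf("'%s': dropping trailing partial codon (%d nt)",
                    id, nchar(dna) %% 3L))
    dna <- substr(dna, 1L, nchar(dna) - nchar(dna) %% 3L)
  }
  structure(list(id = id, dna = dna), class = "coding_sequence")
}

#' @export
print.coding_sequence <- function(x, ...) {
  cat(sprintf("<coding_sequence> %s: %d nt (%d codons)\n",
              x$id, nchar(x$dna), nchar(x$dna) %/% 3L))
  invisible(x)
}

#' Codon view of a coding sequence
#'
#' @param x A [coding_sequence()] or a DNA string whose length is a multiple
#'   of three.
#' @return Character vector of contiguous nucleotide triplets; concatenating
#'   them reproduces the DNA exactly.
#' @export
codons <- function(x) {
  dna <- if (inherits(x, "coding_sequence")) x$dna else toupper(as.character(x))
  n <- nchar(dna)
  if (n == 0L) return(character(0))
  stopifnot(n %% 3L == 0L)
  substring(dna, seq(1L, n - 2L, by = 3L), seq(3L, n, by = 3L))
}

#' Protein sequence
#'
#' Amino-acid sequence over the 20-letter alphabet. `X` is permitted but
#' flagged via the `has_x` attribute; any other character is rejected with
#' the offending position named.
#'
#' @param id Single character identifier.
#' @param residues Amino-acid string (upper-cased on construction).
#' @return An object of class `protein_sequence` with elements `id` and
#'   `residues`.
#' @export
protein_sequence <- function(id, residues) {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  residues <- toupper(as.character(residues))
  if (!nzchar(residues)) stop(sprintf("'%s': empty protein sequence", id))
  chars <- strsplit(residues, "", fixed = TRUE)[[1]]
  bad <- which(!chars %in% c(AA_ALPHABET, "X"))
  if (length(bad) > 0L) {
    stop(sprintf("invalid amino-acid character '%s' at position %d in '%s'",
                 chars[bad[1]], bad[1], id))
  }
  structure(list(id = id, residues = residues,
                 has_x = any(chars == "X")),
            class = "protein_sequence")
}

#' @export
print.protein_sequence <- function(x, ...) {
  cat(sprintf("<protein_sequence> %s: %d aa%s\n", x$id, nchar(x$residues),
              if (isTRUE(x$has_x)) " (contains X)" else ""))
  invisible(x)
}

# Accept either a protein_sequence or a plain string and return the residue
# string; used by the aligners and pipeline internals.
as_residues <- function(x) {
  if (inherits(x, "protein_sequence")) x$residues
  else if (inherits(x, "coding_sequence")) translate(x)$residues
  else toupper(as.character(x))
}

#' Natural reference protein set
#'
#' Holds the natural reference proteins used for novelty (MaxID) scoring and
#' ranking, together with the length statistics of the family used by the
#' length filter. Defaults are the TrpB family statistics (mean 363.55 aa,
#' sd 57.91 aa).
#'
#' @param members Named character vector of residue strings, or a list of
#'   [protein_sequence()] objects.
#' @param length_mean,length_sd Family length mean and standard deviation in
#'   amino acids.
#' @return Object of class `reference_set` with elements `members` (named
#'   character vector), `length_mean`, `length_sd`.
#' @export
reference_set <- function(members, length_mean = 363.55, length_sd = 57.91) {
  if (is.list(members)) {
    members <- setNames(
      vapply(members, as_residues, character(1)),
      vapply(members, function(m) m$id, character(1)))
  }
  stopifnot(is.character(members), length(members) >= 1L,
            !is.null(names(members)), all(nzchar(names(members))),
            length_mean > 0, length_sd >= 0)
  if (anyDuplicated(names(members)))
    stop("duplicate reference ids: ",
         paste(unique(names(members)[duplicated(names(members))]),
               collapse = ", "))
  structure(list(members = toupper(members),
                 length_mean = length_mean, length_sd = length_sd),
            class = "reference_set")
}

#' @export
print.reference_set <- function(x, ...) {
  cat(sprintf("<reference_set> %d members; length mean %.2f aa, sd %.2f aa\n",
              length(x$members), x$length_mean, x$length_sd))
  invisible(x)
}

#' Read a FASTA file
#'
#' Thin validating wrapper around [Biostrings::readBStringSet()]: input order
#' is preserved, ids (the first whitespace-delimited word of each header)
#' must be unique, and every sequence is validated against the requested
#' alphabet with the offending record and position named.
#'
#' @param path Path to a FASTA file (wrapped or unwrapped lines).
#' @param alphabet `"dna"` or `"protein"`.
#' @return Named character vector of sequences (possibly empty, with a
#'   warning for an empty file).
#' @export
read_fasta <- function(path, alphabet = c("protein", "dna")) {
  alphabet <- match.arg(alphabet)
  if (!file.exists(path)) stop("file not found: ", path)
  set <- tryCatch(Biostrings::readBStringSet(path),
                  error = function(e) stop("malformed FASTA in '", path,
                                           "': ", conditionMessage(e)))
  if (length(set) == 0L) {
    warning("empty FASTA file: ", path)
    return(setNames(character(0), character(0)))
  }
  ids <- vapply(strsplit(names(set), "\\s+"), `[`, character(1), 1L)
  if (anyDuplicated(ids))
    stop("duplicate FASTA ids in '", path, "': ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  seqs <- toupper(as.character(set))
  names(seqs) <- ids
  allowed <- if (alphabet == "dna") DNA_ALPHABET else c(AA_ALPHABET, "X")
  for (k in seq_along(seqs)) {
    chars <- strsplit(seqs[[k]], "", fixed = TRUE)[[1]]
    bad <- which(!chars %in% allowed)
    if (length(bad) > 0L)
      stop(sprintf("record '%s': invalid %s character '%s' at position %d",
                   ids[k], alphabet, chars[bad[1]], bad[1]))
  }
  seqs
}

#' Write sequences to FASTA
#'
#' @param seqs Named character vector of sequences.
#' @param path Output path. Lines are wrapped at 60 columns.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  stopifnot(is.character(seqs), !is.null(names(seqs)))
  set <- Biostrings::BStringSet(seqs)
  names(set) <- names(seqs)
  Biostrings::writeXStringSet(set, filepath = path, width = 60L)
  invisible(path)
}

#' Translate a coding sequence
#'
#' Standard genetic code, reading frame 0, stopping at the first in-frame
#' stop codon; codons after the stop are ignored. A trailing partial codon
#' is dropped with a warning (at [coding_sequence()] construction or here
#' for plain strings).
#'
#' @param seq A [coding_sequence()] or DNA string of length >= 3.
#' @param id Identifier for the result when `seq` is a plain string.
#' @return A [protein_sequence()].
#' @examples
#' translate("ATGAAATAA")$residues  # "MK"
#' @export
translate <- function(seq, id = NULL) {
  if (inherits(seq, "coding_sequence")) {
    if (is.null(id)) id <- seq$id
  } else {
    if (is.null(id)) id <- "translated"
    seq <- coding_sequence(id, seq)
  }
  if (nchar(seq$dna) < 3L) stop(sprintf("'%s': DNA shorter than one codon", id))
  cods <- codons(seq)
  aas <- GENETIC_CODE_TABLE[cods]
  stop_at <- which(aas == "*")
  if (length(stop_at) > 0L) aas <- aas[seq_len(stop_at[1] - 1L)]
  if (length(aas) == 0L)
    stop(sprintf("'%s': sequence starts with a stop codon", id))
  protein_sequence(id, paste(aas, collapse = ""))
}

#' Codon usage table
#'
#' Relative synonymous codon frequencies per amino acid (including `*` for
#' stop). Frequencies are renormalized to sum to one within each amino acid;
#' every amino acid of the standard code must have at least one codon with
#' positive frequency.
#'
#' @param freq Named numeric vector of codon frequencies (names are codons).
#' @return Object of class `codon_usage_table`: list with `freq` (named
#'   numeric, normalized per amino acid) and `by_aa` (amino acid -> named
#'   frequency vector).
#' @seealso [default_codon_usage()] for the shipped E. coli table.
#' @export
codon_usage_table <- function(freq) {
  stopifnot(is.numeric(freq), !is.null(names(freq)), all(freq >= 0))
  names(freq) <- toupper(names(freq))
  bad <- setdiff(names(freq), names(GENETIC_CODE_TABLE))
  if (length(bad) > 0L) stop("unknown codons: ", paste(bad, collapse = ", "))
  aa_of <- GENETIC_CODE_TABLE[names(freq)]
  by_aa <- split(freq, aa_of)
  need <- c(AA_ALPHABET, "*")
  missing_aa <- setdiff(need, names(by_aa)[vapply(by_aa, function(v)
    any(v > 0), logical(1))])
  if (length(missing_aa) > 0L)
    stop("no codon with positive frequency for: ",
         paste(missing_aa, collapse = ", "))
  by_aa <- lapply(by_aa, function(v) v / sum(v))
  structure(list(freq = freq, by_aa = by_aa), class = "codon_usage_table")
}

#' Default E. coli codon usage
#'
#' Loads the codon usage table shipped with the package
#' (`inst/extdata/ecoli_codon_usage.tsv`), standard E. coli K-12 relative
#' synonymous codon frequencies.
#'
#' @return A [codon_usage_table()].
#' @export
default_codon_usage <- function() {
  path <- system.file("extdata", "ecoli_codon_usage.tsv",
                      package = "enztriage", mustWork = TRUE)
  tab <- read.delim(path, stringsAsFactors = FALSE)
  codon_usage_table(setNames(tab$frequency, tab$codon))
}

#' Codon-optimize a protein
#'
#' Reverse-translates a protein into DNA using the `max_usage` strategy:
#' each residue gets its highest-frequency codon (ties broken alphabetically
#' by codon), and the highest-frequency stop codon is appended. The result
#' is deterministic and `translate(codon_optimize(p))` reproduces `p`.
#'
#' @param protein A [protein_sequence()] or residue string.
#' @param table A [codon_usage_table()]; defaults to the shipped E. coli
#'   usage.
#' @param strategy Only `"max_usage"` is supported.
#' @param id Identifier for the resulting coding sequence.
#' @return A [coding_sequence()] ending in a stop codon.
#' @export
codon_optimize <- function(protein, table = default_codon_usage(),
                           strategy = "max_usage", id = NULL) {
  strategy <- match.arg(strategy, "max_usage")
  stopifnot(inherits(table, "codon_usage_table"))
  if (!inherits(protein, "protein_sequence")) {
    protein <- protein_sequence(if (is.null(id)) "optimized" else id, protein)
  }
  if (is.null(id)) id <- protein$id
  pick <- function(aa) {
    v <- table$by_aa[[aa]]
    if (is.null(v) || !any(v > 0))
      stop(sprintf("amino acid '%s' absent from codon usage table", aa))
    v <- v[order(-v, names(v))]  # max usage, alphabetical tie-break
    names(v)[1]
  }
  chars <- strsplit(protein$residues, "", fixed = TRUE)[[1]]
  cods <- vapply(chars, pick, character(1))
  coding_sequence(id, paste(c(cods, pick("*")), collapse = ""))
}
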