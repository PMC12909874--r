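# Global and local pairwise alignment with affine gaps, percent identity,
# MaxID novelty scoring and the composite (weighted global + local)
# alignment score used for ranking.

#' Alignment scoring scheme
#'
#' Match/mismatch/gap parameters of the pairwise aligners plus the weights
#' of the composite alignment score. A gap run of length `g` costs
#' `gap_open + (g - 1) * gap_extend`: the first gapped position carries the
#' opening penalty, so a length-1 gap costs `gap_open`.
#'
#' Defaults are the ranking parameters used throughout the triage pipeline:
#' +1 match, -1 mismatch, -0.5 gap opening, -0.1 gap extension, and weights
#' 3 (global) : 8 (local) for the composite score.
#'
#' @param match,mismatch Per-column residue scores (`match > mismatch`).
#' @param gap_open,gap_extend Non-positive gap increments with
#'   `|gap_extend| <= |gap_open|`.
#' @param w_global,w_local Composite-score weights.
#' @return Object of class `scoring_scheme`.
#' @export
scoring_scheme <- function(match = 1, mismatch = -1, gap_open = -0.5,
                           gap_extend = -0.1, w_global = 3, w_local = 8) {
  stopifnot(match > mismatch, gap_open <= 0, gap_extend <= 0,
            abs(gap_extend) <= abs(gap_open))
  structure(list(match = match, mismatch = mismatch, gap_open = gap_open,
                 gap_extend = gap_extend, w_global = w_global,
                 w_local = w_local),
            class = "scoring_scheme")
}

#' @export
print.scoring_scheme <- function(x, ...) {
  cat(sprintf(
    "<scoring_scheme> match %+g mismatch %+g gap_open %+g gap_extend %+g; weights global %g : local %g\n",
    x$match, x$mismatch, x$gap_open, x$gap_extend, x$w_global, x$w_local))
  invisible(x)
}

new_alignment_result <- function(raw, a, b, local) {
  columns <- raw$columns
  matches <- raw$matches
  identity <- if (!is.na(columns) && columns > 0) matches / columns else 0
  structure(list(score = raw$score, aligned_a = raw$aligned_a,
                 aligned_b = raw$aligned_b, matches = matches,
                 columns = columns, identity = identity,
                 type = if (local) "local" else "global"),
            class = "alignment_result")
}

#' @export
print.alignment_result <- function(x, ...) {
  cat(sprintf("<alignment_result> %s score %.2f, %d/%d matches (%.1f%%)\n",
              x$type, x$score, x$matches, x$columns, 100 * x$identity))
  if (nchar(x$aligned_a) > 0) {
    cat(" ", x$aligned_a, "\n ", x$aligned_b, "\n", sep = "")
  }
  invisible(x)
}

check_alignment_input <- function(a, b) {
  a <- as_residues(a); b <- as_residues(b)
  if (!nzchar(a) || !nzchar(b)) stop("alignment inputs must be non-empty")
  list(a = a, b = b)
}

#' Global pairwise alignment (Needleman-Wunsch with affine gaps)
#'
#' Optimal global alignment under the affine gap model of
#' [scoring_scheme()], end gaps penalized, deterministic traceback (ties
#' resolved diagonal > up > left). Degapping the aligned strings recovers
#' the inputs exactly.
#'
#' @param a,b [protein_sequence()] objects or residue strings, non-empty.
#' @param scheme A [scoring_scheme()].
#' @return An `alignment_result`: `score`, gapped `aligned_a`/`aligned_b`,
#'   `matches`, `columns`, `identity` (matches / columns).
#' @examples
#' global_align("MKT", "MKT")$score  # 3
#' @export
global_align <- function(a, b, scheme = scoring_scheme()) {
  inp <- check_alignment_input(a, b)
  raw <- .gotoh_align_cpp(inp$a, inp$b, scheme$match, scheme$mismatch,
                          scheme$gap_open, scheme$gap_extend,
                          local = FALSE, traceback = TRUE)
  new_alignment_result(raw, inp$a, inp$b, local = FALSE)
}

#' Local pairwise alignment (Smith-Waterman with affine gaps)
#'
#' Optimal local alignment under the same affine gap model; the score is
#' always >= 0 and the empty alignment (score 0) is allowed. The aligned
#' strings cover only the aligned substrings.
#'
#' @inheritParams global_align
#' @return An `alignment_result` (see [global_align()]); for the empty
#'   alignment `columns` is 0 and `identity` 0.
#' @export
local_align <- function(a, b, scheme = scoring_scheme()) {
  inp <- check_alignment_input(a, b)
  raw <- .gotoh_align_cpp(inp$a, inp$b, scheme$match, scheme$mismatch,
                          scheme$gap_open, scheme$gap_extend,
                          local = TRUE, traceback = TRUE)
  new_alignment_result(raw, inp$a, inp$b, local = TRUE)
}

ref_members <- function(refs) {
  if (inherits(refs, "reference_set")) refs$members
  else if (is.character(refs) && !is.null(names(refs))) refs
  else stop("refs must be a reference_set or a named character vector")
}

#' Composite alignment score of a candidate against a reference set
#'
#' The ranking statistic of the triage pipeline: a weighted combination of
#' the candidate's mean global and mean local alignment scores over the
#' reference set,
#' `w_global * mean(global) + w_local * mean(local)`
#' (defaults 3 and 8). Aggregation is by mean, so the score does not grow
#' with reference-set size. Higher is better; fully deterministic.
#'
#' @param candidate A [protein_sequence()] or residue string.
#' @param refs A [reference_set()] or named character vector.
#' @param scheme A [scoring_scheme()].
#' @return Single numeric score.
#' @export
composite_score <- function(candidate, refs, scheme = scoring_scheme()) {
  members <- ref_members(refs)
  stopifnot(length(members) >= 1L)
  a <- as_residues(candidate)
  if (!nzchar(a)) stop("alignment inputs must be non-empty")
  g <- .gotoh_scores_cpp(a, members, scheme$match, scheme$mismatch,
                         scheme$gap_open, scheme$gap_extend, local = FALSE)
  l <- .gotoh_scores_cpp(a, members, scheme$match, scheme$mismatch,
                         scheme$gap_open, scheme$gap_extend, local = TRUE)
  scheme$w_global * mean(g) + scheme$w_local * mean(l)
}

#' Maximum sequence identity (MaxID) to a reference set
#'
#' For each reference, the candidate is globally aligned and percent
#' identity computed as matches over all alignment columns (end gaps
#' included in the denominator; in a pairwise alignment every column holds
#' at least one residue). Returns the maximum over references; identity
#' ties are broken by reference id order (first id in sort order wins).
#'
#' @param candidate A [protein_sequence()] or residue string.
#' @param refs A [reference_set()] or named character vector.
#' @param scheme A [scoring_scheme()] used by the underlying global aligner.
#' @return List with `identity` (percent, 0-100), `best_ref_id`, `matches`,
#'   `columns` of the best reference alignment.
#' @export
max_identity <- function(candidate, refs, scheme = scoring_scheme()) {
  members <- ref_members(refs)
  stopifnot(length(members) >= 1L)
  a <- as_residues(candidate)
  if (!nzchar(a)) stop("alignment inputs must be non-empty")
  ord <- order(names(members))  # id order for deterministic tie-breaks
  members <- members[ord]
  res <- .gotoh_identities_cpp(a, members, scheme$match, scheme$mismatch,
                               scheme$gap_open, scheme$gap_extend)
  best <- which.max(res$identity)  # first maximum in id order
  list(identity = 100 * res$identity[best],
       best_ref_id = names(members)[best],
       matches = res$matches[best],
       columns = res$columns[best])
}

#' Batch MaxID and composite scores for candidate proteins
#'
#' Convenience batch interface over [max_identity()] and
#' [composite_score()]: candidates x references -> one row per candidate.
#'
#' @param candidates Named character vector of candidate residue strings.
#' @param refs A [reference_set()] or named character vector.
#' @param scheme A [scoring_scheme()].
#' @return `data.frame` with columns `id`, `best_ref_id`, `maxid` (percent)
#'   and `score` (composite alignment score), in input order.
#' @export
score_candidates <- function(candidates, refs, scheme = scoring_scheme()) {
  stopifnot(is.character(candidates), !is.null(names(candidates)))
  rows <- lapply(names(candidates), function(id) {
    mi <- max_identity(candidates[[id]], refs, scheme)
    data.frame(id = id, best_ref_id = mi$best_ref_id, maxid = mi$identity,
               score = composite_score(candidates[[id]], refs, scheme),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
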