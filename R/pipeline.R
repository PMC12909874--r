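# Ordered candidate triage: start codon -> length -> pLDDT -> novelty
# (MaxID) -> identity binning -> composite-score ranking -> active-site
# check -> greedy identity clustering -> stratified quota selection.

BIN_LEVELS <- c("<40", "40-50", "50-60", "60-70", "70-80", "80-90", "90-100")
SELECTABLE_BINS <- c("40-50", "50-60", "60-70", "70-80", "80-90", "90-100")

#' Identity bin of a MaxID value
#'
#' Maps percent MaxID to the identity bins used for stratified selection:
#' 40-50, 50-60, 60-70, 70-80, 80-90, 90-100. Intervals are
#' lower-exclusive / upper-inclusive, except 40-50 which is closed below,
#' so every value in \[40, 100\] maps to exactly one bin (e.g. exactly 90
#' falls in 80-90). Values below 40 map to `"<40"` and are never
#' selectable.
#'
#' @param maxid Numeric vector of percent identities in \[0, 100\].
#' @return Factor with levels `<40`, `40-50`, ..., `90-100`.
#' @export
assign_bins <- function(maxid) {
  stopifnot(is.numeric(maxid), all(maxid >= 0 & maxid <= 100, na.rm = TRUE))
  out <- cut(maxid, breaks = c(-Inf, seq(40, 100, by = 10)),
             labels = BIN_LEVELS, right = TRUE)
  out[!is.na(maxid) & maxid == 40] <- "40-50"  # 40-50 is closed below
  out
}

#' Stratified selection plan
#'
#' Per-identity-bin selection quotas and excluded bins. The default plan
#' selects 30 sequences at 80-90% MaxID, 40 at 70-80%, 20 at 60-70%, 10 at
#' 50-60% and 5 at 40-50% (105 total) and excludes the 90-100 bin.
#'
#' @param quotas Named non-negative integer vector, names in
#'   `40-50 ... 90-100`.
#' @param exclude_bins Bins never selected from.
#' @return Object of class `selection_plan`.
#' @export
selection_plan <- function(quotas = c("80-90" = 30, "70-80" = 40,
                                      "60-70" = 20, "50-60" = 10,
                                      "40-50" = 5),
                           exclude_bins = "90-100") {
  stopifnot(is.numeric(quotas), all(quotas >= 0),
            all(names(quotas) %in% SELECTABLE_BINS),
            all(exclude_bins %in% SELECTABLE_BINS),
            !any(names(quotas) %in% exclude_bins))
  structure(list(quotas = quotas, exclude_bins = exclude_bins),
            class = "selection_plan")
}

#' @export
print.selection_plan <- function(x, ...) {
  cat("<selection_plan>",
      paste(sprintf("%s: %d", names(x$quotas), x$quotas), collapse = ", "),
      sprintf("(total %d); excluded: %s\n", sum(x$quotas),
              paste(x$exclude_bins, collapse = ", ")))
  invisible(x)
}

#' Build a candidate table
#'
#' Assembles the per-candidate state table the filter stages operate on.
#' Candidates are translated up front (reading frame 0, stop-at-first-stop);
#' untranslatable candidates get `NA` protein/length and fail the length
#' filter downstream.
#'
#' @param seqs Named character vector of candidate DNA strings, or a list
#'   of [coding_sequence()] objects.
#' @param plddt Optional named numeric vector of structure-confidence
#'   scores (0-1 or 0-100 scale).
#' @return `data.frame` with columns `id`, `dna`, `protein`, `length`,
#'   `plddt`.
#' @export
candidate_table <- function(seqs, plddt = NULL) {
  if (is.list(seqs)) {
    seqs <- setNames(vapply(seqs, function(s) s$dna, character(1)),
                     vapply(seqs, function(s) s$id, character(1)))
  }
  stopifnot(is.character(seqs), !is.null(names(seqs)), all(nzchar(names(seqs))))
  if (anyDuplicated(names(seqs)))
    stop("duplicate candidate ids: ",
         paste(unique(names(seqs)[duplicated(names(seqs))]), collapse = ", "))
  prot <- vapply(names(seqs), function(id) {
    tryCatch(translate(seqs[[id]], id = id)$residues,
             error = function(e) NA_character_,
             warning = function(w) NA_character_)
  }, character(1))
  df <- data.frame(id = names(seqs), dna = unname(seqs),
                   protein = unname(prot),
                   length = ifelse(is.na(prot), NA_integer_, nchar(prot)),
                   stringsAsFactors = FALSE)
  if (!is.null(plddt)) df$plddt <- unname(plddt[df$id])
  df
}

stage_report <- function(stage, n_in, n_pass) {
  data.frame(stage = stage, n_in = n_in, n_passed = n_pass,
             pass_rate = if (n_in > 0) n_pass / n_in else NA_real_,
             stringsAsFactors = FALSE)
}

filter_result <- function(stage, cands, keep, reason) {
  if (sum(keep) == 0L)
    warning("stage '", stage, "' removed every candidate")
  list(kept = cands[keep, , drop = FALSE],
       report = stage_report(stage, nrow(cands), sum(keep)),
       failures = data.frame(id = cands$id[!keep],
                             reason = reason[!keep],
                             stringsAsFactors = FALSE))
}

#' Start-codon filter
#'
#' Keeps exactly the candidates whose first codon is ATG.
#'
#' @param cands Candidate table (see [candidate_table()]).
#' @return List with `kept` (subset of `cands`), `report` (one-row stage
#'   summary) and `failures` (id + reason).
#' @export
filter_start_codon <- function(cands) {
  keep <- substr(cands$dna, 1L, 3L) == "ATG"
  filter_result("start_codon", cands, keep,
                sprintf("first codon %s != ATG", substr(cands$dna, 1L, 3L)))
}

#' Protein length filter
#'
#' Keeps candidates whose translated length L lies in `bounds` (inclusive).
#' The default bounds are the family's valid range of 306-421 amino acids.
#' Passing `multiplier = m` together with `refs` recomputes the bounds from
#' the reference length statistics as the integer lengths within
#' `mean +/- m * sd`.
#'
#' @param cands Candidate table with `length`.
#' @param refs A [reference_set()]; only consulted when `multiplier` is
#'   given.
#' @param bounds Integer length bounds, inclusive.
#' @param multiplier Optional number of reference-length standard
#'   deviations used to recompute `bounds`.
#' @return As [filter_start_codon()].
#' @export
filter_length <- function(cands, refs = NULL, bounds = c(306L, 421L),
                          multiplier = NULL) {
  if (!is.null(multiplier)) {
    stopifnot(inherits(refs, "reference_set"))
    bounds <- c(ceiling(refs$length_mean - multiplier * refs$length_sd),
                floor(refs$length_mean + multiplier * refs$length_sd))
  }
  keep <- !is.na(cands$length) &
    cands$length >= bounds[1] & cands$length <= bounds[2]
  filter_result("length", cands, keep,
                ifelse(is.na(cands$length), "untranslatable",
                       sprintf("length %d outside [%d, %d]", cands$length,
                               as.integer(bounds[1]), as.integer(bounds[2]))))
}

#' Structure-confidence (pLDDT) filter
#'
#' Keeps candidates with pLDDT >= `threshold` (boundary inclusive). Scores
#' are accepted on either the 0-1 or the 0-100 scale; any score above 1 is
#' divided by 100. A candidate without a score is an error.
#'
#' @param cands Candidate table.
#' @param scores Optional named numeric vector overriding `cands$plddt`.
#' @param threshold Minimum confidence on the 0-1 scale.
#' @return As [filter_start_codon()]; `kept$plddt` is on the 0-1 scale.
#' @export
filter_plddt <- function(cands, scores = NULL, threshold = 0.80) {
  if (!is.null(scores)) cands$plddt <- unname(scores[cands$id])
  if (is.null(cands$plddt) || anyNA(cands$plddt))
    stop("missing pLDDT score for candidate(s): ",
         paste(cands$id[is.na(cands$plddt)], collapse = ", "))
  cands$plddt <- ifelse(cands$plddt > 1, cands$plddt / 100, cands$plddt)
  keep <- cands$plddt >= threshold
  filter_result("plddt", cands, keep,
                sprintf("pLDDT %.3f < %.2f", cands$plddt, threshold))
}

#' Novelty filter on MaxID
#'
#' Excludes candidates with more than `max_maxid` percent identity to any
#' reference (default: drop everything above 90%; exactly 90% is kept).
#'
#' @param cands Candidate table with a `maxid` column (percent).
#' @param max_maxid Inclusive upper bound on MaxID.
#' @return As [filter_start_codon()].
#' @export
filter_novelty <- function(cands, max_maxid = 90) {
  if (is.null(cands$maxid) || anyNA(cands$maxid))
    stop("MaxID missing for candidate(s): ",
         paste(cands$id[is.na(cands$maxid)], collapse = ", "))
  keep <- cands$maxid <= max_maxid
  filter_result("novelty", cands, keep,
                sprintf("MaxID %.1f%% > %.0f%%", cands$maxid, max_maxid))
}

#' Active-site conservation check
#'
#' Globally aligns the candidate to an anchor sequence carrying a known
#' catalytic residue and reports whether the candidate residue in the
#' alignment column of `anchor_pos` (1-based in the anchor) is `required`.
#' A gap in that column fails the check. The anchor must itself carry
#' `required` at `anchor_pos`, else the call is a configuration error.
#'
#' @param cand,anchor [protein_sequence()] objects or residue strings.
#' @param anchor_pos 1-based anchor position of the catalytic residue
#'   (default 82, the catalytic lysine of the anchor TrpB).
#' @param required Required residue (default `"K"`).
#' @param scheme A [scoring_scheme()].
#' @return `TRUE` or `FALSE`.
#' @export
check_active_site <- function(cand, anchor, anchor_pos = 82L,
                              required = "K", scheme = scoring_scheme()) {
  anchor_res <- as_residues(anchor)
  if (nchar(anchor_res) < anchor_pos)
    stop("anchor shorter than anchor_pos")
  if (substr(anchor_res, anchor_pos, anchor_pos) != required)
    stop(sprintf("anchor residue at position %d is '%s', expected '%s'",
                 anchor_pos, substr(anchor_res, anchor_pos, anchor_pos),
                 required))
  aln <- global_align(cand, anchor_res, scheme)
  anchor_chars <- strsplit(aln$aligned_b, "", fixed = TRUE)[[1]]
  col <- which(cumsum(anchor_chars != "-") == anchor_pos &
                 anchor_chars != "-")[1]
  cand_chars <- strsplit(aln$aligned_a, "", fixed = TRUE)[[1]]
  identical(cand_chars[col], required)
}

#' Greedy identity clustering
#'
#' CD-HIT-style greedy incremental clustering at a pairwise-identity
#' threshold: candidates are processed in descending composite-score order
#' (ties by id); each joins the first existing cluster whose representative
#' it matches at >= `threshold` global-alignment identity, otherwise it
#' founds a new cluster. Because processing is score-ordered, the founder
#' of each cluster is its highest-scoring member and serves as the
#' representative.
#'
#' @param cands Candidate table with `protein` and `score` columns.
#' @param threshold Identity threshold as a fraction (default 0.70).
#' @param scheme A [scoring_scheme()] for the identity alignments.
#' @return `cands` with added integer `cluster` (1-based, in founding
#'   order) and logical `is_representative` columns.
#' @export
cluster_by_identity <- function(cands, threshold = 0.70,
                                scheme = scoring_scheme()) {
  stopifnot(!is.null(cands$protein), !is.null(cands$score))
  ord <- order(-cands$score, cands$id)
  reps <- character(0)   # representative proteins in founding order
  rep_ids <- character(0)
  cluster <- integer(nrow(cands))
  for (i in ord) {
    assigned <- NA_integer_
    if (length(reps) > 0L) {
      ident <- .gotoh_identities_cpp(cands$protein[i], reps, scheme$match,
                                     scheme$mismatch, scheme$gap_open,
                                     scheme$gap_extend)$identity
      hit <- which(ident >= threshold - 1e-12)
      if (length(hit) > 0L) assigned <- hit[1]
    }
    if (is.na(assigned)) {
      reps <- c(reps, cands$protein[i])
      rep_ids <- c(rep_ids, cands$id[i])
      assigned <- length(reps)
    }
    cluster[i] <- assigned
  }
  cands$cluster <- cluster
  cands$is_representative <- cands$id %in% rep_ids
  cands
}

#' Stratified quota selection
#'
#' Final selection stage: within each identity bin of the plan, takes the
#' top-quota cluster representatives by composite score (ties broken by
#' id). Bins with fewer representatives than their quota yield what they
#' have, with a shortfall warning. Excluded bins and the `<40` bin are
#' never selected from.
#'
#' @param cands Candidate table with `bin`, `score`, `cluster`,
#'   `is_representative`.
#' @param plan A [selection_plan()].
#' @return `data.frame` of selected candidates with `bin_rank` (1 = best in
#'   bin), ordered by bin (descending identity) then rank.
#' @export
select_candidates <- function(cands, plan = selection_plan()) {
  stopifnot(inherits(plan, "selection_plan"),
            !is.null(cands$bin), !is.null(cands$score))
  if (is.null(cands$is_representative)) cands$is_representative <- TRUE
  pool <- cands[cands$is_representative &
                  !(as.character(cands$bin) %in% plan$exclude_bins) &
                  as.character(cands$bin) %in% names(plan$quotas), ,
                drop = FALSE]
  bins_order <- names(sort(vapply(names(plan$quotas), function(b)
    -as.numeric(sub("-.*", "", b)), numeric(1))))
  out <- list()
  for (b in bins_order) {
    inbin <- pool[as.character(pool$bin) == b, , drop = FALSE]
    inbin <- inbin[order(-inbin$score, inbin$id), , drop = FALSE]
    quota <- plan$quotas[[b]]
    if (nrow(inbin) < quota)
      warning(sprintf("bin %s: only %d representatives for quota %d",
                      b, nrow(inbin), quota))
    take <- inbin[seq_len(min(quota, nrow(inbin))), , drop = FALSE]
    if (nrow(take) > 0L) take$bin_rank <- seq_len(nrow(take))
    out[[b]] <- take
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Triage pipeline configuration
#'
#' Bundles every knob of [run_pipeline()]. All defaults follow the standard
#' triage conditions: length bounds 306-421 aa, pLDDT >= 0.80, novelty cut
#' at 90% MaxID, catalytic lysine at anchor position 82, clustering at 70%
#' identity, and the default 105-sequence selection plan.
#'
#' @param length_bounds Inclusive protein length bounds.
#' @param length_multiplier Optional: recompute bounds as reference mean
#'   +/- multiplier * sd (see [filter_length()]).
#' @param plddt_threshold Minimum pLDDT on the 0-1 scale.
#' @param novelty_max Inclusive MaxID upper bound (percent).
#' @param active_site Logical: apply the active-site conservation check
#'   (requires an anchor).
#' @param anchor_pos,anchor_residue Anchor coordinates of the catalytic
#'   residue.
#' @param clustering Logical: apply greedy identity clustering.
#' @param cluster_threshold Identity threshold (fraction) for clustering.
#' @param stability_hook Optional per-candidate stability filter: a
#'   function taking the candidate table and returning a logical keep
#'   vector. Disabled (`NULL`) by default.
#' @param scheme A [scoring_scheme()].
#' @param plan A [selection_plan()].
#' @return Object of class `triage_config`.
#' @export
triage_config <- function(length_bounds = c(306L, 421L),
                          length_multiplier = NULL,
                          plddt_threshold = 0.80,
                          novelty_max = 90,
                          active_site = TRUE,
                          anchor_pos = 82L,
                          anchor_residue = "K",
                          clustering = TRUE,
                          cluster_threshold = 0.70,
                          stability_hook = NULL,
                          scheme = scoring_scheme(),
                          plan = selection_plan()) {
  structure(list(length_bounds = length_bounds,
                 length_multiplier = length_multiplier,
                 plddt_threshold = plddt_threshold,
                 novelty_max = novelty_max,
                 active_site = active_site,
                 anchor_pos = as.integer(anchor_pos),
                 anchor_residue = anchor_residue,
                 clustering = clustering,
                 cluster_threshold = cluster_threshold,
                 stability_hook = stability_hook,
                 scheme = scheme, plan = plan),
            class = "triage_config")
}

#' Run the full triage pipeline
#'
#' Executes the stages in fixed order: start codon, length, pLDDT,
#' optional stability hook, MaxID + novelty, identity binning, composite
#' alignment-score ranking, optional active-site check, optional greedy
#' identity clustering, stratified quota selection. The run is fully
#' deterministic given its inputs.
#'
#' @param candidates Named character vector of candidate DNA strings, a
#'   list of [coding_sequence()], or a path to a DNA FASTA.
#' @param refs A [reference_set()], a named character vector of reference
#'   proteins, or a path to a protein FASTA.
#' @param plddt Named numeric vector of structure-confidence scores, or a
#'   path to a two-column (id, plddt) TSV with header.
#' @param anchor Anchor protein ([protein_sequence()], residue string or
#'   single-record protein FASTA path); required when the active-site
#'   check is enabled.
#' @param config A [triage_config()].
#' @return Object of class `triage_result`: list with `report` (per-stage
#'   counts), `candidates` (full per-candidate table with stage flags),
#'   `selected` (the stratified selection), `selected_seqs` (named DNA
#'   vector) and `failures` (per-candidate failure reasons).
#' @export
run_pipeline <- function(candidates, refs, plddt, anchor = NULL,
                         config = triage_config()) {
  if (is.character(candidates) && length(candidates) == 1L &&
      is.null(names(candidates)) && file.exists(candidates))
    candidates <- read_fasta(candidates, "dna")
  if (is.character(refs) && length(refs) == 1L && is.null(names(refs)) &&
      file.exists(refs))
    refs <- read_fasta(refs, "protein")
  if (!inherits(refs, "reference_set")) refs <- reference_set(refs)
  if (is.character(plddt) && length(plddt) == 1L && file.exists(plddt)) {
    tab <- read.delim(plddt, stringsAsFactors = FALSE)
    plddt <- setNames(tab[[2]], tab[[1]])
  }
  if (!is.null(anchor) && is.character(anchor) && length(anchor) == 1L &&
      file.exists(anchor))
    anchor <- read_fasta(anchor, "protein")[[1]]

  cands <- candidate_table(candidates, plddt)
  reports <- list()
  failures <- list()
  run_stage <- function(res) {
    reports[[length(reports) + 1L]] <<- res$report
    failures[[length(failures) + 1L]] <<- res$failures
    res$kept
  }

  cands <- run_stage(filter_start_codon(cands))
  cands <- run_stage(filter_length(cands, refs,
                                   bounds = config$length_bounds,
                                   multiplier = config$length_multiplier))
  cands <- run_stage(filter_plddt(cands, threshold = config$plddt_threshold))
  if (!is.null(config$stability_hook)) {
    keep <- config$stability_hook(cands)
    cands <- run_stage(filter_result("stability", cands, keep,
                                     rep("stability hook", nrow(cands))))
  }

  scored <- score_candidates(setNames(cands$protein, cands$id), refs,
                             config$scheme)
  cands$maxid <- scored$maxid[match(cands$id, scored$id)]
  cands$best_ref <- scored$best_ref_id[match(cands$id, scored$id)]
  cands$score <- scored$score[match(cands$id, scored$id)]
  cands <- run_stage(filter_novelty(cands, max_maxid = config$novelty_max))
  cands$bin <- assign_bins(cands$maxid)

  if (isTRUE(config$active_site)) {
    if (is.null(anchor))
      stop("active-site check enabled but no anchor supplied")
    ok <- vapply(cands$protein, check_active_site, logical(1),
                 anchor = anchor, anchor_pos = config$anchor_pos,
                 required = config$anchor_residue, scheme = config$scheme)
    cands$active_site_ok <- unname(ok)
    cands <- run_stage(filter_result("active_site", cands, unname(ok),
                                     rep(sprintf("no %s aligned to anchor %d",
                                                 config$anchor_residue,
                                                 config$anchor_pos),
                                         nrow(cands))))
  } else {
    cands$active_site_ok <- NA
  }

  if (isTRUE(config$clustering)) {
    cands <- cluster_by_identity(cands, threshold = config$cluster_threshold,
                                 scheme = config$scheme)
  } else {
    cands$cluster <- seq_len(nrow(cands))
    cands$is_representative <- TRUE
  }

  selected <- select_candidates(cands, config$plan)
  reports[[length(reports) + 1L]] <-
    stage_report("selection", nrow(cands), nrow(selected))
  cands$selected <- cands$id %in% selected$id

  structure(list(
    report = do.call(rbind, reports),
    candidates = cands,
    selected = selected,
    selected_seqs = setNames(selected$dna, selected$id),
    failures = do.call(rbind, failures)), class = "triage_result")
}

#' @export
print.triage_result <- function(x, ...) {
  cat("<triage_result>\n")
  print(x$report, row.names = FALSE)
  cat(sprintf("selected: %d candidates\n", nrow(x$selected)))
  invisible(x)
}

#' Write pipeline outputs
#'
#' Writes `selected.fasta` (selected DNA sequences), `candidates.tsv` (one
#' row per surviving candidate with all stage fields), `report.tsv`
#' (per-stage counts) and `failures.tsv` into `dir`.
#'
#' @param result A `triage_result` from [run_pipeline()].
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_pipeline_output <- function(result, dir) {
  stopifnot(inherits(result, "triage_result"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_fasta(result$selected_seqs, file.path(dir, "selected.fasta"))
  tsv <- function(df, name) write.table(
    df, file.path(dir, name), sep = "\t", quote = FALSE, row.names = FALSE)
  tsv(result$candidates, "candidates.tsv")
  tsv(result$report, "report.tsv")
  tsv(result$failures, "failures.tsv")
  invisible(dir)
}
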