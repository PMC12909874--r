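# Synthetic fixtures with controlled identity structure. These stand in for
# the real inputs of a triage campaign (generated candidate pools, natural
# reference families, plate screens) so every stage is testable offline at
# desk scale.

#' Random protein sequence
#'
#' Uniform over the 20 amino acids, with a methionine forced at position 1
#' and (optionally) a lysine at `anchor_pos`, mirroring the catalytic-residue
#' convention of the triage fixtures.
#'
#' @param length Protein length in residues.
#' @param anchor_pos Optional position forced to `K`.
#' @return Residue string.
#' @export
random_protein <- function(length, anchor_pos = NULL) {
  chars <- sample(AA_ALPHABET, length, replace = TRUE)
  chars[1] <- "M"
  if (!is.null(anchor_pos)) {
    stopifnot(anchor_pos >= 1L, anchor_pos <= length)
    chars[anchor_pos] <- "K"
  }
  paste(chars, collapse = "")
}

#' Substitute residues at random positions
#'
#' Applies exactly `n_mut` substitutions (each to a different residue) at
#' distinct positions, never touching position 1 or `protect` positions.
#' With equal-length sequences and the default scoring scheme this pins the
#' global-alignment identity to `(L - n_mut) / L` exactly, which is how the
#' fixtures control MaxID.
#'
#' @param residues Residue string.
#' @param n_mut Number of substitutions.
#' @param protect Positions that must not be mutated (position 1 is always
#'   protected).
#' @return Mutated residue string.
#' @export
mutate_protein <- function(residues, n_mut, protect = integer(0)) {
  chars <- strsplit(residues, "", fixed = TRUE)[[1]]
  eligible <- setdiff(seq_along(chars)[-1], protect)
  stopifnot(n_mut <= length(eligible))
  pos <- sample(eligible, n_mut)
  for (p in pos) {
    chars[p] <- sample(setdiff(AA_ALPHABET, chars[p]), 1L)
  }
  paste(chars, collapse = "")
}

#' Simulate a complete triage fixture
#'
#' Builds, from one ancestor protein, a reference family plus a candidate
#' pool with controlled MaxID structure:
#'
#' * one parent reference per binned candidate. Parents diverge from the
#'   ancestor by `parent_divergence` of the mutable positions, so parents
#'   are mutually ~30% identical and each candidate's MaxID is its
#'   identity to its own parent;
#' * eligible candidates populating each identity bin per `bin_targets`.
#'   Because gapped alignments can lower realized identity below the
#'   naive substitution count, each candidate's mutation load is
#'   calibrated against the package's own global aligner until its
#'   identity to its parent falls strictly inside the bin;
#' * redundant cluster members (a few extra mutations on an eligible
#'   candidate) to exercise clustering;
#' * candidates that fail the start-codon, length, pLDDT and active-site
#'   stages, plus unrelated sequences below 40% MaxID.
#'
#' A catalytic motif — `anchor_pos` plus `conserved_radius` residues on
#' each side — is conserved across the ancestor, all parents and all
#' family-derived candidates, the way an active-site motif is conserved in
#' a real enzyme family; this keeps the anchor lysine alignable even in
#' low-identity candidates. The active-site failures substitute exactly
#' that lysine. DNA is produced by max-usage codon optimization, so every
#' candidate except the start-codon failures begins with ATG.
#'
#' The default pool (~455 candidates of length 100) is the desk-scale
#' analogue of a generated-library triage: every non-excluded bin holds
#' more cluster representatives than the default selection quota.
#'
#' @param seed Integer seed; the fixture is fully reproducible.
#' @param protein_length Candidate/reference protein length.
#' @param anchor_pos Catalytic-residue position (1-based).
#' @param conserved_radius Residues on each side of `anchor_pos` forming
#'   the conserved catalytic motif.
#' @param parent_divergence Fraction of mutable positions mutated between
#'   the ancestor and each parent reference.
#' @param bin_targets Named integer vector: candidates per identity bin.
#' @param n_active_site_fail Candidates with the anchor lysine substituted.
#' @param n_cluster_members Redundant near-copies of eligible candidates.
#' @param n_bad_start,n_bad_length,n_low_plddt,n_unrelated Counts of
#'   candidates failing the respective stages (unrelated = below 40%
#'   MaxID).
#' @return List with `candidates` (named DNA vector), `plddt` (named
#'   numeric), `refs` ([reference_set()]), `anchor` (residue string),
#'   `anchor_pos`, `truth` (`data.frame`: id, role, parent, target_maxid
#'   = realized identity to the parent, bin) and `length_bounds` (bounds
#'   matched to the fixture protein length).
#' @export
simulate_triage_fixture <- function(seed = 1L,
                                    protein_length = 100L,
                                    anchor_pos = 82L,
                                    conserved_radius = 5L,
                                    parent_divergence = 0.45,
                                    bin_targets = c("40-50" = 12L,
                                                    "50-60" = 18L,
                                                    "60-70" = 30L,
                                                    "70-80" = 50L,
                                                    "80-90" = 40L,
                                                    "90-100" = 15L),
                                    n_active_site_fail = 10L,
                                    n_cluster_members = 100L,
                                    n_bad_start = 50L,
                                    n_bad_length = 50L,
                                    n_low_plddt = 50L,
                                    n_unrelated = 30L) {
  stopifnot(all(names(bin_targets) %in% SELECTABLE_BINS),
            protein_length > anchor_pos + conserved_radius)
  set.seed(seed)
  L <- protein_length
  motif <- seq.int(max(2L, anchor_pos - conserved_radius),
                   min(L, anchor_pos + conserved_radius))
  n_mutable <- L - 1L - length(motif)
  ancestor <- random_protein(L, anchor_pos)
  n_parents <- sum(bin_targets) + n_active_site_fail
  n_div <- round(parent_divergence * n_mutable)
  parents <- vapply(seq_len(n_parents), function(i)
    mutate_protein(ancestor, n_div, protect = motif), character(1))
  names(parents) <- sprintf("ref%03d", seq_len(n_parents))

  # mutate until the aligner-measured identity to the parent lies strictly
  # inside [lo, hi] (gaps can push realized identity below the naive
  # substitution count, so the load is adjusted iteratively)
  calibrate <- function(parent, lo, hi, protect) {
    target <- (lo + hi) / 2
    k <- min(round((1 - target / 100) * L), n_mutable)
    for (iter in seq_len(60L)) {
      prot <- mutate_protein(parent, k, protect)
      real <- 100 * global_align(prot, parent)$identity
      if (real >= lo + 0.6 && real <= hi - 0.6)
        return(list(protein = prot, realized = real))
      step <- max(1L, round(abs(real - target) * 0.6))
      k <- if (real > target) k + step else k - step
      k <- max(1L, min(k, n_mutable))
    }
    stop("identity calibration failed for bin [", lo, ", ", hi, "]")
  }

  usage <- default_codon_usage()
  truth <- list()
  dna <- character(0)
  plddt <- numeric(0)
  add <- function(id, protein, role, parent, realized, plddt_value,
                  dna_override = NULL) {
    d <- if (is.null(dna_override))
      codon_optimize(protein, usage, id = id)$dna else dna_override
    dna[[id]] <<- d
    plddt[[id]] <<- plddt_value
    truth[[id]] <<- data.frame(
      id = id, role = role, parent = parent,
      target_maxid = realized,
      bin = if (is.na(realized)) NA_character_
            else as.character(assign_bins(realized)),
      stringsAsFactors = FALSE)
  }

  p_idx <- 0L
  bases <- list()  # eligible candidates usable as cluster-duplicate bases
  for (bin in names(bin_targets)) {
    lo <- as.numeric(sub("-.*", "", bin))
    for (i in seq_len(bin_targets[[bin]])) {
      p_idx <- p_idx + 1L
      id <- sprintf("cand%03d", p_idx)
      cal <- calibrate(parents[[p_idx]], lo, lo + 10, motif)
      add(id, cal$protein, "eligible", names(parents)[p_idx],
          cal$realized, runif(1, 0.82, 0.98))
      if (bin != "90-100" && cal$realized >= lo + 3.5) {
        bases[[length(bases) + 1L]] <-
          list(id = id, protein = cal$protein,
               parent = names(parents)[p_idx], bin = bin)
      }
    }
  }

  # active-site failures: in-bin candidates whose anchor lysine is mutated
  for (i in seq_len(n_active_site_fail)) {
    p_idx <- p_idx + 1L
    cal <- calibrate(parents[[p_idx]], 80, 90, motif)
    chars <- strsplit(cal$protein, "", fixed = TRUE)[[1]]
    chars[anchor_pos] <- "R"
    add(sprintf("ksub%03d", i), paste(chars, collapse = ""),
        "active_site_fail", names(parents)[p_idx], cal$realized - 1,
        runif(1, 0.82, 0.98))
  }

  # redundant cluster members: few extra mutations, same family as base
  for (i in seq_len(n_cluster_members)) {
    base <- bases[[((i - 1L) %% length(bases)) + 1L]]
    prot <- mutate_protein(base$protein, sample(2:3, 1L), protect = motif)
    add(sprintf("dup%03d", i), prot, "cluster_member", base$parent,
        NA_real_, runif(1, 0.82, 0.98))
  }

  for (i in seq_len(n_bad_start)) {
    prot <- random_protein(L, anchor_pos)
    d <- codon_optimize(prot, usage)$dna
    substr(d, 1L, 3L) <- "CTG"
    add(sprintf("nostart%03d", i), prot, "bad_start", NA_character_,
        NA_real_, runif(1, 0.82, 0.98), dna_override = d)
  }
  for (i in seq_len(n_bad_length)) {
    len <- if (i %% 2L == 0L) round(L * 0.6) else round(L * 1.5)
    add(sprintf("badlen%03d", i), random_protein(len), "bad_length",
        NA_character_, NA_real_, runif(1, 0.82, 0.98))
  }
  for (i in seq_len(n_low_plddt)) {
    add(sprintf("lowconf%03d", i), random_protein(L, anchor_pos),
        "low_plddt", NA_character_, NA_real_, runif(1, 0.30, 0.79))
  }
  for (i in seq_len(n_unrelated)) {
    add(sprintf("far%03d", i), random_protein(L, anchor_pos), "unrelated",
        NA_character_, NA_real_, runif(1, 0.82, 0.98))
  }

  truth <- do.call(rbind, truth)
  rownames(truth) <- NULL
  list(candidates = dna,
       plddt = plddt,
       refs = reference_set(parents, length_mean = L, length_sd = 0),
       anchor = ancestor,
       anchor_pos = anchor_pos,
       truth = truth,
       length_bounds = c(round(L * 0.9), round(L * 1.1)))
}

#' Simulate a plate screen with known detection truth
#'
#' Generates a tidy plate table from the detection rule itself: per
#' substrate, negative-control areas are drawn around a background mean;
#' each enzyme x substrate pair is assigned a truth state (`quantified`,
#' `detectable`, `not_detected`) and given an MS area clearly above or
#' below the per-substrate mean + 3 sd threshold (and a UV yield only when
#' quantified). Recovering the truth from [call_plate()] is then exact.
#'
#' @param seed Integer seed.
#' @param n_enzymes Number of enzymes.
#' @param substrates Substrate panel (character).
#' @param n_control_rep Negative-control replicates per substrate.
#' @param background_mean,background_sd Control area distribution.
#' @return List with `plate` (data.frame: enzyme, substrate, uv_yield,
#'   ms_area, is_control) and `truth` (data.frame: enzyme, substrate,
#'   call).
#' @export
simulate_plate <- function(seed = 1L, n_enzymes = 12L,
                           substrates = paste0("S", 1:7),
                           n_control_rep = 4L,
                           background_mean = 1000,
                           background_sd = 120) {
  set.seed(seed)
  enzymes <- sprintf("enz%02d", seq_len(n_enzymes))
  plate <- list()
  truth <- list()
  for (s in substrates) {
    ctrl <- round(rnorm(n_control_rep, background_mean, background_sd))
    ctrl <- pmax(ctrl, 0)
    thr <- ms_detection_threshold(ctrl)
    plate[[length(plate) + 1L]] <- data.frame(
      enzyme = "pUC19", substrate = s, uv_yield = NA_real_,
      ms_area = ctrl, is_control = TRUE, stringsAsFactors = FALSE)
    states <- sample(c("quantified", "detectable", "not_detected"),
                     n_enzymes, replace = TRUE, prob = c(0.3, 0.3, 0.4))
    area <- ifelse(states == "not_detected",
                   round(runif(n_enzymes, 0, max(thr - 1, 0))),
                   round(thr * runif(n_enzymes, 1.5, 6)))
    uv <- ifelse(states == "quantified", round(runif(n_enzymes, 5, 99)),
                 NA_real_)
    plate[[length(plate) + 1L]] <- data.frame(
      enzyme = enzymes, substrate = s, uv_yield = uv, ms_area = area,
      is_control = FALSE, stringsAsFactors = FALSE)
    truth[[length(truth) + 1L]] <- data.frame(
      enzyme = enzymes, substrate = s, call = states,
      stringsAsFactors = FALSE)
  }
  list(plate = do.call(rbind, plate), truth = do.call(rbind, truth))
}
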