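---
title: "Methods: triage of generated enzyme coding sequences"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: triage of generated enzyme coding sequences}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Generative sequence models can emit tens of thousands of candidate
protein-coding DNA sequences for an enzyme family, but only a small,
carefully chosen subset can be synthesized and screened in the lab. The
bottleneck this package addresses is the *triage* between generation and
experiment: discard candidates that cannot work (no start codon, wrong
length, poor predicted structure), quantify each survivor's novelty
relative to the natural family, and assemble a final panel that is
simultaneously high-quality, diverse, and stratified across novelty
levels. The working example throughout is the β-subunit of tryptophan
synthase (TrpB), a PLP-dependent enzyme whose catalytic lysine provides a
convenient single-residue functional check, but nothing in the machinery
is family-specific.

`enztriage` implements the full path: sequence handling and translation, a
stand-in generator for testing, pairwise alignment and scoring, the
ordered filtering pipeline with stratified selection, conservation
profiling of the resulting sets, and the detection statistics used when
screening the selected enzymes on substrate panels.

## Pipeline model

`run_pipeline()` executes a fixed stage order; each stage consumes the
survivors of the previous one, so attrition is monotone and the per-stage
report rates compose:

1. **Start codon** — keep candidates whose first codon is ATG. A
   codon-level generator prompted with ATG should pass this trivially; the
   filter guards against malformed input.
2. **Length** — keep translated lengths in a fixed inclusive window,
   306–421 amino acids by default. These bounds are the family's valid
   length range and correspond to roughly one standard deviation around
   the default family statistics (mean 363.55 aa, sd 57.91 aa) shipped
   with `reference_set()`; note that a literal two-sigma window around
   those statistics would give ≈[248, 479]. Because the printed range and
   the two-sigma formula cannot both hold, the package defaults to the
   explicit bounds and exposes `length_multiplier` for users who prefer
   bounds recomputed as mean ± m·sd from their own reference set.
3. **Structure confidence (pLDDT)** — keep candidates with predicted
   structure confidence ≥ 0.80. Scores are supplied externally (structure
   prediction is out of scope) on either the 0–1 or 0–100 scale;
   anything above 1 is divided by 100. The boundary is inclusive.
4. **Novelty (MaxID)** — compute each candidate's maximum percent
   identity over the reference set and drop everything above 90%.
   Exactly 90% is kept (and then excluded from selection via the 90–100
   bin), so the two 90% rules agree at the boundary.
5. **Identity binning** — partition MaxID into 40–50, …, 90–100 percent
   bins. Bins are lower-exclusive/upper-inclusive except 40–50, which is
   closed below, so every value in [40, 100] maps to exactly one bin;
   values below 40 land in a non-selectable `<40` category.
6. **Ranking** — the composite alignment score (below), computed against
   the whole reference set.
7. **Active-site check** (optional, on by default) — globally align each
   candidate to an anchor sequence and require the residue in the
   alignment column of the anchor's catalytic position (default lysine
   at position 82) to be that residue; a gap fails. A pairwise
   alignment per candidate was chosen over one joint MSA so that each
   candidate's verdict is independent of which other candidates are in
   the batch, and deterministic.
8. **Diversity clustering** (optional, on by default) — greedy
   incremental clustering at 70% pairwise identity, CD-HIT style:
   process candidates in descending score order; each joins the first
   cluster whose representative it matches at or above the threshold,
   else founds a new cluster. Processing in score order makes the
   founder the highest-scoring member, hence the representative. This
   replaces an external BLAST-based clustering with an internal,
   deterministic equivalent at the same threshold.
9. **Stratified selection** — per-bin quotas, by default 30 from 80–90,
   40 from 70–80, 20 from 60–70, 10 from 50–60 and 5 from 40–50 (105
   total), taken from cluster representatives in descending score order
   with ties broken by candidate id. Bins short of quota yield what they
   have with a warning.

A per-candidate scalar stability filter (e.g. a folding-energy score) can
be plugged in via `triage_config(stability_hook = ...)`; it is disabled by
default because confidence-based filtering already removes most unstable
candidates and a hard stability threshold biases the panel toward
conservative sequences.

## Alignment scoring

Both aligners are affine-gap Gotoh dynamic programs implemented in C++
(`global_align()` penalizes end gaps; `local_align()` allows the empty
alignment at score 0). The scoring scheme is +1 match, −1 mismatch, −0.5
gap opening, −0.1 gap extension. A gap run of length g costs
`gap_open + (g − 1)·gap_extend`: the first gapped residue *is* the
opening, so a length-1 gap costs exactly −0.5, which is the reading under
which the parameter names make sense. Traceback ties are resolved
diagonal > up > left, making aligned strings reproducible; scores are
unaffected by tie choice.

The ranking statistic is

```
score(c) = 3 · mean_r global(c, r)  +  8 · mean_r local(c, r)
```

over the reference set. Aggregation is by **mean**, not sum, so the score
does not scale with reference-set size and remains comparable across
reference sets; with a single identical reference of length L the score
is exactly 11·L.

Percent identity is `matches / columns` of the optimal global alignment,
where every alignment column counts (end gaps included; in a pairwise
alignment no column is gapped in both rows). This full-length denominator
is the convention under which two ~400-residue homologs sharing 322
matching positions in a 400-column alignment score 80.5%. The
alternative shorter-sequence denominator is deliberately not the default
but the `alignment_result` fields (`matches`, `columns`) let users derive
any convention.

Correctness of the dynamic programs is established two independent ways
in the test suite: exhaustive enumeration of the entire alignment space
for short sequences (hundreds of random pairs up to length 7), and
`Biostrings::pairwiseAlignment` under the translated gap convention for
longer pairs.

## The stand-in generator

`fit_codon_markov()` / `sample_sequence()` provide a codon-level Markov
model with the sampling interface of an autoregressive generator:
temperature scaling, then top-k truncation, then nucleus (top-p)
truncation, then renormalization — the conventional composition of
nucleus-with-top-k sampling. Defaults are temperature 1.0, top-k 50,
top-p 0.9, at most 512 codons, ATG prompt. Probability ties during
truncation are broken by codon lexicographic order, so the processed
distribution is deterministic. A dedicated end token is learned from
sequence ends; sampling terminates on the end token, on an in-frame stop
codon (kept in the DNA, matching `translate()` semantics), or at the
length cap. Unseen contexts back off by dropping the oldest codon, down
to the unconditional codon distribution, which keeps generation total on
small training corpora.

This generator exists so the triage pipeline can be exercised and tested
without any model weights; it makes no claim to reproduce a transformer's
output distribution beyond the sampling interface itself.

## Synthetic fixtures: what they emulate and what they do not

`simulate_triage_fixture()` builds a reference family and candidate pool
with *controlled identity structure*: an ancestor protein, parent
references diverged from it, and candidates mutated away from their
parents until the package's own aligner measures their identity strictly
inside a chosen bin (naive substitution counts are insufficient because
gapped alignments inflate the column denominator once mismatch runs
appear). A conserved catalytic motif — the anchor lysine plus five
residues on each side — is held fixed across the family, the way real
active-site motifs are conserved; this is what keeps the anchor column
alignable even in 40–50% identity candidates. Dedicated sub-populations
fail each stage on purpose: wrong start codon, wrong length, low pLDDT,
substituted catalytic lysine, near-duplicate cluster members, and
unrelated sequences below 40% identity.

The default fixture is desk-scale: ~455 candidates of length 100 against
175 references, sized so the whole pipeline runs in seconds while every
non-excluded bin still holds more cluster representatives than its
default quota. What passing tests on this fixture shows is that the
*decision logic* — boundaries, ordering, tie-breaks, quotas — is correct;
it does not show that real generated libraries have any particular bin
occupancy, nor does the uniform random substitution model reproduce the
position-specific conservation structure of real families (beyond the
single conserved motif). Length-100 fixtures use proportionally scaled
length bounds ([90, 110]) via `triage_config(length_bounds = ...)`; the
production default remains [306, 421].

`simulate_plate()` likewise generates screening plates *from the
detection rule itself* (areas clearly above or below each substrate's
threshold), so recovering the truth is exact by construction — a test of
the rule's implementation, not of any instrument model.

## Conservation analysis

`build_small_msa()` is a deterministic center-star progressive aligner
for fixture-scale inputs; externally computed alignments are accepted via
`read_msa()` and are the expected route for real data. Gap-heavy columns
are trimmed by `trim_high_gap_columns()`; the threshold is a parameter
(default 0.5) rather than solved for a target column count, because the
appropriate value depends on the alignment at hand. Entropy is Shannon
entropy in bits (`log2`), computed per column over the 20 amino acids
with gaps excluded from the distribution rather than treated as a 21st
symbol — the conventional choice for sequence logos, where information
content is `log2(20) − H`. All-gap columns have undefined entropy and are
reported as `NA` rather than 0.

## Screening statistics

The detection threshold is `mean + 3·sd` of the negative-control peak
areas, with the sample (n−1) standard deviation and a *strict* inequality
at the threshold — both conservative choices for calling detection. The
phrase "three times the standard deviation of the control average" admits
a literal reading without the mean; `literal_3sd = TRUE` provides it.
Control statistics are pooled per substrate, not per plate, since
background chemistry is substrate-specific. UV-quantified yields take
precedence over the MS channel: a measurable UV yield is `quantified`
regardless of peak area. Promiscuity is the percentage of a substrate
panel with a `quantified` or `detectable` call.

## Numerical choices and degenerate inputs

* Floating-point comparisons in the aligner tracebacks use a 1e-9
  tolerance; all scheme values are small decimals, so distinct alignment
  scores differ by at least 0.1.
* The clustering threshold comparison allows 1e-12 slack so an identity
  of exactly 0.70 joins a cluster.
* Empty alignment inputs, missing pLDDT scores, missing MaxID values,
  unknown codons, out-of-table residues and misconfigured anchors are
  errors naming the offending record; empty FASTA files and stages that
  eliminate every candidate are warnings.
* Coordinates are 1-based and inclusive in all user-facing output.
* The pipeline itself consumes no randomness; only fixture generation
  and the stand-in sampler take seeds.

## Problem sizes used by the test and acceptance runs

The test suite verifies the aligners against exhaustive enumeration on
500 random pairs of length ≤ 7 and against `Biostrings` on pairs of
length 10–35; generator recovery refits an order-1 model from 10,000
sampled sequences and checks transitions within three standard errors;
pipeline-level tests run the ~455-candidate fixture described above. The
acceptance script regenerates that fixture from the supplied seed, runs
the full pipeline, and reports the selected-set size (105 under the
default plan).

## Known limitations

* `build_small_msa()` is quadratic and intended for ≲200 short
  sequences; it is a testing convenience, not an MSA tool.
* MaxID uses the exact global aligner against every reference — robust
  and deterministic, but not engineered for >10^4-member reference sets
  at full protein length in interactive time.
* The identity convention (all columns in the denominator) and the bin
  edge conventions are documented defaults, not universal standards;
  both are configurable or derivable from returned fields.
* Structure prediction, folding-energy scoring, external BLAST/MAFFT
  invocation and yield calibration are out of scope by design; their
  outputs enter as plain inputs.
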