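# enztriage

Triage of machine-generated enzyme coding sequences against a natural
reference set.

Generative sequence models can emit thousands of candidate
protein-coding DNA sequences for an enzyme family; only a small panel can
be synthesized and screened. `enztriage` implements the decision layer in
between, for protein engineers designing such panels: validity filters,
novelty quantification, ranking, diversity clustering, and a stratified
final selection, plus the surrounding analyses (conservation profiles of
the selected set, detection statistics for the eventual plate screens)
and a codon-level Markov generator so the whole path is testable without
model weights. The running example is the β-subunit of tryptophan
synthase (TrpB), but nothing is family-specific.

## The method

Candidates flow through a fixed stage order:

1. **start codon** — first codon must be ATG;
2. **length** — translated length L in [306, 421] aa (inclusive;
   configurable, or recomputable as mean ± m·σ from the reference set);
3. **structure confidence** — externally supplied pLDDT ≥ 0.80;
4. **novelty** — MaxID, the maximum percent identity to any reference
   under global alignment, must be ≤ 90%;
5. **binning** — MaxID partitioned into (40–50], (50–60], … (90–100]
   percent bins (40–50 closed below);
6. **ranking** — composite alignment score
   `3 · mean(global) + 8 · mean(local)` over the reference set, with
   +1 match, −1 mismatch, −0.5 gap open, −0.1 gap extend (affine gaps;
   a length-g gap run costs `open + (g−1)·extend`);
7. **active site** — the candidate residue aligned to the anchor's
   catalytic lysine (position 82) must be K;
8. **diversity** — greedy identity clustering at 70%, one representative
   (the highest-scoring member) per cluster;
9. **selection** — per-bin quotas 30/40/20/10/5 from bins 80–90 down to
   40–50: 105 sequences total.

The aligners are affine-gap Gotoh dynamic programs in C++, verified in
the tests against exhaustive enumeration of the alignment space and
against `Biostrings::pairwiseAlignment`.

## Worked example

Alignment-level primitives:

```r
library(enztriage)

global_align("MKVL", "MKVI")
#> <alignment_result> global score 2.00, 3/4 matches (75.0%)
#>  MKVL
#>  MKVI

max_identity("MKVL", c(ref = "MKVI"))$identity
#> [1] 75

composite_score("MKTA", c(ref = "MKTA"))   # identical ref, length 4: 11 * 4
#> [1] 44
```

One mismatch in four columns gives 75% identity (the denominator is all
alignment columns), and a candidate identical to its single length-L
reference scores exactly `3·L + 8·L = 11·L`.

End-to-end triage on a synthetic pool with controlled identity structure
(~455 candidates of length 100; fixture-scaled length bounds):

```r
fx  <- simulate_triage_fixture(seed = 42)
cfg <- triage_config(length_bounds = fx$length_bounds)
res <- run_pipeline(fx$candidates, fx$refs, fx$plddt,
                    anchor = fx$anchor, config = cfg)
res
#> <triage_result>
#>        stage n_in n_passed pass_rate
#>  start_codon  455      405 0.8901099
#>       length  405      355 0.8765432
#>        plddt  355      305 0.8591549
#>      novelty  305      290 0.9508197
#>  active_site  290      261 0.9000000
#>    selection  261      105 0.4022989
#> selected: 105 candidates

table(as.character(res$selected$bin))
#> 40-50 50-60 60-70 70-80 80-90
#>     5    10    20    40    30

head(res$selected[, c("id", "bin", "maxid", "score", "bin_rank")], 5)
#>        id   bin    maxid    score bin_rank
#> 1 cand118 80-90 83.65385 258.8069        1
#> 2 cand136 80-90 86.27451 238.8343        2
#> 3 cand125 80-90 81.73077 238.5600        3
#> 4 cand113 80-90 84.61538 237.0194        4
#> 5 cand148 80-90 86.53846 236.8823        5
```

Each stage removes exactly its designated failures (50 wrong-start, 50
wrong-length, 50 low-pLDDT candidates, the >90%-identity bin, the
substituted-lysine candidates), and the final panel holds the full
30/40/20/10/5 stratification — 105 sequences, one per identity cluster,
ranked by composite score within each bin.

A thin command-line front end wraps the same functions:

```sh
Rscript inst/cli/triage.R run \
  --candidates cands.fasta --references refs.fasta \
  --plddt plddt.tsv --anchor anchor.fasta --out out/
```

with `score`, `select` and `report` subcommands for the individual
stages; see `vignettes/enzyme-triage-methods.Rmd` for the full model,
parameter meanings and design rationale.

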