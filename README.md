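# orthofam

Gene-family detection and pivot-anchored orthology inference for protein
proteomes, with a simulator that provides evolutionary ground truth.

## The problem

Plant genomes carry large transcription-factor families — the NAC/NAM
architecture is the motivating case: a highly conserved ~150-residue
N-terminal DNA-binding domain followed by a divergent C-terminal
activation region, sometimes ending in a membrane-anchoring helix.
Comparative studies of such families ask three questions across dozens of
proteomes: *which proteins belong to the family*, *which genes are
orthologs of which*, and *which ortholog groups are ancient* (shared with
an early-diverging outgroup). orthofam implements that whole chain as a
tested, seed-reproducible R pipeline for researchers who want the method
itself — on their own proteomes or on simulated ones with known truth.

## What it computes

* **Family detection** — a profile HMM built from a seed domain alignment
  (columns containing any gap are excluded from the match states),
  scored by exact local Viterbi in bits, with an acceptance threshold
  calibrated between re-scored seed sequences and an empirical random
  null; redundancy is removed by greedy clustering at identity ≥ 0.7
  (identity counted over the shorter sequence).
* **Pairwise similarity** — affine-gap Smith–Waterman (BLOSUM62, gap
  open/extend 11/1) with Karlin–Altschul bit scores
  `S' = (λS − ln K)/ln 2` (λ = 0.267, K = 0.041).
* **Orthology** — reciprocal best hits (RBH) under the significance
  filter *bit score > 200 and coverage ≥ 50% of both sequences*;
  pivot-anchored orthologous groups (OGs) with attached within-species
  paralogs and a presence matrix; basal orthologous groups (BOGs) as the
  n-way intersection of outgroup-anchored OG collections, with full Venn
  region counts.
* **Annotation** — diagnostic motifs (e.g. the LP-box `LP[QX]L[ED]SP`,
  WQ-box `W[RA]ALD[KR][FL][VL]ASQL`, `GxxFxP`, `WxMHEY`) and
  Kyte–Doolittle hydropathy transmembrane segments (window 19,
  cutoff 1.6).
* **Grouping** — Kimura protein distances `d = −ln(1 − p − 0.2p²)`,
  neighbor joining with bootstrap support, and nearest-anchor group
  assignment.
* **Simulation** — gene families evolving on a species tree under a
  birth–death process with whole-genome duplications (Gillespie walk per
  edge), emitting proteomes with a conserved domain, fast-evolving tail,
  optional transmembrane insertions, decoy proteins, and complete
  ortholog/paralog truth tables.

See `vignettes/orthofam-methods.Rmd` for the models, parameter rationale,
and design decisions.

## Worked example

```r
library(orthofam)

## similarity + the orthology filter
aln <- local_align("NAMWQSDPLK", "NAMWTSDPLK")
aln
#> local alignment NA vs NA: raw 51, 24.3 bits, id 0.900, cov 1.00/1.00
hit_filter(aln)      # 24.3 bits < 200: not an ortholog-grade hit
#> [1] FALSE

## simulate five proteomes with truth, then detect the family
sim  <- simulate_proteomes(benchmark_tree_5sp(), benchmark_params(),
                           n_families = 6, seed = 42)
seed_aln <- truth_seed_alignment(sim, max_rows = 20)
hmm  <- build_profile(seed_aln)
hmm  <- set_threshold(hmm, calibrate_threshold(hmm, seed_aln,
                                               null_samples = 500,
                                               seed_rng = 42))
hmm
#> profile HMM: 150 match states, consensus HFESPTAKPQ...
#>   calibrated threshold: 205.30 bits
hits <- scan_proteomes(hmm, sim$proteomes)
attr(hits, "counts")
#> A B C D E
#> 7 6 6 6 5

## reciprocal best hits between two species
ab  <- all_vs_all(sim$proteomes$A, sim$proteomes$B)
rbh <- reciprocal_best_hits(ab, "A", "B")
head(rbh, 3)
#>   gene_a gene_b  bits_ab  bits_ba
#> 1  A_F01  B_F01 442.1950 442.1950
#> 2  A_F02  B_F02 450.2841 450.2841
#> 3  A_F03  B_F03 486.1077 486.1077
```

The per-species counts are the detected family members (7 in species A
includes a retained duplicate; the simulator's truth table says which),
and each RBH row is an inferred ortholog pair with its bidirectional bit
scores.

The full orchestrated run — simulate, detect, align, orthologs, BOGs,
annotate, group, report — is one call:

```r
report <- run_pipeline(default_run_config(seed = 1, outdir = "run1"))
```

which writes per-stage artifacts plus `report.json`/`report.txt` under
`run1/`, or from a shell:

```sh
Rscript inst/cli/orthofam.R run --seed 1 --outdir run1
```

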