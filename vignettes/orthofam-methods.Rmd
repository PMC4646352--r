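---
title: "orthofam: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{orthofam: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

orthofam is a comparative-genomics toolkit for a classic question: given
many proteomes, which proteins belong to a transcription-factor family
defined by a conserved N-terminal DNA-binding domain (the NAC/NAM
architecture: a slowly evolving ~150-residue domain followed by a divergent
C-terminal activation region that sometimes carries a membrane-anchoring
helix), and how are those proteins related across species? The package
implements the full chain — family detection by profile HMM, pairwise
similarity by Smith–Waterman, orthology by reciprocal best hits (RBH)
against pivot genomes, basal orthologous groups (BOGs) by n-way
intersection with an outgroup, motif/transmembrane annotation, and
distance-based grouping — together with a birth–death/WGD simulator that
provides proteomes with known evolutionary truth, so that every stage can
be validated quantitatively without downloading genomes.

This vignette records the models, the tunable parameters, and the design
decisions that were genuinely open.

## The synthetic evolutionary model

`evolve_family()` runs a Gillespie walk along each species-tree edge: every
live gene lineage draws exponential waiting times for duplication (rate
$\lambda$, per gene per time unit) and loss (rate $\mu$); at a speciation
every lineage enters both daughter edges; at a whole-genome duplication
(WGD, placed at a fixed fractional position on an edge) every live gene
duplicates and each *new* copy survives with the event's retention
probability. The walk is exact for the stated Poisson process — no time
discretisation is involved — and the expected copy number per extant
species is the linear birth–death value $e^{(\lambda-\mu)T}$ for
root-to-tip time $T$, which the test suite checks by Monte Carlo.

Gene identifiers encode the species and the lineage path (`-1`/`-2` for
duplication daughters, `-w1`/`-w2` for WGD copies), so every truth table is
self-describing. Ground-truth orthology is read off the labelled gene tree:
a pair of surviving genes is orthologous iff its most recent common
ancestor is a speciation node, paralogous iff it is a duplication or WGD
node. These two sets partition all surviving cross-gene pairs.

`emit_sequences()` draws the ancestral protein from a stationary
amino-acid distribution and evolves it along the gene tree with
Poisson($r \cdot m_c \cdot t$) substitutions per site ($r$ =
`base_subs_rate`, $m_c$ = 0.3 for domain columns, 1.5 for tail columns by
default), replacements drawn from the stationary distribution excluding
the current residue. Two deliberate departures from the most naive choice:

* **Soluble stationary composition.** Family proteins are emitted from a
  polar-biased composition (`aa_soluble_background()`: BLOSUM62 background
  with the strongly hydrophobic residues I, L, V, F, M, A, C, W
  down-weighted by 0.45 and renormalised). Sequences drawn from the raw
  BLOSUM62 background contain a spurious 19-residue window of mean
  Kyte–Doolittle hydropathy > 1.6 in roughly 40% of 250-residue proteins —
  they look like membrane proteins, which a soluble transcription-factor
  family is not. With the soluble composition the spurious rate is ~1%,
  so the transmembrane truth flag is meaningful. Decoys, the profile-HMM
  null model and the alignment statistics keep the standard BLOSUM62
  background.
* **A shared radiation.** `simulate_proteomes()` evolves each family's
  root sequence from one common ancestor along a pre-root branch of
  `radiation_time` (default 5) time units. The families of a run are
  therefore ancient paralog lineages sharing the conserved domain — the
  family-level homology that makes one profile HMM detect all of them —
  while being far enough apart that cross-family alignments fall below
  the 200-bit orthology filter.

Transmembrane segments are inserted per gene with probability
`tm_insertion_prob` (default 0.2): one contiguous run of `tm_length` = 21
residues sampled from {I, L, V, F, A, M} at a random tail position. By
construction its windowed hydropathy always exceeds the 1.6 cutoff, so the
predictor oracle can verify insertion truth.

What the generator does *not* emulate: insertions/deletions (other than
the TM segment), codon structure, selection, empirical substitution
matrices, rate variation beyond the two column classes, and alternative
isoforms. Passing tests therefore demonstrate correctness of the
*inference machinery* under a clean substitution process, not performance
on real annotation artefacts.

## Family detection

`build_profile()` turns a seed alignment into a profile HMM. Alignment
columns containing **any** gap are excluded from the match states — the
strict reading of the rule that gapped or missing positions are not used
to build and calibrate the model. The wording also supports a
majority-gap reading, so a fractional-occupancy option
(`max_gap_frac`) is exposed but off by default; strictness was chosen for
determinism. Match emissions are
$(\mathrm{count} + w\,\mathrm{bg})/(n + w)$ with pseudocount weight $w$
(default 1), reported as log2-odds against the background; insert states
emit at background (0 bits); transitions are estimated from
retained-column adjacency with Laplace (+1) smoothing.

`viterbi_score()` computes the best *local* state path (entry and exit at
any match state, unscored background flanks), in bits. Unknown residues
(X, B, Z, U) emit at background — log-odds 0 — so they can never create a
hit. The implementation is exact dynamic programming in C++; the test
suite proves it equal to exhaustive enumeration over all legal state
paths for every model with up to 4 match states on sequences up to length
6.

Because the source study never prints its HMMER cutoffs,
`calibrate_threshold()` defines a reproducible two-sided procedure: score
the (ungapped) seed rows, score `null_samples` background-random
sequences of matched lengths, and set the threshold to the midpoint
between the minimum seed score and the 99.9th percentile of the null. If
the two distributions overlap, the calibration failure is surfaced with a
warning (threshold falls back to the null percentile) rather than hidden.

`cluster_redundant()` reduces redundancy in the CD-HIT manner: sequences
sorted longest-first, each joining the first representative it matches at
identity ≥ 0.7, where identity = identical aligned residues divided by
the *shorter* sequence's length (the cited tool's convention).

## Pairwise similarity and the orthology filter

`local_align()` is an affine-gap Smith–Waterman (Gotoh three-matrix
recurrence) over BLOSUM62 with gap open 11 / extend 1. Opening a gap costs
`gap_open + gap_extend` for its first position — the BLAST accounting
dialect. One optimal alignment is reported with deterministic traceback
preference: diagonal, then gap-in-subject, then gap-in-query.

Raw scores are converted to bits with the Karlin–Altschul normalisation
$S' = (\lambda S - \ln K)/\ln 2$ using $\lambda = 0.267$, $K = 0.041$,
the standard constants for gapped BLOSUM62/11/1; the study relied on
BLASTP defaults it never printed, so these are fixed as defaults and
overridable in the `scoring_scheme()`.

`hit_filter()` implements the orthology significance filter: bit score
strictly greater than 200 and alignment coverage of at least 50% of
**both** sequences' lengths. The plural wording ("their lengths")
supports the both-sequences reading chosen as default; a query-only mode
exists but is off. E-values are intentionally absent — the procedure
filters on bits and coverage only.

## Orthologous groups, paralogs, and BOGs

`all_vs_all()` aligns every cross pair, keeps filter-passing records in
both directions, and reports the proteins with no surviving hit (the
"ruled out" set). `reciprocal_best_hits()` takes the best hit per query —
maximal bit score, ties broken by higher identity then lexicographically
smallest subject id (the study states no tie rule; this one is fixed for
determinism) — and keeps mutual pairs only, yielding a partial matching.

`build_ogs()` anchors one orthologous group per pivot gene with at least
one RBH partner, assembles per-species membership, the presence matrix
(the pivot column counts the anchor itself), per-lineage core OGs, and
the pivot-specific gene list. `attach_paralogs()` adds, per species,
every non-member gene whose best filter-passing within-species hit lands
on an OG member; a gene attaches to at most one OG. The exact paralog
rule is not stated in the source tables ("duplications shown below the
blocks"); best-hit attachment is this package's reconstruction.

`intersect_bogs()` intersects two or more outgroup-anchored OG
collections: the basal orthologous groups are the outgroup genes present
in *every* collection, and all $2^n - 1$ Venn region counts are computed
(they provably sum to the union size, which the report checks at run
time).

## Annotation

Motif patterns use the bracket syntax of discovered-motif reports:
literals, `[...]` residue classes, and `x`/`X` wildcards. An `X` *inside*
a bracket (as in the LP-box `LP[QX]L[ED]SP`) is read as "any residue",
making the bracket vacuous but faithful to the printed pattern; a literal-X
reading was rejected because X is not an amino acid. Scanning defaults to
the leftmost single occurrence per sequence, mirroring the
one-per-sequence occurrence convention; an exhaustive mode exists.

Transmembrane prediction is the classic Kyte–Doolittle sliding-window
heuristic (window 19, cutoff 1.6, overlapping windows merged). This is a
declared stand-in for an external transmembrane HMM server, so absolute
TMM counts are not comparable with published server-based counts; within
the package it is validated against the simulator's insertion truth.

## Grouping

The published family tree is a maximum-likelihood tree (JTT + gamma, 100
bootstraps) over ~2,000 sequences with externally curated genomes — not
reproducible at desk scale. The package keeps the *pipeline role* of that
stage (placing members into major groups) with an exactly testable
distance method: Kimura protein distances
$d = -\ln(1 - p - 0.2p^2)$ (pairwise gap exclusion; $p$ beyond the
formula's domain capped at $d_{\max} = 10$ with a warning, keeping
saturated pairs finite instead of dropping them), Saitou–Nei neighbor
joining with deterministic tie-breaking (smallest sorted label pair;
negative branch lengths floored at zero with the deficit shifted to the
sibling edge), and nonparametric column-resampling bootstrap (the
parametric variant would need the generating model, which the distance
stand-in does not retain). NJ provably recovers every additive matrix's
topology, which the suite sweeps over random trees of up to 8 taxa.

`assign_groups()` places each member with its nearest labelled anchor by
the Kimura distance of their local alignment, ignoring anchors whose
alignment fails the bit/coverage filter; members with no usable anchor
are `"unplaced"`. Anchor sets are user-supplied, as in reference-guided
phylogenomics; the simulated pipeline emits one labelled pivot-species
exemplar per family as its anchor file, playing the role the curated
model-species references play on real data.

## The pipeline and its standard scenario

`run_pipeline()` executes simulate → detect (+ clustering) → align →
orthologs → bogs → annotate → group → report, persisting every stage's
artifacts (FASTA, TSV with 0-based half-open coordinates internally and
1-based inclusive coordinates in the BLAST-style tables, JSON reports)
and logging timings to stderr. Each stage draws from its own seed derived
from the master seed and the stage name, so a stage can be rerun in
isolation and reproduce its artifacts byte-for-byte.

The standard simulated scenario uses six species — an outgroup `F` and
two lineages (`A`,`B`,`C` with pivot `A`; `D`,`E` with pivot `D`) — on a
tree normalised to unit root-to-tip depth, six families, duplication 0.1
and loss 0.05 per gene per time unit, and base substitution rate 0.25 per
site per time unit, placing the deepest species pair at 0.5 substitutions
per site overall (0.15 in the conserved domain). Unit depth makes the
per-time rates directly interpretable as expected events per root-to-tip
lineage; the divergence ceiling keeps ortholog alignments comfortably
above the 200-bit filter while ancient (radiation-separated) paralog
families fall below it. The benchmark scenarios use five species at the
same rates, 20–30 families for the ortholog-recovery benchmark, 12
families with 3× decoys for the detection benchmark, 2,000 replicates for
the birth–death check, and 100 random trees for the NJ sweep — sizes
chosen so the whole validation runs in well under a minute each on one
core.

On these conditions the package's measured operating points (recomputed
by `scripts/acceptance.R` and the test suite at run time) are: RBH
precision ≈ 1.0 and recall ≈ 0.8–0.9 (the shortfall from 1.0 is
structural: a 1:1 matching cannot recover many-to-many ortholog pairs
created by post-speciation duplications), detection precision and recall
≈ 1.0 at the calibrated threshold with a decoy false-positive rate ≈ 0,
exactly five BOGs in the constructed basal scenario, and exact NJ
topology recovery.

## Known limitations

* The orthology model is plain pivot-anchored RBH: no graph clustering,
  synteny, or tree reconciliation; in-paralog-rich families will be
  under-counted (visible as the recall ceiling above).
* The TM predictor is a hydropathy heuristic; its counts are not
  comparable with dedicated topology predictors.
* Group assignment is nearest-anchor, not tree-based; groups are only as
  good as the anchor set.
* The simulator has no indel process, so seed alignments from simulated
  truth are gapless; the gap-column exclusion rule is exercised by
  constructed alignments in the tests instead.
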