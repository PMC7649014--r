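---
title: "Methods: curation, clustering and motif discovery for the Notch receptor family"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: curation, clustering and motif discovery for the Notch receptor family}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Scope

`notchfam` re-implements, as a tested and reusable workflow, a classical
distance-based evolutionary analysis of the Notch receptor family: curate a
noisy protein FASTA set down to bona-fide family members, align them
progressively, cluster them into sub-families on a UPGMA tree built from
protein Jukes–Cantor distances, summarize each sub-family by a consensus
sequence, build a bootstrapped consensus-level phylogeny, and locate the
family's conserved motifs — including EGF-like repeats called purely from
their six-cysteine spacing and the per-receptor "digital" calcium-binding
signature. Because the historical input (a large NCBI keyword query and an
unpublished accession list) is not reproducible, the package ships a
synthetic-data generator with planted ground truth; every stage of the
pipeline is verified against that truth at desk scale.

# The model and its stages

## Curation

Curation is a fixed three-stage filter; each removed record carries exactly
one rejection reason (its first failing stage), so the report counts always
reconcile with the input.

1. **Keyword filter.** Case-insensitive regular expressions over the
   defline description. The defaults are the noise classes that plague
   NCBI "Notch" query hits: `strawberry notch` (an unrelated protein
   family), `hypothetical`, `partial`, `low quality`, `PREDICTED`,
   `synthetic construct`.
2. **Reference screen.** Affine-gap Smith–Waterman (Gonnet-250 matrix)
   of each record against a small set of family exemplars. The score is
   normalized by the self-score of the aligned *reference segment*, so a
   verbatim copy of a reference scores exactly 1. The default threshold
   0.3 cleanly separates true homologs (a reference with 10%
   substitutions scores ≈ 0.88) from shuffled sequences (100 seeded
   shuffles all score < 0.18). The threshold is configurable; no
   published value exists for this step.
3. **Deduplication.** Greedy sweep in descending length order (ties by
   accession): a record is removed when its global-alignment identity to
   an already-kept record reaches 0.95, so every near-duplicate group
   retains its longest member. Identity is matches over aligned columns —
   this denominator (rather than the shorter sequence's length)
   deliberately penalizes length-discordant partial records. By default
   only records of the same organism are compared (`within_species`),
   with a global mode available.

## Alignment

Pairwise alignment is textbook Gotoh dynamic programming (affine gaps, a
gap of length L costs `gap_open + gap_extend * L`, defaults 10/0.5 on the
Gonnet-250 scale; the matrix is bundled as plain text). Traceback ties are
resolved diagonal > up > left, making every alignment deterministic. The
multiple alignment is progressive: pairwise p-distances ("differences per
comparable column") feed a neighbour-joining guide tree (negative branches
clamped to zero, midpoint-rooted), and profiles are merged post-order with
profile–profile dynamic programming, columns scored by the
frequency-weighted average substitution score. Gaps once inserted are never
removed, and no iterative refinement is attempted — matching the simple
progressive recipe the workflow models. The per-column conservation
profile (modal residue and frequency, top-2 cumulative frequency, gap
fraction) and a majority consensus (columns gappier than 0.5 omitted, ties
alphabetical) summarize the result.

## Distances, clustering, bootstrap

Cluster analysis uses the 20-state ("protein-adapted") Jukes–Cantor
correction

$$d = -\tfrac{19}{20}\,\ln\!\left(1 - \tfrac{20\,p}{19}\right),$$

applied to p-distances computed with pairwise deletion (only columns where
neither row is gapped). Pairwise deletion is essential here: family members
span a ~25-fold length range, and complete deletion would leave no usable
columns. The correction is undefined at p ≥ 19/20; by default a saturated
pair is an error, with an explicit `clamp` option that substitutes the
largest finite corrected distance (and warns). UPGMA merges the closest
pair, averages distances size-weighted, places each node at half the merge
distance, and breaks ties toward the smallest pair indices — the output is
exactly ultrametric, and a brute-force re-implementation that rescans the
full matrix each step is kept in the test suite as an oracle.

Sub-families are the maximal subtrees below a height threshold. The
published analysis used a manual threshold whose value was never stated;
the package's documented substitute, `auto_threshold()`, cuts at the
midpoint of the largest gap between consecutive sorted merge heights. This
works whenever within-group merges are well separated from between-group
merges (the planted benchmark guarantees a wide gap). A known limitation:
near JC saturation the correction inflates the deepest merges nonlinearly,
and the largest height gap can migrate *above* the biologically meaningful
gap — at desk scale this can appear for tiny sequences whose alignments
are dominated by non-homologous linker columns. The production-scale
roster stays far from this regime; for very small simulations the `clamp`
option plus inspection of the merge-height ladder is advised.

Bootstrap supports resample alignment columns with replacement, rebuild
the tree per replicate, and report for each reference clade the percentage
of replicates containing the same leaf set (rooted-clade comparison, which
matches UPGMA's rooted output). Replicate r draws its RNG seed as
`seed + r`, so runs are reproducible and individual replicates
re-derivable; a replicate whose distance matrix is undefined is redrawn
(at most 10 times). Note that UPGMA's deterministic tie-break is
index-dependent, so clades whose internal distances contain exact ties can
legitimately differ under row permutation; supports for tie-free clades
are order-invariant.

The consensus-level ("specialized") phylogeny builds one consensus per
cluster from the cluster's rows of the master alignment, appends any
outgroup homolog records (the planted GLP-1-like and LIN-12-like
sequences join here, not in the main clustering — mirroring a workflow in
which *C. elegans* homologs were added at the consensus stage), re-aligns,
and bootstraps a protein-JC UPGMA tree.

## Motif grammar and the EGF layer

Patterns use a PROSITE-like grammar: fixed residues, `X` wildcards,
residue classes like `[FY]`, and bounded gaps `x(m,n)`. An input `X`
ambiguity character satisfies wildcards but never a fixed position or a
class. The built-in conserved motifs are **A** `CXNGGXC` and **B**
`CXCXXG[FY]XG`; motifs C/D/E ship as *experimental, configurable
placeholders* because their exact residues are not legible from published
material. Scanning is left-to-right; bounded gaps expand minimally
(lazily). Minimal expansion is not cosmetic: greedy expansion provably
mis-frames tandem repeats, chaining cysteines across adjacent EGF units
and destroying the repeat count, whereas leftmost-minimal scanning parses
a tandem array unit by unit.

EGF-like repeats are called from cysteine spacing alone:
`C-x(2,14)-C-x(1,10)-C-x(1,6)-C-x(2,14)-C-x(1,8)-C`, non-overlapping, with
the canonical disulfide pairing (1–3, 2–4, 5–6) annotated. A repeat is
classified calcium-binding when the five residues before its first
cysteine contain the surrogate consensus `[DN]-x-[DN]-[EQ]` — a documented
simplification of the Asp/Asn-hydroxylation consensus. The digital
signature is then simply the N→C bitstring of these calls: `1` for a
calcium-binding repeat, `0` otherwise.

Motif discovery inverts the scanner: each alignment column becomes a fixed
residue (modal frequency ≥ 0.95), a two-residue class (top-2 cumulative
≥ 0.95), or a wildcard (also for columns gappier than 50%); reported
patterns are maximal windows of ≥ 7 columns that start and end on
non-wildcard columns and contain no wildcard run longer than 2. The
planted benchmark is built so that recovering motifs A and B *verbatim* is
a sharp test: the three columns flanking each motif inside the canonical
EGF unit are forced-variable, which terminates discovery windows exactly
at the motif boundaries.

# The synthetic generator: what it emulates, and what it does not

`canonical_roster()` fixes the study conditions: eight clades — bacteria
(110 aa, one EGF-like unit plus the Motif-D block), plants (400 aa),
protist (600 aa), invertebrate (2,700 aa), and the chordate paralogs
Notch1–4 at 2,627/2,471/2,321/2,059 aa with 36/36/34/29 EGF units, 3 LNR
and 7 ANK each. Each clade ancestor instantiates fixed synthetic domain
templates connected by uniform cysteine-free linkers; clade divergence
redraws the EGF variable columns, flips each unit's F/Y column, and
mutates template and linker positions at the clade's planted rate
(0.10–0.28, chordate paralogs arranged so Notch2 and Notch3 are each
other's closest clade). Members then evolve by i.i.d. substitutions at
unprotected positions and geometric-length indels confined to linkers, so
planted domain coordinates remain exact in the truth table.

Three deliberate simplifications, and their consequences:

* **Uniform substitutions** (no empirical rate matrix) keep every
  expectation analytic — the expected member-member p-distance is
  `2·rate·(1 − protected fraction)`, which the tests check directly.
  Consequence: substitution scores are less informative than on real
  proteins, making the alignment problem, if anything, harder.
* **No cysteines outside planted positions.** Linker backgrounds,
  variable-column redraws and substitutions all exclude C, treating the
  disulfide skeleton as a structural invariant. This keeps the
  cysteine-spacing caller's truth exact; real sequences contain free
  cysteines, so on real data the caller's precision depends on the
  spacing bounds, which are configuration constants.
* **Non-homologous linkers between clades.** Aligned linker columns
  between clades are effectively random (p ≈ 0.94), so between-clade
  distances combine conserved-domain divergence with junk-column noise —
  the regime that motivates pairwise deletion and the `clamp` option.

Passing tests therefore demonstrate that the pipeline recovers planted
structure under controlled, analytically tractable conditions; they do not
certify performance on real NCBI data, where domain gain/loss,
compositional bias and alignment ambiguity are all harsher.

# Numerical and design choices

* Gap penalties default to open 10 / extend 0.5 on the Gonnet-250 scale;
  the alignment literature for this workflow names the matrix but no
  penalties, so these follow common usage for that matrix family and are
  exposed as configuration.
* Guide-tree distances are *raw* p-distances, while clustering distances
  are JC-corrected — two distinct distance recipes, kept separate on
  purpose.
* Consensus and conservation tie-breaks are alphabetical; UPGMA ties go to
  the smallest pair indices; DP traceback prefers diagonal, then up, then
  left. Every tie rule is deterministic and documented, so reruns are
  bit-identical.
* All coordinates in R structures are 1-based inclusive (the R/ape
  convention); reports print the same convention.
* Randomness: every public entry point takes an explicit seed;
  `make_benchmark` derives per-stage sub-seeds additively from its master
  seed, and bootstrap replicate r uses `seed + r`.
* Problem sizes used by the checks: the full canonical benchmark (8
  clades × 6 members plus noise, duplicates and outgroups, sequences up
  to ~2,700 aa) for cluster-count recovery, and a 0.15-scale roster
  (~80–400 aa, same planted structure) for the per-module suites —
  chosen so the whole battery runs comfortably on a laptop core.

# Known limitations

* Distance phylogenetics only: no ML/Bayesian inference, no rate
  heterogeneity, no substitution-model selection.
* `auto_threshold()` assumes one dominant gap in the merge-height ladder;
  multimodal ladders or near-saturated deep distances can defeat it (see
  above).
* Pairwise deletion interacts with extreme length variation: a short
  taxon is compared only over the columns it occupies, which are enriched
  for conserved architecture, so its distances are systematically deflated
  relative to comparisons between long taxa. At the consensus level this
  can compress the between-cluster ordering (e.g. pull a short kingdom
  consensus into the chordate paralog band); the planted sister
  relationships are therefore asserted under controlled, comparable-length
  conditions in the test suite.
* The cbEGF call is a 4-residue flank consensus — a screening surrogate,
  not a structural prediction.
* Motifs C/D/E are placeholders pending a citable residue-level source;
  they are flagged experimental in `notch_motifs()`.
* Real-data ingestion (FASTA with NCBI deflines) is supported but the
  package never fetches from Entrez; taxonomy is taken verbatim from the
  bracketed organism token.
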