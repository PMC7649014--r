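# notchfam

Distance-based evolutionary analysis of the Notch receptor protein family,
re-implemented as a tested R package plus a scripted analysis workflow.

Notch receptors (Notch1–4 in mammals, LIN-12/GLP-1 in *C. elegans*, and
Notch-like proteins down to bacteria) are single-pass transmembrane
receptors whose extracellular domain is a tandem array of EGF-like repeats
— each built on six cysteines forming three disulfide bonds — followed by
three LIN-12/Notch repeats (LNR); the intracellular domain carries seven
ankyrin repeats. Comparative studies of this family face a noisy starting
point: keyword queries against NCBI return tens of thousands of hits mixed
with unrelated proteins ("strawberry notch"), hypothetical/partial/predicted
records, and near-duplicates. `notchfam` packages the full workflow that
turns such a set into a family phylogeny and a motif catalogue:

1. **Curation** — keyword/regex header filters, an affine-gap
   Smith–Waterman screen against reference exemplars (Gonnet-250 matrix,
   score normalized by the aligned reference segment's self-score), and
   deduplication at 95% global-alignment identity keeping the longest
   representative.
2. **Alignment** — progressive MSA: Gonnet-scored pairwise p-distances, a
   neighbour-joining guide tree, post-order profile–profile dynamic
   programming (Rcpp kernels).
3. **Clustering** — protein-adapted Jukes–Cantor correction
   d = −(19/20)·ln(1 − 20p/19) of pairwise-deletion p-distances, UPGMA,
   and automatic threshold extraction of sub-family clusters.
4. **Consensus phylogeny** — per-cluster majority consensus sequences
   (plus outgroup homologs), UPGMA with bootstrap supports (column
   resampling, seeded).
5. **Motifs** — a PROSITE-style pattern grammar (built-ins: Motif A
   `CXNGGXC`, Motif B `CXCXXG[FY]XG`), an EGF-like repeat caller driven
   purely by six-cysteine spacing, calcium-binding (cbEGF) classification
   from the Asp/Asn flank consensus, the per-receptor digital 0/1 calcium
   signature, and conservation-window motif discovery that re-derives
   motifs from an alignment.

Because the original NCBI snapshot is not reproducible, the package
includes a synthetic-data generator (`make_benchmark()`) that plants eight
architecture-faithful clades — bacteria (~110 aa) through invertebrate
(~2,700 aa) and the chordate paralogs Notch1–4 (2,627/2,471/2,321/2,059 aa,
36 EGF repeats, 3 LNR, 7 ANK) — along with noise records, near-duplicates
and two outgroup homologs, all with an exact truth table. Every pipeline
stage is tested against that truth.

## Worked example

A desk-scale run of the whole pipeline (a 0.15-scale roster keeps the
planted architecture but shrinks sequences to ~80–400 aa):

```r
library(notchfam)

cfg <- pipeline_config(members_per_clade = 4, bootstrap = 25, clamp = TRUE)
ros <- scale_roster(canonical_roster(), 0.15)
res <- run_pipeline(cfg, roster = ros, out_dir = "results/demo")

res$curation
#> curation: 43 input -> 34 retained (5 keyword, 0 reference screen, 4 duplicates removed)
res$clustering
#> clustering: 8 clusters at height 0.1845
cat(res$report$text, sep = "\n")
#> 32 sequences in 8 clusters (threshold 0.1845)
#>   C1: 4 members (12.5%), lengths 87-89
#>   C2: 4 members (12.5%), lengths 76-76
#>   ...
vapply(res$discovered, `[[`, "", "source")[1:2]
#> [1] "CXNGGXC"      "CXCXXG[FY]XG"
```

The curation line says the three-stage filter removed exactly the planted
noise (keyword stage) and near-duplicates (dedup stage) while keeping every
clean record; the cut recovered the eight planted sub-families; and motif
discovery on the alignment re-derived the two conserved EGF-internal
motifs verbatim. At full scale (`pipeline_config()` defaults, ~5 minutes
on one core) the same run partitions the canonical benchmark into the
eight published sub-family clusters.

The architecture layer on its own:

```r
spec <- canonical_roster()[canonical_roster()$clade == "Notch1", ]
anc <- make_ancestor(spec, seed = 1)
necd <- substr(anc$record$residues, 1, anc$necd_end)
nrow(find_egf_repeats(necd))
#> [1] 36
digital_signature(anc$record$residues)
#> [1] "111011101110111011101110111011101110"
```

36 EGF-like repeats in the extracellular region, and a digital calcium
signature matching the planted cbEGF plan bit for bit.

## The analysis scripts

`analysis/01_simulate.R` … `analysis/06_motifs.R` run the same stages as
numbered drivers, writing tables, FASTA/Newick artifacts and narrative
summaries under `results/`. Each script states what it found (curation
recall, cluster–truth Rand index, bootstrap supports, motif recovery).

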