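# histrace

Group-defining residues and their gain/loss histories in histone families.

## The problem

Histone H3 carries a cysteine at position 110 (H3C110) in most eukaryotes.
Most fungi lack it; within the ascomycetes it was regained and then lost
again in the Saccharomycetaceae, the family that includes *Saccharomyces
cerevisiae*. Distributions like this raise two questions that `histrace`
answers computationally, for anyone doing comparative genomics of histone
(or other conserved multi-paralog) families:

1. **Which alignment columns define the split** between the lineages that
   lost a focal residue and those that kept it?
2. **Which of those residues changed on the same branches** of the species
   tree as the focal residue (co-divergence, suggesting a shared selective
   episode), and which changed at alternative points in time?

## What the package computes

* **Profile search** — a PSSM with log-odds emissions
  `e_c(a) = log2(((n_ca + τ b_a)/(n_c + τ)) / b_a)` and affine gap
  penalties, aligned locally (Smith–Waterman, C++ kernel) against proteome
  sequences; significance from a Gumbel fit to shuffled-decoy scores
  (expected-decoy cutoff 1e-5, floored at the empirical decoy maximum);
  hits longer than 300 residues excluded; matched domains extracted in
  profile coordinates.
* **Curation** — per-species collapse of identical sequences; gap-threshold
  column trimming (trimAl `-gt` semantics; defaults 0.3 and 0.8);
  reference-anchored core vs centromeric family assignment on a
  neighbor-joining or user tree, with an identity fallback.
* **Group-specificity (GroupSim)** — per column,
  `s = ((W_a + W_b)/2) · (1 − B)` with within-/between-group mean
  similarities under min–max-normalized BLOSUM62 (identical pairs = 1), so
  `s ∈ [0,1]`; z-scores standardized within one histone family
  (population SD); columns flagged at `z > 5`.
* **Focal-residue classification** — presence of the target amino acid
  within 5 aligned positions of the focal column; per-group sequence-logo
  matrices (counts, frequencies, information content in bits).
* **Parsimony and co-divergence** — Fitch parsimony for binary
  presence/absence characters with *complete enumeration* of
  most-parsimonious labelings; change-edge sets; co-divergence as the
  Jaccard overlap of always-changing edge sets (1 = co-diverged,
  0 = alternative timing); iTOL binary-dataset export.
* **Synthetic data** — species-tree simulation (Yule, balanced,
  caterpillar), histone-like families with planted group-defining,
  co-diverging and confounding columns, indels and paralogous subfamilies,
  with a machine-readable truth table.

## Worked example

```r
library(histrace)

# Gain/loss history of H3C110 on the eukaryote backbone
tree <- scenario_backbone_tree()
rec  <- fitch_parsimony(tree, scenario_backbone_states())
rec
#> parsimony_reconstruction [H3C110]: 3 change(s), 2 MP labeling(s)
```

Three events — a loss in the fungal ancestor after the Cryptomycota split,
a reversion on the ascomycete stem, a second loss on the Saccharomycetaceae
stem — and one of the two most-parsimonious labelings places them exactly
on those branches.

```r
# Score a simulated two-group histone family and test co-divergence
sc  <- scenario_two_groups(seed = 1)
ds  <- simulate_family(sc$tree, sc$config)
aln <- as_stacked_alignment(ds$sequences)
part <- group_partition(paste0(sc$partition$group_a, "_core"),
                        paste0(sc$partition$group_b, "_core"),
                        labels = sc$partition$labels)
gs <- score_alignment(aln, part, z_threshold = 5)
head(as.data.frame(gs)[order(-gs$z), c("column", "score", "z", "flagged")], 3)
#>     column     score        z flagged
#> 110    109 0.7333333 8.356234    TRUE
#> 120    119 0.6000000 6.807602    TRUE
#> 101    100 0.3157895 3.506570   FALSE

focal <- fitch_parsimony(sc$tree, residue_state_map(aln, 109L, "C", by = "species", label = "H3C110"))
comp  <- fitch_parsimony(sc$tree, residue_state_map(aln, 119L, "D", by = "species", label = "D120"))
conf  <- fitch_parsimony(sc$tree, residue_state_map(aln, 100L, "D", by = "species", label = "D101"))
rbind(codivergence(focal, comp), codivergence(focal, conf))
#>   candidate jaccard           category n_focal_edges n_candidate_edges
#> 1      D120       1        co-diverged             1                 1
#> 2      D101       0 alternative-timing             1                 1
```

The planted focal column (109, i.e. H3 position 110) tops the z ranking at
its analytic score `1 − 4/15 ≈ 0.733`; the same-stem companion is flagged
too but is classified by *timing*, not score: it changed on the same branch
(Jaccard 1, co-diverged), while the confound — also correlated with the
groups — changed on a different branch (Jaccard 0, alternative timing).

## The analysis workflow

Numbered drivers under `analysis/` run the study end to end on the
synthetic datasets and write their tables under `results/`:

```sh
Rscript analysis/01_simulate.R    # datasets + ground truth (results/data/)
Rscript analysis/02_search.R     # profile build, calibration, search (results/search/)
Rscript analysis/03_score.R      # curation, GroupSim, logos (results/score/)
Rscript analysis/04_parsimony.R  # gain/loss + co-divergence + iTOL (results/phylo/)
```

Each script states what it found on stdout; all computation lives in the
package functions, so the scripts are thin narratives.

## Scope

Tree *inference* beyond neighbor joining (maximum likelihood, model
selection, bootstraps) is out of scope — supply a published Newick tree
for real analyses. See the vignette
(`vignettes/histone-residue-codivergence.Rmd`) for the models, parameter
defaults, design decisions and known limitations.
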