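---
title: "Tracing group-defining residues and their gain/loss histories in histone families"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tracing group-defining residues and their gain/loss histories in histone families}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(histrace)
```

## The question

Core histone H3 carries a cysteine at position 110 (H3C110) in most
eukaryotes, but most fungi lack it, and within the ascomycetes the
budding-yeast family Saccharomycetaceae lost it again after an earlier
reversion. Two questions follow from such a distribution. First, which
alignment columns best *define* the split between the lineages that lost the
residue and those that kept it — is the focal residue alone, or did other
residues diverge with it? Second, among the residues that correlate with the
split, which ones changed on the *same branches* of the species tree (true
co-divergence, suggesting a shared selective episode) and which changed at
alternative points in time (correlation without shared timing)?

`histrace` implements the full desk pipeline for this kind of analysis:
finding histone homologs in proteomes with a position-specific scoring
model, extracting and stacking the matched domains, curating them,
scoring every column for group specificity, classifying the focal residue
per sequence, reconstructing each residue's gain/loss history by parsimony,
and comparing change-edge sets between residues. Because the real datasets
behind such studies are assembled ad hoc from many proteome sources, the
package also ships a synthetic-data generator that plants known signals, so
every stage is testable against ground truth.

## Profile search

The search model is a position-specific scoring matrix (PSSM) with affine
gap penalties, built from a seed alignment of histone sequences. Match
columns are seed columns with at most 50% gaps (configurable). The emission
for amino acid $a$ at column $c$ is the log-odds

$$ e_c(a) = \log_2 \frac{(n_{c,a} + \tau\, b_a) / (n_c + \tau)}{b_a}, $$

with $n_{c,a}$ the count of $a$ among the column's non-gap residues, $n_c$
the non-gap count, $b_a$ the background frequency (Robinson–Robinson
composition by default) and $\tau > 0$ the pseudocount mass (default 1).

Proteins are aligned to the profile by Smith–Waterman-style local alignment
(implemented in C++): flanking unaligned regions are free, a gap run of
length $L$ costs `gap_open` $+ (L-1)\,$`gap_extend` (defaults 4 and 1 bits —
conventional values; the scores are in bits because the emissions are), and
ties are broken toward the earliest target start, then the earliest profile
start. The best-scoring cell and its traceback give the extracted domain as
a per-column residue map, which is what all downstream stages consume: the
profile defines the coordinate system, so extracted domains stack into a
rectangular alignment without any de novo multiple alignment. That design
deliberately trades the ability to discover novel insert states (terminal
deletions and target-side insertions are modelled; novel alignment columns
are not) for fully reproducible column homology.

Significance is calibrated empirically, in the role that an E-value plays
in profile-HMM searches: `n_decoys` i.i.d. background sequences are scored,
a Gumbel distribution is fitted to the decoy scores by the method of
moments, and `evalue_like(s)` is the expected number of decoys scoring at
least $s$. The reporting threshold is the score where that expectation
falls below the cutoff (default $10^{-5}$), floored at the empirical decoy
maximum. Hits are also excluded when the protein exceeds 300 residues, a
guard against mispredicted fusion proteins; the boundary is inclusive at
exactly 300.

## Curation

Within each species, byte-identical sequences collapse to one
representative (the lexicographically smallest id); identical sequences
from *different* species are always kept, because cross-species identity is
signal, not redundancy. Columns are then trimmed by a gap threshold with
the same semantics as trimAl's `-gt`: a column is retained iff its fraction
of non-gap residues is at least the threshold. The pipeline default is 0.3
for the family-discrimination pass; 0.8 is the stricter setting appropriate
for within-clade ortholog sets.

Core versus centromeric histone assignment is reference-anchored: a tree
over the rows (user-supplied or built by neighbor joining from
Poisson-corrected distances) is searched for a bipartition with all core
references on one side and all centromeric references on the other. Several
edges can qualify — every edge on the paths between the reference sets
does — so the package picks the bipartition with the widest gap (the
largest minimum cross-side patristic distance), which is the family
boundary whenever the families coalesce deeper than anything within either
family. Supplying at least two references per family is recommended: a
single reference leaves the choice under-determined when a rogue long
branch exists. If no separating bipartition exists (e.g. the gene tree
breaks a family's monophyly), the function falls back, with a warning, to
mean sequence identity against each reference set; rows within the
configurable margin of equidistance stay `unassigned`.

## Group-specificity scoring

For a two-group partition of the alignment rows, each column receives a
GroupSim score under a normalized BLOSUM62 similarity $m'$:

$$ s_c = \frac{W_a + W_b}{2}\,(1 - B), $$

where $W_g$ is the mean $m'$ over unordered residue pairs within group $g$
(gap-involving pairs excluded) and $B$ the mean over cross-group pairs.
$m'$ maps raw BLOSUM62 scores to $[0,1]$ by global min–max scaling
($m'(C,A) = (0-(-4))/(11-(-4)) = 4/15$), **with identical-residue pairs set
to 1 exactly**. The diagonal convention matters: under raw min–max scaling
alone a fully conserved column would keep a nonzero score (e.g. an
all-alanine column would score $\tfrac{8}{15}(1-\tfrac{8}{15}) \approx
0.25$), whereas a conserved column carries no group-specific information
and must score 0. With the convention, a column that is pure cysteine in
one group and pure alanine in the other scores $1 - 4/15 \approx 0.733$.
Scores are therefore bounded in $[0,1]$, symmetric under group swap, and a
column is left unscored when either group has more than 50% gaps
(configurable) or fewer than two residues.

Scores are standardized to z-scores against the mean and *population*
standard deviation of all scored columns of the same alignment — one
histone family at a time, never pooled across families, so that a family
with generally higher divergence does not drown out another's signal.
Zero-variance score sets get $z = 0$ by convention so the flag logic stays
total; fewer than two scored columns leave z undefined with a warning. A
column is flagged when $z$ exceeds the threshold (default 5.0). A raw-score
flag threshold also exists but is off by default: this score lives in
$[0,1]$, so any fixed raw cutoff above 1 would be meaningless, and scales
on which published figures quote larger values are not reconstructable
from a scatter plot.

Per-sequence classification of the focal residue follows a windowed rule:
a sequence carries the focal residue iff the target amino acid occurs
within five aligned positions of the focal column (inclusive; window
configurable). Gap columns count as positions by default — the window is
defined on the alignment, which is what a curator inspects — with a config
switch to count residue positions instead. Sequence-logo matrices
(per-group residue counts, frequencies and information content
$IC = \log_2 20 - H$ in bits) are produced for the focal column ± 5 flank.

## Gain/loss histories and co-divergence

Each residue of interest becomes a binary presence/absence character over
the species-tree leaves. Fitch parsimony (equal gain and loss costs — no
direction of the narrative is presupposed) gives the minimum number of
state changes; the implementation additionally enumerates *every*
most-parsimonious ancestral labeling by dynamic-programming traceback
(capped at 10,000 with an explicit truncation flag) and reports two edge
sets: `change_edges_always` (branches that change state in every MP
labeling) and `change_edges_ever` (in at least one). Edges are identified
by the sorted leaf set below them, which is stable across serialization
and rerooting.

Co-divergence between a candidate residue and the focal residue is the
Jaccard overlap of their `change_edges_always` sets: overlap 1 with both
sets non-empty is `co-diverged` ("changed at the same time"); overlap 0
with both non-empty is `alternative-timing`; anything else — partial
overlap, or a candidate whose change edges are ambiguous across MP
labelings — is `correlated-only`. Using the *always* sets makes
co-divergence claims robust to MP ambiguity; a relaxed mode expands both
sets to a k-step edge neighborhood first, for users who want "within one
internode" matching. "Same time" here means "same branch": branches are
the resolution limit of any character-based timing argument.

Root-adjacent changes deserve a note: on a rooted tree whose root has two
children, a character that differs between the two root clades can change
on either root edge at equal cost, so its `always` set is empty and it can
never be called co-diverged. This is not an implementation quirk but a real
identifiability limit — resolved, as in practice, by including an outgroup,
which the shipped scenarios do.

On the shipped eight-leaf eukaryote backbone (outgroup and Cryptomycota
carrying the focal cysteine; three paraphyletic non-ascomycete fungal
lineages lacking it; Pezizomycotina and non-Saccharomycetaceae
Saccharomycotina carrying it; Saccharomycetaceae lacking it), the minimum
is three events, and one MP labeling places them exactly where the
comparative narrative does: a loss on the fungal stem after the
Cryptomycota split, a reversion on the ascomycete stem, and a second loss
on the Saccharomycetaceae stem. The paraphyly of the cysteine-lacking
fungi is essential: if they are collapsed to a single lineage, two
independent losses cost less than loss-plus-reversion-plus-loss, and the
three-event history is no longer most parsimonious. With three separate
lineages, three independent losses (cost 4 with the Saccharomycetaceae
loss) lose to the three-event history (cost 3).

Neighbor joining is provided as the desk-scale tree builder (distances are
Poisson-corrected mismatch fractions $d = -\ln(1-p)$ over mutually non-gap
columns, saturated pairs capped with a warning); a user-supplied Newick
tree is the faithful alternative for published phylogenies. Maximum
likelihood inference, model selection and bootstrap support are out of
scope: the package's contribution is the scoring and reconstruction layer,
not tree estimation.

## The synthetic-data generator

The generator evolves histone-like families along binary species trees.
Background columns follow an i.i.d. replacement process: the number of
substitutions on an edge is Poisson(rate × branch length) and each
replacement is drawn from the background composition excluding the current
residue. This is deliberately simpler than empirical substitution models
(no LG-style exchangeabilities, no rate heterogeneity): downstream scoring
consumes the alignment, not the generating process, so the extra realism
would add parameters without changing what the tests demonstrate. Planted
columns are deterministic: held at `state_before`, toggled between the two
states on each listed switch edge (so one column can encode
gain–loss–reversion chains), and optionally blurred by a per-leaf
`conservation` probability. Indels are modelled only as gap-run deletions
(no insertion states), keeping profile coordinates well defined, and gap
runs never erase a planted column so the ground truth stays exact.
Paralogous subfamilies are produced by duplicating the family at a named
edge: the duplicate diverges along a stem (default: the duplication edge's
length) and then radiates at a rate-multiplied pace, emulating an
anciently duplicated fast-evolving variant such as centromeric H3.

The canned two-group scenario mirrors the study design the pipeline is
for: an outgroup plus two 20-species clades (Saccharomycetaceae-like vs
other ascomycetes), a 135-column family, and three planted columns — the
focal column 109 (C→A on the Saccharomycetaceae stem), a conservative
companion (D→E, same stem) and a confound (D→H on a 10-species subclade
stem of the other group). Branch lengths are 0.005 with a background rate
of 0.1 per site per unit branch length, i.e. ≈ 0.04 expected substitutions
per column across the whole tree, about one residue difference between two
random species — core-histone-level conservation, consistent with the
near-total flanking conservation such families show. The two group stems
are short internodes (0.001): the planted toggles are deterministic
regardless of stem length, while background substitutions rarely land
there. That choice keeps the benchmark's ground truth unambiguous — a
background substitution on a group stem produces a *genuine*
group-defining column, indistinguishable in kind from the planted one
(it is the very process that creates real co-diverged residues), and with
long stems such columns appear often enough to contest the planted
column's top rank. The companion was likewise chosen conservative (D/E)
so that the focal column is the strongest planted signal, as it is in the
system being emulated.

What passing tests on this generator do **not** show: robustness to
alignment error (profile coordinates are exact by construction),
heterotachy or rate variation across sites, compositional bias, or the
behaviour of GroupSim when groups are defined by non-monophyletic
assemblages. Real analyses inherit all of those.

## Numerical choices and degenerate inputs

* Alignment tie-breaks: equal-scoring local alignments resolve to the
  earliest target start, then earliest profile start; equal-scoring NJ
  joins follow `ape::nj`; modal residues resolve alphabetically.
* The Gumbel fit uses method-of-moments (scale $= \hat\sigma\sqrt{6}/\pi$);
  the reporting threshold is floored at the empirical decoy maximum so a
  poor fit can never admit a decoy-level score.
* Unknown residue symbols are treated as gaps (with a warning) in scoring,
  and as neutral (0-bit) positions in local alignment.
* Zero-length or negative NJ branch lengths are clamped to 0 with a
  message; saturated distances are capped at a configured maximum.
* Empty proteomes return empty hit lists; an empty alignment or a focal
  column outside the alignment is an error, not a silent skip.
* All stochastic steps take explicit integer seeds, and the pipeline
  driver persists every intermediate as TSV/FASTA/Newick so a run is
  byte-reproducible from its config.

## Problem sizes

The shipped analyses and tests run at desk scale by design: 41-taxon
two-group families (135 columns, 100 replicate seeds), an 8-leaf backbone
tree, 200-decoy calibrations checked against 1,000 fresh decoys, 128
simulated homologs, and complete parsimony verification over every rooted
binary tree shape with up to 7 leaves crossed with every leaf labeling
(1,928 instances, which covers all labeled trees up to leaf renaming
because renaming only permutes the assignment set). These sizes exercise
every code path; scaling to hundreds of proteomes is a matter of input
volume, not algorithm.

## Known limitations

* The PSSM search has no insert-state emissions; extremely gappy histone
  variants may align with artifactually low scores.
* Fitch parsimony weighs gains and losses equally; a Sankoff variant with
  asymmetric costs is a natural extension and is not implemented.
* Co-divergence at branch resolution cannot distinguish events on the same
  branch that were separated in time.
* The identity fallback for family assignment can leave rows unassigned
  in low-signal alignments; that is intentional (it mirrors what a curator
  would flag for manual review) but means downstream per-family scoring
  can silently shrink.
* `evalue_like` is calibrated against i.i.d. decoys of one length; it is
  an expected decoy count under that null, not a database-wide E-value.
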