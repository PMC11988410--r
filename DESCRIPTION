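Package: histrace
Title: Group-Discriminating Residues and Gain/Loss Histories in Histone Families
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identifies histone homologs in proteomes with a position-specific
    scoring model, extracts and stacks matched domains in profile coordinates,
    collapses per-species redundancy, trims alignment columns by gap threshold,
    and classifies core versus centromeric histone paralogs. Scores every
    alignment column for how well it separates two taxon groups (GroupSim with
    a normalized BLOSUM62 similarity), standardizes scores to z-scores within a
    histone family, classifies a focal residue (such as histone H3 cysteine
    110) per sequence, reconstructs gain/loss events for binary residue
    characters by Fitch parsimony on a species tree, and tests whether
    candidate residues co-diverged with the focal residue by comparing
    change-edge sets. Includes a synthetic-data generator that evolves
    histone-like protein families along simulated species trees with planted
    group-defining, co-diverging and confounding columns, so the whole
    pipeline is testable against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    ape,
    Biostrings,
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    phangorn,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
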