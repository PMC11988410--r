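#!/usr/bin/env Rscript
# Curate the extracted domains (per-species dedup, gap-threshold trimming),
# score every column for how well it separates the two taxon groups
# (GroupSim + z-score), classify the focal residue per sequence, and write
# the per-column results and logo matrices under results/score/.

suppressMessages(library(histrace))

out <- "results/score"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

fx <- read_fixture("results/data/two_groups")
aln <- as_stacked_alignment(fx$sequences)
dd <- dedup_identical(fx$sequences)
cat("dedup:", length(fx$sequences$ids), "->", length(dd$sequences$ids),
    "sequences\n")
aln <- as_stacked_alignment(dd$sequences)
aln <- trim_by_gap_threshold(aln, 0.3)
cat("trim (gap threshold 0.3):", ncol(aln$matrix), "columns retained\n")

sacc <- sprintf("t%03d", 21:40)
part <- group_partition(aln$ids[!aln$species %in% c(sacc)],
                        aln$ids[aln$species %in% sacc],
                        labels = c("other_ascomycetes", "Saccharomycetaceae"))
# the outgroup row belongs to neither group and is excluded from scoring
part$group_a <- setdiff(part$group_a, aln$ids[aln$species == "outgroup"])

gs <- score_alignment(aln, part, z_threshold = 5)
utils::write.table(as.data.frame(gs), file.path(out, "groupsim.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)
top <- head(as.data.frame(gs)[order(-gs$z), c("column", "score", "z")], 5)
cat("top columns by z (column, score, z):\n")
print(top, row.names = FALSE)
cat("flagged (z > 5):", paste(gs$column[which(gs$flagged)], collapse = ", "),
    "\n")

focal_idx <- match(109L, aln$column_provenance) - 1L
cls <- vapply(seq_along(aln$ids), function(i) {
  classify_focal_residue(aln$matrix[i, ], focal_idx, window = 5, residue = "C")
}, character(1))
utils::write.table(data.frame(id = aln$ids, species = aln$species,
                              H3C110 = cls),
                   file.path(out, "focal_classification.tsv"), sep = "\t",
                   quote = FALSE, row.names = FALSE)
cat("focal residue present in", sum(cls == "present"), "of", length(cls),
    "sequences\n")

logos <- logo_counts(aln, part, focal_idx, flank = 5)
for (g in names(logos)) {
  lg <- logos[[g]]
  utils::write.table(
    data.frame(position = rep(lg$positions, each = 20),
               residue = rep(AA_ALPHABET20, length(lg$positions)),
               count = as.vector(lg$counts),
               ic_bits = rep(lg$ic, each = 20)),
    file.path(out, paste0("logo_", g, ".tsv")), sep = "\t", quote = FALSE,
    row.names = FALSE)
}
cat("wrote groupsim.tsv, focal_classification.tsv and logo matrices to",
    out, "\n")
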