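#!/usr/bin/env Rscript
# Generate the study's synthetic datasets and write them as plain-text
# fixtures under results/data/: the two-group ascomycete-like histone family
# (planted focal, companion and confound columns) and the eukaryote backbone
# used for the gain/loss reconstruction.

suppressMessages(library(histrace))

out <- "results/data"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

sc <- scenario_two_groups(seed = 1)
ds <- simulate_family(sc$tree, sc$config)
paths <- write_fixture(ds, sc$tree, file.path(out, "two_groups"))
cat("two-group family:", length(ds$sequences$ids), "sequences x",
    ncol(ds$sequences$aln), "columns\n")
cat("planted columns: focal", sc$focal_column, "(C->A on the",
    "Saccharomycetaceae stem), companion", sc$companion_column,
    "(D->E, same stem), confound", sc$confound_column,
    "(D->H on a subclade stem)\n")

ape::write.tree(scenario_backbone_tree(), file.path(out, "backbone.nwk"))
states <- scenario_backbone_states()
utils::write.table(
  data.frame(leaf = names(states$states), H3C110 = unname(states$states)),
  file.path(out, "backbone_states.tsv"), sep = "\t", quote = FALSE,
  row.names = FALSE)
cat("backbone tree and focal-residue states written to", out, "\n")
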