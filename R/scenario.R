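# Canned study scenarios: the eukaryote backbone for gain/loss parsimony and
# the two-group ascomycete configuration for specificity scoring.

#' The six-lineage eukaryote backbone tree
#'
#' A fixed species tree encoding the lineages relevant to the history of
#' histone H3 cysteine 110: an outgroup eukaryote and Cryptomycota (both
#' carrying the cysteine), three paraphyletic non-ascomycete fungal lineages
#' (chytrid-, mucoromycete- and basidiomycete-like, all lacking it),
#' Pezizomycotina and non-Saccharomycetaceae Saccharomycotina (carrying it),
#' and the Saccharomycetaceae (lacking it). Representing the C110-lacking
#' fungi as paraphyletic lineages is what makes the three-event history
#' (loss in the fungal ancestor after the Cryptomycota split, reversion on
#' the ascomycete stem, second loss on the Saccharomycetaceae stem) the
#' most parsimonious explanation.
#'
#' @return Rooted binary `ape::phylo` with 8 leaves and unit branch lengths.
#' @export
scenario_backbone_tree <- function() {
  ape::read.tree(text = paste0(
    "(outgroup:1,(Cryptomycota:1,(chytrid_like:1,(mucoromycete_like:1,",
    "(basidiomycete_like:1,(Pezizomycotina:1,(Saccharomycotina_other:1,",
    "Saccharomycetaceae:1):1):1):1):1):1):1);"))
}

#' Observed focal-residue states on the backbone tree
#'
#' @return A `character_state_map` of H3C110 presence per backbone leaf.
#' @export
scenario_backbone_states <- function() {
  character_state_map(c(
    outgroup = "present", Cryptomycota = "present",
    chytrid_like = "absent", mucoromycete_like = "absent",
    basidiomycete_like = "absent", Pezizomycotina = "present",
    Saccharomycotina_other = "present", Saccharomycetaceae = "absent"),
    label = "H3C110")
}

#' The two-group ascomycete scoring scenario
#'
#' An outgroup-rooted tree over 20 Saccharomycetaceae-like species and 20
#' other ascomycete-like species (balanced 20-leaf clades; the outgroup
#' makes the direction of root-adjacent changes identifiable, as it does in
#' the real analysis), carrying a 135-column histone-like family with three
#' planted columns. Branch lengths are 0.005 throughout, which at the
#' default background substitution rate of 0.1 per site per unit branch
#' length gives about 0.04 expected substitutions per column over the whole
#' tree — core-histone-level conservation, roughly one residue difference
#' between two random species, with the group-defining signal carried by
#' the planted columns:
#'
#' * the focal column 109 (H3 position 110), cysteine toggled to alanine on
#'   the Saccharomycetaceae stem — the group-defining residue;
#' * a companion column 119, aspartate toggled to glutamate on the same
#'   stem — a residue that co-diverged with the focal one (a conservative
#'   change, so the focal column keeps the top specificity score);
#' * a confound column 100, aspartate toggled to histidine on the stem of a
#'   10-species subclade of the other-ascomycete group — a CenH3D200H-like
#'   residue that changed at an alternative point in time.
#'
#' @param seed Integer seed for the stochastic background columns.
#' @return List: `tree`, `config` ([sim_config()]), `partition`
#'   ([group_partition()] by species), `focal_column`, `companion_column`,
#'   `confound_column` (0-based), `focal_edge`, `confound_edge` (edge ids).
#' @export
scenario_two_groups <- function(seed = 1L) {
  sub20 <- function(labels) {
    rec <- function(lab) {
      if (length(lab) == 1) return(paste0(lab, ":0.005"))
      h <- ceiling(length(lab) / 2)
      paste0("(", rec(lab[seq_len(h)]), ",", rec(lab[-seq_len(h)]), "):0.005")
    }
    rec(labels)
  }
  other <- sprintf("t%03d", 1:20)
  sacc <- sprintf("t%03d", 21:40)
  # The two group stems are short internodes (0.001): the planted toggles on
  # them are deterministic regardless of length, while background
  # substitutions rarely land there — keeping organically arising
  # group-defining columns (signal leakage, not noise) out of the planted
  # benchmark's way.
  stem <- function(core) sub("0\\.005;?$", "0.001", core)
  tree <- ape::read.tree(text = paste0(
    "(outgroup:0.005,(", stem(sub20(other)), ",", stem(sub20(sacc)),
    "):0.005);"))
  focal_edge <- clade_edge(tree, sacc)
  confound_edge <- clade_edge(tree, sprintf("t%03d", 1:10))
  plants <- list(
    plant_spec(109L, "C", "A", focal_edge),
    plant_spec(119L, "D", "E", focal_edge),
    plant_spec(100L, "D", "H", confound_edge))
  config <- sim_config(n_species = 40L, tree_model = "balanced",
                       seq_length = 135L, subst_rate = 0.1,
                       planted_columns = plants, seed = seed,
                       root_seq = scenario_reference_sequence())
  list(tree = tree, config = config,
       partition = group_partition(other, sacc,
                                   labels = c("other_ascomycetes",
                                              "Saccharomycetaceae")),
       focal_column = 109L, companion_column = 119L, confound_column = 100L,
       focal_edge = focal_edge, confound_edge = confound_edge)
}

#' Reference histone-like sequence for profile scenarios
#'
#' A fixed 135-residue sequence drawn once from the background composition
#' with a cysteine at column 109; serves as the common ancestor tying the
#' synthetic seed alignment and simulated homolog sets together. Synthetic:
#' it is not a real histone sequence.
#'
#' @param seq_length Sequence length (default 135).
#' @return Character vector of residues.
#' @export
scenario_reference_sequence <- function(seq_length = 135L) {
  with_seed(424242L, {
    s <- sample(AA_ALPHABET20, seq_length, replace = TRUE,
                prob = default_background())
    s[110] <- "C"
    s
  })
}

#' Synthetic seed alignment for profile building
#'
#' Evolves the reference sequence along a 12-species tree at low divergence;
#' the resulting gap-free alignment is the seed from which the default
#' profile model is built.
#'
#' @param seed Integer seed.
#' @return A `sequence_set`.
#' @export
scenario_seed_alignment <- function(seed = 99L) {
  tree <- simulate_tree(12, "yule", seed = 7L)
  tree$edge.length <- tree$edge.length / max(ape::node.depth.edgelength(tree))
  cfg <- sim_config(n_species = 12L, seq_length = 135L, subst_rate = 0.1,
                    seed = seed, root_seq = scenario_reference_sequence())
  simulate_family(tree, cfg)$sequences
}

#' Simulated homologs of the reference sequence
#'
#' Evolves the reference along a balanced 16-species tree with root-to-leaf
#' path scaled to the requested divergence, giving homologs whose expected
#' distance from the common ancestor is `divergence` substitutions per site.
#'
#' @param divergence Expected substitutions per site from root to leaf
#'   (default 0.3).
#' @param n_species Number of homologs (default 16).
#' @param seed Integer seed.
#' @return Named character vector of ungapped protein sequences.
#' @export
scenario_homologs <- function(divergence = 0.3, n_species = 16L, seed = 1L) {
  tree <- simulate_tree(n_species, "balanced")
  depth <- max(ape::node.depth.edgelength(tree))
  cfg <- sim_config(n_species = n_species, seq_length = 135L,
                    subst_rate = divergence / depth, seed = seed,
                    root_seq = scenario_reference_sequence())
  ungapped_sequences(simulate_family(tree, cfg)$sequences)
}
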