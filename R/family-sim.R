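# Evolving histone-like protein families along a tree with planted columns.

#' Specify a planted alignment column
#'
#' A planted column is held at `state_before` from the root and toggled
#' between `state_before` and `state_after` on each listed switch edge, then
#' held again. Toggling (rather than one-way flipping) lets a single column
#' encode gain/loss/reversion chains such as a cysteine lost in a fungal
#' ancestor, regained in the ascomycetes and lost again in the
#' Saccharomycetaceae.
#'
#' @param column 0-based alignment column index.
#' @param state_before,state_after Single amino-acid characters; must differ.
#' @param switch_edges Character vector of edge ids (see [edge_ids()]).
#' @param conservation Probability that a leaf retains its clade's planted
#'   state; with probability `1 - conservation` the leaf shows the other
#'   planted state instead. Default 1 (perfectly conserved).
#' @return `plant_spec` list.
#' @export
plant_spec <- function(column, state_before, state_after, switch_edges,
                       conservation = 1.0) {
  stopifnot(length(state_before) == 1, length(state_after) == 1)
  if (state_before == state_after) stop("state_before and state_after must differ")
  if (length(switch_edges) < 1) stop("switch_edges must be non-empty")
  if (conservation < 0 || conservation > 1) stop("conservation must be in [0, 1]")
  structure(list(column = as.integer(column), state_before = state_before,
                 state_after = state_after,
                 switch_edges = as.character(switch_edges),
                 conservation = conservation),
            class = "plant_spec")
}

#' Specify a paralogous subfamily duplication
#'
#' Duplicates the family at a named edge: every leaf below the duplication
#' edge carries a second, faster-evolving copy (a centromeric-like paralog)
#' seeded from the ancestral sequence at the duplication point.
#'
#' @param duplication_edge Edge id at which the family duplicates.
#' @param rate_multiplier Substitution-rate multiplier for the duplicate
#'   subfamily (default 2, i.e. at least twice the core rate).
#' @param stem_length Branch length along which the duplicate diverges from
#'   the ancestral sequence before its subtree radiates (the paralog stem;
#'   defaults to the duplication edge's own branch length). A positive stem
#'   keeps the duplicate subfamily separable from the core family in gene
#'   trees, as real centromeric histones are.
#' @param planted_columns Optional list of [plant_spec()]s that apply to the
#'   duplicate subfamily only (switch edges must lie within the subtree).
#' @param label Family label for the duplicate copies (default `"cen"`).
#' @return `paralog_spec` list.
#' @export
paralog_spec <- function(duplication_edge, rate_multiplier = 2,
                         stem_length = NULL, planted_columns = list(),
                         label = "cen") {
  stopifnot(rate_multiplier > 0)
  if (!is.null(stem_length)) stopifnot(stem_length >= 0)
  structure(list(duplication_edge = duplication_edge,
                 rate_multiplier = rate_multiplier, stem_length = stem_length,
                 planted_columns = planted_columns, label = label),
            class = "paralog_spec")
}

#' Simulation configuration for a histone-like family
#'
#' @param n_species Number of species (used when the config also drives tree
#'   simulation).
#' @param tree_model Tree shape passed to [simulate_tree()].
#' @param seq_length Alignment length in columns; default 135, the length of
#'   histone H3.
#' @param subst_rate Expected substitutions per site per unit branch length.
#' @param indel_rate Gap-run events per site per unit branch length.
#' @param planted_columns List of [plant_spec()]s.
#' @param paralog_spec Optional [paralog_spec()].
#' @param background_freqs Named frequencies over the 20 amino acids.
#' @param seed Integer seed.
#' @param root_seq Optional root sequence (character vector of length
#'   `seq_length`); drawn from the background when `NULL`. Supplying it ties
#'   independent simulations to a common ancestor (e.g. seed alignment and
#'   homolog sets for the same profile).
#' @return `sim_config` list, validated.
#' @export
sim_config <- function(n_species = 12L, tree_model = "yule", seq_length = 135L,
                       subst_rate = 0.1, indel_rate = 0, planted_columns = list(),
                       paralog_spec = NULL,
                       background_freqs = default_background(), seed = 1L,
                       root_seq = NULL) {
  if (seq_length < 1) stop("seq_length must be at least 1")
  if (subst_rate < 0 || indel_rate < 0) stop("rates must be non-negative")
  background_freqs <- check_background(background_freqs)
  cols <- vapply(planted_columns, `[[`, integer(1), "column")
  if (length(cols)) {
    if (any(cols < 0) || any(cols >= seq_length)) {
      stop("planted column indices must lie in [0, seq_length)")
    }
    if (anyDuplicated(cols)) stop("planted columns must be pairwise distinct")
  }
  if (!is.null(root_seq)) {
    stopifnot(length(root_seq) == seq_length, all(root_seq %in% AA_ALPHABET20))
  }
  structure(list(n_species = as.integer(n_species), tree_model = tree_model,
                 seq_length = as.integer(seq_length), subst_rate = subst_rate,
                 indel_rate = indel_rate, planted_columns = planted_columns,
                 paralog_spec = paralog_spec, background_freqs = background_freqs,
                 seed = as.integer(seed), root_seq = root_seq),
            class = "sim_config")
}

#' Evolve a protein family along a tree
#'
#' Background columns evolve under an i.i.d. replacement process: the number
#' of substitutions on an edge is Poisson(`subst_rate` x branch length), and
#' each replacement is drawn from the background frequencies excluding the
#' current residue. Planted columns follow their [plant_spec()]
#' deterministically. Indels are modelled as gap-run deletion events (no true
#' insertion states), so profile coordinates stay well defined; gap runs
#' never erase a planted column, keeping the ground truth exact.
#'
#' @param tree Rooted binary `ape::phylo` with at least 3 leaves.
#' @param config A [sim_config()].
#' @return List with `sequences` (a `sequence_set`) and `truth` (a
#'   `truth_table`).
#' @export
simulate_family <- function(tree, config) {
  stopifnot(inherits(config, "sim_config"))
  if (length(tree$tip.label) < 3) stop("tree must have at least 3 leaves")
  all_edges <- edge_ids(tree)
  for (p in config$planted_columns) {
    missing <- setdiff(p$switch_edges, all_edges)
    if (length(missing)) {
      stop("switch edge(s) absent from tree: ", paste(missing, collapse = "; "))
    }
  }
  if (!is.null(config$paralog_spec) &&
      !config$paralog_spec$duplication_edge %in% all_edges) {
    stop("switch edge(s) absent from tree: ", config$paralog_spec$duplication_edge)
  }

  with_seed(config$seed, {
    core <- evolve_on_tree(tree, config, rate = config$subst_rate,
                           plants = config$planted_columns,
                           root_seq = config$root_seq)
    ids <- paste0(tree$tip.label, "_core")
    seqs <- core$leaf_seqs
    species <- tree$tip.label
    family <- rep("core", length(ids))
    truth_cols <- plant_truth(tree, config$planted_columns, family = "core")

    ps <- config$paralog_spec
    if (!is.null(ps)) {
      sub_tips <- strsplit(ps$duplication_edge, ",", fixed = TRUE)[[1]]
      dup_node <- node_of_clade(tree, sub_tips)
      sub <- if (length(sub_tips) > 1) {
        ape::keep.tip(tree, sub_tips)
      } else NULL
      anc_seq <- core$node_seqs[[dup_node]]
      # paralog stem: extra divergence before the duplicate subtree radiates
      stem <- ps$stem_length %||%
        tree$edge.length[match(ps$duplication_edge, all_edges)]
      anc_seq <- mutate_chain(anc_seq, config,
                              rate = config$subst_rate * ps$rate_multiplier,
                              bl = stem,
                              skip = vapply(ps$planted_columns,
                                            function(p) p$column + 1L,
                                            integer(1)))
      if (is.null(sub)) {
        # single-leaf duplicate: evolve along the pendant edge only
        dup_seqs <- evolve_single_edge(anc_seq, ps, config,
                                       bl = pendant_length(tree, sub_tips))
        rownames(dup_seqs) <- sub_tips
      } else {
        dup <- evolve_on_tree(sub, config, rate = config$subst_rate * ps$rate_multiplier,
                              plants = ps$planted_columns, root_seq = anc_seq)
        dup_seqs <- dup$leaf_seqs
      }
      ids <- c(ids, paste0(rownames(dup_seqs), "_", ps$label))
      seqs <- rbind(seqs, dup_seqs)
      species <- c(species, rownames(dup_seqs))
      family <- c(family, rep(ps$label, nrow(dup_seqs)))
      if (!is.null(sub)) {
        truth_cols <- rbind(truth_cols, plant_truth(sub, ps$planted_columns,
                                                    family = ps$label))
      }
    }

    rownames(seqs) <- ids
    sequences <- sequence_set(ids = ids, species = species, family = family,
                              aln = seqs)
    truth <- structure(list(columns = truth_cols$columns,
                            leaf_states = truth_cols$leaf_states,
                            families = data.frame(id = ids, species = species,
                                                  family = family,
                                                  stringsAsFactors = FALSE)),
                       class = "truth_table")
    list(sequences = sequences, truth = truth)
  })
}

# Core recursion: evolve sequences over every node of `tree`.
evolve_on_tree <- function(tree, config, rate, plants, root_seq = NULL) {
  n_tip <- length(tree$tip.label)
  n_node <- n_tip + tree$Nnode
  root <- n_tip + 1L
  L <- config$seq_length
  bg <- config$background_freqs
  planted_idx <- vapply(plants, function(p) p$column + 1L, integer(1))
  ids <- edge_ids(tree)

  if (is.null(root_seq)) {
    root_seq <- sample(AA_ALPHABET20, L, replace = TRUE, prob = bg)
    for (p in plants) root_seq[p$column + 1L] <- p$state_before
  } else {
    root_seq <- root_seq  # duplicate subfamily inherits the ancestral sequence
    for (p in plants) root_seq[p$column + 1L] <- p$state_before
  }

  node_seqs <- vector("list", n_node)
  node_gap <- vector("list", n_node)
  node_seqs[[root]] <- root_seq
  node_gap[[root]] <- rep(FALSE, L)

  edge_order <- rev(ape::postorder(tree))  # preorder over edges
  for (e in edge_order) {
    p <- tree$edge[e, 1]; ch <- tree$edge[e, 2]
    bl <- tree$edge.length[e]
    s <- node_seqs[[p]]
    g <- node_gap[[p]]
    # background substitutions
    free <- setdiff(seq_len(L), planted_idx)
    k <- stats::rpois(length(free), rate * bl)
    hit <- free[k > 0]
    for (j in seq_along(hit)) {
      col <- hit[j]
      for (r in seq_len(k[match(col, free)])) {
        cur <- s[col]
        w <- bg[AA_ALPHABET20 != cur]
        s[col] <- sample(names(w), 1, prob = w)
      }
    }
    # planted toggles
    for (pl in plants) {
      if (ids[e] %in% pl$switch_edges) {
        col <- pl$column + 1L
        s[col] <- if (s[col] == pl$state_before) pl$state_after else pl$state_before
      }
    }
    # gap-run deletion events (never on planted columns)
    if (config$indel_rate > 0) {
      n_events <- stats::rpois(1, config$indel_rate * bl * L)
      for (ev in seq_len(n_events)) {
        start <- sample.int(L, 1)
        len <- stats::rgeom(1, 1 / 3) + 1L
        run <- setdiff(start:min(L, start + len - 1L), planted_idx)
        g[run] <- TRUE
      }
    }
    node_seqs[[ch]] <- s
    node_gap[[ch]] <- g
  }

  leaf_seqs <- matrix(NA_character_, nrow = n_tip, ncol = L,
                      dimnames = list(tree$tip.label, NULL))
  for (i in seq_len(n_tip)) {
    s <- node_seqs[[i]]
    s[node_gap[[i]]] <- GAP_CHAR
    leaf_seqs[i, ] <- s
  }
  # conservation noise at the leaves
  for (pl in plants) {
    if (pl$conservation < 1) {
      col <- pl$column + 1L
      flip <- stats::runif(n_tip) > pl$conservation
      other <- ifelse(leaf_seqs[flip, col] == pl$state_before,
                      pl$state_after, pl$state_before)
      leaf_seqs[flip, col] <- other
    }
  }
  list(leaf_seqs = leaf_seqs, node_seqs = node_seqs)
}

# Expected leaf states of planted columns by deterministic toggling.
plant_truth <- function(tree, plants, family) {
  ids <- edge_ids(tree)
  cols <- data.frame(column = integer(0), state_before = character(0),
                     state_after = character(0), switch_edges = character(0),
                     family = character(0), stringsAsFactors = FALSE)
  leaf_states <- data.frame(column = integer(0), leaf = character(0),
                            state = character(0), family = character(0),
                            stringsAsFactors = FALSE)
  n_tip <- length(tree$tip.label)
  root <- n_tip + 1L
  for (pl in plants) {
    cols <- rbind(cols, data.frame(column = pl$column,
                                   state_before = pl$state_before,
                                   state_after = pl$state_after,
                                   switch_edges = paste(pl$switch_edges, collapse = ";"),
                                   family = family, stringsAsFactors = FALSE))
    state <- rep(NA_character_, n_tip + tree$Nnode)
    state[root] <- pl$state_before
    for (e in rev(ape::postorder(tree))) {
      p <- tree$edge[e, 1]; ch <- tree$edge[e, 2]
      s <- state[p]
      if (ids[e] %in% pl$switch_edges) {
        s <- if (s == pl$state_before) pl$state_after else pl$state_before
      }
      state[ch] <- s
    }
    leaf_states <- rbind(leaf_states,
                         data.frame(column = pl$column, leaf = tree$tip.label,
                                    state = state[seq_len(n_tip)],
                                    family = family, stringsAsFactors = FALSE))
  }
  list(columns = cols, leaf_states = leaf_states)
}

node_of_clade <- function(tree, tip_names) {
  below <- clade_leaf_sets(tree)
  target <- sort(tip_names)
  for (v in seq_along(below)) {
    if (identical(sort(below[[v]]), target)) return(v)
  }
  stop("no node spans exactly the clade {", paste(target, collapse = ","), "}")
}

pendant_length <- function(tree, tip_name) {
  i <- match(tip_name, tree$tip.label)
  tree$edge.length[tree$edge[, 2] == i]
}

evolve_single_edge <- function(anc_seq, ps, config, bl) {
  s <- mutate_chain(anc_seq, config, rate = config$subst_rate * ps$rate_multiplier,
                    bl = bl, skip = integer(0))
  matrix(s, nrow = 1)
}

# Apply a Poisson number of background replacements per site (skipping the
# given 1-based columns) for one branch.
mutate_chain <- function(s, config, rate, bl, skip = integer(0)) {
  bg <- config$background_freqs
  k <- stats::rpois(length(s), rate * bl)
  k[skip] <- 0L
  for (col in which(k > 0)) {
    for (r in seq_len(k[col])) {
      w <- bg[AA_ALPHABET20 != s[col]]
      s[col] <- sample(names(w), 1, prob = w)
    }
  }
  s
}

#' Simulate unrelated decoy proteins
#'
#' Independent residues drawn from the background composition; used to
#' calibrate and stress-test the profile search.
#'
#' @param n Number of decoys.
#' @param length Protein length.
#' @param background Amino-acid frequencies.
#' @param seed Integer seed.
#' @return Named character vector of sequences (`decoy001`, ...).
#' @export
simulate_decoys <- function(n, length, background = default_background(),
                            seed = 1L) {
  background <- check_background(background)
  with_seed(seed, {
    out <- vapply(seq_len(n), function(i) {
      paste(sample(AA_ALPHABET20, length, replace = TRUE, prob = background),
            collapse = "")
    }, character(1))
    names(out) <- sprintf("decoy%03d", seq_len(n))
    out
  })
}
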