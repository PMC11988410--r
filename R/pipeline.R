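# End-to-end orchestration: search -> curate -> classify -> score ->
# parsimony -> co-divergence, with persisted intermediates and a manifest.

#' Build and validate a pipeline configuration
#'
#' Houses every analysis setting under a named key: the homolog-search
#' cutoffs (expected-decoy cutoff, 300-residue length exclusion), the
#' gap-threshold for column trimming (0.3 for the family-discrimination
#' pass; 0.8 is the within-clade ortholog setting), the focal-residue window
#' (5 aligned positions), the logo flank (5), and the z-score flag threshold
#' (5.0; the raw-score threshold is off by default).
#'
#' @param simulate List with `tree` (`ape::phylo`) and `config`
#'   ([sim_config()]): the synthetic input block. (Alternatively supply
#'   `proteomes`, a named list of FASTA paths by species, plus `tree`.)
#' @param seed_alignment Seed alignment for the profile: matrix,
#'   `sequence_set` or FASTA path.
#' @param groups List `a`, `b` of species names plus optional `labels`.
#' @param focal List: `column` (0-based profile coordinate), `residue`,
#'   optional `label`.
#' @param candidates Integer vector of candidate columns (0-based profile
#'   coordinates) always carried into the parsimony stage; flagged columns
#'   are added automatically.
#' @param refs Optional list `core`, `cen` of reference row ids for family
#'   assignment; skipped when `NULL`.
#' @param evalue_cutoff,max_len,gap_threshold,z_threshold,score_threshold,
#'   focal_window,flank,gap_ceiling Thresholds (defaults as above).
#' @param n_decoys Decoys for significance calibration (default 200).
#' @param seed Integer master seed.
#' @param out_dir Output directory.
#' @return Validated `pipeline_config` list.
#' @export
pipeline_config <- function(simulate = NULL, proteomes = NULL, tree = NULL,
                            seed_alignment, groups, focal,
                            candidates = integer(0), refs = NULL,
                            evalue_cutoff = 1e-5, max_len = 300L,
                            gap_threshold = 0.3, z_threshold = 5,
                            score_threshold = NULL, focal_window = 5L,
                            flank = 5L, gap_ceiling = 0.5, n_decoys = 200L,
                            seed = 1L, out_dir = tempfile("histrace_run_")) {
  if (is.null(simulate) && is.null(proteomes)) {
    stop("either a simulate block or proteome inputs must be given")
  }
  if (is.null(groups$a) || length(groups$a) == 0 ||
      is.null(groups$b) || length(groups$b) == 0) {
    stop("both groups must be non-empty")
  }
  if (length(intersect(groups$a, groups$b))) stop("groups must be disjoint")
  stopifnot(evalue_cutoff > 0, max_len >= 1,
            gap_threshold >= 0, gap_threshold <= 1,
            focal_window >= 0, flank >= 0,
            gap_ceiling >= 0, gap_ceiling <= 1)
  if (is.null(focal$column) || is.null(focal$residue)) {
    stop("focal must name a column and a residue")
  }
  structure(list(simulate = simulate, proteomes = proteomes, tree = tree,
                 seed_alignment = seed_alignment, groups = groups,
                 focal = focal, candidates = as.integer(candidates),
                 refs = refs, evalue_cutoff = evalue_cutoff,
                 max_len = as.integer(max_len), gap_threshold = gap_threshold,
                 z_threshold = z_threshold, score_threshold = score_threshold,
                 focal_window = as.integer(focal_window),
                 flank = as.integer(flank), gap_ceiling = gap_ceiling,
                 n_decoys = as.integer(n_decoys), seed = as.integer(seed),
                 out_dir = out_dir),
            class = "pipeline_config")
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the full analysis pipeline
#'
#' Executes, in order: input acquisition (simulation or FASTA reading),
#' profile building and decoy calibration, proteome search with domain
#' extraction, per-species redundancy collapse, stacking and gap-threshold
#' trimming, optional family assignment, focal-residue classification,
#' group-specificity scoring, parsimony reconstruction of the focal and
#' candidate characters, co-divergence classification, logo matrices, and
#' iTOL export. Every intermediate is written as plain text under
#' `config$out_dir`; identical config and seeds give byte-identical
#' outputs. The run manifest is written last.
#'
#' @param config A [pipeline_config()].
#' @return The manifest, invisibly (list; also written as `manifest.json`).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  counts <- list()
  warnings_log <- character(0)
  note <- function(...) message("[histrace] ", ...)

  # --- inputs ---------------------------------------------------------------
  if (!is.null(config$simulate)) {
    note("stage simulate")
    ds <- simulate_family(config$simulate$tree, config$simulate$config)
    tree <- config$simulate$tree
    write_fixture(ds, tree, file.path(out, "fixture"))
    proteome_by_species <- split(ungapped_sequences(ds$sequences),
                                 ds$sequences$species)
    truth <- ds$truth
  } else {
    note("stage read-inputs")
    tree <- if (is.character(config$tree)) ape::read.tree(config$tree) else config$tree
    proteome_by_species <- lapply(config$proteomes, function(p) {
      s <- Biostrings::readAAStringSet(p)
      stats::setNames(as.character(s), names(s))
    })
    truth <- NULL
  }
  counts$species <- length(proteome_by_species)
  counts$proteins <- sum(lengths(proteome_by_species))

  # --- profile + calibration ------------------------------------------------
  note("stage profile")
  profile <- build_profile(config$seed_alignment)
  calib <- calibrate_significance(profile, length_model = profile$n_columns,
                                  n_decoys = config$n_decoys,
                                  seed = config$seed,
                                  cutoff = config$evalue_cutoff)

  # --- search ---------------------------------------------------------------
  note("stage search")
  hits <- list()
  for (sp in names(proteome_by_species)) {
    hits <- c(hits, search_proteome(profile, proteome_by_species[[sp]], calib,
                                    max_len = config$max_len, species = sp))
  }
  if (length(hits) == 0) stop("search stage: no hits passed the thresholds")
  counts$hits <- length(hits)
  write_tsv(data.frame(
    protein_id = vapply(hits, `[[`, character(1), "protein_id"),
    species = vapply(hits, function(h) as.character(h$species), character(1)),
    score_bits = vapply(hits, `[[`, numeric(1), "raw_score"),
    evalue_like = vapply(hits, `[[`, numeric(1), "evalue_like"),
    start = vapply(hits, function(h) h$target_interval[1], numeric(1)),
    end = vapply(hits, function(h) h$target_interval[2], numeric(1))),
    file.path(out, "hits.tsv"))

  # --- curate ---------------------------------------------------------------
  note("stage curate")
  stacked <- stack_alignment(hits)
  seqs <- sequence_set(ids = stacked$ids, species = stacked$species,
                       aln = stacked$matrix)
  dd <- dedup_identical(seqs)
  write_tsv(dd$clusters, file.path(out, "dedup_clusters.tsv"))
  counts$after_dedup <- length(dd$sequences$ids)
  stacked <- as_stacked_alignment(dd$sequences)
  write_tsv(trim_report(stacked, config$gap_threshold),
            file.path(out, "trim_report.tsv"))
  trimmed <- trim_by_gap_threshold(stacked, config$gap_threshold)
  counts$columns_retained <- ncol(trimmed$matrix)

  if (!is.null(config$refs)) {
    note("stage assign-family")
    fa <- assign_family(trimmed, config$refs$core, config$refs$cen)
    write_tsv(fa, file.path(out, "family_assignment.tsv"))
    trimmed$family <- fa$family[match(trimmed$ids, fa$id)]
  }

  # --- classify focal residue -----------------------------------------------
  note("stage classify")
  fcol_idx <- match(config$focal$column, trimmed$column_provenance)
  if (is.na(fcol_idx)) stop("focal column was trimmed away")
  classification <- vapply(seq_along(trimmed$ids), function(i) {
    classify_focal_residue(trimmed$matrix[i, ], fcol_idx - 1L,
                           window = config$focal_window,
                           residue = config$focal$residue)
  }, character(1))
  write_tsv(data.frame(id = trimmed$ids, species = trimmed$species,
                       focal = classification),
            file.path(out, "focal_classification.tsv"))

  # --- group-specificity scoring --------------------------------------------
  note("stage score")
  by_species <- !all(c(config$groups$a, config$groups$b) %in% trimmed$ids)
  row_group <- function(members) {
    if (by_species) trimmed$ids[trimmed$species %in% members] else members
  }
  part <- group_partition(row_group(config$groups$a), row_group(config$groups$b),
                          labels = config$groups$labels %||% c("group_a", "group_b"))
  gs <- score_alignment(trimmed, part, z_threshold = config$z_threshold,
                        score_threshold = config$score_threshold,
                        gap_ceiling = config$gap_ceiling)
  write_tsv(as.data.frame(gs), file.path(out, "groupsim.tsv"))
  counts$flagged_columns <- sum(gs$flagged, na.rm = TRUE)

  logos <- logo_counts(trimmed, part, fcol_idx - 1L, flank = config$flank)
  for (g in names(logos)) {
    write_tsv(data.frame(position = rep(logos[[g]]$positions, each = 20),
                         residue = rep(AA_ALPHABET20, length(logos[[g]]$positions)),
                         count = as.vector(logos[[g]]$counts),
                         ic_bits = rep(logos[[g]]$ic, each = 20)),
              file.path(out, paste0("logo_", gsub("[^A-Za-z0-9_]", "_", g), ".tsv")))
  }

  # --- parsimony + co-divergence --------------------------------------------
  note("stage parsimony")
  species_of <- trimmed$species
  if (anyDuplicated(species_of)) {
    warnings_log <- c(warnings_log,
                      "multiple rows per species; parsimony uses the first row per species")
  }
  first_per_species <- !duplicated(species_of)
  sub <- stacked_alignment(trimmed$matrix[first_per_species, , drop = FALSE],
                           species = species_of[first_per_species],
                           family = trimmed$family[first_per_species],
                           column_provenance = trimmed$column_provenance)
  rownames(sub$matrix) <- sub$species
  sub$ids <- sub$species
  keep_tips <- intersect(tree$tip.label, sub$species)
  ptree <- if (length(keep_tips) < length(tree$tip.label)) {
    ape::keep.tip(tree, keep_tips)
  } else tree

  focal_states <- character_state_map(stats::setNames(
    vapply(seq_along(sub$ids), function(i) {
      classify_focal_residue(sub$matrix[i, ], fcol_idx - 1L,
                             window = config$focal_window,
                             residue = config$focal$residue)
    }, character(1)) == "present", sub$species),
    label = config$focal$label %||% paste0(config$focal$residue,
                                           config$focal$column + 1L))
  focal_rec <- fitch_parsimony(ptree, focal_states)

  cand_cols <- sort(unique(c(config$candidates,
                             gs$column[which(gs$flagged)])))
  cand_cols <- setdiff(cand_cols, config$focal$column)
  reports <- data.frame(character = focal_rec$label,
                        min_changes = focal_rec$min_changes,
                        change_edges_always = paste(focal_rec$change_edges_always,
                                                    collapse = ";"),
                        change_edges_ever = paste(focal_rec$change_edges_ever,
                                                  collapse = ";"),
                        truncated = focal_rec$truncated,
                        stringsAsFactors = FALSE)
  codiv <- NULL
  for (cc in cand_cols) {
    idx <- match(cc, sub$column_provenance)
    if (is.na(idx)) next
    # candidate state: presence of the modal residue of group_a (the
    # ancestral-like group) at that column
    col <- sub$matrix[, idx]
    ga_species <- unique(trimmed$species[trimmed$ids %in% part$group_a])
    ga_res <- col[sub$species %in% ga_species]
    ga_res <- ga_res[ga_res != GAP_CHAR]
    if (!length(ga_res)) next
    modal <- names(sort(table(ga_res), decreasing = TRUE))[1]
    rec <- fitch_parsimony(ptree, character_state_map(
      stats::setNames(col == modal, sub$species),
      label = paste0(modal, "@", cc)))
    reports <- rbind(reports, data.frame(
      character = rec$label, min_changes = rec$min_changes,
      change_edges_always = paste(rec$change_edges_always, collapse = ";"),
      change_edges_ever = paste(rec$change_edges_ever, collapse = ";"),
      truncated = rec$truncated, stringsAsFactors = FALSE))
    codiv <- rbind(codiv, cbind(column = cc, codivergence(focal_rec, rec)))
  }
  write_tsv(reports, file.path(out, "parsimony_report.tsv"))
  if (!is.null(codiv)) write_tsv(codiv, file.path(out, "codivergence.tsv"))

  note("stage export")
  export_itol(list(focal_states), ptree, file.path(out, "itol_binary.txt"))

  manifest <- list(
    seed = config$seed,
    thresholds = list(evalue_cutoff = config$evalue_cutoff,
                      max_len = config$max_len,
                      gap_threshold = config$gap_threshold,
                      z_threshold = config$z_threshold,
                      focal_window = config$focal_window,
                      flank = config$flank),
    counts = counts, warnings = warnings_log,
    outputs = list.files(out, recursive = TRUE))
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}

#' Export character states as an iTOL binary dataset
#'
#' Writes the text annotation format iTOL uses to attach per-leaf
#' presence/absence squares to a displayed phylogeny: a `DATASET_BINARY`
#' header block with one field per character, then one row per tree leaf
#' with 1 (present), 0 (absent) or -1 (missing).
#'
#' @param states List of `character_state_map`s (leaves must be tree tips;
#'   leaves missing from a map are emitted as -1).
#' @param tree `ape::phylo` whose tips define the rows.
#' @param path Output file.
#' @param label Dataset label.
#' @return `path`, invisibly.
#' @export
export_itol <- function(states, tree, path, label = "residue presence") {
  stopifnot(length(states) >= 1)
  states <- lapply(states, function(s) {
    if (inherits(s, "character_state_map")) s else character_state_map(s)
  })
  labs <- vapply(states, `[[`, character(1), "label")
  lines <- c("DATASET_BINARY", "SEPARATOR TAB",
             paste0("DATASET_LABEL\t", label), "COLOR\t#1f78b4",
             paste0("FIELD_SHAPES\t", paste(rep("1", length(states)), collapse = "\t")),
             paste0("FIELD_LABELS\t", paste(labs, collapse = "\t")),
             "DATA")
  for (tip in tree$tip.label) {
    vals <- vapply(states, function(s) {
      st <- s$states[tip]
      if (is.na(st)) "-1" else if (st == "present") "1" else "0"
    }, character(1))
    lines <- c(lines, paste(c(tip, vals), collapse = "\t"))
  }
  writeLines(lines, path)
  invisible(path)
}
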