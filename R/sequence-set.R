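# Sequence containers and fixture I/O (FASTA, Newick, TSV).

#' Construct a sequence set
#'
#' The basic container for a collection of (optionally aligned) protein
#' sequences tagged with species and family labels. Aligned sets are stored
#' as a character matrix of single residues/gaps.
#'
#' @param ids Unique sequence identifiers.
#' @param species Species tag per sequence.
#' @param family Family label per sequence (e.g. `"core"`, `"cen"`), or `NA`.
#' @param aln Character matrix (rows = sequences) of residues and `"-"` gaps.
#' @return Object of class `sequence_set`.
#' @export
sequence_set <- function(ids, species, family = rep(NA_character_, length(ids)),
                         aln) {
  stopifnot(length(ids) == nrow(aln), length(species) == length(ids),
            length(family) == length(ids))
  if (anyDuplicated(ids)) stop("sequence ids must be unique")
  rownames(aln) <- ids
  structure(list(ids = as.character(ids), species = as.character(species),
                 family = as.character(family), aln = aln),
            class = "sequence_set")
}

#' @export
print.sequence_set <- function(x, ...) {
  cat("sequence_set:", length(x$ids), "sequences x", ncol(x$aln), "columns\n")
  invisible(x)
}

#' Ungapped sequences of a set
#'
#' @param x A `sequence_set`.
#' @return Named character vector of sequences with gaps removed, as they
#'   would appear in a proteome FASTA.
#' @export
ungapped_sequences <- function(x) {
  out <- apply(x$aln, 1, function(r) paste(r[r != GAP_CHAR], collapse = ""))
  names(out) <- x$ids
  out
}

#' Read an aligned FASTA into a character matrix
#'
#' @param path FASTA file; all records must have equal length.
#' @return Character matrix, one row per record, rownames = record ids.
#' @export
read_alignment_fasta <- function(path) {
  s <- Biostrings::readAAStringSet(path)
  w <- Biostrings::width(s)
  if (length(unique(w)) > 1) stop("alignment FASTA has unequal record lengths")
  m <- do.call(rbind, strsplit(as.character(s), ""))
  rownames(m) <- names(s)
  m
}

#' Write sequences to FASTA
#'
#' @param seqs Named character vector of sequence strings.
#' @param path Output file.
#' @export
write_fasta <- function(seqs, path) {
  x <- Biostrings::AAStringSet(seqs)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Write a simulated dataset as plain-text fixtures
#'
#' Emits, under `out_dir`: one ungapped FASTA per species
#' (`proteomes/<species>.fasta`), the full aligned family
#' (`alignment.fasta`), the species tree (`tree.nwk`) and the ground truth as
#' TSV (`truth_columns.tsv`, `truth_leaf_states.tsv`, `families.tsv`).
#'
#' @param dataset List with `sequences` and `truth` from [simulate_family()].
#' @param tree The `ape::phylo` the dataset was simulated along.
#' @param out_dir Output directory, created if needed.
#' @return Named list of written paths, invisibly.
#' @export
write_fixture <- function(dataset, tree, out_dir) {
  seqs <- dataset$sequences
  if (!inherits(seqs, "sequence_set") || length(seqs$ids) == 0) {
    stop("dataset must contain a non-empty sequence_set")
  }
  dir.create(file.path(out_dir, "proteomes"), recursive = TRUE, showWarnings = FALSE)
  prot <- ungapped_sequences(seqs)
  prot_paths <- character(0)
  for (sp in unique(seqs$species)) {
    p <- file.path(out_dir, "proteomes", paste0(sp, ".fasta"))
    write_fasta(prot[seqs$species == sp], p)
    prot_paths <- c(prot_paths, p)
  }
  aln_path <- file.path(out_dir, "alignment.fasta")
  aligned <- apply(seqs$aln, 1, paste, collapse = "")
  write_fasta(stats::setNames(aligned, seqs$ids), aln_path)
  tree_path <- file.path(out_dir, "tree.nwk")
  ape::write.tree(tree, tree_path)
  tt <- dataset$truth
  paths <- list(proteomes = prot_paths, alignment = aln_path, tree = tree_path)
  for (nm in c("columns", "leaf_states", "families")) {
    f <- file.path(out_dir, paste0(if (nm == "families") nm else paste0("truth_", nm),
                                   ".tsv"))
    utils::write.table(tt[[nm]], f, sep = "\t", quote = FALSE, row.names = FALSE)
    paths[[nm]] <- f
  }
  invisible(paths)
}

#' Read fixtures written by [write_fixture()]
#'
#' @param out_dir Directory previously written by [write_fixture()].
#' @return List with `sequences` (a `sequence_set`), `truth` (a
#'   `truth_table`) and `tree` (`ape::phylo`).
#' @export
read_fixture <- function(out_dir) {
  m <- read_alignment_fasta(file.path(out_dir, "alignment.fasta"))
  fam <- utils::read.table(file.path(out_dir, "families.tsv"), sep = "\t",
                           header = TRUE, stringsAsFactors = FALSE)
  fam <- fam[match(rownames(m), fam$id), ]
  seqs <- sequence_set(ids = rownames(m), species = fam$species,
                       family = fam$family, aln = m)
  truth <- structure(list(
    columns = utils::read.table(file.path(out_dir, "truth_columns.tsv"),
                                sep = "\t", header = TRUE,
                                stringsAsFactors = FALSE,
                                colClasses = c(column = "integer")),
    leaf_states = utils::read.table(file.path(out_dir, "truth_leaf_states.tsv"),
                                    sep = "\t", header = TRUE,
                                    stringsAsFactors = FALSE),
    families = fam), class = "truth_table")
  tree <- ape::read.tree(file.path(out_dir, "tree.nwk"))
  list(sequences = seqs, truth = truth, tree = tree)
}
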