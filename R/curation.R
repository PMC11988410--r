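# Redundancy collapse, domain stacking, gap-threshold trimming,
# core vs centromeric family assignment.

#' Construct a stacked alignment
#'
#' The rectangular container used downstream of domain extraction: one row
#' per sequence, one column per retained profile column.
#'
#' @param mat Character matrix of residues/gaps, rownames = ids.
#' @param species Species per row.
#' @param family Optional family label per row.
#' @param column_provenance 0-based original profile column index per
#'   retained column (strictly increasing).
#' @return Object of class `stacked_alignment`.
#' @export
stacked_alignment <- function(mat, species, family = rep(NA_character_, nrow(mat)),
                              column_provenance = seq_len(ncol(mat)) - 1L) {
  stopifnot(is.matrix(mat), !is.null(rownames(mat)),
            length(species) == nrow(mat),
            length(column_provenance) == ncol(mat))
  if (anyDuplicated(rownames(mat))) stop("row ids must be unique")
  if (is.unsorted(column_provenance, strictly = TRUE)) {
    stop("column_provenance must be strictly increasing")
  }
  structure(list(matrix = mat, ids = rownames(mat),
                 species = as.character(species), family = as.character(family),
                 column_provenance = as.integer(column_provenance)),
            class = "stacked_alignment")
}

#' @export
print.stacked_alignment <- function(x, ...) {
  cat("stacked_alignment:", nrow(x$matrix), "rows x", ncol(x$matrix), "columns\n")
  invisible(x)
}

#' Stacked view of a sequence set
#'
#' @param x A `sequence_set` (aligned).
#' @return A `stacked_alignment` over the same rows and columns.
#' @export
as_stacked_alignment <- function(x) {
  stopifnot(inherits(x, "sequence_set"))
  stacked_alignment(x$aln, species = x$species, family = x$family)
}

#' Collapse identical sequences within each species
#'
#' Byte-identical sequences from the same species (recent paralogs or
#' assembly redundancy) collapse to one representative, the
#' lexicographically smallest id. Identical sequences from different species
#' are all retained.
#'
#' @param x A `sequence_set` with species tags on every sequence.
#' @return List with `sequences` (deduplicated `sequence_set`) and
#'   `clusters` (data.frame `representative`, `member`).
#' @export
dedup_identical <- function(x) {
  stopifnot(inherits(x, "sequence_set"))
  if (anyNA(x$species) || any(x$species == "")) {
    stop("every sequence must carry a species tag")
  }
  seq_str <- apply(x$aln, 1, paste, collapse = "")
  key <- paste(x$species, seq_str, sep = "\r")
  groups <- split(x$ids, key)
  reps <- vapply(groups, function(g) sort(g)[1], character(1))
  clusters <- do.call(rbind, lapply(groups, function(g) {
    data.frame(representative = sort(g)[1], member = g, stringsAsFactors = FALSE)
  }))
  rownames(clusters) <- NULL
  keep <- x$ids %in% reps
  out <- sequence_set(ids = x$ids[keep], species = x$species[keep],
                      family = x$family[keep], aln = x$aln[keep, , drop = FALSE])
  clusters <- clusters[order(clusters$representative, clusters$member), ]
  list(sequences = out, clusters = clusters)
}

#' Stack extracted domains into a profile-coordinate alignment
#'
#' Row r, column c holds the residue hit r maps to profile column c, or a
#' gap. Rectangular by construction; all hits must come from the same
#' profile.
#'
#' @param hits List of `profile_hit`s from [search_proteome()] /
#'   [score_sequence()].
#' @return A `stacked_alignment` in full profile coordinates.
#' @export
stack_alignment <- function(hits) {
  if (length(hits) == 0) stop("no hits to stack")
  fps <- lapply(hits, `[[`, "profile_fingerprint")
  if (!all(vapply(fps, identical, logical(1), fps[[1]]))) {
    stop("hits come from mismatched profiles")
  }
  mat <- do.call(rbind, lapply(hits, `[[`, "column_map"))
  rownames(mat) <- vapply(hits, `[[`, character(1), "protein_id")
  stacked_alignment(mat,
                    species = vapply(hits, function(h) as.character(h$species),
                                     character(1)))
}

#' Trim alignment columns by gap threshold
#'
#' Retains column c iff its fraction of non-gap residues is at least
#' `gap_threshold` (trimAl `-gt` semantics). Rows are never removed. The
#' pipeline defaults are 0.3 for the family-discrimination pass and 0.8 for
#' the within-clade ortholog pass.
#'
#' @param aln A `stacked_alignment`.
#' @param gap_threshold Minimum non-gap fraction in `[0, 1]`.
#' @return Trimmed `stacked_alignment` with updated `column_provenance`.
#' @export
trim_by_gap_threshold <- function(aln, gap_threshold) {
  stopifnot(inherits(aln, "stacked_alignment"),
            gap_threshold >= 0, gap_threshold <= 1)
  nongap <- colMeans(aln$matrix != GAP_CHAR)
  keep <- nongap >= gap_threshold
  stacked_alignment(aln$matrix[, keep, drop = FALSE], species = aln$species,
                    family = aln$family,
                    column_provenance = aln$column_provenance[keep])
}

#' Trim report: per-column non-gap fraction and retention
#'
#' @param aln A `stacked_alignment`.
#' @param gap_threshold As in [trim_by_gap_threshold()].
#' @return data.frame (`column`, `nongap_fraction`, `retained`).
#' @export
trim_report <- function(aln, gap_threshold) {
  nongap <- colMeans(aln$matrix != GAP_CHAR)
  data.frame(column = aln$column_provenance, nongap_fraction = unname(nongap),
             retained = unname(nongap >= gap_threshold))
}

#' Assign rows to the core or centromeric histone family
#'
#' With a tree over the rows (supplied, or built by neighbor joining from
#' the alignment), the assignment uses the bipartition that separates the
#' core references from the centromeric references: every row takes the
#' label of the reference clade on its side. When several edges separate
#' the reference sets, the bipartition with the widest gap (largest minimum
#' cross-side patristic distance) is used; supplying two or more references
#' per family narrows the candidates and makes the assignment much more
#' reliable. When no edge separates the two reference sets, the function
#' falls back (with a warning) to mean sequence identity against each
#' reference set, requiring a minimum margin; equidistant rows stay
#' unassigned.
#'
#' @param aln A `stacked_alignment`.
#' @param core_refs,cen_refs Row ids anchoring each family; at least one of
#'   each must be present.
#' @param tree Optional `ape::phylo` whose tips are the row ids.
#' @param margin Minimum identity margin for the fallback mode (default 0).
#' @param mode `"auto"` (tree if possible), `"tree"`, or `"identity"`.
#' @return data.frame (`id`, `family` in core/centromeric/unassigned,
#'   `evidence`).
#' @export
assign_family <- function(aln, core_refs, cen_refs, tree = NULL, margin = 0,
                          mode = c("auto", "tree", "identity")) {
  mode <- match.arg(mode)
  stopifnot(inherits(aln, "stacked_alignment"))
  ids <- aln$ids
  if (!any(core_refs %in% ids) || !any(cen_refs %in% ids)) {
    stop("at least one reference id per family must be present in the alignment")
  }
  core_refs <- intersect(core_refs, ids)
  cen_refs <- intersect(cen_refs, ids)
  if (length(intersect(core_refs, cen_refs))) stop("reference sets overlap")

  if (mode != "identity") {
    if (is.null(tree)) {
      tree <- tryCatch(neighbor_joining(pairwise_distance(aln)),
                       error = function(e) NULL)
    }
    if (!is.null(tree) && all(ids %in% tree$tip.label)) {
      side <- separating_split(tree, core_refs, cen_refs)
      if (!is.null(side)) {
        fam <- ifelse(ids %in% side, "core", "centromeric")
        return(data.frame(id = ids, family = fam,
                          evidence = "tree-bipartition",
                          stringsAsFactors = FALSE))
      }
      if (mode == "tree") {
        warning("core and centromeric references are not separable into two clades; ",
                "falling back to identity mode")
      }
    }
    if (mode == "auto" || mode == "tree") {
      if (mode == "auto") {
        warning("no separating bipartition found; using identity fallback")
      }
    }
  }

  mat <- aln$matrix
  mean_ident <- function(row, refs) {
    mean(vapply(refs, function(r) {
      a <- mat[row, ]; b <- mat[r, ]
      ok <- a != GAP_CHAR & b != GAP_CHAR
      if (!any(ok)) return(0)
      mean(a[ok] == b[ok])
    }, numeric(1)))
  }
  fam <- character(length(ids))
  for (i in seq_along(ids)) {
    dcore <- mean_ident(ids[i], core_refs)
    dcen <- mean_ident(ids[i], cen_refs)
    fam[i] <- if (dcore - dcen > margin) "core"
              else if (dcen - dcore > margin) "centromeric"
              else "unassigned"
  }
  fam[ids %in% core_refs] <- "core"
  fam[ids %in% cen_refs] <- "centromeric"
  data.frame(id = ids, family = fam, evidence = "identity-margin",
             stringsAsFactors = FALSE)
}

# Find a tree split with all core refs on one side and all cen refs on the
# other. Several edges can qualify (every edge on the paths between the
# reference sets does), so take the bipartition whose two sides are most
# divergent — maximal mean cross-side patristic distance — which is the
# family boundary when the two paralog families coalesce deeper than
# anything within either family. Returns the tip set on the core side, or
# NULL when no edge separates the references.
separating_split <- function(tree, core_refs, cen_refs) {
  tips <- tree$tip.label
  below <- clade_leaf_sets(tree)
  pat <- ape::cophenetic.phylo(tree)
  best <- NULL
  best_sep <- -Inf
  for (e in seq_len(nrow(tree$edge))) {
    s <- below[[tree$edge[e, 2]]]
    comp <- setdiff(tips, s)
    side <- if (all(core_refs %in% s) && all(cen_refs %in% comp)) s
            else if (all(cen_refs %in% s) && all(core_refs %in% comp)) comp
            else NULL
    if (!is.null(side)) {
      other <- setdiff(tips, side)
      sep <- min(pat[side, other])   # largest-gap rule
      if (sep > best_sep) {
        best <- side
        best_sep <- sep
      }
    }
  }
  best
}
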