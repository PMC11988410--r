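# Distances, neighbor joining, Fitch parsimony with full enumeration of
# most-parsimonious labelings, and co-divergence of residue characters.

#' Poisson-corrected pairwise distances from a stacked alignment
#'
#' For each pair, `p` is the mismatch fraction over mutually non-gap
#' columns and the distance is `-ln(1 - p)`. Saturated pairs
#' (`p >= p_cap`) are set to `max_dist` with a warning.
#'
#' @param aln A `stacked_alignment` with at least 3 rows.
#' @param min_overlap Minimum number of mutually non-gap columns per pair.
#' @param p_cap Saturation cap on the mismatch fraction (default 0.95).
#' @param max_dist Distance assigned to saturated pairs (default 5).
#' @return Symmetric numeric matrix with zero diagonal, dimnames = row ids.
#' @export
pairwise_distance <- function(aln, min_overlap = 10L, p_cap = 0.95,
                              max_dist = 5) {
  stopifnot(inherits(aln, "stacked_alignment"))
  m <- aln$matrix
  n <- nrow(m)
  if (n < 3) stop("need at least 3 rows")
  D <- matrix(0, n, n, dimnames = list(aln$ids, aln$ids))
  gap <- m == GAP_CHAR
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      ok <- !gap[i, ] & !gap[j, ]
      if (sum(ok) < min_overlap) {
        stop("overlap below minimum for pair ", aln$ids[i], " / ", aln$ids[j])
      }
      p <- mean(m[i, ok] != m[j, ok])
      d <- if (p >= p_cap) {
        warning("saturated pair ", aln$ids[i], " / ", aln$ids[j],
                "; distance capped")
        max_dist
      } else {
        -log(1 - p)
      }
      D[i, j] <- D[j, i] <- d
    }
  }
  D
}

#' Neighbor-joining tree from a distance matrix
#'
#' Standard NJ agglomeration (via `ape::nj`); negative branch lengths are
#' clamped to zero with a message. NJ is consistent: additive distances
#' recover the generating topology exactly.
#'
#' @param D Symmetric distance matrix with dimnames, at least 3 taxa.
#' @return Unrooted `ape::phylo`.
#' @export
neighbor_joining <- function(D) {
  if (!is.matrix(D) || nrow(D) != ncol(D) || nrow(D) < 3) {
    stop("D must be a square matrix over at least 3 taxa")
  }
  if (!isSymmetric(unname(D), tol = 1e-8)) stop("D must be symmetric")
  tr <- ape::nj(as.dist(D))
  if (any(tr$edge.length < 0)) {
    message("clamping ", sum(tr$edge.length < 0), " negative NJ branch length(s) to 0")
    tr$edge.length[tr$edge.length < 0] <- 0
  }
  tr
}

#' A binary character state map over tree leaves
#'
#' @param states Named vector over leaf names with values `"present"`/
#'   `"absent"` (or logical, `TRUE` = present).
#' @param label Character label, e.g. `"H3C110"`.
#' @return Object of class `character_state_map`.
#' @export
character_state_map <- function(states, label = "character") {
  if (is.logical(states)) {
    states <- ifelse(states, "present", "absent")
  }
  if (is.null(names(states)) || anyDuplicated(names(states))) {
    stop("states must be named uniquely by leaf")
  }
  if (!all(states %in% c("present", "absent"))) {
    stop("states must be 'present' or 'absent'")
  }
  structure(list(states = states, label = label), class = "character_state_map")
}

#' Fitch parsimony for a binary character, with all MP labelings
#'
#' Computes the minimum number of state changes on the tree (unit-cost
#' parsimony, equal gain and loss costs), enumerates every ancestral
#' labeling attaining it (capped, with a truncation flag), and reports the
#' branches that change state in every MP labeling (`change_edges_always`)
#' and in at least one (`change_edges_ever`). The change count is invariant
#' to root placement.
#'
#' @param tree Rooted binary `ape::phylo`.
#' @param states A `character_state_map` (or named vector) covering every
#'   leaf.
#' @param max_labelings Enumeration cap (default 10000).
#' @return Object of class `parsimony_reconstruction`: `min_changes`,
#'   `mp_labelings` (list of named state vectors over internal nodes),
#'   `change_edges_always`, `change_edges_ever` (edge ids, see
#'   [edge_ids()]), `truncated`, `label`, `tree_key`.
#' @export
fitch_parsimony <- function(tree, states, max_labelings = 10000L) {
  if (!inherits(states, "character_state_map")) {
    states <- character_state_map(states)
  }
  tips <- tree$tip.label
  missing <- setdiff(tips, names(states$states))
  if (length(missing)) {
    stop("missing leaf state(s): ", paste(missing, collapse = ", "))
  }
  n_tip <- length(tips)
  n_node <- n_tip + tree$Nnode
  root <- n_tip + 1L
  S <- c("present", "absent")
  INF <- .Machine$integer.max %/% 4L

  cost <- matrix(INF, nrow = n_node, ncol = 2)
  for (i in seq_len(n_tip)) {
    cost[i, match(states$states[[tips[i]]], S)] <- 0L
  }
  children <- vector("list", n_node)
  for (e in seq_len(nrow(tree$edge))) {
    p <- tree$edge[e, 1]
    children[[p]] <- c(children[[p]], tree$edge[e, 2])
  }
  po <- ape::postorder(tree)
  # bottom-up over internal nodes in child-before-parent order
  internal_order <- unique(tree$edge[po, 1])
  for (v in internal_order) {
    for (s in 1:2) {
      tot <- 0L
      for (ch in children[[v]]) {
        tot <- tot + min(cost[ch, 1] + as.integer(s != 1L),
                         cost[ch, 2] + as.integer(s != 2L))
      }
      cost[v, s] <- tot
    }
  }
  min_changes <- min(cost[root, ])

  # top-down enumeration of all optimal assignments over internal nodes
  eids <- edge_ids(tree)
  results <- new.env()
  results$list <- list()
  results$truncated <- FALSE
  enum <- function(partial) {
    # partial: list(assign = named int vector over internal nodes processed,
    #               frontier = list of (node, state) internal nodes to expand)
    if (results$truncated) return()
    if (length(partial$frontier) == 0) {
      if (length(results$list) >= max_labelings) {
        results$truncated <- TRUE
        return()
      }
      results$list[[length(results$list) + 1]] <- partial$assign
      return()
    }
    fr <- partial$frontier[[1]]
    rest <- partial$frontier[-1]
    v <- fr[1]; s <- fr[2]
    assign <- partial$assign
    assign[as.character(v)] <- s
    kids <- children[[v]]
    child_opts <- lapply(kids, function(ch) {
      if (ch <= n_tip) return(0L)   # leaves carry their observed state
      v1 <- cost[ch, 1] + as.integer(s != 1L)
      v2 <- cost[ch, 2] + as.integer(s != 2L)
      which(c(v1, v2) == min(v1, v2))
    })
    int_kids <- kids[kids > n_tip]
    int_opts <- child_opts[kids > n_tip]
    if (length(int_kids) == 0) {
      enum(list(assign = assign, frontier = rest))
    } else {
      grid <- expand.grid(int_opts)
      for (g in seq_len(nrow(grid))) {
        newfr <- rest
        for (ci in seq_along(int_kids)) {
          newfr[[length(newfr) + 1]] <- c(int_kids[ci], as.integer(grid[g, ci]))
        }
        enum(list(assign = assign, frontier = newfr))
        if (results$truncated) return()
      }
    }
  }
  for (rs in which(cost[root, ] == min_changes)) {
    enum(list(assign = stats::setNames(integer(0), character(0)),
              frontier = list(c(root, rs))))
    if (results$truncated) break
  }
  labelings <- lapply(results$list, function(a) {
    stats::setNames(S[a], names(a))
  })

  node_state <- function(lab, v) {
    if (v <= n_tip) states$states[[tips[v]]] else lab[[as.character(v)]]
  }
  change_sets <- lapply(labelings, function(lab) {
    ch <- character(0)
    for (e in seq_len(nrow(tree$edge))) {
      p <- tree$edge[e, 1]; c2 <- tree$edge[e, 2]
      if (node_state(lab, p) != node_state(lab, c2)) ch <- c(ch, eids[e])
    }
    sort(ch)
  })
  stopifnot(all(vapply(change_sets, length, integer(1)) == min_changes))
  always <- if (length(change_sets)) Reduce(intersect, change_sets) else character(0)
  ever <- if (length(change_sets)) sort(unique(unlist(change_sets))) else character(0)

  structure(list(min_changes = as.integer(min_changes),
                 mp_labelings = labelings,
                 change_sets = change_sets,
                 change_edges_always = sort(always),
                 change_edges_ever = ever,
                 truncated = results$truncated,
                 label = states$label,
                 tree_key = paste(sort(eids), collapse = "|")),
            class = "parsimony_reconstruction")
}

#' @export
print.parsimony_reconstruction <- function(x, ...) {
  cat("parsimony_reconstruction [", x$label, "]: ", x$min_changes,
      " change(s), ", length(x$mp_labelings), " MP labeling(s)",
      if (x$truncated) " (truncated)", "\n", sep = "")
  invisible(x)
}

#' Present/absent states of one alignment column
#'
#' @param aln A `stacked_alignment`.
#' @param column 0-based column index within `aln`.
#' @param residue Residue whose presence defines the `"present"` state.
#' @param by `"species"` (default) or `"id"`: how to name the states.
#' @param label Character label for the map.
#' @return A `character_state_map`.
#' @export
residue_state_map <- function(aln, column, residue, by = c("species", "id"),
                              label = NULL) {
  by <- match.arg(by)
  stopifnot(inherits(aln, "stacked_alignment"))
  if (column < 0 || column >= ncol(aln$matrix)) stop("column out of range")
  nm <- if (by == "species") aln$species else aln$ids
  if (anyDuplicated(nm)) stop("state names not unique; dedup or use by = 'id'")
  character_state_map(
    stats::setNames(aln$matrix[, column + 1L] == residue, nm),
    label = label %||% paste0(residue, "@", aln$column_provenance[column + 1L]))
}

#' Co-divergence of a candidate character with the focal character
#'
#' Compares change-edge sets of two parsimony reconstructions on the same
#' tree. With the strict default the overlap is the Jaccard index of
#' `change_edges_always`: `co-diverged` iff the sets are identical and
#' non-empty ("diverged at approximately the same time"), and
#' `alternative-timing` iff both are non-empty but disjoint (changes at
#' alternative points in time). Everything else — partial overlap, or a
#' candidate with no change edges — is `correlated-only`. `relax_k > 0`
#' expands each change-edge set to its k-step edge neighborhood before the
#' comparison.
#'
#' @param focal,candidate `parsimony_reconstruction`s on the same tree.
#' @param tree The common tree (needed only when `relax_k > 0`).
#' @param relax_k Edge-neighborhood radius (default 0, strict).
#' @return data.frame row: `candidate`, `jaccard`, `category`,
#'   `n_focal_edges`, `n_candidate_edges`.
#' @export
codivergence <- function(focal, candidate, tree = NULL, relax_k = 0L) {
  stopifnot(inherits(focal, "parsimony_reconstruction"),
            inherits(candidate, "parsimony_reconstruction"))
  if (!identical(focal$tree_key, candidate$tree_key)) {
    stop("reconstructions are on different trees")
  }
  A <- focal$change_edges_always
  B <- candidate$change_edges_always
  if (relax_k > 0) {
    if (is.null(tree)) stop("tree required for relaxed matching")
    A <- expand_edge_set(tree, A, relax_k)
    B <- expand_edge_set(tree, B, relax_k)
  }
  u <- union(A, B)
  jac <- if (length(u) == 0) 0 else length(intersect(A, B)) / length(u)
  category <- if (length(A) && length(B) && jac == 1) {
    "co-diverged"
  } else if (length(A) && length(B) && jac == 0) {
    "alternative-timing"
  } else {
    "correlated-only"
  }
  data.frame(candidate = candidate$label, jaccard = jac, category = category,
             n_focal_edges = length(A), n_candidate_edges = length(B),
             stringsAsFactors = FALSE)
}

# Expand a set of edge ids to all edges within k steps in the tree.
expand_edge_set <- function(tree, ids_in, k) {
  eids <- edge_ids(tree)
  adj <- lapply(seq_len(nrow(tree$edge)), function(e) {
    nodes <- tree$edge[e, ]
    which(tree$edge[, 1] %in% nodes | tree$edge[, 2] %in% nodes)
  })
  cur <- which(eids %in% ids_in)
  seen <- cur
  for (step in seq_len(k)) {
    cur <- setdiff(unique(unlist(adj[cur])), seen)
    if (!length(cur)) break
    seen <- c(seen, cur)
  }
  sort(eids[seen])
}
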