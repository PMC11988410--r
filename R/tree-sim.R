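# Species-tree simulation and edge identifiers.

#' Simulate a rooted binary species tree
#'
#' Generates the species tree that a histone family is evolved along. Three
#' shapes are available: `"yule"` draws a forward pure-birth (Yule) tree with
#' exponential waiting times and a uniformly chosen splitting lineage, so the
#' number of leaves under each root child is uniform on `1..n-1`;
#' `"balanced"` is the maximally balanced shape with unit branch lengths;
#' `"caterpillar"` is the pectinate ladder with unit branch lengths.
#'
#' @param n_species Number of leaves, at least 3.
#' @param tree_model One of `"yule"`, `"balanced"`, `"caterpillar"`.
#' @param seed Integer seed; identical `(n_species, tree_model, seed)` give
#'   identical trees. Ignored by the deterministic shapes.
#' @return A rooted, binary `ape::phylo` with positive branch lengths and
#'   stable leaf names `t001, t002, ...`.
#' @export
simulate_tree <- function(n_species, tree_model = c("yule", "balanced", "caterpillar"),
                          seed = 1L) {
  tree_model <- match.arg(tree_model)
  if (!is.numeric(n_species) || n_species < 3) {
    stop("n_species must be at least 3")
  }
  n <- as.integer(n_species)
  labels <- sprintf("t%03d", seq_len(n))
  nwk <- switch(tree_model,
    yule = with_seed(seed, yule_newick(n, labels)),
    balanced = balanced_newick(labels),
    caterpillar = caterpillar_newick(labels)
  )
  tr <- ape::read.tree(text = nwk)
  stopifnot(ape::is.binary(tr), ape::is.rooted(tr))
  tr
}

# Forward Yule construction; every active lineage is a growing tip.
yule_newick <- function(n, labels) {
  parent <- c(NA_integer_, 1L, 1L)   # node 1 = root with two children
  birth <- c(0, 0, 0)
  elen <- c(NA_real_, NA_real_, NA_real_)
  active <- c(2L, 3L)
  t_now <- 0
  nxt <- 4L
  while (length(active) < n) {
    k <- length(active)
    t_now <- t_now + stats::rexp(1, rate = k)
    victim <- active[sample.int(k, 1L)]
    elen[victim] <- t_now - birth[victim]
    for (child in c(nxt, nxt + 1L)) {
      parent[child] <- victim
      birth[child] <- t_now
      elen[child] <- NA_real_
    }
    active <- c(setdiff(active, victim), nxt, nxt + 1L)
    nxt <- nxt + 2L
  }
  t_now <- t_now + stats::rexp(1, rate = n)
  elen[active] <- t_now - birth[active]
  # Positive lengths are guaranteed by the exponential waits; tiny floor for safety.
  elen <- pmax(elen, 1e-9)
  tip_label <- rep(NA_character_, length(parent))
  tip_label[sort(active)] <- labels
  children <- split(seq_along(parent)[-1], parent[-1])
  rec <- function(v) {
    kids <- children[[as.character(v)]]
    core <- if (is.null(kids)) {
      tip_label[v]
    } else {
      paste0("(", rec(kids[1]), ",", rec(kids[2]), ")")
    }
    if (v == 1L) paste0(core, ";") else paste0(core, ":", sprintf("%.10g", elen[v]))
  }
  rec(1L)
}

balanced_newick <- function(labels) {
  rec <- function(lab) {
    if (length(lab) == 1) return(paste0(lab, ":1"))
    h <- ceiling(length(lab) / 2)
    paste0("(", rec(lab[seq_len(h)]), ",", rec(lab[-seq_len(h)]), "):1")
  }
  h <- ceiling(length(labels) / 2)
  paste0("(", rec(labels[seq_len(h)]), ",", rec(labels[-seq_len(h)]), ");")
}

caterpillar_newick <- function(labels) {
  n <- length(labels)
  core <- paste0("(", labels[n - 1], ":1,", labels[n], ":1):1")
  for (i in rev(seq_len(n - 2))) {
    tail <- if (i == 1) ");" else "):1"
    core <- paste0("(", labels[i], ":1,", core, tail)
  }
  if (n == 2) core <- paste0("(", labels[1], ":1,", labels[2], ":1);")
  core
}

#' Stable edge identifiers for a rooted tree
#'
#' Each edge is identified by the canonical (sorted, comma-joined) set of leaf
#' names below its child node. The identifier is stable across serialization
#' and re-reading of the tree, and is how planted switch edges, parsimony
#' change edges and co-divergence comparisons refer to branches.
#'
#' @param tree `ape::phylo`.
#' @return Character vector, one id per row of `tree$edge`.
#' @export
edge_ids <- function(tree) {
  n_tip <- length(tree$tip.label)
  below <- clade_leaf_sets(tree)
  vapply(tree$edge[, 2], function(child) {
    paste(sort(below[[child]]), collapse = ",")
  }, character(1))
}

# Leaf-name sets below every node (tips included), indexed by node number.
clade_leaf_sets <- function(tree) {
  n_tip <- length(tree$tip.label)
  n_node <- n_tip + tree$Nnode
  below <- vector("list", n_node)
  for (i in seq_len(n_tip)) below[[i]] <- tree$tip.label[i]
  ord <- rev(ape::postorder(tree))  # we need children before parents: postorder
  for (e in ape::postorder(tree)) {
    p <- tree$edge[e, 1]; c <- tree$edge[e, 2]
    below[[p]] <- c(below[[p]], below[[c]])
  }
  below
}

#' Edge identifier of the stem edge of a clade
#'
#' @param tree `ape::phylo`.
#' @param tip_names Leaf names spanning the clade exactly.
#' @return The edge id (see [edge_ids()]) whose child clade is `tip_names`.
#' @export
clade_edge <- function(tree, tip_names) {
  id <- paste(sort(tip_names), collapse = ",")
  ids <- edge_ids(tree)
  if (!id %in% ids) stop("no edge subtends exactly the clade {", id, "}")
  id
}
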