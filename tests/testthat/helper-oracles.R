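# Independent oracles: deliberately naive re-implementations used only to
# cross-check the package's optimized code paths.

# Exhaustive parsimony: try every assignment of states to internal nodes and
# count change edges directly.
oracle_fitch_min_changes <- function(tree, states) {
  n_tip <- length(tree$tip.label)
  n_int <- tree$Nnode
  leaf_state <- states[tree$tip.label]
  best <- Inf
  for (mask in 0:(2^n_int - 1)) {
    int_states <- ifelse(bitwAnd(mask, 2^(seq_len(n_int) - 1)) > 0,
                         "present", "absent")
    all_states <- c(leaf_state, int_states)
    changes <- sum(all_states[tree$edge[, 1]] != all_states[tree$edge[, 2]])
    if (changes < best) best <- changes
  }
  best
}

# All rooted binary tree shapes on n leaves (Wedderburn-Etherington
# enumeration), as newick strings with unit branch lengths and leaves
# labelled in left-to-right order.
all_tree_shapes <- function(n) {
  shapes <- function(k) {
    if (k == 1) return("L")
    out <- character(0)
    for (a in 1:(k %/% 2)) {
      left <- shapes(a)
      right <- shapes(k - a)
      for (li in seq_along(left)) {
        for (rj in seq_along(right)) {
          if (a == k - a && rj < li) next  # mirror duplicate
          out <- c(out, paste0("(", left[li], ",", right[rj], ")"))
        }
      }
    }
    unique(out)
  }
  lapply(shapes(n), function(s) {
    i <- 0
    labelled <- gsub("L", "@", s)
    while (grepl("@", labelled)) {
      i <- i + 1
      labelled <- sub("@", sprintf("x%02d:1", i), labelled)
    }
    labelled <- gsub(")", "):1", labelled, fixed = TRUE)
    labelled <- sub(":1$", ";", labelled)
    ape::read.tree(text = labelled)
  })
}

# Pair-enumeration GroupSim: explicit double loops over residue pairs.
oracle_groupsim <- function(column, group_a, group_b, norm_sim,
                            gap_ceiling = 0.5) {
  pair_mean <- function(res1, res2, within) {
    vals <- c()
    if (within) {
      k <- length(res1)
      if (k >= 2) {
        for (i in 1:(k - 1)) for (j in (i + 1):k) {
          vals <- c(vals, norm_sim[res1[i], res1[j]])
        }
      }
    } else {
      for (i in seq_along(res1)) for (j in seq_along(res2)) {
        vals <- c(vals, norm_sim[res1[i], res2[j]])
      }
    }
    mean(vals)
  }
  ra <- column[group_a]; rb <- column[group_b]
  gap_a <- mean(ra == "-"); gap_b <- mean(rb == "-")
  ra <- ra[ra != "-"]; rb <- rb[rb != "-"]
  if (gap_a > gap_ceiling || gap_b > gap_ceiling ||
      length(ra) < 2 || length(rb) < 2) {
    return(NA_real_)
  }
  wa <- pair_mean(ra, NULL, TRUE)
  wb <- pair_mean(rb, NULL, TRUE)
  btw <- pair_mean(ra, rb, FALSE)
  ((wa + wb) / 2) * (1 - btw)
}

# Brute-force affine local alignment: memoized recursion written
# independently of the C++ dynamic program (suffix-based, explicit states).
oracle_local_align <- function(emis, target_idx, gap_open, gap_extend) {
  P <- nrow(emis); Tn <- length(target_idx)
  memo <- new.env()
  # best score of an alignment that starts by matching target i to column j
  # and extends to the right; state: 0 entering a match at (i, j)
  extend <- function(i, j) {
    key <- paste(i, j)
    if (!is.null(memo[[key]])) return(memo[[key]])
    aa <- target_idx[i]
    e <- if (!is.na(aa) && aa >= 1) unname(emis[j, aa]) else 0
    best <- e   # stop here
    # continue with a match at (i + di, j + dj); the skipped residues /
    # columns in between form insertion / deletion runs
    for (ni in (i + 1):(Tn + 1)) {
      if (ni > Tn) break
      for (nj in (j + 1):(P + 1)) {
        if (nj > P) break
        ins <- ni - i - 1   # inserted target residues
        del <- nj - j - 1   # deleted profile columns
        pen <- 0
        if (ins > 0) pen <- pen + gap_open + (ins - 1) * gap_extend
        if (del > 0) pen <- pen + gap_open + (del - 1) * gap_extend
        cand <- e - pen + extend(ni, nj)
        if (cand > best) best <- cand
      }
    }
    memo[[key]] <- best
    best
  }
  best <- 0
  for (i in seq_len(Tn)) for (j in seq_len(P)) {
    s <- extend(i, j)
    if (s > best) best <- s
  }
  best
}

random_profile <- function(n_cols, seed_rows = 3) {
  aln <- matrix(sample(histrace::AA_ALPHABET20, n_cols * seed_rows,
                       replace = TRUE),
                nrow = seed_rows)
  rownames(aln) <- paste0("s", seq_len(seed_rows))
  build_profile(aln, pseudocount = 1)
}
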