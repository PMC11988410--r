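test_that("Poisson-corrected distances follow the closed form", {
  m <- rbind(a = rep("A", 20), b = rep("A", 20), c = rep("A", 20))
  m["b", 1:2] <- "C"                      # p = 0.1
  aln <- stacked_alignment(m, species = c("s1", "s2", "s3"))
  D <- pairwise_distance(aln)
  expect_equal(D["a", "b"], -log(0.9))
  expect_equal(D["a", "c"], 0)
  expect_true(isSymmetric(D))
  expect_equal(unname(diag(D)), rep(0, 3))
  # saturated pairs are capped with a warning
  m2 <- m; m2["b", ] <- rep("W", 20)
  aln2 <- stacked_alignment(m2, species = c("s1", "s2", "s3"))
  w <- capture_warnings(D2 <- pairwise_distance(aln2))
  expect_true(length(w) >= 1 && all(grepl("saturated", w)))
  expect_equal(D2["a", "b"], 5)
  # insufficient overlap errors with the pair named
  m3 <- m; m3["b", 1:15] <- "-"
  aln3 <- stacked_alignment(m3, species = c("s1", "s2", "s3"))
  expect_error(pairwise_distance(aln3, min_overlap = 10), "a / b")
})

test_that("neighbor joining solves the 3-taxon closed form", {
  D <- matrix(c(0, 3, 4, 3, 0, 5, 4, 5, 0), 3, 3,
              dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  tr <- neighbor_joining(D)
  # three-point formulas: la = (dab + dac - dbc)/2, etc.
  bl <- stats::setNames(tr$edge.length, tr$tip.label[tr$edge[, 2]])
  expect_equal(unname(bl[c("a", "b", "c")]), c(1, 2, 3))
  expect_error(neighbor_joining(matrix(c(0, 1, 2, 0), 2, 2)), "3 taxa")
  Dbad <- D; Dbad[1, 2] <- 99
  expect_error(neighbor_joining(Dbad), "symmetric")
})

test_that("NJ recovers generating topologies from additive distances", {
  set.seed(55)
  for (i in 1:20) {
    n <- sample(5:12, 1)
    tr <- simulate_tree(n, "yule", seed = 1000 + i)
    D <- ape::cophenetic.phylo(tr)
    rec <- neighbor_joining(D[tr$tip.label, tr$tip.label])
    expect_equal(ape::dist.topo(ape::unroot(tr), ape::unroot(rec)), 0,
                 ignore_attr = TRUE)
  }
})

test_that("Fitch matches the exhaustive oracle on every small shape", {
  # every rooted binary shape on 3..6 leaves x every leaf assignment;
  # leaf relabeling permutes the assignment set, so this covers all trees
  for (n in 3:6) {
    for (tr in all_tree_shapes(n)) {
      for (mask in 0:(2^n - 1)) {
        states <- ifelse(bitwAnd(mask, 2^(seq_len(n) - 1)) > 0,
                         "present", "absent")
        names(states) <- tr$tip.label
        rec <- fitch_parsimony(tr, states)
        expect_equal(rec$min_changes,
                     oracle_fitch_min_changes(tr, states),
                     info = paste("n", n, "mask", mask))
        # every enumerated labeling attains the minimum and the edge sets
        # are consistent
        expect_true(all(lengths(rec$change_sets) == rec$min_changes))
        expect_true(all(rec$change_edges_always %in% rec$change_edges_ever))
      }
    }
  }
})

test_that("Fitch change count is invariant to rerooting and leaf order", {
  skip_if_not_installed("phangorn")
  set.seed(9)
  for (i in 1:20) {
    tr <- simulate_tree(sample(4:10, 1), "yule", seed = 300 + i)
    n <- length(tr$tip.label)
    states <- sample(c("present", "absent"), n, replace = TRUE)
    names(states) <- tr$tip.label
    rec <- fitch_parsimony(tr, states)
    # independent implementation: phangorn's Fitch on the same data
    dat <- phangorn::phyDat(matrix(states, ncol = 1,
                                   dimnames = list(names(states), NULL)),
                            type = "USER", levels = c("present", "absent"))
    expect_equal(rec$min_changes,
                 as.integer(phangorn::fitch(tr, dat)))
    # reroot on a random tip as outgroup
    rerooted <- ape::root(ape::unroot(tr), outgroup = sample(tr$tip.label, 1),
                          resolve.root = TRUE)
    rec2 <- fitch_parsimony(rerooted, states)
    expect_equal(rec2$min_changes, rec$min_changes)
    # permute leaf order
    perm <- sample(names(states))
    expect_equal(fitch_parsimony(tr, states[perm])$min_changes,
                 rec$min_changes)
  }
})

test_that("constant characters need no changes; missing leaves error", {
  tr <- simulate_tree(6, "balanced")
  states <- stats::setNames(rep("present", 6), tr$tip.label)
  rec <- fitch_parsimony(tr, states)
  expect_equal(rec$min_changes, 0L)
  expect_length(rec$change_edges_ever, 0)
  expect_length(rec$mp_labelings, 1)
  expect_error(fitch_parsimony(tr, states[-1]), "missing leaf state")
})

test_that("co-divergence categories follow change-edge overlap", {
  tr <- scenario_backbone_tree()
  st <- scenario_backbone_states()$states
  rec <- fitch_parsimony(tr, character_state_map(st, "H3C110"))
  same <- fitch_parsimony(tr, character_state_map(st, "companion"))
  expect_identical(codivergence(rec, same)$category, "co-diverged")
  expect_equal(codivergence(rec, same)$jaccard, 1)
  # a character changing only on a disjoint (non-root-adjacent) edge
  st2 <- st; st2[] <- "present"; st2["Saccharomycotina_other"] <- "absent"
  other <- fitch_parsimony(tr, character_state_map(st2, "alt"))
  expect_identical(codivergence(rec, other)$category, "alternative-timing")
  expect_equal(codivergence(rec, other)$jaccard, 0)
  # no change edges at all -> correlated-only by convention
  st3 <- st; st3[] <- "present"
  none <- fitch_parsimony(tr, character_state_map(st3, "flat"))
  expect_identical(codivergence(rec, none)$category, "correlated-only")
  expect_equal(codivergence(rec, none)$jaccard, 0)
  # different trees are refused
  tr2 <- simulate_tree(8, "balanced")
  st4 <- stats::setNames(sample(c("present", "absent"), 8, replace = TRUE),
                         tr2$tip.label)
  rec2 <- fitch_parsimony(tr2, st4)
  expect_error(codivergence(rec, rec2), "different trees")
})

test_that("relaxed matching tolerates adjacent change edges", {
  tr <- simulate_tree(8, "caterpillar")
  tips <- tr$tip.label
  # character 1 changes on the stem of {t5..t8}; character 2 on {t4..t8}
  mk <- function(absent) {
    s <- stats::setNames(rep("present", 8), tips)
    s[absent] <- "absent"
    fitch_parsimony(tr, s)
  }
  r1 <- mk(tips[5:8]); r2 <- mk(tips[4:8])
  strict <- codivergence(r1, r2)
  expect_identical(strict$category, "alternative-timing")
  relaxed <- codivergence(r1, r2, tree = tr, relax_k = 1)
  expect_gt(relaxed$jaccard, 0)
})
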