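test_that("simulated trees are binary, rooted, deterministic under a seed", {
  tr <- simulate_tree(8, "yule", seed = 1)
  expect_true(ape::is.binary(tr))
  expect_true(ape::is.rooted(tr))
  expect_equal(length(tr$tip.label), 8)
  expect_true(all(tr$edge.length > 0))
  expect_identical(ape::write.tree(tr),
                   ape::write.tree(simulate_tree(8, "yule", seed = 1)))
  expect_false(identical(ape::write.tree(tr),
                         ape::write.tree(simulate_tree(8, "yule", seed = 2))))
  expect_error(simulate_tree(2, "yule"), "at least 3")
})

test_that("a 3-leaf tree has the unique rooted shape", {
  for (m in c("yule", "balanced", "caterpillar")) {
    tr <- simulate_tree(3, m, seed = 5)
    expect_equal(tr$Nnode, 2)
    expect_equal(length(tr$tip.label), 3)
  }
})

test_that("yule root splits follow the uniform split law", {
  # For a Yule tree on n leaves the number of leaves under one root child is
  # uniform on 1..n-1 (mean n/2, sd ~ (n-2)/sqrt(12)).
  n <- 50
  splits <- vapply(1:200, function(s) {
    tr <- simulate_tree(n, "yule", seed = s)
    root_children <- tr$edge[tr$edge[, 1] == n + 1, 2]
    kid <- root_children[1]
    if (kid <= n) 1L else length(ape::extract.clade(tr, kid)$tip.label)
  }, integer(1))
  mu <- mean(splits)
  se <- sqrt((n - 2)^2 / 12) / sqrt(200)
  expect_lt(abs(mu - n / 2), 4 * se)
  # both extremes occur: cherries next to the root and near-even splits
  expect_gt(length(unique(splits)), 10)
})

test_that("zero rates and no plants propagate the root sequence unchanged", {
  tr <- simulate_tree(6, "balanced")
  cfg <- sim_config(n_species = 6, seq_length = 40, subst_rate = 0,
                    indel_rate = 0, seed = 3)
  ds <- simulate_family(tr, cfg)
  aln <- ds$sequences$aln
  expect_true(all(apply(aln, 2, function(col) length(unique(col)) == 1)))
})

test_that("planted columns follow the truth table for every seed", {
  tr <- simulate_tree(10, "yule", seed = 11)
  clade <- ape::extract.clade(tr, 14)$tip.label   # an internal clade
  edge <- clade_edge(tr, clade)
  for (s in 1:20) {
    cfg <- sim_config(n_species = 10, seq_length = 120, subst_rate = 0.05,
                      planted_columns = list(plant_spec(109L, "A", "C", edge)),
                      seed = s)
    ds <- simulate_family(tr, cfg)
    obs <- ds$sequences$aln[, 110]
    names(obs) <- ds$sequences$species
    expect_true(all(obs[clade] == "C"))
    expect_true(all(obs[setdiff(tr$tip.label, clade)] == "A"))
    truth <- ds$truth$leaf_states
    expect_identical(unname(obs[truth$leaf]), truth$state)
  }
})

test_that("switch edges toggle through gain/loss/reversion chains", {
  tr <- scenario_backbone_tree()
  fungi <- c("chytrid_like", "mucoromycete_like", "basidiomycete_like",
             "Pezizomycotina", "Saccharomycotina_other", "Saccharomycetaceae")
  asco <- c("Pezizomycotina", "Saccharomycotina_other", "Saccharomycetaceae")
  edges <- c(clade_edge(tr, fungi), clade_edge(tr, asco),
             clade_edge(tr, "Saccharomycetaceae"))
  cfg <- sim_config(n_species = 8, seq_length = 135, subst_rate = 0,
                    planted_columns = list(plant_spec(109L, "C", "A", edges)),
                    seed = 1)
  ds <- simulate_family(tr, cfg)
  obs <- ds$sequences$aln[, 110]
  names(obs) <- ds$sequences$species
  expect_identical(unname(obs[c("outgroup", "Cryptomycota")]), c("C", "C"))
  expect_identical(unname(obs[c("chytrid_like", "basidiomycete_like")]), c("A", "A"))
  expect_identical(unname(obs[c("Pezizomycotina", "Saccharomycotina_other")]), c("C", "C"))
  expect_identical(unname(obs["Saccharomycetaceae"]), "A")
})

test_that("substitution counts calibrate to rate x tree length", {
  # low per-path divergence, so multiple hits are negligible and the
  # root-to-leaf difference count estimates the substitution count
  tr <- simulate_tree(6, "caterpillar")
  cfg <- sim_config(n_species = 6, seq_length = 2000, subst_rate = 0.01,
                    seed = 17)
  ds <- simulate_family(tr, cfg)
  # the zero-rate run with the same seed exposes the identical root sequence
  cfg0 <- sim_config(n_species = 6, seq_length = 2000, subst_rate = 0,
                     seed = 17)
  root_seq <- simulate_family(tr, cfg0)$sequences$aln[1, ]
  depths <- ape::node.depth.edgelength(tr)[1:6]
  expected <- sum(0.01 * depths)    # per-site differences, summed over leaves
  obs <- sum(vapply(1:6, function(i) {
    mean(ds$sequences$aln[i, ] != root_seq)
  }, numeric(1)))
  se <- sqrt(expected * 2000) / 2000
  # small downward bias from multiple hits; 2% allowance
  expect_lt(abs(obs - expected), 3 * se + 0.02 * expected)
})

test_that("fixtures round-trip losslessly and are byte-identical per seed", {
  tr <- simulate_tree(5, "yule", seed = 2)
  cfg <- sim_config(n_species = 5, seq_length = 60, subst_rate = 0.1,
                    indel_rate = 0.002, seed = 4)
  ds <- simulate_family(tr, cfg)
  d1 <- file.path(tempdir(), "fx1"); d2 <- file.path(tempdir(), "fx2")
  write_fixture(ds, tr, d1)
  write_fixture(simulate_family(tr, cfg), tr, d2)
  back <- read_fixture(d1)
  expect_identical(back$sequences$aln, ds$sequences$aln)
  expect_identical(back$sequences$species, ds$sequences$species)
  expect_identical(sort(back$tree$tip.label), sort(tr$tip.label))
  f1 <- list.files(d1, recursive = TRUE)
  expect_identical(f1, list.files(d2, recursive = TRUE))
  for (f in f1) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     info = f)
  }
  expect_error(write_fixture(list(sequences = NULL), tr, tempdir()),
               "non-empty")
})

test_that("paralog duplication produces a labelled faster subfamily", {
  tr <- simulate_tree(8, "balanced")
  dup_clade <- sprintf("t%03d", 1:4)
  cfg <- sim_config(n_species = 8, seq_length = 100, subst_rate = 0.05,
                    paralog_spec = paralog_spec(clade_edge(tr, dup_clade),
                                                rate_multiplier = 3),
                    seed = 9)
  ds <- simulate_family(tr, cfg)
  expect_equal(sum(ds$sequences$family == "cen"), 4)
  expect_equal(sum(ds$sequences$family == "core"), 8)
  expect_setequal(ds$sequences$species[ds$sequences$family == "cen"], dup_clade)
})

test_that("invalid configurations are rejected", {
  expect_error(sim_config(seq_length = 0), "seq_length")
  expect_error(sim_config(subst_rate = -1), "non-negative")
  expect_error(sim_config(planted_columns = list(plant_spec(200L, "A", "C", "e")),
                          seq_length = 135), "planted column")
  expect_error(plant_spec(1, "A", "A", "e"), "must differ")
  tr <- simulate_tree(4, "balanced")
  cfg <- sim_config(planted_columns = list(plant_spec(3L, "A", "C", "no,such,clade")),
                    seq_length = 10)
  expect_error(simulate_family(tr, cfg), "absent from tree")
})
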