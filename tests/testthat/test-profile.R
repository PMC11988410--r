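test_that("profile emissions match the hand-computed log-odds on a toy seed", {
  aln <- rbind(c("A", "C"), c("A", "C"), c("A", "G"), c("C", "G"))
  rownames(aln) <- paste0("s", 1:4)
  bg <- rep(1 / 20, 20); names(bg) <- AA_ALPHABET20
  p <- build_profile(aln, pseudocount = 0.5, background = bg)
  # column 1: counts A=3, C=1, n=4; e_A = log2((3 + 0.5/20) / 4.5 / 0.05)
  expect_equal(unname(p$emissions[1, "A"]), log2((3 + 0.5 / 20) / 4.5 / 0.05))
  expect_equal(unname(p$emissions[1, "C"]), log2((1 + 0.5 / 20) / 4.5 / 0.05))
  expect_equal(unname(p$emissions[1, "G"]), log2((0.5 / 20) / 4.5 / 0.05))
  expect_equal(unname(p$emissions[2, "G"]), log2((2 + 0.5 / 20) / 4.5 / 0.05))
})

test_that("a single-sequence seed approaches consensus log-odds as pseudocount vanishes", {
  aln <- matrix(c("W", "C", "A"), nrow = 1)
  rownames(aln) <- "only"
  p <- build_profile(aln, pseudocount = 1e-9)
  bg <- default_background()
  expect_equal(unname(p$emissions[1, "W"]), log2(1 / bg[["W"]]), tolerance = 1e-6)
  expect_equal(unname(p$emissions[2, "C"]), log2(1 / bg[["C"]]), tolerance = 1e-6)
})

test_that("duplicating seed rows leaves observed-residue emissions unchanged", {
  # frequencies are what matter: as the pseudocount vanishes, emissions of
  # observed residues depend only on column proportions, not row counts
  aln <- rbind(c("A", "C", "W"), c("G", "C", "W"))
  rownames(aln) <- c("a", "b")
  dup <- rbind(aln, aln)
  rownames(dup) <- c("a", "b", "c", "d")
  p1 <- build_profile(aln, pseudocount = 1e-9)
  p2 <- build_profile(dup, pseudocount = 1e-9)
  for (j in 1:3) {
    obs <- unique(aln[, j])
    expect_equal(p1$emissions[j, obs], p2$emissions[j, obs], tolerance = 1e-6)
  }
  expect_identical(profile_consensus(p1), profile_consensus(p2))
})

test_that("match columns follow the seed gap ceiling and ragged seeds error", {
  aln <- rbind(c("A", "-", "C"), c("A", "-", "-"), c("A", "G", "C"),
               c("A", "G", "C"))
  rownames(aln) <- paste0("s", 1:4)
  p <- build_profile(aln, max_gap = 0.5)
  expect_equal(p$n_columns, 3)          # 50% gaps is still a match column
  p2 <- build_profile(aln, max_gap = 0.4)
  expect_equal(p2$match_cols, c(0L, 2L))
  expect_error(build_profile(matrix(character(0), 0, 0)), "non-empty")
})

test_that("the consensus attains the sum of per-column maxima, gaplessly", {
  p <- random_profile(12)
  cons <- profile_consensus(p)
  h <- score_sequence(p, cons)
  expect_equal(h$raw_score, sum(apply(p$emissions, 1, max)))
  expect_false(any(h$column_map == "-"))
  expect_equal(h$target_interval, c(0L, 12L))
  rev_cons <- paste(rev(strsplit(cons, "")[[1]]), collapse = "")
  expect_lt(score_sequence(p, rev_cons)$raw_score, h$raw_score)
})

test_that("deleting one consensus column costs its emission plus gap_open", {
  set.seed(42)
  p <- random_profile(8)
  cons <- strsplit(profile_consensus(p), "")[[1]]
  full <- score_sequence(p, paste(cons, collapse = ""))$raw_score
  k <- 4
  del <- paste(cons[-k], collapse = "")
  expect_equal(score_sequence(p, del)$raw_score,
               full - max(p$emissions[k, ]) - p$gap_open)
})

test_that("local alignment equals the brute-force oracle on random instances", {
  set.seed(101)
  n_ok <- 0
  for (case in 1:500) {
    P <- sample(2:8, 1); Tn <- sample(2:12, 1)
    p <- random_profile(P)
    target <- sample(AA_ALPHABET20, Tn, replace = TRUE)
    h <- score_sequence(p, paste(target, collapse = ""))
    want <- oracle_local_align(p$emissions, match(target, AA_ALPHABET20),
                               p$gap_open, p$gap_extend)
    expect_equal(h$raw_score, want, tolerance = 1e-9,
                 info = paste("case", case))
    # re-scoring the column map reproduces the raw score exactly
    expect_equal(rescore_hit(p, h), h$raw_score, tolerance = 1e-9)
    n_ok <- n_ok + 1
  }
  expect_equal(n_ok, 500)
})

test_that("appending residues never decreases the best local score", {
  set.seed(7)
  p <- random_profile(6)
  for (i in 1:50) {
    base <- paste(sample(AA_ALPHABET20, 8, replace = TRUE), collapse = "")
    longer <- paste0(base, paste(sample(AA_ALPHABET20, 3, replace = TRUE),
                                 collapse = ""))
    expect_gte(score_sequence(p, longer)$raw_score,
               score_sequence(p, base)$raw_score)
  }
})

test_that("calibration is deterministic and centres the fit on the decoys", {
  p <- random_profile(20)
  c1 <- calibrate_significance(p, length_model = 50, n_decoys = 200, seed = 5)
  c2 <- calibrate_significance(p, length_model = 50, n_decoys = 200, seed = 5)
  expect_identical(c1, c2)
  expect_gte(c1$threshold_bits, max(c1$decoy_scores))
  # at the decoy median the expected count of higher-scoring decoys is ~ n/2
  ev_med <- evalue_like(c1, stats::median(c1$decoy_scores))
  expect_gt(ev_med, 0.35 * 200)
  expect_lt(ev_med, 0.65 * 200)
  expect_error(calibrate_significance(p, 50, n_decoys = 50), "at least 100")
})

test_that("search applies the length filter and significance threshold", {
  seed_aln <- scenario_seed_alignment()
  p <- build_profile(seed_aln, id = "synthetic-seed")
  calib <- calibrate_significance(p, length_model = 135, n_decoys = 200,
                                  seed = 2)
  cons <- profile_consensus(p)
  long_prot <- paste0(cons, paste(rep("A", 301 - nchar(cons)), collapse = ""))
  stopifnot(nchar(long_prot) == 301)
  prot300 <- substr(long_prot, 1, 300)
  res <- search_proteome(p, c(too_long = long_prot, ok = prot300), calib,
                         max_len = 300)
  expect_equal(vapply(res, `[[`, character(1), "protein_id"), "ok")
  expect_identical(search_proteome(p, character(0), calib), list())
  # mismatched calibration is refused
  other <- random_profile(10)
  expect_error(search_proteome(other, c(x = cons), calib), "does not match")
})

test_that("calibrated search separates homologs from fresh decoys", {
  seed_aln <- scenario_seed_alignment()
  p <- build_profile(seed_aln, id = "synthetic-seed")
  calib <- calibrate_significance(p, length_model = 135, n_decoys = 200,
                                  seed = 11)
  fresh <- simulate_decoys(300, 135, seed = 987L)
  fresh_hits <- search_proteome(p, fresh, calib)
  expect_length(fresh_hits, 0)
  hom <- scenario_homologs(divergence = 0.3, n_species = 16, seed = 13)
  hom_hits <- search_proteome(p, hom, calib)
  expect_gte(length(hom_hits), 16 * 0.99)
})
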