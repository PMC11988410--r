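SIM <- normalize_similarity()

test_that("normalized BLOSUM62 similarity has the documented range and diagonal", {
  m <- SIM$normalized
  expect_true(isSymmetric(unname(m)))
  expect_equal(min(m), 0)
  expect_equal(max(m), 1)
  expect_true(all(diag(m) == 1))
  expect_equal(m["C", "A"], 4 / 15)   # raw 0, range -4..11
})

test_that("hand-computed GroupSim values on two-vs-two columns", {
  part <- group_partition(c("a1", "a2"), c("b1", "b2"))
  # conserved C vs conserved A: within 1 and 1, between 4/15
  expect_equal(column_groupsim(c(a1 = "C", a2 = "C", b1 = "A", b2 = "A"),
                               part, SIM),
               1 - 4 / 15)
  # a fully conserved column carries no group-specific signal
  expect_equal(column_groupsim(c(a1 = "A", a2 = "A", b1 = "A", b2 = "A"),
                               part, SIM), 0)
  # identical mixtures: agrees with the pair-enumeration oracle
  col <- c(a1 = "C", a2 = "A", b1 = "C", b2 = "A")
  expect_equal(column_groupsim(col, part, SIM),
               oracle_groupsim(col, c("a1", "a2"), c("b1", "b2"),
                               SIM$normalized))
})

test_that("GroupSim agrees with the pair-enumeration oracle on random columns", {
  set.seed(2024)
  ids_all <- paste0("r", 1:12)
  for (case in 1:500) {
    n <- sample(4:12, 1)
    ids <- ids_all[1:n]
    na <- sample(2:(n - 2), 1)
    ga <- ids[1:na]; gb <- ids[(na + 1):n]
    col <- sample(c(AA_ALPHABET20, "-"), n, replace = TRUE,
                  prob = c(rep(0.9 / 20, 20), 0.1))
    names(col) <- ids
    part <- group_partition(ga, gb)
    got <- column_groupsim(col, part, SIM)
    want <- oracle_groupsim(col, ga, gb, SIM$normalized)
    if (is.na(want)) {
      expect_true(is.na(got))
    } else {
      expect_equal(got, want, tolerance = 1e-12)
      expect_gte(got, 0); expect_lte(got, 1)
      # swapping the groups leaves the score unchanged
      expect_equal(column_groupsim(col, group_partition(gb, ga), SIM), got,
                   tolerance = 1e-12)
      # permuting rows within groups leaves the score unchanged
      perm <- c(sample(ga), sample(gb))
      expect_equal(column_groupsim(col[perm], group_partition(ga, gb), SIM),
                   got, tolerance = 1e-12)
    }
  }
})

test_that("score decreases as the between-group pair becomes more similar", {
  part <- group_partition(c("a1", "a2"), c("b1", "b2"))
  s_of <- function(x) column_groupsim(
    c(a1 = "C", a2 = "C", b1 = x, b2 = x), part, SIM)
  # order candidate residues by their similarity to C; s must reverse it
  cand <- c("W", "A", "S", "C")
  sims <- SIM$normalized["C", cand]
  scores <- vapply(cand, s_of, numeric(1))
  expect_identical(order(sims), order(-scores))
})

test_that("column z-scores standardize within the family", {
  mk <- function(cols) {
    m <- do.call(cbind, cols)
    rownames(m) <- c("a1", "a2", "b1", "b2")
    stacked_alignment(m, species = rownames(m))
  }
  part <- group_partition(c("a1", "a2"), c("b1", "b2"))
  # two scored columns with s = 0 and s = 1 - 4/15: z = -1, +1
  aln <- mk(list(c("A", "A", "A", "A"), c("C", "C", "A", "A")))
  gs <- score_alignment(aln, part)
  expect_equal(gs$z, c(-1, 1))
  # all-identical columns: zero variance, z = 0 everywhere, nothing flagged
  aln0 <- mk(list(c("A", "A", "A", "A"), c("W", "W", "W", "W"),
                  c("C", "C", "C", "C")))
  gs0 <- score_alignment(aln0, part)
  expect_true(all(gs0$score == 0))
  expect_true(all(gs0$z == 0))
  expect_false(any(gs0$flagged))
  # mean 0, population SD 1 on a real-sized alignment
  sc <- scenario_two_groups(seed = 3)
  ds <- simulate_family(sc$tree, sc$config)
  big <- as_stacked_alignment(ds$sequences)
  bp <- group_partition(paste0(sc$partition$group_a, "_core"),
                        paste0(sc$partition$group_b, "_core"))
  z <- score_alignment(big, bp)$z
  z <- z[!is.na(z)]
  expect_lt(abs(mean(z)), 1e-9)
  expect_lt(abs(sqrt(mean(z^2)) - 1), 1e-9)
})

test_that("focal-residue classification honours the aligned window", {
  row <- rep("A", 30)
  expect_equal(classify_focal_residue(replace(row, 15, "C"), 14L), "present")
  expect_equal(classify_focal_residue(row, 14L), "absent")
  # boundary: offset +5 in, +6 out (0-based focal 14 -> columns 10..20)
  expect_equal(classify_focal_residue(replace(row, 20, "C"), 14L), "present")
  expect_equal(classify_focal_residue(replace(row, 21, "C"), 14L), "absent")
  expect_equal(classify_focal_residue(replace(row, 9, "C"), 14L), "absent")
  # gap columns count as positions by default, not when count_gaps = FALSE
  gappy <- replace(rep("A", 30), 15:19, "-")
  gappy[20] <- "C"
  expect_equal(classify_focal_residue(gappy, 14L), "present")
  expect_equal(classify_focal_residue(gappy, 14L, count_gaps = FALSE), "present")
  gappy[20] <- "-"; gappy[21] <- "C"   # 6 aligned positions away
  expect_equal(classify_focal_residue(gappy, 14L), "absent")
  expect_equal(classify_focal_residue(gappy, 14L, count_gaps = FALSE), "present")
  expect_error(classify_focal_residue(row, 30L), "out of range")
})

test_that("logo matrices count residues and information content correctly", {
  m <- rbind(one = strsplit("ACDEFGHIKLMNP", "")[[1]],
             two = strsplit("ACDEFGHIKLMNP", "")[[1]],
             b1 = strsplit("AAAAAAAAAAAAA", "")[[1]],
             b2 = strsplit("CCCCCCCCCCCCC", "")[[1]])
  aln <- stacked_alignment(m, species = rownames(m))
  part <- group_partition(c("one"), c("b1", "b2"), labels = c("ga", "gb"))
  lg <- logo_counts(aln, part, focal_column = 6L, flank = 5L)
  # single-row group: one-hot counts and maximal information content
  expect_true(all(colSums(lg$ga$counts) == 1))
  expect_equal(unname(lg$ga$ic), rep(log2(20), 11), tolerance = 1e-12)
  # 50/50 split: 1 bit of entropy below the maximum
  expect_equal(unname(lg$gb$ic[1]), log2(20) - 1)
  expect_equal(lg$ga$positions, 1:11)
  expect_warning(logo_counts(aln, part, focal_column = 2L), "truncated")
  expect_error(logo_counts(aln, part, focal_column = 99L), "out of range")
  # focal-column tallies agree with exact-position classification
  counts_c <- lg$gb$counts["C", "6"]
  direct <- sum(vapply(c("b1", "b2"), function(r) {
    classify_focal_residue(m[r, ], 6L, window = 0L, residue = "C") == "present"
  }, logical(1)))
  expect_equal(unname(counts_c), direct)
})

test_that("uniform residue usage gives zero information content", {
  m <- matrix(rep(AA_ALPHABET20, 2), ncol = 1)
  rownames(m) <- paste0("r", 1:40)
  aln <- stacked_alignment(m, species = rownames(m))
  part <- group_partition(paste0("r", 1:20), paste0("r", 21:40))
  lg <- logo_counts(aln, part, 0L, flank = 0L)
  expect_equal(unname(lg$group_a$ic), 0, tolerance = 1e-12)
  expect_equal(unname(lg$group_b$ic), 0, tolerance = 1e-12)
})
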