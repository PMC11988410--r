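# Position-specific scoring model: build, align, calibrate, search.

#' Build a position-specific scoring model from a seed alignment
#'
#' Match columns are the seed columns whose gap occupancy does not exceed
#' `max_gap` (default 50%, the usual profile heuristic). Per match column the
#' emission for amino acid `a` is the log-odds
#' `log2((c_a + pseudocount * bg_a) / (n + pseudocount) / bg_a)`, where `c_a`
#' counts `a` among the column's non-gap residues and `n` is the non-gap
#' count.
#'
#' @param seed_alignment Character matrix (rows = sequences), a
#'   `sequence_set`, or a path to an aligned FASTA.
#' @param pseudocount Positive pseudocount mass (default 1).
#' @param background Named amino-acid frequencies (default
#'   [default_background()]).
#' @param max_gap Maximum seed gap fraction for a column to become a match
#'   column (default 0.5).
#' @param gap_open,gap_extend Affine gap penalties in bits; a gap run of
#'   length L costs `gap_open + (L - 1) * gap_extend`.
#' @param id Provenance string recorded on the model.
#' @return Object of class `profile_model`.
#' @export
build_profile <- function(seed_alignment, pseudocount = 1,
                          background = default_background(), max_gap = 0.5,
                          gap_open = 4, gap_extend = 1,
                          id = "seed") {
  if (is.character(seed_alignment) && length(seed_alignment) == 1 &&
      file.exists(seed_alignment)) {
    seed_alignment <- read_alignment_fasta(seed_alignment)
  }
  if (inherits(seed_alignment, "sequence_set")) seed_alignment <- seed_alignment$aln
  if (!is.matrix(seed_alignment) || nrow(seed_alignment) == 0) {
    stop("seed alignment must be a non-empty matrix of equal-length rows")
  }
  if (pseudocount <= 0) stop("pseudocount must be positive")
  background <- check_background(background)
  gap_frac <- colMeans(seed_alignment == GAP_CHAR)
  match_cols <- which(gap_frac <= max_gap)
  if (length(match_cols) == 0) stop("no match columns under the gap ceiling")
  emis <- matrix(NA_real_, nrow = length(match_cols), ncol = 20,
                 dimnames = list(NULL, AA_ALPHABET20))
  for (k in seq_along(match_cols)) {
    col <- seed_alignment[, match_cols[k]]
    col <- col[col != GAP_CHAR]
    bad <- !col %in% AA_ALPHABET20
    if (any(bad)) col <- col[!bad]
    n <- length(col)
    cnt <- table(factor(col, levels = AA_ALPHABET20))
    emis[k, ] <- log2((as.numeric(cnt) + pseudocount * background) /
                        (n + pseudocount) / background)
  }
  if (any(!is.finite(emis))) stop("non-finite emissions; check the seed alignment")
  structure(list(n_columns = length(match_cols), emissions = emis,
                 gap_open = gap_open, gap_extend = gap_extend,
                 background_freqs = background,
                 match_cols = match_cols - 1L,   # 0-based seed coordinates
                 seed_alignment_id = id),
            class = "profile_model")
}

#' @export
print.profile_model <- function(x, ...) {
  cat("profile_model:", x$n_columns, "match columns, gap open/extend =",
      x$gap_open, "/", x$gap_extend, "bits\n")
  invisible(x)
}

#' Consensus sequence of a profile
#'
#' The highest-emission residue at each match column.
#'
#' @param profile A `profile_model`.
#' @return Single character string of length `n_columns`.
#' @export
profile_consensus <- function(profile) {
  paste(AA_ALPHABET20[apply(profile$emissions, 1, which.max)], collapse = "")
}

#' Best local alignment of a protein to a profile
#'
#' Smith-Waterman-style local alignment of the protein against the model's
#' emissions under affine gap penalties, maximised over all start/end pairs.
#' Ties are broken by the earliest target start, then the earliest profile
#' start. Flanking unaligned regions are free; the score is 0 with an empty
#' alignment when no positive-scoring local match exists.
#'
#' @param profile A `profile_model`.
#' @param protein Protein sequence string (length >= 1).
#' @param id,species Labels carried on the hit.
#' @return Object of class `profile_hit` with fields `raw_score` (bits),
#'   `target_interval` (0-based half-open), `column_map` (per profile column:
#'   matched residue or `"-"`), `profile_interval`, `insertions` (inserted
#'   target residues after each profile column, length `n_columns + 1`).
#' @export
score_sequence <- function(profile, protein, id = "protein", species = NA_character_) {
  stopifnot(inherits(profile, "profile_model"))
  if (!is.character(protein) || length(protein) != 1 || nchar(protein) < 1) {
    stop("protein must be a single non-empty sequence string")
  }
  tgt <- strsplit(protein, "")[[1]]
  code <- match(tgt, AA_ALPHABET20, nomatch = 0L)
  res <- .local_align_cpp(profile$emissions, code, profile$gap_open,
                          profile$gap_extend)
  P <- profile$n_columns
  column_map <- rep(GAP_CHAR, P)
  matched <- res$colmap > 0
  column_map[matched] <- tgt[res$colmap[matched]]
  structure(list(protein_id = id, species = species,
                 raw_score = res$score,
                 target_interval = c(res$t_start - 1L, res$t_end),
                 profile_interval = c(res$p_start - 1L, res$p_end),
                 column_map = column_map,
                 deleted = res$colmap == 0L,
                 insertions = res$ins,
                 evalue_like = NA_real_,
                 profile_fingerprint = profile_fingerprint(profile)),
            class = "profile_hit")
}

#' Re-score a hit from its column map
#'
#' Sums the emissions of matched residues and subtracts affine penalties for
#' internal deletion runs and recorded insertion runs; reproduces
#' `raw_score` exactly.
#'
#' @param profile The `profile_model` that produced the hit.
#' @param hit A `profile_hit`.
#' @return Score in bits.
#' @export
rescore_hit <- function(profile, hit) {
  p0 <- hit$profile_interval[1] + 1L
  p1 <- hit$profile_interval[2]
  if (p0 < 1 || p1 < p0) return(0)   # empty alignment
  s <- 0
  for (j in p0:p1) {
    r <- hit$column_map[j]
    if (r != GAP_CHAR) {
      a <- match(r, AA_ALPHABET20)
      s <- s + if (is.na(a)) 0 else profile$emissions[j, a]
    }
  }
  gap_run_cost <- function(lens) {
    sum(vapply(lens, function(L) profile$gap_open + (L - 1) * profile$gap_extend,
               numeric(1)))
  }
  del <- hit$deleted[p0:p1]
  if (any(del)) {
    runs <- rle(del)
    s <- s - gap_run_cost(runs$lengths[runs$values])
  }
  ins <- hit$insertions[hit$insertions > 0]
  if (length(ins)) s <- s - gap_run_cost(ins)
  unname(s)
}

#' Calibrate a significance threshold on shuffled decoys
#'
#' Scores `n_decoys` i.i.d. background sequences of length `length_model`
#' against the profile, fits a Gumbel (extreme-value) distribution to the
#' decoy scores by the method of moments, and derives the score threshold at
#' which the expected number of decoys scoring at least as high falls below
#' `cutoff`. The reported threshold is floored at the empirical decoy
#' maximum.
#'
#' @param profile A `profile_model`.
#' @param length_model Decoy length (use a typical target length).
#' @param n_decoys Number of decoys, at least 100 (default 1000).
#' @param seed Integer seed.
#' @param cutoff Expected-decoy cutoff (default 1e-5).
#' @return Object of class `significance_calibration`.
#' @export
calibrate_significance <- function(profile, length_model, n_decoys = 1000L,
                                   seed = 1L, cutoff = 1e-5) {
  stopifnot(inherits(profile, "profile_model"))
  if (n_decoys < 100) stop("n_decoys must be at least 100")
  decoys <- simulate_decoys(n_decoys, length_model,
                            background = profile$background_freqs, seed = seed)
  scores <- vapply(decoys, function(s) score_sequence(profile, s)$raw_score,
                   numeric(1))
  scale <- stats::sd(scores) * sqrt(6) / pi
  loc <- mean(scores) - 0.57721566490153286 * scale
  gumbel_thr <- loc - scale * log(-log(1 - cutoff / n_decoys))
  structure(list(n_decoys = as.integer(n_decoys), decoy_scores = unname(scores),
                 location = loc, scale = scale, cutoff = cutoff,
                 length_model = as.integer(length_model),
                 threshold_bits = max(gumbel_thr, max(scores)),
                 profile_fingerprint = profile_fingerprint(profile)),
            class = "significance_calibration")
}

profile_fingerprint <- function(profile) {
  c(n = profile$n_columns, s = round(sum(profile$emissions), 9))
}

#' Expected number of decoys scoring at least `score`
#'
#' Evaluated under the fitted Gumbel law, scaled by the calibration's decoy
#' count (an E-value-like quantity).
#'
#' @param calib A `significance_calibration`.
#' @param score Score(s) in bits.
#' @return Numeric vector of expected decoy counts.
#' @export
evalue_like <- function(calib, score) {
  p_ge <- 1 - exp(-exp(-(score - calib$location) / calib$scale))
  calib$n_decoys * p_ge
}

#' Search a proteome for profile matches
#'
#' Scores every protein no longer than `max_len` residues (longer proteins
#' are excluded as likely mispredictions) and keeps hits whose
#' expected-decoy value falls below the calibration cutoff and whose score
#' reaches the calibrated threshold. Each retained hit carries its extracted
#' domain as a per-column residue map in profile coordinates.
#'
#' @param profile A `profile_model`.
#' @param proteome Named character vector of protein sequences, or a
#'   `sequence_set` (searched ungapped).
#' @param calib A matching `significance_calibration`.
#' @param max_len Maximum protein length considered (default 300).
#' @param species Species tag(s): scalar or one per protein; taken from the
#'   `sequence_set` when available.
#' @return List of `profile_hit`s (possibly empty), each with `evalue_like`
#'   filled in.
#' @export
search_proteome <- function(profile, proteome, calib, max_len = 300L,
                            species = NA_character_) {
  stopifnot(inherits(profile, "profile_model"),
            inherits(calib, "significance_calibration"))
  if (!identical(profile_fingerprint(profile), calib$profile_fingerprint)) {
    stop("calibration does not match this profile")
  }
  if (inherits(proteome, "sequence_set")) {
    species <- proteome$species
    proteome <- ungapped_sequences(proteome)
  }
  if (length(proteome) == 0) return(list())
  if (length(species) == 1) species <- rep(species, length(proteome))
  hits <- list()
  for (i in seq_along(proteome)) {
    if (nchar(proteome[i]) > max_len) next
    h <- score_sequence(profile, proteome[i],
                        id = names(proteome)[i] %||% paste0("protein", i),
                        species = species[i])
    ev <- evalue_like(calib, h$raw_score)
    if (ev < calib$cutoff && h$raw_score >= calib$threshold_bits) {
      h$evalue_like <- ev
      hits[[length(hits) + 1]] <- h
    }
  }
  hits
}

`%||%` <- function(a, b) if (is.null(a)) b else a
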