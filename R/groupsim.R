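# Group-specificity (GroupSim) scoring, z-normalization, focal-residue
# classification, sequence-logo matrices.

#' Define a two-group partition of alignment rows
#'
#' @param group_a,group_b Disjoint, non-empty row-id vectors.
#' @param labels Display names, e.g. `c("Saccharomycetaceae", "other ascomycetes")`.
#' @return Object of class `group_partition`.
#' @export
group_partition <- function(group_a, group_b,
                            labels = c("group_a", "group_b")) {
  if (length(group_a) == 0 || length(group_b) == 0) {
    stop("both groups must be non-empty")
  }
  if (length(intersect(group_a, group_b))) stop("groups must be disjoint")
  structure(list(group_a = as.character(group_a),
                 group_b = as.character(group_b), labels = labels),
            class = "group_partition")
}

check_partition <- function(part, ids) {
  stopifnot(inherits(part, "group_partition"))
  missing <- setdiff(c(part$group_a, part$group_b), ids)
  if (length(missing)) {
    stop("partition ids absent from alignment: ", paste(missing, collapse = ", "))
  }
  invisible(part)
}

#' Group-specificity score of one alignment column
#'
#' GroupSim under a normalized residue-similarity matrix `m'`:
#' `WithinSim_g` is the mean `m'` over unordered residue pairs within group
#' `g` (pairs involving gaps excluded), `BetweenSim` the mean over
#' cross-group pairs, and the score is
#' `s = ((WithinSim_a + WithinSim_b) / 2) * (1 - BetweenSim)`.
#' The column is undefined (`NA`) when either group's gap fraction exceeds
#' `gap_ceiling` or has fewer than 2 non-gap residues. Unknown residue
#' symbols are treated as gaps with a warning.
#'
#' @param column Named character vector of residues (names = row ids), or
#'   unnamed with `part` given as indices.
#' @param part A `group_partition`.
#' @param sim A `similarity_matrix` from [normalize_similarity()].
#' @param gap_ceiling Maximum tolerated gap fraction per group (default 0.5).
#' @return Score in `[0, 1]`, or `NA` if undefined.
#' @export
column_groupsim <- function(column, part, sim = normalize_similarity(),
                            gap_ceiling = 0.5) {
  stopifnot(inherits(sim, "similarity_matrix"))
  check_partition(part, names(column))
  M <- sim$normalized[AA_ALPHABET20, AA_ALPHABET20]
  stats <- lapply(list(part$group_a, part$group_b), function(g) {
    res <- column[g]
    unknown <- !(res %in% AA_ALPHABET20) & res != GAP_CHAR
    if (any(unknown)) {
      warning("unknown residue symbol(s) treated as gap: ",
              paste(unique(res[unknown]), collapse = ","))
      res[unknown] <- GAP_CHAR
    }
    n <- as.numeric(table(factor(res[res != GAP_CHAR], levels = AA_ALPHABET20)))
    list(n = n, k = sum(n), gap_frac = mean(res == GAP_CHAR))
  })
  a <- stats[[1]]; b <- stats[[2]]
  if (a$gap_frac > gap_ceiling || b$gap_frac > gap_ceiling ||
      a$k < 2 || b$k < 2) {
    return(NA_real_)
  }
  within <- function(n, k) {
    tot <- drop(crossprod(n, M %*% n)) - sum(n * diag(M))
    tot / 2 / (k * (k - 1) / 2)
  }
  wa <- within(a$n, a$k)
  wb <- within(b$n, b$k)
  between <- drop(crossprod(a$n, M %*% b$n)) / (a$k * b$k)
  ((wa + wb) / 2) * (1 - between)
}

#' Score every column of an alignment for group specificity
#'
#' Computes the GroupSim score of each column, then standardizes scores to
#' z-scores against the mean and population standard deviation of all
#' scored columns of the same alignment (one histone family; never pooled
#' across families). Columns whose scores all coincide get z = 0 (the
#' zero-variance convention). A column is flagged when its z-score exceeds
#' `z_threshold` and, if `score_threshold` is non-`NULL`, its raw score
#' exceeds that too.
#'
#' @param aln A `stacked_alignment`.
#' @param part A `group_partition` over its row ids.
#' @param sim A `similarity_matrix`.
#' @param z_threshold Flagging threshold on z (default 5).
#' @param score_threshold Optional flagging threshold on the raw score
#'   (default `NULL`, disabled).
#' @param gap_ceiling Per-group gap ceiling for scoring a column.
#' @return Object of class `groupsim_result`: data.frame with `column`
#'   (original profile coordinate), `score`, `z`, `flagged`,
#'   `gap_fraction_a`, `gap_fraction_b`, `modal_a`, `modal_b`.
#' @export
score_alignment <- function(aln, part, sim = normalize_similarity(),
                            z_threshold = 5, score_threshold = NULL,
                            gap_ceiling = 0.5) {
  stopifnot(inherits(aln, "stacked_alignment"))
  check_partition(part, aln$ids)
  ncols <- ncol(aln$matrix)
  s <- numeric(ncols); gfa <- numeric(ncols); gfb <- numeric(ncols)
  moda <- character(ncols); modb <- character(ncols)
  modal <- function(res) {
    res <- res[res != GAP_CHAR]
    if (!length(res)) return(GAP_CHAR)
    names(sort(table(res), decreasing = TRUE))[1]
  }
  for (c in seq_len(ncols)) {
    col <- aln$matrix[, c]
    names(col) <- aln$ids
    s[c] <- suppressWarnings(column_groupsim(col, part, sim, gap_ceiling))
    gfa[c] <- mean(col[part$group_a] == GAP_CHAR)
    gfb[c] <- mean(col[part$group_b] == GAP_CHAR)
    moda[c] <- modal(col[part$group_a])
    modb[c] <- modal(col[part$group_b])
  }
  scored <- !is.na(s)
  z <- rep(NA_real_, ncols)
  if (sum(scored) >= 2) {
    mu <- mean(s[scored])
    sdp <- sqrt(mean((s[scored] - mu)^2))
    z[scored] <- if (sdp > 0) (s[scored] - mu) / sdp else 0
  } else {
    warning("fewer than 2 scored columns; z-scores undefined")
  }
  flagged <- !is.na(z) & z > z_threshold
  if (!is.null(score_threshold)) flagged <- flagged & !is.na(s) & s > score_threshold
  out <- data.frame(column = aln$column_provenance, score = s, z = z,
                    flagged = flagged, gap_fraction_a = gfa,
                    gap_fraction_b = gfb, modal_a = moda, modal_b = modb,
                    stringsAsFactors = FALSE)
  class(out) <- c("groupsim_result", "data.frame")
  out
}

#' Classify the focal residue of one aligned sequence
#'
#' A sequence is classified as carrying the focal residue when the target
#' amino acid occurs within `window` aligned positions of the focal column
#' (inclusive on both sides). By default gap columns count as positions,
#' mirroring classification over an alignment; set `count_gaps = FALSE` to
#' count only this row's residue positions instead.
#'
#' @param row Character vector: one aligned sequence (residues/gaps).
#' @param focal_column 0-based column index within the alignment.
#' @param window Number of aligned positions either side (default 5).
#' @param residue Target amino acid (default `"C"`).
#' @param count_gaps Whether gap columns count toward the window (default
#'   `TRUE`).
#' @return `"present"` or `"absent"`.
#' @export
classify_focal_residue <- function(row, focal_column, window = 5L,
                                   residue = "C", count_gaps = TRUE) {
  n <- length(row)
  if (focal_column < 0 || focal_column >= n) stop("focal column out of range")
  if (window < 0) stop("window must be non-negative")
  f <- focal_column + 1L
  if (count_gaps) {
    idx <- max(1L, f - window):min(n, f + window)
  } else {
    pos <- which(row != GAP_CHAR)
    if (!length(pos)) return("absent")
    rank_f <- sum(pos <= f)      # residue positions up to the focal column
    keep <- abs(seq_along(pos) - rank_f) <= window
    idx <- pos[keep]
  }
  if (any(row[idx] == residue)) "present" else "absent"
}

#' Per-group residue counts and information content around a focal column
#'
#' Builds the matrices behind sequence logos: per alignment position in
#' `focal_column` +/- `flank`, per group, the 20 amino-acid counts, their
#' frequencies over non-gap residues, and the information content
#' `IC = log2(20) - H` in bits (0 for positions with no residues).
#'
#' @param aln A `stacked_alignment`.
#' @param part A `group_partition`.
#' @param focal_column 0-based column index within `aln`.
#' @param flank Positions either side (default 5); truncated at the
#'   alignment edge with a warning.
#' @return Named list (one `sequence_logo_matrix` per group) with fields
#'   `positions` (0-based indices within `aln`), `counts` (20 x positions),
#'   `freqs`, `ic`.
#' @export
logo_counts <- function(aln, part, focal_column, flank = 5L) {
  stopifnot(inherits(aln, "stacked_alignment"))
  check_partition(part, aln$ids)
  n <- ncol(aln$matrix)
  if (focal_column < 0 || focal_column >= n) stop("focal column out of range")
  lo <- focal_column - flank; hi <- focal_column + flank
  if (lo < 0 || hi >= n) {
    warning("flank truncated at the alignment edge")
    lo <- max(0, lo); hi <- min(n - 1, hi)
  }
  idx <- (lo:hi) + 1L
  one_group <- function(g) {
    sub <- aln$matrix[g, idx, drop = FALSE]
    counts <- apply(sub, 2, function(col) {
      as.numeric(table(factor(col[col %in% AA_ALPHABET20], levels = AA_ALPHABET20)))
    })
    rownames(counts) <- AA_ALPHABET20
    colnames(counts) <- lo:hi
    freqs <- apply(counts, 2, function(v) if (sum(v) > 0) v / sum(v) else v)
    ic <- apply(freqs, 2, function(p) {
      if (sum(p) == 0) return(0)
      p <- p[p > 0]
      log2(20) + sum(p * log2(p))
    })
    structure(list(positions = lo:hi, counts = counts, freqs = freqs, ic = ic),
              class = "sequence_logo_matrix")
  }
  out <- list(one_group(part$group_a), one_group(part$group_b))
  names(out) <- part$labels
  out
}
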