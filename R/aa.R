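# Amino-acid alphabet, background frequencies, similarity matrices.

#' The 20 standard amino acids
#'
#' One-letter codes in the conventional BLOSUM row order.
#'
#' @format Character vector of length 20.
#' @export
AA_ALPHABET20 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
                   "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

GAP_CHAR <- "-"

#' Default amino-acid background frequencies
#'
#' Robinson & Robinson composition frequencies, the background commonly used
#' by profile search tools. Normalized to sum exactly to 1.
#'
#' @return Named numeric vector over [AA_ALPHABET20], summing to 1.
#' @export
default_background <- function() {
  f <- c(A = 0.07805, R = 0.05129, N = 0.04487, D = 0.05364, C = 0.01925,
         Q = 0.04264, E = 0.06295, G = 0.07377, H = 0.02199, I = 0.05142,
         L = 0.09019, K = 0.05744, M = 0.02243, F = 0.03856, P = 0.05203,
         S = 0.07120, T = 0.05841, W = 0.01330, Y = 0.03216, V = 0.06441)
  f <- f[AA_ALPHABET20]
  f / sum(f)
}

#' BLOSUM62 restricted to the 20 standard amino acids
#'
#' @return 20 x 20 symmetric integer score matrix (rows/cols [AA_ALPHABET20]).
#' @export
blosum62_matrix <- function() {
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  m <- e$BLOSUM62[AA_ALPHABET20, AA_ALPHABET20]
  storage.mode(m) <- "double"
  m
}

#' Normalize a similarity matrix to the unit interval
#'
#' Maps raw scores to `(m - min) / (max - min)` over all entries, so the most
#' dissimilar residue pair scores 0 and the most similar scores 1, and sets
#' identical-residue pairs to similarity 1 exactly. The diagonal convention
#' makes a fully conserved column carry zero group-specificity signal
#' (between-group similarity 1), which the raw min-max scaling alone would
#' not (e.g. BLOSUM62 A-A maps to 8/15). This is the similarity used by the
#' group-specificity (GroupSim) score.
#'
#' @param m Symmetric square numeric matrix with residue dimnames.
#' @return Object of class `similarity_matrix`: list with `raw` and
#'   `normalized` matrices.
#' @export
normalize_similarity <- function(m = blosum62_matrix()) {
  stopifnot(is.matrix(m), nrow(m) == ncol(m))
  if (!isSymmetric(unname(m))) stop("similarity matrix must be symmetric")
  rng <- range(m)
  if (rng[1] == rng[2]) stop("similarity matrix is constant; cannot normalize")
  norm <- (m - rng[1]) / (rng[2] - rng[1])
  diag(norm) <- 1
  structure(list(raw = m, normalized = norm),
            class = "similarity_matrix")
}

# Validate a background-frequency vector.
check_background <- function(bg) {
  if (is.null(names(bg))) names(bg) <- AA_ALPHABET20
  bg <- bg[AA_ALPHABET20]
  if (anyNA(bg) || any(bg <= 0)) stop("background_freqs must be positive over the 20 amino acids")
  if (abs(sum(bg) - 1) > 1e-9) stop("background_freqs must sum to 1 (tolerance 1e-9)")
  bg
}

# Internal: run expr with a local RNG seed, restoring global state afterwards.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv())) {
      get(".Random.seed", envir = globalenv())
    }
    on.exit({
      if (is.null(old)) {
        rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(as.integer(seed))
  }
  expr
}
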