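## small shared helpers; sequence conventions: uppercase ACGTN character
## vectors, coordinates 0-based half-open unless a function says otherwise.

#' Levenshtein distance between character vectors
#'
#' Thin wrapper around [utils::adist()] restricted to plain edit distance
#' (unit costs, no partial matching). `N` never matches anything, including
#' another `N`: each `N` position contributes at least one edit against any
#' base, which `adist` guarantees for `N` vs. non-`N`; `N` vs `N` is forced
#' to mismatch by pre-substitution with distinct sentinels.
#'
#' @param a,b character vectors; distances are computed pairwise (outer).
#' @return integer matrix `length(a)` x `length(b)`.
#' @export
levDist <- function(a, b) {
  a <- toupper(a); b <- toupper(b)
  # make N self-mismatching: N -> '!' on one side only
  a2 <- gsub("N", "!", a, fixed = TRUE)
  matrix(as.integer(adist(a2, b)), nrow = length(a))
}

#' Nearest-rank empirical quantile
#'
#' The quantile convention used for all length windows and bootstrap
#' percentiles in this package: the p-th quantile of a sample of size n is
#' the `ceiling(p * n)`-th order statistic (p = 0 maps to the minimum).
#'
#' @param x numeric vector.
#' @param p probabilities in `[0, 1]`.
#' @return numeric vector of quantiles.
#' @export
nearestRankQuantile <- function(x, p) {
  stopifnot(length(x) >= 1, all(p >= 0 & p <= 1))
  xs <- sort(x)
  idx <- pmax(1L, ceiling(p * length(xs)))
  xs[idx]
}

#' Reverse-complement of plain character sequences
#' @param x character vector of DNA sequences.
#' @return character vector.
#' @export
revComp <- function(x) {
  as.character(reverseComplement(DNAStringSet(x)))
}

# run code under a local RNG state seeded with `seed`, restoring the
# caller's RNG afterwards (keeps simulators deterministic and side-effect
# free); RNGkind pinned so results do not depend on session settings
withSeed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed), kind = "Mersenne-Twister",
           normal.kind = "Inversion", sample.kind = "Rejection")
  force(code)
}

# random DNA of given lengths under the current RNG
randomDNA <- function(n, len) {
  vapply(rep(len, length.out = n), function(L) {
    paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = "")
  }, character(1))
}

# Fisher-Yates single shuffle of one sequence's bases (used for homology nulls)
shuffleSeq <- function(x) {
  ch <- strsplit(x, "", fixed = TRUE)[[1]]
  paste(sample(ch), collapse = "")
}

#' Local pairwise alignment score (Smith-Waterman)
#'
#' Scores one pair of sequences with the package-wide local alignment
#' scheme (match +2, mismatch -2, gap open -3, gap extend -1), via
#' [Biostrings::pairwiseAlignment()].
#'
#' @param a,b character scalars or `DNAString`s.
#' @param match,mismatch,gap_open,gap_extend scoring parameters (positive
#'   costs for gaps).
#' @return numeric alignment score.
#' @export
localAlignScore <- function(a, b, match = 2, mismatch = -2,
                            gap_open = 3, gap_extend = 1) {
  mat <- nucleotideSubstitutionMatrix(match = match, mismatch = mismatch,
                                      baseOnly = FALSE)
  # Biostrings charges gapOpening + gapExtension for the first gapped base;
  # the scheme here (as in striped Smith-Waterman tools) charges gap_open
  # for the first base and gap_extend thereafter
  pairwiseAlignment(DNAString(as.character(a)), DNAString(as.character(b)),
                    type = "local", substitutionMatrix = mat,
                    gapOpening = gap_open - gap_extend,
                    gapExtension = gap_extend,
                    scoreOnly = TRUE)
}
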