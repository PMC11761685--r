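# Independent oracles used across tests: deliberately naive
# implementations kept separate from the package's code paths.

# plain dynamic-programming Levenshtein distance (no banding, no C)
levDP <- function(a, b) {
  a <- strsplit(a, "")[[1]]
  b <- strsplit(b, "")[[1]]
  n <- length(a); m <- length(b)
  d <- matrix(0L, n + 1, m + 1)
  d[, 1] <- 0:n
  d[1, ] <- 0:m
  for (i in seq_len(n))
    for (j in seq_len(m))
      d[i + 1, j + 1] <- min(d[i, j + 1] + 1L, d[i + 1, j] + 1L,
                             d[i, j] + (a[i] != b[j]))
  d[n + 1, m + 1]
}

# two-sided Fisher p by direct enumeration of the conditional
# hypergeometric distribution (sum of tables as or less likely)
fisherEnumTwoSided <- function(tab) {
  a <- tab[1, 1]; b <- tab[1, 2]; c <- tab[2, 1]; d <- tab[2, 2]
  r1 <- a + b; c1 <- a + c; n <- a + b + c + d
  ks <- max(0, r1 + c1 - n):min(r1, c1)
  probs <- dhyper(ks, c1, n - c1, r1)
  p_obs <- dhyper(a, c1, n - c1, r1)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# exact expectation of the one-sided bootstrap FDR for two Bernoulli
# samples resampled with replacement (ties at half weight), by full
# enumeration of resampled counts
bootstrapFdrEnum <- function(nca, nda, ncb, ndb) {
  na <- nca + nda; nb <- ncb + ndb
  pa <- nca / na; pb <- ncb / nb
  ka <- 0:na; kb <- 0:nb
  pka <- dbinom(ka, na, pa); pkb <- dbinom(kb, nb, pb)
  fa <- ka / na; fb <- kb / nb
  tot <- 0
  for (i in seq_along(ka)) {
    gt <- fa[i] > fb
    eq <- abs(fa[i] - fb) < 1e-12
    tot <- tot + pka[i] * sum(pkb * (gt + 0.5 * eq))
  }
  tot
}

# a tiny dictionary built directly from a truth table (used when the
# test exercises parsing, not dictionary construction)
dictFromTruth <- function(truth) {
  new("PairDictionary", valid_bc1 = truth$bc1, valid_bc2 = truth$bc2,
      pairs = data.frame(bc1 = truth$bc1, bc2 = truth$bc2),
      uniqueness_threshold = 0.99, provenance = list())
}

# shared small fixtures
smallTruth <- function(n = 50, seed = 11)
  generateBarcodeTruth(n, min_pairwise_dist = 5, seed = seed)

shortDesign <- function() defaultLibraryDesigns()$short_homologous
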