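# Dictionary module: pile-up, abundance classes, artifact filters,
# Levenshtein pruning, component correction, unique-pairing filter.

test_that("tallyPairs counts exact multisets and rejects bad lengths", {
  b1 <- strrep("A", 15); b1b <- strrep("C", 15)
  b2 <- strrep("G", 16); b2b <- strrep("T", 16)
  recs <- data.frame(bc1_obs = c(b1, b1, b1, b1b),
                     bc2_obs = c(b2, b2, b2, b2b))
  tal <- tallyPairs(recs)
  expect_equal(nrow(tal), 2L)
  expect_equal(tal$reads, c(3L, 1L))
  # order invariance
  tal2 <- tallyPairs(recs[sample(4), , drop = FALSE])
  expect_equal(as.data.frame(tal)[order(tal$bc1), ],
               as.data.frame(tal2)[order(tal2$bc1), ],
               ignore_attr = TRUE)
  # lowercase normalized, wrong lengths rejected and counted
  recs2 <- rbind(recs, data.frame(bc1_obs = tolower(b1), bc2_obs = b2),
                 data.frame(bc1_obs = "ACGT", bc2_obs = b2))
  tal3 <- tallyPairs(recs2)
  expect_equal(sum(tal3$reads), 5L)
  expect_equal(attr(tal3, "rejects"), 1L)
})

test_that("tallyPairs conserves reads on simulated input", {
  truth <- smallTruth(300, seed = 30)
  sim <- simulateAssociationReads(truth, mean_depth = 300,
                                  error_rate = 0.003, seed = 31)
  tal <- tallyPairs(data.frame(bc1_obs = sim$reads$bc1_obs,
                               bc2_obs = sim$reads$bc2_obs))
  # substitution errors never change barcode length, so nothing rejected
  expect_equal(sum(tal$reads), nrow(sim$reads))
  expect_equal(attr(tal, "rejects"), 0L)
})

test_that("abundance classification follows the low/mid/high rules", {
  pc <- data.table::data.table(
    bc1 = c("A", "B", "C", "D", "E"),
    bc2 = paste0("Z", 1:5),
    reads = c(4L, 6L, 50000L, 2L, 10L))
  cls <- classifyAbundance(pc, "BC1", low_max = 5, high_cutoff = 1e4,
                           pileup_min = 3)
  cls <- setNames(cls$class, cls$barcode)
  expect_equal(cls[["A"]], "low")     # 4 <= 5
  expect_equal(cls[["B"]], "mid")     # 6 with cutoff 1e4
  expect_equal(cls[["C"]], "high")
  expect_false("D" %in% names(cls))   # below pileup_min: no total at all
  expect_error(classifyAbundance(pc, "BC1", low_max = 5, high_cutoff = 5),
               "high_cutoff")
})

test_that("jackpot clones are classified high at 100x median cutoff", {
  truth <- smallTruth(400, seed = 32)
  sim <- simulateAssociationReads(truth, mean_depth = 30,
                                  jackpot_fraction = 0.01,
                                  jackpot_multiplier = 1000, seed = 33)
  tal <- tallyPairs(data.frame(bc1_obs = sim$reads$bc1_obs,
                               bc2_obs = sim$reads$bc2_obs))
  cls <- classifyAbundance(tal, "BC1", high_cutoff =
                             100 * median(tal$reads))
  jack <- truth$bc1[sim$truth$clone_weight > 1]
  expect_true(length(jack) >= 1)
  got <- cls$class[match(jack, cls$barcode)]
  expect_true(all(got == "high"))
  body <- cls$class[!cls$barcode %in% jack]
  expect_true(all(body == "mid"))
})

test_that("the proposed high cutoff separates body from jackpot modes", {
  set.seed(46)
  totals <- c(rpois(5000, 30), rpois(50, 30) * 1000)
  cut <- proposeHighCutoff(totals)
  expect_gt(cut, max(rpois(5000, 30)))
  expect_lt(cut, 20000)
})

test_that("dominant artifact removal covers its Levenshtein neighborhood", {
  dom <- "ATAACGACTTGTGAGC"
  near1 <- paste0("TTAACGACTTGTGAGC")          # 1 substitution
  near2 <- paste0("ATAACGACTTGTGA")            # 2 deletions -> dist 2
  far <- strrep("G", 16)
  expect_equal(levDP(dom, near1), 1L)
  expect_equal(levDP(dom, near2), 2L)
  rem <- removeDominant(c(dom, near1, near2, far), dominant = dom)
  expect_setequal(rem, c(dom, near1, near2))
  expect_equal(removeDominant(c(dom, far), dominant = dom, radius = 2), dom)
  # auto-detection takes the highest-total barcode
  cls <- data.frame(barcode = c(dom, far), total_reads = c(100, 5))
  expect_true(dom %in% removeDominant(cls, dominant = "auto"))
})

test_that("artifact filters remove G runs and truncation signatures", {
  expect_equal(filterArtifacts("GGGGGGGGGGAAAAA", "BC1"),
               "GGGGGGGGGGAAAAA")                     # 10 G run: removed
  expect_equal(length(filterArtifacts("GGGGGGGGGACGTAC", "BC1")), 0L) # 9 Gs
  expect_equal(filterArtifacts("CCATTAAACCCCCCC", "BC1"),
               "CCATTAAACCCCCCC")                     # BC1 signature
  expect_equal(length(filterArtifacts("CCATTAAACCCCCCC", "BC2")), 0L)
  expect_equal(filterArtifacts("ATAGCGCGAAAAAAAA", "BC2"),
               "ATAGCGCGAAAAAAAA")                    # BC2 signature
})

test_that("mid pruning near high barcodes matches a brute-force oracle", {
  expect_equal(pruneMidByHigh(c("AAAA", "CCCC"), character()),
               c("AAAA", "CCCC"))
  high <- "ACGTACGTACGTACGT"
  mid_del <- "ACGTACGTACGTACG"  # one deletion
  expect_equal(length(pruneMidByHigh(mid_del, high)), 0L)
  set.seed(44)
  mid <- unique(vapply(1:2000, function(i)
    paste(sample(c("A", "C", "G", "T"), 16, TRUE), collapse = ""), ""))
  high <- vapply(1:10, function(i)
    paste(sample(c("A", "C", "G", "T"), 16, TRUE), collapse = ""), "")
  mid <- setdiff(mid, high)
  pruned <- pruneMidByHigh(mid, high, radius = 2)
  # independent oracle: utils::adist full cross matrix
  d <- utils::adist(mid, high)
  keep_oracle <- mid[apply(d, 1, min) > 2]
  expect_setequal(pruned, keep_oracle)
})

test_that("connected-component correction keeps argmax and drops ambiguity", {
  # singleton kept
  expect_equal(correctHighCounts(c(AAAAAAAAAAAAAAAA = 50)),
               "AAAAAAAAAAAAAAAA")
  b <- "ACGTACGTACGTACGT"
  b1 <- "ACGTACGTACGTACGA"   # dist 1 from b
  c0 <- strrep("GT", 8)
  counts <- setNames(c(1000, 5, 70), c(b, b1, c0))
  expect_setequal(correctHighCounts(counts, min_fold = 10), c(b, c0))
  # fold below threshold: whole component discarded
  counts2 <- setNames(c(100, 20, 70), c(b, b1, c0))
  expect_setequal(correctHighCounts(counts2, min_fold = 10), c0)
  # tied argmax: discarded as ambiguous
  counts3 <- setNames(c(100, 100, 70), c(b, b1, c0))
  expect_setequal(correctHighCounts(counts3, min_fold = 10), c0)
})

test_that("unique-pairing filter applies the strict >99% rule on both sides", {
  one <- data.table::data.table(bc1 = strrep("A", 15),
                                bc2 = strrep("C", 16), reads = 10L)
  dict <- buildPairDictionary(one, one$bc1, one$bc2)
  expect_equal(nrow(validPairs(dict)), 1L)
  # X pairs with Y (990) and Z (10): fraction 0.99 is not > 0.99
  x <- strrep("A", 15); y <- strrep("C", 16); z <- strrep("G", 16)
  pc <- data.table::data.table(bc1 = c(x, x), bc2 = c(y, z),
                               reads = c(990L, 10L))
  expect_warning(dict2 <- buildPairDictionary(pc, x, c(y, z)), "empty")
  expect_equal(nrow(validPairs(dict2)), 0L)
})

test_that("noiseless dictionary reconstruction equals truth exactly", {
  truth <- generateBarcodeTruth(1000, min_pairwise_dist = 0, seed = 40)
  sim <- simulateAssociationReads(truth, mean_depth = 30, seed = 41)
  tal <- tallyPairs(data.frame(bc1_obs = sim$reads$bc1_obs,
                               bc2_obs = sim$reads$bc2_obs))
  dict <- buildDictionary(tal, high_cutoff = Inf)
  expect_setequal(paste(validPairs(dict)$bc1, validPairs(dict)$bc2),
                  paste(truth$bc1, truth$bc2))
})

test_that("raising uniqueness or pair floor never adds pairs", {
  truth <- smallTruth(300, seed = 42)
  sim <- simulateAssociationReads(truth, mean_depth = 25,
                                  error_rate = 0.01, seed = 43)
  tal <- tallyPairs(data.frame(bc1_obs = sim$reads$bc1_obs,
                               bc2_obs = sim$reads$bc2_obs))
  base <- buildDictionary(tal, high_cutoff = Inf)
  keys <- function(d) paste(validPairs(d)$bc1, validPairs(d)$bc2)
  for (u in c(0.995, 0.999)) {
    d2 <- buildDictionary(tal, high_cutoff = Inf, uniqueness = u)
    expect_true(all(keys(d2) %in% keys(base)))
  }
  for (mr in c(3L, 5L)) {
    d3 <- buildDictionary(tal, high_cutoff = Inf, min_pair_reads = mr)
    expect_true(all(keys(d3) %in% keys(base)))
  }
})

test_that("provenance counts are non-increasing along the pair filters", {
  truth <- smallTruth(200, seed = 44)
  sim <- simulateAssociationReads(truth, mean_depth = 25,
                                  error_rate = 0.01, seed = 45)
  tal <- tallyPairs(data.frame(bc1_obs = sim$reads$bc1_obs,
                               bc2_obs = sim$reads$bc2_obs))
  dict <- buildDictionary(tal, high_cutoff = Inf)
  pr <- provenance(dict)
  expect_true(pr$pairs_read_floor <= pr$pairs_piled)
  expect_true(pr$pairs_both_valid <= pr$pairs_read_floor)
  expect_true(pr$pairs_unique <= pr$pairs_both_valid)
})

test_that("1% errors admit no false pairs with well-separated truth", {
  for (seed in 1:5) {
    truth <- generateBarcodeTruth(300, min_pairwise_dist = 5, seed = seed)
    sim <- simulateAssociationReads(truth, mean_depth = 30,
                                    error_rate = 0.01, seed = seed + 100)
    tal <- tallyPairs(data.frame(bc1_obs = sim$reads$bc1_obs,
                                 bc2_obs = sim$reads$bc2_obs))
    dict <- buildDictionary(tal, high_cutoff = Inf)
    got <- paste(validPairs(dict)$bc1, validPairs(dict)$bc2)
    want <- paste(truth$bc1, truth$bc2)
    expect_equal(length(setdiff(got, want)), 0L)
  }
})

test_that("pair dictionaries round-trip through plain-text files", {
  truth <- smallTruth(50, seed = 46)
  sim <- simulateAssociationReads(truth, mean_depth = 30, seed = 47)
  tal <- tallyPairs(data.frame(bc1_obs = sim$reads$bc1_obs,
                               bc2_obs = sim$reads$bc2_obs))
  dict <- buildDictionary(tal, high_cutoff = Inf)
  dir <- file.path(tempdir(), "dict_rt")
  writePairDictionary(dict, dir)
  back <- readPairDictionary(dir)
  expect_setequal(back@valid_bc1, dict@valid_bc1)
  expect_equal(as.data.frame(validPairs(back)),
               as.data.frame(validPairs(dict)))
  expect_equal(back@uniqueness_threshold, 0.99)
})
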