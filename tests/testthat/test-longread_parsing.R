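# Parsing module: signpost location, layout validation, feature
# extraction, demultiplexing, dictionary matching, length windows and
# dimer handling.

mutateAt <- function(s, pos) {
  ch <- strsplit(s, "")[[1]]
  for (p in pos) ch[p] <- setdiff(c("A", "C", "G", "T"), ch[p])[1]
  paste(ch, collapse = "")
}

test_that("signpost hits respect the 75% identity threshold", {
  set.seed(50)
  sp <- defaultSignposts()
  bg <- paste(sample(c("A", "C", "G", "T"), 600, TRUE), collapse = "")
  ru <- sp[["right_up"]]  # 20 nt
  embed <- function(q) paste0(substr(bg, 1, 300), q, substr(bg, 301, 600))
  # 2 substitutions: identity 0.9, retained
  h2 <- locateSignposts(embed(mutateAt(ru, c(3, 11))), sp)
  h2 <- h2[h2$signpost_id == "right_up" & h2$strand == "+", ]
  expect_equal(nrow(h2), 1L)
  expect_equal(h2$identity, 18 / 20)
  # 6 substitutions: identity 0.7, dropped
  h6 <- locateSignposts(embed(mutateAt(ru, c(1, 4, 8, 12, 16, 19))), sp)
  expect_false(any(h6$signpost_id == "right_up" & h6$strand == "+" &
                     h6$identity >= 0.75))
})

test_that("reverse-complemented cargo yields mirrored minus-strand hits", {
  truth <- smallTruth(3, seed = 51)
  d <- shortDesign()
  cargo <- buildCargo(d, truth$bc1[1], truth$bc2[1])
  L <- nchar(cargo)
  fwd <- locateSignposts(cargo, d@signposts)
  fwd <- fwd[fwd$identity == 1 & fwd$strand == "+", ]
  rev <- locateSignposts(revComp(cargo), d@signposts)
  rev <- rev[rev$identity == 1 & rev$strand == "-", ]
  expect_equal(nrow(rev), 4L)
  m <- merge(as.data.frame(fwd), as.data.frame(rev), by = "signpost_id")
  expect_true(all(m$read_start.y == L - m$read_end.x))
  expect_true(all(m$read_end.y == L - m$read_start.x))
})

test_that("layout validation enforces completeness, strand and order", {
  truth <- smallTruth(3, seed = 52)
  d <- shortDesign()
  cargo <- buildCargo(d, truth$bc1[1], truth$bc2[1])
  hits <- locateSignposts(cargo, d@signposts)
  lay <- validateLayout(hits)
  expect_true(lay$pass)
  expect_equal(lay$strand, "+")
  # reverse complement: passes on minus
  lay_rc <- validateLayout(locateSignposts(revComp(cargo), d@signposts))
  expect_true(lay_rc$pass)
  expect_equal(lay_rc$strand, "-")
  # drop one signpost: incomplete
  h4 <- hits[hits$strand == "+", ]
  expect_false(validateLayout(h4[h4$signpost_id != "left_up", ])$pass)
  # mixed strands among the four best hits
  hmix <- data.table::copy(h4)
  hmix$strand[1] <- "-"
  expect_equal(validateLayout(hmix)$reason, "mixed_strands")
  # BC2 block upstream of BC1 on plus: order violation
  hperm <- data.table::copy(h4)
  sw <- match(c("right_up", "right_down"), hperm$signpost_id)
  lu <- match(c("left_up", "left_down"), hperm$signpost_id)
  tmp <- hperm$read_start[sw]
  hperm$read_start[sw] <- hperm$read_start[lu]
  hperm$read_start[lu] <- tmp
  expect_equal(validateLayout(hperm)$reason, "order_violation")
})

test_that("feature extraction round-trips and is strand invariant", {
  truth <- smallTruth(3, seed = 53)
  d <- shortDesign()
  cargo <- buildCargo(d, truth$bc1[2], truth$bc2[2])
  f <- extractFeatures(cargo, locateSignposts(cargo, d@signposts), d)
  expect_true(f$ok)
  expect_equal(f$bc1, truth$bc1[2])
  expect_equal(f$bc2, truth$bc2[2])
  expect_equal(f$index_obs, d@insert_index)
  expect_equal(f$insert_seq, d@insert_seq)
  rc <- revComp(cargo)
  f2 <- extractFeatures(rc, locateSignposts(rc, d@signposts), d)
  expect_equal(f2$strand, "-")
  expect_equal(f2[c("bc1", "bc2", "index_obs", "insert_seq",
                    "bc_to_bc_len")],
               f[c("bc1", "bc2", "index_obs", "insert_seq",
                   "bc_to_bc_len")])
  # a single inserted base inside the insert: length +1, barcodes intact
  feat <- attr(cargo, "features")
  ins_at <- feat$start[feat$name == "insert"] + 10L
  bumped <- paste0(substr(cargo, 1, ins_at), "A",
                   substr(cargo, ins_at + 1, nchar(cargo)))
  f3 <- extractFeatures(bumped, locateSignposts(bumped, d@signposts), d)
  expect_equal(f3$bc_to_bc_len, f$bc_to_bc_len + 1L)
  expect_equal(f3$bc1, f$bc1)
  expect_equal(f3$bc2, f$bc2)
})

test_that("demultiplexing follows the best<=1, margin>=2 rule", {
  idx <- defaultInsertIndices()
  # the configured indices are mutually separated (Levenshtein >= 3)
  pairs <- t(combn(length(idx), 2))
  dmat <- vapply(seq_len(nrow(pairs)), function(k)
    levDP(idx[[pairs[k, 1]]], idx[[pairs[k, 2]]]), 0L)
  expect_gte(min(dmat), 3)
  expect_equal(demultiplexIndex("AGACTCAAGT"), "short_homologous")
  # every single-substitution observation follows the rule exactly as
  # decided by the exhaustive distance-matrix oracle
  for (lib in names(idx)) {
    for (p in 1:10) {
      obs <- mutateAt(idx[[lib]], p)
      dists <- vapply(idx, function(x) levDP(obs, x), 0L)
      oracle <- if (min(dists) <= 1 && sort(dists)[2] - min(dists) >= 2)
        names(idx)[which.min(dists)] else "ambiguous"
      expect_equal(demultiplexIndex(obs), oracle)
      if (oracle != "ambiguous") expect_equal(oracle, lib)
    }
  }
  # an observation equidistant from two indices is ambiguous
  expect_equal(demultiplexIndex(NA_character_), "ambiguous")
})

test_that("dictionary matching is exact with no error tolerance", {
  truth <- smallTruth(10, seed = 54)
  dict <- dictFromTruth(truth)
  md <- matchDictionary(truth$bc1[1], truth$bc2[1], dict)
  expect_true(md$bc1_valid & md$bc2_valid & md$concordant)
  # the swap signature: both valid, pair not in dictionary
  md2 <- matchDictionary(truth$bc1[1], truth$bc2[2], dict)
  expect_true(md2$bc1_valid & md2$bc2_valid)
  expect_false(md2$concordant)
  # one substitution invalidates the barcode and leaves concordance NA
  md3 <- matchDictionary(mutateAt(truth$bc1[1], 3), truth$bc2[1], dict)
  expect_false(md3$bc1_valid)
  expect_true(is.na(md3$concordant))
})

test_that("length windows use nearest-rank quantiles", {
  expect_warning(w0 <- deriveLengthWindow(rep(100, 50)), "100 control")
  expect_equal(unname(w0), c(100, 100), ignore_attr = TRUE)
  w <- suppressWarnings(deriveLengthWindow(1:100))
  # nearest-rank oracle: ceiling(p * n)-th order statistic
  expect_equal(unname(w), c(1, 99), ignore_attr = TRUE)
  expect_error(deriveLengthWindow(numeric()), "empty")
  set.seed(55)
  u <- runif(1e4, 2000, 2400)
  wu <- deriveLengthWindow(u)
  expect_lt(abs(wu[["low"]] - 2004), 3)
  expect_lt(abs(wu[["high"]] - 2396), 3)
})

test_that("full-length classification uses closed windows per library", {
  parsed <- data.frame(library_id = c("a", "a", "b", "c"),
                       bc_to_bc_len = c(200, 250, 199, 225),
                       read_len = c(600, 800, 620, 700))
  out <- classifyReadLengths(parsed, bc_to_bc_window = c(200, 250),
                             itr_windows = list(a = c(500, 750),
                                                b = c(650, 900)))
  expect_equal(out$full_bc_to_bc, c(TRUE, TRUE, FALSE, TRUE)) # closed ends
  expect_equal(out$full_itr_to_itr, c(TRUE, FALSE, FALSE, NA))
})

test_that("hairpin dimers are detected, split and survive noise", {
  truth <- smallTruth(30, seed = 56)
  d <- shortDesign()
  cargo <- buildCargo(d, truth$bc1[1], truth$bc2[1])
  dimer <- paste0(cargo, "GCGGACCGAGCGGCCGC", revComp(cargo))
  dm <- detectDimer(dimer, expected_len = nchar(cargo))
  expect_true(dm$is_dimer)
  expect_equal(dm$split_start, nchar(cargo))
  expect_false(detectDimer(cargo, expected_len = nchar(cargo))$is_dimer)
  # noisy dimers: detection rate at least 95%
  cfg <- simulationConfig(n_reads = 300, swap_rate = 0, frac_dimer = 1,
                          sub_rate = 0.05, seed = 57)
  sim <- simulatePackagedReads(d, truth, cfg)
  hitrate <- mean(vapply(sim$reads$seq, function(s)
    detectDimer(s, expected_len = d@itr_to_itr_target)$is_dimer, TRUE))
  expect_gte(hitrate, 0.95)
  # and the split forward pass parses like a normal read
  pr <- parseReads(setNames(sim$reads$seq[1:50], sim$reads$read_id[1:50]),
                   d, dict = dictFromTruth(truth))
  expect_gte(mean(pr$parsed$is_dimer[1:50]), 0.9)
  expect_gt(mean(pr$parsed$pass_layout[pr$parsed$is_dimer]), 0.8)
})

test_that("parse tallies are invariant to reverse-complementing all reads", {
  truth <- smallTruth(60, seed = 58)
  d <- shortDesign()
  cfg <- simulationConfig(n_reads = 300, swap_rate = 0.3, sub_rate = 0.005,
                          ins_rate = 0.002, del_rate = 0.002, seed = 59)
  sim <- simulatePackagedReads(d, truth, cfg)
  dict <- dictFromTruth(truth)
  reads <- setNames(sim$reads$seq, sim$reads$read_id)
  pr1 <- parseReads(reads, d, dict = dict, bc_to_bc_window = c(200, 320))
  pr2 <- parseReads(setNames(revComp(reads), names(reads)), d, dict = dict,
                    bc_to_bc_window = c(200, 320))
  cols <- c("bc1", "bc2", "index_obs", "insert_seq", "bc_to_bc_len",
            "bc1_valid", "bc2_valid", "concordant", "full_bc_to_bc")
  expect_equal(as.data.frame(pr1$parsed)[, cols],
               as.data.frame(pr2$parsed)[, cols])
  expect_equal(tallySwaps(pr1$parsed, by = character(0)),
               tallySwaps(pr2$parsed, by = character(0)))
})

test_that("noise-free multi-library reads all parse to their true library", {
  truth <- smallTruth(80, seed = 60)
  designs <- defaultLibraryDesigns()
  main <- designs[names(designs) != "parental"]
  cfg <- simulationConfig(n_reads = 300, swap_rate = 0, seed = 61)
  sim <- simulatePackagedReads(main, truth, cfg)
  pr <- parseReads(setNames(sim$reads$seq, sim$reads$read_id), designs,
                   dict = dictFromTruth(truth))
  expect_true(all(pr$parsed$pass_layout))
  expect_equal(pr$parsed$library_id, sim$truth$library_id)
  expect_true(all(pr$parsed$concordant))
})

test_that("vectorized parsing agrees with the single-read operations", {
  truth <- smallTruth(40, seed = 62)
  d <- shortDesign()
  cfg <- simulationConfig(n_reads = 60, swap_rate = 0.2, sub_rate = 0.02,
                          ins_rate = 0.005, del_rate = 0.005, seed = 63)
  sim <- simulatePackagedReads(d, truth, cfg)
  pr <- parseReads(setNames(sim$reads$seq, sim$reads$read_id), d)
  expect_gte(sum(pr$parsed$pass_layout), 40)
  for (i in which(pr$parsed$pass_layout)) {
    # the pipeline canonicalizes minus reads before extraction; apply
    # the single-read operations to the same orientation
    s <- sim$reads$seq[i]
    if (pr$parsed$strand[i] == "-") s <- revComp(s)
    f <- extractFeatures(s, locateSignposts(s, d@signposts), d)
    expect_true(f$ok)
    expect_equal(pr$parsed$bc1[i], f$bc1)
    expect_equal(pr$parsed$bc2[i], f$bc2)
    expect_equal(pr$parsed$insert_seq[i], f$insert_seq)
    expect_equal(pr$parsed$bc_to_bc_len[i], f$bc_to_bc_len)
  }
})

test_that("reads failing any filter never enter the swap denominator", {
  truth <- smallTruth(60, seed = 64)
  d <- shortDesign()
  cfg <- simulationConfig(n_reads = 400, swap_rate = 0.2, sub_rate = 0.02,
                          ins_rate = 0.005, del_rate = 0.005,
                          frac_truncated = 0.15, seed = 65)
  sim <- simulatePackagedReads(d, truth, cfg)
  win <- c(200, 320)
  pr <- parseReads(setNames(sim$reads$seq, sim$reads$read_id), d,
                   dict = dictFromTruth(truth), bc_to_bc_window = win)
  tal <- tallySwaps(pr$parsed, by = character(0))
  expect_equal(tal$n_concordant + tal$n_discordant,
               unname(pr$retention[["full_bc_to_bc"]]))
  # retention cascade is non-increasing
  expect_true(all(diff(unname(pr$retention)) <= 0))
})
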