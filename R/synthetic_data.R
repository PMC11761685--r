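## Simulation of association short reads and packaged long reads with
## ground truth, so every downstream stage can be tested at desk scale.

#' Generate a ground-truth table of unique BC1-BC2 pairs
#'
#' Samples random barcodes, enforcing a minimum pairwise Levenshtein
#' distance within each side by rejection: offending barcodes are
#' resampled until the set is separated or a bounded number of rounds is
#' exhausted (an explicit error when the barcode space is too saturated
#' for the requested separation). Barcodes containing a side's
#' truncation-artifact signature (`ATTAAAC` for BC1, `TAGCGCG` for BC2)
#' or a 10-base G run are never emitted: such clones are
#' indistinguishable from artifacts and cannot survive dictionary
#' validation, so they cannot be part of a recoverable ground truth.
#'
#' @param n_pairs number of clones.
#' @param bc1_len,bc2_len barcode lengths (defaults 15 and 16 nt).
#' @param min_pairwise_dist minimum Levenshtein distance within each
#'   barcode side (0 requests only uniqueness).
#' @param seed RNG seed.
#' @param max_rounds resampling rounds before giving up.
#' @return data.frame with `pair_id`, `bc1`, `bc2`, `clone_weight` (all
#'   weights 1; jackpotting is applied at read simulation).
#' @examples
#' truth <- generateBarcodeTruth(5, seed = 7)
#' truth
#' @export
generateBarcodeTruth <- function(n_pairs, bc1_len = 15L, bc2_len = 16L,
                                 min_pairwise_dist = 0L, seed = 1L,
                                 max_rounds = 60L) {
  stopifnot(n_pairs >= 1)
  sampleSide <- function(len, trunc_signature) {
    clean <- function(v)
      v[!grepl(trunc_signature, v, fixed = TRUE) &
          !grepl("GGGGGGGGGG", v, fixed = TRUE)]
    x <- unique(clean(randomDNA(n_pairs, len)))
    round <- 0L
    repeat {
      # top up to n, then drop one member of every too-close pair
      while (length(x) < n_pairs) {
        x <- unique(c(x, clean(randomDNA(n_pairs - length(x), len))))
        round <- round + 1L
        if (round > max_rounds)
          stop("could not sample ", n_pairs, " unique barcodes of length ",
               len, ": barcode space too saturated")
      }
      if (min_pairwise_dist <= 1L) {
        if (length(x) == n_pairs) return(x)
      } else {
        cp <- .close_pairs(x, as.integer(min_pairwise_dist) - 1L)
        if (nrow(cp) == 0L && length(x) == n_pairs) return(x)
        if (nrow(cp) > 0L) x <- x[-unique(cp$j)]
      }
      round <- round + 1L
      if (round > max_rounds)
        stop("could not achieve min_pairwise_dist = ", min_pairwise_dist,
             " for ", n_pairs, " barcodes of length ", len,
             ": barcode space too saturated")
    }
  }
  withSeed(seed, {
    bc1 <- sampleSide(bc1_len, "ATTAAAC")
    bc2 <- sampleSide(bc2_len, "TAGCGCG")
    data.frame(pair_id = seq_len(n_pairs), bc1 = bc1, bc2 = bc2,
               clone_weight = 1, stringsAsFactors = FALSE)
  })
}

# substitute each base independently with probability `rate`, always to a
# different base; vectorized over sequences of equal length
substituteErrors <- function(seqs, rate) {
  if (rate <= 0 || !length(seqs)) return(seqs)
  L <- nchar(seqs[1])
  nerr <- rbinom(length(seqs), L, rate)
  hit <- which(nerr > 0L)
  bases <- c("A", "C", "G", "T")
  for (i in hit) {
    ch <- strsplit(seqs[i], "", fixed = TRUE)[[1]]
    pos <- sample.int(L, nerr[i])
    repl <- sample(bases, nerr[i], replace = TRUE)
    while (any(same <- repl == ch[pos]))
      repl[same] <- sample(bases, sum(same), replace = TRUE)
    ch[pos] <- repl
    seqs[i] <- paste(ch, collapse = "")
  }
  seqs
}

#' Simulate short-read barcode association data
#'
#' Emits per-read BC1/BC2 observations from a truth table of clones:
#' read counts per clone are Poisson around `mean_depth`, a configurable
#' fraction of clones is "jackpotted" (clonal over-representation), an
#' optional dominant artifact BC2 can capture a fixed fraction of reads,
#' and independent per-base substitution errors are applied last.
#'
#' @param truth pair table from [generateBarcodeTruth()].
#' @param mean_depth mean reads per (unit-weight) clone.
#' @param jackpot_fraction fraction of clones receiving
#'   `jackpot_multiplier` weight.
#' @param jackpot_multiplier relative depth of jackpot clones.
#' @param dominant_bc2 optional artifact BC2 sequence (`NULL` to disable).
#' @param dominant_weight fraction of reads whose BC2 observation is
#'   replaced by the artifact.
#' @param error_rate per-base substitution probability.
#' @param seed RNG seed.
#' @return list with `reads` (data.table: `read_id`, `pair_id`,
#'   `bc1_obs`, `bc2_obs`) and `truth` (the input table with realized
#'   `clone_weight`).
#' @examples
#' truth <- generateBarcodeTruth(10, seed = 1)
#' sim <- simulateAssociationReads(truth, mean_depth = 5, seed = 2)
#' head(sim$reads)
#' @export
simulateAssociationReads <- function(truth, mean_depth,
                                     jackpot_fraction = 0,
                                     jackpot_multiplier = 1000,
                                     dominant_bc2 = NULL,
                                     dominant_weight = 0.025,
                                     error_rate = 0, seed = 1L) {
  stopifnot(mean_depth > 0)
  withSeed(seed, {
    n <- nrow(truth)
    w <- rep(1, n)
    if (jackpot_fraction > 0) {
      nj <- rbinom(1, n, jackpot_fraction)
      if (nj > 0) w[sample.int(n, nj)] <- jackpot_multiplier
    }
    truth$clone_weight <- w
    counts <- rpois(n, mean_depth * w)
    pair_idx <- rep.int(seq_len(n), counts)
    bc1_obs <- truth$bc1[pair_idx]
    bc2_obs <- truth$bc2[pair_idx]
    if (!is.null(dominant_bc2) && !is.na(dominant_bc2) && length(pair_idx)) {
      dom <- runif(length(pair_idx)) < dominant_weight
      bc2_obs[dom] <- dominant_bc2
    }
    bc1_obs <- substituteErrors(bc1_obs, error_rate)
    bc2_obs <- substituteErrors(bc2_obs, error_rate)
    reads <- data.table(read_id = seq_along(pair_idx),
                        pair_id = truth$pair_id[pair_idx],
                        bc1_obs = bc1_obs, bc2_obs = bc2_obs)
    list(reads = reads, truth = truth)
  })
}

#' Apply ONT-like noise to sequences
#'
#' Independent per-base events: deletion, substitution (to a different
#' base), and insertion of one random base after a position. A simple
#' i.i.d. error model -- no homopolymer awareness.
#'
#' @param seqs character vector.
#' @param sub_rate,ins_rate,del_rate per-base probabilities in `[0, 1)`.
#' @param seed RNG seed.
#' @return character vector of noisy sequences.
#' @examples
#' applyOntNoise("ACGTACGTACGT", sub_rate = 0.2, seed = 1)
#' @export
applyOntNoise <- function(seqs, sub_rate = 0, ins_rate = 0, del_rate = 0,
                          seed = 1L) {
  stopifnot(sub_rate >= 0, sub_rate < 1, ins_rate >= 0, ins_rate < 1,
            del_rate >= 0, del_rate < 1)
  if (sub_rate == 0 && ins_rate == 0 && del_rate == 0) return(seqs)
  bases <- c("A", "C", "G", "T")
  noiseChunk <- function(sq) {
    lens <- nchar(sq)
    total <- sum(lens)
    if (total == 0L) return(sq)
    ch <- strsplit(paste(sq, collapse = ""), "", fixed = TRUE)[[1]]
    del <- runif(total) < del_rate
    sub <- runif(total) < sub_rate & !del
    if (any(sub)) {
      idx <- which(sub)
      repl <- sample(bases, length(idx), replace = TRUE)
      while (any(same <- repl == ch[idx]))
        repl[same] <- sample(bases, sum(same), replace = TRUE)
      ch[idx] <- repl
    }
    ins <- runif(total) < ins_rate
    ch[del] <- ""
    if (any(ins))
      ch[ins] <- paste0(ch[ins], sample(bases, sum(ins), replace = TRUE))
    # regroup by read via output-offset arithmetic (no split/paste loop)
    piece_len <- as.integer(!del) + as.integer(ins)
    big <- paste(ch, collapse = "")
    ends_all <- c(0L, cumsum(piece_len))
    out_ends <- ends_all[cumsum(lens) + 1L]
    out_starts <- c(1L, head(out_ends, -1) + 1L)
    substring(big, out_starts, out_ends)
  }
  withSeed(seed, {
    # fixed-size chunks keep peak memory flat on large read sets
    chunk <- pmin(length(seqs),
                  max(1L, as.integer(2e6 / max(1L, nchar(seqs[1])))))
    out <- character(length(seqs))
    starts <- seq(1L, length(seqs), by = chunk)
    for (s in starts) {
      e <- min(s + chunk - 1L, length(seqs))
      out[s:e] <- noiseChunk(seqs[s:e])
    }
    out
  })
}

# clone inserts for one design: homologous/parental designs have one
# fixed insert; non-homologous clones each carry their own fragment from
# the reference pool (plasmid with prob f_plasmid, else genome)
cloneInserts <- function(design, n_clones, pool) {
  if (design@insert_class != "non_homologous")
    return(list(seq = rep(design@insert_seq, n_clones),
                origin = rep("fixed", n_clones)))
  lens <- sample(design@insert_length_range[1]:design@insert_length_range[2],
                 n_clones, replace = TRUE)
  from_plasmid <- runif(n_clones) < design@f_plasmid
  seqs <- character(n_clones)
  for (i in seq_len(n_clones)) {
    ref <- if (from_plasmid[i]) pool$plasmid else pool$genome
    start <- sample.int(nchar(ref) - lens[i], 1)
    seqs[i] <- substr(ref, start, start + lens[i] - 1)
  }
  list(seq = seqs, origin = ifelse(from_plasmid, "plasmid", "genome"))
}

# constant cargo pieces of one design, so whole-library read sets can be
# assembled by vectorized concatenation; mirrors buildCargo exactly
cargoConstants <- function(design) {
  sp <- design@signposts
  spacer <- if (design@index_offset > 0)
    substr(design@filler_pool, 3101, 3100 + design@index_offset) else ""
  fixed <- sum(nchar(sp)) + design@bc1_length + design@bc2_length +
    nchar(design@r2_handle) + nchar(design@insert_index) +
    design@index_offset
  filler_right_len <- design@itr_to_itr_target - fixed -
    design@insert_length - design@filler_left_length
  if (filler_right_len < 0)
    stop("design components exceed itr_to_itr_target; no non-negative filler")
  list(
    pre = paste0(substr(design@filler_pool, 1, design@filler_left_length),
                 sp[["left_up"]]),
    mid = sp[["left_down"]],
    post = paste0(design@r2_handle, design@insert_index, spacer,
                  sp[["right_up"]]),
    tail = paste0(sp[["right_down"]],
                  substr(design@filler_pool, 1001, 1000 + filler_right_len)))
}

# composite off-product insert: two segments from random reference
# loci; same-reference loci are forced apart so the product is
# structurally composite, not an accidental contiguous fragment
compositeInsert <- function(total_len, pool) {
  l1 <- max(20L, as.integer(round(total_len * runif(1, 0.3, 0.7))))
  l2 <- max(20L, total_len - l1)
  draw <- function(l) {
    ref_id <- if (runif(1) < 0.5) "plasmid" else "genome"
    ref <- pool[[ref_id]]
    start <- sample.int(nchar(ref) - l, 1)
    list(ref_id = ref_id, start = start,
         seq = substr(ref, start, start + l - 1))
  }
  s1 <- draw(l1)
  repeat {
    s2 <- draw(l2)
    if (s2$ref_id != s1$ref_id || abs(s2$start - s1$start) > 200) break
  }
  paste0(s1$seq, s2$seq)
}

# hairpin at the junction of dimer reads (forward + hairpin + reverse pass)
dimerHairpin <- function() "GCGGACCGAGCGGCCGC"

#' Simulate packaged long reads with ground truth
#'
#' Draws each read from a clone of the truth table and emits the
#' assembled cargo sequence, injecting barcode-swap chimeras per the
#' configured mechanism, off-products (truncated / composite / parental
#' carryover), hairpin-dimer reads, random strand, and ONT-like noise
#' (applied last; truth labels always refer to the pre-noise template).
#'
#' Mechanisms: `label_swap` replaces BC2 by a uniformly drawn other
#' clone's BC2 with probability `swap_rate` per read (exact rate
#' control). `template_switch` is a mechanistic crossover model, offered
#' as a model rather than an established mechanism: a crossover can occur
#' only inside sequence tracts shared by the two templates (the 67 nt of
#' adapter handles, plus the whole insert when inserts are homologous),
#' with per-base crossover probability `swap_rate`, making the realized
#' swap rate length- and homology-dependent.
#'
#' @param designs a [LibraryDesign-class] or named list of them; reads
#'   are split evenly across designs (parental designs enter only via
#'   `frac_parental`).
#' @param truth pair table from [generateBarcodeTruth()].
#' @param config a [SimulationConfig-class].
#' @param pool reference pool from [syntheticReferencePool()].
#' @return list with `reads` (data.table: `read_id`, `library_id`,
#'   `seq`), `truth` (per-read data.table: `read_id`, `library_id`,
#'   `true_bc1_pair_id`, `true_bc2_pair_id`, `is_swap`, `offproduct`,
#'   `is_dimer`, `strand`), `pairs` (the clone table) and
#'   `clone_inserts` (per design).
#' @examples
#' truth <- generateBarcodeTruth(20, seed = 1)
#' cfg <- simulationConfig(n_reads = 50, swap_rate = 0.5, seed = 3)
#' sim <- simulatePackagedReads(defaultLibraryDesigns()$short_homologous,
#'                              truth, cfg)
#' table(sim$truth$is_swap)
#' @export
simulatePackagedReads <- function(designs, truth, config,
                                  pool = syntheticReferencePool()) {
  stopifnot(is(config, "SimulationConfig"), nrow(truth) >= 1)
  validObject(config)
  if (is(designs, "LibraryDesign")) designs <- setNames(list(designs),
                                                        designs@library_id)
  main <- designs[vapply(designs, function(d) d@insert_class, "") != "parental"]
  if (!length(main)) stop("need at least one non-parental design")
  parental_design <- NULL
  if (config@frac_parental > 0) {
    par <- designs[vapply(designs, function(d) d@insert_class, "") == "parental"]
    parental_design <- if (length(par)) par[[1]] else
      defaultLibraryDesigns(pool)$parental
  }
  n <- config@n_reads
  npairs <- nrow(truth)
  withSeed(config@seed, {
    # clone weights (jackpotting) and per-design clone inserts
    w <- rep(1, npairs)
    if (config@jackpot_fraction > 0) {
      nj <- rbinom(1, npairs, config@jackpot_fraction)
      if (nj > 0) w[sample.int(npairs, nj)] <- config@jackpot_multiplier
    }
    clone_ins <- lapply(main, cloneInserts, n_clones = npairs, pool = pool)
    lib_of_read <- rep(names(main), length.out = n)
    if (n > 1) lib_of_read <- sample(lib_of_read)
    # off-product class per read
    off_levels <- c("none", "truncated", "composite", "parental")
    offp <- sample(off_levels, n, replace = TRUE,
                   prob = c(1 - config@frac_truncated - config@frac_composite -
                              config@frac_parental, config@frac_truncated,
                            config@frac_composite, config@frac_parental))
    is_dimer <- runif(n) < config@frac_dimer
    strand <- sample(c("+", "-"), n, replace = TRUE)
    pairA <- sample.int(npairs, n, replace = TRUE, prob = w)

    pairB <- pairA
    shared_handles <- nchar(main[[1]]@signposts[["left_down"]]) +
      nchar(main[[1]]@r2_handle)
    hom_lib <- vapply(main, function(d) d@insert_class == "homologous",
                      logical(1))
    hom_read <- hom_lib[lib_of_read]

    # nominal (clone) insert per read
    ins <- character(n)
    for (lib in names(main)) {
      sel <- lib_of_read == lib
      ins[sel] <- clone_ins[[lib]]$seq[pairA[sel]]
    }

    # chimera decisions (vectorized per mechanism)
    eligible <- offp != "parental" & npairs > 1 & config@swap_rate > 0
    swap <- rep(FALSE, n)
    cross_pos <- rep(NA_integer_, n)
    if (any(eligible)) {
      if (config@mechanism == "label_swap") {
        swap <- eligible & runif(n) < config@swap_rate
      } else {
        tract <- shared_handles + ifelse(hom_read, nchar(ins), 0L)
        if (any(eligible & tract == 0L))
          warning("template_switch with zero shared tract: no swaps")
        p_swap <- 1 - (1 - config@swap_rate)^tract
        swap <- eligible & tract > 0L & runif(n) < p_swap
        cross_pos[swap] <- 1L + as.integer(floor(runif(sum(swap)) *
                                                   tract[swap]))
      }
    }
    if (any(swap)) {
      # uniformly drawn other clone
      b <- sample.int(npairs - 1L, sum(swap), replace = TRUE)
      b <- b + (b >= pairA[swap])
      pairB[swap] <- b
      if (config@mechanism == "template_switch") {
        # crossover in the R1 handle (upstream of the insert): the insert
        # and everything downstream come from clone b
        r1 <- nchar(main[[1]]@signposts[["left_down"]])
        sel_b_ins <- swap & !hom_read & !is.na(cross_pos) & cross_pos <= r1
        for (lib in names(main)) {
          sel <- sel_b_ins & lib_of_read == lib
          ins[sel] <- clone_ins[[lib]]$seq[pairB[sel]]
        }
      }
    }

    # off-products
    tsel <- which(offp == "truncated")
    if (length(tsel)) {
      L <- nchar(ins[tsel])
      keep <- runif(length(tsel), 0.15, 0.6)
      drop_len <- pmax(1L, as.integer(round(L * (1 - keep))))
      drop_start <- 1L + as.integer(floor(runif(length(tsel)) *
                                            pmax(1L, L - drop_len)))
      ins[tsel] <- paste0(substr(ins[tsel], 1, drop_start - 1),
                          substr(ins[tsel], drop_start + drop_len, L))
    }
    for (i in which(offp == "composite"))
      ins[i] <- compositeInsert(nchar(ins[i]), pool)

    # assemble cargoes per design (vectorized concatenation)
    seqs <- character(n)
    bc1v <- truth$bc1[pairA]
    bc2v <- truth$bc2[pairB]
    for (lib in names(main)) {
      sel <- lib_of_read == lib & offp != "parental"
      if (!any(sel)) next
      k <- cargoConstants(main[[lib]])
      seqs[sel] <- paste0(k$pre, bc1v[sel], k$mid, ins[sel], k$post,
                          bc2v[sel], k$tail)
    }
    psel <- offp == "parental"
    if (any(psel)) {
      k <- cargoConstants(parental_design)
      seqs[psel] <- paste0(k$pre, bc1v[psel], k$mid,
                           parental_design@insert_seq, k$post,
                           truth$bc2[pairA[psel]], k$tail)
    }
    if (any(is_dimer))
      seqs[is_dimer] <- paste0(seqs[is_dimer], dimerHairpin(),
                               revComp(seqs[is_dimer]))
    neg <- strand == "-"
    if (any(neg)) seqs[neg] <- revComp(seqs[neg])
    # derived stream for the noise stage; double arithmetic avoids
    # integer overflow for large user seeds
    noise_seed <- as.integer((as.numeric(config@seed) * 7919 + 13) %%
                               2147483629)
    seqs <- applyOntNoise(seqs, config@sub_rate, config@ins_rate,
                          config@del_rate, seed = noise_seed)
    tr <- data.table(read_id = paste0("read_", seq_len(n)),
                     library_id = lib_of_read,
                     true_bc1_pair_id = truth$pair_id[pairA],
                     true_bc2_pair_id = truth$pair_id[pairB],
                     is_swap = pairB != pairA, offproduct = offp,
                     is_dimer = is_dimer, strand = strand)
    list(reads = data.table(read_id = tr$read_id, library_id = lib_of_read,
                            seq = seqs),
         truth = tr, pairs = truth, clone_inserts = clone_ins)
  })
}

#' Write a simulation to FASTQ plus truth tables
#'
#' Writes `reads.fastq` (constant dummy qualities), `truth_pairs.tsv`,
#' `truth_reads.tsv` and a `config.json` sidecar echoing the
#' configuration.
#'
#' @param sim result of [simulatePackagedReads()].
#' @param config the [SimulationConfig-class] used.
#' @param outdir output directory (created if needed).
#' @param quality_char dummy base quality character.
#' @return invisibly, the paths written.
#' @export
writeSimulation <- function(sim, config, outdir, quality_char = "I") {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  fq <- file.path(outdir, "reads.fastq")
  seqs <- DNAStringSet(setNames(sim$reads$seq, sim$reads$read_id))
  quals <- PhredQuality(vapply(width(seqs), function(wd)
    strrep(quality_char, wd), character(1)))
  writeXStringSet(QualityScaledDNAStringSet(seqs, quals), fq,
                  format = "fastq")
  p1 <- file.path(outdir, "truth_pairs.tsv")
  p2 <- file.path(outdir, "truth_reads.tsv")
  fwrite(sim$pairs, p1, sep = "\t")
  fwrite(sim$truth[, c("read_id", "library_id", "is_swap", "offproduct",
                       "is_dimer", "strand")], p2, sep = "\t")
  cfgfile <- file.path(outdir, "config.json")
  slots <- methods::slotNames(class(config))
  cfg <- lapply(setNames(slots, slots), function(s) slot(config, s))
  jsonlite::write_json(cfg, cfgfile, auto_unbox = TRUE, pretty = TRUE)
  invisible(c(fastq = fq, truth_pairs = p1, truth_reads = p2,
              config = cfgfile))
}
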