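## Building the validated BC1-BC2 pair dictionary from association reads:
## pile-up, abundance classes, artifact filters, Levenshtein pruning,
## connected-component error correction, and the unique-pairing filter.

#' Extract barcode observations from association FASTQ files
#'
#' Pulls the BC1 and BC2 cycle windows out of a paired-end run. By
#' default BC1 is read2 cycles 1-15 (a 16-cycle barcode read truncated to
#' the 15-nt barcode) and BC2 is read1 cycles 21-36; both windows are
#' configurable.
#'
#' @param read1_fastq,read2_fastq FASTQ paths (read1 carries BC2, read2
#'   carries BC1 under the default layout).
#' @param bc1_window,bc2_window 1-based inclusive cycle windows
#'   `c(first, last)` within read2 and read1 respectively.
#' @return data.table with `bc1_obs`, `bc2_obs` (uppercase).
#' @export
extractAssociationBarcodes <- function(read1_fastq, read2_fastq,
                                       bc1_window = c(1L, 15L),
                                       bc2_window = c(21L, 36L)) {
  r1 <- readDNAStringSet(read1_fastq, format = "fastq")
  r2 <- readDNAStringSet(read2_fastq, format = "fastq")
  if (length(r1) != length(r2)) stop("read1/read2 record counts differ")
  data.table(
    bc1_obs = toupper(substr(as.character(r2), bc1_window[1], bc1_window[2])),
    bc2_obs = toupper(substr(as.character(r1), bc2_window[1], bc2_window[2])))
}

#' Pile up barcode-pair read counts
#'
#' Exact multiset counts of observed (BC1, BC2) pairs, uppercase
#' normalized. Observations whose barcodes have unexpected lengths are
#' skipped and reported in a rejects attribute.
#'
#' @param records data.frame/data.table with columns `bc1_obs`,
#'   `bc2_obs` (one row per read).
#' @param bc1_length,bc2_length expected barcode lengths; `NULL` skips
#'   the length check.
#' @return data.table with `bc1`, `bc2`, `reads`, sorted by decreasing
#'   count; attribute `rejects` gives the number of skipped records.
#' @examples
#' recs <- data.frame(bc1_obs = c("AAACCCGGGTTTAAA", "AAACCCGGGTTTAAA"),
#'                    bc2_obs = c("AAACCCGGGTTTAAAC", "AAACCCGGGTTTAAAC"))
#' tallyPairs(recs)
#' @export
tallyPairs <- function(records, bc1_length = 15L, bc2_length = 16L) {
  dt <- as.data.table(records)[, .(bc1 = toupper(bc1_obs),
                                   bc2 = toupper(bc2_obs))]
  n0 <- nrow(dt)
  if (!is.null(bc1_length)) dt <- dt[nchar(bc1) == bc1_length]
  if (!is.null(bc2_length)) dt <- dt[nchar(bc2) == bc2_length]
  rejects <- n0 - nrow(dt)
  out <- dt[, .(reads = .N), by = .(bc1, bc2)]
  setorder(out, -reads, bc1, bc2)
  setattr(out, "rejects", rejects)
  out[]
}

# per-side totals over pairs with at least `pileup_min` reads
sideTotals <- function(pair_counts, side = c("BC1", "BC2"), pileup_min = 3L) {
  side <- match.arg(side)
  pc <- as.data.table(pair_counts)[reads >= pileup_min]
  key <- if (side == "BC1") "bc1" else "bc2"
  tot <- pc[, .(total_reads = sum(reads)), by = key]
  setnames(tot, key, "barcode")
  setorder(tot, -total_reads, barcode)
  tot[]
}

#' Classify per-barcode abundance into low / mid / high
#'
#' Totals are computed per side over pairs with `pileup_min` or more
#' reads; barcodes with totals at or below `low_max` are `low` (likely
#' sequencing or PCR errors), at or above `high_cutoff` are `high`
#' (jackpotted clones), the rest `mid`. The mid/high boundary is data
#' dependent; see [proposeHighCutoff()].
#'
#' @param pair_counts pair table from [tallyPairs()].
#' @param side `"BC1"` or `"BC2"`.
#' @param low_max inclusive upper bound of the low class (default 5).
#' @param high_cutoff inclusive lower bound of the high class.
#' @param pileup_min minimum pair reads entering the totals (default 3).
#' @return data.table with `barcode`, `side`, `total_reads`, `class`.
#' @export
classifyAbundance <- function(pair_counts, side = c("BC1", "BC2"),
                              low_max = 5L, high_cutoff, pileup_min = 3L) {
  side <- match.arg(side)
  if (high_cutoff <= low_max) stop("high_cutoff must exceed low_max")
  tot <- sideTotals(pair_counts, side, pileup_min)
  tot$side <- side
  tot$class <- ifelse(tot$total_reads <= low_max, "low",
                      ifelse(tot$total_reads >= high_cutoff, "high", "mid"))
  tot[]
}

#' Propose a mid/high abundance boundary
#'
#' Heuristic helper: the count at the valley of the log10 per-barcode
#' total histogram between the bulk mode and the high-count tail.
#'
#' @param totals numeric vector of per-barcode totals (or the table from
#'   [classifyAbundance()]).
#' @param low_max low-class bound excluded from the fit.
#' @return proposed `high_cutoff` (numeric).
#' @export
proposeHighCutoff <- function(totals, low_max = 5L) {
  if (is.data.frame(totals)) totals <- totals$total_reads
  x <- log10(totals[totals > low_max])
  if (length(x) < 10) return(100 * stats::median(totals))
  d <- stats::density(x, bw = "nrd0")
  # valley: minimum of the density above the main mode
  main_mode <- d$x[which.max(d$y)]
  right <- d$x > main_mode
  if (!any(right)) return(100 * stats::median(totals))
  valley <- d$x[right][which.min(d$y[right])]
  10^valley
}

#' Remove a dominant artifact barcode and its Levenshtein neighborhood
#'
#' The artifact barcode (given, or auto-detected as the most abundant)
#' plus all barcodes within `radius` edits of it are removed from
#' consideration.
#'
#' @param barcodes character vector (one side's barcodes), or the table
#'   from [classifyAbundance()] when `dominant = "auto"`.
#' @param dominant the artifact sequence, or `"auto"` to take the
#'   highest-total barcode of `barcodes` (then a data.frame with
#'   `barcode`, `total_reads`).
#' @param radius Levenshtein radius (default 2).
#' @return character vector of removed barcodes (including the dominant
#'   itself when present).
#' @examples
#' removeDominant(c("AAAA", "AAAT", "GGGG"), dominant = "AAAA", radius = 1)
#' @export
removeDominant <- function(barcodes, dominant, radius = 2L) {
  if (identical(dominant, "auto")) {
    stopifnot(is.data.frame(barcodes))
    dominant <- barcodes$barcode[which.max(barcodes$total_reads)]
  }
  if (is.data.frame(barcodes)) barcodes <- barcodes$barcode
  hit <- .has_close_in(barcodes, dominant, as.integer(radius))
  unique(c(dominant[dominant %in% barcodes], barcodes[hit]))
}

#' Remove artifact barcodes: G homopolymers and truncation signatures
#'
#' Removes barcodes containing a run of `max_homopolymer_G` or more
#' consecutive G, or containing the side-specific post-barcode sequence
#' that marks a truncated barcode (the constant sequence read into when
#' the barcode is short).
#'
#' @param barcodes character vector.
#' @param side `"BC1"` or `"BC2"` (selects the default signature).
#' @param max_homopolymer_G minimum removed G-run length (default 10).
#' @param trunc_signature the post-barcode sequence; defaults to
#'   `ATTAAAC` for BC1 and `TAGCGCG` for BC2.
#' @return character vector of removed barcodes.
#' @examples
#' filterArtifacts(c("GGGGGGGGGGAAAAA", "ACGTACGTACGTACG"), side = "BC1")
#' @export
filterArtifacts <- function(barcodes, side = c("BC1", "BC2"),
                            max_homopolymer_G = 10L,
                            trunc_signature = NULL) {
  side <- match.arg(side)
  if (is.null(trunc_signature))
    trunc_signature <- if (side == "BC1") "ATTAAAC" else "TAGCGCG"
  g_run <- strrep("G", max_homopolymer_G)
  bad <- grepl(g_run, barcodes, fixed = TRUE) |
    grepl(trunc_signature, barcodes, fixed = TRUE)
  barcodes[bad]
}

#' Prune mid-count barcodes near high-count barcodes
#'
#' Mid-class barcodes within `radius` edits of any high-class barcode
#' are removed, so that sequencing errors of abundant clones are not
#' retained as spurious mid-count barcodes.
#'
#' @param mid,high character vectors (disjoint).
#' @param radius Levenshtein radius (default 2).
#' @return pruned `mid` vector.
#' @export
pruneMidByHigh <- function(mid, high, radius = 2L) {
  if (!length(high) || !length(mid)) return(mid)
  if (any(mid %in% high)) stop("mid and high sets must be disjoint")
  mid[!.has_close_in(mid, high, as.integer(radius))]
}

#' Error-correct high-count barcodes by connected components
#'
#' Builds the undirected graph connecting high-count barcodes within
#' `radius` edits and keeps the most abundant member of each connected
#' component. Components of two or more members whose max/min count fold
#' change is below `min_fold` are discarded entirely as ambiguous, as are
#' components whose maximum count is tied.
#'
#' @param counts named numeric vector: high-class barcode -> total reads.
#' @param radius Levenshtein radius (default 2).
#' @param min_fold minimum max/min fold change for a multi-member
#'   component to be trusted (default 10).
#' @return character vector of representative (valid) barcodes.
#' @examples
#' correctHighCounts(c(AAAA = 1000, AAAT = 5, GGGG = 70))
#' @export
correctHighCounts <- function(counts, radius = 2L, min_fold = 10) {
  stopifnot(all(counts > 0), !is.null(names(counts)))
  bcs <- names(counts)
  if (!length(bcs)) return(character())
  cp <- .close_pairs(bcs, as.integer(radius))
  memb <- if (nrow(cp)) {
    g <- graph_from_data_frame(
      data.frame(from = bcs[cp$i], to = bcs[cp$j]),
      directed = FALSE, vertices = data.frame(name = bcs))
    components(g)$membership[bcs]
  } else setNames(seq_along(bcs), bcs)
  keep <- character()
  for (comp in split(bcs, memb)) {
    cc <- counts[comp]
    if (length(cc) >= 2) {
      if (max(cc) / min(cc) < min_fold) next      # ambiguous cluster
      if (sum(cc == max(cc)) > 1) next            # tied argmax: discard
    }
    keep <- c(keep, comp[which.max(cc)])
  }
  keep
}

#' Filter pairs for unique BC1-BC2 pairing
#'
#' Retains pairs with at least `min_pair_reads` reads whose barcodes are
#' both in the separately valid sets and for which, on both sides,
#' strictly more than `uniqueness` of that barcode's reads (summed over
#' all pairs passing the read floor) map to this single pair.
#'
#' @param pair_counts table from [tallyPairs()].
#' @param valid_bc1,valid_bc2 separately valid barcode sets.
#' @param min_pair_reads pair read floor (default 2).
#' @param uniqueness per-barcode read fraction that must be strictly
#'   exceeded on both sides (default 0.99).
#' @param provenance optional named list of upstream retained counts to
#'   carry into the dictionary.
#' @return a [PairDictionary-class] (with a warning if empty).
#' @export
buildPairDictionary <- function(pair_counts, valid_bc1, valid_bc2,
                                min_pair_reads = 2L, uniqueness = 0.99,
                                provenance = list()) {
  pc <- as.data.table(pair_counts)[reads >= min_pair_reads]
  prov <- c(provenance,
            list(pairs_read_floor = nrow(pc)))
  pc <- pc[bc1 %in% valid_bc1 & bc2 %in% valid_bc2]
  prov$pairs_both_valid <- nrow(pc)
  if (nrow(pc)) {
    pc[, frac1 := reads / sum(reads), by = bc1]
    pc[, frac2 := reads / sum(reads), by = bc2]
    pc <- pc[frac1 > uniqueness & frac2 > uniqueness]
  }
  prov$pairs_unique <- nrow(pc)
  if (!nrow(pc)) warning("empty pair dictionary")
  pairs <- as.data.frame(pc[, .(bc1, bc2, reads)])
  new("PairDictionary",
      valid_bc1 = as.character(valid_bc1),
      valid_bc2 = as.character(valid_bc2),
      pairs = pairs, uniqueness_threshold = uniqueness,
      provenance = prov)
}

#' Build a pair dictionary from raw pair counts (full filter chain)
#'
#' Runs the whole dictionary construction: abundance classification per
#' side, optional dominant-artifact removal (with Levenshtein
#' neighborhood), homopolymer/truncation artifact filters, pruning of
#' mid-count barcodes near (pre-correction) high-count barcodes,
#' connected-component error correction of the high class, and the
#' unique-pairing filter. Low-class barcodes are excluded outright.
#'
#' @param pair_counts table from [tallyPairs()].
#' @param high_cutoff mid/high boundary (required; see
#'   [proposeHighCutoff()]).
#' @param low_max,pileup_min abundance-class parameters.
#' @param dominant_bc2 artifact BC2 to remove (`NULL` = none, `"auto"` =
#'   most abundant BC2).
#' @param dominant_radius Levenshtein radius around the dominant.
#' @param prune_radius,correct_radius,min_fold pruning/correction
#'   parameters.
#' @param min_pair_reads,uniqueness unique-pairing parameters.
#' @return a [PairDictionary-class] with full provenance.
#' @export
buildDictionary <- function(pair_counts, high_cutoff, low_max = 5L,
                            pileup_min = 3L, dominant_bc2 = NULL,
                            dominant_radius = 2L, prune_radius = 2L,
                            correct_radius = 2L, min_fold = 10,
                            min_pair_reads = 2L, uniqueness = 0.99) {
  pc <- as.data.table(pair_counts)
  prov <- list(pairs_piled = nrow(pc), reads_piled = sum(pc$reads))
  validSide <- function(side) {
    cls <- classifyAbundance(pc, side, low_max, high_cutoff, pileup_min)
    removed <- character()
    if (side == "BC2" && !is.null(dominant_bc2))
      removed <- removeDominant(cls, dominant_bc2, dominant_radius)
    keep <- cls[!cls$barcode %in% removed]
    removed_art <- filterArtifacts(keep$barcode, side)
    keep <- keep[!keep$barcode %in% removed_art]
    mid <- keep$barcode[keep$class == "mid"]
    high <- keep$barcode[keep$class == "high"]
    mid_pruned <- pruneMidByHigh(mid, high, prune_radius)
    high_counts <- setNames(keep$total_reads[keep$class == "high"], high)
    high_valid <- correctHighCounts(high_counts, correct_radius, min_fold)
    prov[[paste0(tolower(side), "_classified")]] <<- nrow(cls)
    prov[[paste0(tolower(side), "_dominant_removed")]] <<- length(removed)
    prov[[paste0(tolower(side), "_artifacts_removed")]] <<- length(removed_art)
    prov[[paste0(tolower(side), "_mid_pruned")]] <<- length(mid) -
      length(mid_pruned)
    prov[[paste0(tolower(side), "_valid")]] <<- length(mid_pruned) +
      length(high_valid)
    c(mid_pruned, high_valid)
  }
  v1 <- validSide("BC1")
  v2 <- validSide("BC2")
  buildPairDictionary(pc, v1, v2, min_pair_reads, uniqueness,
                      provenance = prov)
}

#' Write / read a PairDictionary as plain text
#'
#' `writePairDictionary` writes `pairs.tsv`, `valid_bc1.tsv`,
#' `valid_bc2.tsv` and `provenance.json` under `dir`;
#' `readPairDictionary` reconstructs the object.
#'
#' @param dict a [PairDictionary-class].
#' @param dir directory.
#' @return the directory (write) or a `PairDictionary` (read).
#' @export
writePairDictionary <- function(dict, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fwrite(dict@pairs, file.path(dir, "pairs.tsv"), sep = "\t")
  writeLines(dict@valid_bc1, file.path(dir, "valid_bc1.tsv"))
  writeLines(dict@valid_bc2, file.path(dir, "valid_bc2.tsv"))
  jsonlite::write_json(c(list(uniqueness_threshold =
                                dict@uniqueness_threshold),
                         dict@provenance),
                       file.path(dir, "provenance.json"), auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(dir)
}

#' @rdname writePairDictionary
#' @export
readPairDictionary <- function(dir) {
  pairs <- as.data.frame(fread(file.path(dir, "pairs.tsv")))
  prov <- jsonlite::read_json(file.path(dir, "provenance.json"),
                              simplifyVector = TRUE)
  new("PairDictionary",
      valid_bc1 = readLines(file.path(dir, "valid_bc1.tsv")),
      valid_bc2 = readLines(file.path(dir, "valid_bc2.tsv")),
      pairs = pairs,
      uniqueness_threshold = prov$uniqueness_threshold,
      provenance = prov[setdiff(names(prov), "uniqueness_threshold")])
}
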