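## Insert alignment filtering, redundancy resolution, circular-junction
## fix and simple/composite categorization, plus pairwise insert
## homology against a shuffled null and its analytic expectation.
## Segment coordinates are 0-based half-open; match_fraction is matching
## bases / alignment length including gaps.

# substitution matrix in which N is strongly penalized, so alignments
# never extend through masked (N-replaced) intervals
maskedSubMatrix <- function(match = 2, mismatch = -2) {
  mat <- nucleotideSubstitutionMatrix(match = match, mismatch = mismatch,
                                      baseOnly = FALSE)
  mat["N", ] <- -10
  mat[, "N"] <- -10
  mat
}

# best local alignment of (possibly masked) insert against one reference
# strand; returns NULL below min_score
bestLocalAln <- function(insert_masked, ref, min_score, mat,
                         gap_open, gap_extend) {
  aln <- pairwiseAlignment(DNAString(insert_masked), ref, type = "local",
                           substitutionMatrix = mat,
                           gapOpening = gap_open - gap_extend,
                           gapExtension = gap_extend)
  if (score(aln) < min_score) return(NULL)
  aln
}

#' Align inserts to references into local alignment segments
#'
#' A deliberately small segmental local aligner for desk-scale
#' references: the best Smith-Waterman hit is recorded, its read
#' interval is masked, and the search repeats until the score drops
#' below `min_score` or `max_segments` is reached, over every reference
#' and both strands. External alignments (e.g. PAF from a long-read
#' mapper) can be substituted anywhere downstream -- the filter chain
#' only consumes the segment table.
#'
#' @param inserts named character vector of insert sequences.
#' @param refs named character vector (or `DNAStringSet`) of reference
#'   sequences.
#' @param min_score minimum local alignment score per segment.
#' @param max_segments per-read cap on extracted segments.
#' @param match,mismatch,gap_open,gap_extend scoring; the defaults
#'   (+2 / -4, gap 4 + 2 per base) penalize mismatches and gaps strongly
#'   enough that alignments cannot drift across splice junctions, so
#'   composite inserts stay split into separate segments.
#' @return data.table with `read_id`, `ref_id`, `read_start`,
#'   `read_end`, `ref_start`, `ref_end`, `strand`, `score`,
#'   `match_fraction`.
#' @export
alignSegments <- function(inserts, refs, min_score = 40,
                          max_segments = 5L, match = 2, mismatch = -4,
                          gap_open = 4, gap_extend = 2) {
  if (is.null(names(inserts)))
    names(inserts) <- paste0("read_", seq_along(inserts))
  refs_chr <- as.character(refs)
  nm <- names(refs_chr)
  refs_fwd <- DNAStringSet(toupper(refs_chr))
  names(refs_fwd) <- if (is.null(nm)) paste0("ref_", seq_along(refs_fwd))
    else nm
  mat <- maskedSubMatrix(match, mismatch)
  out <- list()
  for (rid in names(inserts)) {
    cur <- toupper(inserts[[rid]])
    if (is.na(cur) || nchar(cur) < 10) next
    for (seg in seq_len(max_segments)) {
      best <- NULL
      for (ref_id in names(refs_fwd)) {
        for (strand in c("+", "-")) {
          target <- if (strand == "+") refs_fwd[[ref_id]] else
            reverseComplement(refs_fwd[[ref_id]])
          aln <- bestLocalAln(cur, target, min_score, mat, gap_open,
                              gap_extend)
          if (!is.null(aln) &&
              (is.null(best) || score(aln) > best$score_val))
            best <- list(aln = aln, ref_id = ref_id, strand = strand,
                         score_val = score(aln),
                         ref_len = length(refs_fwd[[ref_id]]))
        }
      }
      if (is.null(best)) break
      aln <- best$aln
      rs <- IRanges::start(Biostrings::pattern(aln)) - 1L   # 0-based
      re <- rs + IRanges::width(Biostrings::pattern(aln))
      ss <- IRanges::start(Biostrings::subject(aln)) - 1L
      se <- ss + IRanges::width(Biostrings::subject(aln))
      if (best$strand == "-") {
        tmp <- best$ref_len - se
        se <- best$ref_len - ss
        ss <- tmp
      }
      alen <- Biostrings::nchar(aln)              # incl. gaps
      out[[length(out) + 1L]] <- data.table(
        read_id = rid, ref_id = best$ref_id,
        read_start = rs, read_end = re, ref_start = ss, ref_end = se,
        strand = best$strand, score = best$score_val,
        match_fraction = nmatch(aln) / alen)
      # mask the aligned interval and continue
      substr(cur, rs + 1L, re) <- strrep("N", re - rs)
      if (seg == max_segments) break
    }
  }
  if (!length(out))
    return(data.table(read_id = character(), ref_id = character(),
                      read_start = integer(), read_end = integer(),
                      ref_start = integer(), ref_end = integer(),
                      strand = character(), score = numeric(),
                      match_fraction = numeric()))
  rbindlist(out)
}

#' Filter alignment segments by match fraction
#'
#' Retains segments with match fraction strictly above
#' `min_match_fraction`; per (read, read start) only the best
#' match-fraction segment survives.
#'
#' @param segments segment table (see [alignSegments()]).
#' @param min_match_fraction strict lower bound (default 0.65).
#' @return filtered data.table.
#' @export
filterSegments <- function(segments, min_match_fraction = 0.65) {
  dt <- as.data.table(segments)
  dt <- dt[match_fraction > min_match_fraction]
  if (nrow(dt)) {
    setorder(dt, read_id, read_start, -match_fraction, -score)
    dt <- dt[, .SD[1], by = .(read_id, read_start)]
  }
  dt[]
}

# overlap fraction between two read intervals: overlap / shorter length
overlapFraction <- function(s1, e1, s2, e2) {
  ov <- pmax(0, pmin(e1, e2) - pmax(s1, s2))
  ov / pmin(e1 - s1, e2 - s2)
}

#' Resolve redundant (overlapping) segments within each read
#'
#' Segments overlapping by more than `overlap_threshold` (overlap length
#' over the shorter segment) are redundant; the better match-fraction
#' segment is kept, greedily from best to worst, so the output is
#' mutually at-most-threshold overlapping.
#'
#' @param segments segment table of one or more reads.
#' @param overlap_threshold redundancy threshold (default 0.5).
#' @return non-redundant data.table.
#' @export
resolveRedundancy <- function(segments, overlap_threshold = 0.5) {
  dt <- as.data.table(segments)
  if (nrow(dt) < 2) return(dt[])
  keepRows <- function(sd) {
    o <- order(-sd$match_fraction, -sd$score, sd$read_start)
    kept <- integer()
    for (i in o) {
      if (!length(kept) ||
          all(overlapFraction(sd$read_start[i], sd$read_end[i],
                              sd$read_start[kept],
                              sd$read_end[kept]) <= overlap_threshold))
        kept <- c(kept, i)
    }
    sort(kept)
  }
  dt[, .SD[keepRows(.SD)], by = read_id][]
}

#' Re-categorize two-segment reads spanning a circular junction
#'
#' For reads with exactly two disjoint segments on a circular reference,
#' when one segment starts within `margin` nt of the reference start or
#' the other ends within `margin` nt of the reference end, the pair is a
#' single insert spanning the junction, not a composite.
#'
#' @param segments non-redundant segment table.
#' @param circular_refs named integer vector: circular reference id ->
#'   reference length.
#' @param margin junction margin (default 5 nt).
#' @return character vector of read ids to re-categorize as simple.
#' @export
applyCircularFix <- function(segments, circular_refs, margin = 5L) {
  dt <- as.data.table(segments)
  fixed <- character()
  for (rid in unique(dt$read_id)) {
    sd <- dt[read_id == rid]
    if (nrow(sd) != 2L) next
    ref <- unique(sd$ref_id)
    if (length(ref) != 1L || !ref %in% names(circular_refs)) next
    L <- circular_refs[[ref]]
    touches_start <- any(sd$ref_start < margin)
    touches_end <- any(sd$ref_end > L - margin)
    if (touches_start || touches_end) fixed <- c(fixed, rid)
  }
  fixed
}

#' Categorize inserts as not mapped, simple or composite
#'
#' Zero non-redundant segments: `not_mapped`; one: `simple`; two or
#' more: `composite`, unless re-categorized by the circular-junction
#' fix. Categorization is invariant to segment order, and the fix only
#' ever converts composite to simple.
#'
#' @param segments non-redundant segment table (after
#'   [filterSegments()] and [resolveRedundancy()]).
#' @param read_ids all read ids considered (reads without segments are
#'   `not_mapped`).
#' @param circular_refs named integer vector of circular reference
#'   lengths (optional).
#' @param margin junction margin.
#' @return data.table with `read_id`, `category`, `refs`
#'   (comma-collapsed), `n_segments`, `circular_fixed`.
#' @export
categorizeInsert <- function(segments, read_ids = NULL,
                             circular_refs = NULL, margin = 5L) {
  dt <- as.data.table(segments)
  fixed <- if (!is.null(circular_refs) && nrow(dt))
    applyCircularFix(dt, circular_refs, margin) else character()
  if (nrow(dt)) {
    cat_dt <- dt[, .(n_segments = .N,
                     refs = paste(sort(unique(ref_id)), collapse = ",")),
                 by = read_id]
    cat_dt[, circular_fixed := read_id %in% fixed]
    cat_dt[, category := ifelse(n_segments == 1L | circular_fixed,
                                "simple", "composite")]
  } else {
    cat_dt <- data.table(read_id = character(), n_segments = integer(),
                         refs = character(), circular_fixed = logical(),
                         category = character())
  }
  if (!is.null(read_ids)) {
    missing_ids <- setdiff(read_ids, cat_dt$read_id)
    if (length(missing_ids))
      cat_dt <- rbind(cat_dt,
                      data.table(read_id = missing_ids, n_segments = 0L,
                                 refs = "", circular_fixed = FALSE,
                                 category = "not_mapped"))
  }
  setorder(cat_dt, read_id)
  cat_dt[, c("read_id", "category", "refs", "n_segments",
             "circular_fixed"), with = FALSE][]
}

#' Null score threshold for insert homology calls
#'
#' Draws `n_null` pairs of distinct inserts, shuffles one member of each
#' pair once (uniform base permutation), aligns locally, and takes the
#' maximum score: an empirical null with an approximately 1/`n_null`
#' exceedance level for unrelated pairs.
#'
#' @param insert_sample character vector of insert sequences (>= 2).
#' @param n_null number of null alignments (default 1000).
#' @param seed RNG seed.
#' @param match,mismatch,gap_open,gap_extend scoring.
#' @return numeric threshold score; attributes `n_null`, `fdr_level`.
#' @export
homologyThreshold <- function(insert_sample, n_null = 1000L, seed = 1L,
                              match = 2, mismatch = -2, gap_open = 3,
                              gap_extend = 1) {
  insert_sample <- insert_sample[!is.na(insert_sample) &
                                   nchar(insert_sample) > 0]
  if (length(insert_sample) < 2) stop("need at least two inserts")
  withSeed(seed, {
    scores <- numeric(n_null)
    for (i in seq_len(n_null)) {
      ab <- sample.int(length(insert_sample), 2)
      a <- insert_sample[ab[1]]
      b <- shuffleSeq(insert_sample[ab[2]])
      scores[i] <- localAlignScore(a, b, match, mismatch, gap_open,
                                   gap_extend)
    }
    thr <- max(scores)
  })
  attr(thr, "n_null") <- n_null
  attr(thr, "fdr_level") <- 1 / n_null
  thr
}

#' Call homology between two inserts
#'
#' Local alignment score compared against a shuffled-null threshold
#' (strictly greater = homologous); the raw score is always reported so
#' score-based enrichment analyses stay reproducible under any scheme.
#'
#' @param insert_a,insert_b sequences.
#' @param threshold from [homologyThreshold()].
#' @param match,mismatch,gap_open,gap_extend scoring.
#' @return list with `score`, `threshold`, `homologous`.
#' @export
callHomology <- function(insert_a, insert_b, threshold, match = 2,
                         mismatch = -2, gap_open = 3, gap_extend = 1) {
  sc <- localAlignScore(insert_a, insert_b, match, mismatch, gap_open,
                        gap_extend)
  list(score = sc, threshold = as.numeric(threshold),
       homologous = sc > as.numeric(threshold))
}

#' Analytic expectation of the shared-origin insert-pair fraction
#'
#' Under even random fragmentation, the expected fraction of insert
#' pairs with detectable shared origin is
#' `f_plasmid^2 * insert_len / plasmid_len`: both inserts must come from
#' the plasmid and their windows must overlap.
#'
#' @param f_plasmid fraction of inserts originating from the plasmid.
#' @param insert_len insert length (nt).
#' @param plasmid_len plasmid length (nt).
#' @return expected fraction (numeric scalar).
#' @examples
#' expectedHomologyFraction(0.65, 100, 5000)  # 0.00845
#' @export
expectedHomologyFraction <- function(f_plasmid, insert_len, plasmid_len) {
  stopifnot(f_plasmid >= 0, f_plasmid <= 1, insert_len > 0,
            plasmid_len > 0)
  if (insert_len > plasmid_len)
    stop("insert_len must not exceed plasmid_len")
  f_plasmid^2 * insert_len / plasmid_len
}
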