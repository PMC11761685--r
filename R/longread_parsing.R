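## Long-read parsing: signpost search, layout validation, feature
## extraction, demultiplexing, dictionary matching, length windows and
## dimer handling. Coordinates are 0-based half-open on the raw read;
## minus-strand features are reported after reverse complementing into
## the construct's forward frame.

#' Locate signpost hits in long reads
#'
#' Runs local (Smith-Waterman) alignment of each signpost against each
#' read on both strands and keeps the best hit per signpost per strand
#' when its identity (matching bases / signpost length) reaches
#' `min_identity`. A hit is flagged ambiguous when its best
#' non-overlapping secondary hit also reaches the identity threshold at
#' a comparable score (at least `score_margin` of the best score):
#' short signposts accumulate scattered low-score partial matches by
#' chance, so identity alone does not make a secondary hit a plausible
#' alternative location.
#'
#' @param reads character vector (or `DNAStringSet`) of reads.
#' @param signposts named character of signpost sequences (default
#'   [defaultSignposts()]).
#' @param min_identity identity threshold (default 0.75).
#' @param match,mismatch,gap_open,gap_extend scoring (gap costs
#'   positive: first gapped base costs `gap_open`, further bases
#'   `gap_extend`).
#' @param score_margin fraction of the best score a secondary hit must
#'   reach to flag ambiguity (default 0.9).
#' @return data.table with `read` (index), `signpost_id`, `strand`,
#'   `read_start`, `read_end` (0-based half-open), `score`, `identity`,
#'   `ambiguous`.
#' @examples
#' d <- defaultLibraryDesigns()$short_homologous
#' cargo <- buildCargo(d, strrep("A", 15), strrep("C", 16))
#' locateSignposts(cargo)
#' @export
locateSignposts <- function(reads, signposts = defaultSignposts(),
                            min_identity = 0.75, match = 2, mismatch = -2,
                            gap_open = 3, gap_extend = 1,
                            score_margin = 0.9) {
  reads <- toupper(as.character(reads))
  sp <- toupper(signposts)
  queries <- c(sp, revComp(sp))
  qstrand <- rep(c("+", "-"), each = length(sp))
  qid <- rep(names(sp), 2)
  res <- .sw_scan(reads, queries, match, mismatch, gap_open, gap_extend,
                  min_identity, score_margin,
                  as.integer(qstrand == "-"))
  qlen <- nchar(queries)
  hits <- data.table(
    read = rep(seq_along(reads), times = length(queries)),
    signpost_id = rep(qid, each = length(reads)),
    strand = rep(qstrand, each = length(reads)),
    read_start = as.vector(res$start),
    read_end = as.vector(res$end),
    score = as.vector(res$score),
    identity = as.vector(res$matches) / rep(qlen, each = length(reads)),
    identity2 = as.vector(res$matches2) / rep(qlen, each = length(reads)),
    score2 = as.vector(res$score2))
  hits <- hits[identity >= min_identity]
  hits[, ambiguous := identity2 >= min_identity &
         score2 >= score_margin * score & score2 > 0]
  hits[, c("identity2", "score2") := NULL]
  setorder(hits, read, read_start)
  hits[]
}

#' Validate the signpost layout of one read
#'
#' A read passes when all four signposts are present (reduced to the
#' best-scoring hit per signpost when both strands yield one; a score
#' tie between strands is itself ambiguous), none is ambiguous, all lie
#' on the same strand, and their positional order matches that strand
#' (BC1 block before BC2 block on `+`, reversed on `-`).
#'
#' @param hits signpost hits of a single read (from
#'   [locateSignposts()]).
#' @return list with `pass` (logical), `strand` (`+`/`-`/`NA`),
#'   `reason`, and (on pass) `hits`: the four retained hits after the
#'   per-signpost reduction.
#' @export
validateLayout <- function(hits) {
  expected <- c("left_up", "left_down", "right_up", "right_down")
  fail <- function(reason) list(pass = FALSE, strand = NA_character_,
                                reason = reason)
  if (nrow(hits) > 4L) {
    # best hit per signpost across strands; a cross-strand score tie is
    # an ambiguous location
    by_sp <- split(seq_len(nrow(hits)), hits$signpost_id)
    keep <- integer()
    for (ix in by_sp) {
      if (length(ix) > 1L) {
        sc <- hits$score[ix]
        if (sum(sc == max(sc)) > 1L) return(fail("signpost_ambiguous"))
        ix <- ix[which.max(sc)]
      }
      keep <- c(keep, ix)
    }
    hits <- hits[sort(keep)]
  }
  if (nrow(hits) != 4L || !setequal(hits$signpost_id, expected))
    return(fail("signposts_incomplete"))
  if (any(hits$ambiguous)) return(fail("signpost_ambiguous"))
  if (length(unique(hits$strand)) != 1L) return(fail("mixed_strands"))
  strand <- hits$strand[1]
  pos <- setNames(hits$read_start, hits$signpost_id)[expected]
  ord <- if (strand == "+") all(diff(pos) > 0) else all(diff(pos) < 0)
  if (!ord) return(fail("order_violation"))
  list(pass = TRUE, strand = strand, reason = NA_character_, hits = hits)
}

# mirror hits of a minus-strand read into the coordinates of the
# reverse-complemented (forward-frame) read
mirrorHits <- function(hits, read_len) {
  out <- data.table::copy(hits)
  rs <- read_len - out$read_end
  re <- read_len - out$read_start
  out$read_start <- rs
  out$read_end <- re
  out
}

#' Extract barcode, index and insert features from one read
#'
#' Uses the signpost positions as local reference frames: BC1 is the
#' interval between the left signposts, BC2 between the right signposts,
#' the index sits immediately interior to the right BC2-upstream
#' signpost (offset by the design spacer), and the insert is the
#' interval between the left-downstream signpost and the R2
#' handle/index block. Minus-strand reads are reverse complemented
#' first, so all features are reported in the forward frame.
#'
#' @param read the raw read sequence (character).
#' @param hits its signpost hits ([locateSignposts()]).
#' @param design a [LibraryDesign-class] (geometry of handle, index and
#'   spacer).
#' @return list with `bc1`, `bc2`, `index_obs`, `insert_seq`,
#'   `bc_to_bc_len`, `strand`, `ok`, `reason`.
#' @export
extractFeatures <- function(read, hits, design) {
  lay <- validateLayout(hits)
  if (lay$pass) hits <- lay$hits
  if (!lay$pass)
    return(list(bc1 = NA_character_, bc2 = NA_character_,
                index_obs = NA_character_, insert_seq = NA_character_,
                bc_to_bc_len = NA_integer_, strand = lay$strand, ok = FALSE,
                reason = lay$reason))
  read <- toupper(as.character(read))
  if (lay$strand == "-") {
    read <- revComp(read)
    hits <- mirrorHits(hits, nchar(read))
  }
  p <- split(hits, hits$signpost_id)
  s <- function(id) p[[id]]$read_start
  e <- function(id) p[[id]]$read_end
  idx_len <- nchar(design@insert_index)
  r2_len <- nchar(design@r2_handle)
  bc1_iv <- c(e("left_up"), s("left_down"))
  bc2_iv <- c(e("right_up"), s("right_down"))
  idx_iv <- c(s("right_up") - design@index_offset - idx_len,
              s("right_up") - design@index_offset)
  ins_iv <- c(e("left_down"), idx_iv[1] - r2_len)
  if (bc1_iv[2] < bc1_iv[1] || bc2_iv[2] < bc2_iv[1] ||
      ins_iv[2] < ins_iv[1] || idx_iv[1] < 0)
    return(list(bc1 = NA_character_, bc2 = NA_character_,
                index_obs = NA_character_, insert_seq = NA_character_,
                bc_to_bc_len = NA_integer_, strand = lay$strand, ok = FALSE,
                reason = "negative_interval"))
  sub0 <- function(iv) substr(read, iv[1] + 1L, iv[2]) # 0-based half-open
  list(bc1 = sub0(bc1_iv), bc2 = sub0(bc2_iv), index_obs = sub0(idx_iv),
       insert_seq = sub0(ins_iv),
       bc_to_bc_len = s("right_down") - e("left_up"),
       strand = lay$strand, ok = TRUE, reason = NA_character_)
}

#' Demultiplex an observed index against the design index table
#'
#' Assigns the library whose index is closest in Levenshtein distance,
#' provided the best distance is at most 1 and the margin to the second
#' best is at least 2; otherwise `"ambiguous"`.
#'
#' @param index_obs character vector of observed 10-nt indices.
#' @param index_table named character of design indices (default
#'   [defaultInsertIndices()]).
#' @return character vector of library ids or `"ambiguous"`.
#' @examples
#' demultiplexIndex("AGACTCAAGT")
#' @export
demultiplexIndex <- function(index_obs, index_table = defaultInsertIndices()) {
  out <- rep("ambiguous", length(index_obs))
  known <- !is.na(index_obs) & nzchar(index_obs)
  if (any(known)) {
    d <- levDist(index_obs[known], index_table)
    best <- apply(d, 1, min)
    best_idx <- apply(d, 1, which.min)
    second <- if (ncol(d) > 1) apply(d, 1, function(r) sort(r)[2]) else Inf
    ok <- best <= 1 & (second - best) >= 2
    res <- rep("ambiguous", sum(known))
    res[ok] <- names(index_table)[best_idx[ok]]
    out[known] <- res
  }
  out
}

#' Match extracted barcodes against the pair dictionary
#'
#' Validity is exact membership in the separately valid sets (no error
#' tolerance); concordance is membership of the (BC1, BC2) pair in the
#' dictionary and is defined only when both barcodes are valid.
#'
#' @param bc1,bc2 character vectors of extracted barcodes.
#' @param dict a [PairDictionary-class].
#' @return data.table with `bc1_valid`, `bc2_valid`, `concordant`
#'   (logical, `NA` unless both valid).
#' @export
matchDictionary <- function(bc1, bc2, dict) {
  stopifnot(is(dict, "PairDictionary"))
  v1 <- !is.na(bc1) & bc1 %in% dict@valid_bc1
  v2 <- !is.na(bc2) & bc2 %in% dict@valid_bc2
  conc <- rep(NA, length(bc1))
  both <- v1 & v2
  pair_keys <- paste(dict@pairs$bc1, dict@pairs$bc2)
  conc[both] <- paste(bc1[both], bc2[both]) %in% pair_keys
  data.table(bc1_valid = v1, bc2_valid = v2, concordant = conc)
}

#' Derive an empirical length window from control reads
#'
#' Nearest-rank empirical quantiles of the control length distribution
#' (by default the 1st and 99th percentiles of the size-selected,
#' digested control reads).
#'
#' @param control_lengths numeric vector of control BC-to-BC lengths.
#' @param lo,hi quantile probabilities (defaults 0.01 and 0.99).
#' @return numeric `c(low, high)`; attribute `quantile_convention`
#'   records the nearest-rank rule.
#' @export
deriveLengthWindow <- function(control_lengths, lo = 0.01, hi = 0.99) {
  if (!length(control_lengths)) stop("empty control length set")
  if (length(control_lengths) < 100)
    warning("fewer than 100 control lengths; window unstable")
  w <- nearestRankQuantile(control_lengths, c(lo, hi))
  out <- c(low = w[1], high = w[2])
  attr(out, "quantile_convention") <- "nearest-rank"
  out
}

#' Classify parsed reads as full length
#'
#' `full_bc_to_bc` is true when the BC-to-BC length lies inside the
#' (closed) control-derived window; `full_itr_to_itr` when the total
#' read length lies inside the library's fixed window (`NA` when the
#' library has no window).
#'
#' @param parsed data.frame with `bc_to_bc_len`, `read_len` and
#'   `library_id`.
#' @param bc_to_bc_window numeric `c(low, high)`.
#' @param itr_windows named list of per-library `c(low, high)` windows
#'   (optional).
#' @return `parsed` with `full_bc_to_bc` and `full_itr_to_itr` columns.
#' @export
classifyReadLengths <- function(parsed, bc_to_bc_window,
                                itr_windows = NULL) {
  parsed <- as.data.table(parsed)
  parsed$full_bc_to_bc <- !is.na(parsed$bc_to_bc_len) &
    parsed$bc_to_bc_len >= bc_to_bc_window[1] &
    parsed$bc_to_bc_len <= bc_to_bc_window[2]
  itr <- rep(NA, nrow(parsed))
  if (!is.null(itr_windows)) {
    for (lib in names(itr_windows)) {
      sel <- parsed$library_id == lib & !is.na(parsed$read_len)
      wv <- itr_windows[[lib]]
      itr[sel] <- parsed$read_len[sel] >= wv[1] & parsed$read_len[sel] <= wv[2]
    }
  }
  parsed$full_itr_to_itr <- itr
  parsed[]
}

#' Detect hairpin-dimer reads
#'
#' A dimer read is a forward and a reverse pass of the same molecule
#' joined at a hairpin. Detection requires (a) read length at least
#' `len_ratio` times the expected cargo length, (b) a hairpin match
#' located near the read midpoint, and (c) reverse-complement similarity
#' of the two flanks. A hairpin within `max_hairpin_dist` edits needs
#' only baseline flank similarity; a weaker hairpin (up to twice that
#' distance, as happens under heavy read noise) is accepted only with
#' strong flank similarity. The returned split point yields the forward
#' pass for downstream parsing.
#'
#' @param read read sequence (character scalar).
#' @param expected_len expected (non-dimer) read length.
#' @param hairpin hairpin sequence at the junction.
#' @param max_hairpin_dist maximum edits in the hairpin match.
#' @param len_ratio minimum read length / expected length.
#' @param mid_frac maximum relative distance of the hairpin from the
#'   midpoint.
#' @param flank_identity minimum identity between the left flank and the
#'   reverse complement of the right flank.
#' @return list with `is_dimer`, `split_start`, `split_end` (0-based
#'   half-open hairpin interval, `NA` when not a dimer).
#' @export
detectDimer <- function(read, expected_len,
                        hairpin = dimerHairpin(), max_hairpin_dist = 2L,
                        len_ratio = 1.6, mid_frac = 0.2,
                        flank_identity = 0.6) {
  notdimer <- list(is_dimer = FALSE, split_start = NA_integer_,
                   split_end = NA_integer_)
  read <- toupper(as.character(read))
  L <- nchar(read)
  if (L < len_ratio * expected_len) return(notdimer)
  hp_len <- nchar(hairpin)
  res <- .sw_scan(read, c(hairpin, revComp(hairpin)), 2, -2, 3, 1, 1.1)
  k <- which.max(res$matches[1, ])
  # matches >= hp_len - dist approximates an <= dist edit match
  strong_hp <- res$matches[1, k] >= hp_len - max_hairpin_dist
  weak_hp <- res$matches[1, k] >= hp_len - 2L * max_hairpin_dist
  if (!weak_hp) return(notdimer)
  s <- res$start[1, k]; e <- res$end[1, k]
  mid <- (s + e) / 2
  if (abs(mid - L / 2) > mid_frac * L) return(notdimer)
  flank <- min(200L, s, L - e)
  if (flank >= 30L) {
    left <- substr(read, s - flank + 1L, s)
    right <- substr(read, e + 1L, e + flank)
    mat <- nucleotideSubstitutionMatrix(match = 2, mismatch = -2,
                                        baseOnly = FALSE)
    aln <- pairwiseAlignment(DNAString(left),
                             reverseComplement(DNAString(right)),
                             type = "local", substitutionMatrix = mat,
                             gapOpening = 2, gapExtension = 1)
    need <- if (strong_hp) flank_identity else
      min(0.95, flank_identity + 0.15)
    if (nmatch(aln) / flank < need) return(notdimer)
  } else if (!strong_hp) return(notdimer)
  list(is_dimer = TRUE, split_start = s, split_end = e)
}

#' Parse long reads into ParsedRead records
#'
#' The full parsing cascade: dimer detection and splitting, signpost
#' location, layout validation, feature extraction, demultiplexing,
#' dictionary matching and length classification, with a retention count
#' at every step and a rejection reason per failed read.
#'
#' @param reads named character vector (or `DNAStringSet`) of raw reads.
#' @param designs list of [LibraryDesign-class] (default
#'   [defaultLibraryDesigns()]); supplies signposts, index table and
#'   feature geometry (these are shared across designs).
#' @param dict optional [PairDictionary-class] for validity/concordance.
#' @param bc_to_bc_window optional `c(low, high)` from
#'   [deriveLengthWindow()].
#' @param itr_windows optional named per-library windows.
#' @param min_identity signpost identity threshold.
#' @param expected_len expected cargo length for dimer detection
#'   (default: max design target).
#' @param detect_dimers logical.
#' @return list with `parsed` (data.table, one row per read: `read_id`,
#'   `strand`, `bc1`, `bc2`, `index_obs`, `library_id`, `insert_seq`,
#'   `bc_to_bc_len`, `read_len`, `is_dimer`, `bc1_valid`, `bc2_valid`,
#'   `concordant`, `full_bc_to_bc`, `full_itr_to_itr`, `pass_layout`,
#'   `reject_reason`) and `retention` (named integer vector).
#' @export
parseReads <- function(reads, designs = defaultLibraryDesigns(),
                       dict = NULL, bc_to_bc_window = NULL,
                       itr_windows = NULL, min_identity = 0.75,
                       expected_len = NULL, detect_dimers = TRUE) {
  seqs <- toupper(as.character(reads))
  ids <- names(seqs)
  if (is.null(ids)) ids <- paste0("read_", seq_along(seqs))
  if (is(designs, "LibraryDesign")) designs <- setNames(list(designs),
                                                        designs@library_id)
  d0 <- designs[[1]]
  index_table <- setNames(vapply(designs, function(d) d@insert_index, ""),
                          vapply(designs, function(d) d@library_id, ""))
  if (is.null(expected_len))
    expected_len <- max(vapply(designs, function(d) d@itr_to_itr_target, 1L))
  n <- length(seqs)
  read_len <- nchar(seqs)

  # dimer detection and splitting to the forward pass
  is_dimer <- logical(n)
  parse_seq <- seqs
  if (detect_dimers) {
    cand <- which(read_len >= 1.6 * expected_len)
    for (i in cand) {
      dm <- detectDimer(seqs[i], expected_len)
      if (dm$is_dimer) {
        is_dimer[i] <- TRUE
        parse_seq[i] <- substr(seqs[i], 1L, dm$split_start)
      }
    }
  }

  # reduce to the best hit per (read, signpost) across strands; a score
  # tie between strands is ambiguous (same rule as validateLayout)
  reduceHits <- function(hits) {
    setorder(hits, read, signpost_id, -score)
    hits[, .(strand = strand[1], read_start = read_start[1],
             read_end = read_end[1], score = score[1],
             ambiguous = ambiguous[1] |
               (.N > 1L && score[1] == score[2])),
         by = .(read, signpost_id)]
  }
  red <- reduceHits(locateSignposts(parse_seq, d0@signposts, min_identity))
  # canonicalize orientation: minus-strand reads (by total signpost
  # score) are reverse complemented and re-scanned, so a read and its
  # reverse complement take identical alignment paths and all features
  # mirror exactly
  orig_neg <- rep(FALSE, n)
  if (nrow(red)) {
    ssum <- red[, .(tot = sum(score)), by = .(read, strand)]
    setorder(ssum, read, -tot, strand)
    best_str <- ssum[, .SD[1], by = read]
    neg0 <- best_str$read[best_str$strand == "-"]
    if (length(neg0)) {
      orig_neg[neg0] <- TRUE
      parse_seq[neg0] <- revComp(parse_seq[neg0])
      red2 <- reduceHits(locateSignposts(parse_seq[neg0], d0@signposts,
                                         min_identity))
      red2[, read := neg0[read]]
      red <- rbind(red[!red$read %in% neg0], red2)
    }
  }
  sp_names <- c("left_up", "left_down", "right_up", "right_down")
  w <- if (nrow(red))
    data.table::dcast(red, read ~ signpost_id,
                      value.var = c("read_start", "read_end", "strand",
                                    "ambiguous"))
  else data.table(read = integer())
  for (sp in sp_names) { # reads may miss whole signposts
    for (v in c("read_start_", "read_end_", "strand_", "ambiguous_")) {
      cn <- paste0(v, sp)
      if (!cn %in% names(w))
        w[, (cn) := if (v == "strand_") NA_character_ else
          if (v == "ambiguous_") NA else NA_integer_]
    }
  }
  w <- w[data.table(read = seq_len(n)), on = "read"]
  gs <- function(v, sp) w[[paste0(v, "_", sp)]]
  strand_mat <- cbind(gs("strand", "left_up"), gs("strand", "left_down"),
                      gs("strand", "right_up"), gs("strand", "right_down"))
  complete <- rowSums(!is.na(strand_mat)) == 4L
  amb <- rowSums(cbind(gs("ambiguous", "left_up"),
                       gs("ambiguous", "left_down"),
                       gs("ambiguous", "right_up"),
                       gs("ambiguous", "right_down")), na.rm = TRUE) > 0
  same_strand <- complete & strand_mat[, 1] == strand_mat[, 2] &
    strand_mat[, 2] == strand_mat[, 3] & strand_mat[, 3] == strand_mat[, 4]
  same_strand[is.na(same_strand)] <- FALSE
  strand_v <- ifelse(same_strand, strand_mat[, 1], NA_character_)
  s_lu <- gs("read_start", "left_up");  e_lu <- gs("read_end", "left_up")
  s_ld <- gs("read_start", "left_down"); e_ld <- gs("read_end", "left_down")
  s_ru <- gs("read_start", "right_up");  e_ru <- gs("read_end", "right_up")
  s_rd <- gs("read_start", "right_down"); e_rd <- gs("read_end", "right_down")
  ord_ok <- ifelse(strand_v == "+",
                   s_lu < s_ld & s_ld < s_ru & s_ru < s_rd,
                   s_lu > s_ld & s_ld > s_ru & s_ru > s_rd)
  ord_ok[is.na(ord_ok)] <- FALSE
  pass <- complete & !amb & same_strand & ord_ok
  reason <- rep(NA_character_, n)
  reason[!complete] <- "signposts_incomplete"
  reason[complete & amb] <- "signpost_ambiguous"
  reason[complete & !amb & !same_strand] <- "mixed_strands"
  reason[complete & !amb & same_strand & !ord_ok] <- "order_violation"

  # forward-frame sequences and mirrored coordinates for minus reads
  fwd <- parse_seq
  plen <- nchar(parse_seq)
  negp <- which(pass & strand_v == "-")
  if (length(negp)) {
    fwd[negp] <- revComp(fwd[negp])
    mirror <- function(s, e) {
      ns <- plen[negp] - e[negp]
      ne <- plen[negp] - s[negp]
      list(ns, ne)
    }
    m1 <- mirror(s_lu, e_lu); s_lu[negp] <- m1[[1]]; e_lu[negp] <- m1[[2]]
    m2 <- mirror(s_ld, e_ld); s_ld[negp] <- m2[[1]]; e_ld[negp] <- m2[[2]]
    m3 <- mirror(s_ru, e_ru); s_ru[negp] <- m3[[1]]; e_ru[negp] <- m3[[2]]
    m4 <- mirror(s_rd, e_rd); s_rd[negp] <- m4[[1]]; e_rd[negp] <- m4[[2]]
  }
  idx_len <- nchar(d0@insert_index)
  r2_len <- nchar(d0@r2_handle)
  idx_hi <- s_ru - d0@index_offset
  idx_lo <- idx_hi - idx_len
  neg_iv <- pass & (s_ld < e_lu | s_rd < e_ru | idx_lo < 0 |
                      (idx_lo - r2_len) < e_ld)
  neg_iv[is.na(neg_iv)] <- FALSE
  reason[neg_iv] <- "negative_interval"
  pass <- pass & !neg_iv
  sub0 <- function(lo, hi) { # 0-based half-open, only where pass
    out <- rep(NA_character_, n)
    out[pass] <- substr(fwd[pass], lo[pass] + 1L, hi[pass])
    out
  }
  # report the original read orientation (canonicalized reads flipped)
  rep_strand <- ifelse(orig_neg, ifelse(strand_v == "+", "-", "+"),
                       strand_v)
  parsed <- data.table(
    read_id = ids,
    strand = ifelse(pass, rep_strand, NA_character_),
    bc1 = sub0(e_lu, s_ld),
    bc2 = sub0(e_ru, s_rd),
    index_obs = sub0(idx_lo, idx_hi),
    insert_seq = sub0(e_ld, idx_lo - r2_len),
    bc_to_bc_len = ifelse(pass, s_rd - e_lu, NA_integer_),
    read_len = read_len,
    is_dimer = is_dimer,
    pass_layout = pass,
    reject_reason = reason)
  parsed$library_id <- ifelse(parsed$pass_layout,
                              demultiplexIndex(parsed$index_obs, index_table),
                              NA_character_)
  if (!is.null(dict)) {
    md <- matchDictionary(parsed$bc1, parsed$bc2, dict)
    parsed <- cbind(parsed, md)
  } else {
    parsed$bc1_valid <- NA
    parsed$bc2_valid <- NA
    parsed$concordant <- NA
  }
  if (!is.null(bc_to_bc_window)) {
    parsed <- classifyReadLengths(parsed, bc_to_bc_window, itr_windows)
  } else {
    parsed$full_bc_to_bc <- NA
    parsed$full_itr_to_itr <- NA
  }
  retention <- c(
    input = n,
    layout_pass = sum(parsed$pass_layout),
    demultiplexed = sum(parsed$pass_layout &
                          parsed$library_id != "ambiguous", na.rm = TRUE),
    bc_valid = if (!is.null(dict))
      sum(parsed$pass_layout & parsed$library_id != "ambiguous" &
            parsed$bc1_valid & parsed$bc2_valid, na.rm = TRUE) else NA_integer_,
    full_bc_to_bc = if (!is.null(bc_to_bc_window) && !is.null(dict))
      sum(parsed$pass_layout & parsed$library_id != "ambiguous" &
            parsed$bc1_valid & parsed$bc2_valid & parsed$full_bc_to_bc,
          na.rm = TRUE) else NA_integer_)
  list(parsed = parsed[], retention = retention)
}
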