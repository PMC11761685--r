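#' LibraryDesign: the fixed architecture of one barcoded AAV cargo library
#'
#' Describes one library's cargo layout: the four constant signpost
#' sequences flanking the two barcodes, the 10-nt insert index used for
#' demultiplexing, the insert class and nominal length, and the filler
#' geometry that pads every cargo to a common ITR-to-ITR target length.
#' The assembled forward-strand layout is
#' `[fillerL][SP_left_up][BC1][SP_left_down = Nextera R1 handle][insert]`
#' `[R2 handle][index][spacer][SP_right_up][BC2][SP_right_down][fillerR]`.
#'
#' @slot library_id single identifier string.
#' @slot insert_class one of `"homologous"`, `"non_homologous"`,
#'   `"parental"`.
#' @slot insert_length nominal insert length (nt), excluding the two
#'   adapter handles.
#' @slot insert_length_range length-2 integer; sampling range for
#'   non-homologous inserts (equal to `insert_length` for fixed inserts).
#' @slot insert_index 10-nt library index sequence.
#' @slot insert_seq the fixed insert sequence for homologous/parental
#'   designs (`NA` for non-homologous designs, whose inserts are drawn
#'   from a reference pool).
#' @slot f_plasmid for non-homologous designs, the fraction of inserts
#'   originating from the plasmid (rest from the genome reference).
#' @slot signposts named character(4):
#'   `left_up`, `left_down`, `right_up`, `right_down`.
#' @slot r2_handle the partial Nextera R2 adapter (34 nt) between insert
#'   and index.
#' @slot index_offset spacer length (nt) between index and the right
#'   BC2-upstream signpost.
#' @slot bc1_length,bc2_length barcode lengths (15 and 16 nt).
#' @slot filler_left_length fixed left filler length (nt).
#' @slot filler_pool constant sequence from which both fillers are taken.
#' @slot itr_to_itr_target target total cargo length (nt).
#' @export
setClass("LibraryDesign", representation(
  library_id = "character",
  insert_class = "character",
  insert_length = "integer",
  insert_length_range = "integer",
  insert_index = "character",
  insert_seq = "character",
  f_plasmid = "numeric",
  signposts = "character",
  r2_handle = "character",
  index_offset = "integer",
  bc1_length = "integer",
  bc2_length = "integer",
  filler_left_length = "integer",
  filler_pool = "character",
  itr_to_itr_target = "integer"
))

setValidity("LibraryDesign", function(object) {
  msg <- character()
  if (length(object@library_id) != 1L) msg <- c(msg, "library_id must be scalar")
  if (!object@insert_class %in% c("homologous", "non_homologous", "parental"))
    msg <- c(msg, "invalid insert_class")
  sp <- object@signposts
  if (length(sp) != 4L ||
      !setequal(names(sp), c("left_up", "left_down", "right_up", "right_down")))
    msg <- c(msg, "signposts must be named left_up/left_down/right_up/right_down")
  if (any(!grepl("^[ACGT]+$", sp))) msg <- c(msg, "signposts must be ACGT")
  if (nchar(object@insert_index) != 10L) msg <- c(msg, "insert_index must be 10 nt")
  if (object@insert_class != "non_homologous" && is.na(object@insert_seq))
    msg <- c(msg, "fixed-insert designs need insert_seq")
  if (object@bc1_length < 1L || object@bc2_length < 1L)
    msg <- c(msg, "barcode lengths must be positive")
  if (length(msg)) msg else TRUE
})

#' SimulationConfig: parameters of one packaged-library simulation
#'
#' Bundles the read count, chimera mechanism and rate, ONT-like noise
#' rates, off-product fractions and the RNG seed for
#' [simulatePackagedReads()]. Identical config + seed gives byte-identical
#' output.
#'
#' @slot n_reads number of long reads to emit.
#' @slot swap_rate in `label_swap` mode the per-read probability that BC2
#'   is replaced by another clone's BC2; in `template_switch` mode the
#'   per-base crossover probability within shared sequence tracts.
#' @slot mechanism `"label_swap"` or `"template_switch"`.
#' @slot sub_rate,ins_rate,del_rate per-base ONT noise probabilities.
#' @slot frac_truncated,frac_composite,frac_parental off-product
#'   fractions (sum must be <= 1).
#' @slot frac_dimer probability a read is emitted as a hairpin dimer.
#' @slot jackpot_fraction fraction of clones given jackpot weight.
#' @slot jackpot_multiplier relative abundance of jackpot clones.
#' @slot dominant_bc2 optional artifact BC2 sequence (`NA` to disable).
#' @slot seed RNG seed.
#' @export
setClass("SimulationConfig", representation(
  n_reads = "integer",
  swap_rate = "numeric",
  mechanism = "character",
  sub_rate = "numeric",
  ins_rate = "numeric",
  del_rate = "numeric",
  frac_truncated = "numeric",
  frac_composite = "numeric",
  frac_parental = "numeric",
  frac_dimer = "numeric",
  jackpot_fraction = "numeric",
  jackpot_multiplier = "numeric",
  dominant_bc2 = "character",
  seed = "integer"
))

setValidity("SimulationConfig", function(object) {
  msg <- character()
  pr <- c(swap_rate = object@swap_rate, sub_rate = object@sub_rate,
          ins_rate = object@ins_rate, del_rate = object@del_rate,
          frac_truncated = object@frac_truncated,
          frac_composite = object@frac_composite,
          frac_parental = object@frac_parental,
          frac_dimer = object@frac_dimer,
          jackpot_fraction = object@jackpot_fraction)
  bad <- pr < 0 | pr > 1
  if (any(bad)) msg <- c(msg, paste("probabilities outside [0,1]:",
                                    paste(names(pr)[bad], collapse = ", ")))
  if (object@frac_truncated + object@frac_composite + object@frac_parental > 1)
    msg <- c(msg, "frac_truncated + frac_composite + frac_parental > 1")
  if (!object@mechanism %in% c("label_swap", "template_switch"))
    msg <- c(msg, "mechanism must be label_swap or template_switch")
  if (object@n_reads < 0L) msg <- c(msg, "n_reads must be >= 0")
  if (length(msg)) msg else TRUE
})

#' PairDictionary: the validated set of unique BC1-BC2 pairs
#'
#' Holds the separately valid BC1 and BC2 sets (exact membership tests for
#' long-read filtering), the retained unique pairs, the uniqueness
#' threshold used, and the provenance counts at each filtering step.
#'
#' @slot valid_bc1,valid_bc2 character vectors of valid barcodes.
#' @slot pairs data.frame with columns `bc1`, `bc2` (and optionally
#'   `reads`).
#' @slot uniqueness_threshold the per-barcode read-fraction a pair must
#'   strictly exceed on both sides.
#' @slot provenance named list of counts retained at each filter step.
#' @export
setClass("PairDictionary", representation(
  valid_bc1 = "character",
  valid_bc2 = "character",
  pairs = "data.frame",
  uniqueness_threshold = "numeric",
  provenance = "list"
))

setValidity("PairDictionary", function(object) {
  msg <- character()
  p <- object@pairs
  if (!all(c("bc1", "bc2") %in% colnames(p)))
    msg <- c(msg, "pairs must have columns bc1, bc2")
  else {
    if (!all(p$bc1 %in% object@valid_bc1))
      msg <- c(msg, "some pair bc1 not in valid_bc1")
    if (!all(p$bc2 %in% object@valid_bc2))
      msg <- c(msg, "some pair bc2 not in valid_bc2")
    if (anyDuplicated(paste(p$bc1, p$bc2)))
      msg <- c(msg, "duplicate pairs")
  }
  u <- object@uniqueness_threshold
  if (length(u) != 1L || u < 0 || u > 1)
    msg <- c(msg, "uniqueness_threshold must be a scalar in [0,1]")
  if (length(msg)) msg else TRUE
})

#' @describeIn LibraryDesign compact display
#' @param object a `LibraryDesign`.
#' @export
setMethod("show", "LibraryDesign", function(object) {
  cat("LibraryDesign <", object@library_id, ">\n", sep = "")
  cat("  insert: ", object@insert_class, ", ", object@insert_length,
      " nt (range ", paste(object@insert_length_range, collapse = "-"),
      ")\n", sep = "")
  cat("  index:  ", object@insert_index, "\n", sep = "")
  cat("  target ITR-to-ITR: ", object@itr_to_itr_target, " nt\n", sep = "")
})

#' @describeIn SimulationConfig compact display
#' @param object a `SimulationConfig`.
#' @export
setMethod("show", "SimulationConfig", function(object) {
  cat("SimulationConfig: n_reads=", object@n_reads,
      ", mechanism=", object@mechanism,
      ", swap_rate=", object@swap_rate, "\n", sep = "")
  cat("  noise sub/ins/del: ", object@sub_rate, "/", object@ins_rate, "/",
      object@del_rate, "\n", sep = "")
  cat("  off-products trunc/comp/parental/dimer: ",
      object@frac_truncated, "/", object@frac_composite, "/",
      object@frac_parental, "/", object@frac_dimer, "\n", sep = "")
  cat("  seed: ", object@seed, "\n", sep = "")
})

#' @describeIn PairDictionary compact display
#' @param object a `PairDictionary`.
#' @export
setMethod("show", "PairDictionary", function(object) {
  cat("PairDictionary: ", nrow(object@pairs), " pairs, ",
      length(object@valid_bc1), " valid BC1, ",
      length(object@valid_bc2), " valid BC2\n", sep = "")
  cat("  uniqueness threshold: >", object@uniqueness_threshold, "\n", sep = "")
  if (length(object@provenance))
    cat("  provenance steps: ",
        paste(names(object@provenance), collapse = " > "), "\n", sep = "")
})

#' @rdname PairDictionary-accessors
#' @param x a `PairDictionary`.
#' @export
setGeneric("validPairs", function(x) standardGeneric("validPairs"))

#' Accessors for PairDictionary
#'
#' `validPairs` returns the retained pair table; `validBarcodes` the
#' separately valid barcode set of one side; `provenance` the retained
#' counts along the filter chain.
#'
#' @name PairDictionary-accessors
#' @param x a `PairDictionary`.
#' @param side `"BC1"` or `"BC2"`.
#' @export
setMethod("validPairs", "PairDictionary", function(x) x@pairs)

#' @rdname PairDictionary-accessors
#' @export
setGeneric("validBarcodes", function(x, side = c("BC1", "BC2"))
  standardGeneric("validBarcodes"))

#' @rdname PairDictionary-accessors
#' @export
setMethod("validBarcodes", "PairDictionary", function(x, side = c("BC1", "BC2")) {
  side <- match.arg(side)
  if (side == "BC1") x@valid_bc1 else x@valid_bc2
})

#' @rdname PairDictionary-accessors
#' @export
setGeneric("provenance", function(x) standardGeneric("provenance"))

#' @rdname PairDictionary-accessors
#' @export
setMethod("provenance", "PairDictionary", function(x) x@provenance)

#' Construct a SimulationConfig
#'
#' @param n_reads number of long reads.
#' @param swap_rate chimera rate; see [SimulationConfig-class] for its
#'   meaning under each mechanism.
#' @param mechanism `"label_swap"` (exact rate control) or
#'   `"template_switch"` (homology-tract crossover model).
#' @param sub_rate,ins_rate,del_rate per-base noise probabilities.
#' @param frac_truncated,frac_composite,frac_parental,frac_dimer
#'   off-product fractions.
#' @param jackpot_fraction,jackpot_multiplier clonal jackpotting.
#' @param dominant_bc2 optional artifact BC2 sequence.
#' @param seed RNG seed.
#' @return a validated `SimulationConfig`.
#' @examples
#' simulationConfig(n_reads = 100, swap_rate = 0.2, seed = 1)
#' @export
simulationConfig <- function(n_reads, swap_rate = 0, mechanism = "label_swap",
                             sub_rate = 0, ins_rate = 0, del_rate = 0,
                             frac_truncated = 0, frac_composite = 0,
                             frac_parental = 0, frac_dimer = 0,
                             jackpot_fraction = 0, jackpot_multiplier = 1000,
                             dominant_bc2 = NA_character_, seed = 1L) {
  new("SimulationConfig", n_reads = as.integer(n_reads),
      swap_rate = swap_rate, mechanism = mechanism,
      sub_rate = sub_rate, ins_rate = ins_rate, del_rate = del_rate,
      frac_truncated = frac_truncated, frac_composite = frac_composite,
      frac_parental = frac_parental, frac_dimer = frac_dimer,
      jackpot_fraction = jackpot_fraction,
      jackpot_multiplier = jackpot_multiplier,
      dominant_bc2 = as.character(dominant_bc2), seed = as.integer(seed))
}
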