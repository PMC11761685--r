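## Library design constants and cargo assembly.

#' The four constant signpost sequences flanking the barcodes
#'
#' Constant regions used to anchor feature extraction in long reads:
#' upstream/downstream of BC1 on the left (the downstream one being the
#' 33-nt Nextera R1 adapter handle) and upstream/downstream of BC2 on the
#' right.
#'
#' @return named character(4).
#' @examples defaultSignposts()
#' @export
defaultSignposts <- function() {
  c(left_up    = "CGCGTTTAAT",
    left_down  = "TCGTCGGCAGCGTCAGATGTGTATAAGAGACAG",
    right_up   = "GATCCGTCGATCGACTGAGT",
    right_down = "TAGCGCGCCATTAGGCATGA")
}

#' The seven 10-nt insert indices used for demultiplexing
#'
#' One index per library (parental plus the six length-by-class
#' libraries); all pairwise Levenshtein distances are at least 3, so the
#' best-within-1 / margin-2 demultiplexing rule is unambiguous.
#'
#' @return named character(7).
#' @examples defaultInsertIndices()
#' @export
defaultInsertIndices <- function() {
  c(parental            = "CTCTTCAGAT",
    short_homologous    = "AGACTCAAGT",
    short_nonhomologous = "GAGACGGTCA",
    mid_homologous      = "AGACGATCTG",
    mid_nonhomologous   = "GAGACCCTAA",
    long_homologous     = "AGACATTGGC",
    long_nonhomologous  = "GAGACCATCG")
}

# partial Nextera R2 mosaic-end adapter, 34 nt; together with the 33-nt R1
# handle this is the 67 bp of adapter homology shared by all inserts
nexteraR2Handle <- function() "GTCTCGTGGGCTCGGAGATGTGTATAAGAGACAG"

#' Synthetic reference pool for insert generation
#'
#' A deterministic pair of references standing in for the insert source
#' material: a circular "plasmid" and a linear "genome" fragment, both
#' i.i.d. random sequence under a fixed seed. Homologous inserts are fixed
#' windows of the plasmid; non-homologous inserts are sampled from either
#' reference. Both sequences are synthetic.
#'
#' @param plasmid_length,genome_length reference lengths (nt).
#' @param seed RNG seed (fixed default so the pool is a package constant).
#' @return list with `plasmid`, `genome` (character), and `circular`
#'   (named logical).
#' @examples
#' pool <- syntheticReferencePool()
#' nchar(pool$plasmid)
#' @export
syntheticReferencePool <- function(plasmid_length = 5000L,
                                   genome_length = 50000L, seed = 146L) {
  withSeed(seed, {
    plasmid <- randomDNA(1, plasmid_length)
    genome <- randomDNA(1, genome_length)
    list(plasmid = plasmid, genome = genome,
         circular = c(plasmid = TRUE, genome = FALSE))
  })
}

#' Construct a LibraryDesign
#'
#' @param library_id identifier.
#' @param insert_class `"homologous"`, `"non_homologous"` or
#'   `"parental"`.
#' @param insert_length nominal insert length (nt).
#' @param insert_index 10-nt index sequence.
#' @param insert_seq fixed insert sequence (required unless
#'   non-homologous).
#' @param insert_length_range sampling range for non-homologous insert
#'   lengths.
#' @param f_plasmid fraction of non-homologous inserts drawn from the
#'   plasmid reference.
#' @param signposts named character(4); defaults to [defaultSignposts()].
#' @param r2_handle partial Nextera R2 adapter.
#' @param index_offset spacer between index and right_up signpost (nt).
#' @param bc1_length,bc2_length barcode lengths.
#' @param filler_left_length fixed left filler length (nt).
#' @param filler_pool constant filler source sequence (defaults to a
#'   window of the synthetic genome reference).
#' @param itr_to_itr_target total cargo target length (nt).
#' @return a validated `LibraryDesign`.
#' @examples
#' d <- libraryDesign("demo", "homologous", insert_seq = strrep("ACGT", 40),
#'                    insert_index = "AGACTCAAGT")
#' d
#' @export
libraryDesign <- function(library_id, insert_class, insert_length = NULL,
                          insert_index, insert_seq = NA_character_,
                          insert_length_range = NULL, f_plasmid = 0,
                          signposts = defaultSignposts(),
                          r2_handle = nexteraR2Handle(),
                          index_offset = 0L, bc1_length = 15L,
                          bc2_length = 16L, filler_left_length = 20L,
                          filler_pool = NULL,
                          itr_to_itr_target = 2300L) {
  if (is.null(insert_length)) {
    if (is.na(insert_seq)) stop("need insert_length or insert_seq")
    insert_length <- nchar(insert_seq)
  }
  if (is.null(insert_length_range))
    insert_length_range <- c(insert_length, insert_length)
  if (is.null(filler_pool)) {
    pool <- syntheticReferencePool()
    filler_pool <- substr(pool$genome, 40001, 40000 + 3200)
  }
  new("LibraryDesign", library_id = library_id, insert_class = insert_class,
      insert_length = as.integer(insert_length),
      insert_length_range = as.integer(insert_length_range),
      insert_index = toupper(insert_index),
      insert_seq = toupper(insert_seq), f_plasmid = f_plasmid,
      signposts = toupper(signposts[c("left_up", "left_down",
                                      "right_up", "right_down")]),
      r2_handle = toupper(r2_handle), index_offset = as.integer(index_offset),
      bc1_length = as.integer(bc1_length), bc2_length = as.integer(bc2_length),
      filler_left_length = as.integer(filler_left_length),
      filler_pool = filler_pool,
      itr_to_itr_target = as.integer(itr_to_itr_target))
}

#' The default set of seven library designs
#'
#' The parental dictionary library plus six insert libraries crossing
#' three lengths (short 127 nt, mid-sized 739 nt, long 2034 nt) with two
#' classes (homologous: one fixed insert per library; non-homologous:
#' size-matched fragments sampled from the synthetic reference pool).
#' Cargoes are padded with filler to a common ~2.3 kb ITR-to-ITR target
#' (parental: 881 nt). Plasmid-derived fractions of the non-homologous
#' libraries default to 0.65 / 0.19 / 0.15 (short / mid / long).
#'
#' @param pool reference pool from [syntheticReferencePool()].
#' @return named list of [LibraryDesign-class] objects.
#' @examples
#' designs <- defaultLibraryDesigns()
#' names(designs)
#' @export
defaultLibraryDesigns <- function(pool = syntheticReferencePool()) {
  idx <- defaultInsertIndices()
  homIns <- function(start, len) substr(pool$plasmid, start, start + len - 1)
  list(
    parental = libraryDesign("parental", "parental",
      insert_seq = homIns(3301, 600), insert_index = idx[["parental"]],
      itr_to_itr_target = 881L),
    short_homologous = libraryDesign("short_homologous", "homologous",
      insert_seq = homIns(101, 127), insert_index = idx[["short_homologous"]]),
    short_nonhomologous = libraryDesign("short_nonhomologous",
      "non_homologous", insert_length = 127L,
      insert_length_range = c(100L, 150L), f_plasmid = 0.65,
      insert_index = idx[["short_nonhomologous"]]),
    mid_homologous = libraryDesign("mid_homologous", "homologous",
      insert_seq = homIns(301, 739), insert_index = idx[["mid_homologous"]]),
    mid_nonhomologous = libraryDesign("mid_nonhomologous", "non_homologous",
      insert_length = 739L, insert_length_range = c(650L, 850L),
      f_plasmid = 0.19, insert_index = idx[["mid_nonhomologous"]]),
    long_homologous = libraryDesign("long_homologous", "homologous",
      insert_seq = homIns(1201, 2034), insert_index = idx[["long_homologous"]]),
    long_nonhomologous = libraryDesign("long_nonhomologous",
      "non_homologous", insert_length = 2034L,
      insert_length_range = c(1900L, 2100L), f_plasmid = 0.15,
      insert_index = idx[["long_nonhomologous"]])
  )
}

#' Assemble one forward-strand cargo sequence
#'
#' Concatenates filler, signposts, barcodes, insert, adapter handle,
#' index and spacer in the design's layout, padding with right filler so
#' the total equals `itr_to_itr_target` when the insert has the design's
#' nominal length (inserts of other lengths shift the total by the
#' difference; filler lengths are fixed per design).
#'
#' @param design a [LibraryDesign-class].
#' @param bc1,bc2 barcode sequences.
#' @param insert insert sequence; defaults to the design's fixed insert.
#' @return character scalar with attribute `features`: a data.frame of
#'   0-based half-open `[start, end)` coordinates for every component.
#' @examples
#' d <- defaultLibraryDesigns()$short_homologous
#' cargo <- buildCargo(d, strrep("A", 15), strrep("C", 16))
#' nchar(cargo)
#' @export
buildCargo <- function(design, bc1, bc2, insert = design@insert_seq) {
  stopifnot(is(design, "LibraryDesign"))
  sp <- design@signposts
  spacer <- if (design@index_offset > 0)
    substr(design@filler_pool, 3101, 3100 + design@index_offset) else ""
  fixed <- sum(nchar(sp)) + nchar(bc1) + nchar(bc2) + nchar(design@r2_handle) +
    nchar(design@insert_index) + design@index_offset
  filler_right_len <- design@itr_to_itr_target - fixed -
    design@insert_length - design@filler_left_length
  if (filler_right_len < 0)
    stop("design components exceed itr_to_itr_target; no non-negative filler")
  fillerL <- substr(design@filler_pool, 1, design@filler_left_length)
  fillerR <- substr(design@filler_pool, 1001, 1000 + filler_right_len)
  parts <- c(fillerL = fillerL, left_up = sp[["left_up"]], bc1 = bc1,
             left_down = sp[["left_down"]], insert = insert,
             r2_handle = design@r2_handle, index = design@insert_index,
             spacer = spacer, right_up = sp[["right_up"]], bc2 = bc2,
             right_down = sp[["right_down"]], fillerR = fillerR)
  lens <- nchar(parts)
  ends <- cumsum(lens)
  feat <- data.frame(name = names(parts), start = ends - lens, end = ends,
                     row.names = NULL, stringsAsFactors = FALSE)
  out <- paste(parts, collapse = "")
  attr(out, "features") <- feat
  out
}
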