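# Seed-anchored star alignment.  Group members are close homologs sharing a
# template, so pairwise-aligning each member to the anchor seed and merging
# on the seed's coordinates ("once a gap, always a gap") is adequate and
# keeps the box coordinate system exact.

blosum62 <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      e <- new.env()
      utils::data("BLOSUM62", package = "Biostrings", envir = e)
      cache <<- e$BLOSUM62
    }
    cache
  }
})

# decompose a member/anchor pairwise alignment into: res[p] = member char
# aligned to anchor position p, and ins[[p + 1]] = member insertion after p
decompose_alignment <- function(member_gapped, anchor_gapped, anchor_len) {
  mc <- strsplit(member_gapped, "")[[1]]
  ac <- strsplit(anchor_gapped, "")[[1]]
  res <- rep("-", anchor_len)
  ins <- vector("list", anchor_len + 1L)
  pos <- 0L
  for (k in seq_along(ac)) {
    if (ac[k] == "-") {
      ins[[pos + 1L]] <- c(ins[[pos + 1L]], mc[k])
    } else {
      pos <- pos + 1L
      res[pos] <- mc[k]
    }
  }
  list(res = res, ins = ins)
}

#' Star-align a group of proteins around an anchor seed
#'
#' Each member is globally aligned to the anchor (BLOSUM62, affine gaps,
#' open 10 / extend 1 in matrix half-bits) and the pairwise alignments are
#' merged on the anchor's coordinates.  Row order follows input order; the
#' anchor must be one of the members (or is appended).
#'
#' @param members a [protein_set()] of group members.
#' @param anchor_id protein id of the anchor seed.
#' @param anchor_seq anchor sequence; defaults to the member with `anchor_id`.
#' @return a list of class `tr_msa` with `member_ids`, `rows` (named
#'   equal-length gapped strings) and `anchor_id`.
#' @export
star_align <- function(members, anchor_id, anchor_seq = NULL) {
  if (nrow(members) < 2L) stop_format("need at least 2 sequences to align")
  if (is.null(anchor_seq)) {
    k <- match(anchor_id, members$protein_id)
    if (is.na(k)) stop_format("anchor '%s' not among members", anchor_id)
    anchor_seq <- members$sequence[k]
  }
  L <- nchar(anchor_seq)
  aln <- Biostrings::pairwiseAlignment(members$sequence, anchor_seq,
                                       type = "global",
                                       substitutionMatrix = blosum62(),
                                       gapOpening = 10, gapExtension = 1)
  pat <- as.character(Biostrings::alignedPattern(aln))
  sub <- as.character(Biostrings::alignedSubject(aln))
  dec <- lapply(seq_len(nrow(members)), function(i)
    decompose_alignment(pat[i], sub[i], L))
  ins_width <- integer(L + 1L)
  for (d in dec) for (p in seq_len(L + 1L))
    ins_width[p] <- max(ins_width[p], length(d$ins[[p]]))
  rows <- vapply(dec, function(d) {
    parts <- character(0)
    for (p in 0L:L) {
      iw <- ins_width[p + 1L]
      if (iw > 0L) {
        block <- d$ins[[p + 1L]] %||% character(0)
        parts <- c(parts, block, rep("-", iw - length(block)))
      }
      if (p < L) parts <- c(parts, d$res[p + 1L])
    }
    paste(parts, collapse = "")
  }, "")
  names(rows) <- members$protein_id
  structure(list(member_ids = members$protein_id, rows = rows,
                 anchor_id = anchor_id,
                 column_count = unique(nchar(rows))),
            class = "tr_msa")
}

#' Remove gaps from an alignment row
#'
#' @param row gapped string.
#' @return the ungapped sequence.
#' @export
ungap <- function(row) gsub("-", "", row, fixed = TRUE)

#' Extract the BoxA and BoxB sub-regions from a group alignment
#'
#' Box columns follow the anchor seed's residues: BoxA is the 31 alignment
#' columns carrying the seed's BoxA template positions and BoxB the
#' corresponding 20 columns, so seed-relative insertions never inflate the
#' box width and every member's box string is exactly 31/20 characters
#' (possibly with gaps).
#'
#' @param msa a `tr_msa` from [star_align()].
#' @param layout optional list with `boxA_start` and `boxB_start` (1-based
#'   positions in the anchor's ungapped sequence); located via the CxxC
#'   anchor rule ([locate_boxes()]) when omitted.
#' @return a list of class `tr_boxes` with a data frame `boxes`
#'   (member_id, boxA, boxB) and the anchor MSA columns as attributes.
#' @export
extract_boxes <- function(msa, layout = NULL) {
  anchor_row <- msa$rows[[msa$anchor_id]]
  if (is.null(anchor_row)) stop_format("anchor row '%s' missing", msa$anchor_id)
  anchor_seq <- ungap(anchor_row)
  if (is.null(layout)) layout <- locate_boxes(anchor_seq)
  chars <- strsplit(anchor_row, "")[[1]]
  res_cols <- which(chars != "-")  # MSA column of each anchor residue
  if (layout$boxA_start + 30L > length(res_cols) ||
      layout$boxB_start + 19L > length(res_cols))
    stop_format("box layout exceeds anchor length")
  colsA <- res_cols[layout$boxA_start:(layout$boxA_start + 30L)]
  colsB <- res_cols[layout$boxB_start:(layout$boxB_start + 19L)]
  pick <- function(row, cols) {
    rc <- strsplit(row, "")[[1]]
    paste(rc[cols], collapse = "")
  }
  boxes <- data.frame(member_id = msa$member_ids,
                      boxA = vapply(msa$rows, pick, "", cols = colsA),
                      boxB = vapply(msa$rows, pick, "", cols = colsB),
                      stringsAsFactors = FALSE, row.names = NULL)
  structure(list(boxes = boxes,
                 anchors = c(boxA_col = colsA[1L], boxB_col = colsB[1L]),
                 layout = layout),
            class = "tr_boxes")
}
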