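# Fixed-width position-specific scoring models in bits, with the
# trusted-cutoff convention: a profile's acceptance threshold is the minimal
# score of the sequences it was built from.  An ungapped sliding-window PSSM
# stands in for a profile HMM: the regions modelled here are fixed-width
# (31/20/51 columns), so insert/delete states add nothing.

#' Build a position-specific scoring model from equal-length region strings
#'
#' Per column j and residue a the implied frequency is
#' `f(j,a) = (count(j,a) + pseudocount * background(a)) / (n_nongap(j) + pseudocount)`
#' and the score is `log2(f / background)` bits.  Gap (`-`) and `X`
#' characters contribute nothing to the counts; an all-gap column therefore
#' scores 0 everywhere.
#'
#' @param region_strings character vector of equal-length strings over the
#'   amino-acid alphabet plus `-` and `X`.
#' @param background length-20 probability vector (default uniform).
#' @param pseudocount positive Dirichlet total mass, spread proportionally to
#'   the background (default 1).
#' @param member_ids optional ids of the sequences the strings came from.
#' @return a list of class `tr_profile` with fields `width`, `log_odds`
#'   (width x 20 matrix of bits), `background`, `pseudocount`,
#'   `trusted_cutoff` (NA until [trusted_cutoff()] is applied), `member_ids`.
#' @export
build_profile <- function(region_strings, background = rep(1 / 20, 20),
                          pseudocount = 1, member_ids = NULL) {
  if (length(region_strings) == 0L) stop_format("empty region string set")
  w <- unique(nchar(region_strings))
  if (length(w) != 1L) stop_format("region strings have unequal lengths")
  if (w < 1L) stop_format("profile width must be >= 1")
  if (length(background) != 20L || abs(sum(background) - 1) > 1e-8)
    stop_format("background must be 20 probabilities summing to 1")
  if (pseudocount <= 0) stop_format("pseudocount must be positive")
  background <- setNames(background, AA_ALPHABET)
  mat <- do.call(rbind, strsplit(region_strings, ""))
  lo <- matrix(0, nrow = w, ncol = 20L, dimnames = list(NULL, AA_ALPHABET))
  for (j in seq_len(w)) {
    col <- mat[, j]
    col <- col[col %in% AA_ALPHABET]
    cnt <- table(factor(col, levels = AA_ALPHABET))
    f <- (as.numeric(cnt) + pseudocount * background) /
      (length(col) + pseudocount)
    lo[j, ] <- log2(f / background)
  }
  structure(list(width = w, log_odds = lo, background = background,
                 pseudocount = pseudocount, trusted_cutoff = NA_real_,
                 member_ids = member_ids %||% character(0)),
            class = "tr_profile")
}

#' Score a sequence against a profile
#'
#' Ungapped sliding-window scoring: the score is the maximum over all
#' windows of the summed per-column log-odds; ties are broken by the
#' smallest start.  `X` scores 0 in every column; gap characters are not
#' allowed in a query.
#'
#' @param profile a `tr_profile`.
#' @param sequence a single protein sequence at least `width` long.
#' @return a list with `score_bits` and `start` (1-based offset of the
#'   best-scoring window).
#' @export
score_profile <- function(profile, sequence) {
  stopifnot(inherits(profile, "tr_profile"))
  chars <- strsplit(sequence, "")[[1]]
  if (any(chars == "-")) stop_format("gap characters are not allowed in a query")
  L <- length(chars)
  w <- profile$width
  if (L < w) stop_format("sequence (length %d) shorter than profile width %d", L, w)
  lo <- cbind(profile$log_odds, X = 0)
  idx <- match(chars, c(AA_ALPHABET, "X"))
  if (anyNA(idx)) stop_format("sequence contains letters outside the alphabet")
  starts <- seq_len(L - w + 1L)
  jj <- seq_len(w)
  scores <- vapply(starts, function(s) sum(lo[cbind(jj, idx[s + jj - 1L])]), 0)
  best <- which.max(scores)  # which.max returns the first (smallest) maximum
  list(score_bits = scores[best], start = starts[best])
}

#' Set the trusted cutoff of a profile from its building members
#'
#' The trusted cutoff is the score of the lowest-scoring known true
#' positive: the minimum over `member_sequences` of their best-window score
#' against the profile.  By construction every member re-passes its own
#' profile.
#'
#' @param profile a `tr_profile`.
#' @param member_sequences the full-length sequences the profile was built
#'   from.
#' @return the profile with `trusted_cutoff` set (bits).
#' @export
trusted_cutoff <- function(profile, member_sequences) {
  if (length(member_sequences) == 0L) stop_format("empty member list")
  sc <- vapply(member_sequences, function(s) score_profile(profile, s)$score_bits, 0)
  profile$trusted_cutoff <- min(sc)
  profile
}

#' Build the PNDO detection profile from a seed set
#'
#' Concatenates each seed's BoxA and BoxB region strings (width 51), builds
#' the profile and sets the trusted cutoff from the full seed sequences.
#'
#' @param seeds a `seed_set`.
#' @param pseudocount passed to [build_profile()].
#' @return a `tr_profile` with cutoff set.
#' @export
pndo_profile <- function(seeds, pseudocount = 1) {
  regions <- vapply(seeds$sequence, function(s) {
    loc <- locate_boxes(s)
    paste0(substr(s, loc$boxA_start, loc$boxA_start + 30L),
           substr(s, loc$boxB_start, loc$boxB_start + 19L))
  }, "")
  prof <- build_profile(unname(regions), pseudocount = pseudocount,
                        member_ids = seeds$protein_id)
  trusted_cutoff(prof, seeds$sequence)
}

#' Locate the BoxA/BoxB coordinates in an unaligned sequence
#'
#' Anchors on the first `C..C` active-site match: BoxA column 1 (the Trx
#' G\[R/K\]G start) sits 6 residues upstream of the first cysteine, and
#' BoxB starts right after BoxA column 31.  Sequences without the CxxC
#' (the FdR case) fall back to the Trx-binding `G[R/K]G` at BoxA column 1.
#'
#' @param sequence protein sequence.
#' @param spacer residues between BoxA column 31 and BoxB column 1.
#' @param scan_to only consider anchors starting at or before this position
#'   (default: whole sequence).
#' @return list with `boxA_start` and `boxB_start` (1-based).
#' @export
locate_boxes <- function(sequence, spacer = BOX_SPACER, scan_to = nchar(sequence)) {
  m <- regexpr("C..C", substr(sequence, 1L, scan_to + 3L))
  a <- if (m > 0) as.integer(m) - 6L else {
    m2 <- regexpr("G[RK]GV.[YH]", substr(sequence, 1L, scan_to + 5L))
    if (m2 < 0) stop_format("no CxxC (or G[R/K]G fallback) anchor found")
    as.integer(m2)
  }
  b <- a + 31L + spacer
  if (a < 1L || b + 19L > nchar(sequence))
    stop_format("CxxC anchor at %d leaves no room for the boxes", as.integer(m))
  list(boxA_start = a, boxB_start = b)
}

#' Scan genomes for PNDO-domain proteins
#'
#' Scores every protein against the trusted-cutoff profile and returns all
#' proteins at or above the cutoff, sorted by descending score.
#'
#' @param genomes list of `genome_record`s, or a [protein_set()].
#' @param profile a `tr_profile` with `trusted_cutoff` set.
#' @return data frame with `protein_id`, `organism_id`, `score_bits`, `start`.
#' @export
find_pndo <- function(genomes, profile) {
  if (is.na(profile$trusted_cutoff)) stop_format("profile has no trusted cutoff")
  prot <- if (inherits(genomes, "protein_set")) genomes else all_proteins(genomes)
  keep <- nchar(prot$sequence) >= profile$width
  prot <- prot[keep, , drop = FALSE]
  hits <- lapply(prot$sequence, function(s) score_profile(profile, s))
  out <- data.frame(protein_id = prot$protein_id,
                    organism_id = prot$organism_id,
                    score_bits = vapply(hits, `[[`, 0, "score_bits"),
                    start = vapply(hits, `[[`, 0L, "start"),
                    stringsAsFactors = FALSE)
  out <- out[out$score_bits >= profile$trusted_cutoff, , drop = FALSE]
  out[order(-out$score_bits, out$protein_id), , drop = FALSE]
}

#' Serialize a profile to TSV plus a JSON sidecar
#'
#' @param profile a `tr_profile`.
#' @param path base path; writes `<path>.tsv` and `<path>.json`.
#' @return base path, invisibly.
#' @export
write_profile <- function(profile, path) {
  long <- data.frame(column = rep(seq_len(profile$width), each = 20L),
                     residue = rep(AA_ALPHABET, profile$width),
                     log_odds = as.vector(t(profile$log_odds)))
  write.table(long, paste0(path, ".tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  jsonlite::write_json(list(background = unname(profile$background),
                            pseudocount = profile$pseudocount,
                            trusted_cutoff = profile$trusted_cutoff,
                            member_ids = profile$member_ids),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA,
                       null = "null", na = "null")
  invisible(path)
}

#' Read back a profile written by [write_profile()]
#'
#' @param path base path used at write time.
#' @return a `tr_profile`.
#' @export
read_profile <- function(path) {
  long <- read.delim(paste0(path, ".tsv"))
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  w <- max(long$column)
  lo <- matrix(long$log_odds[order(long$column, match(long$residue, AA_ALPHABET))],
               nrow = w, ncol = 20L, byrow = TRUE,
               dimnames = list(NULL, AA_ALPHABET))
  structure(list(width = w, log_odds = lo,
                 background = setNames(side$background, AA_ALPHABET),
                 pseudocount = side$pseudocount,
                 trusted_cutoff = side$trusted_cutoff %||% NA_real_,
                 member_ids = side$member_ids %||% character(0)),
            class = "tr_profile")
}
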