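# Sequence logos (per-column frequencies and information content in bits)
# and consensus-motif extraction for the BoxA/BoxB sub-regions.

#' Compute a sequence logo from equal-length region strings
#'
#' Per column, frequencies are taken over the non-gap, non-X letters and
#' renormalized; the information content is
#' `R_j = log2(20) + sum_a f(j,a) * log2 f(j,a)` bits (no small-sample
#' correction).  An all-gap column has an empty frequency vector and
#' `R_j = 0`.
#'
#' @param box_strings character vector of equal-length strings.
#' @return a list of class `tr_logo` with `freq` (20 x width matrix) and
#'   `info` (width-length vector of bits).
#' @export
make_logo <- function(box_strings) {
  if (!length(box_strings)) stop_format("empty string set")
  w <- unique(nchar(box_strings))
  if (length(w) != 1L) stop_format("strings have unequal lengths")
  mat <- do.call(rbind, strsplit(box_strings, ""))
  freq <- matrix(0, nrow = 20L, ncol = w, dimnames = list(AA_ALPHABET, NULL))
  info <- numeric(w)
  for (j in seq_len(w)) {
    col <- mat[, j]
    col <- col[col %in% AA_ALPHABET]
    if (!length(col)) next
    f <- as.numeric(table(factor(col, levels = AA_ALPHABET))) / length(col)
    freq[, j] <- f
    nz <- f[f > 0]
    info[j] <- log2(20) + sum(nz * log2(nz))
  }
  structure(list(freq = freq, info = info, width = w,
                 n = length(box_strings)), class = "tr_logo")
}

#' Consensus motif pattern from a logo
#'
#' Per column: a single letter when the information content reaches
#' `info_threshold_bits` and the top letter's frequency reaches
#' `majority_fraction`; a bracketed pair when the top two letters jointly
#' reach the majority fraction; otherwise `x`.
#'
#' @param logo a `tr_logo`.
#' @param info_threshold_bits minimum column information (default 2 bits).
#' @param majority_fraction minimum (joint) frequency (default 0.7).
#' @return the consensus pattern string.
#' @export
consensus_motif <- function(logo, info_threshold_bits = 2,
                            majority_fraction = 0.7) {
  if (info_threshold_bits <= 0 || majority_fraction <= 0)
    stop_format("thresholds must be positive")
  out <- vapply(seq_len(logo$width), function(j) {
    f <- logo$freq[, j]
    if (logo$info[j] < info_threshold_bits || sum(f) == 0) return("x")
    o <- order(-f, names(f))
    if (f[o[1]] >= majority_fraction) return(names(f)[o[1]])
    if (f[o[1]] + f[o[2]] >= majority_fraction)
      return(paste0("[", names(f)[o[1]], names(f)[o[2]], "]"))
    "x"
  }, "")
  paste(out, collapse = "")
}

#' Count active-site cysteines in a BoxA string
#'
#' The CxxC active site occupies BoxA columns 7 and 10; the count of
#' cysteines at those two columns (0, 1 or 2) drives the TR1 versus FdR
#' split.
#'
#' @param boxA a 31-character BoxA string.
#' @return integer in 0:2.
#' @export
active_site_cys_count <- function(boxA) {
  if (nchar(boxA) != 31L)
    stop_format("BoxA must be exactly 31 characters, got %d", nchar(boxA))
  sum(c(substr(boxA, 7, 7), substr(boxA, 10, 10)) == "C")
}

#' Write a logo as a TSV (column, residue, frequency, info_bits)
#'
#' @param logo a `tr_logo`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_logo <- function(logo, path) {
  long <- data.frame(column = rep(seq_len(logo$width), each = 20L),
                     residue = rep(AA_ALPHABET, logo$width),
                     frequency = as.vector(logo$freq),
                     info_bits = rep(logo$info, each = 20L))
  write.table(long, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
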