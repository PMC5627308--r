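#' The 20-letter amino-acid alphabet used throughout the package
#'
#' Sequences are strict: the 20 standard residues plus the ambiguity code X.
#' Non-standard letters (U, B, Z, J, O, ...) are coerced to X on input with a
#' warning rather than rejected, so real-world proteomes pass.
#'
#' @format character vector of 20 single letters.
#' @export
AA_ALPHABET <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

# residues + X; gap "-" is only legal inside alignments
aa_ok_pattern <- function() sprintf("^[%sX]*$", paste(AA_ALPHABET, collapse = ""))

#' Normalize a protein sequence to the package alphabet
#'
#' Uppercases and maps any letter outside the 20-residue alphabet (plus X)
#' to X, warning once per call with the letters that were replaced.
#'
#' @param x character vector of sequences.
#' @return character vector of normalized sequences.
#' @export
normalize_sequence <- function(x) {
  x <- toupper(x)
  x <- gsub("[*.]$", "", x)  # trailing stop codons occur in real proteomes
  bad <- unique(unlist(regmatches(x, gregexpr("[^-ACDEFGHIKLMNPQRSTVWYX]", x))))
  if (length(bad)) {
    warning(sprintf("non-standard residue(s) %s coerced to X",
                    paste(bad, collapse = ",")), call. = FALSE)
    for (b in bad) x <- gsub(b, "X", x, fixed = TRUE)
  }
  x
}

#' Construct a validated protein set
#'
#' The package-wide container for protein records: a data frame with columns
#' `protein_id`, `organism_id`, `sequence` and `description`.
#'
#' @param protein_id unique, non-empty id tokens.
#' @param sequence amino-acid sequences (normalized via [normalize_sequence()]).
#' @param organism_id organism each protein belongs to (may be `""`).
#' @param description free-text description.
#' @return a `data.frame` of class `protein_set`.
#' @export
protein_set <- function(protein_id, sequence, organism_id = "", description = "") {
  protein_id <- as.character(protein_id)
  if (any(!nzchar(protein_id))) stop_format("empty protein_id")
  dup <- protein_id[duplicated(protein_id)]
  if (length(dup)) stop_format("duplicate protein id(s): %s",
                               paste(unique(dup), collapse = ", "))
  sequence <- normalize_sequence(as.character(sequence))
  if (any(nchar(sequence) < 1L)) stop_format("zero-length sequence")
  if (any(grepl("[[:space:]]", sequence))) stop_format("whitespace in sequence")
  out <- data.frame(protein_id = protein_id,
                    organism_id = rep_len(as.character(organism_id), length(protein_id)),
                    sequence = sequence,
                    description = rep_len(as.character(description), length(protein_id)),
                    stringsAsFactors = FALSE)
  class(out) <- c("protein_set", "data.frame")
  out
}
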