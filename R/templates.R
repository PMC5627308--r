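# Family templates for the synthetic proteome generator.
#
# Every planted TR-family protein is built on one fixed 300-residue scaffold
# (a frozen random draw containing no cysteine, so the first C..C match in a
# planted sequence is always the active site) with family-specific motif
# tokens overwritten at fixed offsets:
#
#   pos   8- 13  FAD dinucleotide-binding motif GxGxxG (instantiated GSGPAG)
#   pos  40- 42  FAD motif ATG
#   pos  70- 76  FAD motif GxFAAGD (instantiated GHFAAGD)
#   pos 121-151  BoxA (31 columns: Trx G[R/K]G, VSY, CxxC, Trx F, GGGxxAxE)
#   pos 152-192  spacer (41 residues; free design choice, fixed constant)
#   pos 193-212  BoxB (20 columns: the 2'P-binding motif region)
#
# Tokens are single residues (fixed), "x" (free, drawn uniformly from the
# 20-letter alphabet per protein) or multi-letter strings (bracketed
# alternatives, one letter drawn per protein).

TEMPLATE_SCAFFOLD <- paste0(
  "LWERTFWAIYQSIHQWAKLPAMWQMQETRAYNHQVYTGHYVPQLYWAPVFLGGQQFVYQMENWLAKELMN",
  "WFLKSNEMFPWMRGFVSGVLHFTATLYIVWRSGTYEDMFEAENSRQMDPRGDSEKVWVTMYAKDMRLEWR",
  "PKGMMRPKSRRSQMSPHMGKQSIMVFDRTIFNPGTGHNQAGNLHWVYKTADFIKEPYTYFMYLNKKDFTP",
  "SRMIDEEWEYHNNAKTTGSHRHVVVKGDRYGVWKSEYQQHIQAKVTPQGNGLPLDNASSWYKWVLKYMPY",
  "VFSKAEMRMTKSLTQMVQVQ")

TEMPLATE_TRX3 <- paste0(
  "GFYSEEESIHQIVTPATSQSGWNGKYRKIMIYHAIYSTIGMSLQMSWRNIAPKDKYHLWIANYDTVRGKH",
  "ARYAGSEIKQSKRNAPYPHMEPWKMKMAMENTIMW")

BOXA_START <- 121L
BOXB_START <- 152L
BOX_SPACER <- 0L  # BoxA and BoxB are adjacent halves of one split region

# scaffold substitutions defining the divergent EcTrxB-like TR1 seed: a true
# TR1 whose non-motif positions differ enough that plain similarity misses it
DIVERGENT_TR1_POS <- c(19L, 20L, 34L, 46L, 54L, 57L, 58L, 62L, 63L, 64L, 88L,
  92L, 96L, 102L, 104L, 114L, 131L, 132L, 133L, 134L, 135L, 136L, 138L, 139L,
  140L, 141L, 142L, 143L,
  223L, 233L, 248L, 254L, 257L, 258L, 260L, 261L, 267L, 276L, 283L, 284L,
  288L, 299L)
DIVERGENT_TR1_RES <- strsplit(
  "ALMRFLAPKDWVRWIGKEFMETNNWMWFEDDSDRLYRHPNHL", "")[[1]]

# the clostridial TRi seed is itself a distant homolog of the canonical TRi
# (all 12 non-motif BoxA columns plus 12 linker/tail positions substituted)
DIVERGENT_TRI_POS <- c(16L, 47L, 55L, 66L, 93L, 103L, 109L, 116L, 131L, 132L,
                       133L, 134L, 135L, 136L, 138L, 139L, 140L, 141L, 142L,
                       143L, 218L, 226L, 241L, 262L)
DIVERGENT_TRI_RES <- strsplit("SSTLDHWEKINTRVRAWVVQHKRE", "")[[1]]

# class-marker positions: disjoint per class (linker/tail only, never inside
# boxes or FAD motifs); at one class's marker column the other classes keep
# the scaffold residue, so the column survives the >50% flank-conservation
# rule and carries the class signal into the trees.  The outgroup carries
# twice as many markers so it branches off first.
CLASS_MARKER_POS <- list(
  Deltaproteobacteria = c(85L, 90L, 95L, 100L, 105L, 110L),
  Clostridia = c(87L, 92L, 97L, 102L, 107L, 112L),
  Actinobacteria = c(84L, 89L, 94L, 99L, 216L, 221L, 231L, 236L, 246L, 251L,
                     266L, 271L))

FAMILY_LABELS <- c("TRi", "TR1", "FdR", "TR3", "dcTR1")

box_tokens <- function(label) {
  scaf <- strsplit(TEMPLATE_SCAFFOLD, "")[[1]]
  a <- scaf[BOXA_START:(BOXA_START + 30L)]
  b <- scaf[BOXB_START:(BOXB_START + 19L)]
  # BoxA columns 1-3 Trx G[R/K]G (TR3: CxQ), 4-6 VSY (TR3/dcTR1: VHY),
  # 7-10 CxxC active site (FdR: SxxS), 17 Trx aromatic, 24-31 PP motif
  a[1:10] <- switch(label,
    TRi   = c("G", "RK", "G", "V", "S", "Y", "C", "A", "T", "C"),
    TR1   = c("G", "RK", "G", "V", "S", "Y", "C", "A", "T", "C"),
    FdR   = c("G", "RK", "G", "V", "S", "Y", "S", "A", "T", "S"),
    TR3   = c("C", "x",  "Q", "V", "H", "Y", "C", "A", "T", "C"),
    dcTR1 = c("G", "K",  "G", "V", "H", "Y", "C", "A", "T", "C"))
  a[17] <- switch(label, TRi = "F", TR1 = "F", FdR = "F", TR3 = "P", dcTR1 = "M")
  a[24:31] <- if (label == "TRi")
    c("G", "x", "G", "x", "x", "A", "x", "N")  # degenerate PP motif, >=4 free
  else
    c("G", "G", "G", "x", "x", "A", "x", "E")
  # BoxB columns 4-15 carry the 2'P motif; the flanking columns 1-3 and
  # 16-20 are family-specific (the 2'P region as a whole differs between
  # the TR1/FdR and TRi/TR3/dcTR1 groups, not just the motif columns)
  b[4:15] <- switch(label,
    TRi   = c("V", "x", "x", "x", "T", "Q", "G", "K", "x", "x", "S", "I"),
    TR1   = c("V", "x", "x", "x", "H", "R", "R", "D", "x", "FL", "R", b[15]),
    FdR   = c("V", "x", "x", "x", "H", "R", "R", "D", "x", "FL", "R", b[15]),
    TR3   = c("V", "x", "x", "x", "N", "G", "K", "D", "x", "x", "S", "R"),
    dcTR1 = c("V", "x", "x", "x", "N", "G", "K", "D", "x", "x", "S", "R"))
  flank <- switch(label,
    TRi   = c("P", "E", "M", "I", "D", "A", "N", "T"),
    TR1   = c("G", "T", "R", "L", "E", "K", "V", "A"),
    FdR   = c("G", "T", "R", "L", "E", "K", "V", "A"),
    TR3   = c("A", "Q", "W", "T", "S", "E", "G", "M"),
    dcTR1 = c("A", "Q", "W", "T", "S", "E", "G", "M"))
  b[c(1:3, 16:20)] <- flank
  list(boxA = a, boxB = b)
}

tokens_to_pattern <- function(tok) {
  paste(vapply(tok, function(t)
    if (nchar(t) > 1L) paste0("[", t, "]") else t, ""), collapse = "")
}

#' Family template for a TR subfamily
#'
#' Returns the fixed-offset token layout used to plant synthetic TR-family
#' proteins: FAD motifs (GxGxxG, ATG, GxFAAGD), the 31-column BoxA and the
#' 20-column BoxB on a shared 300-residue scaffold.
#'
#' @param label one of `"TRi"`, `"TR1"`, `"FdR"`, `"TR3"`, `"dcTR1"`.
#' @return a list of class `family_template` with fields `label`, `tokens`
#'   (length-300 token vector), `boxA_template` and `boxB_template` (pattern
#'   strings with bracketed alternatives), `boxA_start`, `boxB_start`,
#'   `total_length`.
#' @export
family_template <- function(label) {
  if (!label %in% FAMILY_LABELS)
    stop_format("unknown family label '%s' (expected one of %s)",
                label, paste(FAMILY_LABELS, collapse = ", "))
  tok <- strsplit(TEMPLATE_SCAFFOLD, "")[[1]]
  tok[8:13] <- c("G", "S", "G", "P", "A", "G")   # GxGxxG
  tok[40:42] <- c("A", "T", "G")
  tok[70:76] <- c("G", "H", "F", "A", "A", "G", "D")  # GxFAAGD
  bx <- box_tokens(label)
  tok[BOXA_START:(BOXA_START + 30L)] <- bx$boxA
  tok[BOXB_START:(BOXB_START + 19L)] <- bx$boxB
  structure(list(label = label, tokens = tok,
                 boxA_template = tokens_to_pattern(bx$boxA),
                 boxB_template = tokens_to_pattern(bx$boxB),
                 boxA_start = BOXA_START, boxB_start = BOXB_START,
                 fad_motifs = list(GxGxxG = 8L, ATG = 40L, GxFAAGD = 70L),
                 total_length = 300L),
            class = "family_template")
}

apply_class_markers <- function(tok, class) {
  if (!class %in% names(CLASS_MARKER_POS))
    stop_format("unknown taxonomy class '%s'", class)
  marker <- switch(class,
    Deltaproteobacteria = "D", Clostridia = "K", Actinobacteria = "W")
  alt <- switch(class,
    Deltaproteobacteria = "E", Clostridia = "R", Actinobacteria = "F")
  pos <- CLASS_MARKER_POS[[class]]
  tok[pos] <- ifelse(tok[pos] == marker, alt, marker)
  tok
}

instantiate_tokens <- function(tok) {
  n <- length(tok)
  out <- character(n)
  for (i in seq_len(n)) {
    t <- tok[i]
    out[i] <- if (t == "x") sample(AA_ALPHABET, 1L)
    else if (nchar(t) > 1L) sample(strsplit(t, "")[[1]], 1L)
    else t
  }
  out
}
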