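#' Read a FASTA file of protein sequences
#'
#' The first whitespace-delimited header token becomes the protein id; the
#' remainder of the header line is kept as the description.  Sequences are
#' uppercased and non-standard letters are coerced to X with a warning.
#'
#' @param path path to a FASTA file.
#' @param organism_id organism id stamped onto every record (default `""`).
#' @return a [protein_set()] data frame, one row per FASTA entry.
#' @export
read_fasta <- function(path, organism_id = "") {
  if (!file.exists(path)) stop_format("no such file: %s", path)
  # readBStringSet parses the FASTA structure; normalization is ours
  set <- Biostrings::readBStringSet(path, format = "fasta")
  if (length(set) == 0L) stop_format("empty FASTA file: %s", path)
  headers <- names(set)
  ids <- sub("\\s.*$", "", headers)
  desc <- ifelse(grepl("\\s", headers), sub("^\\S+\\s+", "", headers), "")
  protein_set(ids, as.character(set), organism_id = organism_id,
              description = desc)
}

#' Write a protein set as FASTA
#'
#' @param proteins a [protein_set()] data frame.
#' @param path output path.
#' @param width line width for wrapping (default 70).
#' @return `path`, invisibly.
#' @export
write_fasta <- function(proteins, path, width = 70L) {
  hdr <- ifelse(nzchar(proteins$description),
                paste(proteins$protein_id, proteins$description),
                proteins$protein_id)
  wrap <- function(s) paste(substring(s, seq(1L, nchar(s), width),
                                      pmin(seq(1L, nchar(s), width) + width - 1L,
                                           nchar(s))), collapse = "\n")
  txt <- paste0(">", hdr, "\n", vapply(proteins$sequence, wrap, ""))
  writeLines(txt, path)
  invisible(path)
}

#' Read a genome/taxonomy table and its proteomes
#'
#' The table is a TSV with header columns `organism_id`, `phylum`, `class`,
#' `order`, `family`, `genus`, `proteome_file`; each row names a FASTA
#' proteome relative to `proteome_dir`.
#'
#' @param path path to the TSV table.
#' @param proteome_dir directory holding the proteome FASTA files.
#' @return a list of genome records, each a list with `organism_id`,
#'   `lineage` (named character of the 5 ranks) and `proteins`
#'   (a [protein_set()]).
#' @export
read_genome_table <- function(path, proteome_dir = dirname(path)) {
  if (!file.exists(path)) stop_format("no such file: %s", path)
  tab <- read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                    check.names = FALSE)
  ranks <- c("phylum", "class", "order", "family", "genus")
  need <- c("organism_id", ranks, "proteome_file")
  miss <- setdiff(need, names(tab))
  if (length(miss)) stop_format("genome table missing column(s): %s",
                                paste(miss, collapse = ", "))
  for (r in ranks) if (any(is.na(tab[[r]]) | !nzchar(tab[[r]])))
    stop_format("missing lineage rank '%s' in genome table", r)
  lapply(seq_len(nrow(tab)), function(i) {
    f <- file.path(proteome_dir, tab$proteome_file[i])
    if (!file.exists(f)) stop_format("missing proteome file: %s", f)
    prot <- read_fasta(f, organism_id = tab$organism_id[i])
    genome_record(tab$organism_id[i],
                  setNames(unlist(tab[i, ranks]), ranks), prot)
  })
}

#' Construct a genome record
#'
#' @param organism_id organism identifier.
#' @param lineage named character vector of exactly the 5 ranks
#'   phylum, class, order, family, genus.
#' @param proteins a [protein_set()]; `organism_id` is stamped onto it.
#' @return a list of class `genome_record`.
#' @export
genome_record <- function(organism_id, lineage, proteins) {
  if (length(lineage) != 5L)
    stop_format("lineage must have exactly 5 ranks, got %d", length(lineage))
  names(lineage) <- c("phylum", "class", "order", "family", "genus")
  proteins$organism_id <- organism_id
  structure(list(organism_id = organism_id, lineage = lineage,
                 proteins = proteins), class = "genome_record")
}

#' Write a set of genomes as per-genome FASTA plus a genome table
#'
#' @param genomes list of `genome_record`s.
#' @param dir output directory (created if needed).
#' @return path of the written genome table, invisibly.
#' @export
write_genome_table <- function(genomes, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rows <- lapply(genomes, function(g) {
    f <- paste0(g$organism_id, ".faa")
    write_fasta(g$proteins, file.path(dir, f))
    c(organism_id = g$organism_id, g$lineage, proteome_file = f)
  })
  tab <- as.data.frame(do.call(rbind, rows), stringsAsFactors = FALSE)
  path <- file.path(dir, "genomes.tsv")
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Flatten a list of genome records into one protein set
#'
#' @param genomes list of `genome_record`s.
#' @return a [protein_set()] with all proteins; ids must be globally unique.
#' @export
all_proteins <- function(genomes) {
  parts <- lapply(genomes, function(g) g$proteins)
  out <- do.call(rbind, parts)
  dup <- out$protein_id[duplicated(out$protein_id)]
  if (length(dup)) stop_format("duplicate protein id(s) across genomes: %s",
                               paste(unique(dup), collapse = ", "))
  class(out) <- c("protein_set", "data.frame")
  out
}

#' Read a seed set (FASTA plus label TSV)
#'
#' @param fasta_path FASTA of seed sequences.
#' @param label_path TSV with columns `protein_id`, `family_label`
#'   (one of TRi, TR1, TR3).
#' @return a `seed_set`: a data frame with columns `protein_id`,
#'   `family_label`, `sequence`.
#' @export
read_seed_set <- function(fasta_path, label_path) {
  prot <- read_fasta(fasta_path)
  lab <- read.delim(label_path, sep = "\t", stringsAsFactors = FALSE)
  if (!all(c("protein_id", "family_label") %in% names(lab)))
    stop_format("seed label table needs protein_id and family_label columns")
  seed_set(lab$protein_id, lab$family_label,
           prot$sequence[match(lab$protein_id, prot$protein_id)])
}

#' Construct a validated seed set
#'
#' @param protein_id seed ids.
#' @param family_label labels from the closed set TRi, TR1, TR3.
#' @param sequence seed sequences.
#' @return a data frame of class `seed_set`.
#' @export
seed_set <- function(protein_id, family_label, sequence) {
  ok <- c("TRi", "TR1", "TR3")
  if (!all(family_label %in% ok))
    stop_format("seed family labels must be in {%s}", paste(ok, collapse = ", "))
  if (any(is.na(sequence))) stop_format("seed id(s) missing from FASTA")
  out <- protein_set(protein_id, sequence)
  out$family_label <- family_label
  class(out) <- c("seed_set", "protein_set", "data.frame")
  out
}

#' Read a Newick tree
#'
#' Absent branch lengths are treated as length 0; unbalanced parentheses
#' raise a parse error naming the offending position.
#'
#' @param path path to a Newick file.
#' @return an [ape::read.tree()] `phylo` object.
#' @export
read_newick <- function(path) {
  txt <- paste(readLines(path, warn = FALSE), collapse = "")
  depth <- 0L
  for (i in seq_len(nchar(txt))) {
    ch <- substr(txt, i, i)
    if (ch == "(") depth <- depth + 1L
    if (ch == ")") {
      depth <- depth - 1L
      if (depth < 0L) stop_format("unbalanced ')' at position %d", i)
    }
  }
  if (depth != 0L)
    stop_format("unbalanced '(' (%d unclosed) at end of input", depth)
  tree <- ape::read.tree(text = txt)
  if (is.null(tree)) stop_format("could not parse Newick in %s", path)
  if (is.null(tree$edge.length))
    tree$edge.length <- rep(0, nrow(tree$edge))
  tree
}

#' Write a tree in Newick format
#'
#' Leaf names are sanitized by replacing the characters `();:,` and space
#' with `_` so the unquoted Newick dialect round-trips.
#'
#' @param tree a `phylo` object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_newick <- function(tree, path) {
  tree$tip.label <- sanitize_label(tree$tip.label)
  if (anyDuplicated(tree$tip.label))
    stop_format("duplicate leaf names after sanitization")
  if (!is.null(tree$edge.length) && any(tree$edge.length < 0))
    stop_format("negative branch length")
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' Write the classification report
#'
#' Emits the per-protein TSV (`report.tsv`) and a JSON summary
#' (`summary.json`) into `dir`.
#'
#' @param census a `tr_census` result from [run_census()].
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_report <- function(census, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write.table(census$report, file.path(dir, "report.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  summary <- list(
    schema_version = "1",
    label_counts = as.list(table(census$report$assigned_label)),
    occurrence = census$occurrence,
    cooccurrence = census$cooccurrence,
    consensus_motifs = census$consensus,
    enrichment = lapply(census$traces, function(tr)
      list(converged = tr$converged,
           member_counts = vapply(tr$iterations, `[[`, 0, "member_count"),
           cutoffs = vapply(tr$iterations, `[[`, 0, "cutoff_bits"))))
  jsonlite::write_json(summary, file.path(dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
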