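# Synthetic proteome generator: plants TR-family proteins, optional Trx3
# partners and random background proteins into genomes with a three-class
# taxonomy (two ingroup classes modelled on Deltaproteobacteria and
# Clostridia plus an Actinobacteria-like outgroup).

CLASS_LINEAGES <- list(
  Deltaproteobacteria = c(phylum = "Proteobacteria", class = "Deltaproteobacteria",
                          order = "Desulfovibrionales", family = "Desulfovibrionaceae",
                          genus = "Desulfovibrio"),
  Clostridia = c(phylum = "Firmicutes", class = "Clostridia",
                 order = "Clostridiales", family = "Clostridiaceae",
                 genus = "Clostridium"),
  Actinobacteria = c(phylum = "Actinobacteria", class = "Actinobacteria",
                     order = "Actinomycetales", family = "Streptomycetaceae",
                     genus = "Streptomyces"))

#' Generate one synthetic TR-family protein
#'
#' Instantiates the family template (free positions drawn uniformly from the
#' 20-letter alphabet, bracketed alternatives resolved at random), optionally
#' applies class-divergence markers, then mutates each position to a random
#' residue with probability `mutation_rate`.  Deterministic given the label
#' and the RNG state (or `seed`).
#'
#' @param label family label, see [family_template()].
#' @param mutation_rate per-position substitution probability in `[0, 1]`.
#' @param class optional taxonomy class whose divergence markers to apply.
#' @param seed optional integer; when given the RNG state is set locally.
#' @return a list with `label`, `sequence`, the planted `boxA` (31 characters)
#'   and `boxB` (20 characters) strings, `boxA_start` and `boxB_start`.
#' @export
make_protein <- function(label, mutation_rate = 0, class = NULL, seed = NULL) {
  if (mutation_rate < 0 || mutation_rate > 1)
    stop_format("mutation_rate must be in [0, 1]")
  if (!is.null(seed))
    return(with_seed(seed, make_protein(label, mutation_rate, class)))
  tmpl <- family_template(label)
  tok <- tmpl$tokens
  if (!is.null(class)) tok <- apply_class_markers(tok, class)
  res <- instantiate_tokens(tok)
  hit <- runif(length(res)) < mutation_rate
  if (any(hit)) res[hit] <- sample(AA_ALPHABET, sum(hit), replace = TRUE)
  seq <- paste(res, collapse = "")
  list(label = label, sequence = seq,
       boxA = substr(seq, tmpl$boxA_start, tmpl$boxA_start + 30L),
       boxB = substr(seq, tmpl$boxB_start, tmpl$boxB_start + 19L),
       boxA_start = tmpl$boxA_start, boxB_start = tmpl$boxB_start)
}

#' Generate a synthetic Trx3-like partner protein
#'
#' A fixed ~105-residue template carrying a CGPC active site; presence or
#' absence of this protein in a genome is the signal the TR3/dcTR1 split
#' detects.
#'
#' @inheritParams make_protein
#' @return a list with `sequence` and `label = "Trx3"`.
#' @export
make_trx3 <- function(mutation_rate = 0, seed = NULL) {
  if (!is.null(seed)) return(with_seed(seed, make_trx3(mutation_rate)))
  res <- strsplit(TEMPLATE_TRX3, "")[[1]]
  res[30:33] <- c("C", "G", "P", "C")
  hit <- runif(length(res)) < mutation_rate
  if (any(hit)) res[hit] <- sample(AA_ALPHABET, sum(hit), replace = TRUE)
  list(label = "Trx3", sequence = paste(res, collapse = ""))
}

make_background_protein <- function(len) {
  paste(sample(AA_ALPHABET, len, replace = TRUE), collapse = "")
}

#' The fixed synthetic seed set
#'
#' Six experimentally-known-style seeds: canonical TRi, TR1 and TR3
#' templates, Clostridia-marked TRi and TR3 variants, and a divergent
#' EcTrxB-like TR1 whose scaffold differs at 42 positions (12 of them in the
#' non-motif BoxA columns).  The divergent seed keeps every BoxA/BoxB motif
#' column but anchors the trusted cutoff from below, the role a divergent
#' true positive plays in a trusted-cutoff search.  Deterministic: the
#' instantiation RNG is fixed internally.
#'
#' @return a `seed_set` data frame with attribute `boxes` holding the planted
#'   BoxA/BoxB strings per seed.
#' @export
make_seed_set <- function() {
  with_seed(derive_seed(1234L, "seed-set"), {
    tri <- make_protein("TRi")
    tok_ct <- apply_class_markers(family_template("TRi")$tokens, "Clostridia")
    tok_ct[DIVERGENT_TRI_POS] <- DIVERGENT_TRI_RES
    res_ct <- instantiate_tokens(tok_ct)
    cseq <- paste(res_ct, collapse = "")
    tric <- list(label = "TRi", sequence = cseq,
                 boxA = substr(cseq, BOXA_START, BOXA_START + 30L),
                 boxB = substr(cseq, BOXB_START, BOXB_START + 19L))
    tr1 <- make_protein("TR1")
    tr3 <- make_protein("TR3")
    tr3c <- make_protein("TR3", class = "Clostridia")
    # divergent TR1: substitute the frozen scaffold positions, then instantiate
    tmpl <- family_template("TR1")
    tok <- tmpl$tokens
    tok[DIVERGENT_TR1_POS] <- DIVERGENT_TR1_RES
    res <- instantiate_tokens(tok)
    eseq <- paste(res, collapse = "")
    ec <- list(label = "TR1", sequence = eseq,
               boxA = substr(eseq, BOXA_START, BOXA_START + 30L),
               boxB = substr(eseq, BOXB_START, BOXB_START + 19L))
    ids <- c("TRi_Dv", "TRi_Ct", "TR1_Dv", "TR1_Ec", "TR3_Dv", "TR3_Cl")
    labs <- c("TRi", "TRi", "TR1", "TR1", "TR3", "TR3")
    prots <- list(tri, tric, tr1, ec, tr3, tr3c)
    ss <- seed_set(ids, labs, vapply(prots, `[[`, "", "sequence"))
    attr(ss, "boxes") <- data.frame(
      protein_id = ids,
      boxA = vapply(prots, `[[`, "", "boxA"),
      boxB = vapply(prots, `[[`, "", "boxB"), stringsAsFactors = FALSE)
    ss
  })
}

#' Generate a full synthetic dataset
#'
#' Builds `n_genomes` genomes, each containing the planted TR-family proteins
#' requested in `per_genome_composition`, an optional Trx3-like partner for
#' TR3-bearing genomes, and `n_background` random background proteins.
#' Organisms rotate round-robin through the two ingroup classes and the
#' outgroup class; the reference tree groups organisms by class.
#'
#' @param n_genomes number of genomes.
#' @param per_genome_composition named integer vector, e.g.
#'   `c(TRi = 1, TR1 = 1, TR3 = 1)`; names from the family label set.  A
#'   `dcTR1` entry plants dcTR1-template proteins and forces the genome to
#'   lack a Trx3 partner.
#' @param frac_trx3 probability that a TR3-bearing genome carries a Trx3
#'   partner gene.
#' @param n_background random background proteins per genome.
#' @param mutation_rate per-position substitution probability.
#' @param seed master RNG seed for the dataset.
#' @param n_hgt number of planted horizontal transfers: extra TR1 genes with
#'   Deltaproteobacteria sequence markers placed in Clostridia genomes.
#' @return a list of class `tr_dataset` with fields `genomes`, `truth`
#'   (data frame: protein_id, organism_id, label, boxA, boxB), `reference_tree`
#'   (`phylo` over organism ids), `seeds`, `trx3_seed`, `hgt_ids`, `rng_seed`.
#' @export
make_dataset <- function(n_genomes = 20L,
                         per_genome_composition = c(TRi = 1L, TR1 = 1L, TR3 = 1L),
                         frac_trx3 = 0.5, n_background = 4L,
                         mutation_rate = 0.02, seed = 1L, n_hgt = 0L) {
  if (frac_trx3 < 0 || frac_trx3 > 1) stop_format("frac_trx3 must be in [0, 1]")
  comp <- per_genome_composition
  if (is.null(names(comp)) || !all(names(comp) %in% FAMILY_LABELS))
    stop_format("composition names must be in {%s}",
                paste(FAMILY_LABELS, collapse = ", "))
  if (any(comp < 0)) stop_format("composition counts must be >= 0")
  classes <- rep(c("Deltaproteobacteria", "Clostridia", "Actinobacteria"),
                 length.out = n_genomes)
  hgt_targets <- head(which(classes == "Clostridia"), n_hgt)
  if (length(hgt_targets) < n_hgt)
    stop_format("not enough Clostridia genomes for %d planted transfers", n_hgt)
  with_seed(derive_seed(seed, "dataset"), {
    genomes <- vector("list", n_genomes)
    truth <- list()
    hgt_ids <- character(0)
    for (i in seq_len(n_genomes)) {
      org <- sprintf("org%03d", i)
      cls <- classes[i]
      seqs <- character(0); labs <- character(0)
      boxA <- character(0); boxB <- character(0)
      for (lab in names(comp)) for (k in seq_len(comp[[lab]])) {
        p <- make_protein(lab, mutation_rate, class = cls)
        seqs <- c(seqs, p$sequence); labs <- c(labs, lab)
        boxA <- c(boxA, p$boxA); boxB <- c(boxB, p$boxB)
      }
      if (i %in% hgt_targets) {
        p <- make_protein("TR1", mutation_rate, class = "Deltaproteobacteria")
        seqs <- c(seqs, p$sequence); labs <- c(labs, "TR1")
        boxA <- c(boxA, p$boxA); boxB <- c(boxB, p$boxB)
        hgt_ids <- c(hgt_ids, sprintf("%s_p%03d", org, length(seqs)))
      }
      tr3_here <- labs %in% c("TR3", "dcTR1")
      partner <- any(labs == "TR3") && !any(labs == "dcTR1") &&
        runif(1) < frac_trx3
      if (any(tr3_here) && !partner)
        labs[labs == "TR3"] <- "dcTR1"
      if (partner) {
        t3 <- make_trx3(mutation_rate)
        seqs <- c(seqs, t3$sequence); labs <- c(labs, "Trx3")
        boxA <- c(boxA, NA); boxB <- c(boxB, NA)
      }
      for (k in seq_len(n_background)) {
        seqs <- c(seqs, make_background_protein(sample(250:350, 1L)))
        labs <- c(labs, "background"); boxA <- c(boxA, NA); boxB <- c(boxB, NA)
      }
      ids <- sprintf("%s_p%03d", org, seq_along(seqs))
      genomes[[i]] <- genome_record(org, CLASS_LINEAGES[[cls]],
                                    protein_set(ids, seqs, organism_id = org))
      truth[[i]] <- data.frame(protein_id = ids, organism_id = org,
                               class = cls, label = labs,
                               boxA = boxA, boxB = boxB,
                               stringsAsFactors = FALSE)
    }
    truth <- do.call(rbind, truth)
    structure(list(genomes = genomes, truth = truth,
                   reference_tree = class_reference_tree(
                     vapply(genomes, `[[`, "", "organism_id"), classes),
                   seeds = make_seed_set(),
                   trx3_seed = make_trx3(0),
                   hgt_ids = hgt_ids, rng_seed = seed,
                   params = list(n_genomes = n_genomes, composition = comp,
                                 frac_trx3 = frac_trx3,
                                 n_background = n_background,
                                 mutation_rate = mutation_rate, n_hgt = n_hgt)),
              class = "tr_dataset")
  })
}

# pectinate subtree per class, classes joined with the outgroup basal
class_reference_tree <- function(orgs, classes) {
  pect <- function(tips, bl) {
    if (length(tips) == 1L) return(sprintf("%s:%.4f", tips, bl))
    s <- sprintf("%s:%.4f", tips[1], bl)
    for (t in tips[-1]) s <- sprintf("(%s,%s:%.4f):%.4f", s, t, bl, bl / 2)
    s
  }
  ing <- c("Deltaproteobacteria", "Clostridia")
  sub <- lapply(ing, function(cl) {
    tips <- orgs[classes == cl]
    if (length(tips)) pect(tips, 0.05) else NULL
  })
  sub <- sub[!vapply(sub, is.null, TRUE)]
  out_tips <- orgs[classes == "Actinobacteria"]
  core <- if (length(sub) == 2L)
    sprintf("(%s:0.3,%s:0.3)", sub[[1]], sub[[2]])
  else sub[[1]]
  txt <- if (length(out_tips))
    sprintf("(%s:0.3,%s:0.6);", core, pect(out_tips, 0.05))
  else sprintf("%s;", core)
  ape::read.tree(text = txt)
}

#' Write a synthetic dataset to disk
#'
#' Emits per-genome FASTA files plus `genomes.tsv`, `truth.tsv`,
#' `reference.nwk`, `seeds.faa`/`seeds.tsv` and `trx3.faa`.
#'
#' @param dataset a `tr_dataset` from [make_dataset()].
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_genome_table(dataset$genomes, dir)
  write.table(dataset$truth, file.path(dir, "truth.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write_newick(dataset$reference_tree, file.path(dir, "reference.nwk"))
  write_fasta(dataset$seeds, file.path(dir, "seeds.faa"))
  write.table(dataset$seeds[, c("protein_id", "family_label")],
              file.path(dir, "seeds.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write_fasta(protein_set("Trx3_Dv", dataset$trx3_seed$sequence),
              file.path(dir, "trx3.faa"))
  invisible(dir)
}
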