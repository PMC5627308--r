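# Iterative trusted-cutoff enrichment of seed groups, the two split rules
# (TR1 vs FdR by active-site cysteines; TR3 vs dcTR1 by Trx3 partner
# presence) and the end-to-end census.

#' Enrich a homolog group with a BoxB trusted-cutoff profile search
#'
#' One run: star-align the current members on the group's original anchor
#' seed, extract the BoxB region, build a profile, set the trusted cutoff
#' from the current members' full sequences, score the whole PNDO pool and
#' add every protein at or above the cutoff.  Runs repeat until the member
#' set is unchanged or `max_runs` is reached; membership never shrinks.
#'
#' @param group a `homolog_group` (its first seed is the alignment anchor).
#' @param pool a [protein_set()] of PNDO proteins, a superset of the members.
#' @param max_runs maximal number of runs (default 10; convergence is
#'   typically immediate at desk scale).
#' @param pseudocount profile pseudocount.
#' @return list with the enriched `group` and an `enrichment_trace`
#'   (`iterations`: run_index, member_count, cutoff_bits, newly_added_ids;
#'   `converged` flag).
#' @export
enrich_group <- function(group, pool, max_runs = 10L, pseudocount = 1) {
  if (!all(group$member_ids %in% pool$protein_id))
    stop_format("pool must contain all group members")
  anchor <- if (length(group$seed_ids)) sort(group$seed_ids)[1L]
            else sort(group$member_ids)[1L]
  members <- group$member_ids
  iterations <- list()
  converged <- FALSE
  for (run in seq_len(max_runs)) {
    mem_set <- pool[match(members, pool$protein_id), , drop = FALSE]
    boxB <- if (nrow(mem_set) == 1L) {
      loc <- locate_boxes(mem_set$sequence)
      substr(mem_set$sequence, loc$boxB_start, loc$boxB_start + 19L)
    } else {
      msa <- star_align(mem_set, anchor)
      extract_boxes(msa)$boxes$boxB
    }
    prof <- build_profile(boxB, pseudocount = pseudocount, member_ids = members)
    prof <- trusted_cutoff(prof, mem_set$sequence)
    hits <- find_pndo(pool, prof)
    new_ids <- setdiff(hits$protein_id, members)
    members <- c(members, new_ids)
    iterations[[run]] <- list(run_index = run,
                              member_count = length(members),
                              cutoff_bits = prof$trusted_cutoff,
                              newly_added_ids = new_ids)
    if (!length(new_ids)) { converged <- TRUE; break }
  }
  if (!converged)
    warning(sprintf("enrichment of %s group not converged after %d runs",
                    group$label, max_runs), call. = FALSE)
  out <- homolog_group(group$label, members, group$seed_ids)
  out$history <- lapply(iterations, function(it)
    it[c("run_index", "member_count", "cutoff_bits")])
  list(group = out,
       trace = structure(list(iterations = iterations, converged = converged),
                         class = "enrichment_trace"),
       profile = prof)
}

#' Split a TR1 group into TR1 and FdR by active-site cysteines
#'
#' A member stays TR1 iff both conserved active-site cysteines are present
#' (BoxA columns 7 and 10); otherwise it is a ferredoxin (flavodoxin)
#' reductase.  The two-cysteine requirement is strict: a single cysteine
#' goes to FdR.
#'
#' @param tr1_group a `homolog_group`.
#' @param box_regions a `tr_boxes` covering the group members.
#' @return list with `TR1` and `FdR` groups and `unassigned` ids (members
#'   whose BoxA could not be extracted).
#' @export
split_tr1_fdr <- function(tr1_group, box_regions) {
  boxes <- box_regions$boxes
  tr1 <- character(0); fdr <- character(0); un <- character(0)
  for (id in tr1_group$member_ids) {
    k <- match(id, boxes$member_id)
    if (is.na(k) || is.na(boxes$boxA[k])) {
      message(sprintf("no BoxA for %s; leaving unassigned", id))
      un <- c(un, id)
    } else if (active_site_cys_count(boxes$boxA[k]) == 2L) {
      tr1 <- c(tr1, id)
    } else {
      fdr <- c(fdr, id)
    }
  }
  list(TR1 = homolog_group("TR1", tr1, intersect(tr1_group$seed_ids, tr1)),
       FdR = homolog_group("FdR", fdr),
       unassigned = un)
}

#' Detect a Trx3 partner gene in a genome
#'
#' Smith-Waterman local alignment of the Trx3 seed against every genome
#' protein (BLOSUM62, gap open 11 / extend 1), converted to an E-value with
#' the gapped Karlin-Altschul defaults `lambda = 0.267`, `K = 0.041`,
#' `m` = seed length and `n` = summed genome protein length.  Returns TRUE
#' iff the minimal E-value is below `evalue_max`.
#'
#' @param genome a `genome_record`.
#' @param trx3_seed Trx3 seed sequence (string).
#' @param evalue_max E-value threshold (default 1e-10).
#' @return logical; attribute `min_evalue` carries the best E-value.
#' @export
detect_trx3_partner <- function(genome, trx3_seed, evalue_max = 1e-10) {
  if (evalue_max <= 0) stop_format("evalue_max must be positive")
  seqs <- genome$proteins$sequence
  if (!length(seqs)) return(structure(FALSE, min_evalue = Inf))
  s <- Biostrings::pairwiseAlignment(seqs, trx3_seed, type = "local",
                                     substitutionMatrix = blosum62(),
                                     gapOpening = 11, gapExtension = 1,
                                     scoreOnly = TRUE)
  lambda <- 0.267; K <- 0.041
  m <- nchar(trx3_seed); n <- sum(nchar(seqs))
  e <- K * m * n * exp(-lambda * max(s))
  structure(e < evalue_max, min_evalue = e)
}

#' Split a TR3 group into TR3 and dcTR1 by Trx3 partner presence
#'
#' A member is TR3 iff its genome carries a detectable non-canonical Trx3
#' partner; otherwise it is a degenerated Clostridium TR1 (dcTR1).
#'
#' @param tr3_group a `homolog_group`.
#' @param genomes list of `genome_record`s.
#' @param trx3_seed Trx3 seed sequence.
#' @param evalue_max E-value threshold (default 1e-10).
#' @return list with `TR3` and `dcTR1` groups and `unassigned` ids.
#' @export
split_tr3_dctr1 <- function(tr3_group, genomes, trx3_seed,
                            evalue_max = 1e-10) {
  orgs <- vapply(genomes, `[[`, "", "organism_id")
  prot_org <- do.call(rbind, lapply(genomes, function(g)
    data.frame(protein_id = g$proteins$protein_id,
               organism_id = g$organism_id, stringsAsFactors = FALSE)))
  partner <- setNames(rep(NA, length(genomes)), orgs)
  tr3 <- character(0); dc <- character(0); un <- character(0)
  for (id in tr3_group$member_ids) {
    org <- prot_org$organism_id[match(id, prot_org$protein_id)]
    if (is.na(org)) {
      message(sprintf("organism of %s unresolvable; leaving unassigned", id))
      un <- c(un, id)
      next
    }
    if (is.na(partner[org]))
      partner[org] <- detect_trx3_partner(genomes[[match(org, orgs)]],
                                          trx3_seed, evalue_max)
    if (partner[org]) tr3 <- c(tr3, id) else dc <- c(dc, id)
  }
  list(TR3 = homolog_group("TR3", tr3, intersect(tr3_group$seed_ids, tr3)),
       dcTR1 = homolog_group("dcTR1", dc),
       unassigned = un)
}

#' Census configuration with validated defaults
#'
#' @param ... overrides for: `psn_threshold` (0.35), `pseudocount` (80),
#'   `evalue_max` (1e-10), `max_runs` (10), `info_threshold_bits` (2),
#'   `majority_fraction` (0.7), `min_clade_size` (3), `seed` (1).
#' @return named list of class `census_config`.
#' @export
census_config <- function(...) {
  cfg <- list(psn_threshold = 0.35, pseudocount = 80, evalue_max = 1e-10,
              max_runs = 10L, info_threshold_bits = 2, majority_fraction = 0.7,
              min_clade_size = 3L, seed = 1L)
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown)) stop_format("unknown config key(s): %s",
                                   paste(unknown, collapse = ", "))
  cfg[names(dots)] <- dots
  if (cfg$psn_threshold < 0 || cfg$psn_threshold > 1)
    stop_format("psn_threshold must be in [0, 1]")
  if (cfg$pseudocount <= 0) stop_format("pseudocount must be positive")
  if (cfg$evalue_max <= 0) stop_format("evalue_max must be positive")
  if (cfg$max_runs < 1) stop_format("max_runs must be >= 1")
  structure(cfg, class = "census_config")
}

#' Run the full TR-subfamily census
#'
#' Pipeline: PNDO detection with the seed-built trusted-cutoff profile;
#' seed-anchored similarity-network grouping; iterative BoxB enrichment per
#' family; margin-based resolution of proteins claimed by several families;
#' the TR1/FdR active-site-cysteine split and the TR3/dcTR1 Trx3-partner
#' split; finally the per-protein report, the label-by-class occurrence
#' table and the per-genome co-occurrence table.
#'
#' @param genomes list of `genome_record`s.
#' @param seeds a `seed_set`.
#' @param trx3_seed Trx3 seed sequence (string), or NULL to skip the
#'   TR3/dcTR1 split (everything stays TR3).
#' @param config a [census_config()].
#' @return a list of class `tr_census` with `report` (per-protein data
#'   frame), `occurrence` (label x class counts), `cooccurrence` (per-genome
#'   family presence), `groups`, `traces`, `consensus` (per-family BoxA/BoxB
#'   motifs), `boxes`, `pndo_hits`.
#' @export
run_census <- function(genomes, seeds, trx3_seed = NULL,
                       config = census_config()) {
  prot <- all_proteins(genomes)
  org_class <- setNames(vapply(genomes, function(g) g$lineage[["class"]], ""),
                        vapply(genomes, `[[`, "", "organism_id"))

  # stage 1: PNDO detection
  prof51 <- pndo_profile(seeds, pseudocount = config$pseudocount)
  hits <- find_pndo(genomes, prof51)

  # stage 2: similarity network over the PNDO universe, seeds injected
  seed_prot <- protein_set(seeds$protein_id, seeds$sequence,
                           organism_id = "seed")
  universe <- rbind(prot[match(hits$protein_id, prot$protein_id),
                         , drop = FALSE], seed_prot)
  class(universe) <- c("protein_set", "data.frame")
  psn <- build_psn(universe, threshold = config$psn_threshold)
  groups <- seed_components(psn, seeds, universe)

  # stage 3: iterative enrichment per family against the PNDO pool
  pool <- universe
  traces <- list(); profiles <- list()
  for (fam in names(groups)) {
    en <- enrich_group(groups[[fam]], pool, max_runs = config$max_runs,
                       pseudocount = config$pseudocount)
    groups[[fam]] <- en$group
    traces[[fam]] <- en$trace
    profiles[[fam]] <- en$profile
  }

  # stage 4: margin rule for proteins claimed by several families
  claimed <- unlist(lapply(groups, `[[`, "member_ids"))
  dup_ids <- unique(claimed[duplicated(claimed)])
  for (id in dup_ids) {
    fams <- names(groups)[vapply(groups, function(g) id %in% g$member_ids, TRUE)]
    seq <- pool$sequence[match(id, pool$protein_id)]
    margin <- vapply(fams, function(f)
      score_profile(profiles[[f]], seq)$score_bits -
        profiles[[f]]$trusted_cutoff, 0)
    best <- fams[order(-margin, fams)][1L]
    message(sprintf("%s claimed by %s; kept in %s (margin rule)",
                    id, paste(fams, collapse = "+"), best))
    for (f in setdiff(fams, best))
      groups[[f]]$member_ids <- setdiff(groups[[f]]$member_ids, id)
  }

  # stage 5: box extraction per final group (anchored on the primary seed)
  boxes <- list()
  for (fam in names(groups)) {
    g <- groups[[fam]]
    anchor <- sort(g$seed_ids)[1L]
    mem <- pool[match(g$member_ids, pool$protein_id), , drop = FALSE]
    boxes[[fam]] <- if (nrow(mem) == 1L) {
      loc <- locate_boxes(mem$sequence)
      structure(list(boxes = data.frame(
        member_id = mem$protein_id,
        boxA = substr(mem$sequence, loc$boxA_start, loc$boxA_start + 30L),
        boxB = substr(mem$sequence, loc$boxB_start, loc$boxB_start + 19L),
        stringsAsFactors = FALSE)), class = "tr_boxes")
    } else extract_boxes(star_align(mem, anchor))
  }

  # stage 6: split rules
  final <- list()
  rule <- list()
  if ("TR1" %in% names(groups)) {
    sp <- split_tr1_fdr(groups$TR1, boxes$TR1)
    final$TR1 <- sp$TR1$member_ids; final$FdR <- sp$FdR$member_ids
    rule$TR1 <- "cys2"; rule$FdR <- "cys<2"
    boxes$FdR <- structure(list(boxes = boxes$TR1$boxes[
      boxes$TR1$boxes$member_id %in% sp$FdR$member_ids, , drop = FALSE]),
      class = "tr_boxes")
  }
  if ("TR3" %in% names(groups)) {
    if (is.null(trx3_seed)) {
      final$TR3 <- groups$TR3$member_ids
      rule$TR3 <- "no-trx3-seed"
    } else {
      sp <- split_tr3_dctr1(groups$TR3, genomes, trx3_seed,
                            evalue_max = config$evalue_max)
      final$TR3 <- sp$TR3$member_ids; final$dcTR1 <- sp$dcTR1$member_ids
      rule$TR3 <- "trx3-present"; rule$dcTR1 <- "trx3-absent"
      boxes$dcTR1 <- structure(list(boxes = boxes$TR3$boxes[
        boxes$TR3$boxes$member_id %in% sp$dcTR1$member_ids, , drop = FALSE]),
        class = "tr_boxes")
    }
  }
  if ("TRi" %in% names(groups)) {
    final$TRi <- groups$TRi$member_ids
    rule$TRi <- "psn-seed"
  }

  # per-protein report (seeds excluded: they are reference inputs)
  label <- setNames(rep("unassigned", nrow(prot)), prot$protein_id)
  trace_str <- setNames(rep("", nrow(prot)), prot$protein_id)
  in_pool <- prot$protein_id %in% hits$protein_id
  trace_str[in_pool] <- "pndo_hit"
  for (fam in names(final)) {
    ids <- intersect(final[[fam]], prot$protein_id)
    label[ids] <- fam
    trace_str[ids] <- paste(trace_str[ids], paste0("group:", fam),
                            paste0("rule:", rule[[fam]]), sep = ";")
  }
  score <- setNames(rep(NA_real_, nrow(prot)), prot$protein_id)
  score[hits$protein_id[hits$protein_id %in% prot$protein_id]] <-
    hits$score_bits[hits$protein_id %in% prot$protein_id]
  report <- data.frame(protein_id = prot$protein_id,
                       organism_id = prot$organism_id,
                       class = unname(org_class[prot$organism_id]),
                       assigned_label = unname(label),
                       score_bits = unname(score),
                       rule_trace = unname(trace_str),
                       stringsAsFactors = FALSE)

  occurrence <- as.data.frame.matrix(table(report$assigned_label, report$class))
  fams_present <- setdiff(unique(report$assigned_label), "unassigned")
  cooccurrence <- do.call(rbind, lapply(names(org_class), function(o) {
    labs <- report$assigned_label[report$organism_id == o]
    row <- as.list(setNames(vapply(fams_present, function(f) f %in% labs, TRUE),
                            fams_present))
    cbind(data.frame(organism_id = o, class = unname(org_class[o]),
                     stringsAsFactors = FALSE),
          as.data.frame(row))
  }))

  consensus <- lapply(boxes, function(bx) {
    bb <- bx$boxes[!is.na(bx$boxes$boxA), , drop = FALSE]
    if (!nrow(bb)) return(NULL)
    list(boxA = consensus_motif(make_logo(bb$boxA),
                                config$info_threshold_bits,
                                config$majority_fraction),
         boxB = consensus_motif(make_logo(bb$boxB),
                                config$info_threshold_bits,
                                config$majority_fraction))
  })

  structure(list(report = report, occurrence = occurrence,
                 cooccurrence = cooccurrence, groups = groups,
                 traces = traces, consensus = consensus, boxes = boxes,
                 pndo_hits = hits, pndo_profile = prof51, psn = psn,
                 config = config),
            class = "tr_census")
}
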