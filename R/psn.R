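# Protein similarity network over the PNDO universe: global-alignment
# identity edges, connected components anchored by seed proteins.

#' Global-alignment identity between two protein sequences
#'
#' Needleman-Wunsch with match +1, mismatch 0 and linear gap penalty -1;
#' similarity is matches / alignment length, a symmetric value in `[0, 1]`.
#' X never counts as a match (it is an ambiguity code, not evidence of
#' identity).  Computed in C (src/nw.cpp); among co-optimal alignments the
#' one with the most matches, then the shortest, is reported.
#'
#' @param a,b protein sequences (strings).
#' @return numeric similarity in `[0, 1]`.
#' @export
pairwise_similarity <- function(a, b) {
  if (!nzchar(a) || !nzchar(b)) stop_format("empty sequence")
  .nw_identity(a, b)[1L]
}

#' Build the protein similarity network
#'
#' All-vs-all global-alignment identity; an edge is kept iff the similarity
#' is at or above `threshold`.
#'
#' @param proteins a [protein_set()].
#' @param threshold minimum retained similarity in `[0, 1]` (default 0.35).
#' @return a list of class `tr_psn` with `nodes` (protein ids), `edges`
#'   (data frame id_a, id_b, similarity) and `threshold`.
#' @export
build_psn <- function(proteins, threshold = 0.35) {
  if (threshold < 0 || threshold > 1) stop_format("threshold must be in [0, 1]")
  ids <- proteins$protein_id
  seqs <- proteins$sequence
  n <- length(ids)
  ea <- character(0); eb <- character(0); es <- numeric(0)
  if (n >= 2L) for (i in seq_len(n - 1L)) {
    js <- (i + 1L):n
    sim <- .nw_identity(seqs[js], seqs[i])
    keep <- sim >= threshold
    ea <- c(ea, rep(ids[i], sum(keep)))
    eb <- c(eb, ids[js][keep])
    es <- c(es, sim[keep])
  }
  structure(list(nodes = ids,
                 edges = data.frame(id_a = ea, id_b = eb, similarity = es,
                                    stringsAsFactors = FALSE),
                 threshold = threshold),
            class = "tr_psn")
}

psn_components <- function(psn) {
  g <- igraph::graph_from_data_frame(psn$edges[, c("id_a", "id_b")],
                                     directed = FALSE,
                                     vertices = data.frame(name = psn$nodes))
  comp <- igraph::components(g)
  split(names(comp$membership), comp$membership)
}

#' Construct a homolog group
#'
#' @param label family label (or `"PNDO"` for the unassigned pool).
#' @param member_ids member protein ids.
#' @param seed_ids seed ids anchoring the group (subset of members).
#' @return a list of class `homolog_group`.
#' @export
homolog_group <- function(label, member_ids, seed_ids = character(0)) {
  member_ids <- unique(member_ids)
  if (!all(seed_ids %in% member_ids))
    stop_format("seed ids must be a subset of member ids")
  structure(list(label = label, member_ids = member_ids,
                 seed_ids = seed_ids, history = list()),
            class = "homolog_group")
}

#' Extract seed-anchored homolog groups from a similarity network
#'
#' Connected components holding at least one seed become groups labeled by
#' the seed family; in a component holding seeds of several families each
#' non-seed member goes to the family of its highest-similarity seed (ties
#' to the lexicographically smallest label, logged).  Components with the
#' same family label are merged.  Seedless components are not grouped but
#' stay in the PNDO pool for later enrichment.
#'
#' @param psn a `tr_psn`; seed ids must be among its nodes.
#' @param seeds a `seed_set`.
#' @param proteins the [protein_set()] the network was built from (used to
#'   resolve mixed components by direct similarity to the seeds).
#' @return named list of `homolog_group`s (one per family present).
#' @export
seed_components <- function(psn, seeds, proteins) {
  missing <- setdiff(seeds$protein_id, psn$nodes)
  if (length(missing))
    stop_format("seed(s) absent from the network: %s",
                paste(missing, collapse = ", "))
  comps <- psn_components(psn)
  assign <- list()
  for (comp in comps) {
    sidx <- which(seeds$protein_id %in% comp)
    if (!length(sidx)) next
    fams <- sort(unique(seeds$family_label[sidx]))
    if (length(fams) == 1L) {
      assign[[length(assign) + 1L]] <-
        data.frame(protein_id = comp, label = fams,
                   seed = seeds$protein_id[sidx[1L]], stringsAsFactors = FALSE)
    } else {
      message(sprintf("mixed-seed component (%s): assigning members to nearest seed",
                      paste(fams, collapse = "+")))
      comp_seeds <- seeds[sidx, , drop = FALSE]
      rows <- lapply(comp, function(id) {
        if (id %in% comp_seeds$protein_id) {
          k <- match(id, comp_seeds$protein_id)
          return(data.frame(protein_id = id, label = comp_seeds$family_label[k],
                            seed = id, stringsAsFactors = FALSE))
        }
        seq <- proteins$sequence[match(id, proteins$protein_id)]
        sims <- vapply(comp_seeds$sequence, function(s)
          pairwise_similarity(seq, s), 0)
        best <- sims == max(sims)
        labs <- sort(comp_seeds$family_label[best])
        if (length(unique(comp_seeds$family_label[best])) > 1L)
          message(sprintf("similarity tie for %s: choosing label %s", id, labs[1L]))
        k <- which(best & comp_seeds$family_label == labs[1L])[1L]
        data.frame(protein_id = id, label = labs[1L],
                   seed = comp_seeds$protein_id[k], stringsAsFactors = FALSE)
      })
      assign[[length(assign) + 1L]] <- do.call(rbind, rows)
    }
  }
  if (!length(assign)) return(list())
  tab <- do.call(rbind, assign)
  out <- lapply(split(tab, tab$label), function(d)
    homolog_group(d$label[1L], sort(d$protein_id),
                  sort(intersect(d$protein_id, seeds$protein_id))))
  out[order(names(out))]
}

#' Write a similarity network as an edge-list TSV
#'
#' @param psn a `tr_psn`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_psn <- function(psn, path) {
  write.table(psn$edges, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
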