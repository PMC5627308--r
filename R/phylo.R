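# Distance-based phylogenetics: conserved-block selection with the modified
# Gblocks-style parameters, Poisson-corrected protein distances,
# neighbor-joining trees, outgroup rooting, Robinson-Foulds comparison and
# incongruence-based flags for duplication and HGT candidates.

msa_rows <- function(msa) {
  if (inherits(msa, "tr_msa")) msa$rows
  else if (is.character(msa)) msa
  else stop_format("expected a tr_msa or a character vector of aligned rows")
}

#' Select conserved alignment blocks
#'
#' A column is flank-conserved iff its most frequent non-gap residue occurs
#' in more than `flank_min_fraction` of the sequences (strictly more, the
#' ">50% of the number of sequences" rule).  Kept columns are the maximal
#' runs of flank-conserved columns of length at least `min_block_length`;
#' with `gaps_allowed = FALSE`, columns containing any gap are ineligible.
#'
#' @param msa a `tr_msa` or character vector of equal-length aligned rows.
#' @param flank_min_fraction conservation fraction (default 0.5).
#' @param min_block_length minimal accepted block length (default 2).
#' @param gaps_allowed whether gap-containing columns are eligible
#'   (default TRUE).
#' @return a list of class `block_selection` with `kept_columns` (sorted
#'   1-based indices), `runs` (data frame start/end/length) and `parameters`.
#' @export
select_blocks <- function(msa, flank_min_fraction = 0.5, min_block_length = 2L,
                          gaps_allowed = TRUE) {
  rows <- msa_rows(msa)
  if (!length(rows)) stop_format("empty alignment")
  w <- unique(nchar(rows))
  if (length(w) != 1L) stop_format("rows have unequal lengths")
  mat <- do.call(rbind, strsplit(rows, ""))
  n <- nrow(mat)
  conserved <- vapply(seq_len(w), function(j) {
    col <- mat[, j]
    if (!gaps_allowed && any(col == "-")) return(FALSE)
    res <- col[col %in% AA_ALPHABET]
    length(res) > 0 && max(table(res)) > flank_min_fraction * n
  }, TRUE)
  r <- rle(conserved)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep_run <- r$values & r$lengths >= min_block_length
  runs <- data.frame(start = starts[keep_run], end = ends[keep_run],
                     length = r$lengths[keep_run])
  kept <- unlist(mapply(seq, runs$start, runs$end, SIMPLIFY = FALSE))
  structure(list(kept_columns = as.integer(kept %||% integer(0)),
                 runs = runs,
                 parameters = list(flank_min_fraction = flank_min_fraction,
                                   min_block_length = min_block_length,
                                   gaps_allowed = gaps_allowed)),
            class = "block_selection")
}

#' Poisson-corrected distance between two aligned rows
#'
#' `p` is the mismatch fraction over the kept columns where both rows carry
#' a residue; the distance is `-ln(1 - p)`, with saturation (`p >= 0.95`)
#' capped at `-ln(0.05)` with a warning.
#'
#' @param row_a,row_b gapped aligned strings of equal length.
#' @param kept_columns column indices to use (default: all).
#' @return non-negative distance.
#' @export
protein_distance <- function(row_a, row_b,
                             kept_columns = seq_len(nchar(row_a))) {
  a <- strsplit(row_a, "")[[1]][kept_columns]
  b <- strsplit(row_b, "")[[1]][kept_columns]
  ok <- a %in% AA_ALPHABET & b %in% AA_ALPHABET
  if (!any(ok)) stop_format("no mutually non-gap kept columns")
  p <- mean(a[ok] != b[ok])
  if (p >= 0.95) {
    warning("distance saturated (p >= 0.95); capping", call. = FALSE)
    p <- 0.95
  }
  -log(1 - p)
}

#' Pairwise distance matrix over an alignment
#'
#' @param msa a `tr_msa` or character vector of aligned rows (named).
#' @param kept_columns columns to use, e.g. from [select_blocks()].
#' @return symmetric matrix with zero diagonal, leaf ids as dimnames.
#' @export
dist_matrix <- function(msa, kept_columns = NULL) {
  rows <- msa_rows(msa)
  if (is.null(kept_columns)) kept_columns <- seq_len(nchar(rows[[1L]]))
  ids <- names(rows) %||% as.character(seq_along(rows))
  n <- length(rows)
  d <- matrix(0, n, n, dimnames = list(ids, ids))
  if (n >= 2L) for (i in 1:(n - 1L)) for (j in (i + 1L):n) {
    d[i, j] <- d[j, i] <- protein_distance(rows[[i]], rows[[j]], kept_columns)
  }
  d
}

#' Neighbor-joining tree from a distance matrix
#'
#' Saitou-Nei neighbor joining: iteratively joins the pair minimizing
#' `Q(i,j) = (n-2) d(i,j) - r_i - r_j`; ties are broken by the
#' lexicographically smallest pair of subtree representatives so the output
#' is deterministic.  Negative branch lengths are clamped to 0 with the
#' deficit moved to the sister branch.  Exact on additive matrices.
#'
#' @param d symmetric distance matrix with unique dimnames.
#' @return an unrooted `phylo` tree.
#' @export
nj_tree <- function(d) {
  if (!isSymmetric(unname(d), tol = 1e-8)) stop_format("matrix is not symmetric")
  labs <- rownames(d)
  if (is.null(labs) || anyDuplicated(labs)) stop_format("need unique leaf names")
  n <- nrow(d)
  if (n < 3L) stop_format("need at least 3 leaves")
  labs <- sanitize_label(labs)
  nwk <- labs          # growing newick fragment per active node
  repr <- labs         # lexicographic representative per active node
  D <- d
  while (length(nwk) > 3L) {
    m <- length(nwk)
    r <- rowSums(D)
    Q <- (m - 2) * D - outer(r, r, `+`)
    diag(Q) <- Inf
    qmin <- min(Q)
    cand <- which(Q - qmin < 1e-9, arr.ind = TRUE)
    cand <- cand[cand[, 1] < cand[, 2], , drop = FALSE]
    key <- apply(cand, 1L, function(ij) {
      pr <- sort(c(repr[ij[1]], repr[ij[2]]))
      paste(pr, collapse = "\r")
    })
    pick <- cand[order(key)[1L], ]
    i <- pick[1L]; j <- pick[2L]
    vi <- 0.5 * D[i, j] + (r[i] - r[j]) / (2 * (m - 2))
    vj <- D[i, j] - vi
    if (vi < 0) { vj <- D[i, j]; vi <- 0 }
    if (vj < 0) { vi <- D[i, j]; vj <- 0 }
    newd <- 0.5 * (D[i, ] + D[j, ] - D[i, j])
    node_nwk <- sprintf("(%s:%.10g,%s:%.10g)", nwk[i], vi, nwk[j], vj)
    node_repr <- min(repr[i], repr[j])
    keep <- setdiff(seq_len(m), c(i, j))
    D <- rbind(cbind(D[keep, keep, drop = FALSE], newd[keep]),
               c(newd[keep], 0))
    nwk <- c(nwk[keep], node_nwk)
    repr <- c(repr[keep], node_repr)
  }
  # final three-point formulas
  va <- max(0, 0.5 * (D[1, 2] + D[1, 3] - D[2, 3]))
  vb <- max(0, 0.5 * (D[1, 2] + D[2, 3] - D[1, 3]))
  vc <- max(0, 0.5 * (D[1, 3] + D[2, 3] - D[1, 2]))
  txt <- sprintf("(%s:%.10g,%s:%.10g,%s:%.10g);",
                 nwk[1], va, nwk[2], vb, nwk[3], vc)
  ape::read.tree(text = txt)
}

# canonical non-trivial bipartitions of an (un)rooted tree, as strings
tree_splits <- function(tree) {
  tree <- ape::unroot(tree)
  pp <- ape::prop.part(tree)
  labels <- attr(pp, "labels")
  ntip <- length(labels)
  anchor <- min(labels)
  keys <- vapply(pp, function(part) {
    tips <- labels[part]
    if (length(tips) < 2L || length(tips) > ntip - 2L) return(NA_character_)
    side <- if (anchor %in% tips) setdiff(labels, tips) else tips
    paste(sort(side), collapse = "|")
  }, "")
  unique(keys[!is.na(keys)])
}

#' Robinson-Foulds distance between two trees
#'
#' Symmetric-difference count of the non-trivial bipartitions of the two
#' unrooted trees; both must have identical leaf sets.
#'
#' @param tree_a,tree_b `phylo` objects.
#' @return non-negative integer.
#' @export
robinson_foulds <- function(tree_a, tree_b) {
  if (!setequal(tree_a$tip.label, tree_b$tip.label))
    stop_format("trees have different leaf sets")
  sa <- tree_splits(tree_a)
  sb <- tree_splits(tree_b)
  length(setdiff(sa, sb)) + length(setdiff(sb, sa))
}

#' Root a tree with the outgroup approach
#'
#' Checks that the outgroup leaves form a clade of the unrooted tree, then
#' places the root at the midpoint of the edge separating outgroup from
#' ingroup.
#'
#' @param tree an unrooted (or rooted) `phylo`.
#' @param outgroup_leaf_ids character vector of outgroup leaf names.
#' @return a rooted `phylo`.
#' @export
root_with_outgroup <- function(tree, outgroup_leaf_ids) {
  tips <- tree$tip.label
  missing <- setdiff(outgroup_leaf_ids, tips)
  if (length(missing)) stop_format("outgroup leaves not in tree: %s",
                                   paste(missing, collapse = ", "))
  k <- length(outgroup_leaf_ids)
  if (k == length(tips)) stop_format("outgroup cannot be all leaves")
  if (k > 1L && k < length(tips) - 1L) {
    key <- paste(sort(if (min(tips) %in% outgroup_leaf_ids)
      setdiff(tips, outgroup_leaf_ids) else outgroup_leaf_ids), collapse = "|")
    if (!key %in% tree_splits(tree))
      stop_format("outgroup not monophyletic in the unrooted tree: %s",
                  paste(sort(outgroup_leaf_ids), collapse = ", "))
  }
  rooted <- ape::root(ape::unroot(tree), outgroup = outgroup_leaf_ids,
                      resolve.root = TRUE)
  root_node <- length(rooted$tip.label) + 1L
  basal <- which(rooted$edge[, 1] == root_node)
  total <- sum(rooted$edge.length[basal])
  rooted$edge.length[basal] <- total / 2
  rooted
}

#' Flag leaves nesting inside a foreign taxonomic class
#'
#' A leaf is flagged iff its smallest enclosing clade with at least
#' `min_clade_size` leaves has a strict majority class (more than half of
#' the clade's leaves, the leaf itself included) different from the leaf's
#' own class.  This is the operational HGT signal: a gene-tree leaf
#' surrounded by another clade's sequences.  The default clade size of 3
#' means a lone foreign cherry partner does not poison the test in either
#' direction.
#'
#' @param tree a rooted `phylo`.
#' @param classes named character vector mapping every leaf to its class.
#' @param min_clade_size minimal clade size considered (default 3, min 2).
#' @return data frame (leaf, own_class, surrounding_class), sorted by leaf;
#'   zero rows when the tree is class-pure.
#' @export
flag_incongruent_leaves <- function(tree, classes, min_clade_size = 3L) {
  if (min_clade_size < 2L) stop_format("min_clade_size must be >= 2")
  tips <- tree$tip.label
  if (!all(tips %in% names(classes)))
    stop_format("unlabeled leaf/leaves: %s",
                paste(setdiff(tips, names(classes)), collapse = ", "))
  ntip <- length(tips)
  if (min_clade_size > ntip) {
    warning("min_clade_size exceeds the number of leaves", call. = FALSE)
    return(data.frame(leaf = character(0), own_class = character(0),
                      surrounding_class = character(0)))
  }
  parent <- integer(max(tree$edge))
  parent[tree$edge[, 2]] <- tree$edge[, 1]
  pp <- ape::prop.part(tree)  # tip sets per internal node, root first
  clade_tips <- function(node) tips[pp[[node - ntip]]]
  root_node <- ntip + 1L
  flags <- list()
  for (t in seq_len(ntip)) {
    nd <- parent[t]
    while (nd != root_node && length(pp[[nd - ntip]]) < min_clade_size)
      nd <- parent[nd]
    clade <- clade_tips(nd)
    tab <- sort(table(classes[clade]), decreasing = TRUE)
    if (tab[1L] > length(clade) / 2 && names(tab)[1L] != classes[[tips[t]]])
      flags[[length(flags) + 1L]] <- data.frame(
        leaf = tips[t], own_class = classes[[tips[t]]],
        surrounding_class = names(tab)[1L], stringsAsFactors = FALSE)
  }
  if (!length(flags)) return(data.frame(leaf = character(0),
                                        own_class = character(0),
                                        surrounding_class = character(0)))
  out <- do.call(rbind, flags)
  out[order(out$leaf), , drop = FALSE]
}

#' Report duplication candidates: organisms with several leaves in one tree
#'
#' @param tree a `phylo` whose leaves map to organisms.
#' @param tip_organism named character vector leaf -> organism id.
#' @return data frame (organism, n_copies, tips, mrca_node); zero rows when
#'   every organism contributes a single leaf.
#' @export
detect_duplications <- function(tree, tip_organism) {
  tips <- tree$tip.label
  if (!all(tips %in% names(tip_organism)))
    stop_format("leaf/leaves without organism mapping")
  orgs <- tip_organism[tips]
  dup_orgs <- names(which(table(orgs) >= 2L))
  rows <- lapply(sort(dup_orgs), function(o) {
    tt <- tips[orgs == o]
    data.frame(organism = o, n_copies = length(tt),
               tips = paste(sort(tt), collapse = ";"),
               mrca_node = ape::getMRCA(tree, tt), stringsAsFactors = FALSE)
  })
  if (!length(rows)) return(data.frame(organism = character(0),
                                       n_copies = integer(0),
                                       tips = character(0),
                                       mrca_node = integer(0)))
  do.call(rbind, rows)
}

#' Bootstrap support for a neighbor-joining tree
#'
#' Resamples the kept columns with replacement, rebuilds the NJ tree and
#' counts, for each internal edge of the point-estimate tree, the fraction
#' of replicates containing the same bipartition.
#'
#' @param msa a `tr_msa` or named character vector of aligned rows.
#' @param kept_columns columns to resample (default all).
#' @param n_replicates number of replicates (default 100).
#' @param seed RNG seed.
#' @return the NJ tree with `node.label` holding support percentages.
#' @export
nj_bootstrap <- function(msa, kept_columns = NULL, n_replicates = 100L,
                         seed = 1L) {
  rows <- msa_rows(msa)
  if (is.null(kept_columns)) kept_columns <- seq_len(nchar(rows[[1L]]))
  tree <- nj_tree(dist_matrix(rows, kept_columns))
  target <- tree_splits(tree)
  counts <- setNames(numeric(length(target)), target)
  with_seed(derive_seed(seed, "bootstrap"), {
    for (b in seq_len(n_replicates)) {
      cols <- sample(kept_columns, length(kept_columns), replace = TRUE)
      rep_tree <- try(nj_tree(dist_matrix(rows, cols)), silent = TRUE)
      if (inherits(rep_tree, "try-error")) next
      hit <- intersect(tree_splits(rep_tree), target)
      counts[hit] <- counts[hit] + 1
    }
  })
  support <- round(100 * counts / n_replicates)
  # attach support to internal nodes via their bipartition keys
  pp <- ape::prop.part(tree)
  labels <- attr(pp, "labels")
  ntip <- length(labels)
  anchor <- min(labels)
  node_keys <- vapply(pp, function(part) {
    tips <- labels[part]
    if (length(tips) < 2L || length(tips) > ntip - 2L) return(NA_character_)
    side <- if (anchor %in% tips) setdiff(labels, tips) else tips
    paste(sort(side), collapse = "|")
  }, "")
  tree$node.label <- ifelse(is.na(node_keys), "",
                            as.character(support[node_keys]))
  tree
}

#' Compare a gene tree against the reference taxonomy tree
#'
#' Restricts both trees to the organisms contributing exactly one gene-tree
#' leaf, renames the gene-tree leaves to organism ids and reports the
#' Robinson-Foulds distance.
#'
#' @param gene_tree `phylo` with protein leaves.
#' @param reference_tree `phylo` with organism leaves.
#' @param tip_organism named character vector leaf -> organism id.
#' @return list with `rf`, `n_shared` and `max_rf` (`2 * (n - 3)`).
#' @export
compare_to_reference <- function(gene_tree, reference_tree, tip_organism) {
  orgs <- tip_organism[gene_tree$tip.label]
  single <- names(which(table(orgs) == 1L))
  shared <- intersect(single, reference_tree$tip.label)
  if (length(shared) < 4L)
    return(list(rf = NA_real_, n_shared = length(shared), max_rf = NA_real_))
  gt <- ape::keep.tip(gene_tree, gene_tree$tip.label[orgs %in% shared])
  gt$tip.label <- unname(tip_organism[gt$tip.label])
  rt <- ape::keep.tip(reference_tree, shared)
  list(rf = robinson_foulds(gt, rt), n_shared = length(shared),
       max_rf = 2 * (length(shared) - 3))
}
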