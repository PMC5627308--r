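test_that("block selection drops isolated conserved columns", {
  # column 3 conserved but isolated; columns 6-7 conserved and adjacent
  rows <- c("ADCAAGGA",
            "ECCEEGGE",
            "FDCFFGGF",
            "GECGGGGK")
  sel <- select_blocks(rows, 0.5, 2L, TRUE)
  expect_equal(sel$runs$length, 2L)
  expect_equal(sel$kept_columns, c(6L, 7L))
  expect_false(3L %in% sel$kept_columns)
})

test_that("block selection boundary and degenerate cases", {
  invariant <- rep("MKVACD", 4)
  expect_equal(select_blocks(invariant)$kept_columns, 1:6)
  # adjacent pair at the very edge of the rule is kept
  rows <- c("AAG", "AAT", "AAW", "KAV")
  expect_equal(select_blocks(rows)$kept_columns, 1:2)
  # >50% strictly: a 2/4 column is not conserved
  rows2 <- c("AA", "AA", "GA", "TA")
  expect_equal(select_blocks(rows2)$kept_columns, integer(0))
  # row order invariance
  with_seed(5, {
    msa <- vapply(1:8, function(i)
      paste(sample(c("A", "C", "-"), 30, TRUE, prob = c(5, 2, 1)),
            collapse = ""), "")
    expect_equal(select_blocks(msa)$kept_columns,
                 select_blocks(sample(msa))$kept_columns)
  })
  # gaps_allowed = FALSE excludes gap-containing columns
  rows3 <- c("AAC", "A-C", "AAC", "AAC")
  expect_equal(select_blocks(rows3, gaps_allowed = FALSE)$kept_columns,
               integer(0))
  expect_equal(select_blocks(rows3, gaps_allowed = TRUE,
                             min_block_length = 1L)$kept_columns, c(1:3))
})

test_that("Poisson-corrected distances", {
  expect_equal(protein_distance("MKVACDEFGH", "MKVACDEFGH"), 0)
  expect_equal(protein_distance("MKVACDEFGH", "MKVACDEFGW"),
               -log(0.9), tolerance = 1e-9)
  expect_warning(d <- protein_distance("AAAA", "TTTT"), "saturated")
  expect_equal(d, -log(0.05))
  expect_error(protein_distance("A-", "-A"), "no mutually")
  # gapped positions are excluded
  expect_equal(protein_distance("MK-ACD", "MKWACD"), 0)
})

test_that("neighbor joining is exact on a hand-built additive matrix", {
  # ((A:2,B:3):1,(C:4,D:5)) as an unrooted additive tree
  d <- matrix(0, 4, 4, dimnames = list(c("A", "B", "C", "D"),
                                       c("A", "B", "C", "D")))
  d["A", "B"] <- d["B", "A"] <- 5
  d["A", "C"] <- d["C", "A"] <- 7
  d["A", "D"] <- d["D", "A"] <- 8
  d["B", "C"] <- d["C", "B"] <- 8
  d["B", "D"] <- d["D", "B"] <- 9
  d["C", "D"] <- d["D", "C"] <- 9
  tr <- nj_tree(d)
  ref <- ape::read.tree(text = "((A:2,B:3):1,(C:4,D:5));")
  expect_equal(robinson_foulds(tr, ref), 0)
  expect_equal(ape::cophenetic.phylo(tr)[rownames(d), colnames(d)], d,
               tolerance = 1e-9)

  d3 <- d[1:3, 1:3]
  t3 <- nj_tree(d3)
  expect_equal(ape::cophenetic.phylo(t3)[rownames(d3), colnames(d3)], d3,
               tolerance = 1e-9)
  bad <- d; bad[1, 2] <- 99
  expect_error(nj_tree(bad), "symmetric")
  expect_error(nj_tree(d[1:2, 1:2]), "3 leaves")
})

test_that("NJ recovers random additive trees exactly (n <= 12)", {
  for (s in 1:8) {
    ra <- random_additive(sample(4:12, 1, prob = rep(1, 9)), seed = 300 + s)
    tr <- nj_tree(ra$d)
    expect_equal(robinson_foulds(tr, ra$tree), 0)
    expect_equal(ape::cophenetic.phylo(tr)[rownames(ra$d), colnames(ra$d)],
                 ra$d, tolerance = 1e-6)
  }
})

test_that("NJ on ultrametric matrices matches average-linkage topology", {
  for (s in 1:4) {
    with_seed(400 + s, {
      n <- sample(5:10, 1)
      tr0 <- ape::rcoal(n)
      d <- ape::cophenetic.phylo(tr0)
      nj <- nj_tree(d)
      hc <- ape::as.phylo(hclust(as.dist(d), method = "average"))
      expect_equal(robinson_foulds(nj, hc), 0)
    })
  }
})

test_that("Robinson-Foulds distance: examples, symmetry, oracle", {
  t1 <- ape::read.tree(text = "((A,B),(C,D));")
  t2 <- ape::read.tree(text = "((A,C),(B,D));")
  expect_equal(robinson_foulds(t1, t1), 0)
  expect_equal(robinson_foulds(t1, t2), 2)
  with_seed(17, {
    for (i in 1:6) {
      n <- sample(4:12, 1)
      a <- ape::rtree(n); b <- ape::rtree(n)
      b$tip.label <- a$tip.label <- paste0("t", 1:n)
      expect_equal(robinson_foulds(a, b), robinson_foulds(b, a))
      expect_equal(robinson_foulds(a, b),
                   as.integer(phangorn::RF.dist(ape::unroot(a),
                                                ape::unroot(b))))
    }
  })
  t3 <- ape::read.tree(text = "((A,B),(C,E));")
  expect_error(robinson_foulds(t1, t3), "leaf sets")
})

test_that("outgroup rooting: placement, monophyly check, split identity", {
  tr <- ape::read.tree(text = "((A:1,B:1):1,(C:1,D:3):2);")
  r <- root_with_outgroup(tr, "D")
  expect_true(ape::is.rooted(r))
  kids <- r$edge[r$edge[, 1] == length(r$tip.label) + 1L, 2]
  expect_true(any(kids == which(r$tip.label == "D")))
  basal <- which(r$edge[, 1] == length(r$tip.label) + 1L)
  expect_equal(r$edge.length[basal][1], r$edge.length[basal][2])

  r2 <- root_with_outgroup(tr, c("C", "D"))
  expect_equal(robinson_foulds(ape::unroot(r2), ape::unroot(tr)), 0)
  expect_error(root_with_outgroup(tr, c("A", "C")), "not monophyletic")
  expect_error(root_with_outgroup(tr, c("A", "B", "C", "D")), "all leaves")
  expect_error(root_with_outgroup(tr, "Z"), "not in tree")
})

test_that("incongruence flags: planted transfer found, pure tree clean", {
  # class-pure tree: no flags
  tr <- ape::read.tree(text = "(((a1,a2),a3),((b1,b2),b3));")
  cls <- setNames(rep(c("A", "B"), each = 3), c("a1", "a2", "a3",
                                                "b1", "b2", "b3"))
  expect_equal(nrow(flag_incongruent_leaves(tr, cls)), 0L)
  # a B leaf grafted among the As is the only flag
  tr2 <- ape::read.tree(text = "(((a1,bX),(a2,a3)),((b1,b2),b3));")
  cls2 <- c(cls, bX = "B")
  fl <- flag_incongruent_leaves(tr2, cls2)
  expect_equal(fl$leaf, "bX")
  expect_equal(fl$own_class, "B")
  expect_equal(fl$surrounding_class, "A")
  expect_warning(out <- flag_incongruent_leaves(tr, cls, min_clade_size = 99),
                 "exceeds")
  expect_equal(nrow(out), 0L)
  expect_error(flag_incongruent_leaves(tr2, cls), "bX")
})

test_that("generator-planted HGT is flagged on the gene tree", {
  ds <- make_dataset(12L, c(TR1 = 1L), mutation_rate = 0.01, seed = 37L,
                     n_hgt = 1L)
  prot <- all_proteins(ds$genomes)
  ids <- ds$truth$protein_id[ds$truth$label == "TR1"]
  mem <- prot[match(ids, prot$protein_id), ]
  class(mem) <- c("protein_set", "data.frame")
  msa <- star_align(mem, ids[1])
  sel <- select_blocks(msa)
  tree <- nj_tree(dist_matrix(msa, sel$kept_columns))
  cls <- setNames(ds$truth$class[match(tree$tip.label, ds$truth$protein_id)],
                  tree$tip.label)
  out_tips <- names(cls)[cls == "Actinobacteria"]
  rooted <- root_with_outgroup(tree, out_tips)
  fl <- flag_incongruent_leaves(rooted, cls)
  expect_true(ds$hgt_ids %in% fl$leaf)
  expect_true(all(fl$leaf == ds$hgt_ids))

  # the same dataset without the transfer yields no flags
  ds0 <- make_dataset(12L, c(TR1 = 1L), mutation_rate = 0.01, seed = 37L)
  prot0 <- all_proteins(ds0$genomes)
  ids0 <- ds0$truth$protein_id[ds0$truth$label == "TR1"]
  mem0 <- prot0[match(ids0, prot0$protein_id), ]
  class(mem0) <- c("protein_set", "data.frame")
  msa0 <- star_align(mem0, ids0[1])
  tree0 <- nj_tree(dist_matrix(msa0, select_blocks(msa0)$kept_columns))
  cls0 <- setNames(ds0$truth$class[match(tree0$tip.label,
                                         ds0$truth$protein_id)],
                   tree0$tip.label)
  rooted0 <- root_with_outgroup(tree0, names(cls0)[cls0 == "Actinobacteria"])
  expect_equal(nrow(flag_incongruent_leaves(rooted0, cls0)), 0L)
})

test_that("duplication candidates are organisms with several leaves", {
  tr <- ape::read.tree(text = "((x1,x2),(y1,z1));")
  org <- c(x1 = "gx", x2 = "gx", y1 = "gy", z1 = "gz")
  dup <- detect_duplications(tr, org)
  expect_equal(dup$organism, "gx")
  expect_equal(dup$n_copies, 2L)
  expect_equal(dup$mrca_node, ape::getMRCA(tr, c("x1", "x2")))
  expect_equal(nrow(detect_duplications(tr, c(x1 = "a", x2 = "b", y1 = "c",
                                              z1 = "d"))), 0L)
  expect_error(detect_duplications(tr, org[1:3]), "mapping")
})

test_that("TRi/TR1 co-planted genomes surface as duplication candidates", {
  ds <- make_dataset(6L, c(TR1 = 1L, TRi = 1L), mutation_rate = 0.01,
                     seed = 43L)
  prot <- all_proteins(ds$genomes)
  ids <- ds$truth$protein_id[ds$truth$label %in% c("TR1", "TRi")]
  mem <- prot[match(ids, prot$protein_id), ]
  class(mem) <- c("protein_set", "data.frame")
  msa <- star_align(mem, ids[1])
  tree <- nj_tree(dist_matrix(msa, select_blocks(msa)$kept_columns))
  org <- setNames(ds$truth$organism_id[match(tree$tip.label,
                                             ds$truth$protein_id)],
                  tree$tip.label)
  dup <- detect_duplications(tree, org)
  expect_setequal(dup$organism,
                  vapply(ds$genomes, `[[`, "", "organism_id"))
  expect_true(all(dup$n_copies == 2L))
})

test_that("gene tree vs reference comparison and bootstrap support", {
  ds <- make_dataset(9L, c(TR1 = 1L), mutation_rate = 0.01, seed = 51L)
  prot <- all_proteins(ds$genomes)
  ids <- ds$truth$protein_id[ds$truth$label == "TR1"]
  mem <- prot[match(ids, prot$protein_id), ]
  class(mem) <- c("protein_set", "data.frame")
  msa <- star_align(mem, ids[1])
  sel <- select_blocks(msa)
  tree <- nj_tree(dist_matrix(msa, sel$kept_columns))
  cmp <- compare_to_reference(tree, ds$reference_tree,
                              setNames(ds$truth$organism_id,
                                       ds$truth$protein_id))
  expect_equal(cmp$n_shared, 9L)
  expect_true(cmp$rf >= 0 && cmp$rf <= cmp$max_rf)

  bs <- nj_bootstrap(msa, sel$kept_columns, n_replicates = 20L, seed = 2L)
  sup <- suppressWarnings(as.numeric(bs$node.label))
  sup <- sup[!is.na(sup)]
  expect_true(all(sup >= 0 & sup <= 100))
  expect_equal(robinson_foulds(bs, tree), 0)
})
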