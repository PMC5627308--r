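test_that("build_profile matches the hand-computed pseudocount formula", {
  # one string "CA", uniform background, pseudocount 1:
  # f = (1 + 0.05) / (1 + 1) = 0.525; log2(0.525 / 0.05) = log2(10.5)
  p <- build_profile("CA", pseudocount = 1)
  expect_equal(unname(p$log_odds[1, "C"]), log2(10.5), tolerance = 1e-9)
  expect_equal(unname(p$log_odds[2, "A"]), log2(10.5), tolerance = 1e-9)
  expect_equal(unname(p$log_odds[1, "W"]), log2((0.05 / 2) / 0.05),
               tolerance = 1e-9)

  # all-gap column carries no information
  p2 <- build_profile(c("-A", "-C"))
  expect_equal(unname(p2$log_odds[1, ]), rep(0, 20))

  # the pseudocount formula is additive in observations: duplicating the
  # member strings sharpens the profile (n doubles) but keeps the consensus
  p3 <- build_profile(c("CA", "CA"), pseudocount = 1)
  expect_equal(unname(p3$log_odds[1, "C"]), log2(((2 + 0.05) / 3) / 0.05),
               tolerance = 1e-9)
  expect_equal(which.max(p3$log_odds[1, ]), which.max(p$log_odds[1, ]))

  expect_error(build_profile(c("CA", "CAT")), "unequal")
  expect_error(build_profile(character(0)), "empty")
})

test_that("score_profile: brute-force window example and edge rules", {
  p <- build_profile("CA", pseudocount = 1)
  hit <- score_profile(p, "GCAG")
  expect_equal(hit$start, 2L)
  expect_equal(hit$score_bits,
               unname(p$log_odds[1, "C"] + p$log_odds[2, "A"]))
  # X scores 0 everywhere
  expect_equal(score_profile(p, "XXXX")$score_bits, 0)
  expect_equal(score_profile(p, "XXXX")$start, 1L)  # smallest offset on ties
  expect_error(score_profile(p, "C"), "shorter")
  expect_error(score_profile(p, "A-C"), "gap characters")
})

test_that("oracle equivalence: scoring equals window enumeration", {
  with_seed(31, {
    for (i in 1:25) {
      w <- sample(1:3, 1)
      n <- sample(1:4, 1)
      strs <- vapply(seq_len(n), function(k)
        paste(sample(c(AA_ALPHABET, "-"), w, replace = TRUE,
                     prob = c(rep(1, 20), 3)), collapse = ""), "")
      if (all(grepl("^-+$", strs))) strs[1] <- paste(rep("A", w), collapse = "")
      p <- build_profile(strs)
      seq <- paste(sample(c(AA_ALPHABET, "X"), sample(w:8, 1), replace = TRUE),
                   collapse = "")
      got <- score_profile(p, seq)
      want <- oracle_best_window(p, seq)
      expect_equal(got$score_bits, want$score_bits, tolerance = 1e-9)
      expect_equal(got$start, want$start)
    }
  })
})

test_that("consensus dominance: no same-length sequence beats the consensus", {
  # width-2 profile over a 4-letter sub-alphabet, exhaustively enumerated
  p <- build_profile(c("CA", "CA", "CG", "TA"))
  letters4 <- c("A", "C", "G", "T")
  combos <- expand.grid(a = letters4, b = letters4, stringsAsFactors = FALSE)
  scores <- apply(combos, 1, function(r)
    score_profile(p, paste0(r[1], r[2]))$score_bits)
  consensus <- score_profile(p, "CA")$score_bits
  expect_true(all(scores <= consensus + 1e-9))
})

test_that("profile invariants: additivity, shift, pseudocount monotonicity", {
  with_seed(13, {
    left <- c("CAD", "CAE")
    right <- c("GW", "GW")
    pl <- build_profile(left); pr <- build_profile(right)
    pc <- build_profile(paste0(left, right))
    seq <- "MCADGWKL"
    expect_equal(score_profile(pc, seq)$score_bits,
                 oracle_best_window(pl, substr(seq, 2, 4))$score_bits +
                   oracle_best_window(pr, substr(seq, 5, 6))$score_bits,
                 tolerance = 1e-9)

    # shift equivariance for a unique planted window
    p <- build_profile("WCDW")
    base <- score_profile(p, "AWCDWAA")
    shifted <- score_profile(p, paste0("KLM", "AWCDWAA"))
    expect_equal(shifted$start, base$start + 3L)
    expect_equal(shifted$score_bits, base$score_bits)

    # raising the pseudocount never increases the consensus score
    cons <- "CADGW"
    sc <- vapply(c(0.5, 1, 2, 5, 20, 80), function(a)
      score_profile(build_profile(c("CADGW", "CADGW", "CKDGW"),
                                  pseudocount = a), cons)$score_bits, 0)
    expect_true(all(diff(sc) <= 1e-9))
  })
})

test_that("trusted_cutoff is the minimal member score and members re-pass", {
  grp <- fixture_group("TR1", n = 4L, mutation_rate = 0.05, seed = 8L)
  boxes <- substr(grp$sequence, 121L, 171L)  # planted template coordinates
  p <- build_profile(unname(boxes), pseudocount = 80)
  sc <- vapply(grp$sequence, function(s) score_profile(p, s)$score_bits, 0)
  p <- trusted_cutoff(p, grp$sequence)
  expect_equal(p$trusted_cutoff, min(sc))
  expect_true(all(sc >= p$trusted_cutoff))
  p1 <- trusted_cutoff(build_profile(unname(boxes[1])), grp$sequence[1])
  expect_equal(p1$trusted_cutoff,
               score_profile(p1, grp$sequence[1])$score_bits)
  expect_error(trusted_cutoff(p, character(0)), "empty")
})

test_that("find_pndo recovers the planted proteins exactly at zero noise", {
  prof <- pndo_profile(make_seed_set(), pseudocount = 80)
  ds <- make_dataset(6L, mutation_rate = 0, seed = 3L)
  hits <- find_pndo(ds$genomes, prof)
  planted <- ds$truth$protein_id[ds$truth$label %in%
                                   c("TRi", "TR1", "FdR", "TR3", "dcTR1")]
  expect_setequal(hits$protein_id, planted)
  expect_true(all(diff(hits$score_bits) <= 0))  # sorted by descending score

  # background-only dataset gives an empty hit list
  ds_bg <- make_dataset(4L, c(TR1 = 0L), n_background = 6L, seed = 5L)
  expect_equal(nrow(find_pndo(ds_bg$genomes, prof)), 0L)
})

test_that("find_pndo recall at mutation 0.05 on ~200 planted proteins", {
  prof <- pndo_profile(make_seed_set(), pseudocount = 80)
  ds <- make_dataset(67L, mutation_rate = 0.05, seed = 2024L)
  hits <- find_pndo(ds$genomes, prof)
  planted <- ds$truth$protein_id[ds$truth$label %in%
                                   c("TRi", "TR1", "FdR", "TR3", "dcTR1")]
  recall <- mean(planted %in% hits$protein_id)
  expect_gte(length(planted), 200L)
  expect_gte(recall, 0.95)
  expect_equal(sum(!hits$protein_id %in% planted), 0L)
})

test_that("profile serialization round-trips", {
  grp <- fixture_group("TRi", n = 3L, seed = 2L)
  p <- trusted_cutoff(build_profile(substr(grp$sequence, 121, 171),
                                    pseudocount = 80,
                                    member_ids = grp$protein_id),
                      grp$sequence)
  base <- file.path(withr::local_tempdir(), "prof")
  write_profile(p, base)
  q <- read_profile(base)
  expect_equal(q$log_odds, p$log_odds, tolerance = 1e-12)
  expect_equal(q$trusted_cutoff, p$trusted_cutoff, tolerance = 1e-12)
  expect_equal(q$member_ids, p$member_ids)
  s <- grp$sequence[1]
  expect_equal(score_profile(q, s)$score_bits,
               score_profile(p, s)$score_bits, tolerance = 1e-9)
})
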