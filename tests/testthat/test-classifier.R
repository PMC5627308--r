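test_that("enrichment on a fixed-point pool converges in one run", {
  grp <- fixture_group("TR1", n = 4L, mutation_rate = 0.02, seed = 12L)
  g <- homolog_group("TR1", grp$protein_id)
  en <- enrich_group(g, grp, pseudocount = 80)
  expect_true(en$trace$converged)
  expect_length(en$trace$iterations, 1L)
  expect_setequal(en$group$member_ids, grp$protein_id)
  expect_equal(en$trace$iterations[[1]]$newly_added_ids, character(0))
})

test_that("a straddling homolog is picked up in run 2", {
  # fixture built by choosing BoxB positions so scores straddle the two
  # cutoffs; the relations are verified here by direct scoring
  P <- make_protein("TR1", 0, seed = 21)$sequence
  free <- c(156, 157, 158, 163)  # BoxB free columns 5, 6, 7, 12
  A <- poke(P, free, c("A", "A", "A", "A"))
  B <- poke(P, free, c("G", "G", "G", "G"))
  D <- poke(poke(P, free, c("A", "A", "A", "A")), 250, "W")
  C <- poke(P, free, c("A", "A", "A", "T"))
  pool <- protein_set(c("A", "B", "C", "D"), c(A, B, C, D))

  mkprof <- function(ids) {
    mem <- pool[match(ids, pool$protein_id), ]
    class(mem) <- c("protein_set", "data.frame")
    bx <- extract_boxes(star_align(mem, ids[1]))$boxes$boxB
    trusted_cutoff(build_profile(bx, pseudocount = 80, member_ids = ids),
                   mem$sequence)
  }
  p1 <- mkprof(c("A", "B"))
  p2 <- mkprof(c("A", "B", "D"))
  expect_lt(score_profile(p1, C)$score_bits, p1$trusted_cutoff)
  expect_gte(score_profile(p1, D)$score_bits, p1$trusted_cutoff)
  expect_gte(score_profile(p2, C)$score_bits, p2$trusted_cutoff)

  en <- enrich_group(homolog_group("TR1", c("A", "B")), pool,
                     pseudocount = 80)
  runs <- en$trace$iterations
  expect_equal(runs[[1]]$newly_added_ids, "D")
  expect_equal(runs[[2]]$newly_added_ids, "C")
  expect_true(en$trace$converged)
  counts <- vapply(runs, `[[`, 0, "member_count")
  expect_true(all(diff(counts) >= 0))
})

test_that("enrichment never removes members and keeps the seeds", {
  with_seed(61, {
    for (rep in 1:10) {
      lab <- sample(c("TRi", "TR1", "TR3"), 1)
      grp <- fixture_group(lab, n = sample(3:6, 1),
                           mutation_rate = 0.03, seed = 100L + rep)
      extra <- fixture_group(lab, n = 3L, mutation_rate = 0.1,
                             seed = 200L + rep)
      extra$protein_id <- paste0("x_", extra$protein_id)
      pool <- rbind(grp, extra)
      class(pool) <- c("protein_set", "data.frame")
      g0 <- homolog_group(lab, grp$protein_id, grp$protein_id[1])
      en <- enrich_group(g0, pool, pseudocount = 80)
      expect_true(all(grp$protein_id %in% en$group$member_ids))
      counts <- vapply(en$trace$iterations, `[[`, 0, "member_count")
      expect_true(all(diff(counts) >= 0))
    }
  })
})

test_that("TR1/FdR split follows the strict two-cysteine rule", {
  grp <- rbind(fixture_group("TR1", n = 10L, seed = 31L),
               local({
                 f <- fixture_group("FdR", n = 4L, seed = 31L)
                 f$protein_id <- paste0("f_", f$protein_id)
                 f
               }))
  class(grp) <- c("protein_set", "data.frame")
  g <- homolog_group("TR1", grp$protein_id)
  bx <- extract_boxes(star_align(grp, grp$protein_id[1]))
  sp <- split_tr1_fdr(g, bx)
  expect_setequal(sp$TR1$member_ids, grp$protein_id[1:10])
  expect_setequal(sp$FdR$member_ids, grp$protein_id[11:14])
  expect_equal(length(sp$TR1$member_ids) + length(sp$FdR$member_ids),
               length(g$member_ids))

  # a single remaining cysteine is not enough for TR1
  one <- bx
  one$boxes$boxA[1] <- poke(one$boxes$boxA[1], 10L, "S")
  sp1 <- split_tr1_fdr(g, one)
  expect_true(grp$protein_id[1] %in% sp1$FdR$member_ids)

  empty <- split_tr1_fdr(homolog_group("TR1", character(0)), bx)
  expect_length(empty$TR1$member_ids, 0L)
  expect_length(empty$FdR$member_ids, 0L)
})

test_that("Trx3 partner detection by local-alignment E-value", {
  trx3 <- make_trx3(0)$sequence
  lin <- c(phylum = "F", class = "Clostridia", order = "O", family = "Fa",
           genus = "G")
  with_partner <- genome_record("g1", lin, protein_set(
    c("t1", "b1"), c(make_trx3(0.02, seed = 3)$sequence,
                     paste(with_seed(5, sample(AA_ALPHABET, 300, TRUE)),
                           collapse = ""))))
  expect_true(detect_trx3_partner(with_partner, trx3))

  with_seed(71, {
    for (rep in 1:5) {
      bg <- vapply(1:6, function(i)
        paste(sample(AA_ALPHABET, sample(250:350, 1), TRUE), collapse = ""), "")
      g <- genome_record(paste0("bg", rep), lin,
                         protein_set(paste0("p", 1:6), bg))
      expect_false(detect_trx3_partner(g, trx3, 1e-10))
      expect_true(detect_trx3_partner(g, trx3, 1e12))
    }
  })
  expect_error(detect_trx3_partner(with_partner, trx3, -1), "positive")
})

test_that("TR3/dcTR1 split tracks planted Trx3 presence exactly", {
  for (f in c(0, 1)) {
    ds <- make_dataset(9L, mutation_rate = 0.02, seed = 5L, frac_trx3 = f)
    planted <- ds$truth[ds$truth$label %in% c("TR3", "dcTR1"), ]
    g <- homolog_group("TR3", planted$protein_id)
    sp <- split_tr3_dctr1(g, ds$genomes, ds$trx3_seed$sequence)
    expect_setequal(sp$TR3$member_ids,
                    planted$protein_id[planted$label == "TR3"])
    expect_setequal(sp$dcTR1$member_ids,
                    planted$protein_id[planted$label == "dcTR1"])
  }
})

test_that("census config validates keys and ranges", {
  expect_error(census_config(bogus_key = 1), "bogus_key")
  expect_error(census_config(psn_threshold = 2), "psn_threshold")
  expect_error(census_config(pseudocount = 0), "pseudocount")
  cfg <- census_config(max_runs = 3L)
  expect_equal(cfg$max_runs, 3L)
})

test_that("run_census is deterministic and robust to absent families", {
  ds <- make_dataset(6L, mutation_rate = 0.02, seed = 29L)
  c1 <- suppressMessages(run_census(ds$genomes, ds$seeds,
                                    ds$trx3_seed$sequence))
  c2 <- suppressMessages(run_census(ds$genomes, ds$seeds,
                                    ds$trx3_seed$sequence))
  expect_identical(c1$report, c2$report)
  expect_identical(c1$consensus, c2$consensus)

  ds_no3 <- make_dataset(6L, c(TR1 = 1L, TRi = 1L), mutation_rate = 0.02,
                         seed = 29L)
  cen <- suppressMessages(run_census(ds_no3$genomes, ds_no3$seeds,
                                     ds_no3$trx3_seed$sequence))
  got <- cen$report$assigned_label[cen$report$assigned_label != "unassigned"]
  expect_false(any(got %in% c("TR3", "dcTR1")))
})
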