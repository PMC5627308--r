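# End-to-end orchestration: simulate -> census -> logos -> trees ->
# incongruence, with a single seed fanned out to stage-specific child seeds
# and a JSON summary of everything the run produced.

#' Pipeline configuration with validated defaults
#'
#' @param ... overrides for: `outdir` (required for [run_pipeline()]),
#'   `seed` (1), `n_genomes` (20), `composition`
#'   (`c(TRi = 1, TR1 = 1, TR3 = 1)`), `frac_trx3` (0.5), `n_background` (4),
#'   `mutation_rate` (0.02), `n_hgt` (0), `genome_table` (optional path: use
#'   an on-disk dataset instead of simulating), `seeds_fasta`, `seeds_tsv`,
#'   `trx3_fasta`, `reference_newick` (optional paths), `bootstrap` (0),
#'   plus every [census_config()] key.
#' @return named list of class `pipeline_config`.
#' @export
pipeline_config <- function(...) {
  cfg <- list(outdir = NULL, seed = 1L, n_genomes = 20L,
              composition = c(TRi = 1L, TR1 = 1L, TR3 = 1L),
              frac_trx3 = 0.5, n_background = 4L, mutation_rate = 0.02,
              n_hgt = 0L, genome_table = NULL, seeds_fasta = NULL,
              seeds_tsv = NULL, trx3_fasta = NULL, reference_newick = NULL,
              bootstrap = 0L,
              psn_threshold = 0.35, pseudocount = 80, evalue_max = 1e-10,
              max_runs = 10L, info_threshold_bits = 2, majority_fraction = 0.7,
              min_clade_size = 3L)
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown)) stop_format("unknown config key(s): %s",
                                   paste(unknown, collapse = ", "))
  cfg[names(dots)] <- dots
  if (cfg$mutation_rate < 0 || cfg$mutation_rate > 1)
    stop_format("mutation_rate must be in [0, 1]")
  structure(cfg, class = "pipeline_config")
}

#' Run the whole pipeline
#'
#' Simulates (or loads) the genomes, runs the census, writes logos, builds
#' per-family NJ trees rooted on the outgroup class, compares them with the
#' reference taxonomy tree, and flags duplication and HGT candidates.  All
#' outputs land under `config$outdir`; the JSON summary is returned
#' invisibly and written as `summary.json`.  Deterministic given the config.
#'
#' @param config a [pipeline_config()] with `outdir` set.
#' @return the summary list, invisibly.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  if (is.null(config$outdir)) stop_format("config$outdir is required")
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)

  if (is.null(config$genome_table)) {
    dataset <- make_dataset(n_genomes = config$n_genomes,
                            per_genome_composition = config$composition,
                            frac_trx3 = config$frac_trx3,
                            n_background = config$n_background,
                            mutation_rate = config$mutation_rate,
                            seed = derive_seed(config$seed, "simulate"),
                            n_hgt = config$n_hgt)
    write_dataset(dataset, file.path(config$outdir, "data"))
    genomes <- dataset$genomes
    seeds <- dataset$seeds
    trx3 <- dataset$trx3_seed$sequence
    reference <- dataset$reference_tree
    truth <- dataset$truth
  } else {
    genomes <- read_genome_table(config$genome_table)
    seeds <- read_seed_set(config$seeds_fasta, config$seeds_tsv)
    trx3 <- if (!is.null(config$trx3_fasta))
      read_fasta(config$trx3_fasta)$sequence[1L] else NULL
    reference <- if (!is.null(config$reference_newick))
      read_newick(config$reference_newick) else NULL
    truth <- NULL
  }

  ccfg <- census_config(psn_threshold = config$psn_threshold,
                        pseudocount = config$pseudocount,
                        evalue_max = config$evalue_max,
                        max_runs = config$max_runs,
                        info_threshold_bits = config$info_threshold_bits,
                        majority_fraction = config$majority_fraction,
                        min_clade_size = config$min_clade_size,
                        seed = config$seed)
  census <- run_census(genomes, seeds, trx3, ccfg)
  write_report(census, config$outdir)

  for (fam in names(census$boxes)) {
    bb <- census$boxes[[fam]]$boxes
    bb <- bb[!is.na(bb$boxA), , drop = FALSE]
    if (nrow(bb)) {
      write_logo(make_logo(bb$boxA),
                 file.path(config$outdir, sprintf("logo_%s_boxA.tsv", fam)))
      write_logo(make_logo(bb$boxB),
                 file.path(config$outdir, sprintf("logo_%s_boxB.tsv", fam)))
    }
  }

  org_class <- setNames(vapply(genomes, function(g) g$lineage[["class"]], ""),
                        vapply(genomes, `[[`, "", "organism_id"))
  prot_org <- setNames(census$report$organism_id, census$report$protein_id)
  trees <- list(); rf <- list(); hgt <- list(); dup <- list()
  for (fam in intersect(c("TRi", "TR1", "TR3", "dcTR1"),
                        unique(census$report$assigned_label))) {
    ids <- census$report$protein_id[census$report$assigned_label == fam]
    if (length(ids) < 4L) next
    g <- census$groups[[if (fam == "dcTR1") "TR3" else fam]]
    anchor <- sort(g$seed_ids)[1L]
    pool <- rbind(all_proteins(genomes),
                  protein_set(seeds$protein_id, seeds$sequence,
                              organism_id = "seed"))
    mem <- pool[match(ids, pool$protein_id), , drop = FALSE]
    anchor_seq <- pool$sequence[match(anchor, pool$protein_id)]
    msa <- star_align(mem, anchor, anchor_seq = anchor_seq)
    sel <- select_blocks(msa)
    if (length(sel$kept_columns) < 10L) next
    tree <- if (config$bootstrap > 0L)
      nj_bootstrap(msa, sel$kept_columns, config$bootstrap, config$seed)
    else nj_tree(dist_matrix(msa, sel$kept_columns))
    classes <- setNames(unname(org_class[prot_org[tree$tip.label]]),
                        tree$tip.label)
    out_tips <- tree$tip.label[!is.na(classes) &
                                 classes == "Actinobacteria"]
    rooted <- tree
    if (length(out_tips) && length(out_tips) < length(tree$tip.label)) {
      rooted <- tryCatch(root_with_outgroup(tree, out_tips),
                         error = function(e) tree)
    }
    trees[[fam]] <- rooted
    write_newick(rooted, file.path(config$outdir,
                                   sprintf("tree_%s.nwk", fam)))
    if (!is.null(reference))
      rf[[fam]] <- compare_to_reference(rooted, reference, prot_org)
    ok <- !is.na(classes)
    if (all(ok))
      hgt[[fam]] <- flag_incongruent_leaves(rooted, classes,
                                            config$min_clade_size)
    dup[[fam]] <- detect_duplications(rooted, prot_org[rooted$tip.label])
  }

  summary <- list(
    schema_version = "1",
    seed = config$seed,
    label_counts = as.list(table(census$report$assigned_label)),
    consensus_motifs = census$consensus,
    enrichment = lapply(census$traces, function(tr) list(
      converged = tr$converged,
      member_counts = vapply(tr$iterations, `[[`, 0, "member_count"))),
    rf_to_reference = rf,
    hgt_flags = lapply(hgt, function(h) h$leaf),
    duplications = lapply(dup, function(d) d$organism))
  if (!is.null(truth)) {
    pred <- census$report$assigned_label
    names(pred) <- census$report$protein_id
    tl <- truth$label
    tl[tl %in% c("background", "Trx3")] <- "unassigned"
    cm <- table(truth = tl, predicted = pred[truth$protein_id])
    summary$confusion <- as.data.frame(cm)
    summary$accuracy <- mean(tl == pred[truth$protein_id])
  }
  jsonlite::write_json(summary, file.path(config$outdir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       na = "null")
  invisible(summary)
}

#' Command-line entry point
#'
#' Subcommands: `simulate`, `census`, `report` (run the full pipeline).
#' Exit codes: 0 ok, 2 validation error, 3 stage failure.  Installed as
#' `inst/cli/trcensus`.
#'
#' @param args character vector of command-line arguments.
#' @return integer exit code, invisibly.
#' @export
cli_main <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- paste(
    "usage: trcensus <simulate|census|report> [--out-dir DIR] [--seed N]",
    "  [--n-genomes N] [--mutation-rate X] [--frac-trx3 X] [--n-hgt N]",
    "  [--genomes-table TSV --seeds-fasta FAA --seeds-tsv TSV [--trx3-fasta FAA]]",
    sep = "\n")
  if (!length(args)) { message(usage); return(invisible(2L)) }
  cmd <- args[1L]
  opts <- list()
  rest <- args[-1L]
  i <- 1L
  while (i <= length(rest)) {
    key <- sub("^--", "", rest[i])
    if (!startsWith(rest[i], "--") || i == length(rest)) {
      message("bad argument: ", rest[i]); return(invisible(2L))
    }
    opts[[gsub("-", "_", key)]] <- rest[i + 1L]
    i <- i + 2L
  }
  num <- function(x, d) if (is.null(x)) d else as.numeric(x)
  res <- tryCatch({
    if (cmd == "simulate") {
      ds <- make_dataset(n_genomes = as.integer(num(opts$n_genomes, 20)),
                         mutation_rate = num(opts$mutation_rate, 0.02),
                         frac_trx3 = num(opts$frac_trx3, 0.5),
                         seed = as.integer(num(opts$seed, 1)),
                         n_hgt = as.integer(num(opts$n_hgt, 0)))
      write_dataset(ds, opts$out_dir %||% "trcensus_out")
      0L
    } else if (cmd %in% c("census", "report")) {
      cfg <- if (!is.null(opts$genomes_table))
        pipeline_config(outdir = opts$out_dir %||% "trcensus_out",
                        seed = as.integer(num(opts$seed, 1)),
                        genome_table = opts$genomes_table,
                        seeds_fasta = opts$seeds_fasta,
                        seeds_tsv = opts$seeds_tsv,
                        trx3_fasta = opts$trx3_fasta,
                        reference_newick = opts$reference_newick)
      else
        pipeline_config(outdir = opts$out_dir %||% "trcensus_out",
                        seed = as.integer(num(opts$seed, 1)),
                        n_genomes = as.integer(num(opts$n_genomes, 20)),
                        mutation_rate = num(opts$mutation_rate, 0.02),
                        frac_trx3 = num(opts$frac_trx3, 0.5),
                        n_hgt = as.integer(num(opts$n_hgt, 0)))
      run_pipeline(cfg)
      0L
    } else {
      message(usage)
      2L
    }
  }, error = function(e) { message("stage failure: ", conditionMessage(e)); 3L })
  invisible(res)
}
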