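# shared fixture builders; everything is generated in code at test time

# a small group of one family; the first member is always noise-free so it
# can serve as the alignment anchor (the role seeds play in the census)
fixture_group <- function(label = "TR1", n = 5L, mutation_rate = 0,
                          seed = 1L) {
  prots <- with_seed(derive_seed(seed, paste0("grp-", label)), {
    lapply(seq_len(n), function(i)
      make_protein(label, if (i == 1L) 0 else mutation_rate))
  })
  protein_set(sprintf("%s_m%02d", label, seq_len(n)),
              vapply(prots, `[[`, "", "sequence"))
}

planted_boxes <- function(label = "TR1", n = 5L, mutation_rate = 0,
                          seed = 1L) {
  prots <- with_seed(derive_seed(seed, paste0("grp-", label)), {
    lapply(seq_len(n), function(i) make_protein(label, mutation_rate))
  })
  data.frame(member_id = sprintf("%s_m%02d", label, seq_len(n)),
             boxA = vapply(prots, `[[`, "", "boxA"),
             boxB = vapply(prots, `[[`, "", "boxB"),
             stringsAsFactors = FALSE)
}

# replace single positions of a sequence string
poke <- function(seq, pos, residues) {
  s <- strsplit(seq, "")[[1]]
  s[pos] <- residues
  paste(s, collapse = "")
}

# brute-force best ungapped window score, the enumeration oracle for
# score_profile (independent: direct sums, no shared code path)
oracle_best_window <- function(profile, sequence) {
  chars <- strsplit(sequence, "")[[1]]
  w <- profile$width
  lo <- cbind(profile$log_odds, X = 0)
  best <- -Inf; at <- NA_integer_
  for (s in seq_len(length(chars) - w + 1L)) {
    tot <- 0
    for (j in seq_len(w)) tot <- tot + unname(lo[j, chars[s + j - 1L]])
    if (tot > best + 1e-12) { best <- tot; at <- s }
  }
  list(score_bits = best, start = at)
}

# brute-force global alignment oracle for pairwise identity: enumerate all
# alignments recursively, maximizing (score, matches, -length)
oracle_identity <- function(a, b) {
  A <- strsplit(a, "")[[1]]; B <- strsplit(b, "")[[1]]
  rec <- function(i, j) {
    if (i > length(A) && j > length(B)) return(c(s = 0, m = 0, l = 0))
    cand <- list()
    if (i <= length(A) && j <= length(B)) {
      r <- rec(i + 1L, j + 1L)
      mt <- as.integer(A[i] == B[j] && A[i] != "X")
      cand[[length(cand) + 1L]] <- c(r["s"] + mt, r["m"] + mt, r["l"] + 1)
    }
    if (i <= length(A)) {
      r <- rec(i + 1L, j)
      cand[[length(cand) + 1L]] <- c(r["s"] - 1, r["m"], r["l"] + 1)
    }
    if (j <= length(B)) {
      r <- rec(i, j + 1L)
      cand[[length(cand) + 1L]] <- c(r["s"] - 1, r["m"], r["l"] + 1)
    }
    key <- vapply(cand, function(x) x[1] * 1e6 + x[2] * 1e3 - x[3], 0)
    cand[[which.max(key)]]
  }
  r <- rec(1L, 1L)
  unname(r[2] / r[3])
}

# transitive-closure components oracle over an edge list
oracle_components <- function(nodes, edges) {
  comp <- setNames(seq_along(nodes), nodes)
  repeat {
    changed <- FALSE
    for (k in seq_len(nrow(edges))) {
      a <- edges$id_a[k]; b <- edges$id_b[k]
      if (comp[a] != comp[b]) {
        comp[comp == comp[b]] <- comp[a]
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  split(names(comp), comp)
}

# random additive tree and its exact leaf distance matrix
random_additive <- function(n, seed) {
  with_seed(seed, {
    tr <- ape::rtree(n, br = function(k) runif(k, 0.1, 1))
    tr$tip.label <- paste0("t", seq_len(n))
    list(tree = tr, d = ape::cophenetic.phylo(tr))
  })
}
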