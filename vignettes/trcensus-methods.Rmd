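---
title: "Methods: a desk-scale census of thioredoxin-reductase subfamilies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a desk-scale census of thioredoxin-reductase subfamilies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

Prokaryotic low-molecular-weight thioredoxin reductases (TRs) all carry one
pyridine nucleotide-disulfide oxidoreductase (PNDO) domain, yet they split
into functionally distinct subfamilies: the canonical NADPH-dependent TR1,
an NAD(P)H-independent isolated TR (TRi), a TR3 that works with a
non-canonical thioredoxin (Trx3), degenerated clostridial TR1-like proteins
(dcTR1) in genomes lacking that partner, and ferredoxin/flavodoxin
reductases (FdR) that resemble TR1 but lack the redox-active cysteines.
The discriminating information is concentrated in a contiguous ~51-residue
stretch of the active-site/NAD(P)H-binding region, which this package
handles as two adjacent fixed-width sub-regions: **BoxA** (31 columns:
Trx-binding G[R/K]G, VSY, the CxxC active site, a Trx-binding aromatic
position, and the GGGxxAxE pyrophosphate-binding motif) and **BoxB** (20
columns around the 2'-phosphate-binding motif: VxxxHRRDx[F/L]R in TR1/FdR,
VxxxTQGKxxSI in TRi, and a TQ/NGK-bearing variant in TR3/dcTR1).

`trcensus` implements the census as a chain of small, testable operations:
profile search with a trusted cutoff, similarity-network grouping,
box extraction, iterative enrichment, rule-based splits, sequence logos,
and distance-based phylogenetics with incongruence flags.

## Profile model and the trusted cutoff

A profile is a fixed-width position-specific scoring matrix in bits.
Column frequencies use a background-proportional pseudocount:

$$f_{ja} = \frac{c_{ja} + \alpha\, b_a}{n_j + \alpha}, \qquad
  s_{ja} = \log_2 \frac{f_{ja}}{b_a},$$

with uniform background $b_a = 1/20$.  Gaps and X are excluded from the
counts; X scores 0 at query time; an all-gap column is uninformative by
construction.  Scoring is an ungapped sliding window (best window wins,
ties to the smallest offset).  This deliberately replaces a profile HMM:
the modelled regions are fixed-width, so insert/delete states add nothing,
and the single-best-window bit score stands in for the HMM bit score.

The **trusted cutoff** of a profile is the minimal best-window score of the
sequences the profile was built from — the lowest-scoring known true
positive.  Every member re-passes its own profile by construction.

### Why the pipeline default pseudocount is large

`build_profile()` defaults to $\alpha = 1$, which is the right primitive
default (it merely prevents $-\infty$ log-odds).  The *census* default is
$\alpha = 80$ (i.e. four pseudo-observations per residue).  The reason is
the small-$n$ regime of the seed stage: with 5–6 members, a lightly
smoothed profile memorizes each member's idiosyncratic residues at the
degenerate template positions, so the members score systematically higher
than genuinely homologous queries and the min-member cutoff rejects true
positives.  On the synthetic benchmark, zero-noise recovery of planted
proteins is 11–51% at $\alpha \in \{1, 2\}$ and 100% at $\alpha = 80$,
while background specificity is untouched (the best background window
scores ~8 bits against a cutoff of ~29; no false positives among >500
background proteins).  Census accuracy is flat (0.994–0.996) for
$\alpha \in \{40, 60, 80\}$; recall at mutation rate 0.05 rises
0.935 → 0.980 across that range, which fixed the default at 80.

## Similarity network and seed groups

Pairwise similarity is global-alignment identity (match +1, mismatch 0,
linear gap −1; identity = matches / alignment length), computed by a small
C++ Needleman–Wunsch kernel with a deterministic tie-break (maximal score,
then maximal matches, then shortest alignment).  Edges at or above the
threshold (default 0.35) define the network; connected components holding
seeds become family groups.  When one component holds seeds of several
families — common at 0.35, since all TR subfamilies descend from one
scaffold — each non-seed member goes to its highest-similarity seed, with
ties resolved to the lexicographically smallest label and logged.  The
construction details of the original similarity network are not public;
the metric and threshold here are explicit, config-exposed stand-ins.

## Box extraction

Groups are star-aligned around their anchor seed (BLOSUM62, gap open 10 /
extend 1, "once a gap, always a gap" merge on the seed's coordinates).
Box columns are the alignment columns carrying the seed's template
positions, located from the seed's first `C..C` match (BoxA column 1 is six
residues upstream of that cysteine; BoxB starts right after BoxA column
31).  Because member insertions relative to the seed are skipped, every
member's BoxA/BoxB strings are exactly 31/20 characters, possibly gapped.

## Iterative enrichment and the split rules

Per family, the loop rebuilds the member alignment (always re-anchored on
the original seed, keeping coordinates stable), extracts BoxB, builds a
profile, sets the trusted cutoff from the current members, rescans the
PNDO pool, and adds everything at or above the cutoff.  Membership is
non-decreasing in a finite universe, so termination is guaranteed;
convergence is declared when a run adds nothing (max 10 runs).  A protein
claimed by several families goes to the family with the largest margin
(score − cutoff), logged.

Splits: a TR1-group member is TR1 only with **both** cysteines at BoxA
columns 7 and 10 (a single cysteine goes to FdR — the one-cysteine case is
not discussed in the source analysis, so the strict reading is used and
recorded in the rule trace).  A TR3-group member is TR3 iff its genome
contains a Trx3 partner: Smith–Waterman against the Trx3 seed (BLOSUM62,
open 11 / extend 1) converted to an E-value with the gapped
Karlin–Altschul defaults $\lambda = 0.267$, $K = 0.041$, $m$ = seed
length, $n$ = summed genome protein length, threshold $10^{-10}$.

## Logos and consensus motifs

Per column of a box, frequencies are over non-gap letters and the
information content is $R_j = \log_2 20 + \sum_a f_{ja} \log_2 f_{ja}$
bits, without small-sample correction (group sizes here make the
correction negligible relative to the 2-bit consensus threshold).
Consensus: a letter needs $R_j \ge 2$ bits and a 0.7 majority; two letters
jointly reaching 0.7 give a bracketed pair; everything else is `x`.

## Phylogenetics

Block selection honors exactly the three modified parameters: a column is
kept when its most frequent non-gap residue occurs in strictly more than
50% of sequences, gap-containing columns are eligible, and only maximal
runs of length ≥ 2 survive.  The original tool's two-tier
conserved/highly-conserved thresholds are collapsed into the single >50%
rule — a documented simplification.  Distances are Poisson-corrected
mismatch fractions over mutually non-gap kept columns,
$d = -\ln(1 - p)$, capped at $p = 0.95$ with a warning.  Trees are
Saitou–Nei neighbor joining (deterministic lexicographic tie-break;
negative branch lengths clamped to 0 with the deficit moved to the sister
branch), exact on additive matrices.  Bayesian inference and
substitution-model selection are out of scope by design; NJ with optional
column-resampling bootstrap is the desk-scale replacement, and bootstrap
percentages are not claimed to match posterior probabilities.

Rooting uses the outgroup approach (root at the midpoint of the edge
separating a verified-monophyletic outgroup).  A leaf is an **HGT
candidate** when the *other* leaves of its smallest enclosing clade of at
least `min_clade_size` leaves have a strict majority class different from
its own; organisms contributing two or more leaves to a tree are
**duplication candidates**.  Gene trees are compared to the reference
taxonomy tree by Robinson–Foulds distance over single-copy organisms.

## The synthetic world

`make_dataset()` plants proteins built from per-family token templates on
one fixed 300-residue scaffold: FAD motifs (GxGxxG, ATG, GxFAAGD) at fixed
offsets, BoxA at positions 121–151, BoxB at 152–172 (adjacent, because the
source region is one contiguous stretch split into two sub-regions), free
positions (`x`) drawn uniformly from the 20-letter alphabet per protein,
bracketed alternatives resolved per protein, and per-position mutation at
the requested rate.  The scaffold contains no cysteine, so the first
`C..C` match is always the planted active site.  Total length ~300
residues matches the seed proteins the census is modelled on; the spacing
of the FAD motifs is a documented free choice.

Taxonomy: organisms rotate through Deltaproteobacteria-like and
Clostridia-like ingroup classes plus an Actinobacteria-like outgroup.
Class divergence uses *disjoint* marker positions per class (6, 6 and 12
substitutions in linkers/tails): at each marker column two thirds of the
rows keep the scaffold residue, so the column survives the strict >50%
block-selection rule and the class signal reaches the trees; the outgroup
carries twice as many markers and therefore branches off first.  A planted
transfer (`n_hgt`) is a TR1 gene with Deltaproteobacteria markers inside a
Clostridia genome.

The seed set has six members: canonical TRi/TR1/TR3 templates,
Clostridia-marked TRi and TR3 variants, and a divergent TR1 whose scaffold
differs at 42 positions (12 of them in non-motif BoxA columns).  The two
divergent seeds play the role divergent true positives play in a real
trusted-cutoff search — they anchor the cutoff below the family cores —
mirroring the fact that the census this emulates used distant,
experimentally validated TRs as seeds.

What a green test does **not** establish: the generator has no indels, no
genome-specific composition, iid mutations, and family templates derived
from one scaffold, so within-family "free" positions are uncorrelated —
real homologs share ancestry at those positions.  Parameter-recovery
results therefore validate the machinery, not census counts on real
genomes; reproducing the published counts against a historical genome
snapshot is explicitly out of scope.

## Numerical choices and degenerate inputs

Bits (log2) everywhere; ties in window scoring go to the smallest offset;
ties in NJ to the lexicographically smallest leaf-pair; mixed-component
similarity ties to the smallest family label.  Sequences shorter than a
profile's width are skipped in scans and rejected in direct scoring.
Non-standard residues are coerced to X (warning), never dropped.  Newick
names are sanitized (`();:, ` → `_`); unbalanced parentheses are reported
with their position.  Empty groups, empty hit lists and datasets without a
family are legal and propagate as empty results, not errors.

## Known limitations

- The single-best-window score ignores secondary occurrences of the
  region; fine here (one PNDO domain per protein by construction).
- The Karlin–Altschul parameters are fixed BLOSUM62 gapped defaults, not
  estimated per search; only the E-value threshold is calibrated data.
- The 0.35 identity threshold merges all TR subfamilies into one
  similarity component; classification then rests on the nearest-seed rule
  and the BoxB profiles, which is the intended behavior at desk scale.
- HGT flags on very small trees (fewer than ~6 leaves) are noisy because a
  cherry majority is a weak signal; the flags are candidates, not calls.
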