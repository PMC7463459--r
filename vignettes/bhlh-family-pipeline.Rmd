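---
title: "Methods: genome-wide bHLH family characterization with bhlhscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: genome-wide bHLH family characterization with bhlhscan}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bhlhscan)
```

## Scope and model

`bhlhscan` implements the standard analysis battery of a plant transcription
factor family survey for the basic helix-loop-helix (bHLH) family, organized
as independent, composable stages plus seeded generators that synthesize
every input with recorded ground truth.

The domain model is a fixed 55-column block: a 17-residue basic region,
two 15-residue helices, and an 8-column loop (55 − 17 − 15 − 15; the loop
length is the remainder, as family surveys leave it implicit).  All
positional rules are 1-based within the region they name, e.g. "position 13
of the basic region" is domain column 13.

### Domain detection

`build_profile()` turns a gapless 55-column seed alignment into a
position-specific scoring matrix with log-odds weights

\[ w_{a,j} = \log_2 \frac{(c_{a,j} + \lambda p_a)/(n + \lambda)}{p_a} \]

with pseudocount \(\lambda\) (default 1) and background \(p_a\) (default
uniform 1/20).  `scan_domain()` scores every ungapped 55-residue window;
windows running past the C-terminus are padded with `-`, a gap scoring the
column minimum.  The detection threshold is not hard-coded: it is the 99.9th
percentile of best-window scores over i.i.d. random proteins
(`calibrate_threshold()`), so a random 500-residue protein is accepted well
under 1% of the time.  The packaged seed alignment is synthetic (the file
name says so): ten 55-mers built around the residues that family surveys
report as conserved (Arg-16, Leu-27, Asp-40, Leu-55 and companions).  It
stands in for a curated domain model and is sufficient because every
analysis here is relative to the profile, not to an external database.

### DNA-binding classification

`classify_binding()` applies the published residue rules literally, in this
order:

1. fewer than 6 residues from {R, K, H} in the 17-column basic region →
   non-DNA-binding;
2. otherwise Glu at position 13 and Arg at position 16 → E-box binder,
   refined to G-box iff position 9 is His/Lys **and position 17** is Arg;
3. otherwise non-E-box binder.

The E-box rule reads position 16 while the G-box refinement reads position
17.  That asymmetry is in the source rules; we apply both as printed rather
than "correcting" either, and a gap at a rule position fails that test.  The
basic-residue set and the cutoff are configuration-exposed because the
source does not pin the set ({R,K} vs {R,K,H}); {R,K,H} is the standard
definition of the basic amino acids and is the default.

### Physical properties

Molecular weight is the sum of Expasy average residue masses plus one water;
`X` contributes the mean residue mass.  The isoelectric point solves the
Henderson–Hasselbalch net-charge equation by bisection on pH ∈ (0, 14) to
|charge| < 1e-4, over the N/C termini and D, E, C, Y, H, K, R with Expasy
pKa constants.  Agreement with other pI implementations is expected to
within a few tenths of a pH unit, not bit-exact, because published pKa sets
differ; the test suite cross-checks against `seqinr::computePI` at a 0.75
tolerance.

### Phylogeny and clades

Distances are p-distances (mismatches over compared columns, pairwise gap
deletion) on the 55-column domain alignment — not on a full-length
progressive MSA.  The domain carries the clade signal, and this keeps the
stage self-contained; tree topologies therefore need not match a
full-length ClustalW/MEGA run, which is explicitly not a goal.  The
neighbor-joining implementation is the Saitou–Nei Q-criterion agglomeration
with two deterministic choices: ties on Q break to the smallest (i, j) pair
in current label order, and negative branch lengths are clamped to zero with
a log line.  On distances that are exactly additive, the implementation
provably reconstructs the generating topology and branch lengths; the test
suite verifies this on 50 random trees to 1e-9 and cross-checks topologies
against `ape::nj`.  Bootstrap support resamples alignment columns with
replacement and counts bipartitions of the full-data tree across replicate
trees (via `ape::boot.phylo`); with tied distances the deterministic
tie-break makes replicate topologies depend on input label order, so
supports are reproducible for a fixed seed and input order but are not
guaranteed invariant under permutation.

Clade assignment is nearest-labelled-reference by p-distance rather than
tree traversal: it is deterministic, testable, and the tree remains
available separately.

### Gene structure

`infer_structure()` decomposes a CDS into exact genomic substrings separated
by gaps of at least 20 nt (`min_intron`; shorter gaps are treated as
alignment artifacts — the shortest plausible plant interval is well above
this, and observed minima in family surveys are ~44 bp).  Search order:
fewest introns first; at equal counts, decompositions whose introns all
start `GT` and end `AG` are preferred; remaining ties resolve to leftmost
exon starts with longest exons tried first.  Matching is exact — CDS and
genomic sequence derive from the same assembly, so mismatch tolerance is out
of scope.  Exon start candidates are anchored on exact 8-mer seeds through a
rolling-hash index, which means internal exons shorter than 8 nt are not
discoverable; the generator's exon minimum (30 nt) is far above that, and
real internal coding exons below 8 nt are vanishingly rare.

### Promoters and cis-elements

Promoters are the 2000 bp upstream of the TSS, reported 5'→3' on the coding
strand and flagged when truncated by a contig edge.  Motifs are IUPAC
consensi matched exactly; all overlapping occurrences count (totals like
"201 ABRE" imply occurrence counting), both strands are scanned with minus
hits reported at their forward-coordinate start, and a palindromic pattern
is scanned once so each site is counted once.  An ambiguous base in the
promoter (e.g. N) matches nothing, so masked regions cannot inflate counts.
The packaged dictionary covers the consensi that are stable across
references (G-box `CACGTG`, ABRE `ACGTG`, CGTCA/TGACG, ERE `ATTTCAAA`, MBS
`CAACTG`, LTR `CCGAAA`, ARE `AAACCA`, CAT-box `GCCACT`); elements whose
exact definition is scanner-internal (TC-rich repeats, WUN-motif, O2-site)
are deliberately left to the user, because reproducing a web service's
counts requires its unpublished patterns.

### Expression and qPCR

FPKM tiers use half-open bins [0,2), [2,10), [10,50), [50,∞): "below 2"
is not expressed (the only threshold the source pins), 10 separates low from
moderate (from the "5 < FPKM < 10 is low" usage) and 50 separates moderate
from abundant (inferred from values ≥ 60 being called abundant and ~40
moderate); all three are configuration-exposed.  Heatmap grouping clusters
log2(FPKM + 0.01) rows agglomeratively (average linkage, Euclidean) and cuts
at k = 5 by default, matching the five-group presentation of such surveys;
recovering any particular published gene-to-group mapping is not a contract,
since those groupings typically mix clustering with manual curation.

qPCR analysis averages technical replicates, forms ΔCT = CT(target) −
CT(reference) per biological replicate, ΔΔCT against the baseline sample
(default: the 0 h control, following the convention that the 0 h level is
the calibrator), and reports fold = 2^−ΔΔCT.  Significance is a two-sided
pooled-variance Student's t-test on replicate ΔCT values (the source names
Student's test with equal n = 3; Welch is available by flag), starred at
0.05/0.01 on raw p values to match the usual presentation, with a
Benjamini–Hochberg column emitted alongside for transparency.  When both
groups have zero variance (noise-free synthetic data) the degenerate case is
reported as p = 1 for equal means and p = 0 otherwise.

### Interaction projection

`best_hits()` maps each query to its minimum-p-distance reference (domain
distance in place of an alignment bitscore, keeping the stage offline and
self-contained); `project_network()` lifts each reference edge (A, B) to all
query pairs mapped to A and B, deduplicated, self-edges dropped.  A
reference homodimer edge projects to the distinct query pairs sharing that
reference, and those queries are annotated as homodimer candidates rather
than given self-edges.

## The synthetic study set

The generators emulate the study conditions of a 98-member orchid bHLH
survey and record every planted feature:

* **Family** (`make_family`): 98 proteins over 18 clades.  The packaged
  clade sizes follow the family roster, except that the two singleton clades
  are generated with two members (the generator requires ≥ 2 per clade so
  that within-clade signal exists) and the two largest clades give up one
  member each to keep the total at 98.  Binding categories are planted in
  the 61/4/11/22 mix.  Clade ancestors diverge from the profile consensus at
  rate 0.25 and members from their ancestor at 0.05, both restricted to
  columns 18–55: the basic region is set from per-category templates and
  never mutated, so the planted binding category is exact by construction
  and inter-clade distance exceeds intra-clade distance.
* **Genes** (`make_gene`): exons 30–300 nt, introns 44–2000 nt (44 is the
  observed family minimum; 2000 keeps the default desk-scale), every intron
  GT..AG.
* **Promoters** (`make_promoters`): 2000 nt, i.i.d. background at GC 0.44
  (plant promoters are AT-rich), planted instances non-overlapping on random
  strands.  By default the background is re-randomized until scanning the
  library finds no match outside a planted span ("clean" background), which
  makes planted counts exactly recoverable — the property the recovery tests
  check.  With `background = "iid"` chance matches remain, at the
  analytically expected rate for i.i.d. sequence.
* **Expression** (`make_expression`): five tissue-pattern groups
  (flower-specific, sporadic-low, root-specific, broad, ubiquitous) over the
  eight surveyed tissues; tier draws are uniform inside the exact tier bins
  so zero-noise recovery is exact.
* **qPCR** (`make_qpcr`): CT = baseline − log2fc + Gaussian noise per
  technical replicate, reference gene planted at fold change 0.

What the generators do **not** emulate: indels (substitutions only), repeat
structure in promoters, library-size or length biases in FPKM, and
amplification-efficiency deviations in qPCR.  Passing recovery tests
therefore demonstrate correctness of the implementations under the stated
generative model, not robustness to those real-data effects.

## Numerical choices and degenerate inputs

* Percentages print half-up to two decimals (exact integer ratios are kept
  internally), matching the usual table style.  The derived E-box row equals
  G-box plus non-G-box E-box counts by construction.
* Profile consensus ties break alphabetically; conservation top-residue ties
  break alphabetically; scan ties break leftmost.
* Proteins with a trailing `*` stop are accepted with the stop stripped and
  a warning.  Internal coordinates are 0-based half-open everywhere;
  conversion to 1-based inclusive happens only at the GFF3 boundary.
* All stochastic operations draw from private seeded streams; the caller's
  global random state is never consulted or modified, and reruns with one
  seed are byte-identical.

## Problem sizes

The shipped tests and the acceptance script use the sizes the package treats
as its reference workload: the 98-member family, 50 additive trees of up to
10 taxa, 200 genes with 0–11 introns, 100 promoters of 2000 nt, and 100
seeded qPCR replicates of a 5-gene panel; threshold calibration uses 300
random proteins in scripted runs and up to 1000 interactively.

## Known limitations

* Ungapped domain scanning (no insert/delete states) — a profile HMM would
  detect domains interrupted by long insertions that this scanner misses.
* Clade labels are only as good as the labelled reference set; queries
  equidistant to two references resolve by reference order.
* The E-box/G-box rule asymmetry (positions 16 vs 17) is reproduced as
  published; users who believe it is an off-by-one can supply their own rule
  positions by editing the classifier call sites.
* Bootstrap supports on tie-rich alignments depend on input order (see
  above).
* `run_pipeline()` drives the synthetic study set end to end; applying the
  stages to a real proteome is done by composing the exported functions on
  user data, for which the stages were designed but which the driver does
  not automate.
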