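# bhlhscan

Genome-wide characterization of plant basic helix-loop-helix (bHLH)
transcription factor families, as a reusable and fully tested R pipeline.

Plant bHLH proteins share a ~55-residue domain — a DNA-contacting basic
region followed by two helices separated by a loop — and family surveys of a
newly sequenced genome follow a standard battery: find every protein
carrying the domain, partition and align the domain, measure per-column
conservation, predict each member's DNA-binding mode from basic-region
residues, build a neighbor-joining phylogeny with bootstrap support and
assign clades, infer exon–intron structures, scan 2-kb promoters for
cis-regulatory elements, tier tissue expression from FPKM matrices, quantify
hormone-response qPCR by 2^−ΔΔCT, and project protein–protein interactions
from a reference organism.  `bhlhscan` implements every one of those stages
for users running such a survey — and ships seeded synthetic-data
generators that produce every input with recorded ground truth, so each
stage is testable end to end.

The core statistics, in the field's notation:

* **Domain score**: for window $w$,
  $S(w) = \sum_{j=1}^{55} \log_2 \frac{(c_{w_j,j} + \lambda p_{w_j})/(n+\lambda)}{p_{w_j}}$,
  with the detection threshold calibrated as the 99.9th percentile of
  best-window scores on random proteins.
* **Binding rule** (basic region, 1-based positions): < 6 residues from
  {R,K,H} → non-binder; Glu-13 ∧ Arg-16 → E-box binder, refined to G-box iff
  position 9 ∈ {H,K} ∧ Arg-17; otherwise non-E-box binder.
* **p-distance**: mismatches / compared columns with pairwise gap deletion,
  feeding Saitou–Nei NJ with the Q-criterion and two-point branch lengths.
* **Relative expression**: ΔCT = CT(target) − CT(reference) per biological
  replicate, ΔΔCT against the 0 h baseline, fold = 2^−ΔΔCT, pooled-variance
  Student's *t* on replicate ΔCT values.

## Worked example

Generate the packaged 98-member, 18-clade synthetic family, detect and
classify every domain, and summarize the family's DNA-binding composition:

```r
library(bhlhscan)

spec <- default_family_spec()
fam  <- make_family(98, spec$clade_spec, mutation_rate = 0.05, seed = 42,
                    categories = spec$categories)

profile   <- build_profile(system.file("extdata",
               "bhlh_seed_alignment_synthetic.fasta", package = "bhlhscan"))
threshold <- calibrate_threshold(profile, n = 300, seed = 42)

hit <- scan_domain(fam$proteins[["synbHLH01"]], profile, threshold,
                   id = "synbHLH01")
hit
#> domain hit in synbHLH01: start 26 (0-based), score 149.95 bits
#>   ADRRKAANHRERERRRRINISERLMERQELVPVGRKASIDKFSMLDEAFEYEKWV

classify_binding(hit)
#> binding call: G_box (basic count 10; 9/13/16/17 = H/E/R/R)

protein_properties(fam$proteins[["synbHLH01"]], id = "synbHLH01")
#> synbHLH01: 142 aa, MW 17216.37 Da (17.22 kDa), pI 7.98

hits  <- lapply(names(fam$proteins), function(id)
           scan_domain(fam$proteins[[id]], profile, threshold, id = id))
calls <- lapply(hits, classify_binding)
summarize_binding(calls)
#>              type count percent
#> 1           E_box    65   66.33
#> 2           G_box    61   62.24
#> 3       non_G_box     4    4.08
#> 4       non_E_box    11   11.22
#> 5     DNA_binding    76   77.55
#> 6 non_DNA_binding    22   22.45
```

Reading the output: the scanner locates the planted domain at its true
offset; the classifier reads the basic-region rule residues (His-9, Glu-13,
Arg-16, Arg-17 with 10 basic residues) and calls a G-box binder; the family
summary reports 76/98 members (77.55%) as DNA-binding, 61 of them (62.24%)
G-box binders — the composition the family was generated with.

Other stages follow the same pattern; for instance
`infer_structure(cds, genomic)` returns the exon–intron model whose exon
concatenation reproduces the CDS exactly, and
`nj_tree(p_distance_matrix(domains))` returns an `ape::phylo` tree.
`run_pipeline(run_config(seed = 42))` drives every stage on the synthetic
study set and writes one seeded, reproducible TSV per stage.  The methods
vignette (`vignettes/bhlh-family-pipeline.Rmd`) documents the models,
defaults and limitations.

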