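# splicecodes

ACMG/AMP evidence codes for variant effects on RNA splicing.

`splicecodes` is for variant curators, clinical-genetics pipelines and
expert panels who need to turn splice-prediction scores, variant
positions and RNA splicing assay results into ACMG/AMP evidence codes in
a consistent, auditable way. It implements:

* **Likelihood-ratio calibration** of splice-prediction score thresholds
  against spliceogenicity truth data. For a score bin with in-bin/total
  spliceogenic counts *a/A* and non-spliceogenic counts *b/B*,

  LR = (a/A) / (b/B),  CI₉₅ = exp( ln LR ± 1.96·√((1−a/A)/a + (1−b/B)/b) ),

  with LRs mapped to evidence strengths on the Bayesian odds scale at a
  prior of 0.10 (Very Strong 350, then its square/fourth/eighth roots;
  benign boundaries are reciprocals). Includes exhaustive cut-off search,
  score-band sensitivity analysis and region-stratified calibration.
* **Splice-region classification** of variant positions (canonical
  dinucleotide; standard donor −3..+6 / acceptor +1..−20; minimal
  acceptor −3; all configurable), with HGVS-like strand-aware offsets.
* A **gene-configurable PVS1 decision tree** (NMD, critical domains,
  protein-size threshold, rescue transcripts, start-loss), with RNA assay
  read-outs re-entering through the same tree as PVS1_Strength(RNA) —
  including leaky, complex and construct-only read-outs.
* The **splicing adaptations of PS1, PP3/BP4 and BP7** (BP7_Strong(RNA)
  for assays showing no impact), and a **combiner** that enforces the
  mutual exclusions (PP3 never with PVS1 or BP4; computational BP7 only
  on top of BP4; PS3/BS3 never for splicing-only evidence) and logs every
  suppressed code with its reason.
* A **synthetic truth-set generator** and deterministic fixtures so the
  whole stack is testable offline.

Inputs: VCF with SpliceAI annotations (or a score TSV), GTF/GFF3 or an
exon-table TSV for transcripts, a per-gene YAML context, and TSV tables
for assay read-outs and PS1 comparators. The package emits evidence
codes, not final 5-tier classifications.

## Worked example

```r
library(splicecodes)

## calibration: the high-score bin of the bundled reference fixture
compute_lr(bin_counts(381, 491, 109, 2246))
#> LR 15.99 [13.23, 19.32]  MODERATE  (pos 381/491, neg 109/2246)

ss <- sensitivity_specificity(truth_fixture(), 0.1, 0.2)
round(100 * c(ss$sensitivity, ss$specificity))
#> 78 87
```

A score of ≥ 0.2 is moderate-strength evidence of spliceogenicity
(LR 15.99, 95% CI 13.23–19.32) at 78% sensitivity; ≤ 0.1 is
moderate-strength evidence against (87% specificity). The codes are still
applied at supporting weight by default (conservative application).

```r
## a deep-intronic variant, 21 bases upstream of an acceptor
tx <- make_fixture_transcript(3, 100, 200, "+")
rc <- classify_region(variant_allele("chrS", 1279, "A", "G"), tx)
rc
#> region_class: OUTSIDE (side ACCEPTOR, offset -21, intronic)

combine_codes(rc, "intronic", scores = spliceai_scores(0.02, 0.01, 0.0, 0.01))
#> assigned:
#>   BP4_Supporting  (prediction supports no splicing impact; max delta 0.02 <= 0.1)
#>   BP7_Supporting  (BP4 met and position outside designated splice region)
```

The position is at/beyond −21, so with BP4 met the computational BP7 is
added. A canonical-site variant instead goes through the PVS1 tree:

```r
ev <- splice_event("EXON_SKIP", 2L, frame = "OUT_OF_FRAME", nmd_predicted = TRUE)
assign_pvs1(ev, gene_context())
#> PVS1
#>   path: lof_mechanism_established > out_of_frame > nmd_predicted
```

Every result carries the ordered decision path, and `combine_codes()`
records suppressed codes (e.g. PP3 replaced by an RNA-based PVS1) so the
bookkeeping is auditable.

A command-line interface wrapping these functions (subcommands
`calibrate`, `classify-region`, `assign-codes`, `simulate`) is installed
at `system.file("cli", "splicecodes.R", package = "splicecodes")`.

## Documentation

The methods vignette (`vignettes/splicing-evidence.Rmd`) describes the
model, the region definitions, the decision trees, every operational
threshold and its default, the synthetic generator, and known
limitations.
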