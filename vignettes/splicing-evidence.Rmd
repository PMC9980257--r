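---
title: "Calibrating and combining splicing evidence under the ACMG/AMP framework"
author: "splicecodes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calibrating and combining splicing evidence under the ACMG/AMP framework}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(splicecodes)
```

## The problem

ACMG/AMP variant classification uses several evidence codes that touch RNA
splicing: PVS1 (presumed loss of function), PP3/BP4 (computational
predictions), BP7 (silent/intronic variants with low prior of splice
impact), PS1 (same molecular consequence as a known Pathogenic variant),
and PS3/BS3 (functional assays). In practice, expert panels have applied
these codes very differently, and splicing evidence is easy to double-count
(a prediction, the variant's position, and an RNA assay all reflect the
same mechanism). `splicecodes` implements one coherent scheme:

* prediction scores are *calibrated* against spliceogenicity truth data via
  likelihood ratios mapped to evidence strengths;
* variant positions are classified into nested splice-region categories
  that gate positional codes;
* PVS1 weight comes from a gene-configurable decision tree, and RNA assay
  read-outs re-enter through the *same* tree (reported as
  PVS1_Strength(RNA) rather than PS3);
* assays showing no impact are captured as BP7_Strong(RNA) rather than
  BS3; and
* a combiner enforces the mutual exclusions (no PP3 with PVS1, no PP3 with
  BP4, computational BP7 only on top of BP4, PS3/BS3 never for
  splicing-only evidence).

The final 5-tier classification is deliberately out of scope: the package
emits evidence codes, not verdicts.

## Likelihood-ratio calibration

For a score bin, with `a/A` the in-bin and total spliceogenic counts and
`b/B` the non-spliceogenic counts, the likelihood ratio of spliceogenicity
is

$$ LR = \frac{a/A}{b/B}, \qquad
   CI_{95} = \exp\!\Big(\ln LR \pm 1.96\,
   \sqrt{\tfrac{1-a/A}{a} + \tfrac{1-b/B}{b}}\Big), $$

the standard log-method interval for diagnostic likelihood ratios. When an
in-bin count is zero, 0.5 is added to all four cells of the underlying 2×2
table and the result is flagged; the correction is a numerical guard, not a
statistical claim.

```{r}
r <- compute_lr(bin_counts(381, 491, 109, 2246))
r
```

Strength boundaries follow the exponential point scale of the Bayesian
adaptation of the framework at a global prior of pathogenicity of 0.10:
Very Strong at odds 350, then the square, fourth and eighth roots (≈ 18.7,
4.33, 2.08) for Strong/Moderate/Supporting; benign boundaries are exact
reciprocals. Pathogenic categories are inclusive at their lower boundary
and benign at their upper, matching the `≥ high` / `≤ low` bin
conventions. All boundaries are configurable through
`strength_thresholds()`.

The bundled `truth_fixture()` reproduces the marginal bin counts of the
curated multi-gene truth set used to choose the default cut-offs (2,246
non-spliceogenic and 491 spliceogenic records; 3,021 variants of which 767
are spliceogenic in the full collection — the fixture covers the
non-canonical subset). At the default cuts this yields a moderate-strength
LR of 15.99 above 0.2, a moderate-benign LR of 0.17 at or below 0.1, an
uninformative middle band, 78% sensitivity and 87% specificity:

```{r}
ss <- sensitivity_specificity(truth_fixture(), 0.1, 0.2)
round(100 * c(sensitivity = ss$sensitivity, specificity = ss$specificity))
```

Although the default cut-offs calibrate to Moderate, `combine_codes()`
applies PP3/BP4 at Supporting weight by default: single-tool predictions do
not capture all aberration types (large retentions, multi-exon skips,
enhancer loss), and band-level LRs immediately adjacent to the cuts are
weaker than the aggregate bins, so the conservative application weight is
the package default (`applied_weight = "moderate"` is available).

### The cut-off search and its flat objective

`optimize_cutoffs()` performs an exhaustive grid search minimising

$$ w_{fn}\,\mathrm{FN\ rate} + w_{fp}\,\mathrm{FP\ rate} +
   w_{u}\,\mathrm{uninformative\ fraction}, $$

with FN = spliceogenic records at or below the low cut, FP =
non-spliceogenic at or above the high cut, default weights (1, 1, 1), and
exact ties broken towards the wider uninformative zone. A caveat worth
knowing: on data with the bundled fixture's margins this objective is
nearly flat across the middle score band — the marginal cost of moving the
low cut upward (FN density over spliceogenic records, ≈ 0.774 per unit
score) almost exactly cancels the marginal gain in uninformative fraction
(total middle density over all records, ≈ 0.778). Differences between
candidate pairs inside the band are of order 10⁻³ while resampling noise
in the same quantity is of comparable size, so on *resampled* data the
selected pair wanders within the band (the sharp density discontinuities at
the historical cuts do anchor it from outside). The search is therefore
reported with its full diagnostics, and we recommend treating its output on
modest datasets as a candidate to be reviewed against the band-level LRs
(`band_lrs()`), not as an oracle. The objective weights are exposed so that
a user who prioritises a small uninformative zone differently can say so
explicitly.

## Splice-region classification

Coordinates are 1-based and fully closed (GTF convention); offsets are
reported in transcript orientation with HGVS-like signs: intronic donor
+1, +2, …; intronic acceptor −1, −2, …; the last exonic base before a
donor is −1 and the first exonic base after an acceptor is +1. The
windows are:

* **canonical dinucleotide** — intronic ±1, 2;
* **standard splice region** — donor: last 3 exonic + first 6 intronic
  bases; acceptor: first exonic base + 20 intronic bases;
* **minimal splice region** — as standard, acceptor restricted to 3
  intronic bases.

The categories nest (canonical ⊂ minimal ⊂ standard), which the test
suite asserts by exhaustive scans. Membership is checked against *both*
flanking boundaries, so a base 8 nt past a donor that is also 18 nt before
the next acceptor is recognised as inside the standard acceptor window —
this matters for short introns and makes the BP7 position rule ("at or
beyond +7 **and** −21") fall out of the classification itself. Windows
are per-call configurable (`region_config()`), e.g. a 9-nt donor intronic
window for U12-type introns; intron-type detection itself is out of scope.

Choices the window definitions do not determine:

* *Indels* classify by the most motif-proximal affected base; a deletion
  spanning a canonical dinucleotide is canonical. Insertions are classified
  by their two flanking bases. This is the conservative reading.
* *Very short exons* can sit in both a donor and an acceptor window; the
  class is taken from the side granting the higher category, ties to the
  smaller absolute offset, then the donor side.
* *Terminal exons* have no donor (last exon) or acceptor (first exon)
  side; operations report side `NONE` where neither exists.

BP7 positional eligibility is purely positional: synonymous exonic
variants outside the first base and last three bases of the exon, and
intronic variants at or beyond +7/−21 (standard mode, the default) or
+7/−4 (minimal mode). Evolutionary conservation is deliberately absent
from the signature: prediction tools already internalise motif
conservation, and an extra conservation filter removes eligible variants
without improving negative predictive value.

## The PVS1 decision tree

`assign_pvs1()` implements the loss-of-function decision tree with
splicing-specific modifications, configured per gene via `gene_context()`:

* no predicted impact at the native site (e.g. a GT→GC change that keeps
  a functional donor) → PVS1_N/A;
* UTR-confined outcomes → PVS1_N/A unless a critical UTR element is
  flagged;
* a plausible naturally occurring rescue transcript — skipping the same
  exon(s), encoding a functional protein, at ≥ 10% of gene expression
  (operational default, configurable) → PVS1_N/A;
* out-of-frame with NMD predicted (50-nt rule as the conventional
  boundary) → PVS1;
* in-frame or NMD-escaping: Strong if a critical region or > 10% of the
  protein is removed, Moderate otherwise; *upweighted to PVS1* when a
  Pathogenic missense variant is known in the removed domain or the
  complementary splice site of the same exon carries Pathogenic variation
  with the same predicted outcome;
* start-loss → Moderate, with an explicit context flag for the upweight
  to Strong (the package does not infer alternative-ATG frames).

Upweights fire only when the triggering context flags are set, and every
decision node is recorded in an ordered rationale path, so a reviewer can
audit exactly which branch produced the strength.

## RNA assay evidence

`apply_rna_evidence()` routes assay read-outs through the same tree.
Design choices:

* **Complete/near-complete threshold.** Aberrant transcripts must carry ≥
  90% of variant-allele expression (default, `assay_thresholds()`) for
  full tree weight. The threshold is explicitly operational: genes where
  20–30% residual functional transcript is already non-pathogenic need
  gene-specific values, which is why it is a parameter and not a constant.
* **Leaky read-outs** (full-length above 10%) are demoted one strength
  level and flagged `LEAKY`.
* **Complex read-outs** (several aberrant transcripts from one allele) are
  pooled by `pool_complex_readout()`: transcripts are grouped by their own
  tree strength and the pooled strength is the strongest group at which
  the cumulative aberrant contribution reaches the threshold — the
  conservative "overall" weight.
* **Construct-only evidence** (minigene/MPRA, or controls not from matched
  tissue) is capped one level below full weight and flagged. The cap is
  applied symmetrically to the no-impact path (BP7_Strong(RNA) →
  Supporting) on the same conservative reasoning.
* A read-out with no aberrant transcripts returns a BP7_Strong(RNA)
  signal; an *absent* assay file is `NULL` and produces no RNA codes at
  all — absence of evidence is not evidence of absence.

## PS1 for predicted splicing events and the combiner

`assign_ps1()` transfers evidence from a classified comparator only when
the predicted events match exactly (type, exons, cryptic-site position)
and the variant under assessment predicts at similar or higher strength —
operationalised as a score tolerance of 0.05 on the maximum delta, a
number the weight table itself does not fix and which is therefore a
parameter. Weights fall one level when the comparator sits elsewhere in
the same motif, and further rules prevent a canonical variant from
out-weighting the comparator it borrows from; Likely Pathogenic canonical
comparators additionally require supporting clinical evidence. The full
matrix is enumerated in the tests against a hand-transcribed table.

`combine_codes()` applies the mutual-exclusion bookkeeping and keeps an
explicit `suppressed` ledger (every code withheld, with the reason) and a
`record_only` list for evidence that is noted but deliberately not scored
— e.g. a no-impact splicing assay for a missense variant without protein
functional data, where the most deleterious prediction is retained.

## The synthetic generator

`generate_truth_dataset()` is a test instrument, not a splicing simulator.
Its defaults emulate the *structure* of the curated truth set behind the
default cut-offs: 767 spliceogenic and 2,254 non-spliceogenic records,
with Beta(0.35, 0.15) scores for the spliceogenic class and Beta(0.25, 6)
for the non-spliceogenic class — chosen once so that the three-bin masses
approximate the reference margins (≈ 15/5/81% and ≈ 87/8/5%). A
`binned` distribution type draws scores uniformly within specified bins,
giving closed-form per-bin likelihood ratios for estimator-recovery tests;
a `point` type builds degenerate separable datasets. The generator does
*not* model per-motif-position score distributions, gene effects, or
curation bias, so passing tests demonstrate correctness of the estimators
and rules, not real-data performance of any prediction tool.

Problem sizes in the test and acceptance runs were chosen to keep the
whole suite under a minute while leaving Monte-Carlo noise well inside the
asserted tolerances: coverage checks use 200 replicates of n = 10,000
(binomial SE on a 95% coverage proportion ≈ 1.5 points, against a
92–98% acceptance band), and recovery checks use n = 10,000 against a
±15% tolerance on LRs of magnitude 0.17–15.4.

## Numerical conventions and known limitations

* LRs and CIs are reported at full precision and *displayed* at two
  decimals; proportions likewise. One consequence: the middle reference
  bin computes to LR 0.9933, which displays as 0.99 — the historical
  table shows 1.00 for the same counts (the ratio of its rounded
  proportions, 0.08/0.08). The package always computes from raw counts.
* Outer score bins are closed (`≤ low`, `≥ high`); score bands in
  `band_lrs()` are half-open with the top band closed, so complementary
  bands partition without double counting.
* The truth fixture places scores deterministically: evenly across closed
  bins including edges, and across the open interior of the middle bin.
* The package consumes prediction scores; it never computes them. It also
  performs no transcript-effect prediction: event descriptions
  (`splice_event()`) are inputs, typically derived from a predictor or an
  assay.
* Non-GT-AG introns are supported only through window overrides;
  branchpoints, pseudoexonisation and splicing enhancers/silencers are out
  of scope, as is any automatic critical-domain discovery or
  tissue-expression lookup (these enter as `gene_context()` fields).
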