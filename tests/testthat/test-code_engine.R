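test_that("PP3/BP4 follow the calibrated cut-offs at supporting weight", {
  expect_equal(assign_pp3_bp4(spliceai_scores(0.35, 0.1, 0, 0))$code, "PP3")
  expect_equal(assign_pp3_bp4(spliceai_scores(0.35, 0.1, 0, 0))$strength,
               "Supporting")
  expect_equal(assign_pp3_bp4(spliceai_scores(0.01, 0.05, 0.02, 0))$code,
               "BP4")
  expect_null(assign_pp3_bp4(spliceai_scores(0.15, 0.1, 0, 0))$code)
  # boundary scores meet the codes
  expect_equal(assign_pp3_bp4(spliceai_scores(0.2, 0, 0, 0))$code, "PP3")
  expect_equal(assign_pp3_bp4(spliceai_scores(0.1, 0, 0, 0))$code, "BP4")
  # missing scores yield no code with a recorded reason
  miss <- assign_pp3_bp4(spliceai_scores(NA, NA, NA, NA))
  expect_null(miss$code)
  expect_match(miss$reason, "missing")
  # moderate application weight is available but not the default
  expect_equal(assign_pp3_bp4(spliceai_scores(0.5, 0, 0, 0),
                              applied_weight = "moderate")$strength,
               "Moderate")
  expect_equal(spliceai_scores(0.1, 0.9, 0.2, 0.3)$max_delta, 0.9)
  expect_error(spliceai_scores(1.2, 0, 0, 0), "\\[0, 1\\]")
})

test_that("BP7 requires BP4 plus positional eligibility, nothing else", {
  expect_equal(assign_bp7(TRUE, TRUE)$code, "BP7")
  expect_null(assign_bp7(TRUE, FALSE)$code)
  expect_null(assign_bp7(FALSE, TRUE)$code)
  # no conservation argument exists in the signature by design
  expect_named(formals(assign_bp7), c("bp4_met", "position_eligible"))
})

test_that("PS1 weights match the hand-transcribed comparator matrix", {
  tab <- ps1_oracle_table()
  for (i in seq_len(nrow(tab))) {
    r <- ps1_case(tab$vua[i], tab$relation[i], tab$cls[i])
    if (is.na(tab$expected[i])) {
      expect_null(r$code, info = paste(tab$vua[i], tab$relation[i], tab$cls[i]))
    } else {
      expect_equal(r$strength, tab$expected[i],
                   info = paste(tab$vua[i], tab$relation[i], tab$cls[i]))
    }
  }
  # every baseline strength of the reduced-canonical rows behaves alike
  for (frac in c(0.25, 0.04)) {  # Strong and Moderate baselines
    ev <- splice_event("EXON_SKIP", 2L, frame = "OUT_OF_FRAME",
                       nmd_predicted = TRUE)
    base <- assign_pvs1(splice_event("EXON_SKIP", 2L, frame = "IN_FRAME",
                                     fraction_protein_removed = frac),
                        gene_context())
    cmp <- comparator_variant(
      "c", "PATHOGENIC",
      region_class("CANONICAL_DINUCLEOTIDE", "DONOR", 2L, FALSE), ev, 0.9,
      same_motif_as_vua = TRUE)
    r <- assign_ps1(region_class("CANONICAL_DINUCLEOTIDE", "DONOR", 1L,
                                 FALSE), ev, 0.9, cmp, vua_pvs1 = base)
    expect_equal(r$strength, "Strong")
  }
})

test_that("PS1 prerequisites gate the comparison", {
  ev_skip <- splice_event("EXON_SKIP", 2L)
  ev_cryp <- splice_event("CRYPTIC_DONOR", 2L, cryptic_site_offset = 5L)
  out <- region_class("STANDARD_SPLICE_REGION", "DONOR", 5L, FALSE)
  cmp <- function(ev, score = 0.9, cls = "PATHOGENIC", ...)
    comparator_variant("c", cls, out, ev, score,
                       same_nucleotide_as_vua = TRUE, ...)
  # event mismatch
  expect_null(assign_ps1(out, ev_skip, 0.9, cmp(ev_cryp))$code)
  # cryptic-site position mismatch
  ev_cryp2 <- splice_event("CRYPTIC_DONOR", 2L, cryptic_site_offset = 8L)
  expect_null(assign_ps1(out, ev_cryp, 0.9, cmp(ev_cryp2))$code)
  # prediction strength shortfall beyond tolerance
  expect_null(assign_ps1(out, ev_skip, 0.5, cmp(ev_skip, score = 0.9))$code)
  # within tolerance passes
  expect_equal(assign_ps1(out, ev_skip, 0.86, cmp(ev_skip, score = 0.9))$code,
               "PS1")
  # comparator outside the motif
  far <- comparator_variant("c", "PATHOGENIC", out, ev_skip, 0.9)
  expect_null(assign_ps1(out, ev_skip, 0.9, far)$code)
  # Likely Pathogenic canonical comparators need clinical support
  r_no <- ps1_case("noncanonical", "same_motif_canonical",
                   "LIKELY_PATHOGENIC", clinical_support = FALSE)
  expect_null(r_no$code)
  expect_match(r_no$reason, "clinical")
  # a canonical VUA without its baseline PVS1 is a contract error
  ev <- splice_event("EXON_SKIP", 2L)
  cano <- region_class("CANONICAL_DINUCLEOTIDE", "DONOR", 1L, FALSE)
  cc <- comparator_variant("c", "PATHOGENIC", cano, ev, 0.9,
                           same_motif_as_vua = TRUE)
  expect_error(assign_ps1(cano, ev, 0.9, cc), "baseline")
})

test_that("combined assignment follows the decision scheme", {
  out_region <- region_class("OUTSIDE", "ACCEPTOR", -15L, FALSE)
  # intronic variant, strong prediction, no assay: PP3 supporting only
  cs <- combine_codes(out_region, "intronic",
                      scores = spliceai_scores(0.6, 0, 0, 0))
  expect_equal(cs$assigned$code, "PP3")
  expect_equal(cs$assigned$strength, "Supporting")

  # same variant with an assay-confirmed out-of-frame aberration:
  # RNA-based PVS1 replaces PP3
  ro <- assay_readout(data.frame(
    event_type = "CRYPTIC_ACCEPTOR", affected_exons = "2",
    frame = "OUT_OF_FRAME", nmd_predicted = TRUE,
    fraction_protein_removed = 0.2, removes_critical_region = FALSE,
    aberrant_fraction = 0.95), source = "patient_rna")
  rna <- apply_rna_evidence(ro, gene_context())
  cs2 <- combine_codes(out_region, "intronic",
                       scores = spliceai_scores(0.6, 0, 0, 0), rna = rna)
  expect_equal(cs2$assigned$code, "PVS1")
  expect_true(cs2$assigned$rna)
  expect_true("PP3" %in% cs2$suppressed$code)
  expect_true("PS3" %in% cs2$suppressed$code)

  # intronic variant with a no-impact assay: BP7_Strong(RNA)
  none <- apply_rna_evidence(
    assay_readout(data.frame(event_type = character(),
                             aberrant_fraction = numeric()),
                  source = "patient_rna"), gene_context())
  cs3 <- combine_codes(out_region, "intronic",
                       scores = spliceai_scores(0.05, 0, 0, 0), rna = none)
  expect_equal(cs3$assigned$code, "BP7")
  expect_equal(cs3$assigned$strength, "Strong")
  expect_true(cs3$assigned$rna)
  expect_true("BS3" %in% cs3$suppressed$code)

  # missense with BP4-range scores and a no-impact assay but no protein
  # functional data: splicing result recorded only, BP4 retained
  exonic_out <- region_class("OUTSIDE", "NONE", 40L, TRUE)
  cs4 <- combine_codes(exonic_out, "missense",
                       scores = spliceai_scores(0.02, 0, 0, 0), rna = none)
  expect_true("BP4" %in% cs4$assigned$code)
  expect_false("BP7" %in% cs4$assigned$code)
  expect_true(nrow(cs4$record_only) > 0)

  # ... and BP7_Strong(RNA) once protein impact is excluded
  cs5 <- combine_codes(exonic_out, "missense",
                       scores = spliceai_scores(0.02, 0, 0, 0), rna = none,
                       protein_functional_impact_excluded = TRUE)
  expect_true("BP7" %in% cs5$assigned$code)
})

test_that("canonical variants take the PVS1 path, never PP3/BP4", {
  cano <- region_class("CANONICAL_DINUCLEOTIDE", "DONOR", 1L, FALSE)
  base <- assign_pvs1(splice_event("EXON_SKIP", 2L, frame = "OUT_OF_FRAME",
                                   nmd_predicted = TRUE), gene_context())
  cs <- combine_codes(cano, "other", scores = spliceai_scores(0.99, 0, 0, 0),
                      pvs1 = base)
  expect_equal(cs$assigned$code, "PVS1")
  expect_true(all(c("PP3", "BP4") %in% cs$suppressed$code))
})

test_that("computational BP7 rides on BP4 and position, within combine_codes", {
  deep <- region_class("OUTSIDE", "ACCEPTOR", -30L, FALSE)
  cs <- combine_codes(deep, "intronic", scores = spliceai_scores(0.02, 0, 0, 0))
  expect_setequal(cs$assigned$code, c("BP4", "BP7"))
  # synonymous at the last exon base: BP4 without BP7
  edge <- region_class("MINIMAL_SPLICE_REGION", "DONOR", -1L, TRUE)
  cs2 <- combine_codes(edge, "synonymous",
                       scores = spliceai_scores(0.02, 0, 0, 0))
  expect_equal(cs2$assigned$code, "BP4")
})

test_that("contradictory RNA inputs are rejected with no codes emitted", {
  out_region <- region_class("OUTSIDE", "DONOR", 40L, FALSE)
  ro <- assay_readout(data.frame(
    event_type = "EXON_SKIP", affected_exons = "2", frame = "OUT_OF_FRAME",
    nmd_predicted = TRUE, fraction_protein_removed = 0.1,
    removes_critical_region = FALSE, aberrant_fraction = 0.95),
    source = "patient_rna")
  impact <- apply_rna_evidence(ro, gene_context())
  none <- apply_rna_evidence(
    assay_readout(data.frame(event_type = character(),
                             aberrant_fraction = numeric()),
                  source = "patient_rna"), gene_context())
  expect_error(combine_codes(out_region, "intronic",
                             rna = list(impact, none)), "conflicting")
})

test_that("mutual-exclusion invariants hold under randomized inputs", {
  set.seed(99)
  ctx <- gene_context()
  regions <- list(region_class("OUTSIDE", "DONOR", 25L, FALSE),
                  region_class("OUTSIDE", "NONE", 40L, TRUE),
                  region_class("STANDARD_SPLICE_REGION", "ACCEPTOR", -8L, FALSE),
                  region_class("MINIMAL_SPLICE_REGION", "DONOR", 4L, FALSE),
                  region_class("CANONICAL_DINUCLEOTIDE", "ACCEPTOR", -1L, FALSE))
  ro_impact <- assay_readout(data.frame(
    event_type = "EXON_SKIP", affected_exons = "2", frame = "OUT_OF_FRAME",
    nmd_predicted = TRUE, fraction_protein_removed = 0.2,
    removes_critical_region = FALSE, aberrant_fraction = 0.95),
    source = "patient_rna")
  ro_none <- assay_readout(data.frame(event_type = character(),
                                      aberrant_fraction = numeric()),
                           source = "patient_rna")
  base <- assign_pvs1(splice_event("EXON_SKIP", 2L, frame = "OUT_OF_FRAME",
                                   nmd_predicted = TRUE), ctx)
  for (i in 1:200) {
    region <- regions[[sample.int(length(regions), 1)]]
    consequence <- sample(c("intronic", "synonymous", "missense", "other"), 1)
    scores <- if (runif(1) < 0.85)
      spliceai_scores(runif(1), runif(1), runif(1), runif(1)) else NULL
    rna <- switch(sample(3, 1), NULL,
                  apply_rna_evidence(ro_impact, ctx),
                  apply_rna_evidence(ro_none, ctx))
    pvs1 <- if (region$category == "CANONICAL_DINUCLEOTIDE") base else NULL
    cs <- combine_codes(region, consequence, scores = scores, pvs1 = pvs1,
                        rna = rna,
                        protein_functional_impact_excluded = runif(1) < 0.5)
    expect_true(validate_code_set(cs))
    a <- cs$assigned$code
    expect_false(all(c("PP3", "PVS1") %in% a))
    expect_false(all(c("PP3", "BP4") %in% a))
    expect_false(any(c("PS3", "BS3") %in% a))
    if ("BP7" %in% a && !any(cs$assigned$rna[cs$assigned$code == "BP7"]))
      expect_true("BP4" %in% a)
  }
})
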