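ctx0 <- gene_context()

test_that("the PVS1 tree requires an established LoF mechanism", {
  ctx <- gene_context(lof_mechanism_established = FALSE)
  ev <- splice_event("EXON_SKIP", 2L, frame = "OUT_OF_FRAME",
                     nmd_predicted = TRUE)
  err <- tryCatch(assign_pvs1(ev, ctx), condition = identity)
  expect_s3_class(err, "splicecodes_not_applicable")
  expect_match(conditionMessage(err), "PM4")
})

test_that("out-of-frame events subject to NMD reach full PVS1", {
  ev <- splice_event("EXON_SKIP", 2L, frame = "OUT_OF_FRAME",
                     nmd_predicted = TRUE)
  r <- assign_pvs1(ev, ctx0)
  expect_equal(r$strength, "PVS1")
  expect_false(r$rna_based)
  expect_true("nmd_predicted" %in% r$rationale)
})

test_that("splicing-specific tree modifications return the stated strengths", {
  # UTR-confined outcome -> N/A unless a critical UTR element is flagged
  utr <- splice_event("CRYPTIC_DONOR", 1L, utr_only = TRUE)
  expect_equal(assign_pvs1(utr, ctx0)$strength, "PVS1_NA")
  ctx_utr <- gene_context(utr_critical_element = TRUE)
  expect_true(assign_pvs1(utr, ctx_utr)$strength != "PVS1_NA")

  # start-loss branch: Moderate, upweighted to Strong on context evidence
  sl <- splice_event("EXON_SKIP", 1L, start_loss = TRUE)
  expect_equal(assign_pvs1(sl, ctx0)$strength, "PVS1_Moderate")
  ctx_sl <- gene_context(start_loss_upweight = TRUE)
  expect_equal(assign_pvs1(sl, ctx_sl)$strength, "PVS1_Strong")

  # in-frame removal of a critical region: Strong, upweighted to PVS1 when
  # a Pathogenic missense variant is known in the removed domain
  crit <- splice_event("EXON_SKIP", 3L, frame = "IN_FRAME",
                       fraction_protein_removed = 0.05,
                       removes_critical_region = TRUE,
                       critical_domain = "RING")
  expect_equal(assign_pvs1(crit, ctx0)$strength, "PVS1_Strong")
  ctx_mis <- gene_context(critical_domains = data.frame(
    domain = "RING", pathogenic_missense = TRUE))
  r <- assign_pvs1(crit, ctx_mis)
  expect_equal(r$strength, "PVS1")
  expect_true("upweighted_to_PVS1" %in% r$rationale)

  # complementary-site Pathogenic variation also upweights
  ctx_comp <- gene_context(complementary_site_pathogenic_exons = 3L)
  expect_equal(assign_pvs1(crit, ctx_comp)$strength, "PVS1")

  # >10% of protein removed without criticality: Strong; below: Moderate
  big <- splice_event("EXON_SKIP", 4L, frame = "IN_FRAME",
                      fraction_protein_removed = 0.25)
  expect_equal(assign_pvs1(big, ctx0)$strength, "PVS1_Strong")
  small <- splice_event("EXON_SKIP", 4L, frame = "IN_FRAME",
                        fraction_protein_removed = 0.04)
  expect_equal(assign_pvs1(small, ctx0)$strength, "PVS1_Moderate")

  # out-of-frame escaping NMD follows the same truncation rules
  oof <- splice_event("CRYPTIC_ACCEPTOR", 5L, frame = "OUT_OF_FRAME",
                      nmd_predicted = FALSE,
                      fraction_protein_removed = 0.25)
  expect_equal(assign_pvs1(oof, ctx0)$strength, "PVS1_Strong")
})

test_that("a plausible rescue transcript yields PVS1_N/A at the 10% threshold", {
  ev <- splice_event("EXON_SKIP", 2L, frame = "OUT_OF_FRAME",
                     nmd_predicted = TRUE)
  ctx_resc <- gene_context(rescue_transcripts = data.frame(
    transcript_id = "alt1", skips_exons = "2",
    expression_fraction = 0.15, encodes_functional_protein = TRUE))
  r <- assign_pvs1(ev, ctx_resc)
  expect_equal(r$strength, "PVS1_NA")
  expect_match(paste(r$rationale, collapse = " "), "rescue")
  # below-threshold or non-functional rescue transcripts do not rescue
  ctx_low <- gene_context(rescue_transcripts = data.frame(
    transcript_id = "alt1", skips_exons = "2",
    expression_fraction = 0.05, encodes_functional_protein = TRUE))
  expect_equal(assign_pvs1(ev, ctx_low)$strength, "PVS1")
  ctx_nf <- gene_context(rescue_transcripts = data.frame(
    transcript_id = "alt1", skips_exons = "2",
    expression_fraction = 0.5, encodes_functional_protein = FALSE))
  expect_equal(assign_pvs1(ev, ctx_nf)$strength, "PVS1")
  # rescue transcript skipping a different exon is irrelevant
  ctx_other <- gene_context(rescue_transcripts = data.frame(
    transcript_id = "alt1", skips_exons = "5",
    expression_fraction = 0.5, encodes_functional_protein = TRUE))
  expect_equal(assign_pvs1(ev, ctx_other)$strength, "PVS1")
})

test_that("predicted-functional native site changes are PVS1_N/A", {
  # e.g. a GT>GC donor change predicted to keep a functional donor site
  ev <- splice_event("NO_IMPACT")
  r <- assign_pvs1(ev, ctx0,
                   region = region_class("CANONICAL_DINUCLEOTIDE",
                                         "DONOR", 2L, FALSE))
  expect_equal(r$strength, "PVS1_NA")
  expect_true("no_predicted_splicing_impact" %in% r$rationale)
})

test_that("the tree is deterministic and every leaf is reachable", {
  ev <- splice_event("EXON_SKIP", 2L, frame = "OUT_OF_FRAME",
                     nmd_predicted = TRUE)
  expect_identical(assign_pvs1(ev, ctx0), assign_pvs1(ev, ctx0))

  cases <- list(
    splice_event("NO_IMPACT"),
    splice_event("CRYPTIC_DONOR", 1L, utr_only = TRUE),
    splice_event("EXON_SKIP", 1L, start_loss = TRUE),
    ev,
    splice_event("EXON_SKIP", 3L, frame = "IN_FRAME",
                 removes_critical_region = TRUE, critical_domain = "RING"),
    splice_event("EXON_SKIP", 4L, frame = "IN_FRAME",
                 fraction_protein_removed = 0.25),
    splice_event("EXON_SKIP", 4L, frame = "IN_FRAME",
                 fraction_protein_removed = 0.04))
  ctxs <- list(ctx0,
               gene_context(critical_domains = data.frame(
                 domain = "RING", pathogenic_missense = TRUE)),
               gene_context(rescue_transcripts = data.frame(
                 transcript_id = "alt1", skips_exons = "2",
                 expression_fraction = 0.2,
                 encodes_functional_protein = TRUE)))
  seen <- character()
  for (ev_i in cases) for (cx in ctxs) {
    r <- assign_pvs1(ev_i, cx)
    expect_true(length(r$rationale) >= 1)
    seen <- union(seen, r$strength)
  }
  expect_setequal(seen, c("PVS1", "PVS1_Strong", "PVS1_Moderate", "PVS1_NA"))
})

test_that("criticality strengthens and rescue weakens, never the reverse", {
  set.seed(21)
  rank <- function(s) match(s, c("PVS1_NA", "PVS1_Supporting",
                                 "PVS1_Moderate", "PVS1_Strong", "PVS1"))
  ctx_resc <- gene_context(rescue_transcripts = data.frame(
    transcript_id = "alt1", skips_exons = "2",
    expression_fraction = 0.2, encodes_functional_protein = TRUE))
  for (i in 1:40) {
    ev <- splice_event(sample(c("EXON_SKIP", "CRYPTIC_DONOR",
                                "INTRON_RETENTION"), 1),
                       affected_exons = 2L,
                       frame = sample(c("IN_FRAME", "OUT_OF_FRAME"), 1),
                       nmd_predicted = sample(c(TRUE, FALSE), 1),
                       fraction_protein_removed = runif(1))
    base <- assign_pvs1(ev, ctx0)
    ev_crit <- ev; ev_crit$removes_critical_region <- TRUE
    expect_gte(rank(assign_pvs1(ev_crit, ctx0)$strength),
               rank(base$strength))
    expect_lte(rank(assign_pvs1(ev, ctx_resc)$strength),
               rank(base$strength))
  }
})

test_that("complete patient-RNA read-outs carry full tree weight", {
  ro <- assay_readout(data.frame(
    event_type = "EXON_SKIP", affected_exons = "2", frame = "OUT_OF_FRAME",
    nmd_predicted = TRUE, fraction_protein_removed = 0.2,
    removes_critical_region = FALSE, aberrant_fraction = 1.0,
    allele_specific = TRUE), source = "patient_rna")
  r <- apply_rna_evidence(ro, ctx0)
  expect_s3_class(r, "pvs1_result")
  expect_equal(r$strength, "PVS1")
  expect_true(r$rna_based)
})

test_that("no-aberration read-outs signal BP7_Strong(RNA)", {
  ro <- assay_readout(data.frame(event_type = character(),
                                 aberrant_fraction = numeric()),
                      source = "patient_rna")
  r <- apply_rna_evidence(ro, ctx0)
  expect_s3_class(r, "bp7_rna_signal")
  expect_equal(r$code, "BP7")
  expect_equal(r$strength, "Strong")
  expect_false(r$low_confidence)
})

test_that("construct-only evidence is capped one level below full weight", {
  # complete in-frame skip of a non-critical exon removing >10% of protein:
  # tree gives Strong, construct cap demotes to Moderate
  ro <- assay_readout(data.frame(
    event_type = "EXON_SKIP", affected_exons = "3", frame = "IN_FRAME",
    nmd_predicted = FALSE, fraction_protein_removed = 0.15,
    removes_critical_region = FALSE, aberrant_fraction = 0.95),
    source = "minigene")
  r <- apply_rna_evidence(ro, ctx0)
  expect_equal(r$strength, "PVS1_Moderate")
  expect_true("CONSTRUCT_CAPPED" %in% r$flags)
  # unmatched-tissue controls trigger the same cap
  ro2 <- assay_readout(data.frame(
    event_type = "EXON_SKIP", affected_exons = "2", frame = "OUT_OF_FRAME",
    nmd_predicted = TRUE, fraction_protein_removed = 0.2,
    removes_critical_region = FALSE, aberrant_fraction = 0.95),
    source = "patient_rna", controls_matched_tissue = FALSE)
  expect_equal(apply_rna_evidence(ro2, ctx0)$strength, "PVS1_Strong")
  # construct-only no-impact read-outs drop to supporting weight
  ro3 <- assay_readout(data.frame(event_type = character(),
                                  aberrant_fraction = numeric()),
                       source = "mpra")
  r3 <- apply_rna_evidence(ro3, ctx0)
  expect_equal(r3$strength, "Supporting")
  expect_true(r3$low_confidence)
})

test_that("complex read-outs pool conservatively across strength groups", {
  mk <- function(frame, nmd, frac, contrib) {
    ev <- splice_event("EXON_SKIP", 2L, frame = frame, nmd_predicted = nmd,
                       fraction_protein_removed = frac)
    list(result = assign_pvs1(ev, ctx0), contribution = contrib)
  }
  # single dominant aberrant transcript keeps its own strength
  r1 <- pool_complex_readout(list(mk("OUT_OF_FRAME", TRUE, 0, 0.95)))
  expect_equal(r1$strength, "PVS1")
  expect_equal(r1$flags, character())

  # hand enumeration: PVS1 at 50% + Moderate at 45%, full-length 5%.
  # Cumulative contribution reaches the 0.90 threshold only once the
  # Moderate group is included, so the pooled strength is Moderate.
  r2 <- pool_complex_readout(list(mk("OUT_OF_FRAME", TRUE, 0, 0.50),
                                  mk("IN_FRAME", FALSE, 0.04, 0.45)))
  expect_equal(r2$strength, "PVS1_Moderate")

  # 80% full-length with 20% aberrant is leaky: demoted one level, flagged
  r3 <- pool_complex_readout(list(mk("OUT_OF_FRAME", TRUE, 0, 0.20)))
  expect_equal(r3$strength, "PVS1_Strong")
  expect_true("LEAKY" %in% r3$flags)

  expect_error(pool_complex_readout(list()), "at least one")
  expect_error(pool_complex_readout(list(mk("OUT_OF_FRAME", TRUE, 0, 0.8),
                                         mk("IN_FRAME", FALSE, 0, 0.5))),
               "sum to <= 1")
})

test_that("leaky single-event read-outs are downgraded and flagged", {
  ro <- assay_readout(data.frame(
    event_type = "EXON_SKIP", affected_exons = "2", frame = "OUT_OF_FRAME",
    nmd_predicted = TRUE, fraction_protein_removed = 0.2,
    removes_critical_region = FALSE, aberrant_fraction = 0.5),
    source = "patient_rna")
  r <- apply_rna_evidence(ro, ctx0)
  expect_equal(r$strength, "PVS1_Strong")
  expect_true("LEAKY" %in% r$flags)
})
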