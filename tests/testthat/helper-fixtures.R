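# Shared fixtures and independent oracles used across the suite.

# three-exon fixture: exons [1000,1099], [1300,1399], [1600,1699]
fx_tx <- function(strand = "+") make_fixture_transcript(3, 100, 200, strand)

# Independent position-classification oracle for the plus-strand fixture.
# Derived directly from the window definitions, without going through the
# package's offset machinery: for every genomic position of the fixture,
# compute canonical/minimal/standard membership from the exon coordinates.
oracle_position_map <- function(cfg = region_config()) {
  exons <- data.frame(start = c(1000, 1300, 1600), end = c(1099, 1399, 1699))
  out <- list()
  for (p in 1000:1699) {
    inside <- which(p >= exons$start & p <= exons$end)
    if (length(inside)) {
      i <- inside
      don <- i < 3 && p >= exons$end[i] - (cfg$donor_exonic - 1)
      acc <- i > 1 && p <= exons$start[i] + (cfg$acceptor_exonic - 1)
      canon <- FALSE
      minimal <- don || acc
      standard <- don || acc
      exonic <- TRUE
    } else {
      i <- max(which(exons$end < p))     # intron follows exon i
      d <- p - exons$end[i]              # donor offset, 1-based
      a <- p - exons$start[i + 1]        # acceptor offset, negative
      canon <- d %in% 1:2 || a %in% -(1:2)
      don <- d <= cfg$donor_intronic
      minimal <- don || a >= -cfg$acceptor_intronic_minimal
      standard <- don || a >= -cfg$acceptor_intronic_standard
      exonic <- FALSE
    }
    out[[length(out) + 1]] <- data.frame(
      pos = p, exonic = exonic, canonical = canon,
      in_minimal = canon || minimal, in_standard = canon || minimal || standard)
  }
  do.call(rbind, out)
}

mk_variant <- function(pos, ref = "A", alt = "C", chrom = "chrS")
  variant_allele(chrom, pos, ref, alt)

# Independent closed-form oracle for the likelihood ratio and its
# log-method interval, written separately from compute_lr().
oracle_lr <- function(a, A, b, B, z = 1.96) {
  p1 <- a / A; p2 <- b / B
  lr <- p1 / p2
  se <- sqrt((1 - p1) / a + (1 - p2) / b)
  list(lr = lr, lo = lr * exp(-z * se), hi = lr * exp(z * se))
}

# Independent brute-force cut-off search (plain loops, no vectorisation),
# mirroring the published objective: FN rate + FP rate + uninformative
# fraction, equal weights, ties to the widest uninformative zone.
oracle_cutoffs <- function(records, grid_step = 0.01, w = c(1, 1, 1)) {
  pos <- records$score[records$spliceogenic]
  neg <- records$score[!records$spliceogenic]
  N <- length(pos) + length(neg)
  grid <- seq(0, 1, by = grid_step)
  best <- NULL; bestv <- Inf; bestwd <- -1
  for (lo in grid) for (hi in grid) {
    if (lo >= hi) next
    v <- w[1] * sum(pos <= lo) / length(pos) +
      w[2] * sum(neg >= hi) / length(neg) +
      w[3] * (sum(pos > lo & pos < hi) + sum(neg > lo & neg < hi)) / N
    wd <- hi - lo
    if (v < bestv - 1e-12 ||
        (abs(v - bestv) <= 1e-12 && (wd > bestwd ||
                                     (wd == bestwd && lo < best[1])))) {
      bestv <- v; best <- c(lo, hi); bestwd <- wd
    }
  }
  list(low_cut = best[1], high_cut = best[2], objective = bestv)
}

# Hand-transcribed PS1 weight table: one row per populated cell of the
# weight matrix, plus the not-applicable cells. vua is "noncanonical",
# "canonical_full" (baseline PVS1) or "canonical_reduced"; relation is the
# comparator position relative to the VUA.
ps1_oracle_table <- function() {
  rbind(
    data.frame(vua = "noncanonical", relation = "same_nucleotide",
               cls = c("PATHOGENIC", "LIKELY_PATHOGENIC"),
               expected = c("Strong", "Moderate")),
    data.frame(vua = "noncanonical", relation = "same_motif_noncanonical",
               cls = c("PATHOGENIC", "LIKELY_PATHOGENIC"),
               expected = c("Moderate", "Supporting")),
    data.frame(vua = "noncanonical", relation = "same_motif_canonical",
               cls = c("PATHOGENIC", "LIKELY_PATHOGENIC"),
               expected = c("Moderate", "Supporting")),   # LP needs clinical support
    data.frame(vua = "canonical_full", relation = "same_canonical",
               cls = c("PATHOGENIC", "LIKELY_PATHOGENIC"),
               expected = c("Supporting", NA)),
    data.frame(vua = "canonical_full", relation = "same_motif_noncanonical",
               cls = c("PATHOGENIC", "LIKELY_PATHOGENIC"),
               expected = c("Supporting", "Supporting")),
    data.frame(vua = "canonical_reduced", relation = "same_canonical",
               cls = c("PATHOGENIC", "LIKELY_PATHOGENIC"),
               expected = c("Strong", NA)),
    data.frame(vua = "canonical_reduced", relation = "same_motif_noncanonical",
               cls = c("PATHOGENIC", "LIKELY_PATHOGENIC"),
               expected = c("Moderate", "Supporting")))
}

# build assign_ps1 inputs for one oracle-table row
ps1_case <- function(vua, relation, cls, clinical_support = TRUE,
                     vua_score = 0.9, comp_score = 0.9) {
  ev <- splice_event("EXON_SKIP", 2L, frame = "OUT_OF_FRAME",
                     nmd_predicted = TRUE)
  vua_region <- if (vua == "noncanonical")
    region_class("STANDARD_SPLICE_REGION", "DONOR", 5L, FALSE)
  else region_class("CANONICAL_DINUCLEOTIDE", "DONOR", 1L, FALSE)
  comp_region <- if (relation %in% c("same_canonical"))
    region_class("CANONICAL_DINUCLEOTIDE", "DONOR", 2L, FALSE)
  else if (relation == "same_motif_canonical")
    region_class("CANONICAL_DINUCLEOTIDE", "DONOR", 1L, FALSE)
  else if (relation == "same_nucleotide")
    region_class("STANDARD_SPLICE_REGION", "DONOR", 5L, FALSE)
  else region_class("STANDARD_SPLICE_REGION", "DONOR", 4L, FALSE)
  cmp <- comparator_variant(
    "cmp", cls, comp_region, ev, comp_score,
    same_nucleotide_as_vua = relation == "same_nucleotide",
    same_motif_as_vua = relation != "unrelated",
    clinical_support_flag = clinical_support)
  baseline <- if (vua == "canonical_full")
    assign_pvs1(ev, gene_context())           # OOF + NMD -> full PVS1
  else if (vua == "canonical_reduced")
    assign_pvs1(splice_event("EXON_SKIP", 2L, frame = "IN_FRAME",
                             fraction_protein_removed = 0.05),
                gene_context())               # -> PVS1_Moderate
  else NULL
  assign_ps1(vua_region, ev, vua_score, cmp, vua_pvs1 = baseline)
}

write_tsv <- function(d, path) {
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}
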