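.pvs1_levels <- c("PVS1_NA", "PVS1_Supporting", "PVS1_Moderate",
                  "PVS1_Strong", "PVS1")

.pvs1_demote <- function(strength, steps = 1L) {
  i <- match(strength, .pvs1_levels)
  .pvs1_levels[max(1L, i - steps)]
}

.event_types <- c("EXON_SKIP", "CRYPTIC_DONOR", "CRYPTIC_ACCEPTOR",
                  "INTRON_RETENTION", "MULTI_EXON_SKIP", "NO_IMPACT")

#' Predicted (or observed) splicing event
#'
#' Describes the transcript-level consequence of a variant: the aberration
#' type, the exons involved, whether the reading frame is preserved, whether
#' a premature termination codon is expected to trigger nonsense-mediated
#' decay, and how much of the protein the event removes.
#'
#' @param event_type One of `"EXON_SKIP"`, `"CRYPTIC_DONOR"`,
#'   `"CRYPTIC_ACCEPTOR"`, `"INTRON_RETENTION"`, `"MULTI_EXON_SKIP"`,
#'   `"NO_IMPACT"`.
#' @param affected_exons Integer indices of the exons involved.
#' @param frame `"IN_FRAME"` or `"OUT_OF_FRAME"`.
#' @param nmd_predicted Whether the resulting transcript is predicted to be
#'   degraded by nonsense-mediated decay (conventionally, a premature stop
#'   more than 50 nt upstream of the last exon-exon junction).
#' @param fraction_protein_removed Proportion of the protein removed or
#'   altered by the event, in `[0, 1]`.
#' @param removes_critical_region Whether the removed/altered region is
#'   critical to protein function.
#' @param cryptic_site_offset Optional signed offset of a cryptic site
#'   relative to the native boundary; used for exact event matching.
#' @param critical_domain Optional name of the affected critical domain in
#'   the gene context.
#' @param utr_only Whether the splicing outcome is confined to untranslated
#'   regions.
#' @param start_loss Whether the event removes the translation start.
#' @return An object of class `splice_event`.
#' @export
splice_event <- function(event_type,
                         affected_exons = integer(),
                         frame = c("IN_FRAME", "OUT_OF_FRAME"),
                         nmd_predicted = FALSE,
                         fraction_protein_removed = 0,
                         removes_critical_region = FALSE,
                         cryptic_site_offset = NULL,
                         critical_domain = NA_character_,
                         utr_only = FALSE,
                         start_loss = FALSE) {
  event_type <- match.arg(event_type, .event_types)
  frame <- match.arg(frame)
  if (fraction_protein_removed < 0 || fraction_protein_removed > 1)
    stop("fraction_protein_removed must be in [0, 1]")
  structure(list(event_type = event_type,
                 affected_exons = as.integer(affected_exons),
                 frame = frame,
                 nmd_predicted = isTRUE(nmd_predicted),
                 fraction_protein_removed = fraction_protein_removed,
                 removes_critical_region = isTRUE(removes_critical_region),
                 cryptic_site_offset =
                   if (is.null(cryptic_site_offset)) NULL
                   else as.integer(cryptic_site_offset),
                 critical_domain = as.character(critical_domain),
                 utr_only = isTRUE(utr_only),
                 start_loss = isTRUE(start_loss)),
            class = "splice_event")
}

#' Gene-specific interpretation context
#'
#' Everything gene-specific the PVS1 decision tree needs: whether loss of
#' function is an established disease mechanism (informed by resources such
#' as the ClinGen haploinsufficiency score, pLI or LOEUF), a map of critical
#' protein domains and whether Pathogenic missense variants have been
#' reported in them, naturally occurring candidate rescue transcripts, and
#' the operational thresholds.
#'
#' @param gene Gene symbol (metadata).
#' @param lof_mechanism_established Whether LoF is an established disease
#'   mechanism; the PVS1 tree is not applicable otherwise.
#' @param critical_domains Data frame with columns `domain`, and
#'   `pathogenic_missense` (logical: a Pathogenic missense variant is known
#'   in that domain); optional columns `cds_start`, `cds_end`.
#' @param rescue_transcripts Data frame with columns `transcript_id`,
#'   `skips_exons` (comma-separated exon indices), `expression_fraction`
#'   and `encodes_functional_protein`.
#' @param protein_size_threshold Fraction of protein above which an in-frame
#'   removal is weighted Strong regardless of criticality (operational
#'   default 0.10).
#' @param rescue_expression_threshold Minimum fraction of overall gene
#'   expression for a rescue transcript to be plausible (operational
#'   default 0.10).
#' @param start_loss_upweight Upweight the start-loss branch one level based
#'   on the frame/location of alternative start sites and Pathogenic
#'   variants between the native and alternative starts.
#' @param utr_critical_element UTR regions contain elements proven critical
#'   for function/expression, so UTR-confined outcomes are still scored.
#' @param complementary_site_pathogenic_exons Exon indices whose
#'   complementary splice site (the other end of the same exon) carries a
#'   Pathogenic variant with the same predicted outcome.
#' @return An object of class `gene_context`.
#' @export
gene_context <- function(gene = NA_character_,
                         lof_mechanism_established = TRUE,
                         critical_domains = NULL,
                         rescue_transcripts = NULL,
                         protein_size_threshold = 0.10,
                         rescue_expression_threshold = 0.10,
                         start_loss_upweight = FALSE,
                         utr_critical_element = FALSE,
                         complementary_site_pathogenic_exons = integer()) {
  if (protein_size_threshold <= 0 || protein_size_threshold >= 1)
    stop("protein_size_threshold must be in (0, 1)")
  if (rescue_expression_threshold <= 0 || rescue_expression_threshold >= 1)
    stop("rescue_expression_threshold must be in (0, 1)")
  if (!is.null(critical_domains)) {
    if (!all(c("domain", "pathogenic_missense") %in% names(critical_domains)))
      stop("critical_domains needs columns 'domain' and 'pathogenic_missense'")
  }
  if (!is.null(rescue_transcripts)) {
    need <- c("transcript_id", "skips_exons", "expression_fraction",
              "encodes_functional_protein")
    miss <- setdiff(need, names(rescue_transcripts))
    if (length(miss))
      stop("rescue_transcripts missing column(s): ",
           paste(miss, collapse = ", "))
    ef <- rescue_transcripts$expression_fraction
    if (any(ef < 0 | ef > 1)) stop("expression_fraction must be in [0, 1]")
  }
  structure(list(gene = gene,
                 lof_mechanism_established = isTRUE(lof_mechanism_established),
                 critical_domains = critical_domains,
                 rescue_transcripts = rescue_transcripts,
                 protein_size_threshold = protein_size_threshold,
                 rescue_expression_threshold = rescue_expression_threshold,
                 start_loss_upweight = isTRUE(start_loss_upweight),
                 utr_critical_element = isTRUE(utr_critical_element),
                 complementary_site_pathogenic_exons =
                   as.integer(complementary_site_pathogenic_exons)),
            class = "gene_context")
}

.pvs1_result <- function(strength, rationale, rna_based = FALSE,
                         per_transcript = NULL, flags = character()) {
  structure(list(strength = strength, rna_based = isTRUE(rna_based),
                 rationale = rationale, per_transcript = per_transcript,
                 flags = flags),
            class = "pvs1_result")
}

#' @export
print.pvs1_result <- function(x, ...) {
  cat(sprintf("%s%s%s\n  path: %s\n", x$strength,
              if (x$rna_based) " (RNA)" else "",
              if (length(x$flags)) paste0(" [", paste(x$flags, collapse = ","), "]") else "",
              paste(x$rationale, collapse = " > ")))
  invisible(x)
}

# upgrade evidence per the splicing-specific tree modifications: Pathogenic
# missense in the removed critical domain, or Pathogenic variation at the
# complementary splice site of the same exon
.pvs1_upgrade_evidence <- function(pred, ctx) {
  dom <- FALSE
  if (!is.null(ctx$critical_domains) && nrow(ctx$critical_domains)) {
    cd <- ctx$critical_domains
    dom <- if (!is.na(pred$critical_domain))
      any(cd$pathogenic_missense[cd$domain == pred$critical_domain])
    else any(cd$pathogenic_missense)
  }
  comp <- length(pred$affected_exons) > 0 &&
    any(pred$affected_exons %in% ctx$complementary_site_pathogenic_exons)
  list(any = dom || comp, domain = dom, complementary = comp)
}

.find_rescue <- function(pred, ctx) {
  rt <- ctx$rescue_transcripts
  if (is.null(rt) || nrow(rt) == 0 || length(pred$affected_exons) == 0)
    return(NULL)
  for (i in seq_len(nrow(rt))) {
    skipped <- as.integer(strsplit(as.character(rt$skips_exons[i]), ",")[[1]])
    if (all(pred$affected_exons %in% skipped) &&
        isTRUE(as.logical(rt$encodes_functional_protein[i])) &&
        rt$expression_fraction[i] >= ctx$rescue_expression_threshold)
      return(rt$transcript_id[i])
  }
  NULL
}

#' Gene-configurable PVS1 decision tree for splicing events
#'
#' Assigns a PVS1 strength to a predicted or observed splicing event in a
#' gene with an established loss-of-function mechanism. The tree follows the
#' LoF decision-tree logic with splicing-specific modifications: events with
#' no predicted impact and UTR-confined outcomes are PVS1_N/A (unless a
#' critical UTR element is flagged); a plausible naturally occurring rescue
#' transcript (skipping the same exons, encoding a functional protein, at or
#' above the expression threshold) yields PVS1_N/A; out-of-frame events
#' subject to nonsense-mediated decay get full PVS1; in-frame (or
#' NMD-escaping) events are weighted Strong when they remove a critical
#' region or more than the protein-size threshold, Moderate otherwise, and
#' are upweighted to full PVS1 when a Pathogenic missense variant lies in
#' the removed domain or the complementary splice site of the same exon
#' carries Pathogenic variation; start-loss events are Moderate, with an
#' optional context-driven upweight to Strong.
#'
#' @param pred A [splice_event()].
#' @param ctx A [gene_context()]; `lof_mechanism_established` must be `TRUE`
#'   or an error of class `splicecodes_not_applicable` (pointing to PM4) is
#'   raised.
#' @param region Optional `region_class` of the variant, recorded in the
#'   rationale.
#' @return An object of class `pvs1_result` with `strength` in
#'   `"PVS1"`, `"PVS1_Strong"`, `"PVS1_Moderate"`, `"PVS1_Supporting"`,
#'   `"PVS1_NA"`, plus the ordered `rationale` path.
#' @export
assign_pvs1 <- function(pred, ctx, region = NULL) {
  stopifnot(inherits(pred, "splice_event"), inherits(ctx, "gene_context"))
  if (!ctx$lof_mechanism_established)
    stop(structure(class = c("splicecodes_not_applicable", "error",
                             "condition"),
                   list(message = paste("LoF is not an established disease",
                                        "mechanism for this gene: PVS1 not",
                                        "applicable; we recommend use of the",
                                        "PM4 code for in-frame consequences"),
                        call = sys.call(-1))))
  path <- "lof_mechanism_established"
  if (!is.null(region))
    path <- c(path, paste0("region:", region$category))

  if (pred$event_type == "NO_IMPACT")
    return(.pvs1_result("PVS1_NA", c(path, "no_predicted_splicing_impact")))

  if (pred$utr_only) {
    if (!ctx$utr_critical_element)
      return(.pvs1_result("PVS1_NA", c(path, "utr_confined_outcome")))
    path <- c(path, "utr_outcome_with_critical_element")
  }

  if (pred$start_loss) {
    path <- c(path, "start_loss")
    if (ctx$start_loss_upweight)
      return(.pvs1_result("PVS1_Strong",
                          c(path, "alternative_start_context_upweight")))
    return(.pvs1_result("PVS1_Moderate", path))
  }

  rescue <- .find_rescue(pred, ctx)
  if (!is.null(rescue))
    return(.pvs1_result("PVS1_NA",
                        c(path, paste0("plausible_rescue_transcript:", rescue))))

  up <- .pvs1_upgrade_evidence(pred, ctx)
  trunc_branch <- function(path) {
    if (pred$removes_critical_region) {
      path <- c(path, "removes_critical_region")
      if (up$any) {
        lab <- if (up$domain) "pathogenic_missense_in_removed_domain"
        else "complementary_site_pathogenic"
        return(.pvs1_result("PVS1", c(path, lab, "upweighted_to_PVS1")))
      }
      return(.pvs1_result("PVS1_Strong", path))
    }
    if (pred$fraction_protein_removed > ctx$protein_size_threshold)
      return(.pvs1_result("PVS1_Strong",
                          c(path, sprintf("removes_>%.0f%%_of_protein",
                                          100 * ctx$protein_size_threshold))))
    .pvs1_result("PVS1_Moderate",
                 c(path, sprintf("removes_<=%.0f%%_of_protein_noncritical",
                                 100 * ctx$protein_size_threshold)))
  }

  if (pred$frame == "OUT_OF_FRAME") {
    path <- c(path, "out_of_frame")
    if (pred$nmd_predicted)
      return(.pvs1_result("PVS1", c(path, "nmd_predicted")))
    trunc_branch(c(path, "nmd_escape"))
  } else {
    trunc_branch(c(path, "in_frame"))
  }
}

#' Operational thresholds for splicing assay interpretation
#'
#' @param complete_fraction Minimum fraction of variant-allele expression
#'   carried by aberrant transcripts for a read-out to count as
#'   complete/near-complete (operational default 0.90; should be refined in
#'   a disease- and gene-specific manner).
#' @return An object of class `assay_thresholds`.
#' @export
assay_thresholds <- function(complete_fraction = 0.90) {
  if (complete_fraction <= 0 || complete_fraction > 1)
    stop("complete_fraction must be in (0, 1]")
  structure(list(complete_fraction = complete_fraction),
            class = "assay_thresholds")
}

#' Splicing assay read-out
#'
#' Per-transcript quantification of a splicing assay: each aberrant
#' transcript is described like a [splice_event()] plus its fraction of
#' variant-allele expression. Fractions sum to at most 1; the remainder is
#' full-length transcript.
#'
#' @param transcripts Data frame with columns `event_type`, `frame`,
#'   `nmd_predicted`, `fraction_protein_removed`, `removes_critical_region`,
#'   `aberrant_fraction`, and optionally `affected_exons` (comma-separated),
#'   `allele_specific`, `transcript_desc`.
#' @param source `"patient_rna"`, `"minigene"`, `"mpra"` or `"other"`.
#' @param controls_matched_tissue Whether control samples came from matched
#'   tissue.
#' @param psi Optional percent-spliced-in value for the aberrant event.
#' @return An object of class `assay_readout`.
#' @export
assay_readout <- function(transcripts,
                          source = c("patient_rna", "minigene", "mpra",
                                     "other"),
                          controls_matched_tissue = TRUE, psi = NULL) {
  source <- match.arg(source)
  if (is.null(transcripts))
    transcripts <- data.frame(event_type = character(),
                              aberrant_fraction = numeric())
  if (nrow(transcripts) > 0) {
    need <- c("event_type", "aberrant_fraction")
    miss <- setdiff(need, names(transcripts))
    if (length(miss))
      stop("assay transcripts missing column(s): ",
           paste(miss, collapse = ", "))
    if (sum(transcripts$aberrant_fraction) > 1 + 1e-6)
      stop("aberrant fractions must sum to <= 1")
    if (any(transcripts$aberrant_fraction < 0))
      stop("aberrant fractions must be non-negative")
  }
  if (!is.null(psi) && (psi < 0 || psi > 1)) stop("psi must be in [0, 1]")
  structure(list(transcripts = transcripts, source = source,
                 controls_matched_tissue = isTRUE(controls_matched_tissue),
                 psi = psi),
            class = "assay_readout")
}

.row_to_event <- function(row) {
  splice_event(
    event_type = as.character(row$event_type),
    affected_exons = if (!is.null(row$affected_exons) &&
                         !is.na(row$affected_exons) &&
                         nzchar(as.character(row$affected_exons)))
      as.integer(strsplit(as.character(row$affected_exons), ",")[[1]])
    else integer(),
    frame = if (!is.null(row$frame)) as.character(row$frame) else "IN_FRAME",
    nmd_predicted = isTRUE(as.logical(row$nmd_predicted)),
    fraction_protein_removed =
      if (!is.null(row$fraction_protein_removed) &&
          !is.na(row$fraction_protein_removed))
        as.numeric(row$fraction_protein_removed) else 0,
    removes_critical_region = isTRUE(as.logical(row$removes_critical_region))
  )
}

#' Pool a complex assay read-out into one overall PVS1 strength
#'
#' For read-outs with two or more aberrant transcripts from the same allele:
#' each transcript has already been assigned its own PVS1 strength; the pool
#' groups transcripts by strength and walks from the strongest group down,
#' accumulating expression contribution, until the cumulative aberrant
#' contribution reaches the complete/near-complete threshold — that group's
#' strength is the conservative overall strength. If the residual
#' full-length contribution alone exceeds one minus the threshold, the
#' read-out is leaky: the pooled strength (over the aberrant transcripts,
#' renormalised) is demoted one level and flagged `LEAKY`.
#'
#' @param per_transcript A list of `list(result = <pvs1_result>,
#'   contribution = <fraction>)`.
#' @param thresholds An [assay_thresholds()].
#' @param full_length Residual full-length contribution; defaults to one
#'   minus the summed contributions.
#' @return A `pvs1_result` with `per_transcript` detail.
#' @export
pool_complex_readout <- function(per_transcript,
                                 thresholds = assay_thresholds(),
                                 full_length = NULL) {
  if (length(per_transcript) == 0)
    stop("per_transcript must contain at least one transcript")
  contrib <- vapply(per_transcript, function(x) x$contribution, numeric(1))
  if (any(contrib < 0)) stop("contributions must be non-negative")
  if (is.null(full_length)) full_length <- max(0, 1 - sum(contrib))
  if (sum(contrib) + full_length > 1 + 1e-6)
    stop("contributions (including full-length) must sum to <= 1")
  strengths <- vapply(per_transcript, function(x) x$result$strength,
                      character(1))
  detail <- data.frame(strength = strengths, contribution = contrib)

  leaky <- full_length > 1 - thresholds$complete_fraction
  # walk strength groups strongest-first until the cumulative contribution
  # (renormalised to the aberrant total when leaky) reaches the threshold
  denom_contrib <- if (leaky) contrib / sum(contrib) else contrib
  ord <- order(-match(strengths, .pvs1_levels))
  cum <- 0
  overall <- strengths[ord[1]]
  for (i in ord) {
    cum <- cum + denom_contrib[i]
    overall <- strengths[i]
    if (cum >= thresholds$complete_fraction - 1e-9) break
  }
  flags <- character()
  rationale <- c("pooled_complex_readout",
                 sprintf("aberrant_total=%.2f_full_length=%.2f",
                         sum(contrib), full_length))
  if (leaky) {
    overall <- .pvs1_demote(overall)
    flags <- "LEAKY"
    rationale <- c(rationale, "leaky_readout_downgraded_one_level")
  }
  .pvs1_result(overall, rationale, rna_based = TRUE,
               per_transcript = detail, flags = flags)
}

#' Interpret a splicing assay read-out as RNA-based evidence
#'
#' A read-out showing aberrant transcripts is evaluated per transcript
#' through the PVS1 decision tree and pooled ([pool_complex_readout()]),
#' returning an RNA-based `pvs1_result` that supersedes any predictive
#' PP3/BP4 code (the replacement itself is bookkept by [combine_codes()]).
#' Variants observed to produce the exact same aberration (type and level)
#' therefore receive the same experimentally derived weight irrespective of
#' their position. A read-out showing no aberration relative to matched
#' controls returns a BP7_Strong(RNA) signal instead. Incomplete ("leaky")
#' read-outs are demoted one level and flagged; evidence from construct
#' systems alone (minigene/MPRA) or with unmatched-tissue controls is capped
#' one level below full weight and flagged low-confidence.
#'
#' @param readout An [assay_readout()].
#' @param ctx A [gene_context()].
#' @param thresholds An [assay_thresholds()].
#' @param baseline Optional predictive `pvs1_result` being replaced
#'   (recorded in the rationale).
#' @return A `pvs1_result` (aberration observed) or an object of class
#'   `bp7_rna_signal` (no impact observed).
#' @export
apply_rna_evidence <- function(readout, ctx,
                               thresholds = assay_thresholds(),
                               baseline = NULL) {
  stopifnot(inherits(readout, "assay_readout"))
  construct_only <- readout$source != "patient_rna" ||
    !readout$controls_matched_tissue
  tr <- readout$transcripts
  aberrant <- if (nrow(tr)) tr[tr$aberrant_fraction > 0, , drop = FALSE]
  else tr

  if (nrow(aberrant) == 0) {
    strength <- if (construct_only) "Supporting" else "Strong"
    return(structure(list(
      code = "BP7", strength = strength, rna_based = TRUE,
      low_confidence = construct_only,
      rationale = c("assay_shows_no_aberrant_splicing",
                    if (construct_only) "construct_data_capped_one_level")),
      class = "bp7_rna_signal"))
  }

  per <- lapply(seq_len(nrow(aberrant)), function(i) {
    ev <- .row_to_event(aberrant[i, , drop = FALSE])
    list(result = assign_pvs1(ev, ctx),
         contribution = aberrant$aberrant_fraction[i])
  })
  pooled <- pool_complex_readout(per, thresholds = thresholds)
  rationale <- c(sprintf("assay_source:%s", readout$source),
                 pooled$rationale)
  if (!is.null(baseline))
    rationale <- c(rationale,
                   sprintf("replaces_predictive:%s", baseline$strength))
  strength <- pooled$strength
  flags <- pooled$flags
  if (construct_only && strength != "PVS1_NA") {
    strength <- .pvs1_demote(strength)
    flags <- c(flags, "CONSTRUCT_CAPPED")
    rationale <- c(rationale, "construct_data_capped_one_level")
  }
  .pvs1_result(strength, rationale, rna_based = TRUE,
               per_transcript = pooled$per_transcript, flags = flags)
}
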