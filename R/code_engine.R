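#' SpliceAI delta scores for one variant allele
#'
#' Holds the four delta scores (acceptor/donor gain and loss) and optional
#' positions, and derives the maximum delta — the maximum probability of
#' altered splicing across the four outputs — which drives PP3/BP4.
#'
#' @param ds_ag,ds_al,ds_dg,ds_dl Delta scores in `[0, 1]` (NA allowed for
#'   missing annotations).
#' @param dp_ag,dp_al,dp_dg,dp_dl Optional positions relative to the
#'   variant.
#' @return An object of class `spliceai_scores` with element `max_delta`.
#' @export
spliceai_scores <- function(ds_ag, ds_al, ds_dg, ds_dl,
                            dp_ag = NA_integer_, dp_al = NA_integer_,
                            dp_dg = NA_integer_, dp_dl = NA_integer_) {
  ds <- c(ds_ag = ds_ag, ds_al = ds_al, ds_dg = ds_dg, ds_dl = ds_dl)
  if (any(!is.na(ds) & (ds < 0 | ds > 1)))
    stop("delta scores must lie in [0, 1]")
  structure(list(ds_ag = ds_ag, ds_al = ds_al, ds_dg = ds_dg, ds_dl = ds_dl,
                 dp_ag = dp_ag, dp_al = dp_al, dp_dg = dp_dg, dp_dl = dp_dl,
                 max_delta = if (all(is.na(ds))) NA_real_
                 else max(ds, na.rm = TRUE)),
            class = "spliceai_scores")
}

#' Comparator variant for the splicing PS1 code
#'
#' A previously classified (Likely) Pathogenic variant whose predicted
#' splicing event is compared against the variant under assessment (VUA).
#'
#' @param variant_key Identifier of the comparator.
#' @param classification `"PATHOGENIC"` or `"LIKELY_PATHOGENIC"`.
#' @param region `region_class` of the comparator on the curation
#'   transcript.
#' @param predicted_event A [splice_event()].
#' @param prediction_strength Prediction score (e.g. SpliceAI max delta) for
#'   the comparator.
#' @param same_nucleotide_as_vua Comparator affects the same nucleotide as
#'   the VUA.
#' @param same_motif_as_vua Comparator lies within the same donor or
#'   acceptor motif as the VUA.
#' @param clinical_support_flag For Likely Pathogenic comparators at
#'   canonical positions: additional supporting clinical evidence exists.
#' @return An object of class `comparator_variant`.
#' @export
comparator_variant <- function(variant_key, classification, region,
                               predicted_event, prediction_strength,
                               same_nucleotide_as_vua = FALSE,
                               same_motif_as_vua = FALSE,
                               clinical_support_flag = FALSE) {
  classification <- match.arg(classification,
                              c("PATHOGENIC", "LIKELY_PATHOGENIC"))
  stopifnot(inherits(region, "region_class"),
            inherits(predicted_event, "splice_event"))
  structure(list(variant_key = variant_key,
                 classification = classification, region = region,
                 predicted_event = predicted_event,
                 prediction_strength = as.numeric(prediction_strength),
                 same_nucleotide_as_vua = isTRUE(same_nucleotide_as_vua),
                 same_motif_as_vua = isTRUE(same_motif_as_vua),
                 clinical_support_flag = isTRUE(clinical_support_flag)),
            class = "comparator_variant")
}

#' Assign the PP3/BP4 computational splicing codes
#'
#' For variants outside the canonical dinucleotides (canonical sites are
#' handled by the PVS1 decision path): a maximum delta score at or above
#' `high_cut` supports impact on splicing (PP3), at or below `low_cut`
#' supports no impact (BP4), and the band in between is uninformative —
#' neither code is met. Although the default cut-offs calibrate to a
#' moderate level of evidence, the codes are conservatively applied at
#' supporting weight by default.
#'
#' @param scores A [spliceai_scores()].
#' @param low_cut,high_cut Calibrated score cut-offs.
#' @param applied_weight `"supporting"` (default, conservative) or
#'   `"moderate"`.
#' @return A list with `code` (`"PP3"`, `"BP4"` or `NULL`), `strength` and
#'   `reason`.
#' @export
assign_pp3_bp4 <- function(scores, low_cut = 0.1, high_cut = 0.2,
                           applied_weight = c("supporting", "moderate")) {
  applied_weight <- match.arg(applied_weight)
  strength <- if (applied_weight == "supporting") "Supporting" else "Moderate"
  md <- if (inherits(scores, "spliceai_scores")) scores$max_delta
  else as.numeric(scores)
  if (is.null(md) || length(md) == 0 || is.na(md))
    return(list(code = NULL, strength = NULL,
                reason = "prediction scores missing"))
  if (md >= high_cut)
    list(code = "PP3", strength = strength,
         reason = sprintf("max delta %.3g >= %.3g", md, high_cut))
  else if (md <= low_cut)
    list(code = "BP4", strength = strength,
         reason = sprintf("max delta %.3g <= %.3g", md, low_cut))
  else
    list(code = NULL, strength = NULL,
         reason = sprintf("max delta %.3g in uninformative band", md))
}

#' Assign the computational BP7 code
#'
#' BP7 applies only when BP4 is met and the position is eligible
#' ([bp7_position_eligible()]). Evolutionary conservation is deliberately
#' not an input.
#'
#' @param bp4_met Whether BP4 was assigned.
#' @param position_eligible Result of [bp7_position_eligible()].
#' @return A list with `code` (`"BP7"` or `NULL`), `strength`, `reason`.
#' @export
assign_bp7 <- function(bp4_met, position_eligible) {
  if (isTRUE(bp4_met) && isTRUE(position_eligible))
    list(code = "BP7", strength = "Supporting",
         reason = "BP4 met and position outside designated splice region")
  else if (!isTRUE(bp4_met))
    list(code = NULL, strength = NULL, reason = "BP4 not met")
  else
    list(code = NULL, strength = NULL,
         reason = "position within designated splice region")
}

# weight matrix for the splicing PS1 adaptation; NULL = not applicable
.ps1_matrix <- function(vua_canonical, baseline_full, relation,
                        classification) {
  P <- classification == "PATHOGENIC"
  if (!vua_canonical) {
    switch(relation,
           same_nucleotide = if (P) "Strong" else "Moderate",
           same_motif = if (P) "Moderate" else "Supporting",
           NULL)
  } else {
    switch(relation,
           same_canonical =
             if (!P) NULL else if (baseline_full) "Supporting" else "Strong",
           same_motif =
             if (baseline_full) "Supporting"
             else if (P) "Moderate" else "Supporting",
           NULL)
  }
}

#' Assign the splicing adaptation of the PS1 code
#'
#' Transfers evidence from a previously classified (Likely) Pathogenic
#' variant to a variant under assessment (VUA) with the *same predicted
#' splicing event*. Prerequisites: the predicted events match exactly (type,
#' affected exons, cryptic-site position) and the VUA's prediction is of
#' similar or higher strength (within `tolerance`) than the comparator's.
#' The code weight then depends on the relative positions: for a VUA outside
#' the canonical dinucleotide, a Pathogenic comparator at the same
#' nucleotide gives full PS1 (Moderate for Likely Pathogenic), and a
#' comparator elsewhere in the same motif gives Moderate (Supporting for
#' LP). For a VUA at the canonical dinucleotide the weight additionally
#' depends on its baseline PVS1 strength, preventing the VUA from
#' out-weighting the comparator it borrows from; Likely Pathogenic
#' comparators within the same canonical dinucleotide are not usable, and
#' Likely Pathogenic comparators at canonical positions require additional
#' supporting clinical evidence (`clinical_support_flag`).
#'
#' @param vua_region `region_class` of the VUA.
#' @param vua_event The VUA's predicted [splice_event()].
#' @param vua_score The VUA's prediction score (max delta).
#' @param comparator A [comparator_variant()].
#' @param vua_pvs1 The VUA's baseline `pvs1_result` (required when the VUA
#'   is canonical).
#' @param tolerance Allowed prediction-strength shortfall of the VUA
#'   relative to the comparator.
#' @return A list with `code` (`"PS1"` or `NULL`), `strength` (`"Strong"`,
#'   `"Moderate"`, `"Supporting"`) and `reason`.
#' @export
assign_ps1 <- function(vua_region, vua_event, vua_score, comparator,
                       vua_pvs1 = NULL, tolerance = 0.05) {
  stopifnot(inherits(vua_region, "region_class"),
            inherits(comparator, "comparator_variant"))
  none <- function(reason) list(code = NULL, strength = NULL, reason = reason)

  if (!.events_match(vua_event, comparator$predicted_event))
    return(none("predicted events do not match"))
  if (is.na(vua_score) ||
      vua_score < comparator$prediction_strength - tolerance)
    return(none("VUA prediction weaker than comparator beyond tolerance"))

  vua_canonical <- vua_region$category == "CANONICAL_DINUCLEOTIDE"
  comp_canonical <- comparator$region$category == "CANONICAL_DINUCLEOTIDE"

  relation <- if (vua_canonical) {
    if (comp_canonical &&
        (comparator$same_motif_as_vua || comparator$same_nucleotide_as_vua))
      "same_canonical"
    else if (comparator$same_motif_as_vua) "same_motif"
    else "unrelated"
  } else {
    if (comparator$same_nucleotide_as_vua) "same_nucleotide"
    else if (comparator$same_motif_as_vua) "same_motif"
    else "unrelated"
  }
  if (relation == "unrelated")
    return(none("comparator not within the same splice motif"))

  LP <- comparator$classification == "LIKELY_PATHOGENIC"
  if (LP && comp_canonical && relation == "same_motif" &&
      !comparator$clinical_support_flag)
    return(none(paste("Likely Pathogenic canonical comparator requires",
                      "additional supporting clinical evidence")))

  baseline_full <- FALSE
  if (vua_canonical) {
    if (is.null(vua_pvs1))
      stop("a canonical VUA requires its baseline PVS1 result")
    baseline_full <- vua_pvs1$strength == "PVS1"
  }
  strength <- .ps1_matrix(vua_canonical, baseline_full, relation,
                          comparator$classification)
  if (is.null(strength))
    return(none(paste("not applicable for a Likely Pathogenic comparator",
                      "within the same canonical dinucleotide")))
  list(code = "PS1", strength = strength,
       reason = sprintf("matching event; comparator %s, %s",
                        comparator$classification, relation))
}

.events_match <- function(e1, e2) {
  if (!identical(e1$event_type, e2$event_type)) return(FALSE)
  if (!setequal(e1$affected_exons, e2$affected_exons)) return(FALSE)
  c1 <- e1$cryptic_site_offset; c2 <- e2$cryptic_site_offset
  if (is.null(c1) != is.null(c2)) return(FALSE)
  if (!is.null(c1) && !identical(as.integer(c1), as.integer(c2)))
    return(FALSE)
  TRUE
}

.code_set <- function(assigned, suppressed, record_only) {
  empty_a <- data.frame(code = character(), strength = character(),
                        rna = logical(), rationale = character())
  empty_s <- data.frame(code = character(), reason = character())
  empty_r <- data.frame(note = character())
  structure(list(assigned = if (nrow(assigned)) assigned else empty_a,
                 suppressed = if (nrow(suppressed)) suppressed else empty_s,
                 record_only = if (nrow(record_only)) record_only else empty_r),
            class = "code_set")
}

#' @export
print.code_set <- function(x, ...) {
  if (nrow(x$assigned)) {
    cat("assigned:\n")
    for (i in seq_len(nrow(x$assigned)))
      cat(sprintf("  %s_%s%s  (%s)\n", x$assigned$code[i],
                  x$assigned$strength[i],
                  if (x$assigned$rna[i]) " (RNA)" else "",
                  x$assigned$rationale[i]))
  } else cat("assigned: none\n")
  if (nrow(x$suppressed)) {
    cat("suppressed:\n")
    for (i in seq_len(nrow(x$suppressed)))
      cat(sprintf("  %s: %s\n", x$suppressed$code[i], x$suppressed$reason[i]))
  }
  if (nrow(x$record_only)) {
    cat("record only:\n")
    for (n in x$record_only$note) cat("  ", n, "\n")
  }
  invisible(x)
}

#' Check the mutual-exclusion invariants of a code set
#'
#' PP3 is never co-assigned with any PVS1 strength; BP4 and PP3 are mutually
#' exclusive; computational BP7 requires BP4; PS3/BS3 are never assigned for
#' splicing-only evidence.
#'
#' @param cs A `code_set`.
#' @return `TRUE` invisibly, or an error describing the violated invariant.
#' @export
validate_code_set <- function(cs) {
  stopifnot(inherits(cs, "code_set"))
  a <- cs$assigned
  has <- function(code) code %in% a$code
  if (has("PP3") && has("PVS1"))
    stop("invariant violated: PP3 co-assigned with PVS1")
  if (has("PP3") && has("BP4"))
    stop("invariant violated: PP3 co-assigned with BP4")
  if (has("PS3") || has("BS3"))
    stop("invariant violated: PS3/BS3 assigned for splicing evidence")
  if (has("BP7") && !any(a$code == "BP7" & a$rna) && !has("BP4"))
    stop("invariant violated: computational BP7 without BP4")
  invisible(TRUE)
}

#' Combine splicing-related ACMG/AMP codes for one variant
#'
#' Applies the overall decision scheme: canonical-dinucleotide variants
#' follow the PVS1 path only (no PP3/BP4); RNA-assay evidence of an
#' interpretable aberration yields an RNA-based PVS1 strength that replaces
#' PP3/BP4; RNA evidence of no splicing impact yields BP7_Strong(RNA) for
#' intronic and synonymous variants, while for missense/in-frame variants
#' the splicing result is only recorded unless protein-level functional
#' impact has also been excluded; the computational BP7 rides on BP4 plus
#' positional eligibility; PS3/BS3 are suppressed whenever the evidence is
#' splicing-based. Contradictory RNA inputs raise an error and no codes are
#' emitted.
#'
#' @param region `region_class` of the variant on the curation transcript.
#' @param consequence One of `"intronic"`, `"synonymous"`, `"missense"`,
#'   `"inframe_indel"`, `"nonsense"`, `"other"`.
#' @param scores Optional [spliceai_scores()].
#' @param pvs1 Optional baseline (predictive) `pvs1_result` for canonical
#'   variants.
#' @param rna Optional result of [apply_rna_evidence()]: a `pvs1_result`
#'   or a `bp7_rna_signal`. Supplying both raises a conflict error.
#' @param ps1 Optional result of [assign_ps1()].
#' @param protein_functional_impact_excluded For missense/in-frame
#'   variants: protein-level functional impact has been experimentally
#'   excluded.
#' @param low_cut,high_cut Calibrated score cut-offs (shared with the
#'   calibration module).
#' @param applied_weight Weight at which PP3/BP4 are applied.
#' @param region_mode BP7 region mode, `"standard"` or `"minimal"`.
#' @param cfg A [region_config()].
#' @return An object of class `code_set`.
#' @export
combine_codes <- function(region,
                          consequence = c("intronic", "synonymous",
                                          "missense", "inframe_indel",
                                          "nonsense", "other"),
                          scores = NULL, pvs1 = NULL, rna = NULL,
                          ps1 = NULL,
                          protein_functional_impact_excluded = FALSE,
                          low_cut = 0.1, high_cut = 0.2,
                          applied_weight = c("supporting", "moderate"),
                          region_mode = c("standard", "minimal"),
                          cfg = region_config()) {
  consequence <- match.arg(consequence)
  applied_weight <- match.arg(applied_weight)
  region_mode <- match.arg(region_mode)
  stopifnot(inherits(region, "region_class"))

  if (!is.null(rna) && !inherits(rna, c("pvs1_result", "bp7_rna_signal"))) {
    if (is.list(rna) &&
        any(vapply(rna, inherits, logical(1), "pvs1_result")) &&
        any(vapply(rna, inherits, logical(1), "bp7_rna_signal")))
      stop("conflicting RNA evidence: aberration and no-impact supplied together")
    stop("rna must be a pvs1_result or bp7_rna_signal")
  }

  assigned <- data.frame(code = character(), strength = character(),
                         rna = logical(), rationale = character())
  suppressed <- data.frame(code = character(), reason = character())
  record <- data.frame(note = character())
  add <- function(code, strength, rna_flag, rationale)
    rbind(assigned, data.frame(code = code, strength = strength,
                               rna = rna_flag, rationale = rationale))
  supp <- function(code, reason)
    rbind(suppressed, data.frame(code = code, reason = reason))

  canonical <- region$category == "CANONICAL_DINUCLEOTIDE"
  rna_impact <- inherits(rna, "pvs1_result")
  rna_no_impact <- inherits(rna, "bp7_rna_signal")
  predictive_allowed <- TRUE

  if (rna_impact) {
    if (rna$strength == "PVS1_NA") {
      record <- rbind(record, data.frame(
        note = paste("RNA-observed aberration interpreted as PVS1_N/A",
                     paste(rna$rationale, collapse = " > "), sep = ": ")))
    } else {
      assigned <- add("PVS1", rna$strength, TRUE,
                      paste(rna$rationale, collapse = " > "))
    }
    suppressed <- supp("PP3", "replaced by RNA-based PVS1 evidence")
    suppressed <- supp("BP4", "replaced by RNA-based PVS1 evidence")
    suppressed <- supp("PS3",
                       "splicing assay data captured via PVS1_Strength (RNA)")
    predictive_allowed <- FALSE
  } else if (rna_no_impact) {
    if (consequence %in% c("intronic", "synonymous")) {
      assigned <- add("BP7", rna$strength, TRUE,
                      paste(rna$rationale, collapse = " > "))
      suppressed <- supp("BP4", "superseded by RNA-based BP7 evidence")
      suppressed <- supp("BS3",
                         "splicing assay data captured via BP7_Strong (RNA)")
      predictive_allowed <- FALSE
    } else if (consequence %in% c("missense", "inframe_indel")) {
      if (protein_functional_impact_excluded) {
        assigned <- add("BP7", rna$strength, TRUE,
                        paste(c(rna$rationale,
                                "protein_functional_impact_excluded"),
                              collapse = " > "))
        suppressed <- supp("BS3",
                           "splicing assay data captured via BP7_Strong (RNA)")
        predictive_allowed <- FALSE
      } else {
        record <- rbind(record, data.frame(
          note = paste("splicing assay showed no impact; recorded as",
                       "explanatory text only, pending protein-level",
                       "functional data (most deleterious prediction",
                       "retained)")))
        suppressed <- supp("BS3",
                           "splicing assay data recorded, not scored via BS3")
        # predictive codes retained for the protein-level mechanism
      }
    } else {
      assigned <- add("BP7", rna$strength, TRUE,
                      paste(rna$rationale, collapse = " > "))
      suppressed <- supp("BS3",
                         "splicing assay data captured via BP7_Strong (RNA)")
      predictive_allowed <- FALSE
    }
  }

  if (predictive_allowed) {
    if (canonical) {
      if (!is.null(pvs1)) {
        if (pvs1$strength == "PVS1_NA") {
          record <- rbind(record, data.frame(
            note = paste("PVS1_N/A:",
                         paste(pvs1$rationale, collapse = " > "))))
        } else {
          assigned <- add("PVS1", pvs1$strength, pvs1$rna_based,
                          paste(pvs1$rationale, collapse = " > "))
        }
      } else {
        record <- rbind(record, data.frame(
          note = "canonical variant without a PVS1 evaluation"))
      }
      suppressed <- supp("PP3",
                         "canonical dinucleotide: position captured by PVS1")
      suppressed <- supp("BP4",
                         "canonical dinucleotide: position captured by PVS1")
    } else if (!is.null(scores)) {
      pb <- assign_pp3_bp4(scores, low_cut, high_cut, applied_weight)
      if (!is.null(pb$code)) {
        lab <- if (pb$code == "PP3") "splicing-based prediction supports impact"
        else "prediction supports no splicing impact"
        assigned <- add(pb$code, pb$strength, FALSE,
                        paste(lab, pb$reason, sep = "; "))
      } else {
        record <- rbind(record, data.frame(note = pb$reason))
      }
      eligible <- bp7_position_eligible(region,
                                        consequence == "synonymous",
                                        cfg, region_mode)
      b7 <- assign_bp7(identical(pb$code, "BP4"), eligible)
      if (!is.null(b7$code))
        assigned <- add("BP7", b7$strength, FALSE, b7$reason)
    }
  }

  if (!is.null(ps1) && !is.null(ps1$code))
    assigned <- add("PS1", ps1$strength, FALSE, ps1$reason)

  if ((rna_impact || rna_no_impact) && !"PS3" %in% suppressed$code)
    suppressed <- supp("PS3",
                       "splicing assays not scored via PS3/BS3")

  cs <- .code_set(assigned, suppressed, record)
  validate_code_set(cs)
  cs
}

#' @export
as.data.frame.code_set <- function(x, row.names = NULL, optional = FALSE,
                                   variant = NA_character_, ...) {
  rows <- list()
  if (nrow(x$assigned))
    rows <- c(rows, list(data.frame(variant = variant, status = "assigned",
                                    code = x$assigned$code,
                                    strength = x$assigned$strength,
                                    rna = x$assigned$rna,
                                    detail = x$assigned$rationale)))
  if (nrow(x$suppressed))
    rows <- c(rows, list(data.frame(variant = variant, status = "suppressed",
                                    code = x$suppressed$code,
                                    strength = NA_character_, rna = NA,
                                    detail = x$suppressed$reason)))
  if (nrow(x$record_only))
    rows <- c(rows, list(data.frame(variant = variant, status = "record_only",
                                    code = NA_character_,
                                    strength = NA_character_, rna = NA,
                                    detail = x$record_only$note)))
  if (!length(rows))
    return(data.frame(variant = character(), status = character(),
                      code = character(), strength = character(),
                      rna = logical(), detail = character()))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
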