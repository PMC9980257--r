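#' Splice-region window configuration
#'
#' Defines the extent of the donor and acceptor splice-site motifs used to
#' classify variant positions, and the intronic distance bounds for the
#' computational BP7 code. Defaults describe U2-type GT-AG introns: the
#' standard splice region spans the last 3 exonic and first 6 intronic bases
#' at the donor side, and the first exonic base plus 20 intronic bases at the
#' acceptor side. The minimal splice region keeps the donor window but
#' restricts the acceptor to 3 intronic bases. Windows are overridable per
#' intron, e.g. extending the donor intronic window to 9 bases for U12-type
#' introns.
#'
#' @param donor_exonic Number of exonic bases in the donor motif.
#' @param donor_intronic Number of intronic bases in the donor motif.
#' @param acceptor_exonic Number of exonic bases in the acceptor motif.
#' @param acceptor_intronic_standard Intronic bases in the standard acceptor
#'   motif.
#' @param acceptor_intronic_minimal Intronic bases in the minimal acceptor
#'   motif; must not exceed the standard window.
#' @param bp7_intronic_bound_donor First donor-side intronic position (in
#'   transcript orientation, positive into the intron) at which BP7 becomes
#'   applicable.
#' @param bp7_intronic_bound_acceptor First acceptor-side intronic position
#'   (negative into the intron) at which BP7 becomes applicable in standard
#'   region mode.
#' @param bp7_intronic_bound_acceptor_minimal As above, for minimal region
#'   mode.
#' @return An object of class `region_config`.
#' @export
region_config <- function(donor_exonic = 3L,
                          donor_intronic = 6L,
                          acceptor_exonic = 1L,
                          acceptor_intronic_standard = 20L,
                          acceptor_intronic_minimal = 3L,
                          bp7_intronic_bound_donor = 7L,
                          bp7_intronic_bound_acceptor = -21L,
                          bp7_intronic_bound_acceptor_minimal = -4L) {
  counts <- c(donor_exonic, donor_intronic, acceptor_exonic,
              acceptor_intronic_standard, acceptor_intronic_minimal)
  if (any(counts < 0)) stop("splice-region window counts must be >= 0")
  if (acceptor_intronic_minimal > acceptor_intronic_standard)
    stop("minimal acceptor window must not exceed the standard window")
  structure(list(
    donor_exonic = as.integer(donor_exonic),
    donor_intronic = as.integer(donor_intronic),
    acceptor_exonic = as.integer(acceptor_exonic),
    acceptor_intronic_standard = as.integer(acceptor_intronic_standard),
    acceptor_intronic_minimal = as.integer(acceptor_intronic_minimal),
    bp7_intronic_bound_donor = as.integer(bp7_intronic_bound_donor),
    bp7_intronic_bound_acceptor = as.integer(bp7_intronic_bound_acceptor),
    bp7_intronic_bound_acceptor_minimal =
      as.integer(bp7_intronic_bound_acceptor_minimal)
  ), class = "region_config")
}

#' Transcript model
#'
#' A minimal transcript representation: ordered exons on one strand of one
#' chromosome, with optional CDS bounds. Coordinates are 1-based, fully
#' closed (GTF convention). Exons are stored in transcription order, so for a
#' minus-strand transcript exon 1 has the largest genomic coordinates.
#'
#' @param transcript_id Transcript identifier.
#' @param chrom Chromosome/contig name.
#' @param strand `"+"` or `"-"`.
#' @param exon_start,exon_end Genomic start/end of each exon (any order;
#'   sorted internally).
#' @param cds_start,cds_end Optional genomic CDS bounds.
#' @param is_reference Whether this is the curation reference transcript
#'   (MANE-Select analog).
#' @return An object of class `transcript_model`.
#' @export
transcript_model <- function(transcript_id, chrom, strand,
                             exon_start, exon_end,
                             cds_start = NA_integer_, cds_end = NA_integer_,
                             is_reference = FALSE) {
  if (!strand %in% c("+", "-")) stop("strand must be '+' or '-'")
  if (length(exon_start) != length(exon_end) || length(exon_start) < 1)
    stop("exon_start and exon_end must be non-empty and of equal length")
  o <- order(exon_start)
  s <- as.integer(exon_start[o]); e <- as.integer(exon_end[o])
  if (any(e < s)) stop("every exon must satisfy start <= end (length >= 1)")
  if (length(s) > 1 && any(s[-1] <= e[-length(e)]))
    stop("exons must be non-overlapping")
  if (strand == "-") { s <- rev(s); e <- rev(e) }   # transcription order
  structure(list(
    transcript_id = as.character(transcript_id),
    chrom = as.character(chrom),
    strand = strand,
    exons = data.frame(rank = seq_along(s), start = s, end = e),
    cds_start = as.integer(cds_start), cds_end = as.integer(cds_end),
    is_reference = isTRUE(is_reference)
  ), class = "transcript_model")
}

#' @export
print.transcript_model <- function(x, ...) {
  cat(sprintf("transcript_model %s (%s%s), %d exon(s), span %d-%d\n",
              x$transcript_id, x$chrom, x$strand, nrow(x$exons),
              min(x$exons$start), max(x$exons$end)))
  invisible(x)
}

#' Variant allele
#'
#' @param chrom Chromosome name.
#' @param pos 1-based genomic position of the first reference base.
#' @param ref,alt Reference and alternate allele strings (REF != ALT).
#' @return An object of class `variant_allele`.
#' @export
variant_allele <- function(chrom, pos, ref, alt) {
  if (pos < 1) stop("pos must be >= 1")
  ref <- toupper(as.character(ref)); alt <- toupper(as.character(alt))
  if (identical(ref, alt)) stop("ref and alt must differ")
  structure(list(chrom = as.character(chrom), pos = as.integer(pos),
                 ref = ref, alt = alt), class = "variant_allele")
}

# Offsets of a single genomic position from the flanking exon boundaries, in
# transcript orientation. Donor offsets are negative exonic / positive
# intronic; acceptor offsets are positive exonic / negative intronic. A
# boundary that does not exist (donor side of the terminal exon, acceptor
# side of the first exon) is returned as NA with defined = FALSE.
.position_offsets <- function(pos, tx) {
  ex <- tx$exons
  n <- nrow(ex)
  lo <- min(ex$start); hi <- max(ex$end)
  if (pos < lo || pos > hi)
    stop(sprintf("position %d outside transcript span %d-%d of %s",
                 pos, lo, hi, tx$transcript_id))
  plus <- tx$strand == "+"
  hit <- which(pos >= ex$start & pos <= ex$end)
  if (length(hit) == 1) {
    i <- hit
    d_start <- if (plus) pos - ex$start[i] + 1L else ex$end[i] - pos + 1L
    d_end <- if (plus) ex$end[i] - pos + 1L else pos - ex$start[i] + 1L
    acc_def <- i > 1L          # first exon has no acceptor side
    don_def <- i < n           # last exon has no donor side
    list(exonic = TRUE, index = i,
         donor = if (don_def) -d_end else NA_integer_,
         acceptor = if (acc_def) d_start else NA_integer_,
         donor_defined = don_def, acceptor_defined = acc_def)
  } else {
    # intron between transcript-order exons i and i+1
    if (plus) {
      i <- max(which(ex$end < pos))
      don <- pos - ex$end[i]
      acc <- pos - ex$start[i + 1L]
    } else {
      i <- max(which(ex$start > pos))
      don <- ex$start[i] - pos
      acc <- ex$end[i + 1L] - pos
    }
    list(exonic = FALSE, index = i, donor = as.integer(don),
         acceptor = as.integer(acc),
         donor_defined = TRUE, acceptor_defined = TRUE)
  }
}

#' HGVS-like offset of a variant from the nearest exon/intron boundary
#'
#' Reports which boundary (donor or acceptor) a variant position is nearest
#' to and the signed distance in transcript orientation: intronic offsets are
#' positive on the donor side (+1 is the first intronic base) and negative on
#' the acceptor side (-1 is the last intronic base); exonic offsets are
#' negative towards a donor (-1 is the last exonic base) and positive from an
#' acceptor (+1 is the first exonic base). Ties are broken towards the donor
#' side. The donor side is undefined for the terminal exon and the acceptor
#' side for the first exon; a single-exon transcript yields side `"NONE"`.
#'
#' @param variant A [variant_allele()].
#' @param tx A [transcript_model()].
#' @return A list with elements `side` (`"DONOR"`, `"ACCEPTOR"` or `"NONE"`),
#'   `offset` (signed integer) and `exonic` (logical).
#' @export
splice_offset <- function(variant, tx) {
  if (!identical(variant$chrom, tx$chrom))
    stop("variant and transcript are on different chromosomes")
  po <- .position_offsets(variant$pos, tx)
  .choose_side(po)
}

.choose_side <- function(po) {
  if (po$donor_defined && po$acceptor_defined) {
    if (abs(po$donor) <= abs(po$acceptor))
      list(side = "DONOR", offset = po$donor, exonic = po$exonic)
    else
      list(side = "ACCEPTOR", offset = po$acceptor, exonic = po$exonic)
  } else if (po$donor_defined) {
    list(side = "DONOR", offset = po$donor, exonic = po$exonic)
  } else if (po$acceptor_defined) {
    list(side = "ACCEPTOR", offset = po$acceptor, exonic = po$exonic)
  } else {
    list(side = "NONE", offset = NA_integer_, exonic = po$exonic)
  }
}

#' Construct a splice-region class directly
#'
#' Used when the position category is already known (e.g. from a curated
#' table) rather than derived from a transcript model via
#' [classify_region()].
#'
#' @param category One of `"CANONICAL_DINUCLEOTIDE"`,
#'   `"MINIMAL_SPLICE_REGION"`, `"STANDARD_SPLICE_REGION"`, `"OUTSIDE"`.
#' @param side `"DONOR"`, `"ACCEPTOR"` or `"NONE"`.
#' @param offset Signed offset from the exon boundary in transcript
#'   orientation.
#' @param exonic Whether the position is exonic.
#' @param in_standard,in_minimal Optional explicit membership flags; derived
#'   from `category` when missing (minimal membership implies standard).
#' @return An object of class `region_class`.
#' @export
region_class <- function(category, side = "NONE", offset = NA_integer_,
                         exonic = FALSE, in_standard = NULL,
                         in_minimal = NULL) {
  cats <- c("CANONICAL_DINUCLEOTIDE", "MINIMAL_SPLICE_REGION",
            "STANDARD_SPLICE_REGION", "OUTSIDE")
  category <- match.arg(category, cats)
  side <- match.arg(side, c("DONOR", "ACCEPTOR", "NONE"))
  if (is.null(in_minimal))
    in_minimal <- category %in% c("CANONICAL_DINUCLEOTIDE",
                                  "MINIMAL_SPLICE_REGION")
  if (is.null(in_standard))
    in_standard <- in_minimal || category == "STANDARD_SPLICE_REGION"
  structure(list(category = category, side = side,
                 offset = as.integer(offset), exonic = isTRUE(exonic),
                 in_standard = isTRUE(in_standard),
                 in_minimal = isTRUE(in_minimal)),
            class = "region_class")
}

#' @export
print.region_class <- function(x, ...) {
  cat(sprintf("region_class: %s (side %s, offset %s, %s)\n", x$category,
              x$side, x$offset, if (x$exonic) "exonic" else "intronic"))
  invisible(x)
}

# Classify one genomic position. Membership is checked against BOTH flanking
# boundaries so that, e.g., a base 8 nt past a donor but 18 nt before the
# next acceptor is still recognised as inside the standard acceptor window.
.classify_position <- function(pos, tx, cfg) {
  po <- .position_offsets(pos, tx)
  don <- po$donor; acc <- po$acceptor
  if (po$exonic) {
    canon <- FALSE
    don_std <- po$donor_defined && don >= -cfg$donor_exonic
    acc_std <- po$acceptor_defined && acc <= cfg$acceptor_exonic
    acc_min <- acc_std
  } else {
    canon <- (don %in% 1:2) || (acc %in% -(1:2))
    don_std <- don <= cfg$donor_intronic
    acc_std <- acc >= -cfg$acceptor_intronic_standard
    acc_min <- acc >= -cfg$acceptor_intronic_minimal
  }
  in_standard <- don_std || acc_std
  in_minimal <- don_std || acc_min
  category <- if (canon) "CANONICAL_DINUCLEOTIDE"
  else if (in_minimal) "MINIMAL_SPLICE_REGION"
  else if (in_standard) "STANDARD_SPLICE_REGION"
  else "OUTSIDE"

  # side/offset: the motif that granted the category; nearest boundary
  # otherwise; ties towards the side with the smaller absolute offset, then
  # the donor side.
  pick <- function(don_ok, acc_ok) {
    if (don_ok && acc_ok) {
      if (abs(don) <= abs(acc)) list(side = "DONOR", offset = don)
      else list(side = "ACCEPTOR", offset = acc)
    } else if (don_ok) list(side = "DONOR", offset = don)
    else list(side = "ACCEPTOR", offset = acc)
  }
  sd <- if (canon) {
    pick((!po$exonic) && don %in% 1:2, (!po$exonic) && acc %in% -(1:2))
  } else if (in_minimal) {
    pick(don_std, acc_min)
  } else if (in_standard) {
    pick(don_std, acc_std)
  } else {
    ns <- .choose_side(po)
    list(side = ns$side, offset = ns$offset)
  }
  region_class(category, sd$side, sd$offset, exonic = po$exonic,
               in_standard = in_standard, in_minimal = in_minimal)
}

#' Classify a variant position into a splice-region category
#'
#' Categories nest: every canonical dinucleotide position lies inside the
#' minimal splice region, and every minimal position inside the standard
#' region. `MINIMAL_SPLICE_REGION` therefore implies standard-region
#' membership; `STANDARD_SPLICE_REGION` labels positions in the standard but
#' not the minimal region. For multi-nucleotide variants the most
#' motif-proximal affected base determines the class, so a deletion spanning
#' a canonical dinucleotide is classified canonical.
#'
#' @param variant A [variant_allele()].
#' @param tx A [transcript_model()].
#' @param cfg A [region_config()].
#' @return An object of class `region_class`.
#' @export
classify_region <- function(variant, tx, cfg = region_config()) {
  if (!identical(variant$chrom, tx$chrom))
    stop("variant and transcript are on different chromosomes")
  span <- if (nchar(variant$alt) > nchar(variant$ref) &&
              nchar(variant$ref) == 1L) {
    c(variant$pos, variant$pos + 1L)        # insertion: the two flanks
  } else {
    seq.int(variant$pos, variant$pos + nchar(variant$ref) - 1L)
  }
  lo <- min(tx$exons$start); hi <- max(tx$exons$end)
  span <- span[span >= lo & span <= hi]
  if (length(span) == 0)
    stop(sprintf("variant %s:%d outside transcript span of %s",
                 variant$chrom, variant$pos, tx$transcript_id))
  classes <- lapply(span, .classify_position, tx = tx, cfg = cfg)
  rank <- vapply(classes, function(rc) {
    switch(rc$category, CANONICAL_DINUCLEOTIDE = 4L,
           MINIMAL_SPLICE_REGION = 3L, STANDARD_SPLICE_REGION = 2L, 1L)
  }, integer(1))
  best <- which(rank == max(rank))
  if (length(best) > 1) {
    offs <- vapply(classes[best], function(rc) abs(rc$offset), integer(1))
    don <- vapply(classes[best], function(rc) rc$side == "DONOR", logical(1))
    best <- best[order(offs, !don)][1]
  }
  classes[[best]]
}

#' Positional eligibility for the computational BP7 code
#'
#' BP7 (in addition to BP4) is reserved for positions with a low prior of
#' affecting splicing: synonymous exonic variants outside the first exon base
#' and the last three exon bases, and intronic variants at or beyond the +7
#' (donor) / -21 (acceptor) positions in standard mode, or +7 / -4 in minimal
#' mode. Evolutionary conservation is deliberately not an input.
#'
#' @param rc A `region_class` for the curation transcript.
#' @param is_synonymous Whether an exonic variant is synonymous.
#' @param cfg A [region_config()].
#' @param region_mode `"standard"` (conservative, default) or `"minimal"`.
#' @return Logical scalar.
#' @export
bp7_position_eligible <- function(rc, is_synonymous,
                                  cfg = region_config(),
                                  region_mode = c("standard", "minimal")) {
  region_mode <- match.arg(region_mode)
  if (rc$exonic)
    return(isTRUE(is_synonymous) && rc$category == "OUTSIDE")
  if (rc$category == "CANONICAL_DINUCLEOTIDE") return(FALSE)
  if (region_mode == "standard") rc$category == "OUTSIDE" else !rc$in_minimal
}
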