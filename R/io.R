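#' Read a spliceogenicity truth dataset
#'
#' Headered TSV with columns `variant_key`, `score`, `spliceogenic` (0/1 or
#' TRUE/FALSE) and optional `gene`, `region`, `source`.
#'
#' @param path Path to the TSV.
#' @return A validated data frame of truth records.
#' @export
read_truth <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("variant_key", "score", "spliceogenic")
  miss <- setdiff(need, names(d))
  if (length(miss))
    stop("truth TSV missing column(s): ", paste(miss, collapse = ", "))
  d$spliceogenic <- as.logical(d$spliceogenic) |
    (suppressWarnings(as.numeric(d$spliceogenic)) == 1)
  .check_truth(d)
}

.spliceai_fields <- c("allele", "symbol", "ds_ag", "ds_al", "ds_dg",
                      "ds_dl", "dp_ag", "dp_al", "dp_dg", "dp_dl")

# parse one SpliceAI INFO entry "ALT|SYMBOL|DS_AG|DS_AL|DS_DG|DS_DL|DP_AG|..."
.parse_spliceai_entry <- function(entry) {
  f <- strsplit(entry, "|", fixed = TRUE)[[1]]
  if (length(f) < 6) return(NULL)
  length(f) <- 10
  names(f) <- .spliceai_fields
  ds <- suppressWarnings(as.numeric(f[3:6]))
  dp <- suppressWarnings(as.integer(f[7:10]))
  list(allele = f[["allele"]], gene = f[["symbol"]],
       ds_ag = ds[1], ds_al = ds[2], ds_dg = ds[3], ds_dl = ds[4],
       dp_ag = dp[1], dp_al = dp[2], dp_dg = dp[3], dp_dl = dp[4])
}

#' Read variants with SpliceAI annotations
#'
#' Accepts a VCF annotated with the standard SpliceAI INFO field
#' (`SpliceAI=ALLELE|SYMBOL|DS_AG|DS_AL|DS_DG|DS_DL|DP_AG|DP_AL|DP_DG|DP_DL`,
#' raw or masked dialect) or a headered TSV with columns `chrom`, `pos`,
#' `ref`, `alt`, `ds_ag`, `ds_al`, `ds_dg`, `ds_dl` (optional `dp_*`,
#' `gene`). Multiallelic VCF records are split into one row per alternate
#' allele; a SpliceAI entry is matched to its allele, and alleles without a
#' matching entry get `NA` scores and are listed in the `skipped` attribute
#' with a warning.
#'
#' @param path Input path.
#' @param format `"auto"` (by extension), `"vcf"` or `"tsv"`.
#' @return A data frame with one row per variant allele: `variant_key`,
#'   `chrom`, `pos`, `ref`, `alt`, `gene`, the four `ds_*` and `dp_*`
#'   columns, and `max_delta`.
#' @export
read_variants <- function(path, format = c("auto", "vcf", "tsv")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.vcf(\\.gz)?$", path, ignore.case = TRUE))
      "vcf" else "tsv"
  if (format == "tsv") return(.read_variants_tsv(path))
  if (!requireNamespace("vcfR", quietly = TRUE))
    stop("reading VCF requires the 'vcfR' package")
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1,
                                       dimnames = list(NULL, names(fix)))
  info <- vcfR::extract.info(v, element = "SpliceAI")
  rows <- list(); skipped <- character()
  for (i in seq_len(nrow(fix))) {
    alts <- strsplit(fix[i, "ALT"], ",", fixed = TRUE)[[1]]
    entries <- if (!is.na(info[i]))
      lapply(strsplit(info[i], ",", fixed = TRUE)[[1]],
             .parse_spliceai_entry)
    else list()
    entries <- Filter(Negate(is.null), entries)
    for (alt in alts) {
      key <- paste(fix[i, "CHROM"], fix[i, "POS"], fix[i, "REF"], alt,
                   sep = ":")
      hit <- Filter(function(e) identical(e$allele, alt), entries)
      e <- if (length(hit)) hit[[1]] else NULL
      if (is.null(e)) {
        skipped <- c(skipped, key)
        e <- list(gene = NA_character_, ds_ag = NA_real_, ds_al = NA_real_,
                  ds_dg = NA_real_, ds_dl = NA_real_, dp_ag = NA_integer_,
                  dp_al = NA_integer_, dp_dg = NA_integer_,
                  dp_dl = NA_integer_)
      }
      ds <- c(e$ds_ag, e$ds_al, e$ds_dg, e$ds_dl)
      rows[[length(rows) + 1]] <- data.frame(
        variant_key = key, chrom = fix[i, "CHROM"],
        pos = as.integer(fix[i, "POS"]), ref = fix[i, "REF"], alt = alt,
        gene = e$gene, ds_ag = e$ds_ag, ds_al = e$ds_al, ds_dg = e$ds_dg,
        ds_dl = e$ds_dl, dp_ag = e$dp_ag, dp_al = e$dp_al, dp_dg = e$dp_dg,
        dp_dl = e$dp_dl,
        max_delta = if (all(is.na(ds))) NA_real_ else max(ds, na.rm = TRUE))
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  if (length(skipped))
    warning("no matching SpliceAI annotation for: ",
            paste(skipped, collapse = ", "))
  attr(out, "skipped") <- skipped
  out
}

.read_variants_tsv <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("chrom", "pos", "ref", "alt", "ds_ag", "ds_al", "ds_dg", "ds_dl")
  miss <- setdiff(need, names(d))
  if (length(miss))
    stop("variant TSV missing column(s): ", paste(miss, collapse = ", "))
  for (col in c("gene", "dp_ag", "dp_al", "dp_dg", "dp_dl"))
    if (is.null(d[[col]])) d[[col]] <- NA
  ds <- as.matrix(d[, c("ds_ag", "ds_al", "ds_dg", "ds_dl")])
  out <- data.frame(
    variant_key = paste(d$chrom, d$pos, d$ref, d$alt, sep = ":"),
    chrom = as.character(d$chrom), pos = as.integer(d$pos),
    ref = d$ref, alt = d$alt, gene = d$gene,
    ds_ag = d$ds_ag, ds_al = d$ds_al, ds_dg = d$ds_dg, ds_dl = d$ds_dl,
    dp_ag = d$dp_ag, dp_al = d$dp_al, dp_dg = d$dp_dg, dp_dl = d$dp_dl,
    max_delta = apply(ds, 1, function(x)
      if (all(is.na(x))) NA_real_ else max(x, na.rm = TRUE)))
  attr(out, "skipped") <- character()
  out
}

#' Read a splicing assay read-out table
#'
#' Headered TSV with one row per observed transcript: `transcript_desc`,
#' `event_type`, `frame`, `nmd_predicted`, `fraction_protein_removed`,
#' `removes_critical_region`, `aberrant_fraction`, plus per-assay columns
#' `source` and `controls_matched_tissue` (first row wins) and optional
#' `affected_exons`, `allele_specific`. A file with a header but no rows
#' yields `NULL` (no RNA evidence).
#'
#' @param path Path to the TSV.
#' @return An [assay_readout()] or `NULL`.
#' @export
read_assay <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (nrow(d) == 0) return(NULL)
  need <- c("event_type", "aberrant_fraction", "source")
  miss <- setdiff(need, names(d))
  if (length(miss))
    stop("assay TSV missing column(s): ", paste(miss, collapse = ", "))
  bad <- which(!d$event_type %in% .event_types)
  if (length(bad))
    stop("assay TSV line ", bad[1] + 1, ": unknown event_type '",
         d$event_type[bad[1]], "'")
  bad <- which(is.na(d$aberrant_fraction) | d$aberrant_fraction < 0 |
                 d$aberrant_fraction > 1)
  if (length(bad))
    stop("assay TSV line ", bad[1] + 1, ": aberrant_fraction must be in [0, 1]")
  assay_readout(d, source = d$source[1],
                controls_matched_tissue =
                  if (!is.null(d$controls_matched_tissue))
                    isTRUE(as.logical(d$controls_matched_tissue[1]))
                else TRUE)
}

#' Read comparator variants for PS1
#'
#' Headered TSV with columns `variant_key`, `classification` (`PATHOGENIC`
#' or `LIKELY_PATHOGENIC`), `region_category`, `side`, `offset`, `exonic`,
#' `event_type`, `prediction_strength`, and optional `affected_exons`
#' (comma-separated), `cryptic_site_offset`, `same_nucleotide_as_vua`,
#' `same_motif_as_vua`, `clinical_support_flag`. Unknown classification
#' strings are a hard error.
#'
#' @param path Path to the TSV.
#' @return A list of [comparator_variant()] objects.
#' @export
read_comparators <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("variant_key", "classification", "region_category", "side",
            "offset", "exonic", "event_type", "prediction_strength")
  miss <- setdiff(need, names(d))
  if (length(miss))
    stop("comparator TSV missing column(s): ", paste(miss, collapse = ", "))
  bad <- which(!d$classification %in% c("PATHOGENIC", "LIKELY_PATHOGENIC"))
  if (length(bad))
    stop("comparator TSV line ", bad[1] + 1, ": unknown classification '",
         d$classification[bad[1]], "'")
  lapply(seq_len(nrow(d)), function(i) {
    ev <- .row_to_event(d[i, , drop = FALSE])
    if (!is.null(d$cryptic_site_offset) && !is.na(d$cryptic_site_offset[i]))
      ev$cryptic_site_offset <- as.integer(d$cryptic_site_offset[i])
    flag <- function(col) !is.null(d[[col]]) && isTRUE(as.logical(d[[col]][i]))
    comparator_variant(
      variant_key = d$variant_key[i],
      classification = d$classification[i],
      region = region_class(d$region_category[i], d$side[i], d$offset[i],
                            isTRUE(as.logical(d$exonic[i]))),
      predicted_event = ev,
      prediction_strength = d$prediction_strength[i],
      same_nucleotide_as_vua = flag("same_nucleotide_as_vua"),
      same_motif_as_vua = flag("same_motif_as_vua"),
      clinical_support_flag = flag("clinical_support_flag"))
  })
}

#' Read a per-gene interpretation context from YAML
#'
#' The YAML file maps directly onto the arguments of [gene_context()];
#' `critical_domains` and `rescue_transcripts` are given as lists of
#' records.
#'
#' @param path Path to the YAML file.
#' @return A [gene_context()].
#' @export
read_gene_config <- function(path) {
  y <- yaml::read_yaml(path)
  to_df <- function(x) if (is.null(x)) NULL
  else do.call(rbind, lapply(x, function(r) as.data.frame(r)))
  gene_context(
    gene = if (is.null(y$gene)) NA_character_ else y$gene,
    lof_mechanism_established = isTRUE(y$lof_mechanism_established),
    critical_domains = to_df(y$critical_domains),
    rescue_transcripts = to_df(y$rescue_transcripts),
    protein_size_threshold =
      if (is.null(y$protein_size_threshold)) 0.10
    else y$protein_size_threshold,
    rescue_expression_threshold =
      if (is.null(y$rescue_expression_threshold)) 0.10
    else y$rescue_expression_threshold,
    start_loss_upweight = isTRUE(y$start_loss_upweight),
    utr_critical_element = isTRUE(y$utr_critical_element),
    complementary_site_pathogenic_exons =
      if (is.null(y$complementary_site_pathogenic_exons)) integer()
    else as.integer(y$complementary_site_pathogenic_exons))
}

#' Write and read a code-assignment report
#'
#' The report is a TSV with one row per variant and code (assigned,
#' suppressed or record-only), with columns `variant`, `status`, `code`,
#' `strength`, `rna`, `detail`.
#'
#' @param code_sets A named list of `code_set` objects (names are variant
#'   keys) or a single `code_set`.
#' @param path Output path.
#' @return `write_report` returns the report data frame invisibly;
#'   `read_report` returns it.
#' @export
write_report <- function(code_sets, path) {
  if (inherits(code_sets, "code_set"))
    code_sets <- list(variant = code_sets)
  keys <- names(code_sets)
  if (is.null(keys)) keys <- sprintf("variant%d", seq_along(code_sets))
  out <- do.call(rbind, lapply(seq_along(code_sets), function(i)
    as.data.frame(code_sets[[i]], variant = keys[i])))
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(out)
}

#' @rdname write_report
#' @export
read_report <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE, na.strings = "NA")
  need <- c("variant", "status", "code", "strength", "rna", "detail")
  miss <- setdiff(need, names(d))
  if (length(miss))
    stop("report missing column(s): ", paste(miss, collapse = ", "))
  d
}
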