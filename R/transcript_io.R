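#' Read transcript models from GTF/GFF3 or a tabular exon file
#'
#' GTF/GFF3 input is parsed with `rtracklayer`; `exon` features are grouped
#' by their `transcript_id` attribute (GFF3 `Parent` is used when
#' `transcript_id` is absent) and `CDS` features, when present, set the CDS
#' bounds. The tabular format is a headered TSV with columns
#' `transcript_id`, `chrom`, `strand`, `exon_start`, `exon_end` and one row
#' per exon.
#'
#' @param path Path to the transcript file.
#' @param format `"auto"` (by extension), `"gtf"`, `"gff3"` or `"tsv"`.
#' @return A named list of [transcript_model()] objects.
#' @export
read_transcripts <- function(path, format = c("auto", "gtf", "gff3", "tsv")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- switch(tolower(sub(".*\\.", "", sub("\\.gz$", "", path))),
                     gtf = "gtf", gff = "gff3", gff3 = "gff3", "tsv")
  }
  if (format == "tsv") return(.read_transcripts_tsv(path))
  if (!requireNamespace("rtracklayer", quietly = TRUE))
    stop("reading GTF/GFF3 requires the 'rtracklayer' package")
  gr <- rtracklayer::import(path, format = if (format == "gtf") "gtf" else "gff3")
  m <- as.data.frame(gr)
  txid <- m$transcript_id
  if (is.null(txid) && !is.null(m$Parent))
    txid <- sub("^transcript:", "", vapply(m$Parent, function(p)
      if (length(p)) as.character(p[[1]]) else NA_character_, character(1)))
  if (is.null(txid)) stop("no transcript_id/Parent attribute found in ", path)
  m$..tx <- as.character(txid)
  ex <- m[tolower(m$type) == "exon" & !is.na(m$..tx), , drop = FALSE]
  if (nrow(ex) == 0) stop("no exon features found in ", path)
  cds <- m[tolower(m$type) == "cds" & !is.na(m$..tx), , drop = FALSE]
  out <- lapply(split(ex, ex$..tx), function(d) {
    cc <- cds[cds$..tx == d$..tx[1], , drop = FALSE]
    transcript_model(
      transcript_id = d$..tx[1],
      chrom = as.character(d$seqnames[1]),
      strand = as.character(d$strand[1]),
      exon_start = d$start, exon_end = d$end,
      cds_start = if (nrow(cc)) min(cc$start) else NA_integer_,
      cds_end = if (nrow(cc)) max(cc$end) else NA_integer_
    )
  })
  out[order(names(out))]
}

.read_transcripts_tsv <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("transcript_id", "chrom", "strand", "exon_start", "exon_end")
  miss <- setdiff(need, names(d))
  if (length(miss))
    stop("transcript TSV is missing column(s): ", paste(miss, collapse = ", "))
  lapply(split(d, d$transcript_id), function(x)
    transcript_model(x$transcript_id[1], x$chrom[1], x$strand[1],
                     x$exon_start, x$exon_end))
}
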