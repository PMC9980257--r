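#' Configuration for synthetic truth datasets
#'
#' Describes a two-class score-generating process on `[0, 1]`. Defaults
#' emulate the structure of the curated multi-gene spliceogenicity truth set
#' behind the default cut-offs: 3,021 variants of which 767 are spliceogenic,
#' with spliceogenic scores concentrated near 1 and non-spliceogenic scores
#' near 0 (beta shapes chosen so that roughly 87%/8%/5% of non-spliceogenic
#' and 15%/5%/80% of spliceogenic scores fall at or below 0.1, between the
#' cuts, and at or above 0.2).
#'
#' Distributions are given as lists: `list(type = "beta", shape1, shape2)`,
#' `list(type = "binned", edges, probs)` (piecewise-uniform with known bin
#' masses, so per-bin likelihood ratios are available in closed form), or
#' `list(type = "point", value)`.
#'
#' @param n_pos,n_neg Numbers of spliceogenic and non-spliceogenic records.
#' @param pos_score_dist,neg_score_dist Score distributions (see Details).
#' @param region_mix Named proportions over region classes, summing to 1.
#' @param seed Optional integer seed for reproducibility.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_pos = 767, n_neg = 2254,
                       pos_score_dist = list(type = "beta",
                                             shape1 = 0.35, shape2 = 0.15),
                       neg_score_dist = list(type = "beta",
                                             shape1 = 0.25, shape2 = 6),
                       region_mix = c(STANDARD_SPLICE_REGION = 0.5,
                                      OUTSIDE = 0.5),
                       seed = NULL) {
  if (n_pos <= 0 || n_neg <= 0) stop("class counts must be positive")
  if (abs(sum(region_mix) - 1) > 1e-6) stop("region_mix must sum to 1")
  if (is.null(names(region_mix)) || any(!nzchar(names(region_mix))))
    stop("region_mix must be named")
  .check_dist <- function(d) {
    if (!is.list(d) || is.null(d$type)) stop("distributions must be lists with a 'type'")
    switch(d$type,
           beta = if (is.null(d$shape1) || is.null(d$shape2) ||
                      d$shape1 <= 0 || d$shape2 <= 0)
             stop("beta distribution needs positive shape1/shape2"),
           binned = {
             if (is.null(d$edges) || is.null(d$probs) ||
                 length(d$edges) != length(d$probs) + 1)
               stop("binned distribution needs edges (k+1) and probs (k)")
             if (any(diff(d$edges) <= 0) || any(d$probs < 0) ||
                 abs(sum(d$probs) - 1) > 1e-6)
               stop("binned distribution needs increasing edges and probs summing to 1")
           },
           point = if (is.null(d$value) || d$value < 0 || d$value > 1)
             stop("point distribution needs a value in [0, 1]"),
           stop("unknown distribution type: ", d$type))
    invisible(TRUE)
  }
  .check_dist(pos_score_dist); .check_dist(neg_score_dist)
  structure(list(n_pos = as.integer(n_pos), n_neg = as.integer(n_neg),
                 pos_score_dist = pos_score_dist,
                 neg_score_dist = neg_score_dist,
                 region_mix = region_mix, seed = seed),
            class = "sim_config")
}

.draw_scores <- function(n, d) {
  switch(d$type,
         beta = stats::rbeta(n, d$shape1, d$shape2),
         binned = {
           k <- sample.int(length(d$probs), n, replace = TRUE,
                           prob = d$probs)
           stats::runif(n, d$edges[k], d$edges[k + 1])
         },
         point = rep(d$value, n))
}

#' Generate a synthetic spliceogenicity truth dataset
#'
#' Draws scores for the configured numbers of spliceogenic and
#' non-spliceogenic records and assigns region labels by the configured mix.
#' Deterministic for a fixed seed.
#'
#' @param cfg A [sim_config()].
#' @return A data frame with columns `variant_key`, `gene`, `score`,
#'   `spliceogenic`, `region`, `source`.
#' @export
generate_truth_dataset <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  n <- cfg$n_pos + cfg$n_neg
  score <- c(.draw_scores(cfg$n_pos, cfg$pos_score_dist),
             .draw_scores(cfg$n_neg, cfg$neg_score_dist))
  score <- pmin(1, pmax(0, score))
  region <- sample(names(cfg$region_mix), n, replace = TRUE,
                   prob = cfg$region_mix)
  data.frame(variant_key = sprintf("sim%05d", seq_len(n)),
             gene = "SIMGENE",
             score = score,
             spliceogenic = rep(c(TRUE, FALSE), c(cfg$n_pos, cfg$n_neg)),
             region = region,
             source = "other")
}

#' Deterministic calibration fixture with the reference bin margins
#'
#' Emits the truth dataset used to validate the default cut-offs: 2,246
#' non-spliceogenic records with 1962/175/109 scores in the bins at or below
#' 0.1, strictly between 0.1 and 0.2, and at or above 0.2, and 491
#' spliceogenic records with 72/38/381 in the same bins (the marginal counts
#' of the curated multi-gene calibration set). Scores are placed
#' deterministically: evenly across the closed outer bins (edges included)
#' and across the open interior of the middle bin (edges excluded), so
#' binning at (0.1, 0.2) reproduces the counts exactly.
#'
#' @return A data frame of truth records (see [generate_truth_dataset()]).
#' @export
truth_fixture <- function() {
  closed <- function(lo, hi, n) seq(lo, hi, length.out = n)
  interior <- function(lo, hi, n) lo + (hi - lo) * seq_len(n) / (n + 1)
  neg <- c(closed(0, 0.1, 1962), interior(0.1, 0.2, 175),
           closed(0.2, 1, 109))
  pos <- c(closed(0, 0.1, 72), interior(0.1, 0.2, 38), closed(0.2, 1, 381))
  n <- length(pos) + length(neg)
  data.frame(variant_key = sprintf("fix%04d", seq_len(n)),
             gene = "FIXTURE",
             score = c(pos, neg),
             spliceogenic = rep(c(TRUE, FALSE), c(length(pos), length(neg))),
             region = "outside_canonical",
             source = "other")
}

#' Deterministic multi-exon fixture transcript
#'
#' Builds a transcript with equal-length exons separated by equal-length
#' introns, used for exhaustive position-classification scans. Exon `i`
#' (in genomic order) starts at `start + (i - 1) * (exon_len + intron_len)`.
#'
#' @param n_exons Number of exons (>= 2).
#' @param exon_len,intron_len Exon and intron lengths in bases.
#' @param strand `"+"` or `"-"`.
#' @param chrom Chromosome label.
#' @param start Genomic start of the first (genomic-order) exon.
#' @param transcript_id Identifier.
#' @return A [transcript_model()].
#' @export
make_fixture_transcript <- function(n_exons = 3, exon_len = 100,
                                    intron_len = 200, strand = "+",
                                    chrom = "chrS", start = 1000,
                                    transcript_id = NULL) {
  if (n_exons < 2) stop("need n_exons >= 2")
  if (exon_len < 1 || intron_len < 1) stop("exon and intron lengths must be >= 1")
  s <- start + (seq_len(n_exons) - 1) * (exon_len + intron_len)
  e <- s + exon_len - 1
  if (is.null(transcript_id))
    transcript_id <- sprintf("FIX%d_%d_%d%s", n_exons, exon_len, intron_len,
                             if (strand == "+") "p" else "m")
  transcript_model(transcript_id, chrom, strand, s, e)
}
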