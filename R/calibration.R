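#' Two-class bin counts
#'
#' Counts of spliceogenic ("positive") and non-spliceogenic ("negative")
#' records inside one score bin, together with the class totals.
#'
#' @param n_pos_in Spliceogenic records in the bin.
#' @param n_pos_total All spliceogenic records.
#' @param n_neg_in Non-spliceogenic records in the bin.
#' @param n_neg_total All non-spliceogenic records.
#' @return An object of class `bin_counts`.
#' @export
bin_counts <- function(n_pos_in, n_pos_total, n_neg_in, n_neg_total) {
  v <- c(n_pos_in, n_pos_total, n_neg_in, n_neg_total)
  if (any(is.na(v)) || any(v < 0)) stop("counts must be non-negative")
  if (n_pos_total <= 0 || n_neg_total <= 0)
    stop("class totals must be positive")
  if (n_pos_in > n_pos_total || n_neg_in > n_neg_total)
    stop("in-bin counts cannot exceed class totals")
  structure(list(n_pos_in = as.numeric(n_pos_in),
                 n_pos_total = as.numeric(n_pos_total),
                 n_neg_in = as.numeric(n_neg_in),
                 n_neg_total = as.numeric(n_neg_total)),
            class = "bin_counts")
}

#' Evidence-strength boundaries on the odds scale
#'
#' Pathogenic-side odds boundaries follow the exponential point scale of the
#' Bayesian adaptation of the ACMG/AMP framework at a global prior
#' probability of pathogenicity of 0.10: Very Strong 350, Strong 350^(1/2),
#' Moderate 350^(1/4), Supporting 350^(1/8). Benign-side boundaries are the
#' exact reciprocals. A likelihood ratio at or above a pathogenic boundary
#' (or at or below a benign boundary) meets that strength.
#'
#' @param prior Global prior probability of pathogenicity (metadata; the
#'   default odds boundaries correspond to prior 0.10).
#' @param odds_very_strong,odds_strong,odds_moderate,odds_supporting
#'   Pathogenic odds boundaries, strictly decreasing.
#' @return An object of class `strength_thresholds`.
#' @export
strength_thresholds <- function(prior = 0.10,
                                odds_very_strong = 350,
                                odds_strong = 350^(1 / 2),
                                odds_moderate = 350^(1 / 4),
                                odds_supporting = 350^(1 / 8)) {
  if (prior <= 0 || prior >= 1) stop("prior must be in (0, 1)")
  b <- c(odds_supporting, odds_moderate, odds_strong, odds_very_strong)
  if (any(diff(b) <= 0) || b[1] <= 1)
    stop("odds boundaries must satisfy 1 < supporting < moderate < strong < very_strong")
  structure(list(prior = prior,
                 odds_very_strong = odds_very_strong,
                 odds_strong = odds_strong,
                 odds_moderate = odds_moderate,
                 odds_supporting = odds_supporting),
            class = "strength_thresholds")
}

.strength_levels <- c("VERY_STRONG_BENIGN", "STRONG_BENIGN",
                      "MODERATE_BENIGN", "SUPPORTING_BENIGN",
                      "UNINFORMATIVE",
                      "SUPPORTING", "MODERATE", "STRONG", "VERY_STRONG")

#' Map a likelihood ratio to an ACMG/AMP evidence strength
#'
#' Pathogenic categories are inclusive at their lower odds boundary and
#' benign categories at their upper (reciprocal) boundary, matching the
#' `>=`/`<=` conventions of the score bins. With `use_ci_bound = TRUE` the
#' conservative 95% CI bound (lower bound for pathogenic strengths, upper
#' for benign) must additionally clear the next-weaker category's boundary
#' (neutrality, LR = 1, for the supporting level), otherwise the strength is
#' demoted one level.
#'
#' @param lr Likelihood ratio (>= 0).
#' @param thresholds A [strength_thresholds()].
#' @param use_ci_bound Demote when the conservative CI bound does not support
#'   the category.
#' @param ci Length-2 numeric `c(low, high)`; required when `use_ci_bound`.
#' @return One of `"VERY_STRONG"`, `"STRONG"`, `"MODERATE"`, `"SUPPORTING"`,
#'   `"UNINFORMATIVE"`, `"SUPPORTING_BENIGN"`, `"MODERATE_BENIGN"`,
#'   `"STRONG_BENIGN"`, `"VERY_STRONG_BENIGN"`.
#' @export
map_lr_to_strength <- function(lr, thresholds = strength_thresholds(),
                               use_ci_bound = FALSE, ci = NULL) {
  if (is.na(lr) || lr < 0) stop("lr must be a non-negative number")
  if (use_ci_bound && (is.null(ci) || length(ci) != 2 || any(is.na(ci))))
    stop("use_ci_bound = TRUE requires ci = c(low, high)")
  b <- c(thresholds$odds_supporting, thresholds$odds_moderate,
         thresholds$odds_strong, thresholds$odds_very_strong)
  cat_for <- function(x) {
    if (x >= b[4]) "VERY_STRONG"
    else if (x >= b[3]) "STRONG"
    else if (x >= b[2]) "MODERATE"
    else if (x >= b[1]) "SUPPORTING"
    else if (x <= 1 / b[4]) "VERY_STRONG_BENIGN"
    else if (x <= 1 / b[3]) "STRONG_BENIGN"
    else if (x <= 1 / b[2]) "MODERATE_BENIGN"
    else if (x <= 1 / b[1]) "SUPPORTING_BENIGN"
    else "UNINFORMATIVE"
  }
  out <- cat_for(lr)
  if (!use_ci_bound || out == "UNINFORMATIVE") return(out)
  patho <- out %in% c("SUPPORTING", "MODERATE", "STRONG", "VERY_STRONG")
  # boundary of the next-weaker category; neutrality below supporting
  lower_bound <- function(categ) {
    idx <- match(categ, c("SUPPORTING", "MODERATE", "STRONG", "VERY_STRONG"))
    if (idx == 1) 1 else b[idx - 1]
  }
  ok <- if (patho) ci[1] >= lower_bound(out)
  else ci[2] <= 1 / lower_bound(sub("_BENIGN$", "", out))
  if (ok) return(out)
  i <- match(out, .strength_levels)
  .strength_levels[i + if (patho) -1L else 1L]
}

#' Likelihood ratio of spliceogenicity for one score bin
#'
#' The likelihood ratio is the ratio of in-bin proportions,
#' \eqn{LR = (a/A) / (b/B)}, where \eqn{a/A} are the in-bin and total
#' spliceogenic counts and \eqn{b/B} the non-spliceogenic counts. The 95%
#' interval uses the log method for diagnostic likelihood ratios:
#' \eqn{\exp(\ln LR \pm z \sqrt{(1-p_a)/a + (1-p_b)/b})}. When either
#' in-bin count is zero, 0.5 is added to all four cells of the underlying
#' 2x2 table (in/out of bin by class) and the result is flagged
#' `corrected`.
#'
#' @param counts A [bin_counts()].
#' @param z Normal quantile for the interval (1.96 for 95%).
#' @param thresholds A [strength_thresholds()] used to label the result, or
#'   `NULL` to skip strength assignment.
#' @return An object of class `lr_result` with elements `lr`, `ci_low`,
#'   `ci_high`, `counts`, `strength`, `corrected`.
#' @export
compute_lr <- function(counts, z = 1.96, thresholds = strength_thresholds()) {
  stopifnot(inherits(counts, "bin_counts"))
  a <- counts$n_pos_in; A <- counts$n_pos_total
  b <- counts$n_neg_in; B <- counts$n_neg_total
  corrected <- FALSE
  if (a == 0 || b == 0) {
    # 0.5 continuity correction on all four cells of the 2x2 table
    a <- a + 0.5; b <- b + 0.5
    A <- A + 1; B <- B + 1
    corrected <- TRUE
  }
  pa <- a / A; pb <- b / B
  lr <- pa / pb
  se <- sqrt((1 - pa) / a + (1 - pb) / b)
  res <- list(lr = lr, ci_low = lr * exp(-z * se), ci_high = lr * exp(z * se),
              counts = counts, corrected = corrected, strength = NA_character_)
  if (!is.null(thresholds))
    res$strength <- map_lr_to_strength(lr, thresholds)
  structure(res, class = "lr_result")
}

#' @export
print.lr_result <- function(x, ...) {
  cat(sprintf("LR %.2f [%.2f, %.2f]%s%s  (pos %g/%g, neg %g/%g)\n",
              x$lr, x$ci_low, x$ci_high,
              if (!is.na(x$strength)) paste0("  ", x$strength) else "",
              if (x$corrected) " (continuity-corrected)" else "",
              x$counts$n_pos_in, x$counts$n_pos_total,
              x$counts$n_neg_in, x$counts$n_neg_total))
  invisible(x)
}

.check_truth <- function(records) {
  need <- c("score", "spliceogenic")
  miss <- setdiff(need, names(records))
  if (length(miss))
    stop("truth records need column(s): ", paste(miss, collapse = ", "))
  if (any(is.na(records$score)) ||
      any(records$score < 0 | records$score > 1))
    stop("scores must lie in [0, 1]")
  records$spliceogenic <- as.logical(records$spliceogenic)
  if (any(is.na(records$spliceogenic)))
    stop("spliceogenic labels must be binary")
  records
}

#' Partition a truth dataset into three score bins
#'
#' Bins are `score <= low_cut`, `low_cut < score < high_cut` and
#' `score >= high_cut`: the outer boundaries are inclusive, so a score equal
#' to `high_cut` falls in the high bin.
#'
#' @param records Data frame with columns `score` and `spliceogenic`.
#' @param low_cut,high_cut Score cut-offs, `0 <= low_cut < high_cut <= 1`.
#' @return A list of three [bin_counts()] named `low`, `mid`, `high`.
#' @export
bin_dataset <- function(records, low_cut, high_cut) {
  records <- .check_truth(records)
  if (!(low_cut >= 0 && low_cut < high_cut && high_cut <= 1))
    stop("need 0 <= low_cut < high_cut <= 1")
  s <- records$score; y <- records$spliceogenic
  A <- sum(y); B <- sum(!y)
  mk <- function(keep) bin_counts(sum(keep & y), A, sum(keep & !y), B)
  list(low = mk(s <= low_cut),
       mid = mk(s > low_cut & s < high_cut),
       high = mk(s >= high_cut))
}

#' Sensitivity and specificity at the outer cut-offs
#'
#' Sensitivity is the fraction of spliceogenic records with
#' `score >= high_cut`; specificity the fraction of non-spliceogenic records
#' with `score <= low_cut` (true negatives out of all negatives).
#'
#' @inheritParams bin_dataset
#' @return A list with `sensitivity`, `specificity` (proportions) and the
#'   underlying counts.
#' @export
sensitivity_specificity <- function(records, low_cut = 0.1, high_cut = 0.2) {
  records <- .check_truth(records)
  y <- records$spliceogenic
  if (!any(y) || all(y)) stop("need records from both classes")
  s <- records$score
  list(sensitivity = sum(y & s >= high_cut) / sum(y),
       specificity = sum(!y & s <= low_cut) / sum(!y),
       n_pos = sum(y), n_neg = sum(!y),
       tp = sum(y & s >= high_cut), tn = sum(!y & s <= low_cut))
}

#' Exhaustive grid search for score cut-offs
#'
#' Evaluates every pair `(low, high)` with `low < high` on a regular score
#' grid and returns the pair minimising
#' `w_fn * FN_rate + w_fp * FP_rate + w_uninf * uninformative_fraction`,
#' where the false-negative rate is the fraction of spliceogenic records at
#' or below `low`, the false-positive rate the fraction of non-spliceogenic
#' records at or above `high`, and the uninformative fraction the share of
#' all records strictly between the cuts. Exact objective ties are broken
#' towards the wider uninformative zone (more conservative), then the lower
#' `low` cut.
#'
#' @param records Data frame with columns `score` and `spliceogenic`.
#' @param grid_step Grid resolution on the score axis.
#' @param objective_weights Named or positional weights `(w_fn, w_fp,
#'   w_uninf)`.
#' @return A list with `low_cut`, `high_cut`, `objective` and `diagnostics`
#'   (rates and counts at the optimum).
#' @export
optimize_cutoffs <- function(records, grid_step = 0.01,
                             objective_weights = c(1, 1, 1)) {
  records <- .check_truth(records)
  y <- records$spliceogenic
  if (sum(y) < 2 || sum(!y) < 2) stop("need >= 2 records per class")
  if (length(objective_weights) != 3 || any(objective_weights < 0))
    stop("objective_weights must be three non-negative numbers")
  w <- as.numeric(objective_weights)
  grid <- seq(0, 1, by = grid_step)
  if (length(grid) < 2) stop("grid_step yields an empty grid")
  pos <- records$score[y]; neg <- records$score[!y]
  np <- length(pos); nn <- length(neg); N <- np + nn
  pos_le <- vapply(grid, function(g) sum(pos <= g), numeric(1))
  neg_le <- vapply(grid, function(g) sum(neg <= g), numeric(1))
  pos_lt <- vapply(grid, function(g) sum(pos < g), numeric(1))
  neg_lt <- vapply(grid, function(g) sum(neg < g), numeric(1))

  ng <- length(grid)
  li <- rep(seq_len(ng), times = ng)
  hi <- rep(seq_len(ng), each = ng)
  keep <- grid[li] < grid[hi]
  li <- li[keep]; hi <- hi[keep]
  fn <- pos_le[li] / np
  fp <- (nn - neg_lt[hi]) / nn
  mid <- ((pos_lt[hi] - pos_le[li]) + (neg_lt[hi] - neg_le[li])) / N
  obj <- w[1] * fn + w[2] * fp + w[3] * mid
  best <- which(obj <= min(obj) + 1e-12)
  if (length(best) > 1) {
    width <- grid[hi[best]] - grid[li[best]]
    best <- best[order(-width, grid[li[best]])][1]
  }
  list(low_cut = grid[li[best]], high_cut = grid[hi[best]],
       objective = obj[best],
       diagnostics = list(
         fn_rate = fn[best], fp_rate = fp[best],
         uninformative_fraction = mid[best],
         n_fn = fn[best] * np, n_fp = fp[best] * nn,
         n_uninformative = round(mid[best] * N),
         n_pos = np, n_neg = nn, weights = w, grid_step = grid_step))
}

#' Likelihood ratios over arbitrary score bands
#'
#' Each band is half-open, `lower <= score < upper`, except that a band
#' reaching the top of the score range (`upper >= 1`) is closed, so
#' complementary bands partition the data without double counting. A band
#' containing no record of one class is returned with `NA` ratio and flagged
#' `empty`.
#'
#' @param records Data frame with columns `score` and `spliceogenic`.
#' @param band_edges A data frame with columns `lower` and `upper`, or a list
#'   of length-2 numeric vectors. Bands must not overlap.
#' @param thresholds A [strength_thresholds()] for strength labels.
#' @param z Normal quantile for intervals.
#' @return A data frame with one row per band: bounds, counts, `lr`,
#'   `ci_low`, `ci_high`, `strength`, `empty`.
#' @export
band_lrs <- function(records, band_edges,
                     thresholds = strength_thresholds(), z = 1.96) {
  records <- .check_truth(records)
  if (is.list(band_edges) && !is.data.frame(band_edges))
    band_edges <- data.frame(lower = vapply(band_edges, `[`, numeric(1), 1),
                             upper = vapply(band_edges, `[`, numeric(1), 2))
  if (!all(c("lower", "upper") %in% names(band_edges)))
    stop("band_edges needs columns 'lower' and 'upper'")
  be <- band_edges[order(band_edges$lower), , drop = FALSE]
  if (any(be$upper <= be$lower)) stop("bands must have lower < upper")
  if (nrow(be) > 1 && any(be$lower[-1] < be$upper[-nrow(be)]))
    stop("bands must not overlap")
  s <- records$score; y <- records$spliceogenic
  A <- sum(y); B <- sum(!y)
  out <- lapply(seq_len(nrow(be)), function(i) {
    lo <- be$lower[i]; up <- be$upper[i]
    keep <- s >= lo & (if (up >= 1) s <= up else s < up)
    a <- sum(keep & y); b <- sum(keep & !y)
    if (a == 0 && b == 0)
      return(data.frame(lower = lo, upper = up, n_pos = 0, n_neg = 0,
                        lr = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
                        strength = NA_character_, empty = TRUE))
    r <- compute_lr(bin_counts(a, A, b, B), z = z, thresholds = thresholds)
    data.frame(lower = lo, upper = up, n_pos = a, n_neg = b, lr = r$lr,
               ci_low = r$ci_low, ci_high = r$ci_high,
               strength = r$strength, empty = FALSE)
  })
  do.call(rbind, out)
}

#' Per-stratum likelihood-ratio calibration at fixed cut-offs
#'
#' Splits the truth dataset by a grouping column (typically the splice-region
#' class), bins each stratum at the same cut-offs and computes per-bin
#' likelihood ratios and strengths. Strata lacking records of either class
#' are skipped with a warning.
#'
#' @param records Data frame with columns `score`, `spliceogenic` and the
#'   grouping column.
#' @param low_cut,high_cut Score cut-offs.
#' @param by Name of the grouping column (default `"region"`).
#' @param thresholds A [strength_thresholds()].
#' @return A data frame with one row per stratum and bin.
#' @export
stratified_calibration <- function(records, low_cut = 0.1, high_cut = 0.2,
                                   by = "region",
                                   thresholds = strength_thresholds()) {
  records <- .check_truth(records)
  if (!by %in% names(records)) stop("grouping column '", by, "' not found")
  out <- lapply(split(records, records[[by]]), function(d) {
    if (!any(d$spliceogenic) || all(d$spliceogenic)) {
      warning("stratum '", d[[by]][1], "' lacks one class; skipped")
      return(NULL)
    }
    bins <- bin_dataset(d, low_cut, high_cut)
    rows <- lapply(names(bins), function(nm) {
      r <- compute_lr(bins[[nm]], thresholds = thresholds)
      data.frame(stratum = as.character(d[[by]][1]), bin = nm,
                 n_pos = r$counts$n_pos_in, n_neg = r$counts$n_neg_in,
                 lr = r$lr, ci_low = r$ci_low, ci_high = r$ci_high,
                 strength = r$strength)
    })
    do.call(rbind, rows)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
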