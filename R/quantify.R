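## Spot-volume normalization, fold changes and thresholds; expression-matrix
## centering and fold differences.

#' Normalize spot volumes within each gel
#'
#' Each spot's normalized volume is its raw optical density divided by the
#' total density over all spots in the same condition, so normalized
#' volumes sum to one per gel.  Fold change is symmetric
#' (`max(normA, normB) / min(normA, normB)`, always >= 1) with the
#' direction carried separately.
#'
#' @param spots data frame with columns `spot_id`, `raw_A`, `raw_B` (extra
#'   columns such as `accession` are carried through).  Spots missing in
#'   one gel (`NA` or negative volume) are dropped with a warning.
#' @return the input plus `norm_A`, `norm_B`, `fold_change`, `direction`
#'   (`"up_A"`, `"up_B"` or `"unchanged"`).
#' @export
normalize_volumes <- function(spots) {
  stopifnot(is.data.frame(spots),
            all(c("spot_id", "raw_A", "raw_B") %in% names(spots)))
  bad <- !is.finite(spots$raw_A) | !is.finite(spots$raw_B) |
    spots$raw_A < 0 | spots$raw_B < 0
  if (any(bad)) {
    warning(sum(bad), " spot(s) absent or invalid in one gel; excluded")
    spots <- spots[!bad, , drop = FALSE]
  }
  if (!nrow(spots) || sum(spots$raw_A) <= 0 || sum(spots$raw_B) <= 0)
    stop("degenerate input: a condition has no positive spot volume")
  spots$norm_A <- spots$raw_A / sum(spots$raw_A)
  spots$norm_B <- spots$raw_B / sum(spots$raw_B)
  hi <- pmax(spots$norm_A, spots$norm_B)
  lo <- pmin(spots$norm_A, spots$norm_B)
  spots$fold_change <- ifelse(lo > 0, hi / lo, Inf)
  spots$direction <- ifelse(spots$norm_A > spots$norm_B, "up_A",
                            ifelse(spots$norm_B > spots$norm_A, "up_B",
                                   "unchanged"))
  spots
}

#' Retain spots changed by at least a given fold
#'
#' "At least" is inclusive: a spot at exactly the threshold survives, so
#' the conventional 1.5-fold cut keeps 1.5-fold spots.  Input order is
#' preserved.
#'
#' @param records output of [normalize_volumes()].
#' @param threshold fold-change threshold, >= 1.
#' @return the filtered data frame.
#' @export
fold_filter <- function(records, threshold = 1.5) {
  if (!is.numeric(threshold) || threshold < 1)
    stop("threshold must be >= 1")
  stopifnot("fold_change" %in% names(records))
  records[records$fold_change >= threshold, , drop = FALSE]
}

#' Center a log-abundance expression matrix and compute fold differences
#'
#' Each probe (row) is centered by subtracting its mean across cell lines;
#' the fold difference between two named lines is the difference of their
#' log10 abundances (sign gives direction).  Probes with missing values
#' are excluded and reported.
#'
#' @param expr numeric matrix, probes x cell lines, log10 abundances.
#' @param line_a,line_b column names to contrast (default first two).
#' @return list with `centered` (matrix), `fold_difference` (named vector,
#'   log10 units, `line_a` minus `line_b`) and `excluded` (probe ids
#'   dropped for missingness).
#' @export
center_and_fold <- function(expr, line_a = colnames(expr)[1],
                            line_b = colnames(expr)[2]) {
  stopifnot(is.matrix(expr), ncol(expr) >= 2,
            line_a %in% colnames(expr), line_b %in% colnames(expr))
  ok <- stats::complete.cases(expr)
  excluded <- rownames(expr)[!ok]
  if (length(excluded))
    message(length(excluded), " probe(s) excluded for missing values")
  expr <- expr[ok, , drop = FALSE]
  centered <- expr - rowMeans(expr)
  fold <- expr[, line_a] - expr[, line_b]
  list(centered = centered, fold_difference = fold, excluded = excluded)
}
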