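## Canonical-pathway over-representation: 2x2 contingency tables,
## right-tailed Fisher's exact test, Benjamini-Hochberg correction and
## significance ranking.

#' Build the enrichment contingency table for each pathway
#'
#' For a focus set against a pathway of size `n` inside a universe of `N`
#' annotated molecules, the 2x2 table is determined by the quadruple
#' `(k, n, K, N)`: `k` focus molecules in the pathway, `K` focus molecules
#' in total.  The universe defaults to the union of all pathway members;
#' focus molecules outside the universe are dropped with a warning (they
#' cannot inform annotation-based enrichment).
#'
#' @param focus character vector of focus accessions.
#' @param pathways named list of character vectors (pathway members).
#' @param universe optional explicit background; default
#'   `unique(unlist(pathways))`.
#' @return data frame `pathway_id`, `k`, `n`, `K`, `N`.
#' @export
build_tables <- function(focus, pathways, universe = NULL) {
  stopifnot(is.list(pathways))
  if (is.null(universe)) universe <- unique(unlist(pathways))
  focus <- unique(focus)
  out_univ <- setdiff(focus, universe)
  if (length(out_univ))
    warning(length(out_univ),
            " focus accession(s) absent from the annotation universe; dropped")
  focus <- intersect(focus, universe)
  K <- length(focus); N <- length(universe)
  data.frame(
    pathway_id = names(pathways),
    k = vapply(pathways, function(p) length(intersect(focus, p)), 0L),
    n = vapply(pathways, function(p) length(intersect(p, universe)), 0L),
    K = K, N = N, row.names = NULL, stringsAsFactors = FALSE)
}

#' Right-tailed Fisher's exact test on an enrichment table
#'
#' The p-value is the hypergeometric upper tail: the probability of at
#' least `k` focus molecules in a pathway of size `n`, when `K` of the `N`
#' universe molecules are focus, computed as the explicit tail sum
#' `sum_{x=k}^{min(n,K)} C(K,x) C(N-K,n-x) / C(N,n)`.
#'
#' @param k,n,K,N contingency quadruple (see [build_tables()]); vectors
#'   are recycled element-wise.
#' @return p-value(s) in (0, 1].
#' @export
fisher_right_tail <- function(k, n, K, N) {
  args <- cbind(k, n, K, N)
  vapply(seq_len(nrow(args)), function(i) {
    k <- args[i, 1]; n <- args[i, 2]; K <- args[i, 3]; N <- args[i, 4]
    if (k < 0 || k > min(n, K) || n > N || K > N ||
        (N - n) - (K - k) < 0)
      stop("invalid contingency table (k=", k, ", n=", n, ", K=", K,
           ", N=", N, ")")
    support <- k:min(n, K)
    min(1, sum(dhyper(support, K, N - K, n)))
  }, 0)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate correction (delegates to
#' [stats::p.adjust()] after validating the inputs); adjusted values are
#' returned in input order.
#'
#' @param p raw p-values in [0, 1].
#' @return adjusted p-values.
#' @export
bh_adjust <- function(p) {
  if (any(!is.finite(p)) || any(p < 0 | p > 1))
    stop("p-values must lie in [0, 1]")
  p.adjust(p, method = "BH")
}

#' Pathway over-representation analysis
#'
#' Builds the per-pathway contingency tables, computes the right-tailed
#' Fisher p-value and its Benjamini-Hochberg adjustment, and the coverage
#' ratio `k / n` (focus molecules in the pathway over pathway size).
#'
#' @inheritParams build_tables
#' @param alpha significance level applied to the adjusted p-value
#'   (strict `<`).
#' @return data frame `pathway_id`, `k`, `n`, `K`, `N`, `ratio`, `p_raw`,
#'   `p_bh`, `significant`, `rank_by_p`, `rank_by_ratio`, ordered by
#'   ascending adjusted p (ties by pathway id).
#' @export
enrich_pathways <- function(focus, pathways, universe = NULL, alpha = 0.05) {
  tab <- build_tables(focus, pathways, universe)
  tab$ratio <- ifelse(tab$n > 0, tab$k / tab$n, 0)
  tab$p_raw <- fisher_right_tail(tab$k, tab$n, tab$K, tab$N)
  tab$p_bh <- bh_adjust(tab$p_raw)
  tab$significant <- tab$p_bh < alpha
  ord_p <- order(tab$p_bh, tab$pathway_id)
  ord_r <- order(-tab$ratio, tab$pathway_id)
  tab$rank_by_p[ord_p] <- seq_len(nrow(tab))
  tab$rank_by_ratio[ord_r] <- seq_len(nrow(tab))
  tab[ord_p, , drop = FALSE]
}

#' @rdname enrich_pathways
#' @param results a data frame from [enrich_pathways()] (re-ranks it).
#' @export
rank_pathways <- function(results, alpha = 0.05) {
  results$significant <- results$p_bh < alpha
  ord_p <- order(results$p_bh, results$pathway_id)
  ord_r <- order(-results$ratio, results$pathway_id)
  results$rank_by_p[ord_p] <- seq_len(nrow(results))
  results$rank_by_ratio[ord_r] <- seq_len(nrow(results))
  results[ord_p, , drop = FALSE]
}
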