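## Peptide-mass-fingerprint identification: background filtering, ppm
## matching, three scoring algorithms with a two-of-three consensus, and
## the Mr/pI plausibility check.

.check_peaklist <- function(peaks) {
  stopifnot(is.data.frame(peaks), all(c("mz", "intensity") %in% names(peaks)))
  if (nrow(peaks) > 1 && any(diff(peaks$mz) <= 0))
    stop("peak list m/z must be strictly increasing")
  if (any(peaks$intensity <= 0)) stop("peak intensities must be positive")
  peaks
}

#' Remove shared background peaks from a batch of peak lists
#'
#' Peaks are pooled across the batch and clustered into m/z bins by
#' single-linkage agglomeration (consecutive sorted peaks join a bin while
#' their relative gap is at most `bin_tolerance` ppm).  A bin observed in
#' strictly more than `occurrence_threshold` of the lists is treated as a
#' shared contaminant and removed from every list.
#'
#' @param batch named list of peak-list data frames (`mz`, `intensity`).
#' @param occurrence_threshold fraction of lists above which a bin is
#'   eliminated (strict `>`; the default 0.10 is the "more than 10%" rule).
#' @param bin_tolerance single-linkage gap in ppm (default 100, i.e. twice
#'   a typical 50 ppm calibration error).
#' @param min_batch smallest batch for which the filter is meaningful;
#'   smaller batches are refused rather than silently gutted.
#' @return list with `batch` (filtered lists, same names/order) and
#'   `removed` (data frame `bin_mz`, `n_lists`, `occurrence`).
#' @export
filter_background <- function(batch, occurrence_threshold = 0.10,
                              bin_tolerance = 100, min_batch = 10) {
  stopifnot(is.list(batch))
  if (length(batch) < min_batch)
    stop("background filtering needs at least ", min_batch,
         " peak lists (got ", length(batch),
         "); occurrence fractions are meaningless in tiny batches")
  lapply(batch, .check_peaklist)
  pool <- do.call(rbind, lapply(seq_along(batch), function(i) {
    data.frame(list = i, mz = batch[[i]]$mz)
  }))
  pool <- pool[order(pool$mz), , drop = FALSE]
  gap_ppm <- diff(pool$mz) / pool$mz[-nrow(pool)] * 1e6
  bin <- cumsum(c(1, as.integer(gap_ppm > bin_tolerance)))
  occ <- tapply(pool$list, bin, function(l) length(unique(l)))
  frac <- occ / length(batch)
  bad_bins <- names(frac)[frac > occurrence_threshold]
  bad_mz <- pool$mz[bin %in% bad_bins]
  removed <- data.frame(
    bin_mz = as.numeric(tapply(pool$mz, bin, mean)[bad_bins]),
    n_lists = as.integer(occ[bad_bins]),
    occurrence = as.numeric(frac[bad_bins]))
  filtered <- lapply(batch, function(pl) {
    pl[!pl$mz %in% bad_mz, , drop = FALSE]
  })
  names(filtered) <- names(batch)
  list(batch = filtered, removed = removed[order(removed$bin_mz), ,
                                           drop = FALSE])
}

#' Match observed peaks to theoretical masses within a ppm tolerance
#'
#' Each observed peak matches at most one theoretical mass: the nearest in
#' ppm, with ties broken toward the lower theoretical m/z; a match requires
#' `|obs - theo| / theo * 1e6 <= tolerance` (inclusive).
#'
#' @param mz observed m/z values.
#' @param theoretical theoretical m/z values.
#' @param tolerance_ppm match window in ppm.
#' @return data frame `obs`, `theo`, `ppm` (one row per matched peak).
#' @export
match_peaks <- function(mz, theoretical, tolerance_ppm = 50) {
  stopifnot(tolerance_ppm > 0)
  if (!length(mz) || !length(theoretical))
    return(data.frame(obs = numeric(), theo = numeric(), ppm = numeric()))
  theo <- sort(theoretical)
  rows <- lapply(mz, function(o) {
    ppm <- abs(o - theo) / theo * 1e6
    j <- which(ppm == min(ppm))[1]  # ties -> lower m/z (theo sorted)
    if (ppm[j] <= tolerance_ppm)
      data.frame(obs = o, theo = theo[j], ppm = ppm[j])
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) data.frame(obs = numeric(), theo = numeric(),
                               ppm = numeric()) else out
}

# theoretical [M+H]+ masses of a protein under a search config, with the
# variable Met-oxidation expansion; positions kept for coverage
.theoretical_peptides <- function(sequence, config) {
  fr <- tryptic_fragments(sequence, config$missed_cleavages)
  rows <- lapply(seq_len(nrow(fr)), function(i) {
    mzs <- peptide_mz(fr$peptide[i], config)
    data.frame(peptide = fr$peptide[i], start = fr$start[i],
               end = fr$end[i], mz = mzs)
  })
  out <- do.call(rbind, rows)
  out[out$mz >= config$mz_range[1] & out$mz <= config$mz_range[2], ,
      drop = FALSE]
}

#' Score every database protein against one peak list
#'
#' Three scoring algorithms stand in for the usual trio of PMF search
#' engines; their verdicts are combined by the published two-of-three
#' consensus rule:
#' \describe{
#'   \item{score1 (shared peaks)}{number of observed peaks matching a
#'     theoretical peptide mass of the candidate.}
#'   \item{score2 (coverage)}{percent of the candidate's residues covered
#'     by at least one matched peptide.}
#'   \item{score3 (rarity-weighted)}{sum over matched peptides of
#'     `-log10` of the fraction of all database peptide masses falling in
#'     the peptide's 100 Da mass bin, so matches at sparsely populated
#'     masses count more.}
#' }
#' Ranks are assigned per scorer among candidates with a positive score
#' (ties broken by accession order); a candidate is a consensus
#' identification when it ranks within `config$r_top` in at least two of
#' the three scorers.
#'
#' @param peaks one peak-list data frame (`mz`, `intensity`).
#' @param db named character vector of protein sequences (names are
#'   accessions).
#' @param config a [pmf_config()].
#' @param theo optional precomputed theoretical-peptide tables (internal
#'   cache used by [pmf_identify()]).
#' @return data frame, one row per database protein, ordered by consensus
#'   then rank sum: `accession`, `matched`, `coverage_pct`, `score1`,
#'   `score2`, `score3`, `rank1`, `rank2`, `rank3`, `consensus`.
#' @export
score_candidates <- function(peaks, db, config = pmf_config(),
                             theo = NULL) {
  stopifnot(length(db) > 0, !is.null(names(db)))
  db <- db[order(names(db))]
  if (is.null(theo))
    theo <- lapply(db, .theoretical_peptides, config = config)
  all_mz <- unlist(lapply(theo, `[[`, "mz"), use.names = FALSE)
  bin_counts <- table(floor(all_mz / 100))
  rarity <- function(mzs) {
    fr <- as.numeric(bin_counts[as.character(floor(mzs / 100))]) /
      length(all_mz)
    -log10(pmax(fr, .Machine$double.xmin))
  }
  rows <- lapply(names(db), function(acc) {
    tp <- theo[[acc]]
    m <- if (nrow(peaks)) match_peaks(peaks$mz, tp$mz, config$tolerance_ppm)
         else data.frame(obs = numeric(), theo = numeric(), ppm = numeric())
    hit <- tp[tp$mz %in% m$theo, , drop = FALSE]
    covered <- rep(FALSE, nchar(db[[acc]]))
    if (nrow(hit))
      for (i in seq_len(nrow(hit))) covered[hit$start[i]:hit$end[i]] <- TRUE
    uniq_hit <- hit[!duplicated(hit$mz), , drop = FALSE]
    data.frame(accession = acc,
               matched = nrow(m),
               coverage_pct = 100 * mean(covered),
               score1 = nrow(m),
               score2 = 100 * mean(covered),
               score3 = if (nrow(uniq_hit)) sum(rarity(uniq_hit$mz)) else 0,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rank_of <- function(score) {
    r <- rep(Inf, length(score))
    pos <- which(score > 0)
    if (length(pos)) {
      ord <- pos[order(-score[pos], out$accession[pos])]
      r[ord] <- seq_along(ord)
    }
    r
  }
  out$rank1 <- rank_of(out$score1)
  out$rank2 <- rank_of(out$score2)
  out$rank3 <- rank_of(out$score3)
  high <- (out$rank1 <= config$r_top) + (out$rank2 <= config$r_top) +
    (out$rank3 <= config$r_top)
  out$consensus <- high >= 2
  out[order(-out$consensus, out$rank1 + out$rank2 + out$rank3,
            out$accession), , drop = FALSE]
}

#' Batch PMF identification
#'
#' Applies the batch background filter, scores every list against the
#' database and reports the best consensus candidate per list (accession
#' `NA` when no candidate reaches consensus).
#'
#' @param batch named list of peak-list data frames.
#' @param db named character vector of protein sequences.
#' @param config a [pmf_config()].
#' @param filter apply [filter_background()] first (default TRUE).
#' @param ... passed to [filter_background()].
#' @return data frame, one row per peak list: `list_id`, `accession`,
#'   `matched`, `coverage_pct`, `score1..3`, `rank1..3`, `consensus`.
#' @export
pmf_identify <- function(batch, db, config = pmf_config(), filter = TRUE,
                         ...) {
  if (filter) batch <- filter_background(batch, ...)$batch
  db <- db[order(names(db))]
  theo <- lapply(db, .theoretical_peptides, config = config)
  rows <- lapply(names(batch), function(id) {
    sc <- score_candidates(batch[[id]], db, config, theo = theo)
    best <- sc[1, , drop = FALSE]
    if (!isTRUE(best$consensus[1]))
      best$accession <- NA_character_
    cbind(list_id = id, best)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Check agreement between observed and theoretical Mr and pI
#'
#' A gel spot's apparent molecular mass and isoelectric point lend support
#' to an identification when they agree with the candidate's theoretical
#' values: relative Mr deviation at most `mr_tol` and absolute pI
#' deviation at most `pi_tol`.
#'
#' @param accession candidate accession (must be in `db`).
#' @param observed_mr_kda apparent molecular mass from the gel, kDa.
#' @param observed_pi apparent isoelectric point, pH units.
#' @param db named character vector of protein sequences.
#' @param mr_tol relative Mr tolerance (default 0.20).
#' @param pi_tol absolute pI tolerance in pH units (default 1.0).
#' @return list `consistent`, `theoretical_mr_kda`, `theoretical_pi`.
#' @export
check_mr_pi <- function(accession, observed_mr_kda, observed_pi, db,
                        mr_tol = 0.20, pi_tol = 1.0) {
  if (!accession %in% names(db))
    stop("accession '", accession, "' not in database")
  mr <- protein_mass(db[[accession]]) / 1000
  pi <- isoelectric_point(db[[accession]])
  list(consistent = abs(mr - observed_mr_kda) / mr <= mr_tol &&
         abs(pi - observed_pi) <= pi_tol,
       theoretical_mr_kda = mr, theoretical_pi = pi)
}
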