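## Synthetic-data generators: every input the pipeline consumes, with
## planted ground truth, so the full chain is testable offline.

# approximate amino-acid frequencies of a vertebrate proteome
.AA_FREQ <- c(
  A = 0.070, R = 0.056, N = 0.036, D = 0.047, C = 0.023,
  Q = 0.048, E = 0.071, G = 0.066, H = 0.026, I = 0.043,
  L = 0.100, K = 0.057, M = 0.021, F = 0.037, P = 0.063,
  S = 0.083, T = 0.054, W = 0.012, Y = 0.027, V = 0.060
)

#' Generate a synthetic protein sequence database
#'
#' Random sequences over the 20 standard amino acids at vertebrate-like
#' residue frequencies.  Each sequence is rejected and redrawn until its
#' tryptic digest yields at least one peptide inside the instrument's
#' 800-3000 m/z window, so every record is identifiable in principle.
#'
#' @param n_proteins number of records (>= 1).
#' @param length_range inclusive sequence-length interval (min >= 10).
#' @param seed integer seed; output is deterministic per seed.
#' @param config a [pmf_config()] supplying the m/z window.
#' @return named character vector of sequences; accessions `SYP0001`...
#' @export
make_protein_db <- function(n_proteins, length_range = c(100, 400),
                            seed = 1, config = pmf_config()) {
  if (!is.numeric(n_proteins) || n_proteins < 1)
    stop("n_proteins must be >= 1")
  stopifnot(length_range[1] >= 10, length_range[2] >= length_range[1])
  set.seed(seed)
  draw <- function() {
    len <- sample(length_range[1]:length_range[2], 1)
    paste(sample(names(.AA_FREQ), len, replace = TRUE, prob = .AA_FREQ),
          collapse = "")
  }
  seqs <- character(n_proteins)
  for (i in seq_len(n_proteins)) {
    repeat {
      s <- draw()
      mzs <- unlist(lapply(digest(s, config$missed_cleavages),
                           function(p) peptide_mz(p, config)))
      if (any(mzs >= config$mz_range[1] & mzs <= config$mz_range[2])) break
    }
    seqs[i] <- s
  }
  names(seqs) <- sprintf("SYP%04d", seq_len(n_proteins))
  seqs
}

#' Generate a synthetic pathway/interaction knowledgebase
#'
#' Pathways are member sets sampled without replacement; the interaction
#' graph is simple and undirected with exactly `n_edges` edges.  When
#' `de_proteins` is supplied, one planted pathway draws at least
#' `planted_purity` of its members from the differentially expressed
#' proteins (so enrichment has a true top hit), and the interaction graph
#' concentrates the de proteins inside one densely wired community (so
#' network growth has a true high-scoring target).
#'
#' @param accessions universe of protein accessions.
#' @param n_pathways number of pathway sets (0 allowed).
#' @param size_range inclusive pathway-size interval; max must not exceed
#'   the number of accessions.
#' @param n_edges number of interaction edges.
#' @param seed integer seed.
#' @param de_proteins optional accessions to plant as enriched.
#' @param planted_purity fraction of the planted pathway drawn from
#'   `de_proteins` (default 0.8).
#' @param community_size nodes in the planted dense community
#'   (default 20).
#' @param community_density fraction of within-community pairs wired
#'   (default 0.6).
#' @return list `pathways` (named list of member vectors), `edges`
#'   (data frame `from`, `to`), `planted_pathway` (id or `NULL`),
#'   `community` (accessions or `NULL`).
#' @export
make_knowledgebase <- function(accessions, n_pathways, size_range,
                               n_edges, seed = 1, de_proteins = NULL,
                               planted_purity = 0.8, community_size = 20,
                               community_density = 0.6) {
  n <- length(accessions)
  stopifnot(size_range[2] <= n, size_range[1] >= 1)
  max_edges <- n * (n - 1) / 2
  if (n_edges > max_edges)
    stop("n_edges (", n_edges, ") exceeds the ", max_edges,
         " possible edges among ", n, " accessions")
  set.seed(seed)
  de <- intersect(de_proteins, accessions)
  pathways <- list()
  planted_id <- NULL
  if (n_pathways > 0) {
    sizes <- sample(size_range[1]:size_range[2], n_pathways, replace = TRUE)
    for (i in seq_len(n_pathways)) {
      if (i == 1 && length(de)) {
        s <- max(sizes[i], min(length(de), size_range[2]))
        n_in <- min(length(de), ceiling(planted_purity * s))
        members <- c(sample(de, n_in),
                     sample(setdiff(accessions, de), s - n_in))
        planted_id <- "PW001"
      } else {
        members <- sample(accessions, sizes[i])
      }
      pathways[[sprintf("PW%03d", i)]] <- sort(members)
    }
  }
  # interaction edges: planted community first, random remainder
  pair_id <- function(a, b) paste(pmin(a, b), pmax(a, b), sep = "\r")
  community <- NULL
  edges_from <- character(); edges_to <- character()
  if (length(de)) {
    community <- unique(c(de, sample(setdiff(accessions, de),
                                     max(0, min(community_size, n) -
                                           length(de)))))
    cp <- utils::combn(sort(community), 2)
    keep <- sample(ncol(cp), min(ncol(cp),
                                 floor(community_density * ncol(cp)),
                                 n_edges))
    edges_from <- cp[1, keep]; edges_to <- cp[2, keep]
  }
  used <- pair_id(edges_from, edges_to)
  n_left <- n_edges - length(used)
  while (n_left > 0) {
    a <- sample(accessions, 2 * n_left, replace = TRUE)
    b <- sample(accessions, 2 * n_left, replace = TRUE)
    ok <- a != b & !pair_id(a, b) %in% used & !duplicated(pair_id(a, b))
    a <- a[ok][seq_len(min(sum(ok), n_left))]
    b <- b[ok][seq_len(min(sum(ok), n_left))]
    edges_from <- c(edges_from, pmin(a, b))
    edges_to <- c(edges_to, pmax(a, b))
    used <- c(used, pair_id(a, b))
    n_left <- n_edges - length(used)
  }
  list(pathways = pathways,
       edges = data.frame(from = edges_from, to = edges_to,
                          stringsAsFactors = FALSE),
       planted_pathway = planted_id,
       community = if (is.null(community)) NULL else sort(community))
}

#' Generate a synthetic spot-volume table
#'
#' Differentially expressed spots get a raw A/B volume ratio of their
#' planted fold (alternating direction, up in A then up in B) times
#' multiplicative log-normal noise of coefficient of variation `cv`;
#' null spots get ratio 1 times noise.  Consecutive de spots are paired
#' to share a base volume so that, at a common fold, the two gels' total
#' volumes balance and normalized ratios equal the planted folds exactly
#' in the zero-noise limit.
#'
#' @param truth list with `de_proteins`, `planted_folds` (named, >= 1)
#'   and `accessions` (the database accessions to label spots with).
#' @param n_spots total spots (>= number of de proteins).
#' @param cv coefficient of variation of the multiplicative noise,
#'   `0 <= cv < 1`.
#' @param seed integer seed.
#' @return data frame `spot_id`, `accession`, `raw_A`, `raw_B` plus
#'   ground-truth columns `is_de`, `true_fold`, `true_direction`.
#' @export
make_spot_table <- function(truth, n_spots, cv = 0.1, seed = 1) {
  stopifnot(cv >= 0, cv < 1)
  de <- truth$de_proteins
  stopifnot(n_spots >= length(de))
  set.seed(seed)
  accs <- c(de, rep_len(setdiff(truth$accessions, de),
                        n_spots - length(de)))
  is_de <- c(rep(TRUE, length(de)), rep(FALSE, n_spots - length(de)))
  fold <- ifelse(is_de, truth$planted_folds[accs], 1)
  dir <- ifelse(is_de,
                ifelse(seq_len(n_spots) %% 2 == 1, "up_A", "up_B"),
                "unchanged")
  base <- rlnorm(n_spots, meanlog = log(1e5), sdlog = 0.5)
  # paired de spots share a base so planted folds cancel in the totals
  de_idx <- which(is_de)
  if (length(de_idx) > 1)
    for (j in seq(2, length(de_idx), by = 2))
      base[de_idx[j]] <- base[de_idx[j - 1]]
  raw_A <- ifelse(dir == "up_A", fold * base, base)
  raw_B <- ifelse(dir == "up_B", fold * base, base)
  if (cv > 0) {
    sl <- sqrt(log(1 + cv^2))
    raw_A <- raw_A * exp(rnorm(n_spots, -sl^2 / 2, sl))
    raw_B <- raw_B * exp(rnorm(n_spots, -sl^2 / 2, sl))
  }
  data.frame(spot_id = sprintf("S%03d", seq_len(n_spots)),
             accession = unname(accs), raw_A = unname(raw_A),
             raw_B = unname(raw_B), is_de = is_de,
             true_fold = unname(fold), true_direction = dir,
             stringsAsFactors = FALSE)
}

#' Generate synthetic peptide-mass-fingerprint peak lists
#'
#' One peak list per identity: a Bernoulli(`detect_prob`) subset of the
#' protein's tryptic [M+H]+ masses inside the acquisition window, each
#' perturbed by Gaussian relative error of scale `ppm_jitter`, plus a
#' pool of `n_background` shared contaminant peaks (uniform on the
#' window) each inserted into a given list with probability
#' `background_occurrence`.  Intensities are log-normal; masses are
#' strictly ascending.
#'
#' @param db named character vector of protein sequences.
#' @param identities character vector of accessions, one per peak list
#'   (names become list ids; default `PL001`...).
#' @param detect_prob per-peptide detection probability in (0, 1].
#' @param ppm_jitter Gaussian mass-error scale in ppm (>= 0).
#' @param n_background size of the shared contaminant pool.
#' @param background_occurrence per-list insertion probability of each
#'   contaminant peak.
#' @param seed integer seed.
#' @param config a [pmf_config()].
#' @return list `peak_lists` (named list of data frames `mz`,
#'   `intensity`), `identity` (named accession vector),
#'   `background_mz` (the contaminant pool).
#' @export
make_peak_lists <- function(db, identities, detect_prob = 0.6,
                            ppm_jitter = 15, n_background = 5,
                            background_occurrence = 0.15, seed = 1,
                            config = pmf_config()) {
  stopifnot(detect_prob > 0, detect_prob <= 1, ppm_jitter >= 0)
  if (!length(identities))
    return(list(peak_lists = list(),
                identity = setNames(character(), character()),
                background_mz = numeric()))
  stopifnot(all(identities %in% names(db)))
  set.seed(seed)
  ids <- if (!is.null(names(identities))) names(identities)
         else sprintf("PL%03d", seq_along(identities))
  bg <- sort(runif(n_background, config$mz_range[1], config$mz_range[2]))
  lists <- lapply(seq_along(identities), function(i) {
    true_mz <- unique(sort(unlist(
      lapply(digest(db[[identities[i]]], config$missed_cleavages),
             peptide_mz, config = config, n_oxidized_met = 0))))
    true_mz <- true_mz[true_mz >= config$mz_range[1] &
                         true_mz <= config$mz_range[2]]
    det <- true_mz[runif(length(true_mz)) < detect_prob]
    if (ppm_jitter > 0)
      det <- det * (1 + rnorm(length(det), 0, ppm_jitter * 1e-6))
    mz <- c(det, bg[runif(n_background) < background_occurrence])
    mz <- sort(unique(mz))
    data.frame(mz = mz,
               intensity = rlnorm(length(mz), meanlog = log(100),
                                  sdlog = 0.8))
  })
  names(lists) <- ids
  list(peak_lists = lists, identity = setNames(unname(identities), ids),
       background_mz = bg)
}

#' Generate synthetic densitometry replicates
#'
#' Paired target and loading-control band densities for conditions A and
#' B such that the replicate log10 loading-normalized ratio is
#' `Normal(true_R, sigma^2)`.
#'
#' @param true_R true log10 expression ratio.
#' @param sigma replicate log10 standard deviation (> 0).
#' @param n_replicates number of paired replicates (>= 2).
#' @param seed integer seed.
#' @return data frame `replicate`, `condition`, `target_density`,
#'   `loading_density` (long format, one row per lane).
#' @export
make_densitometry <- function(true_R, sigma, n_replicates, seed = 1) {
  if (n_replicates < 2)
    stop("n_replicates must be >= 2 (replicate variance undefined)")
  stopifnot(sigma > 0)
  set.seed(seed)
  y <- rnorm(n_replicates, true_R, sigma)
  x_B <- rlnorm(n_replicates, meanlog = 0, sdlog = 0.2)
  x_A <- x_B * 10 ^ y
  load_A <- rlnorm(n_replicates, meanlog = log(50), sdlog = 0.1)
  load_B <- rlnorm(n_replicates, meanlog = log(50), sdlog = 0.1)
  rbind(
    data.frame(replicate = seq_len(n_replicates), condition = "A",
               target_density = x_A * load_A, loading_density = load_A),
    data.frame(replicate = seq_len(n_replicates), condition = "B",
               target_density = x_B * load_B, loading_density = load_B))
}

#' Generate a complete synthetic study with planted ground truth
#'
#' One call builds every input of the inference chain under a single
#' global seed (split into per-generator child seeds by
#' [child_seed()]): a protein database, a spot table with a planted
#' fraction of differentially expressed spots, one peak list per spot, a
#' pathway/interaction knowledgebase enriched for the de proteins, and
#' densitometry replicates with a known log10 ratio.
#'
#' @param seed global integer seed.
#' @param n_proteins,length_range protein database shape.
#' @param n_spots,n_de,fold,cv spot-table shape: `n_de` spots planted at
#'   `fold` with multiplicative noise `cv`.
#' @param n_pathways,pathway_size,n_edges knowledgebase shape.
#' @param detect_prob,ppm_jitter,n_background,background_occurrence peak
#'   list generator settings.
#' @param true_R,dens_sigma,n_replicates densitometry settings.
#' @param config a [pmf_config()].
#' @return list with `db`, `spots`, `peaks` (see [make_peak_lists()]),
#'   `kb` (see [make_knowledgebase()]), `densitometry` and `truth`
#'   (`de_proteins`, `planted_folds`, `spectrum_identity`,
#'   `enriched_pathways`, `true_R`, `seed`).
#' @export
make_synthetic_study <- function(seed = 1, n_proteins = 60,
                                 length_range = c(150, 400),
                                 n_spots = 60, n_de = 10, fold = 2.0,
                                 cv = 0.1, n_pathways = 12,
                                 pathway_size = c(4, min(10, n_proteins)),
                                 n_edges = min(4 * n_proteins,
                                               n_proteins *
                                                 (n_proteins - 1) %/% 2),
                                 detect_prob = 0.7, ppm_jitter = 10,
                                 n_background = 6,
                                 background_occurrence = 0.15,
                                 true_R = log10(1.4), dens_sigma = 0.05,
                                 n_replicates = 6,
                                 config = pmf_config()) {
  db <- make_protein_db(n_proteins, length_range,
                        child_seed(seed, .seed_streams[["protein_db"]]),
                        config)
  de <- names(db)[seq_len(n_de)]
  truth <- list(de_proteins = de,
                planted_folds = setNames(rep(fold, n_de), de),
                accessions = names(db), true_R = true_R, seed = seed)
  spots <- make_spot_table(truth, n_spots, cv,
                           child_seed(seed, .seed_streams[["spot_table"]]))
  peaks <- make_peak_lists(
    db, setNames(spots$accession, sprintf("PL%03d", seq_len(n_spots))),
    detect_prob, ppm_jitter, n_background, background_occurrence,
    child_seed(seed, .seed_streams[["peak_lists"]]), config)
  kb <- make_knowledgebase(names(db), n_pathways, pathway_size, n_edges,
                           child_seed(seed,
                                      .seed_streams[["knowledgebase"]]),
                           de_proteins = de)
  dens <- make_densitometry(true_R, dens_sigma, n_replicates,
                            child_seed(seed,
                                       .seed_streams[["densitometry"]]))
  truth$spectrum_identity <- peaks$identity
  truth$enriched_pathways <- kb$planted_pathway
  list(db = db, spots = spots, peaks = peaks, kb = kb,
       densitometry = dens, truth = truth)
}
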