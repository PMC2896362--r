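## End-to-end orchestration: quantify -> identify -> enrich -> network
## (-> Bayesian ratio), with every threshold recorded in the run report.

#' Pipeline configuration
#'
#' Collects the file paths and thresholds of a full run.  Defaults are
#' the published settings of the workflow this package implements:
#' spots are picked at 1.1-fold, analyzed at 1.5-fold, searched at 50 ppm
#' with one missed cleavage, background peaks are dropped above 10%
#' batch occurrence, pathways are flagged at adjusted p < 0.05, networks
#' are capped at 35 nodes and called significant at score >= 6, and the
#' sampler is tuned to a 0.4 acceptance fraction with a 1.1 Gelman-Rubin
#' convergence bound.
#'
#' @param spot_csv,mgf,fasta,gmt,sif,densitometry_csv input file paths
#'   (`densitometry_csv` may be `NULL`).
#' @param pick_fold,analysis_fold spot fold-change thresholds.
#' @param tolerance_ppm,missed_cleavages,background_occurrence,r_top PMF
#'   search settings.
#' @param alpha pathway significance level on adjusted p.
#' @param network_max,score_cutoff network growth cap and score
#'   convention.
#' @param n_iter,n_burn,target_acceptance,psrf_threshold MCMC settings.
#' @param seeds three MCMC chain seeds.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(spot_csv, mgf, fasta, gmt, sif,
                            densitometry_csv = NULL,
                            pick_fold = 1.1, analysis_fold = 1.5,
                            tolerance_ppm = 50, missed_cleavages = 1,
                            background_occurrence = 0.10, r_top = 5,
                            alpha = 0.05, network_max = 35,
                            score_cutoff = 6, n_iter = 6000,
                            n_burn = 2000, target_acceptance = 0.4,
                            psrf_threshold = 1.1, seeds = c(1L, 2L, 3L)) {
  structure(as.list(environment()), class = "pipeline_config")
}

#' Run the full inference chain
#'
#' Stages: (1) normalize spot volumes, pick spots at the picking fold
#' threshold; (2) identify picked spots from their peak lists by
#' consensus PMF search; (3) re-threshold identified spots at the
#' analysis fold to form the focus set; (4) pathway over-representation;
#' (5) focus-network growth and scoring; (6) when densitometry is
#' supplied, Bayesian MCMC estimation of the expression ratio.  A stage
#' failure aborts with the stage name; artifacts computed so far are
#' returned in the error condition where possible.
#'
#' @param config a [pipeline_config()].
#' @return list of class `pipeline_report`: `counts` (spots at each
#'   funnel stage), `spots`, `identifications`, `focus`, `pathways`,
#'   `networks`, `ratio` (or `NULL`), `config`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  pconf <- pmf_config(tolerance_ppm = config$tolerance_ppm,
                      missed_cleavages = config$missed_cleavages,
                      r_top = config$r_top)

  spots_raw <- stage("quantify", read_spot_csv(config$spot_csv))
  spots <- stage("quantify", normalize_volumes(spots_raw))
  picked <- fold_filter(spots, config$pick_fold)

  idents <- stage("pmf", {
    db <- read_fasta(config$fasta)
    batch <- read_mgf(config$mgf)
    # peak lists pair with spot-table rows by position
    spot2list <- setNames(names(batch),
                          spots_raw$spot_id[seq_along(batch)])
    keep <- unname(spot2list[picked$spot_id])
    keep <- keep[!is.na(keep)]
    res <- pmf_identify(batch[keep], db, pconf,
                        occurrence_threshold =
                          config$background_occurrence)
    res$spot_id <- names(spot2list)[match(res$list_id, spot2list)]
    res
  })
  ids <- setNames(idents$accession, idents$spot_id)
  identified <- picked
  identified$identified_as <- unname(ids[identified$spot_id])
  identified <- identified[!is.na(identified$identified_as), ,
                           drop = FALSE]

  analysis <- fold_filter(identified, config$analysis_fold)
  focus <- unique(analysis$identified_as)

  pathways <- stage("enrichment", {
    enrich_pathways(focus, read_gmt(config$gmt), alpha = config$alpha)
  })

  networks <- stage("network", {
    edges <- read_sif(config$sif)
    g <- igraph::graph_from_data_frame(edges, directed = FALSE)
    grow_networks(g, focus, config$network_max, config$score_cutoff)
  })

  ratio <- NULL
  if (!is.null(config$densitometry_csv)) {
    ratio <- stage("bayes_ratio", {
      dens <- normalize_blots(read_densitometry_csv(
        config$densitometry_csv))
      ch <- run_mcmc(dens, n_iter = config$n_iter, n_burn = config$n_burn,
                     target_acceptance = config$target_acceptance,
                     seeds = config$seeds)
      summarize_posterior(ch, psrf_threshold = config$psrf_threshold)
    })
  }

  structure(list(
    counts = c(spots = nrow(spots), picked = nrow(picked),
               identified = nrow(identified),
               analysis_fold = nrow(analysis),
               focus_proteins = length(focus)),
    spots = spots, identifications = idents, focus = focus,
    pathways = pathways, networks = networks, ratio = ratio,
    config = config), class = "pipeline_report")
}

#' Generate a synthetic study and run the pipeline on it
#'
#' Writes the synthetic inputs to `dir`, builds a default
#' [pipeline_config()] pointing at them and calls [run_pipeline()].
#'
#' @param seed global seed for the synthetic study.
#' @param dir working directory for the generated files.
#' @param ... overrides passed to [make_synthetic_study()].
#' @return list `report` (the [run_pipeline()] result), `study`, `paths`.
#' @export
demo_pipeline <- function(seed = 1, dir = tempfile("protpipe_demo"),
                          ...) {
  study <- make_synthetic_study(seed = seed, ...)
  paths <- write_study(study, dir)
  config <- pipeline_config(
    spot_csv = paths[["spots"]], mgf = paths[["mgf"]],
    fasta = paths[["fasta"]], gmt = paths[["gmt"]],
    sif = paths[["sif"]],
    densitometry_csv = paths[["densitometry"]],
    seeds = child_seed(seed, .seed_streams[c("mcmc_chain1",
                                             "mcmc_chain2",
                                             "mcmc_chain3")]))
  list(report = run_pipeline(config), study = study, paths = paths)
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("protpipe run\n")
  cat("  funnel:", paste(names(x$counts), x$counts, sep = "=",
                         collapse = "  "), "\n")
  cat("  top pathway:",
      if (nrow(x$pathways)) sprintf("%s (p_bh=%.3g, ratio=%.3f)",
                                    x$pathways$pathway_id[1],
                                    x$pathways$p_bh[1],
                                    x$pathways$ratio[1]) else "none", "\n")
  if (nrow(x$networks$summary))
    cat("  top network: score",
        sprintf("%.1f with %d focus proteins of %d nodes",
                x$networks$summary$score[1],
                x$networks$summary$focus_count[1],
                x$networks$summary$size[1]), "\n")
  if (!is.null(x$ratio))
    cat(sprintf(
      "  expression ratio: R=%.3f (fold %.2f), 95%% CI [%.3f, %.3f], P(R<=0)=%.3g\n",
      x$ratio$mean, x$ratio$fold, x$ratio$ci[1], x$ratio$ci[2],
      x$ratio$p_le_0))
  invisible(x)
}
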