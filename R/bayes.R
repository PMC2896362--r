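## Empirical-Bayes MCMC estimation of the densitometry expression ratio:
## loading-control normalization, adaptive random-walk Metropolis,
## Gelman-Rubin diagnostic and posterior summaries.

#' Normalize densitometry replicates to the loading control
#'
#' Each lane's target band density is divided by its loading-control
#' (e.g. GAPDH) density; replicate log-ratios are
#' `y_i = log10(x_A,i) - log10(x_B,i)` under the model
#' `log10(X_A) = R + log10(X_B)`.
#'
#' @param raw data frame with columns `replicate`, `condition` (two
#'   levels, `"A"`/`"B"`), `target_density`, `loading_density`; densities
#'   must be positive.
#' @return list of class `densitometry_set`: `x_A`, `x_B` (normalized
#'   levels per replicate), `y` (replicate log10 ratios), `n`.
#' @export
normalize_blots <- function(raw) {
  stopifnot(is.data.frame(raw),
            all(c("replicate", "condition", "target_density",
                  "loading_density") %in% names(raw)))
  bad <- which(raw$target_density <= 0 | raw$loading_density <= 0)
  if (length(bad))
    stop("non-positive band density in lane(s): ",
         paste(bad, collapse = ", "))
  x <- raw$target_density / raw$loading_density
  a <- raw$condition == "A"
  xa <- x[a][order(raw$replicate[a])]
  xb <- x[!a][order(raw$replicate[!a])]
  if (length(xa) != length(xb))
    stop("conditions A and B must have paired replicates")
  if (length(xa) < 2) stop("need at least 2 replicates")
  structure(list(x_A = xa, x_B = xb, y = log10(xa) - log10(xb),
                 n = length(xa)), class = "densitometry_set")
}

.log_posterior <- function(R, log_sigma, y, sigma_floor = 1e-6,
                           prior = "flat", prior_tau = 1) {
  s <- max(exp(log_sigma), sigma_floor)
  lp <- -length(y) * log(s) - sum((y - R)^2) / (2 * s^2)
  if (prior == "normal") lp <- lp - R^2 / (2 * prior_tau^2)
  lp  # flat prior on R and on log sigma otherwise
}

#' Random-walk Metropolis sampler for the expression ratio
#'
#' Samples `(R, log sigma)` under a Gaussian likelihood on the replicate
#' log10 ratios with flat priors (a zero-mean Gaussian prior on R is
#' available via `prior = "normal"`).  Proposals are zero-mean Gaussian
#' perturbations of the current state; during burn-in the proposal scale
#' is multiplied or divided by 1.1 after each 100-iteration block
#' according to whether the block's acceptance exceeded or fell short of
#' `target_acceptance`, and is frozen afterwards so post-burn-in samples
#' form a genuine Markov chain.  Three chains are started overdispersed at
#' the sample mean and at +/- 2 sample standard deviations.
#'
#' @param data a `densitometry_set` (see [normalize_blots()]) or a numeric
#'   vector of replicate log10 ratios.
#' @param n_iter total iterations per chain (burn-in included).
#' @param n_burn burn-in iterations discarded (and used for adaptation).
#' @param target_acceptance tuning target for the acceptance fraction.
#' @param seeds integer seed per chain.
#' @param sigma_floor lower bound on sigma, guards the degenerate
#'   zero-spread data case.
#' @param adapt_block burn-in block length between scale updates.
#' @param prior `"flat"` (default) or `"normal"` on R.
#' @param prior_tau sd of the optional normal prior.
#' @return object of class `ratio_chains`: list with `chains` (one matrix
#'   per chain, columns `R`, `log_sigma`, post-burn-in rows only),
#'   `acceptance` (pooled post-burn-in fraction), `acceptance_per_chain`,
#'   `scales` (frozen proposal scales), `psrf` (Gelman-Rubin factor for R
#'   and log sigma), `n_burn`, `n_iter`, `y`.
#' @export
run_mcmc <- function(data, n_iter = 15000, n_burn = 5000,
                     target_acceptance = 0.4, seeds = c(1L, 2L, 3L),
                     sigma_floor = 1e-6, adapt_block = 100,
                     prior = c("flat", "normal"), prior_tau = 1) {
  y <- if (inherits(data, "densitometry_set")) data$y else as.numeric(data)
  prior <- match.arg(prior)
  if (length(y) < 2) stop("need at least 2 replicates (sigma unidentifiable)")
  stopifnot(n_iter > n_burn, n_burn >= 0, length(seeds) >= 1)
  m <- mean(y); s0 <- max(sd(y), sigma_floor)
  starts <- c(m - 2 * s0, m, m + 2 * s0)[seq_along(seeds)]
  run_chain <- function(start_R, seed) {
    set.seed(seed)
    R <- start_R; ls <- log(s0)
    lp <- .log_posterior(R, ls, y, sigma_floor, prior, prior_tau)
    scale <- s0
    keep <- matrix(NA_real_, n_iter - n_burn, 2,
                   dimnames = list(NULL, c("R", "log_sigma")))
    acc_block <- 0L; acc_post <- 0L
    for (i in seq_len(n_iter)) {
      Rp <- R + scale * rnorm(1)
      lsp <- ls + scale * rnorm(1)
      lpp <- .log_posterior(Rp, lsp, y, sigma_floor, prior, prior_tau)
      if (log(runif(1)) < lpp - lp) {
        R <- Rp; ls <- lsp; lp <- lpp
        if (i <= n_burn) acc_block <- acc_block + 1L
        else acc_post <- acc_post + 1L
      }
      if (i <= n_burn && i %% adapt_block == 0) {
        rate <- acc_block / adapt_block
        if (rate > target_acceptance) scale <- scale * 1.1
        else if (rate < target_acceptance) scale <- scale / 1.1
        acc_block <- 0L
      }
      if (i > n_burn) keep[i - n_burn, ] <- c(R, ls)
    }
    list(samples = keep, acceptance = acc_post / (n_iter - n_burn),
         scale = scale)
  }
  chains <- Map(run_chain, starts, seeds)
  samples <- lapply(chains, `[[`, "samples")
  acc <- vapply(chains, `[[`, 0, "acceptance")
  psrf <- c(
    R = gelman_rubin(lapply(samples, function(s) s[, "R"])),
    log_sigma = gelman_rubin(lapply(samples, function(s) s[, "log_sigma"])))
  structure(list(chains = samples,
                 acceptance = mean(acc),
                 acceptance_per_chain = acc,
                 scales = vapply(chains, `[[`, 0, "scale"),
                 psrf = psrf, n_burn = n_burn, n_iter = n_iter, y = y),
            class = "ratio_chains")
}

#' Gelman-Rubin potential scale reduction factor
#'
#' With `m` chains of length `n`, `W` is the mean within-chain variance,
#' `B/n` the variance of the chain means, and the pooled posterior
#' variance estimate is `var+ = (n-1)/n W + B/n`; the PSRF is
#' `sqrt(var+ / W)`.  Values near 1 indicate convergence; identical
#' chains give exactly `sqrt((n-1)/n)`.
#'
#' @param chains list of equal-length numeric vectors (>= 2 chains,
#'   length >= 2).
#' @return the PSRF (`Inf` when chains are internally constant but
#'   disagree).
#' @export
gelman_rubin <- function(chains) {
  stopifnot(is.list(chains), length(chains) >= 2)
  n <- unique(vapply(chains, length, 0L))
  if (length(n) != 1 || n < 2) stop("chains must share a length >= 2")
  W <- mean(vapply(chains, var, 0))
  B_over_n <- var(vapply(chains, mean, 0))
  if (W == 0) return(if (B_over_n > 0) Inf else NaN)
  sqrt(((n - 1) / n * W + B_over_n) / W)
}

#' Posterior summary of the expression ratio
#'
#' Pools the post-burn-in tails of the chains (after checking the
#' Gelman-Rubin factor for R against `psrf_threshold`) and reports the
#' posterior mean, median, an equal-tail credible interval, the tail
#' probability `P(R <= 0)` used as the significance measure for
#' up-in-A claims, and the linear fold-change point estimate `10^R`.
#'
#' @param chains a `ratio_chains` object from [run_mcmc()].
#' @param psrf_threshold refuse to summarize when the PSRF for R is at or
#'   above this (default 1.1).
#' @param ci_level credible-interval mass (default 0.95).
#' @return list `mean`, `median`, `ci` (length 2), `p_le_0`,
#'   `p_le_0_bound` (the `< 1/n` style bound when no sample is <= 0),
#'   `fold`, `n_samples`, `psrf`, `acceptance`.
#' @export
summarize_posterior <- function(chains, psrf_threshold = 1.1,
                                ci_level = 0.95) {
  stopifnot(inherits(chains, "ratio_chains"))
  psrf_R <- chains$psrf[["R"]]
  if (!is.finite(psrf_R) || psrf_R >= psrf_threshold)
    stop("chains not converged: PSRF for R = ", format(psrf_R),
         " (threshold ", psrf_threshold, ")")
  r <- unlist(lapply(chains$chains, function(s) s[, "R"]))
  alpha <- (1 - ci_level) / 2
  p0 <- mean(r <= 0)
  list(mean = mean(r), median = median(r),
       ci = unname(quantile(r, c(alpha, 1 - alpha))),
       p_le_0 = p0,
       p_le_0_bound = if (p0 == 0) 1 / length(r) else NA_real_,
       fold = 10 ^ mean(r),
       n_samples = length(r), psrf = chains$psrf,
       acceptance = chains$acceptance)
}
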