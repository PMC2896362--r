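test_that("loading-control normalization and log-ratios are exact", {
  raw <- rbind(
    data.frame(replicate = 1:2, condition = "A",
               target_density = c(4, 4), loading_density = c(2, 2)),
    data.frame(replicate = 1:2, condition = "B",
               target_density = c(2, 2), loading_density = c(2, 2)))
  ds <- normalize_blots(raw)
  expect_equal(ds$x_A, c(2, 2))
  expect_equal(ds$y, rep(log10(2), 2))
  raw0 <- raw; raw0$target_density[3] <- 0
  expect_error(normalize_blots(raw0), "lane")
  # identical lanes give a null ratio
  raw$target_density[raw$condition == "B"] <- 4
  expect_equal(normalize_blots(raw)$y, c(0, 0))
})

test_that("the Gelman-Rubin factor matches its closed form", {
  expect_equal(gelman_rubin(list(c(1, 2, 3), c(1, 2, 3))), sqrt(2 / 3))
  for (n in c(2, 5, 50)) for (m in 2:3) {
    ch <- replicate(m, seq_len(n) + 0.5, simplify = FALSE)
    expect_equal(gelman_rubin(ch), sqrt((n - 1) / n))
  }
  # far-separated chains with tiny within-variance diverge
  expect_gt(gelman_rubin(list(c(0, 0, 1e-4), c(10, 10, 10 + 1e-4))), 1.1)
  # zero within-variance but disagreement is reported as +Inf
  expect_equal(gelman_rubin(list(c(1, 1), c(2, 2))), Inf)
})

test_that("the sampler recovers a planted expression ratio", {
  dens <- make_densitometry(true_R = 0.146, sigma = 0.05,
                            n_replicates = 6, seed = 5)
  ch <- run_mcmc(normalize_blots(dens), n_iter = 6000, n_burn = 2000,
                 seeds = c(1L, 2L, 3L))
  expect_lt(ch$psrf[["R"]], 1.1)
  s <- summarize_posterior(ch)
  expect_lt(abs(s$mean - 0.146), 0.05)
  expect_true(s$ci[1] < s$ci[2])
  expect_equal(s$fold, 10 ^ s$mean)
})

test_that("the posterior mean approaches the sample mean under flat priors", {
  set.seed(101)
  y <- rnorm(8, 0.3, 0.1)
  ch <- run_mcmc(y, n_iter = 12000, n_burn = 3000, seeds = c(4L, 5L, 6L))
  r <- unlist(lapply(ch$chains, function(s) s[, "R"]))
  expect_lt(abs(mean(r) - mean(y)), 3 * sd(r) / sqrt(length(r) / 50))
})

test_that("adaptation lands near the target acceptance across noise scales", {
  for (sig in c(0.02, 0.1, 0.5)) {
    dens <- make_densitometry(true_R = 0.2, sigma = sig,
                              n_replicates = 6, seed = 23)
    ch <- run_mcmc(normalize_blots(dens), n_iter = 6000, n_burn = 3000,
                   seeds = c(1L, 2L, 3L))
    expect_lt(abs(ch$acceptance - 0.4), 0.1)
  }
})

test_that("shifting every log-ratio shifts the posterior exactly", {
  y <- c(0.1, 0.15, 0.2, 0.05, 0.12, 0.18)
  ch1 <- run_mcmc(y, n_iter = 2000, n_burn = 1000, seeds = c(7L, 8L, 9L))
  ch2 <- run_mcmc(y + 0.5, n_iter = 2000, n_burn = 1000,
                  seeds = c(7L, 8L, 9L))
  for (i in 1:3) {
    expect_equal(ch2$chains[[i]][, "R"], ch1$chains[[i]][, "R"] + 0.5,
                 tolerance = 1e-12)
    expect_equal(ch2$chains[[i]][, "log_sigma"],
                 ch1$chains[[i]][, "log_sigma"], tolerance = 1e-12)
  }
})

test_that("degenerate zero-spread data concentrate the posterior", {
  ch <- run_mcmc(rep(0.25, 4), n_iter = 4000, n_burn = 2000,
                 seeds = c(1L, 2L, 3L))
  r <- unlist(lapply(ch$chains, function(s) s[, "R"]))
  expect_lt(abs(mean(r) - 0.25), 1e-3)
  expect_error(run_mcmc(0.3), "at least 2")
})

test_that("summaries refuse unconverged chains and report tails honestly", {
  fake <- structure(list(
    chains = list(cbind(R = rnorm(100, 0), log_sigma = rnorm(100)),
                  cbind(R = rnorm(100, 50), log_sigma = rnorm(100))),
    acceptance = 0.4, psrf = c(R = 5, log_sigma = 1)),
    class = "ratio_chains")
  expect_error(summarize_posterior(fake), "PSRF")
  dens <- make_densitometry(0.146, 0.05, 6, seed = 5)
  s <- summarize_posterior(run_mcmc(normalize_blots(dens),
                                    n_iter = 4000, n_burn = 2000,
                                    seeds = c(1L, 2L, 3L)))
  # every sample above zero: the tail probability becomes a 1/n bound
  if (s$p_le_0 == 0) expect_equal(s$p_le_0_bound, 1 / s$n_samples)
})

test_that("credible intervals cover the truth at near-nominal rate", {
  hits <- 0
  for (i in 1:100) {
    dens <- make_densitometry(true_R = 0.146, sigma = 0.05,
                              n_replicates = 6, seed = 1000 + i)
    ch <- run_mcmc(normalize_blots(dens), n_iter = 2000, n_burn = 500,
                   seeds = c(3L, 4L, 5L) + i)
    s <- summarize_posterior(ch, psrf_threshold = Inf)
    if (s$ci[1] <= 0.146 && 0.146 <= s$ci[2]) hits <- hits + 1
  }
  expect_gte(hits, 90)
})
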