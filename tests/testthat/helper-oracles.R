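# Independent oracles and small fixtures shared across tests.

# uniform integer draw that is safe when lo == hi
rand_int <- function(lo, hi) lo + sample.int(hi - lo + 1, 1) - 1

# hypergeometric right tail by explicit binomial-coefficient enumeration
brute_hyper_tail <- function(k, n, K, N) {
  xs <- k:min(n, K)
  sum(choose(K, xs) * choose(N - K, n - xs)) / choose(N, n)
}

# step-up FDR adjustment written out longhand, independent of p.adjust
hand_bh <- function(p) {
  m <- length(p)
  ord <- order(p)
  q <- p[ord] * m / seq_len(m)
  q <- rev(cummin(rev(q)))
  out <- numeric(m)
  out[ord] <- pmin(q, 1)
  out
}

# maximum focus count over all connected induced subgraphs of exactly
# `size` nodes (exhaustive enumeration; only for small graphs)
max_focus_subgraph <- function(g, focus, size) {
  vs <- igraph::V(g)$name
  best <- 0L
  for (ss in utils::combn(vs, size, simplify = FALSE)) {
    sub <- igraph::induced_subgraph(g, ss)
    if (igraph::is_connected(sub))
      best <- max(best, length(intersect(ss, focus)))
  }
  best
}

# tiny three-protein database with engineered tryptic peptides, all
# inside the 800-3000 m/z window: P1 and P2 share two peptides and P1
# uniquely owns a third
toy_db <- function() {
  c(P1 = "AAAAGGGGVVVVKLLLLTTTTEEEEKTTTTSSSSYYYYR",
    P2 = "AAAAGGGGVVVVKLLLLTTTTEEEEKHHHHFFFFNNNNK",
    P3 = "WWWWYYYYFFFFRMMMMFFFFVVVVK")
}

# a batch of peak lists containing one planted bin at a chosen
# occurrence fraction, on top of distinct per-list peaks
occurrence_batch <- function(n_lists = 20, bin_mz = 1500,
                             n_with_bin = 3, jitter_ppm = 0,
                             seed = 99) {
  set.seed(seed)
  lapply(seq_len(n_lists), function(i) {
    mz <- 800 + i * 7 + c(0, 250, 500)  # unique to each list
    if (i <= n_with_bin) {
      b <- bin_mz * (1 + if (jitter_ppm > 0)
        rnorm(1, 0, jitter_ppm * 1e-6) else 0)
      mz <- c(mz, b)
    }
    data.frame(mz = sort(mz), intensity = rep(1, length(mz)))
  })
}
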