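make_graph <- function(edges, nodes = NULL) {
  g <- igraph::graph_from_data_frame(
    data.frame(from = edges[c(TRUE, FALSE)], to = edges[c(FALSE, TRUE)]),
    directed = FALSE, vertices = nodes)
  g
}

test_that("hanging nodes are exactly those of degree at most one", {
  tri <- grow_network(make_graph(c("a","b", "b","c", "a","c")),
                      focus = c("a", "b", "c"))
  expect_equal(classify_hanging(tri), character(0))
  star <- grow_network(make_graph(c("h","l1", "h","l2", "h","l3",
                                    "h","l4")),
                       focus = c("h", "l1", "l2", "l3", "l4"))
  expect_equal(classify_hanging(star), c("l1", "l2", "l3", "l4"))
  lone <- grow_network(make_graph(c("x","y"), nodes = c("f", "x", "y")),
                       focus = "f")
  expect_equal(lone$nodes, "f")
  expect_equal(lone$edges, data.frame(from = character(),
                                      to = character()))
  expect_equal(classify_hanging(lone), "f")
})

test_that("two focus proteins joined by a connector are both captured", {
  nw <- grow_network(make_graph(c("F1","x", "x","F2")),
                     focus = c("F1", "F2"))
  expect_setequal(nw$nodes, c("F1", "x", "F2"))
  expect_setequal(nw$hanging, c("F1", "F2"))  # x has degree 2
})

test_that("a clique of focus proteins is fully included", {
  vs <- paste0("F", 1:5)
  pr <- utils::combn(vs, 2)
  g <- make_graph(as.vector(rbind(pr[1, ], pr[2, ])))
  nw <- grow_network(g, focus = vs, max_size = 35)
  expect_setequal(nw$focus_nodes, vs)
})

test_that("growth tunnels through non-focus connectors to distant focus", {
  # F1 - x - y - F2: reaching F2 needs two zero-gain steps
  nw <- grow_network(make_graph(c("F1","x", "x","y", "y","F2")),
                     focus = c("F1", "F2"))
  expect_setequal(nw$nodes, c("F1", "x", "y", "F2"))
})

test_that("an unmapped focus set is an explicit error", {
  expect_error(grow_network(make_graph(c("a","b")), focus = "zz"),
               "no focus protein")
})

test_that("growth is invariant to edge-list order", {
  set.seed(31)
  for (i in 1:10) {
    n <- 12
    g <- igraph::sample_gnp(n, 0.3)
    igraph::V(g)$name <- sprintf("N%02d", seq_len(n))
    ed <- igraph::as_data_frame(g, what = "edges")
    if (!nrow(ed)) next
    focus <- sample(igraph::V(g)$name, 3)
    perm <- ed[sample(nrow(ed)), ]
    swap <- sample(c(TRUE, FALSE), nrow(perm), replace = TRUE)
    tmp <- perm$from[swap]; perm$from[swap] <- perm$to[swap]
    perm$to[swap] <- tmp
    n1 <- grow_network(igraph::graph_from_data_frame(
      ed, directed = FALSE, vertices = sort(igraph::V(g)$name)), focus)
    n2 <- grow_network(igraph::graph_from_data_frame(
      perm, directed = FALSE, vertices = sort(igraph::V(g)$name)), focus)
    expect_equal(n1$nodes, n2$nodes)
    expect_equal(n1$focus_nodes, n2$focus_nodes)
  }
})

test_that("greedy growth matches exhaustive search on small graphs", {
  # at the default (non-binding) size cap the grown network must contain
  # as many focus nodes as any connected subgraph of the same size
  set.seed(41)
  tried <- 0
  while (tried < 15) {
    n <- sample(6:10, 1)
    g <- igraph::sample_gnp(n, runif(1, 0.25, 0.45))
    if (!igraph::is_connected(g)) next
    igraph::V(g)$name <- sprintf("N%02d", seq_len(n))
    focus <- sample(igraph::V(g)$name, sample(2:4, 1))
    nw <- grow_network(g, focus, max_size = 35)
    expect_equal(length(nw$focus_nodes),
                 max_focus_subgraph(g, focus, nw$size))
    tried <- tried + 1
  }
})

test_that("the score transform and significance convention are exact", {
  expect_identical(network_score(1e-6), 6)
  expect_identical(network_score(1), 0)
  g <- make_graph(c("F1","x", "x","F2", "x","F3"))
  nw <- grow_network(g, paste0("F", 1:3))
  sc <- score_network(nw, K = 5, N = 20)
  # same quadruple as the enrichment oracle: (k,n,K,N) = (3,4,5,20)
  expect_equal(sc$score, -log10(155 / 4845), tolerance = 1e-10)
  expect_false(sc$significant)
})

test_that("adding a focus node at fixed size never lowers the score", {
  for (k in 1:3)
    expect_gte(network_score(fisher_right_tail(k + 1, 5, 6, 30)),
               network_score(fisher_right_tail(k, 5, 6, 30)))
})

test_that("a planted focus community scores above the significance bar", {
  accs <- sprintf("P%03d", 1:300)
  de <- accs[1:10]
  kb <- make_knowledgebase(accs, n_pathways = 0, size_range = c(1, 5),
                           n_edges = 500, seed = 8, de_proteins = de)
  expect_equal(nrow(kb$edges), 500)
  g <- igraph::graph_from_data_frame(kb$edges, directed = FALSE,
                                     vertices = accs)
  res <- grow_networks(g, de, max_size = 35)
  expect_gte(max(res$summary$score), 6)
  expect_true(res$summary$significant[1])
})

test_that("networks are emitted until the focus set is exhausted", {
  g <- make_graph(c("F1","x", "F2","y"), nodes = c("F1","x","F2","y"))
  res <- grow_networks(g, c("F1", "F2"))
  expect_equal(length(res$networks), 2)
  expect_setequal(unlist(lapply(res$networks, `[[`, "focus_nodes")),
                  c("F1", "F2"))
  expect_equal(res$summary$p_bh, bh_adjust(res$summary$p))
})
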