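## Focus-protein network construction by greedy growth over the
## interaction graph, scored as -log10 of a hypergeometric p-value.

.as_interaction_graph <- function(graph) {
  if (igraph::is_igraph(graph)) {
    g <- graph
  } else if (is.data.frame(graph)) {
    g <- igraph::graph_from_data_frame(graph[, 1:2], directed = FALSE)
  } else stop("graph must be an igraph object or an edge data frame")
  g <- igraph::simplify(igraph::as_undirected(g))
  if (is.null(igraph::V(g)$name))
    igraph::V(g)$name <- as.character(seq_len(igraph::vcount(g)))
  g
}

#' Grow one focus-protein network
#'
#' Greedy surrogate for knowledgebase network generation: starting from
#' the focus protein with the most focus neighbors, repeatedly add the
#' neighboring protein that (1) prospectively connects the most
#' not-yet-included focus proteins (itself counted if focus), then (2) has
#' the most edges into the current network, then (3) comes first in
#' accession order.  When no candidate adds focus connectivity but
#' reachable focus proteins remain, growth tunnels toward the nearest one
#' along shortest paths.  Growth stops at `max_size` or when every
#' reachable focus protein is included.
#'
#' @param graph interaction network (igraph object or two-column edge data
#'   frame; treated as simple and undirected).
#' @param focus character vector of focus accessions.
#' @param max_size maximum number of nodes (default 35).
#' @return object of class `focus_network`: list with `nodes`, `edges`
#'   (data frame `from`, `to`), `focus_nodes`, `hanging` (degree <= 1) and
#'   `size`.
#' @export
grow_network <- function(graph, focus, max_size = 35) {
  g <- .as_interaction_graph(graph)
  nodes <- sort(igraph::V(g)$name)
  focus <- sort(intersect(unique(focus), nodes))
  if (!length(focus))
    stop("no focus protein maps to the interaction graph")
  nbrs <- lapply(setNames(nodes, nodes), function(v)
    sort(igraph::neighbors(g, v)$name))
  # seed: focus node with most focus neighbors, ties by accession order
  seed_score <- vapply(focus, function(f)
    length(intersect(nbrs[[f]], focus)), 0L)
  current <- focus[order(-seed_score, focus)][1]
  inset <- current
  repeat {
    if (length(inset) >= max_size) break
    cand <- sort(setdiff(unique(unlist(nbrs[inset])), inset))
    if (!length(cand)) break
    remaining <- setdiff(focus, inset)
    gain <- vapply(cand, function(c)
      as.integer(c %in% remaining) +
        length(intersect(nbrs[[c]], setdiff(remaining, c))), 0L)
    deg_in <- vapply(cand, function(c)
      length(intersect(nbrs[[c]], inset)), 0L)
    if (max(gain) > 0) {
      pick <- cand[order(-gain, -deg_in, cand)][1]
    } else {
      if (!length(remaining)) break
      d <- igraph::distances(g, v = cand, to = remaining)
      mind <- apply(d, 1, min)
      if (!any(is.finite(mind))) break  # remaining focus unreachable
      pick <- cand[order(mind, -deg_in, cand)][1]
    }
    inset <- c(inset, pick)
  }
  sub <- igraph::induced_subgraph(g, inset)
  ed <- igraph::as_data_frame(sub, what = "edges")
  deg <- igraph::degree(sub)
  structure(list(
    nodes = sort(inset),
    edges = ed[, c("from", "to"), drop = FALSE],
    focus_nodes = sort(intersect(inset, focus)),
    hanging = sort(names(deg)[deg <= 1]),
    size = length(inset)), class = "focus_network")
}

#' Nodes that hang off a network without closing a loop
#'
#' @param network a `focus_network`.
#' @return accessions with degree at most 1 in the network's induced edge
#'   set.
#' @export
classify_hanging <- function(network) {
  stopifnot(inherits(network, "focus_network"))
  network$hanging
}

#' Significance score from a network p-value
#'
#' `score = -log10(p)`; a score of 6 or greater (p < 1e-6) flags a network
#' whose focus-protein content has a one-in-a-million chance of arising by
#' random sampling alone.
#'
#' @param p probability in (0, 1].
#' @return the score (>= 0).
#' @export
network_score <- function(p) {
  stopifnot(all(p > 0), all(p <= 1))
  -log10(p)
}

#' Score a focus network against the whole interaction graph
#'
#' The p-value is the right-tailed hypergeometric probability of observing
#' at least as many focus proteins in a uniform sample of `size` nodes
#' from the `N`-node graph containing `K` focus proteins in total
#' (see [fisher_right_tail()]); the score is its negative decadic log.
#'
#' @param network a `focus_network`.
#' @param K total number of focus proteins in the graph.
#' @param N total number of nodes in the graph.
#' @param score_cutoff significance convention (default 6).
#' @return list `p`, `score`, `significant`, `k`, `n`.
#' @export
score_network <- function(network, K, N, score_cutoff = 6) {
  stopifnot(inherits(network, "focus_network"))
  k <- length(network$focus_nodes); n <- network$size
  p <- fisher_right_tail(k, n, K, N)
  list(p = p, score = network_score(p),
       significant = network_score(p) >= score_cutoff, k = k, n = n)
}

#' Grow networks until the focus set is exhausted
#'
#' After a network is emitted its focus proteins are removed from the
#' focus set and growth repeats, mirroring the way knowledgebase tools
#' report several networks per upload.  Network p-values are
#' Benjamini-Hochberg adjusted across the emitted set.
#'
#' @inheritParams grow_network
#' @param score_cutoff significance convention on the score (default 6).
#' @return list with `networks` (list of `focus_network`) and `summary`
#'   (data frame `network_id`, `size`, `focus_count`, `p`, `p_bh`,
#'   `score`, `significant`).
#' @export
grow_networks <- function(graph, focus, max_size = 35, score_cutoff = 6) {
  g <- .as_interaction_graph(graph)
  N <- igraph::vcount(g)
  all_focus <- intersect(unique(focus), igraph::V(g)$name)
  K <- length(all_focus)
  remaining <- all_focus
  nets <- list()
  while (length(remaining)) {
    nw <- grow_network(g, remaining, max_size)
    nets[[length(nets) + 1L]] <- nw
    remaining <- setdiff(remaining, nw$focus_nodes)
  }
  sc <- lapply(nets, score_network, K = K, N = N,
               score_cutoff = score_cutoff)
  p <- vapply(sc, `[[`, 0, "p")
  p_bh <- if (length(p)) bh_adjust(p) else numeric()
  summary <- data.frame(
    network_id = seq_along(nets),
    size = vapply(nets, `[[`, 0L, "size"),
    focus_count = vapply(nets, function(n) length(n$focus_nodes), 0L),
    p = p, p_bh = p_bh,
    score = network_score(pmax(p, .Machine$double.xmin)),
    significant = network_score(pmax(p, .Machine$double.xmin)) >=
      score_cutoff)
  summary <- summary[order(-summary$score, summary$network_id), ,
                     drop = FALSE]
  list(networks = nets, summary = summary)
}
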