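# Small programmatic fixtures and independent oracles shared across tests.

`%||%` <- function(a, b) if (is.null(a)) b else a

# plain-R BFS over an undirected edge list; independent of igraph
bfs_distance <- function(edges_u, edges_v, from, to) {
  nodes <- unique(c(edges_u, edges_v, from, to))
  adj <- lapply(setNames(nodes, nodes), function(n) character())
  for (i in seq_along(edges_u)) {
    adj[[edges_u[i]]] <- c(adj[[edges_u[i]]], edges_v[i])
    adj[[edges_v[i]]] <- c(adj[[edges_v[i]]], edges_u[i])
  }
  dist <- setNames(rep(Inf, length(nodes)), nodes)
  dist[from] <- 0
  queue <- from
  while (length(queue) > 0L) {
    cur <- queue[1L]; queue <- queue[-1L]
    for (nb in adj[[cur]]) {
      if (is.infinite(dist[nb])) {
        dist[nb] <- dist[cur] + 1
        queue <- c(queue, nb)
      }
    }
  }
  dist[to]
}

# exhaustive pairwise-comparison AUC (normalized Mann-Whitney U, ties = 1/2)
u_statistic_auc <- function(labels, scores) {
  pos <- scores[labels == 1L]
  neg <- scores[labels == 0L]
  total <- 0
  for (p in pos) {
    total <- total + sum(p > neg) + 0.5 * sum(p == neg)
  }
  total / (length(pos) * length(neg))
}

# a tiny deterministic bipartite interaction table
toy_edges <- function() {
  data.frame(
    lnc = c("L1", "L1", "L2", "L2", "L3"),
    prot = c("P1", "P2", "P1", "P2", "P3"),
    stringsAsFactors = FALSE
  )
}

# random interaction table over nl lncRNAs and np proteins
random_edges <- function(nl, np, n_edges, seed = 1L) {
  set.seed(seed)
  grid <- expand.grid(lnc = sprintf("L%02d", seq_len(nl)),
                      prot = sprintf("P%02d", seq_len(np)),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  grid[sample.int(nrow(grid), n_edges), , drop = FALSE]
}

# small planted benchmark reused by several end-to-end tests
small_planted <- function(seed = 7L) {
  generate_planted_network(planted_network_spec(
    n_lnc = 40L, n_prot = 12L, k_blocks = 2L, p_within = 0.7,
    p_between = 0.03, sim_noise = 0.05, seed = seed
  ))
}
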