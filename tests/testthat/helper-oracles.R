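# Independent oracles and fixture builders used across the suite.

# BFS distances from one source over an adjacency list
bfs_dist <- function(adj, s) {
  n <- length(adj)
  d <- rep(Inf, n)
  d[s] <- 0
  queue <- s
  while (length(queue)) {
    v <- queue[1]; queue <- queue[-1]
    for (u in adj[[v]]) if (!is.finite(d[u])) {
      d[u] <- d[v] + 1
      queue <- c(queue, u)
    }
  }
  d
}

edges_to_adj <- function(edges, n) {
  adj <- vector("list", n)
  for (k in seq_len(nrow(edges))) {
    a <- edges[k, 1]; b <- edges[k, 2]
    adj[[a]] <- c(adj[[a]], b)
    adj[[b]] <- c(adj[[b]], a)
  }
  adj
}

# all-pairs distance matrix by repeated BFS
bf_distances <- function(topo) {
  n <- topo$n_nodes
  adj <- edges_to_adj(topo$edges, n)
  t(vapply(seq_len(n), function(s) bfs_dist(adj, s), numeric(n)))
}

# brute-force normalized betweenness: enumerate every shortest s-t path and
# credit interior vertices fractionally over the geodesic multiplicity
bf_betweenness <- function(topo) {
  n <- topo$n_nodes
  adj <- edges_to_adj(topo$edges, n)
  D <- bf_distances(topo)
  bet <- numeric(n)
  all_paths <- function(s, v) {
    if (v == s) return(list(s))
    preds <- adj[[v]][D[s, adj[[v]]] == D[s, v] - 1]
    out <- list()
    for (p in preds) for (pp in all_paths(s, p)) {
      out[[length(out) + 1]] <- c(pp, v)
    }
    out
  }
  for (s in seq_len(n - 1)) for (t in (s + 1):n) {
    paths <- all_paths(s, t)
    for (p in paths) {
      interior <- p[-c(1, length(p))]
      bet[interior] <- bet[interior] + 1 / length(paths)
    }
  }
  bet / ((n - 1) * (n - 2) / 2)
}

# random connected simple graph as a topology
random_connected_topology <- function(n, p = 0.4) {
  repeat {
    g <- igraph::sample_gnp(n, p)
    if (igraph::is_connected(g) && igraph::gsize(g) > 0) {
      return(lingnet:::new_topology(g, kind = "custom"))
    }
  }
}

topology_from_edges <- function(edges, kind = "custom") {
  g <- igraph::graph_from_edgelist(as.matrix(edges), directed = FALSE)
  lingnet:::new_topology(g, kind = kind)
}

# an environment of exactly k chips far apart (pairwise distance > 50)
far_apart_env <- function(k = 4, spacing = 60) {
  chips <- cbind(L = seq(0, by = spacing, length.out = k), a = 0, b = 0)
  structure(list(chips = chips, focal = NULL, sigma = NULL, label = "fixture",
                 seed = NULL), class = "lab_environment")
}

# agent with one single-unit category per row of `centers`
agent_with_categories <- function(centers, ...) {
  a <- new_agent(...)
  for (i in seq_len(nrow(centers))) learn_topic(a, centers[i, ])
  a
}

# force an agent's trailing window to a given success count out of `total`
fill_history <- function(agent, successes, total) {
  for (i in seq_len(total)) record_outcome(agent, i <= successes)
  agent
}

make_context <- function(stimuli, topic_index = 1L) {
  structure(list(stimuli = stimuli, topic_index = topic_index),
            class = "game_context")
}

# analytic star means: n leaves + hub
star_mean_closeness <- function(n) (1 + n * n / (2 * n - 1)) / (n + 1)
star_mean_betweenness <- function(n) 1 / (n + 1)
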