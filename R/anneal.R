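# Objective functions for the regular-topology optimizer. Each takes an
# igraph and returns the scalar being optimized. Mean normalized betweenness
# is computed through the exact identity
#   mean_norm_betweenness = (mean geodesic distance - 1) / (n - 2),
# which follows from summing, over all s < t pairs, the d(s,t) - 1 interior
# vertices of each geodesic (fractionally over geodesic multiplicity); it is
# far cheaper per annealing step than a full betweenness computation and is
# asserted against igraph::betweenness in the test suite.
regular_objective <- function(objective) {
  switch(objective,
    "avg-betweenness" = function(g) {
      n <- igraph::gorder(g)
      (igraph::mean_distance(g) - 1) / (n - 2)
    },
    "max-betweenness" = function(g) max(igraph::betweenness(g, normalized = TRUE)),
    "max-closeness" = function(g) max(igraph::closeness(g, normalized = TRUE)),
    "avg-clustering" = function(g) {
      mean(igraph::transitivity(g, type = "local", isolates = "zero"))
    },
    "var-constraint" = function(g) stats::var(igraph::constraint(g)),
    stop("unknown objective: ", objective, call. = FALSE)
  )
}

# deterministic connected degree-regular starting graph: a cycle, full chord
# sets i -- i+k (each adds 2 to every degree), and for odd residual degree an
# antipodal perfect matching i -- i + n/2 (adds 1; n must then be even, which
# the n*degree parity check guarantees)
regular_seed_graph <- function(n, degree) {
  if (degree < 2) stop("degree must be >= 2", call. = FALSE)
  edges <- cbind(seq_len(n), c(seq_len(n - 1) + 1L, 1L))  # cycle
  need <- as.integer(degree) - 2L
  k <- 2L
  while (need >= 2L) {
    if (k >= (n + 1L) %/% 2L)
      stop("cannot seed a degree-", degree, " graph on ", n, " nodes",
           call. = FALSE)
    edges <- rbind(edges, cbind(seq_len(n), ((seq_len(n) + k - 1L) %% n) + 1L))
    need <- need - 2L
    k <- k + 1L
  }
  if (need == 1L) {
    half <- n %/% 2L
    edges <- rbind(edges, cbind(seq_len(half), seq_len(half) + half))
  }
  edges
}

#' Optimize a degree-regular topology for a centrality objective
#'
#' Simulated-annealing search over connected simple degree-regular graphs.
#' Moves are connectivity-preserving double edge swaps: two edges (a,b) and
#' (c,d) with four distinct endpoints are replaced by (a,c),(b,d) or
#' (a,d),(b,c), which preserves every node's degree; proposals that create a
#' multi-edge or disconnect the graph are rejected outright. Acceptance is
#' Metropolis with geometric cooling; the best graph visited is returned.
#'
#' @param n Number of nodes (`n * degree` must be even, `n > degree`).
#' @param degree Uniform node degree (default 3).
#' @param objective One of `"avg-betweenness"`, `"max-betweenness"`,
#'   `"max-closeness"`, `"avg-clustering"`, `"var-constraint"`.
#' @param direction `"minimize"` or `"maximize"`.
#' @param seed Integer seed; the search is deterministic for a fixed seed.
#' @param n_steps Proposed swaps (default 2e5).
#' @param t0 Initial temperature on the objective scale (default 0.02).
#' @param t_end Final temperature (default 1e-6).
#' @return A `topology` of kind `"regular-optimized"` with attributes
#'   `objective`, `direction` and `objective_value` (the achieved value).
#' @export
optimize_regular_topology <- function(n, degree = 3,
                                      objective = c("avg-betweenness",
                                                    "max-betweenness",
                                                    "max-closeness",
                                                    "avg-clustering",
                                                    "var-constraint"),
                                      direction = c("minimize", "maximize"),
                                      seed = 1, n_steps = 2e5,
                                      t0 = 0.02, t_end = 1e-6) {
  objective <- match.arg(objective)
  direction <- match.arg(direction)
  if ((n * degree) %% 2 != 0)
    stop("n * degree must be even", call. = FALSE)
  if (n <= degree) stop("n must exceed the degree", call. = FALSE)
  obj_fun <- regular_objective(objective)
  sgn <- if (direction == "minimize") 1 else -1
  cool <- (t_end / t0)^(1 / max(n_steps - 1, 1))

  with_seed(seed, {
    edges <- regular_seed_graph(as.integer(n), as.integer(degree))
    g <- igraph::graph_from_edgelist(edges, directed = FALSE)
    cur <- sgn * obj_fun(g)
    best <- cur
    best_edges <- edges
    m <- nrow(edges)
    # adjacency lookup for the simplicity check
    adj <- matrix(FALSE, n, n)
    adj[edges] <- TRUE
    adj[edges[, 2:1]] <- TRUE
    temp <- t0
    for (step in seq_len(n_steps)) {
      ij <- sample.int(m, 2)
      e1 <- edges[ij[1], ]; e2 <- edges[ij[2], ]
      ends <- c(e1, e2)
      if (anyDuplicated(ends)) { temp <- temp * cool; next }
      # two possible rewirings; pick one at random
      if (stats::runif(1) < 0.5) {
        f1 <- c(e1[1], e2[1]); f2 <- c(e1[2], e2[2])
      } else {
        f1 <- c(e1[1], e2[2]); f2 <- c(e1[2], e2[1])
      }
      if (adj[f1[1], f1[2]] || adj[f2[1], f2[2]]) { temp <- temp * cool; next }
      new_edges <- edges
      new_edges[ij[1], ] <- f1
      new_edges[ij[2], ] <- f2
      ng <- igraph::graph_from_edgelist(new_edges, directed = FALSE)
      if (!igraph::is_connected(ng)) { temp <- temp * cool; next }
      val <- sgn * obj_fun(ng)
      if (val <= cur || stats::runif(1) < exp((cur - val) / temp)) {
        edges <- new_edges
        cur <- val
        adj[e1[1], e1[2]] <- adj[e1[2], e1[1]] <- FALSE
        adj[e2[1], e2[2]] <- adj[e2[2], e2[1]] <- FALSE
        adj[f1[1], f1[2]] <- adj[f1[2], f1[1]] <- TRUE
        adj[f2[1], f2[2]] <- adj[f2[2], f2[1]] <- TRUE
        if (cur < best) {
          best <- cur
          best_edges <- edges
        }
      }
      temp <- temp * cool
    }
    g_best <- igraph::graph_from_edgelist(best_edges, directed = FALSE)
    t <- new_topology(g_best, kind = "regular-optimized")
    attr(t, "objective") <- objective
    attr(t, "direction") <- direction
    attr(t, "objective_value") <- sgn * best
    t
  })
}
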