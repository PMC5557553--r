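#' Enumerate all connected 3-regular graphs on n nodes
#'
#' Exhaustive backtracking over labeled simple graphs in which every node has
#' degree exactly 3, followed by a connectivity filter and deduplication up
#' to isomorphism. Serves as the exact oracle against which the annealing
#' optimizer ([optimize_regular_topology()]) is checked. Enumeration order is
#' deterministic (lexicographic in the labeled edge list), so argmin/argmax
#' selections over the result are reproducible.
#'
#' @param n Number of nodes; must be 4, 6 or 8 (larger sizes are refused:
#'   the labeled search space grows combinatorially).
#' @return List of `topology` objects of kind `"regular"`, one per isomorphism
#'   class (1 for n = 4, 2 for n = 6, 5 for n = 8).
#' @export
enumerate_cubic_graphs <- function(n) {
  if (!n %in% c(4, 6, 8))
    stop("n must be 4, 6 or 8 (exhaustive enumeration beyond 8 nodes is ",
         "refused: combinatorial blow-up)", call. = FALSE)
  n <- as.integer(n)
  reps <- list()
  recurse <- function(deg, edges) {
    v <- which(deg < 3L)[1]
    if (is.na(v)) {
      g <- igraph::graph_from_edgelist(edges, directed = FALSE)
      if (!igraph::is_connected(g)) return(invisible())
      for (r in reps) if (igraph::isomorphic(r, g)) return(invisible())
      reps[[length(reps) + 1L]] <<- g
      return(invisible())
    }
    need <- 3L - deg[v]
    cand <- which(deg < 3L)
    cand <- cand[cand > v]
    if (nrow(edges)) {
      nb <- c(edges[edges[, 1] == v, 2], edges[edges[, 2] == v, 1])
      cand <- setdiff(cand, nb)
    }
    if (length(cand) < need) return(invisible())
    combs <- utils::combn(cand, need)
    for (k in seq_len(ncol(combs))) {
      ch <- combs[, k]
      d2 <- deg
      d2[v] <- 3L
      d2[ch] <- d2[ch] + 1L
      recurse(d2, rbind(edges, cbind(v, ch)))
    }
  }
  recurse(integer(n), matrix(0L, nrow = 0, ncol = 2))
  lapply(reps, new_topology, kind = "regular")
}
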