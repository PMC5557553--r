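new_topology <- function(graph, kind, role_mode = "balanced", hub = NA_integer_) {
  structure(list(
    graph = graph,
    n_nodes = igraph::gorder(graph),
    edges = igraph::as_edgelist(graph, names = FALSE),
    kind = kind,
    role_policy = list(mode = role_mode, hub = hub)
  ), class = "topology")
}

#' @export
print.topology <- function(x, ...) {
  cat(sprintf("<topology: %s, %d nodes, %d edges, roles=%s%s>\n",
              x$kind, x$n_nodes, nrow(x$edges), x$role_policy$mode,
              if (!is.na(x$role_policy$hub))
                paste0(", hub=", x$role_policy$hub) else ""))
  invisible(x)
}

#' Fully connected interaction topology
#'
#' @param n Number of nodes (>= 2).
#' @return A `topology` with all `n(n-1)/2` edges and balanced roles.
#' @export
build_complete <- function(n) {
  if (!is.numeric(n) || length(n) != 1 || n < 2)
    stop("n must be a single integer >= 2", call. = FALSE)
  new_topology(igraph::make_full_graph(as.integer(n)), kind = "complete")
}

#' Star interaction topology
#'
#' One hub (node 1) connected to `n_leaves` leaves: `n_leaves + 1` nodes in
#' total. Note the naming convention used throughout: a "star of size n"
#' means n leaves plus the hub. The `mode` sets the role-bias policy: in
#' `"star-speaker"` the hub, when involved in a game, speaks with probability
#' `(d - 1) / d` where `d` is the hub degree (information flows hub ->
#' periphery); `"star-hearer"` is the mirror image; `"balanced"` assigns roles
#' uniformly.
#'
#' @param n_leaves Number of leaves (>= 2).
#' @param mode `"balanced"`, `"star-speaker"` or `"star-hearer"`.
#' @return A `topology` of kind `"star"` with radius 1 and diameter 2.
#' @export
build_star <- function(n_leaves, mode = c("balanced", "star-speaker",
                                          "star-hearer")) {
  mode <- match.arg(mode)
  if (!is.numeric(n_leaves) || length(n_leaves) != 1 || n_leaves < 2)
    stop("n_leaves must be a single integer >= 2", call. = FALSE)
  g <- igraph::make_star(as.integer(n_leaves) + 1L, mode = "undirected",
                         center = 1)
  new_topology(g, kind = "star", role_mode = mode, hub = 1L)
}

check_connected <- function(t) {
  if (!igraph::is_connected(t$graph))
    stop("topology must be connected", call. = FALSE)
}

#' Node centrality measures
#'
#' Per-node centralities with the conventions used throughout the package:
#' betweenness counts shortest s-t paths through a node fractionally over
#' geodesic multiplicity and is normalized by `(n-1)(n-2)/2` per node
#' (endpoints excluded); closeness is `(n-1) / sum_u dist(v, u)`; clustering
#' is the local transitivity (triangles over wedges), 0 for nodes of degree
#' < 2; `burt_constraint` is Burt's structural-holes constraint with
#' `p_ij = 1/deg(i)` for unweighted graphs.
#'
#' @param t A connected `topology`.
#' @return Numeric vector of per-node values.
#' @name centralities
NULL

#' @rdname centralities
#' @export
betweenness_centrality <- function(t) {
  check_connected(t)
  igraph::betweenness(t$graph, normalized = TRUE)
}

#' @rdname centralities
#' @export
closeness_centrality <- function(t) {
  check_connected(t)
  igraph::closeness(t$graph, normalized = TRUE)
}

#' @rdname centralities
#' @export
clustering_coefficient <- function(t) {
  cc <- igraph::transitivity(t$graph, type = "local", isolates = "zero")
  cc[igraph::degree(t$graph) < 2] <- 0
  cc
}

#' @rdname centralities
#' @export
burt_constraint <- function(t) {
  if (any(igraph::degree(t$graph) == 0))
    stop("constraint undefined for isolated nodes", call. = FALSE)
  igraph::constraint(t$graph)
}

#' Radius and diameter of a topology
#'
#' @param t A connected `topology`.
#' @return Integer vector `c(radius, diameter)` (min and max eccentricity).
#' @export
radius_diameter <- function(t) {
  check_connected(t)
  ecc <- igraph::eccentricity(t$graph)
  c(radius = as.integer(min(ecc)), diameter = as.integer(max(ecc)))
}

#' Structural summary of a topology
#'
#' Radius, diameter, and per-node closeness, betweenness, clustering and
#' Burt constraint together with their means (and, for constraint, the
#' across-node variance: the objective of the max-var-constraint topology).
#'
#' @param t A connected `topology`.
#' @return A `centrality_report`: list with `radius`, `diameter`, a `nodes`
#'   data.frame of per-node values, and a `summary` list of means.
#' @export
centrality_report <- function(t) {
  rd <- radius_diameter(t)
  nodes <- data.frame(
    node = seq_len(t$n_nodes),
    closeness = closeness_centrality(t),
    betweenness = betweenness_centrality(t),
    clustering = clustering_coefficient(t),
    constraint = burt_constraint(t)
  )
  structure(list(
    radius = rd[["radius"]], diameter = rd[["diameter"]], nodes = nodes,
    summary = list(
      closeness = mean(nodes$closeness),
      betweenness = mean(nodes$betweenness),
      clustering = mean(nodes$clustering),
      constraint_var = stats::var(nodes$constraint)
    )
  ), class = "centrality_report")
}

#' @export
print.centrality_report <- function(x, ...) {
  cat(sprintf(
    "<centrality report: radius %d, diameter %d, closeness %.2f, betweenness %.2f, clustering %.2f>\n",
    x$radius, x$diameter, x$summary$closeness, x$summary$betweenness,
    x$summary$clustering))
  invisible(x)
}

#' Write a centrality report to CSV and JSON
#'
#' Per-node values go to `csv_path`; the summary (Radius, Diameter, Closeness,
#' Betweenness, Clustering means) to `json_path`.
#'
#' @param rep A `centrality_report`.
#' @param csv_path,json_path Output paths.
#' @return Invisibly, `rep`.
#' @export
write_centrality_report <- function(rep, csv_path, json_path) {
  utils::write.csv(rep$nodes, csv_path, row.names = FALSE)
  jsonlite::write_json(list(
    Radius = rep$radius, Diameter = rep$diameter,
    Closeness = rep$summary$closeness,
    Betweenness = rep$summary$betweenness,
    Clustering = rep$summary$clustering,
    ConstraintVariance = rep$summary$constraint_var
  ), json_path, auto_unbox = TRUE, digits = NA)
  invisible(rep)
}

#' Assign speaker and hearer roles on an edge
#'
#' Under the `balanced` policy the speaker is chosen uniformly from the pair.
#' Under `star-speaker` (`star-hearer`), if the hub is one of the two nodes it
#' becomes the speaker (hearer) with probability `(d - 1) / d`, `d` being the
#' hub degree. Uses the current RNG stream.
#'
#' @param t A `topology`.
#' @param edge Integer pair of adjacent nodes.
#' @return Named integer vector `c(speaker =, hearer =)`.
#' @export
assign_roles <- function(t, edge) {
  a <- edge[1]; b <- edge[2]
  if (!any((t$edges[, 1] == a & t$edges[, 2] == b) |
           (t$edges[, 1] == b & t$edges[, 2] == a)))
    stop("edge is not in the topology", call. = FALSE)
  mode <- t$role_policy$mode
  hub <- t$role_policy$hub
  if (mode != "balanced" && !is.na(hub) && hub %in% c(a, b)) {
    d <- igraph::degree(t$graph, hub)
    p_hub_first <- (d - 1) / d
    other <- if (a == hub) b else a
    if (mode == "star-speaker") {
      if (stats::runif(1) < p_hub_first) c(speaker = hub, hearer = other)
      else c(speaker = other, hearer = hub)
    } else { # star-hearer
      if (stats::runif(1) < p_hub_first) c(speaker = other, hearer = hub)
      else c(speaker = hub, hearer = other)
    }
  } else {
    if (stats::runif(1) < 0.5) c(speaker = a, hearer = b)
    else c(speaker = b, hearer = a)
  }
}

#' Write / read a topology as a plain edge list
#'
#' Whitespace-separated 0-based node ids, one edge per line.
#'
#' @param t A `topology`.
#' @param path Output path.
#' @return `write_edge_list`: invisibly `path`; `read_edge_list`: a
#'   `topology`.
#' @export
write_edge_list <- function(t, path) {
  writeLines(paste(t$edges[, 1] - 1L, t$edges[, 2] - 1L), path)
  invisible(path)
}

#' @rdname write_edge_list
#' @param kind Kind tag to attach on read.
#' @param role_mode,hub Role policy to attach on read.
#' @export
read_edge_list <- function(path, kind = "custom", role_mode = "balanced",
                           hub = NA_integer_) {
  e <- as.matrix(utils::read.table(path, col.names = c("from", "to"))) + 1L
  g <- igraph::graph_from_edgelist(e, directed = FALSE)
  new_topology(g, kind = kind, role_mode = role_mode, hub = hub)
}

#' Write a topology as GraphML
#'
#' @param t A `topology`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_graphml <- function(t, path) {
  igraph::write_graph(t$graph, path, format = "graphml")
  invisible(path)
}
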