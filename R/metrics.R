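#' Average degree
#'
#' AD = 2E / N: the mean number of interaction partners per protein, a
#' first-order measure of how interconnected the network is.
#'
#' @param net An [interactome] with at least one node.
#' @return A single number.
#' @export
average_degree <- function(net) {
  stopifnot(is_interactome(net))
  n <- n_nodes(net)
  if (n == 0L) abort("Average degree is undefined on an empty network.")
  2 * n_edges(net) / n
}

#' Average clustering coefficient
#'
#' Ca = (1/N) sum_i Ci with Ci = 2 T_i / (k_i (k_i - 1)), the fraction of a
#' node's neighbour pairs that interact (T_i = triangles through i). Nodes of
#' degree < 2 contribute Ci = 0 and are included in the mean over all N
#' nodes. High values indicate a tendency to form interconnected communities.
#'
#' @param net An [interactome] with at least one node.
#' @param per_node If `TRUE`, return a tibble of per-node coefficients
#'   instead of the average.
#' @return A single number, or a tibble (`node`, `clustering`) when
#'   `per_node = TRUE`.
#' @export
average_clustering <- function(net, per_node = FALSE) {
  stopifnot(is_interactome(net))
  if (n_nodes(net) == 0L) abort("Clustering is undefined on an empty network.")
  ci <- igraph::transitivity(net, type = "local", isolates = "zero")
  ci[is.nan(ci)] <- 0
  if (per_node) {
    return(tibble(node = igraph::V(net)$name, clustering = ci) |> arrange(.data$node))
  }
  mean(ci)
}

#' Network density
#'
#' D = 2E / (N (N - 1)): realized interactions relative to the maximum
#' possible among N proteins.
#'
#' @param net An [interactome] with at least two nodes.
#' @return A single number in \[0, 1\].
#' @export
net_density <- function(net) {
  stopifnot(is_interactome(net))
  n <- n_nodes(net)
  if (n < 2L) abort("Density needs at least two nodes.")
  2 * n_edges(net) / (n * (n - 1))
}

as_membership_vec <- function(partition, nodes) {
  if (is.data.frame(partition)) {
    memb <- setNames(partition$community, canon_id(partition$node))
  } else {
    memb <- setNames(partition, canon_id(names(partition)))
  }
  missing <- setdiff(nodes, names(memb))
  if (length(missing) > 0) {
    abort(sprintf("Partition does not cover node(s): %s", paste(head(missing, 5), collapse = ", ")))
  }
  memb[nodes]
}

#' Modularity of a partition
#'
#' Q = (1/2E) sum_ij \[A_ij - k_i k_j / 2E\] delta(c_i, c_j) over ordered
#' node pairs, with A the 0/1 adjacency indicator: how much denser the
#' communities are internally than expected under a degree-preserving random
#' rewiring. Computed in the equivalent per-community form
#' Q = sum_c (e_c / E - (K_c / 2E)^2).
#'
#' @param net An [interactome] with at least one edge.
#' @param partition Community assignment covering every node: a named vector
#'   (node -> community id) or tibble with `node`, `community`.
#' @return Q, a number in \[-0.5, 1\].
#' @export
modularity_q <- function(net, partition) {
  stopifnot(is_interactome(net))
  E <- n_edges(net)
  if (E == 0L) abort("Modularity needs at least one edge.")
  nodes <- igraph::V(net)$name
  memb <- as_membership_vec(partition, nodes)
  deg <- igraph::degree(net)
  ed <- edge_table(net)
  within <- memb[ed$from] == memb[ed$to]
  comm_ids <- sort(unique(memb))
  e_in <- vapply(comm_ids, function(cid) {
    sum(within & memb[ed$from] == cid)
  }, numeric(1))
  K <- vapply(comm_ids, function(cid) sum(deg[memb == cid]), numeric(1))
  sum(e_in / E - (K / (2 * E))^2)
}

#' Louvain community detection
#'
#' Maximizes modularity with the two-phase Louvain heuristic (greedy local
#' moves followed by community aggregation, repeated until Q stops
#' improving). Randomized node visiting is made reproducible by seeding the
#' RNG with `rng_seed`; community ids are renumbered contiguously from 0.
#'
#' @param net An [interactome] with at least one edge.
#' @param rng_seed Integer seed controlling the (shuffled) node order.
#' @return A `louvain_partition`: list with `partition` (tibble `node`,
#'   `community`), `modularity` (Q of that partition, from [modularity_q()]),
#'   and `n_communities`.
#' @export
louvain_communities <- function(net, rng_seed = 1L) {
  stopifnot(is_interactome(net))
  if (n_edges(net) == 0L) abort("Community detection needs at least one edge.")
  g <- net
  class(g) <- "igraph"
  cl <- with_seed(rng_seed, igraph::cluster_louvain(g, weights = NA))
  memb <- igraph::membership(cl)
  ids <- as.integer(factor(memb, levels = unique(memb[order_c(names(memb))]))) - 1L
  partition <- tibble(node = names(memb), community = ids) |> arrange(.data$node)
  structure(
    list(
      partition = partition,
      modularity = modularity_q(net, partition),
      n_communities = length(unique(ids))
    ),
    class = "louvain_partition"
  )
}

#' @export
print.louvain_partition <- function(x, ...) {
  cat(sprintf("<louvain_partition> %d communities, Q = %.4f\n",
              x$n_communities, x$modularity))
  invisible(x)
}

#' Graph diameter
#'
#' The longest shortest-path distance (hop count) between any two proteins.
#' On a disconnected network the diameter of the largest connected component
#' is returned with a warning.
#'
#' @param net An [interactome] with at least one node.
#' @return An integer hop count (0 for a single node).
#' @export
net_diameter <- function(net) {
  stopifnot(is_interactome(net))
  if (n_nodes(net) == 0L) abort("Diameter is undefined on an empty network.")
  comp <- igraph::components(net)
  g <- net
  if (comp$no > 1L) {
    warn("Network is disconnected; reporting the diameter of the largest component.")
    big <- which.max(comp$csize)
    g <- induce(net, names(comp$membership)[comp$membership == big])
  }
  if (n_nodes(g) == 1L) return(0L)
  as.integer(igraph::diameter(g, weights = NA))
}

#' All printed network statistics at once
#'
#' Computes the statistics used to characterize each case network: node and
#' edge counts, average degree, density, average clustering coefficient,
#' Louvain-maximized modularity (with its partition) and diameter.
#'
#' @param net An [interactome].
#' @param rng_seed Seed for the Louvain maximization.
#' @return A `network_metrics` object; see [glance()] for the one-row tibble
#'   form and [tidy()] for per-node degree/clustering/community detail.
#' @export
network_metrics <- function(net, rng_seed = 1L) {
  stopifnot(is_interactome(net))
  lv <- if (n_edges(net) > 0) louvain_communities(net, rng_seed) else NULL
  structure(
    list(
      network = net_name(net),
      n_nodes = n_nodes(net),
      n_edges = n_edges(net),
      average_degree = average_degree(net),
      density = if (n_nodes(net) >= 2) net_density(net) else NA_real_,
      average_clustering = average_clustering(net),
      modularity = if (is.null(lv)) NA_real_ else lv$modularity,
      n_communities = if (is.null(lv)) NA_integer_ else lv$n_communities,
      partition = if (is.null(lv)) NULL else lv$partition,
      diameter = net_diameter(net),
      per_node = tibble(
        node = igraph::V(net)$name,
        degree = as.integer(igraph::degree(net))
      ) |>
        left_join(average_clustering(net, per_node = TRUE), by = "node") |>
        arrange(.data$node)
    ),
    class = "network_metrics"
  )
}

#' @export
print.network_metrics <- function(x, ...) {
  cat(sprintf("<network_metrics> '%s'\n", x$network))
  print(glance(x))
  invisible(x)
}

#' @method glance network_metrics
#' @export
glance.network_metrics <- function(x, ...) {
  tibble(
    network = x$network,
    n_nodes = x$n_nodes,
    n_edges = x$n_edges,
    average_degree = x$average_degree,
    density = x$density,
    average_clustering = x$average_clustering,
    modularity = x$modularity,
    n_communities = x$n_communities,
    diameter = x$diameter
  )
}

#' @method tidy network_metrics
#' @export
tidy.network_metrics <- function(x, ...) {
  out <- x$per_node
  if (!is.null(x$partition)) out <- left_join(out, x$partition, by = "node")
  out
}
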