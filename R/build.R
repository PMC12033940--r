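#' Restrict a reference interactome to a protein universe
#'
#' Returns the induced subgraph of `reference` on the intersection of its
#' nodes with `universe` — the standard way a tissue-specific PPI network is
#' carved out of a global interactome given the proteins detected in that
#' tissue. Edge confidences are preserved.
#'
#' @param reference The global [interactome].
#' @param universe Character vector of protein identifiers (e.g. the
#'   MS-detected proteome or the secretome analyte panel).
#' @return An [interactome] on `nodes(reference)` intersected with `universe`.
#' @export
filter_by_universe <- function(reference, universe) {
  stopifnot(is_interactome(reference))
  universe <- canon_id(universe)
  keep <- intersect(igraph::V(reference)$name, universe)
  if (length(keep) == 0L) {
    abort(sprintf(
      "No universe protein matches the reference interactome (first unmatched: %s).",
      paste(head(sort_c(universe), 5), collapse = ", ")
    ))
  }
  induce(reference, keep)
}

#' Add condition proteins and their first neighbours
#'
#' Expands `net` with the given condition (stimulus) proteins and their
#' direct interactors in `reference`, then closes over all reference edges
#' among the resulting node set — a subnetwork conventionally retains every
#' known interaction among its members. Condition proteins absent from the
#' reference are skipped with a warning.
#'
#' @param net Current [interactome] (typically the universe-filtered network).
#' @param reference The global [interactome].
#' @param condition_proteins Proteins to add (with their neighbourhoods).
#' @return An [interactome]; attribute `"add_report"` counts the condition
#'   proteins and neighbours actually added.
#' @export
add_condition_neighbourhood <- function(net, reference, condition_proteins) {
  stopifnot(is_interactome(net), is_interactome(reference))
  condition_proteins <- unique(canon_id(condition_proteins))
  present <- condition_proteins %in% igraph::V(reference)$name
  if (any(!present)) {
    warn(sprintf("Condition protein(s) not in reference, skipped: %s",
                 paste(condition_proteins[!present], collapse = ", ")))
  }
  cond <- condition_proteins[present]
  before <- net_nodes(net)
  nbrs <- character()
  if (length(cond) > 0) {
    nbrs <- unique(names(unlist(igraph::ego(reference, order = 1, nodes = cond, mindist = 1))))
  }
  nodes <- unique(c(before, cond, nbrs))
  out <- induce(reference, nodes, name = net_name(net))
  attr(out, "add_report") <- list(
    n_condition_added = length(setdiff(cond, before)),
    n_neighbours_added = length(setdiff(nbrs, c(before, cond)))
  )
  out
}

# Lexicographically smallest shortest path from `a` to `b` in `reference`
# (unweighted). Greedy walk: at each step take the alphabetically first
# neighbour that still lies on some shortest path.
lex_shortest_path <- function(reference, a, b) {
  d_from_b <- igraph::distances(reference, v = b)[1, ]
  total <- d_from_b[a]
  if (!is.finite(total)) return(NULL)
  path <- a
  cur <- a
  while (cur != b) {
    nb <- names(igraph::neighbors(reference, cur))
    onpath <- nb[d_from_b[nb] == d_from_b[cur] - 1]
    cur <- sort_c(onpath)[1]
    path <- c(path, cur)
  }
  path
}

#' Connect a fragmented network through reference shortest paths
#'
#' Repeatedly merges the two connected components whose closest node pair is
#' at minimal unweighted shortest-path distance in `reference`, adding the
#' interior nodes of one such path (ties broken deterministically: smallest
#' distance, then lexicographically smallest endpoint pair, then
#' lexicographically smallest interior sequence) and closing over the
#' reference-induced edges. Stops when one component remains or when the
#' reference cannot connect the remainder (warned, `connected = FALSE`).
#'
#' @param net [interactome] whose nodes all exist in `reference`.
#' @param reference The global [interactome] supplying bridge paths.
#' @return A list with elements `network` (the enriched [interactome]),
#'   `report` (one-row tibble: `n_bridge_nodes_added`, `final_n_nodes`,
#'   `final_n_edges`, `connected`) and `steps` (one record per merge with the
#'   chosen endpoints, distance and interior nodes).
#' @export
enrich_connect <- function(net, reference) {
  stopifnot(is_interactome(net), is_interactome(reference))
  missing <- setdiff(net_nodes(net), igraph::V(reference)$name)
  if (length(missing) > 0) {
    abort(sprintf("Nodes absent from reference: %s", paste(head(missing, 5), collapse = ", ")))
  }
  nodes <- net_nodes(net)
  cur <- induce(reference, nodes, name = net_name(net))
  steps <- list()
  bridge_nodes <- character()
  connected <- TRUE

  repeat {
    comp <- igraph::components(cur)
    if (comp$no <= 1L) break
    vnames <- igraph::V(cur)$name
    D <- igraph::distances(reference, v = vnames, to = vnames)
    memb <- comp$membership[vnames]
    # best (distance, endpointA, endpointB) over all component pairs
    best <- NULL
    for (ci in seq_len(comp$no - 1L)) {
      for (cj in (ci + 1L):comp$no) {
        sub <- D[memb == ci, memb == cj, drop = FALSE]
        dmin <- min(sub)
        if (!is.finite(dmin)) next
        hit <- which(sub == dmin, arr.ind = TRUE)
        ends <- tibble(
          a = pmin(rownames(sub)[hit[, 1]], colnames(sub)[hit[, 2]]),
          b = pmax(rownames(sub)[hit[, 1]], colnames(sub)[hit[, 2]])
        ) |> arrange(.data$a, .data$b)
        cand <- list(d = dmin, a = ends$a[1], b = ends$b[1])
        if (is.null(best) ||
            cand$d < best$d ||
            (cand$d == best$d && (cand$a < best$a ||
                                  (cand$a == best$a && cand$b < best$b)))) {
          best <- cand
        }
      }
    }
    if (is.null(best)) {
      warn("Reference interactome cannot connect the remaining components; returning a partial result.")
      connected <- FALSE
      break
    }
    path <- lex_shortest_path(reference, best$a, best$b)
    interior <- setdiff(path, c(best$a, best$b))
    bridge_nodes <- c(bridge_nodes, setdiff(interior, igraph::V(cur)$name))
    steps[[length(steps) + 1L]] <- list(
      from = best$a, to = best$b, distance = best$d, interior = interior
    )
    cur <- induce(reference, c(igraph::V(cur)$name, interior), name = net_name(net))
  }

  report <- tibble(
    n_bridge_nodes_added = length(unique(bridge_nodes)),
    final_n_nodes = n_nodes(cur),
    final_n_edges = n_edges(cur),
    connected = connected
  )
  list(network = cur, report = report, steps = steps)
}

#' Build one experimental case's network
#'
#' Composes the three construction steps: filter the reference interactome to
#' the measured protein universe, add the condition (stimulus) proteins and
#' their first neighbours, then connect any remaining fragments through
#' reference shortest paths so the final network is a single component
#' whenever the reference allows it.
#'
#' @inheritParams filter_by_universe
#' @param condition_proteins Stimulus proteins for this case (may be empty).
#' @param seeds Optional seed proteins; with `include_seeds = TRUE` their
#'   neighbourhoods are added like the condition proteins'.
#' @param include_seeds Whether seeds are also expanded with their
#'   neighbours. Default `FALSE`: only stimulus proteins are expanded.
#' @param name Label for the built network.
#' @return A list with `network` (the final [interactome]) and `report`
#'   (one-row tibble: `n_universe_kept`, `n_condition_added`,
#'   `n_neighbours_added`, `n_bridge_nodes_added`, `final_n_nodes`,
#'   `final_n_edges`, `connected`).
#' @export
build_case_network <- function(reference, universe, condition_proteins = character(),
                               seeds = character(), include_seeds = FALSE,
                               name = "case") {
  base <- filter_by_universe(reference, universe)
  expand <- unique(canon_id(condition_proteins))
  if (include_seeds) expand <- unique(c(expand, canon_id(seeds)))
  grown <- add_condition_neighbourhood(base, reference, expand)
  add_rep <- attr(grown, "add_report")
  enr <- enrich_connect(grown, reference)
  net <- enr$network
  igraph::graph_attr(net, "name") <- name
  report <- tibble(
    n_universe_kept = n_nodes(base),
    n_condition_added = add_rep$n_condition_added,
    n_neighbours_added = add_rep$n_neighbours_added,
    n_bridge_nodes_added = enr$report$n_bridge_nodes_added,
    final_n_nodes = enr$report$final_n_nodes,
    final_n_edges = enr$report$final_n_edges,
    connected = enr$report$connected
  )
  list(network = net, report = report)
}
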