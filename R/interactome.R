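#' Protein-protein interaction network container
#'
#' An `interactome` is a simple undirected graph whose vertices are canonical
#' (upper-case) protein symbols and whose edges carry a confidence score in
#' \[0, 1\]. It is stored as an [igraph][igraph::igraph-package] graph so all
#' standard graph machinery applies, with the construction rules PPI pipelines
#' expect: self-interactions are dropped, duplicated pairs (in either
#' orientation) are collapsed keeping the maximum confidence, and every edge
#' endpoint is a registered node.
#'
#' @param edges A data frame with columns `from`, `to` and (optionally)
#'   `confidence` (defaulting to 1). May be `NULL` for an edgeless network.
#' @param nodes Additional node identifiers to include even if isolated.
#' @param name Label for the network.
#'
#' @return An object of class `interactome` (also a valid igraph object).
#'
#' @examples
#' net <- interactome(
#'   data.frame(from = c("a", "B"), to = c("b", "C"), confidence = c(0.9, 0.6))
#' )
#' net
#' edge_table(net)
#' @export
interactome <- function(edges = NULL, nodes = character(), name = "interactome") {
  nodes <- canon_id(nodes)
  if (is.null(edges) || nrow(edges) == 0L) {
    ed <- tibble(from = character(), to = character(), confidence = double())
  } else {
    if (!all(c("from", "to") %in% names(edges))) {
      abort("`edges` must have columns `from` and `to`.")
    }
    conf <- if ("confidence" %in% names(edges)) as.numeric(edges$confidence) else rep(1, nrow(edges))
    if (anyNA(conf) || any(conf < 0) || any(conf > 1)) {
      abort("Edge confidences must be numeric values in [0, 1].")
    }
    a <- canon_id(edges$from)
    b <- canon_id(edges$to)
    keep <- a != b  # no self-interactions
    a <- a[keep]; b <- b[keep]; conf <- conf[keep]
    lo <- pmin(a, b)
    hi <- pmax(a, b)
    ed <- tibble(from = lo, to = hi, confidence = conf) |>
      group_by(.data$from, .data$to) |>
      summarise(confidence = max(.data$confidence), .groups = "drop")
  }
  all_nodes <- sort_c(unique(c(nodes, ed$from, ed$to)))
  g <- igraph::graph_from_data_frame(ed, directed = FALSE, vertices = all_nodes)
  g <- igraph::set_graph_attr(g, "name", name)
  class(g) <- c("interactome", class(g))
  g
}

new_interactome_from_igraph <- function(g, name = "interactome") {
  ed <- igraph::as_data_frame(g, what = "edges")
  if (!"confidence" %in% names(ed)) ed$confidence <- rep(1, nrow(ed))
  interactome(ed, nodes = igraph::V(g)$name, name = name)
}

#' @rdname interactome
#' @param x Object to test or coerce.
#' @export
is_interactome <- function(x) inherits(x, "interactome")

#' Interactome accessors
#'
#' `net_nodes()` returns the sorted node identifiers, `n_nodes()`/`n_edges()`
#' the counts N and E, and `edge_table()` a tibble of undirected edges
#' (`from` < `to` lexicographically) with their confidences.
#'
#' @param net An [interactome].
#' @return `edge_table()` returns a tibble with columns `from`, `to`,
#'   `confidence`; the others return vectors/scalars.
#' @export
net_nodes <- function(net) {
  stopifnot(is_interactome(net))
  sort_c(igraph::V(net)$name)
}

#' @rdname net_nodes
#' @export
n_nodes <- function(net) igraph::vcount(net)

#' @rdname net_nodes
#' @export
n_edges <- function(net) igraph::ecount(net)

#' @rdname net_nodes
#' @export
edge_table <- function(net) {
  stopifnot(is_interactome(net))
  ed <- igraph::as_data_frame(net, what = "edges")
  if (nrow(ed) == 0L) {
    return(tibble(from = character(), to = character(), confidence = double()))
  }
  if (!"confidence" %in% names(ed)) ed$confidence <- rep(1, nrow(ed))
  tibble(
    from = pmin(ed$from, ed$to),
    to = pmax(ed$from, ed$to),
    confidence = as.numeric(ed$confidence)
  ) |>
    arrange(.data$from, .data$to)
}

#' @rdname net_nodes
#' @export
net_name <- function(net) {
  nm <- igraph::graph_attr(net, "name")
  if (is.null(nm)) "interactome" else nm
}

# Induced subgraph on `keep` (character ids), preserving confidences and class.
induce <- function(net, keep, name = net_name(net)) {
  keep <- intersect(canon_id(keep), igraph::V(net)$name)
  sub <- igraph::induced_subgraph(net, vids = keep)
  ed <- igraph::as_data_frame(sub, what = "edges")
  interactome(ed, nodes = keep, name = name)
}

#' @export
print.interactome <- function(x, ...) {
  cat(sprintf(
    "<interactome '%s'>  %d nodes, %d edges\n",
    net_name(x), n_nodes(x), n_edges(x)
  ))
  ed <- edge_table(x)
  if (nrow(ed) > 0) {
    print(head(ed, 5))
    if (nrow(ed) > 5) cat(sprintf("# ... with %d more edges\n", nrow(ed) - 5L))
  }
  invisible(x)
}

#' @method tidy interactome
#' @export
tidy.interactome <- function(x, ...) edge_table(x)

#' @method glance interactome
#' @export
glance.interactome <- function(x, ...) {
  comp <- igraph::components(x)
  tibble(
    name = net_name(x),
    n_nodes = n_nodes(x),
    n_edges = n_edges(x),
    n_components = comp$no,
    connected = comp$no <= 1L
  )
}
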