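#' Propagation settings
#'
#' Controls the hop-limited message-passing prioritization: `n_repetitions`
#' full passes are made, each letting scores travel along shortest paths of
#' at most `n_iterations` hops, and (by default) each pass rescales scores so
#' the maximum is 1 before re-seeding the next pass. The defaults (3
#' repetitions, 2 iterations) follow the GUILD reference implementation of
#' NetScore.
#'
#' @param n_repetitions Positive integer, default 3.
#' @param n_iterations Positive integer (hop limit per repetition), default 2.
#' @param normalize_each_repetition Divide by the maximum score after every
#'   repetition (default `TRUE`).
#' @return A `propagation_config` list.
#' @export
propagation_config <- function(n_repetitions = 3, n_iterations = 2,
                               normalize_each_repetition = TRUE) {
  structure(
    list(
      n_repetitions = assert_count(n_repetitions, "n_repetitions", min = 1L),
      n_iterations = assert_count(n_iterations, "n_iterations", min = 1L),
      normalize_each_repetition = isTRUE(normalize_each_repetition)
    ),
    class = "propagation_config"
  )
}

# Exact-distance hop rings for every node: rings[[d]][[u]] = integer ids of
# nodes at unweighted distance exactly d from u. Computed once per graph and
# reused across repetitions.
hop_rings <- function(net, h) {
  n <- igraph::vcount(net)
  rings <- vector("list", h)
  for (d in seq_len(h)) {
    eg <- igraph::ego(net, order = d, nodes = igraph::V(net), mindist = d)
    rings[[d]] <- lapply(eg, as.integer)
  }
  rings
}

#' Propagate seed scores by hop-limited message passing
#'
#' NetScore-style guilt-by-association propagation. In each repetition every
#' node u collects messages from all origin nodes o within `n_iterations`
#' hops (including itself at distance 0): the new score is the mean over
#' those origins of s(o) / (d(u, o) + 1), where d is the unweighted
#' shortest-path distance; the repetition optionally ends with division by
#' the maximum score. Repetitions re-seed the next pass with the updated
#' scores, so influence travels at most `n_iterations * n_repetitions` hops
#' in total. Edge confidences are carried as metadata but not used as
#' weights.
#'
#' @param net An [interactome] with at least one node.
#' @param initial Initial scores: a `score_vector`, named numeric vector, or
#'   tibble with `node`, `score`. Nodes of `net` missing from `initial`
#'   start at 0; entries for nodes outside `net` are dropped with a warning.
#' @param config A [propagation_config()].
#' @return A `propagation_result`: list with `final` (a `score_vector`,
#'   provenance `"propagated"`), `initial`, `snapshots` (scores after each
#'   repetition), `config`, and the network size.
#' @export
propagate <- function(net, initial, config = propagation_config()) {
  stopifnot(is_interactome(net), inherits(config, "propagation_config"))
  n <- igraph::vcount(net)
  if (n == 0L) abort("Cannot propagate on an empty network.")
  vnames <- igraph::V(net)$name
  init <- as_named_scores(initial)
  if (is.null(names(init))) abort("`initial` must be named by node.")
  names(init) <- canon_id(names(init))
  extra <- setdiff(names(init), vnames)
  if (length(extra) > 0) {
    warn(sprintf("Dropping %d initial score(s) for nodes outside the network.", length(extra)))
    init <- init[setdiff(names(init), extra)]
  }
  s <- setNames(rep(0, n), vnames)
  s[names(init)] <- as.numeric(init)
  s0 <- s
  if (all(s == 0)) {
    warn("All initial scores are zero; propagation returns zeros.")
  }

  h <- config$n_iterations
  rings <- hop_rings(net, h)
  n_origins <- rep(1, n)  # self at distance 0
  for (d in seq_len(h)) n_origins <- n_origins + lengths(rings[[d]])

  snapshots <- vector("list", config$n_repetitions)
  for (r in seq_len(config$n_repetitions)) {
    contrib <- s  # self term: s(u) / (0 + 1)
    for (d in seq_len(h)) {
      ring_d <- rings[[d]]
      contrib <- contrib +
        vapply(ring_d, function(idx) sum(s[idx]), numeric(1)) / (d + 1)
    }
    s <- contrib / n_origins
    if (config$normalize_each_repetition) {
      m <- max(s)
      if (m > 0) s <- s / m
    }
    snapshots[[r]] <- setNames(s, vnames)
  }

  structure(
    list(
      final = score_vector(s, provenance = "propagated"),
      initial = score_vector(s0, provenance = attr(initial, "provenance") %||% "binary"),
      snapshots = snapshots,
      config = config,
      n_nodes = n,
      n_edges = igraph::ecount(net),
      network = net_name(net)
    ),
    class = "propagation_result"
  )
}

#' @export
print.propagation_result <- function(x, ...) {
  cat(sprintf(
    "<propagation_result> network '%s' (%d nodes), %d repetition(s) x %d iteration(s)\n",
    x$network, x$n_nodes, x$config$n_repetitions, x$config$n_iterations
  ))
  print(head(rank_nodes(x), 5))
  invisible(x)
}

#' Rank nodes by propagated score
#'
#' Orders nodes by decreasing final score; ties are broken lexicographically
#' by node identifier so the ranking is fully deterministic. Ranks are
#' 1-based and distinct.
#'
#' @param result A `propagation_result`, `score_vector`, or named numeric
#'   vector.
#' @return A tibble with columns `node`, `score`, `rank`.
#' @export
rank_nodes <- function(result) {
  s <- if (inherits(result, "propagation_result")) {
    as_named_scores(result$final)
  } else {
    as_named_scores(result)
  }
  ord <- order_c(-s, names(s))
  tibble(
    node = names(s)[ord],
    score = unname(s[ord]),
    rank = seq_along(s)
  )
}

#' @method tidy propagation_result
#' @export
tidy.propagation_result <- function(x, ...) {
  rk <- rank_nodes(x)
  init <- as_named_scores(x$initial)
  rk |>
    mutate(initial = unname(init[.data$node]), .after = "node") |>
    dplyr::rename(final = "score")
}

#' @method glance propagation_result
#' @export
glance.propagation_result <- function(x, ...) {
  fin <- as_named_scores(x$final)
  init <- as_named_scores(x$initial)
  tibble(
    network = x$network,
    n_nodes = x$n_nodes,
    n_edges = x$n_edges,
    n_seeds = sum(init > 0),
    n_repetitions = x$config$n_repetitions,
    n_iterations = x$config$n_iterations,
    normalized = x$config$normalize_each_repetition,
    n_nonzero = sum(fin > 0),
    max_score = max(fin)
  )
}
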