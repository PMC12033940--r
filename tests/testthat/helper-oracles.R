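# Independent brute-force oracles used to verify the package's graph code.
# Everything here is written from first principles on adjacency matrices /
# edge lists, deliberately avoiding the code paths under test.

# Random simple undirected graph as an edge tibble (base-R RNG only).
rand_edges <- function(n, p, seed) {
  set.seed(seed)
  nodes <- sprintf("N%02d", seq_len(n))
  idx <- which(upper.tri(matrix(FALSE, n, n)), arr.ind = TRUE)
  keep <- stats::runif(nrow(idx)) < p
  tibble::tibble(
    from = nodes[idx[keep, 1]],
    to = nodes[idx[keep, 2]],
    confidence = stats::runif(sum(keep), 0.5, 1)
  )
}

make_net <- function(edges, nodes = character(), name = "test") {
  interactome(edges, nodes = nodes, name = name)
}

# 0/1 adjacency matrix (nodes sorted) straight from the edge table.
adj_matrix <- function(net) {
  nodes <- net_nodes(net)
  A <- matrix(0L, length(nodes), length(nodes), dimnames = list(nodes, nodes))
  ed <- edge_table(net)
  if (nrow(ed) > 0) {
    A[cbind(ed$from, ed$to)] <- 1L
    A[cbind(ed$to, ed$from)] <- 1L
  }
  A
}

# All-pairs hop distances by hand-rolled BFS over the adjacency matrix.
bfs_distances <- function(A) {
  n <- nrow(A)
  D <- matrix(Inf, n, n, dimnames = dimnames(A))
  for (s in seq_len(n)) {
    dist <- rep(Inf, n)
    dist[s] <- 0
    frontier <- s
    d <- 0
    while (length(frontier) > 0) {
      d <- d + 1
      nxt <- integer()
      for (v in frontier) {
        nb <- which(A[v, ] == 1L)
        new <- nb[!is.finite(dist[nb])]
        dist[new] <- d
        nxt <- c(nxt, new)
      }
      frontier <- unique(nxt)
    }
    D[s, ] <- dist
  }
  D
}

# Brute-force per-node clustering: fraction of neighbour pairs adjacent.
bf_clustering <- function(A) {
  n <- nrow(A)
  ci <- numeric(n)
  for (i in seq_len(n)) {
    nb <- which(A[i, ] == 1L)
    k <- length(nb)
    if (k < 2) next
    tri <- 0
    for (a in seq_len(k - 1)) {
      for (b in (a + 1):k) {
        tri <- tri + A[nb[a], nb[b]]
      }
    }
    ci[i] <- 2 * tri / (k * (k - 1))
  }
  ci
}

# Modularity straight from the printed double sum over ordered node pairs.
bf_modularity <- function(A, memb) {
  deg <- rowSums(A)
  twoE <- sum(deg)
  q <- 0
  n <- nrow(A)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (memb[i] == memb[j]) {
        q <- q + A[i, j] - deg[i] * deg[j] / twoE
      }
    }
  }
  unname(q / twoE)
}

# All set partitions of n labelled items as restricted-growth strings.
set_partitions <- function(n) {
  out <- list()
  recurse <- function(prefix, maxblock) {
    pos <- length(prefix) + 1L
    if (pos > n) {
      out[[length(out) + 1L]] <<- prefix
      return(invisible())
    }
    for (b in seq_len(maxblock + 1L)) {
      recurse(c(prefix, b), max(maxblock, b))
    }
  }
  recurse(integer(), 0L)
  out
}

# Exhaustive message-passing oracle: direct enumeration of origins within h
# hops (BFS distances), mean of s(o)/(d+1), optional max-normalization,
# repeated r times.
oracle_propagate <- function(A, s0, r, h, normalize = TRUE) {
  D <- bfs_distances(A)
  n <- nrow(A)
  s <- s0
  for (rep_i in seq_len(r)) {
    s_new <- numeric(n)
    for (u in seq_len(n)) {
      origins <- which(D[u, ] <= h)
      acc <- 0
      for (o in origins) {
        acc <- acc + s[o] / (D[u, o] + 1)
      }
      s_new[u] <- acc / length(origins)
    }
    if (normalize && max(s_new) > 0) s_new <- s_new / max(s_new)
    s <- s_new
  }
  names(s) <- rownames(A)
  s
}

# Named paths/cliques used across tests.
k3 <- function() make_net(tibble::tibble(
  from = c("A", "A", "B"), to = c("B", "C", "C"), confidence = 1
))

path_graph <- function(k) {
  nodes <- LETTERS[seq_len(k)]
  make_net(tibble::tibble(
    from = nodes[-k], to = nodes[-1], confidence = 1
  ))
}

two_k3 <- function(bridge = FALSE) {
  ed <- tibble::tibble(
    from = c("A", "A", "B", "D", "D", "E"),
    to = c("B", "C", "C", "E", "F", "F"),
    confidence = 1
  )
  if (bridge) ed <- dplyr::bind_rows(ed, tibble::tibble(from = "C", to = "D", confidence = 1))
  make_net(ed)
}
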