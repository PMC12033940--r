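test_that("closed-form metric values on canonical graphs", {
  expect_equal(average_degree(k3()), 2)
  expect_equal(average_degree(path_graph(3)), 4 / 3)
  expect_equal(average_clustering(k3()), 1)
  star <- interactome(tibble::tibble(from = "S", to = c("A", "B", "C"), confidence = 1))
  expect_equal(average_clustering(star), 0)
  expect_equal(net_density(k3()), 1)
  expect_equal(net_density(path_graph(3)), 2 / 3)
  expect_equal(net_density(interactome(nodes = sprintf("I%d", 1:10))), 0)
  expect_equal(net_diameter(k3()), 1L)
  expect_equal(net_diameter(path_graph(5)), 4L)
})

test_that("modularity worked examples: single community 0, two K3s 1/2, bridged K3s 5/14", {
  part1 <- setNames(rep(1L, 3), net_nodes(k3()))
  expect_equal(modularity_q(k3(), part1), 0)

  tri2 <- setNames(c(1, 1, 1, 2, 2, 2), c("A", "B", "C", "D", "E", "F"))
  expect_equal(modularity_q(two_k3(), tri2), 0.5)
  expect_equal(modularity_q(two_k3(bridge = TRUE), tri2), 5 / 14)

  expect_error(modularity_q(k3(), c(A = 1, B = 1)), "cover")
})

test_that("metrics agree with brute-force oracles on random graphs", {
  for (seed in 1:30) {
    n <- sample(5:30, 1)
    net <- make_net(rand_edges(n, 0.25, seed = seed), nodes = sprintf("N%02d", 1:n))
    if (n_edges(net) == 0) next
    A <- adj_matrix(net)
    expect_equal(average_degree(net), mean(rowSums(A)), tolerance = 1e-12)
    expect_equal(net_density(net), sum(A) / (n * (n - 1)), tolerance = 1e-12)
    expect_equal(average_clustering(net), mean(bf_clustering(A)), tolerance = 1e-12)
    set.seed(seed + 2000)
    memb <- setNames(sample(1:3, n, replace = TRUE), rownames(A))
    expect_equal(modularity_q(net, memb), bf_modularity(A, memb), tolerance = 1e-12)
    D <- bfs_distances(A)
    comp_sizes <- igraph::components(net)$csize
    if (length(comp_sizes) == 1L) {
      expect_equal(net_diameter(net), max(D[is.finite(D)]))
    } else {
      expect_warning(di <- net_diameter(net), "disconnected")
      expect_true(di <= max(D[is.finite(D)]))
    }
  }
})

test_that("modularity stays within [-0.5, 1] for fuzzed partitions", {
  for (seed in 1:20) {
    net <- make_net(rand_edges(12, 0.3, seed = seed), nodes = sprintf("N%02d", 1:12))
    if (n_edges(net) == 0) next
    set.seed(seed)
    memb <- setNames(sample(1:4, 12, replace = TRUE), net_nodes(net))
    q <- modularity_q(net, memb)
    expect_gte(q, -0.5)
    expect_lte(q, 1)
  }
})

test_that("metrics are invariant under node relabeling", {
  ed <- rand_edges(15, 0.3, seed = 3)
  net <- make_net(ed, nodes = sprintf("N%02d", 1:15))
  perm <- setNames(sprintf("Q%02d", sample(15)), net_nodes(net))
  net2 <- make_net(
    tibble::tibble(from = perm[ed$from], to = perm[ed$to], confidence = ed$confidence),
    nodes = unname(perm)
  )
  expect_equal(average_degree(net2), average_degree(net))
  expect_equal(average_clustering(net2), average_clustering(net))
  expect_equal(net_density(net2), net_density(net))
  expect_equal(suppressWarnings(net_diameter(net2)), suppressWarnings(net_diameter(net)))
})

test_that("Louvain recovers planted structure on easy cases and never scores below 0", {
  lv <- louvain_communities(two_k3(), rng_seed = 1)
  expect_equal(lv$n_communities, 2L)
  expect_equal(lv$modularity, 0.5)
  # the two triangles are exactly the communities
  memb <- setNames(lv$partition$community, lv$partition$node)
  expect_length(unique(memb[c("A", "B", "C")]), 1L)
  expect_length(unique(memb[c("D", "E", "F")]), 1L)

  k5 <- make_net(tibble::tibble(
    from = rep(LETTERS[1:4], times = 4:1),
    to = unlist(lapply(2:5, function(i) LETTERS[i:5])),
    confidence = 1
  ))
  expect_equal(n_edges(k5), 10L)
  lv5 <- louvain_communities(k5, rng_seed = 1)
  expect_equal(lv5$modularity, 0)

  for (seed in 1:10) {
    net <- make_net(rand_edges(14, 0.25, seed = seed), nodes = sprintf("N%02d", 1:14))
    if (n_edges(net) == 0) next
    expect_gte(louvain_communities(net, rng_seed = seed)$modularity, 0)
  }
})

test_that("Louvain is deterministic per seed and beats the planted partition on SBM graphs", {
  sim <- generate_interactome(n_nodes = 120, n_communities = 4, p_in = 0.35,
                              p_out = 0.02, rng_seed = 9, n_seeds = 0)
  lv1 <- louvain_communities(sim$network, rng_seed = 5)
  lv2 <- louvain_communities(sim$network, rng_seed = 5)
  expect_identical(lv1$partition, lv2$partition)

  planted <- setNames(sim$ground_truth$partition$community,
                      sim$ground_truth$partition$node)
  q_planted <- modularity_q(sim$network, planted)
  expect_gte(lv1$modularity, q_planted - 0.05)
})

test_that("network_metrics bundles all statistics consistently", {
  sim <- generate_interactome(n_nodes = 60, n_communities = 3, p_in = 0.4,
                              p_out = 0.05, rng_seed = 2, n_seeds = 0)
  m <- network_metrics(sim$network, rng_seed = 1)
  g <- glance(m)
  expect_equal(g$average_degree, 2 * g$n_edges / g$n_nodes)
  expect_equal(g$density, 2 * g$n_edges / (g$n_nodes * (g$n_nodes - 1)))
  td <- tidy(m)
  expect_equal(nrow(td), g$n_nodes)
  expect_equal(mean(td$clustering), g$average_clustering)
  expect_equal(g$modularity, modularity_q(sim$network, m$partition))
})
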