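test_that("universe filtering is the induced subgraph", {
  p4 <- path_graph(4)  # A-B-C-D
  sub <- filter_by_universe(p4, c("A", "B", "D"))
  expect_setequal(net_nodes(sub), c("A", "B", "D"))
  expect_equal(edge_table(sub)$from, "A")
  expect_equal(edge_table(sub)$to, "B")

  # universe covering everything is the identity
  same <- filter_by_universe(p4, LETTERS[1:4])
  expect_identical(edge_table(same), edge_table(p4))

  expect_error(filter_by_universe(p4, c("X", "Y")), "unmatched")
})

test_that("universe filtering matches a brute-force membership check on random graphs", {
  for (seed in 1:5) {
    ref <- make_net(rand_edges(40, 0.1, seed = seed), nodes = sprintf("N%02d", 1:40))
    set.seed(seed + 100)
    uni <- sample(net_nodes(ref), 15)
    sub <- filter_by_universe(ref, uni)
    ed_ref <- edge_table(ref)
    expected <- ed_ref[ed_ref$from %in% uni & ed_ref$to %in% uni, ]
    expect_equal(edge_table(sub), expected, ignore_attr = TRUE)
    expect_setequal(net_nodes(sub), intersect(net_nodes(ref), uni))
  }
})

test_that("condition neighbourhood adds the stimulus and its first neighbours with induced closure", {
  # star: S at the center, leaves A, B, C
  ref <- make_net(tibble::tibble(from = "S", to = c("A", "B", "C"), confidence = 1))
  net <- filter_by_universe(ref, "A")
  grown <- add_condition_neighbourhood(net, ref, "S")
  expect_setequal(net_nodes(grown), c("A", "B", "C", "S"))
  expect_equal(n_edges(grown), 3L)

  # no new proteins: identity
  again <- add_condition_neighbourhood(grown, ref, "S")
  expect_identical(edge_table(again), edge_table(grown))

  # absent condition protein is skipped with a warning
  expect_warning(add_condition_neighbourhood(net, ref, "ZZZ"), "skipped")
})

test_that("neighbour counting reports only genuinely new nodes", {
  # hub H with 7 neighbours in the reference, 3 already present in net
  ed <- tibble::tibble(from = "H", to = sprintf("X%d", 1:7), confidence = 1)
  ref <- make_net(ed)
  net <- filter_by_universe(ref, c("X1", "X2", "X3"))
  grown <- add_condition_neighbourhood(net, ref, "H")
  rep <- attr(grown, "add_report")
  expect_equal(rep$n_condition_added, 1L)
  expect_equal(rep$n_neighbours_added, 4L)
})

test_that("enrich_connect bridges components along reference shortest paths deterministically", {
  # path A-B-C: net {A, C} gains B
  ref <- path_graph(3)
  net <- interactome(nodes = c("A", "C"))
  enr <- enrich_connect(net, ref)
  expect_true(enr$report$connected)
  expect_equal(enr$report$n_bridge_nodes_added, 1L)
  expect_setequal(net_nodes(enr$network), c("A", "B", "C"))

  # already connected: identity, nothing added
  enr2 <- enrich_connect(ref, ref)
  expect_equal(enr2$report$n_bridge_nodes_added, 0L)
  expect_identical(edge_table(enr2$network), edge_table(ref))

  # tie between two 2-hop paths A-B-D / A-C-D: lexicographically smaller interior wins
  sq <- make_net(tibble::tibble(
    from = c("A", "B", "A", "C"), to = c("B", "D", "C", "D"), confidence = 1
  ))
  net3 <- interactome(nodes = c("A", "D"))
  enr3 <- enrich_connect(net3, sq)
  expect_setequal(net_nodes(enr3$network), c("A", "B", "D"))

  # reference that cannot connect: partial result with connected = FALSE
  disc <- make_net(tibble::tibble(from = c("A", "C"), to = c("B", "D"), confidence = 1))
  net4 <- interactome(nodes = c("A", "C"))
  expect_warning(enr4 <- enrich_connect(net4, disc), "cannot connect")
  expect_false(enr4$report$connected)
})

test_that("every bridge node lies on a reference shortest path between prior nodes (property)", {
  n_checked <- 0
  for (seed in 1:20) {
    ref <- make_net(rand_edges(25, 0.2, seed = seed), nodes = sprintf("N%02d", 1:25))
    if (igraph::components(ref)$no != 1L) next
    set.seed(seed + 500)
    keep <- sample(net_nodes(ref), 8)
    net <- filter_by_universe(ref, keep)
    enr <- enrich_connect(net, ref)
    expect_true(enr$report$connected)
    expect_equal(igraph::components(enr$network)$no, 1L)
    D <- bfs_distances(adj_matrix(ref))
    for (st in enr$steps) {
      for (x in st$interior) {
        expect_equal(unname(D[st$from, x] + D[x, st$to]), unname(D[st$from, st$to]))
      }
      expect_equal(unname(D[st$from, st$to]), st$distance)
    }
    n_checked <- n_checked + 1
  }
  expect_gte(n_checked, 10)
})

test_that("node growth is monotone and edges are always the reference-induced set", {
  for (seed in 1:8) {
    ref <- make_net(rand_edges(30, 0.1, seed = seed), nodes = sprintf("N%02d", 1:30))
    set.seed(seed)
    uni <- sample(net_nodes(ref), 12)
    cond <- sample(net_nodes(ref), 2)
    base <- filter_by_universe(ref, uni)
    grown <- suppressWarnings(add_condition_neighbourhood(base, ref, cond))
    expect_true(all(net_nodes(base) %in% net_nodes(grown)))
    enr <- suppressWarnings(enrich_connect(grown, ref))
    expect_true(all(net_nodes(grown) %in% net_nodes(enr$network)))
    # induced closure: edges equal reference edges restricted to final nodes
    fin <- net_nodes(enr$network)
    ed_ref <- edge_table(ref)
    expect_equal(
      edge_table(enr$network),
      ed_ref[ed_ref$from %in% fin & ed_ref$to %in% fin, ],
      ignore_attr = TRUE
    )
  }
})

test_that("build_case_network composes the three steps and reports counts", {
  # identity case: full universe, no condition proteins, connected reference
  ref <- make_net(rand_edges(20, 0.25, seed = 7), nodes = sprintf("N%02d", 1:20))
  stopifnot(igraph::components(ref)$no == 1L)
  built <- build_case_network(ref, net_nodes(ref), name = "identity")
  expect_identical(edge_table(built$network), edge_table(ref))
  expect_equal(built$report$n_bridge_nodes_added, 0L)
  expect_true(built$report$connected)

  # planted communities: universe = community 1, condition = a hub in community 2
  sim <- generate_interactome(n_nodes = 80, n_communities = 2, p_in = 0.4,
                              p_out = 0.05, rng_seed = 11, n_seeds = 0)
  gt <- sim$ground_truth
  uni <- gt$partition$node[gt$partition$community == 1]
  hub <- gt$partition$node[gt$partition$community == 2][1]
  built2 <- build_case_network(sim$network, uni, condition_proteins = hub, name = "case")
  expect_equal(built2$report$n_condition_added, 1L)
  expect_true(built2$report$connected)
  expect_true(hub %in% net_nodes(built2$network))
  expect_equal(built2$report$final_n_nodes, n_nodes(built2$network))
})
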