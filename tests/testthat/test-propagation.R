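test_that("degenerate propagation cases: single node, all-zero seeds, empty graph", {
  single <- interactome(nodes = "A")
  res <- propagate(single, c(A = 1))
  expect_equal(res$final$score, 1)

  expect_warning(zero <- propagate(k3(), c(A = 0)), "zero")
  expect_true(all(zero$final$score == 0))

  expect_error(propagate(interactome(), c(A = 1)), "empty")
})

test_that("star-center seeding: hand-enumerated messages match (1 repetition, 2 iterations)", {
  star <- interactome(tibble::tibble(from = "S", to = paste0("L", 1:4), confidence = 1))
  res <- propagate(star, c(S = 1), propagation_config(1, 2))
  s <- setNames(res$final$score, res$final$node)
  # pre-normalization: center (1/5)(1/1) = 0.2, leaves (1/5)(1/2) = 0.1
  expect_equal(unname(s["S"]), 1)
  expect_equal(unname(s[paste0("L", 1:4)]), rep(0.5, 4))
  rk <- rank_nodes(res)
  expect_equal(rk$node[1], "S")
})

test_that("hop-limited spread: distant nodes stay at zero until enough repetitions", {
  p5 <- path_graph(5)  # A-B-C-D-E
  # with h = 2 the middle node is reached in the very first repetition
  res1 <- propagate(p5, c(A = 1, E = 1), propagation_config(1, 2))
  s1 <- setNames(res1$final$score, res1$final$node)
  expect_gt(s1["C"], 0)
  # with h = 1 it takes a second repetition for the signal to arrive
  res1b <- propagate(p5, c(A = 1), propagation_config(1, 1))
  s1b <- setNames(res1b$final$score, res1b$final$node)
  expect_equal(unname(s1b[c("C", "D", "E")]), c(0, 0, 0))
  res2 <- propagate(p5, c(A = 1), propagation_config(2, 1))
  s2 <- setNames(res2$final$score, res2$final$node)
  expect_gt(s2["C"], 0)
  expect_equal(unname(s2[c("D", "E")]), c(0, 0))
})

test_that("propagation matches the exhaustive message-enumeration oracle on random graphs", {
  for (seed in 1:25) {
    n <- sample(4:12, 1)
    net <- make_net(rand_edges(n, 0.3, seed = seed), nodes = sprintf("N%02d", 1:n))
    A <- adj_matrix(net)
    set.seed(seed + 1000)
    s0 <- setNames(round(runif(nrow(A)), 3), rownames(A))
    s0[sample(length(s0), max(1, n %/% 2))] <- 0
    if (all(s0 == 0)) s0[1] <- 1
    for (r in 1:3) {
      for (h in 1:2) {
        for (norm in c(TRUE, FALSE)) {
          got <- propagate(net, s0, propagation_config(r, h, norm))
          expected <- oracle_propagate(A, unname(s0[net_nodes(net)]), r, h, norm)
          gotv <- setNames(got$final$score, got$final$node)[names(expected)]
          expect_equal(unname(gotv), unname(expected), tolerance = 1e-12)
        }
      }
    }
  }
})

test_that("locality: nodes beyond h*r hops from every seed score exactly zero", {
  for (seed in 1:10) {
    net <- make_net(rand_edges(15, 0.12, seed = seed), nodes = sprintf("N%02d", 1:15))
    A <- adj_matrix(net)
    D <- bfs_distances(A)
    seeds <- rownames(A)[1:2]
    s0 <- setNames(as.numeric(rownames(A) %in% seeds), rownames(A))
    for (r in 1:2) {
      for (h in 1:2) {
        res <- propagate(net, s0, propagation_config(r, h))
        s <- setNames(res$final$score, res$final$node)
        dmin <- apply(D[, seeds, drop = FALSE], 1, min)
        far <- names(dmin)[dmin > h * r]
        expect_true(all(s[far] == 0))
      }
    }
  }
})

test_that("relabeling nodes permutes the result (isomorphism equivariance)", {
  ed <- rand_edges(10, 0.35, seed = 8)
  net <- make_net(ed, nodes = sprintf("N%02d", 1:10))
  s0 <- setNames(c(1, rep(0, 9)), net_nodes(net))
  res <- propagate(net, s0)
  perm <- setNames(sprintf("Z%02d", 10:1), net_nodes(net))
  ed2 <- tibble::tibble(from = perm[ed$from], to = perm[ed$to], confidence = ed$confidence)
  net2 <- make_net(ed2, nodes = unname(perm))
  s02 <- setNames(s0, perm[names(s0)])
  res2 <- propagate(net2, s02)
  s <- setNames(res$final$score, res$final$node)
  s2 <- setNames(res2$final$score, res2$final$node)
  expect_equal(unname(s2[perm[names(s)]]), unname(s), tolerance = 1e-12)
})

test_that("uniform scores on a vertex-transitive graph stay uniform", {
  ring <- interactome(tibble::tibble(
    from = sprintf("R%d", 1:6), to = sprintf("R%d", c(2:6, 1)), confidence = 1
  ))
  res <- propagate(ring, setNames(rep(0.7, 6), net_nodes(ring)))
  expect_true(all(abs(res$final$score - res$final$score[1]) < 1e-12))
})

test_that("increasing a seed score never decreases unnormalized final scores (monotonicity)", {
  for (seed in 1:5) {
    net <- make_net(rand_edges(10, 0.3, seed = seed), nodes = sprintf("N%02d", 1:10))
    s0 <- setNames(rep(0, 10), net_nodes(net))
    s0[1:2] <- c(0.4, 0.6)
    cfg <- propagation_config(2, 2, normalize_each_repetition = FALSE)
    base <- propagate(net, s0, cfg)
    s0_up <- s0
    s0_up[1] <- 0.9
    up <- propagate(net, s0_up, cfg)
    expect_true(all(up$final$score >= base$final$score - 1e-12))
  }
})

test_that("ranking is descending with deterministic lexicographic tie-breaks", {
  expect_equal(rank_nodes(c(A = 0.5, B = 0.9)),
               tibble::tibble(node = c("B", "A"), score = c(0.9, 0.5), rank = 1:2))
  expect_equal(rank_nodes(c(B = 0.5, A = 0.5))$node, c("A", "B"))

  set.seed(77)
  s <- setNames(round(runif(100), 2), sprintf("N%03d", sample(1:100)))
  rk <- rank_nodes(s)
  ord <- order(-s, names(s), method = "radix")
  expect_equal(rk$node, names(s)[ord])
  expect_equal(rk$rank, 1:100)
})
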