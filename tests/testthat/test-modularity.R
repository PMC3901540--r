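test_that("realized modularity reproduces the worked 36-edge example", {
  fx <- fixture_network(36, 31, sizes = c(9, 9, 9, 9), seed = 1)
  rm_ <- realized_modularity(fx$network, fx$partition)
  expect_equal(rm_$e, 36L)
  expect_equal(rm_$w, 31L)
  expect_equal(rm_$qr, 31 / 36)
  expect_equal(round(rm_$qr, 2), 0.86)
  expect_equal(round(rm_$qprime, 2), 0.72)
})

test_that("realized modularity hits its analytic extremes", {
  net <- random_test_graph(8, 0.5, seed = 3, directed = TRUE)
  one <- partition(setNames(rep(0, n_nodes(net)), net$nodes))
  rm_all <- realized_modularity(net, one)
  expect_equal(rm_all$w, rm_all$e)
  expect_equal(rm_all$qr, 1)
  expect_equal(rm_all$qprime, 1)

  # triangle, every node its own module
  tri <- network(rbind(c("a", "b"), c("b", "c"), c("c", "a")))
  rm0 <- realized_modularity(tri, partition(c(a = 0, b = 1, c = 2)))
  expect_equal(rm0$qr, 0)
  expect_equal(rm0$qprime, -1)

  # equal within/between counts -> the minimum for a genuinely modular split
  half <- fixture_network(20, 10, sizes = c(6, 6), seed = 5)
  rm_h <- realized_modularity(half$network, half$partition)
  expect_equal(rm_h$qr, 0.5)
  expect_equal(rm_h$qprime, 0)
})

test_that("realized modularity counts self-loops as within-module edges", {
  net <- network(rbind(c("a", "a"), c("a", "b")))
  p <- partition(c(a = 0, b = 1))
  rm_ <- realized_modularity(net, p)
  expect_equal(rm_$w, 1L)
  expect_equal(rm_$qr, 0.5)
})

test_that("edgeless networks are refused", {
  net <- network(NULL, nodes = c("a", "b"))
  p <- partition(c(a = 0, b = 0))
  expect_error(realized_modularity(net, p), "edgeless")
  expect_error(newman_girvan_q(net, p), "edgeless")
  expect_error(louvain(net), "edgeless")
})

test_that("q_prime is the affine rescaling 2x - 1 on [0, 1]", {
  expect_equal(q_prime(31 / 36), 2 * 31 / 36 - 1)
  expect_equal(round(q_prime(31 / 36), 2), 0.72)
  expect_equal(q_prime(0.5), 0)
  expect_equal(q_prime(1), 1)
  expect_equal(q_prime(0.25), -0.5)
  expect_equal(q_prime(c(0, 1)), c(-1, 1))
  expect_error(q_prime(1.2), "0, 1")
  expect_error(q_prime(-0.1), "0, 1")
})

test_that("q_prime of a result equals q_prime(W/E) with no floating drift", {
  for (seed in 1:25) {
    net <- random_test_graph(8, 0.45, seed = seed, directed = TRUE)
    p <- partition(random_membership(net, 3, seed = seed + 500))
    rm_ <- realized_modularity(net, p)
    expect_identical(rm_$qprime, q_prime(rm_$w / rm_$e))
  }
})

test_that("Newman-Girvan Q matches hand-derivable cases", {
  tri2 <- network(rbind(c("a", "b"), c("b", "c"), c("a", "c"),
                        c("x", "y"), c("y", "z"), c("x", "z")),
                  directed = FALSE)
  # whole graph as one module: e_11 = 1, a_1 = 1, Q = 0
  one <- partition(setNames(rep(0, 6), tri2$nodes))
  s1 <- newman_girvan_q(tri2, one)
  expect_equal(s1$q, 0)
  expect_equal(s1$e_mm, 1)
  expect_equal(s1$a_m, 1)
  # the two triangles: e = (1/2, 1/2), a = (1/2, 1/2), Q = 1/2
  p2 <- partition(c(a = 0, b = 0, c = 0, x = 1, y = 1, z = 1))
  expect_equal(newman_girvan_q(tri2, p2)$q, 0.5)
  # singletons on a 4-cycle: Q = -sum (d/2E)^2 = -0.25
  cyc <- network(rbind(c("a", "b"), c("b", "c"), c("c", "d"), c("d", "a")),
                 directed = FALSE)
  expect_equal(newman_girvan_q(cyc, partition(c(a = 0, b = 1, c = 2, d = 3)))$q,
               -0.25)
})

test_that("per-module fractions satisfy sum a_m = 1 and sum e_mm <= 1", {
  for (seed in 1:20) {
    net <- random_test_graph(8, 0.4, seed = seed, directed = TRUE)
    sc <- newman_girvan_q(net, partition(random_membership(net, 4, seed + 90)))
    expect_equal(sum(sc$a_m), 1)
    expect_lte(sum(sc$e_mm), 1 + 1e-12)
    expect_lte(sc$q, 1)
  }
})

test_that("Newman-Girvan Q agrees with the adjacency-matrix oracle", {
  for (seed in 1:40) {
    directed <- seed %% 2 == 0
    net <- random_test_graph(4 + seed %% 5, 0.45, seed = seed,
                             directed = directed)
    mem <- random_membership(net, 3, seed = seed + 1000)
    got <- newman_girvan_q(net, partition(mem))$q
    # the oracle consumes raw labels, not canonical ones: same grouping
    expect_equal(got, q_matrix_oracle(net, mem), tolerance = 1e-12)
  }
})

test_that("Newman-Girvan Q agrees with igraph's implementation", {
  skip_if_not_installed("igraph")
  for (seed in 1:15) {
    net <- random_test_graph(8, 0.4, seed = seed, directed = FALSE)
    g <- igraph::graph_from_edgelist(net$edges, directed = FALSE)
    mem <- random_membership(net, 3, seed = seed + 77)
    ours <- newman_girvan_q(net, partition(mem))$q
    theirs <- igraph::modularity(g, mem[igraph::V(g)$name])
    expect_equal(ours, theirs, tolerance = 1e-12)
  }
})

test_that("score_partition pairs both measures consistently", {
  fx <- fixture_network(36, 31, sizes = c(9, 9, 9, 9), seed = 2)
  sc <- score_partition(fx$network, fx$partition)
  expect_identical(sc$realized$w, 31L)
  expect_equal(sc$q$q, newman_girvan_q(fx$network, fx$partition)$q)

  # all-singletons on a 4-cycle: Q_R = 0, Q'_R = -1
  cyc <- network(rbind(c("a", "b"), c("b", "c"), c("c", "d"), c("d", "a")),
                 directed = FALSE)
  sing <- partition(c(a = 0, b = 1, c = 2, d = 3))
  sc2 <- score_partition(cyc, sing)
  expect_equal(sc2$realized$qr, 0)
  expect_equal(sc2$realized$qprime, -1)
})

test_that("random balanced bisections center Q'_R near zero", {
  er <- erdos_renyi(100, 0.1, directed = FALSE, seed = 42)
  qp <- vapply(1:300, function(s)
    realized_modularity(er, random_partition(er, 2, seed = s))$qprime,
    numeric(1))
  expect_lt(abs(mean(qp)), 0.05)
})
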