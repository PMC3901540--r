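test_that("edge lists parse with set semantics, comments and extra columns", {
  f <- withr::local_tempfile(lines = c("a b", "b c", "c a"))
  net <- read_edgelist(f, directed = TRUE)
  expect_equal(n_nodes(net), 3L)
  expect_equal(n_edges(net), 3L)
  expect_true(net$directed)

  dup <- withr::local_tempfile(lines = c("a b", "a b"))
  expect_equal(n_edges(read_edgelist(dup)), 1L)

  extra <- withr::local_tempfile(lines = c("# comment", "a b x 1.0"))
  expect_warning(net3 <- read_edgelist(extra), "extra columns")
  expect_equal(n_edges(net3), 1L)
  expect_identical(unname(net3$edges[1, ]), c("a", "b"))

  # undirected: (a,b) and (b,a) are one edge
  rec <- withr::local_tempfile(lines = c("a b", "b a"))
  expect_equal(n_edges(read_edgelist(rec, directed = FALSE)), 1L)
  expect_equal(n_edges(read_edgelist(rec, directed = TRUE)), 2L)
})

test_that("malformed and empty edge lists fail with informative errors", {
  bad <- withr::local_tempfile(lines = c("a b", "lonely"))
  expect_error(read_edgelist(bad), "line 2")
  empty <- withr::local_tempfile(lines = c("# nothing", ""))
  expect_error(read_edgelist(empty), "no edges")
  expect_error(read_edgelist(file.path(tempdir(), "does-not-exist.txt")),
               "not found")
})

test_that("edge-list write/read round-trips canonicalized networks", {
  for (directed in c(TRUE, FALSE)) {
    net <- random_test_graph(7, 0.4, seed = 17, directed = directed)
    f <- withr::local_tempfile()
    write_edgelist(net, f)
    back <- read_edgelist(f, directed = directed)
    back$nodes <- net$nodes   # isolated nodes are not representable in a file
    expect_identical(back$edges, net$edges)
  }
})

test_that("partitions canonicalize labels by first appearance", {
  p <- partition(c(a = "x", b = "x", c = "y"))
  expect_identical(unname(p$membership), c(0L, 0L, 1L))
  expect_equal(p$k, 2L)
  # same grouping, different label alphabet -> same canonical labels
  p2 <- partition(c(a = 7, b = 7, c = -1))
  expect_identical(p$membership, p2$membership)
})

test_that("partition files are validated against the network", {
  net <- read_edgelist(withr::local_tempfile(lines = c("a b", "b c")))
  ok <- withr::local_tempfile(lines = c("a 0", "b 0", "c 1"))
  p <- read_partition(ok, net)
  expect_equal(p$k, 2L)

  miss <- withr::local_tempfile(lines = c("a 0", "b 0"))
  expect_error(read_partition(miss, net), "missing network node.*c")
  alien <- withr::local_tempfile(lines = c("a 0", "b 0", "c 1", "zz 1"))
  expect_error(read_partition(alien, net), "absent from the network.*zz")

  # round-trip through write_partition
  f <- withr::local_tempfile()
  write_partition(p, f)
  expect_identical(read_partition(f, net)$membership, p$membership)
})

test_that("bipartite incidence matrices become directed row->column networks", {
  id2 <- diag(2)
  dimnames(id2) <- list(c("h1", "h2"), c("p1", "p2"))
  net <- bipartite_to_unipartite(id2)
  expect_equal(n_nodes(net), 4L)
  expect_equal(n_edges(net), 2L)
  expect_true(net$directed && net$bipartite_origin)

  ones <- matrix(1, 2, 3, dimnames = list(c("h1", "h2"), c("p1", "p2", "p3")))
  net2 <- bipartite_to_unipartite(ones)
  expect_equal(n_edges(net2), 6L)
  prof <- degree_profile(net2)
  expect_equal(prof$g[prof$node %in% c("h1", "h2")], c(3L, 3L))
  expect_equal(prof$v[prof$node %in% c("h1", "h2")], c(0L, 0L))
  expect_equal(prof$g[grepl("^p", prof$node)], rep(0L, 3))

  bad <- ones; bad[1, 1] <- 0.5
  expect_error(bipartite_to_unipartite(bad), "binary")

  # colliding name spaces get prefixed
  clash <- diag(2)
  dimnames(clash) <- list(c("s1", "s2"), c("s1", "s2"))
  net3 <- bipartite_to_unipartite(clash)
  expect_setequal(net3$nodes, c("R:s1", "R:s2", "C:s1", "C:s2"))

  # dense-text reader round-trip
  f <- withr::local_tempfile()
  write.table(ones, f, quote = FALSE)
  expect_equal(unname(read_incidence(f)), unname(ones))
})

test_that("degree profiles follow the loop and reciprocal conventions", {
  chain <- network(rbind(c("a", "b"), c("b", "c")))
  prof <- degree_profile(chain)
  expect_equal(prof$g, c(1L, 1L, 0L))
  expect_equal(prof$v, c(0L, 1L, 1L))
  expect_equal(prof$d, c(1L, 2L, 1L))

  loop <- network(rbind(c("a", "a")))
  pl <- degree_profile(loop)
  expect_equal(pl[pl$node == "a", c("d", "g", "v")],
               data.frame(d = 2L, g = 1L, v = 1L), ignore_attr = TRUE)

  recip <- network(rbind(c("a", "b"), c("b", "a")))
  pr <- degree_profile(recip)
  expect_equal(pr$d, c(2L, 2L))
})

test_that("degree sums match edge counts on random directed graphs", {
  for (seed in 1:20) {
    net <- random_test_graph(8, 0.4, seed = seed, directed = TRUE)
    prof <- degree_profile(net)
    expect_equal(sum(prof$g), n_edges(net))
    expect_equal(sum(prof$v), n_edges(net))
    expect_equal(sum(prof$d), 2L * n_edges(net))
    expect_true(all(prof$g <= prof$d & prof$v <= prof$d & prof$d >= 0))
  }
})

test_that("symmetrize collapses reciprocal edges and keeps loops", {
  net <- network(rbind(c("a", "b"), c("b", "a"), c("c", "c")))
  und <- symmetrize(net)
  expect_false(und$directed)
  expect_equal(n_edges(und), 2L)
  expect_true(any(und$edges[, 1] == und$edges[, 2]))

  one <- symmetrize(network(rbind(c("a", "b"))))
  expect_equal(n_edges(one), 1L)

  empty <- symmetrize(network(NULL, nodes = c("a", "b")))
  expect_equal(n_edges(empty), 0L)
  expect_equal(n_nodes(empty), 2L)
})
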