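# Independent oracles used across the suite. These deliberately take a
# different computational route from the package: modularity is evaluated
# from the adjacency matrix, and the best partition is found by exhaustive
# enumeration of all set partitions (feasible for n <= 8).

# Symmetric adjacency matrix of a network's undirected projection; a
# self-loop contributes 2 to its diagonal cell so that row sums equal the
# loop-counts-twice degree.
adjacency_oracle <- function(net) {
  und <- if (net$directed) symmetrize(net) else net
  n <- n_nodes(und)
  a <- matrix(0, n, n, dimnames = list(und$nodes, und$nodes))
  for (r in seq_len(nrow(und$edges))) {
    i <- und$edges[r, 1]; j <- und$edges[r, 2]
    if (i == j) a[i, i] <- a[i, i] + 2
    else { a[i, j] <- a[i, j] + 1; a[j, i] <- a[j, i] + 1 }
  }
  a
}

# Newman-Girvan Q from the pairwise form
#   Q = (1/2m) * sum_ij (A_ij - k_i k_j / 2m) * [c_i == c_j]
# -- an independent route from the package's per-module e_mm/a_m counting.
q_matrix_oracle <- function(net, membership) {
  a <- adjacency_oracle(net)
  k <- rowSums(a)
  m2 <- sum(a)
  mem <- membership[rownames(a)]
  b <- (a - outer(k, k) / m2) / m2
  sum(b[outer(mem, mem, "==")])
}

# Modularity-aware pieces precomputed once per graph, for fast enumeration.
q_oracle_precompute <- function(net) {
  a <- adjacency_oracle(net)
  k <- rowSums(a)
  m2 <- sum(a)
  (a - outer(k, k) / m2) / m2
}

q_from_b <- function(b, mem) sum(b[outer(mem, mem, "==")])

# All set partitions of n elements as restricted-growth strings (list of
# integer membership vectors with labels 1..k). Memoized per n.
.partition_cache <- new.env(parent = emptyenv())
all_set_partitions <- function(n) {
  key <- as.character(n)
  if (!is.null(.partition_cache[[key]])) return(.partition_cache[[key]])
  out <- list()
  rec <- function(prefix, maxlab) {
    if (length(prefix) == n) {
      out[[length(out) + 1L]] <<- prefix
      return(invisible())
    }
    for (lab in seq_len(maxlab + 1L))
      rec(c(prefix, lab), max(maxlab, lab))
  }
  rec(integer(0), 0L)
  .partition_cache[[key]] <- out
  out
}

# Maximum Q over every possible partition of the graph's nodes.
max_q_exhaustive <- function(net) {
  b <- q_oracle_precompute(net)
  n <- nrow(b)
  max(vapply(all_set_partitions(n), function(mem) q_from_b(b, mem),
             numeric(1)))
}

# Small random test graph with at least one edge.
random_test_graph <- function(n, p, seed, directed = FALSE) {
  g <- erdos_renyi(n, p, directed = directed, seed = seed)
  i <- 0L
  while (n_edges(g) == 0L) {
    i <- i + 1L
    g <- erdos_renyi(n, p, directed = directed, seed = seed + 100000L * i)
  }
  g
}

# Random membership vector over a network's nodes (1..k labels, not
# necessarily all used), as a named vector suitable for partition().
random_membership <- function(net, k, seed) {
  mem <- with_seed_test(seed, sample.int(k, n_nodes(net), replace = TRUE))
  names(mem) <- net$nodes
  mem
}

with_seed_test <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  expr
}
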