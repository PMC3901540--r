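#' Planted-partition network generator
#'
#' Draws a network with known ground-truth modules: every within-module node
#' pair receives an edge independently with probability `p_in`, every
#' between-module pair with probability `p_out` (for directed networks, each
#' ordered pair is drawn separately; self-pairs are never drawn). Requires
#' `p_out <= p_in`: anti-modular specifications are refused.
#'
#' @param sizes vector of positive module sizes.
#' @param p_in within-module edge probability.
#' @param p_out between-module edge probability.
#' @param directed logical (default `TRUE`).
#' @param seed integer seed; generation is bit-reproducible.
#' @return list with `network` (a `realmod_network`) and `partition` (the
#'   ground-truth `realmod_partition`).
#' @examples
#' pp <- planted_partition(c(3, 3), p_in = 1, p_out = 0, directed = FALSE,
#'                         seed = 1)
#' pp$network   # two disjoint triangles
#' @export
planted_partition <- function(sizes, p_in, p_out, directed = TRUE,
                              seed = 1L) {
  sizes <- as.integer(sizes)
  if (length(sizes) < 1L || any(is.na(sizes)) || any(sizes < 1L))
    stop("'sizes' must be positive integers")
  if (!(p_out >= 0 && p_out <= p_in && p_in <= 1))
    stop("need 0 <= p_out <= p_in <= 1 (anti-modular specs refused)")
  n <- sum(sizes)
  nodes <- sprintf("n%0*d", nchar(n), seq_len(n))
  mem <- rep(seq_along(sizes) - 1L, sizes)
  names(mem) <- nodes
  pairs <- all_pairs(n, directed)
  same <- mem[pairs[, 1]] == mem[pairs[, 2]]
  p <- ifelse(same, p_in, p_out)
  keep <- with_seed(seed, stats::runif(nrow(pairs)) < p)
  edges <- cbind(nodes[pairs[keep, 1]], nodes[pairs[keep, 2]])
  list(network = network(edges, nodes = nodes, directed = directed),
       partition = partition(mem))
}

# all ordered (directed) or unordered (undirected) node-index pairs, no
# self-pairs
all_pairs <- function(n, directed) {
  idx <- seq_len(n)
  if (directed) {
    g <- expand.grid(from = idx, to = idx)
    as.matrix(g[g$from != g$to, ])
  } else {
    t(utils::combn(idx, 2))
  }
}

#' Erdos-Renyi random network
#'
#' Baseline generator: every node pair receives an edge independently with
#' probability `p`. Equivalent to [planted_partition()] with
#' `p_in = p_out = p`.
#'
#' @param n node count.
#' @param p edge probability.
#' @param directed logical (default `FALSE`).
#' @param seed integer seed.
#' @return a `realmod_network`.
#' @export
erdos_renyi <- function(n, p, directed = FALSE, seed = 1L) {
  planted_partition(n, p_in = p, p_out = p,
                    directed = directed, seed = seed)$network
}

#' Fixture network with exact within/between edge counts
#'
#' Builds an undirected network with exactly `n_edges` edges of which exactly
#' `n_within` join two nodes of the same module, the placements drawn
#' uniformly at random among the feasible ones. Useful as a worked-example
#' fixture: [realized_modularity()] on the result returns `(W, E)` exactly,
#' e.g. the textbook E = 36, W = 31 network with Q_R = 31/36 ~ 0.86 and
#' Q'_R ~ 0.72.
#'
#' @param n_edges total edge count E.
#' @param n_within number of within-module edges W (`<= n_edges`).
#' @param sizes vector of module sizes; capacities must accommodate the
#'   requested counts.
#' @param seed integer seed.
#' @return list with `network` (undirected `realmod_network`) and `partition`
#'   (the module assignment used).
#' @export
fixture_network <- function(n_edges, n_within, sizes, seed = 1L) {
  sizes <- as.integer(sizes)
  stopifnot(n_edges >= 1, n_within >= 0, all(sizes >= 1))
  if (n_within > n_edges) stop("n_within must not exceed n_edges")
  n <- sum(sizes)
  nodes <- sprintf("n%0*d", nchar(n), seq_len(n))
  mem <- rep(seq_along(sizes) - 1L, sizes)
  names(mem) <- nodes
  pairs <- all_pairs(n, directed = FALSE)
  same <- mem[pairs[, 1]] == mem[pairs[, 2]]
  cap_w <- sum(same)
  cap_b <- sum(!same)
  if (n_within > cap_w)
    stop("infeasible: ", n_within, " within-module edges requested but only ",
         cap_w, " within-module pairs exist")
  if (n_edges - n_within > cap_b)
    stop("infeasible: ", n_edges - n_within, " between-module edges requested ",
         "but only ", cap_b, " between-module pairs exist")
  pick <- with_seed(seed, {
    w_idx <- sample(which(same), n_within)
    b_idx <- sample(which(!same), n_edges - n_within)
    c(w_idx, b_idx)
  })
  edges <- cbind(nodes[pairs[pick, 1]], nodes[pairs[pick, 2]])
  list(network = network(edges, nodes = nodes, directed = FALSE),
       partition = partition(mem))
}

#' Random balanced partition of a network's nodes
#'
#' Assigns the nodes uniformly at random to `k` modules of (near-)equal
#' size. Used to study the behaviour of the modularity measures under
#' arbitrary module assignments: Q'_R of balanced random bisections is
#' centered on 0.
#'
#' @param network a `realmod_network`.
#' @param k number of modules (default 2: a bisection).
#' @param seed integer seed.
#' @return a `realmod_partition`.
#' @export
random_partition <- function(network, k = 2L, seed = 1L) {
  stopifnot(inherits(network, "realmod_network"), k >= 1L,
            k <= n_nodes(network))
  n <- n_nodes(network)
  labels <- rep(seq_len(k) - 1L, length.out = n)
  mem <- with_seed(seed, sample(labels))
  names(mem) <- network$nodes
  partition(mem)
}

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement between two module assignments over the same
#' node set: 1 for identical groupings, ~0 for independent ones. Computed
#' from the pair-counting contingency table:
#' \deqn{ARI = \frac{\sum_{ij}\binom{n_{ij}}{2} - t}{\tfrac12(\sum_i\binom{a_i}{2} + \sum_j\binom{b_j}{2}) - t},
#'  \quad t = \frac{\sum_i\binom{a_i}{2}\sum_j\binom{b_j}{2}}{\binom{n}{2}}.}
#'
#' @param p1,p2 `realmod_partition`s (or named module-label vectors) over the
#'   same nodes.
#' @return ARI value (1 = identical partitions).
#' @export
adjusted_rand_index <- function(p1, p2) {
  m1 <- if (inherits(p1, "realmod_partition")) p1$membership else p1
  m2 <- if (inherits(p2, "realmod_partition")) p2$membership else p2
  if (!setequal(names(m1), names(m2)))
    stop("partitions cover different node sets")
  m2 <- m2[names(m1)]
  tab <- table(m1, m2)
  choose2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(choose2(tab))
  a <- sum(choose2(rowSums(tab)))
  b <- sum(choose2(colSums(tab)))
  n2 <- choose2(length(m1))
  expected <- a * b / n2
  max_idx <- (a + b) / 2
  if (max_idx == expected) return(1)   # both partitions trivial
  (sum_ij - expected) / (max_idx - expected)
}
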