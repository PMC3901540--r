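#' Link-probability matrix of the degree-profile null model
#'
#' For each ordered pair of nodes (i, j) the probability that i interacts
#' with j is
#' \deqn{P(i \to j) = \frac{1}{2}\left(\frac{g_i}{d_i} + \frac{v_j}{d_j}\right),}
#' where g is the node's generality (successor count), v its vulnerability
#' (predecessor count) and d = g + v its degree (see [degree_profile()]).
#' Terms with d = 0 contribute 0, so isolated nodes stay isolated in every
#' replicate. Self-pairs (i, i) get probability 0 unless the empirical
#' network itself contains a self-loop (cannibalistic food webs), in which
#' case they are treated like any other pair.
#'
#' Note that, as defined, the model conserves the expected degree, generality
#' and vulnerability *profiles* rather than the exact expected connectance:
#' a node that only has successors paired with a node that only has
#' predecessors is forced to P = 1 regardless of network size. The
#' alternative `normalization = "size"` replaces the degree denominators with
#' the node count n, P = (g_i/n + v_j/n)/2, trading the per-node profile for
#' a connectance-like scaling.
#'
#' @param network a directed `realmod_network`.
#' @param normalization `"degree"` (the model above, default) or `"size"`.
#' @return square numeric matrix, dimnames = node identifiers; `P[i, j]` is
#'   the probability of the edge i -> j, clipped to `[0, 1]`.
#' @export
link_probabilities <- function(network, normalization = c("degree", "size")) {
  stopifnot(inherits(network, "realmod_network"))
  if (!network$directed)
    stop("the null model is defined for directed networks; see ",
         "bipartite_to_unipartite() for incidence matrices")
  normalization <- match.arg(normalization)
  prof <- degree_profile(network)
  n <- nrow(prof)
  if (normalization == "degree") {
    out_frac <- ifelse(prof$d > 0, prof$g / prof$d, 0)
    in_frac <- ifelse(prof$d > 0, prof$v / prof$d, 0)
  } else {
    out_frac <- prof$g / n
    in_frac <- prof$v / n
  }
  p <- 0.5 * outer(out_frac, rep(1, n)) + 0.5 * outer(rep(1, n), in_frac)
  p[prof$d == 0, ] <- 0
  p[, prof$d == 0] <- 0
  p <- pmin(pmax(p, 0), 1)
  if (!has_self_loops(network)) diag(p) <- 0
  dimnames(p) <- list(prof$node, prof$node)
  p
}

#' Draw one pseudo-random replicate network
#'
#' A Bernoulli process over the [link_probabilities()] matrix: each ordered
#' pair receives an edge independently with its probability P(i -> j). The
#' node set is preserved (replicates can contain isolated nodes, and an
#' edgeless draw is legal; callers decide what to do with it).
#'
#' @inheritParams link_probabilities
#' @param seed integer seed; a given (network, seed) always yields the same
#'   replicate.
#' @param p optional precomputed probability matrix (to avoid recomputing it
#'   across many replicates).
#' @return a directed `realmod_network` on the same node set.
#' @export
sample_null <- function(network, seed = 1L,
                        normalization = c("degree", "size"), p = NULL) {
  if (is.null(p)) p <- link_probabilities(network, normalization)
  nodes <- rownames(p)
  hit <- with_seed(seed, which(matrix(stats::runif(length(p)), nrow(p)) < p,
                               arr.ind = TRUE))
  network(cbind(nodes[hit[, 1]], nodes[hit[, 2]]), nodes = nodes,
          directed = TRUE, bipartite_origin = network$bipartite_origin)
}

#' Generate and score a null ensemble
#'
#' Draws `replicates` pseudo-random networks from the degree-profile null
#' model, runs the community detector on each (Louvain by default, on the
#' symmetrized replicate), and records the Newman-Girvan Q of the detected
#' partition together with the realized modularity Q'_R of the replicate's
#' native directed edge set under that partition. Replicates with fewer than
#' 2 edges are discarded and counted rather than resampled (resampling would
#' bias the ensemble). Per-replicate seeds are derived deterministically from
#' `seed`, so the whole ensemble is reproducible.
#'
#' @inheritParams link_probabilities
#' @param replicates number of replicates to draw (default 1000).
#' @param seed master seed.
#' @param detector a function `(network, seed) -> realmod_detection`;
#'   defaults to [louvain()].
#' @return An object of class `realmod_ensemble`: list with numeric vectors
#'   `q` and `qprime` (one entry per retained replicate), `replicates`,
#'   `retained`, `discarded`, `seed`.
#' @export
null_ensemble <- function(network, replicates = 1000L, seed = 1L,
                          detector = louvain,
                          normalization = c("degree", "size")) {
  stopifnot(inherits(network, "realmod_network"))
  replicates <- as.integer(replicates)
  if (is.na(replicates) || replicates < 1L)
    stop("at least 1 replicate is required")
  p <- link_probabilities(network, normalization)
  rep_seeds <- with_seed(seed,
                         sample.int(.Machine$integer.max, replicates))
  q <- qp <- numeric(0)
  discarded <- 0L
  for (r in seq_len(replicates)) {
    g <- sample_null(network, seed = rep_seeds[r], p = p)
    if (n_edges(g) < 2L) {
      discarded <- discarded + 1L
      next
    }
    det <- detector(g, seed = rep_seeds[r])
    q <- c(q, newman_girvan_q(g, det$partition)$q)
    qp <- c(qp, realized_modularity(g, det$partition)$qprime)
  }
  if (length(q) == 0L)
    stop("all ", replicates, " null replicates were discarded (fewer than ",
         "2 edges each); the network is too sparse for this null model")
  structure(list(q = q, qprime = qp, replicates = replicates,
                 retained = length(q), discarded = discarded, seed = seed),
            class = "realmod_ensemble")
}

#' @export
print.realmod_ensemble <- function(x, ...) {
  cat(sprintf("Null ensemble: %d/%d replicates retained (%d discarded)\n",
              x$retained, x$replicates, x$discarded))
  cat(sprintf("  Q:    mean %.3g (sd %.3g)\n", mean(x$q), stats::sd(x$q)))
  cat(sprintf("  Q'_R: mean %.3g (sd %.3g)\n", mean(x$qprime),
              stats::sd(x$qprime)))
  invisible(x)
}
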