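#' Realized modularity of a partitioned network
#'
#' The a-posteriori measure at the core of this package. Of the `E`
#' interactions in the network, `W` are established between members of the
#' same module; the realized modularity is the ratio
#' \deqn{Q_R = W / E,}
#' which takes its maximal value 1 when no between-module links exist and
#' the value 1/2 when between-module interactions are as numerous as
#' within-module ones. Because it only counts edges against an existing
#' node -> module assignment, it is agnostic to the method (or criterion)
#' that produced the partition and can rank competing partitions from any
#' community detection algorithm.
#'
#' Self-loops are within-module edges by definition. The measure is computed
#' on the network's native edge set: directed networks are not symmetrized
#' first (reciprocal links count as two interactions).
#'
#' @param network a `realmod_network` with at least one edge.
#' @param partition a `realmod_partition` covering the network's nodes.
#' @return An object of class `realmod_qr`: list with `e` (edge count),
#'   `w` (within-module edge count), `qr` (= W/E) and `qprime`
#'   (= 2 Q_R - 1, see [q_prime()]).
#' @examples
#' net <- network(rbind(c("a", "b"), c("b", "c"), c("c", "a")))
#' p <- partition(c(a = 0, b = 0, c = 1))
#' realized_modularity(net, p)
#' @export
realized_modularity <- function(network, partition) {
  check_partition(network, partition)
  e <- n_edges(network)
  if (e == 0L) stop("realized modularity undefined for edgeless network")
  mem <- partition$membership
  w <- sum(mem[network$edges[, 1]] == mem[network$edges[, 2]])
  structure(list(e = e, w = as.integer(w), qr = w / e,
                 qprime = q_prime(w / e)),
            class = "realmod_qr")
}

#' @export
print.realmod_qr <- function(x, ...) {
  cat(sprintf("Realized modularity: W = %d of E = %d within modules\n",
              x$w, x$e))
  cat(sprintf("  Q_R = %.2f   Q'_R = %.2f\n", x$qr, x$qprime))
  invisible(x)
}

#' Rescale realized modularity to [-1, 1]
#'
#' \deqn{Q'_R = 2 Q_R - 1.}
#' Under random balanced module assignments Q'_R is centered on 0;
#' positive values mean more interactions within than between modules,
#' negative values the reverse.
#'
#' @param qr realized modularity value(s) in `[0, 1]`.
#' @return `2 * qr - 1`, vectorized.
#' @export
q_prime <- function(qr) {
  if (any(qr < -1e-12 | qr > 1 + 1e-12, na.rm = TRUE) || anyNA(qr))
    stop("'qr' must lie in [0, 1]")
  2 * pmin(pmax(qr, 0), 1) - 1
}

#' Newman-Girvan modularity of a partition
#'
#' The classic optimization criterion
#' \deqn{Q = \sum_m (e_{mm} - a_m^2),}
#' where \eqn{e_{mm}} is the fraction of edges with both endpoints in module
#' m and \eqn{a_m} the fraction of edge endpoints attached to module m. It is
#' evaluated on the undirected projection of the network (see
#' [symmetrize()]); a self-loop contributes one within-module edge and both
#' of its endpoints to its module.
#'
#' @param network a `realmod_network` with at least one edge; symmetrized
#'   internally if directed.
#' @param partition a `realmod_partition` covering the network's nodes.
#' @return An object of class `realmod_q`: list with `q`, module count `k`,
#'   and per-module vectors `e_mm`, `a_m`.
#' @export
newman_girvan_q <- function(network, partition) {
  check_partition(network, partition)
  if (network$directed) network <- symmetrize(network)
  m <- n_edges(network)
  if (m == 0L) stop("modularity undefined for edgeless network")
  mem <- partition$membership
  k <- partition$k
  cf <- mem[network$edges[, 1]]
  ct <- mem[network$edges[, 2]]
  within <- tabulate(ifelse(cf == ct, cf + 1L, NA_integer_), nbins = k)
  ends <- tabulate(c(cf, ct) + 1L, nbins = k)
  e_mm <- within / m
  a_m <- ends / (2 * m)
  structure(list(q = sum(e_mm - a_m^2), k = k, e_mm = e_mm, a_m = a_m),
            class = "realmod_q")
}

#' @export
print.realmod_q <- function(x, ...) {
  cat(sprintf("Newman-Girvan modularity: Q = %.3g over %d modules\n",
              x$q, x$k))
  invisible(x)
}

#' Score a partition with both modularity measures
#'
#' Convenience wrapper pairing [newman_girvan_q()] (the optimization
#' criterion) with [realized_modularity()] (the a-posteriori measure), so
#' that partitions produced by different methods can be ranked on either.
#'
#' @inheritParams realized_modularity
#' @return list with elements `q` (a `realmod_q`) and `realized`
#'   (a `realmod_qr`).
#' @export
score_partition <- function(network, partition) {
  list(q = newman_girvan_q(network, partition),
       realized = realized_modularity(network, partition))
}
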