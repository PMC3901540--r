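# Internal helper: evaluate expr with a temporarily seeded RNG, restoring the
# caller's RNG state afterwards so seeded package functions do not perturb a
# user's random stream.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Louvain community detection
#'
#' Reference implementation of the two-phase greedy modularity optimization.
#' Phase 1 sweeps the nodes in seeded-random order and moves each node to the
#' neighboring community offering the largest strictly positive modularity
#' gain (ties broken toward the lowest community label, for determinism).
#' Phase 2 collapses each community into a super-node, accumulating
#' within-community weight as self-loops, and the two phases repeat until a
#' full pass improves Q by less than `tol`.
#'
#' The input is symmetrized first if directed: the method optimizes the
#' undirected Newman-Girvan Q. Runs are deterministic given `(network,
#' seed)`; because the method is sweep-order sensitive, different seeds can
#' return different (locally optimal) partitions. `restarts > 1` runs
#' independent seeded restarts and keeps the partition with the highest Q.
#'
#' @param network a `realmod_network` with at least one edge.
#' @param seed integer seed for the sweep order.
#' @param tol minimum Q improvement for another aggregation pass.
#' @param restarts number of independent restarts (best-of-k by Q).
#' @return An object of class `realmod_detection`: list with `partition`
#'   (a `realmod_partition` on the original nodes), `q_trace` (Q after each
#'   aggregation pass, evaluated on the original graph; non-decreasing),
#'   `passes`, `q` (final modularity, the last trace entry) and `seed`.
#' @examples
#' tri2 <- network(rbind(c("a","b"), c("b","c"), c("a","c"),
#'                       c("x","y"), c("y","z"), c("x","z")),
#'                 directed = FALSE)
#' louvain(tri2, seed = 1)
#' @export
louvain <- function(network, seed = 1L, tol = 1e-8, restarts = 1L) {
  stopifnot(inherits(network, "realmod_network"))
  if (n_edges(network) == 0L)
    stop("cannot detect communities in an edgeless network")
  if (restarts > 1L) {
    runs <- lapply(seq_len(restarts) - 1L,
                   function(i) louvain(network, seed = seed + i, tol = tol))
    best <- which.max(vapply(runs, `[[`, numeric(1), "q"))
    out <- runs[[best]]
    out$seed <- seed
    return(out)
  }
  und <- if (network$directed) symmetrize(network) else network
  nodes <- und$nodes
  n <- length(nodes)
  oei <- match(und$edges[, 1], nodes)
  oej <- match(und$edges[, 2], nodes)
  ow <- rep(1, length(oei))
  ei <- oei; ej <- oej; ew <- ow
  nlev <- n

  membership <- seq_len(n)   # original node -> community id in current level
  q_trace <- numeric(0)
  with_seed(seed, {
    repeat {
      lev <- louvain_one_level(ei, ej, ew, nlev)
      if (!lev$moved && length(q_trace) > 0L) break
      membership <- lev$comm[membership]
      q_now <- modularity_from_counts(oei, oej, ow, membership)
      q_prev <- if (length(q_trace)) q_trace[length(q_trace)] else -Inf
      q_trace <- c(q_trace, q_now)
      if (!lev$moved || q_now - q_prev <= tol) break
      agg <- aggregate_graph(ei, ej, ew, lev$comm)
      ei <- agg$ei; ej <- agg$ej; ew <- agg$ew
      nlev <- max(lev$comm)
    }
  })
  mem <- membership
  names(mem) <- nodes
  part <- partition(mem)
  structure(list(partition = part,
                 q_trace = q_trace,
                 passes = length(q_trace),
                 q = q_trace[length(q_trace)],
                 seed = seed),
            class = "realmod_detection")
}

#' @export
print.realmod_detection <- function(x, ...) {
  cat(sprintf("Louvain detection: %d modules, Q = %.3g (%d pass%s, seed %d)\n",
              x$partition$k, x$q, x$passes, if (x$passes > 1) "es" else "",
              x$seed))
  invisible(x)
}

# Q of an integer membership vector (values 1..k) on the weighted undirected
# graph given by parallel vectors (ei, ej, ew); loops appear once. Same
# convention as newman_girvan_q(): e_mm = within-weight / m,
# a_m = endpoint-weight / 2m (a loop contributes both endpoints).
modularity_from_counts <- function(ei, ej, ew, mem) {
  m <- sum(ew)
  k <- max(mem)
  ci <- mem[ei]; cj <- mem[ej]
  within <- numeric(k)
  sel <- ci == cj
  if (any(sel)) {
    t1 <- rowsum(ew[sel], ci[sel])
    within[as.integer(rownames(t1))] <- t1
  }
  ends <- numeric(k)
  t2 <- rowsum(c(ew, ew), c(ci, cj))
  ends[as.integer(rownames(t2))] <- t2
  sum(within / m - (ends / (2 * m))^2)
}

# One Louvain level: local moves until no node improves Q. Weighted
# undirected graph as parallel edge vectors over nodes 1..n; loops allowed
# (ei == ej). Returns canonical communities (1..K, relabeled by lowest member
# node) and whether any node moved.
louvain_one_level <- function(ei, ej, ew, n) {
  loop <- ei == ej
  self_w <- numeric(n)
  if (any(loop)) {
    sw <- rowsum(ew[loop], ei[loop])
    self_w[as.integer(rownames(sw))] <- sw
  }
  # symmetric adjacency in CSR-like layout, loops excluded
  ii <- c(ei[!loop], ej[!loop])
  jj <- c(ej[!loop], ei[!loop])
  ww <- c(ew[!loop], ew[!loop])
  ord <- order(ii)
  ii <- ii[ord]; jj <- jj[ord]; ww <- ww[ord]
  cnt <- tabulate(ii, nbins = n)
  ends_at <- cumsum(cnt)
  starts_at <- ends_at - cnt + 1L
  # node degree: a loop counts twice
  deg <- numeric(n)
  if (length(ii) > 0L) {
    ds <- rowsum(ww, ii)
    deg[as.integer(rownames(ds))] <- ds
  }
  deg <- deg + 2 * self_w
  m2 <- 2 * sum(ew)

  comm <- seq_len(n)
  tot <- deg                      # endpoint weight attached to each community
  moved_any <- FALSE
  repeat {
    moved_pass <- FALSE
    for (i in sample.int(n)) {
      c0 <- comm[i]
      if (cnt[i] > 0L) {
        sel <- starts_at[i]:ends_at[i]
        kc <- rowsum(ww[sel], comm[jj[sel]])
        cand <- as.integer(rownames(kc))
        kin <- as.numeric(kc)
      } else {
        cand <- integer(0); kin <- numeric(0)
      }
      if (!(c0 %in% cand)) { cand <- c(cand, c0); kin <- c(kin, 0) }
      tot[c0] <- tot[c0] - deg[i]
      gain <- kin - tot[cand] * deg[i] / m2
      stay <- gain[match(c0, cand)]
      best <- max(gain)
      pick <- min(cand[gain >= best - 1e-14])
      if (pick != c0 && best - stay > 1e-12) {
        comm[i] <- pick
        tot[pick] <- tot[pick] + deg[i]
        moved_pass <- TRUE
        moved_any <- TRUE
      } else {
        tot[c0] <- tot[c0] + deg[i]
      }
    }
    if (!moved_pass) break
  }
  list(comm = match(comm, unique(comm)), moved = moved_any)
}

# Collapse communities into super-nodes; within-community weight becomes
# self-loop weight.
aggregate_graph <- function(ei, ej, ew, comm) {
  ci <- comm[ei]; cj <- comm[ej]
  lo <- pmin(ci, cj); hi <- pmax(ci, cj)
  agg <- rowsum(ew, lo * (max(comm) + 1L) + hi)
  key <- as.numeric(rownames(agg))
  base <- max(comm) + 1L
  list(ei = as.integer(key %/% base),
       ej = as.integer(key %% base),
       ew = as.numeric(agg))
}
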