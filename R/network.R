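#' Construct an interaction network
#'
#' Central container for all analyses in this package. A network is a set of
#' node identifiers (opaque strings) and a set of edges between them. Directed
#' networks (food webs: edges point from consumer to resource, or however the
#' source data are oriented) keep `(a, b)` and `(b, a)` as two distinct edges;
#' undirected networks treat them as one. Duplicate edges are collapsed:
#' the edge set has set semantics.
#'
#' @param edges two-column character matrix (or coercible) of (source, target)
#'   pairs; zero rows allowed.
#' @param nodes optional character vector of node identifiers; endpoints of
#'   `edges` are added automatically, so this only matters for isolated nodes.
#' @param directed logical; are edges ordered pairs?
#' @param bipartite_origin logical; was the network derived from a bipartite
#'   incidence matrix (see [bipartite_to_unipartite()])?
#' @return An object of class `realmod_network` with elements `nodes`
#'   (sorted), `edges` (canonicalized two-column character matrix),
#'   `directed`, `bipartite_origin`.
#' @examples
#' net <- network(rbind(c("a", "b"), c("b", "c")), directed = TRUE)
#' n_edges(net)
#' @export
network <- function(edges, nodes = NULL, directed = TRUE,
                    bipartite_origin = FALSE) {
  if (is.null(edges) || length(edges) == 0L) {
    edges <- matrix(character(0), ncol = 2)
  }
  edges <- as.matrix(edges)
  if (ncol(edges) != 2L) stop("'edges' must have exactly two columns")
  storage.mode(edges) <- "character"
  if (nrow(edges) > 0L && anyNA(edges)) stop("edge endpoints must not be NA")
  if (!directed && nrow(edges) > 0L) {
    swap <- edges[, 1] > edges[, 2]
    edges[swap, ] <- edges[swap, 2:1, drop = FALSE]
  }
  if (nrow(edges) > 0L) {
    edges <- edges[!duplicated(paste(edges[, 1], edges[, 2], sep = "\r")), ,
                   drop = FALSE]
    edges <- edges[order(edges[, 1], edges[, 2]), , drop = FALSE]
  }
  nodes <- sort(unique(c(nodes, as.vector(edges))))
  dimnames(edges) <- list(NULL, c("from", "to"))
  structure(
    list(nodes = nodes, edges = edges, directed = isTRUE(directed),
         bipartite_origin = isTRUE(bipartite_origin)),
    class = "realmod_network"
  )
}

#' @export
print.realmod_network <- function(x, ...) {
  cat(sprintf("Interaction network: %d nodes, %d edges (%s%s)\n",
              n_nodes(x), n_edges(x),
              if (x$directed) "directed" else "undirected",
              if (x$bipartite_origin) ", bipartite origin" else ""))
  invisible(x)
}

#' Network accessors
#'
#' @param network a `realmod_network`.
#' @return `n_nodes()` and `n_edges()` return single integers;
#'   `connectance()` the realized fraction of possible links (self-pairs are
#'   counted as possible only when the network contains a self-loop).
#' @name network-accessors
NULL

#' @rdname network-accessors
#' @export
n_nodes <- function(network) length(network$nodes)

#' @rdname network-accessors
#' @export
n_edges <- function(network) nrow(network$edges)

#' @rdname network-accessors
#' @export
connectance <- function(network) {
  stopifnot(inherits(network, "realmod_network"))
  n <- n_nodes(network)
  if (n == 0L) return(NA_real_)
  loops <- any(network$edges[, 1] == network$edges[, 2])
  possible <- if (network$directed) n * (n - 1) else n * (n - 1) / 2
  if (loops) possible <- possible + n
  n_edges(network) / possible
}

has_self_loops <- function(network) {
  nrow(network$edges) > 0L && any(network$edges[, 1] == network$edges[, 2])
}

#' Read a network from a plain-text edge list
#'
#' One interaction per line, two whitespace-separated node identifiers
#' (source, then target). Lines starting with `#` and blank lines are
#' skipped. A third column (e.g. an interaction weight), if present, is
#' ignored with a warning: this package analyzes binary interaction
#' matrices. Duplicate edges are collapsed.
#'
#' @param path path to the edge-list file.
#' @param directed logical; read edges as ordered pairs (default `TRUE`).
#' @return A [network()].
#' @export
read_edgelist <- function(path, directed = TRUE) {
  if (!file.exists(path)) stop("edge-list file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*(#|$)", lines)
  idx <- which(keep)
  if (length(idx) == 0L) stop("no edges in '", path, "'")
  toks <- strsplit(trimws(lines[idx]), "\\s+")
  nt <- lengths(toks)
  if (any(nt < 2L)) {
    bad <- idx[which(nt < 2L)[1]]
    stop("malformed edge-list line ", bad, " in '", path,
         "': need at least two whitespace-separated tokens")
  }
  if (any(nt > 2L)) {
    warning("extra columns in '", path, "' ignored (edges read as binary)")
  }
  edges <- t(vapply(toks, function(x) x[1:2], character(2)))
  network(edges, directed = directed)
}

#' Write a network as an edge list
#'
#' Inverse of [read_edgelist()]: edges are written in canonical (sorted)
#' order, one per line.
#'
#' @param network a `realmod_network`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_edgelist <- function(network, path) {
  stopifnot(inherits(network, "realmod_network"))
  writeLines(paste(network$edges[, 1], network$edges[, 2]), path)
  invisible(path)
}

#' Construct a community partition
#'
#' A partition is a total mapping node -> module label. Labels are
#' canonicalized to contiguous integers `0..k-1`, renumbered by first
#' appearance in the supplied assignment, so that partitions read from
#' different tools with different label alphabets compare equal when the
#' grouping is the same.
#'
#' @param membership named vector (names = node identifiers, values = module
#'   labels, any atomic type).
#' @return An object of class `realmod_partition` with elements `membership`
#'   (named integer vector, canonical labels) and `k` (module count).
#' @export
partition <- function(membership) {
  if (is.null(names(membership)) || anyNA(names(membership)))
    stop("'membership' must be a named vector (names = node identifiers)")
  if (anyNA(membership)) stop("module labels must not be NA")
  if (anyDuplicated(names(membership)))
    stop("duplicate node in partition: ",
         names(membership)[anyDuplicated(names(membership))])
  lab <- as.character(membership)
  canon <- match(lab, unique(lab)) - 1L
  names(canon) <- names(membership)
  structure(list(membership = canon, k = length(unique(canon))),
            class = "realmod_partition")
}

#' @export
print.realmod_partition <- function(x, ...) {
  cat(sprintf("Community partition: %d nodes in %d modules\n",
              length(x$membership), x$k))
  invisible(x)
}

check_partition <- function(network, partition) {
  stopifnot(inherits(network, "realmod_network"),
            inherits(partition, "realmod_partition"))
  missing <- setdiff(network$nodes, names(partition$membership))
  if (length(missing) > 0L)
    stop("partition does not cover network node(s): ",
         paste(missing, collapse = ", "))
  invisible(TRUE)
}

#' Read a node -> module partition file
#'
#' Each non-comment line holds a node identifier and a module label,
#' whitespace-separated. The file must cover exactly the network's nodes:
#' this is the entry point for partitions produced by any external community
#' detection method (walktrap, spinglass, edge betweenness, ...), which can
#' then be scored a posteriori with [realized_modularity()].
#'
#' @param path path to the partition file.
#' @param network the `realmod_network` the partition refers to.
#' @return A [partition()] with canonical labels.
#' @export
read_partition <- function(path, network) {
  stopifnot(inherits(network, "realmod_network"))
  if (!file.exists(path)) stop("partition file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*(#|$)", lines)
  idx <- which(keep)
  if (length(idx) == 0L) stop("no assignments in '", path, "'")
  toks <- strsplit(trimws(lines[idx]), "\\s+")
  nt <- lengths(toks)
  if (any(nt < 2L)) {
    bad <- idx[which(nt < 2L)[1]]
    stop("malformed partition line ", bad, " in '", path, "'")
  }
  nodes <- vapply(toks, `[`, character(1), 1L)
  labels <- vapply(toks, `[`, character(1), 2L)
  unknown <- setdiff(nodes, network$nodes)
  if (length(unknown) > 0L)
    stop("partition file names node(s) absent from the network: ",
         paste(unknown, collapse = ", "))
  missing <- setdiff(network$nodes, nodes)
  if (length(missing) > 0L)
    stop("partition file is missing network node(s): ",
         paste(missing, collapse = ", "))
  names(labels) <- nodes
  partition(labels)
}

#' Write a partition file
#'
#' @param partition a `realmod_partition`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_partition <- function(partition, path) {
  stopifnot(inherits(partition, "realmod_partition"))
  writeLines(paste(names(partition$membership), partition$membership,
                   sep = "\t"), path)
  invisible(path)
}

#' Convert a bipartite incidence matrix to a directed unipartite network
#'
#' Bipartite networks (e.g. host-parasite) are transformed into unipartite
#' networks before analysis: every nonzero cell of the 0/1 incidence matrix
#' becomes one directed edge from its row node to its column node, so each
#' interaction is preserved as exactly one edge. If row and column names
#' collide they are namespaced with `R:`/`C:` prefixes.
#'
#' @param incidence numeric matrix of 0s and 1s with row and column names.
#' @return A directed [network()] with `bipartite_origin = TRUE`. Row nodes
#'   have vulnerability 0 and column nodes generality 0 by construction.
#' @export
bipartite_to_unipartite <- function(incidence) {
  incidence <- as.matrix(incidence)
  if (is.null(rownames(incidence)) || is.null(colnames(incidence)))
    stop("incidence matrix must have row and column names")
  if (!all(incidence %in% c(0, 1)))
    stop("incidence matrix must be binary (0/1); quantitative matrices are ",
         "not supported")
  rn <- rownames(incidence)
  cn <- colnames(incidence)
  if (length(intersect(rn, cn)) > 0L) {
    rn <- paste0("R:", rn)
    cn <- paste0("C:", cn)
  }
  hit <- which(incidence == 1, arr.ind = TRUE)
  edges <- cbind(rn[hit[, 1]], cn[hit[, 2]])
  network(edges, nodes = c(rn, cn), directed = TRUE, bipartite_origin = TRUE)
}

#' Read a dense incidence matrix from text
#'
#' First row = column names, first column = row names, cells 0/1,
#' whitespace-separated.
#'
#' @param path path to the matrix file.
#' @return numeric incidence matrix with dimnames.
#' @export
read_incidence <- function(path) {
  tab <- utils::read.table(path, header = TRUE, row.names = 1,
                           check.names = FALSE)
  as.matrix(tab)
}

#' Per-node degree profile
#'
#' For each node of a directed network: its generality `g` (number of
#' successors, i.e. distinct nodes it links to -- in food-web terms, the
#' number of prey), its vulnerability `v` (number of predecessors -- its
#' predators), and its degree `d = g + v`. Reciprocal links count as two
#' distinct edges, and a self-loop (cannibalism) contributes 1 to both `g`
#' and `v`, hence 2 to `d`. For undirected networks the convention
#' `g = v = d =` number of incident edges is used.
#'
#' @param network a `realmod_network`.
#' @return data.frame with columns `node`, `d`, `g`, `v`, one row per node,
#'   sorted by node identifier.
#' @export
degree_profile <- function(network) {
  stopifnot(inherits(network, "realmod_network"))
  nodes <- network$nodes
  fi <- factor(network$edges[, 1], levels = nodes)
  ti <- factor(network$edges[, 2], levels = nodes)
  if (network$directed) {
    g <- as.integer(table(fi))
    v <- as.integer(table(ti))
    d <- g + v
  } else {
    inc <- as.integer(table(fi)) + as.integer(table(ti))
    loops <- network$edges[, 1] == network$edges[, 2]
    inc <- inc - as.integer(table(factor(network$edges[loops, 1],
                                         levels = nodes)))
    d <- g <- v <- inc
  }
  data.frame(node = nodes, d = d, g = g, v = v, stringsAsFactors = FALSE)
}

#' Undirected projection of a network
#'
#' Collapses each ordered pair onto its unordered counterpart: reciprocal
#' edges `a -> b`, `b -> a` become the single edge `{a, b}`. Self-loops are
#' preserved. Community detection and Newman-Girvan modularity operate on
#' this projection; realized modularity does not (it is defined on the
#' interactions as stored).
#'
#' @param network a `realmod_network`.
#' @return An undirected [network()] on the same node set.
#' @export
symmetrize <- function(network) {
  stopifnot(inherits(network, "realmod_network"))
  network(network$edges, nodes = network$nodes, directed = FALSE,
          bipartite_origin = network$bipartite_origin)
}
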