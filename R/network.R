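#' Coordination networks
#'
#' A `cg_network` is an undirected simple graph over `n_nodes` agents,
#' stored as a canonical edge matrix plus an adjacency list. Node ids are
#' 0-based contiguous integers and every edge is stored once as the pair
#' `(min, max)`, so each undirected edge has exactly one canonical
#' orientation — convenient for keying one Q-table per edge.
#'
#' @param n_nodes number of agents (positive integer).
#' @param edges two-column integer matrix of 0-based node ids, one row per
#'   undirected edge. Orientation and row order are canonicalised; self-loops
#'   and duplicate edges are rejected.
#'
#' @return An object of class `cg_network`: a list with elements `n_nodes`,
#'   `edges` (E x 2 integer matrix, each row `(i, j)` with `i < j`, rows in
#'   lexicographic order) and `adjacency` (list of length `n_nodes`; element
#'   `i + 1` holds the sorted 0-based neighbour ids of node `i`).
#' @examples
#' net <- cg_network(3, rbind(c(0, 1), c(1, 2)))
#' net$adjacency
#' @export
cg_network <- function(n_nodes, edges) {
  n_nodes <- as.integer(n_nodes)
  stopifnot(length(n_nodes) == 1L, n_nodes >= 1L)
  if (is.null(edges) || length(edges) == 0L) {
    edges <- matrix(integer(0), ncol = 2L)
  }
  edges <- matrix(as.integer(edges), ncol = 2L)
  if (nrow(edges) > 0L) {
    if (any(!is.finite(edges)) || any(edges < 0L) || any(edges >= n_nodes)) {
      stop("edge endpoints must be node ids in [0, n_nodes)")
    }
    if (any(edges[, 1L] == edges[, 2L])) {
      stop("self-loops are not allowed")
    }
    edges <- cbind(pmin(edges[, 1L], edges[, 2L]),
                   pmax(edges[, 1L], edges[, 2L]))
    ord <- order(edges[, 1L], edges[, 2L])
    edges <- edges[ord, , drop = FALSE]
    if (anyDuplicated(edges)) stop("duplicate edges are not allowed")
  }
  adjacency <- rep(list(integer(0)), n_nodes)
  for (r in seq_len(nrow(edges))) {
    i <- edges[r, 1L]; j <- edges[r, 2L]
    adjacency[[i + 1L]] <- c(adjacency[[i + 1L]], j)
    adjacency[[j + 1L]] <- c(adjacency[[j + 1L]], i)
  }
  adjacency <- lapply(adjacency, function(v) sort(unique(v)))
  structure(list(n_nodes = n_nodes, edges = edges, adjacency = adjacency),
            class = "cg_network")
}

#' @export
print.cg_network <- function(x, ...) {
  cat(sprintf("<cg_network: %d nodes, %d edges, mean degree %.2f>\n",
              x$n_nodes, nrow(x$edges),
              if (x$n_nodes > 0) 2 * nrow(x$edges) / x$n_nodes else 0))
  invisible(x)
}

#' Number of edges / neighbours
#'
#' @param net a [cg_network].
#' @param i 0-based node id.
#' @return `n_edges()`: the number of undirected edges. `neighbours_of()`:
#'   sorted integer vector of 0-based neighbour ids of node `i`.
#' @export
n_edges <- function(net) nrow(net$edges)

#' @rdname n_edges
#' @export
neighbours_of <- function(net, i) {
  stopifnot(i >= 0L, i < net$n_nodes)
  net$adjacency[[i + 1L]]
}

# Convert an igraph object (0-based relabelled) into a cg_network.
from_igraph <- function(g) {
  el <- igraph::as_edgelist(g, names = FALSE) - 1L
  cg_network(igraph::vcount(g), el)
}

#' Convert a coordination network to an igraph object
#'
#' @param net a [cg_network].
#' @return an undirected `igraph` graph with `n_nodes` vertices (igraph uses
#'   1-based vertex ids internally).
#' @export
as_igraph <- function(net) {
  g <- igraph::make_empty_graph(net$n_nodes, directed = FALSE)
  igraph::add_edges(g, as.vector(t(net$edges + 1L)))
}

#' Network generators
#'
#' Generators for the four topologies the simulations run on: ring-lattice
#' regular networks, Erdős–Rényi random graphs, Watts–Strogatz small-world
#' networks and Barabási–Albert scale-free networks. All of them return a
#' [cg_network] and are deterministic given `seed`.
#'
#' @param n number of nodes.
#' @param k even degree of the ring lattice (each node is connected to its
#'   `k/2` nearest neighbours on each side of the ring); `k = n - 1` (complete
#'   graph) is also allowed.
#' @param p edge probability in `[0, 1]` (Erdős–Rényi).
#' @param d target mean degree; the ER wrapper sets `p = d / (n - 1)`.
#' @param beta rewiring probability in `[0, 1]` (Watts–Strogatz).
#' @param m number of edges each newly attached node brings (Barabási–Albert);
#'   growth starts from a complete graph ("clique") on `m` seed nodes, so
#'   every non-seed node has degree at least `m`.
#' @param seed optional integer seed; when supplied the generator seeds R's
#'   RNG locally so the same seed always yields the same edge set.
#'
#' @return a [cg_network].
#' @examples
#' make_regular(6, 2)               # a 6-cycle
#' make_small_world(20, 4, 0.1, seed = 1)
#' @export
make_regular <- function(n, k) {
  n <- as.integer(n); k <- as.integer(k)
  if (k < 2L || k >= n) stop("require 2 <= k <= n - 1")
  if (k %% 2L == 1L && k != n - 1L) stop("k must be even unless k == n - 1")
  if (k == n - 1L) {
    idx <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
    return(cg_network(n, idx - 1L))
  }
  half <- k %/% 2L
  from <- rep(0:(n - 1L), each = half)
  to <- (from + rep(seq_len(half), n)) %% n
  cg_network(n, cbind(from, to))
}

#' @rdname make_regular
#' @export
make_er <- function(n, p, seed = NULL) {
  if (p < 0 || p > 1) stop("p must lie in [0, 1]")
  with_seed(seed, from_igraph(igraph::sample_gnp(n, p)))
}

#' @rdname make_regular
#' @export
make_er_degree <- function(n, d, seed = NULL) {
  make_er(n, d / (n - 1), seed = seed)
}

#' @rdname make_regular
#' @export
make_small_world <- function(n, k, beta, seed = NULL) {
  if (beta < 0 || beta > 1) stop("beta must lie in [0, 1]")
  n <- as.integer(n); k <- as.integer(k)
  if (k < 2L || k >= n) stop("require 2 <= k <= n - 1")
  if (k %% 2L == 1L) stop("k must be even")
  if (beta == 0) return(make_regular(n, k))
  with_seed(seed, from_igraph(igraph::sample_smallworld(1, n, k %/% 2L, beta)))
}

#' @rdname make_regular
#' @export
make_scale_free <- function(n, m, seed = NULL) {
  n <- as.integer(n); m <- as.integer(m)
  if (m < 1L || m >= n) stop("require 1 <= m < n")
  with_seed(seed, {
    g <- igraph::sample_pa(n, power = 1, m = m, directed = FALSE,
                           start.graph = igraph::make_full_graph(m))
    from_igraph(g)
  })
}

# Run expr with the RNG seeded locally (restoring the caller's RNG state),
# or with the ambient RNG stream when seed is NULL.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(force(expr))
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  }
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(as.integer(seed))
  force(expr)
}

#' Read and write edge-list files
#'
#' Plain-text edge lists: one `i j` pair of 0-based integer node ids per
#' line, whitespace separated, with `#` starting a comment. Reading is strict:
#' malformed lines, self-loops and (when `n_nodes` is given) out-of-range ids
#' fail with a message naming the offending line.
#'
#' @param path file path.
#' @param n_nodes optional node count; defaults to `max(id) + 1` so isolated
#'   trailing nodes need an explicit count.
#' @param net a [cg_network] to write.
#' @return `read_edgelist()` returns a [cg_network]; `write_edgelist()`
#'   returns `path` invisibly. Round trip is the identity:
#'   `read_edgelist(write_edgelist(net, p))` has the same edge set as `net`.
#' @export
read_edgelist <- function(path, n_nodes = NULL) {
  lines <- readLines(path)
  stripped <- sub("#.*$", "", lines)
  keep <- which(nzchar(trimws(stripped)))
  edges <- matrix(integer(0), ncol = 2L)
  for (ln in keep) {
    toks <- strsplit(trimws(stripped[ln]), "[[:space:]]+")[[1]]
    ids <- suppressWarnings(as.integer(toks))
    if (length(ids) != 2L || anyNA(ids)) {
      stop(sprintf("line %d: expected two integer node ids, got '%s'",
                   ln, trimws(lines[ln])))
    }
    if (ids[1] == ids[2]) {
      stop(sprintf("line %d: self-loop '%s' not allowed", ln, trimws(lines[ln])))
    }
    if (any(ids < 0L)) {
      stop(sprintf("line %d: negative node id", ln))
    }
    if (!is.null(n_nodes) && any(ids >= n_nodes)) {
      stop(sprintf("line %d: node id out of range [0, %d)", ln, n_nodes))
    }
    edges <- rbind(edges, ids)
  }
  if (is.null(n_nodes)) {
    n_nodes <- if (nrow(edges)) max(edges) + 1L else 1L
  }
  cg_network(n_nodes, edges)
}

#' @rdname read_edgelist
#' @export
write_edgelist <- function(net, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# %d nodes, %d edges", net$n_nodes, n_edges(net)), con)
  if (n_edges(net) > 0) {
    writeLines(paste(net$edges[, 1], net$edges[, 2]), con)
  }
  invisible(path)
}
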