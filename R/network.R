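#' Build a Watts-Strogatz small-world network
#'
#' Constructs a ring lattice of `n` nodes each linked to its `k` nearest
#' neighbours (`k/2` on each side) and rewires each lattice edge with
#' probability `p`, avoiding self-loops and duplicate edges, so the result
#' is an undirected simple graph with exactly `n * k / 2` edges.
#'
#' @param n Number of nodes.
#' @param k Even lattice degree, `0 < k < n`.
#' @param p Rewiring probability in `[0, 1]`.
#' @param seed Optional integer seed; when `NULL` the current RNG stream is
#'   used (as inside a simulation trial).
#' @return An object of class `"trust_network"`: a list with `n`, the
#'   two-column `edges` matrix, the sparse symmetric adjacency matrix `adj`,
#'   and the degree vector `deg`.
#' @export
#' @examples
#' net <- build_network(10, 4, 0)   # pure ring lattice
#' net$deg                          # all 4
build_network <- function(n, k, p, seed = NULL) {
  if (k %% 2 != 0) stop("`k` must be even.", call. = FALSE)
  if (k <= 0 || k >= n) stop("`k` must satisfy 0 < k < n.", call. = FALSE)
  if (p < 0 || p > 1) stop("`p` must be in [0, 1].", call. = FALSE)
  if (!is.null(seed)) set.seed(as.integer(seed))
  g <- igraph::sample_smallworld(dim = 1, size = n, nei = k / 2, p = p,
                                 loops = FALSE, multiple = FALSE)
  edges <- igraph::as_edgelist(g, names = FALSE)
  storage.mode(edges) <- "integer"
  new_trust_network(n, edges)
}

new_trust_network <- function(n, edges) {
  adj <- Matrix::sparseMatrix(
    i = c(edges[, 1], edges[, 2]),
    j = c(edges[, 2], edges[, 1]),
    x = 1,
    dims = c(n, n)
  )
  structure(
    list(n = n, edges = edges, adj = adj,
         deg = as.numeric(Matrix::rowSums(adj))),
    class = "trust_network"
  )
}

#' @export
print.trust_network <- function(x, ...) {
  cat("<trust_network> ", x$n, " nodes, ", nrow(x$edges),
      " edges, mean degree ", round(mean(x$deg), 2), "\n", sep = "")
  invisible(x)
}

#' Export a network as an edge-list file
#'
#' @param network A `trust_network`.
#' @param path Output path (two whitespace-separated node ids per line).
#' @return `path`, invisibly.
#' @export
write_edgelist <- function(network, path) {
  utils::write.table(network$edges, path, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

# Redirect a fraction of edges toward the top trust decile. One randomly
# chosen endpoint of each selected edge is re-attached to an agent sampled
# uniformly from the decile with highest trust (ties broken by lowest id).
# Self-loops and duplicate edges are avoided by redrawing, giving up after
# 10 attempts and keeping the original edge; the edge count is conserved.
rewire_to_top_decile <- function(network, trust, fraction = 0.10) {
  n <- network$n
  edges <- network$edges
  m <- nrow(edges)
  n_rewire <- round(fraction * m)
  if (n_rewire == 0L) return(network)

  n_top <- max(1L, floor(n / 10))
  top <- order(-trust, seq_len(n))[seq_len(n_top)]

  edge_key <- function(a, b) pmin(a, b) * (n + 1) + pmax(a, b)
  keys <- new.env(hash = TRUE, parent = emptyenv())
  for (kk in edge_key(edges[, 1], edges[, 2])) {
    assign(as.character(kk), TRUE, envir = keys)
  }

  chosen <- sample.int(m, n_rewire)
  for (e in chosen) {
    u <- edges[e, 1]; v <- edges[e, 2]
    keep_first <- stats::runif(1) < 0.5
    anchor <- if (keep_first) u else v
    old_key <- as.character(edge_key(u, v))
    done <- FALSE
    for (attempt in 1:10) {
      w <- top[sample.int(length(top), 1L)]
      if (w == anchor) next
      new_key <- as.character(edge_key(anchor, w))
      if (new_key != old_key && exists(new_key, envir = keys)) next
      rm(list = old_key, envir = keys)
      assign(new_key, TRUE, envir = keys)
      edges[e, ] <- c(anchor, w)
      done <- TRUE
      break
    }
    if (!done) next  # keep the original edge
  }
  new_trust_network(n, edges)
}
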