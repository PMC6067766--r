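#' Oscillator interaction networks
#'
#' An `oscillator_network` is a symmetric, zero-diagonal, nonnegative
#' (optionally weighted) adjacency matrix over `n_nodes` oscillators. It is the
#' topology slot of every simulation in the package: all-to-all for the
#' classical Kuramoto setting, Newman-Watts small-world graphs for the
#' seizure-protocol experiments, Erdos-Renyi graphs and user-supplied weighted
#' graphs for robustness checks.
#'
#' @param adjacency Square numeric matrix; symmetric, zero diagonal,
#'   nonnegative entries.
#' @return An object of class `oscillator_network` with fields `n_nodes` and
#'   `adjacency`.
#' @examples
#' net <- oscillator_network(matrix(c(0, 1, 1, 0), 2))
#' net$n_nodes
#' @export
oscillator_network <- function(adjacency) {
  if (!is.matrix(adjacency) || !is.numeric(adjacency) ||
      nrow(adjacency) != ncol(adjacency))
    abort("adjacency must be a square numeric matrix", "invalid_parameter")
  n <- nrow(adjacency)
  if (n < 1L) abort("network needs at least one node", "invalid_size")
  if (any(!is.finite(adjacency)) || any(adjacency < 0))
    abort("adjacency entries must be finite and nonnegative", "invalid_parameter")
  if (any(abs(adjacency - t(adjacency)) > 0))
    abort("adjacency must be symmetric", "invalid_parameter")
  if (any(diag(adjacency) != 0))
    abort("adjacency must have a zero diagonal (no self-loops)", "invalid_parameter")
  dimnames(adjacency) <- NULL
  structure(list(n_nodes = n, adjacency = adjacency),
            class = "oscillator_network")
}

#' @export
print.oscillator_network <- function(x, ...) {
  m <- sum(x$adjacency > 0) / 2
  cat(sprintf("<oscillator_network> %d nodes, %d edges, %s\n",
              x$n_nodes, m,
              if (all(x$adjacency %in% c(0, 1))) "unweighted" else "weighted"))
  invisible(x)
}

as_igraph <- function(net) {
  igraph::graph_from_adjacency_matrix(net$adjacency, mode = "undirected",
                                      weighted = TRUE)
}

#' Test whether a network is connected
#'
#' @param net An [oscillator_network()].
#' @return Logical scalar.
#' @export
is_connected_network <- function(net) {
  igraph::is_connected(as_igraph(net))
}

#' Complete (all-to-all) coupling network
#'
#' The topology of the classical Kuramoto model: every pair of distinct
#' oscillators is coupled with unit weight.
#'
#' @param n Number of oscillators, at least 2.
#' @return An [oscillator_network()].
#' @examples
#' all_to_all(3)$adjacency
#' @export
all_to_all <- function(n) {
  n <- check_count(n, "n", lower = 2L)
  a <- matrix(1, n, n)
  diag(a) <- 0
  oscillator_network(a)
}

#' Newman-Watts small-world network
#'
#' Starts from a 1D ring lattice in which each node is linked to its `k_half`
#' nearest neighbours clockwise and `k_half` counterclockwise, then considers
#' every currently unconnected pair once and adds a shortcut edge independently
#' with probability `p`. Because edges are only ever added, the ring backbone is
#' always present and the graph is connected for every `p`; at `p = 1` the
#' result is the complete graph.
#'
#' @param n Number of nodes, at least 2.
#' @param p Shortcut-addition probability in `[0, 1]`; controls density.
#' @param k_half Half coordination number of the ring backbone (each node has
#'   `2 * k_half` lattice neighbours). Default 2.
#' @param seed Optional integer seed; the draw is reproducible given a seed.
#' @return An [oscillator_network()] containing the full ring lattice plus
#'   shortcuts.
#' @examples
#' net <- newman_watts(20, p = 0.2, seed = 1)
#' is_connected_network(net)
#' @export
newman_watts <- function(n, p, k_half = 2, seed = NULL) {
  n <- check_count(n, "n", lower = 2L)
  check_scalar(p, "p", 0, 1)
  k_half <- check_count(k_half, "k_half", lower = 1L)
  if (k_half >= n / 2)
    abort(sprintf("k_half = %d must be below n/2 = %g", k_half, n / 2),
          "invalid_parameter")
  a <- matrix(0, n, n)
  idx <- which(upper.tri(a), arr.ind = TRUE)
  ring_gap <- pmin(idx[, 2] - idx[, 1], n - (idx[, 2] - idx[, 1]))
  on_ring <- ring_gap <= k_half
  a[idx[on_ring, , drop = FALSE]] <- 1
  free <- idx[!on_ring, , drop = FALSE]
  if (nrow(free) > 0 && p > 0) {
    add <- with_seed(seed, stats::runif(nrow(free)) < p)
    a[free[add, , drop = FALSE]] <- 1
  }
  a[lower.tri(a)] <- t(a)[lower.tri(a)]
  oscillator_network(a)
}

#' Connected Erdos-Renyi network
#'
#' Samples G(n, q) and conditions on connectivity by resampling with an
#' incremented seed until a connected graph appears or `max_attempts` is
#' exhausted.
#'
#' @param n Number of nodes, at least 2.
#' @param q Edge probability in `(0, 1]`.
#' @param seed Optional integer seed.
#' @param max_attempts Resampling cap before a generation-failure error.
#' @return A connected [oscillator_network()].
#' @export
erdos_renyi_connected <- function(n, q, seed = NULL, max_attempts = 100L) {
  n <- check_count(n, "n", lower = 2L)
  check_scalar(q, "q", 0, 1)
  if (q <= 0) abort("q must be positive", "invalid_parameter")
  max_attempts <- check_count(max_attempts, "max_attempts")
  for (attempt in seq_len(max_attempts)) {
    g <- with_seed(if (is.null(seed)) NULL else seed + attempt - 1L,
                   igraph::sample_gnp(n, q))
    if (igraph::is_connected(g)) {
      a <- as.matrix(igraph::as_adjacency_matrix(g, sparse = FALSE))
      return(oscillator_network(a))
    }
  }
  abort(sprintf("no connected G(%d, %g) sample in %d attempts",
                n, q, max_attempts), "generation_failure")
}

#' Read a network from a plain-text file
#'
#' Two formats are supported. `"edgelist"`: one `i j [w]` triple per line,
#' whitespace-separated, `#` starts a comment; indices are 0-based (the
#' on-disk convention throughout the package) and are converted to the R API's
#' 1-based indexing on load. `"adjacency"`: a square CSV whose header row
#' holds the 0-based node indices.
#'
#' Input is symmetrised by taking the larger of the two directed entries when
#' only one direction is given; genuinely conflicting weights (both directions
#' present and different) raise an error naming the pair, as do self-loops and
#' negative weights.
#'
#' @param path File to read.
#' @param format `"edgelist"` or `"adjacency"`.
#' @return An [oscillator_network()] with attribute `"connected"` reporting
#'   connectivity.
#' @seealso [save_network()]
#' @export
load_network <- function(path, format = c("edgelist", "adjacency")) {
  format <- match.arg(format)
  if (!file.exists(path)) abort(paste("no such file:", path), "io_error")
  if (format == "edgelist") {
    lines <- readLines(path)
    lines <- sub("#.*$", "", lines)
    lines <- trimws(lines)
    lines <- lines[nzchar(lines)]
    if (length(lines) == 0) abort("empty edge list", "parse_error")
    parts <- strsplit(lines, "[[:space:]]+")
    bad <- lengths(parts) < 2 | lengths(parts) > 3
    if (any(bad))
      abort(sprintf("malformed edge-list line: '%s'", lines[which(bad)[1]]),
            "parse_error")
    i <- as.integer(vapply(parts, `[`, "", 1L))
    j <- as.integer(vapply(parts, `[`, "", 2L))
    w <- vapply(parts, function(p) if (length(p) == 3) as.numeric(p[3]) else 1,
                numeric(1))
    if (anyNA(i) || anyNA(j) || anyNA(w)) abort("non-numeric edge entry", "parse_error")
    if (any(i < 0) || any(j < 0)) abort("negative node index", "parse_error")
    if (any(w < 0)) abort("negative edge weight", "parse_error")
    self <- i == j
    if (any(self))
      abort(sprintf("self-loop on node %d not allowed", i[which(self)[1]]),
            "parse_error")
    n <- max(i, j) + 1L
    a <- matrix(0, n, n)
    for (e in seq_along(i)) {
      ii <- i[e] + 1L; jj <- j[e] + 1L
      prev <- a[jj, ii]   # weight already recorded for the opposite direction
      if (prev != 0 && prev != w[e])
        abort(sprintf("conflicting weights for pair (%d, %d): %g vs %g",
                      i[e], j[e], prev, w[e]), "conflicting_weights")
      a[ii, jj] <- max(a[ii, jj], w[e])
    }
    a <- pmax(a, t(a))
  } else {
    df <- utils::read.csv(path, check.names = FALSE)
    a <- as.matrix(df)
    if (nrow(a) != ncol(a)) abort("adjacency CSV is not square", "parse_error")
    if (any(!is.finite(a))) abort("non-numeric adjacency entry", "parse_error")
    if (any(a < 0)) abort("negative edge weight", "parse_error")
    if (any(diag(a) != 0)) abort("nonzero diagonal (self-loop) in adjacency",
                                 "parse_error")
    conflict <- a != t(a) & a != 0 & t(a) != 0
    if (any(conflict)) {
      kk <- which(conflict, arr.ind = TRUE)[1, ]
      abort(sprintf("conflicting weights for pair (%d, %d): %g vs %g",
                    kk[1] - 1L, kk[2] - 1L, a[kk[1], kk[2]], a[kk[2], kk[1]]),
            "conflicting_weights")
    }
    a <- pmax(a, t(a))
  }
  storage.mode(a) <- "double"
  net <- oscillator_network(a)
  attr(net, "connected") <- is_connected_network(net)
  net
}

#' Write a network to a plain-text file
#'
#' Inverse of [load_network()]; node indices on disk are 0-based.
#'
#' @param net An [oscillator_network()].
#' @param path Destination file.
#' @param format `"edgelist"` or `"adjacency"`.
#' @return `path`, invisibly.
#' @export
save_network <- function(net, path, format = c("edgelist", "adjacency")) {
  format <- match.arg(format)
  if (format == "edgelist") {
    idx <- which(upper.tri(net$adjacency) & net$adjacency > 0, arr.ind = TRUE)
    lines <- sprintf("%d %d %.17g", idx[, 1] - 1L, idx[, 2] - 1L,
                     net$adjacency[idx])
    writeLines(c("# edge list, 0-based indices: i j w", lines), path)
  } else {
    df <- as.data.frame(net$adjacency)
    names(df) <- as.character(seq_len(net$n_nodes) - 1L)
    utils::write.csv(df, path, row.names = FALSE)
  }
  invisible(path)
}

#' Node degrees (weighted row sums)
#'
#' @param net An [oscillator_network()].
#' @return Numeric vector of length `n_nodes`.
#' @export
degrees <- function(net) rowSums(net$adjacency)
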