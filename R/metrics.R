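#' Pairwise shortest-path lengths of a thresholded network
#'
#' Binary networks use hop counts; weighted networks use nonnegative-weight
#' shortest paths with edge length `1/weight`, the standard distance for
#' correlation-weighted connectomes. Unreachable pairs are `Inf`.
#'
#' @param net A `thresholded_network` from [proportional_threshold()].
#' @return Symmetric numeric matrix of distances with zero diagonal.
#' @export
shortest_path_lengths <- function(net) {
  stopifnot(inherits(net, "thresholded_network"))
  distance_matrix(net$adjacency, net$binary)
}

distance_matrix <- function(adjacency, binary) {
  d <- cpp_distance_matrix(unname(as.matrix(adjacency)), binary)
  dimnames(d) <- dimnames(adjacency)
  d
}

#' Clustering coefficient
#'
#' Binary: `C_i = 2 t_i / (k_i (k_i - 1))` with `t_i` the triangle count at
#' node i; nodes with fewer than two neighbours get `C_i = 0`. Weighted:
#' Onnela's form, the geometric mean of triangle weights after normalising
#' all weights by the network maximum, with the binary degree in the
#' denominator. `Cp` is the unweighted mean over all nodes.
#'
#' @param net A `thresholded_network`.
#' @return List with `C_i` (per-node vector) and `Cp` (scalar mean).
#' @export
clustering_coefficient <- function(net) {
  stopifnot(inherits(net, "thresholded_network"))
  a <- net$adjacency
  k <- rowSums(a > 0)
  s <- if (net$binary) (a > 0) + 0 else (a / max(a))^(1 / 3)
  t_i <- diag(s %*% s %*% s) / 2
  c_i <- ifelse(k < 2, 0, 2 * t_i / (k * (k - 1)))
  list(C_i = c_i, Cp = mean(c_i))
}

#' Characteristic path length
#'
#' Mean shortest-path length over all ordered pairs of distinct nodes with a
#' finite path; the proportion of disconnected pairs is reported rather than
#' substituted with an arbitrary finite value.
#'
#' @param net A `thresholded_network`.
#' @return List with `Lp` and `frac_disconnected_pairs`.
#' @export
characteristic_path_length <- function(net) {
  d <- shortest_path_lengths(net)
  off <- d[row(d) != col(d)]
  finite <- is.finite(off)
  if (!any(finite)) {
    abort("no finite paths: cannot compute characteristic path length")
  }
  list(
    Lp = mean(off[finite]),
    frac_disconnected_pairs = mean(!finite)
  )
}

#' Nodal, global and local efficiency
#'
#' Nodal efficiency `Ne_i` is the mean inverse shortest-path length from node
#' i to every other node (`1/Inf = 0`); global efficiency `Eg` is the mean of
#' `Ne_i`; local efficiency `Eloc_i` is the global efficiency of the subgraph
#' induced by i's neighbours (0 with fewer than two neighbours), and `Eloc`
#' its mean.
#'
#' @param net A `thresholded_network`.
#' @param distances Optional precomputed [shortest_path_lengths()] matrix.
#' @return List with `Ne_i`, `Eg`, `Eloc_i`, `Eloc`.
#' @export
efficiencies <- function(net, distances = NULL) {
  stopifnot(inherits(net, "thresholded_network"))
  d <- distances %||% shortest_path_lengths(net)
  ne <- nodal_efficiency_from_distances(d)
  eloc_i <- as.numeric(
    cpp_local_efficiency(unname(as.matrix(net$adjacency)), net$binary)
  )
  list(Ne_i = ne, Eg = mean(ne), Eloc_i = eloc_i, Eloc = mean(eloc_i))
}

nodal_efficiency_from_distances <- function(d) {
  inv <- 1 / d
  diag(inv) <- 0
  inv[!is.finite(inv)] <- 0
  rowSums(inv) / (nrow(d) - 1)
}

#' Betweenness centrality
#'
#' The number of shortest paths between other node pairs that pass through
#' each node, with fractional credit when several shortest paths tie;
#' endpoints excluded, counts unnormalised (Brandes' algorithm). Weighted
#' networks use `1/weight` edge lengths.
#'
#' @param net A `thresholded_network`.
#' @return Per-node numeric vector.
#' @export
betweenness_centrality <- function(net) {
  stopifnot(inherits(net, "thresholded_network"))
  if (net$n_edges == 0) {
    return(setNames(rep(0, net$n_nodes), colnames(net$adjacency)))
  }
  g <- igraph::graph_from_adjacency_matrix(
    net$adjacency, mode = "undirected", weighted = TRUE, diag = FALSE
  )
  w <- if (net$binary) NA else 1 / igraph::E(g)$weight
  bc <- igraph::betweenness(g, weights = w, normalized = FALSE)
  setNames(as.numeric(bc), colnames(net$adjacency))
}

#' Degree centrality
#'
#' Number of incident edges (binary) or sum of incident edge weights
#' (weighted).
#'
#' @param net A `thresholded_network`.
#' @return Per-node numeric vector of adjacency row sums.
#' @export
degree_centrality <- function(net) {
  stopifnot(inherits(net, "thresholded_network"))
  rowSums(net$adjacency)
}

#' All seven global metrics of one network
#'
#' Computes Cp, Lp, Eg, Eloc and, when a null ensemble is supplied (or
#' `n_random > 0`), the normalised metrics gamma, lambda and their ratio
#' sigma.
#'
#' @param net A `thresholded_network`.
#' @param ensemble Optional [null_ensemble()] result; if `NULL` and
#'   `n_random > 0` one is generated internally.
#' @param n_random Ensemble size used when `ensemble` is `NULL`.
#' @param seed Seed for the internally generated ensemble.
#' @return One-row tibble: `Cp`, `Gamma`, `Lp`, `Lambda`, `Sigma`, `Eg`,
#'   `Eloc`, `frac_disconnected_pairs` (normalised entries `NA` when no
#'   ensemble is used).
#' @export
global_metrics <- function(net, ensemble = NULL, n_random = 100, seed = 1L) {
  cp <- clustering_coefficient(net)$Cp
  d <- shortest_path_lengths(net)
  off <- d[row(d) != col(d)]
  finite <- is.finite(off)
  if (!any(finite)) {
    abort("no finite paths: cannot compute characteristic path length")
  }
  lp <- mean(off[finite])
  eff <- efficiencies(net, distances = d)
  gamma <- lambda <- sigma <- NA_real_
  if (is.null(ensemble) && n_random > 0) {
    ensemble <- null_ensemble(net, n_random = n_random, seed = seed)
  }
  if (!is.null(ensemble)) {
    sw <- normalized_smallworld_values(cp, lp, ensemble)
    gamma <- sw$gamma
    lambda <- sw$lambda
    sigma <- sw$sigma
  }
  tibble::tibble(
    Cp = cp, Gamma = gamma, Lp = lp, Lambda = lambda, Sigma = sigma,
    Eg = eff$Eg, Eloc = eff$Eloc,
    frac_disconnected_pairs = mean(!finite)
  )
}

#' All three nodal metrics of one network
#'
#' @param net A `thresholded_network`.
#' @return Tibble `node`, `Dc` (degree), `Bc` (betweenness), `Ne` (nodal
#'   efficiency), one row per node.
#' @export
nodal_metrics <- function(net) {
  d <- shortest_path_lengths(net)
  tibble::tibble(
    node = colnames(net$adjacency) %||% sprintf("roi%03d", seq_len(net$n_nodes)),
    Dc = as.numeric(degree_centrality(net)),
    Bc = as.numeric(betweenness_centrality(net)),
    Ne = as.numeric(nodal_efficiency_from_distances(d))
  )
}
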