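# Independent brute-force oracles for graphs of <= 8 nodes, used to verify
# the shipped metric implementations. Everything here enumerates: simple
# paths for distances and betweenness, neighbour pairs for triangles,
# literal sums of squares for the ICC. Nothing calls the package's own
# metric code paths.

# edge-length matrix: Inf where no edge; 1 (binary) or 1/w (weighted)
oracle_edge_lengths <- function(a, binary) {
  el <- matrix(Inf, nrow(a), ncol(a))
  pos <- a > 0
  el[pos] <- if (binary) 1 else 1 / a[pos]
  diag(el) <- Inf
  el
}

# all simple paths s -> t as list(nodes = ..., length = ...)
oracle_simple_paths <- function(el, s, t) {
  n <- nrow(el)
  out <- list()
  rec <- function(v, visited, path, acc) {
    if (v == t) {
      out[[length(out) + 1]] <<- list(nodes = path, length = acc)
      return()
    }
    for (u in seq_len(n)) {
      if (!visited[u] && is.finite(el[v, u])) {
        visited[u] <- TRUE
        rec(u, visited, c(path, u), acc + el[v, u])
        visited[u] <- FALSE
      }
    }
  }
  vis <- rep(FALSE, n)
  vis[s] <- TRUE
  rec(s, vis, s, 0)
  out
}

oracle_distances <- function(a, binary) {
  n <- nrow(a)
  el <- oracle_edge_lengths(a, binary)
  d <- matrix(Inf, n, n)
  diag(d) <- 0
  for (s in seq_len(n - 1)) {
    for (t in (s + 1):n) {
      paths <- oracle_simple_paths(el, s, t)
      if (length(paths) > 0) {
        d[s, t] <- d[t, s] <- min(vapply(paths, `[[`, numeric(1), "length"))
      }
    }
  }
  d
}

# fractional-credit betweenness over all shortest paths, endpoints excluded
oracle_betweenness <- function(a, binary, tol = 1e-9) {
  n <- nrow(a)
  el <- oracle_edge_lengths(a, binary)
  bc <- numeric(n)
  for (s in seq_len(n - 1)) {
    for (t in (s + 1):n) {
      paths <- oracle_simple_paths(el, s, t)
      if (length(paths) == 0) next
      lens <- vapply(paths, `[[`, numeric(1), "length")
      shortest <- paths[lens <= min(lens) * (1 + tol) + tol]
      credit <- 1 / length(shortest)
      for (p in shortest) {
        interior <- setdiff(p$nodes, c(s, t))
        bc[interior] <- bc[interior] + credit
      }
    }
  }
  bc # each unordered pair counted once (undirected convention)
}

oracle_clustering <- function(a, binary) {
  n <- nrow(a)
  sh <- if (binary) (a > 0) + 0 else (a / max(a))^(1 / 3)
  c_i <- numeric(n)
  for (i in seq_len(n)) {
    nb <- which(a[i, ] > 0)
    k <- length(nb)
    if (k < 2) next
    t_i <- 0
    for (p in seq_len(k - 1)) {
      for (q in (p + 1):k) {
        j <- nb[p]
        h <- nb[q]
        if (a[j, h] > 0) t_i <- t_i + sh[i, j] * sh[i, h] * sh[j, h]
      }
    }
    c_i[i] <- 2 * t_i / (k * (k - 1))
  }
  c_i
}

oracle_lp <- function(a, binary) {
  d <- oracle_distances(a, binary)
  off <- d[row(d) != col(d)]
  mean(off[is.finite(off)])
}

oracle_nodal_efficiency <- function(a, binary) {
  d <- oracle_distances(a, binary)
  inv <- 1 / d
  diag(inv) <- 0
  inv[!is.finite(inv)] <- 0
  rowSums(inv) / (nrow(a) - 1)
}

oracle_local_efficiency <- function(a, binary) {
  n <- nrow(a)
  vapply(seq_len(n), function(i) {
    nb <- which(a[i, ] > 0)
    if (length(nb) < 2) {
      return(0)
    }
    mean(oracle_nodal_efficiency(a[nb, nb, drop = FALSE], binary))
  }, numeric(1))
}

# literal two-way sums-of-squares ICC(A,1), written against the mean-square
# definitions, loop by loop
oracle_icc_a1 <- function(m) {
  n <- nrow(m)
  k <- ncol(m)
  grand <- mean(m)
  bms <- 0
  for (i in seq_len(n)) bms <- bms + (mean(m[i, ]) - grand)^2
  bms <- k * bms / (n - 1)
  jms <- 0
  for (j in seq_len(k)) jms <- jms + (mean(m[, j]) - grand)^2
  jms <- n * jms / (k - 1)
  sse <- 0
  for (i in seq_len(n)) {
    for (j in seq_len(k)) {
      sse <- sse + (m[i, j] - mean(m[i, ]) - mean(m[, j]) + grand)^2
    }
  }
  ems <- sse / ((n - 1) * (k - 1))
  (bms - ems) / (bms + (k - 1) * ems + (jms - ems) * k / n)
}

# random connected test graph as a connectivity-style matrix (positive
# weights in (0, 1)); retries until connected so path-based metrics are
# fully exercised
random_test_graph <- function(n, p = 0.5, weighted = TRUE) {
  repeat {
    a <- matrix(0, n, n)
    ut <- upper.tri(a)
    edges <- stats::runif(sum(ut)) < p
    w <- if (weighted) stats::runif(sum(ut), 0.1, 1) else 1
    a[ut] <- edges * w
    a <- a + t(a)
    d <- oracle_distances(a, binary = !weighted)
    if (all(is.finite(d))) {
      return(a)
    }
  }
}

as_net <- function(a, binary) {
  structure(
    list(
      adjacency = a, density = sum(a[upper.tri(a)] > 0) / (nrow(a) * (nrow(a) - 1) / 2),
      realized_density = NA_real_, binary = binary,
      n_nodes = nrow(a), n_edges = sum(a[upper.tri(a)] > 0)
    ),
    class = "thresholded_network"
  )
}

# complete graph / path / star / ring-lattice constructors
k_graph <- function(n) {
  a <- matrix(1, n, n)
  diag(a) <- 0
  a
}

path_graph <- function(n) {
  a <- matrix(0, n, n)
  for (i in seq_len(n - 1)) a[i, i + 1] <- a[i + 1, i] <- 1
  a
}

star_graph <- function(leaves) {
  a <- matrix(0, leaves + 1, leaves + 1)
  a[1, -1] <- a[-1, 1] <- 1
  a
}

# Watts-Strogatz-style ring lattice: n nodes, each joined to `k` nearest
# neighbours per side, then a fraction `p_rewire` of edges rewired
ring_lattice_rewired <- function(n, k = 2, p_rewire = 0.1) {
  a <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (s in seq_len(k)) {
      j <- ((i - 1 + s) %% n) + 1
      a[i, j] <- a[j, i] <- 1
    }
  }
  idx <- which(upper.tri(a) & a > 0, arr.ind = TRUE)
  rewire_rows <- which(stats::runif(nrow(idx)) < p_rewire)
  for (r in rewire_rows) {
    i <- idx[r, 1]
    free <- which(a[i, ] == 0 & seq_len(n) != i)
    if (length(free) == 0) next
    j_new <- free[sample.int(length(free), 1)]
    j_old <- idx[r, 2]
    a[i, j_old] <- a[j_old, i] <- 0
    a[i, j_new] <- a[j_new, i] <- 1
  }
  a
}
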