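#' Density grid for a proportional-threshold sweep
#'
#' @param start,stop,step Densities with `0 < start <= stop <= 1`, `step > 0`.
#' @return Numeric vector of densities (class `density_grid`).
#' @examples
#' density_grid(0.15, 0.35, 0.05)  # the 5-point global grid
#' density_grid(0.05, 0.50, 0.05)  # the 10-point nodal AUC grid
#' @export
density_grid <- function(start, stop, step) {
  if (!(start > 0 && start <= stop && stop <= 1 && step > 0)) {
    abort("need 0 < start <= stop <= 1 and step > 0")
  }
  # round away accumulated fp error so 0.15 + 4 * 0.05 prints as 0.35
  g <- round(seq(start, stop, by = step), 10)
  structure(g, class = c("density_grid", "numeric"))
}

#' Threshold a connectivity matrix at a proportional density
#'
#' Keeps the strongest `round(density * N(N-1)/2)` positive correlations
#' (round-half-up; ties broken by ascending (row, column) index) and drops
#' the rest. Binary networks set retained edges to 1; weighted networks keep
#' the correlation value as the edge weight.
#'
#' Negative correlations are never retained: if the target edge count exceeds
#' the number of strictly positive entries the call fails and reports the
#' achievable maximum density. With `partial = TRUE` it instead keeps every
#' positive edge and flags the network as capped — the behaviour connectome
#' pipelines need at high densities after global signal regression, which
#' centres the correlation distribution near zero so that densities around
#' 0.5 can exceed the positive supply.
#'
#' @param conn Symmetric ROI-by-ROI correlation matrix with zero diagonal.
#' @param density Target proportion of retained edges in `(0, 1]`.
#' @param binary Build a binary (TRUE) or weighted (FALSE) network.
#' @param partial Cap at the achievable density instead of failing.
#' @return A `thresholded_network`: list with `adjacency`, `density`
#'   (target), `realized_density`, `binary`, `n_nodes`, `n_edges`, `capped`.
#' @examples
#' m <- matrix(0, 4, 4)
#' m[upper.tri(m)] <- c(.9, .8, .7, .3, .2, .1)
#' m <- m + t(m)
#' net <- proportional_threshold(m, 2 / 6, binary = TRUE)
#' net$n_edges
#' @export
proportional_threshold <- function(conn, density, binary = TRUE, partial = FALSE) {
  conn <- as.matrix(conn)
  n <- nrow(conn)
  stopifnot(n == ncol(conn), n >= 2)
  if (!(density > 0 && density <= 1)) {
    abort("density must lie in (0, 1]")
  }
  n_pairs <- n * (n - 1) / 2
  m <- floor(density * n_pairs + 0.5) # round half up, platform-stable
  idx <- which(upper.tri(conn), arr.ind = TRUE)
  vals <- conn[idx]
  n_pos <- sum(vals > 0)
  capped <- m > n_pos
  if (capped) {
    if (!partial) {
      abort(sprintf(
        "only %d positive correlations: target density %.3f needs %d edges (achievable maximum density %.3f)",
        n_pos, density, m, n_pos / n_pairs
      ))
    }
    m <- n_pos
  }
  ord <- order(-vals, idx[, 1], idx[, 2])
  keep <- ord[seq_len(m)]
  a <- matrix(0, n, n, dimnames = dimnames(conn))
  w <- if (binary) rep(1, m) else vals[keep]
  a[idx[keep, , drop = FALSE]] <- w
  a <- a + t(a)
  structure(
    list(
      adjacency = a,
      density = density,
      realized_density = m / n_pairs,
      binary = binary,
      n_nodes = n,
      n_edges = m,
      capped = capped
    ),
    class = "thresholded_network"
  )
}

#' @export
print.thresholded_network <- function(x, ...) {
  cat(sprintf(
    "<thresholded_network> %s, %d nodes, %d edges (density %.3f, target %.3f)\n",
    if (x$binary) "binary" else "weighted",
    x$n_nodes, x$n_edges, x$realized_density, x$density
  ))
  invisible(x)
}

#' Threshold a connectivity matrix over a density grid
#'
#' Because thresholding is rank-based, the edge set at a lower density is
#' always a subset of the edge set at a higher density (nested sweep).
#'
#' @inheritParams proportional_threshold
#' @param grid A [density_grid()] (any numeric vector of densities works).
#' @return Tibble with columns `density` and `network` (list of
#'   `thresholded_network`), one row per grid point in order.
#' @export
density_sweep <- function(conn, grid, binary = TRUE, partial = FALSE) {
  tibble::tibble(
    density = as.numeric(grid),
    network = purrr::map(as.numeric(grid), function(d) {
      proportional_threshold(conn, d, binary = binary, partial = partial)
    })
  )
}
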