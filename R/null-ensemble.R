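#' Degree-preserving null ensemble for small-world normalization
#'
#' Generates `n_random` randomised surrogates of a network by repeated
#' degree-preserving double-edge swaps (10 x |E| attempted swaps per
#' surrogate). Weighted networks additionally receive a random permutation
#' of the original weight multiset over the rewired topology, preserving the
#' degree sequence and the weight multiset. The ensemble means of the
#' clustering coefficient and characteristic path length are recorded for
#' use in [normalized_smallworld()].
#'
#' @param net A `thresholded_network` with at least 2 edges.
#' @param n_random Ensemble size (default 100).
#' @param seed RNG seed for the rewiring stream.
#' @param keep_members Also return each surrogate network (memory-heavy;
#'   meant for auditing the ensemble invariants).
#' @return A `null_ensemble` list: `n_random`, `seed`, `mean_Cp_rand`,
#'   `mean_Lp_rand`, the per-member `Cp_rand`, `Lp_rand` vectors, and
#'   `members` (list of `thresholded_network`, or `NULL`).
#' @export
null_ensemble <- function(net, n_random = 100, seed = 1L, keep_members = FALSE) {
  stopifnot(inherits(net, "thresholded_network"))
  if (net$n_edges < 2) {
    abort("null ensemble needs a network with >= 2 edges")
  }
  set.seed(seed)
  res <- cpp_null_ensemble(
    unname(as.matrix(net$adjacency)), net$binary,
    as.integer(n_random), 10L, keep_members
  )
  if (res$unchanged > n_random / 2) {
    warn(sprintf(
      "double-edge swaps failed to move the edge set for %d of %d surrogates; degree sequence may be pathological",
      res$unchanged, n_random
    ))
  }
  members <- NULL
  if (keep_members) {
    members <- purrr::map(res$members, function(el) {
      ar <- matrix(0, net$n_nodes, net$n_nodes)
      ar[el[, 1:2, drop = FALSE]] <- el[, 3]
      ar <- ar + t(ar)
      structure(
        list(
          adjacency = ar, density = net$density,
          realized_density = net$realized_density,
          binary = net$binary, n_nodes = net$n_nodes, n_edges = net$n_edges
        ),
        class = "thresholded_network"
      )
    })
  }
  structure(
    list(
      n_random = n_random, seed = seed,
      mean_Cp_rand = mean(res$Cp_rand), mean_Lp_rand = mean(res$Lp_rand),
      Cp_rand = res$Cp_rand, Lp_rand = res$Lp_rand,
      swaps = res$swaps,
      members = members
    ),
    class = "null_ensemble"
  )
}

#' Small-world indices normalised by a null ensemble
#'
#' `gamma = Cp / mean(Cp_rand)`, `lambda = Lp / mean(Lp_rand)` and
#' `sigma = gamma / lambda`. A small-world network has clustering well above
#' its randomised surrogates at comparable path length, hence `sigma > 1`.
#'
#' @param net A `thresholded_network`.
#' @param ensemble A [null_ensemble()] for the same network.
#' @return List with `gamma`, `lambda`, `sigma`.
#' @export
normalized_smallworld <- function(net, ensemble) {
  cp <- clustering_coefficient(net)$Cp
  lp <- characteristic_path_length(net)$Lp
  normalized_smallworld_values(cp, lp, ensemble)
}

normalized_smallworld_values <- function(cp, lp, ensemble) {
  stopifnot(inherits(ensemble, "null_ensemble"))
  if (!(ensemble$mean_Cp_rand > 0)) {
    abort("ensemble mean Cp is zero: gamma undefined (near-empty graph)")
  }
  if (!(ensemble$mean_Lp_rand > 0)) {
    abort("ensemble mean Lp is zero or undefined")
  }
  gamma <- cp / ensemble$mean_Cp_rand
  lambda <- lp / ensemble$mean_Lp_rand
  list(gamma = gamma, lambda = lambda, sigma = gamma / lambda)
}
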