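#' Global and nodal metric tables for every subject-session
#'
#' Sweeps each connectivity matrix over the two density grids and computes
#' the seven global metrics (with null-ensemble normalisation for gamma,
#' lambda, sigma) on the global grid and the three nodal metrics on the
#' nodal grid.
#'
#' Null-ensemble seeds are derived deterministically from `seed` and the row
#' and density indices, so reruns with the same inputs are byte-identical.
#'
#' @param conn_tbl Tibble from [connectivity_table()].
#' @param method Label attached to every output row (e.g. `"WG90"`).
#' @param global_grid [density_grid()] for the global metrics (default the
#'   5-point 0.15-0.35 grid).
#' @param nodal_grid [density_grid()] for the nodal metrics (default the
#'   10-point 0.05-0.50 grid).
#' @param binary Binary (TRUE) or weighted (FALSE) networks.
#' @param n_random Null-ensemble size per network.
#' @param seed Master seed for the ensembles.
#' @return List of two long tibbles: `global` with columns `method`,
#'   `subject`, `session`, `density`, `metric` (Cp, Gamma, Lp, Lambda,
#'   Sigma, Eg, Eloc), `value`; and `nodal` with `method`, `subject`,
#'   `session`, `density`, `node`, `metric` (Dc, Bc, Ne), `value`.
#' @export
network_metric_table <- function(conn_tbl, method,
                                 global_grid = density_grid(0.15, 0.35, 0.05),
                                 nodal_grid = density_grid(0.05, 0.50, 0.05),
                                 binary = TRUE,
                                 n_random = 100,
                                 seed = 1L) {
  global_d <- as.numeric(global_grid)
  nodal_d <- as.numeric(nodal_grid)
  all_d <- sort(unique(c(global_d, nodal_d)))

  per_session <- purrr::pmap(
    list(conn_tbl$subject, conn_tbl$session, conn_tbl$conn, seq_len(nrow(conn_tbl))),
    function(subject, session, conn, row_i) {
      # the nodal grid may exceed the positive-edge supply after GSR; those
      # networks are capped at the achievable density (see
      # ?proportional_threshold), but the global grid must never be
      sweep <- density_sweep(conn, all_d, binary = binary, partial = TRUE)
      glob <- purrr::map2_dfr(sweep$network, sweep$density, function(net, d) {
        if (!d %in% global_d) {
          return(NULL)
        }
        if (isTRUE(net$capped)) {
          abort(sprintf(
            "global-grid density %.2f unreachable for subject %s session %s (achievable %.3f)",
            d, subject, session, net$realized_density
          ))
        }
        ens_seed <- item_seed(seed, row_i, match(d, all_d))
        gm <- global_metrics(net, n_random = n_random, seed = ens_seed)
        gm$density <- d
        gm
      })
      glob <- tidyr::pivot_longer(
        glob[c("density", "Cp", "Gamma", "Lp", "Lambda", "Sigma", "Eg", "Eloc")],
        cols = -"density", names_to = "metric", values_to = "value"
      )
      glob$subject <- subject
      glob$session <- session
      nod <- purrr::map2_dfr(sweep$network, sweep$density, function(net, d) {
        if (!d %in% nodal_d) {
          return(NULL)
        }
        nm <- nodal_metrics(net)
        nm$density <- d
        nm
      })
      nod <- tidyr::pivot_longer(
        nod, cols = c("Dc", "Bc", "Ne"), names_to = "metric", values_to = "value"
      )
      nod$subject <- subject
      nod$session <- session
      list(global = glob, nodal = nod)
    }
  )

  global_tbl <- dplyr::bind_rows(purrr::map(per_session, "global"))
  nodal_tbl <- dplyr::bind_rows(purrr::map(per_session, "nodal"))
  global_tbl <- dplyr::select(
    dplyr::mutate(global_tbl, method = method),
    "method", "subject", "session", "density", "metric", "value"
  )
  nodal_tbl <- dplyr::select(
    dplyr::mutate(nodal_tbl, method = method),
    "method", "subject", "session", "density", "node", "metric", "value"
  )
  list(global = global_tbl, nodal = nodal_tbl)
}

#' Collapse nodal metric curves to their area under the curve
#'
#' Nodal metrics are summarised threshold-free as the trapezoidal area under
#' the metric-versus-density curve over the nodal grid, per node, metric and
#' subject-session.
#'
#' @param nodal_tbl The `nodal` tibble from [network_metric_table()].
#' @return Tibble `method`, `subject`, `session`, `node`, `metric`, `value`
#'   where `value` is the AUC over densities.
#' @export
nodal_auc_table <- function(nodal_tbl) {
  dplyr::summarise(
    dplyr::group_by(
      nodal_tbl,
      .data$method, .data$subject, .data$session, .data$node, .data$metric
    ),
    value = auc_over_densities(.data$value[order(.data$density)], sort(.data$density)),
    .groups = "drop"
  )
}
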