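#' Test-retest reliability of the global metrics
#'
#' For every (method, metric, density) cell, arranges the values into a
#' subjects-by-sessions table and computes [icc_a1()] and the within-subject
#' CV. With `include_mean = TRUE` a threshold-averaged summary row per
#' (method, metric) is appended (`density = "mean"`): the arithmetic mean of
#' the clamped per-density ICCs (and of the CVs), the form in which global
#' reliability is compared across strategies.
#'
#' @param global_tbl Long tibble from [network_metric_table()]'s `global`
#'   element (possibly several methods bound together).
#' @param include_mean Append the threshold-averaged rows?
#' @return Tibble `method`, `metric`, `density` (character; `"mean"` for the
#'   averaged rows), `icc`, `icc_raw`, `cv`, `BMS`, `JMS`, `EMS`,
#'   `category`.
#' @export
reliability_global <- function(global_tbl, include_mean = TRUE) {
  per_density <- global_tbl |>
    dplyr::group_by(.data$method, .data$metric, .data$density) |>
    dplyr::group_modify(function(df, key) icc_row(df)) |>
    dplyr::ungroup() |>
    dplyr::mutate(density = format(.data$density, trim = TRUE))
  if (!include_mean) {
    return(per_density)
  }
  means <- per_density |>
    dplyr::group_by(.data$method, .data$metric) |>
    dplyr::summarise(
      density = "mean",
      icc = mean(.data$icc),
      icc_raw = mean(.data$icc_raw),
      cv = mean(.data$cv),
      BMS = NA_real_, JMS = NA_real_, EMS = NA_real_,
      category = icc_category(mean(.data$icc)),
      .groups = "drop"
    )
  dplyr::bind_rows(per_density, means)
}

icc_row <- function(df) {
  fit <- icc_a1(df[c("subject", "session", "value")])
  tibble::tibble(
    icc = fit$icc, icc_raw = fit$icc_raw, cv = fit$cv,
    BMS = fit$components$BMS, JMS = fit$components$JMS, EMS = fit$components$EMS,
    category = fit$category
  )
}

#' Test-retest reliability of the nodal metrics
#'
#' Applies [icc_a1()] per (method, metric, node) to the AUC-over-densities
#' values, the threshold-free summary used for nodal reliability.
#'
#' @param nodal_auc_tbl Tibble from [nodal_auc_table()].
#' @return Tibble `method`, `metric`, `node`, `icc`, `icc_raw`, `cv`,
#'   `BMS`, `JMS`, `EMS`, `category`.
#' @export
reliability_nodal <- function(nodal_auc_tbl) {
  nodal_auc_tbl |>
    dplyr::group_by(.data$method, .data$metric, .data$node) |>
    dplyr::group_modify(function(df, key) icc_row(df)) |>
    dplyr::ungroup()
}

#' Threshold-averaged ICC
#'
#' Arithmetic mean of the clamped per-density ICC estimates; the scalar used
#' when comparing strategies after the threshold effect proves negligible.
#'
#' @param iccs Numeric vector of per-density (clamped) ICCs, or a list of
#'   [icc_a1()] objects.
#' @return Scalar mean.
#' @export
threshold_averaged_icc <- function(iccs) {
  if (is.list(iccs)) iccs <- vapply(iccs, function(x) x$icc, numeric(1))
  mean(iccs)
}

#' Pairwise-visit ICC
#'
#' ICC(A,1) restricted to one pair of sessions (k = 2), for studying how
#' reliability changes with the inter-scan interval.
#'
#' @param table Matrix or long data frame as in [icc_a1()].
#' @param session_pair Length-2 vector of session labels (data frame input)
#'   or column indices (matrix input).
#' @return An `icc_a1` object.
#' @export
pairwise_visit_icc <- function(table, session_pair) {
  stopifnot(length(session_pair) == 2)
  m <- as_measurement_matrix(table)
  cols <- if (is.character(session_pair)) {
    match(session_pair, colnames(m))
  } else {
    session_pair
  }
  if (anyNA(cols)) {
    abort("both sessions of the pair must be present")
  }
  icc_a1(m[, cols, drop = FALSE])
}

#' Reliability within subject subgroups
#'
#' Computes [icc_a1()] separately within each subject subset defined by a
#' grouping label (e.g. sex, or a median split on age).
#'
#' @param table Matrix (rownames = subjects) or long data frame as in
#'   [icc_a1()].
#' @param grouping Named vector mapping subject label to group label.
#' @return Tibble `group`, `n`, `icc`, `icc_raw`, `cv`, `category`.
#' @export
subgroup_reliability <- function(table, grouping) {
  m <- as_measurement_matrix(table)
  subjects <- rownames(m) %||% as.character(seq_len(nrow(m)))
  if (!all(subjects %in% names(grouping))) {
    abort("every subject needs a group label")
  }
  groups <- split(subjects, grouping[subjects])
  purrr::map_dfr(names(groups), function(gname) {
    rows <- match(groups[[gname]], subjects)
    if (length(rows) < 2) {
      abort(sprintf("group '%s' has fewer than 2 subjects", gname))
    }
    fit <- icc_a1(m[rows, , drop = FALSE])
    tibble::tibble(
      group = gname, n = length(rows),
      icc = fit$icc, icc_raw = fit$icc_raw, cv = fit$cv, category = fit$category
    )
  })
}

#' Median split of subjects on a covariate
#'
#' Splits subjects at the median of a covariate into `"low"`/`"high"` groups
#' of (for even n) equal size, as used for the age subgrouping.
#'
#' @param covariate Named numeric vector (names = subject labels).
#' @return Named character vector of group labels.
#' @export
median_split <- function(covariate) {
  ord <- order(covariate, names(covariate))
  half <- length(covariate) %/% 2
  labels <- rep("high", length(covariate))
  labels[ord[seq_len(half)]] <- "low"
  setNames(labels, names(covariate))
}
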