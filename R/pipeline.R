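#' The eight processing strategies
#'
#' Every combination of network type (binary/weighted), global signal
#' regression (with/without) and parcellation size (90/264) gives one
#' strategy, named `B|W` + `G|NG` + atlas size (e.g. `WNG264` = weighted,
#' no GSR, 264 ROIs).
#'
#' @param names Optional subset of strategy names to keep.
#' @return Tibble `name`, `binary`, `gsr`, `n_rois`, `family` (atlas-free
#'   label, e.g. `WNG`).
#' @examples
#' method_specs()
#' method_specs(c("BG90", "WNG264"))
#' @export
method_specs <- function(names = NULL) {
  grid <- tidyr::expand_grid(
    n_rois = c(90L, 264L),
    binary = c(TRUE, FALSE),
    gsr = c(TRUE, FALSE)
  )
  specs <- dplyr::mutate(
    grid,
    family = paste0(ifelse(.data$binary, "B", "W"), ifelse(.data$gsr, "G", "NG")),
    name = paste0(.data$family, .data$n_rois)
  )
  specs <- dplyr::select(specs, "name", "binary", "gsr", "n_rois", "family")
  if (!is.null(names)) {
    missing <- setdiff(names, specs$name)
    if (length(missing) > 0) {
      abort(sprintf("unknown method(s): %s", paste(missing, collapse = ", ")))
    }
    specs <- specs[match(names, specs$name), ]
  }
  specs
}

#' Run the full test-retest reliability study
#'
#' End-to-end pipeline: simulate (or accept) the multi-session study for
#' each parcellation size, then for every processing strategy compute
#' connectivity (with or without GSR), sweep densities, compute the global
#' and nodal metrics, and assess reliability (per-density ICC with
#' threshold-averaged summaries for global metrics; AUC-based per-node ICC
#' for nodal metrics; pairwise-visit ICC), finishing with the comparison
#' statistics between strategies. Deterministic given `config$seed`.
#'
#' @param config A [sim_config()]; its `n_rois` is overridden by each
#'   method's atlas size (one dataset is simulated per distinct size, with
#'   an atlas-specific seed derived from `config$seed`).
#' @param methods Tibble from [method_specs()].
#' @param global_grid,nodal_grid Density grids; defaults are the 5-point
#'   0.15-0.35 and the 10-point 0.05-0.50 grids.
#' @param n_random Null-ensemble size per network (100 for final runs; small
#'   values give a fast approximate sweep).
#' @param studies Optional pre-simulated named list of study tibbles keyed
#'   by atlas size (`"90"`, `"264"`); bypasses simulation.
#' @param subject_info Optional tibble `subject`, `sex`, `age` used for the
#'   subgroup analyses; synthesised deterministically when absent
#'   (alternating sex, ages uniform on 22-50).
#' @return A `reliability_study` list: `config`, `methods`, `subject_info`,
#'   `metrics_global`, `metrics_nodal`, `nodal_auc`, `reliability_global`,
#'   `reliability_nodal`, `pairwise`, `comparisons` (see
#'   [compare_strategies()]).
#' @export
run_study <- function(config,
                      methods = method_specs(),
                      global_grid = density_grid(0.15, 0.35, 0.05),
                      nodal_grid = density_grid(0.05, 0.50, 0.05),
                      n_random = 100,
                      studies = NULL,
                      subject_info = NULL) {
  stopifnot(inherits(config, "sim_config"))
  atlas_sizes <- sort(unique(methods$n_rois))

  if (is.null(studies)) {
    studies <- setNames(
      purrr::map(atlas_sizes, function(a) {
        cfg <- config
        cfg$n_rois <- as.integer(a)
        cfg$seed <- item_seed(config$seed, 0L, a)
        simulate_study(cfg)
      }),
      as.character(atlas_sizes)
    )
  }

  subjects <- unique(studies[[1]]$subject)
  if (is.null(subject_info)) {
    set.seed(item_seed(config$seed, 0L, 1L))
    subject_info <- tibble::tibble(
      subject = subjects,
      sex = rep_len(c("male", "female"), length(subjects)),
      age = round(stats::runif(length(subjects), 22, 50), 1)
    )
  }

  # connectivity depends only on atlas x GSR; compute each combination once
  conn_key <- unique(methods[c("n_rois", "gsr")])
  conns <- purrr::pmap(conn_key, function(n_rois, gsr) {
    connectivity_table(studies[[as.character(n_rois)]], gsr = gsr)
  })
  names(conns) <- paste(conn_key$n_rois, conn_key$gsr)

  tables <- purrr::pmap(methods, function(name, binary, gsr, n_rois, family) {
    network_metric_table(
      conns[[paste(n_rois, gsr)]],
      method = name,
      global_grid = global_grid,
      nodal_grid = nodal_grid,
      binary = binary,
      n_random = n_random,
      seed = item_seed(config$seed, match(name, methods$name), 2L)
    )
  })

  metrics_global <- dplyr::bind_rows(purrr::map(tables, "global"))
  metrics_nodal <- dplyr::bind_rows(purrr::map(tables, "nodal"))
  nodal_auc <- nodal_auc_table(metrics_nodal)

  rel_global <- reliability_global(metrics_global)
  rel_nodal <- reliability_nodal(nodal_auc)
  pairwise <- pairwise_visit_table(metrics_global)

  comparisons <- compare_strategies(
    rel_global, rel_nodal, pairwise, metrics_global, methods, subject_info
  )

  structure(
    list(
      config = config,
      methods = methods,
      subject_info = subject_info,
      global_grid = as.numeric(global_grid),
      nodal_grid = as.numeric(nodal_grid),
      n_random = n_random,
      metrics_global = metrics_global,
      metrics_nodal = metrics_nodal,
      nodal_auc = nodal_auc,
      reliability_global = rel_global,
      reliability_nodal = rel_nodal,
      pairwise = pairwise,
      comparisons = comparisons
    ),
    class = "reliability_study"
  )
}

#' @export
print.reliability_study <- function(x, ...) {
  cat(sprintf(
    "<reliability_study> %d methods, %d subjects x %d sessions, seed %d\n",
    nrow(x$methods), x$config$n_subjects, x$config$n_sessions, x$config$seed
  ))
  cat(sprintf(
    "  global reliability rows: %d; nodal reliability rows: %d\n",
    nrow(x$reliability_global), nrow(x$reliability_nodal)
  ))
  invisible(x)
}

#' Pairwise-visit (k = 2) reliability averaged over the global grid
#'
#' For every method, metric and pair of sessions, computes the per-density
#' ICC(A,1) on the two-session sub-table and averages the clamped estimates
#' over the densities.
#'
#' @param global_tbl The `global` metric tibble of a run.
#' @return Tibble `method`, `metric`, `pair` (e.g. `"ses1-ses2"`), `icc`,
#'   `icc_raw`.
#' @export
pairwise_visit_table <- function(global_tbl) {
  sessions <- sort(unique(global_tbl$session))
  pairs <- utils::combn(sessions, 2, simplify = FALSE)
  purrr::map_dfr(pairs, function(pr) {
    sub <- dplyr::filter(global_tbl, .data$session %in% pr)
    out <- sub |>
      dplyr::group_by(.data$method, .data$metric, .data$density) |>
      dplyr::group_modify(function(df, key) {
        fit <- icc_a1(df[c("subject", "session", "value")])
        tibble::tibble(icc = fit$icc, icc_raw = fit$icc_raw)
      }) |>
      dplyr::ungroup() |>
      dplyr::group_by(.data$method, .data$metric) |>
      dplyr::summarise(
        icc = mean(.data$icc), icc_raw = mean(.data$icc_raw), .groups = "drop"
      )
    out$pair <- paste(pr, collapse = "-")
    out
  }) |>
    dplyr::select("method", "metric", "pair", "icc", "icc_raw")
}

#' Comparison statistics between processing strategies
#'
#' Reproduces the study's comparison battery on the computed reliability
#' tables:
#' * threshold effect: one-way repeated-measures ANOVA (GG-corrected) on the
#'   per-density global ICCs, cases = method-by-metric cells;
#' * paired t-tests of threshold-averaged global ICC for the three
#'   strategy contrasts (binary vs weighted, GSR vs none, 90 vs 264 ROIs),
#'   pooling metrics by strategy pairings (7 metrics x 4 pairings, df 27);
#' * two-way repeated-measures ANOVA of the pairwise-visit ICCs with
#'   inter-scan interval (3 pairs) and method family (4 levels, atlas
#'   variants averaged) as within factors, cases = the 7 metrics;
#' * per-family one-way repeated-measures ANOVA of interval;
#' * subgroup (sex, age median split) ICCs and their paired t-tests pooled
#'   over metric-by-method cells (df 55 for 8 methods x 7 metrics);
#' * per-metric between-groups ANOVA of nodal ICCs across all methods
#'   (nodes as observations), and a paired t-test of nodal ICC with vs
#'   without GSR matched on atlas, network type, metric and node.
#'
#' @param rel_global,rel_nodal,pairwise Reliability tables of a run.
#' @param metrics_global Global metric tibble (for the subgroup ICCs).
#' @param methods [method_specs()] tibble used in the run.
#' @param subject_info Tibble `subject`, `sex`, `age`.
#' @return Named list: `threshold_effect`, `strategy_ttests`,
#'   `interval_by_method`, `interval_per_family`, `subgroup` (list with
#'   `icc` table and `ttests`), `nodal_anova`, `nodal_gsr_ttest`.
#' @export
compare_strategies <- function(rel_global, rel_nodal, pairwise,
                               metrics_global, methods, subject_info) {
  mean_rows <- dplyr::filter(rel_global, .data$density == "mean")

  # threshold effect: cases are method x metric, levels are densities
  per_density <- dplyr::filter(rel_global, .data$density != "mean")
  thr_wide <- tidyr::pivot_wider(
    per_density[c("method", "metric", "density", "icc")],
    names_from = "density", values_from = "icc"
  )
  threshold_effect <- if (ncol(thr_wide) - 2 >= 2) {
    rm_anova_1way(as.matrix(thr_wide[-(1:2)]), effect = "density")
  }

  atlas_sides <- sort(unique(methods$n_rois))
  strategy_ttests <- dplyr::bind_rows(
    strategy_ttest(mean_rows, methods, "binary", c(`TRUE` = "binary", `FALSE` = "weighted")),
    strategy_ttest(mean_rows, methods, "gsr", c(`TRUE` = "GSR", `FALSE` = "no-GSR")),
    strategy_ttest(
      mean_rows, methods, "n_rois",
      setNames(paste(atlas_sides, "ROIs"), atlas_sides)
    )
  )

  # interval x family: average the two atlas variants of each family
  fam <- setNames(methods$family, methods$name)
  pw_fam <- pairwise |>
    dplyr::mutate(family = fam[.data$method]) |>
    dplyr::group_by(.data$metric, .data$pair, .data$family) |>
    dplyr::summarise(icc = mean(.data$icc), .groups = "drop")
  metrics_lev <- sort(unique(pw_fam$metric))
  pair_lev <- sort(unique(pw_fam$pair))
  fam_lev <- sort(unique(pw_fam$family))
  arr <- array(
    NA_real_,
    dim = c(length(metrics_lev), length(pair_lev), length(fam_lev)),
    dimnames = list(metrics_lev, pair_lev, fam_lev)
  )
  arr[cbind(
    match(pw_fam$metric, metrics_lev),
    match(pw_fam$pair, pair_lev),
    match(pw_fam$family, fam_lev)
  )] <- pw_fam$icc
  interval_by_method <- if (min(dim(arr)) >= 2) {
    rm_anova_2way(arr, effects = c("interval", "method"))
  }

  interval_per_family <- purrr::map_dfr(fam_lev, function(f) {
    w <- tidyr::pivot_wider(
      dplyr::filter(pw_fam, .data$family == f)[c("metric", "pair", "icc")],
      names_from = "pair", values_from = "icc"
    )
    out <- rm_anova_1way(as.matrix(w[-1]), effect = "interval")
    out$effect <- paste0("interval (", f, ")")
    out
  })

  subgroup <- subgroup_comparison(metrics_global, subject_info)

  nodal_anova <- rel_nodal |>
    dplyr::group_by(.data$metric) |>
    dplyr::group_modify(function(df, key) nodal_method_anova(df)) |>
    dplyr::ungroup()

  nodal_gsr_ttest <- nodal_gsr_comparison(rel_nodal, methods)

  list(
    threshold_effect = threshold_effect,
    strategy_ttests = strategy_ttests,
    interval_by_method = interval_by_method,
    interval_per_family = interval_per_family,
    subgroup = subgroup,
    nodal_anova = nodal_anova,
    nodal_gsr_ttest = nodal_gsr_ttest
  )
}

# Paired t-test for one strategy toggle, pooling (metric, strategy-pairing)
# cells: methods identical in everything but `toggle` are paired.
strategy_ttest <- function(mean_rows, methods, toggle, labels) {
  if (length(labels) != 2) {
    return(NULL) # toggle has a single level in this method subset
  }
  key_cols <- setdiff(c("binary", "gsr", "n_rois"), toggle)
  meth <- dplyr::mutate(
    methods,
    pairing = paste(.data[[key_cols[1]]], .data[[key_cols[2]]]),
    side = as.character(.data[[toggle]])
  )
  joined <- dplyr::inner_join(
    mean_rows[c("method", "metric", "icc")],
    meth[c("name", "pairing", "side")],
    by = c(method = "name")
  )
  wide <- tidyr::pivot_wider(
    joined[c("metric", "pairing", "side", "icc")],
    names_from = "side", values_from = "icc"
  )
  sides <- names(labels)
  if (!all(sides %in% names(wide))) {
    return(NULL) # toggle not represented in this method subset
  }
  wide <- tidyr::drop_na(wide, dplyr::all_of(sides))
  if (nrow(wide) < 2) {
    return(NULL)
  }
  out <- paired_t(wide[[sides[1]]], wide[[sides[2]]], labels = unname(labels))
  out$test <- "paired-t (threshold-averaged ICC)"
  out
}

# Subgroup (sex and age median split) ICCs per (method, metric), threshold-
# averaged, plus paired t-tests across the pooled metric-by-method cells.
subgroup_comparison <- function(metrics_global, subject_info) {
  age_cov <- setNames(subject_info$age, subject_info$subject)
  groupings <- list(
    sex = setNames(subject_info$sex, subject_info$subject),
    age = c(low = "younger", high = "older")[median_split(age_cov)] |>
      setNames(subject_info$subject)
  )
  icc_tbl <- purrr::imap_dfr(groupings, function(grouping, split_name) {
    metrics_global |>
      dplyr::group_by(.data$method, .data$metric, .data$density) |>
      dplyr::group_modify(function(df, key) {
        sub <- subgroup_reliability(df[c("subject", "session", "value")], grouping)
        sub[c("group", "icc")]
      }) |>
      dplyr::ungroup() |>
      dplyr::group_by(.data$method, .data$metric, .data$group) |>
      dplyr::summarise(icc = mean(.data$icc), .groups = "drop") |>
      dplyr::mutate(split = split_name)
  })
  ttests <- icc_tbl |>
    dplyr::group_by(.data$split) |>
    dplyr::group_modify(function(df, key) {
      wide <- tidyr::pivot_wider(df, names_from = "group", values_from = "icc")
      grp <- setdiff(names(wide), c("method", "metric"))
      paired_t(wide[[grp[1]]], wide[[grp[2]]], labels = grp)
    }) |>
    dplyr::ungroup()
  list(icc = icc_tbl, ttests = ttests)
}

# Nodal GSR effect: pair ICCs with/without GSR matched on atlas, network
# type, metric and node.
nodal_gsr_comparison <- function(rel_nodal, methods) {
  meth <- dplyr::mutate(
    methods,
    key = paste(.data$binary, .data$n_rois)
  )
  joined <- dplyr::inner_join(
    rel_nodal[c("method", "metric", "node", "icc")],
    meth[c("name", "key", "gsr")],
    by = c(method = "name")
  )
  wide <- tidyr::pivot_wider(
    joined[c("metric", "node", "key", "gsr", "icc")],
    names_from = "gsr", values_from = "icc"
  )
  if (!all(c("TRUE", "FALSE") %in% names(wide))) {
    return(NULL)
  }
  wide <- tidyr::drop_na(wide, "TRUE", "FALSE")
  if (nrow(wide) < 2) {
    return(NULL)
  }
  out <- paired_t(wide[["TRUE"]], wide[["FALSE"]], labels = c("GSR", "no-GSR"))
  out$test <- "paired-t (nodal ICC)"
  out
}

#' Write the result tables of a study run as CSV files
#'
#' Writes `reliability_global.csv`, `reliability_nodal.csv`, `pairwise.csv`,
#' `metrics_global.csv`, `metrics_nodal_auc.csv`, `comparisons.csv` and a
#' `run_metadata.yaml` provenance block (seed, grids, methods, ensemble
#' size, analysis conventions). Identical runs produce byte-identical files.
#'
#' @param result A `reliability_study` from [run_study()].
#' @param dir Output directory; created if missing.
#' @return `dir`, invisibly.
#' @export
write_study_results <- function(result, dir) {
  stopifnot(inherits(result, "reliability_study"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  w <- function(x, f) readr::write_csv(x, file.path(dir, f), progress = FALSE)
  w(result$reliability_global, "reliability_global.csv")
  w(result$reliability_nodal, "reliability_nodal.csv")
  w(result$pairwise, "pairwise.csv")
  w(result$metrics_global, "metrics_global.csv")
  w(result$nodal_auc, "metrics_nodal_auc.csv")
  cmp <- result$comparisons
  w(
    dplyr::bind_rows(
      cmp$threshold_effect,
      cmp$strategy_ttests,
      cmp$interval_by_method,
      cmp$interval_per_family,
      cmp$subgroup$ttests |>
        dplyr::mutate(effect = paste0("subgroup ", .data$split, ": ", .data$effect)) |>
        dplyr::select(-"split"),
      dplyr::mutate(cmp$nodal_anova, effect = paste0("nodal method (", .data$metric, ")"))[
        , c("test", "effect", "statistic", "df1", "df2", "p", "epsilon")
      ],
      cmp$nodal_gsr_ttest
    ),
    "comparisons.csv"
  )
  yaml::write_yaml(
    list(
      seed = result$config$seed,
      config = unclass(result$config),
      methods = result$methods$name,
      global_grid = result$global_grid,
      nodal_grid = result$nodal_grid,
      n_random = result$n_random,
      conventions = list(
        edge_weights = "raw Pearson correlations (no Fisher z before thresholding)",
        negative_correlations = "never retained as edges",
        edge_count_rounding = "round half up, ties by (row, col) index",
        weighted_distance = "1/weight",
        weighted_clustering = "Onnela geometric mean, weights normalised by network maximum",
        disconnected_pairs = "excluded from Lp; 1/Inf = 0 in efficiencies",
        icc_reporting = "clamped at 0; raw estimate retained",
        cv = "sample SD (k-1), percent"
      )
    ),
    file.path(dir, "run_metadata.yaml")
  )
  invisible(dir)
}
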