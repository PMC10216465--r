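#' Single-measure absolute-agreement intraclass correlation, ICC(A,1)
#'
#' Two-way random-effects decomposition of a complete subjects-by-sessions
#' table into between-subject (BMS), between-session (JMS) and residual
#' (EMS) mean squares, combined as
#'
#' \deqn{ICC(A,1) = \frac{BMS - EMS}{BMS + (k-1)\,EMS + (JMS - EMS)\,k/n}}
#'
#' with `n` subjects and `k` sessions. The signed estimate is kept as
#' `icc_raw`; the reported `icc` is clamped at 0. Categories follow the
#' Winer bands: < 0.25 poor, 0.25-0.4 low, 0.4-0.6 fair, 0.6-0.75 good,
#' 0.75-1 excellent.
#'
#' @param table Numeric matrix (subjects as rows, sessions as columns) or a
#'   data frame with columns `subject`, `session`, `value` forming a
#'   complete two-way layout.
#' @return An object of class `icc_a1` with fields `icc`, `icc_raw`, `cv`
#'   (mean within-subject coefficient of variation, percent; `NA` if any
#'   subject mean is 0), `category`, `n`, `k` and `components` (BMS, JMS,
#'   EMS and their degrees of freedom). Has [tidy()] and [glance()] methods.
#' @examples
#' m <- matrix(c(1, 2, 3, 2, 3, 4, 3, 4, 5, 4, 5, 6), 4, 3, byrow = TRUE)
#' icc_a1(m)$icc # 0.625
#' @export
icc_a1 <- function(table) {
  m <- as_measurement_matrix(table)
  n <- nrow(m)
  k <- ncol(m)
  if (n < 2 || k < 2) {
    abort("ICC(A,1) needs >= 2 subjects and >= 2 sessions")
  }
  grand <- mean(m)
  if (all(m == m[1])) {
    abort("degenerate table: zero total variance")
  }
  row_m <- rowMeans(m)
  col_m <- colMeans(m)
  ss_subj <- k * sum((row_m - grand)^2)
  ss_sess <- n * sum((col_m - grand)^2)
  ss_tot <- sum((m - grand)^2)
  ss_err <- ss_tot - ss_subj - ss_sess
  bms <- ss_subj / (n - 1)
  jms <- ss_sess / (k - 1)
  ems <- ss_err / ((n - 1) * (k - 1))
  icc_raw <- (bms - ems) / (bms + (k - 1) * ems + (jms - ems) * k / n)
  icc <- min(max(icc_raw, 0), 1)
  cv <- tryCatch(coefficient_of_variation(m)$mean_cv, error = function(e) NA_real_)
  structure(
    list(
      icc = icc,
      icc_raw = icc_raw,
      cv = cv,
      category = icc_category(icc),
      n = n, k = k,
      components = list(
        BMS = bms, JMS = jms, EMS = ems,
        df_subject = n - 1, df_session = k - 1, df_error = (n - 1) * (k - 1)
      )
    ),
    class = "icc_a1"
  )
}

icc_category <- function(icc) {
  cut(icc,
    breaks = c(-Inf, 0.25, 0.4, 0.6, 0.75, Inf),
    labels = c("poor", "low", "fair", "good", "excellent"),
    right = FALSE
  ) |> as.character()
}

as_measurement_matrix <- function(table) {
  if (is.matrix(table)) {
    if (anyNA(table)) abort("measurement table must be complete (no missing cells)")
    return(table)
  }
  df <- as.data.frame(table)
  stopifnot(all(c("subject", "session", "value") %in% names(df)))
  wide <- tidyr::pivot_wider(
    df[c("subject", "session", "value")],
    names_from = "session", values_from = "value"
  )
  m <- as.matrix(wide[-1])
  rownames(m) <- as.character(wide$subject)
  if (anyNA(m)) abort("measurement table must be complete (no missing cells)")
  m
}

#' @export
print.icc_a1 <- function(x, ...) {
  cat(sprintf(
    "ICC(A,1) = %.3f (%s; raw %.3f), n = %d subjects, k = %d sessions, CV = %.1f%%\n",
    x$icc, x$category, x$icc_raw, x$n, x$k, x$cv
  ))
  invisible(x)
}

#' @rdname icc_a1
#' @param x An `icc_a1` object.
#' @param ... Unused.
#' @export
tidy.icc_a1 <- function(x, ...) {
  tibble::tibble(
    term = c("subjects", "sessions", "residual"),
    meansq = c(x$components$BMS, x$components$JMS, x$components$EMS),
    df = c(x$components$df_subject, x$components$df_session, x$components$df_error)
  )
}

#' @rdname icc_a1
#' @export
glance.icc_a1 <- function(x, ...) {
  tibble::tibble(
    icc = x$icc, icc_raw = x$icc_raw, cv = x$cv, category = x$category,
    n = x$n, k = x$k
  )
}

#' Within-subject coefficient of variation
#'
#' For each subject, `CV = S / M` where `S` is the sample (k-1 denominator)
#' standard deviation of its session values and `M` their mean; reported as
#' a percentage, plus the average over subjects.
#'
#' @param table Matrix or long data frame as in [icc_a1()].
#' @return List with `cv` (per-subject percentages, named) and `mean_cv`.
#' @examples
#' coefficient_of_variation(matrix(c(2, 4, 6), 1, 3))$cv # 50
#' @export
coefficient_of_variation <- function(table) {
  m <- as_measurement_matrix(table)
  means <- rowMeans(m)
  if (any(means == 0)) {
    bad <- rownames(m)[means == 0] %||% as.character(which(means == 0))
    abort(sprintf("zero within-subject mean for subject(s): %s", paste(bad, collapse = ", ")))
  }
  sds <- apply(m, 1, sd)
  cv <- 100 * sds / means
  list(cv = cv, mean_cv = mean(cv))
}

#' Area under a metric-versus-density curve
#'
#' Trapezoidal integral of the metric values over the density grid points;
#' no interpolation beyond the grid.
#'
#' @param values Finite metric values, one per grid point.
#' @param grid Densities (same length as `values`, >= 2 points).
#' @return Scalar AUC.
#' @examples
#' auc_over_densities(rep(2, 10), density_grid(0.05, 0.5, 0.05)) # 0.9
#' @export
auc_over_densities <- function(values, grid) {
  grid <- as.numeric(grid)
  if (length(values) != length(grid) || length(grid) < 2) {
    abort("need >= 2 grid points and one value per point")
  }
  if (any(!is.finite(values))) {
    abort("metric values must be finite for AUC")
  }
  pracma::trapz(grid, values)
}
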