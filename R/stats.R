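#' Paired t-test between two reliability samples
#'
#' Thin wrapper around [stats::t.test()] (paired, two-sided) returning a
#' broom-style one-row tibble; errors on zero-variance differences, where
#' the statistic is undefined.
#'
#' @param x,y Paired numeric vectors of equal length >= 2.
#' @param labels Optional length-2 labels for the two conditions.
#' @return Tibble `test`, `effect`, `statistic`, `df1`, `df2`, `p`,
#'   `epsilon` (the ANOVA columns are `NA` here).
#' @export
paired_t <- function(x, y, labels = c("x", "y")) {
  stopifnot(length(x) == length(y), length(x) >= 2)
  if (sd(x - y) == 0) {
    abort("zero variance of paired differences: t statistic undefined")
  }
  fit <- t.test(x, y, paired = TRUE)
  comparison_row(
    "paired-t", paste(labels, collapse = " vs "),
    unname(fit$statistic), unname(fit$parameter), NA_real_, fit$p.value
  )
}

comparison_row <- function(test, effect, statistic, df1, df2, p, epsilon = NA_real_) {
  tibble::tibble(
    test = test, effect = effect, statistic = statistic,
    df1 = df1, df2 = df2, p = p, epsilon = epsilon
  )
}

# Greenhouse-Geisser epsilon from the covariance of within-subject scores.
# `z` is cases x levels; epsilon uses the eigenvalues of the double-centered
# covariance (equivalently, of orthonormal-contrast-transformed scores).
gg_epsilon <- function(z) {
  p <- ncol(z)
  cmat <- diag(p) - 1 / p
  s <- cmat %*% stats::cov(z) %*% cmat
  tr <- sum(diag(s))
  if (tr <= 0) {
    return(1)
  }
  max(min((tr^2) / ((p - 1) * sum(s * s)), 1), 1 / (p - 1))
}

# Epsilon from already contrast-transformed scores (cases x d); no further
# centering across columns.
gg_epsilon_contrast <- function(z) {
  d <- ncol(z)
  s <- stats::cov(z)
  tr <- sum(diag(s))
  if (tr <= 0) {
    return(1)
  }
  max(min((tr^2) / (d * sum(s * s)), 1), 1 / d)
}

#' One-way repeated-measures ANOVA with Greenhouse-Geisser correction
#'
#' Explicit sums-of-squares within-subject F-test for a complete
#' cases-by-levels layout; degrees of freedom are multiplied by the
#' Greenhouse-Geisser epsilon estimated from the level covariance matrix,
#' giving the fractional dfs conventional for repeated-measures designs.
#'
#' @param values Numeric matrix, cases as rows and within-subject levels as
#'   columns (complete, >= 2 cases, >= 2 levels).
#' @param effect Label for the within-subject factor.
#' @return One-row tibble as in [paired_t()], with `df1`, `df2` the
#'   epsilon-corrected degrees of freedom and `epsilon` the estimate.
#' @export
rm_anova_1way <- function(values, effect = "level") {
  values <- as.matrix(values)
  n <- nrow(values)
  a <- ncol(values)
  if (n < 2 || a < 2 || anyNA(values)) {
    abort("need a complete cases x levels matrix with >= 2 of each")
  }
  grand <- mean(values)
  col_m <- colMeans(values)
  row_m <- rowMeans(values)
  ss_a <- n * sum((col_m - grand)^2)
  resid <- values - outer(row_m, rep(1, a)) - outer(rep(1, n), col_m) + grand
  ss_as <- sum(resid^2)
  tol <- 1e-12 * sum((values - grand)^2)
  if (ss_a <= tol) {
    # no level effect at all: F is 0 by convention even when the error term
    # is degenerate (identical columns)
    return(comparison_row(
      "rm-anova-1way", effect, 0, a - 1, (a - 1) * (n - 1), 1, 1
    ))
  }
  if (ss_as <= tol) {
    abort("degenerate within-subject covariance: zero error sum of squares")
  }
  ms_a <- ss_a / (a - 1)
  ms_as <- ss_as / ((a - 1) * (n - 1))
  f <- ms_a / ms_as
  eps <- gg_epsilon(values)
  df1 <- eps * (a - 1)
  df2 <- eps * (a - 1) * (n - 1)
  comparison_row(
    "rm-anova-1way", effect, f, df1, df2,
    pf(f, df1, df2, lower.tail = FALSE), eps
  )
}

orthonormal_contrasts <- function(p) {
  cmat <- stats::contr.helmert(p)
  sweep(cmat, 2, sqrt(colSums(cmat^2)), "/")
}

#' Two-way repeated-measures ANOVA with Greenhouse-Geisser correction
#'
#' Fully within-subject two-factor design with one observation per case and
#' cell: explicit sums of squares for both main effects and the interaction,
#' each tested against its own effect-by-case error term, with a
#' Greenhouse-Geisser epsilon per effect (estimated from the covariance of
#' the orthonormal-contrast scores of that effect).
#'
#' @param values 3-d numeric array, `cases x levelsA x levelsB`, complete.
#' @param effects Length-2 labels for the two factors.
#' @return Tibble with three rows (`A`, `B`, `A:B`) in the format of
#'   [paired_t()].
#' @export
rm_anova_2way <- function(values, effects = c("A", "B")) {
  stopifnot(length(dim(values)) == 3)
  n <- dim(values)[1]
  a <- dim(values)[2]
  b <- dim(values)[3]
  if (n < 2 || a < 2 || b < 2 || anyNA(values)) {
    abort("need a complete cases x levelsA x levelsB array with >= 2 in each dimension")
  }
  grand <- mean(values)
  m_a <- apply(values, 2, mean)
  m_b <- apply(values, 3, mean)
  m_s <- apply(values, 1, mean)
  m_ab <- apply(values, c(2, 3), mean)
  m_sa <- apply(values, c(1, 2), mean)
  m_sb <- apply(values, c(1, 3), mean)

  ss_a <- n * b * sum((m_a - grand)^2)
  ss_b <- n * a * sum((m_b - grand)^2)
  ss_s <- a * b * sum((m_s - grand)^2)
  ss_as <- b * sum((m_sa - outer(m_s, rep(1, a)) - outer(rep(1, n), m_a) + grand)^2)
  ss_bs <- a * sum((m_sb - outer(m_s, rep(1, b)) - outer(rep(1, n), m_b) + grand)^2)
  ss_ab <- n * sum((m_ab - outer(m_a, rep(1, b)) - outer(rep(1, a), m_b) + grand)^2)
  ss_tot <- sum((values - grand)^2)
  ss_abs <- ss_tot - ss_a - ss_b - ss_s - ss_as - ss_bs - ss_ab

  tol <- 1e-12 * ss_tot
  eff_row <- function(label, ss_eff, df_eff, ss_err, df_err, eps) {
    if (ss_eff <= tol) {
      return(comparison_row("rm-anova-2way", label, 0, df_eff, df_err, 1, 1))
    }
    if (ss_err <= tol) {
      abort(sprintf("degenerate covariance for effect %s", label))
    }
    f <- (ss_eff / df_eff) / (ss_err / df_err)
    df1 <- eps * df_eff
    df2 <- eps * df_err
    comparison_row(
      "rm-anova-2way", label, f, df1, df2,
      pf(f, df1, df2, lower.tail = FALSE), eps
    )
  }

  ca <- orthonormal_contrasts(a)
  cb <- orthonormal_contrasts(b)
  z_ab <- t(apply(values, 1, function(y) as.vector(t(ca) %*% matrix(y, a, b) %*% cb)))
  if (nrow(z_ab) != n) z_ab <- t(z_ab) # single-contrast case returns a row
  dplyr::bind_rows(
    eff_row(effects[1], ss_a, a - 1, ss_as, (a - 1) * (n - 1), gg_epsilon(m_sa)),
    eff_row(effects[2], ss_b, b - 1, ss_bs, (b - 1) * (n - 1), gg_epsilon(m_sb)),
    eff_row(
      paste(effects, collapse = ":"), ss_ab, (a - 1) * (b - 1),
      ss_abs, (a - 1) * (b - 1) * (n - 1), gg_epsilon_contrast(z_ab)
    )
  )
}

#' Bonferroni adjustment
#'
#' `p_adj = min(1, p * m)`, via [stats::p.adjust()].
#'
#' @param pvalues Numeric vector of p-values.
#' @param m Number of comparisons (default `length(pvalues)`).
#' @return Adjusted p-values.
#' @export
posthoc_bonferroni <- function(pvalues, m = length(pvalues)) {
  p.adjust(pvalues, method = "bonferroni", n = m)
}

#' Between-groups one-way ANOVA of nodal reliabilities across methods
#'
#' Treats nodes as observations and the processing strategy as a
#' between-groups factor (group sizes may differ, e.g. 90 versus 264
#' nodes), using [stats::aov()].
#'
#' @param nodal_icc Data frame with columns `method` and `icc` (one row per
#'   node-method cell), typically one metric's slice of
#'   [reliability_nodal()].
#' @return One-row tibble as in [paired_t()].
#' @export
nodal_method_anova <- function(nodal_icc) {
  df <- as.data.frame(nodal_icc)
  stopifnot(all(c("method", "icc") %in% names(df)))
  counts <- table(df$method)
  if (any(counts == 0)) {
    abort("every method group must be non-empty")
  }
  if (var(df$icc) == 0) {
    abort("all nodal ICCs identical: F undefined")
  }
  fit <- summary(aov(icc ~ factor(method), data = df))[[1]]
  comparison_row(
    "anova-between", "method",
    fit[["F value"]][1], fit[["Df"]][1], fit[["Df"]][2], fit[["Pr(>F)"]][1]
  )
}
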