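#' Simulate a multi-subject, multi-session ROI time-series study
#'
#' Draws one timepoints-by-ROIs matrix per subject-session under a
#' variance-components model on the Fisher-z correlation scale, so the
#' ground-truth edgewise reliability is known by construction:
#'
#' 1. a population latent-connectivity matrix with mean `base_connectivity`
#'    and SD `sigma_edge` on the off-diagonal (z scale), minus
#'    `anticorr_strength` on edges that cross the anticorrelated-system
#'    boundary (see [sim_config()]);
#' 2. per subject, symmetric zero-mean deviations with SD `sigma_between`;
#' 3. per subject-session, symmetric zero-mean deviations with SD
#'    `sigma_within`;
#' 4. back-transform (`tanh`) to correlations and project to the nearest
#'    valid correlation matrix (eigenvalue clipping at 1e-8, rescaled to unit
#'    diagonal);
#' 5. sample a stationary AR(1) Gaussian series whose marginal correlation is
#'    that matrix;
#' 6. add `global_amplitude` times a shared scalar AR(1) process to every
#'    column.
#'
#' Each subject-session uses its own RNG stream with seed
#' `(seed + 100003 * subject_index + 1009 * session_index) mod (2^31 - 1)`
#' (session index 0 is the subject-level stream, subject index 0 the
#' population stream), so any single item can be regenerated without
#' replaying the whole study.
#'
#' @param config A [sim_config()].
#' @return A tibble with one row per subject-session: `subject`, `session`
#'   (labels `sub01`, `ses1`, ...), and `ts`, a list-column of
#'   timepoints-by-ROIs matrices with ROI column names `roi001`, ....
#' @examples
#' study <- simulate_study(sim_config(4, 2, 80, 10, seed = 7))
#' study
#' dim(study$ts[[1]])
#' @seealso [write_study()] to materialise the study as TSV files.
#' @export
simulate_study <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  n_rois <- config$n_rois
  roi_labels <- sprintf("roi%03d", seq_len(n_rois))

  # deterministic two-system structure: the last `anticorr_fraction` of ROIs
  # form an anticorrelated system; between-system edges are weakened
  n_anti <- round(config$anticorr_fraction * n_rois)
  system_of <- rep(c(1L, 2L), c(n_rois - n_anti, n_anti))
  between <- outer(system_of, system_of, `!=`)
  z_pop <- local({
    set.seed(item_seed(config$seed, 0L, 0L))
    z <- sym_noise(n_rois, config$sigma_edge) +
      off_diag_const(n_rois, config$base_connectivity)
    z[between] <- z[between] - config$anticorr_strength
    z
  })

  grid <- tidyr::expand_grid(
    subject = seq_len(config$n_subjects),
    session = seq_len(config$n_sessions)
  )

  subj_dev <- purrr::map(seq_len(config$n_subjects), function(s) {
    set.seed(item_seed(config$seed, s, 0L))
    sym_noise(n_rois, config$sigma_between)
  })

  ts_list <- purrr::pmap(grid, function(subject, session) {
    set.seed(item_seed(config$seed, subject, session))
    z <- z_pop + subj_dev[[subject]] + sym_noise(n_rois, config$sigma_within)
    r <- tanh(z)
    diag(r) <- 1
    r <- nearest_correlation(r)
    x <- tryCatch(
      ar1_mvn_series(config$n_timepoints, r, config$ar1_coef),
      error = function(e) {
        abort(sprintf(
          "degenerate correlation target for subject %d, session %d: %s",
          subject, session, conditionMessage(e)
        ))
      }
    )
    if (config$global_amplitude > 0) {
      g <- ar1_series(config$n_timepoints, config$ar1_coef)
      x <- x + config$global_amplitude * g
    }
    colnames(x) <- roi_labels
    x
  })

  tibble::tibble(
    subject = sprintf("sub%02d", grid$subject),
    session = sprintf("ses%d", grid$session),
    ts = ts_list
  )
}

# Deterministic per-item RNG stream key (documented in ?simulate_study).
item_seed <- function(master, subject_index, session_index) {
  as.integer((as.numeric(master) +
    100003 * subject_index +
    1009 * session_index) %% (2^31 - 1))
}

# Symmetric zero-diagonal Gaussian noise matrix with edgewise SD `sigma`.
sym_noise <- function(n, sigma) {
  m <- matrix(0, n, n)
  if (sigma > 0) {
    ut <- upper.tri(m)
    m[ut] <- rnorm(sum(ut), sd = sigma)
    m <- m + t(m)
  }
  m
}

off_diag_const <- function(n, value) {
  m <- matrix(value, n, n)
  diag(m) <- 0
  m
}

#' Project a symmetric matrix to a nearby valid correlation matrix
#'
#' Clips eigenvalues below `floor` and rescales to unit diagonal; the standard
#' deterministic nearest-correlation surrogate.
#'
#' @param s Symmetric matrix.
#' @param floor Eigenvalue floor (default 1e-8).
#' @return A symmetric positive-definite matrix with unit diagonal.
#' @keywords internal
#' @export
nearest_correlation <- function(s, floor = 1e-8) {
  e <- eigen((s + t(s)) / 2, symmetric = TRUE)
  vals <- pmax(e$values, floor)
  r <- e$vectors %*% (vals * t(e$vectors))
  d <- sqrt(diag(r))
  r <- r / tcrossprod(d)
  r <- (r + t(r)) / 2
  diag(r) <- 1
  r
}

# Stationary AR(1) vector series with marginal correlation matrix `r`.
ar1_mvn_series <- function(n_t, r, phi) {
  l <- chol(r)
  n <- ncol(r)
  eps <- matrix(rnorm(n_t * n), n_t, n) %*% l
  if (phi == 0) {
    return(eps)
  }
  x <- matrix(0, n_t, n)
  x[1, ] <- eps[1, ]
  scl <- sqrt(1 - phi^2)
  for (t in 2:n_t) {
    x[t, ] <- phi * x[t - 1, ] + scl * eps[t, ]
  }
  x
}

# Stationary scalar AR(1) with unit marginal variance.
ar1_series <- function(n_t, phi) {
  as.vector(ar1_mvn_series(n_t, matrix(1, 1, 1), phi))
}
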