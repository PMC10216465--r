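#' Simulation design for a multi-session test-retest study
#'
#' Bundles the design constants and variance components of the synthetic
#' resting-state study emulated by [simulate_study()]. The defaults mirror a
#' 16-subject, 3-session, 210-timepoint design with a 90-region parcellation.
#'
#' Connectivity is modelled on the Fisher-z scale, where additive variance
#' components are well defined: every subject-session target correlation
#' matrix is built as `population + subject deviation + session deviation`,
#' then back-transformed and repaired to the nearest valid correlation matrix.
#'
#' @param n_subjects Number of subjects (>= 2).
#' @param n_sessions Number of repeated sessions per subject (>= 2).
#' @param n_timepoints Number of timepoints per scan (>= 2).
#' @param n_rois Number of regions of interest; 90 (AAL-style) and 264
#'   (Power-style) are the two parcellation sizes the pipeline compares.
#' @param base_connectivity Mean edge strength on the Fisher-z scale.
#' @param sigma_edge SD of population-level edge heterogeneity (z scale).
#'   Zero makes every edge exchangeable; a positive value gives the stable
#'   edge-rank structure real connectomes have.
#' @param anticorr_fraction Fraction of ROIs assigned to an anticorrelated
#'   system (task-negative versus task-positive organisation). Edges between
#'   the two systems have their latent strength reduced by
#'   `anticorr_strength`. This left-skews the edge distribution, which is
#'   what keeps a majority of edges positive after global signal regression
#'   (GSR residuals sum to zero, so their mean covariance is necessarily
#'   negative); without it, proportional thresholds near 0.5 would be
#'   unreachable after GSR.
#' @param anticorr_strength Latent (z-scale) reduction applied to
#'   between-system edges.
#' @param sigma_between SD of subject-level edge deviations (z scale); the
#'   trait signal that test-retest reliability should detect.
#' @param sigma_within SD of session-level edge deviations (z scale); the
#'   state noise that degrades reliability.
#' @param global_amplitude SD of a shared scalar signal added to every ROI
#'   column, in units of the (unit) ROI signal SD. Set 0 to disable.
#' @param ar1_coef Lag-1 temporal autocorrelation of both the ROI signals and
#'   the global signal, in `[0, 1)`.
#' @param seed Master RNG seed; every subject-session draws from its own
#'   stream derived from it (see [simulate_study()]).
#'
#' @return An object of class `sim_config` (a validated named list).
#' @examples
#' sim_config(n_subjects = 4, n_sessions = 3, n_timepoints = 60, n_rois = 10)
#' @export
sim_config <- function(n_subjects = 16,
                       n_sessions = 3,
                       n_timepoints = 210,
                       n_rois = 90,
                       base_connectivity = 0.25,
                       sigma_edge = 0.15,
                       anticorr_fraction = 0.2,
                       anticorr_strength = 0.6,
                       sigma_between = 0.12,
                       sigma_within = 0.06,
                       global_amplitude = 0.5,
                       ar1_coef = 0.3,
                       seed = 1L) {
  counts <- c(
    n_subjects = n_subjects, n_sessions = n_sessions,
    n_timepoints = n_timepoints, n_rois = n_rois
  )
  if (any(counts < 2) || any(counts != as.integer(counts))) {
    abort("all design counts (subjects, sessions, timepoints, ROIs) must be integers >= 2")
  }
  if (sigma_edge < 0 || sigma_between < 0 || sigma_within < 0 || global_amplitude < 0) {
    abort("sigma_edge, sigma_between, sigma_within and global_amplitude must be >= 0")
  }
  if (ar1_coef < 0 || ar1_coef >= 1) {
    abort("ar1_coef must lie in [0, 1)")
  }
  if (anticorr_fraction < 0 || anticorr_fraction > 0.5 || anticorr_strength < 0) {
    abort("anticorr_fraction must lie in [0, 0.5] and anticorr_strength must be >= 0")
  }
  structure(
    list(
      n_subjects = as.integer(n_subjects),
      n_sessions = as.integer(n_sessions),
      n_timepoints = as.integer(n_timepoints),
      n_rois = as.integer(n_rois),
      base_connectivity = base_connectivity,
      sigma_edge = sigma_edge,
      anticorr_fraction = anticorr_fraction,
      anticorr_strength = anticorr_strength,
      sigma_between = sigma_between,
      sigma_within = sigma_within,
      global_amplitude = global_amplitude,
      ar1_coef = ar1_coef,
      seed = as.integer(seed)
    ),
    class = "sim_config"
  )
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  cat(sprintf(
    "  design: %d subjects x %d sessions x %d timepoints x %d ROIs\n",
    x$n_subjects, x$n_sessions, x$n_timepoints, x$n_rois
  ))
  cat(sprintf(
    "  z-scale components: base %.3g, edge SD %.3g, between-subject SD %.3g, within-subject SD %.3g\n",
    x$base_connectivity, x$sigma_edge, x$sigma_between, x$sigma_within
  ))
  cat(sprintf(
    "  anticorrelated system: %.0f%% of ROIs, strength %.3g\n",
    100 * x$anticorr_fraction, x$anticorr_strength
  ))
  cat(sprintf(
    "  global signal SD %.3g, AR(1) %.3g, seed %d\n",
    x$global_amplitude, x$ar1_coef, x$seed
  ))
  invisible(x)
}
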