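#' Remove the global signal from ROI time series
#'
#' The global signal is the unweighted mean across ROI columns at each
#' timepoint. Every column is replaced by its residual from an ordinary
#' least-squares fit on an intercept plus that global signal — the standard
#' global signal regression (GSR) step, applied here at the ROI level.
#'
#' @param ts Numeric matrix, timepoints by ROIs (>= 3 timepoints, >= 2 ROIs).
#' @return A matrix of the same shape with attribute `gsr_applied = TRUE`.
#' @examples
#' x <- matrix(rnorm(40), 10, 4)
#' r <- global_signal_regress(x)
#' max(abs(colMeans(r)))  # residuals are demeaned
#' @export
global_signal_regress <- function(ts) {
  ts <- as.matrix(ts)
  if (nrow(ts) < 3 || ncol(ts) < 2) {
    abort("global signal regression needs >= 3 timepoints and >= 2 ROIs")
  }
  g <- rowMeans(ts)
  if (sd(g) <= 1e-10 * max(1, abs(mean(g)))) {
    abort("global signal has zero variance: degenerate regressor")
  }
  x <- cbind(1, g)
  resid <- ts - x %*% qr.solve(x, ts)
  dimnames(resid) <- dimnames(ts)
  attr(resid, "gsr_applied") <- TRUE
  resid
}

#' Pearson connectivity matrix from ROI time series
#'
#' Pairwise Pearson correlation of the ROI columns, with the diagonal set to
#' zero so self-connections never enter edge ranking.
#'
#' @param ts Numeric matrix, timepoints by ROIs (>= 3 timepoints; every
#'   column must have nonzero variance).
#' @return Symmetric ROI-by-ROI matrix with zero diagonal and attribute
#'   `gsr_applied` carried over from `ts` (FALSE if absent).
#' @examples
#' x <- matrix(rnorm(60), 20, 3)
#' pearson_connectivity(x)
#' @export
pearson_connectivity <- function(ts) {
  ts <- as.matrix(ts)
  if (nrow(ts) < 3) {
    abort("Pearson connectivity needs >= 3 timepoints")
  }
  sds <- apply(ts, 2, sd)
  if (any(sds == 0)) {
    bad <- colnames(ts)[sds == 0] %||% as.character(which(sds == 0))
    abort(sprintf("constant ROI column(s): %s", paste(bad, collapse = ", ")))
  }
  r <- cor(ts)
  diag(r) <- 0
  r <- (r + t(r)) / 2
  attr(r, "gsr_applied") <- isTRUE(attr(ts, "gsr_applied"))
  r
}

#' Connectivity matrices for every subject-session of a study
#'
#' Applies optional global signal regression and Pearson correlation to each
#' row of a study tibble.
#'
#' @param study Study tibble from [simulate_study()] or [read_study()].
#' @param gsr Apply [global_signal_regress()] first?
#' @return Tibble `subject`, `session`, `gsr`, `conn` (list-column of
#'   symmetric zero-diagonal correlation matrices).
#' @examples
#' study <- simulate_study(sim_config(3, 2, 60, 8, seed = 1))
#' connectivity_table(study, gsr = TRUE)
#' @export
connectivity_table <- function(study, gsr = FALSE) {
  conn <- purrr::map(study$ts, function(ts) {
    if (gsr) ts <- global_signal_regress(ts)
    pearson_connectivity(ts)
  })
  tibble::tibble(
    subject = study$subject,
    session = study$session,
    gsr = gsr,
    conn = conn
  )
}
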