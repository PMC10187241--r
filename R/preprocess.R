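#' Background expression threshold from a not-expressed gene panel
#'
#' Estimates the participant's background expression level as the grand
#' mean over all panel genes and all timepoints. The panel lists genes
#' asserted not to be expressed in the tissue (the blood study used a
#' 62-gene panel); genes whose temporal mean does not exceed this
#' threshold are treated as not expressed.
#'
#' @param matrix an [expression_matrix()].
#' @param panel character vector of background gene ids; all must be
#'   present in the matrix.
#' @return scalar threshold (expression units).
#' @seealso [filter_expressed()]
#' @export
background_threshold <- function(matrix, panel) {
  if (length(panel) == 0) stopf("background panel is empty")
  missing <- setdiff(panel, rownames(matrix))
  if (length(missing))
    stopf("panel genes absent from matrix: %s",
          paste(missing, collapse = ", "))
  mean(matrix[panel, , drop = FALSE])
}

#' Remove lowly expressed genes
#'
#' Retains genes whose temporal mean expression strictly exceeds the
#' threshold; gene order is preserved.
#'
#' @param matrix an [expression_matrix()].
#' @param threshold expression threshold (>= 0), typically from
#'   [background_threshold()].
#' @return filtered `expr_matrix`.
#' @export
filter_expressed <- function(matrix, threshold) {
  if (threshold < 0) stopf("threshold must be >= 0")
  keep <- rowMeans(matrix) > threshold
  out <- unclass(matrix)[keep, , drop = FALSE]
  expression_matrix(out, time_points(matrix), participant_id(matrix))
}

#' Linear and polynomial detrending
#'
#' Subtracts the least-squares polynomial fit over time from a series.
#' `linear_detrend()` is the degree-1 case applied before oscillation
#' identification; degree-2 detrending is used for intron-retention and
#' splicing-gene series. Both are projections: applying twice equals
#' applying once.
#'
#' @param series numeric vector (>= 3 points; more than `degree + 1` for
#'   the polynomial case).
#' @param timepoints sampling times (hours), same length as `series`.
#' @param degree polynomial degree (`>= 0`; `0` mean-centres).
#' @return detrended numeric vector (residuals; may be negative).
#' @export
linear_detrend <- function(series, timepoints) {
  polynomial_detrend(series, timepoints, degree = 1L)
}

#' @rdname linear_detrend
#' @export
polynomial_detrend <- function(series, timepoints, degree) {
  n <- length(series)
  if (length(timepoints) != n) stopf("series/timepoints length mismatch")
  if (n < 3) stopf("need at least 3 points to detrend")
  if (!is_count(degree)) stopf("degree must be a nonnegative count")
  if (degree >= n - 1) stopf("degree must be < number of points - 1")
  tu <- unique(timepoints)
  if (length(tu) < degree + 1) stopf("time vector too degenerate for degree %d", degree)
  ts <- (timepoints - mean(timepoints)) / max(sd(timepoints), 1e-12)
  X <- outer(ts, 0:degree, `^`)
  fit <- stats::lm.fit(X, series)
  as.numeric(fit$residuals)
}

#' Detrend every gene of an expression matrix
#'
#' Applies [linear_detrend()] (or a polynomial detrend) row-wise.
#' Detrended values are residuals and may be negative, so the result is a
#' plain numeric matrix (with the timepoints kept as an attribute), not an
#' `expr_matrix`.
#'
#' @param matrix an [expression_matrix()].
#' @param degree polynomial degree (1 = linear).
#' @return numeric matrix of residuals with attribute `timepoints`.
#' @export
detrend_matrix <- function(matrix, degree = 1L) {
  tp <- time_points(matrix)
  out <- t(apply(unclass(matrix), 1L, polynomial_detrend,
                 timepoints = tp, degree = degree))
  dimnames(out) <- dimnames(matrix)
  attr(out, "timepoints") <- tp
  out
}

#' Fold a 48h series into 24h with duplicate timepoints
#'
#' Samples collected at the same clock time on two consecutive days are
#' treated as biological replicates: timepoints `t` and `t + 24` become
#' two replicates of phase `t`. Requires a grid spanning two full days
#' (every first-day timepoint must reappear 24h later).
#'
#' @param matrix an [expression_matrix()] over (at least) 48h.
#' @return `expr_matrix` with each timepoint `t < 24` appearing twice
#'   (day-1 then day-2 replicate).
#' @export
fold_duplicates <- function(matrix) {
  tp <- time_points(matrix)
  day1 <- which(tp < 24)
  day2 <- which(tp >= 24 & tp < 48)
  if (!length(day1) || !setequal(tp[day1] + 24, tp[day2]))
    stopf("matrix must span two full days on a matching grid")
  o1 <- day1[order(tp[day1])]
  o2 <- day2[order(tp[day2])]
  idx <- as.vector(rbind(o1, o2))  # t0_d1, t0_d2, t2_d1, t2_d2, ...
  newt <- rep(tp[o1], each = 2L)
  out <- unclass(matrix)[, idx, drop = FALSE]
  colnames(out) <- paste0("t", newt, c("_d1", "_d2"))
  em <- expression_matrix(out, newt, participant_id(matrix))
  em
}

#' Subsample an expression matrix to a coarser interval
#'
#' Retains timepoints congruent to `offset` modulo `interval` — e.g. the
#' 4h-interval subset of a 2h-interval dataset used by the harmonic
#' control to match the number of samples per period between the circadian
#' and ~12h scans.
#'
#' @param matrix an [expression_matrix()].
#' @param interval new sampling interval (hours); must be a multiple of
#'   the current grid spacing.
#' @param offset phase of the retained samples (hours); must fall on the
#'   grid.
#' @return subsampled `expr_matrix`.
#' @export
subsample_interval <- function(matrix, interval, offset = 0) {
  tp <- time_points(matrix)
  dt <- sampling_interval(matrix)
  if (abs(interval / dt - round(interval / dt)) > 1e-9)
    stopf("interval must be a multiple of the grid spacing (%gh)", dt)
  if (!any(abs((tp - offset) %% interval) < 1e-9))
    stopf("offset %gh does not fall on the grid", offset)
  keep <- abs((tp - offset) %% interval) < 1e-9
  out <- unclass(matrix)[, keep, drop = FALSE]
  expression_matrix(out, tp[keep], participant_id(matrix))
}
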