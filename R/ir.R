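#' Filter intron-retention events by read-support thresholds
#'
#' Keeps records meeting every criterion (inclusive comparisons):
#' intron read count `T >= 20`, junction count `J >= 1`, `FPKM >= 2`
#' (raised to `FPKM >= 3` under `"strict"`), `NE >= 0.9`.
#'
#' @param records data.frame with columns `T`, `J`, `FPKM`, `NE` (plus
#'   any identifier/time columns, which are carried through).
#' @param stringency `"default"` or `"strict"`.
#' @return the retained subset of `records`.
#' @export
filter_retained <- function(records, stringency = c("default", "strict")) {
  stringency <- match.arg(stringency)
  need <- c("T", "J", "FPKM", "NE")
  if (!all(need %in% names(records)))
    stopf("records must have columns %s", paste(need, collapse = ", "))
  fpkm_min <- if (stringency == "strict") 3 else 2
  keep <- records$T >= 20 & records$J >= 1 & records$FPKM >= fpkm_min &
    records$NE >= 0.9
  records[keep, , drop = FALSE]
}

#' Temporal course of retained-intron events and its ~12h rhythm
#'
#' Counts the retained events per timepoint (or averages the NE score
#' with `metric = "mean_ne"`), applies a degree-2 polynomial detrend, and
#' tests the series for rhythmicity at `period` with the umbrella scan.
#'
#' @param records IR table with a `time_h` column (plus the filter
#'   metrics).
#' @param stringency passed to [filter_retained()].
#' @param period test period in hours (default 12).
#' @param metric `"count"` (retained events per timepoint) or
#'   `"mean_ne"` (mean NE of retained events).
#' @param B Monte-Carlo null size for the rhythm test.
#' @return list of class `ir_series`: `timepoints`, `counts`,
#'   `detrended`, `period`, `p_value`, `peak_phase_h`.
#' @export
ir_time_course <- function(records, stringency = c("default", "strict"),
                           period = 12, metric = c("count", "mean_ne"),
                           B = 4999L) {
  metric <- match.arg(metric)
  if (!"time_h" %in% names(records)) stopf("records need a time_h column")
  tp <- sort(unique(records$time_h))
  if (length(tp) < 6) stopf("need at least 6 timepoints")
  kept <- filter_retained(records, stringency)
  counts <- vapply(tp, function(t0) {
    sub <- kept[kept$time_h == t0, , drop = FALSE]
    if (metric == "count") as.numeric(nrow(sub))
    else if (nrow(sub)) mean(sub$NE) else NA_real_
  }, numeric(1))
  if (anyNA(counts)) stopf("no retained events at some timepoints under metric 'mean_ne'")
  if (max(counts) == min(counts)) {
    # perfectly flat course: no rhythm by definition (avoids ranking the
    # ~1e-15 numerical residue of the polynomial fit)
    return(structure(list(timepoints = tp, counts = counts,
                          detrended = rep(0, length(tp)), period = period,
                          p_value = 1, peak_phase_h = NA_real_),
                     class = "ir_series"))
  }
  detr <- polynomial_detrend(counts, tp, degree = 2L)
  sc <- scan_gene(detr, tp, period_grid = period, B = B)
  structure(list(timepoints = tp, counts = counts, detrended = detr,
                 period = period, p_value = sc$best_p,
                 peak_phase_h = sc$best_peak_phase),
            class = "ir_series")
}

#' @export
print.ir_series <- function(x, ...) {
  cat(sprintf("<ir_series> %d timepoints, %s retained events/timepoint, p(%gh) = %.3g\n",
              length(x$timepoints), signif(mean(x$counts), 4), x$period,
              x$p_value))
  invisible(x)
}

# First-harmonic acrophase of a series at a given period (hours), via the
# circular mean; NA when the harmonic amplitude is negligible.
acrophase_first_harmonic <- function(series, timepoints, period) {
  y <- series - mean(series)
  C <- sum(y * cos(2 * pi * timepoints / period))
  S <- sum(y * sin(2 * pi * timepoints / period))
  amp <- 2 * sqrt(C^2 + S^2) / length(y)
  if (!is.finite(amp) || amp < 1e-9 * max(1e-12, stats::sd(series)) ||
      stats::sd(series) < 1e-13)
    return(NA_real_)
  ph <- atan2(S, C) / (2 * pi) * period
  ((ph %% period) + period) %% period
}

#' Phase synchronization of IR rhythms and splicing-gene expression
#'
#' Compares the acrophase (first-harmonic circular mean at the test
#' period) of the retained-intron time course with that of the mean
#' z-scored expression of mRNA-splicing genes, and reports their circular
#' phase difference in hours. A difference near 0 indicates synchronized
#' rhythms; near `period/2`, antiphase.
#'
#' @param ir_series an [ir_time_course()] result.
#' @param splicing_matrix numeric matrix of splicing-gene expression
#'   (genes x timepoints) on the same grid, or an `expr_matrix`.
#' @param degree detrend degree applied to the splicing series (2, as for
#'   the IR series).
#' @return list with `ir_acrophase_h`, `splicing_acrophase_h`,
#'   `phase_difference_h` (circular, in `[0, period/2]`), `period`. An
#'   acrophase is `NA` (and the difference `NA`) for a flat series.
#' @export
synchronization_report <- function(ir_series, splicing_matrix, degree = 2L) {
  stopifnot(inherits(ir_series, "ir_series"))
  tp <- ir_series$timepoints
  Tm <- ir_series$period
  sm <- if (inherits(splicing_matrix, "expr_matrix"))
    unclass(splicing_matrix) else as.matrix(splicing_matrix)
  stp <- if (inherits(splicing_matrix, "expr_matrix"))
    time_points(splicing_matrix) else attr(splicing_matrix, "timepoints")
  if (is.null(stp)) stp <- tp
  if (!isTRUE(all.equal(sort(stp), sort(tp))))
    stopf("IR and splicing series must share the time grid")
  # z-score each gene, average, detrend
  zs <- t(apply(sm, 1L, function(r) {
    s <- stats::sd(r)
    if (s < 1e-13) rep(0, length(r)) else (r - mean(r)) / s
  }))
  if (nrow(sm) == 1L) zs <- matrix(zs, 1L)
  avg <- colMeans(zs)[order(stp)]
  avg_d <- if (stats::sd(avg) < 1e-13) avg
           else polynomial_detrend(avg, sort(stp), degree = degree)
  ir_ph <- acrophase_first_harmonic(ir_series$detrended, tp, Tm)
  sp_ph <- acrophase_first_harmonic(avg_d, sort(stp), Tm)
  diff_h <- if (is.na(ir_ph) || is.na(sp_ph)) NA_real_ else {
    d <- abs(ir_ph - sp_ph) %% Tm
    min(d, Tm - d)
  }
  list(ir_acrophase_h = ir_ph, splicing_acrophase_h = sp_ph,
       phase_difference_h = diff_h, period = Tm)
}
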