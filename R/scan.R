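#' Scan an expression matrix for rhythms over a period grid
#'
#' For every gene and every candidate period, phase-folds the series and
#' computes the cyclic umbrella rank statistic at each of the `m`
#' candidate peak positions. The per-period p-value is the permutation
#' tail probability of the *maximum standardized* statistic over peak
#' positions, evaluated against a deterministic cached Monte-Carlo null of
#' size `B` (so the multiplicity over peak positions is calibrated by
#' construction; `adjust = "bonferroni"` instead multiplies the smallest
#' per-peak normal p-value by the number of distinct umbrella orderings).
#'
#' In `"duplicate"` mode a 48h matrix is first folded into 24h with
#' day-1/day-2 samples pooled as biological replicates of the same phase
#' ([fold_duplicates()]); periods that leave empty phase groups on the
#' folded grid (those above 24h) are dropped with a warning.
#'
#' @param matrix an [expression_matrix()], or a detrended numeric matrix
#'   with a `timepoints` attribute (as returned by [detrend_matrix()]).
#' @param period_grid candidate periods in hours; multiples of the
#'   sampling interval (default 6-32h in 2h steps).
#' @param mode `"continuous"` (use the full series as one cycle sequence)
#'   or `"duplicate"` (fold consecutive days into replicates).
#' @param B Monte-Carlo null size; the smallest attainable p-value is
#'   `1/(B+1)`.
#' @param adjust peak-position multiplicity scheme (see above).
#' @return data.frame with one row per (gene, period): `gene`,
#'   `period_h`, `p_value`, `peak_phase_h`, `mode`.
#' @seealso [best_periods()], [umbrella_test()]
#' @export
scan_matrix <- function(matrix, period_grid = seq(6, 32, by = 2),
                        mode = c("continuous", "duplicate"),
                        B = 4999L, adjust = c("montecarlo", "bonferroni")) {
  mode <- match.arg(mode)
  adjust <- match.arg(adjust)
  if (!length(period_grid)) stopf("period grid is empty")
  tp <- if (inherits(matrix, "expr_matrix")) time_points(matrix)
        else attr(matrix, "timepoints")
  if (is.null(tp)) stopf("matrix carries no timepoints")
  X <- unclass(matrix)
  attr(X, "timepoints") <- NULL
  if (mode == "duplicate" && max(tp) >= 24 && !anyDuplicated(tp)) {
    # pool day-1/day-2 samples as replicates of the same clock phase
    # (values may be negative after detrending, so fold by relabelling
    # rather than through the nonnegative expr_matrix constructor)
    d1 <- tp[tp < 24]
    if (!setequal(d1 + 24, tp[tp >= 24 & tp < 48]))
      stopf("duplicate mode needs a grid spanning two matching days")
    ord <- order(tp %% 24, tp)
    X <- X[, ord, drop = FALSE]
    tp <- tp[ord] %% 24
  }
  dt <- sampling_interval(sort(unique(tp)))
  genes <- rownames(X)
  out <- vector("list", length(period_grid))
  for (k in seq_along(period_grid)) {
    Tk <- period_grid[k]
    pg <- tryCatch(phase_groups(tp, Tk, dt), error = function(e) e)
    if (inherits(pg, "error")) {
      warning(sprintf("period %gh skipped: %s", Tk, conditionMessage(pg)),
              call. = FALSE)
      next
    }
    null <- umbrella_null(pg$g, pg$m, as.integer(B))
    w <- umbrella_weights(pg$g, pg$m)
    A <- umbrella_stat_matrix(X, w)
    Z <- sweep(sweep(A, 2L, null$mu), 2L, null$sd, `/`)
    maxZ <- apply(Z, 1L, max)
    peak <- w$peak[apply(Z, 1L, which.max)]
    cnt <- null$B - findInterval(maxZ - 1e-9, null$maxZ_sorted)
    if (adjust == "montecarlo") {
      p <- (1 + cnt) / (null$B + 1)
    } else {
      pmin_peak <- stats::pnorm(maxZ, lower.tail = FALSE)
      p <- pmin(1, null$n_orderings * pmin_peak)
    }
    degenerate <- apply(X, 1L, function(r) max(r) == min(r))
    p[degenerate] <- 1
    peak_phase <- (peak - 1L) * dt
    peak_phase[degenerate] <- NA_real_
    out[[k]] <- data.frame(gene = genes, period_h = Tk, p_value = p,
                           peak_phase_h = peak_phase, mode = mode,
                           stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  if (is.null(res)) stopf("no period in the grid is scannable on this grid")
  rownames(res) <- NULL
  res
}

#' @rdname scan_matrix
#' @param series numeric vector (one gene).
#' @param timepoints sampling times for `series`.
#' @return [scan_gene()] returns a list with `table` (the per-period rows)
#'   and `best_period`, `best_peak_phase`, `best_p`.
#' @export
scan_gene <- function(series, timepoints, period_grid = seq(6, 32, by = 2),
                      mode = c("continuous", "duplicate"), B = 4999L,
                      adjust = c("montecarlo", "bonferroni")) {
  m <- matrix(series, 1L, dimnames = list("gene", NULL))
  attr(m, "timepoints") <- timepoints
  tab <- scan_matrix(m, period_grid, mode, B, adjust)
  i <- which.min(tab$p_value)
  list(table = tab, best_period = tab$period_h[i],
       best_peak_phase = tab$peak_phase_h[i], best_p = tab$p_value[i])
}

#' Best period per gene from a scan table
#'
#' @param scan data.frame from [scan_matrix()].
#' @return data.frame with one row per gene: `gene`, `best_period_h`,
#'   `best_peak_phase_h`, `best_p` (minimum p over the grid; ties go to
#'   the shorter period).
#' @export
best_periods <- function(scan) {
  sp <- split(scan, scan$gene)
  rows <- lapply(sp, function(d) {
    d <- d[order(d$p_value, d$period_h), , drop = FALSE]
    data.frame(gene = d$gene[1], best_period_h = d$period_h[1],
               best_peak_phase_h = d$peak_phase_h[1], best_p = d$p_value[1],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
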