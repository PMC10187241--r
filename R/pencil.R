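#' Matrix-pencil decomposition of a series into damped sinusoids
#'
#' Estimates up to `max_components` damped oscillations
#' `A * d^(t/T) * cos(2*pi*(t - phi)/T)` from an evenly sampled series by
#' the matrix-pencil (eigenvalue/pencil) method: Hankel data matrices are
#' formed with pencil parameter `L = floor(N/3)`, the dominant signal
#' subspace is obtained by singular-value truncation, and the signal poles
#' `z_k` are the generalized eigenvalues of the shifted/unshifted pencil.
#' Complex-conjugate pole pairs are converted to period
#' `T = 2*pi*dt/|arg z|` and per-cycle decay `d = |z|^(T/dt)`; real poles
#' (non-oscillatory trends) are discarded. Amplitudes and acrophases are
#' recovered by least squares on the retained damped-sinusoid basis.
#' Amplitude is referenced to the first timepoint; the series is assumed
#' detrended (see [linear_detrend()]).
#'
#' @param series numeric vector (detrended expression).
#' @param timepoints evenly spaced sampling times (hours).
#' @param max_components maximum number of oscillations to keep
#'   (default 4).
#' @param mean_expression gene temporal mean of the *original*
#'   (pre-detrend) series, used for the relative amplitude; defaults to
#'   `mean(series)` which is only meaningful when the series still
#'   contains its baseline.
#' @param sv_threshold relative singular-value threshold for rank
#'   truncation. Use the default `1e-8` for (near-)noiseless data; for
#'   noisy data a coarser threshold (e.g. `0.05`) suppresses noise poles.
#' @return data.frame of class `pencil_components`, sorted by amplitude
#'   (descending), with columns `period`, `amplitude`, `decay`,
#'   `acrophase`, `relative_amplitude`. Zero rows when no oscillatory
#'   component is found (e.g. constant series).
#' @examples
#' t <- seq(0, 46, 2)
#' y <- 3 * cos(2 * pi * t / 24) + 1 * cos(2 * pi * t / 12)
#' pencil_decompose(y, t, mean_expression = 10)
#' @export
pencil_decompose <- function(series, timepoints, max_components = 4L,
                             mean_expression = mean(series),
                             sv_threshold = 1e-8) {
  N <- length(series)
  if (length(timepoints) != N) stopf("series/timepoints length mismatch")
  if (N < 6) stopf("series too short for pencil decomposition (need >= 6 points)")
  dt <- diff(timepoints)
  if (max(abs(dt - dt[1])) > 1e-8) stopf("timepoints must be evenly spaced")
  dt <- dt[1]
  empty <- data.frame(period = numeric(), amplitude = numeric(),
                      decay = numeric(), acrophase = numeric(),
                      relative_amplitude = numeric())
  class(empty) <- c("pencil_components", "data.frame")
  if (sd(series) < 1e-13) return(empty)

  L <- floor(N / 3)
  # Hankel data matrix, (N - L) x (L + 1)
  Y <- matrix(0, N - L, L + 1L)
  for (j in seq_len(L + 1L)) Y[, j] <- series[(j - 1L) + seq_len(N - L)]
  sv <- svd(Y)
  M <- sum(sv$d >= sv_threshold * sv$d[1])
  M <- min(M, 2L * max_components, L, N - L)
  if (M == 0) return(empty)
  # rank-truncated filtered matrix; pencil on its shifted/unshifted columns
  Yf <- sv$u[, seq_len(M), drop = FALSE] %*%
    (sv$d[seq_len(M)] * t(sv$v[, seq_len(M), drop = FALSE]))
  Y1 <- Yf[, 1:L, drop = FALSE]
  Y2 <- Yf[, 2:(L + 1L), drop = FALSE]
  # pinv(Y1) %*% Y2 via the SVD of Y1 truncated at rank M
  s1 <- svd(Y1)
  k <- sum(s1$d >= max(1e-12, 1e-10 * s1$d[1]))
  k <- min(k, M)
  pinvY1 <- s1$v[, seq_len(k), drop = FALSE] %*%
    ((1 / s1$d[seq_len(k)]) * t(s1$u[, seq_len(k), drop = FALSE]))
  z <- eigen(pinvY1 %*% Y2, only.values = TRUE)$values
  z <- z[Mod(z) > 1e-9]
  # keep one member of each complex-conjugate (oscillatory) pair
  osc <- z[Im(z) > 1e-7 & abs(Arg(z)) > 1e-6 & abs(Arg(z)) < pi - 1e-9]
  if (!length(osc)) return(empty)

  period <- 2 * pi * dt / abs(Arg(osc))
  decay <- Mod(osc)^(period / dt)
  # least-squares fit of damped cosine/sine pairs (plus intercept)
  n <- (timepoints - timepoints[1]) / dt
  X <- matrix(1, N, 1L + 2L * length(osc))
  for (i in seq_along(osc)) {
    r <- Mod(osc[i])^n
    th <- abs(Arg(osc[i])) * n
    X[, 2 * i] <- r * cos(th)
    X[, 2 * i + 1] <- r * sin(th)
  }
  cf <- stats::lm.fit(X, series)$coefficients
  cf[is.na(cf)] <- 0
  a <- cf[2 * seq_along(osc)]
  b <- cf[2 * seq_along(osc) + 1]
  amplitude <- sqrt(a^2 + b^2)
  acro <- (atan2(b, a) / (2 * pi)) * period
  acro <- ((acro %% period) + period) %% period
  out <- data.frame(period = period, amplitude = amplitude, decay = decay,
                    acrophase = acro,
                    relative_amplitude = amplitude / mean_expression)
  out <- out[order(-out$amplitude, out$period), , drop = FALSE]
  if (nrow(out) > max_components)
    out <- out[seq_len(max_components), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("pencil_components", "data.frame")
  out
}

#' Period/decay classification rules for oscillation components
#'
#' Named period windows (hours) with a shared per-cycle decay window. The
#' blood-study defaults: circadian 20-25h, ultradian12 10-14h, ultradian8
#' 6-8h, with decay in [0.8, 1.2] (a stable, at most mildly damped or
#' amplified oscillation). Windows must not overlap.
#'
#' @param windows named list of `c(lo, hi)` period windows in hours.
#' @param decay_window `c(lo, hi)` per-cycle decay window; must contain 1.
#' @return list of class `classification_rules`.
#' @export
classification_rules <- function(windows = list(circadian = c(20, 25),
                                                ultradian12 = c(10, 14),
                                                ultradian8 = c(6, 8)),
                                 decay_window = c(0.8, 1.2)) {
  if (is.null(names(windows)) || any(!nzchar(names(windows))))
    stopf("windows must be a named list")
  for (w in windows)
    if (length(w) != 2 || w[1] >= w[2]) stopf("each window must be c(lo, hi), lo < hi")
  if (length(windows) > 1) {
    ord <- order(vapply(windows, `[`, 0, 1L))
    ws <- windows[ord]
    for (i in seq_len(length(ws) - 1L))
      if (ws[[i + 1L]][1] < ws[[i]][2])
        stopf("period windows '%s' and '%s' overlap",
              names(ws)[i], names(ws)[i + 1L])
  }
  if (decay_window[1] > 1 || decay_window[2] < 1)
    stopf("decay window must contain 1")
  structure(list(windows = windows, decay_window = decay_window),
            class = "classification_rules")
}

#' Classify oscillation components into period bands
#'
#' A component receives a window's label iff its period lies inside the
#' window (inclusive) *and* its per-cycle decay lies in the decay window;
#' otherwise it is labelled `"none"` (over-damped or out-of-band).
#'
#' @param components a `pencil_components` data.frame.
#' @param rules a [classification_rules()].
#' @return character vector of labels, one per component.
#' @export
classify_components <- function(components, rules) {
  stopifnot(inherits(rules, "classification_rules"))
  if (!nrow(components)) return(character())
  lab <- rep("none", nrow(components))
  dok <- components$decay >= rules$decay_window[1] &
    components$decay <= rules$decay_window[2]
  for (nm in names(rules$windows)) {
    w <- rules$windows[[nm]]
    hit <- dok & components$period >= w[1] & components$period <= w[2]
    lab[hit] <- nm
  }
  lab
}

#' Dominant oscillation of a gene
#'
#' Returns the maximum-amplitude component (ties broken toward the lower
#' period). A gene is called "dominant-X" iff its dominant component is
#' classified X; dominant classes are mutually exclusive by construction.
#'
#' @param components a `pencil_components` data.frame.
#' @return one-row data.frame, or `NULL` for an empty component list.
#' @export
dominant_component <- function(components) {
  if (is.null(components) || !nrow(components)) return(NULL)
  o <- order(-components$amplitude, components$period)
  components[o[1], , drop = FALSE]
}

#' Pencil-decompose and classify every gene of a matrix
#'
#' Linearly detrends each gene, runs [pencil_decompose()] with the gene's
#' raw temporal mean as the relative-amplitude reference, classifies each
#' component with [classify_components()], and flags the dominant one.
#'
#' @param matrix an [expression_matrix()] (raw, not detrended).
#' @param rules a [classification_rules()].
#' @param max_components maximum oscillations per gene.
#' @param sv_threshold singular-value truncation threshold (see
#'   [pencil_decompose()]; default 0.05 for noisy data).
#' @return data.frame with columns `gene`, `component_rank`, `period_h`,
#'   `amplitude`, `decay_per_cycle`, `acrophase_h`, `relative_amplitude`,
#'   `label`, `dominant`.
#' @export
decompose_matrix <- function(matrix, rules = classification_rules(),
                             max_components = 4L, sv_threshold = 0.05) {
  tp <- time_points(matrix)
  res <- vector("list", nrow(matrix))
  for (g in seq_len(nrow(matrix))) {
    y <- as.numeric(matrix[g, ])
    comps <- pencil_decompose(linear_detrend(y, tp), tp,
                              max_components = max_components,
                              mean_expression = mean(y),
                              sv_threshold = sv_threshold)
    if (!nrow(comps)) next
    lab <- classify_components(comps, rules)
    res[[g]] <- data.frame(gene = rownames(matrix)[g],
                           component_rank = seq_len(nrow(comps)),
                           period_h = comps$period,
                           amplitude = comps$amplitude,
                           decay_per_cycle = comps$decay,
                           acrophase_h = comps$acrophase,
                           relative_amplitude = comps$relative_amplitude,
                           label = lab,
                           dominant = seq_len(nrow(comps)) == 1L,
                           stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, res)
  if (is.null(out))
    out <- data.frame(gene = character(), component_rank = integer(),
                      period_h = numeric(), amplitude = numeric(),
                      decay_per_cycle = numeric(), acrophase_h = numeric(),
                      relative_amplitude = numeric(), label = character(),
                      dominant = logical(), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Count genes carrying a classified oscillation
#'
#' Builds a deterministic detector closure for [estimate_fdr()]: given an
#' expression matrix it returns the number of genes with at least one
#' component classified into `band` (or, with `dominant_only`, whose
#' dominant component is in `band`).
#'
#' @param band window name from `rules` (e.g. `"ultradian12"`).
#' @param rules a [classification_rules()].
#' @param dominant_only count only dominant-band genes.
#' @param sv_threshold passed to [decompose_matrix()].
#' @return function(matrix) -> integer count.
#' @export
pencil_band_counter <- function(band, rules = classification_rules(),
                                dominant_only = FALSE, sv_threshold = 0.05) {
  force(band); force(rules); force(dominant_only); force(sv_threshold)
  function(matrix) {
    tp <- time_points(matrix)
    n <- 0L
    for (g in seq_len(nrow(matrix))) {
      y <- as.numeric(matrix[g, ])
      comps <- pencil_decompose(linear_detrend(y, tp), tp,
                                mean_expression = mean(y),
                                sv_threshold = sv_threshold)
      if (!nrow(comps)) next
      lab <- classify_components(comps, rules)
      hit <- if (dominant_only) lab[1] == band else any(lab == band)
      if (hit) n <- n + 1L
    }
    n
  }
}
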