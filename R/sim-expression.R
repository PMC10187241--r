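#' Simulation configuration for synthetic expression cohorts
#'
#' Defines a seeded synthetic cohort with the statistical structure the
#' rhythm analysis assumes: a minority of genes carrying circadian (~24h)
#' and/or ultradian (~12h) damped cosine components superimposed on a
#' baseline with mild linear drift, lognormal-like spread of baselines,
#' additive Gaussian noise floored at zero, a majority of arrhythmic genes,
#' and a panel of not-expressed background genes used for expression
#' filtering. Participant-specific acrophase offsets default to
#' `c(0, 0, -4)` hours, mirroring the observed 8am/8pm peaks in two
#' participants and 4am/4pm in the third.
#'
#' Amplitudes and noise are parameterised *relative to each gene's
#' baseline*: a relative amplitude of 0.3 with `noise_rel_sd = 0.15` gives
#' an amplitude-to-noise ratio of 2, the default study condition. The
#' circadian amplitude is the ultradian amplitude divided by
#' `rel_amplitude_ratio_12_vs_24` (default 0.5: circadian rhythms have
#' about twice the relative amplitude of ~12h rhythms, as observed).
#'
#' @param n_genes number of foreground genes.
#' @param timepoints sampling grid in hours (default 0,2,...,46: 48h at 2h
#'   intervals, 24 samples).
#' @param n_participants number of participants.
#' @param frac_circadian,frac_ultradian12,frac_both class proportions;
#'   remainder is arrhythmic. Allocation is by deterministic slicing of a
#'   seeded shuffle, so class counts are exact (`floor(frac * n_genes)`).
#' @param period_circadian_h,period_ultradian_h planted periods (hours).
#' @param baseline_range baseline expression range; baselines are drawn
#'   log-uniformly within it.
#' @param rel_amplitude_range range of the ~12h relative amplitude
#'   (amplitude / baseline).
#' @param rel_amplitude_ratio_12_vs_24 ratio of ~12h to circadian relative
#'   amplitude.
#' @param decay_range per-cycle amplitude ratio range (1 = sustained,
#'   < 1 damped).
#' @param phase_offsets_per_participant acrophase offset in hours added
#'   per participant (recycled/truncated to `n_participants`).
#' @param noise_rel_sd Gaussian noise SD as a fraction of baseline.
#' @param trend_rel_slope_range linear drift slope range, as fraction of
#'   baseline per hour.
#' @param n_background_genes number of not-expressed background panel
#'   genes appended to the matrix (default 62).
#' @param waveform_circadian `"cosine"`, `"square"` or `"peaked"`.
#'   `"peaked"` is the squared-cosine waveform `cos(theta) +
#'   0.25*cos(2*theta)`: a smooth, peaked circadian shape that consists
#'   of exactly a 24h fundamental plus a true ~12h second harmonic at a
#'   quarter of its amplitude -- the canonical positive control for
#'   harmonic-artifact analyses of spectral methods. The square option
#'   is a zero-mean rectangular wave with 30% duty cycle (peak centred on
#'   the acrophase): unlike a symmetric square wave it carries strong
#'   *even* harmonics (the 2nd harmonic is ~56% of the fundamental), so
#'   circadian genes with this waveform genuinely contain a ~12h
#'   component — the positive control for the harmonic-artifact analysis.
#' @param seed integer seed; together with the config it fully determines
#'   the simulated output.
#' @return A list of class `sim_config`.
#' @seealso [simulate_expression()]
#' @export
sim_config <- function(n_genes = 1000,
                       timepoints = seq(0, 46, by = 2),
                       n_participants = 3,
                       frac_circadian = 0.15,
                       frac_ultradian12 = 0.10,
                       frac_both = 0,
                       period_circadian_h = 24,
                       period_ultradian_h = 12,
                       baseline_range = c(5, 50),
                       rel_amplitude_range = c(0.3, 0.3),
                       rel_amplitude_ratio_12_vs_24 = 0.5,
                       decay_range = c(0.9, 1.1),
                       phase_offsets_per_participant = c(0, 0, -4),
                       noise_rel_sd = 0.15,
                       trend_rel_slope_range = c(-0.002, 0.002),
                       n_background_genes = 62,
                       waveform_circadian = c("cosine", "square", "peaked"),
                       seed = 1L) {
  waveform_circadian <- match.arg(waveform_circadian)
  cfg <- list(n_genes = n_genes, timepoints = as.numeric(timepoints),
              n_participants = n_participants,
              frac_circadian = frac_circadian,
              frac_ultradian12 = frac_ultradian12,
              frac_both = frac_both,
              period_circadian_h = period_circadian_h,
              period_ultradian_h = period_ultradian_h,
              baseline_range = baseline_range,
              rel_amplitude_range = rel_amplitude_range,
              rel_amplitude_ratio_12_vs_24 = rel_amplitude_ratio_12_vs_24,
              decay_range = decay_range,
              phase_offsets_per_participant = phase_offsets_per_participant,
              noise_rel_sd = noise_rel_sd,
              trend_rel_slope_range = trend_rel_slope_range,
              n_background_genes = n_background_genes,
              waveform_circadian = waveform_circadian,
              seed = as.integer(seed))
  validate_sim_config(cfg)
  class(cfg) <- "sim_config"
  cfg
}

validate_sim_config <- function(cfg) {
  if (!is_count(cfg$n_genes) || cfg$n_genes < 1)
    stopf("n_genes must be a positive count")
  if (!is_count(cfg$n_participants) || cfg$n_participants < 1)
    stopf("n_participants must be a positive count")
  fr <- c(cfg$frac_circadian, cfg$frac_ultradian12, cfg$frac_both)
  if (any(fr < 0) || sum(fr) > 1 + 1e-12)
    stopf("class proportions must be nonnegative and sum to <= 1")
  tp <- cfg$timepoints
  if (length(tp) < 3 || is.unsorted(tp, strictly = TRUE))
    stopf("timepoints must be strictly increasing, length >= 3")
  if (max(abs(diff(tp) - diff(tp)[1])) > 1e-8)
    stopf("timepoints must be evenly spaced")
  if (cfg$noise_rel_sd < 0) stopf("noise_rel_sd must be >= 0")
  if (!is_count(cfg$n_background_genes))
    stopf("n_background_genes must be a count")
  invisible(cfg)
}

#' Evaluate a sum of damped cosine components plus baseline and drift
#'
#' The signal model underlying both the generator and the spectral
#' decomposition: `baseline + slope*t + sum_i A_i * d_i^(t/T_i) *
#' cos(2*pi*(t - phi_i)/T_i)`, where `d_i` is the per-cycle amplitude
#' ratio and `phi_i` the acrophase in hours.
#'
#' @param t numeric times (hours).
#' @param baseline,slope intercept and linear drift (units, units/hour).
#' @param components data.frame with columns `period`, `amplitude`,
#'   `phase`, `decay` (one row per component); may have zero rows.
#' @return numeric vector of signal values at `t`.
#' @export
damped_signal <- function(t, baseline = 0, slope = 0,
                          components = data.frame(period = numeric(),
                                                  amplitude = numeric(),
                                                  phase = numeric(),
                                                  decay = numeric())) {
  y <- baseline + slope * t
  if (nrow(components)) {
    for (i in seq_len(nrow(components))) {
      Tm <- components$period[i]
      A <- components$amplitude[i]
      d <- components$decay[i]
      ph <- components$phase[i]
      wf <- if (is.null(components$waveform)) "cosine" else components$waveform[i]
      fr <- (t - ph) / Tm
      wav <- switch(wf,
                    square = rect_wave(fr),
                    peaked = cos(2 * pi * fr) + 0.25 * cos(4 * pi * fr),
                    cos(2 * pi * fr))
      y <- y + A * d^(t / Tm) * wav
    }
  }
  y
}

#' Simulate a synthetic expression cohort
#'
#' Generates one expression matrix per participant on the configured grid,
#' plus the ground truth of planted components. Gene-level parameters
#' (class, baseline, amplitudes, phases, decay, drift) are drawn once and
#' shared across participants; each participant receives the configured
#' acrophase offset and an independent noise realisation. Background genes
#' (`BG_*`) are pure low-level noise and form the not-expressed panel used
#' by [background_threshold()]. Identical config (including seed)
#' reproduces bit-identical output.
#'
#' @param config a [sim_config()].
#' @return A list with elements:
#'   \describe{
#'     \item{matrices}{list of `expr_matrix`, one per participant.}
#'     \item{truth}{data.frame with one row per gene: `gene`, `label`
#'       (circadian / ultradian12 / both / arrhythmic / background),
#'       `baseline`, `slope`, and planted component parameters
#'       (`period24`, `amp24`, `phase24`, `decay24`, `period12`, `amp12`,
#'       `phase12`, `decay12`; `NA` where no component is planted).}
#'     \item{panel}{character vector of background gene ids.}
#'     \item{config}{the input config.}
#'   }
#' @examples
#' cohort <- simulate_expression(sim_config(n_genes = 50, seed = 7))
#' table(cohort$truth$label)
#' @export
simulate_expression <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  validate_sim_config(config)
  cfg <- config
  with_private_seed(cfg$seed, {
    n <- cfg$n_genes
    tp <- cfg$timepoints
    n_circ <- floor(cfg$frac_circadian * n)
    n_ultr <- floor(cfg$frac_ultradian12 * n)
    n_both <- floor(cfg$frac_both * n)
    ord <- sample.int(n)
    labels <- rep("arrhythmic", n)
    labels[ord[seq_len(n_circ)]] <- "circadian"
    if (n_ultr) labels[ord[n_circ + seq_len(n_ultr)]] <- "ultradian12"
    if (n_both) labels[ord[n_circ + n_ultr + seq_len(n_both)]] <- "both"

    genes <- sprintf("G%05d", seq_len(n))
    baseline <- exp(runif(n, log(cfg$baseline_range[1]),
                          log(cfg$baseline_range[2])))
    slope <- runif(n, cfg$trend_rel_slope_range[1],
                   cfg$trend_rel_slope_range[2]) * baseline
    rel12 <- runif(n, cfg$rel_amplitude_range[1], cfg$rel_amplitude_range[2])
    rel24 <- rel12 / cfg$rel_amplitude_ratio_12_vs_24
    phase24 <- runif(n, 0, cfg$period_circadian_h)
    phase12 <- runif(n, 0, cfg$period_ultradian_h)
    decay24 <- runif(n, cfg$decay_range[1], cfg$decay_range[2])
    decay12 <- runif(n, cfg$decay_range[1], cfg$decay_range[2])

    has24 <- labels %in% c("circadian", "both")
    has12 <- labels %in% c("ultradian12", "both")
    truth <- data.frame(
      gene = genes, label = labels, baseline = baseline, slope = slope,
      period24 = ifelse(has24, cfg$period_circadian_h, NA_real_),
      amp24 = ifelse(has24, rel24 * baseline, NA_real_),
      phase24 = ifelse(has24, phase24, NA_real_),
      decay24 = ifelse(has24, decay24, NA_real_),
      period12 = ifelse(has12, cfg$period_ultradian_h, NA_real_),
      amp12 = ifelse(has12, rel12 * baseline, NA_real_),
      phase12 = ifelse(has12, phase12, NA_real_),
      decay12 = ifelse(has12, decay12, NA_real_),
      stringsAsFactors = FALSE)

    nb <- cfg$n_background_genes
    bg_genes <- if (nb) sprintf("BG%03d", seq_len(nb)) else character()
    bg_base <- if (nb) runif(nb, 0.01, 0.2) else numeric()

    offs <- rep_len(cfg$phase_offsets_per_participant, cfg$n_participants)
    # vectorized damped-cosine bank: genes x timepoints contribution of one
    # component class (amplitude 0 where the class is not planted)
    component_bank <- function(amp, Tm, phase, decay, waveform = "cosine") {
      damp <- exp(outer(log(decay), tp / Tm))       # d^(t/T)
      fr <- outer(-phase, tp, "+") / Tm
      wav <- switch(waveform,
                    square = rect_wave(fr),
                    peaked = cos(2 * pi * fr) + 0.25 * cos(4 * pi * fr),
                    cos(2 * pi * fr))
      amp * damp * wav
    }
    matrices <- vector("list", cfg$n_participants)
    for (p in seq_len(cfg$n_participants)) {
      amp24v <- ifelse(has24, rel24 * baseline, 0)
      amp12v <- ifelse(has12, rel12 * baseline, 0)
      sig <- outer(baseline, rep(1, length(tp))) + outer(slope, tp) +
        component_bank(amp24v, cfg$period_circadian_h, phase24 + offs[p],
                       decay24, cfg$waveform_circadian) +
        component_bank(amp12v, cfg$period_ultradian_h, phase12 + offs[p],
                       decay12)
      sig <- rbind(sig, matrix(rep(bg_base, length(tp)), nb, length(tp)))
      dimnames(sig) <- list(c(genes, bg_genes), paste0("t", tp))
      noise_sd <- c(cfg$noise_rel_sd * baseline, 0.05 * pmax(bg_base, 0.02))
      if (cfg$noise_rel_sd > 0 || nb) {
        noise <- matrix(rnorm(length(sig), 0, rep(noise_sd, length(tp))),
                        nrow(sig), ncol(sig))
        if (cfg$noise_rel_sd == 0) noise[seq_len(n), ] <- 0
        sig <- sig + noise
      }
      sig[sig < 0] <- 0
      matrices[[p]] <- expression_matrix(sig, tp,
                                         participant = sprintf("P%d", p))
    }
    bg_truth <- if (nb) data.frame(
      gene = bg_genes, label = "background", baseline = bg_base, slope = 0,
      period24 = NA_real_, amp24 = NA_real_, phase24 = NA_real_,
      decay24 = NA_real_, period12 = NA_real_, amp12 = NA_real_,
      phase12 = NA_real_, decay12 = NA_real_, stringsAsFactors = FALSE)
      else NULL
    list(matrices = matrices, truth = rbind(truth, bg_truth),
         panel = bg_genes, config = cfg)
  })
}

#' Write a simulated cohort to plain-text files
#'
#' Writes one expression TSV per participant (`expr_P<i>.tsv`), the ground
#' truth as JSON (`truth.json`) and the background panel as one id per
#' line (`panel.txt`).
#'
#' @param cohort result of [simulate_expression()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (p in seq_along(cohort$matrices))
    write_expression_tsv(cohort$matrices[[p]],
                         file.path(dir, sprintf("expr_P%d.tsv", p)))
  jsonlite::write_json(cohort$truth, file.path(dir, "truth.json"),
                       dataframe = "rows", na = "null", digits = NA)
  writeLines(cohort$panel, file.path(dir, "panel.txt"))
  invisible(dir)
}
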