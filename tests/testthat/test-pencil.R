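test_that("pencil recovers noiseless tones exactly", {
  tp <- tgrid()
  # single tone after mean removal, relative amplitude vs the raw mean
  y <- 5 + 2 * cos(2 * pi * tp / 12)
  cp <- pencil_decompose(y - mean(y), tp, mean_expression = 5)
  expect_identical(nrow(cp), 1L)
  expect_equal(cp$period, 12, tolerance = 1e-9)
  expect_equal(cp$amplitude, 2, tolerance = 1e-9)
  expect_equal(cp$decay, 1, tolerance = 1e-9)
  expect_equal(cp$acrophase %% 12, 0, tolerance = 1e-7)
  expect_equal(cp$relative_amplitude, 0.4, tolerance = 1e-9)

  # two-tone
  y2 <- 3 * cos(2 * pi * tp / 24) + 1 * cos(2 * pi * tp / 12)
  cp2 <- pencil_decompose(y2, tp, mean_expression = 1)
  expect_equal(cp2$period, c(24, 12), tolerance = 1e-9)
  expect_equal(cp2$amplitude, c(3, 1), tolerance = 1e-9)
  expect_equal(cp2$decay, c(1, 1), tolerance = 1e-9)

  # damped tone
  y3 <- 2 * 0.9^(tp / 12) * cos(2 * pi * tp / 12)
  cp3 <- pencil_decompose(y3, tp, mean_expression = 1)
  expect_equal(cp3$period, 12, tolerance = 1e-9)
  expect_equal(cp3$amplitude, 2, tolerance = 1e-9)
  expect_equal(cp3$decay, 0.9, tolerance = 1e-9)
})

test_that("pencil recovers four damped components and reconstructs the series", {
  tp <- tgrid()
  truth <- data.frame(period = c(24, 12, 8, 16),
                      amplitude = c(1.5, 0.8, 0.5, 0.3),
                      phase = c(5, 3, 1, 7),
                      decay = c(1, 0.95, 1, 1.05))
  y <- damped_signal(tp, components = truth)
  cp <- pencil_decompose(y, tp, mean_expression = 1)
  expect_identical(nrow(cp), 4L)
  o <- match(round(cp$period), truth$period)
  expect_false(anyNA(o))
  expect_equal(cp$period, truth$period[o], tolerance = 1e-6)
  expect_equal(cp$amplitude, truth$amplitude[o], tolerance = 1e-6)
  expect_equal(cp$decay, truth$decay[o], tolerance = 1e-6)
  expect_equal(cp$acrophase, truth$phase[o] %% truth$period[o],
               tolerance = 1e-5)
  # reconstruction
  rec <- damped_signal(tp, components = data.frame(
    period = cp$period, amplitude = cp$amplitude, phase = cp$acrophase,
    decay = cp$decay))
  expect_lt(max(abs(rec - y)), 1e-6)
})

test_that("pencil edge cases behave", {
  tp <- tgrid()
  expect_identical(nrow(pencil_decompose(rep(2, 24), tp)), 0L)
  expect_error(pencil_decompose(1:4, seq(0, 6, 2)[1:4]), "too short")
  # a pure trend has no oscillatory component
  expect_identical(nrow(pencil_decompose(linear_detrend(0.2 * tp, tp), tp)), 0L)
})

test_that("period/decay classification follows the windows", {
  rules <- classification_rules()
  comp <- function(T, d) data.frame(period = T, amplitude = 1, decay = d,
                                    acrophase = 0, relative_amplitude = 0.1)
  expect_identical(classify_components(comp(12, 1.0), rules), "ultradian12")
  expect_identical(classify_components(comp(12, 0.5), rules), "none")
  expect_identical(classify_components(comp(22, 1.0), rules), "circadian")
  expect_identical(classify_components(comp(30, 1.0), rules), "none")
  # participant-specific windows are constructible
  r3 <- classification_rules(windows = list(circadian = c(24, 30),
                                            ultradian12 = c(9.6, 13.6)))
  expect_identical(classify_components(comp(26, 1.1), r3), "circadian")
  expect_error(classification_rules(windows = list(a = c(10, 14),
                                                   b = c(13, 20))), "overlap")
  expect_error(classification_rules(decay_window = c(1.1, 1.3)), "contain 1")
})

test_that("dominant component is the amplitude maximum with period tie-break", {
  cp <- data.frame(period = c(24, 12), amplitude = c(3, 1), decay = 1,
                   acrophase = 0, relative_amplitude = c(0.3, 0.1))
  expect_equal(dominant_component(cp)$period, 24)
  expect_null(dominant_component(cp[0, ]))
  tie <- data.frame(period = c(24, 12), amplitude = c(2, 2), decay = 1,
                    acrophase = 0, relative_amplitude = 0.2)
  expect_equal(dominant_component(tie)$period, 12)
  expect_true(all(dominant_component(cp)$amplitude >= cp$amplitude))
})

test_that("period estimates stay accurate at moderate noise", {
  tp <- tgrid()
  set.seed(99)
  errs <- replicate(500, {
    ph <- runif(1, 0, 12)
    y <- 10 + 3 * cos(2 * pi * (tp - ph) / 12) + rnorm(24, 0, 1.5)
    cp <- pencil_decompose(linear_detrend(y, tp), tp, mean_expression = 10,
                           sv_threshold = 0.05)
    if (!nrow(cp)) return(NA_real_)
    abs(cp$period[which.min(abs(cp$period - 12))] - 12) / 12
  })
  expect_lt(median(errs, na.rm = TRUE), 0.05)
})

test_that("matrix-level decomposition table is coherent", {
  out <- simulate_expression(sim_config(n_genes = 30, frac_ultradian12 = 0.5,
                                        rel_amplitude_range = c(0.5, 0.5),
                                        noise_rel_sd = 0.05,
                                        decay_range = c(0.95, 1.05),
                                        n_background_genes = 0, seed = 8))
  tab <- decompose_matrix(out$matrices[[1]])
  expect_true(all(tab$component_rank >= 1 & tab$component_rank <= 4))
  expect_true(all(tab$dominant == (tab$component_rank == 1L)))
  # planted strong 12h genes carry an ultradian12 label
  true12 <- out$truth$gene[out$truth$label == "ultradian12"]
  lab12 <- unique(tab$gene[tab$label == "ultradian12"])
  expect_gt(mean(true12 %in% lab12), 0.9)
  # counter closure agrees with the table
  n_dom <- pencil_band_counter("ultradian12", dominant_only = TRUE)(out$matrices[[1]])
  tab_dom <- length(unique(tab$gene[tab$dominant & tab$label == "ultradian12"]))
  expect_identical(n_dom, tab_dom)
})
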